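#' Top-loaded ions per component
#'
#' Ranks each component's ions by loading value on the unit-norm loading
#' vector ("most significantly loaded" means largest loading; no
#' statistical test is implied). Ties break by ascending m/z.
#'
#' @param model an `mcr_model`.
#' @param peaklist the matching [peaklist].
#' @param n_top ions per component (default 10); values above the
#'   channel count are truncated with a warning.
#' @return data.frame with columns `component`, `rank`, `label`, `mz`,
#'   `loading`.
#' @export
top_ions <- function(model, peaklist, n_top = 10) {
  stopifnot(inherits(peaklist, "peaklist"))
  nch <- ncol(model$loadings)
  if (nch != length(peaklist))
    stop("model channels (", nch, ") do not match peak list length (",
         length(peaklist), ")")
  if (n_top > nch) {
    warning("n_top = ", n_top, " exceeds ", nch, " channels; truncated")
    n_top <- nch
  }
  out <- lapply(seq_len(model$k), function(j) {
    v <- model$loadings[j, ]
    ord <- order(-v, peaklist$mz)[seq_len(n_top)]
    data.frame(component = j, rank = seq_len(n_top),
               label = peaklist$label[ord], mz = peaklist$mz[ord],
               loading = v[ord], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise over-fit diagnostic
#'
#' Over-fitting shows up as several components describing the same
#' spatially located feature with the same associated secondary ions.
#' For every component pair this computes the cosine between their score
#' columns (spatial similarity) and between their loading rows (spectral
#' similarity); a pair is flagged when both exceed their thresholds.
#'
#' @param model an `mcr_model`.
#' @param matrix the fitted `consolidated_matrix` (unused beyond
#'   dimension checks; kept so callers can pass the fit context).
#' @param score_thresh,loading_thresh flag thresholds (defaults 0.9).
#' @return an `overfit_diagnostic`: data.frame with columns `i`, `j`
#'   (`i < j`), `score_cosine`, `loading_cosine`, `flagged`; attributes
#'   record the thresholds.
#' @export
overfit_check <- function(model, matrix = NULL, score_thresh = 0.9,
                          loading_thresh = 0.9) {
  k <- model$k
  if (!is.null(matrix) && inherits(matrix, "consolidated_matrix") &&
      nrow(model$scores) != nrow(matrix$data))
    stop("model scores do not match matrix pixel count")
  if (k < 2) {
    out <- data.frame(i = integer(0), j = integer(0),
                      score_cosine = numeric(0), loading_cosine = numeric(0),
                      flagged = logical(0))
  } else {
    pairs <- utils::combn(k, 2)
    sc <- cosine_rows(t(model$scores), t(model$scores))
    lc <- cosine_rows(model$loadings, model$loadings)
    out <- data.frame(i = pairs[1, ], j = pairs[2, ],
                      score_cosine = sc[t(pairs)],
                      loading_cosine = lc[t(pairs)])
    out$flagged <- out$score_cosine >= score_thresh &
      out$loading_cosine >= loading_thresh
  }
  structure(out, score_thresh = score_thresh,
            loading_thresh = loading_thresh, class = c("overfit_diagnostic",
                                                       "data.frame"))
}

#' Per-component summary across samples
#'
#' For each component: its top-loaded ions, its mean score in every
#' sample, and a coarse role hint — `ubiquitous` when the per-sample
#' means are uniform (coefficient of variation < 0.5), `flagged-redundant`
#' when the component sits in a flagged over-fit pair, `localized`
#' otherwise. Substrate-like chemistries read as ubiquitous; spot and
#' contamination chemistries as localized.
#'
#' @param model an `mcr_model`.
#' @param matrix the fitted `consolidated_matrix`.
#' @param peaklist the matching [peaklist].
#' @param n_top ions per component in the table.
#' @param diagnostic optional [overfit_check()] result for redundancy
#'   flags.
#' @return list of `component_report`s; each has `component_index`,
#'   `top_ions`, `per_sample_mean_score`, `role_hint`.
#' @export
component_summary <- function(model, matrix, peaklist, n_top = 10,
                              diagnostic = NULL) {
  stopifnot(inherits(matrix, "consolidated_matrix"))
  ions <- top_ions(model, peaklist, n_top)
  ids <- unique(matrix$row_map$sample_id)
  mean_by_sample <- vapply(ids, function(id) {
    colMeans(model$scores[matrix$row_map$sample_id == id, , drop = FALSE])
  }, numeric(model$k))
  mean_by_sample <- matrix(mean_by_sample, nrow = model$k,
                           dimnames = list(NULL, ids))
  flagged_comps <- integer(0)
  if (!is.null(diagnostic) && any(diagnostic$flagged))
    flagged_comps <- unique(unlist(diagnostic[diagnostic$flagged, c("i", "j")]))
  lapply(seq_len(model$k), function(j) {
    m <- mean_by_sample[j, ]
    cv <- if (mean(m) > 0) sd(m) / mean(m) else Inf
    role <- if (j %in% flagged_comps) "flagged-redundant"
            else if (cv < 0.5) "ubiquitous" else "localized"
    structure(list(component_index = j,
                   top_ions = ions[ions$component == j, ],
                   per_sample_mean_score = m,
                   role_hint = role),
              class = "component_report")
  })
}

#' @export
print.component_report <- function(x, ...) {
  cat(sprintf("<component_report> component %d (%s); top ions: %s\n",
              x$component_index, x$role_hint,
              paste(utils::head(x$top_ions$label, 3), collapse = ", ")))
  invisible(x)
}

#' Scan component numbers with over-fit assessment
#'
#' Runs the full consensus pipeline for every component count in
#' `k_range` and assesses each solution for over-fitting. The
#' recommended k is the largest in range with zero flagged pairs, all
#' per-cluster stabilities at or above `stability_thresh` and all
#' per-cluster repeat coverages at or above `coverage_thresh *
#' n_repeats`; the recommendation is advisory and always reported next
#' to the full table so it can be overruled.
#'
#' @inheritParams run_consensus
#' @param k_range integer vector of component counts to scan.
#' @param score_thresh,loading_thresh over-fit flag thresholds.
#' @param stability_thresh minimum per-cluster mean cosine.
#' @param coverage_thresh minimum per-cluster repeat coverage as a
#'   fraction of `n_repeats`.
#' @param keep_results keep the per-k `consensus_result`s (memory)?
#' @return a `component_scan`: list with `summary` (data.frame `k`,
#'   `lof_percent`, `n_flagged`, `n_degenerate` (repeats lost to
#'   component collapse — itself over-fit evidence), `min_stability`,
#'   `min_coverage`, `admissible`), `recommended_k` (`NA` when nothing
#'   is admissible) and, if kept, `results`. A component count whose
#'   repeats collapse entirely is recorded as inadmissible with `NA`
#'   metrics rather than aborting the scan.
#' @export
scan_components <- function(matrix, k_range, n_repeats = 10, master_seed = 1,
                            tol = 1e-6, max_iter = 500,
                            score_thresh = 0.9, loading_thresh = 0.9,
                            stability_thresh = 0.9, coverage_thresh = 0.8,
                            parallel = FALSE, cores = 2L,
                            keep_results = TRUE) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("k_range is empty")
  rows <- list(); results <- list()
  for (k in k_range) {
    res <- tryCatch(
      run_consensus(matrix, k, n_repeats = n_repeats,
                    master_seed = derive_seed(master_seed, k),
                    tol = tol, max_iter = max_iter,
                    parallel = parallel, cores = cores),
      error = function(e) e)
    if (inherits(res, "error")) {
      # a k whose repeats collapse (e.g. far into the over-fit regime)
      # is recorded as inadmissible, not fatal to the scan
      rows[[as.character(k)]] <- data.frame(
        k = k, lof_percent = NA_real_, n_flagged = NA_integer_,
        n_degenerate = n_repeats, min_stability = NA_real_,
        min_coverage = 0, admissible = FALSE)
      next
    }
    diag <- overfit_check(res$final_model, matrix,
                          score_thresh = score_thresh,
                          loading_thresh = loading_thresh)
    n_degen <- n_repeats - length(res$repeat_models) +
      sum(vapply(res$repeat_models, function(m) isTRUE(m$degenerate),
                 logical(1)))
    admissible <- sum(diag$flagged) == 0 &&
      !isTRUE(res$final_model$degenerate) &&
      min(res$stability$mean_cosine) >= stability_thresh &&
      min(res$stability$coverage) >= coverage_thresh * n_repeats
    rows[[as.character(k)]] <- data.frame(
      k = k, lof_percent = res$final_model$lof_percent,
      n_flagged = sum(diag$flagged),
      n_degenerate = n_degen,
      min_stability = min(res$stability$mean_cosine),
      min_coverage = min(res$stability$coverage),
      admissible = admissible)
    if (keep_results) results[[as.character(k)]] <- res
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  adm <- summary$k[summary$admissible]
  structure(list(summary = summary,
                 recommended_k = if (length(adm)) max(adm) else NA_integer_,
                 results = if (keep_results) results else NULL,
                 thresholds = list(score = score_thresh,
                                   loading = loading_thresh,
                                   stability = stability_thresh,
                                   coverage = coverage_thresh)),
            class = "component_scan")
}

#' @export
print.component_scan <- function(x, ...) {
  cat("<component_scan>\n")
  print(x$summary, row.names = FALSE)
  cat("recommended k:", x$recommended_k, "(advisory)\n")
  invisible(x)
}
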