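#' Export score images for one component across all samples
#'
#' Writes one 16-bit grayscale TIFF per sample per component. Scores are
#' min-max scaled per component across ALL samples jointly, so grey
#' levels are comparable between samples and effects such as
#' contamination masking stay visible; a lossless delimited-text copy of
#' the raw scores accompanies the images.
#'
#' @param model an `mcr_model`.
#' @param matrix the fitted `consolidated_matrix`.
#' @param dir output directory.
#' @return character vector of written image paths, invisibly.
#' @export
export_score_images <- function(model, matrix, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  images <- refold_scores(model, matrix)
  paths <- character(0)
  for (j in seq_len(model$k)) {
    vals <- model$scores[, j]
    lo <- min(vals); hi <- max(vals)
    rng <- if (hi > lo) hi - lo else 1
    for (id in names(images)) {
      img <- (images[[id]][, , j] - lo) / rng
      p <- file.path(dir, sprintf("component_%02d_%s.tiff", j, id))
      tiff::writeTIFF(img, p, bits.per.sample = 16L, compression = "none")
      paths <- c(paths, p)
      raw_p <- file.path(dir, sprintf("component_%02d_%s.tsv", j, id))
      write.table(images[[id]][, , j], raw_p, sep = "\t",
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(paths)
}

#' Export loadings as CSV
#'
#' One row per component, columns named by peak labels.
#'
#' @param model an `mcr_model`.
#' @param peaklist the matching [peaklist].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_loadings <- function(model, peaklist, path) {
  stopifnot(inherits(peaklist, "peaklist"))
  df <- as.data.frame(model$loadings)
  names(df) <- peaklist$label
  write.csv(cbind(component = seq_len(model$k), df), path,
            row.names = FALSE)
  invisible(path)
}

#' Render the full report bundle
#'
#' Writes, under `out_dir`: per-component score-image grids
#' (`components/`), `loadings.csv`, `top_ions.csv`, `overfit.json`,
#' optional `scan_summary.csv`, the repeat lack-of-fit table
#' (`repeats.csv`), consensus stability (`stability.csv`), the
#' serialised final model (`model/`) and `run_meta.json` with every
#' seed and setting needed to reproduce the run exactly. Rendering is
#' deterministic: re-rendering from the same serialised model yields
#' byte-identical text outputs.
#'
#' @param consensus_result a [run_consensus()] result.
#' @param matrix the fitted `consolidated_matrix`.
#' @param peaklist the matching [peaklist] (defaults to
#'   `matrix$peaklist`).
#' @param out_dir output directory.
#' @param scan optional [scan_components()] result to include.
#' @param n_top ions per component in the table.
#' @param score_thresh,loading_thresh thresholds for the over-fit
#'   section.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(consensus_result, matrix, peaklist = NULL,
                          out_dir = ".", scan = NULL, n_top = 10,
                          score_thresh = 0.9, loading_thresh = 0.9) {
  stopifnot(inherits(consensus_result, "consensus_result"),
            inherits(matrix, "consolidated_matrix"))
  peaklist <- peaklist %||% matrix$peaklist
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- consensus_result$final_model

  export_score_images(model, matrix, file.path(out_dir, "components"))
  write_loadings(model, peaklist, file.path(out_dir, "loadings.csv"))

  diag <- overfit_check(model, matrix, score_thresh, loading_thresh)
  write.csv(top_ions(model, peaklist, n_top),
            file.path(out_dir, "top_ions.csv"), row.names = FALSE)

  flagged <- diag[diag$flagged, , drop = FALSE]
  jsonlite::write_json(
    list(score_thresh = score_thresh, loading_thresh = loading_thresh,
         n_pairs = nrow(diag),
         flagged_pairs = if (nrow(flagged) == 0) "none" else
           lapply(seq_len(nrow(flagged)), function(r) as.list(flagged[r, ])),
         pairs = lapply(seq_len(nrow(diag)), function(r) as.list(diag[r, ]))),
    file.path(out_dir, "overfit.json"), auto_unbox = TRUE, digits = NA)

  lofs <- data.frame(
    repeat_index = seq_along(consensus_result$repeat_models),
    seed = vapply(consensus_result$repeat_models, function(m) m$seed,
                  integer(1)),
    lof_percent = vapply(consensus_result$repeat_models,
                         function(m) m$lof_percent, numeric(1)),
    n_iter = vapply(consensus_result$repeat_models, function(m) m$n_iter,
                    integer(1)),
    converged = vapply(consensus_result$repeat_models,
                       function(m) m$converged, logical(1)))
  write.csv(lofs, file.path(out_dir, "repeats.csv"), row.names = FALSE)
  write.csv(consensus_result$stability,
            file.path(out_dir, "stability.csv"), row.names = FALSE)
  if (!is.null(scan))
    write.csv(scan$summary, file.path(out_dir, "scan_summary.csv"),
              row.names = FALSE)
  write_model(model, file.path(out_dir, "model"), peaklist = peaklist)

  meta <- list(
    package_version = as.character(utils::packageVersion("mcrsims")),
    k = consensus_result$k,
    n_repeats = consensus_result$n_repeats,
    master_seed = consensus_result$master_seed,
    repeat_seeds = lofs$seed,
    final_seed = model$seed,
    final_lof_percent = model$lof_percent,
    score_thresh = score_thresh, loading_thresh = loading_thresh,
    samples = unique(matrix$row_map$sample_id),
    n_channels = length(peaklist))
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
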