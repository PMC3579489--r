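#' Repeated random-start ALS fits
#'
#' Because the converged ALS solution depends on its random starting
#' point, the analysis is repeated from independent random
#' initialisations (ten by default). Repeat `i` uses a seed derived
#' deterministically from `(master_seed, i)`, so repeats are independent
#' streams that may run concurrently; concurrent and sequential
#' execution give bit-identical model lists.
#'
#' A repeat that fails outright is recorded and skipped as long as at
#' least two repeats succeed.
#'
#' @param matrix a [consolidate()]d matrix (or plain matrix).
#' @param k number of components.
#' @param n_repeats number of random starts (>= 2; default 10).
#' @param master_seed integer master seed.
#' @param als_config optional [als_config()] template; its `k`, `seed`
#'   and `init_loadings` are overridden per repeat.
#' @param parallel run repeats via [parallel::mclapply()]?
#' @param cores worker count when `parallel = TRUE`.
#' @return list of `mcr_model` (length `n_repeats` minus hard failures),
#'   with attribute `"failures"` describing any failed repeats.
#' @export
run_repeats <- function(matrix, k, n_repeats = 10, master_seed = 1,
                        als_config = NULL, parallel = FALSE, cores = 2L) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  template <- als_config %||% mcrsims::als_config(k = k)
  run_one <- function(i) {
    cfg <- mcrsims::als_config(k = k, max_iter = template$max_iter,
                               tol = template$tol,
                               seed = derive_seed(master_seed, i),
                               init_loadings = NULL,
                               update_order = "loadings_first")
    tryCatch(fit_mcr(matrix, cfg),
             error = function(e) structure(list(message = conditionMessage(e),
                                                repeat_index = i),
                                           class = "mcr_failure"))
  }
  results <- if (parallel) {
    parallel::mclapply(seq_len(n_repeats), run_one,
                       mc.cores = cores, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_repeats), run_one)
  }
  ok <- vapply(results, inherits, logical(1), "mcr_model")
  if (sum(ok) < 2)
    stop("fewer than 2 of ", n_repeats, " repeats succeeded; first error: ",
         results[[which(!ok)[1]]]$message)
  models <- results[ok]
  attr(models, "failures") <- results[!ok]
  attr(models, "master_seed") <- master_seed
  models
}

#' k-means consensus of repeat loadings
#'
#' Pools the unit-norm loading vectors of all repeats (`n_repeats * k`
#' vectors) and k-means clusters them into `k` groups; squared Euclidean
#' distance on unit vectors is monotonically related to cosine
#' dissimilarity. Cluster means, re-normalised to unit rows, become the
#' consensus initial loadings for the final ALS round. Per-cluster
#' stability is reported as the mean cosine of members to their cluster
#' mean plus the number of distinct repeats represented (coverage).
#'
#' Repeats flagged degenerate are excluded from the pool; unconverged
#' but non-degenerate repeats still contribute.
#'
#' @param repeat_models list of `mcr_model` sharing `k` and channels.
#' @param k number of clusters (defaults to the models' `k`).
#' @param seed seed for the k-means restarts (10 restarts).
#' @return list with `cluster_assignment` (per pooled vector),
#'   `consensus_loadings` (`k x channels`, unit rows), `stability`
#'   (data.frame `cluster`, `mean_cosine`, `coverage`, `size`) and
#'   `pooled` (the pooled loading matrix with repeat/component index
#'   columns in its attributes).
#' @export
cluster_loadings <- function(repeat_models, k = NULL, seed = 1) {
  stopifnot(length(repeat_models) >= 2)
  ks <- vapply(repeat_models, function(m) m$k, integer(1))
  if (length(unique(ks)) != 1) stop("repeat models disagree on k")
  k <- k %||% ks[1]
  use <- !vapply(repeat_models, function(m) isTRUE(m$degenerate), logical(1))
  models <- repeat_models[use]
  pooled <- do.call(rbind, lapply(models, function(m) m$loadings))
  rep_idx <- rep(seq_along(models), each = ks[1])
  comp_idx <- rep(seq_len(ks[1]), times = length(models))
  norms <- sqrt(rowSums(pooled^2))
  keep <- norms > 0
  pooled <- pooled[keep, , drop = FALSE] / norms[keep]
  rep_idx <- rep_idx[keep]; comp_idx <- comp_idx[keep]
  if (nrow(unique(round(pooled, 12))) < k)
    stop("insufficient diversity: fewer than k = ", k,
         " distinct pooled loading vectors")
  if (nrow(pooled) == k) {
    # one surviving repeat: the trivial partition is the only one
    km <- list(cluster = seq_len(k), centers = pooled)
  } else
  km <- with_seed(seed, {
    fit <- NULL
    for (attempt in 1:10) {
      fit <- tryCatch(kmeans(pooled, centers = k, nstart = 10,
                             iter.max = 100),
                      error = function(e) NULL)
      if (!is.null(fit) && all(tabulate(fit$cluster, k) > 0)) break
      fit <- NULL
    }
    if (is.null(fit)) {
      # random restarts keep drawing duplicated pooled vectors as
      # centres; fall back to deterministic farthest-point seeding
      centres <- farthest_point_centers(pooled, k)
      fit <- tryCatch(kmeans(pooled, centers = centres, iter.max = 100),
                      error = function(e) NULL)
      if (is.null(fit) || any(tabulate(fit$cluster, k) == 0))
        stop("k-means failed to produce ", k,
             " non-empty clusters within the restart budget")
    }
    fit
  })
  centers <- km$centers
  dimnames(centers) <- NULL
  cn <- sqrt(rowSums(centers^2))
  consensus <- centers / cn
  consensus[consensus < 0] <- 0          # guard against -0/rounding
  consensus <- consensus / sqrt(rowSums(consensus^2))
  stability <- data.frame(
    cluster = seq_len(k),
    mean_cosine = vapply(seq_len(k), function(g) {
      members <- pooled[km$cluster == g, , drop = FALSE]
      mean(pmin(1, pmax(0, members %*% consensus[g, ])))
    }, numeric(1)),
    coverage = vapply(seq_len(k), function(g)
      length(unique(rep_idx[km$cluster == g])), numeric(1)),
    size = as.numeric(tabulate(km$cluster, k)))
  list(cluster_assignment = km$cluster,
       consensus_loadings = consensus,
       stability = stability,
       pooled = structure(pooled, repeat_index = rep_idx,
                          component_index = comp_idx))
}

# deterministic farthest-point (maximin) choice of k distinct rows
farthest_point_centers <- function(X, k) {
  n <- nrow(X)
  chosen <- integer(k)
  chosen[1] <- which.max(rowSums(X^2))
  d <- rowSums((X - matrix(X[chosen[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    chosen[j] <- which.max(d)
    d <- pmin(d, rowSums((X - matrix(X[chosen[j], ], n, ncol(X),
                                     byrow = TRUE))^2))
  }
  X[chosen, , drop = FALSE]
}

#' Final ALS round from consensus loadings
#'
#' Runs one ALS fit initialised with the consensus cluster means as
#' loadings and fresh random scores; the first scores update solves the
#' scores from those loadings, so the consensus information seeds the
#' solution.
#'
#' @param matrix a [consolidate()]d matrix.
#' @param consensus_loadings `k x channels` non-negative matrix.
#' @param als_config optional [als_config()] template (for `tol`,
#'   `max_iter`, `seed`, `update_order`).
#' @return an `mcr_model`.
#' @export
consensus_fit <- function(matrix, consensus_loadings, als_config = NULL) {
  consensus_loadings <- as.matrix(consensus_loadings)
  k <- nrow(consensus_loadings)
  template <- als_config %||% mcrsims::als_config(k = k)
  cfg <- mcrsims::als_config(k = k, max_iter = template$max_iter,
                             tol = template$tol, seed = template$seed,
                             init_loadings = consensus_loadings,
                             update_order = template$update_order)
  fit_mcr(matrix, cfg)
}

#' Full consensus MCR pipeline
#'
#' The complete protocol for one component count: `n_repeats`
#' random-start ALS fits, k-means consensus clustering of the pooled
#' loadings, and one final ALS round seeded with the cluster means. The
#' final model is the pipeline's headline result.
#'
#' @inheritParams run_repeats
#' @param tol,max_iter ALS settings applied to every fit.
#' @return a `consensus_result`: list with `repeat_models`,
#'   `cluster_assignment`, `consensus_loadings`, `stability`,
#'   `final_model`, `k`, `master_seed`.
#' @examples
#' truth <- generate_phantom(phantom_spec(n_samples = 2, height = 12,
#'                                        width = 12, n_channels = 12))
#' cm <- consolidate(truth$cubes, truth$peaklist)
#' res <- run_consensus(cm, k = 5, n_repeats = 3, master_seed = 42)
#' res$final_model$lof_percent
#' @export
run_consensus <- function(matrix, k, n_repeats = 10, master_seed = 1,
                          tol = 1e-6, max_iter = 500, parallel = FALSE,
                          cores = 2L) {
  template <- als_config(k = k, tol = tol, max_iter = max_iter,
                         seed = derive_seed(master_seed, 999))
  models <- run_repeats(matrix, k, n_repeats = n_repeats,
                        master_seed = master_seed, als_config = template,
                        parallel = parallel, cores = cores)
  cl <- cluster_loadings(models, k = k,
                         seed = derive_seed(master_seed, 555))
  final <- consensus_fit(matrix, cl$consensus_loadings, template)
  structure(list(repeat_models = models,
                 cluster_assignment = cl$cluster_assignment,
                 consensus_loadings = cl$consensus_loadings,
                 stability = cl$stability,
                 pooled = cl$pooled,
                 final_model = final,
                 k = k, n_repeats = n_repeats,
                 master_seed = master_seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  lofs <- vapply(x$repeat_models, function(m) m$lof_percent, numeric(1))
  cat(sprintf(paste0("<consensus_result> k=%d, %d repeats (lack of fit ",
                     "%.4g-%.4g%%), final %.4g%%\n"),
              x$k, length(x$repeat_models), min(lofs), max(lofs),
              x$final_model$lof_percent))
  invisible(x)
}
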