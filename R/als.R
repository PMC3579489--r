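#' ALS configuration
#'
#' Collects the tunables of one non-negativity-constrained alternating
#' least-squares run.
#'
#' @param k number of components (>= 1).
#' @param max_iter iteration cap (default 500).
#' @param tol convergence threshold on the relative change of the
#'   lack-of-fit between full iterations (default 1e-6).
#' @param seed integer seed for the random initial estimates.
#' @param init_loadings optional `k x channels` non-negative matrix used
#'   as the initial loadings (e.g. consensus cluster means); rows are
#'   normalised to unit norm on input.
#' @param update_order `"auto"` (scores first when `init_loadings` is
#'   given — the supplied loadings carry the information and the random
#'   scores are immediately replaced — otherwise loadings first),
#'   `"scores_first"` or `"loadings_first"`.
#' @return an `als_config` object.
#' @export
als_config <- function(k, max_iter = 500, tol = 1e-6, seed = 1,
                       init_loadings = NULL,
                       update_order = c("auto", "scores_first",
                                        "loadings_first")) {
  update_order <- match.arg(update_order)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  if (!is.null(init_loadings)) {
    init_loadings <- as.matrix(init_loadings)
    if (nrow(init_loadings) != k)
      stop("init_loadings must have k = ", k, " rows")
    if (any(init_loadings < 0))
      stop("init_loadings must be non-negative")
  }
  structure(list(k = k, max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), init_loadings = init_loadings,
                 update_order = update_order),
            class = "als_config")
}

#' Random initial scores and loadings
#'
#' Draws strictly positive uniform entries for both factors and
#' normalises loading rows to unit Euclidean norm; fully reproducible
#' from the seed.
#'
#' @param k components; `channels` and `total_pixels` the factor
#'   dimensions.
#' @param channels number of spectral channels.
#' @param total_pixels number of pixels (rows of the data matrix).
#' @param seed integer seed.
#' @return list with `scores` (`total_pixels x k`) and `loadings`
#'   (`k x channels`).
#' @export
random_init <- function(k, channels, total_pixels, seed) {
  if (k < 1 || channels < 1 || total_pixels < 1)
    stop("all dimensions must be >= 1")
  with_seed(seed, {
    scores <- matrix(runif(total_pixels * k, min = 0.05, max = 1),
                     total_pixels, k)
    loadings <- matrix(runif(k * channels, min = 0.05, max = 1), k, channels)
    loadings <- loadings / sqrt(rowSums(loadings^2))
    list(scores = scores, loadings = loadings)
  })
}

#' Non-negative least-squares update of the scores
#'
#' Given fixed loadings `S` (`k x channels`), returns the score matrix
#' `C` minimising `||D - C S||_F` subject to `C >= 0`; each pixel row is
#' an independent NNLS problem solved exactly (active-set on the Gram
#' matrix), not by clipping an unconstrained solution.
#'
#' @param data pixels x channels matrix `D`.
#' @param loadings `k x channels` matrix.
#' @return pixels x k non-negative score matrix.
#' @export
update_scores <- function(data, loadings) {
  data <- as.matrix(data); loadings <- as.matrix(loadings)
  if (ncol(data) != ncol(loadings))
    stop("data and loadings disagree on channel count")
  G <- tcrossprod(loadings)              # k x k
  FtB <- data %*% t(loadings)            # pixels x k
  nnls_gram(G, FtB)
}

#' Non-negative least-squares update of the loadings
#'
#' Given fixed scores `C`, returns loadings `S` minimising
#' `||D - C S||_F` subject to `S >= 0`; each channel column of `D` is an
#' independent NNLS problem. With `normalize = TRUE` rows are rescaled
#' to unit Euclidean norm and the row norms are returned in the
#' `"scales"` attribute so the caller can push the scale into the
#' scores, resolving the bilinear scale ambiguity.
#'
#' @param data pixels x channels matrix `D`.
#' @param scores pixels x k matrix.
#' @param normalize rescale rows to unit norm (default `TRUE`).
#' @return `k x channels` non-negative matrix; if normalised, with a
#'   `"scales"` attribute of the pre-normalisation row norms.
#' @export
update_loadings <- function(data, scores, normalize = TRUE) {
  data <- as.matrix(data); scores <- as.matrix(scores)
  if (nrow(data) != nrow(scores))
    stop("data and scores disagree on pixel count")
  G <- crossprod(scores)                 # k x k
  FtB <- crossprod(data, scores)         # channels x k
  S <- t(nnls_gram(G, FtB))              # k x channels
  if (normalize) {
    scales <- sqrt(rowSums(S^2))
    nz <- scales > 0
    S[nz, ] <- S[nz, , drop = FALSE] / scales[nz]
    attr(S, "scales") <- scales
  }
  S
}

#' Lack of fit of a bilinear model
#'
#' The standard MCR fit statistic:
#' `100 * ||D - C S||_F / ||D||_F` (percent).
#'
#' @param matrix a `consolidated_matrix` or plain data matrix `D`.
#' @param model a fitted model (anything with `scores` and `loadings`).
#' @return lack of fit in percent.
#' @export
lack_of_fit <- function(matrix, model) {
  D <- if (inherits(matrix, "consolidated_matrix")) matrix$data else as.matrix(matrix)
  dn <- sqrt(sum(D^2))
  if (dn == 0) stop("data matrix has zero norm; lack of fit is undefined")
  R <- D - model$scores %*% model$loadings
  100 * sqrt(sum(R^2)) / dn
}

# reinitialize dead components from the residual's dominant direction
reseed_component <- function(D, scores, loadings, dead_rows) {
  R <- D - scores %*% loadings
  cp <- crossprod(R)
  v <- eigen(cp, symmetric = TRUE)$vectors[, 1]
  v <- if (sum(pmax(v, 0)^2) >= sum(pmax(-v, 0)^2)) pmax(v, 0) else pmax(-v, 0)
  nv <- sqrt(sum(v^2))
  v <- if (nv > 0) v / nv else rep(1 / sqrt(ncol(D)), ncol(D))
  for (j in dead_rows) loadings[j, ] <- v
  loadings
}

#' Fit one non-negativity-constrained ALS-MCR model
#'
#' Decomposes the consolidated matrix `D` (pixels x channels) as
#' `D = C S + E` with `C >= 0` (concentration scores) and `S >= 0`
#' (pure-component spectra, unit-norm rows), alternating exact NNLS
#' updates of each factor until the relative change in lack of fit drops
#' below `tol` or `max_iter` is reached. Because each half-step solves
#' its constrained subproblem exactly, the lack of fit is non-increasing
#' across full iterations.
#'
#' A component whose loading row or score column collapses to zero is
#' re-initialised once from the dominant non-negative direction of the
#' residual; if it collapses again the fit returns with
#' `converged = FALSE` and `degenerate = TRUE`.
#'
#' @param matrix a [consolidate()]d matrix or plain non-negative matrix.
#' @param config an [als_config()].
#' @return an `mcr_model`: list with `k`, `scores`, `loadings`
#'   (unit-norm rows), `lof_percent`, `lof_trace` (per full iteration),
#'   `n_iter`, `converged`, `degenerate`, `seed`.
#' @examples
#' D <- matrix(runif(60), 20, 3) %*% matrix(runif(9), 3, 3)
#' m <- fit_mcr(D, als_config(k = 3, seed = 7))
#' m$lof_percent
#' @export
fit_mcr <- function(matrix, config) {
  stopifnot(inherits(config, "als_config"))
  D <- if (inherits(matrix, "consolidated_matrix")) matrix$data else as.matrix(matrix)
  if (any(!is.finite(D))) stop("data contains non-finite values")
  if (config$k > min(dim(D)))
    stop("k = ", config$k, " exceeds min(total_pixels, channels) = ",
         min(dim(D)))
  dn <- sqrt(sum(D^2))
  if (dn == 0) stop("data matrix has zero norm")

  init <- random_init(config$k, ncol(D), nrow(D), config$seed)
  scores <- init$scores
  loadings <- if (!is.null(config$init_loadings)) {
    L <- config$init_loadings
    n <- sqrt(rowSums(L^2))
    if (any(n == 0)) stop("init_loadings contains an all-zero row")
    L / n
  } else init$loadings
  order_sf <- switch(config$update_order,
                     scores_first = TRUE,
                     loadings_first = FALSE,
                     auto = !is.null(config$init_loadings))

  lof_trace <- numeric(0)
  lof_prev <- Inf
  converged <- FALSE
  degenerate <- FALSE
  reseeded <- FALSE
  n_iter <- 0L

  for (it in seq_len(config$max_iter)) {
    n_iter <- it
    # inlined half-steps (exact NNLS on the Gram system, as in
    # update_scores / update_loadings) avoiding redundant transposes
    if (order_sf) {
      scores <- nnls_gram(tcrossprod(loadings), tcrossprod(D, loadings))
      loadings <- t(nnls_gram(crossprod(scores), crossprod(D, scores)))
      scales <- sqrt(rowSums(loadings^2))
      nz <- scales > 0
      loadings[nz, ] <- loadings[nz, , drop = FALSE] / scales[nz]
      scores <- sweep(scores, 2, scales, "*")
    } else {
      loadings <- t(nnls_gram(crossprod(scores), crossprod(D, scores)))
      scales <- sqrt(rowSums(loadings^2))
      nz <- scales > 0
      loadings[nz, ] <- loadings[nz, , drop = FALSE] / scales[nz]
      scores <- nnls_gram(tcrossprod(loadings), tcrossprod(D, loadings))
    }
    dead <- which(rowSums(loadings) == 0 | colSums(scores) == 0)
    if (length(dead) > 0) {
      if (!reseeded) {
        loadings <- reseed_component(D, scores, loadings, dead)
        scores <- update_scores(D, loadings)
        reseeded <- TRUE
        # reseeding may raise the objective; the recorded trace covers the
        # monotone post-reseed phase only
        lof_prev <- Inf
        lof_trace <- numeric(0)
      } else {
        degenerate <- TRUE
        break
      }
    }
    lof <- 100 * sqrt(resid_ss(D, scores, loadings)) / dn
    lof_trace <- c(lof_trace, lof)
    # converged when the relative change in lack of fit falls below tol,
    # or at an essentially exact fit (noiseless data never satisfies the
    # relative test: the residual keeps shrinking proportionally)
    if (lof < 1e-8 ||
        (is.finite(lof_prev) &&
         abs(lof_prev - lof) < config$tol * max(lof_prev,
                                                .Machine$double.eps))) {
      converged <- TRUE
      lof_prev <- lof
      break
    }
    lof_prev <- lof
  }
  lof_final <- if (length(lof_trace)) lof_trace[length(lof_trace)] else
    lack_of_fit(D, list(scores = scores, loadings = loadings))
  structure(list(k = config$k, scores = scores, loadings = loadings,
                 lof_percent = lof_final, lof_trace = lof_trace,
                 n_iter = n_iter, converged = converged,
                 degenerate = degenerate, seed = config$seed),
            class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf(paste0("<mcr_model> k=%d, lack of fit %.4g%%, %d iterations",
                     " (%s%s), seed=%d\n"),
              x$k, x$lof_percent, x$n_iter,
              if (x$converged) "converged" else "not converged",
              if (x$degenerate) ", degenerate" else "", x$seed))
  invisible(x)
}

#' Serialise / load a fitted model
#'
#' Loadings go to CSV (components x labelled channels), scores to a
#' delimited text matrix, metadata (k, seed, iterations, lack of fit,
#' convergence) to JSON.
#'
#' @param model an `mcr_model`.
#' @param dir output directory.
#' @param peaklist optional [peaklist] for labelled loading columns.
#' @return `dir` invisibly (`write_model`); an `mcr_model`
#'   (`read_model`).
#' @export
write_model <- function(model, dir, peaklist = NULL) {
  stopifnot(inherits(model, "mcr_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  L <- as.data.frame(model$loadings)
  names(L) <- if (!is.null(peaklist)) peaklist$label else
    paste0("ch", seq_len(ncol(model$loadings)))
  write.csv(cbind(component = seq_len(model$k), L),
            file.path(dir, "loadings.csv"), row.names = FALSE)
  write.table(model$scores, file.path(dir, "scores.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  meta <- list(k = model$k, seed = model$seed, n_iter = model$n_iter,
               lof_percent = model$lof_percent, converged = model$converged,
               degenerate = model$degenerate, lof_trace = model$lof_trace)
  jsonlite::write_json(meta, file.path(dir, "model_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model_meta.json"),
                              simplifyVector = TRUE)
  L <- read.csv(file.path(dir, "loadings.csv"), check.names = FALSE)
  loadings <- as.matrix(L[, -1, drop = FALSE])
  scores <- as.matrix(read.table(file.path(dir, "scores.tsv"), sep = "\t"))
  dimnames(scores) <- NULL
  structure(list(k = meta$k, scores = scores, loadings = loadings,
                 lof_percent = meta$lof_percent,
                 lof_trace = meta$lof_trace %||% numeric(0),
                 n_iter = meta$n_iter, converged = meta$converged,
                 degenerate = meta$degenerate %||% FALSE, seed = meta$seed),
            class = "mcr_model")
}
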