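#' PCA scree evaluation of a consolidated matrix
#'
#' Computes the eigenvalue spectrum of the data covariance and an
#' advisory component-count range for the curve resolution. PCA is used
#' purely as a precursor diagnostic: the scree curve rarely pins down a
#' single component number for ToF-SIMS image data, so the result is a
#' range bracketing the elbow, never an automatic choice.
#'
#' By default no pre-treatment is applied, i.e. the eigendecomposition is
#' of the uncentred cross-product; column mean-centring is available as
#' an explicit flag. The decomposition runs on the channels x channels
#' cross-product, which is cheap because channels are few relative to
#' pixels.
#'
#' The advisory range comes from a fixed elbow heuristic: the elbow index
#' is the smallest i with eigenvalue ratio `lambda_i / lambda_{i+1} <
#' 1.5` (where the plateau of near-equal eigenvalues begins; eigenvalues
#' below `1e-10 * lambda_1` count as a plateau), and the suggested range
#' is `(elbow - 2, elbow + 3)` clipped to `[1, channels]`.
#'
#' @param matrix a [consolidate()]d matrix, or a plain numeric matrix.
#' @param centred column mean-centre before the decomposition?
#' @return a `scree_result`: list with `eigenvalues` (descending,
#'   `>= 0`), `variance_fraction` (normalised to sum 1),
#'   `suggested_range` (`c(low, high)`) and `centred`.
#' @export
pca_scree <- function(matrix, centred = FALSE) {
  D <- if (inherits(matrix, "consolidated_matrix")) matrix$data else as.matrix(matrix)
  if (length(D) == 0 || nrow(D) < 1) stop("matrix is empty")
  if (ncol(D) > 1e6) stop("more than 1e6 channels is not supported")
  n <- nrow(D)
  if (centred) D <- sweep(D, 2, colMeans(D))
  cp <- crossprod(D) / max(1, n - 1)
  ev <- eigen(cp, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  total <- sum(ev)
  if (total <= .Machine$double.eps * nrow(cp))
    stop("zero-variance matrix: scree is undefined",
         if (centred) " (all rows identical after centring)" else "")
  vf <- ev / total
  elbow <- scree_elbow(ev)
  low <- max(1L, elbow - 2L)
  high <- min(length(ev), elbow + 3L)
  structure(list(eigenvalues = ev, variance_fraction = vf,
                 suggested_range = c(low, high), centred = centred),
            class = "scree_result")
}

scree_elbow <- function(ev) {
  p <- length(ev)
  if (p == 1) return(1L)
  floor_v <- 1e-10 * ev[1]
  ratios <- vapply(seq_len(p - 1), function(i) {
    a <- ev[i]; b <- ev[i + 1]
    if (a <= floor_v && b <= floor_v) return(1)      # numerical-zero plateau
    if (b <= floor_v) return(Inf)                    # cliff into the null space
    a / b
  }, numeric(1))
  hit <- which(ratios < 1.5)
  if (length(hit) == 0) p else as.integer(hit[1])
}

#' @export
print.scree_result <- function(x, ...) {
  cat(sprintf("<scree_result> %d eigenvalues (%scentred), suggested components: %d-%d\n",
              length(x$eigenvalues), if (x$centred) "" else "un",
              x$suggested_range[1], x$suggested_range[2]))
  invisible(x)
}

#' Plot a scree curve
#'
#' Log-scale eigenvalue-versus-index plot with the suggested component
#' range shaded and annotated. Output is deterministic for a fixed input
#' (no timestamps are embedded).
#'
#' @param result a [pca_scree()] result.
#' @param path output image path; `.png` or `.svg` by extension.
#' @param max_index largest component index to draw (default all).
#' @return `path`, invisibly.
#' @export
plot_scree <- function(result, path, max_index = NULL) {
  stopifnot(inherits(result, "scree_result"))
  ev <- result$eigenvalues
  n <- min(max_index %||% length(ev), length(ev))
  ev <- ev[seq_len(n)]
  floor_v <- max(ev) * 1e-16
  ext <- tolower(tools::file_ext(path))
  opened <- FALSE
  if (ext == "svg") {
    grDevices::svg(path, width = 7, height = 5)
    opened <- TRUE
  } else {
    grDevices::png(path, width = 700, height = 500, type = "cairo")
    opened <- TRUE
  }
  ok <- try({
    rng <- result$suggested_range
    plot(seq_len(n), pmax(ev, floor_v), log = "y", type = "b", pch = 16,
         xlab = "Component index", ylab = "Eigenvalue (log scale)",
         main = "PCA scree")
    usr <- graphics::par("usr")
    graphics::rect(rng[1] - 0.5, 10^usr[3], rng[2] + 0.5, 10^usr[4],
                   col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
    graphics::points(seq_len(n), pmax(ev, floor_v), type = "b", pch = 16)
    graphics::legend("topright",
                     legend = sprintf("suggested range: %d-%d", rng[1], rng[2]),
                     fill = grDevices::adjustcolor("steelblue", 0.15),
                     bty = "n")
  }, silent = TRUE)
  if (opened) grDevices::dev.off()
  if (inherits(ok, "try-error"))
    stop("failed to render scree plot to ", path, ": ",
         attr(ok, "condition")$message)
  invisible(path)
}

#' Export scree values as CSV
#'
#' Columns `index,eigenvalue,variance_fraction`.
#'
#' @param result a [pca_scree()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scree <- function(result, path) {
  stopifnot(inherits(result, "scree_result"))
  df <- data.frame(index = seq_along(result$eigenvalues),
                   eigenvalue = result$eigenvalues,
                   variance_fraction = result$variance_fraction)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
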