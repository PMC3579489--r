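#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded analysis steps do not perturb user
#' simulations.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Per-repeat and per-sample random streams are seeded independently so
#' repeats can run concurrently yet reproduce the sequential results.
#' The derivation is a fixed affine map modulo a Mersenne prime, keeping
#' every sub-seed a valid 32-bit integer.
#'
#' @param master integer master seed.
#' @param index 1-based stream index.
#' @return integer sub-seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (abs(as.double(master)) %% m) + 1
  v <- (s * 48271 + as.double(index) * 1000003) %% m
  as.integer(max(1, v))
}

#' Cosine similarity between two vectors
#' @keywords internal
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Cosine similarity matrix between rows of two matrices
#' @keywords internal
cosine_rows <- function(A, B) {
  An <- A / pmax(sqrt(rowSums(A^2)), .Machine$double.eps)
  Bn <- B / pmax(sqrt(rowSums(B^2)), .Machine$double.eps)
  tcrossprod(An, Bn)
}

#' Match estimated components to reference components
#'
#' Bilinear models are identified only up to permutation of components;
#' comparisons against ground truth or between repeats must first align
#' components. Rows of `est` are matched one-to-one to rows of `ref` to
#' maximise total cosine similarity (exhaustive for k <= 7, greedy
#' otherwise).
#'
#' @param est,ref matrices with the same number of rows (components).
#' @return list with `perm` (est row matched to each ref row) and
#'   `cosines` (per-reference-component cosine under the matching).
#' @export
match_components <- function(est, ref) {
  stopifnot(nrow(est) == nrow(ref), ncol(est) == ncol(ref))
  k <- nrow(ref)
  S <- cosine_rows(ref, est)  # S[i, j] = cos(ref_i, est_j)
  if (k <= 7) {
    perms <- all_permutations(k)
    best <- NULL; best_val <- -Inf
    for (p in seq_len(nrow(perms))) {
      val <- sum(S[cbind(seq_len(k), perms[p, ])])
      if (val > best_val) { best_val <- val; best <- perms[p, ] }
    }
    perm <- best
  } else {
    perm <- integer(k); used <- rep(FALSE, k)
    ord <- order(apply(S, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(used, -Inf, S[i, ]))
      perm[i] <- j; used[j] <- TRUE
    }
  }
  list(perm = perm, cosines = S[cbind(seq_len(k), perm)])
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
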