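test_that("repeats are deterministic and pool n_repeats x k loadings", {
  cm <- tiny_matrix(n_samples = 2, height = 10, width = 10,
                    noise = "poisson")
  m1 <- run_repeats(cm, k = 3, n_repeats = 4, master_seed = 11)
  m2 <- run_repeats(cm, k = 3, n_repeats = 4, master_seed = 11)
  expect_identical(lapply(m1, `[[`, "loadings"),
                   lapply(m2, `[[`, "loadings"))
  expect_length(m1, 4)
  cl <- cluster_loadings(m1, seed = 1)
  expect_length(cl$cluster_assignment, 4 * 3)
  expect_error(run_repeats(cm, k = 3, n_repeats = 1), ">= 2")
})

test_that("concurrent and sequential repeats give identical models", {
  cm <- tiny_matrix(n_samples = 2, height = 8, width = 8)
  seq_m <- run_repeats(cm, k = 3, n_repeats = 4, master_seed = 5,
                       parallel = FALSE)
  par_m <- run_repeats(cm, k = 3, n_repeats = 4, master_seed = 5,
                       parallel = TRUE, cores = 2)
  for (i in seq_along(seq_m)) {
    expect_identical(seq_m[[i]]$loadings, par_m[[i]]$loadings)
    expect_identical(seq_m[[i]]$scores, par_m[[i]]$scores)
    expect_identical(seq_m[[i]]$lof_trace, par_m[[i]]$lof_trace)
  }
})

test_that("clustering permutation-equivalent repeats is perfect", {
  # identical loadings, shuffled component order per repeat
  set.seed(13)
  base <- matrix(rexp(4 * 10), 4, 10)
  base <- base / sqrt(rowSums(base^2))
  models <- lapply(1:5, function(i) {
    perm <- sample(4)
    structure(list(k = 4L, loadings = base[perm, ],
                   scores = matrix(1, 2, 4), degenerate = FALSE,
                   lof_percent = 1, n_iter = 1L, converged = TRUE,
                   seed = i), class = "mcr_model")
  })
  cl <- cluster_loadings(models, seed = 2)
  expect_equal(sort(cl$stability$size), rep(5, 4))
  expect_equal(cl$stability$coverage, rep(5, 4))
  expect_true(all(cl$stability$mean_cosine >= 1 - 1e-10))
  # consensus rows equal the base spectra up to permutation
  m <- match_components(cl$consensus_loadings, base)
  expect_true(all(m$cosines >= 1 - 1e-10))
})

test_that("well-separated loading families cluster by family", {
  # two families: disjoint support -> cosine 0 between, ~1 within
  set.seed(17)
  fam1 <- c(rep(1, 5), rep(0, 5)); fam2 <- c(rep(0, 5), rep(1, 5))
  jitter_unit <- function(v) {
    x <- pmax(v + rnorm(10, sd = 0.02) * (v > 0), 0)
    x / sqrt(sum(x^2))
  }
  models <- lapply(1:6, function(i)
    structure(list(k = 2L,
                   loadings = rbind(jitter_unit(fam1), jitter_unit(fam2)),
                   degenerate = FALSE, lof_percent = 1, n_iter = 1L,
                   converged = TRUE, seed = i,
                   scores = matrix(1, 2, 2)), class = "mcr_model"))
  cl <- cluster_loadings(models, seed = 3)
  pooled <- cl$pooled
  # brute-force nearest-centroid oracle over both possible labellings
  truth_fam <- apply(pooled, 1, function(v) which.max(c(sum(v[1:5]),
                                                        sum(v[6:10]))))
  agreement <- max(mean(cl$cluster_assignment == truth_fam),
                   mean(cl$cluster_assignment == 3 - truth_fam))
  expect_equal(agreement, 1)
  expect_error(cluster_loadings(models, k = 30, seed = 1),
               "insufficient diversity")
})

test_that("consensus seeding is a fixed point at an exact solution", {
  truth <- tiny_truth(n_samples = 2, height = 10, width = 10,
                      n_channels = 14, n_spots = 2)
  cm <- consolidate(truth$cubes, truth$peaklist)
  final <- consensus_fit(cm, truth$true_loadings, als_config(k = 3, seed = 9))
  expect_lt(final$lof_percent, 1e-6)
  m <- match_components(final$loadings, truth$true_loadings)
  expect_true(all(m$cosines >= 1 - 1e-6))
})

test_that("the full pipeline is reproducible and beats its repeats", {
  cm <- tiny_matrix(n_samples = 2, height = 10, width = 10, n_spots = 2,
                    n_channels = 14)
  r1 <- run_consensus(cm, k = 3, n_repeats = 4, master_seed = 33)
  r2 <- run_consensus(cm, k = 3, n_repeats = 4, master_seed = 33)
  expect_identical(r1$final_model$loadings, r2$final_model$loadings)
  expect_identical(r1$consensus_loadings, r2$consensus_loadings)
  lofs <- vapply(r1$repeat_models, function(m) m$lof_percent, numeric(1))
  expect_lte(r1$final_model$lof_percent, min(lofs) + 1e-6)
  expect_lte(r1$final_model$lof_percent, median(lofs))
  expect_true(all(r1$stability$mean_cosine >= 0 &
                    r1$stability$mean_cosine <= 1))
  expect_equal(sqrt(rowSums(r1$consensus_loadings^2)), rep(1, 3),
               tolerance = 1e-12)
})
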