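test_that("random initialisation is seeded, positive and unit-norm", {
  a <- random_init(3, 20, 50, seed = 4)
  b <- random_init(3, 20, 50, seed = 4)
  expect_identical(a, b)
  c <- random_init(3, 20, 50, seed = 5)
  expect_false(identical(a$scores, c$scores))
  expect_true(all(a$scores > 0) && all(a$loadings > 0))
  expect_equal(sqrt(rowSums(a$loadings^2)), rep(1, 3), tolerance = 1e-12)
  expect_error(random_init(0, 5, 5, 1), ">= 1")
})

test_that("half-step updates solve their constrained subproblems", {
  set.seed(31)
  # rank-1 exact case: given the true spectrum, scores are recovered
  s <- c(0.6, 0.8, 0)
  c_true <- runif(40, 0, 5)
  D <- c_true %*% t(s)
  expect_equal(update_scores(D, matrix(s, 1))[, 1], c_true,
               tolerance = 1e-8)
  # and the transposed problem recovers the spectrum
  L <- update_loadings(D, matrix(c_true, ncol = 1), normalize = TRUE)
  expect_equal(L[1, ], s, tolerance = 1e-8)
  expect_equal(attr(L, "scales"), sqrt(sum(s^2)), tolerance = 1e-8)
  # interior case: constrained update equals unconstrained least squares
  S0 <- matrix(runif(2 * 6, 0.2, 1), 2, 6)
  C0 <- matrix(runif(30 * 2, 0.5, 2), 30, 2)
  D2 <- C0 %*% S0
  expect_equal(update_scores(D2, S0), C0, tolerance = 1e-7)
  expect_equal(unclass(update_loadings(D2, C0, normalize = FALSE)), S0,
               tolerance = 1e-7)
})

test_that("lack_of_fit matches its definition on edge and random cases", {
  set.seed(8)
  D <- matrix(runif(12 * 5, 0.1, 2), 12, 5)
  C <- matrix(runif(12 * 2), 12, 2)
  S <- matrix(runif(2 * 5), 2, 5)
  # naive elementwise oracle
  resid <- 0; denom <- 0
  for (i in 1:12) for (j in 1:5) {
    fit_ij <- sum(C[i, ] * S[, j])
    resid <- resid + (D[i, j] - fit_ij)^2
    denom <- denom + D[i, j]^2
  }
  expect_equal(lack_of_fit(D, list(scores = C, loadings = S)),
               100 * sqrt(resid / denom), tolerance = 1e-10)
  expect_equal(lack_of_fit(D, list(scores = D, loadings = diag(5))), 0)
  expect_equal(lack_of_fit(D, list(scores = C * 0, loadings = S)), 100)
  expect_error(lack_of_fit(D * 0, list(scores = C, loadings = S)),
               "zero norm")
})

test_that("ALS recovers noiseless low-rank factorisations", {
  truth <- tiny_truth(n_samples = 2, height = 12, width = 12,
                      n_channels = 14, n_spots = 1)  # k = 2
  cm <- consolidate(truth$cubes, truth$peaklist)
  model <- fit_mcr(cm, als_config(k = 2, seed = 1))
  expect_lt(model$lof_percent, 0.1)
  m <- match_components(model$loadings, truth$true_loadings)
  expect_true(all(m$cosines >= 0.99))
  # k = 1 on a rank-1 matrix is exact
  set.seed(2)
  D1 <- runif(60, 0.5, 2) %*% t(runif(7))
  m1 <- fit_mcr(D1, als_config(k = 1, seed = 3))
  expect_lt(m1$lof_percent, 1e-4)
})

test_that("lack of fit never increases across ALS iterations", {
  for (seed in 1:4) {
    truth <- tiny_truth(n_samples = 2, height = 10, width = 10,
                        n_channels = 12, noise = "poisson", seed = seed)
    cm <- consolidate(truth$cubes, truth$peaklist)
    model <- fit_mcr(cm, als_config(k = 3, seed = seed))
    expect_true(all(diff(model$lof_trace) <= 1e-10))
    expect_true(all(model$scores >= 0))
    expect_true(all(model$loadings >= 0))
    nrm <- sqrt(rowSums(model$loadings^2))
    expect_true(all(abs(nrm - 1) < 1e-9 | nrm == 0))
  }
})

test_that("fit_mcr validates its inputs", {
  D <- matrix(runif(20), 5, 4)
  expect_error(fit_mcr(D, als_config(k = 5)), "exceeds")
  D[2, 2] <- Inf
  expect_error(fit_mcr(D, als_config(k = 2)), "non-finite")
  expect_error(als_config(k = 2, tol = 0), "tol")
  expect_error(als_config(k = 2, init_loadings = matrix(1, 3, 4)), "rows")
})

test_that("models serialise and reload faithfully", {
  truth <- tiny_truth(n_samples = 2, height = 8, width = 8)
  cm <- consolidate(truth$cubes, truth$peaklist)
  model <- fit_mcr(cm, als_config(k = 3, seed = 6))
  dir <- withr::local_tempdir()
  write_model(model, dir, peaklist = truth$peaklist)
  back <- read_model(dir)
  expect_equal(back$loadings, model$loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$scores, model$scores, tolerance = 1e-12)
  expect_equal(back$lof_percent, model$lof_percent)
  expect_equal(back$seed, model$seed)
})
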