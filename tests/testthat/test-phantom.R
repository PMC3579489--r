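test_that("noiseless phantoms are exactly bilinear with matching rank", {
  truth <- tiny_truth(n_samples = 2, height = 12, width = 12,
                      n_channels = 14, n_spots = 2, contam = TRUE)
  k <- nrow(truth$true_loadings)
  expect_equal(k, 4)
  for (s in seq_along(truth$cubes)) {
    arr <- truth$true_scores[[s]]
    smat <- matrix(aperm(arr, c(2, 1, 3)), ncol = k)
    expect_equal(unfold_cube(truth$cubes[[s]]),
                 smat %*% truth$true_loadings)
  }
  cm <- consolidate(truth$cubes, truth$peaklist)
  sv <- svd(cm$data, nu = 0, nv = 0)$d
  expect_lt(sv[k + 1], 1e-8 * sv[1])
  expect_gt(sv[k], 1e-6 * sv[1])
})

test_that("ground-truth factors are non-negative with unit-norm spectra", {
  truth <- study_truth()
  expect_true(all(truth$true_loadings >= 0))
  expect_equal(unname(sqrt(rowSums(truth$true_loadings^2))),
               rep(1, nrow(truth$true_loadings)))
  expect_true(all(vapply(truth$true_scores, function(a) all(a >= 0),
                         logical(1))))
  # pure spectra pairwise distinct
  cs <- mcrsims:::cosine_rows(truth$true_loadings, truth$true_loadings)
  expect_lt(max(cs[upper.tri(cs)]), 0.95)
})

test_that("generation is reproducible from the master seed", {
  t1 <- tiny_truth(noise = "poisson", seed = 9)
  t2 <- tiny_truth(noise = "poisson", seed = 9)
  expect_identical(t1$cubes[[1]]$intensities, t2$cubes[[1]]$intensities)
  expect_identical(t1$true_loadings, t2$true_loadings)
  t3 <- tiny_truth(noise = "poisson", seed = 10)
  expect_false(identical(t1$cubes[[1]]$intensities,
                         t3$cubes[[1]]$intensities))
})

test_that("poisson noise has variance approximately equal to the mean", {
  # pool many pixels of similar noiseless intensity and compare moments
  truth <- tiny_truth(n_samples = 2, height = 64, width = 64,
                      n_channels = 12, noise = "poisson", seed = 3)
  clean <- generate_phantom(tiny_spec(n_samples = 2, height = 64,
                                      width = 64, n_channels = 12,
                                      noise = "none", seed = 3))
  noisy <- do.call(rbind, lapply(truth$cubes, unfold_cube))
  mu <- do.call(rbind, lapply(clean$cubes, unfold_cube))
  bins <- cut(mu, breaks = c(10, 20, 40, 80, 160))
  for (b in levels(bins)) {
    sel <- !is.na(bins) & bins == b
    if (sum(sel) < 1e4) next
    resid_var <- mean((noisy[sel] - mu[sel])^2)
    expect_equal(resid_var, mean(mu[sel]), tolerance = 0.05)
  }
})

test_that("phantoms refuse under-determined channel counts", {
  expect_error(tiny_spec(n_channels = 3, n_spots = 3), "under-determined|>=")
})

test_that("written phantoms round-trip and record provenance", {
  truth <- tiny_truth(n_samples = 2, height = 6, width = 5,
                      noise = "poisson", seed = 21)
  dir <- withr::local_tempdir()
  write_phantom(truth, dir)
  back <- read_cube_dir(dir)
  expect_length(back$cubes, 2)
  for (i in 1:2)
    expect_equal(back$cubes[[i]]$intensities,
                 truth$cubes[[i]]$intensities * 1.0)
  expect_equal(back$peaklist$label, truth$peaklist$label)
  echo <- jsonlite::read_json(file.path(dir, "truth_spec.json"),
                              simplifyVector = TRUE)
  expect_equal(echo$seed, 21)
  expect_equal(echo$noise, "poisson")
  # same seed writes byte-identical cube files
  dir2 <- withr::local_tempdir()
  write_phantom(generate_phantom(tiny_spec(n_samples = 2, height = 6,
                                           width = 5, noise = "poisson",
                                           seed = 21)), dir2)
  f <- "sample_02.tsv"
  expect_identical(unname(tools::md5sum(file.path(dir, f))),
                   unname(tools::md5sum(file.path(dir2, f))))
})
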