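test_that("peaklist enforces ordering, positivity and unique labels", {
  pl <- peaklist(c(15.02, 23.0, 45.03), c("CH3+", "Na+", "C2H5O+"))
  expect_s3_class(pl, "peaklist")
  expect_length(pl, 3)
  expect_error(peaklist(c(2, 1)), "increasing")
  expect_error(peaklist(c(-1, 2)), "> 0")
  expect_error(peaklist(c(1, 2), c("a", "a")), "unique")
  expect_error(peaklist(c(1, 2), c("a", "")), "unique|non-empty")
})

test_that("peak lists round-trip through CSV", {
  pl <- peaklist(c(15.02, 23.0, 45.03), c("CH3+", "Na+", "C2H5O+"),
                 polarity = "negative")
  path <- withr::local_tempfile(fileext = ".csv")
  write_peaklist(pl, path)
  pl2 <- read_peaklist(path)
  expect_equal(pl2$mz, pl$mz)
  expect_equal(pl2$label, pl$label)
  expect_equal(pl2$polarity, "negative")
})

test_that("sample_cube rejects negative and non-finite intensities", {
  arr <- array(1, c(2, 3, 4))
  cube <- sample_cube("s1", arr)
  expect_equal(cube$height, 2)
  expect_equal(cube$width, 3)
  expect_equal(cube$channels, 4)
  arr[1, 1, 1] <- -0.1
  expect_error(sample_cube("s1", arr), "negative")
  arr[1, 1, 1] <- NA
  expect_error(sample_cube("s1", arr), "non-finite")
})

test_that("unfolding is 0-based row-major with origin top-left", {
  # pixel (r, c) of channel 1 carries value 10*r + c
  arr <- array(0, c(2, 3, 2))
  for (r in 1:2) for (c in 1:3) arr[r, c, ] <- c(10 * r + c, 0)
  m <- unfold_cube(sample_cube("s", arr))
  expect_equal(m[, 1], c(11, 12, 13, 21, 22, 23))
})

test_that("consolidation stacks cubes in order without altering values", {
  pl <- peaklist(1:3)
  a <- array(runif(2 * 2 * 3), c(2, 2, 3))
  b <- array(runif(2 * 2 * 3), c(2, 2, 3))
  cm <- consolidate(list(sample_cube("a", a), sample_cube("b", b)), pl)
  expect_equal(dim(cm$data), c(8, 3))
  expect_equal(nrow(cm$row_map), 8)
  expect_equal(cm$row_map$sample_id[1:4], rep("a", 4))
  # values pass through bit-exactly (no pre-treatment)
  expect_identical(cm$data[1:4, ], unfold_cube(sample_cube("a", a)))
  expect_identical(cm$data[5:8, ], unfold_cube(sample_cube("b", b)))
  # Frobenius norm adds in quadrature across cubes
  expect_equal(sum(cm$data^2), sum(a^2) + sum(b^2))
})

test_that("eight full-resolution cubes consolidate to 524288 pixels", {
  pl <- peaklist(1:2)
  cubes <- lapply(1:8, function(i)
    sample_cube(paste0("s", i), array(1, c(256, 256, 2))))
  cm <- consolidate(cubes, pl)
  expect_equal(nrow(cm$data), 8 * 256 * 256)
  expect_equal(nrow(cm$data), 524288)
})

test_that("consolidation rejects channel mismatches and duplicate ids", {
  pl417 <- peaklist(seq_len(417))
  cube461 <- sample_cube("spot_3", array(1, c(2, 2, 461)))
  expect_error(consolidate(list(cube461), pl417), "spot_3")
  expect_error(consolidate(list(cube461), pl417), "417")
  pl <- peaklist(1:3)
  c1 <- sample_cube("dup", array(1, c(2, 2, 3)))
  expect_error(consolidate(list(c1, c1), pl), "duplicate")
})

test_that("row_map is a bijection onto all (sample, pixel) pairs", {
  cm <- tiny_matrix(n_samples = 3, height = 5, width = 7)
  rm <- cm$row_map
  key <- paste(rm$sample_id, rm$row, rm$col)
  expect_equal(anyDuplicated(key), 0)
  expect_equal(nrow(rm), 3 * 5 * 7)
  for (id in unique(rm$sample_id)) {
    sub <- rm[rm$sample_id == id, ]
    expect_equal(sub$row, rep(1:5, each = 7))
    expect_equal(sub$col, rep(1:7, times = 5))
  }
})

test_that("refold_scores inverts unfolding exactly", {
  cm <- tiny_matrix(n_samples = 2, height = 4, width = 6)
  set.seed(11)
  scores <- matrix(runif(nrow(cm$data) * 3), ncol = 3)
  model <- list(scores = scores)
  imgs <- refold_scores(model, cm)
  expect_named(imgs, c("sample_01", "sample_02"))
  expect_equal(dim(imgs$sample_01), c(4, 6, 3))
  # explicit ordering contract on one sample
  expect_equal(imgs$sample_01[1, , 2], scores[1:6, 2])
  expect_equal(imgs$sample_01[2, , 2], scores[7:12, 2])
  # round trip is the identity
  expect_identical(unfold_scores(imgs, cm), scores)
  # constant column refolds to uniform images
  model1 <- list(scores = matrix(1, nrow(cm$data), 1))
  imgs1 <- refold_scores(model1, cm)
  expect_true(all(imgs1$sample_02 == 1))
  # row-count mismatch is a dimensional error
  expect_error(refold_scores(list(scores = scores[-1, , drop = FALSE]), cm),
               "do not match")
})

test_that("area equivalence reports totals and a near-square tiling", {
  mk <- function(n, fw, fh) lapply(seq_len(n), function(i)
    sample_cube(paste0("s", i), array(1, c(4, 4, 2)),
                field_size_um = c(fw, fh)))
  eight <- area_equivalent(mk(8, 500, 500))
  expect_equal(eight$area_mm2, 2)
  expect_equal(eight$rect_mm, c(1, 2))
  expect_equal(area_equivalent(mk(1, 500, 500))$area_mm2, 0.25)
  expect_equal(area_equivalent(mk(4, 100, 100))$area_mm2, 0.04)
  mixed <- c(mk(1, 500, 500), mk(1, 100, 100))
  mixed[[2]]$sample_id <- "other"
  expect_error(area_equivalent(mixed), "homogeneous")
})

test_that("cubes round-trip through the on-disk format", {
  truth <- tiny_truth(n_samples = 1, height = 5, width = 4,
                      noise = "poisson")
  dir <- withr::local_tempdir()
  write_cube(truth$cubes[[1]], dir, peaklist = truth$peaklist)
  back <- read_cube(file.path(dir, "sample_01.json"))
  expect_identical(back$intensities, truth$cubes[[1]]$intensities * 1.0)
  expect_equal(back$field_size_um, c(500, 500))
})
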