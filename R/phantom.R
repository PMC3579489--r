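#' Specify a multi-sample hyperspectral phantom
#'
#' Defines a ground-truth scene emulating a polymer-microarray ToF-SIMS
#' study: each sample is one printed spot imaged over a fixed field, with
#' a substrate chemistry everywhere (strongest outside the spot), spot
#' chemistries shared across subsets of samples, and an optional
#' contamination overlay that adds its own spectrum while multiplicatively
#' masking the spot chemistry beneath it.
#'
#' The default scene has 8 samples of 64 x 64 pixels over 500 x 500 um,
#' 30 channels and 5 components: one substrate background (all samples),
#' three spot chemistries over the sample subsets \{1,2,4,8\}, \{3,7\} and
#' \{5,6\}, and one contamination patch on sample 4 masking the spot
#' chemistry it covers. `preset = "full_scale"` switches to 8 samples of
#' 256 x 256 pixels with 461 channels, the shape of a full positive-ion
#' microarray acquisition.
#'
#' @param n_samples number of sample cubes.
#' @param height,width pixels per cube.
#' @param n_channels number of m/z channels; must be at least the number
#'   of components.
#' @param components optional list of component definitions; each element
#'   a list with `spatial_role` (`"background"`, `"spot"` or
#'   `"contamination"`), `present_in` (sample indices), `amplitude`
#'   (mean intensity scale, counts) and `spot_radius_fraction` (of field
#'   width; ignored for the background). `NULL` builds the default
#'   5-component scene.
#' @param noise `"none"`, `"poisson"` (counting noise with the noiseless
#'   intensity as mean) or `"gaussian"` (additive, truncated at zero).
#' @param gaussian_sd standard deviation for `noise = "gaussian"`.
#' @param field_size_um physical field, `c(width, height)` in um.
#' @param seed master seed; per-sample and noise streams are derived from
#'   it deterministically.
#' @param preset `"default"` or `"full_scale"`.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(n_samples = 8, height = 64, width = 64,
                         n_channels = 30, components = NULL,
                         noise = c("none", "poisson", "gaussian"),
                         gaussian_sd = 5, field_size_um = c(500, 500),
                         seed = 1, preset = c("default", "full_scale")) {
  preset <- match.arg(preset)
  noise <- match.arg(noise)
  if (preset == "full_scale") {
    n_samples <- 8; height <- 256; width <- 256; n_channels <- 461
  }
  if (is.null(components)) components <- default_components(n_samples)
  roles <- vapply(components, function(x) x$spatial_role, character(1))
  if (sum(roles == "background") != 1)
    stop("exactly one background component is required")
  bg <- components[[which(roles == "background")]]
  if (!setequal(bg$present_in, seq_len(n_samples)))
    stop("the background component must be present in every sample")
  amps <- vapply(components, function(x) x$amplitude, numeric(1))
  if (any(amps <= 0)) stop("component amplitudes must be > 0")
  if (n_channels < length(components))
    stop("n_channels (", n_channels, ") must be >= number of components (",
         length(components), "): pure spectra would be under-determined")
  for (comp in components) {
    if (any(comp$present_in < 1) || any(comp$present_in > n_samples))
      stop("present_in indices must lie in 1..n_samples")
  }
  structure(list(n_samples = n_samples, height = height, width = width,
                 n_channels = n_channels, components = components,
                 noise = noise, gaussian_sd = gaussian_sd,
                 field_size_um = field_size_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

default_components <- function(n_samples) {
  all_s <- seq_len(n_samples)
  in_range <- function(idx) idx[idx <= n_samples]
  list(
    list(spatial_role = "background", present_in = all_s,
         amplitude = 100, spot_radius_fraction = 0.32),
    list(spatial_role = "spot", present_in = in_range(c(1, 2, 4, 8)),
         amplitude = 150, spot_radius_fraction = 0.32),
    list(spatial_role = "spot", present_in = in_range(c(3, 7)),
         amplitude = 150, spot_radius_fraction = 0.32),
    list(spatial_role = "spot", present_in = in_range(c(5, 6)),
         amplitude = 150, spot_radius_fraction = 0.32),
    # the contamination overlayer covers most of the spot it sits on
    list(spatial_role = "contamination", present_in = in_range(4),
         amplitude = 120, spot_radius_fraction = 0.26)
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d samples of %d x %d px, %d channels, ",
                     "%d components, noise=%s, seed=%d\n"),
              x$n_samples, x$height, x$width, x$n_channels,
              length(x$components), x$noise, x$seed))
  invisible(x)
}

# raised-cosine disc: 1 inside (1-edge)*radius, cosine taper to 0 at radius
smooth_disc <- function(height, width, center_rc, radius_px, edge = 0.25) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  d <- sqrt((r - center_rc[1])^2 + (c - center_rc[2])^2)
  inner <- radius_px * (1 - edge)
  m <- matrix(0, height, width)
  m[d <= inner] <- 1
  taper <- d > inner & d < radius_px
  m[taper] <- 0.5 * (1 + cos(pi * (d[taper] - inner) / (radius_px - inner)))
  m
}

# Sparse positive pure spectra on a handful of dominant channels.
# Sparsity mirrors real fragment spectra over a curated peak list, and
# every component keeps two channels of its own — the analogue of the
# uniquely characteristic ions each surface chemistry shows (e.g. CF3+
# for fluoropolymers, SiC3H9+ for PDMS) — so the scene's pure spectra
# are identifiable, as they are in practice.
random_spectra <- function(k, n_channels, n_dominant = 6, n_unique = 2) {
  if (n_channels < k * n_unique)
    stop("n_channels too small to reserve ", n_unique,
         " characteristic channels per component")
  reserved <- matrix(sample.int(n_channels, k * n_unique), nrow = k)
  L <- matrix(0, k, n_channels)
  for (j in seq_len(k)) {
    shared <- setdiff(seq_len(n_channels), as.vector(reserved))
    n_extra <- min(max(0, n_dominant - n_unique), length(shared))
    idx <- c(reserved[j, ], sample(shared, n_extra))
    s <- numeric(n_channels)
    s[idx] <- rgamma(length(idx), shape = 2, rate = 1) + 0.2
    L[j, ] <- s / sqrt(sum(s^2))
  }
  L
}

#' Generate a phantom data-set with known ground truth
#'
#' Builds the sample cubes of a [phantom_spec] scene together with the
#' exact per-sample concentration maps and pure spectra that produced
#' them. Noiseless intensities equal the bilinear product of the true
#' scores and loadings exactly, so the unfolded matrix has numerical rank
#' equal to the number of components; noise is then applied channel-wise
#' per pixel. The whole construction is reproducible from the master
#' seed.
#'
#' @param spec a [phantom_spec].
#' @return a `phantom_truth`: list with `cubes` (list of [sample_cube]),
#'   `peaklist`, `true_scores` (per-sample list of `height x width x k`
#'   arrays, amplitude-scaled concentrations), `true_loadings`
#'   (`k x channels`, unit-norm rows), and the `spec`.
#' @examples
#' truth <- generate_phantom(phantom_spec(n_samples = 2, height = 8,
#'                                        width = 8, n_channels = 10))
#' length(truth$cubes)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  k <- length(spec$components)
  nch <- spec$n_channels

  # pure spectra: distinct (pairwise cosine < 0.95), unit-norm, positive
  loadings <- with_seed(derive_seed(spec$seed, 1), {
    for (attempt in seq_len(50)) {
      L <- random_spectra(k, nch)
      cs <- cosine_rows(L, L)
      if (max(cs[upper.tri(cs)]) < 0.95) break
      if (attempt == 50)
        stop("could not draw pairwise-distinct pure spectra; ",
             "increase n_channels")
    }
    L
  })

  # peak list: synthetic m/z axis, one label per channel
  mz <- 10 + seq_len(nch) * 7.3
  pl <- peaklist(mz, sprintf("ion_%03d", seq_len(nch)))

  roles <- vapply(spec$components, function(x) x$spatial_role, character(1))
  h <- spec$height; w <- spec$width
  cubes <- vector("list", spec$n_samples)
  true_scores <- vector("list", spec$n_samples)
  names(true_scores) <- sprintf("sample_%02d", seq_len(spec$n_samples))

  for (s in seq_len(spec$n_samples)) {
    maps <- with_seed(derive_seed(spec$seed, 100 + s), {
      m <- array(0, c(h, w, k))
      center <- c(h / 2 + runif(1, -h * 0.03, h * 0.03),
                  w / 2 + runif(1, -w * 0.03, w * 0.03))
      # spot components share the sample's central disc footprint
      for (j in seq_len(k)) {
        comp <- spec$components[[j]]
        if (!(s %in% comp$present_in)) next
        if (comp$spatial_role == "background") next
        if (comp$spatial_role == "spot") {
          disc <- smooth_disc(h, w, center, comp$spot_radius_fraction * w)
          # mild within-spot heterogeneity: printed spots are not uniform
          grad <- 1 + 0.15 * outer(seq_len(h) / h - 0.5, rep(1, w))
          m[, , j] <- comp$amplitude * disc * grad
        } else if (comp$spatial_role == "contamination") {
          off <- c(runif(1, -0.15, 0.15) * h, runif(1, -0.15, 0.15) * w)
          disc <- smooth_disc(h, w, center + off,
                              comp$spot_radius_fraction * w)
          m[, , j] <- comp$amplitude * disc
        }
      }
      # contamination masks co-located spot chemistry multiplicatively
      for (j in which(roles == "contamination")) {
        mask <- m[, , j] / spec$components[[j]]$amplitude
        if (all(mask == 0)) next
        for (jj in which(roles == "spot")) {
          # static SIMS samples only the outermost nanometres: an
          # overlayer fully masks the chemistry beneath its core
          m[, , jj] <- m[, , jj] * (1 - mask)
        }
      }
      # background high outside the spot disc, attenuated inside it
      bg_j <- which(roles == "background")
      bg <- spec$components[[bg_j]]
      disc <- smooth_disc(h, w, center, bg$spot_radius_fraction * w)
      # the printed spot covers the substrate; its signal vanishes at the
      # spot core and recovers smoothly towards the surrounding field
      m[, , bg_j] <- bg$amplitude * (1 - disc)
      m
    })
    clean <- matrix(aperm(maps, c(2, 1, 3)), nrow = h * w, ncol = k) %*% loadings
    noisy <- with_seed(derive_seed(spec$seed, 10000 + s), {
      switch(spec$noise,
        none = clean,
        poisson = matrix(rpois(length(clean), lambda = clean),
                         nrow = nrow(clean)),
        gaussian = pmax(clean + matrix(rnorm(length(clean),
                                             sd = spec$gaussian_sd),
                                       nrow = nrow(clean)), 0))
    })
    arr <- aperm(array(noisy, c(w, h, nch)), c(2, 1, 3))
    cubes[[s]] <- sample_cube(sprintf("sample_%02d", s), arr,
                              field_size_um = spec$field_size_um)
    true_scores[[s]] <- maps
  }
  structure(list(cubes = cubes, peaklist = pl, true_scores = true_scores,
                 true_loadings = loadings, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d cubes, %d true components, noise=%s\n",
              length(x$cubes), nrow(x$true_loadings), x$spec$noise))
  invisible(x)
}

#' Write a phantom (cubes + ground truth) to disk
#'
#' Cubes and the peak list use the standard loader formats, so a written
#' phantom round-trips bit-exactly through [read_cube_dir()] for
#' noiseless integer data. Ground truth (spectra, concentration maps)
#' and a JSON echo of the spec — including the seed — are stored
#' alongside for provenance.
#'
#' @param truth a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cube in truth$cubes) write_cube(cube, dir, peaklist = truth$peaklist)
  write.table(truth$true_loadings, file.path(dir, "truth_loadings.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  for (nm in names(truth$true_scores)) {
    arr <- truth$true_scores[[nm]]
    m <- matrix(aperm(arr, c(2, 1, 3)),
                nrow = dim(arr)[1] * dim(arr)[2], ncol = dim(arr)[3])
    write.table(m, file.path(dir, paste0("truth_scores_", nm, ".tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  spec <- truth$spec
  echo <- list(n_samples = spec$n_samples, height = spec$height,
               width = spec$width, n_channels = spec$n_channels,
               noise = spec$noise, gaussian_sd = spec$gaussian_sd,
               field_size_um = spec$field_size_um, seed = spec$seed,
               components = spec$components)
  jsonlite::write_json(echo, file.path(dir, "truth_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
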