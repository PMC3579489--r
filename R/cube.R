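#' Create a sample image cube
#'
#' One ToF-SIMS acquisition: a pixel grid of peak-integrated, non-negative
#' ion intensities over a known physical field. Intensities are stored as
#' non-negative reals (detector-corrected counts need not be integer);
#' negative values are rejected outright rather than clipped, since a
#' negative intensity indicates an upstream processing error.
#'
#' @param sample_id short unique sample identifier.
#' @param intensities numeric array `height x width x channels`, all
#'   values `>= 0`.
#' @param field_size_um physical field as `c(width_um, height_um)`.
#' @return a `sample_cube` object.
#' @examples
#' cube <- sample_cube("s1", array(1, c(4, 4, 3)), c(500, 500))
#' dim(cube$intensities)
#' @export
sample_cube <- function(sample_id, intensities, field_size_um = c(500, 500)) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) != 1 || !nzchar(sample_id))
    stop("sample_id must be a single non-empty string")
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stop("intensities must be a height x width x channels array")
  d <- dim(intensities)
  if (any(d < 1)) stop("height, width and channels must all be >= 1")
  if (any(!is.finite(intensities)))
    stop("intensities contain non-finite values (sample ", sample_id, ")")
  if (any(intensities < 0))
    stop("negative intensities in sample ", sample_id,
         "; inputs are rejected, not clipped")
  field_size_um <- as.numeric(field_size_um)
  if (length(field_size_um) != 2 || any(field_size_um <= 0))
    stop("field_size_um must be two positive values (width, height) in um")
  structure(list(sample_id = sample_id,
                 height = d[1], width = d[2], channels = d[3],
                 field_size_um = field_size_um,
                 intensities = intensities),
            class = "sample_cube")
}

#' @export
print.sample_cube <- function(x, ...) {
  cat(sprintf("<sample_cube> '%s': %d x %d px, %d channels, %g x %g um\n",
              x$sample_id, x$height, x$width, x$channels,
              x$field_size_um[1], x$field_size_um[2]))
  invisible(x)
}

#' Unfold a cube to a pixels x channels matrix
#'
#' Pixels are ordered row-major with the origin at the top-left: pixel
#' (r, c) maps to row `(r - 1) * width + c` (1-based). This ordering is a
#' package-wide contract so score images are comparable across runs.
#'
#' @param cube a [sample_cube].
#' @return `(height * width) x channels` matrix.
#' @export
unfold_cube <- function(cube) {
  stopifnot(inherits(cube, "sample_cube"))
  h <- cube$height; w <- cube$width; ch <- cube$channels
  # array is stored column-major over (row, col, channel); row-major pixel
  # order means iterating columns fastest within each image row
  m <- matrix(aperm(cube$intensities, c(2, 1, 3)), nrow = h * w, ncol = ch)
  m
}

#' Write a sample cube to disk
#'
#' The cube is stored as a tab-delimited text matrix of
#' `height*width` rows (row-major pixels) by `channels` columns, with a
#' JSON sidecar recording `sample_id`, dimensions, field size, polarity
#' and the peak-list file name.
#'
#' @param cube a [sample_cube].
#' @param dir output directory (created if missing).
#' @param peaklist optional [peaklist]; written once as
#'   `peaklist.csv` and referenced from the sidecar.
#' @return the sidecar path, invisibly.
#' @export
write_cube <- function(cube, dir, peaklist = NULL) {
  stopifnot(inherits(cube, "sample_cube"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, cube$sample_id)
  data_file <- paste0(stem, ".tsv")
  ok <- try(write.table(unfold_cube(cube), data_file, sep = "\t",
                        row.names = FALSE, col.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write cube data to ", data_file)
  pl_file <- NA_character_
  if (!is.null(peaklist)) {
    pl_file <- "peaklist.csv"
    pl_path <- file.path(dir, pl_file)
    if (!file.exists(pl_path)) write_peaklist(peaklist, pl_path)
  }
  meta <- list(sample_id = cube$sample_id,
               height = cube$height, width = cube$width,
               field_size_um = cube$field_size_um,
               polarity = if (is.null(peaklist)) "positive" else peaklist$polarity,
               peaklist_file = pl_file,
               data_file = basename(data_file))
  sidecar <- paste0(stem, ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a sample cube from its JSON sidecar
#'
#' @param sidecar path to the `<sample_id>.json` sidecar written by
#'   [write_cube()].
#' @return a [sample_cube].
#' @export
read_cube <- function(sidecar) {
  if (!file.exists(sidecar)) stop("cube sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  data_file <- file.path(dir, meta$data_file)
  if (!file.exists(data_file)) stop("cube data file not found: ", data_file)
  m <- as.matrix(read.table(data_file, sep = "\t", header = FALSE))
  storage.mode(m) <- "double"
  h <- meta$height; w <- meta$width
  if (nrow(m) != h * w)
    stop("cube data rows (", nrow(m), ") do not match ", h, " x ", w,
         " pixels in ", data_file)
  arr <- aperm(array(m, c(w, h, ncol(m))), c(2, 1, 3))
  sample_cube(meta$sample_id, arr, field_size_um = meta$field_size_um)
}

#' Read all cubes in a directory
#'
#' Loads every `*.json` cube sidecar (phantom/run metadata files are
#' skipped) plus the shared `peaklist.csv` when present.
#'
#' @param dir directory written by [write_cube()] / [write_phantom()].
#' @return list with `cubes` (list of [sample_cube]) and `peaklist`
#'   ([peaklist] or `NULL`).
#' @export
read_cube_dir <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  sidecars <- sidecars[!grepl("(truth|spec|run_meta|overfit)", basename(sidecars))]
  if (length(sidecars) == 0) stop("no cube sidecars (*.json) found in ", dir)
  cubes <- lapply(sidecars, read_cube)
  pl_path <- file.path(dir, "peaklist.csv")
  pl <- if (file.exists(pl_path)) read_peaklist(pl_path) else NULL
  list(cubes = cubes, peaklist = pl)
}
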