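#' Consolidate several image cubes into one analysis matrix
#'
#' Row-stacks the unfolded cubes into the single pixels x channels matrix
#' `D` that the bilinear factorisation consumes, so the samples are
#' analysed jointly as one large data-set instead of one at a time.
#' Intensity values pass through unchanged: no inter-sample scaling,
#' normalisation or other pre-treatment is applied.
#'
#' @param cubes list of [sample_cube] objects with unique `sample_id`s;
#'   heights/widths may differ between samples, channel counts may not.
#' @param peaklist the [peaklist] defining the channel axis; its length
#'   must equal every cube's channel count.
#' @return a `consolidated_matrix`: list with `data`
#'   (total_pixels x channels), `row_map` (data.frame `sample_id`,
#'   `row`, `col`, 1-based, row-major within each cube, cubes in input
#'   order) and `peaklist`.
#' @examples
#' pl <- peaklist(1:3)
#' cubes <- list(sample_cube("a", array(1, c(2, 2, 3))),
#'               sample_cube("b", array(2, c(2, 2, 3))))
#' cm <- consolidate(cubes, pl)
#' dim(cm$data)  # 8 x 3
#' @export
consolidate <- function(cubes, peaklist) {
  stopifnot(inherits(peaklist, "peaklist"))
  if (!is.list(cubes) || length(cubes) < 1 ||
      !all(vapply(cubes, inherits, logical(1), "sample_cube")))
    stop("cubes must be a non-empty list of sample_cube objects")
  ids <- vapply(cubes, function(c) c$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", paste(ids[duplicated(ids)], collapse = ", "))
  nch <- length(peaklist)
  for (cube in cubes) {
    if (cube$channels != nch)
      stop("channel count mismatch for sample '", cube$sample_id, "': cube has ",
           cube$channels, " channels but peak list has ", nch)
  }
  blocks <- lapply(cubes, unfold_cube)
  data <- do.call(rbind, blocks)
  maps <- lapply(cubes, function(cube) {
    data.frame(sample_id = cube$sample_id,
               row = rep(seq_len(cube$height), each = cube$width),
               col = rep(seq_len(cube$width), times = cube$height),
               stringsAsFactors = FALSE)
  })
  row_map <- do.call(rbind, maps)
  rownames(row_map) <- NULL
  structure(list(data = data, row_map = row_map, peaklist = peaklist),
            class = "consolidated_matrix")
}

#' @export
print.consolidated_matrix <- function(x, ...) {
  cat(sprintf("<consolidated_matrix> %d pixels x %d channels from %d samples\n",
              nrow(x$data), ncol(x$data),
              length(unique(x$row_map$sample_id))))
  invisible(x)
}

#' Refold score columns into per-sample images
#'
#' Inverts the unfolding: each component's score column is cut by sample
#' and reshaped onto that sample's pixel grid, giving the spatial
#' distribution (scores image) of each resolved chemistry.
#'
#' @param model an [fit_mcr()] model (or any list with a `scores` matrix).
#' @param matrix the [consolidate()]d matrix the model was fitted to.
#' @return named list (one per sample, in cube input order) of
#'   `height x width x k` arrays.
#' @export
refold_scores <- function(model, matrix) {
  stopifnot(inherits(matrix, "consolidated_matrix"))
  scores <- model$scores
  if (nrow(scores) != nrow(matrix$row_map))
    stop("score rows (", nrow(scores), ") do not match matrix pixels (",
         nrow(matrix$row_map), ")")
  k <- ncol(scores)
  ids <- unique(matrix$row_map$sample_id)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    sel <- matrix$row_map$sample_id == id
    sub <- matrix$row_map[sel, ]
    h <- max(sub$row); w <- max(sub$col)
    block <- scores[sel, , drop = FALSE]
    # rows arrive row-major: invert by filling w x h column-major then transposing
    arr <- aperm(array(block, c(w, h, k)), c(2, 1, 3))
    out[[id]] <- arr
  }
  out
}

#' Unfold per-sample score images back to a score matrix
#'
#' Inverse of [refold_scores()]; `unfold_scores(refold_scores(m, cm), cm)`
#' reproduces `m$scores` exactly.
#'
#' @param images named list of `height x width x k` arrays as returned by
#'   [refold_scores()].
#' @param matrix the matching `consolidated_matrix`.
#' @return total_pixels x k score matrix.
#' @export
unfold_scores <- function(images, matrix) {
  stopifnot(inherits(matrix, "consolidated_matrix"))
  ids <- unique(matrix$row_map$sample_id)
  if (!all(ids %in% names(images)))
    stop("images missing samples: ",
         paste(setdiff(ids, names(images)), collapse = ", "))
  blocks <- lapply(ids, function(id) {
    arr <- images[[id]]
    k <- dim(arr)[3]
    matrix(aperm(arr, c(2, 1, 3)), nrow = dim(arr)[1] * dim(arr)[2], ncol = k)
  })
  do.call(rbind, blocks)
}

#' Total analysed area and its equivalent rectangle
#'
#' Consolidating n fields of `a x b` um is, at equal pixel pitch and peak
#' count, equivalent to a single acquisition over `n * a * b`; e.g. eight
#' 500 x 500 um fields carry the information content of one 1 x 2 mm
#' image. All cubes must share one field size and resolution, since the
#' equivalence assumes a single pixel pitch.
#'
#' @param cubes list of [sample_cube] objects.
#' @return list with `area_mm2`, `rect_mm` (`c(short, long)` in mm) and
#'   `pixel_pitch_um`.
#' @examples
#' cubes <- replicate(8, sample_cube("x", array(1, c(4, 4, 2))),
#'                    simplify = FALSE)
#' for (i in seq_along(cubes)) cubes[[i]]$sample_id <- paste0("s", i)
#' area_equivalent(cubes)$area_mm2  # 2
#' @export
area_equivalent <- function(cubes) {
  if (!is.list(cubes) || length(cubes) < 1 ||
      !all(vapply(cubes, inherits, logical(1), "sample_cube")))
    stop("cubes must be a non-empty list of sample_cube objects")
  fw <- vapply(cubes, function(c) c$field_size_um[1], numeric(1))
  fh <- vapply(cubes, function(c) c$field_size_um[2], numeric(1))
  hs <- vapply(cubes, function(c) c$height, numeric(1))
  ws <- vapply(cubes, function(c) c$width, numeric(1))
  if (length(unique(fw)) > 1 || length(unique(fh)) > 1 ||
      length(unique(hs)) > 1 || length(unique(ws)) > 1)
    stop("area_equivalent requires homogeneous field sizes and resolutions")
  n <- length(cubes)
  area_um2 <- n * fw[1] * fh[1]
  area_mm2 <- area_um2 / 1e6
  # tile the n fields into the grid closest to square; report sides in mm
  divs <- seq_len(n)[n %% seq_len(n) == 0]
  grids <- cbind(divs, n / divs)
  side_a <- grids[, 1] * fw[1] / 1e3
  side_b <- grids[, 2] * fh[1] / 1e3
  best <- which.min(abs(log(side_a / side_b)))
  rect <- sort(c(side_a[best], side_b[best]))
  list(area_mm2 = area_mm2, rect_mm = rect,
       pixel_pitch_um = fw[1] / ws[1])
}
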