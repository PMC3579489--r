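#' Create a peak list
#'
#' The peak list defines the channel axis of every cube analysed with it:
#' one entry per peak-integrated intensity channel, ordered by m/z. The
#' positive- and negative-polarity lists of an experiment are distinct
#' objects and must never be mixed across cubes.
#'
#' @param mz numeric vector of peak centres in u; strictly increasing,
#'   all positive.
#' @param label character vector of short ion labels (e.g. `"C2H5O+"`);
#'   unique and non-empty. Defaults to `"mz<value>"`.
#' @param polarity `"positive"` or `"negative"`.
#' @return a `peaklist` object.
#' @examples
#' pl <- peaklist(c(29.04, 45.03, 69.03), c("CHO+", "C2H5O+", "C4H5O+"))
#' length(pl)
#' @export
peaklist <- function(mz, label = NULL, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  mz <- as.numeric(mz)
  if (length(mz) < 1) stop("peak list must contain at least one peak")
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("all m/z centres must be finite and > 0")
  if (any(diff(mz) <= 0))
    stop("m/z centres must be strictly increasing")
  if (is.null(label)) label <- paste0("mz", format(mz, trim = TRUE))
  label <- as.character(label)
  if (length(label) != length(mz))
    stop("label length must match mz length")
  if (any(!nzchar(label)) || anyDuplicated(label))
    stop("labels must be unique and non-empty")
  structure(list(mz = mz, label = label, polarity = polarity),
            class = "peaklist")
}

#' @export
length.peaklist <- function(x) length(x$mz)

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %d %s-ion peaks, m/z %.2f-%.2f\n",
              length(x), x$polarity, min(x$mz), max(x$mz)))
  invisible(x)
}

#' Read a peak list from CSV
#'
#' Expects a header `mz,label` with one row per channel in channel order;
#' an optional `polarity` column (constant) is honoured.
#'
#' @param path CSV file path.
#' @param polarity polarity to assume when the file has no polarity column.
#' @return a [peaklist].
#' @export
read_peaklist <- function(path, polarity = "positive") {
  if (!file.exists(path)) stop("peak list file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "label") %in% names(df)))
    stop("peak list CSV must have columns 'mz' and 'label': ", path)
  if ("polarity" %in% names(df) && nrow(df) > 0)
    polarity <- df$polarity[1]
  peaklist(df$mz, df$label, polarity = polarity)
}

#' Write a peak list to CSV
#' @param x a [peaklist].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peaklist"))
  df <- data.frame(mz = x$mz, label = x$label, polarity = x$polarity)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
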