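#' Construct a peak table
#'
#' A peak table is the unit of fragment-analysis data: the set of
#' (fragment size, peak height) pairs that a capillary sequencer's peak
#' caller (e.g. GeneMapper) emits for one PCR product of one sample at
#' one locus.
#'
#' @param sample_id Sample label.
#' @param locus Locus label (e.g. `"XDP"`, `"LIPG"`).
#' @param size_bp Numeric vector of fragment sizes in base pairs.
#' @param height Numeric vector of peak heights in relative fluorescence
#'   units (RFU); must be non-negative and the same length as `size_bp`.
#' @return An object of class `peak_table`: a list with elements
#'   `sample_id`, `locus` and `peaks` (a data frame with columns
#'   `size_bp`, `height`, sorted by size).
#' @export
peak_table <- function(sample_id, locus, size_bp, height) {
  if (length(size_bp) != length(height)) {
    stop("`size_bp` and `height` must have the same length")
  }
  if (length(size_bp) == 0L) {
    stop("no peaks: a peak table must contain at least one peak")
  }
  if (!is.numeric(size_bp) || !is.numeric(height)) {
    stop("`size_bp` and `height` must be numeric")
  }
  if (anyNA(size_bp)) stop("`size_bp` contains missing values")
  if (any(height < 0, na.rm = TRUE)) stop("peak heights must be >= 0")
  ord <- order(size_bp)
  structure(
    list(
      sample_id = as.character(sample_id)[1L],
      locus = as.character(locus)[1L],
      peaks = data.frame(size_bp = size_bp[ord], height = height[ord])
    ),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf(
    "<peak_table> sample %s, locus %s: %d peaks, %.1f-%.1f bp\n",
    x$sample_id, x$locus, nrow(x$peaks),
    min(x$peaks$size_bp), max(x$peaks$size_bp)
  ))
  invisible(x)
}

#' Read a fragment-analysis peak table from CSV
#'
#' Expects the column layout `sample_id, locus, size_bp, height`, as
#' written by [write_fixtures()] and as exported from GeneMapper-style
#' software. Rows with a missing height are dropped (with a message
#' giving the count); duplicate `size_bp` rows within a sample have
#' their heights summed, on the grounds that height is a proxy for
#' molecule count.
#'
#' @param path Path to the CSV file.
#' @param locus Optional locus label to filter on.
#' @param sample_id Optional sample label to filter on. When the file
#'   holds a single sample/locus both may be omitted.
#' @return A single [peak_table()] object.
#' @seealso [read_peak_tables()] to read every sample in a file.
#' @export
read_peak_table <- function(path, locus = NULL, sample_id = NULL) {
  tabs <- read_peak_tables(path, locus = locus, sample_id = sample_id)
  if (length(tabs) != 1L) {
    stop(sprintf(
      "%d sample/locus combinations in '%s'; pass `sample_id`/`locus` or use read_peak_tables()",
      length(tabs), path
    ))
  }
  tabs[[1L]]
}

#' Read all peak tables in a CSV file
#'
#' @inheritParams read_peak_table
#' @return A named list of [peak_table()] objects, one per
#'   sample/locus combination, named `"<sample_id>.<locus>"`.
#' @export
read_peak_tables <- function(path, locus = NULL, sample_id = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "locus", "size_bp", "height")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf(
      "peak table '%s' lacks required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0L) stop(sprintf("no peaks: '%s' contains no rows", path))
  bad <- which(is.na(suppressWarnings(as.numeric(raw$size_bp))))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-numeric size_bp in '%s' at data row %d", path, bad[1L]
    ))
  }
  raw$size_bp <- as.numeric(raw$size_bp)
  raw$height <- suppressWarnings(as.numeric(raw$height))
  n_drop <- sum(is.na(raw$height))
  if (n_drop > 0L) {
    message(sprintf("dropping %d row(s) with missing height", n_drop))
    raw <- raw[!is.na(raw$height), , drop = FALSE]
  }
  if (!is.null(locus)) raw <- raw[raw$locus == locus, , drop = FALSE]
  if (!is.null(sample_id)) raw <- raw[raw$sample_id == sample_id, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no peaks after filtering")

  key <- paste(raw$sample_id, raw$locus, sep = ".")
  out <- lapply(split(raw, key), function(d) {
    if (anyDuplicated(d$size_bp)) {
      warning(sprintf(
        "sample %s: duplicate size_bp rows merged (heights summed)",
        d$sample_id[1L]
      ), call. = FALSE)
      agg <- stats::aggregate(height ~ size_bp, data = d, FUN = sum)
      d <- data.frame(
        sample_id = d$sample_id[1L], locus = d$locus[1L],
        size_bp = agg$size_bp, height = agg$height
      )
    }
    peak_table(d$sample_id[1L], d$locus[1L], d$size_bp, d$height)
  })
  out
}
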