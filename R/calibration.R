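#' Fit a bp-to-repeat-unit sizing calibration
#'
#' Fragment sizes reported by capillary electrophoresis are converted to
#' repeat units through a linear map fitted to co-amplified sizing
#' standards of known repeat length (for the XDP locus, cloned alleles
#' of 37, 44 and 50 CCCTCT units). The fitted slope is the apparent
#' length of one repeat unit in bp and must be close to the true 6 bp of
#' a hexameric repeat; a slope outside `slope_range` indicates mislabeled
#' standards or a failed run and aborts the calibration. The intercept is
#' the constant (flanking plus primer) length of the amplicon.
#'
#' @param standards A data frame or matrix with columns `repeat_units`
#'   and `size_bp` (at least two standards), or a list of
#'   `c(repeat_units, size_bp)` pairs.
#' @param accurate_range_bp Length-2 numeric: the fragment-size window
#'   (bp) within which sizing against the standards is considered
#'   accurate. Defaults to 330-560 bp, roughly 32-70 repeat units;
#'   fragments outside it are sized by extrapolation of the same line
#'   and flagged.
#' @param slope_range Acceptable slope window in bp per repeat unit.
#' @return An object of class `size_calibration` with elements
#'   `slope_bp_per_repeat`, `intercept_bp`, `accurate_range_bp`,
#'   `standards`.
#' @examples
#' cal <- fit_calibration(data.frame(
#'   repeat_units = c(32, 70), size_bp = c(330, 558)
#' ))
#' cal$slope_bp_per_repeat # 6
#' @export
fit_calibration <- function(standards,
                            accurate_range_bp = c(330, 560),
                            slope_range = c(5.5, 6.5)) {
  if (is.list(standards) && !is.data.frame(standards)) {
    standards <- do.call(rbind, lapply(standards, function(p) {
      data.frame(repeat_units = p[[1L]], size_bp = p[[2L]])
    }))
  }
  standards <- as.data.frame(standards)
  if (!all(c("repeat_units", "size_bp") %in% names(standards))) {
    stop("`standards` needs columns `repeat_units` and `size_bp`")
  }
  if (nrow(standards) < 2L) stop("at least two sizing standards are required")
  if (length(unique(standards$repeat_units)) < 2L) {
    stop("sizing standards must span at least two distinct repeat lengths")
  }
  fit <- stats::lm(size_bp ~ repeat_units, data = standards)
  slope <- unname(stats::coef(fit)[["repeat_units"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  if (slope < slope_range[1L] || slope > slope_range[2L]) {
    stop(sprintf(
      "calibration failure: fitted slope %.3f bp/repeat outside [%.1f, %.1f]",
      slope, slope_range[1L], slope_range[2L]
    ))
  }
  structure(
    list(
      slope_bp_per_repeat = slope,
      intercept_bp = intercept,
      accurate_range_bp = sort(accurate_range_bp),
      standards = standards[, c("repeat_units", "size_bp")]
    ),
    class = "size_calibration"
  )
}

#' @export
print.size_calibration <- function(x, ...) {
  cat(sprintf(
    "<size_calibration> %.3f bp/repeat + %.1f bp; accurate %g-%g bp (%d standards)\n",
    x$slope_bp_per_repeat, x$intercept_bp,
    x$accurate_range_bp[1L], x$accurate_range_bp[2L], nrow(x$standards)
  ))
  invisible(x)
}

#' Convert fragment sizes to repeat units
#'
#' Inverts the calibration line and rounds to the nearest integer repeat
#' count. Fragments outside the calibration's accurate window are still
#' converted (the same line is extrapolated, as done for rare large
#' single-molecule alleles) but flagged.
#'
#' @param calib A [fit_calibration()] object.
#' @param size_bp Numeric vector of fragment sizes in bp; every size
#'   must exceed the calibration intercept (a fragment at or below the
#'   intercept carries no repeat content).
#' @return A data frame with columns `repeat_units` (integer) and
#'   `extrapolated` (logical).
#' @export
bp_to_repeats <- function(calib, size_bp) {
  stopifnot(inherits(calib, "size_calibration"))
  if (any(size_bp <= calib$intercept_bp)) {
    stop(sprintf(
      "fragment size <= calibration intercept (%.1f bp): no repeat content",
      calib$intercept_bp
    ))
  }
  units <- as.integer(round((size_bp - calib$intercept_bp) / calib$slope_bp_per_repeat))
  extra <- size_bp < calib$accurate_range_bp[1L] | size_bp > calib$accurate_range_bp[2L]
  data.frame(repeat_units = units, extrapolated = extra)
}

#' Convert repeat units to expected fragment size
#'
#' @param calib A [fit_calibration()] object.
#' @param repeat_units Integer vector of repeat counts.
#' @return Numeric vector of fragment sizes in bp.
#' @export
repeats_to_bp <- function(calib, repeat_units) {
  stopifnot(inherits(calib, "size_calibration"))
  calib$intercept_bp + calib$slope_bp_per_repeat * repeat_units
}
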