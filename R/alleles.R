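#' Construct an allele distribution
#'
#' An allele distribution is the repeat-unit-indexed weight vector at
#' the heart of every instability metric: weights are peak heights when
#' the distribution comes from a bulk trace, or molecule counts when it
#' comes from single-molecule small-pool PCR. The modal allele is the
#' repeat length with the largest weight; ties are broken toward the
#' smaller repeat, which is conservative against calling spurious
#' expansion.
#'
#' @param repeats Integer vector of repeat unit counts (distinct).
#' @param weights Non-negative numeric weights, same length.
#' @param locus Locus label.
#' @param extrapolated Logical vector flagging repeat lengths that were
#'   sized outside the calibration's accurate window. Default all FALSE.
#' @return An object of class `allele_distribution` with elements
#'   `locus`, `repeats`, `weights`, `extrapolated`, `modal_repeat`.
#' @export
allele_distribution <- function(repeats, weights, locus = "XDP",
                                extrapolated = NULL) {
  if (length(repeats) == 0L) stop("empty allele distribution")
  if (length(repeats) != length(weights)) {
    stop("`repeats` and `weights` must have the same length")
  }
  if (any(weights < 0)) stop("weights must be >= 0")
  if (anyDuplicated(repeats)) stop("`repeats` must be distinct; merge first")
  if (is.null(extrapolated)) extrapolated <- rep(FALSE, length(repeats))
  ord <- order(repeats)
  repeats <- as.integer(repeats[ord])
  weights <- as.numeric(weights[ord])
  extrapolated <- as.logical(extrapolated[ord])
  # modal = tallest; tie to smaller repeat (repeats sorted ascending)
  modal <- repeats[which.max(weights)]
  structure(
    list(
      locus = as.character(locus)[1L],
      repeats = repeats,
      weights = weights,
      extrapolated = extrapolated,
      modal_repeat = modal
    ),
    class = "allele_distribution"
  )
}

#' @export
print.allele_distribution <- function(x, ...) {
  cat(sprintf(
    "<allele_distribution> locus %s: %d repeat lengths (%d-%d), modal %d\n",
    x$locus, length(x$repeats), min(x$repeats), max(x$repeats), x$modal_repeat
  ))
  invisible(x)
}

#' Call an allele distribution from a peak table
#'
#' Bins each peak to the nearest integer repeat unit under the sizing
#' calibration and takes peak height as the bin weight. A repeat
#' amplification produces a ladder of fragments separated by one repeat
#' unit (6 bp for a hexamer), so after binning the modal allele is
#' simply the tallest bin. Peaks that bin to the same repeat unit have
#' their heights summed, with a warning.
#'
#' @param table A [peak_table()].
#' @param calib A [fit_calibration()] object.
#' @return An [allele_distribution()].
#' @export
call_distribution <- function(table, calib) {
  stopifnot(inherits(table, "peak_table"), inherits(calib, "size_calibration"))
  conv <- bp_to_repeats(calib, table$peaks$size_bp)
  units <- conv$repeat_units
  if (anyDuplicated(units)) {
    warning(sprintf(
      "sample %s: peaks binning to the same repeat unit merged (heights summed)",
      table$sample_id
    ), call. = FALSE)
  }
  w <- tapply(table$peaks$height, units, sum)
  ex <- tapply(conv$extrapolated, units, any)
  u <- as.integer(names(w))
  allele_distribution(
    repeats = u, weights = as.numeric(w),
    locus = table$locus, extrapolated = as.logical(ex)
  )
}

#' Split a two-allele (autosomal) distribution into per-allele halves
#'
#' Autosomal repeat loci usually show two allele clusters in one trace.
#' When the declared modal repeats are far enough apart the distribution
#' is cut at their midpoint and each half is indexed independently;
#' alleles closer than `min_separation` repeat units cannot be
#' attributed reliably and are refused.
#'
#' @param dist An [allele_distribution()].
#' @param modal1,modal2 Declared modal repeats of the two alleles.
#' @param min_separation Minimum allowed separation in repeat units.
#' @return A list of two [allele_distribution()] objects (shorter allele
#'   first).
#' @export
split_biallelic <- function(dist, modal1, modal2, min_separation = 4) {
  stopifnot(inherits(dist, "allele_distribution"))
  lo <- min(modal1, modal2)
  hi <- max(modal1, modal2)
  if (hi - lo < min_separation) {
    stop(sprintf(
      "alleles too close: modal repeats %d and %d are separated by < %d units",
      lo, hi, min_separation
    ))
  }
  cut <- (lo + hi) / 2
  left <- dist$repeats <= cut
  if (!any(left) || all(left)) stop("split leaves one allele empty")
  list(
    allele_distribution(dist$repeats[left], dist$weights[left],
                        dist$locus, dist$extrapolated[left]),
    allele_distribution(dist$repeats[!left], dist$weights[!left],
                        dist$locus, dist$extrapolated[!left])
  )
}
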