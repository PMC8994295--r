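#' Expansion, contraction and instability indices
#'
#' Quantifies bulk somatic instability from a fragment-analysis allele
#' distribution using a relative peak-height threshold. Peaks whose
#' height is below `threshold_fraction` of the modal peak height are
#' discarded (at the default 5% this removes baseline noise and most of
#' the PCR stutter shoulder); the retained heights are normalized to sum
#' to one, and each index is the normalized-height-weighted mean
#' repeat-unit distance from the modal allele on one side of it:
#'
#' \deqn{E = \sum_{\Delta > 0} w_\Delta \, \Delta, \qquad
#'       C = \sum_{\Delta < 0} w_\Delta \, |\Delta|}
#'
#' where \eqn{\Delta} is repeat length minus modal repeat length and
#' \eqn{w_\Delta} is the normalized weight. The normalization
#' denominator is the sum of all retained peaks, including the modal
#' peak and the contraction side. Only peaks longer than the modal
#' allele contribute to the expansion index, because peaks to the left
#' of the mode are dominated by PCR slippage rather than somatic
#' contraction. The instability index is the sum of both sides.
#'
#' @param dist An [allele_distribution()].
#' @param threshold_fraction Relative peak-height cut-off; a peak is
#'   retained iff its weight is at least this fraction of the modal
#'   weight. Default 0.05.
#' @param include_extrapolated Keep repeat lengths sized by
#'   extrapolation beyond the accurate calibration window? Default TRUE
#'   (they are real alleles, just less precisely sized).
#' @return An object of class `index_result`: a list with
#'   `expansion_index`, `contraction_index`, `instability_index`,
#'   `threshold_fraction`, `peaks_retained`, `modal_repeat`.
#' @examples
#' d <- allele_distribution(c(41, 42, 43), c(100, 60, 40))
#' expansion_index(d)$expansion_index # (60*1 + 40*2)/200 = 0.7
#' @export
expansion_index <- function(dist, threshold_fraction = 0.05,
                            include_extrapolated = TRUE) {
  stopifnot(inherits(dist, "allele_distribution"))
  if (threshold_fraction < 0) stop("`threshold_fraction` must be >= 0")
  repeats <- dist$repeats
  weights <- dist$weights
  if (!include_extrapolated) {
    keep_in <- !dist$extrapolated
    repeats <- repeats[keep_in]
    weights <- weights[keep_in]
    if (length(repeats) == 0L) stop("no peaks left after removing extrapolated bins")
  }
  modal_w <- max(weights)
  modal_repeat <- repeats[which.max(weights)]
  keep <- weights >= threshold_fraction * modal_w
  repeats <- repeats[keep]
  weights <- weights[keep]
  w <- weights / sum(weights)
  delta <- repeats - modal_repeat
  structure(
    list(
      expansion_index = sum(w[delta > 0] * delta[delta > 0]),
      contraction_index = sum(w[delta < 0] * abs(delta[delta < 0])),
      instability_index = sum(w * abs(delta)),
      threshold_fraction = threshold_fraction,
      peaks_retained = length(repeats),
      modal_repeat = modal_repeat
    ),
    class = "index_result"
  )
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf(
    "<index_result> modal %d: expansion %.3f, contraction %.3f (threshold %.0f%%, %d peaks)\n",
    x$modal_repeat, x$expansion_index, x$contraction_index,
    100 * x$threshold_fraction, x$peaks_retained
  ))
  invisible(x)
}

#' Summarize index spread across replicate PCRs
#'
#' Replicate amplifications of the same DNA gauge how much of the
#' between-tissue index spread could be technical. Returns the mean,
#' sample standard deviation and coefficient of variation of each index
#' across replicates.
#'
#' @param results List of `index_result` objects from replicate PCRs of
#'   the same sample (at least two).
#' @return A data frame with one row per index (`expansion_index`,
#'   `contraction_index`, `instability_index`) and columns `mean`, `sd`,
#'   `cv`.
#' @export
compare_replicates <- function(results) {
  if (length(results) < 2L) stop("at least two replicates are required")
  stopifnot(all(vapply(results, inherits, logical(1L), "index_result")))
  idx <- c("expansion_index", "contraction_index", "instability_index")
  out <- do.call(rbind, lapply(idx, function(nm) {
    v <- vapply(results, `[[`, numeric(1L), nm)
    m <- mean(v)
    s <- stats::sd(v)
    data.frame(index = nm, mean = m, sd = s,
               cv = if (m > 0) s / m else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
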