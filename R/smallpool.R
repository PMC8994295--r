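#' Small-pool PCR plate sets
#'
#' Single-molecule small-pool PCR (SP-PCR) dilutes genomic DNA until
#' individual template molecules are resolved in separate wells, so that
#' each positive well reports one allele length free of bulk-PCR
#' contraction bias. A plate set is a long-format well table:
#'
#' \describe{
#'   \item{plate_id}{plate label}
#'   \item{dilution_id}{dilution series member the plate belongs to}
#'   \item{well}{well label}
#'   \item{input_class}{one of `dna`, `no_dna_control`,
#'     `sizing_standard`, `machine_control`}
#'   \item{repeat_units}{called repeat length, `NA` for a negative well}
#'   \item{size_bp}{called fragment size, `NA` for a negative well}
#'   \item{height}{peak height of the call, `NA` for a negative well}
#' }
#'
#' @param wells Data frame with the columns above.
#' @param mean_molecules Optional named numeric: ground-truth mean
#'   amplifiable molecules per well for each dilution (available for
#'   simulated plates only).
#' @return The data frame with class `plate_set`.
#' @export
plate_set <- function(wells, mean_molecules = NULL) {
  required <- c("plate_id", "dilution_id", "well", "input_class",
                "repeat_units", "size_bp", "height")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0L) {
    stop("plate set lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ok <- c("dna", "no_dna_control", "sizing_standard", "machine_control")
  if (!all(wells$input_class %in% ok)) {
    stop("input_class must be one of: ", paste(ok, collapse = ", "))
  }
  structure(as.data.frame(wells),
            mean_molecules = mean_molecules,
            class = c("plate_set", "data.frame"))
}

#' Read a plate set from CSV
#'
#' Negative wells may be encoded as `"NEG"` or empty in the
#' `repeat_units`/`size_bp` columns.
#'
#' @param path CSV path with columns `plate_id, dilution_id, well,
#'   input_class, size_bp, height` and optionally `repeat_units`.
#' @param calib Optional [fit_calibration()] used to derive
#'   `repeat_units` from `size_bp` when absent.
#' @return A [plate_set()].
#' @export
read_plate_set <- function(path, calib = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("size_bp", "repeat_units", "height")) {
    if (col %in% names(raw)) {
      raw[[col]][raw[[col]] %in% c("NEG", "")] <- NA
      raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    }
  }
  if (!"repeat_units" %in% names(raw)) {
    raw$repeat_units <- NA_real_
    pos <- !is.na(raw$size_bp)
    if (any(pos)) {
      if (is.null(calib)) stop("`calib` required to size wells lacking repeat_units")
      raw$repeat_units[pos] <- bp_to_repeats(calib, raw$size_bp[pos])$repeat_units
    }
  }
  if (!"height" %in% names(raw)) raw$height <- NA_real_
  if (!"dilution_id" %in% names(raw)) raw$dilution_id <- raw$plate_id
  plate_set(raw)
}

#' Estimate mean amplifiable molecules per well by Poisson titration
#'
#' Under Poisson loading the fraction of product-negative wells equals
#' \eqn{e^{-\lambda}}, so the mean number of amplifiable molecules per
#' well is \eqn{\hat\lambda = -\log(n_0 / n)}. The confidence interval
#' is obtained by a Clopper-Pearson exact binomial interval on the
#' negative fraction, transformed through \eqn{-\log}.
#'
#' @param n_wells Number of DNA-input wells.
#' @param n_negative Number of those with no product.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `lambda_estimate`: `lambda_hat`, `ci_low`,
#'   `ci_high`, `n_wells`, `n_negative`, `too_concentrated`. When no
#'   well is negative the estimate is unbounded: `lambda_hat` is `NA`
#'   and `too_concentrated` is `TRUE`.
#' @examples
#' estimate_lambda(72, 24)$lambda_hat # -log(1/3) = 1.0986
#' @export
estimate_lambda <- function(n_wells, n_negative, conf_level = 0.95) {
  if (n_wells <= 0) stop("`n_wells` must be positive")
  if (n_negative < 0 || n_negative > n_wells) {
    stop("`n_negative` must lie in [0, n_wells]")
  }
  if (n_negative == 0L) {
    return(structure(
      list(lambda_hat = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           n_wells = n_wells, n_negative = 0L, too_concentrated = TRUE),
      class = "lambda_estimate"
    ))
  }
  ci_p <- stats::binom.test(n_negative, n_wells,
                            conf.level = conf_level)$conf.int
  structure(
    list(
      lambda_hat = -log(n_negative / n_wells),
      ci_low = -log(ci_p[2L]),   # upper p bound -> lower lambda bound
      ci_high = -log(ci_p[1L]),
      n_wells = as.integer(n_wells),
      n_negative = as.integer(n_negative),
      too_concentrated = FALSE
    ),
    class = "lambda_estimate"
  )
}

#' @export
print.lambda_estimate <- function(x, ...) {
  if (x$too_concentrated) {
    cat("<lambda_estimate> no negative wells: too concentrated for titration\n")
  } else {
    cat(sprintf(
      "<lambda_estimate> %.3f molecules/well [%.3f, %.3f] (%d/%d negative)\n",
      x$lambda_hat, x$ci_low, x$ci_high, x$n_negative, x$n_wells
    ))
  }
  invisible(x)
}

negative_fraction_by_dilution <- function(plates) {
  dna <- plates[plates$input_class == "dna", , drop = FALSE]
  if (nrow(dna) == 0L) stop("no DNA-input wells in plate set")
  neg <- tapply(is.na(dna$repeat_units), dna$dilution_id, mean)
  neg[order(names(neg))]
}

#' Select the single-molecule dilution from a titration series
#'
#' Single-molecule loading is targeted at about one third of DNA-input
#' wells giving no product (lambda near \eqn{\log 3 \approx 1.1}). The
#' dilution whose negative fraction is nearest `target` is chosen; ties
#' are broken toward the more dilute member (the one with the larger
#' negative fraction), which risks losing wells rather than loading two
#' molecules in one.
#'
#' @param plates A [plate_set()] spanning at least two dilutions.
#' @param target Target negative fraction, default 1/3.
#' @return The selected `dilution_id` (character scalar) with the
#'   per-dilution negative fractions attached as attribute
#'   `negative_fractions`.
#' @export
select_single_molecule_dilution <- function(plates, target = 1 / 3) {
  frac <- negative_fraction_by_dilution(plates)
  if (length(frac) < 2L) stop("at least two dilutions are required")
  if (all(frac == 0) || all(frac == 1)) {
    stop("titration failed: all dilutions fully positive or fully negative")
  }
  dev <- abs(frac - target)
  best <- which(dev == min(dev))
  if (length(best) > 1L) best <- best[which.max(frac[best])]
  structure(names(frac)[best], negative_fractions = frac)
}

#' Quality-control a single SP-PCR plate
#'
#' A plate passes when every no-DNA control well is negative, at least
#' `min_negative_fraction` of the DNA-input wells are negative (the
#' Poisson guarantee that positives are mostly single molecules), and
#' every sized well has peak height at least `min_height` RFU.
#' QC never throws; it reports.
#'
#' @param plate A [plate_set()] (or subset) holding one plate.
#' @param min_negative_fraction Minimum fraction of negative DNA wells.
#' @param min_height Minimum peak height of a sized well, RFU.
#' @return A list with `pass` (logical) and `reasons` (character vector
#'   among `"control_positive"`, `"too_concentrated"`,
#'   `"low_peak_height"`; empty when passing).
#' @export
qc_plate <- function(plate, min_negative_fraction = 1 / 3, min_height = 150) {
  reasons <- character(0L)
  ctrl <- plate[plate$input_class == "no_dna_control", , drop = FALSE]
  if (nrow(ctrl) > 0L && any(!is.na(ctrl$repeat_units))) {
    reasons <- c(reasons, "control_positive")
  }
  dna <- plate[plate$input_class == "dna", , drop = FALSE]
  if (nrow(dna) > 0L &&
      mean(is.na(dna$repeat_units)) < min_negative_fraction) {
    reasons <- c(reasons, "too_concentrated")
  }
  sized <- dna[!is.na(dna$repeat_units), , drop = FALSE]
  if (nrow(sized) > 0L && any(!is.na(sized$height) & sized$height < min_height)) {
    reasons <- c(reasons, "low_peak_height")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Classify sized single-molecule alleles against the modal allele
#'
#' Each sized DNA well is classified as contracted, modal or expanded by
#' the sign of its repeat length minus the modal reference, and binned
#' by magnitude (1-4 units, >= 5, >= 20 on each side; the magnitude bins
#' nest: every >= 20 event is also counted in >= 5).
#'
#' @param plates A [plate_set()].
#' @param modal_reference Reference modal repeat. Default `NULL` uses
#'   the SP-PCR modal: the most frequent sized length, tie broken to the
#'   smaller repeat.
#' @return An object of class `class_counts`: counts `n_contracted`,
#'   `n_modal`, `n_expanded`, `n_total`, `modal_reference`, and a `bins`
#'   data frame (`side`, `magnitude`, `count`).
#' @export
tabulate_alleles <- function(plates, modal_reference = NULL) {
  dna <- plates[plates$input_class == "dna", , drop = FALSE]
  sized <- dna$repeat_units[!is.na(dna$repeat_units)]
  if (length(sized) == 0L) stop("no sized wells to classify")
  if (is.null(modal_reference)) {
    tab <- table(sized)
    lens <- as.integer(names(tab))
    modal_reference <- min(lens[tab == max(tab)])
  }
  delta <- sized - modal_reference
  bins <- rbind(
    data.frame(side = "contraction", magnitude = "1-4",
               count = sum(delta <= -1 & delta >= -4)),
    data.frame(side = "contraction", magnitude = ">=5",
               count = sum(delta <= -5)),
    data.frame(side = "contraction", magnitude = ">=20",
               count = sum(delta <= -20)),
    data.frame(side = "expansion", magnitude = "1-4",
               count = sum(delta >= 1 & delta <= 4)),
    data.frame(side = "expansion", magnitude = ">=5",
               count = sum(delta >= 5)),
    data.frame(side = "expansion", magnitude = ">=20",
               count = sum(delta >= 20))
  )
  structure(
    list(
      n_contracted = sum(delta < 0),
      n_modal = sum(delta == 0),
      n_expanded = sum(delta > 0),
      n_total = length(delta),
      modal_reference = as.integer(modal_reference),
      bins = bins
    ),
    class = "class_counts"
  )
}

#' @export
print.class_counts <- function(x, ...) {
  cat(sprintf(
    "<class_counts> modal ref %d: %d contracted / %d modal / %d expanded of %d\n",
    x$modal_reference, x$n_contracted, x$n_modal, x$n_expanded, x$n_total
  ))
  invisible(x)
}

#' Compare allele class frequencies across tissues
#'
#' Pearson chi-square test (no continuity correction) on the R x 3
#' contingency table of (contracted, modal, expanded) counts across
#' tissues or samples; degrees of freedom are (R - 1) * 2. A warning is
#' issued when any expected cell count falls below 5.
#'
#' @param tables List of `class_counts` objects (at least two).
#' @param labels Optional row labels.
#' @return A list with `statistic`, `df`, `p_value`, `observed`,
#'   `expected`.
#' @export
compare_class_counts <- function(tables, labels = NULL) {
  if (length(tables) < 2L) stop("at least two class-count tables are required")
  m <- t(vapply(tables, function(x) {
    c(contracted = x$n_contracted, modal = x$n_modal, expanded = x$n_expanded)
  }, numeric(3L)))
  if (is.null(labels)) labels <- paste0("sample", seq_len(nrow(m)))
  rownames(m) <- labels
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero-margin row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("some expected cell counts are below 5; chi-square may be inaccurate",
            call. = FALSE)
  }
  list(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    observed = m,
    expected = ct$expected
  )
}

#' Per-sample summary of single-molecule sizing
#'
#' @param plates A [plate_set()] for one sample.
#' @param digits Decimal places for the mean repeat length.
#' @return A data frame row: `n_alleles`, `mean_repeat`, `modal_repeat`,
#'   `highest_repeat`, `lowest_repeat`.
#' @export
summarize_sample <- function(plates, digits = 1) {
  dna <- plates[plates$input_class == "dna", , drop = FALSE]
  sized <- dna$repeat_units[!is.na(dna$repeat_units)]
  if (length(sized) == 0L) stop("no sized wells to summarize")
  tab <- table(sized)
  lens <- as.integer(names(tab))
  data.frame(
    n_alleles = length(sized),
    mean_repeat = round(mean(sized), digits),
    modal_repeat = min(lens[tab == max(tab)]),
    highest_repeat = max(sized),
    lowest_repeat = min(sized)
  )
}
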