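#' Build a cohort index table from a simulated cohort
#'
#' Runs the full bulk pipeline over every individual x tissue: simulate
#' a trace from the ground-truth somatic distribution, call the allele
#' distribution under the calibration, and compute the threshold
#' expansion index. This is the table every cohort-level statistic
#' consumes; for real data assemble the same columns from
#' [read_peak_tables()] + [call_distribution()] + [expansion_index()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param stutter,calib Trace-generation models.
#' @param threshold_fraction Relative peak-height threshold.
#' @param locus Locus label for the output.
#' @return A data frame with columns `individual_id`, `tissue`, `locus`,
#'   `repeat_length`, `modal_repeat`, `expansion_index`,
#'   `contraction_index`, `instability_index`, `aao`, `aad`, `duration`.
#' @export
index_cohort <- function(cohort,
                         stutter = stutter_model(),
                         calib = default_calibration(),
                         threshold_fraction = 0.05,
                         locus = "XDP") {
  stopifnot(inherits(cohort, "sim_cohort"))
  out <- do.call(rbind, lapply(cohort, function(ind) {
    do.call(rbind, lapply(names(ind$tissue_distributions), function(ts) {
      pt <- simulate_trace(ind$tissue_distributions[[ts]], stutter, calib,
                           sample_id = ind$individual_id, locus = locus)
      res <- expansion_index(call_distribution(pt, calib),
                             threshold_fraction = threshold_fraction)
      data.frame(
        individual_id = ind$individual_id, tissue = ts, locus = locus,
        repeat_length = ind$inherited_repeat,
        modal_repeat = res$modal_repeat,
        expansion_index = res$expansion_index,
        contraction_index = res$contraction_index,
        instability_index = res$instability_index,
        aao = ind$aao, aad = ind$aad,
        duration = ind$aad - ind$aao
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Extract the per-individual phenotype table from a simulated cohort
#'
#' One row per individual with inherited repeat length, age at onset,
#' age at death and derived duration — the table used for
#' repeat-length/phenotype regressions when no instability measures are
#' needed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A data frame with columns `individual_id`, `repeat_length`,
#'   `aao`, `aad`, `duration`.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  out <- data.frame(
    individual_id = vapply(cohort, `[[`, character(1L), "individual_id"),
    repeat_length = vapply(cohort, `[[`, integer(1L), "inherited_repeat"),
    aao = vapply(cohort, `[[`, numeric(1L), "aao"),
    aad = vapply(cohort, `[[`, numeric(1L), "aad")
  )
  out$duration <- out$aad - out$aao
  out
}

regression_result <- function(fit, predictor, response) {
  s <- summary(fit)
  co <- s$coefficients
  structure(
    list(
      slope = co[2L, 1L], intercept = co[1L, 1L],
      slope_se = co[2L, 2L],
      r_squared = s$r.squared,
      p_value = co[2L, 4L],
      n = length(stats::residuals(fit)),
      predictor = predictor, response = response
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> %s ~ %s: slope %.3f (SE %.3f), R^2 %.3f, p %.3g, n %d\n",
    x$response, x$predictor, x$slope, x$slope_se, x$r_squared, x$p_value, x$n
  ))
  invisible(x)
}

#' Regress a phenotype on repeat length
#'
#' Ordinary least squares of age at onset, age at death, or disease
#' duration (death minus onset) on inherited repeat length. Rows with a
#' missing response are dropped with a message. The p-value reported is
#' the slope t-test (equivalent to the regression F-test with a single
#' predictor).
#'
#' @param cohort A cohort data frame as from [index_cohort()] (needs
#'   `repeat_length` and the response column; `duration` is derived
#'   from `aad - aao` if absent).
#' @param response One of `"aao"`, `"aad"`, `"duration"`, or any other
#'   numeric column (e.g. `"expansion_index"`).
#' @param tissue Optional tissue to restrict to. Default uses one row
#'   per individual (the first tissue present).
#' @return A `regression_result`.
#' @export
fit_length_phenotype <- function(cohort, response = c("aao", "aad", "duration"),
                                 tissue = NULL) {
  response <- response[1L]
  d <- as.data.frame(cohort)
  if (response == "duration" && !"duration" %in% names(d)) {
    d$duration <- d$aad - d$aao
  }
  if (!response %in% names(d)) stop(sprintf("no `%s` column", response))
  if (!is.null(tissue)) {
    d <- d[d$tissue == tissue, , drop = FALSE]
  } else if ("individual_id" %in% names(d)) {
    d <- d[!duplicated(d$individual_id), , drop = FALSE]
  }
  d <- d[!is.na(d[[response]]) & !is.na(d$repeat_length), , drop = FALSE]
  if (nrow(d) < 3L) stop("fewer than 3 complete rows")
  if (length(unique(d$repeat_length)) < 2L) {
    stop("constant predictor: repeat length does not vary")
  }
  fit <- stats::lm(d[[response]] ~ d$repeat_length)
  regression_result(fit, "repeat_length", response)
}

#' Correlate two variables, choosing Pearson or Spearman by normality
#'
#' Both variables are tested for normality (Shapiro-Wilk at
#' `alpha`); Pearson's r is used when both pass, Spearman's rho
#' otherwise. The method actually applied is part of the return value.
#'
#' @param x,y Numeric vectors, length >= 4.
#' @param alpha Normality-test significance level (default 0.05).
#' @return A list: `method` (`"pearson"` or `"spearman"`),
#'   `estimate`, `p_value`, `n`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("at least 4 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  normal <- stats::shapiro.test(x)$p.value > alpha &&
    stats::shapiro.test(y)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, n = length(x))
}

#' Pairwise tissue comparisons with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum tests of an instability measure between
#' every pair of tissues, with p-values multiplied by the number of
#' pairs tested (capped at 1). Tissues with fewer than two values are
#' skipped with a warning.
#'
#' @param cohort A cohort data frame with `tissue` and the `value`
#'   column.
#' @param value Column to compare; default `"expansion_index"`.
#' @return A symmetric matrix of Bonferroni-adjusted p-values (`NA` on
#'   the diagonal), with the raw p-values attached as attribute
#'   `raw_p`.
#' @export
pairwise_tissue_tests <- function(cohort, value = "expansion_index") {
  d <- as.data.frame(cohort)
  if (!value %in% names(d)) stop(sprintf("no `%s` column", value))
  d <- d[!is.na(d[[value]]), , drop = FALSE]
  sizes <- table(d$tissue)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("skipping tissue(s) with < 2 values: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- d[!d$tissue %in% small, , drop = FALSE]
  }
  tissues <- sort(unique(d$tissue))
  k <- length(tissues)
  if (k < 2L) stop("at least two tissues with >= 2 values are required")
  n_pairs <- k * (k - 1L) / 2L
  raw <- adj <- matrix(NA_real_, k, k, dimnames = list(tissues, tissues))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      p <- suppressWarnings(stats::wilcox.test(
        d[[value]][d$tissue == tissues[i]],
        d[[value]][d$tissue == tissues[j]],
        exact = FALSE
      ))$p.value
      raw[i, j] <- raw[j, i] <- p
      adj[i, j] <- adj[j, i] <- min(1, p * n_pairs)
    }
  }
  structure(adj, raw_p = raw)
}

#' Per-tissue regression of expansion index on repeat length
#'
#' @param cohort A cohort data frame as from [index_cohort()].
#' @param min_n Minimum rows per tissue; smaller tissues are skipped
#'   with a warning.
#' @return Named list of `regression_result`, one per retained tissue.
#' @export
index_length_regression_per_tissue <- function(cohort, min_n = 3L) {
  d <- as.data.frame(cohort)
  tissues <- sort(unique(d$tissue))
  out <- list()
  for (ts in tissues) {
    di <- d[d$tissue == ts & !is.na(d$expansion_index), , drop = FALSE]
    if (nrow(di) < min_n || length(unique(di$repeat_length)) < 2L) {
      warning(sprintf("tissue %s skipped (too few rows or constant length)", ts),
              call. = FALSE)
      next
    }
    out[[ts]] <- fit_length_phenotype(di, response = "expansion_index",
                                      tissue = ts)
  }
  out
}

#' Correlate per-tissue mean expansion indices of two loci
#'
#' Used to ask whether two different unstable repeats share
#' tissue-specific expansion propensities: each locus is reduced to a
#' named vector of per-tissue mean indices and the two vectors are
#' correlated (Pearson) across the shared tissues.
#'
#' @param means_a,means_b Named numeric vectors of per-tissue mean
#'   expansion indices; names are tissue labels.
#' @return A list: `r`, `p_value`, `n_shared`, `tissues`.
#' @export
cross_locus_correlation <- function(means_a, means_b) {
  shared <- intersect(names(means_a), names(means_b))
  if (length(shared) < 4L) {
    stop("fewer than 4 shared tissues between the two loci")
  }
  a <- means_a[shared]; b <- means_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = if (identical(unname(a), unname(b))) 1 else NA_real_,
                p_value = NA_real_, n_shared = length(shared),
                tissues = shared))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_shared = length(shared), tissues = shared)
}

#' Z-score heatmap matrix with Manhattan-distance clustering
#'
#' Builds the individuals x tissues matrix of an instability measure,
#' applies the sparsity exclusions (tissues measured in fewer than
#' `min_measures_per_tissue` individuals and individuals measured in
#' fewer than `min_tissues_per_individual` tissues are removed, to
#' avoid poorly normalized rows/columns), z-scores each tissue column
#' over its non-missing entries, and clusters rows and columns by
#' agglomerative clustering on Manhattan distance. Missing cells stay
#' missing in the scaled output; distances use pairwise-complete
#' entries rescaled by the fraction shared (the behaviour of
#' [stats::dist()]).
#'
#' @param cohort A cohort data frame as from [index_cohort()], or a
#'   numeric matrix (individuals x tissues) directly.
#' @param value Column to pivot when `cohort` is a data frame.
#' @param min_measures_per_tissue,min_tissues_per_individual Exclusion
#'   thresholds (defaults 12 and 6).
#' @param k Number of flat clusters to cut for rows and columns.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"average"`.
#' @return A list: `scaled` (matrix), `row_order`, `col_order`,
#'   `row_clusters`, `col_clusters`, `row_hclust`, `col_hclust`.
#' @export
heatmap_cluster <- function(cohort, value = "expansion_index",
                            min_measures_per_tissue = 12L,
                            min_tissues_per_individual = 6L,
                            k = 2L, linkage = "average") {
  if (is.matrix(cohort)) {
    m <- cohort
  } else {
    d <- as.data.frame(cohort)
    m <- tapply(d[[value]], list(d$individual_id, d$tissue), mean)
  }
  # sparsity exclusions, tissues first (as the display is per-tissue)
  m <- m[, colSums(!is.na(m)) >= min_measures_per_tissue, drop = FALSE]
  m <- m[rowSums(!is.na(m)) >= min_tissues_per_individual, , drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("matrix degenerate after sparsity exclusions")
  }
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  zero_sd <- !is.na(sds) & sds == 0
  all_na <- colSums(!is.na(m)) == 0L
  if (any(zero_sd | all_na)) {
    warning("dropping constant or all-missing column(s): ",
            paste(colnames(m)[zero_sd | all_na], collapse = ", "),
            call. = FALSE)
    m <- m[, !(zero_sd | all_na), drop = FALSE]
  }
  scaled <- scale(m)
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  row_h <- stats::hclust(stats::dist(scaled, method = "manhattan"),
                         method = linkage)
  col_h <- stats::hclust(stats::dist(t(scaled), method = "manhattan"),
                         method = linkage)
  list(
    scaled = scaled,
    row_order = row_h$order,
    col_order = col_h$order,
    row_clusters = stats::cutree(row_h, k = min(k, nrow(scaled))),
    col_clusters = stats::cutree(col_h, k = min(k, ncol(scaled))),
    row_hclust = row_h,
    col_hclust = col_h
  )
}
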