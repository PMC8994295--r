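#' Pipeline run configuration
#'
#' Gathers every tunable constant of an end-to-end run, each defaulted
#' to the value used throughout the package: 5% relative peak-height
#' threshold, one-third target negative fraction for single-molecule
#' titration, 150 RFU minimum sized-peak height, 72 DNA + 18 no-DNA
#' wells per plate, and the 12-measure / 6-tissue heatmap exclusions.
#'
#' @param seed Integer seed for the whole run.
#' @param threshold_fraction Relative peak-height threshold.
#' @param titration_target Target negative-well fraction.
#' @param min_peak_height Minimum height (RFU) for a sized well.
#' @param wells_per_plate,negative_controls_per_plate Plate layout.
#' @param min_measures_per_tissue,min_tissues_per_individual Heatmap
#'   exclusion thresholds.
#' @param cohort A [cohort_config()] (its seed is overridden by `seed`).
#' @param n_cells Cells per simulated tissue distribution.
#' @param plate_means Dilution series means for the single-molecule arm.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       threshold_fraction = 0.05,
                       titration_target = 1 / 3,
                       min_peak_height = 150,
                       wells_per_plate = 72L,
                       negative_controls_per_plate = 18L,
                       min_measures_per_tissue = 12L,
                       min_tissues_per_individual = 6L,
                       cohort = cohort_config(),
                       n_cells = 1000L,
                       plate_means = c(5, 1.1, 0.3)) {
  cohort$seed <- as.integer(seed)
  structure(
    list(
      seed = as.integer(seed),
      threshold_fraction = threshold_fraction,
      titration_target = titration_target,
      min_peak_height = min_peak_height,
      wells_per_plate = as.integer(wells_per_plate),
      negative_controls_per_plate = as.integer(negative_controls_per_plate),
      min_measures_per_tissue = as.integer(min_measures_per_tissue),
      min_tissues_per_individual = as.integer(min_tissues_per_individual),
      cohort = cohort,
      n_cells = as.integer(n_cells),
      plate_means = as.numeric(plate_means)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Any field omitted from the file keeps its [run_config()] default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  vals <- yaml::read_yaml(path)
  cohort_args <- vals$cohort
  vals$cohort <- NULL
  cfg <- do.call(run_config, vals)
  if (!is.null(cohort_args)) {
    cfg$cohort <- do.call(cohort_config, cohort_args)
    cfg$cohort$seed <- cfg$seed
  }
  cfg
}

#' Run the full simulate-size-index-SP-PCR-statistics pipeline
#'
#' Simulates a cohort, generates and sizes bulk traces, computes
#' expansion indices, runs a single-molecule dilution-series analysis
#' on the first individual's tissues, and produces cohort statistics
#' (phenotype regressions, per-tissue index-length regressions,
#' pairwise tissue tests and the clustered heatmap matrix). All outputs
#' are written as CSVs under `out_dir` along with a YAML manifest
#' recording the configuration, the seed and the row/well counts at
#' every stage. Deterministic given the seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param profiles Tissue panel; default [default_tissue_profiles()].
#' @return Invisibly, a list with the in-memory results
#'   (`indices`, `regressions`, `pairwise_p`, `heatmap`, `spcr`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         profiles = default_tissue_profiles()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calib <- default_calibration()
  stutter <- stutter_model()

  message("stage simulate: ", config$cohort$n_individuals, " individuals, ",
          length(profiles), " tissues")
  cohort <- simulate_cohort(config$cohort, profiles, n_cells = config$n_cells)

  message("stage index: sizing traces and computing indices")
  indices <- index_cohort(cohort, stutter, calib,
                          threshold_fraction = config$threshold_fraction)
  utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)

  message("stage spcr: single-molecule dilution series, individual 1")
  first <- cohort[[1L]]
  spcr <- lapply(names(first$tissue_distributions), function(ts) {
    series <- simulate_dilution_series(
      first$tissue_distributions[[ts]], config$plate_means,
      wells_per_dilution = config$wells_per_plate,
      n_negative_controls = config$negative_controls_per_plate,
      calib = calib
    )
    sel <- select_single_molecule_dilution(series,
                                           target = config$titration_target)
    plate <- series[series$dilution_id == as.character(sel), , drop = FALSE]
    qc <- qc_plate(plate, min_height = config$min_peak_height)
    dna <- plate[plate$input_class == "dna", , drop = FALSE]
    lam <- estimate_lambda(nrow(dna), sum(is.na(dna$repeat_units)))
    counts <- tabulate_alleles(plate)
    summary_row <- summarize_sample(plate)
    list(tissue = ts, dilution = as.character(sel), qc = qc,
         lambda = lam, counts = counts, summary = summary_row,
         wells_sized = counts$n_total)
  })
  names(spcr) <- names(first$tissue_distributions)
  spcr_summary <- do.call(rbind, lapply(spcr, function(x) {
    cbind(data.frame(tissue = x$tissue, dilution = x$dilution,
                     qc_pass = x$qc$pass,
                     lambda_hat = x$lambda$lambda_hat),
          x$summary)
  }))
  utils::write.csv(spcr_summary, file.path(out_dir, "spcr_summary.csv"),
                   row.names = FALSE)

  message("stage cohortstats: regressions, pairwise tests, clustering")
  regressions <- list(
    aao = fit_length_phenotype(indices, "aao"),
    duration = tryCatch(fit_length_phenotype(indices, "duration"),
                        error = function(e) NULL),
    per_tissue = suppressWarnings(index_length_regression_per_tissue(indices))
  )
  reg_df <- do.call(rbind, lapply(names(regressions$per_tissue), function(ts) {
    r <- regressions$per_tissue[[ts]]
    data.frame(tissue = ts, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, p_value = r$p_value, n = r$n)
  }))
  utils::write.csv(reg_df, file.path(out_dir, "index_length_regressions.csv"),
                   row.names = FALSE)
  pairwise_p <- suppressWarnings(pairwise_tissue_tests(indices))
  utils::write.csv(as.data.frame(unclass(pairwise_p)),
                   file.path(out_dir, "pairwise_tissue_p.csv"))
  hm <- tryCatch(
    heatmap_cluster(indices,
                    min_measures_per_tissue = config$min_measures_per_tissue,
                    min_tissues_per_individual = config$min_tissues_per_individual),
    error = function(e) NULL
  )
  if (!is.null(hm)) {
    utils::write.csv(as.data.frame(hm$scaled),
                     file.path(out_dir, "heatmap_scaled.csv"))
  }

  manifest <- list(
    seed = config$seed,
    config = rapply(unclass(config), unclass, how = "replace"),
    counts = list(
      individuals = length(cohort),
      tissues = length(profiles),
      traces_sized = nrow(indices),
      alleles_indexed = nrow(indices),
      spcr_tissues = length(spcr),
      spcr_wells_sized = sum(vapply(spcr, `[[`, numeric(1L), "wells_sized")),
      tissues_in_heatmap = if (is.null(hm)) 0L else ncol(hm$scaled)
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(indices = indices, regressions = regressions,
                 pairwise_p = pairwise_p, heatmap = hm, spcr = spcr,
                 manifest = manifest))
}
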