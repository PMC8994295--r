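#' Tissue-specific somatic instability profile
#'
#' The generative model of somatic mosaicism: within a tissue, each cell
#' carries the inherited allele plus a length change drawn from a
#' mixture of (i) a point mass at zero, (ii) a geometric expansion tail,
#' (iii) a geometric contraction tail, and (iv) a rare large-jump
#' component producing changes of 20 or more units. The per-cell
#' expansion probability scales linearly with how far the inherited
#' allele sits above a reference length, which is what makes longer
#' inherited repeats more unstable.
#'
#' @param tissue_name Tissue label.
#' @param expansion_rate_per_unit Expansion probability per repeat unit
#'   of inherited length above `reference_repeat` (see
#'   [simulate_somatic_distribution()]).
#' @param contraction_rate Per-cell probability of a contracted allele.
#' @param expansion_tail,contraction_tail Geometric decay parameters in
#'   (0, 1) for the magnitude of expansions/contractions:
#'   P(|delta| = k) is proportional to tail^(k-1), so mean magnitude is
#'   1/(1 - tail).
#' @param rare_large_event_rate Per-cell probability of a large jump
#'   (|delta| >= 20 units), the events that only single-molecule
#'   methods resolve.
#' @param block Optional anatomical block label (e.g. `"cortical"`,
#'   `"subcortical"`). Tissues sharing a block share a per-individual
#'   random instability factor in [simulate_cohort()], emulating the
#'   within-individual covariation of expansion across related brain
#'   regions that makes tissue blocks cluster together.
#' @return An object of class `tissue_profile`.
#' @export
tissue_profile <- function(tissue_name,
                           expansion_rate_per_unit,
                           contraction_rate,
                           expansion_tail = 0.6,
                           contraction_tail = 0.5,
                           rare_large_event_rate = 0.01,
                           block = NA_character_) {
  rates <- c(expansion_rate_per_unit, contraction_rate, rare_large_event_rate)
  if (any(rates < 0) || any(rates > 1)) stop("all rates must lie in [0, 1]")
  if (contraction_rate + rare_large_event_rate >= 1) {
    stop("contraction and rare-event rates together must leave room for stable cells")
  }
  tails <- c(expansion_tail, contraction_tail)
  if (any(tails <= 0) || any(tails >= 1)) stop("tail parameters must lie in (0, 1)")
  structure(
    list(
      tissue_name = as.character(tissue_name)[1L],
      expansion_rate_per_unit = expansion_rate_per_unit,
      contraction_rate = contraction_rate,
      expansion_tail = expansion_tail,
      contraction_tail = contraction_tail,
      rare_large_event_rate = rare_large_event_rate,
      block = as.character(block)[1L]
    ),
    class = "tissue_profile"
  )
}

#' Default tissue panel
#'
#' Seven tissues with expansion propensities ordered blood < cerebellum
#' < caudate < putamen < hippocampus < cingulate gyrus < occipital
#' cortex, mirroring the rank order of median expansion indices seen in
#' patient material (blood lowest, cerebellum the most stable brain
#' region, occipital cortex the least).
#'
#' @return Named list of [tissue_profile()] objects.
#' @export
default_tissue_profiles <- function() {
  p <- list(
    tissue_profile("blood", 0.004, 0.05,
                   rare_large_event_rate = 0.001, block = "blood"),
    tissue_profile("cerebellum", 0.013, 0.18, block = "subcortical"),
    tissue_profile("caudate", 0.0155, 0.18, block = "subcortical"),
    tissue_profile("putamen", 0.017, 0.18, block = "subcortical"),
    tissue_profile("hippocampus", 0.0185, 0.18, block = "subcortical"),
    tissue_profile("cingulate_gyrus", 0.021, 0.18, block = "cortical"),
    tissue_profile("occipital_cortex", 0.024, 0.18, block = "cortical")
  )
  stats::setNames(p, vapply(p, `[[`, character(1L), "tissue_name"))
}

#' PCR stutter model
#'
#' Slippage during amplification of a pure tandem repeat yields a ladder
#' of minor peaks flanking each template allele, decaying geometrically
#' with distance and much stronger on the minus (shorter) side. Shorter
#' templates also amplify slightly more efficiently, producing the
#' contraction bias inherent to bulk PCR of repeats.
#'
#' @param minus_stutter_rate Per-unit geometric decay of the slippage
#'   shoulder below the template allele (height of the -k peak relative
#'   to the template is `minus_stutter_rate^k`). In [0, 1).
#' @param plus_stutter_rate Same above the template.
#' @param short_allele_amplification_bias Multiplicative amplification
#'   efficiency gain per repeat unit shorter; >= 1 (1 = no bias).
#' @return An object of class `stutter_model`.
#' @export
stutter_model <- function(minus_stutter_rate = 0.2,
                          plus_stutter_rate = 0.04,
                          short_allele_amplification_bias = 1.02) {
  if (minus_stutter_rate < 0 || minus_stutter_rate >= 1 ||
      plus_stutter_rate < 0 || plus_stutter_rate >= 1) {
    stop("stutter rates must lie in [0, 1)")
  }
  if (short_allele_amplification_bias < 1) {
    stop("`short_allele_amplification_bias` must be >= 1 (shorter amplifies better)")
  }
  structure(
    list(
      minus_stutter_rate = minus_stutter_rate,
      plus_stutter_rate = plus_stutter_rate,
      short_allele_amplification_bias = short_allele_amplification_bias
    ),
    class = "stutter_model"
  )
}

#' Default sizing calibration for simulation
#'
#' The 6 bp/repeat line through the 37/44/50-repeat sizing standards
#' with a 138 bp constant (flanking) length, which places the accurate
#' sizing window of 330-560 bp at about 32-70 repeats.
#'
#' @return A [fit_calibration()] object.
#' @export
default_calibration <- function() {
  fit_calibration(data.frame(
    repeat_units = c(37, 44, 50),
    size_bp = 138 + 6 * c(37, 44, 50)
  ))
}

#' Cohort generator configuration
#'
#' Encodes the study-level ground truth: cohort size, the inverse
#' linear repeat-length to age-at-onset relation, its residual noise,
#' and the inherited repeat-length distribution. With the defaults
#' (slope -1.4 y/unit, residual SD 6 y, repeat SD ~3.9 units) repeat
#' length explains about 45% of onset-age variance, and disease
#' duration is drawn independently of repeat length.
#'
#' @param n_individuals Cohort size (default 266).
#' @param aao_intercept,aao_slope Linear model of age at onset (years)
#'   on inherited repeat length; the slope must be negative.
#' @param aao_noise_sd Residual SD of onset age in years (>= 0).
#' @param repeat_range Inclusive inherited repeat-length range.
#' @param repeat_mean,repeat_sd Mean/SD of the (discretized normal)
#'   inherited repeat-length distribution before clamping to
#'   `repeat_range`.
#' @param min_aao Floor on simulated onset age, years.
#' @param duration_mean,duration_sd Disease duration (years), drawn
#'   independently of repeat length; age at death = onset + duration.
#' @param aad_fraction Fraction of individuals with a recorded age at
#'   death.
#' @param block_sd SD of the per-individual log-normal instability
#'   factor shared by tissues of the same anatomical block (0 disables
#'   it). This is what gives tissues of a block correlated expansion
#'   across individuals.
#' @param seed Integer seed, recorded in the output.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 266,
                          aao_intercept = 100,
                          aao_slope = -1.4,
                          aao_noise_sd = 6,
                          repeat_range = c(30, 55),
                          repeat_mean = 42,
                          repeat_sd = 3.9,
                          min_aao = 12,
                          duration_mean = 9,
                          duration_sd = 4,
                          aad_fraction = 0.25,
                          block_sd = 0.3,
                          seed = 1L) {
  if (n_individuals <= 0) stop("`n_individuals` must be positive")
  if (aao_slope >= 0) stop("`aao_slope` must be negative (longer repeat, earlier onset)")
  if (aao_noise_sd < 0) stop("`aao_noise_sd` must be >= 0")
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      aao_intercept = aao_intercept, aao_slope = aao_slope,
      aao_noise_sd = aao_noise_sd,
      repeat_range = as.integer(repeat_range),
      repeat_mean = repeat_mean, repeat_sd = repeat_sd,
      min_aao = min_aao,
      duration_mean = duration_mean, duration_sd = duration_sd,
      aad_fraction = aad_fraction,
      block_sd = block_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a somatic allele distribution for one tissue
#'
#' Draws `n_cells` per-cell length changes under a [tissue_profile()].
#' The per-cell expansion probability is
#' `expansion_rate_per_unit * (inherited - reference_repeat)`, clamped
#' to zero (with a warning) when the inherited allele is below the
#' reference; contraction and rare-jump probabilities are
#' length-independent. Expansion and contraction magnitudes are
#' geometric (1 + Geom); rare jumps are expansions with probability
#' 0.75, of magnitude 20 + Geom(0.08) units when expanding (reaching
#' beyond 100 units) and 20 + Geom(0.3) when contracting.
#'
#' @param inherited Inherited repeat length, units.
#' @param profile A [tissue_profile()].
#' @param n_cells Number of cells (molecules) to draw.
#' @param seed Optional integer seed.
#' @param reference_repeat Length at which expansion propensity reaches
#'   zero; default 30, the bottom of the disease-allele range.
#' @param expansion_scale Multiplier on the expansion probability
#'   (default 1); used by [simulate_cohort()] to apply per-individual
#'   block instability factors. The effective probability is capped so
#'   the total change probability never exceeds 1.
#' @return An [allele_distribution()] whose weights are molecule counts
#'   summing to `n_cells`.
#' @export
simulate_somatic_distribution <- function(inherited, profile, n_cells,
                                          seed = NULL,
                                          reference_repeat = 30,
                                          expansion_scale = 1) {
  stopifnot(inherits(profile, "tissue_profile"))
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p_exp <- profile$expansion_rate_per_unit * (inherited - reference_repeat) *
    expansion_scale
  if (p_exp < 0) {
    warning("inherited length below reference; expansion probability clamped to 0",
            call. = FALSE)
    p_exp <- 0
  }
  p_con <- profile$contraction_rate
  p_rare <- profile$rare_large_event_rate
  p_exp <- min(p_exp, 1 - p_con - p_rare)  # probability-mass cap
  p0 <- max(0, 1 - p_exp - p_con - p_rare)
  cls <- sample.int(4L, n_cells, replace = TRUE,
                    prob = c(p0, p_exp, p_con, p_rare))
  delta <- integer(n_cells)
  n_e <- sum(cls == 2L); n_c <- sum(cls == 3L); n_r <- sum(cls == 4L)
  if (n_e > 0L) {
    delta[cls == 2L] <- 1L + stats::rgeom(n_e, prob = 1 - profile$expansion_tail)
  }
  if (n_c > 0L) {
    delta[cls == 3L] <- -(1L + stats::rgeom(n_c, prob = 1 - profile$contraction_tail))
  }
  if (n_r > 0L) {
    # large jumps are mostly expansions and expansions reach much further
    # (tens to >100 units) than large contractions (~20-30 units)
    sgn <- ifelse(stats::runif(n_r) < 0.75, 1L, -1L)
    mag <- ifelse(sgn > 0L,
                  20L + stats::rgeom(n_r, prob = 0.08),
                  20L + stats::rgeom(n_r, prob = 0.3))
    delta[cls == 4L] <- sgn * mag
  }
  lengths <- pmax(inherited + delta, 1L)
  tab <- table(lengths)
  allele_distribution(
    repeats = as.integer(names(tab)),
    weights = as.integer(tab)
  )
}

#' Simulate a bulk fragment-analysis trace
#'
#' Convolves a ground-truth allele distribution with a PCR stutter
#' ladder and amplification bias, maps repeat units to fragment sizes
#' through the calibration, and applies multiplicative log-normal
#' height jitter. Every true allele contributes a geometric stutter
#' ladder on both sides; contributions are summed across alleles, so
#' adjacent single-unit peaks sit exactly one repeat unit (6 bp for a
#' hexamer) apart.
#'
#' @param dist Ground-truth [allele_distribution()].
#' @param stutter A [stutter_model()].
#' @param calib A [fit_calibration()] object.
#' @param seed Optional integer seed.
#' @param modal_height Height of the tallest peak before jitter, RFU.
#' @param height_cv Coefficient of variation of the multiplicative
#'   log-normal height jitter (0 disables it).
#' @param min_height Detection floor in RFU; peaks below it are not
#'   reported, as in real peak-caller output.
#' @param sample_id,locus Labels for the output table.
#' @return A [peak_table()].
#' @export
simulate_trace <- function(dist, stutter = stutter_model(),
                           calib = default_calibration(),
                           seed = NULL,
                           modal_height = 4000, height_cv = 0.1,
                           min_height = 20,
                           sample_id = "sim", locus = dist$locus) {
  stopifnot(inherits(dist, "allele_distribution"),
            inherits(stutter, "stutter_model"),
            inherits(calib, "size_calibration"))
  if (!is.null(seed)) set.seed(seed)
  # stutter ladder extent: stop once relative contribution < 1e-4
  k_minus <- if (stutter$minus_stutter_rate > 0) {
    max(1L, ceiling(log(1e-4) / log(stutter$minus_stutter_rate)))
  } else 0L
  k_plus <- if (stutter$plus_stutter_rate > 0) {
    max(1L, ceiling(log(1e-4) / log(stutter$plus_stutter_rate)))
  } else 0L

  grid <- seq(max(1L, min(dist$repeats) - k_minus), max(dist$repeats) + k_plus)
  h <- numeric(length(grid))
  names(h) <- grid
  ref <- dist$modal_repeat
  for (i in seq_along(dist$repeats)) {
    r <- dist$repeats[i]
    eff <- stutter$short_allele_amplification_bias^(ref - r)
    base <- dist$weights[i] * eff
    h[as.character(r)] <- h[as.character(r)] + base
    if (k_minus > 0L) {
      ks <- seq_len(k_minus)
      tgt <- r - ks
      keep <- tgt >= grid[1L]
      h[as.character(tgt[keep])] <- h[as.character(tgt[keep])] +
        base * stutter$minus_stutter_rate^(ks[keep])
    }
    if (k_plus > 0L) {
      ks <- seq_len(k_plus)
      tgt <- r + ks
      h[as.character(tgt)] <- h[as.character(tgt)] +
        base * stutter$plus_stutter_rate^ks
    }
  }
  h <- h * (modal_height / max(h))
  if (height_cv > 0) {
    sdlog <- sqrt(log(1 + height_cv^2))
    h <- h * stats::rlnorm(length(h), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  keep <- h >= min_height
  if (!any(keep)) stop("no peaks above the detection floor")
  units <- as.integer(grid[keep])
  peak_table(
    sample_id = sample_id, locus = locus,
    size_bp = repeats_to_bp(calib, units),
    height = h[keep]
  )
}

#' Simulate a small-pool PCR dilution series
#'
#' One 96-well plate per requested dilution: `wells_per_dilution` DNA
#' wells, `n_negative_controls` no-DNA controls, three sizing-standard
#' wells and one machine-control well. Molecules per DNA well are
#' Poisson with the dilution's mean; a well with zero molecules is
#' negative, and a well with two or more molecules reports the shortest
#' allele drawn (shorter templates out-compete longer ones during
#' amplification; the other molecules are lost — a documented
#' simplification that real SP-PCR cannot avoid either).
#'
#' @param dist Ground-truth [allele_distribution()] to draw molecules
#'   from.
#' @param mean_molecules Numeric vector of mean amplifiable molecules
#'   per well, one per dilution (most to least concentrated in any
#'   order; each > 0).
#' @param wells_per_dilution DNA-input wells per plate (default 72).
#' @param n_negative_controls No-DNA control wells per plate (default 18).
#' @param seed Optional integer seed.
#' @param calib Calibration used to report fragment sizes.
#' @return A [plate_set()] with ground-truth `mean_molecules` attached.
#' @export
simulate_dilution_series <- function(dist, mean_molecules,
                                     wells_per_dilution = 72,
                                     n_negative_controls = 18,
                                     seed = NULL,
                                     calib = default_calibration()) {
  stopifnot(inherits(dist, "allele_distribution"))
  if (length(mean_molecules) == 0L) stop("at least one dilution mean is required")
  if (any(mean_molecules <= 0)) stop("dilution means must be > 0")
  if (wells_per_dilution < 1) stop("at least one DNA well per dilution is required")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (d in seq_along(mean_molecules)) {
    lam <- mean_molecules[d]
    did <- sprintf("d%02d", d)
    n_mol <- stats::rpois(wells_per_dilution, lam)
    call <- rep(NA_integer_, wells_per_dilution)
    for (w in which(n_mol > 0L)) {
      mols <- sample(dist$repeats, n_mol[w], replace = TRUE,
                     prob = dist$weights)
      call[w] <- min(mols)
    }
    height <- ifelse(is.na(call), NA_real_,
                     stats::rlnorm(wells_per_dilution,
                                   meanlog = log(2500), sdlog = 0.3))
    dna <- data.frame(
      plate_id = did, dilution_id = did,
      well = sprintf("%s%02d", rep(LETTERS[1:8], length.out = wells_per_dilution),
                     seq_len(wells_per_dilution)),
      input_class = "dna",
      repeat_units = call,
      size_bp = ifelse(is.na(call), NA_real_,
                       repeats_to_bp(calib, ifelse(is.na(call), 0L, call))),
      height = height
    )
    ctrl <- data.frame(
      plate_id = did, dilution_id = did,
      well = sprintf("N%02d", seq_len(n_negative_controls)),
      input_class = "no_dna_control",
      repeat_units = NA_integer_, size_bp = NA_real_, height = NA_real_
    )
    std_units <- calib$standards$repeat_units
    std <- data.frame(
      plate_id = did, dilution_id = did,
      well = sprintf("S%02d", seq_along(std_units)),
      input_class = "sizing_standard",
      repeat_units = std_units,
      size_bp = repeats_to_bp(calib, std_units),
      height = 4000
    )
    mc <- data.frame(
      plate_id = did, dilution_id = did, well = "M01",
      input_class = "machine_control",
      repeat_units = NA_integer_, size_bp = NA_real_, height = NA_real_
    )
    rows[[d]] <- rbind(dna, ctrl, std, mc)
  }
  plate_set(
    do.call(rbind, rows),
    mean_molecules = stats::setNames(mean_molecules,
                                     sprintf("d%02d", seq_along(mean_molecules)))
  )
}

#' Simulate a patient cohort with ground-truth somatic distributions
#'
#' Draws inherited repeat lengths from a discretized normal clamped to
#' the configured range, ages at onset from the inverse linear model
#' `aao_intercept + aao_slope * repeat + N(0, aao_noise_sd)` floored at
#' `min_aao`, disease durations independently of repeat length, and one
#' ground-truth somatic allele distribution per tissue profile.
#'
#' @param config A [cohort_config()].
#' @param profiles List of [tissue_profile()] objects (at least one),
#'   e.g. [default_tissue_profiles()].
#' @param n_cells Cells per tissue distribution (default 1000).
#' @return A list of individuals (class `sim_cohort`); each individual
#'   is a list with `individual_id`, `inherited_repeat`, `aao`, `aad`
#'   (possibly `NA`) and `tissue_distributions` (named list of
#'   [allele_distribution()]).
#' @export
simulate_cohort <- function(config, profiles = default_tissue_profiles(),
                            n_cells = 1000) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(profiles) == 0L) stop("at least one tissue profile is required")
  stopifnot(all(vapply(profiles, inherits, logical(1L), "tissue_profile")))
  set.seed(config$seed)
  n <- config$n_individuals
  inherited <- as.integer(pmin(pmax(
    round(stats::rnorm(n, config$repeat_mean, config$repeat_sd)),
    config$repeat_range[1L]), config$repeat_range[2L]))
  aao <- pmax(
    config$aao_intercept + config$aao_slope * inherited +
      stats::rnorm(n, 0, config$aao_noise_sd),
    config$min_aao
  )
  duration <- pmax(stats::rnorm(n, config$duration_mean, config$duration_sd), 0.5)
  aad <- ifelse(stats::runif(n) < config$aad_fraction, aao + duration, NA_real_)
  tissue_names <- vapply(profiles, `[[`, character(1L), "tissue_name")
  blocks <- vapply(profiles, `[[`, character(1L), "block")
  block_levels <- unique(blocks[!is.na(blocks)])
  cohort <- lapply(seq_len(n), function(i) {
    bf <- if (config$block_sd > 0 && length(block_levels) > 0L) {
      stats::setNames(
        stats::rlnorm(length(block_levels),
                      meanlog = -config$block_sd^2 / 2,
                      sdlog = config$block_sd),
        block_levels
      )
    } else {
      stats::setNames(numeric(0L), character(0L))
    }
    dists <- lapply(profiles, function(p) {
      scale <- if (!is.na(p$block) && p$block %in% names(bf)) bf[[p$block]] else 1
      simulate_somatic_distribution(inherited[i], p, n_cells,
                                    expansion_scale = scale)
    })
    names(dists) <- tissue_names
    list(
      individual_id = sprintf("sim-%03d", i),
      inherited_repeat = inherited[i],
      aao = aao[i],
      aad = aad[i],
      tissue_distributions = dists
    )
  })
  structure(cohort, class = "sim_cohort", seed = config$seed, config = config)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d individuals x %d tissues (seed %d)\n",
    length(x), length(x[[1L]]$tissue_distributions), attr(x, "seed")
  ))
  invisible(x)
}

#' Write simulated data as plain-text fixtures
#'
#' Emits the CSV dialects the readers of this package consume — a peak
#' table (`peaks.csv`), a cohort table (`cohort.csv`), a
#' single-molecule plate table for the first individual's tissues
#' (`plates.csv`) — plus a `ground_truth.yaml` sidecar recording every
#' generator parameter and the seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param stutter,calib Trace-generation models.
#' @param plate_means Dilution means used for `plates.csv`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixtures <- function(cohort, dir,
                           stutter = stutter_model(),
                           calib = default_calibration(),
                           plate_means = c(5, 1.1, 0.3)) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- attr(cohort, "config")
  set.seed(config$seed + 1L)

  peaks <- do.call(rbind, lapply(cohort, function(ind) {
    do.call(rbind, lapply(names(ind$tissue_distributions), function(ts) {
      pt <- simulate_trace(ind$tissue_distributions[[ts]], stutter, calib,
                           sample_id = paste(ind$individual_id, ts, sep = "."))
      data.frame(sample_id = pt$sample_id, locus = pt$locus,
                 size_bp = pt$peaks$size_bp, height = pt$peaks$height)
    }))
  }))
  cohort_df <- do.call(rbind, lapply(cohort, function(ind) {
    data.frame(
      individual_id = ind$individual_id,
      tissue = names(ind$tissue_distributions),
      repeat_length = ind$inherited_repeat,
      aao = ind$aao, aad = ind$aad
    )
  }))
  plates <- do.call(rbind, lapply(
    names(cohort[[1L]]$tissue_distributions),
    function(ts) {
      ps <- simulate_dilution_series(cohort[[1L]]$tissue_distributions[[ts]],
                                     plate_means, calib = calib)
      ps$plate_id <- paste(ts, ps$plate_id, sep = ".")
      as.data.frame(ps)
    }
  ))

  paths <- file.path(dir, c("peaks.csv", "cohort.csv", "plates.csv",
                            "ground_truth.yaml"))
  utils::write.csv(peaks, paths[1L], row.names = FALSE)
  utils::write.csv(cohort_df, paths[2L], row.names = FALSE)
  utils::write.csv(plates, paths[3L], row.names = FALSE)
  yaml::write_yaml(
    list(
      seed = config$seed,
      cohort_config = unclass(config),
      stutter_model = unclass(stutter),
      calibration = list(slope_bp_per_repeat = calib$slope_bp_per_repeat,
                         intercept_bp = calib$intercept_bp),
      plate_means = as.numeric(plate_means),
      inherited_repeats = stats::setNames(
        vapply(cohort, `[[`, integer(1L), "inherited_repeat"),
        vapply(cohort, `[[`, character(1L), "individual_id")
      )
    ),
    paths[4L]
  )
  invisible(paths)
}
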