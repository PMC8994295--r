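test_that("profile and config constructors validate their invariants", {
  expect_error(tissue_profile("x", 1.2, 0.1), "rates")
  expect_error(tissue_profile("x", 0.02, 0.1, expansion_tail = 1), "tail")
  expect_error(tissue_profile("x", 0.02, 0.9, rare_large_event_rate = 0.2),
               "room for stable cells")
  expect_error(cohort_config(aao_slope = 0.5), "negative")
  expect_error(cohort_config(n_individuals = 0), "positive")
  expect_error(stutter_model(short_allele_amplification_bias = 0.9), ">= 1")
})

test_that("somatic distributions conserve cells and honour degenerate profiles", {
  quiet <- tissue_profile("quiet", 0, 0, rare_large_event_rate = 0)
  d <- simulate_somatic_distribution(42, quiet, 500, seed = 1)
  expect_equal(d$repeats, 42L)
  expect_equal(d$weights, 500)

  active <- tissue_profile("active", 0.02, 0.15)
  for (s in 1:5) {
    d <- simulate_somatic_distribution(45, active, 1234, seed = s)
    expect_equal(sum(d$weights), 1234)
  }

  # inherited below the reference: expansion clamped to zero with a warning
  # (rare jumps disabled so only contractions remain possible)
  no_rare <- tissue_profile("nr", 0.02, 0.15, rare_large_event_rate = 0)
  expect_warning(
    d0 <- simulate_somatic_distribution(25, no_rare, 400, seed = 2),
    "clamped"
  )
  expect_true(all(d0$repeats <= 25))

  expect_error(simulate_somatic_distribution(42, active, 0), ">= 1")
})

test_that("expansion-biased profiles shift the mean upward", {
  biased <- tissue_profile("b", 0.03, 0.05)
  d <- simulate_somatic_distribution(45, biased, 2e5, seed = 3)
  expect_gt(sum(d$repeats * d$weights) / sum(d$weights), 45)
})

test_that("rare large jumps occur at the configured binomial rate", {
  p <- tissue_profile("r", 0, 0, rare_large_event_rate = 0.01)
  d <- simulate_somatic_distribution(42, p, 1e4, seed = 4)
  n_large <- sum(d$weights[abs(d$repeats - 42L) >= 20L])
  ci <- qbinom(c(0.005, 0.995), 1e4, 0.01)
  expect_gte(n_large, ci[1])
  expect_lte(n_large, ci[2])
})

test_that("traces carry geometric stutter ladders on a 6 bp comb", {
  cal <- default_calibration()
  point <- allele_distribution(45, 1000)

  # no stutter, no jitter: a single clean peak
  pt0 <- simulate_trace(point, stutter_model(0, 0), cal, height_cv = 0)
  expect_equal(nrow(pt0$peaks), 1L)
  expect_equal(pt0$peaks$size_bp, repeats_to_bp(cal, 45))

  # minus stutter 0.2: heights at -1, -2 are 0.2 and 0.04 of the modal
  pt1 <- simulate_trace(point, stutter_model(0.2, 0), cal,
                        height_cv = 0, min_height = 1)
  h <- pt1$peaks$height
  modal_i <- which.max(h)
  expect_equal(h[modal_i - 1] / h[modal_i], 0.2, tolerance = 1e-9)
  expect_equal(h[modal_i - 2] / h[modal_i], 0.04, tolerance = 1e-9)

  # any trace: inter-peak spacings are multiples of 6 bp
  set.seed(5)
  for (i in 1:10) {
    d <- simulate_somatic_distribution(44, tissue_profile("t", 0.02, 0.15), 800)
    pt <- simulate_trace(d, stutter_model(), cal)
    gaps <- diff(sort(pt$peaks$size_bp))
    expect_true(all(abs(gaps / 6 - round(gaps / 6)) < 1e-9))
  }

  expect_error(simulate_trace(point, stutter_model(), cal, min_height = 1e9),
               "no peaks")
})

test_that("dilution series are Poisson-faithful and controls stay negative", {
  d <- allele_distribution(c(41, 42), c(900, 100))
  lambdas <- c(0.3, log(3), 3)
  series <- simulate_dilution_series(d, lambdas, wells_per_dilution = 2000,
                                     seed = 6)
  dna <- series[series$input_class == "dna", ]
  for (i in seq_along(lambdas)) {
    frac <- mean(is.na(dna$repeat_units[dna$dilution_id == sprintf("d%02d", i)]))
    p0 <- exp(-lambdas[i])
    se <- sqrt(p0 * (1 - p0) / 2000)
    expect_lt(abs(frac - p0), 3 * se)
  }
  ctrl <- series[series$input_class == "no_dna_control", ]
  expect_true(all(is.na(ctrl$repeat_units)))
  # requested layout: 2000 dna + 18 controls + 3 standards + 1 machine per dilution
  expect_equal(nrow(series), 3 * (2000 + 18 + 3 + 1))

  expect_error(simulate_dilution_series(d, numeric(0)), "at least one")
  expect_error(simulate_dilution_series(d, 1, wells_per_dilution = 0),
               "at least one DNA well")
})

test_that("generators are deterministic given the seed", {
  prof <- default_tissue_profiles()[c("cerebellum", "occipital_cortex")]
  cfg <- cohort_config(n_individuals = 4, seed = 7)
  c1 <- simulate_cohort(cfg, prof, n_cells = 200)
  c2 <- simulate_cohort(cfg, prof, n_cells = 200)
  expect_identical(c1[[3]], c2[[3]])

  d <- c1[[1]]$tissue_distributions$cerebellum
  s1 <- simulate_dilution_series(d, c(1.1, 0.4), seed = 8)
  s2 <- simulate_dilution_series(d, c(1.1, 0.4), seed = 8)
  expect_identical(s1, s2)

  # fixture files are byte-identical for the same seed
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_fixtures(c1, dir1, plate_means = c(1.1, 0.4))
  write_fixtures(c1, dir2, plate_means = c(1.1, 0.4))
  for (f in c("peaks.csv", "cohort.csv", "plates.csv", "ground_truth.yaml")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("cohort AAO follows the linear model and its zero-noise limit", {
  # zero-noise limit: AAO is exactly intercept + slope * repeat
  cfg0 <- cohort_config(n_individuals = 50, aao_intercept = 100,
                        aao_slope = -1.4, aao_noise_sd = 0,
                        repeat_mean = 40, repeat_sd = 0, seed = 9)
  co <- simulate_cohort(cfg0, minimal_profile(), n_cells = 2)
  expect_true(all(vapply(co, `[[`, numeric(1), "aao") == 44.0))

  # onset never below the configured floor
  cfg_low <- cohort_config(n_individuals = 200, aao_intercept = 60,
                           aao_slope = -1.4, aao_noise_sd = 10, seed = 10)
  co_low <- simulate_cohort(cfg_low, minimal_profile(), n_cells = 2)
  expect_gte(min(vapply(co_low, `[[`, numeric(1), "aao")), 12)

  # death, when present, is after onset
  co_def <- simulate_cohort(cohort_config(n_individuals = 100, seed = 11),
                            minimal_profile(), n_cells = 2)
  aad <- vapply(co_def, `[[`, numeric(1), "aad")
  aao <- vapply(co_def, `[[`, numeric(1), "aao")
  expect_true(all(is.na(aad) | aad > aao))

  expect_error(simulate_cohort(cohort_config(n_individuals = 3), list()),
               "at least one")
})

test_that("default generator yields about 45% of onset variance explained", {
  r2 <- vapply(1:60, function(s) {
    co <- simulate_cohort(cohort_config(seed = 10000 + s),
                          minimal_profile(), n_cells = 2)
    fit_length_phenotype(cohort_table(co), "aao")$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.45), 0.08)
})

test_that("downstream expansion index rises with the expansion rate and length", {
  cal <- default_calibration()
  idx_of <- function(inherited, rate, seed) {
    p <- tissue_profile("t", rate, 0.15)
    d <- simulate_somatic_distribution(inherited, p, 1000, seed = seed)
    pt <- simulate_trace(d, stutter_model(), cal, seed = seed + 5e5)
    expansion_index(call_distribution(pt, cal))$expansion_index
  }
  # monotone in the expansion rate, paired seeds
  lo <- vapply(1:20, function(s) idx_of(45, 0.010, s), numeric(1))
  hi <- vapply(1:20, function(s) idx_of(45, 0.022, s), numeric(1))
  expect_gt(mean(hi), mean(lo))

  # inherited 50 beats inherited 35 for the same profile (rank test)
  i35 <- vapply(1:50, function(s) idx_of(35, 0.018, 1000 + s), numeric(1))
  i50 <- vapply(1:50, function(s) idx_of(50, 0.018, 2000 + s), numeric(1))
  expect_lt(wilcox.test(i50, i35, alternative = "greater")$p.value, 0.01)
})
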