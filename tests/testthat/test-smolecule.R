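test_that("lambda estimation follows the Poisson zero-class closed form", {
  e <- estimate_lambda(72, 24)
  expect_equal(e$lambda_hat, log(3), tolerance = 1e-12)
  expect_true(e$ci_low < log(3) && log(3) < e$ci_high)

  expect_equal(estimate_lambda(100, 37)$lambda_hat, -log(0.37), tolerance = 1e-12)

  # all wells negative: no template at all
  expect_equal(estimate_lambda(72, 72)$lambda_hat, 0)

  # no negatives: unbounded estimate, flagged rather than numeric
  e0 <- estimate_lambda(72, 0)
  expect_true(e0$too_concentrated)
  expect_true(is.na(e0$lambda_hat))

  expect_error(estimate_lambda(0, 0), "positive")
  expect_error(estimate_lambda(10, 11), "n_wells")
})

test_that("dilution selection targets one-third negative wells, ties to more dilute", {
  mk <- function(fracs, n = 100) {
    rows <- do.call(rbind, lapply(seq_along(fracs), function(i) {
      neg <- round(fracs[i] * n)
      data.frame(
        plate_id = sprintf("d%02d", i), dilution_id = sprintf("d%02d", i),
        well = sprintf("W%03d", 1:n), input_class = "dna",
        repeat_units = c(rep(NA_integer_, neg), rep(41L, n - neg)),
        size_bp = NA_real_, height = NA_real_
      )
    }))
    plate_set(rows)
  }
  expect_equal(as.character(select_single_molecule_dilution(mk(c(0.05, 0.31, 0.80)))),
               "d02")
  # |0.36 - 1/3| = 0.0267 < |0.30 - 1/3| = 0.0333
  expect_equal(as.character(select_single_molecule_dilution(mk(c(0.30, 0.36)))),
               "d02")
  # exact tie in deviation: the more dilute (higher negative fraction) wins
  expect_equal(as.character(select_single_molecule_dilution(mk(c(0.23, 0.43), n = 300))),
               "d02")
  expect_error(select_single_molecule_dilution(mk(0.3)), "at least two")
  expect_error(select_single_molecule_dilution(mk(c(0, 0))), "titration failed")
})

test_that("plate QC enumerates control, concentration and height failures", {
  mk_plate <- function(n_neg = 25, ctrl_pos = FALSE, low_height = FALSE) {
    dna <- data.frame(
      plate_id = "p1", dilution_id = "d01",
      well = sprintf("W%02d", 1:72), input_class = "dna",
      repeat_units = c(rep(NA_integer_, n_neg), rep(41L, 72 - n_neg)),
      size_bp = NA_real_,
      height = c(rep(NA_real_, n_neg),
                 rep(if (low_height) 100 else 2000, 72 - n_neg))
    )
    ctrl <- data.frame(
      plate_id = "p1", dilution_id = "d01",
      well = sprintf("N%02d", 1:18), input_class = "no_dna_control",
      repeat_units = c(if (ctrl_pos) 41L else NA_integer_,
                       rep(NA_integer_, 17)),
      size_bp = NA_real_, height = NA_real_
    )
    plate_set(rbind(dna, ctrl))
  }
  expect_true(qc_plate(mk_plate(25))$pass)
  # 24 = 72/3 exactly meets the one-third rule
  expect_true(qc_plate(mk_plate(24))$pass)
  expect_equal(qc_plate(mk_plate(20))$reasons, "too_concentrated")
  expect_equal(qc_plate(mk_plate(25, ctrl_pos = TRUE))$reasons, "control_positive")
  expect_true("low_peak_height" %in% qc_plate(mk_plate(25, low_height = TRUE))$reasons)
})

test_that("allele classification counts and magnitude bins are consistent", {
  wells <- c(39, 40, 41, 41, 41, 42, 43, 45)
  ps <- plate_set(data.frame(
    plate_id = "p1", dilution_id = "d01",
    well = sprintf("W%02d", seq_along(wells)), input_class = "dna",
    repeat_units = wells, size_bp = NA_real_, height = 2000
  ))
  cc <- tabulate_alleles(ps, modal_reference = 41)
  expect_equal(cc$n_contracted, 2L)
  expect_equal(cc$n_modal, 3L)
  expect_equal(cc$n_expanded, 3L)
  expect_equal(cc$n_total, 8L)
  bins <- cc$bins
  expect_equal(bins$count[bins$side == "expansion" & bins$magnitude == ">=5"], 0L)
  expect_equal(bins$count[bins$side == "expansion" & bins$magnitude == "1-4"], 3L)

  # default modal reference: most frequent sized length
  expect_equal(tabulate_alleles(ps)$modal_reference, 41L)

  # all wells modal
  ps_modal <- plate_set(data.frame(
    plate_id = "p1", dilution_id = "d01", well = sprintf("W%02d", 1:5),
    input_class = "dna", repeat_units = 41, size_bp = NA_real_, height = 2000
  ))
  cc2 <- tabulate_alleles(ps_modal)
  expect_equal(cc2$n_modal, cc2$n_total)

  # conservation and nesting on random wells; idempotent reclassification
  set.seed(41)
  for (i in 1:25) {
    w <- sample(20:80, sample(5:60, 1), replace = TRUE)
    psr <- plate_set(data.frame(
      plate_id = "p", dilution_id = "d", well = sprintf("W%03d", seq_along(w)),
      input_class = "dna", repeat_units = w, size_bp = NA_real_, height = 2000
    ))
    cr <- tabulate_alleles(psr, modal_reference = 45)
    expect_equal(cr$n_contracted + cr$n_modal + cr$n_expanded, cr$n_total)
    b <- cr$bins
    for (side in c("expansion", "contraction")) {
      expect_lte(b$count[b$side == side & b$magnitude == ">=20"],
                 b$count[b$side == side & b$magnitude == ">=5"])
    }
    cr2 <- tabulate_alleles(psr, modal_reference = 45)
    expect_identical(cr, cr2)
  }
})

test_that("class-count chi-square matches the textbook statistic", {
  # worked 2x2 example via raw contingency machinery
  t1 <- make_class_counts(10, 0, 20)
  t2 <- make_class_counts(20, 0, 10)
  expect_error(compare_class_counts(list(t1, t2)), "zero-margin")

  res <- compare_class_counts(list(make_class_counts(10, 20, 15),
                                   make_class_counts(20, 10, 15)))
  want <- oracle_chisq(rbind(c(10, 20, 15), c(20, 10, 15)))
  expect_equal(res$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(res$df, want$df)

  # identical rows: no association
  same <- compare_class_counts(list(make_class_counts(10, 20, 30),
                                    make_class_counts(10, 20, 30)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  # 4 samples x 3 classes gives df = 6
  four <- compare_class_counts(list(
    make_class_counts(30, 40, 60), make_class_counts(25, 45, 55),
    make_class_counts(40, 30, 70), make_class_counts(20, 55, 45)
  ))
  expect_equal(four$df, 6)

  expect_warning(
    compare_class_counts(list(make_class_counts(2, 3, 4),
                              make_class_counts(3, 2, 4))),
    "below 5"
  )
})

test_that("sample summary reports counts, mean, modal and extremes", {
  mk <- function(w) plate_set(data.frame(
    plate_id = "p", dilution_id = "d", well = sprintf("W%03d", seq_along(w)),
    input_class = "dna", repeat_units = w, size_bp = NA_real_, height = 2000
  ))
  s <- summarize_sample(mk(c(rep(54, 150), rep(55, 5), rep(53, 2))))
  expect_equal(s$modal_repeat, 54L)
  s2 <- summarize_sample(mk(c(30, 60)))
  expect_equal(s2$mean_repeat, 45.0)
  expect_equal(s2$highest_repeat, 60)
  expect_equal(s2$lowest_repeat, 30)
  expect_error(summarize_sample(mk(NA_integer_)), "no sized wells")
})

test_that("molecule collisions at high loading shift calls toward contraction", {
  # wells with >= 2 molecules report the shortest allele, so classification
  # at lambda = 1.1 is contraction-shifted relative to lambda = 0.1
  d <- allele_distribution(c(38, 39, 40, 41, 42), c(80, 120, 600, 120, 80),
                           locus = "XDP")
  frac_contracted <- function(lam, seed) {
    s <- simulate_dilution_series(d, lam, wells_per_dilution = 4000, seed = seed)
    cc <- tabulate_alleles(s, modal_reference = 40)
    cc$n_contracted / cc$n_total
  }
  expect_gt(frac_contracted(1.1, 51), frac_contracted(0.1, 52))
})

test_that("simulated sample extremes match the ground-truth molecules drawn", {
  profile <- tissue_profile("occipital_cortex", 0.024, 0.18)
  dist <- simulate_somatic_distribution(50, profile, 5000, seed = 47)
  series <- simulate_dilution_series(dist, 1.1, wells_per_dilution = 300,
                                     seed = 48)
  s <- summarize_sample(series)
  expect_gte(s$highest_repeat, s$modal_repeat)
  expect_lte(s$lowest_repeat, s$modal_repeat)
  # every sized allele must exist in the ground-truth distribution
  sized <- series$repeat_units[series$input_class == "dna" &
                                 !is.na(series$repeat_units)]
  expect_true(all(sized %in% dist$repeats))
})
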