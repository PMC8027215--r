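cal_dna <- fixed_calibration("dna")

test_that("fixed calibrations carry the standard density thresholds", {
  expect_equal(fixed_calibration("rna")$threshold_density, 1.797)
  expect_equal(fixed_calibration("rna")$strong_density, 1.816)
  expect_equal(cal_dna$threshold_density, 1.702)
  expect_equal(cal_dna$strong_density, 1.714)
  expect_identical(cal_dna$source, "fixed")
})

test_that("calibration from standards finds the labelled band's light edge", {
  # perfectly separated standards: threshold = lightest occupied fraction
  dens <- seq(1.74, 1.66, length.out = 13)
  mk <- function(profile) {
    fraction_table(matrix(1, 1, 13, dimnames = list("std", sprintf("F%02d", 1:13))),
                   dens, total_mass = profile, normalized = TRUE)
  }
  unl <- mk(c(rep(0, 9), 0.1, 0.8, 0.1, 0))
  lab <- mk(c(0, 0.1, 0.8, 0.1, rep(0, 9)))
  cal <- calibrate(unl, lab, "dna")
  expect_identical(cal$source, "standards")
  expect_equal(cal$threshold_density, dens[4])

  # identical standards: no separation, fall back to fixed defaults
  expect_warning(cal0 <- calibrate(unl, unl, "dna"), "do not separate")
  expect_identical(cal0$source, "fixed")
  expect_equal(cal0$threshold_density, 1.702)

  # standards without mass information cannot calibrate
  nomass <- mk(rep(NA_real_, 13))
  expect_warning(calnm <- calibrate(nomass, nomass, "rna"), "no per-fraction mass")
  expect_identical(calnm$source, "fixed")

  expect_error(calibrate(unl, random_count_table(), "dna"), "single taxon")
})

test_that("simulated RNA standards calibrate near the reference threshold", {
  sp <- gradient_spec("rna", seed = 11)
  std <- simulate_standards(sp)
  cal <- calibrate(std$unlabelled, std$labelled, "rna")
  expect_identical(cal$source, "standards")
  frac_width <- abs(mean(diff(sp$fraction_densities)))
  expect_lt(abs(cal$threshold_density - 1.797), frac_width)
})

test_that("windows split at the calibrated threshold density", {
  ft <- make_scaled_table(matrix(0.5, 1, 4, dimnames = list("A", paste0("F0", 1:4))),
                          c(1.806, 1.797, 1.790, 1.780))
  w <- partition_windows(ft, fixed_calibration("rna"))
  expect_equal(w$window, c("heavy", "heavy", "light", "light"))
  wd <- partition_windows(
    make_scaled_table(matrix(0.5, 1, 4, dimnames = list("A", paste0("F0", 1:4))),
                      c(1.719, 1.706, 1.700, 1.690)),
    cal_dna)
  expect_equal(wd$window, c("heavy", "heavy", "light", "light"))
  # all fractions below threshold: empty heavy window, nothing is labelled
  ft_light <- make_scaled_table(
    matrix(c(0.9, 0.9, 0.9, 0.9), 1, dimnames = list("A", paste0("F0", 1:4))),
    c(1.695, 1.690, 1.685, 1.680))
  calls <- classify_otus(ft_light, ft_light, cal_dna)
  expect_true(all(calls$status == "unlabelled"))
})

test_that("criteria implement a strict 5-percentage-point boundary", {
  thr <- thresholds()
  dens <- dna4_densities
  # per-case: heavy-window max in labelled table vs control max / light max
  cases <- list(
    list(h = 0.099, ref = 0.05, pass = FALSE), # 4.9 points
    list(h = 0.100, ref = 0.05, pass = FALSE), # exactly 5 points: not "more than"
    list(h = 0.101, ref = 0.05, pass = TRUE),  # 5.1 points
    list(h = 0.090, ref = 0.02, pass = TRUE),  # 7 points
    list(h = 0.060, ref = 0.02, pass = FALSE)  # 4 points
  )
  for (cs in cases) {
    lab <- make_scaled_table(
      matrix(c(cs$h, cs$h / 2, cs$ref, cs$ref), 1, dimnames = list("A", paste0("F0", 1:4))),
      dens)
    ctl <- make_scaled_table(
      matrix(rep(cs$ref, 4), 1, dimnames = list("A", paste0("F0", 1:4))), dens)
    w <- partition_windows(lab, cal_dna)
    expect_identical(criterion_inter("A", lab, ctl, w, thr)$pass, cs$pass)
    # intra: light max equals ref in the same construction
    expect_identical(criterion_intra("A", lab, w, thr)$pass, cs$pass)
  }
  # uniform OTU: zero difference, never passes
  unif <- make_scaled_table(matrix(0.2, 1, 4, dimnames = list("A", paste0("F0", 1:4))), dens)
  w <- partition_windows(unif, cal_dna)
  expect_false(criterion_intra("A", unif, w, thr)$pass)
  # absent OTU: zero evidence, no pass; unknown OTU errors
  zero <- make_scaled_table(matrix(0, 1, 4, dimnames = list("A", paste0("F0", 1:4))), dens)
  wz <- partition_windows(zero, cal_dna)
  res <- criterion_inter("A", zero, zero, wz, thr)
  expect_false(res$pass)
  expect_equal(unname(res$evidence[["heavy_max_pct"]]), 0)
  expect_error(criterion_inter("missing", zero, zero, wz, thr), "not present")
})

test_that("criterion evidence reports the percentages used", {
  lab <- make_scaled_table(
    matrix(c(0.09, 0.01, 0.03, 0.02), 1, dimnames = list("A", paste0("F0", 1:4))),
    dna4_densities)
  ctl <- make_scaled_table(
    matrix(c(0.02, 0.01, 0.02, 0.015), 1, dimnames = list("A", paste0("F0", 1:4))),
    dna4_densities)
  w <- partition_windows(lab, cal_dna)
  ev <- criterion_inter("A", lab, ctl, w)$evidence
  expect_equal(unname(ev[["heavy_max_pct"]]), 9)
  expect_equal(unname(ev[["control_max_pct"]]), 2)
  expect_equal(unname(ev[["inter_diff_pts"]]), 7)
})

test_that("presence rule applies only to OTUs undetectable in controls", {
  thr <- thresholds()
  dens <- dna4_densities
  lab <- make_scaled_table(
    matrix(c(0.9, 0.0, 0.0, 0.0), 1, dimnames = list("A", paste0("F0", 1:4))), dens)
  ctl0 <- make_scaled_table(matrix(0, 1, 4, dimnames = list("A", paste0("F0", 1:4))), dens)
  w <- partition_windows(lab, cal_dna)
  pr <- presence_rule("A", lab, ctl0, w, thr)
  expect_true(pr$applicable)
  expect_true(pr$pass)

  # high control background: rule does not apply
  ctl_hi <- make_scaled_table(matrix(0.02, 1, 4, dimnames = list("A", paste0("F0", 1:4))), dens)
  pr2 <- presence_rule("A", lab, ctl_hi, w, thr)
  expect_false(pr2$applicable)
  expect_false(pr2$pass)

  # labelled OTU only in light fractions: no presence in heavy
  lab_light <- make_scaled_table(
    matrix(c(0.0, 0.0, 0.9, 0.9), 1, dimnames = list("A", paste0("F0", 1:4))), dens)
  w3 <- partition_windows(lab_light, cal_dna)
  expect_false(presence_rule("A", lab_light, ctl0, w3, thr)$pass)
})

test_that("classify combines criteria with the AND gate and degree split", {
  dens <- c(1.820, 1.806, 1.790, 1.780) # RNA-style grid
  cal <- fixed_calibration("rna")
  mk <- function(v) make_scaled_table(matrix(v, 1, dimnames = list("A", paste0("F0", 1:4))), dens)
  ctl <- mk(rep(0.05, 4))
  row_a <- function(calls) calls[calls$otu_id == "A", ]
  # peak at 1.806 (partial zone) and both criteria pass
  calls <- row_a(classify_otus(mk(c(0.10, 0.70, 0.05, 0.05)), ctl, cal))
  expect_identical(calls$status, "partially_labelled")
  # peak at 1.820 >= 1.816: strongly labelled
  calls2 <- row_a(classify_otus(mk(c(0.80, 0.10, 0.05, 0.05)), ctl, cal))
  expect_identical(calls2$status, "strongly_labelled")
  # criterion 1 fails (control high everywhere) -> unlabelled despite intra pass
  ctl_eq <- mk(rep(0.70, 4))
  calls3 <- row_a(classify_otus(mk(c(0.10, 0.70, 0.05, 0.05)), ctl_eq, cal))
  expect_false(calls3$criterion1)
  expect_true(calls3$criterion2)
  expect_identical(calls3$status, "unlabelled")
  # low-background OTU present in heavy -> present_in_heavy
  ctl0 <- mk(rep(0, 4))
  calls4 <- row_a(classify_otus(mk(c(0.9, 0.0, 0.0, 0.0)), ctl0, cal))
  expect_identical(calls4$status, "present_in_heavy")
  expect_identical(calls4$background, "low")
})

test_that("raising delta_points never converts unlabelled to labelled", {
  com <- sip_example_community()
  lab <- simulate_gradient(com, gradient_spec("dna", seed = 33))
  ctl <- simulate_gradient(unlabelled_control(com), gradient_spec("dna", seed = 34))
  labelled_set <- function(delta) {
    calls <- classify_otus(lab, ctl, cal_dna, thresholds(delta_points = delta))
    calls$otu_id[calls$status != "unlabelled"]
  }
  sets <- lapply(c(1, 3, 5, 10, 25, 60), labelled_set)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("GC confound check reproduces the low-GC exclusion argument", {
  expect_true(gc_confound_check(0.30, "dna", cal_dna))   # 1.6894 < 1.702
  expect_true(gc_confound_check(0.55, "rna", fixed_calibration("rna"))) # 1.780 < 1.797
  expect_false(gc_confound_check(0.60, "dna", cal_dna))  # 1.7188 > 1.702
  # a flagged positive call warns
  dens <- dna4_densities
  mk <- function(v) make_scaled_table(matrix(v, 1, dimnames = list("A", paste0("F0", 1:4))), dens)
  ctl <- mk(rep(0.05, 4))
  expect_warning(
    classify_otus(mk(c(0.70, 0.10, 0.05, 0.05)), ctl, cal_dna, gc = c(A = 0.60)),
    "GC-driven")
  calls <- suppressWarnings(
    classify_otus(mk(c(0.70, 0.10, 0.05, 0.05)), ctl, cal_dna, gc = c(A = 0.60)))
  expect_false(calls$gc_confound_ok[calls$otu_id == "A"])
})

test_that("a rare fully labelled taxon is recoverable by the presence rule", {
  # 1e-5 relative abundance, fully labelled; deep sequencing of near-empty
  # heavy fractions makes it dominant there
  com <- community(c("rare", sprintf("bg%d", 1:4)),
                   gc = 0.30,
                   abundance = c(1e-5, rep((1 - 1e-5) / 4, 4)),
                   atom_fraction_13c = c(1, 0, 0, 0, 0))
  sp <- gradient_spec("dna", read_depth = 5000, template_floor = 1e-7, seed = 77)
  lab <- simulate_gradient(com, sp)
  ctl <- simulate_gradient(unlabelled_control(com),
                           gradient_spec("dna", read_depth = 5000,
                                         template_floor = 1e-7, seed = 78))
  calls <- classify_otus(lab, ctl, cal_dna)
  expect_identical(calls$status[calls$otu_id == "rare"], "present_in_heavy")
})
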