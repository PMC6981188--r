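test_that("T7E1 formula endpoints, worked value, and random agreement", {
  expect_identical(t7e1_indel_percent(0, 100), 0)
  expect_equal(t7e1_indel_percent(75, 25), 50)          # f = 0.75 -> 50%
  expect_equal(t7e1_indel_percent(100, 0), 100)
  set.seed(61)
  f <- runif(1000)
  got <- vapply(f, function(fi) t7e1_indel_percent(fi, 1 - fi), numeric(1))
  expect_equal(got, 100 * (1 - sqrt(1 - f)), tolerance = 1e-12)
  expect_true(all(diff(got[order(f)]) > 0))             # monotone in f
})

test_that("T7E1 validates intensities", {
  expect_error(t7e1_indel_percent(0, 0), "> 0")
  expect_error(t7e1_indel_percent(-1, 2), ">= 0")
})

test_that("detection factors reproduce the balanced-mixture arithmetic", {
  expect_equal(detection_factor(16, 53, 0.5), 16 / 26.5, tolerance = 1e-12)
  expect_equal(round(detection_factor(16, 53, 0.5), 2), 0.60)
  expect_equal(detection_factor(16, 61, 0.5), 16 / 30.5, tolerance = 1e-12)
  expect_equal(round(detection_factor(16, 61, 0.5), 2), 0.52)
  expect_identical(detection_factor(25, 50, 0.5), 1)
})

test_that("fit_detection_model recovers an exact line", {
  mix <- tibble::tibble(true_fraction = c(0.05, 0.1, 0.2, 0.5),
                        observed_fraction = (0.5 * c(5, 10, 20, 50) - 0.1) / 100)
  m <- fit_detection_model(mix)
  expect_equal(m$slope, 0.5, tolerance = 1e-9)
  expect_equal(m$intercept, -0.1, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_identical(m$n_points, 4L)
})

test_that("fit_detection_model agrees with the normal-equations oracle", {
  loc <- test_locus()
  mix <- simulate_mixture_series(loc, c(0.05, 0.1, 0.2, 0.5),
                                 c(61, 52, 64, 61),
                                 bias = bias_model("exponential"), seed = 62)
  m <- fit_detection_model(mix)
  o <- oracle_ols(100 * mix$true_fraction, 100 * mix$observed_fraction)
  expect_equal(m$slope, o$slope, tolerance = 1e-9)
  expect_equal(m$intercept, o$intercept, tolerance = 1e-9)
  expect_equal(m$r_squared, o$r2, tolerance = 1e-9)
})

test_that("degenerate designs are rejected", {
  mix <- tibble::tibble(true_fraction = c(0.2, 0.2, 0.2),
                        observed_fraction = c(0.1, 0.12, 0.11))
  expect_error(fit_detection_model(mix), "distinct")
})

test_that("correct_observed reproduces the canonical worked example", {
  m <- detection_model(slope = 0.528, intercept = -0.154)
  expect_equal(correct_observed(4.7, m), (4.7 + 0.154) / 0.528,
               tolerance = 1e-12)
  expect_lt(abs(correct_observed(4.7, m) - 9.185), 0.01)
})

test_that("correction is the algebraic inverse of the forward model", {
  ident <- detection_model(1, 0)
  expect_identical(correct_observed(12.3, ident), 12.3)
  m <- detection_model(0.528, -0.154)
  for (x in c(0.3, 4.7, 22, 87)) {
    y <- m$slope * x + m$intercept
    expect_equal(correct_observed(y, m), x, tolerance = 1e-9)
  }
  expect_error(detection_model(0, 1), "> 0")
})

test_that("absolute rod rates divide the clone fraction by the rod share", {
  expect_equal(absolute_rod_rate(3, 40, 0.75), 10)
  expect_equal(round(absolute_rod_rate(2, 57, 0.75), 1), 4.7)
  expect_identical(absolute_rod_rate(0, 57), 0)
  expect_error(absolute_rod_rate(5, 0), "> 0")
  expect_error(absolute_rod_rate(5, 4), "exceed")
})

test_that("relative success rates reproduce the fixture arithmetic", {
  expect_equal(round(relative_success_rate(2, 18), 1), 11.1)
  expect_equal(round(relative_success_rate(1, 22), 1), 4.5)
  expect_identical(relative_success_rate(7, 7), 100)
  expect_error(relative_success_rate(0, 0), "zero")
})

test_that("efficiency report assembles the full chain and keeps shares normalized", {
  loc <- test_locus()
  aset <- test_alleles()
  cl <- simulate_clone_set(loc, fixture_clone_spec("mmej_1m", seed = 63), aset)
  ct <- classify_set(cl, aset)
  m <- detection_model(0.528, -0.154)
  rep <- efficiency_report(ct, m)
  expect_equal(round(rep$absolute_rod_rate_uncorrected, 1), 4.7)
  expect_equal(rep$absolute_rod_rate_corrected,
               (rep$absolute_rod_rate_uncorrected + 0.154) / 0.528,
               tolerance = 1e-9)
  expect_equal(round(rep$relative_success_among_edited, 1), 11.1)
  sh <- tidy(rep)
  expect_equal(sum(sh$observed_share), 1, tolerance = 1e-12)
  expect_equal(sum(sh$corrected_share), 1, tolerance = 1e-12)
  # only Success and Unedited shares move under the correction
  moved <- sh$category[abs(sh$corrected_share - sh$observed_share) > 1e-12]
  expect_setequal(as.character(moved), c("Success", "Unedited"))
  g <- glance(rep)
  expect_identical(g$total_clones, 57L)
})

test_that("a correction overshooting 100% is clamped with a warning", {
  loc <- test_locus()
  aset <- test_alleles()
  cl <- simulate_clone_set(loc, clone_sim_spec(c(Success = 1), 10, seed = 64),
                           aset)
  ct <- classify_set(cl, aset)
  w <- capture_warnings(rep <- efficiency_report(ct, detection_model(0.5, 0)))
  expect_true(any(grepl("clamp", w)))
  expect_identical(rep$absolute_rod_rate_corrected, 100)
})

test_that("qPCR rescue efficiency interpolates on the standard curve", {
  # perfect 2-fold dilution series: ct = 20 - log2-slope * log10(q)
  q <- c(1, 0.5, 0.25, 0.125, 0.0625)
  slope <- -1 / log10(2)           # one CT per 2-fold dilution
  curve <- tibble::tibble(rel_quantity = q, ct = 20 + slope * log10(q))
  ct_at <- function(quant) 20 + slope * log10(quant)
  expect_equal(rna_rescue_efficiency(ct_at(0.4), ct_at(0.4), curve), 100,
               tolerance = 1e-9)
  expect_equal(rna_rescue_efficiency(ct_at(0.127), ct_at(1), curve), 12.7,
               tolerance = 1e-6)
  expect_warning(
    rna_rescue_efficiency(20, 20,
                          tibble::tibble(rel_quantity = q, ct = rev(curve$ct))),
    "reversed")
})

test_that("ERG rescue efficiency scales by the control mean", {
  expect_equal(erg_rescue_efficiency(41.5), 100)
  expect_identical(erg_rescue_efficiency(0), 0)
  expect_equal(round(erg_rescue_efficiency(4.648), 1), 11.2)
})

test_that("light-sensitivity threshold returns the dimmest supra-criterion intensity", {
  none <- tibble::tibble(intensity = -7:1, amplitude = rep(0, 9))
  expect_true(is.na(light_sensitivity_threshold(none)))
  d <- tibble::tibble(intensity = c(-7, -6, -5), amplitude = c(10, 30, 40))
  expect_identical(light_sensitivity_threshold(d), -6)
  # random monotone series vs a linear-scan oracle
  for (s in 1:20) {
    amp <- withr::with_seed(s, sort(runif(9, 0, 60)))
    d <- tibble::tibble(intensity = -7:1, amplitude = amp)
    got <- light_sensitivity_threshold(d)
    idx <- which(amp > 25)
    want <- if (length(idx) == 0) NA_real_ else (-7:1)[min(idx)]
    expect_identical(got, want)
  }
  expect_error(
    light_sensitivity_threshold(tibble::tibble(intensity = c(1, 1),
                                               amplitude = c(1, 2))),
    "increasing")
})
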