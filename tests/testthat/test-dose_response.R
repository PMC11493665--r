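test_that("the preset trimer dose-response is bell-shaped with a vanishing tail", {
  curve <- sweep_dose_response(table1_preset())
  expect_s3_class(curve, "dose_response_curve")
  expect_identical(nrow(curve), 61L)
  expect_true(all(diff(curve$dose) > 0))
  expect_true(all(as.matrix(curve[-1]) >= 0))
  d <- describe_curve(curve)
  expect_true(d$is_bell)
  expect_true(d$plateau_low <= d$peak_dose && d$peak_dose <= d$plateau_high)
  expect_gte(d$peak_trimer, max(curve$trimer))
  # hook effect: trimer collapses in both dose limits
  expect_lt(curve$trimer[1], 0.05 * d$peak_trimer)
  expect_lt(curve$trimer[61], 0.05 * d$peak_trimer)
  # dimers saturate monotonically
  expect_true(all(diff(curve$dimer_tcr) >= 0))
  expect_true(all(diff(curve$dimer_taa) >= 0))
})

test_that("sweep validates its grid arguments", {
  p <- table1_preset()
  expect_error(sweep_dose_response(p, 1, 1), "dose_min")
  expect_error(sweep_dose_response(p, 1, 10, 4), "n_points")
})

test_that("the dilute closed-pool peak sits at the geometric mean of the Kds", {
  set.seed(33)
  for (i in 1:3) {
    kds <- 10^runif(2, -1, 4)
    q <- closed_trace_params()
    q <- scale_params(q, "kd_tcr", kds[1] / q$kd_tcr)
    q <- scale_params(q, "kd_taa", kds[2] / q$kd_taa)
    gm <- sqrt(prod(kds))
    d <- describe_curve(sweep_dose_response(q, gm / 1e4, gm * 1e4, 81))
    expect_equal(d$peak_dose, gm, tolerance = 0.05)
  }
})

test_that("descriptors handle monotone and degenerate curves", {
  doses <- 10^seq(-2, 2, length.out = 21)
  rising <- structure(
    data.frame(dose = doses, trimer = doses / (1 + doses),
               dimer_tcr = 0, dimer_taa = 0),
    class = c("dose_response_curve", "data.frame"))
  d <- describe_curve(rising)
  expect_false(d$is_bell)
  zero <- rising
  zero$trimer <- 0
  dz <- describe_curve(zero)
  expect_false(dz$is_bell)
  expect_identical(dz$peak_trimer, 0)
  expect_true(is.na(dz$peak_dose))
  expect_true(is.na(dz$plateau_low))
})

test_that("comparing a curve with itself reports no shift", {
  curve <- sweep_dose_response(table1_preset(), n_points = 31)
  rep <- compare_curves(curve, curve)
  expect_identical(rep$classification, "none")
  expect_equal(rep$vertical_ratio, 1)
  expect_equal(rep$horizontal_ratio, 1)
})

test_that("doubling dilute antigen pools doubles the peak without moving it", {
  a <- closed_trace_params()
  b <- scale_params(a, "baseline_taa", 2)
  ca <- sweep_dose_response(a, 1e-2, 1e5, 43)
  cb <- sweep_dose_response(b, 1e-2, 1e5, 43)
  rep <- compare_curves(ca, cb)
  expect_equal(rep$vertical_ratio, 2, tolerance = 0.01)
  expect_equal(rep$horizontal_ratio, 1, tolerance = 0.02)
  expect_identical(rep$classification, "up")
})

test_that("curves on different grids refuse to be compared", {
  a <- sweep_dose_response(table1_preset(), n_points = 11)
  b <- sweep_dose_response(table1_preset(), 1e-2, 1e5, 11)
  expect_error(compare_curves(a, b), "identical dose grid")
})

test_that("curves round-trip through tidy CSV", {
  curve <- sweep_dose_response(table1_preset(), n_points = 13)
  f <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(curve, f)
  back <- read_curve_csv(f)
  for (col in c("dose", "trimer", "dimer_tcr", "dimer_taa"))
    expect_equal(back[[col]], curve[[col]], tolerance = 1e-12)
  expect_identical(readLines(f, n = 1),
                   "dose_nM,trimer_nM,dimer_tcr_nM,dimer_taa_nM")
})
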