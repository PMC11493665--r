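test_that("receptor copy numbers convert to nM as expected", {
  # frozen hand arithmetic: cells/L * fraction * copies / N_A, in nM
  expect_equal(receptors_to_concentration(2.4e9, 0.85, 1e5),
               0.33875, tolerance = 1e-6)
  expect_equal(receptors_to_concentration(2.4e9, 0.15, 1e4),
               0.005977941, tolerance = 1e-6)
  expect_identical(receptors_to_concentration(0, 0.85, 1e5), 0)
  expect_identical(receptors_to_concentration(2.4e9, 0.85, 0), 0)
})

test_that("receptor-to-concentration conversion is linear in each argument", {
  set.seed(42)
  for (i in 1:10) {
    d <- runif(1, 1e8, 1e10); f <- runif(1); cpc <- runif(1, 1e3, 1e6)
    base <- receptors_to_concentration(d, f, cpc)
    expect_equal(receptors_to_concentration(3 * d, f, cpc), 3 * base)
    expect_equal(receptors_to_concentration(d, f / 2, cpc), base / 2)
    expect_equal(receptors_to_concentration(d, f, 10 * cpc), 10 * base)
  }
  expect_error(receptors_to_concentration(-1, 0.5, 10), "negative")
  expect_error(receptors_to_concentration(1e9, 1.5, 10), "exceed")
})

test_that("dependent rates derive from the defining identities", {
  expect_identical(derive_koff(1, 1e-4), 1e-4)
  expect_identical(derive_koff(1000, 1e-4), 0.1)
  expect_identical(derive_koff(1, 1e-3), 1e-3)
  expect_error(derive_koff(-1, 1e-4), "positive")
  expect_error(derive_koff(1, 0), "positive")

  expect_equal(derive_ksyn(1.834e-5, 7.246), 1.329e-4, tolerance = 1e-3)
  expect_equal(derive_ksyn(1.834e-5, 0.04194), 7.691e-7, tolerance = 1e-3)
  expect_identical(derive_ksyn(0.5, 0), 0)
  expect_error(derive_ksyn(0, 1), "positive")
  # round trip: the derived synthesis rate reproduces the baseline
  set.seed(1)
  for (i in 1:10) {
    kdeg <- 10^runif(1, -6, -3); x <- 10^runif(1, -3, 2)
    expect_equal(derive_ksyn(kdeg, x) / kdeg, x)
  }
})

test_that("the physiological preset carries the tabulated rates in both dialects", {
  ap <- table1_preset("as-printed")
  expect_identical(ap$kd_tcr, 1000)
  expect_identical(ap$kd_taa, 1)
  expect_identical(ap$kon_tcr, 1e-4)     # 1e5 M^-1 s^-1
  expect_identical(ap$koff_tcr, 0.26)
  expect_identical(ap$koff_taa, 0.00149)
  expect_identical(ap$kdeg_tcr, 1.834e-5)
  expect_identical(ap$kint_tcr_dimer, 5.501e-5)
  expect_identical(ap$kint_trimer, 1.834e-5)
  expect_equal(ap$ksyn_tcr, 1.329e-4)
  expect_equal(ap$ksyn_taa, 7.691e-7)
  expect_equal(ap$baseline_tcr, 7.246, tolerance = 1e-4)
  expect_equal(ap$baseline_taa, 0.04194, tolerance = 1e-3)
  # printed koff values contradict kd * kon; the dialect is flagged
  expect_false(ap$consistent)

  cn <- table1_preset("consistent")
  expect_equal(cn$koff_tcr, 0.1)
  expect_equal(cn$koff_taa, 1e-4)
  expect_true(cn$consistent)
  # everything except koff and the flag is shared
  same <- setdiff(names(unclass(ap)), c("koff_tcr", "koff_taa", "consistent"))
  expect_identical(unclass(ap)[same], unclass(cn)[same])

  expect_error(table1_preset("bogus"))
})

test_that("parameter validation rejects non-positive rates", {
  expect_error(engagement_params(kd_tcr = -1, kd_taa = 1,
                                 baseline_tcr = 1, baseline_taa = 1),
               "positive")
  expect_error(engagement_params(kd_tcr = 1, kd_taa = 1, kdeg_tcr = -1e-5,
                                 baseline_tcr = 1, baseline_taa = 1),
               "non-negative")
  expect_error(engagement_params(kd_tcr = 1, kd_taa = Inf,
                                 baseline_tcr = 1, baseline_taa = 1),
               "finite|positive")
})

test_that("scale_params preserves the dialect's koff/(kd*kon) ratio", {
  ap <- table1_preset("as-printed")
  sc <- scale_params(ap, "kd_tcr", 10)
  expect_equal(sc$kd_tcr, 1e4)
  expect_equal(sc$koff_tcr / (sc$kd_tcr * sc$kon_tcr),
               ap$koff_tcr / (ap$kd_tcr * ap$kon_tcr))
  sc2 <- scale_params(ap, "baseline_taa", 2)
  expect_equal(sc2$ksyn_taa, sc2$kdeg_taa * sc2$baseline_taa)
  expect_equal(sc2$ksyn_taa, 2 * ap$ksyn_taa)
  expect_error(scale_params(ap, "koff_tcr", 2), "must be one of")
})

test_that("cell context enforces its physiological invariants", {
  ctx <- cell_context()
  expect_equal(tcr_concentration(ctx), 0.33875, tolerance = 1e-6)
  expect_equal(taa_concentration(ctx), 0.005977941, tolerance = 1e-6)
  expect_error(cell_context(t_cell_fraction = 0.9, b_cell_fraction = 0.2),
               "exceed 1")
  expect_error(cell_context(lymphocyte_density = -1), "non-negative")
  expect_error(cell_context(t_cell_fraction = 1.2), "exceed")
})

test_that("parameter sets round-trip through the YAML schema", {
  for (mode in c("as-printed", "consistent")) {
    p <- table1_preset(mode)
    f <- withr::local_tempfile(fileext = ".yml")
    write_engagement_params(p, f)
    q <- read_engagement_params(f)
    expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  }
  # unit-suffixed keys are present in the file
  f <- withr::local_tempfile(fileext = ".yml")
  write_engagement_params(table1_preset(), f)
  txt <- readLines(f)
  expect_true(any(grepl("^kon_tcr_per_nM_per_s:", txt)))
  expect_true(any(grepl("^kd_taa_nM:", txt)))
  # missing key is reported by name
  keep <- txt[!grepl("^kd_taa_nM:", txt)]
  f2 <- withr::local_tempfile(fileext = ".yml")
  writeLines(keep, f2)
  expect_error(read_engagement_params(f2), "kd_taa_nM")
})
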