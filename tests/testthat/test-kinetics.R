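# independent oracle for the right-hand side: stoichiometry matrix times
# reaction-flux vector, assembled reaction by reaction (synthesis,
# degradation, the four reversible binding steps, three internalizations)
oracle_rhs <- function(y, p, clamped = FALSE) {
  E <- y[["tce"]]; R <- y[["tcr"]]; A <- y[["taa"]]
  d1 <- y[["tce_tcr"]]; d2 <- y[["tce_taa"]]; tr <- y[["trimer"]]
  # columns: one reaction each; rows: tce, tcr, taa, d1, d2, tr
  S <- cbind(
    syn_tcr  = c(0,  1,  0,  0,  0,  0),
    deg_tcr  = c(0, -1,  0,  0,  0,  0),
    syn_taa  = c(0,  0,  1,  0,  0,  0),
    deg_taa  = c(0,  0, -1,  0,  0,  0),
    bind_tcr = c(-1, -1, 0,  1,  0,  0), unbind_tcr = c(1, 1, 0, -1, 0, 0),
    bind_taa = c(-1, 0, -1,  0,  1,  0), unbind_taa = c(1, 0, 1, 0, -1, 0),
    tri_via_d1 = c(0, 0, -1, -1, 0, 1), untri_d1 = c(0, 0, 1, 1, 0, -1),
    tri_via_d2 = c(0, -1, 0, 0, -1, 1), untri_d2 = c(0, 1, 0, 0, 1, -1),
    int_d1 = c(0, 0, 0, -1, 0, 0),
    int_d2 = c(0, 0, 0, 0, -1, 0),
    int_tr = c(0, 0, 0, 0, 0, -1))
  v <- c(p$ksyn_tcr, p$kdeg_tcr * R, p$ksyn_taa, p$kdeg_taa * A,
         p$kon_tcr * E * R, p$koff_tcr * d1,
         p$kon_taa * E * A, p$koff_taa * d2,
         p$kon_taa * d1 * A, p$koff_taa * tr,
         p$kon_tcr * d2 * R, p$koff_tcr * tr,
         p$kint_tcr_dimer * d1, p$kint_taa_dimer * d2, p$kint_trimer * tr)
  out <- drop(S %*% v)
  if (clamped) out[1] <- 0
  names(out) <- names(y)
  out
}

random_state <- function() {
  system_state(tce = 10^runif(1, -3, 3), tcr = 10^runif(1, -3, 1),
               taa = 10^runif(1, -4, 0), tce_tcr = 10^runif(1, -6, 0),
               tce_taa = 10^runif(1, -6, 0), trimer = 10^runif(1, -8, -2))
}

test_that("rhs matches a hand-expanded stoichiometric oracle on random states", {
  set.seed(101)
  for (mode in c("as-printed", "consistent")) {
    p <- table1_preset(mode)
    for (i in 1:10) {
      y <- random_state()
      expect_equal(engagement_rhs(y, p, "free"), oracle_rhs(y, p),
                   tolerance = 1e-12)
      expect_equal(engagement_rhs(y, p, "clamped"),
                   oracle_rhs(y, p, clamped = TRUE), tolerance = 1e-12)
    }
  }
})

test_that("fixed points of the turnover balance have zero derivative", {
  # empty system with no synthesis
  p0 <- engagement_params(kd_tcr = 1000, kd_taa = 1,
                          baseline_tcr = 1, baseline_taa = 1)  # kdeg = 0
  y0 <- system_state()
  expect_identical(unname(engagement_rhs(y0, p0)), rep(0, 6))
  # drug-free baseline of the full preset
  p <- table1_preset()
  yb <- baseline_state(p, dose = 0)
  expect_equal(unname(engagement_rhs(yb, p)), rep(0, 6), tolerance = 1e-18)
})

test_that("a lone binding pair produces the single mass-action flux", {
  p <- table1_preset("consistent")
  y <- system_state(tce = 1, tcr = 1)
  dy <- engagement_rhs(y, p)
  expect_equal(unname(dy["tce_tcr"]), p$kon_tcr)  # kon * 1 * 1 = 1e-4 nM/s
  expect_equal(unname(dy["trimer"]), 0)
  expect_error(engagement_rhs(c(y[1:5], trimer = -1), p), "non-negative")
})

test_that("the analytic Jacobian matches finite differences of the rhs", {
  set.seed(202)
  p <- table1_preset()
  for (clamped in c(FALSE, TRUE)) {
    y <- random_state()
    J <- trimerize:::.jac_raw(y, p, clamped)
    h <- 1e-5
    scale <- max(abs(J))
    for (j in 1:6) {
      yp <- y; yp[j] <- yp[j] * (1 + h)
      ym <- y; ym[j] <- ym[j] * (1 - h)
      num <- (trimerize:::.rhs_raw(yp, p, clamped) -
                trimerize:::.rhs_raw(ym, p, clamped)) / (2 * h * y[j])
      expect_lt(max(abs(J[, j] - num)) / scale, 1e-6)
    }
  }
})

test_that("clamped trajectories hold free drug constant; dose 0 stays at baseline", {
  p <- table1_preset()
  tr <- simulate_engagement(p, dose = 10, exposure_mode = "clamped",
                            t_end = 3600, n_report = 50)
  expect_true(all(tr$states$tce == 10))
  tr0 <- simulate_engagement(p, dose = 0, t_end = 48 * 3600, n_report = 25)
  yb <- baseline_state(p, 0)
  for (s in names(yb))
    expect_equal(tr0$states[[s]][1], unname(yb[s]))
  expect_true(all(abs(tr0$states$tcr - p$baseline_tcr) <
                    1e-9 * p$baseline_tcr))
  expect_true(all(tr0$states$trimer == 0))
})

test_that("closed-system totals are conserved through 48 h of integration", {
  p <- closed_trace_params(scale = 1)  # full-size pools, fully closed
  tr <- simulate_engagement(p, dose = 10, exposure_mode = "free",
                            t_end = 48 * 3600, n_report = 101)
  tot <- pool_totals(tr$states)
  drift <- apply(tot, 2, function(x) max(abs(x - x[1])) / x[1])
  expect_lt(max(drift), 1e-9)
  expect_true(min(as.matrix(tr$states)) >= 0)
})

test_that("the terminal state does not depend on the reporting grid", {
  p <- table1_preset()
  a <- simulate_engagement(p, 10, t_end = 6 * 3600, n_report = 5)
  b <- simulate_engagement(p, 10, t_end = 6 * 3600, n_report = 400)
  ya <- unlist(a$states[nrow(a$states), ])
  yb <- unlist(b$states[nrow(b$states), ])
  expect_equal(ya, yb, tolerance = 1e-8)
})

test_that("exposure decay follows the half-life closed form", {
  # 7-day half-life: ~9.4% fall over 24 h
  expect_equal(exposure_decay(100, 168, 24), 100 * 2^(-24 / 168))
  expect_equal(exposure_decay(100, 168, 24), 90.57, tolerance = 1e-4)
  expect_identical(exposure_decay(55, 24, 0), 55)
  expect_equal(exposure_decay(55, 24, 24), 27.5)
  expect_error(exposure_decay(1, 0, 1), "positive")
  expect_error(exposure_decay(-1, 10, 1), "non-negative")
})
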