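## Steady-state computation under clamped exposure.
##
## With free TCE held at the dose L, the five remaining balance equations
## have a unique positive fixed point (monomolecular binding network with
## linear turnover).  The complexes enter their own balances linearly, so
## for given free receptor concentrations (R, A) the dimers and trimer
## solve a 3x3 linear system; substituting back leaves two nonlinear
## equations in (R, A), solved by damped Newton iteration on
## (log R, log A) -- the log transform enforces positivity across the ~6
## orders of magnitude the species span.

## dimers and trimer given free receptors; linear 3x3 solve
.complexes_given_free <- function(p, L, R, A) {
  c5 <- p$koff_tcr + p$koff_taa + p$kint_trimer
  M <- matrix(c(p$koff_tcr + p$kint_tcr_dimer + p$kon_taa * A, 0, -p$koff_taa,
                0, p$koff_taa + p$kint_taa_dimer + p$kon_tcr * R, -p$koff_tcr,
                -p$kon_taa * A, -p$kon_tcr * R, c5),
              3L, 3L, byrow = TRUE)
  drop(solve(M, c(p$kon_tcr * L * R, p$kon_taa * L * A, 0)))
}

## A receptor pool with neither turnover nor any internalization route is
## closed: its steady state is fixed by conservation of the total pool (at
## the baseline concentration), not by the turnover balance, which is then
## degenerate.
.closed_pools <- function(p) {
  c(tcr = p$ksyn_tcr == 0 && p$kdeg_tcr == 0 &&
      p$kint_tcr_dimer == 0 && p$kint_trimer == 0,
    taa = p$ksyn_taa == 0 && p$kdeg_taa == 0 &&
      p$kint_taa_dimer == 0 && p$kint_trimer == 0)
}

## residuals of the two free-receptor conditions at u = (log R, log A):
## turnover balance for open pools, total-pool conservation for closed ones
.free_residual <- function(p, L, u) {
  closed <- .closed_pools(p)
  R <- exp(u[1L]); A <- exp(u[2L])
  v <- .complexes_given_free(p, L, R, A)
  r1 <- if (closed[["tcr"]])
    p$baseline_tcr - R - v[1L] - v[3L]
  else
    p$ksyn_tcr - p$kdeg_tcr * R - p$kon_tcr * L * R - p$kon_tcr * v[2L] * R +
      p$koff_tcr * v[1L] + p$koff_tcr * v[3L]
  r2 <- if (closed[["taa"]])
    p$baseline_taa - A - v[2L] - v[3L]
  else
    p$ksyn_taa - p$kdeg_taa * A - p$kon_taa * L * A - p$kon_taa * v[1L] * A +
      p$koff_taa * v[2L] + p$koff_taa * v[3L]
  c(r1, r2)
}

## damped Newton on (log R, log A); returns u and convergence info
.newton_free <- function(p, L, u0, max_iter = 200L) {
  u <- u0
  f <- .free_residual(p, L, u)
  for (it in seq_len(max_iter)) {
    h <- 1e-7
    J <- matrix(0, 2L, 2L)
    for (j in 1:2) {
      up <- u; up[j] <- up[j] + h
      J[, j] <- (.free_residual(p, L, up) - f) / h
    }
    du <- tryCatch(-solve(J, f), error = function(e) NULL)
    if (is.null(du)) break
    step <- pmin(pmax(du, -5), 5)  # cap log steps for global robustness
    s <- 1
    repeat {
      f_new <- .free_residual(p, L, u + s * step)
      if (sum(f_new^2) < sum(f^2) || s < 1e-8) break
      s <- s / 2
    }
    u <- u + s * step
    f <- f_new
    if (max(abs(s * step)) < 1e-14) break
  }
  list(u = u, fnorm = max(abs(f)))
}

## full steady state at clamped dose L from a warm start; NULL u0 = baseline
.steady_core <- function(p, L, u0 = NULL) {
  if (L == 0) {
    y <- baseline_state(p, 0)
    res <- max(abs(.rhs_raw(y, p, clamped = TRUE)))
    return(list(state = y, residual = res, converged = res < 1e-12,
                u = log(c(p$baseline_tcr, p$baseline_taa))))
  }
  if (is.null(u0)) u0 <- log(c(p$baseline_tcr, p$baseline_taa))
  sol <- .newton_free(p, L, u0)
  R <- exp(sol$u[1L]); A <- exp(sol$u[2L])
  v <- .complexes_given_free(p, L, R, A)
  y <- system_state(tce = L, tcr = R, taa = A,
                    tce_tcr = v[1L], tce_taa = v[2L], trimer = v[3L])
  res <- max(abs(.rhs_raw(y, p, clamped = TRUE)))
  list(state = y, residual = res, converged = res < 1e-12, u = sol$u)
}

.steady_result <- function(core, method) {
  structure(list(state = core$state, method = method,
                 residual = core$residual, converged = core$converged),
            class = "steady_state_result")
}

#' Algebraic steady state under clamped exposure
#'
#' Solves the five balance equations (free TCE suppressed at the dose) for
#' the unique positive fixed point.  The Newton iteration is started from
#' the drug-free baseline; if it fails to converge, the root is approached
#' by homotopy continuation over a geometric ladder of doses from near zero
#' up to the target, which guards against spurious roots.
#'
#' A receptor pool with neither turnover nor any internalization route is
#' treated as closed: its equilibrium condition is conservation of the
#' total pool at the baseline concentration (the turnover balance is
#' degenerate there).  This is the regime of the classical ternary-complex
#' equilibrium, whose dilute-receptor trimer profile peaks at
#' `sqrt(kd_tcr * kd_taa)`.
#'
#' @param params [engagement_params()].
#' @param dose Clamped free-TCE concentration, nM (>= 0).
#' @return A `steady_state_result`: `state` (named vector, nM), `method`
#'   (`"algebraic"`), `residual` (max |dX/dt| in nM/s over all species) and
#'   `converged` (`TRUE` iff residual < 1e-12 nM/s).  Non-convergence is
#'   reported through these fields, never as a silently bad root.
#' @examples
#' ss <- steady_state_algebraic(table1_preset(), dose = 10)
#' ss$state["trimer"]
#' @export
steady_state_algebraic <- function(params, dose) {
  if (!is.finite(dose) || dose < 0) .stopf("dose must be non-negative")
  .validate_params(params)
  core <- .steady_core(params, dose)
  if (!core$converged && dose > 0) {
    # homotopy continuation from a small dose upward
    ladder <- 10^seq(log10(max(dose * 1e-6, 1e-9)), log10(dose),
                     length.out = 25L)
    u <- NULL
    for (L in ladder) {
      core <- .steady_core(params, L, u0 = u)
      u <- core$u
    }
  }
  .steady_result(core, "algebraic")
}

#' Long-time ODE limit of the clamped system
#'
#' Independent route to the same fixed point: integrate the clamped
#' kinetics from baseline and extend the horizon (doubling from `t_start`)
#' until the residual max |dX/dt| falls below `residual_tol`, so the result
#' is a genuine long-time limit even when slow receptor turnover keeps the
#' pools relaxing beyond the initial horizon.
#'
#' @param params [engagement_params()].
#' @param dose Clamped dose, nM.
#' @param t_start Initial integration horizon, seconds (default 48 h).
#' @param t_max Hard cap on the horizon, seconds.
#' @param residual_tol Convergence threshold on max |dX/dt|, nM/s.
#' @param ... Passed to [simulate_engagement()] (e.g. `rtol`, `atol`).
#' @return A `steady_state_result` with `method = "ode-limit"`.
#' @export
steady_state_ode <- function(params, dose, t_start = 48 * 3600,
                             t_max = 16384 * 3600, residual_tol = 1e-12,
                             ...) {
  if (!is.finite(dose) || dose < 0) .stopf("dose must be non-negative")
  y <- baseline_state(params, dose)
  t_tot <- 0
  t_chunk <- t_start
  repeat {
    traj <- simulate_engagement(params, dose, exposure_mode = "clamped",
                                initial = y, t_end = t_chunk, n_report = 2L,
                                ...)
    y <- unlist(traj$states[nrow(traj$states), ])
    t_tot <- t_tot + t_chunk
    res <- max(abs(.rhs_raw(y, params, clamped = TRUE)))
    if (res < residual_tol || t_tot >= t_max) break
    t_chunk <- t_tot  # doubling
  }
  core <- list(state = setNames(y, .SPECIES), residual = res,
               converged = res < residual_tol)
  .steady_result(core, "ode-limit")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("Steady state (%s)%s, residual %.3g nM/s\n", x$method,
              if (x$converged) "" else " [NOT CONVERGED]", x$residual))
  print(x$state)
  invisible(x)
}

#' Time for the engagement system to reach steady state
#'
#' Simulates a clamped dose from the drug-free baseline and returns the
#' earliest time after which the binding species stay within `rel_tol` of
#' their terminal values (band entry and stay).
#'
#' Criteria:
#' \describe{
#'   \item{`"binding"` (default)}{equilibration of the binding subsystem:
#'     receptor turnover and internalization are frozen (total pools fixed
#'     at baseline) and the band is applied to dimers and trimer.  This is
#'     the timescale on which target engagement itself settles -- minutes
#'     to ~1 h at typical doses -- and the quantity the steady-state
#'     dose-response approach rests on.}
#'   \item{`"complexes"`}{full model, band on dimers and trimer.  Because
#'     internalization slowly re-sizes the receptor pools, the complexes
#'     inherit an hours-scale drift and this criterion reports ~10-25 h at
#'     typical doses; it measures pool turnover, not binding.}
#'   \item{`"all"`}{full model, band on all species except free TCE.}
#' }
#'
#' @param params [engagement_params()].
#' @param dose Clamped dose, nM (> 0).
#' @param rel_tol Relative band half-width (0 < rel_tol; >= 1 returns 0).
#' @param criterion See above.
#' @param t_end Horizon and terminal reference time, seconds (default 48 h).
#' @param n_report Number of log-spaced report times.
#' @return Time in hours; `Inf` with a warning if the trajectory never
#'   enters and stays in the band.
#' @export
time_to_steady_state <- function(params, dose, rel_tol = 0.05,
                                 criterion = c("binding", "complexes", "all"),
                                 t_end = 48 * 3600, n_report = 1200L) {
  criterion <- match.arg(criterion)
  if (!is.finite(dose) || dose <= 0) .stopf("dose must be positive")
  if (!is.finite(rel_tol) || rel_tol <= 0) .stopf("rel_tol must be positive")
  p <- params
  if (criterion == "binding") {
    # freeze turnover and internalization: pure engagement kinetics
    for (k in c("ksyn_tcr", "kdeg_tcr", "ksyn_taa", "kdeg_taa",
                "kint_tcr_dimer", "kint_taa_dimer", "kint_trimer"))
      p[[k]] <- 0
  }
  times <- c(0, 10^seq(0, log10(t_end), length.out = n_report - 1L))
  traj <- simulate_engagement(p, dose, exposure_mode = "clamped",
                              times = times)
  cols <- switch(criterion,
                 binding = , complexes = c("tce_tcr", "tce_taa", "trimer"),
                 all = c("tcr", "taa", "tce_tcr", "tce_taa", "trimer"))
  m <- as.matrix(traj$states[, cols, drop = FALSE])
  terminal <- m[nrow(m), ]
  scale <- pmax(abs(terminal), 1e-300)
  in_band <- apply(m, 1L, function(r) all(abs(r - terminal) <= rel_tol * scale))
  stays <- rev(cumprod(rev(in_band))) > 0
  if (!any(stays)) {
    warning("trajectory never stays within the tolerance band; returning Inf")
    return(Inf)
  }
  traj$times[which(stays)[1L]] / 3600
}
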