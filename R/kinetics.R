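## Mass-action kinetics of the six-species engagement system.
##
## Species (all nM): tce (free drug), tcr (free T-cell receptor), taa (free
## tumour antigen), tce_tcr and tce_taa (binary complexes), trimer (the
## TCR-TCE-TAA ternary synapse).  Reactions: reversible binding of each arm
## (including the two association routes to the trimer), receptor synthesis/
## degradation, and internalization of bound complexes.

.SPECIES <- c("tce", "tcr", "taa", "tce_tcr", "tce_taa", "trimer")

#' Construct a system state
#'
#' @param tce,tcr,taa,tce_tcr,tce_taa,trimer Species concentrations, nM.
#' @return Named numeric vector over the six species.
#' @export
system_state <- function(tce = 0, tcr = 0, taa = 0,
                         tce_tcr = 0, tce_taa = 0, trimer = 0) {
  y <- c(tce = tce, tcr = tcr, taa = taa,
         tce_tcr = tce_tcr, tce_taa = tce_taa, trimer = trimer)
  if (any(!is.finite(y)) || any(y < 0))
    .stopf("all concentrations must be finite and non-negative")
  y
}

#' Drug-free baseline state
#'
#' Free receptors at their turnover fixed points (`ksyn/kdeg`, i.e. the
#' configured baselines), no complexes, and `dose` nM of free TCE.
#'
#' @param params [engagement_params()].
#' @param dose Free TCE, nM.
#' @return Named state vector.
#' @export
baseline_state <- function(params, dose = 0) {
  system_state(tce = dose, tcr = params$baseline_tcr,
               taa = params$baseline_taa)
}

## raw right-hand side; no validation, callable from the integrator
.rhs_raw <- function(y, p, clamped = FALSE) {
  E <- y[[1L]]; R <- y[[2L]]; A <- y[[3L]]
  d1 <- y[[4L]]; d2 <- y[[5L]]; tr <- y[[6L]]
  bindR  <- p$kon_tcr * E * R        # TCE + TCR -> TCE_TCR
  bindA  <- p$kon_taa * E * A        # TCE + TAA -> TCE_TAA
  bindR2 <- p$kon_tcr * d2 * R       # TCE_TAA + TCR -> trimer
  bindA2 <- p$kon_taa * d1 * A       # TCE_TCR + TAA -> trimer
  c(if (clamped) 0 else -bindR - bindA + p$koff_tcr * d1 + p$koff_taa * d2,
    -bindR - bindR2 + p$koff_tcr * d1 + p$koff_tcr * tr +
      p$ksyn_tcr - p$kdeg_tcr * R,
    -bindA - bindA2 + p$koff_taa * d2 + p$koff_taa * tr +
      p$ksyn_taa - p$kdeg_taa * A,
    bindR - p$koff_tcr * d1 - bindA2 + p$koff_taa * tr -
      p$kint_tcr_dimer * d1,
    bindA - p$koff_taa * d2 - bindR2 + p$koff_tcr * tr -
      p$kint_taa_dimer * d2,
    bindR2 + bindA2 - (p$koff_tcr + p$koff_taa + p$kint_trimer) * tr)
}

## analytic 6x6 Jacobian of .rhs_raw (rows: equations, cols: species)
.jac_raw <- function(y, p, clamped = FALSE) {
  E <- y[[1L]]; R <- y[[2L]]; A <- y[[3L]]
  d1 <- y[[4L]]; d2 <- y[[5L]]
  a <- p$kon_tcr; b <- p$kon_taa
  qa <- p$koff_tcr; qb <- p$koff_taa
  J <- matrix(0, 6L, 6L)
  if (!clamped)
    J[1L, ] <- c(-a * R - b * A, -a * E, -b * E, qa, qb, 0)
  J[2L, ] <- c(-a * R, -a * E - a * d2 - p$kdeg_tcr, 0, qa, -a * R, qa)
  J[3L, ] <- c(-b * A, 0, -b * E - b * d1 - p$kdeg_taa, -b * A, qb, qb)
  J[4L, ] <- c(a * R, a * E, -b * d1, -qa - b * A - p$kint_tcr_dimer, 0, qb)
  J[5L, ] <- c(b * A, -a * d2, b * E, 0, -qb - a * R - p$kint_taa_dimer, qa)
  J[6L, ] <- c(0, a * d2, b * d1, b * A, a * R,
               -(qa + qb + p$kint_trimer))
  J
}

#' Instantaneous rates of change of the engagement system
#'
#' Evaluates the mass-action right-hand side: binding fluxes `kon * A * B`,
#' unbinding `koff * complex`, receptor turnover `ksyn - kdeg * free`, and
#' internalization `kint * complex`.  The trimer balance carries both
#' association routes (via either dimer) and both dissociation routes.  In
#' `"clamped"` exposure mode the free-TCE derivative is forced to zero
#' (constant local exposure) while every other balance sees the clamped
#' TCE value.
#'
#' @param state Named state vector (see [system_state()]).
#' @param params [engagement_params()].
#' @param exposure_mode `"free"` or `"clamped"`.
#' @return Named vector of derivatives, nM/s.
#' @export
engagement_rhs <- function(state, params,
                           exposure_mode = c("free", "clamped")) {
  exposure_mode <- match.arg(exposure_mode)
  state <- state[.SPECIES]
  if (any(!is.finite(state)) || any(state < 0))
    .stopf("state concentrations must be finite and non-negative")
  setNames(.rhs_raw(state, params, clamped = exposure_mode == "clamped"),
           .SPECIES)
}

#' Integrate the engagement kinetics
#'
#' Stiff integration (deSolve `vode`, BDF with the analytic 6x6 Jacobian;
#' the rate constants span many orders of magnitude, so the system is
#' permanently stiff) of the six-species system.  Two exposure modes: `"clamped"` holds free TCE at
#' `dose` for the whole run (sustained local exposure, the mode used for
#' steady-state dose-response); `"free"` treats the initial `dose` as a
#' closed drug pool that internalization slowly drains.
#'
#' Negative concentrations are never clipped; any reported value below
#' `-atol` aborts with an error, on the view that such excursions signal an
#' integrator misconfiguration rather than model behaviour.
#'
#' @param params [engagement_params()].
#' @param dose Free TCE, nM (initial value in `"free"` mode, held value in
#'   `"clamped"` mode).
#' @param exposure_mode `"clamped"` (default) or `"free"`.
#' @param initial Optional starting state; defaults to the drug-free
#'   baseline plus the dose.
#' @param t_end End time, seconds (default 48 h).
#' @param n_report Number of reported time points (the terminal state does
#'   not depend on it).
#' @param times Optional explicit report times (seconds, increasing,
#'   starting at 0); overrides `n_report`.
#' @param rtol,atol Integrator tolerances (nM for `atol`).
#' @return An `engagement_trajectory`: list with `times` (s), `states`
#'   (data.frame, one column per species), `exposure_mode`, `dose`,
#'   `params`.
#' @export
simulate_engagement <- function(params, dose,
                                exposure_mode = c("clamped", "free"),
                                initial = NULL,
                                t_end = 48 * 3600, n_report = 201,
                                times = NULL,
                                rtol = 1e-10, atol = 1e-14) {
  exposure_mode <- match.arg(exposure_mode)
  if (!is.finite(dose) || dose < 0) .stopf("dose must be non-negative")
  if (!is.finite(t_end) || t_end <= 0) .stopf("t_end must be positive")
  .validate_params(params)
  clamped <- exposure_mode == "clamped"
  if (is.null(initial)) initial <- baseline_state(params, dose)
  initial <- initial[.SPECIES]
  if (clamped) initial[["tce"]] <- dose
  if (is.null(times)) times <- seq(0, t_end, length.out = max(2L, n_report))

  deriv <- function(t, y, parms) list(.rhs_raw(y, parms, clamped))
  jac <- function(t, y, parms) .jac_raw(y, parms, clamped)
  out <- deSolve::vode(y = initial, times = times, func = deriv,
                       parms = params, jacfunc = jac, jactype = "fullusr",
                       mf = 21, rtol = rtol, atol = atol, maxsteps = 50000)
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0)
    .stopf(paste0("integrator failure (istate = %d) at dose = %g nM, ",
                  "mode = %s; parameters: %s"),
           istate, dose, exposure_mode,
           paste(sprintf("%s=%.6g", names(unclass(params))[1:15],
                         unlist(unclass(params))[1:15]), collapse = " "))
  states <- as.data.frame(out[, .SPECIES, drop = FALSE])
  low <- min(as.matrix(states))
  if (low < -atol)
    .stopf("negative concentration %.3g nM beyond tolerance; tighten rtol/atol",
           low)
  structure(list(times = out[, "time"], states = states,
                 exposure_mode = exposure_mode, dose = dose, params = params),
            class = "engagement_trajectory")
}

#' @export
print.engagement_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Engagement trajectory: %d points over %.3g h, %s exposure at %g nM\n",
              n, max(x$times) / 3600, x$exposure_mode, x$dose))
  cat("terminal state (nM):\n")
  print(unlist(x$states[n, ]))
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x An `engagement_trajectory`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame with columns `time_s`, `species`, `concentration_nM`,
#'   `dose_nM`, `exposure_mode`.
#' @export
as.data.frame.engagement_trajectory <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  n <- length(x$times)
  data.frame(time_s = rep(x$times, times = length(.SPECIES)),
             species = rep(.SPECIES, each = n),
             concentration_nM = unlist(x$states, use.names = FALSE),
             dose_nM = x$dose,
             exposure_mode = x$exposure_mode,
             stringsAsFactors = FALSE)
}

#' First-order exponential decay of drug exposure
#'
#' Standalone pharmacokinetic utility (not coupled into the ODE system):
#' concentration remaining after `t` hours given an elimination half-life.
#' A molecule with a 7-day (168 h) half-life loses only about 9.4% of its
#' concentration over 24 h, which motivates treating exposure as constant
#' on the timescale of binding equilibration.
#'
#' @param c0 Initial concentration, nM.
#' @param half_life Elimination half-life, hours.
#' @param t Elapsed time, hours.
#' @return Concentration at `t`, nM: `c0 * 2^(-t / half_life)`.
#' @examples
#' exposure_decay(100, half_life = 7 * 24, t = 24)  # ~90.6 nM
#' @export
exposure_decay <- function(c0, half_life, t) {
  if (any(!is.finite(c0)) || any(c0 < 0)) .stopf("c0 must be non-negative")
  if (!is.finite(half_life) || half_life <= 0)
    .stopf("half_life must be positive")
  if (any(!is.finite(t)) || any(t < 0)) .stopf("t must be non-negative")
  c0 * 2^(-t / half_life)
}
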