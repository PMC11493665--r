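## Monte-Carlo robustness of the dose-response shape.
##
## Each independent parameter is multiplied by a random factor in
## [1/fold, fold]; the dependent rates (koff, ksyn) are re-derived from the
## perturbed independents, never sampled on their own.  Per-draw seed
## substreams make the ensemble prefix-stable: enlarging n reproduces the
## earlier draws unchanged.

## run `expr` under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.draw_seed <- function(seed, i) (as.numeric(seed) + 1664525 * i) %% 2147483647

## apply multiplicative factors to the independent parameters of `base`,
## re-deriving koff (scales with kd * kon factors, preserving the base
## dialect) and ksyn (= kdeg * baseline)
.apply_factors <- function(base, f) {
  engagement_params(
    kd_tcr = base$kd_tcr * f[["kd_tcr"]],
    kd_taa = base$kd_taa * f[["kd_taa"]],
    kon_tcr = base$kon_tcr * f[["kon_tcr"]],
    kon_taa = base$kon_taa * f[["kon_taa"]],
    kdeg_tcr = base$kdeg_tcr * f[["kdeg_tcr"]],
    kdeg_taa = base$kdeg_taa * f[["kdeg_taa"]],
    kint_tcr_dimer = base$kint_tcr_dimer * f[["kint_tcr_dimer"]],
    kint_taa_dimer = base$kint_taa_dimer * f[["kint_taa_dimer"]],
    kint_trimer = base$kint_trimer * f[["kint_trimer"]],
    baseline_tcr = base$baseline_tcr * f[["baseline_tcr"]],
    baseline_taa = base$baseline_taa * f[["baseline_taa"]],
    koff_tcr = base$koff_tcr * f[["kd_tcr"]] * f[["kon_tcr"]],
    koff_taa = base$koff_taa * f[["kd_taa"]] * f[["kon_taa"]])
}

#' Random multiplicative perturbations of the independent parameters
#'
#' Draws `n` parameter sets in which every independent parameter of `base`
#' (association rates, affinities, degradation and internalization rates,
#' baseline receptor concentrations -- 11 in total) is multiplied by an
#' independent random factor in `[1/fold, fold]`.  Dependent rates are
#' re-derived: `koff` scales with the `kd` and `kon` factors (so the
#' `koff/(kd*kon)` ratio of the base dialect is preserved) and
#' `ksyn = kdeg * baseline` exactly.  The factor distribution is
#' log-uniform by default (symmetric on the fold scale); linear-uniform on
#' `[1/fold, fold]` is available.  Draw `i` uses its own seed substream
#' derived from `seed`, so the first draws are identical whatever `n` is.
#'
#' @param base [engagement_params()].
#' @param fold Maximum fold change (> 1).
#' @param n Number of draws.
#' @param seed Integer master seed.
#' @param distribution `"log-uniform"` (default) or `"uniform"`.
#' @return List of `n` `engagement_params`; the n x 11 factor matrix is
#'   attached as `attr(, "factors")`.
#' @export
perturb_params <- function(base, fold = 2, n, seed,
                           distribution = c("log-uniform", "uniform")) {
  distribution <- match.arg(distribution)
  if (!is.finite(fold) || fold <= 1) .stopf("fold must exceed 1")
  if (n < 1L) .stopf("n must be at least 1")
  .validate_params(base)
  k <- length(.INDEPENDENT_PARAMS)
  factors <- matrix(NA_real_, n, k,
                    dimnames = list(NULL, .INDEPENDENT_PARAMS))
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    f <- .with_seed(.draw_seed(seed, i), {
      if (distribution == "log-uniform")
        exp(runif(k, -log(fold), log(fold)))
      else
        runif(k, 1 / fold, fold)
    })
    names(f) <- .INDEPENDENT_PARAMS
    factors[i, ] <- f
    draws[[i]] <- .apply_factors(base, f)
  }
  structure(draws, factors = factors)
}

#' Perturbation ensemble with dose-response shape classification
#'
#' Draws a perturbed parameter ensemble ([perturb_params()]), sweeps each
#' draw's equilibrium dose-response ([sweep_dose_response()]) and records
#' whether the qualitative shape is retained: the trimer curve must be
#' bell-shaped ([describe_curve()]) with a single interior maximum on the
#' grid.
#'
#' @inheritParams perturb_params
#' @param dose_min,dose_max,n_points Dose grid (defaults as in
#'   [sweep_dose_response()]).
#' @return A `perturbation_ensemble`: list with `summary` (data.frame:
#'   `draw`, the 11 factor columns, `peak_trimer`, `peak_dose`, `is_bell`,
#'   `shape_retained`), `curves` (list of `dose_response_curve`), `base`,
#'   `fold`, `n`, `seed`, `distribution`.
#' @export
run_perturbation_ensemble <- function(base, fold = 2, n = 200L, seed = 1L,
                                      distribution = c("log-uniform", "uniform"),
                                      dose_min = 1e-3, dose_max = 1e6,
                                      n_points = 61L) {
  distribution <- match.arg(distribution)
  draws <- perturb_params(base, fold, n, seed, distribution)
  curves <- vector("list", n)
  peak_trimer <- peak_dose <- numeric(n)
  is_bell <- retained <- logical(n)
  for (i in seq_len(n)) {
    curves[[i]] <- sweep_dose_response(draws[[i]], dose_min, dose_max,
                                       n_points)
    d <- describe_curve(curves[[i]])
    peak_trimer[i] <- d$peak_trimer
    peak_dose[i] <- if (is.na(d$peak_dose)) NA_real_ else d$peak_dose
    is_bell[i] <- d$is_bell
    retained[i] <- d$is_bell && .single_interior_max(curves[[i]]$trimer)
  }
  summary <- data.frame(draw = seq_len(n), attr(draws, "factors"),
                        peak_trimer = peak_trimer, peak_dose = peak_dose,
                        is_bell = is_bell, shape_retained = retained)
  structure(list(summary = summary, curves = curves, base = base,
                 fold = fold, n = n, seed = seed,
                 distribution = distribution),
            class = "perturbation_ensemble")
}

#' Fraction of perturbed draws retaining the bell shape
#'
#' @param ensemble A `perturbation_ensemble`.
#' @return Fraction in `[0, 1]` of draws whose trimer dose-response is
#'   bell-shaped with a single interior maximum.
#' @export
shape_robustness <- function(ensemble) {
  stopifnot(inherits(ensemble, "perturbation_ensemble"))
  mean(ensemble$summary$shape_retained)
}

#' @export
print.perturbation_ensemble <- function(x, ...) {
  cat(sprintf("Perturbation ensemble: n = %d, fold = %g (%s), seed = %s\n",
              x$n, x$fold, x$distribution, format(x$seed)))
  cat(sprintf("shape retained: %.1f%% of draws\n", 100 * shape_robustness(x)))
  invisible(x)
}
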