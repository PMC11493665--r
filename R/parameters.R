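#' @importFrom stats runif setNames approx
#' @importFrom utils read.csv write.csv modifyList
NULL

## Avogadro constant, exact SI value (mol^-1)
.AVOGADRO <- 6.02214076e23

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Convert surface-receptor copy numbers to a molar concentration
#'
#' Turns a cell density, the fraction of those cells carrying the receptor,
#' and the number of receptor copies per cell into a bulk concentration in
#' nanomolar, assuming the receptors are dissolved in the same (well-mixed)
#' volume as the cells.
#'
#' @param cell_density Cells per litre.
#' @param fraction Fraction of cells carrying the receptor, in `[0, 1]`.
#' @param copies_per_cell Receptor copies per carrying cell.
#' @return Concentration in nM.
#' @examples
#' # T-cell receptors on blood lymphocytes:
#' receptors_to_concentration(2.4e9, 0.85, 1e5)
#' @export
receptors_to_concentration <- function(cell_density, fraction, copies_per_cell) {
  args <- c(cell_density = cell_density, fraction = fraction,
            copies_per_cell = copies_per_cell)
  if (any(!is.finite(args)))
    .stopf("all arguments must be finite")
  if (any(args < 0))
    .stopf("negative argument to receptors_to_concentration(): %s",
           paste(names(args)[args < 0], collapse = ", "))
  if (fraction > 1)
    .stopf("fraction must not exceed 1 (got %g)", fraction)
  # copies/L -> mol/L -> nmol/L
  cell_density * fraction * copies_per_cell / .AVOGADRO * 1e9
}

#' Dissociation rate constant from affinity and association rate
#'
#' `Kd = koff / kon`, hence `koff = Kd * kon`.
#'
#' @param kd Equilibrium dissociation constant, nM.
#' @param kon Association rate constant, nM^-1 s^-1.
#' @return `koff` in s^-1.
#' @export
derive_koff <- function(kd, kon) {
  if (!is.finite(kd) || kd <= 0) .stopf("kd must be positive (got %g)", kd)
  if (!is.finite(kon) || kon <= 0) .stopf("kon must be positive (got %g)", kon)
  kd * kon
}

#' Synthesis rate that balances degradation at a target baseline
#'
#' With zeroth-order synthesis and first-order degradation the drug-free
#' fixed point of a receptor pool is `ksyn / kdeg`; this returns the `ksyn`
#' that places that fixed point at `baseline_concentration`.
#'
#' @param kdeg First-order degradation rate constant, s^-1.
#' @param baseline_concentration Desired drug-free receptor concentration, nM.
#' @return `ksyn` in nM s^-1.
#' @export
derive_ksyn <- function(kdeg, baseline_concentration) {
  if (!is.finite(kdeg) || kdeg <= 0) .stopf("kdeg must be positive (got %g)", kdeg)
  if (!is.finite(baseline_concentration) || baseline_concentration < 0)
    .stopf("baseline_concentration must be non-negative (got %g)",
           baseline_concentration)
  kdeg * baseline_concentration
}

#' Cell-level physiological context
#'
#' Bundles the cell densities and per-cell receptor copy numbers needed to
#' translate tissue physiology into the molar receptor concentrations that
#' drive the kinetic model (see [receptors_to_concentration()]).
#'
#' @param lymphocyte_density Lymphocytes per litre.
#' @param t_cell_fraction Fraction of lymphocytes that are T cells.
#' @param b_cell_fraction Fraction of lymphocytes that are (target) B cells.
#' @param tcr_copies_per_cell TCR complexes per T cell.
#' @param taa_copies_per_cell Target-antigen copies per B cell.
#' @return An object of class `cell_context`.
#' @examples
#' ctx <- cell_context()
#' tcr_concentration(ctx)
#' @export
cell_context <- function(lymphocyte_density = 2.4e9,
                         t_cell_fraction = 0.85,
                         b_cell_fraction = 0.15,
                         tcr_copies_per_cell = 1e5,
                         taa_copies_per_cell = 1e4) {
  vals <- c(lymphocyte_density = lymphocyte_density,
            t_cell_fraction = t_cell_fraction,
            b_cell_fraction = b_cell_fraction,
            tcr_copies_per_cell = tcr_copies_per_cell,
            taa_copies_per_cell = taa_copies_per_cell)
  if (any(!is.finite(vals)) || any(vals < 0))
    .stopf("all cell_context fields must be finite and non-negative")
  if (t_cell_fraction > 1 || b_cell_fraction > 1)
    .stopf("cell fractions must not exceed 1")
  if (t_cell_fraction + b_cell_fraction > 1 + 1e-12)
    .stopf("t_cell_fraction + b_cell_fraction must not exceed 1 (got %g)",
           t_cell_fraction + b_cell_fraction)
  structure(as.list(vals), class = "cell_context")
}

#' @rdname cell_context
#' @param ctx A `cell_context`.
#' @export
tcr_concentration <- function(ctx) {
  receptors_to_concentration(ctx$lymphocyte_density, ctx$t_cell_fraction,
                             ctx$tcr_copies_per_cell)
}

#' @rdname cell_context
#' @export
taa_concentration <- function(ctx) {
  receptors_to_concentration(ctx$lymphocyte_density, ctx$b_cell_fraction,
                             ctx$taa_copies_per_cell)
}

#' @export
print.cell_context <- function(x, ...) {
  cat("Cell context\n")
  cat(sprintf("  lymphocytes: %.3g cells/L (T %.2f, B %.2f)\n",
              x$lymphocyte_density, x$t_cell_fraction, x$b_cell_fraction))
  cat(sprintf("  TCR: %.3g copies/cell -> %.4g nM\n",
              x$tcr_copies_per_cell, tcr_concentration(x)))
  cat(sprintf("  TAA: %.3g copies/cell -> %.4g nM\n",
              x$taa_copies_per_cell, taa_concentration(x)))
  invisible(x)
}

## independent parameters of the engagement model; koff and ksyn are derived
.INDEPENDENT_PARAMS <- c("kon_tcr", "kon_taa", "kd_tcr", "kd_taa",
                         "kdeg_tcr", "kdeg_taa",
                         "kint_tcr_dimer", "kint_taa_dimer", "kint_trimer",
                         "baseline_tcr", "baseline_taa")

#' Rate constants and affinities of the trimer-formation model
#'
#' Validated container for every rate constant of the engagement kinetics:
#' association/dissociation of the TCE with TCR and with the
#' tumour-associated antigen (TAA), zeroth-order receptor synthesis balanced
#' by first-order degradation, and first-order internalization of
#' drug-bound complexes.  Canonical units are nM and seconds throughout.
#'
#' `koff_tcr`/`koff_taa` default to `kd * kon` ([derive_koff()]); passing
#' them explicitly permits parameter sets in which the printed `koff` does
#' not equal `kd * kon` (see [table1_preset()]).  `ksyn_*` are always
#' derived from `kdeg_* * baseline_*` so that the drug-free fixed point of
#' each receptor pool sits exactly at its baseline concentration.
#'
#' @param kd_tcr,kd_taa Dissociation constants, nM.
#' @param kon_tcr,kon_taa Association rate constants, nM^-1 s^-1.
#' @param kdeg_tcr,kdeg_taa Free-receptor degradation rates, s^-1 (may be 0).
#' @param kint_tcr_dimer,kint_taa_dimer,kint_trimer Internalization rates of
#'   the bound complexes, s^-1 (may be 0).
#' @param baseline_tcr,baseline_taa Drug-free receptor concentrations, nM.
#' @param koff_tcr,koff_taa Dissociation rates, s^-1; `NULL` means derive
#'   from `kd * kon`.
#' @return An object of class `engagement_params` with fields
#'   `kon_*`, `koff_*`, `kd_*`, `ksyn_*`, `kdeg_*`, `kint_*`, `baseline_*`
#'   and a logical `consistent` flag that records whether
#'   `koff == kd * kon` holds (relative tolerance 1e-12) for both arms.
#' @seealso [table1_preset()], [perturb_params()]
#' @export
engagement_params <- function(kd_tcr, kd_taa,
                              kon_tcr = 1e-4, kon_taa = 1e-4,
                              kdeg_tcr = 0, kdeg_taa = 0,
                              kint_tcr_dimer = 0, kint_taa_dimer = 0,
                              kint_trimer = 0,
                              baseline_tcr, baseline_taa,
                              koff_tcr = NULL, koff_taa = NULL) {
  if (is.null(koff_tcr)) koff_tcr <- derive_koff(kd_tcr, kon_tcr)
  if (is.null(koff_taa)) koff_taa <- derive_koff(kd_taa, kon_taa)
  p <- list(kon_tcr = kon_tcr, koff_tcr = koff_tcr,
            kon_taa = kon_taa, koff_taa = koff_taa,
            kd_tcr = kd_tcr, kd_taa = kd_taa,
            ksyn_tcr = kdeg_tcr * baseline_tcr, kdeg_tcr = kdeg_tcr,
            ksyn_taa = kdeg_taa * baseline_taa, kdeg_taa = kdeg_taa,
            kint_tcr_dimer = kint_tcr_dimer,
            kint_taa_dimer = kint_taa_dimer,
            kint_trimer = kint_trimer,
            baseline_tcr = baseline_tcr, baseline_taa = baseline_taa)
  .validate_params(p)
  p$consistent <- .koff_consistent(p)
  structure(p, class = "engagement_params")
}

.koff_consistent <- function(p, rel_tol = 1e-12) {
  ok <- function(koff, kd, kon) abs(koff - kd * kon) <= rel_tol * kd * kon
  ok(p$koff_tcr, p$kd_tcr, p$kon_tcr) && ok(p$koff_taa, p$kd_taa, p$kon_taa)
}

.validate_params <- function(p) {
  strict <- c("kon_tcr", "koff_tcr", "kon_taa", "koff_taa",
              "kd_tcr", "kd_taa", "baseline_tcr", "baseline_taa")
  nonneg <- c("ksyn_tcr", "kdeg_tcr", "ksyn_taa", "kdeg_taa",
              "kint_tcr_dimer", "kint_taa_dimer", "kint_trimer")
  v <- unlist(p[c(strict, nonneg)])
  if (any(!is.finite(v)))
    .stopf("non-finite parameter: %s",
           paste(names(v)[!is.finite(v)], collapse = ", "))
  bad <- unlist(p[strict]) <= 0
  if (any(bad))
    .stopf("parameter must be strictly positive: %s",
           paste(strict[bad], collapse = ", "))
  bad <- unlist(p[nonneg]) < 0
  if (any(bad))
    .stopf("parameter must be non-negative: %s",
           paste(nonneg[bad], collapse = ", "))
  invisible(p)
}

#' Literature-derived physiological parameter preset
#'
#' The built-in baseline parameterization of the model: micromolar TCE
#' affinity for the TCR (Kd 1000 nM) on T cells expressing 1e5 receptor
#' copies, nanomolar affinity for a B-cell antigen (Kd 1 nM) at 1e4
#' copies/cell, association rates of 1e5 M^-1 s^-1 for both arms, receptor
#' half-life of ~10.5 h (kdeg 1.834e-5 s^-1) and internalization of bound
#' receptor at 5.501e-5 s^-1.  Baseline receptor concentrations are taken
#' from the synthesis/degradation ratios of the preset (7.246 nM TCR,
#' 0.04194 nM TAA); use [receptors_to_concentration()] to build contexts
#' from explicit cell counts instead.
#'
#' The preset exists in two dialects because the published dissociation
#' rates are not consistent with `Kd * kon` (0.26 s^-1 vs 0.1 s^-1 for the
#' TCR arm; 1.49e-3 s^-1 vs 1e-4 s^-1 for the TAA arm):
#' \describe{
#'   \item{`"as-printed"`}{every rate exactly as tabulated; the
#'     `consistent` field of the result is `FALSE`.}
#'   \item{`"consistent"`}{keeps `Kd`, `kon`, `kdeg`, `kint` and the
#'     baselines, and re-derives `koff = Kd * kon` (and `ksyn`).}
#' }
#'
#' @param mode `"as-printed"` (default) or `"consistent"`.
#' @return An [engagement_params()] object.
#' @examples
#' table1_preset()$koff_tcr              # 0.26
#' table1_preset("consistent")$koff_tcr  # 0.1
#' @export
table1_preset <- function(mode = c("as-printed", "consistent")) {
  mode <- match.arg(mode)
  base <- list(kd_tcr = 1000, kd_taa = 1,
               kon_tcr = 1e-4, kon_taa = 1e-4,   # 1e5 M^-1 s^-1
               kdeg_tcr = 1.834e-5, kdeg_taa = 1.834e-5,
               kint_tcr_dimer = 5.501e-5, kint_taa_dimer = 5.501e-5,
               kint_trimer = 1.834e-5,
               # drug-free pools implied by the tabulated ksyn/kdeg ratios
               baseline_tcr = 1.329e-4 / 1.834e-5,
               baseline_taa = 7.691e-7 / 1.834e-5)
  if (mode == "as-printed") {
    base$koff_tcr <- 0.26
    base$koff_taa <- 0.00149
  }
  do.call(engagement_params, base)
}

#' Scale one independent parameter of a parameter set
#'
#' Returns a copy of `params` with `field` multiplied by `mult` and the
#' dependent rates re-derived: `ksyn = kdeg * baseline` always, and when an
#' affinity (`kd_*`) or association rate (`kon_*`) moves, the matching
#' `koff` is scaled by the same factor so the `koff/(kd*kon)` ratio of the
#' original dialect is preserved.
#'
#' @param params [engagement_params()].
#' @param field One of the independent parameter names (e.g. `"kd_tcr"`,
#'   `"baseline_taa"`).
#' @param mult Positive multiplier.
#' @return [engagement_params()].
#' @examples
#' high_affinity <- scale_params(table1_preset(), "kd_tcr", 0.1)
#' @export
scale_params <- function(params, field, mult) {
  if (!field %in% .INDEPENDENT_PARAMS)
    .stopf("field must be one of: %s",
           paste(.INDEPENDENT_PARAMS, collapse = ", "))
  if (!is.finite(mult) || mult <= 0) .stopf("mult must be positive")
  args <- c(params[.INDEPENDENT_PARAMS],
            params[c("koff_tcr", "koff_taa")])
  args[[field]] <- args[[field]] * mult
  if (field %in% c("kd_tcr", "kon_tcr")) args$koff_tcr <- args$koff_tcr * mult
  if (field %in% c("kd_taa", "kon_taa")) args$koff_taa <- args$koff_taa * mult
  do.call(engagement_params, args)
}

#' @export
print.engagement_params <- function(x, ...) {
  cat("Engagement parameters (nM, s)",
      if (!x$consistent) " [koff != kd*kon]" else "", "\n", sep = "")
  fmt <- function(k) sprintf("  %-16s %.6g", k, x[[k]])
  keys <- c("kd_tcr", "kon_tcr", "koff_tcr", "kd_taa", "kon_taa", "koff_taa",
            "ksyn_tcr", "kdeg_tcr", "ksyn_taa", "kdeg_taa",
            "kint_tcr_dimer", "kint_taa_dimer", "kint_trimer",
            "baseline_tcr", "baseline_taa")
  cat(paste(vapply(keys, fmt, ""), collapse = "\n"), "\n")
  invisible(x)
}
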