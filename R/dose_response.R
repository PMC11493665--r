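## Equilibrium dose-response sweeps and curve comparison.
##
## Trimer formation over a log-spaced dose grid is bell-shaped (the hook
## effect): at low dose there is too little drug to bridge, at high dose
## each arm is saturated separately and inactive dimers outcompete the
## ternary complex.  Curve descriptors reduce a sweep to peak height, peak
## dose and plateau bounds; shift reports compare two curves to express
## how expression levels and affinities displace the curve.

#' Equilibrium dose-response sweep
#'
#' Computes the clamped-exposure steady state ([steady_state_algebraic()])
#' on a log-spaced dose grid, warm-starting each solve from the previous
#' dose (homotopy continuation along the grid).
#'
#' @param params [engagement_params()].
#' @param dose_min,dose_max Grid end points, nM (0 < min < max).
#' @param n_points Number of grid points (>= 8).
#' @return A `dose_response_curve`: data.frame with columns `dose`,
#'   `trimer`, `dimer_tcr`, `dimer_taa` (nM) and the generating parameters
#'   in `attr(, "params")`.
#' @examples
#' curve <- sweep_dose_response(table1_preset(), n_points = 31)
#' describe_curve(curve)
#' @export
sweep_dose_response <- function(params, dose_min = 1e-3, dose_max = 1e6,
                                n_points = 61L) {
  if (!is.finite(dose_min) || !is.finite(dose_max) ||
      dose_min <= 0 || dose_min >= dose_max)
    .stopf("need 0 < dose_min < dose_max")
  if (n_points < 8L) .stopf("n_points must be at least 8")
  .validate_params(params)
  doses <- 10^seq(log10(dose_min), log10(dose_max), length.out = n_points)
  out <- matrix(NA_real_, n_points, 3L,
                dimnames = list(NULL, c("trimer", "tce_tcr", "tce_taa")))
  ok <- logical(n_points)
  u <- NULL
  for (i in seq_len(n_points)) {
    core <- .steady_core(params, doses[i], u0 = u)
    if (!core$converged) core <- .steady_core(params, doses[i], u0 = NULL)
    u <- core$u
    ok[i] <- core$converged
    out[i, ] <- core$state[c("trimer", "tce_tcr", "tce_taa")]
  }
  if (!all(ok))
    .stopf("steady state did not converge at dose(s): %s nM",
           paste(signif(doses[!ok], 4), collapse = ", "))
  structure(data.frame(dose = doses, trimer = out[, "trimer"],
                       dimer_tcr = out[, "tce_tcr"],
                       dimer_taa = out[, "tce_taa"]),
            params = params,
            class = c("dose_response_curve", "data.frame"))
}

## quadratic vertex through three (x, y) points; NULL if not concave
.quad_vertex <- function(x, y) {
  d1 <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d2 <- (y[3L] - y[2L]) / (x[3L] - x[2L])
  curv <- (d2 - d1) / (x[3L] - x[1L])
  if (!is.finite(curv) || curv >= 0) return(NULL)
  xv <- (x[1L] + x[2L]) / 2 - d1 / (2 * curv)
  xv <- min(max(xv, x[1L]), x[3L])
  yv <- y[1L] + d1 * (xv - x[1L]) + curv * (xv - x[1L]) * (xv - x[2L])
  list(x = xv, y = max(yv, max(y)))
}

## dose where the trimer curve crosses `level`, linear in log-dose between
## grid points i and i+1
.cross_dose <- function(doses, trimer, i, level) {
  lx <- log10(doses)
  frac <- (level - trimer[i]) / (trimer[i + 1L] - trimer[i])
  10^(lx[i] + frac * (lx[i + 1L] - lx[i]))
}

#' Scalar descriptors of a dose-response curve
#'
#' Peak trimer level and dose (grid argmax refined by quadratic
#' interpolation in log-dose, so comparisons resolve below the grid
#' spacing), the dose interval where the trimer stays at or above
#' `plateau_fraction` of the peak, and a bell-shape flag (`is_bell`):
#' the curve must rise by at least 5% and then fall by at least 5% across
#' the grid with an interior maximum.
#'
#' @param curve A `dose_response_curve`.
#' @param plateau_fraction Plateau threshold as a fraction of peak
#'   (default 0.95).
#' @return A `curve_descriptor` list: `peak_trimer`, `peak_dose`,
#'   `plateau_low`, `plateau_high`, `is_bell`.
#' @export
describe_curve <- function(curve, plateau_fraction = 0.95) {
  stopifnot(inherits(curve, "data.frame"), nrow(curve) >= 1L)
  tr <- curve$trimer
  doses <- curve$dose
  n <- length(tr)
  if (all(tr == 0))
    return(structure(list(peak_trimer = 0, peak_dose = NA_real_,
                          plateau_low = NA_real_, plateau_high = NA_real_,
                          is_bell = FALSE),
                     class = "curve_descriptor"))
  i <- which.max(tr)
  peak_trimer <- tr[i]
  peak_dose <- doses[i]
  if (i > 1L && i < n) {
    v <- .quad_vertex(log10(doses[(i - 1L):(i + 1L)]), tr[(i - 1L):(i + 1L)])
    if (!is.null(v)) {
      peak_dose <- 10^v$x
      peak_trimer <- v$y
    }
  }
  level <- plateau_fraction * peak_trimer
  above <- tr >= level
  # contiguous run around the argmax
  lo <- i; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- i; while (hi < n && above[hi + 1L]) hi <- hi + 1L
  plateau_low <- if (lo == 1L) doses[1L] else
    .cross_dose(doses, tr, lo - 1L, level)
  plateau_high <- if (hi == n) doses[n] else
    .cross_dose(doses, tr, hi, level)
  rises <- tr[1L] == 0 || max(tr) >= 1.05 * tr[1L]
  falls <- tr[n] <= 0.95 * max(tr)
  structure(list(peak_trimer = peak_trimer, peak_dose = peak_dose,
                 plateau_low = plateau_low, plateau_high = plateau_high,
                 is_bell = rises && falls && i > 1L && i < n),
            class = "curve_descriptor")
}

#' @export
print.curve_descriptor <- function(x, ...) {
  cat(sprintf("Peak trimer %.4g nM at %.4g nM dose%s\n", x$peak_trimer,
              x$peak_dose, if (x$is_bell) " (bell-shaped)" else ""))
  cat(sprintf("Plateau (>= 95%% peak): %.4g - %.4g nM\n",
              x$plateau_low, x$plateau_high))
  invisible(x)
}

## single interior maximum: non-decreasing up to argmax then non-increasing,
## within a small relative wiggle tolerance
.single_interior_max <- function(trimer, rel_tol = 1e-9) {
  n <- length(trimer)
  i <- which.max(trimer)
  if (i == 1L || i == n) return(FALSE)
  eps <- rel_tol * max(trimer)
  all(diff(trimer[1:i]) >= -eps) && all(diff(trimer[i:n]) <= eps)
}

#' Classify the displacement between two dose-response curves
#'
#' Compares descriptor ratios of curve `b` against reference `a` on the
#' same dose grid.  `vertical_ratio` is the peak-trimer ratio b/a;
#' `horizontal_ratio` the peak-dose ratio; `plateau_low_ratio` the ratio of
#' the doses where the plateau begins (the "exposure at which the plateau
#' is reached").  Classification at threshold `theta` (default 0.10):
#' "up" if `vertical_ratio > 1 + theta`, "down" if `< 1 - theta`; "left"
#' if `horizontal_ratio < 1 - theta`, "right" if `> 1 + theta`; combined
#' labels are hyphenated ("up-left"), and "none" means no component moved
#' beyond threshold.
#'
#' @param a,b `dose_response_curve`s on identical dose grids.
#' @param theta Classification threshold (fractional).
#' @return A `shift_report` list: the three ratios and `classification`.
#' @export
compare_curves <- function(a, b, theta = 0.10) {
  if (!isTRUE(all.equal(a$dose, b$dose)))
    .stopf("curves must share an identical dose grid")
  da <- describe_curve(a)
  db <- describe_curve(b)
  vr <- db$peak_trimer / da$peak_trimer
  hr <- db$peak_dose / da$peak_dose
  pr <- db$plateau_low / da$plateau_low
  vert <- if (vr > 1 + theta) "up" else if (vr < 1 - theta) "down" else ""
  horiz <- if (hr < 1 - theta) "left" else if (hr > 1 + theta) "right" else ""
  cls <- paste(c(vert, horiz)[c(vert, horiz) != ""], collapse = "-")
  if (cls == "") cls <- "none"
  structure(list(vertical_ratio = vr, horizontal_ratio = hr,
                 plateau_low_ratio = pr, classification = cls,
                 theta = theta),
            class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("Shift: %s (vertical %.3g, horizontal %.3g, plateau-onset %.3g; theta = %g)\n",
              x$classification, x$vertical_ratio, x$horizontal_ratio,
              x$plateau_low_ratio, x$theta))
  invisible(x)
}
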