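## Figure regeneration.  Plots are always drawn from the exported CSV
## artifacts, never from in-memory state, so every figure can be rebuilt
## from shipped outputs alone.  ggplot2 is an optional dependency.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    .stopf("figure functions require the ggplot2 package")
}

## stack curve CSVs into one long data.frame with a condition label
.stack_curves <- function(paths) {
  do.call(rbind, lapply(names(paths), function(lab) {
    cv <- read_curve_csv(paths[[lab]])
    data.frame(condition = lab, cv)
  }))
}

#' Plot equilibrium dose-response curves from CSV artifacts
#'
#' @param paths Named character vector of curve CSV paths (written by
#'   [write_curve_csv()]); names label the conditions.
#' @param species Which species to draw (subset of `"trimer"`,
#'   `"dimer_tcr"`, `"dimer_taa"`).
#' @return A ggplot object (log-log axes).
#' @export
plot_dose_response_csv <- function(paths,
                                   species = c("trimer", "dimer_tcr",
                                               "dimer_taa")) {
  .need_ggplot()
  species <- match.arg(species, several.ok = TRUE)
  df <- .stack_curves(as.list(paths))
  long <- do.call(rbind, lapply(species, function(s)
    data.frame(condition = df$condition, dose = df$dose, species = s,
               concentration = df[[s]])))
  long <- long[long$concentration > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(x = dose, y = concentration,
                                     colour = condition,
                                     linetype = species)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "TCE dose (nM)", y = "Concentration (nM)") +
    ggplot2::theme_minimal()
}

#' Regenerate the standard figure set
#'
#' Writes the CSV artifacts and PNG figures for the four standard views of
#' the model into `out_dir`:
#' \describe{
#'   \item{fig_baseline}{trimer and both dimers vs dose at the preset.}
#'   \item{fig_taa_expression}{trimer curves at 0.5x / 1x / 2x TAA
#'     baseline (vertical shift; plateau onset unchanged).}
#'   \item{fig_kd_tcr}{trimer curves at 0.1x / 1x / 10x TCR Kd
#'     (up-and-left shift for higher affinity).}
#'   \item{fig_kd_taa}{trimer curves at 0.1x / 1x / 10x TAA Kd
#'     (mainly leftward shift for higher affinity).}
#' }
#'
#' @param out_dir Output directory.
#' @param dialect Preset dialect (see [table1_preset()]).
#' @param dose_min,dose_max,n_points Dose grid.
#' @return Character vector of PNG paths, invisibly.
#' @export
reproduce_figures <- function(out_dir, dialect = "as-printed",
                              dose_min = 1e-3, dose_max = 1e6,
                              n_points = 61L) {
  .need_ggplot()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- table1_preset(dialect)
  write_variant <- function(tag, field, mults) {
    paths <- character(0)
    for (m in mults) {
      p <- if (is.null(field)) base else scale_params(base, field, m)
      cv <- sweep_dose_response(p, dose_min, dose_max, n_points)
      f <- file.path(out_dir, sprintf("%s_%gx.csv", tag, m))
      write_curve_csv(cv, f)
      paths[sprintf("%gx", m)] <- f
    }
    paths
  }
  pngs <- character(0)
  save_png <- function(name, plot) {
    f <- file.path(out_dir, paste0(name, ".png"))
    ggplot2::ggsave(f, plot, width = 6, height = 4, dpi = 150)
    pngs[[name]] <<- f
  }
  p0 <- write_variant("fig_baseline", NULL, 1)
  save_png("fig_baseline", plot_dose_response_csv(p0))
  p1 <- write_variant("fig_taa_expression", "baseline_taa", c(0.5, 1, 2))
  save_png("fig_taa_expression", plot_dose_response_csv(p1, "trimer"))
  p2 <- write_variant("fig_kd_tcr", "kd_tcr", c(0.1, 1, 10))
  save_png("fig_kd_tcr", plot_dose_response_csv(p2, "trimer"))
  p3 <- write_variant("fig_kd_taa", "kd_taa", c(0.1, 1, 10))
  save_png("fig_kd_taa", plot_dose_response_csv(p3, "trimer"))
  invisible(pngs)
}
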