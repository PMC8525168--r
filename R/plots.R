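# ggplot2 visualisations of runs and sweeps.

#' Plot trait trajectories of a run
#'
#' Generation-by-generation population means of the dispersal-tendency
#' locus and the two learning loci.
#'
#' @param object A `sim_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_run
#' @export
autoplot.sim_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$records,
    cols = c("mean_D", "mean_L_R_locus", "mean_L_D_locus"),
    names_to = "locus", values_to = "mean"
  )
  long$locus <- factor(long$locus,
                       levels = c("mean_L_R_locus", "mean_L_D_locus", "mean_D"),
                       labels = c("L_R", "L_D", "D"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$mean,
                                     colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Population mean locus value",
                  colour = "Locus") +
    ggplot2::theme_minimal()
}

#' Plot a sweep's equilibrium means
#'
#' One point (mean over replicates, error bar = SD) per cell for the two
#' learning loci and the dispersal tendency. The season-length sweep uses a
#' log2 x-axis of season length; the timing sweep uses the split labels.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  sm <- glance(object)
  long <- tidyr::pivot_longer(
    sm,
    cols = c("mean_L_R_locus", "mean_L_D_locus", "mean_D"),
    names_to = "locus", values_to = "mean"
  )
  sds <- tidyr::pivot_longer(
    sm,
    cols = c("sd_L_R_locus", "sd_L_D_locus", "sd_D"),
    names_to = "locus_sd", values_to = "sd"
  )
  long$sd <- sds$sd
  long$locus <- factor(long$locus,
                       levels = c("mean_L_R_locus", "mean_L_D_locus", "mean_D"),
                       labels = c("L_R", "L_D", "D"))
  if (object$sweep == "season_length") {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$season_length,
                                            y = .data$mean,
                                            colour = .data$locus)) +
      ggplot2::scale_x_continuous(trans = "log2") +
      ggplot2::labs(x = "Season length S")
  } else {
    long$cell <- sprintf("(%d,%d)", long$t_before, long$t_after)
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$mean,
                                            colour = .data$locus,
                                            group = .data$locus)) +
      ggplot2::labs(x = "(t_before, t_after)")
  }
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "Equilibrium mean (replicate mean ± SD)",
                  colour = "Locus") +
    ggplot2::theme_minimal()
}
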