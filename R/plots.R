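#' NRR size against generation
#'
#' One line per replicate (grey) plus the replicate mean (black); when more
#' than one replicate is present a mean +/- sd ribbon is drawn.
#'
#' @param reps A [run_replicates()] result.
#' @return A ggplot object.
#' @export
plot_nrr_timeseries <- function(reps) {
  stopifnot(inherits(reps, "sim_replicates"))
  g <- ggplot2::ggplot(reps$replicates,
                       ggplot2::aes(x = .data$generation, y = .data$nrr_bp)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       colour = "grey70", linewidth = 0.3)
  if (length(reps$seeds) > 1) {
    g <- g + ggplot2::geom_ribbon(
      data = reps$summary,
      ggplot2::aes(x = .data$generation,
                   ymin = pmax(0, .data$nrr_bp_mean - .data$nrr_bp_sd),
                   ymax = .data$nrr_bp_mean + .data$nrr_bp_sd),
      inherit.aes = FALSE, alpha = 0.2)
  }
  g + ggplot2::geom_line(
      data = reps$summary,
      ggplot2::aes(x = .data$generation, y = .data$nrr_bp_mean),
      inherit.aes = FALSE, linewidth = 0.8) +
    ggplot2::labs(x = "generation", y = "NRR size (bp)") +
    ggplot2::theme_minimal()
}

#' Final NRR size against a swept parameter
#'
#' @param sweep_result A [run_sweep()] tibble.
#' @param param Name of the swept column (e.g. `"mu"`, `"N"`, `"E"`).
#' @param colour Optional second column mapped to colour.
#' @return A ggplot object.
#' @export
plot_nrr_vs_parameter <- function(sweep_result, param, colour = NULL) {
  stopifnot(param %in% names(sweep_result))
  aes <- ggplot2::aes(x = .data[[param]], y = .data$nrr_bp_mean)
  g <- ggplot2::ggplot(sweep_result, aes)
  if (!is.null(colour))
    g <- g + ggplot2::aes(colour = factor(.data[[colour]]))
  g +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$nrr_bp_mean - .data$nrr_bp_sd),
      ymax = .data$nrr_bp_mean + .data$nrr_bp_sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = param, y = "mean final NRR size (bp)",
                  colour = colour) +
    ggplot2::theme_minimal()
}

#' Per-position male-female FST profile
#'
#' @param profile A profile tibble (from a `sim_run` or the `mean_profile`
#'   of a [run_replicates()] result).
#' @param sd_position Optional SD position to mark.
#' @return A ggplot object.
#' @export
plot_fst_profile <- function(profile, sd_position = NULL) {
  stopifnot(all(c("position", "fst") %in% names(profile)))
  g <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$position, y = .data$fst)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "position (bp)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
  if (!is.null(sd_position))
    g <- g + ggplot2::geom_vline(xintercept = sd_position,
                                 linetype = "dashed", colour = "red")
  g
}
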