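#' Plot a growth-volume sweep
#'
#' Growth rate against cell volume on log axes, one curve per taxon
#' group, optionally overlaid with an observation table.
#'
#' @param sweep a tibble from [sweep_growth()].
#' @param obs optional observations (`volume_um3`, `mu_per_day`, `group`).
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep, obs = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep() needs the ggplot2 package", call. = FALSE)
  }
  gg <- ggplot2::ggplot(sweep, ggplot2::aes(.data$volume_um3,
                                            .data$mu_per_day,
                                            colour = .data$group)) +
    ggplot2::geom_line()
  if (!is.null(obs)) {
    gg <- gg + ggplot2::geom_point(data = obs, alpha = 0.5)
  }
  gg +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Cell ~ volume ~ (mu * m^3)),
                  y = expression(Growth ~ rate ~ (d^-1)),
                  colour = "Group") +
    ggplot2::theme_bw()
}

#' Plot a fate-of-carbon sweep
#'
#' Stacked per-volume carbon fluxes against growth rate, in the order
#' biosynthesis, silica deposition, respiration, excretion.
#'
#' @param fate a tibble from [sweep_fate()].
#' @return a ggplot object.
#' @export
plot_fate <- function(fate) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fate() needs the ggplot2 package", call. = FALSE)
  }
  long <- dplyr::bind_rows(lapply(
    c("biosynthesis_per_volume", "silica_per_volume",
      "respiration_per_volume", "excretion_per_volume"),
    function(col) tibble::tibble(mu_per_day = fate$mu_per_day,
                                 flux = fate[[col]],
                                 fate = sub("_per_volume", "", col))
  ))
  ggplot2::ggplot(long, ggplot2::aes(.data$mu_per_day, .data$flux,
                                     fill = .data$fate)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = expression(Growth ~ rate ~ (d^-1)),
                  y = expression(C ~ flux ~ (mol ~ C ~ mu * m^-3 ~ d^-1)),
                  fill = "Fate of C") +
    ggplot2::theme_bw()
}
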