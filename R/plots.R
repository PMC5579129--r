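#' Fleet CPUE vs sharing level, with the 80% inter-agent interval
#'
#' Solid line: fleet-mean CPUE; ribbon: 10th-90th percentile of
#' agent-season CPUE, showing the spread of success within the fleet.
#'
#' @param analysis A [analyze_sweep()] result containing `fleet_cpue`.
#' @return A ggplot object, faceted by mobility and depletion.
#' @export
plot_cpue_curves <- function(analysis) {
  df <- analysis$fleet_cpue
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lam, y = .data$cpue_mean,
                                   colour = .data$management,
                                   fill = .data$management)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cpue_lo, ymax = .data$cpue_hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(depletion ~ tau_l,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(lambda), y = "CPUE (fish per unit effort)",
                  colour = "management", fill = "management")
}

#' Group-optimal sharing level vs species mobility
#'
#' Sharing level maximizing CPUE for successful (top) and unsuccessful
#' (bottom) percentile groups, across the mobility axis `1 / tau_l`
#' (log scale).
#'
#' @param analysis A [analyze_sweep()] result containing `group_optima`.
#' @return A ggplot object.
#' @export
plot_group_optima <- function(analysis) {
  df <- tidyr::pivot_longer(analysis$group_optima,
                            c("lam_plus", "lam_minus"),
                            names_to = "group", values_to = "lam_opt")
  ggplot2::ggplot(df, ggplot2::aes(x = 1 / .data$tau_l, y = .data$lam_opt,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(depletion ~ management,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "species mobility (1 / tau_l, log scale)",
                  y = expression(lambda ~ "maximizing group CPUE"))
}

#' Divergence map over mobility and depletion
#'
#' Heat map of the divergence index `1 - lam_plus / lam_minus` per
#' management regime; values near 0 mean all agents favor a similar
#' sharing level, values near 1 strongly diverging incentives.
#'
#' @param analysis A [analyze_sweep()] result containing `group_optima`.
#' @return A ggplot object.
#' @export
plot_divergence_map <- function(analysis) {
  ggplot2::ggplot(analysis$group_optima,
                  ggplot2::aes(x = 1 / .data$tau_l, y = .data$depletion,
                               fill = .data$divergence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::facet_wrap(~management) +
    ggplot2::labs(x = "species mobility (1 / tau_l, log scale)",
                  y = "depletion fraction T/P",
                  fill = expression(1 - lambda["+"] / lambda["-"]))
}

#' IFQ-vs-TAC CPUE advantage by group
#'
#' `H_IFQ / H_TAC - 1` across species mobility for the successful and
#' unsuccessful groups; positive favors IFQs, negative favors a TAC.
#'
#' @param analysis A [analyze_sweep()] result containing `ifq_tac`.
#' @return A ggplot object.
#' @export
plot_ifq_tac <- function(analysis) {
  ggplot2::ggplot(analysis$ifq_tac,
                  ggplot2::aes(x = 1 / .data$tau_l, y = .data$ratio,
                               colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~depletion, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "species mobility (1 / tau_l, log scale)",
                  y = expression(H[IFQ] / H[TAC] - 1))
}

#' Objective surfaces over mobility and sharing level
#'
#' The three normalized objectives (fleet catch rate, equity, stability)
#' over the (mobility, lambda) plane; each column of constant mobility has
#' maximum exactly 1.
#'
#' @param analysis A [analyze_sweep()] result containing `objectives`.
#' @return A ggplot object.
#' @export
plot_objective_surfaces <- function(analysis) {
  df <- tidyr::pivot_longer(analysis$objectives,
                            c("o_cpue", "o_equity", "o_stability"),
                            names_to = "objective", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = 1 / .data$tau_l, y = .data$lam,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::facet_grid(management ~ objective) +
    ggplot2::labs(x = "species mobility (1 / tau_l, log scale)",
                  y = expression(lambda), fill = "objective value")
}

#' @rdname plot_cpue_curves
#' @param object A `sweep_analysis`.
#' @param ... Unused.
#' @export
autoplot.sweep_analysis <- function(object, ...) {
  plot_cpue_curves(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
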