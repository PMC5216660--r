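# ggplot2 autoplot methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cycle-test profile with its analysis
#'
#' Orthophosphate and acetate traces over the cycle, split by redox phase.
#'
#' @param object A `cycle_fit` from [analyze_cycle()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cycle_fit <- function(object, ...) {
  prof <- tidyr::pivot_longer(object$profile, c("po4", "hac"),
                              names_to = "analyte", values_to = "conc")
  prof$analyte <- factor(prof$analyte, c("hac", "po4"),
                         c("acetate (C-mmol/L)", "ortho-P (P-mmol/L)"))
  ggplot2::ggplot(prof, ggplot2::aes(.data$t_min, .data$conc,
                                     colour = .data$phase)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$analyte), scales = "free_y") +
    ggplot2::labs(x = "time from end of feed (min)", y = NULL,
                  colour = NULL,
                  title = "SBR cycle test",
                  subtitle = sprintf("qSA = %.0f C-mmol/(C-mol h), P/HAc = %.2f",
                                     object$rates$per_cmol[1],
                                     object$stoichiometry$p_hac)) +
    ggplot2::theme_minimal()
}

#' Plot a mixing-model fit against its end members
#'
#' Each stoichiometric ratio interpolated between the glycogen-only
#' (`lam = 0`) and poly-P (`lam = 1`) end members, with the observed values
#' at the fitted mixing coefficient.
#'
#' @param object A `shift_fit` from [mixing_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_fit <- function(object, ...) {
  grid <- predict_stoichiometry(seq(0, 1, length.out = 101), object$ends)
  lines <- tidyr::pivot_longer(grid[, c("lam", "p_hac", "gly_hac",
                                        "phb_hac", "phv_hac")],
                               -"lam", names_to = "term",
                               values_to = "value")
  obs <- tidy(object)
  obs$lam <- object$lam
  ggplot2::ggplot(lines, ggplot2::aes(.data$lam, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$lam, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(.data$lam, .data$observed),
                        colour = "firebrick", size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(x = "mixing coefficient lam (0 = glycogen-only)",
                  y = "ratio per C-mol HAc",
                  title = sprintf("End-member mixing fit: lam = %.2f, ATP from poly-P = %.0f%%",
                                  object$lam, 100 * object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a simulated long-term trajectory
#'
#' Ash fraction (ISS/TSS), solids and the metabolic mix across the influent
#' phase schedule, one panel per variable with phase boundaries marked.
#'
#' @param object An `sbr_trajectory` from [simulate_phases()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sbr_trajectory <- function(object, ...) {
  traj <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(
    traj[, c("cycle", "phase", "iss_tss", "vss_g_l", "tss_g_l", "lam")],
    c("iss_tss", "vss_g_l", "tss_g_l", "lam"),
    names_to = "variable", values_to = "value")
  starts <- dplyr::summarise(dplyr::group_by(traj, .data$phase),
                             start = min(.data$cycle), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = starts,
                        ggplot2::aes(xintercept = .data$start),
                        linetype = 3, colour = "grey60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "cycle", y = NULL,
                  title = "Simulated SBR trajectory across influent P/C phases") +
    ggplot2::theme_minimal()
}
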