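# ggplot2 views of the main result types. Each autoplot returns a ggplot the
# caller can restyle.

#' @export
autoplot.coevolution_result <- function(object, ...) {
  df <- object$all_pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$MIp,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_point(data = object$pairs, size = 1.6) +
    ggplot2::labs(x = "rank", y = "MIp (nats)",
                  title = "Ranked co-evolution signal",
                  colour = "pair class") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.path_result <- function(object, ...) {
  df <- object$per_frame
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$length)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$average_length,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "frame", y = "path length (hops)",
                  title = sprintf("Shortest path %s → %s per frame",
                                  object$source, object$sink)) +
    ggplot2::theme_minimal()
}

#' Plot the largest-cluster profile used to calibrate I_min
#'
#' @param profile Output of [largest_cluster_profile()].
#' @param selected Optional result of [select_imin()] to mark the transition.
#' @return A ggplot.
#' @export
plot_cluster_profile <- function(profile, selected = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$i_min, y = .data$largest_cluster)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "interaction strength cutoff I_min (%)",
                  y = "largest cluster size",
                  title = "Largest-cluster transition") +
    ggplot2::theme_minimal()
  if (!is.null(selected) && isTRUE(selected$transition_found)) {
    p <- p + ggplot2::geom_vline(xintercept = selected$i_min,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot an interface energy time series
#'
#' @param series Output of [energy_time_series()].
#' @return A ggplot with one line per energy term.
#' @export
plot_energy_series <- function(series) {
  long <- tidyr::pivot_longer(
    series,
    c("hbond_energy", "electrostatic_energy", "vdw_energy",
      "total_stabilizing"),
    names_to = "term", values_to = "energy"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$energy,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "pseudoenergy (kcal/mol)",
                  title = "Interface pseudoenergies along the ensemble") +
    ggplot2::theme_minimal()
}

#' Plot hydrogen-bond occupancies
#'
#' @param occ Output of [hbond_occupancy()].
#' @return A ggplot bar chart with the 50% stability rule marked.
#' @export
plot_hbond_occupancy <- function(occ) {
  occ <- occ %>%
    mutate(pair = paste(.data$donor_residue, "→", .data$acceptor_residue))
  ggplot2::ggplot(occ, ggplot2::aes(x = stats::reorder(.data$pair, .data$occupancy),
                                    y = 100 * .data$occupancy,
                                    fill = .data$stable)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "occupancy (%)",
                  title = "Hydrogen-bond occupancy (stable strictly > 50%)") +
    ggplot2::theme_minimal()
}

#' Plot a per-frame metric series
#'
#' @param series Tibble from [rmsd_series()] or [rg_series()].
#' @return A ggplot.
#' @export
plot_metric_series <- function(series) {
  ycol <- setdiff(names(series), c("frame", "time"))[1]
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = sprintf("%s (Å)", toupper(ycol))) +
    ggplot2::theme_minimal()
}
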