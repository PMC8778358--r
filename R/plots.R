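# ggplot2 visualisations for the result types.

#' @export
autoplot.interaction_profile <- function(object, min_percent = 0, ...) {
  td <- filter(tidy(object), .data$percent > min_percent)
  td$residue <- paste0(td$resname, td$resnum)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$itype,
                                   y = stats::reorder(.data$residue,
                                                      .data$resnum),
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "occurrence %") +
    ggplot2::labs(x = "interaction type", y = NULL,
                  title = "Dynamic noncovalent interaction profile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.series_result <- function(object, ...) {
  td <- tidy(object)
  xcol <- if (object$kind == "rmsd") "frame" else "resnum"
  ggplot2::ggplot(td, ggplot2::aes(x = .data[[xcol]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (object$kind == "rmsd") "frame" else "residue",
                  y = paste0(toupper(object$kind), " (Å)"),
                  subtitle = paste("reference:", object$reference)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_result <- function(object, ...) {
  m <- object$rmsd_matrix
  td <- tidy(object)
  ord <- td$pose # poses grouped by cluster
  lab <- rownames(m) %||% as.character(seq_len(nrow(m)))
  long <- tidyr::expand_grid(i = seq_along(ord), j = seq_along(ord))
  long$rmsd <- m[cbind(ord[long$i], ord[long$j])]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$i, y = .data$j,
                                     fill = .data$rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "RMSD (Å)", direction = -1) +
    ggplot2::labs(x = "pose (cluster order)", y = "pose (cluster order)",
                  title = paste0("Pose RMSD matrix, ",
                                 length(object$clusters),
                                 " subclusters at ", object$cutoff,
                                 " Å")) +
    ggplot2::theme_minimal()
}

#' Plot per-compound screening outcome
#'
#' @param report a `screen_report`.
#' @return a ggplot.
#' @export
plot_screen <- function(report) {
  td <- tidy(report)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$volume,
                                   y = ifelse(is.na(.data$matched_count), 0,
                                              .data$matched_count),
                                   colour = .data$verdict)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = report$params$volume_max,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = report$params$min_match,
                        linetype = "dotted") +
    ggplot2::labs(x = "molecular volume (Å³)",
                  y = "matched pharmacophore elements",
                  title = "Virtual screen outcome") +
    ggplot2::theme_minimal()
}
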