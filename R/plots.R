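# ggplot2 visualization of signals, tidal images and epoch trends.

#' Plot the global impedance signal with detected breaths
#'
#' @param gs Global signal tibble from [global_signal()] (optionally
#'   filtered).
#' @param breaths Optional breath table; end-expiratory troughs and
#'   end-inspiratory peaks are marked.
#' @param ann Optional `sbt_annotation`; phase boundaries are drawn.
#' @return A ggplot object.
#' @export
plot_global_signal <- function(gs, breaths = NULL, ann = NULL) {
  p <- ggplot2::ggplot(gs, ggplot2::aes(x = .data$t, y = .data$z)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Time [s]", y = "Global lung impedance [AU]",
      title = "Global impedance signal"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(breaths) && nrow(breaths)) {
    pts <- dplyr::bind_rows(
      tibble(
        t = gs$t[breaths$i_exp_start], z = gs$z[breaths$i_exp_start],
        what = "end-expiration"
      ),
      tibble(
        t = gs$t[breaths$i_insp_peak], z = gs$z[breaths$i_insp_peak],
        what = "end-inspiration"
      )
    )
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(color = .data$what),
      size = 0.8
    ) + ggplot2::labs(color = NULL)
  }
  if (!is.null(ann)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(ann$t_sbt_start, ann$t_sbt_end),
      linetype = "dashed", color = "grey40"
    )
  }
  p
}

#' Plot a tidal image
#'
#' Raster map of the per-pixel tidal impedance change inside the lung
#' contour; ventral edge at the top.
#'
#' @param ti An `eit_tidal_image`.
#' @return A ggplot object.
#' @export
plot_tidal_image <- function(ti) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(ti$di)), col = seq_len(ncol(ti$di))
  )
  df$di <- as.vector(ti$di)[(df$col - 1L) * nrow(ti$di) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$di)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "dI [AU]",
      title = "Tidal image", subtitle = "ventral at top, dorsal at bottom"
    ) +
    ggplot2::theme_minimal()
}

#' Epoch trend panel
#'
#' Faceted per-parameter trends over the pre-SBT baseline, the five SBT
#' epochs and the post-SBT phase, in the style of an SBT monitoring
#' report. EELI and tidal swing are drawn as percent change from baseline;
#' the other parameters as epoch means with +/- 1 SD ribbons.
#'
#' @param object An `eit_epochs` tibble from [summarize_epochs()].
#' @param parameters Parameter stems to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eit_epochs
#' @export
autoplot.eit_epochs <- function(object,
                                parameters = c(
                                  "pct_change_eeli", "pct_change_dz", "gi",
                                  "rr", "mv_l_min", "rsbi"
                                ),
                                ...) {
  ep <- as_tibble(object)
  long <- purrr::map_dfr(parameters, function(pm) {
    if (pm %in% names(ep)) {
      tibble(
        epoch = ep$epoch, parameter = pm,
        value = ep[[pm]], sd = NA_real_
      )
    } else {
      tibble(
        epoch = ep$epoch, parameter = pm,
        value = ep[[paste0(pm, "_mean")]],
        sd = ep[[paste0(pm, "_sd")]]
      )
    }
  })
  long$parameter <- factor(long$parameter, levels = parameters)
  ggplot2::ggplot(long, ggplot2::aes(
    x = as.integer(.data$epoch), y = .data$value, group = 1
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$value - .data$sd,
        ymax = .data$value + .data$sd
      ),
      fill = "steelblue", alpha = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::scale_x_continuous(
      breaks = seq_along(levels(long$epoch)), labels = levels(long$epoch)
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "SBT epoch trends") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
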