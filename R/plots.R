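# ggplot2 helpers for the main result types. Each returns a ggplot object
# the caller can restyle.

#' @importFrom ggplot2 ggplot aes geom_step geom_ribbon geom_line geom_point
#'   geom_hline geom_crossbar geom_errorbar labs facet_wrap autoplot
NULL

#' Plot a Kaplan-Meier curve
#'
#' @param object A [km_estimate()] result.
#' @param ... Ignored.
#' @return A ggplot: survival step curve with the pointwise confidence band.
#' @export
autoplot.zw_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- bind_rows(tibble(time = 0, estimate = 1, conf_low = 1,
                         conf_high = 1), d)
  ggplot(d0, aes(x = .data$time, y = .data$estimate)) +
    geom_ribbon(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                alpha = 0.2) +
    geom_step() +
    labs(x = "time (days)", y = "survival probability")
}

#' Plot Kaplan-Meier curves per group
#'
#' @param data Survival table (`time_days`, `event` plus the group column).
#' @param group Grouping column (default `"sex"`).
#' @return A ggplot with one step curve and confidence band per group.
#' @export
plot_km_by_group <- function(data, group = "sex") {
  data <- as_tibble(data)
  curves <- purrr::map(unique(data[[group]]), function(gv) {
    km <- km_estimate(data[data[[group]] == gv, ])
    mutate(bind_rows(tibble(time = 0, estimate = 1, conf_low = 1,
                            conf_high = 1),
                     tidy(km)[, c("time", "estimate", "conf_low",
                                  "conf_high")]),
           group = gv)
  })
  ggplot(bind_rows(curves),
         aes(x = .data$time, y = .data$estimate, colour = .data$group,
             fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                alpha = 0.15, colour = NA) +
    geom_step() +
    labs(x = "time (days)", y = "survival probability", colour = group,
         fill = group)
}

#' Plot a scaled metaprofile
#'
#' @param object A [metaprofile()] result.
#' @param ... Ignored.
#' @return A ggplot of median signal along the scaled gene axis, one line
#'   per gene group.
#' @export
autoplot.zw_metaprofile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$median_signal,
                     colour = .data$group)) +
    geom_line() +
    labs(x = "position (bp; body scaled)", y = "median signal (CPM)")
}

#' Plot per-window coverage quartiles along the Z
#'
#' @param ws A [window_summary()] result.
#' @return A ggplot: box-plot-like quartile summaries per window.
#' @export
plot_window_summary <- function(ws) {
  d <- mutate(ws, mid = (.data$start + .data$end) / 2e6)
  ggplot(d, aes(x = .data$mid)) +
    geom_errorbar(aes(ymin = .data$min, ymax = .data$max), width = 0) +
    geom_crossbar(aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
                  width = 2) +
    labs(x = "Z position (Mb)", y = "bin value")
}

#' Manhattan-style plot of a bin-wise differential expression scan
#'
#' @param scan A [bin_de_scan()] result that carries bin coordinates.
#' @param alpha Adjusted-p significance line (default 0.05).
#' @return A ggplot of `-log10(adjusted p)` along the genome.
#' @export
plot_manhattan <- function(scan, alpha = 0.05) {
  if (!all(c("chrom", "start") %in% names(scan))) {
    abort("`scan` needs bin coordinates (pass `bins` to bin_de_scan())")
  }
  ggplot(scan, aes(x = .data$start / 1e6, y = .data$neg_log10_padj)) +
    geom_point(size = 0.5) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    facet_wrap(~ .data$chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = "-log10 adjusted p")
}

#' Plot a per-bin log2 fold-change track along the Z
#'
#' @param log2fc A [bin_log2fc()] result.
#' @param layout A [zw_layout()]; only Z bins are drawn, with the PAR
#'   boundary marked.
#' @param strata Optional [zw_strata()] to shade the stratum intervals.
#' @return A ggplot.
#' @export
plot_log2fc_track <- function(log2fc, layout, strata = NULL) {
  z <- log2fc[log2fc$chrom == layout$z_name, ]
  p <- ggplot(z, aes(x = (.data$start + .data$end) / 2e6,
                     y = .data$log2fc)) +
    geom_point(size = 0.3, alpha = 0.5) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = layout$par_boundary_bp / 1e6,
                        linetype = "dotted") +
    labs(x = "Z position (Mb)", y = "log2 FC (female / male)")
  if (!is.null(strata)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = strata$start_bp / 1e6, xmax = strata$end_bp / 1e6,
      ymin = -Inf, ymax = Inf, alpha = 0.1
    )
  }
  p
}
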