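#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_rect facet_wrap facet_grid labs theme_minimal
NULL

#' Plot a sweep-scan window table
#'
#' FST and pi-ratio tracks along each chromosome, with the pi ratio on a log
#' scale panel so diversity loss in either group is visible.
#'
#' @param object A `sweep_windows` tibble from [sweep_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_windows
#' @export
autoplot.sweep_windows <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(mid = (.data$start + .data$end) / 2) %>%
    tidyr::pivot_longer(c("fst", "pi_ratio"), names_to = "statistic",
                        values_to = "value") %>%
    filter(is.finite(.data$value))
  ggplot(df, aes(x = .data$mid / 1e6, y = .data$value)) +
    geom_line(colour = "grey30") +
    facet_grid(statistic ~ chrom, scales = "free") +
    labs(x = "position (Mb)", y = NULL,
         title = "Windowed FST and pi ratio") +
    theme_minimal()
}

#' Plot called sweep regions over the window scan
#'
#' @param stats A `sweep_windows` tibble.
#' @param regions A `sweep_regions` tibble from [call_sweeps()].
#' @return A ggplot object.
#' @export
plot_sweep_regions <- function(stats, regions) {
  df <- as_tibble(stats) %>% mutate(mid = (.data$start + .data$end) / 2)
  p <- ggplot(df, aes(x = .data$mid / 1e6, y = .data$fst)) +
    geom_line(colour = "grey30") +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = "FST", title = "Selective-sweep regions") +
    theme_minimal()
  if (nrow(regions)) {
    p <- p + geom_rect(
      data = as_tibble(regions),
      aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
          ymin = -Inf, ymax = Inf, fill = .data$selected_group),
      alpha = 0.25, inherit.aes = FALSE)
  }
  p
}

#' Plot LTR insertion-age histograms
#'
#' @param object A dated `ltr_age_table` from [date_ltr_elements()].
#' @param ... Passed to [age_profile()].
#' @return A ggplot object with the young (0-0.5 My) and old (0-5 My) panels.
#' @method autoplot ltr_age_table
#' @export
autoplot.ltr_age_table <- function(object, ...) {
  prof <- age_profile(object, ...)
  ggplot(prof, aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                   y = .data$count)) +
    geom_col(width = NA, fill = "steelblue") +
    facet_wrap(~panel, scales = "free") +
    labs(x = "insertion age (My)", y = "intact LTR-RTs",
         title = "LTR-RT insertion ages") +
    theme_minimal()
}

#' Plot tandem arrays and centromere calls along chromosomes
#'
#' @param object A `tandem_arrays` tibble.
#' @param calls Optional `centromere_calls` tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tandem_arrays
#' @export
autoplot.tandem_arrays <- function(object, calls = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot(df) +
    geom_rect(aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                  ymin = 0, ymax = .data$identity),
              fill = "darkorange") +
    facet_wrap(~chrom, ncol = 1) +
    labs(x = "position (Mb)", y = "periodic identity",
         title = "Tandem satellite arrays") +
    theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + geom_rect(data = as_tibble(calls),
                       aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                           ymin = -0.05, ymax = 0),
                       fill = "red", inherit.aes = FALSE)
  }
  p
}
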