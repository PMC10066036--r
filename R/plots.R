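#' @importFrom ggplot2 ggplot aes geom_violin geom_line geom_ribbon
#'   geom_raster geom_rect geom_hline labs theme_minimal autoplot
#'   scale_fill_viridis_c coord_equal
NULL

#' @export
ggplot2::autoplot

#' Violin summary of a colocalization run
#'
#' Background-subtracted green (new cell wall) maxima for phage-proximal
#' vs non-proximal lines, with median and quartiles drawn as in the
#' standard violin presentation.
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group <- ifelse(df$proximal, "phage proximal", "non-proximal")
  ggplot(df, aes(x = .data$group, y = .data$green_max_bgsub,
                 fill = .data$group)) +
    geom_violin(draw_quantiles = c(0.25, 0.5, 0.75), alpha = 0.7,
                show.legend = FALSE) +
    labs(x = NULL, y = "background-subtracted green maximum",
         title = "New cell wall signal at phage-proximal lines") +
    theme_minimal()
}

#' GC content track with called low-GC regions
#'
#' @param object A `gc_track`.
#' @param regions Optional tibble from [low_gc_regions()] shaded on the
#'   track.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gc_track
#' @export
autoplot.gc_track <- function(object, regions = NULL, ...) {
  p <- ggplot(tibble::as_tibble(object),
              aes(x = (.data$start + .data$end) / 2,
                  y = .data$gc * 100)) +
    geom_line(linewidth = 0.3) +
    geom_hline(yintercept = attr(object, "genome_mean") * 100,
               linetype = "dashed", colour = "grey40") +
    labs(x = "genome position (bp)", y = "GC (%)") +
    theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    p <- p + geom_rect(
      data = regions,
      aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "firebrick",
      inherit.aes = FALSE)
  }
  p
}

#' Population reporter traces with mean and SD band
#'
#' @param population Tibble from [trace_population()].
#' @param frame_interval Minutes per frame for the time axis (default 1 =
#'   frame units).
#' @return A ggplot.
#' @export
plot_traces <- function(population, frame_interval = 1) {
  has_group <- "group" %in% names(population)
  p <- ggplot(population,
              aes(x = .data$frame * frame_interval, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd),
                alpha = 0.25) +
    geom_line() +
    labs(x = if (frame_interval == 1) "frame" else "time (min)",
         y = "background-subtracted reporter intensity") +
    theme_minimal()
  if (has_group) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' Display one channel of a synthetic scene
#'
#' @param scene A `phage_scene`.
#' @param channel Channel name to show.
#' @return A ggplot raster.
#' @export
plot_scene <- function(scene, channel = names(scene$channels)[1]) {
  img <- scene$channels[[channel]]
  df <- tidyr::expand_grid(x = seq_len(ncol(img)), y = seq_len(nrow(img)))
  df$value <- as.vector(img)  # column-major: y varies fastest, matching x-then-y grid
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = channel) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}
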