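#' Simulate an infection time-lapse with known fates
#'
#' Cells elongate exponentially (length doubling time
#' `config$doubling_time` minutes) with old-pole-biased elongation. A
#' fraction `infected_dilution` of cells start infected at frame 1;
#' infected cells follow the outgrowth fate with probability
#' `resistant_fraction` (they never express mCherry and keep growing), and
#' otherwise express mCherry from a drawn onset frame (sigmoidal rise) and
#' disappear at their lysis frame. All event frames are recorded in the
#' ground truth.
#'
#' @inheritParams simulate_scene
#' @param channels Channels rendered per frame (default phase + mcherry).
#' @return A `phage_timelapse`: list with `frames` (per-frame named channel
#'   lists), `masks` (per-frame ground-truth label masks), `cells` (truth
#'   with `fate`, `infection_frame`, `mcherry_onset_frame`, `lysis_frame`),
#'   `geometry` (per-frame cell geometry tibble) and `config`.
#' @export
simulate_timelapse <- function(config,
                               channels = c("phase", "mcherry")) {
  stopifnot(inherits(config, "scene_config"))
  if (config$n_frames < 2) rlang::abort("`n_frames` must be >= 2.")
  channels <- match.arg(channels,
                        c("phase", "green", "red", "mcherry", "focus"),
                        several.ok = TRUE)
  with_seed(config$seed, {
    nf <- config$n_frames
    dt <- config$frame_interval
    growth_total <- 2^((nf - 1) * dt / config$doubling_time)
    cells <- place_cells(config, growth_factor = growth_total)
    n <- nrow(cells)

    infected <- runif(n) < config$infected_dilution
    resistant <- runif(n) < config$resistant_fraction
    fate <- ifelse(!infected, "uninfected",
                   ifelse(resistant, "resistant_outgrow",
                          "susceptible_lyse"))
    onset <- rep(NA_integer_, n)
    lysis <- rep(NA_integer_, n)
    lysing <- fate == "susceptible_lyse"
    if (any(lysing)) {
      onset[lysing] <- pmax(3L, round(rnorm(sum(lysing), 8, 1.5)))
      lysis[lysing] <- onset[lysing] +
        pmax(2L, round(rnorm(sum(lysing), 6, 1.5)))
    }
    cells$fate <- fate
    cells$infection_frame <- ifelse(infected, 1L, NA_integer_)
    cells$mcherry_onset_frame <- onset
    cells$lysis_frame <- lysis

    phages <- if ("red" %in% channels && any(infected)) {
      place_phages_field(cells[infected, ], config)
    } else {
      tibble::tibble(phage_id = integer(), cell_id = integer(),
                     anchor_s = numeric(), x = numeric(), y = numeric(),
                     site_class = character(), photon_intensity = numeric())
    }

    u_old <- ifelse(cells$old_pole_end == 1L, 1, -1)
    frames <- vector("list", nf)
    masks <- vector("list", nf)
    geometry <- vector("list", nf)
    for (f in seq_len(nf)) {
      # growth stalls at mCherry onset in lysing cells
      g_frame <- pmin(f, ifelse(is.na(onset), f, onset))
      len_f <- cells$length_um * 2^((g_frame - 1) * dt / config$doubling_time)
      dL <- len_f - cells$length_um
      shift_px <- (config$old_pole_fraction - 0.5) * dL / config$pixel_size
      cf <- cells
      cf$length_um <- len_f
      cf$x <- cells$x + shift_px * u_old * cos(cells$orientation)
      cf$y <- cells$y + shift_px * u_old * sin(cells$orientation)
      alive <- is.na(lysis) | f < lysis
      expression <- ifelse(
        lysing & !is.na(onset),
        config$mcherry_amplitude * plogis((f - onset) / 0.8), 0)
      sc <- scene_from_truth(cf, phages, config, channels,
                             expression = expression, alive = alive)
      frames[[f]] <- sc$channels
      masks[[f]] <- truth_mask_cells(cf[alive, , drop = FALSE],
                                     config$image_shape, config$pixel_size)
      geometry[[f]] <- tibble::tibble(
        frame = f, cell_id = cells$cell_id, x = cf$x, y = cf$y,
        length_um = len_f, alive = alive)
    }
    structure(list(frames = frames, masks = masks, cells = cells,
                   geometry = dplyr::bind_rows(geometry), config = config),
              class = "phage_timelapse")
  })
}

#' @export
print.phage_timelapse <- function(x, ...) {
  cat("<phage_timelapse>\n")
  cat(sprintf("  %d frames (%g min apart), %d cells\n",
              length(x$frames), x$config$frame_interval, nrow(x$cells)))
  cat(sprintf("  fates: %s\n",
              paste(names(table(x$cells$fate)), table(x$cells$fate),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
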