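#' Configure a synthetic microscopy scene
#'
#' Builds the parameter set consumed by [simulate_scene()] and
#' [simulate_timelapse()]. Defaults emulate widefield imaging of
#' *Mycobacterium smegmatis*: rod-shaped (spherocylindrical) cells whose new
#' cell wall is labelled green at the poles and septa, phage particles
#' visible as red surface puncta, and an mCherry reporter channel for
#' infection time-lapses.
#'
#' @param image_shape Integer vector (rows, cols) in pixels.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param n_cells Number of cells placed in the field.
#' @param cell_length_range Tip-to-tip cell length range in micrometres;
#'   lengths are drawn uniformly within it.
#' @param cell_width Cell width (diameter) in micrometres.
#' @param septum_prob Probability that a cell carries a mid-cell septum.
#' @param polar_green_ratio Old-pole vs new-pole green intensity ratio
#'   (>= 1); encodes the faster-elongating old pole.
#' @param lateral_green_level Green intensity on the non-polar membrane as a
#'   fraction of the new-pole level.
#' @param phage_rate Mean phage particles per cell (Poisson).
#' @param polar_bias Probability that a phage anchors within a pole cap or
#'   septum arc rather than uniformly on the whole boundary, in [0, 1].
#' @param psf_sigma Gaussian point-spread-function sigma in pixels.
#' @param background_level Per-channel background intensity (single value or
#'   named vector with entries for phase/green/red/mcherry/focus).
#' @param gaussian_read_sd Gaussian read-noise standard deviation.
#' @param poisson_scale Photons per intensity unit for shot noise; 0
#'   disables Poisson noise.
#' @param n_operator_sites Operator sites in the reporter array (default 7).
#' @param protomers_per_site Protein protomers accommodated per operator
#'   site (default 2).
#' @param n_frames Number of time-lapse frames.
#' @param frame_interval Minutes between frames (default 12).
#' @param resistant_fraction Probability that an infected cell follows the
#'   outgrowth (never-expressing) fate.
#' @param infected_dilution Fraction of cells that start infected
#'   ("seeder" cells diluted into uninfected cells; default 1/1000).
#' @param doubling_time Cell length doubling time in minutes (default 180).
#' @param old_pole_fraction Fraction of elongation contributed by the old
#'   pole (default 0.7).
#' @param green_amplitude Peak green membrane intensity (per arclength
#'   pixel) at the new pole.
#' @param phage_photon_mean Mean integrated photon intensity per phage
#'   punctum.
#' @param mcherry_amplitude Plateau mCherry intensity in expressing cells.
#' @param seed Integer seed; every stochastic draw in the simulator flows
#'   from it.
#'
#' @return A list of class `scene_config`.
#' @export
#' @examples
#' cfg <- scene_config(n_cells = 5, seed = 1)
#' cfg$phage_rate
scene_config <- function(image_shape = c(256L, 256L),
                         pixel_size = 0.1,
                         n_cells = 10L,
                         cell_length_range = c(2.5, 5),
                         cell_width = 0.7,
                         septum_prob = 0.3,
                         polar_green_ratio = 2,
                         lateral_green_level = 0.15,
                         phage_rate = 3,
                         polar_bias = 0.8,
                         psf_sigma = 1.3,
                         background_level = 100,
                         gaussian_read_sd = 2,
                         poisson_scale = 1,
                         n_operator_sites = 7L,
                         protomers_per_site = 2L,
                         n_frames = 30L,
                         frame_interval = 12,
                         resistant_fraction = 0.5,
                         infected_dilution = 1 / 1000,
                         doubling_time = 180,
                         old_pole_fraction = 0.7,
                         green_amplitude = 60,
                         phage_photon_mean = 500,
                         mcherry_amplitude = 120,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16))
  if (polar_bias < 0 || polar_bias > 1)
    rlang::abort("`polar_bias` must lie in [0, 1].")
  if (polar_green_ratio < 1)
    rlang::abort("`polar_green_ratio` must be >= 1.")
  if (phage_rate < 0 || psf_sigma < 0 || gaussian_read_sd < 0 ||
      poisson_scale < 0)
    rlang::abort("Rates, sigmas and scales must be non-negative.")
  if (frame_interval <= 0)
    rlang::abort("`frame_interval` must be positive.")
  if (resistant_fraction < 0 || resistant_fraction > 1 ||
      infected_dilution < 0 || infected_dilution > 1 ||
      septum_prob < 0 || septum_prob > 1)
    rlang::abort("Probabilities must lie in [0, 1].")
  if (cell_length_range[1] < cell_width)
    rlang::abort("Cells must be at least as long as they are wide.")

  chans <- c("phase", "green", "red", "mcherry", "focus")
  bg <- background_level
  if (is.null(names(bg))) bg <- setNames(rep(bg[1], 5), chans)
  bg <- bg[chans]
  bg[is.na(bg)] <- background_level[[1]]
  names(bg) <- chans

  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_cells = as.integer(n_cells), cell_length_range = cell_length_range,
    cell_width = cell_width, septum_prob = septum_prob,
    polar_green_ratio = polar_green_ratio,
    lateral_green_level = lateral_green_level,
    phage_rate = phage_rate, polar_bias = polar_bias,
    psf_sigma = psf_sigma, background_level = bg,
    gaussian_read_sd = gaussian_read_sd, poisson_scale = poisson_scale,
    n_operator_sites = as.integer(n_operator_sites),
    protomers_per_site = as.integer(protomers_per_site),
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    resistant_fraction = resistant_fraction,
    infected_dilution = infected_dilution,
    doubling_time = doubling_time, old_pole_fraction = old_pole_fraction,
    green_amplitude = green_amplitude,
    phage_photon_mean = phage_photon_mean,
    mcherry_amplitude = mcherry_amplitude,
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  field: %d x %d px (%.3g um/px), %d cells\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$n_cells))
  cat(sprintf("  phage_rate: %.3g, polar_bias: %.3g, polar_green_ratio: %.3g\n",
              x$phage_rate, x$polar_bias, x$polar_green_ratio))
  cat(sprintf("  psf_sigma: %.3g px, noise: poisson_scale %.3g, read sd %.3g\n",
              x$psf_sigma, x$poisson_scale, x$gaussian_read_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
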