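#' Simulate a synthetic multi-channel microscopy field
#'
#' Renders a seeded field of rod-shaped cells with ground truth: a phase
#' channel (dark cells on bright background), a green new-cell-wall channel
#' with polar/septal enrichment (old pole `polar_green_ratio` times the new
#' pole), and a red channel of PSF-convolved phage puncta anchored on the
#' cell surface. Identical `(config, seed)` yield bit-identical scenes.
#'
#' @param config A [scene_config()].
#' @param channels Channels to render, a subset of
#'   `c("phase", "green", "red", "mcherry", "focus")`.
#' @return A `phage_scene`: list with `channels` (named list of matrices),
#'   `cells` and `phages` ground-truth tibbles, and `config`.
#' @export
#' @examples
#' sc <- simulate_scene(scene_config(n_cells = 3, seed = 7,
#'                                   image_shape = c(128, 128)))
#' names(sc$channels)
#' nrow(sc$phages)
simulate_scene <- function(config,
                           channels = c("phase", "green", "red")) {
  stopifnot(inherits(config, "scene_config"))
  channels <- match.arg(channels,
                        c("phase", "green", "red", "mcherry", "focus"),
                        several.ok = TRUE)
  with_seed(config$seed, {
    cells <- place_cells(config)
    phages <- place_phages_field(cells, config)
    scene_from_truth(cells, phages, config, channels)
  })
}

# Draw non-overlapping cell positions/geometries by rejection sampling.
# `length_px_max` reserves room for growth (used by the time-lapse).
place_cells <- function(config, growth_factor = 1) {
  dim <- config$image_shape
  px <- config$pixel_size
  margin_psf <- 4 * config$psf_sigma + 2
  n <- config$n_cells
  placed <- list()
  attempts <- 0L
  max_attempts <- 300L * n
  while (length(placed) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    len_um <- runif(1, config$cell_length_range[1], config$cell_length_range[2])
    len_px <- len_um / px
    len_final <- len_px * growth_factor
    w_px <- config$cell_width / px
    r <- w_px / 2
    half <- len_final / 2 + margin_psf
    if (2 * half >= min(dim)) {
      rlang::abort("Cells do not fit in the field; enlarge `image_shape`.")
    }
    cx <- runif(1, half, dim[2] - half)
    cy <- runif(1, half, dim[1] - half)
    th <- runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th))
    hl <- (len_final - w_px) / 2
    e1 <- c(cx, cy) + hl * u; e2 <- c(cx, cy) - hl * u
    ok <- TRUE
    for (p in placed) {
      if (segment_segment_dist(e1, e2, p$e1, p$e2) < r + p$r + 2) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    placed[[length(placed) + 1]] <- list(
      x = cx, y = cy, orientation = th, length_um = len_um,
      width_um = config$cell_width, e1 = e1, e2 = e2, r = r,
      old_pole_end = sample(1:2, 1),
      has_septum = runif(1) < config$septum_prob
    )
  }
  if (length(placed) < n) {
    rlang::abort(sprintf(
      "Failed to place %d non-overlapping cells after %d attempts; reduce `n_cells` or enlarge the field.",
      n, max_attempts))
  }
  dplyr::bind_rows(lapply(seq_along(placed), function(i) {
    p <- placed[[i]]
    tibble::tibble(
      cell_id = i, x = p$x, y = p$y, orientation = p$orientation,
      length_um = p$length_um, width_um = p$width_um,
      old_pole_end = p$old_pole_end, has_septum = p$has_septum,
      fate = "uninfected",
      infection_frame = NA_integer_, mcherry_onset_frame = NA_integer_,
      lysis_frame = NA_integer_
    )
  }))
}

#' Place phage particles on one cell's boundary
#'
#' Draws a Poisson(`phage_rate`) number of particles. Each anchor falls,
#' with probability `polar_bias`, uniformly within the union of the two pole
#' caps (and septum arcs when the cell has a septum); otherwise uniformly on
#' the whole boundary. Pole caps are the boundary arcs within one cell
#' half-width of the midline endpoints.
#'
#' @param cell One-row tibble from a scene's `cells` table.
#' @param phage_rate Mean particles per cell (Poisson).
#' @param polar_bias Probability of pole/septum-targeted anchoring, in
#'   [0, 1].
#' @param pixel_size Micrometres per pixel (converts the stored geometry).
#' @param photon_mean Mean integrated punctum intensity.
#' @return Tibble with one row per particle: `cell_id`, `anchor_s`
#'   (boundary arclength, px), `x`, `y`, `site_class`
#'   (old_pole/new_pole/septum/lateral) and `photon_intensity`.
#' @export
place_phages <- function(cell, phage_rate, polar_bias, pixel_size,
                         photon_mean = 500) {
  if (phage_rate < 0) rlang::abort("`phage_rate` must be >= 0.")
  if (polar_bias < 0 || polar_bias > 1)
    rlang::abort("`polar_bias` must lie in [0, 1].")
  cap <- capsule_from_cell(cell, pixel_size)
  k <- rpois(1, phage_rate)
  if (k == 0) {
    return(tibble::tibble(cell_id = integer(), anchor_s = numeric(),
                          x = numeric(), y = numeric(),
                          site_class = character(),
                          photon_intensity = numeric()))
  }
  arcs <- capsule_arcs(cap)
  lens <- vapply(arcs, function(a) a[2] - a[1], numeric(1))
  targeted <- runif(k) < polar_bias
  s <- numeric(k)
  if (any(targeted)) {
    pick <- sample(seq_along(arcs), sum(targeted), replace = TRUE,
                   prob = lens)
    s[targeted] <- vapply(pick, function(j)
      runif(1, arcs[[j]][1], arcs[[j]][2]), numeric(1))
  }
  if (any(!targeted)) {
    s[!targeted] <- runif(sum(!targeted), 0, cap$circumference)
  }
  pt <- capsule_point(cap, s)
  tibble::tibble(
    cell_id = cell$cell_id, anchor_s = s, x = pt$x, y = pt$y,
    site_class = capsule_site_class(cap, s),
    photon_intensity = rgamma(k, shape = 25, rate = 25 / photon_mean)
  )
}

place_phages_field <- function(cells, config) {
  out <- lapply(seq_len(nrow(cells)), function(i) {
    place_phages(cells[i, ], config$phage_rate, config$polar_bias,
                 config$pixel_size, config$phage_photon_mean)
  })
  tbl <- dplyr::bind_rows(out)
  if (nrow(tbl)) tbl$phage_id <- seq_len(nrow(tbl))
  else tbl$phage_id <- integer()
  dplyr::select(tbl, "phage_id", dplyr::everything())
}

#' Render one cell's membrane-localized green (new cell wall) signal
#'
#' Deposits intensity along the cell boundary: `lateral_level` on the
#' lateral walls, 1 on the new-pole cap and septum bands, and
#' `polar_green_ratio` on the old-pole cap, so the integrated old-pole
#' intensity is `polar_green_ratio` times the new pole's. No background or
#' noise is added.
#'
#' @inheritParams place_phages
#' @param dim Image dimensions (rows, cols).
#' @param polar_green_ratio Old/new pole intensity ratio (>= 1).
#' @param lateral_level Lateral membrane level relative to the new pole.
#' @param amplitude Intensity per arclength pixel at the new pole.
#' @param psf_sigma Gaussian PSF sigma in pixels (0 = no blur).
#' @return A numeric matrix.
#' @export
render_membrane_green <- function(cell, dim, pixel_size,
                                  polar_green_ratio = 2,
                                  lateral_level = 0.15,
                                  amplitude = 60, psf_sigma = 0) {
  if (polar_green_ratio < 1)
    rlang::abort("`polar_green_ratio` must be >= 1.")
  cap <- capsule_from_cell(cell, pixel_size)
  step <- 0.25
  bd <- capsule_boundary(cap, step = step)
  bd <- bd[-nrow(bd), ]
  ds <- cap$circumference / nrow(bd)
  cls <- capsule_site_class(cap, bd$s)
  w <- dplyr::case_when(
    cls == "old_pole" ~ polar_green_ratio,
    cls == "new_pole" ~ 1,
    cls == "septum" ~ 1,
    TRUE ~ lateral_level
  )
  img <- deposit_points(dim, bd$x, bd$y, w * amplitude * ds)
  psf_blur(img, psf_sigma)
}

#' Fluorescent interactions per phage chromosome in the operator-array
#' reporter
#'
#' Each operator site in the array accommodates a fixed number of protein
#' protomers, so a single phage genome can carry
#' `n_sites * protomers_per_site` fluorescent interactions; this sets the
#' per-genome focus brightness in the optional focus channel.
#'
#' @param n_sites Number of operator sites (default 7).
#' @param protomers_per_site Protomers per site (default 2).
#' @return Integer count.
#' @export
#' @examples
#' binding_capacity(7, 2) # 14
binding_capacity <- function(n_sites = 7L, protomers_per_site = 2L) {
  if (n_sites < 0 || protomers_per_site < 0 ||
      n_sites != round(n_sites) || protomers_per_site != round(protomers_per_site))
    rlang::abort("`n_sites` and `protomers_per_site` must be non-negative integers.")
  as.integer(n_sites) * as.integer(protomers_per_site)
}

# Render all requested channels from ground truth (cells + phages).
# `expression` optionally gives per-cell mCherry amplitude for this frame.
scene_from_truth <- function(cells, phages, config, channels,
                             expression = NULL, alive = NULL) {
  dim <- config$image_shape
  px <- config$pixel_size
  bg <- config$background_level
  if (is.null(alive)) alive <- rep(TRUE, nrow(cells))
  live_cells <- cells[alive, , drop = FALSE]

  mask <- truth_mask_cells(live_cells, dim, px)
  out <- list()
  for (ch in intersect(c("phase", "green", "red", "mcherry", "focus"),
                       channels)) {
    img <- switch(ch,
      phase = {
        base <- matrix(bg[["phase"]], dim[1], dim[2])
        base[mask > 0] <- 0.4 * bg[["phase"]]
        psf_blur(base, max(config$psf_sigma, 1), boundary = "replicate")
      },
      green = {
        img <- matrix(0, dim[1], dim[2])
        for (i in seq_len(nrow(live_cells))) {
          img <- img + render_membrane_green(
            live_cells[i, ], dim, px,
            polar_green_ratio = config$polar_green_ratio,
            lateral_level = config$lateral_green_level,
            amplitude = config$green_amplitude, psf_sigma = 0)
        }
        psf_blur(img, config$psf_sigma) + bg[["green"]]
      },
      red = {
        ph <- phages
        if (nrow(ph)) ph <- ph[ph$cell_id %in% live_cells$cell_id, ]
        img <- deposit_points(dim, ph$x, ph$y, ph$photon_intensity)
        psf_blur(img, config$psf_sigma) + bg[["red"]]
      },
      mcherry = {
        img <- matrix(0, dim[1], dim[2])
        if (!is.null(expression)) {
          amp <- expression[match(live_cells$cell_id, cells$cell_id)]
          for (i in seq_len(nrow(live_cells))) {
            if (is.na(amp[i]) || amp[i] <= 0) next
            cap <- capsule_from_cell(live_cells[i, ], px)
            ras <- rasterize_capsule(cap, dim)
            if (!is.null(ras))
              img[cbind(ras$rows, ras$cols)] <- amp[i]
          }
          img <- psf_blur(img, config$psf_sigma)
        }
        img + bg[["mcherry"]]
      },
      focus = {
        # one focus per adsorbed phage genome, brightness scaled by the
        # operator-array binding capacity
        ph <- phages
        if (nrow(ph)) ph <- ph[ph$cell_id %in% live_cells$cell_id, ]
        bc <- binding_capacity(config$n_operator_sites,
                               config$protomers_per_site)
        img <- deposit_points(dim, ph$x, ph$y,
                              rep(bc * 30, nrow(ph)))
        psf_blur(img, config$psf_sigma) + bg[["focus"]]
      })
    img <- add_camera_noise(img, config$poisson_scale,
                            config$gaussian_read_sd)
    out[[ch]] <- img
  }
  structure(list(channels = out, cells = cells, phages = phages,
                 config = config),
            class = "phage_scene")
}

truth_mask_cells <- function(cells, dim, pixel_size) {
  mask <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(cells))) {
    cap <- capsule_from_cell(cells[i, ], pixel_size)
    ras <- rasterize_capsule(cap, dim)
    if (!is.null(ras))
      mask[cbind(ras$rows, ras$cols)] <- cells$cell_id[i]
  }
  mask
}

#' Ground-truth label mask of a synthetic scene
#'
#' @param scene A `phage_scene` from [simulate_scene()].
#' @return Integer label matrix (0 background, `cell_id` inside each cell).
#' @export
truth_mask <- function(scene) {
  stopifnot(inherits(scene, "phage_scene"))
  truth_mask_cells(scene$cells, scene$config$image_shape,
                   scene$config$pixel_size)
}

#' Ground-truth boundary site class nearest to a point
#'
#' Maps an (x, y) position (e.g. a spline anchor) to the nearest boundary
#' site class (`old_pole`, `new_pole`, `septum`, `lateral`) of a
#' ground-truth cell, by nearest point on the true capsule boundary.
#'
#' @param cell One-row tibble from a scene's `cells` table.
#' @param x,y Positions in pixel coordinates.
#' @param pixel_size Micrometres per pixel.
#' @return Character vector of site classes.
#' @export
truth_site_class <- function(cell, x, y, pixel_size) {
  cap <- capsule_from_cell(cell, pixel_size)
  bd <- capsule_boundary(cap, step = 0.25)
  cls <- capsule_site_class(cap, bd$s)
  idx <- vapply(seq_along(x), function(i) {
    which.min((bd$x - x[i])^2 + (bd$y - y[i])^2)
  }, integer(1))
  cls[idx]
}

#' @export
print.phage_scene <- function(x, ...) {
  cat("<phage_scene>\n")
  cat(sprintf("  channels: %s (%d x %d)\n",
              paste(names(x$channels), collapse = ", "),
              x$config$image_shape[1], x$config$image_shape[2]))
  cat(sprintf("  %d cells, %d phage particles, seed %d\n",
              nrow(x$cells), nrow(x$phages), x$config$seed))
  invisible(x)
}
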