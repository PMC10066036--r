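test_that("scene generation is deterministic given config and seed", {
  cfg <- scene_config(n_cells = 4, seed = 17, image_shape = c(192, 192))
  a <- simulate_scene(cfg)
  b <- simulate_scene(cfg)
  expect_identical(a$channels, b$channels)
  expect_identical(a$cells, b$cells)
  expect_identical(a$phages, b$phages)
  # and the global RNG stream is left untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_scene(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("zero phage rate gives an empty phage table and pure background red", {
  cfg <- scene_config(n_cells = 3, seed = 5, image_shape = c(160, 160),
                      phage_rate = 0, poisson_scale = 0,
                      gaussian_read_sd = 0)
  sc <- simulate_scene(cfg)
  expect_identical(nrow(sc$phages), 0L)
  expect_equal(sc$channels$red,
               matrix(cfg$background_level[["red"]], 160, 160))
})

test_that("phage counts follow the Poisson rate", {
  lambda <- 3
  cfg <- scene_config(n_cells = 1, seed = 1, image_shape = c(96, 96),
                      phage_rate = lambda)
  counts <- vapply(1:500, function(i) {
    set.seed(i)
    nrow(place_phages(simulate_scene(cfg, channels = "phase")$cells[1, ],
                      lambda, 0.5, cfg$pixel_size))
  }, numeric(1))
  se <- sqrt(lambda / length(counts))
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("polar bias 1 anchors only at poles and septa; bias 0 matches arc geometry", {
  cfg <- scene_config(n_cells = 1, seed = 2, image_shape = c(128, 128),
                      septum_prob = 1)
  cell <- simulate_scene(cfg, channels = "phase")$cells[1, ]
  set.seed(11)
  ph1 <- dplyr::bind_rows(lapply(1:50, function(i)
    place_phages(cell, 4, polar_bias = 1, cfg$pixel_size)))
  expect_true(all(ph1$site_class %in% c("old_pole", "new_pole", "septum")))

  set.seed(12)
  ph0 <- dplyr::bind_rows(lapply(1:200, function(i)
    place_phages(cell, 4, polar_bias = 0, cfg$pixel_size)))
  cap <- phagecell:::capsule_from_cell(cell, cfg$pixel_size)
  arcs <- phagecell:::capsule_arcs(cap)
  arc_len <- sum(vapply(arcs, function(a) a[2] - a[1], numeric(1)))
  p_geom <- arc_len / cap$circumference
  p_obs <- mean(ph0$site_class != "lateral")
  se <- sqrt(p_geom * (1 - p_geom) / nrow(ph0))
  expect_lt(abs(p_obs - p_geom), 4 * se)

  expect_identical(nrow(place_phages(cell, 0, 0.5, cfg$pixel_size)), 0L)
})

test_that("every phage anchor lies on its cell's boundary", {
  sc <- quiet_scene(n_cells = 6, seed = 9, phage_rate = 4)
  for (i in seq_len(nrow(sc$phages))) {
    ph <- sc$phages[i, ]
    cell <- sc$cells[sc$cells$cell_id == ph$cell_id, ]
    cap <- phagecell:::capsule_from_cell(cell, sc$config$pixel_size)
    bd <- phagecell:::capsule_boundary(cap, step = 0.25)
    d <- min(sqrt((bd$x - ph$x)^2 + (bd$y - ph$y)^2))
    expect_lt(d, 0.5)
  }
})

test_that("membrane green rendering respects the old/new pole intensity ratio", {
  cfg <- scene_config(n_cells = 1, seed = 4, image_shape = c(128, 128),
                      septum_prob = 0)
  cell <- simulate_scene(cfg, channels = "phase")$cells[1, ]
  px <- cfg$pixel_size
  cap <- phagecell:::capsule_from_cell(cell, px)

  integrate_pole <- function(img, endpoint) {
    idx <- which(img > 0, arr.ind = TRUE)
    d <- sqrt((idx[, 2] - endpoint[1])^2 + (idx[, 1] - endpoint[2])^2)
    sum(img[idx][d <= cap$r + 2])
  }
  old_end <- if (cell$old_pole_end == 1) cap$e1 else cap$e2
  new_end <- if (cell$old_pole_end == 1) cap$e2 else cap$e1

  for (rho in c(1, 2)) {
    img <- render_membrane_green(cell, c(128, 128), px,
                                 polar_green_ratio = rho,
                                 lateral_level = 0, psf_sigma = 0)
    ratio <- integrate_pole(img, old_end) / integrate_pole(img, new_end)
    expect_equal(ratio, rho, tolerance = 0.05)
  }

  # lateral_level 0: no intensity away from the pole caps before noise
  img0 <- render_membrane_green(cell, c(128, 128), px,
                                polar_green_ratio = 2, lateral_level = 0,
                                psf_sigma = 0)
  idx <- which(img0 > 1e-9, arr.ind = TRUE)
  d1 <- sqrt((idx[, 2] - cap$e1[1])^2 + (idx[, 1] - cap$e1[2])^2)
  d2 <- sqrt((idx[, 2] - cap$e2[1])^2 + (idx[, 1] - cap$e2[2])^2)
  expect_true(all(pmin(d1, d2) <= cap$r + 1.5))
})

test_that("red channel flux is conserved through the PSF with noise off", {
  sc <- quiet_scene(n_cells = 5, seed = 7, phage_rate = 5)
  excess <- sum(sc$channels$red) -
    length(sc$channels$red) * sc$config$background_level[["red"]]
  expect_equal(excess, sum(sc$phages$photon_intensity), tolerance = 0.01)
})

test_that("binding capacity is sites times protomers", {
  expect_identical(binding_capacity(7, 2), 14L)
  expect_identical(binding_capacity(0, 2), 0L)
  expect_identical(binding_capacity(3, 2), 6L)
  expect_error(binding_capacity(-1, 2))
})

test_that("optional reporter channels render on request", {
  cfg <- scene_config(n_cells = 3, seed = 43, image_shape = c(160, 160),
                      phage_rate = 3, poisson_scale = 0,
                      gaussian_read_sd = 0)
  sc <- simulate_scene(cfg, channels = c("phase", "green", "red",
                                         "mcherry", "focus"))
  expect_setequal(names(sc$channels),
                  c("phase", "green", "red", "mcherry", "focus"))
  # snapshot scenes have no reporter expression: mcherry is background
  expect_equal(sc$channels$mcherry,
               matrix(cfg$background_level[["mcherry"]], 160, 160))
  # focus flux scales with the operator-array binding capacity
  if (nrow(sc$phages)) {
    excess <- sum(sc$channels$focus) -
      length(sc$channels$focus) * cfg$background_level[["focus"]]
    expect_equal(excess,
                 nrow(sc$phages) * binding_capacity(7, 2) * 30,
                 tolerance = 0.01)
  }
})

test_that("invalid configurations and impossible placements error", {
  expect_error(scene_config(polar_bias = 1.5), "polar_bias")
  expect_error(scene_config(polar_green_ratio = 0.5), "polar_green_ratio")
  expect_error(scene_config(frame_interval = 0), "frame_interval")
  expect_error(
    simulate_scene(scene_config(n_cells = 80, image_shape = c(96, 96),
                                seed = 1)),
    "non-overlapping|fit")
})

test_that("time-lapse fates follow the resistant fraction settings", {
  base <- list(n_cells = 12, image_shape = c(512, 512), n_frames = 8,
               infected_dilution = 1, seed = 31)
  tl1 <- simulate_timelapse(do.call(scene_config,
                                    c(base, resistant_fraction = 1)),
                            channels = "mcherry")
  expect_true(all(is.na(tl1$cells$mcherry_onset_frame)))

  tl0 <- simulate_timelapse(do.call(scene_config,
                                    c(base, resistant_fraction = 0)),
                            channels = "mcherry")
  expect_true(all(!is.na(tl0$cells$lysis_frame)))
  expect_true(all(tl0$cells$mcherry_onset_frame <= tl0$cells$lysis_frame))
})

test_that("scene files round-trip through the on-disk format", {
  sc <- quiet_scene(n_cells = 3, seed = 13, shape = c(128, 128))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("phase.tif", "green.tif", "red.tif", "cells.csv",
           "phages.csv", "events.csv", "config.txt")))))
  red <- read_image_tiff(file.path(dir, "red.tif"))
  expect_equal(dim(red), c(128, 128))
  # 16-bit storage rounds to integers
  expect_equal(red, round(pmin(pmax(sc$channels$red, 0), 65535)),
               ignore_attr = TRUE)
  cfg_lines <- readLines(file.path(dir, "config.txt"))
  expect_true(any(grepl("^seed=13$", cfg_lines)))
})
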