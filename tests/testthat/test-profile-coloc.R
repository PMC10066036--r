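test_that("background model matches closed forms", {
  m <- make_disk_mask(8)
  img <- matrix(7, nrow(m), ncol(m))
  bg <- estimate_background(img, m, dilation = 2, min_pixels = 10)
  expect_equal(bg$mean, 7)
  expect_equal(bg$sd, 0)

  # exactly two background pixels valued 1 and 3 (min check disabled)
  m2 <- matrix(1L, 2, 2); m2[1, 1] <- 0L; m2[2, 2] <- 0L
  img2 <- matrix(0, 2, 2); img2[1, 1] <- 1; img2[2, 2] <- 3
  bg2 <- estimate_background(img2, m2, dilation = 0, min_pixels = 0)
  expect_equal(bg2$mean, 2)
  expect_equal(bg2$sd, sqrt(2))
  expect_identical(bg2$n_pixels, 2L)

  # known read noise is recovered with Poisson noise off
  sc <- simulate_scene(scene_config(n_cells = 3, seed = 19,
                                    image_shape = c(256, 256),
                                    poisson_scale = 0,
                                    gaussian_read_sd = 3),
                       channels = "red")
  bg3 <- estimate_background(sc$channels$red, truth_mask(sc))
  expect_gt(bg3$n_pixels, 1e4)
  expect_equal(bg3$sd, 3, tolerance = 0.1)

  # crowded field errors
  mfull <- matrix(1L, 32, 32)
  expect_error(estimate_background(matrix(0, 32, 32), mfull),
               "background pixels")
})

test_that("splines on a digital disk recover the circle geometry", {
  for (r in c(12, 20)) {
    m <- make_disk_mask(r)
    ctr <- attr(m, "center")
    o <- extract_outline(m, 1)
    sp <- build_splines(o, spacing = 2)
    one <- dplyr::distinct(sp, line_index, .keep_all = TRUE)
    expect_lte(abs(nrow(one) - floor(2 * pi * r / 2)), 1)
    # unit normals, within 2 degrees of radial
    expect_true(all(abs(sqrt(one$normal_x^2 + one$normal_y^2) - 1) < 1e-6))
    rx <- one$anchor_x - ctr[["x"]]; ry <- one$anchor_y - ctr[["y"]]
    rl <- sqrt(rx^2 + ry^2)
    cosang <- abs(rx * one$normal_x + ry * one$normal_y) / rl
    expect_true(all(acos(pmin(cosang, 1)) < 2 * pi / 180))
  }
})

test_that("spacing wider than the circumference still yields one line", {
  m <- make_disk_mask(8)
  o <- extract_outline(m, 1)
  sp <- build_splines(o, spacing = 10 * o$circumference_px)
  expect_identical(max(sp$line_index), 1L)
})

test_that("profile sampling is exact on constant and linear images", {
  m <- make_disk_mask(10)
  o <- extract_outline(m, 1)
  sp <- build_splines(o, spacing = 4)

  const <- matrix(3.5, nrow(m), ncol(m))
  expect_true(all(sample_profile(const, sp)$intensity == 3.5))

  # I(x, y) = x: bilinear interpolation reproduces linear fields exactly
  ramp <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m), ncol(m))
  out <- sample_profile(ramp, sp)
  expect_equal(out$intensity, out$x, tolerance = 1e-12)
})

test_that("an off-grid punctum is localized to within half a sample step", {
  n <- 64
  px <- 32.37; py <- 30.81  # continuous punctum position
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  img <- exp(-((xs - px)^2 + (ys - py)^2) / (2 * 1.5^2))
  # horizontal line through the punctum; the oracle is the same
  # interpolated image sampled densely along the same line
  step <- 0.5
  x_coarse <- px + seq(-8, 8, by = step) + 0.11
  x_dense <- seq(min(x_coarse), max(x_coarse), by = 0.01)
  peak_coarse <- x_coarse[which.max(phagecell:::bilinear(img, x_coarse,
                                                         rep(py, length(x_coarse))))]
  peak_dense <- x_dense[which.max(phagecell:::bilinear(img, x_dense,
                                                       rep(py, length(x_dense))))]
  expect_lt(abs(peak_coarse - peak_dense), step / 2 + 1e-9)
  # the interpolated field's max sits at an x-knot, within one knot
  # spacing of the true projection
  expect_lt(abs(peak_dense - px), 0.5 + 1e-9)
})

test_that("peak detection handles single peaks, plateaus and endpoints", {
  expect_equal(detect_peaks(c(0, 1, 0)),
               tibble::tibble(index = 2L, height = 1))
  # plateau reports its leftmost sample
  expect_equal(detect_peaks(c(0, 1, 1, 0)),
               tibble::tibble(index = 2L, height = 1))
  # endpoints are never peaks
  expect_identical(nrow(detect_peaks(c(0, 1, 2, 3))), 0L)
  expect_identical(nrow(detect_peaks(c(3, 2, 1))), 0L)
  expect_identical(nrow(detect_peaks(numeric(0))), 0L)
})

test_that("peak detection agrees with a brute-force checker on exhaustive small profiles", {
  # all profiles of length <= 6 over {0, 1, 2}
  for (len in 3:6) {
    grid <- expand.grid(rep(list(0:2), len))
    for (i in seq_len(nrow(grid))) {
      v <- as.numeric(grid[i, ])
      got <- detect_peaks(v)
      ref <- reference_peaks(v)
      expect_identical(got$index, as.integer(ref$index))
      expect_identical(got$height, as.numeric(ref$height))
    }
  }
  # random longer profiles with NA gaps
  set.seed(42)
  for (i in 1:200) {
    v <- sample(c(0:4, NA), 12, replace = TRUE)
    got <- detect_peaks(v)
    ref <- reference_peaks(v)
    expect_identical(got$index, as.integer(ref$index))
  }
})

test_that("the proximal call is strict at exactly one SD above background", {
  bg <- structure(list(channel = "red", mean = 10, sd = 2, n_pixels = 1000,
                       exclusion_dilation = 2),
                  class = "background_model")
  at_threshold <- c(0, 12, 0)   # lone peak exactly mean + 1 sd
  above <- c(0, 14, 0)          # mean + 2 sd
  expect_false(call_proximal(at_threshold, bg)$proximal)
  expect_true(call_proximal(above, bg)$proximal)
  expect_identical(call_proximal(c(1, 1, 1), bg)$red_peak_height, 0)
})

test_that("raising k never increases the number of proximal lines", {
  sc <- quiet_scene(n_cells = 4, seed = 23, phage_rate = 3,
                    gaussian_read_sd = 2)
  m <- truth_mask(sc)
  counts <- vapply(c(0.5, 1, 2, 4), function(k) {
    sum(run_coloc(sc$channels$green, sc$channels$red, m, k = k)$proximal)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("green measurement subtracts background without clipping", {
  bg <- structure(list(channel = "green", mean = 5, sd = 1, n_pixels = 1000,
                       exclusion_dilation = 2),
                  class = "background_model")
  expect_equal(measure_green(c(5, 20, 7), rep(TRUE, 3), bg), 15)
  expect_equal(measure_green(c(5, 5, 5), rep(TRUE, 3), bg), 0)
  expect_equal(measure_green(c(2, 3, 1), rep(TRUE, 3), bg), -2)
  expect_error(measure_green(c(1, 2), c(FALSE, FALSE), bg), "intramembrane")
})

test_that("adding a constant to both channels leaves calls and measures unchanged", {
  sc <- quiet_scene(n_cells = 3, seed = 29, phage_rate = 3,
                    gaussian_read_sd = 1.5)
  m <- truth_mask(sc)
  base <- run_coloc(sc$channels$green, sc$channels$red, m)
  shifted <- run_coloc(sc$channels$green + 50, sc$channels$red + 50, m)
  expect_identical(base$proximal, shifted$proximal)
  expect_equal(base$green_max_bgsub, shifted$green_max_bgsub)
})

test_that("polar green enrichment shows up at pole-anchored lines", {
  # noiseless strongly polar cells: pole lines beat mid-cell lines
  sc <- quiet_scene(n_cells = 6, seed = 37, polar_green_ratio = 3,
                    lateral_green_level = 0.1, phage_rate = 0)
  m <- truth_mask(sc)
  bgg <- estimate_background(sc$channels$green, m)
  px <- sc$config$pixel_size
  wins <- 0L; total <- 0L
  for (id in sc$cells$cell_id) {
    o <- extract_outline(m, id)
    sp <- build_splines(o)
    sp <- sample_profile(sc$channels$green, sp)
    per_line <- sp %>%
      dplyr::group_by(line_index) %>%
      dplyr::summarise(
        g = max(intensity[inside & valid]) - bgg$mean,
        ax = anchor_x[1], ay = anchor_y[1], .groups = "drop")
    cls <- truth_site_class(sc$cells[sc$cells$cell_id == id, ],
                            per_line$ax, per_line$ay, px)
    pole <- per_line$g[cls %in% c("old_pole", "new_pole")]
    lateral <- per_line$g[cls == "lateral"]
    if (length(pole) && length(lateral)) {
      total <- total + 1L
      if (median(pole) > median(lateral)) wins <- wins + 1L
    }
  }
  expect_gte(wins / total, 0.95)
})

test_that("a field without phage signal yields no proximal lines", {
  sc <- quiet_scene(n_cells = 4, seed = 41, phage_rate = 0)
  m <- truth_mask(sc)
  cc <- run_coloc(sc$channels$green, sc$channels$red, m)
  expect_false(any(cc$proximal))
  s <- coloc_summary(cc)
  expect_identical(s$n_lines[s$group == "proximal"], 0L)
  expect_true(is.na(s$median[s$group == "proximal"]))
})

test_that("proximal anchors concentrate at poles as polar bias rises", {
  frac_polar <- vapply(c(0, 0.5, 1), function(pb) {
    sc <- simulate_scene(scene_config(
      n_cells = 12, seed = 47, image_shape = c(420, 420),
      polar_bias = pb, phage_rate = 3), channels = c("green", "red"))
    m <- truth_mask(sc)
    cc <- run_coloc(sc$channels$green, sc$channels$red, m)
    prox <- cc[cc$proximal, ]
    if (!nrow(prox)) return(NA_real_)
    cls <- unlist(lapply(split(prox, prox$cell_id), function(df) {
      truth_site_class(sc$cells[sc$cells$cell_id == df$cell_id[1], ],
                       df$anchor_x, df$anchor_y, sc$config$pixel_size)
    }))
    mean(cls != "lateral")
  }, numeric(1))
  expect_true(all(diff(frac_polar) >= 0))
})

test_that("coloc outputs are written to disk", {
  sc <- quiet_scene(n_cells = 3, seed = 53, phage_rate = 3)
  m <- truth_mask(sc)
  cc <- run_coloc(sc$channels$green, sc$channels$red, m)
  dir <- withr::local_tempdir()
  write_coloc(cc, dir)
  expect_true(file.exists(file.path(dir, "coloc_lines.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  back <- utils::read.csv(file.path(dir, "coloc_lines.csv"))
  expect_identical(nrow(back), nrow(cc))
})
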