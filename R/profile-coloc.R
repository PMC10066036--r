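#' Estimate cell-free image background
#'
#' Mean and sample standard deviation of pixels farther than `dilation`
#' pixels from any labelled (cell) pixel — "background measured where no
#' cells are present". Estimated per channel and per frame.
#'
#' @param image 2-D numeric matrix.
#' @param mask Integer label mask of the same shape.
#' @param dilation Exclusion distance from labelled pixels.
#' @param min_pixels Minimum background pixels required (set 0 to disable
#'   the check).
#' @param channel Optional channel name stored in the model.
#' @return A `background_model`: list with `channel`, `mean`, `sd`
#'   (sample SD, n-1), `n_pixels`, `exclusion_dilation`.
#' @export
estimate_background <- function(image, mask, dilation = 2,
                                min_pixels = 500, channel = NA_character_) {
  stopifnot(all(dim(image) == dim(mask)))
  if (any(mask > 0)) {
    # distance from each pixel to the nearest labelled pixel
    d <- EBImage::distmap(matrix(as.numeric(mask == 0), nrow(mask),
                                 ncol(mask)))
    sel <- as.numeric(d) > dilation
  } else {
    sel <- rep(TRUE, length(image))
  }
  vals <- as.numeric(image)[sel]
  if (length(vals) < max(min_pixels, 2)) {
    rlang::abort(sprintf(
      "Only %d background pixels (need >= %d): field too crowded for background estimation.",
      length(vals), max(min_pixels, 2)))
  }
  structure(list(channel = channel, mean = mean(vals), sd = sd(vals),
                 n_pixels = length(vals), exclusion_dilation = dilation),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model%s> mean %.3f, sd %.3f (n = %d px, dilation %g)\n",
              if (is.na(x$channel)) "" else paste0(": ", x$channel),
              x$mean, x$sd, x$n_pixels, x$exclusion_dilation))
  invisible(x)
}

#' Build membrane-perpendicular sampling lines ("splines") around a cell
#'
#' Anchors are equally spaced in boundary arclength
#' (`floor(circumference / spacing)` lines, minimum 1). Each line runs
#' along the outward boundary normal (central-difference tangent, oriented
#' away from the centroid) from `out_len` pixels outside the cell to
#' `in_len` pixels inside, sampled every `step` pixels. Geometry only; use
#' [sample_profile()] to fill intensities.
#'
#' @param outline A `cell_outline`.
#' @param spacing Arclength between anchors in pixels.
#' @param in_len Inward reach in pixels; default `min(width/2, 6)`.
#' @param out_len Outward reach in pixels.
#' @param step Sample spacing along the line in pixels.
#' @return Tibble with one row per sample: `cell_id`, `line_index`,
#'   `position` (negative outside, positive inside), `x`, `y`, `inside`,
#'   plus anchor and outward-normal columns.
#' @export
build_splines <- function(outline, spacing = 2, in_len = NULL, out_len = 3,
                          step = 0.5) {
  stopifnot(inherits(outline, "cell_outline"))
  if (spacing <= 0 || step <= 0)
    rlang::abort("`spacing` and `step` must be positive.")
  if (is.null(in_len)) in_len <- min(outline$width_px / 2, 6)
  C <- outline$circumference_px
  n_lines <- max(1L, floor(C / spacing))

  nb <- max(200L, nrow(outline$boundary))
  bd <- resample_closed(outline$boundary$x, outline$boundary$y, nb)
  ds <- C / nb
  anchors_s <- (seq_len(n_lines) - 1L) * spacing
  ai <- round(anchors_s / ds) %% nb + 1L

  # tangents from a heavily smoothed copy of the polyline with a wide
  # central-difference stencil: chords over symmetric arcs are parallel to
  # the tangent on circular arcs, so this suppresses marching-squares
  # ripple without biasing the direction (windows shrink for small cells)
  hw_t <- max(1L, round(min(5, C / 12) / ds))
  sx <- circular_smooth(bd$x, hw_t)
  sy <- circular_smooth(bd$y, hw_t)
  wd <- max(1L, round(min(4, C / 16) / ds))
  ip <- (ai + wd - 1L) %% nb + 1L
  im <- (ai - wd - 1L) %% nb + 1L
  tx <- sx[ip] - sx[im]
  ty <- sy[ip] - sy[im]
  tl <- sqrt(tx^2 + ty^2)
  tl[tl == 0] <- 1
  nx <- -ty / tl; ny <- tx / tl
  # orient outward: positive dot product with anchor - centroid
  dot <- (bd$x[ai] - outline$centroid[["x"]]) * nx +
         (bd$y[ai] - outline$centroid[["y"]]) * ny
  flip <- dot < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]

  positions <- seq(-out_len, in_len, by = step)
  grid <- tidyr::expand_grid(line_index = seq_len(n_lines),
                             position = positions)
  grid$anchor_x <- bd$x[ai][grid$line_index]
  grid$anchor_y <- bd$y[ai][grid$line_index]
  grid$normal_x <- nx[grid$line_index]
  grid$normal_y <- ny[grid$line_index]
  # position q > 0 lies inside: anchor - q * outward_normal
  grid$x <- grid$anchor_x - grid$position * grid$normal_x
  grid$y <- grid$anchor_y - grid$position * grid$normal_y
  grid$inside <- grid$position >= 0
  grid$cell_id <- outline$cell_id
  dplyr::select(grid, "cell_id", "line_index", "position", "x", "y",
                "inside", "anchor_x", "anchor_y", "normal_x", "normal_y")
}

# Bilinear interpolation of img at continuous (x = col, y = row);
# NA outside the image.
bilinear <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr & is.finite(x) & is.finite(y)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  xo <- x[ok]; yo <- y[ok]
  x0 <- pmin(floor(xo), nc - 1); y0 <- pmin(floor(yo), nr - 1)
  fx <- xo - x0; fy <- yo - y0
  i00 <- y0 + (x0 - 1) * nr
  c00 <- img[i00]; c10 <- img[i00 + nr]
  c01 <- img[i00 + 1]; c11 <- img[i00 + nr + 1]
  # incremental form: exact on constant and linear fields (no roundoff
  # ripple that strict peak detection would pick up)
  v <- c00 + fx * (c10 - c00) + fy * (c01 - c00) +
    fx * fy * (c11 - c10 - c01 + c00)
  out[ok] <- v
  out
}

#' Sample image intensities along spline lines
#'
#' Bilinear interpolation at each sample point; samples outside the image
#' are flagged invalid (`NA` intensity) and excluded from downstream peaks
#' and maxima.
#'
#' @param image 2-D numeric matrix.
#' @param lines Tibble from [build_splines()].
#' @return `lines` with `intensity` and `valid` columns added.
#' @export
sample_profile <- function(image, lines) {
  val <- bilinear(image, lines$x, lines$y)
  if (all(is.na(val))) rlang::abort("All samples fall outside the image.")
  lines$intensity <- val
  lines$valid <- !is.na(val)
  lines
}

#' Detect strict interior local maxima in a 1-D profile
#'
#' A peak is a run of equal values strictly greater than both neighbouring
#' runs; plateaus report their leftmost sample. Endpoints are never peaks.
#' `NA` samples split the profile; run ends adjacent to `NA` are treated
#' like endpoints.
#'
#' @param values Numeric vector (length >= 3 for any peak to exist).
#' @return Tibble with `index` and `height` per peak (possibly empty).
#' @export
detect_peaks <- function(values) {
  n <- length(values)
  empty <- tibble::tibble(index = integer(), height = numeric())
  if (n < 3) return(empty)
  segs <- split(seq_len(n), cumsum(is.na(values)))
  out <- list()
  for (seg in segs) {
    seg <- seg[!is.na(values[seg])]
    if (length(seg) < 3) next
    v <- values[seg]
    r <- rle(v)
    if (length(r$lengths) < 3) next
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    for (j in 2:(length(r$lengths) - 1L)) {
      if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1]) {
        out[[length(out) + 1]] <- tibble::tibble(
          index = seg[starts[j]], height = r$values[j])
      }
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out)
}

#' Call a line "phage proximal" from its red-channel profile
#'
#' The line is phage proximal when its tallest red peak is strictly more
#' than `k` background standard deviations above the background mean.
#'
#' @param red_values Red-channel intensities along the line (full line:
#'   phage particles sit on the cell surface).
#' @param bg A `background_model` for the red channel.
#' @param k Threshold multiplier (default 1 standard deviation).
#' @return One-row tibble: `red_peak_height` (0 if no peak), `threshold`
#'   (`bg$mean + k * bg$sd`), `proximal`, `k`.
#' @export
call_proximal <- function(red_values, bg, k = 1) {
  stopifnot(inherits(bg, "background_model"))
  pk <- detect_peaks(red_values)
  height <- if (nrow(pk)) max(pk$height) else 0
  threshold <- bg$mean + k * bg$sd
  tibble::tibble(red_peak_height = height, threshold = threshold,
                 proximal = height > threshold, k = k)
}

#' Background-subtracted maximum green (new cell wall) signal on a line
#'
#' Maximum over the intramembrane (inside) samples of
#' `intensity - bg$mean`. Not clipped at zero, preserving the symmetric
#' null distribution.
#'
#' @param green_values Green intensities along the line.
#' @param inside Logical flags marking intramembrane samples.
#' @param bg A `background_model` for the green channel.
#' @return Numeric scalar (may be negative).
#' @export
measure_green <- function(green_values, inside, bg) {
  stopifnot(inherits(bg, "background_model"))
  ok <- inside & !is.na(green_values)
  if (!any(ok)) rlang::abort("No valid intramembrane samples on this line.")
  max(green_values[ok]) - bg$mean
}

#' Run the full spline colocalization over a segmented field
#'
#' For every cell in `mask`: extract the outline, build perpendicular
#' splines, sample the red and green channels, call each line phage
#' proximal from its red peak versus the cell-free background threshold,
#' and record the background-subtracted intramembrane green maximum.
#'
#' @param green,red 2-D channel matrices.
#' @param mask Integer label mask (internal segmentation or an imported
#'   external mask).
#' @param k Proximal-call threshold multiplier.
#' @param spacing,in_len,out_len,step Spline geometry, see
#'   [build_splines()].
#' @param dilation,min_bg_pixels Background estimation, see
#'   [estimate_background()].
#' @param bg_green,bg_red Optional precomputed `background_model`s.
#' @param condition Optional condition label carried into summaries.
#' @return A `coloc_result` tibble with one row per line: `cell_id`,
#'   `line_index`, `anchor_x`, `anchor_y`, `red_peak_height`, `threshold`,
#'   `proximal`, `green_max_bgsub`, `condition`. Background models and
#'   parameters are attached as attributes.
#' @export
run_coloc <- function(green, red, mask, k = 1, spacing = 2, in_len = NULL,
                      out_len = 3, step = 0.5, dilation = 2,
                      min_bg_pixels = 500, bg_green = NULL, bg_red = NULL,
                      condition = NA_character_) {
  stopifnot(all(dim(green) == dim(red)), all(dim(green) == dim(mask)))
  if (is.null(bg_green))
    bg_green <- estimate_background(green, mask, dilation, min_bg_pixels,
                                    channel = "green")
  if (is.null(bg_red))
    bg_red <- estimate_background(red, mask, dilation, min_bg_pixels,
                                  channel = "red")
  ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  recs <- lapply(ids, function(id) {
    o <- extract_outline(mask, id)
    sp <- build_splines(o, spacing = spacing, in_len = in_len,
                        out_len = out_len, step = step)
    sp$red <- bilinear(red, sp$x, sp$y)
    sp$green <- bilinear(green, sp$x, sp$y)
    sp %>%
      dplyr::group_by(.data$line_index) %>%
      dplyr::summarise(
        cell_id = id,
        anchor_x = .data$anchor_x[1], anchor_y = .data$anchor_y[1],
        call_proximal(.data$red, bg_red, k = k),
        green_max_bgsub = {
          ok <- .data$inside & !is.na(.data$green)
          if (any(ok)) max(.data$green[ok]) - bg_green$mean else NA_real_
        },
        .groups = "drop")
  })
  out <- dplyr::bind_rows(recs)
  out$condition <- condition
  out <- dplyr::select(out, "condition", "cell_id", "line_index",
                       "anchor_x", "anchor_y", "red_peak_height",
                       "threshold", "proximal", "green_max_bgsub")
  structure(out, class = c("coloc_result", class(tibble::tibble())),
            bg_green = bg_green, bg_red = bg_red,
            params = list(k = k, spacing = spacing, in_len = in_len,
                          out_len = out_len, step = step,
                          dilation = dilation),
            n_cells = length(ids))
}

#' Summarize a colocalization run per condition
#'
#' Median and quartiles of the background-subtracted green maxima for the
#' phage-proximal and non-proximal line groups (the violin-plot summary).
#'
#' @param records A `coloc_result` (or compatible tibble).
#' @return Tibble with one row per (condition, group): `n_lines`,
#'   `median`, `q25`, `q75`; empty groups are reported with `n_lines = 0`
#'   and `NA` statistics. `n_cells` and `n_proximal` ride along.
#' @export
coloc_summary <- function(records) {
  grp <- function(df, label) {
    tibble::tibble(
      condition = if (nrow(df)) df$condition[1] else NA_character_,
      group = label, n_lines = nrow(df),
      median = if (nrow(df)) median(df$green_max_bgsub, na.rm = TRUE)
        else NA_real_,
      q25 = if (nrow(df)) quantile(df$green_max_bgsub, 0.25, na.rm = TRUE,
                                   names = FALSE) else NA_real_,
      q75 = if (nrow(df)) quantile(df$green_max_bgsub, 0.75, na.rm = TRUE,
                                   names = FALSE) else NA_real_)
  }
  out <- records %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::group_map(~ dplyr::bind_rows(
      grp(dplyr::filter(.x, .data$proximal) %>%
            dplyr::mutate(condition = .y$condition), "proximal"),
      grp(dplyr::filter(.x, !.data$proximal) %>%
            dplyr::mutate(condition = .y$condition), "non_proximal"))) %>%
    dplyr::bind_rows()
  out$n_cells <- length(unique(records$cell_id))
  out$n_proximal <- sum(records$proximal)
  out
}

#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  s <- coloc_summary(x)
  tibble::tibble(
    n_cells = s$n_cells[1],
    n_lines = nrow(x),
    n_proximal = s$n_proximal[1],
    median_proximal = s$median[s$group == "proximal"][1],
    median_non_proximal = s$median[s$group == "non_proximal"][1],
    median_difference = s$median[s$group == "proximal"][1] -
      s$median[s$group == "non_proximal"][1]
  )
}

#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Write colocalization outputs
#'
#' `coloc_lines.csv` (per-line records) and `summary.json` (per-group
#' medians/quartiles plus parameters).
#'
#' @param records A `coloc_result`.
#' @param dir Output directory.
#' @export
write_coloc <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tibble::as_tibble(records),
                   file.path(dir, "coloc_lines.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(summary = coloc_summary(records),
           params = attr(records, "params")),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
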