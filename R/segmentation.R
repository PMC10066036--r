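#' Segment a phase-contrast image into a cell label mask
#'
#' Classical pipeline for fields of dark cells on a bright background:
#' Gaussian smoothing, Otsu threshold on the inverted image, hole filling,
#' connected-component labelling, an area filter, and an optional
#' distance-transform watershed to split touching cells. Externally
#' produced label masks (e.g. from a learned model) can be used instead via
#' [read_mask_tiff()]; downstream results are identical for identical
#' masks.
#'
#' @param phase 2-D numeric matrix, cells darker than background.
#' @param smooth_sigma Gaussian smoothing sigma in pixels.
#' @param min_area Minimum object area in pixels; smaller objects dropped.
#' @param split_touching If TRUE, split touching cells by watershed on the
#'   distance transform.
#' @return Integer label mask (0 = background, k > 0 = cell k, relabelled
#'   1..n). An empty or foreground-free image yields an all-zero mask with
#'   a warning.
#' @export
segment_phase <- function(phase, smooth_sigma = 1, min_area = 50,
                          split_touching = FALSE) {
  stopifnot(is.matrix(phase))
  rng <- range(phase, finite = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0) {
    rlang::warn("No foreground found; returning an empty mask.")
    return(matrix(0L, nrow(phase), ncol(phase)))
  }
  norm <- (phase - rng[1]) / diff(rng)
  sm <- if (smooth_sigma > 0) {
    matrix(as.numeric(EBImage::gblur(norm, sigma = smooth_sigma)),
           nrow(phase), ncol(phase))
  } else norm
  inv <- max(sm) - sm
  inv <- inv / max(inv)
  # two-pass threshold: Otsu for a rough foreground, then the half-amplitude
  # level between background and the cell-interior plateau, which tracks the
  # true edge of a PSF-blurred dark rod much more closely than Otsu alone
  thr0 <- EBImage::otsu(EBImage::Image(inv), range = c(0, 1))
  fg0 <- inv > thr0
  if (!any(fg0) || all(fg0)) {
    rlang::warn("No foreground found; returning an empty mask.")
    return(matrix(0L, nrow(phase), ncol(phase)))
  }
  interior <- quantile(inv[fg0], 0.95, names = FALSE)
  bg_level <- median(inv[!fg0])
  thr <- bg_level + 0.5 * (interior - bg_level)
  fg <- matrix(as.numeric(inv > thr), nrow(phase), ncol(phase))
  fg <- EBImage::fillHull(EBImage::Image(fg)) > 0.5
  labels <- if (split_touching) {
    dm <- EBImage::distmap(fg)
    EBImage::watershed(dm, tolerance = 1)
  } else {
    EBImage::bwlabel(fg)
  }
  labels <- matrix(as.integer(labels), nrow(phase), ncol(phase))
  relabel_filtered(labels, min_area)
}

# Drop labels below min_area and relabel 1..n in order of first appearance.
relabel_filtered <- function(labels, min_area) {
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels, nbins = max(labels))
  keep <- which(areas >= min_area)
  if (!length(keep)) {
    rlang::warn("No objects above `min_area`; returning an empty mask.")
    return(matrix(0L, nrow(labels), ncol(labels)))
  }
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- map[labels[nz]]
  out
}

#' Extract a sub-pixel outline, midline and size metrics for one cell
#'
#' The boundary is traced by marching squares (`grDevices::contourLines`)
#' at level 0.5 on a lightly smoothed binary mask of the cell, giving a
#' closed sub-pixel polyline. The midline is a binned centerline along the
#' region's principal axis; cell length is the midline arclength plus the
#' two cap extensions to the pole points.
#'
#' @param mask Integer label mask.
#' @param cell_id Label to extract.
#' @param pixel_size Optional micrometres per pixel; fills the `_um`
#'   metrics.
#' @return A `cell_outline`: list with `boundary` (closed tibble of s, x,
#'   y), `midline` (tibble x, y), `circumference_px`, `length_px`,
#'   `width_px`, `centroid`, `pole_points`, and `_um` versions when
#'   `pixel_size` is given.
#' @export
extract_outline <- function(mask, cell_id, pixel_size = NULL) {
  px <- which(mask == cell_id, arr.ind = TRUE)
  if (!nrow(px)) rlang::abort(sprintf("Label %s not present in mask.", cell_id))
  if (nrow(px) < 3) rlang::abort("Degenerate region: fewer than 3 pixels.")
  xs <- px[, 2]; ys <- px[, 1]  # x = col, y = row

  pad <- 5L
  r0 <- min(ys) - pad; r1 <- max(ys) + pad
  c0 <- min(xs) - pad; c1 <- max(xs) + pad
  sub <- matrix(0, r1 - r0 + 1, c1 - c0 + 1)
  sub[cbind(ys - r0 + 1, xs - c0 + 1)] <- 1
  subs <- matrix(as.numeric(EBImage::gblur(sub, sigma = 1)),
                 nrow(sub), ncol(sub))
  cl <- grDevices::contourLines(x = seq(r0, r1), y = seq(c0, c1),
                                z = subs, levels = 0.5)
  if (!length(cl)) rlang::abort("Degenerate region: no boundary found.")
  cl <- cl[[which.max(vapply(cl, function(u) length(u$x), numeric(1)))]]
  # contourLines: $x follows the first matrix index (rows), $y the second
  bx <- cl$y; by <- cl$x
  bd <- resample_closed(bx, by, max(length(bx) * 2, 64))
  # circular moving average over ~+-1.5 px of arc removes the residual
  # pixel-scale ripple of the marching-squares contour
  ds0 <- polyline_length(c(bd$x, bd$x[1]), c(bd$y, bd$y[1])) / nrow(bd)
  hw <- max(1L, round(1.5 / ds0))
  bd$x <- circular_smooth(bd$x, hw)
  bd$y <- circular_smooth(bd$y, hw)
  bd <- resample_closed(bd$x, bd$y, nrow(bd))
  circumference <- polyline_length(c(bd$x, bd$x[1]), c(bd$y, bd$y[1]))

  centroid <- c(x = mean(xs), y = mean(ys))
  pc <- prcomp(cbind(xs, ys), center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]; w <- pc$rotation[, 2]
  t_px <- (xs - centroid[1]) * v[1] + (ys - centroid[2]) * v[2]
  p_px <- (xs - centroid[1]) * w[1] + (ys - centroid[2]) * w[2]

  brks <- seq(floor(min(t_px)), ceiling(max(t_px)) + 1, by = 1)
  bin <- findInterval(t_px, brks)
  bt <- tapply(t_px, bin, mean)
  bp <- tapply(p_px, bin, mean)
  ext <- tapply(p_px, bin, function(z) diff(range(z)) + 1)
  ord <- order(bt)
  bt <- as.numeric(bt[ord]); bp <- as.numeric(bp[ord])
  ext <- as.numeric(ext[ord])
  if (length(bp) >= 5) {
    sm_bp <- stats::filter(bp, rep(1 / 3, 3), sides = 2)
    bp[!is.na(sm_bp)] <- sm_bp[!is.na(sm_bp)]
  }
  width_rough <- median(ext)
  central <- bt >= (min(t_px) + width_rough / 2) &
    bt <= (max(t_px) - width_rough / 2)
  width_px <- if (any(central)) median(ext[central]) else width_rough

  mid_x <- centroid[1] + bt * v[1] + bp * w[1]
  mid_y <- centroid[2] + bt * v[2] + bp * w[2]

  bt_bd <- (bd$x - centroid[1]) * v[1] + (bd$y - centroid[2]) * v[2]
  i_hi <- which.max(bt_bd); i_lo <- which.min(bt_bd)
  pole_hi <- c(bd$x[i_hi], bd$y[i_hi])
  pole_lo <- c(bd$x[i_lo], bd$y[i_lo])

  mid_len <- polyline_length(mid_x, mid_y)
  cap_lo <- sqrt((mid_x[1] - pole_lo[1])^2 + (mid_y[1] - pole_lo[2])^2)
  cap_hi <- sqrt((mid_x[length(mid_x)] - pole_hi[1])^2 +
                 (mid_y[length(mid_y)] - pole_hi[2])^2)
  length_px <- mid_len + cap_lo + cap_hi

  # store the boundary explicitly closed (first point repeated at the end)
  bd_closed <- dplyr::bind_rows(
    bd, tibble::tibble(s = circumference, x = bd$x[1], y = bd$y[1]))
  out <- list(
    cell_id = cell_id,
    boundary = bd_closed,
    midline = tibble::tibble(x = c(pole_lo[1], mid_x, pole_hi[1]),
                             y = c(pole_lo[2], mid_y, pole_hi[2])),
    circumference_px = circumference,
    length_px = length_px,
    width_px = width_px,
    centroid = centroid,
    pole_points = rbind(pole_lo, pole_hi),
    pixel_size = pixel_size
  )
  if (!is.null(pixel_size)) {
    out$circumference_um <- circumference * pixel_size
    out$length_um <- length_px * pixel_size
    out$width_um <- width_px * pixel_size
  }
  structure(out, class = "cell_outline")
}

#' @export
print.cell_outline <- function(x, ...) {
  cat(sprintf("<cell_outline> cell %s: length %.2f px, width %.2f px, circumference %.2f px\n",
              x$cell_id, x$length_px, x$width_px, x$circumference_px))
  invisible(x)
}

#' Cell length in micrometres
#'
#' Midline arclength plus the two cap extensions to the pole points.
#'
#' @param outline A `cell_outline` with known `pixel_size`.
#' @return Length in micrometres.
#' @export
cell_length <- function(outline) {
  stopifnot(inherits(outline, "cell_outline"))
  if (is.null(outline$pixel_size))
    rlang::abort("`pixel_size` unknown; re-run extract_outline() with it.")
  outline$length_px * outline$pixel_size
}

#' Per-cell geometry table for a label mask
#'
#' Tidy wrapper running [extract_outline()] over every label.
#'
#' @inheritParams extract_outline
#' @return Tibble with one row per cell: `cell_id`, `area_px`,
#'   `circumference_px`, `length_px`, `width_px`, centroid coordinates and
#'   `_um` columns when `pixel_size` is given.
#' @export
outline_table <- function(mask, pixel_size = NULL) {
  ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  areas <- tabulate(mask[mask > 0], nbins = max(c(ids, 1L)))
  rows <- lapply(ids, function(id) {
    o <- extract_outline(mask, id, pixel_size)
    tibble::tibble(
      cell_id = id, area_px = areas[id],
      circumference_px = o$circumference_px,
      length_px = o$length_px, width_px = o$width_px,
      centroid_x = o$centroid[["x"]], centroid_y = o$centroid[["y"]],
      length_um = if (!is.null(pixel_size)) o$length_um else NA_real_,
      circumference_um = if (!is.null(pixel_size)) o$circumference_um
        else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Best-match intersection-over-union between two label masks
#'
#' @param pred,truth Integer label masks of equal shape.
#' @return Tibble with one row per truth label: `truth_id`, the
#'   best-overlapping `pred_id` (NA if none) and `iou`.
#' @export
mask_iou <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  ids <- setdiff(sort(unique(as.vector(truth))), 0L)
  nz <- pred > 0 | truth > 0
  tp <- table(truth = truth[nz], pred = pred[nz])
  areas_t <- tabulate(truth[truth > 0], nbins = max(c(ids, 1L)))
  areas_p <- tabulate(pred[pred > 0],
                      nbins = max(c(as.vector(pred), 1L)))
  rows <- lapply(ids, function(id) {
    ri <- which(rownames(tp) == as.character(id))
    if (!length(ri)) {
      return(tibble::tibble(truth_id = id, pred_id = NA_integer_, iou = 0))
    }
    ov <- tp[ri, ]
    cand <- as.integer(colnames(tp))
    ok <- cand > 0
    if (!any(ok & ov > 0)) {
      return(tibble::tibble(truth_id = id, pred_id = NA_integer_, iou = 0))
    }
    inter <- ov[ok]; cand <- cand[ok]
    union <- areas_t[id] + areas_p[cand] - inter
    j <- which.max(inter / union)
    tibble::tibble(truth_id = id, pred_id = cand[j],
                   iou = as.numeric(inter[j] / union[j]))
  })
  dplyr::bind_rows(rows)
}
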