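# Spherocylinder (capsule) geometry in continuous pixel coordinates.
#
# Convention used throughout the package: images are matrices indexed
# img[row, col]; continuous coordinates are (x = col, y = row) with pixel
# centers at integer positions. Boundary arclength s runs from 0 at one end
# of the E1 pole cap, around the cap, along side 1, around the E2 cap and
# back along side 2 (total = circumference).

# Build the internal capsule descriptor from center, orientation and
# tip-to-tip length / width in pixels.
capsule <- function(cx, cy, orientation, length_px, width_px,
                    old_pole_end = 1L, has_septum = FALSE) {
  r <- width_px / 2
  Lm <- max(length_px - width_px, 0)
  u <- c(cos(orientation), sin(orientation))
  nv <- c(-u[2], u[1])
  e1 <- c(cx, cy) + (Lm / 2) * u
  e2 <- c(cx, cy) - (Lm / 2) * u
  list(
    cx = cx, cy = cy, u = u, n = nv, r = r, Lm = Lm,
    e1 = e1, e2 = e2,
    circumference = 2 * Lm + 2 * pi * r,
    old_pole_end = old_pole_end, has_septum = has_septum
  )
}

capsule_from_cell <- function(cell, pixel_size) {
  capsule(cell$x, cell$y, cell$orientation,
          cell$length_um / pixel_size, cell$width_um / pixel_size,
          old_pole_end = cell$old_pole_end,
          has_septum = isTRUE(cell$has_septum))
}

# Vectorized boundary point + outward unit normal at arclength s (recycled
# modulo the circumference).
capsule_point <- function(cap, s) {
  r <- cap$r; Lm <- cap$Lm; C <- cap$circumference
  s <- s %% C
  x <- numeric(length(s)); y <- numeric(length(s))
  nx <- numeric(length(s)); ny <- numeric(length(s))

  in_cap1 <- s < pi * r
  in_side1 <- !in_cap1 & s < pi * r + Lm
  in_cap2 <- !in_cap1 & !in_side1 & s < 2 * pi * r + Lm
  in_side2 <- !(in_cap1 | in_side1 | in_cap2)

  if (any(in_cap1)) {
    a <- -pi / 2 + s[in_cap1] / r
    dx <- cos(a) * cap$u[1] + sin(a) * cap$n[1]
    dy <- cos(a) * cap$u[2] + sin(a) * cap$n[2]
    x[in_cap1] <- cap$e1[1] + r * dx; y[in_cap1] <- cap$e1[2] + r * dy
    nx[in_cap1] <- dx; ny[in_cap1] <- dy
  }
  if (any(in_side1)) {
    t <- s[in_side1] - pi * r
    x[in_side1] <- cap$e1[1] + cap$n[1] * r - t * cap$u[1]
    y[in_side1] <- cap$e1[2] + cap$n[2] * r - t * cap$u[2]
    nx[in_side1] <- cap$n[1]; ny[in_side1] <- cap$n[2]
  }
  if (any(in_cap2)) {
    b <- pi / 2 + (s[in_cap2] - pi * r - Lm) / r
    dx <- cos(b) * cap$u[1] + sin(b) * cap$n[1]
    dy <- cos(b) * cap$u[2] + sin(b) * cap$n[2]
    x[in_cap2] <- cap$e2[1] + r * dx; y[in_cap2] <- cap$e2[2] + r * dy
    nx[in_cap2] <- dx; ny[in_cap2] <- dy
  }
  if (any(in_side2)) {
    t <- s[in_side2] - 2 * pi * r - Lm
    x[in_side2] <- cap$e2[1] - cap$n[1] * r + t * cap$u[1]
    y[in_side2] <- cap$e2[2] - cap$n[2] * r + t * cap$u[2]
    nx[in_side2] <- -cap$n[1]; ny[in_side2] <- -cap$n[2]
  }
  tibble::tibble(s = s, x = x, y = y, nx = nx, ny = ny)
}

# Closed boundary polyline sampled at arc steps <= `step` pixels
# (first point repeated at the end).
capsule_boundary <- function(cap, step = 0.5) {
  n <- max(ceiling(cap$circumference / step), 16)
  s <- seq(0, cap$circumference, length.out = n + 1)
  capsule_point(cap, c(s[-(n + 1)], 0))
}

# Arclength intervals [start, end] of the pole caps and septum bands.
capsule_arcs <- function(cap) {
  r <- cap$r; Lm <- cap$Lm
  pole1 <- c(0, pi * r)
  pole2 <- c(pi * r + Lm, 2 * pi * r + Lm)
  arcs <- list(pole1 = pole1, pole2 = pole2)
  if (isTRUE(cap$has_septum) && Lm > 2) {
    m1 <- pi * r + Lm / 2
    m2 <- 2 * pi * r + Lm + Lm / 2
    arcs$septum1 <- c(m1 - 1, m1 + 1)
    arcs$septum2 <- c(m2 - 1, m2 + 1)
  }
  arcs
}

# Classify boundary arclengths into old_pole / new_pole / septum / lateral.
capsule_site_class <- function(cap, s) {
  arcs <- capsule_arcs(cap)
  s <- s %% cap$circumference
  cls <- rep("lateral", length(s))
  in_arc <- function(s, a) s >= a[1] & s <= a[2]
  if (!is.null(arcs$septum1))
    cls[in_arc(s, arcs$septum1) | in_arc(s, arcs$septum2)] <- "septum"
  p1 <- in_arc(s, arcs$pole1); p2 <- in_arc(s, arcs$pole2)
  if (cap$old_pole_end == 1L) {
    cls[p1] <- "old_pole"; cls[p2] <- "new_pole"
  } else {
    cls[p1] <- "new_pole"; cls[p2] <- "old_pole"
  }
  cls
}

# Distance from points (px, py) to the segment a--b.
point_segment_dist <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  if (len2 < .Machine$double.eps) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
  sqrt((px - a[1] - t * abx)^2 + (py - a[2] - t * aby)^2)
}

# Minimum distance between two segments (for overlap-free cell placement).
segment_segment_dist <- function(a1, b1, a2, b2) {
  ts <- seq(0, 1, length.out = 9)
  p1x <- a1[1] + ts * (b1[1] - a1[1]); p1y <- a1[2] + ts * (b1[2] - a1[2])
  p2x <- a2[1] + ts * (b2[1] - a2[1]); p2y <- a2[2] + ts * (b2[2] - a2[2])
  min(min(point_segment_dist(p1x, p1y, a2, b2)),
      min(point_segment_dist(p2x, p2y, a1, b1)))
}

capsule_inside <- function(cap, x, y, tol = 0) {
  point_segment_dist(x, y, cap$e1, cap$e2) <= cap$r + tol
}

# Rasterize a capsule onto an nr x nc grid: TRUE at pixel centers inside.
rasterize_capsule <- function(cap, dim) {
  nr <- dim[1]; nc <- dim[2]
  half <- cap$Lm / 2 + cap$r + 1
  rows <- max(1, floor(cap$cy - half)):min(nr, ceiling(cap$cy + half))
  cols <- max(1, floor(cap$cx - half)):min(nc, ceiling(cap$cx + half))
  if (!length(rows) || !length(cols)) return(NULL)
  g <- expand.grid(y = rows, x = cols)
  ins <- capsule_inside(cap, g$x, g$y)
  list(rows = g$y[ins], cols = g$x[ins])
}

# Even-odd scanline fill of a closed polygon given as (x, y) vertices;
# returns a logical nr x nc matrix of pixel centers inside the polygon.
rasterize_polygon <- function(x, y, dim) {
  nr <- dim[1]; nc <- dim[2]
  out <- matrix(FALSE, nr, nc)
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  x0 <- x[-length(x)]; y0 <- y[-length(y)]
  x1 <- x[-1]; y1 <- y[-1]
  for (row in max(1, floor(min(y))):min(nr, ceiling(max(y)))) {
    yl <- row
    crosses <- (y0 <= yl & y1 > yl) | (y1 <= yl & y0 > yl)
    if (!any(crosses)) next
    t <- (yl - y0[crosses]) / (y1[crosses] - y0[crosses])
    xc <- sort(x0[crosses] + t * (x1[crosses] - x0[crosses]))
    for (i in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[i]); hi <- floor(xc[i + 1])
      lo <- max(lo, 1); hi <- min(hi, nc)
      if (lo <= hi) out[row, lo:hi] <- TRUE
    }
  }
  out
}

# Circular moving average with half-window hw (for closed polylines).
circular_smooth <- function(v, hw) {
  n <- length(v)
  if (hw < 1 || n < 2 * hw + 1) return(v)
  ext <- c(v[(n - hw + 1):n], v, v[1:hw])
  as.numeric(stats::filter(ext, rep(1 / (2 * hw + 1), 2 * hw + 1),
                           sides = 2))[(hw + 1):(hw + n)]
}

# Polyline arclength.
polyline_length <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Resample a closed polyline (first point == last point not required) to
# `n` points equally spaced in arclength. Returns tibble(s, x, y).
resample_closed <- function(x, y, n) {
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  s_new <- seq(0, total, length.out = n + 1)[-(n + 1)]
  xi <- stats::approx(cs, x, xout = s_new, ties = "ordered")$y
  yi <- stats::approx(cs, y, xout = s_new, ties = "ordered")$y
  tibble::tibble(s = s_new, x = xi, y = yi)
}
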