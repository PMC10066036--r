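# Low-level rendering: point splatting, PSF convolution, camera noise.

# Bilinear splat of weighted points onto an nr x nc accumulator.
deposit_points <- function(dim, x, y, w) {
  nr <- dim[1]; nc <- dim[2]
  acc <- numeric(nr * nc)
  if (!length(x)) return(matrix(acc, nr, nc))
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  corners <- list(
    list(cx = x0,     cy = y0,     w = (1 - fx) * (1 - fy)),
    list(cx = x0 + 1, cy = y0,     w = fx * (1 - fy)),
    list(cx = x0,     cy = y0 + 1, w = (1 - fx) * fy),
    list(cx = x0 + 1, cy = y0 + 1, w = fx * fy)
  )
  for (cr in corners) {
    ok <- cr$cx >= 1 & cr$cx <= nc & cr$cy >= 1 & cr$cy <= nr & cr$w > 0
    if (!any(ok)) next
    idx <- cr$cy[ok] + (cr$cx[ok] - 1) * nr
    sums <- rowsum(w[ok] * cr$w[ok], group = idx)
    ii <- as.integer(rownames(sums))
    acc[ii] <- acc[ii] + sums[, 1]
  }
  matrix(acc, nr, nc)
}

# Isotropic Gaussian PSF, truncated at 4 sigma, kernel normalized to unit sum
# so integrated intensity is conserved away from the image edge.
psf_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

psf_blur <- function(img, sigma, boundary = 0) {
  if (sigma <= 0) return(img)
  out <- EBImage::filter2(img, psf_kernel(sigma), boundary = boundary)
  matrix(as.numeric(out), nrow(img), ncol(img))
}

# sCMOS-style camera noise: Poisson shot noise on (signal) x poisson_scale
# photons, rescaled back to intensity units, plus Gaussian read noise.
# Both terms are independently switchable (0 disables).
add_camera_noise <- function(img, poisson_scale = 0, read_sd = 0) {
  if (poisson_scale > 0) {
    img <- matrix(rpois(length(img), pmax(img, 0) * poisson_scale),
                  nrow(img), ncol(img)) / poisson_scale
  }
  if (read_sd > 0) {
    img <- img + matrix(rnorm(length(img), sd = read_sd),
                        nrow(img), ncol(img))
  }
  img
}
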