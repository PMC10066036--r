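# Shared fixtures: all synthetic, generated in code at test time.

suppressPackageStartupMessages(library(dplyr))

# Binary digital disk of radius r as an integer label mask.
make_disk_mask <- function(r, pad = 17) {
  n <- 2 * r + 2 * pad
  ctr <- n / 2
  m <- matrix(0L, n, n)
  for (row in seq_len(n)) {
    for (col in seq_len(n)) {
      if ((row - ctr)^2 + (col - ctr)^2 <= r^2) m[row, col] <- 1L
    }
  }
  attr(m, "center") <- c(x = ctr, y = ctr)
  attr(m, "radius") <- r
  m
}

# Small noiseless-by-default field used by several tests; any
# scene_config() argument (including the noise terms) can be overridden.
quiet_scene <- function(n_cells = 5, seed = 3, shape = c(256, 256), ...) {
  args <- list(n_cells = n_cells, seed = seed, image_shape = shape,
               poisson_scale = 0, gaussian_read_sd = 0)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_scene(do.call(scene_config, args))
}

# Brute-force reference peak detector: strict interior local maxima with
# leftmost-plateau reporting, by direct definition scanning.
reference_peaks <- function(values) {
  n <- length(values)
  out <- list()
  i <- 2L
  while (i <= n - 1L) {
    if (is.na(values[i])) { i <- i + 1L; next }
    # extend plateau
    j <- i
    while (j + 1L <= n && !is.na(values[j + 1L]) &&
           values[j + 1L] == values[i]) j <- j + 1L
    left_ok <- i - 1L >= 1L && !is.na(values[i - 1L]) &&
      values[i - 1L] < values[i]
    right_ok <- j + 1L <= n && !is.na(values[j + 1L]) &&
      values[j + 1L] < values[i]
    if (left_ok && right_ok) {
      out[[length(out) + 1L]] <- data.frame(index = i, height = values[i])
    }
    i <- j + 1L
  }
  if (!length(out)) return(data.frame(index = integer(), height = numeric()))
  do.call(rbind, out)
}
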