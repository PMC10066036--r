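#' Red intensity profile along a cell's circumference
#'
#' Bilinear samples of the red (phage) channel at equal arclength intervals
#' along the closed cell boundary. The profile is circular: peak detection
#' wraps around the start.
#'
#' @param red 2-D red-channel matrix.
#' @param outline A `cell_outline`.
#' @param step Arclength sampling interval in pixels.
#' @return Tibble with `s` (arclength), `x`, `y`, `intensity`;
#'   `round(circumference / step)` rows.
#' @export
circumference_profile <- function(red, outline, step = 1) {
  stopifnot(inherits(outline, "cell_outline"))
  if (step <= 0) rlang::abort("`step` must be positive.")
  n <- max(8L, round(outline$circumference_px / step))
  bd <- resample_closed(outline$boundary$x, outline$boundary$y, n)
  bd$intensity <- bilinear(red, bd$x, bd$y)
  bd
}

# Peak detection on a circular profile: rotate so the global minimum is the
# first sample (a minimum can never be a peak, so the cut is endpoint-safe),
# run the linear detector, and map indices back.
detect_peaks_circular <- function(values) {
  n <- length(values)
  if (n < 3 || all(is.na(values)))
    return(tibble::tibble(index = integer(), height = numeric()))
  i0 <- which.min(values)
  rot <- c(values[i0:n], values[seq_len(i0 - 1L)])
  pk <- detect_peaks(rot)
  pk$index <- (pk$index + i0 - 2L) %% n + 1L
  dplyr::arrange(pk, .data$index)
}

#' Circumference-normalized phage adsorption value for one cell
#'
#' Detects circular peaks in the boundary profile, sums their
#' background-subtracted heights (peaks below background contribute 0),
#' and normalizes by the circumference: the per-cell adsorption measure
#' "summed red peak intensity / boundary length".
#'
#' @param profile Tibble from [circumference_profile()].
#' @param bg A `background_model` for the red channel.
#' @param circumference Cell circumference (pixels, or micrometres if the
#'   whole analysis is in micrometres; both groups must use the same
#'   unit).
#' @return One-row tibble: `circumference`, `n_peaks`, `peak_sum`,
#'   `normalized_value`.
#' @export
adsorption_value <- function(profile, bg, circumference) {
  stopifnot(inherits(bg, "background_model"), circumference > 0)
  pk <- detect_peaks_circular(profile$intensity)
  peak_sum <- sum(pmax(pk$height - bg$mean, 0))
  tibble::tibble(circumference = circumference, n_peaks = nrow(pk),
                 peak_sum = peak_sum,
                 normalized_value = peak_sum / circumference)
}

#' Per-cell adsorption table for a segmented field
#'
#' @param red Red-channel matrix.
#' @param mask Integer label mask.
#' @param bg Optional precomputed red `background_model`.
#' @param step Profile sampling interval in pixels.
#' @param pixel_size Optional micrometres per pixel; when given, the
#'   normalization denominator is the circumference in micrometres.
#' @param dilation,min_bg_pixels Passed to [estimate_background()].
#' @return Tibble with one row per cell: `cell_id`, `circumference`,
#'   `n_peaks`, `peak_sum`, `normalized_value`.
#' @export
adsorption_table <- function(red, mask, bg = NULL, step = 1,
                             pixel_size = NULL, dilation = 2,
                             min_bg_pixels = 500) {
  if (is.null(bg))
    bg <- estimate_background(red, mask, dilation, min_bg_pixels,
                              channel = "red")
  ids <- setdiff(sort(unique(as.vector(mask))), 0L)
  rows <- lapply(ids, function(id) {
    o <- extract_outline(mask, id, pixel_size)
    pr <- circumference_profile(red, o, step = step)
    circ <- if (is.null(pixel_size)) o$circumference_px
      else o$circumference_um
    dplyr::bind_cols(tibble::tibble(cell_id = id),
                     adsorption_value(pr, bg, circ))
  })
  dplyr::bind_rows(rows)
}

#' Two-sample Student's t comparison of adsorption values
#'
#' Pooled-variance two-sample t-test (two-tailed), the comparison used for
#' per-cell normalized adsorption between strains; a Welch variant is
#' available via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @param var_equal Pooled variance (classic Student) if TRUE, Welch
#'   otherwise.
#' @param labels Length-2 group labels.
#' @param alpha Significance level for the `significant` flag.
#' @return A `phage_ttest` one-row tibble: group labels, `n`, means,
#'   `t`, `df`, `p_value`, `significant`, `method`, `degenerate` (TRUE
#'   when both groups are constant).
#' @export
#' @examples
#' students_t(c(1, 2, 3), c(2, 3, 4))
students_t <- function(a, b, var_equal = TRUE,
                       labels = c("A", "B"), alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    rlang::abort("Each group needs at least 2 observations.")
  degenerate <- var(a) == 0 && var(b) == 0
  if (degenerate) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    tt <- list(statistic = if (same) 0 else sign(mean(a) - mean(b)) * Inf,
               parameter = length(a) + length(b) - 2,
               p.value = if (same) 1 else 0)
    if (!same)
      rlang::warn("Zero variance in both groups with unequal means; p reported as 0.")
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
  }
  out <- tibble::tibble(
    group1 = labels[1], group2 = labels[2],
    n1 = length(a), n2 = length(b),
    mean1 = mean(a), mean2 = mean(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < alpha,
    method = if (var_equal) "student_pooled" else "welch",
    degenerate = degenerate
  )
  class(out) <- c("phage_ttest", class(out))
  out
}

#' @method tidy phage_ttest
#' @export
tidy.phage_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean1 - x$mean2, estimate1 = x$mean1, estimate2 = x$mean2,
    statistic = x$t, p.value = x$p_value, parameter = x$df,
    method = x$method
  )
}

#' @method glance phage_ttest
#' @export
glance.phage_ttest <- function(x, ...) {
  tibble::as_tibble(x)[, c("t", "df", "p_value", "significant", "method")]
}
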