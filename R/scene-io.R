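#' Write a synthetic scene to disk
#'
#' Writes one 16-bit TIFF per channel, the ground truth as `cells.csv`,
#' `phages.csv` and `events.csv` (fates and event frames), and the
#' configuration (including the seed) as a flat `key=value` text file, so a
#' scene can be regenerated or consumed by external tools.
#'
#' @param scene A `phage_scene`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "phage_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (ch in names(scene$channels)) {
    p <- file.path(dir, paste0(ch, ".tif"))
    write_image_tiff(scene$channels[[ch]], p)
    paths <- c(paths, p)
  }
  utils::write.csv(scene$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$phages, file.path(dir, "phages.csv"),
                   row.names = FALSE)
  events <- scene$cells[, c("cell_id", "fate", "infection_frame",
                            "mcherry_onset_frame", "lysis_frame")]
  utils::write.csv(events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  cfg <- scene$config
  keys <- setdiff(names(cfg), "background_level")
  lines <- vapply(keys, function(k)
    paste0(k, "=", paste(format(cfg[[k]], digits = 12), collapse = ",")),
    character(1))
  lines <- c(lines, paste0("background_level=",
                           paste(cfg$background_level, collapse = ",")))
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(c(paths, file.path(dir, c("cells.csv", "phages.csv",
                                      "config.txt"))))
}

# 16-bit grayscale TIFF round trip. Intensities are stored as integers
# (clamped to [0, 65535]); tiff::writeTIFF expects [0,1] floats and uses
# the same [row, col] layout as the package.
write_image_tiff <- function(img, path) {
  v <- pmin(pmax(round(img), 0), 65535) / 65535
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale image or integer label mask from TIFF
#'
#' @param path TIFF file path.
#' @param as_labels If TRUE, round to integers (label masks).
#' @return A numeric (or integer) matrix in the package's row/col
#'   convention.
#' @export
read_image_tiff <- function(path, as_labels = FALSE) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) == 3) v <- v[, , 1]
  m <- v
  if (as_labels) storage.mode(m) <- "integer"
  m
}

#' Write an integer label mask as TIFF
#'
#' @param mask Integer label matrix.
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an externally produced label mask
#'
#' External masks (for example from a learned segmentation model) bypass
#' [segment_phase()] and feed the same downstream pipeline.
#'
#' @param path TIFF file path holding integer labels.
#' @return Integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) == 3) v <- v[, , 1]
  m <- v
  storage.mode(m) <- "integer"
  m
}
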