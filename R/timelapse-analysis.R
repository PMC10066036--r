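#' Track cells across a sequence of label masks
#'
#' Greedy frame-to-frame assignment by maximal mask overlap: label pairs
#' are matched in decreasing intersection-over-union order (IoU >=
#' `iou_min`), so at a division the parent identity follows the larger
#' daughter and the smaller daughter starts a new track. Unmatched
#' disappearance (e.g. lysis) ends a track. Tracking is invariant to label
#' permutation within frames.
#'
#' @param masks List of integer label matrices, one per frame, equal
#'   shapes, in time order.
#' @param iou_min Minimum IoU to link a label to an existing track.
#' @return A `cell_tracks` tibble: `track_id`, `frame`, `label` (the label
#'   carrying the track in that frame).
#' @export
track_cells <- function(masks, iou_min = 0.5) {
  if (!length(masks)) rlang::abort("Empty mask sequence.")
  dims <- dim(masks[[1]])
  stopifnot(all(vapply(masks, function(m) all(dim(m) == dims), logical(1))))

  rows <- list()
  next_track <- 1L
  # current[label] = track_id for the previous frame
  prev_assign <- NULL
  for (f in seq_along(masks)) {
    m <- masks[[f]]
    labs <- setdiff(sort(unique(as.vector(m))), 0L)
    assign_now <- integer(0)
    if (f == 1L || !length(labs)) {
      for (lb in labs) {
        assign_now[as.character(lb)] <- next_track
        next_track <- next_track + 1L
      }
    } else {
      pm <- masks[[f - 1]]
      nz <- pm > 0 | m > 0
      if (any(nz)) {
        tb <- table(prev = pm[nz], cur = m[nz])
        ap <- tabulate(pm[pm > 0], nbins = max(pm))
        ac <- tabulate(m[m > 0], nbins = max(m))
        prev_ids <- as.integer(rownames(tb))
        cur_ids <- as.integer(colnames(tb))
        cand <- which(tb > 0, arr.ind = TRUE)
        cand <- cand[prev_ids[cand[, 1]] > 0 & cur_ids[cand[, 2]] > 0, ,
                     drop = FALSE]
        if (nrow(cand)) {
          inter <- tb[cand]
          pi <- prev_ids[cand[, 1]]; ci <- cur_ids[cand[, 2]]
          iou <- inter / (ap[pi] + ac[ci] - inter)
          ord <- order(-iou)
          used_prev <- character(0); used_cur <- character(0)
          for (idx in ord) {
            if (iou[idx] < iou_min) break
            pk <- as.character(pi[idx]); ck <- as.character(ci[idx])
            if (pk %in% used_prev || ck %in% used_cur) next
            tid <- prev_assign[[pk]]
            if (is.null(tid) || is.na(tid)) next
            assign_now[ck] <- tid
            used_prev <- c(used_prev, pk); used_cur <- c(used_cur, ck)
          }
        }
      }
      for (lb in labs) {
        ck <- as.character(lb)
        if (is.na(assign_now[ck]) || is.null(assign_now[ck]) ||
            !(ck %in% names(assign_now))) {
          assign_now[ck] <- next_track
          next_track <- next_track + 1L
        }
      }
    }
    if (length(labs)) {
      rows[[f]] <- tibble::tibble(
        track_id = unname(assign_now[as.character(labs)]),
        frame = f, label = labs)
    }
    prev_assign <- as.list(assign_now)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  class(out) <- c("cell_tracks", class(tibble::tibble()))
  out
}

#' Per-track background-subtracted fluorescence traces
#'
#' Mean reporter intensity within each tracked cell mask per frame, minus
#' the per-frame cell-free background mean.
#'
#' @param frames List of reporter-channel matrices, one per frame.
#' @param tracks A `cell_tracks` tibble from [track_cells()].
#' @param masks The label masks used for tracking.
#' @param bg Per-frame background: a numeric vector of means, a list of
#'   `background_model`s, or NULL to estimate from each frame's mask.
#' @return Tibble: `track_id`, `frame`, `intensity` (background
#'   subtracted), `area` (pixels).
#' @export
trace_fluorescence <- function(frames, tracks, masks, bg = NULL) {
  stopifnot(length(frames) == length(masks))
  if (is.null(bg)) {
    bg <- vapply(seq_along(frames), function(f)
      estimate_background(frames[[f]], masks[[f]], min_pixels = 100)$mean,
      numeric(1))
  } else if (is.list(bg)) {
    bg <- vapply(bg, function(b) b$mean, numeric(1))
  }
  rows <- lapply(seq_along(frames), function(f) {
    tf <- tracks[tracks$frame == f, ]
    if (!nrow(tf)) return(NULL)
    img <- frames[[f]]; m <- masks[[f]]
    means <- vapply(tf$label, function(lb) mean(img[m == lb]), numeric(1))
    areas <- vapply(tf$label, function(lb) sum(m == lb), numeric(1))
    tibble::tibble(track_id = tf$track_id, frame = f,
                   intensity = means - bg[f], area = areas)
  })
  dplyr::bind_rows(rows)
}

#' Population mean and SD of traces per frame
#'
#' @param traces Tibble from [trace_fluorescence()].
#' @param groups Optional named assignment `track_id -> group` (e.g.
#'   ground-truth infected vs uninfected); per-group curves are returned
#'   when given.
#' @return Tibble: (`group`,) `frame`, `mean`, `sd`, `n`.
#' @export
trace_population <- function(traces, groups = NULL) {
  if (!is.null(groups)) {
    traces$group <- groups[as.character(traces$track_id)]
    traces %>%
      dplyr::group_by(.data$group, .data$frame) %>%
      dplyr::summarise(mean = mean(.data$intensity),
                       sd = sd(.data$intensity), n = dplyr::n(),
                       .groups = "drop")
  } else {
    traces %>%
      dplyr::group_by(.data$frame) %>%
      dplyr::summarise(mean = mean(.data$intensity),
                       sd = sd(.data$intensity), n = dplyr::n(),
                       .groups = "drop")
  }
}

#' Detect reporter expression onset in a trace
#'
#' First frame at which the trace exceeds `threshold` for `persistence`
#' consecutive frames. Raising the threshold can only delay (never
#' advance) the detected onset.
#'
#' @param values Trace intensities in frame order.
#' @param threshold Intensity threshold (e.g. `k` background noise SDs).
#' @param persistence Required consecutive frames above threshold.
#' @return Frame index within the trace, or `NA` if never reached.
#' @export
detect_onset <- function(values, threshold, persistence = 2) {
  n <- length(values)
  if (n < persistence) return(NA_integer_)
  above <- !is.na(values) & values > threshold
  if (persistence <= 1) {
    idx <- which(above)
    return(if (length(idx)) idx[1] else NA_integer_)
  }
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= persistence) return(as.integer(i - persistence + 1))
  }
  NA_integer_
}

#' Classify infection fate for every track
#'
#' A track alive for at least `min_duration` frames is classified as:
#' `expressed_lysed` if a reporter onset is detected and the track ends
#' before the movie does; `outgrowth` if no onset is detected and the
#' final cell area is at least twice the initial area; `uninfected` if no
#' onset, the track survives to the end, and growth is modest (when
#' ground-truth infection status is supplied, non-infected no-onset tracks
#' are `uninfected` and infected no-onset growers are `outgrowth`);
#' `censored` otherwise.
#'
#' @param tracks A `cell_tracks` tibble.
#' @param traces Tibble from [trace_fluorescence()].
#' @param n_frames Total frames in the movie.
#' @param onset_threshold Threshold passed to [detect_onset()].
#' @param persistence Consecutive frames above threshold for an onset.
#' @param min_duration Minimum track length (frames) for a fate call.
#' @param infected Optional named logical `track_id -> infected` ground
#'   truth.
#' @return Tibble: `track_id`, `start`, `end`, `duration`, `onset_frame`
#'   (absolute frame index or NA), `area_ratio`, `fate`.
#' @export
classify_fates <- function(tracks, traces, n_frames, onset_threshold,
                           persistence = 2, min_duration = 5,
                           infected = NULL) {
  per <- traces %>%
    dplyr::arrange(.data$track_id, .data$frame) %>%
    dplyr::group_by(.data$track_id) %>%
    dplyr::summarise(
      start = min(.data$frame), end = max(.data$frame),
      duration = dplyr::n(),
      onset_rel = detect_onset(.data$intensity, onset_threshold,
                               persistence),
      area_ratio = .data$area[dplyr::n()] / .data$area[1],
      .groups = "drop")
  per$onset_frame <- ifelse(is.na(per$onset_rel), NA_integer_,
                            per$start + per$onset_rel - 1L)
  per$onset_rel <- NULL
  has_truth <- !is.null(infected)
  per$fate <- vapply(seq_len(nrow(per)), function(i) {
    r <- per[i, ]
    if (r$duration < min_duration) return("censored")
    has_onset <- !is.na(r$onset_frame)
    ends_early <- r$end < n_frames
    if (has_onset && ends_early) return("expressed_lysed")
    if (has_onset) return("censored")
    if (has_truth) {
      inf <- infected[as.character(r$track_id)]
      if (isTRUE(inf) && r$area_ratio >= 2) return("outgrowth")
      if (isFALSE(inf)) return("uninfected")
      return("censored")
    }
    if (r$area_ratio >= 2 && !ends_early) return("outgrowth")
    if (!ends_early) return("uninfected")
    "censored"
  }, character(1))
  per
}

#' Confusion matrix of predicted vs ground-truth fates
#'
#' @param predicted Tibble from [classify_fates()].
#' @param truth Named character `track_id -> true fate` (simulator labels
#'   `susceptible_lyse`, `resistant_outgrow`, `uninfected`).
#' @return Tibble: `truth`, `predicted`, `n`, plus an `accuracy` attribute
#'   (fraction of fate-callable tracks whose call matches truth, mapping
#'   `susceptible_lyse -> expressed_lysed` and
#'   `resistant_outgrow -> outgrowth`).
#' @export
fate_confusion <- function(predicted, truth) {
  map <- c(susceptible_lyse = "expressed_lysed",
           resistant_outgrow = "outgrowth",
           uninfected = "uninfected")
  tr <- truth[as.character(predicted$track_id)]
  tab <- predicted %>%
    dplyr::mutate(truth = unname(tr)) %>%
    dplyr::count(.data$truth, .data$fate, name = "n") %>%
    dplyr::rename(predicted = "fate")
  expected <- map[tr]
  acc <- mean(predicted$fate == expected, na.rm = TRUE)
  attr(tab, "accuracy") <- acc
  tab
}
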