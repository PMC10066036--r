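#' Read genome sequences from FASTA
#'
#' @param path FASTA file (multi-record allowed).
#' @return Tibble: `id` (first word of the header), `sequence`
#'   (upper-case character), `length` (bp).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) rlang::abort("No sequences found in FASTA file.")
  tibble::tibble(
    id = vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1),
    sequence = unname(toupper(as.character(seqs))),
    length = Biostrings::width(seqs)
  )
}

# Upper-case base counts with ambiguity codes excluded from numerator and
# denominator.
acgt_counts <- function(seq) {
  s <- Biostrings::DNAString(toupper(seq))
  Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
}

#' Overall GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; ambiguity codes (N, IUPAC) are excluded
#' from both numerator and denominator. Case-insensitive and invariant
#' under reverse complement.
#'
#' @param seq Character scalar DNA sequence (or a `DNAString`).
#' @return GC fraction in [0, 1].
#' @export
#' @examples
#' gc_fraction("ATGC") # 0.5
gc_fraction <- function(seq) {
  cnt <- acgt_counts(as.character(seq))
  tot <- sum(cnt)
  if (tot == 0)
    rlang::abort("Sequence has no unambiguous A/C/G/T bases.")
  unname((cnt[["G"]] + cnt[["C"]]) / tot)
}

#' Sliding-window GC track along a genome
#'
#' Windows of `window` bp every `step` bp, coordinates 0-based half-open;
#' `floor((L - window) / step) + 1` windows for a length-L sequence.
#'
#' @param seq Character scalar DNA sequence.
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @return A `gc_track` tibble: `start`, `end`, `gc`; attributes `window`,
#'   `step` and `genome_mean` (overall GC fraction).
#' @export
gc_sliding <- function(seq, window = 500, step = 100) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (window > L)
    rlang::abort("`window` exceeds the sequence length.")
  ch <- strsplit(seq, "")[[1]]
  is_gc <- ch %in% c("G", "C")
  is_ok <- ch %in% c("A", "C", "G", "T")
  cg <- c(0, cumsum(is_gc))
  cv <- c(0, cumsum(is_ok))
  starts <- seq(0L, L - window, by = step)
  gcs <- (cg[starts + window + 1] - cg[starts + 1])
  oks <- (cv[starts + window + 1] - cv[starts + 1])
  gc <- ifelse(oks > 0, gcs / oks, NA_real_)
  out <- tibble::tibble(start = starts, end = starts + window, gc = gc)
  structure(out, class = c("gc_track", class(tibble::tibble())),
            window = window, step = step,
            genome_mean = gc_fraction(seq))
}

#' Call locally GC-depressed regions from a GC track
#'
#' Runs of at least `min_windows` consecutive windows whose GC is at or
#' below the genome mean minus `drop_threshold` percentage points are
#' merged into regions (0-based half-open, union of member windows);
#' overlapping regions are merged. Raising the threshold can only shrink
#' the calls.
#'
#' @param track A `gc_track` from [gc_sliding()].
#' @param drop_threshold Depth below the genome mean, percentage points.
#' @param min_windows Minimum consecutive qualifying windows.
#' @param genome_mean Override the genome-mean GC fraction (defaults to
#'   the track attribute).
#' @return Tibble of regions: `start`, `end`, `mean_gc`, `depth_pp`
#'   (percentage points below the genome mean); possibly empty.
#' @export
low_gc_regions <- function(track, drop_threshold = 8, min_windows = 3,
                           genome_mean = attr(track, "genome_mean")) {
  if (is.null(genome_mean))
    rlang::abort("`genome_mean` missing (not a gc_track?).")
  qual <- !is.na(track$gc) &
    track$gc <= genome_mean - drop_threshold / 100
  empty <- tibble::tibble(start = integer(), end = integer(),
                          mean_gc = numeric(), depth_pp = numeric())
  if (!any(qual)) return(empty)
  r <- rle(qual)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_windows)
  if (!length(keep)) return(empty)
  regions <- lapply(keep, function(j) {
    idx <- run_start[j]:run_end[j]
    tibble::tibble(start = track$start[idx[1]],
                   end = track$end[idx[length(idx)]],
                   mean_gc = mean(track$gc[idx]))
  })
  out <- dplyr::bind_rows(regions) %>% dplyr::arrange(.data$start)
  # merge overlapping/adjacent intervals
  merged <- list(out[1, ])
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      last <- merged[[length(merged)]]
      if (out$start[i] <= last$end) {
        last$end <- max(last$end, out$end[i])
        last$mean_gc <- mean(c(last$mean_gc, out$mean_gc[i]))
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1]] <- out[i, ]
      }
    }
  }
  out <- dplyr::bind_rows(merged)
  out$depth_pp <- (genome_mean - out$mean_gc) * 100
  out
}

#' Simulate a genome with a target GC content and planted low-GC segments
#'
#' Draws bases i.i.d. at the background GC fraction, then overwrites the
#' given segments with draws at their own GC fraction. Used to validate
#' region calling with known truth.
#'
#' @param length Genome length in bp.
#' @param gc Background GC fraction.
#' @param regions Optional tibble with `start`, `end` (0-based half-open)
#'   and `gc` per planted segment.
#' @param seed Integer seed.
#' @return Character scalar sequence.
#' @export
simulate_genome <- function(length, gc = 0.67, regions = NULL, seed = 1L) {
  with_seed(seed, {
    draw <- function(n, g) {
      sample(c("G", "C", "A", "T"), n, replace = TRUE,
             prob = c(g / 2, g / 2, (1 - g) / 2, (1 - g) / 2))
    }
    ch <- draw(length, gc)
    if (!is.null(regions)) {
      for (i in seq_len(nrow(regions))) {
        idx <- (regions$start[i] + 1):regions$end[i]
        ch[idx] <- draw(length(idx), regions$gc[i])
      }
    }
    paste(ch, collapse = "")
  })
}

#' Write GC-profile outputs
#'
#' `gc_track.tsv` (start, end, gc), `regions.bed` (0-based BED3 + mean GC
#' score) and `summary.json` (overall GC%, parameters).
#'
#' @param track A `gc_track`.
#' @param regions Tibble from [low_gc_regions()].
#' @param dir Output directory.
#' @param id Sequence identifier used in the BED name column.
#' @export
write_gc_outputs <- function(track, regions, dir, id = "genome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tibble::as_tibble(track),
                     file.path(dir, "gc_track.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  bed <- data.frame(chrom = id, start = regions$start, end = regions$end,
                    name = sprintf("low_gc_%d", seq_len(nrow(regions))),
                    score = round(regions$mean_gc * 1000))
  utils::write.table(bed, file.path(dir, "regions.bed"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(id = id, gc_percent = attr(track, "genome_mean") * 100,
         window = attr(track, "window"), step = attr(track, "step"),
         n_regions = nrow(regions)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
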