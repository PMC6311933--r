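# Location-preference profiling: tile transcripts into window-size bins,
# score them, and summarize where confident bins fall relative to the
# 3' UTR start, normalized by 3' UTR length.

#' Tile a transcript into non-overlapping bins
#'
#' Consecutive bins of `bin_size` nt from position 0. A final partial bin
#' is kept only if it is at least half a bin long; a transcript shorter
#' than one bin becomes a single whole-transcript bin.
#'
#' @param length Transcript length (nt, >= 1).
#' @param bin_size Bin size in nt (default 101).
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
tile_transcript <- function(length, bin_size = 101L) {
  length <- as.integer(length)
  stopifnot(length >= 1L, bin_size >= 1L)
  if (length < bin_size) {
    return(data.frame(start = 0L, end = length))
  }
  n <- length %/% bin_size
  starts <- (seq_len(n) - 1L) * bin_size
  ends <- starts + bin_size
  tail_len <- length - n * bin_size
  if (tail_len >= bin_size / 2) {
    starts <- c(starts, n * bin_size)
    ends <- c(ends, length)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Normalized distance from a bin's center to the 3' UTR start
#'
#' `(bin_center - utr3_start) / utr3_length` with
#' `bin_center = (start + end - 1) / 2` (half-integer centers allowed for
#' even bins). Values below -2 are flagged for exclusion from plots, as
#' tiny 3' UTRs blow the normalization up. `NA` when the 3' UTR has zero
#' length.
#'
#' @param start,end Bin coordinates (0-based half-open).
#' @param structure One row of a transcript-structure table
#'   (see [read_structure()]).
#' @return List with `value` (numeric or NA) and `excluded` (value < -2).
#' @export
bin_relative_distance <- function(start, end, structure) {
  utr_len <- structure$length - structure$utr3_start
  if (utr_len <= 0L) return(list(value = NA_real_, excluded = NA))
  center <- (start + end - 1) / 2
  v <- (center - structure$utr3_start) / utr_len
  list(value = v, excluded = v < -2)
}

#' Score transcript bins and build position profiles
#'
#' Tiles every transcript, scores each bin sequence with the model,
#' assigns confidence tiers and, for bins in the last exon (bin center at
#' or past `last_exon_start`), the normalized distance to the 3' UTR
#' start.
#'
#' @param model A trained `m6a_model`.
#' @param fasta Named sequence vector.
#' @param structure Transcript-structure data.frame
#'   (see [read_structure()]); only transcripts present in both are
#'   profiled.
#' @param thresholds An `m6a_thresholds` object.
#' @param bin_size Bin size in nt (default the model's window size).
#' @return data.frame: `transcript_id`, `start`, `end`, `score`, `tier`,
#'   `in_last_exon`, `relative_distance`, `rd_excluded`.
#' @export
profile_transcripts <- function(model, fasta, structure, thresholds,
                                bin_size = NULL) {
  bin_size <- as.integer(bin_size %||% model$config$window_size)
  ids <- intersect(names(fasta), structure$transcript_id)
  if (length(ids) == 0L) stopf("no transcripts shared between FASTA and structure table")
  rows <- lapply(ids, function(tx) {
    len <- nchar(fasta[[tx]])
    bins <- tile_transcript(len, bin_size)
    bins$transcript_id <- tx
    # a short tail bin is scored on the terminus-clamped full-size window
    # (the same clamping the dataset builder applies to terminal sites):
    # the model never sees training windows shorter than bin_size, and
    # truncated inputs systematically mis-score
    seq_start <- ifelse(bins$end - bins$start < bin_size,
                        pmax(0L, bins$end - bin_size), bins$start)
    bins$sequence <- substring(fasta[[tx]], seq_start + 1L, bins$end)
    bins
  })
  bins <- do.call(rbind, rows)
  bins$score <- predict_scores(model, bins$sequence)
  bins$tier <- assign_confidence_tier(bins$score, thresholds)
  st <- structure[match(bins$transcript_id, structure$transcript_id), ]
  center <- (bins$start + bins$end - 1) / 2
  bins$in_last_exon <- center >= st$last_exon_start
  utr_len <- st$length - st$utr3_start
  rd <- ifelse(utr_len > 0, (center - st$utr3_start) / utr_len, NA_real_)
  rd[!bins$in_last_exon] <- NA_real_
  bins$relative_distance <- rd
  bins$rd_excluded <- !is.na(rd) & rd < -2
  bins$sequence <- NULL
  bins[, c("transcript_id", "start", "end", "score", "tier",
           "in_last_exon", "relative_distance", "rd_excluded")]
}

#' Fractions of confident bins by transcript region
#'
#' The fraction of bins at or above moderate confidence among (a) all bins
#' of the whole transcripts, (b) bins in exons, and (c) bins in last
#' exons, with a per-tier breakdown. In this transcript-space
#' representation the mature transcript is all exon, so (a) and (b)
#' coincide; both are reported to mirror the three-way comparison made on
#' genome-space data.
#'
#' @param profiles data.frame from [profile_transcripts()].
#' @return List with `fractions` (named: `whole_transcript`, `all_exons`,
#'   `last_exons`), `counts`, and `per_tier` (data.frame, cumulative
#'   fraction at or above each tier).
#' @export
enrichment_fractions <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L) stopf("empty profile set")
  tier_rank <- c(none = 0L, moderate = 1L, high = 2L, very_high = 3L)
  r <- tier_rank[profiles$tier]
  confident <- r >= 1L
  last <- profiles$in_last_exon
  fractions <- c(whole_transcript = mean(confident),
                 all_exons = mean(confident),
                 last_exons = if (any(last)) mean(confident[last]) else NA_real_)
  per_tier <- do.call(rbind, lapply(1L:3L, function(t) {
    data.frame(tier = names(tier_rank)[t + 1L],
               whole_transcript = mean(r >= t),
               last_exons = if (any(last)) mean(r[last] >= t) else NA_real_)
  }))
  list(fractions = fractions,
       counts = c(bins = nrow(profiles), confident = sum(confident),
                  last_exon_bins = sum(last)),
       per_tier = per_tier)
}
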