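# Construction of the labeled window dataset: merge clustered sites, place
# positive windows with the site at a random in-window location, search for
# the closest nearby site-free negative-control window, and split into
# train / validation / test.

#' Dataset-builder configuration
#'
#' Defaults mirror the published protocol: 101-nt windows, sites within
#' 50 nt merged to their central member, negative candidates enumerated
#' 100 nt up/downstream of the positive window start with a 10-nt stride
#' for 100 steps, an 80/20 train/test split and 1/8 of the training part
#' held out as validation.
#'
#' @param window_size Window size in nt.
#' @param merge_distance Max gap (nt) between consecutive sites joined into
#'   one cluster (single-linkage chaining).
#' @param negative_gap Offset (nt) of the first negative candidate from the
#'   positive window start.
#' @param negative_stride Stride (nt) between candidate starts.
#' @param negative_steps Number of candidate steps per side (k = 0 ..
#'   steps-1, offsets `gap + k * stride`).
#' @param train_fraction Fraction of windows assigned to training (the rest
#'   is the independent test set).
#' @param val_fraction_of_train Fraction of the training part carved out as
#'   validation.
#' @param group_by_transcript If `TRUE`, all windows of a transcript share
#'   one split (off by default, matching window-level splitting).
#' @param seed Integer seed driving placement, tie-breaks and splitting.
#' @return A `builder_config` list.
#' @export
builder_config <- function(window_size = 101L, merge_distance = 50L,
                           negative_gap = 100L, negative_stride = 10L,
                           negative_steps = 100L, train_fraction = 0.8,
                           val_fraction_of_train = 1 / 8,
                           group_by_transcript = FALSE, seed = 1L) {
  stopifnot(window_size >= 1L, merge_distance >= 0L, negative_gap > 0L,
            negative_stride > 0L, negative_steps >= 1L,
            train_fraction > 0, train_fraction <= 1,
            val_fraction_of_train >= 0, val_fraction_of_train < 1)
  structure(list(window_size = as.integer(window_size),
                 merge_distance = as.integer(merge_distance),
                 negative_gap = as.integer(negative_gap),
                 negative_stride = as.integer(negative_stride),
                 negative_steps = as.integer(negative_steps),
                 train_fraction = train_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 group_by_transcript = isTRUE(group_by_transcript),
                 seed = as.integer(seed)),
            class = "builder_config")
}

#' Merge clustered sites to representative positions
#'
#' Consecutive sites no more than `merge_distance` apart are chained into
#' one cluster (single linkage); each cluster is represented by its central
#' member site (the lower median for even cluster sizes). With
#' `merge_distance = 0` this is the identity on unique sorted positions.
#'
#' @param positions Sorted unique 0-based site positions on one transcript.
#' @param merge_distance Max chaining gap in nt.
#' @return Sorted representative positions (integer vector).
#' @export
merge_sites <- function(positions, merge_distance = 50L) {
  if (length(positions) == 0L) return(integer(0))
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    stopf("merge_sites expects sorted unique positions")
  }
  breaks <- which(diff(positions) > merge_distance)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(positions))
  vapply(seq_along(starts), function(i) {
    cl <- positions[starts[i]:ends[i]]
    cl[ceiling(length(cl) / 2)]          # lower median on even sizes
  }, integer(1))
}

#' Place a positive window around a site
#'
#' The window start is drawn uniformly from all starts for which the
#' window both contains the site and fits inside the transcript, so the
#' site ends up at a random in-window location; near a terminus the
#' feasible range collapses and the window is clamped to the terminus.
#' Transcripts shorter than the window yield one truncated whole-transcript
#' window.
#'
#' @param transcript_len Transcript length in nt.
#' @param site 0-based site position.
#' @param config A [builder_config()].
#' @param all_sites All original (pre-merge) site positions on the
#'   transcript; every one falling inside the window is recorded.
#' @return List with `start`, `end` (0-based half-open) and `site_offsets`
#'   (0-based, in-window).
#' @export
place_positive_window <- function(transcript_len, site, config,
                                  all_sites = site) {
  transcript_len <- as.integer(transcript_len)
  if (transcript_len < 1L) stopf("transcript_len must be >= 1")
  site <- as.integer(site)
  stopifnot(site >= 0L, site < transcript_len)
  wlen <- min(config$window_size, transcript_len)
  lo <- max(0L, site - wlen + 1L)
  hi <- min(site, transcript_len - wlen)
  start <- if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  end <- start + wlen
  inside <- sort(as.integer(all_sites[all_sites >= start & all_sites < end]))
  list(start = start, end = end, site_offsets = inside - start)
}

#' Find the closest nearby site-free negative-control window
#'
#' Candidate starts are enumerated symmetrically from the positive window's
#' start at offsets `gap + k * stride`, k = 0..steps-1, on both sides. A
#' candidate is valid when it lies fully inside the transcript and its span
#' contains none of the original (pre-merge) sites. The valid candidate
#' closest to the positive start wins; an exact up/downstream tie is broken
#' uniformly at random. `NULL` when no candidate is valid.
#'
#' @param positive A positive window as returned by
#'   [place_positive_window()].
#' @param transcript_len Transcript length in nt.
#' @param all_sites All original site positions on the transcript.
#' @param config A [builder_config()].
#' @return List with `start`, `end`, or `NULL`.
#' @export
find_negative_window <- function(positive, transcript_len, all_sites, config) {
  transcript_len <- as.integer(transcript_len)
  wlen <- min(config$window_size, transcript_len)
  all_sites <- as.integer(all_sites)
  valid <- function(start) {
    if (start < 0L || start + wlen > transcript_len) return(FALSE)
    !any(all_sites >= start & all_sites < start + wlen)
  }
  for (k in seq_len(config$negative_steps) - 1L) {
    d <- config$negative_gap + k * config$negative_stride
    up <- positive$start - d
    down <- positive$start + d
    ok_up <- valid(up)
    ok_down <- valid(down)
    if (ok_up && ok_down) {
      start <- if (stats::runif(1) < 0.5) up else down
      return(list(start = start, end = start + wlen))
    }
    if (ok_up) return(list(start = up, end = up + wlen))
    if (ok_down) return(list(start = down, end = down + wlen))
  }
  NULL
}

#' Build a labeled windowed dataset from transcripts and sites
#'
#' One positive window per merged site and at most one negative per
#' positive; windows are then randomly assigned to train / validation /
#' test splits at the window level. Fully deterministic given
#' `config$seed`.
#'
#' @param fasta Named sequence vector (from [read_fasta()]).
#' @param sites Site data.frame (from [read_sites()]).
#' @param config A [builder_config()].
#' @param quiet Suppress the counts log line.
#' @return List with `windows` (data.frame: `window_id`, `transcript_id`,
#'   `start`, `end`, `label`, `site_offsets` comma-joined, `sequence`,
#'   `split`) and `meta` (counts + config).
#' @export
build_dataset <- function(fasta, sites, config = builder_config(),
                          quiet = FALSE) {
  validate_sites(sites, fasta)
  with_seed(config$seed, {
    rows <- list()
    for (tx in sort(unique(sites$transcript_id))) {
      seq_tx <- fasta[[tx]]
      len <- nchar(seq_tx)
      pos_all <- sort(unique(sites$position[sites$transcript_id == tx]))
      reps <- merge_sites(pos_all, config$merge_distance)
      for (site in reps) {
        pw <- place_positive_window(len, site, config, all_sites = pos_all)
        rows[[length(rows) + 1L]] <- data.frame(
          window_id = sprintf("pos_%s_%d", tx, site),
          transcript_id = tx, start = pw$start, end = pw$end,
          label = "positive",
          site_offsets = paste(pw$site_offsets, collapse = ","),
          sequence = substr(seq_tx, pw$start + 1L, pw$end),
          stringsAsFactors = FALSE)
        nw <- find_negative_window(pw, len, pos_all, config)
        if (!is.null(nw)) {
          rows[[length(rows) + 1L]] <- data.frame(
            window_id = sprintf("neg_%s_%d", tx, site),
            transcript_id = tx, start = nw$start, end = nw$end,
            label = "negative", site_offsets = "",
            sequence = substr(seq_tx, nw$start + 1L, nw$end),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows) == 0L) {
      windows <- data.frame(window_id = character(0),
                            transcript_id = character(0),
                            start = integer(0), end = integer(0),
                            label = character(0), site_offsets = character(0),
                            sequence = character(0), split = character(0),
                            stringsAsFactors = FALSE)
    } else {
      windows <- do.call(rbind, rows)
      windows$split <- assign_splits(windows, config)
    }
    counts <- c(positive = sum(windows$label == "positive"),
                negative = sum(windows$label == "negative"),
                train = sum(windows$split == "train"),
                val = sum(windows$split == "val"),
                test = sum(windows$split == "test"))
    if (!quiet) {
      message(sprintf(
        "built %d windows: %d positive, %d negative (train %d / val %d / test %d)",
        nrow(windows), counts["positive"], counts["negative"],
        counts["train"], counts["val"], counts["test"]))
    }
    list(windows = windows, meta = list(counts = as.list(counts),
                                        config = unclass(config)))
  })
}

# Random split assignment; consumes the builder RNG stream.
assign_splits <- function(windows, config) {
  n <- nrow(windows)
  units <- if (config$group_by_transcript) unique(windows$transcript_id)
           else windows$window_id
  m <- length(units)
  perm <- sample.int(m)
  n_test <- round(m * (1 - config$train_fraction))
  n_train_all <- m - n_test
  n_val <- round(n_train_all * config$val_fraction_of_train)
  unit_split <- character(m)
  unit_split[perm[seq_len(n_test)]] <- "test"
  unit_split[perm[n_test + seq_len(n_val)]] <- "val"
  unit_split[perm[n_test + n_val + seq_len(n_train_all - n_val)]] <- "train"
  names(unit_split) <- units
  if (config$group_by_transcript) unname(unit_split[windows$transcript_id])
  else unname(unit_split[windows$window_id])
}

#' Intersect two site lists by exact position
#'
#' Keeps sites present (same transcript, same position) in both lists;
#' used e.g. to retain only sites common to two replicates.
#'
#' @param a,b Site data.frames (see [read_sites()]).
#' @return The rows of `a` whose (transcript, position) occur in `b`.
#' @export
intersect_sites <- function(a, b) {
  key <- function(s) paste(s$transcript_id, s$position, sep = "\r")
  a[key(a) %in% key(b), , drop = FALSE]
}
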