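# IO for every external representation the tool touches: FASTA, site lists
# (TSV / BED6), transcript-structure tables, windowed datasets, predictions,
# saliency tracks, MEME minimal motif files and versioned model checkpoints.
#
# Conventions (documented loudly, used everywhere):
#   * all coordinates are 0-based, half-open [start, end);
#   * sequences are transcript-oriented (5'->3' sense) over {A,C,G,U,N};
#     T is accepted on input and converted to U.

CHECKPOINT_MAGIC <- "m6Ascan-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Read transcript sequences from FASTA
#'
#' Sequences are uppercased and DNA-style T is normalized to U. Record ids
#' are the first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file (plain text).
#' @return Named character vector, one sequence per transcript id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("empty FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stopf("duplicate FASTA id(s): %s", paste(dup, collapse = ", "))
  }
  seqs <- normalize_rna(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read single-base modification sites
#'
#' Accepts either a two/three-column TSV (`transcript_id`, `position`
#' 0-based, optional `source_tag`) or BED6, where the site is the 0-based
#' `start` of the feature. BED records on the "-" strand are rejected:
#' inputs must be transcript-oriented, so pre-orient sequences upstream.
#'
#' @param path Path to a TSV or BED file.
#' @param fasta Optional named sequence vector (from [read_fasta()]); when
#'   supplied, every site is validated against its transcript's length.
#' @param format `"auto"` (default; 6+ columns with numeric fields 2-3 is
#'   treated as BED), `"tsv"` or `"bed"`.
#' @return A data.frame of site records: `transcript_id`, `position`
#'   (0-based integer, the modified base itself), `source_tag`.
#' @export
read_sites <- function(path, fasta = NULL, format = c("auto", "tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("site file not found: %s", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           blank.lines.skip = TRUE,
                           colClasses = "character")
  if (format == "auto") {
    looks_bed <- ncol(raw) >= 6L &&
      !anyNA(suppressWarnings(as.numeric(raw[[2L]]))) &&
      !anyNA(suppressWarnings(as.numeric(raw[[3L]])))
    format <- if (looks_bed) "bed" else "tsv"
  }
  if (format == "bed") {
    if (ncol(raw) < 6L) stopf("BED site input needs 6 columns, got %d", ncol(raw))
    strand <- raw[[6L]]
    if (any(strand != "+")) {
      stopf(paste("BED sites with strand '-' (or other) found; inputs must be",
                  "transcript-oriented (5'->3'): pre-orient transcripts and",
                  "re-emit sites on strand '+'"))
    }
    sites <- data.frame(transcript_id = raw[[1L]],
                        position = as.integer(as.numeric(raw[[2L]])),
                        source_tag = raw[[4L]],
                        stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 2L) stopf("site TSV needs >= 2 columns, got %d", ncol(raw))
    pos <- suppressWarnings(as.numeric(raw[[2L]]))
    if (anyNA(pos)) stopf("non-numeric position in site TSV at line(s): %s",
                          paste(which(is.na(pos)), collapse = ", "))
    sites <- data.frame(transcript_id = raw[[1L]],
                        position = as.integer(pos),
                        source_tag = if (ncol(raw) >= 3L) raw[[3L]] else "",
                        stringsAsFactors = FALSE)
  }
  if (any(sites$position < 0L)) {
    stopf("negative site position(s) at line(s): %s",
          paste(which(sites$position < 0L), collapse = ", "))
  }
  if (!is.null(fasta)) validate_sites(sites, fasta)
  sites
}

validate_sites <- function(sites, fasta) {
  missing <- setdiff(unique(sites$transcript_id), names(fasta))
  if (length(missing) > 0L) {
    stopf("site transcript(s) absent from FASTA: %s",
          paste(missing, collapse = ", "))
  }
  len <- nchar(fasta)[sites$transcript_id]
  bad <- which(sites$position >= len)
  if (length(bad) > 0L) {
    stopf("site position beyond transcript end for: %s",
          paste(sprintf("%s:%d (len %d)", sites$transcript_id[bad],
                        sites$position[bad], len[bad]), collapse = ", "))
  }
  invisible(sites)
}

#' Write a site list as TSV
#' @param sites Site data.frame (see [read_sites()]).
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, c("transcript_id", "position", "source_tag")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transcript-structure table
#'
#' A four-column TSV: `transcript_id`, `length`, `last_exon_start`,
#' `utr3_start` (all coordinates 0-based; `utr3_start` is the first base of
#' the 3' UTR). A header row is detected and skipped if present.
#'
#' @param path Path to the TSV.
#' @return data.frame with the four validated columns.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stopf("structure file not found: %s", path)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 4L) stopf("structure TSV needs 4 columns, got %d", ncol(raw))
  if (is.na(suppressWarnings(as.numeric(raw[1L, 2L])))) raw <- raw[-1L, , drop = FALSE]
  st <- data.frame(transcript_id = raw[[1L]],
                   length = as.integer(as.numeric(raw[[2L]])),
                   last_exon_start = as.integer(as.numeric(raw[[3L]])),
                   utr3_start = as.integer(as.numeric(raw[[4L]])),
                   stringsAsFactors = FALSE)
  bad <- which(!(st$last_exon_start >= 0L &
                 st$last_exon_start <= st$utr3_start &
                 st$utr3_start <= st$length))
  if (length(bad) > 0L) {
    stopf("structure invariant 0 <= last_exon_start <= utr3_start <= length violated for: %s",
          paste(st$transcript_id[bad], collapse = ", "))
  }
  st
}

#' Write a transcript-structure table
#' @param structure data.frame as returned by [read_structure()].
#' @param path Output path.
#' @export
write_structure <- function(structure, path) {
  utils::write.table(structure[, c("transcript_id", "length",
                                   "last_exon_start", "utr3_start")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write / read a windowed dataset as TSV
#'
#' Columns: `window_id`, `transcript_id`, `start`, `end` (0-based half-open
#' on the transcript), `label` (`positive`/`negative`), `site_offsets`
#' (comma-joined in-window 0-based offsets, empty for negatives),
#' `sequence`, and `split` (`train`/`val`/`test`) when present.
#'
#' @param windows Window data.frame (see [build_dataset()]).
#' @param path Output path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_windows <- function(windows, path) {
  cols <- c("window_id", "transcript_id", "start", "end", "label",
            "site_offsets", "sequence")
  if ("split" %in% names(windows)) cols <- c(cols, "split")
  utils::write.table(windows[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  w <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  w$start <- as.integer(w$start)
  w$end <- as.integer(w$end)
  w$site_offsets[is.na(w$site_offsets)] <- ""
  w
}

# Parse the comma-joined site_offsets column into a list of integer vectors.
window_offsets <- function(windows) {
  lapply(strsplit(as.character(windows$site_offsets), ",", fixed = TRUE),
         function(x) as.integer(x[nzchar(x)]))
}

#' Write predictions as TSV
#'
#' @param window_id Character vector of window ids.
#' @param score Numeric prediction scores in (0,1).
#' @param tier Optional confidence tier per window (from
#'   [assign_confidence_tier()]); omitted column if `NULL`.
#' @param path Output path.
#' @export
write_predictions <- function(window_id, score, path, tier = NULL) {
  df <- data.frame(window_id = window_id, score = score,
                   stringsAsFactors = FALSE)
  if (!is.null(tier)) df$confidence_tier <- tier
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write saliency tracks as TSV
#'
#' One row per (window, position): `window_id`, `position` (0-based within
#' the window), `base`, `saliency_score`.
#'
#' @param tracks A list of saliency tracks (see [saliency_map()]).
#' @param path Output path.
#' @export
write_saliency <- function(tracks, path) {
  if (inherits(tracks, "m6a_saliency")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(window_id = tr$window_id,
               position = seq_along(tr$score) - 1L,
               base = strsplit(tr$sequence, "")[[1L]],
               saliency_score = tr$score,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write learned motifs in MEME minimal motif format
#'
#' Emits the minimal format consumed by the MEME suite (e.g. TOMTOM):
#' version line, ALPHABET line, strand line, and one letter-probability
#' matrix block per motif. Motif names are the originating filter indices.
#' Zero-support motifs must be filtered out by the caller
#' ([filters_to_motifs()] already excludes them).
#'
#' @param motifs List of learned motifs (see [filters_to_motifs()]).
#' @param path Output path.
#' @param alphabet Alphabet string, default `"ACGU"`.
#' @export
write_meme <- function(motifs, path, alphabet = "ACGU") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", alphabet), "",
               "strands: +", "",
               "Background letter frequencies",
               paste(strsplit(alphabet, "")[[1L]],
                     sprintf("%.4f", rep(1 / nchar(alphabet), nchar(alphabet))),
                     collapse = " "),
               ""), con)
  for (m in motifs) {
    pwm <- m$pwm
    sums <- rowSums(pwm)
    bad <- which(abs(sums - 1) > 1e-6)
    if (length(bad) > 0L) {
      stopf("motif filter_%d: PWM row(s) %s do not sum to 1 (sums: %s)",
            m$filter_index, paste(bad, collapse = ","),
            paste(sprintf("%.6f", sums[bad]), collapse = ","))
    }
    writeLines(c(sprintf("MOTIF filter_%d", m$filter_index),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         nrow(pwm), max(1L, m$support))), con)
    writeLines(apply(pwm, 1L, function(r) paste(sprintf("%.6f", r), collapse = "  ")),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Parse a MEME minimal motif file
#'
#' A small strict parser for the subset of the MEME minimal format written
#' by [write_meme()]; used by the test suite to validate round-trips
#' without running the MEME suite.
#'
#' @param path Path to a MEME-format file.
#' @return List with `alphabet` and `motifs` (each `name` + `pwm`).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  if (!grepl("^MEME version", lines[1L])) stopf("not a MEME file: %s", path)
  alpha_line <- grep("^ALPHABET=", lines, value = TRUE)
  if (length(alpha_line) != 1L) stopf("missing ALPHABET line in %s", path)
  alphabet <- trimws(sub("^ALPHABET=", "", alpha_line))
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF ", lines[i])) {
      name <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]][2L]
      i <- i + 1L
      while (i <= length(lines) && !grepl("^letter-probability matrix:", lines[i])) i <- i + 1L
      if (i > length(lines)) stopf("motif %s has no letter-probability matrix", name)
      hdr <- lines[i]
      w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", hdr))
      rows <- matrix(NA_real_, nrow = w, ncol = 4L)
      for (r in seq_len(w)) {
        i <- i + 1L
        vals <- as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1L]])
        if (length(vals) != 4L) stopf("motif %s row %d: expected 4 values", name, r)
        rows[r, ] <- vals
      }
      motifs[[length(motifs) + 1L]] <- list(name = name, pwm = rows)
    }
    i <- i + 1L
  }
  list(alphabet = alphabet, motifs = motifs)
}

#' Save / load a versioned model checkpoint
#'
#' The checkpoint embeds a format version, the full model configuration
#' (window size, filter sizes/counts, seed) and all weights; loading a file
#' written by a different format version, or a truncated/corrupt file,
#' raises an explicit error rather than silently reinterpreting bytes.
#' Round-trip is exact on weights and config.
#'
#' @param model A trained model (see [build_model()]).
#' @param path Checkpoint path.
#' @param metrics Optional named list of metrics stored alongside.
#' @param expect_window_size Optional window size the caller requires; a
#'   mismatch with the stored config is an error.
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: a list
#'   with `model` and `metrics`.
#' @export
save_checkpoint <- function(model, path, metrics = NULL) {
  stopifnot(inherits(model, "m6a_model"))
  obj <- list(magic = CHECKPOINT_MAGIC,
              format_version = CHECKPOINT_VERSION,
              model = model,
              metrics = metrics)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expect_window_size = NULL) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stopf("corrupt or unreadable checkpoint %s: %s", path, conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$magic, CHECKPOINT_MAGIC)) {
    stopf("not an m6Ascan checkpoint: %s", path)
  }
  if (!identical(obj$format_version, CHECKPOINT_VERSION)) {
    stopf("checkpoint format version %s unsupported (expected %d): %s",
          format(obj$format_version), CHECKPOINT_VERSION, path)
  }
  if (!is.null(expect_window_size) &&
      !identical(as.integer(expect_window_size),
                 as.integer(obj$model$config$window_size))) {
    stopf("checkpoint window size %d does not match requested %d",
          obj$model$config$window_size, as.integer(expect_window_size))
  }
  obj[c("model", "metrics")]
}
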