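# Synthetic miCLIP-like data with known ground truth: random transcripts
# with DRACH-consensus motifs planted at recorded single-base positions
# (the methylated A), matched motif-free background, and transcript
# structures for position profiling.

#' Simulation configuration
#'
#' The stated world: transcript lengths uniform on [500, 3000] nt
#' (desk-scale, long enough for the negative-window search), uniform base
#' composition, one planted GGACU motif instance per transcript (a DRACH
#' consensus; the recorded site is its A, offset 2), a 0.7 mixture weight
#' of placement just downstream of the 3' UTR start versus uniform, and
#' background scrubbed of spurious exact-consensus matches so that the
#' recorded sites are the complete ground truth.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Min/max transcript length (uniform integer).
#' @param base_composition Probabilities for A, C, G, U (sum 1).
#' @param motif Consensus string (deterministic planting) or a
#'   row-stochastic length x 4 PWM (columns A, C, G, U).
#' @param site_offset 0-based offset of the methylated A within the motif;
#'   defaults to the central A of the RAC core (2 for GGACU).
#' @param sites_per_transcript Planted instances per transcript.
#' @param utr_bias Mixture weight of 3'UTR-proximal placement (site drawn
#'   from the first half of the 3' UTR) versus uniform placement.
#' @param utr3_fraction,last_exon_fraction Fractions of transcript length
#'   where the 3' UTR and last exon start.
#' @param spacing `"sparse"` keeps planted motifs at least
#'   `min_spacing` nt apart so the negative-window search always has
#'   room; `"free"` places independently.
#' @param min_spacing Minimum distance between planted loci in sparse
#'   mode; default covers the default negative-candidate range
#'   (gap + steps * stride = 1100 nt).
#' @param scrub_background Remove chance exact-consensus matches from the
#'   background (mutating their central base) so no unrecorded motif
#'   instance exists.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 200L, length_range = c(500L, 3000L),
                       base_composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, U = 0.25),
                       motif = "GGACU", site_offset = NULL,
                       sites_per_transcript = 1L, utr_bias = 0.7,
                       utr3_fraction = 0.7, last_exon_fraction = 0.6,
                       spacing = c("sparse", "free"), min_spacing = 1100L,
                       scrub_background = TRUE, seed) {
  spacing <- match.arg(spacing)
  if (missing(seed)) stopf("sim_config: seed is mandatory")
  stopifnot(n_transcripts >= 1L, length(length_range) == 2L,
            length_range[1L] <= length_range[2L],
            abs(sum(base_composition) - 1) < 1e-9,
            sites_per_transcript >= 0L, utr_bias >= 0, utr_bias <= 1,
            utr3_fraction > 0, utr3_fraction < 1,
            last_exon_fraction > 0, last_exon_fraction <= utr3_fraction)
  if (is.matrix(motif)) {
    stopifnot(ncol(motif) == 4L, all(abs(rowSums(motif) - 1) < 1e-9))
    consensus <- paste(c("A", "C", "G", "U")[apply(motif, 1L, which.max)],
                       collapse = "")
  } else {
    consensus <- normalize_rna(motif)
  }
  if (nchar(consensus) > length_range[1L]) {
    stopf("motif (%d nt) longer than the shortest transcript (%d nt)",
          nchar(consensus), length_range[1L])
  }
  if (is.null(site_offset)) {
    # the methylated A: central A of the RAC core; for a consensus with a
    # unique A this is that A (GGACU -> offset 2)
    a_pos <- which(strsplit(consensus, "")[[1L]] == "A")
    if (length(a_pos) == 0L) stopf("motif consensus %s has no A", consensus)
    site_offset <- a_pos[ceiling(length(a_pos) / 2)] - 1L
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 base_composition = base_composition,
                 motif = motif, consensus = consensus,
                 site_offset = as.integer(site_offset),
                 sites_per_transcript = as.integer(sites_per_transcript),
                 utr_bias = utr_bias,
                 utr3_fraction = utr3_fraction,
                 last_exon_fraction = last_exon_fraction,
                 spacing = spacing, min_spacing = as.integer(min_spacing),
                 scrub_background = isTRUE(scrub_background),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# all 0-based start positions of pattern `pat` in `s`
find_occurrences <- function(s, pat) {
  hits <- gregexpr(pat, s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Simulate transcripts with planted motif sites
#'
#' Background bases are drawn i.i.d. from the configured composition,
#' motif instances are written at the chosen loci (sampled from the PWM
#' when one is given) and the recorded site is the motif's A. The
#' structure table places the 3' UTR start at the configured fraction of
#' each length. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes
#'   `transcripts.fa`, `sites.tsv`, `structure.tsv` and `truth.json`.
#' @return List with `fasta` (named sequences), `sites` (data.frame),
#'   `structure` (data.frame) and `truth` (data.frame: `transcript_id`,
#'   `locus` = motif start, `site` = the A position, `instance` = planted
#'   sequence).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bases <- c("A", "C", "G", "U")
  m_len <- nchar(config$consensus)
  with_seed(config$seed, {
    fasta <- character(config$n_transcripts)
    names(fasta) <- sprintf("tx%04d", seq_len(config$n_transcripts))
    truth <- list()
    st <- list()
    for (i in seq_len(config$n_transcripts)) {
      len <- sample(config$length_range[1L]:config$length_range[2L], 1L)
      chars <- sample(bases, len, replace = TRUE,
                      prob = config$base_composition)
      utr3_start <- floor(config$utr3_fraction * len)
      last_exon_start <- floor(config$last_exon_fraction * len)
      loci <- integer(0)
      for (si in seq_len(config$sites_per_transcript)) {
        for (try in 1:200) {
          if (stats::runif(1) < config$utr_bias) {
            utr_len <- len - utr3_start
            hi <- min(len - m_len, utr3_start + floor(utr_len / 2))
            cand <- if (hi >= utr3_start) {
              utr3_start + sample.int(hi - utr3_start + 1L, 1L) - 1L
            } else len - m_len
          } else {
            cand <- sample.int(len - m_len + 1L, 1L) - 1L
          }
          ok <- config$spacing == "free" ||
            all(abs(cand - loci) >= config$min_spacing)
          if (ok) { loci <- c(loci, cand); break }
        }
      }
      loci <- sort(loci)
      for (locus in loci) {
        inst <- if (is.matrix(config$motif)) {
          paste(vapply(seq_len(m_len), function(p) {
            sample(bases, 1L, prob = config$motif[p, ])
          }, character(1)), collapse = "")
        } else config$consensus
        chars[(locus + 1L):(locus + m_len)] <- strsplit(inst, "")[[1L]]
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = names(fasta)[i], locus = locus,
          site = locus + config$site_offset, instance = inst,
          stringsAsFactors = FALSE)
      }
      s <- paste(chars, collapse = "")
      if (config$scrub_background) {
        mid <- m_len %/% 2L
        repeat {
          occ <- find_occurrences(s, config$consensus)
          # leave alone anything overlapping a planted instance
          if (length(loci) > 0L) {
            occ <- occ[vapply(occ, function(o) all(abs(o - loci) >= m_len),
                              logical(1))]
          }
          if (length(occ) == 0L) break
          for (o in occ) {
            cur <- substr(s, o + mid + 1L, o + mid + 1L)
            substr(s, o + mid + 1L, o + mid + 1L) <-
              sample(setdiff(bases, cur), 1L)
          }
        }
      }
      fasta[i] <- s
      st[[i]] <- data.frame(transcript_id = names(fasta)[i], length = len,
                            last_exon_start = last_exon_start,
                            utr3_start = utr3_start,
                            stringsAsFactors = FALSE)
    }
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(transcript_id = character(0), locus = integer(0),
                 site = integer(0), instance = character(0))
    sites <- data.frame(transcript_id = truth$transcript_id,
                        position = truth$site,
                        source_tag = rep("sim", nrow(truth)),
                        stringsAsFactors = FALSE)
    out <- list(fasta = fasta, sites = sites,
                structure = do.call(rbind, st), truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(out$fasta, file.path(out_dir, "transcripts.fa"))
      write_sites(out$sites, file.path(out_dir, "sites.tsv"))
      write_structure(out$structure, file.path(out_dir, "structure.tsv"))
      jsonlite::write_json(out$truth, file.path(out_dir, "truth.json"),
                           dataframe = "rows")
    }
    out
  })
}

#' Degenerate edge-case fixtures
#'
#' A named set of small deterministic inputs exercising boundary
#' behavior: a site at position 0 and at the final base, a transcript
#' shorter than one window, a site cluster wider than the merge distance,
#' and an all-N transcript.
#'
#' @return Named list; each element has `fasta` (one named sequence) and
#'   `sites` (possibly empty data.frame).
#' @export
degenerate_fixtures <- function() {
  mk_seq <- function(len) {
    paste(rep_len(c("A", "C", "G", "U"), len), collapse = "")
  }
  mk_sites <- function(tx, pos) {
    data.frame(transcript_id = rep(tx, length(pos)), position = as.integer(pos),
               source_tag = rep("fixture", length(pos)),
               stringsAsFactors = FALSE)
  }
  list(
    terminal_site_start = list(
      fasta = c(fix1 = mk_seq(150L)), sites = mk_sites("fix1", 0L)),
    terminal_site_end = list(
      fasta = c(fix2 = mk_seq(150L)), sites = mk_sites("fix2", 149L)),
    short_transcript = list(
      fasta = c(fix3 = mk_seq(60L)), sites = mk_sites("fix3", 10L)),
    wide_cluster = list(
      fasta = c(fix4 = mk_seq(600L)),
      sites = mk_sites("fix4", c(100L, 140L, 180L, 220L))),
    all_N = list(
      fasta = c(fix5 = paste(rep("N", 120L), collapse = "")),
      sites = mk_sites("fix5", integer(0)))
  )
}
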