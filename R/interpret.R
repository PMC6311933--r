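# Model interpretation: convert first-layer convolutional filters to PWM
# motifs (activation-weighted accumulation of maximally responding
# subsequences), and gradient saliency maps that attribute the positive
# class score to individual nucleotides.

#' Convert first-layer filters to PWM motifs
#'
#' For every filter k and every input sequence, the filter-length
#' subsequence with the maximal post-ReLU first-layer activation is
#' extracted as a one-hot matrix and added into the filter's cumulative
#' matrix weighted by that activation alpha; only strictly positive maxima
#' contribute. Rows of the cumulative matrix are then normalized to a
#' position weight matrix. Activations are scanned over the padded input,
#' so a maximal subsequence may overlap the zero padding; those columns
#' contribute zero rows and are normalized to uniform (uninformative)
#' rows. Filters that never activate on any sequence have zero support and
#' an undefined PWM; they are excluded from [write_meme()] output.
#'
#' @param model A trained `m6a_model` (an untrained one is accepted:
#'   garbage in, garbage out).
#' @param sequences Character vector of (positive training) window
#'   sequences to scan.
#' @return List of `m6a_motif` objects: `filter_index` (1-based),
#'   `filter_length`, `M` (cumulative matrix, length x 4, channel order
#'   A,C,G,U), `pwm` (row-stochastic, `NULL` when support is 0) and
#'   `support` (number of sequences with a positive maximal activation).
#' @export
filters_to_motifs <- function(model, sequences) {
  stopifnot(inherits(model, "m6a_model"))
  w1 <- model$config$filter_sizes[1L]
  n1 <- model$config$filter_counts[1L]
  M <- lapply(seq_len(n1), function(k) matrix(0, w1, 4L))
  support <- integer(n1)
  for (s in sequences) {
    fl <- first_layer_activations(model, s)
    act <- fl$act[, seq_len(fl$valid_len), drop = FALSE]
    Xpad <- fl$encoded$matrix
    for (k in seq_len(n1)) {
      pos <- which.max(act[k, ])
      alpha <- act[k, pos]
      if (alpha > 0) {
        sub <- t(Xpad[, pos:(pos + w1 - 1L), drop = FALSE])   # w1 x 4
        M[[k]] <- M[[k]] + alpha * sub
        support[k] <- support[k] + 1L
      }
    }
  }
  lapply(seq_len(n1), function(k) {
    pwm <- NULL
    if (support[k] > 0L) {
      rs <- rowSums(M[[k]])
      pwm <- M[[k]] / ifelse(rs > 0, rs, 1)
      pwm[rs == 0, ] <- 0.25              # pad-overlap rows: uninformative
      colnames(pwm) <- c("A", "C", "G", "U")
    }
    structure(list(filter_index = k, filter_length = w1, M = M[[k]],
                   pwm = pwm, support = support[k],
                   total_activation = sum(M[[k]])),
              class = "m6a_motif")
  })
}

#' Rank learned motifs by how strongly their filters respond
#'
#' Batch-normalized ReLU activations are positive for roughly half of all
#' inputs, so the raw count of contributing sequences (`support`)
#' saturates near the number of scanned sequences for every filter and
#' barely discriminates. Motifs are therefore ranked by
#' `total_activation`, the activation mass actually accumulated into the
#' cumulative matrix, with `support` as tie-break.
#'
#' @param motifs List from [filters_to_motifs()].
#' @return The list reordered, strongest first (zero-support last).
#' @export
rank_motifs <- function(motifs) {
  ta <- vapply(motifs, `[[`, numeric(1), "total_activation")
  sup <- vapply(motifs, `[[`, numeric(1), "support")
  motifs[order(-ta, -sup)]
}

#' Best alignment correlation between two PWMs
#'
#' Slides the shorter PWM along the longer one (full overlap only) and
#' returns the maximum Pearson correlation between the aligned blocks,
#' flattened column-wise.
#'
#' @param pwm,target Row-stochastic matrices (rows = positions, 4
#'   columns, same channel order).
#' @return Maximum Pearson r over alignment offsets.
#' @export
pwm_alignment_cor <- function(pwm, target) {
  if (nrow(pwm) < nrow(target)) { tmp <- pwm; pwm <- target; target <- tmp }
  lw <- nrow(target)
  offs <- 0:(nrow(pwm) - lw)
  max(vapply(offs, function(o) {
    stats::cor(as.vector(pwm[(o + 1):(o + lw), ]), as.vector(target))
  }, numeric(1)))
}

#' One-hot PWM for a consensus sequence
#'
#' @param consensus Sequence over \{A,C,G,U\} (T accepted).
#' @return length x 4 one-hot matrix (channel order A, C, G, U).
#' @export
consensus_pwm <- function(consensus) {
  chars <- strsplit(normalize_rna(consensus), "")[[1L]]
  idx <- BASE_CHANNELS[chars]
  if (anyNA(idx)) stopf("consensus must be over A,C,G,U")
  pwm <- matrix(0, length(chars), 4L, dimnames = list(NULL, c("A", "C", "G", "U")))
  pwm[cbind(seq_along(idx), idx)] <- 1
  pwm
}

#' Gradient saliency map for one window
#'
#' The class score is the pre-sigmoid logit of the positive class; its
#' gradient w with respect to the one-hot input is computed by
#' backpropagation, and the per-position saliency is the elementwise
#' product |w| * X collapsed over the four channels (at most one channel
#' is hot per position, so this picks the gradient magnitude at the
#' observed base; N positions score 0). Pad positions are dropped.
#'
#' @param model A trained `m6a_model`.
#' @param sequence Window sequence.
#' @param window_id Optional id recorded on the track.
#' @return An `m6a_saliency` object: `window_id`, `sequence`, `score`
#'   (per-position saliency, length = window length), `class_score` (the
#'   logit) and `gradient` (4 x length matrix w on the core positions).
#' @export
saliency_map <- function(model, sequence, window_id = NA_character_) {
  stopifnot(inherits(model, "m6a_model"))
  cfg <- model$config
  enc <- encode_onehot(sequence, cfg$filter_sizes[1L], window_id)
  X3 <- array(enc$matrix, dim = c(4L, ncol(enc$matrix), 1L))
  fw <- nn_forward(model, X3, enc$length + 2L * enc$pad, training = FALSE)
  bw <- nn_backward(model, fw, 1)
  grad <- matrix(bw$dX[, , 1L], nrow = 4L)
  core <- enc$pad + seq_len(enc$length)
  w <- grad[, core, drop = FALSE]
  Xc <- enc$matrix[, core, drop = FALSE]
  structure(list(window_id = window_id, sequence = sequence,
                 score = saliency_collapse(w, Xc),
                 class_score = fw$logit, gradient = w),
            class = "m6a_saliency")
}

# |w| . X collapsed over the 4 channels: one score per position (exact for
# a linear class score, where w is its weight matrix).
saliency_collapse <- function(w, X) {
  as.numeric(colSums(abs(w) * X))
}

#' Most salient nucleotide of a track
#'
#' Argmax over positions, leftmost on ties; `NULL` for an all-zero track.
#'
#' @param track An `m6a_saliency` object.
#' @return List with `position` (0-based), `base`, `score`, or `NULL`.
#' @export
most_salient_nucleotide <- function(track) {
  stopifnot(inherits(track, "m6a_saliency"))
  if (length(track$score) == 0L || all(track$score == 0)) return(NULL)
  pos <- which.max(track$score)
  list(position = pos - 1L,
       base = substr(track$sequence, pos, pos),
       score = track$score[pos])
}

#' Ranking percentile of site saliency among all As
#'
#' For each site, the mid-rank percentile of its saliency score among the
#' scores of all A positions in the window: the fraction of A scores
#' strictly below, plus half the ties (including the site itself), in
#' [0, 1]. A site not on an A raises a warning and is ranked among all
#' positions instead (flagged).
#'
#' @param track An `m6a_saliency` object.
#' @param site_offsets 0-based in-window site positions.
#' @return data.frame with `site_offset`, `percentile`, `flagged`.
#' @export
site_saliency_percentile <- function(track, site_offsets) {
  stopifnot(inherits(track, "m6a_saliency"))
  chars <- strsplit(track$sequence, "")[[1L]]
  a_pos <- which(chars == "A")
  out <- lapply(as.integer(site_offsets), function(s) {
    stopifnot(s >= 0L, s < length(chars))
    flagged <- !(s + 1L) %in% a_pos
    pool <- if (flagged) {
      warnf("site offset %d is '%s', not A; percentile computed among all positions",
            s, chars[s + 1L])
      track$score
    } else {
      track$score[a_pos]
    }
    v <- track$score[s + 1L]
    pct <- (sum(pool < v) + 0.5 * sum(pool == v)) / length(pool)
    data.frame(site_offset = s, percentile = pct, flagged = flagged)
  })
  do.call(rbind, out)
}

#' Signed distance from a position to its nearest site
#'
#' `position - nearest_site` in nt; an exact two-sided tie returns the
#' negative (site downstream of the position) value. `NULL` when no sites
#' are given.
#'
#' @param position 0-based position.
#' @param site_offsets 0-based site positions (same coordinate frame).
#' @return Signed integer distance, or `NULL`.
#' @export
distance_to_nearest_site <- function(position, site_offsets) {
  if (length(site_offsets) == 0L) return(NULL)
  d <- as.integer(position) - as.integer(site_offsets)
  cand <- d[abs(d) == min(abs(d))]
  min(cand)
}

#' Plot a saliency track
#'
#' Per-position saliency with optional site marks; written as SVG when
#' `path` is given, drawn on the current device otherwise.
#'
#' @param x An `m6a_saliency` object.
#' @param site_offsets Optional 0-based site positions to mark.
#' @param path Optional output SVG path.
#' @param ... Ignored.
#' @export
plot.m6a_saliency <- function(x, site_offsets = NULL, path = NULL, ...) {
  if (!is.null(path)) {
    grDevices::svg(path, width = 9, height = 3)
    on.exit(grDevices::dev.off())
  }
  pos <- seq_along(x$score) - 1L
  graphics::plot(pos, x$score, type = "h", lwd = 2, col = "grey40",
                 xlab = "position in window (0-based)",
                 ylab = "saliency", main = x$window_id %||% "")
  if (!is.null(site_offsets) && length(site_offsets) > 0L) {
    graphics::points(site_offsets, x$score[site_offsets + 1L],
                     col = "red", pch = 19)
  }
  invisible(x)
}
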