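# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by the most literal route possible
# (scans, loops, rank formulas) and never call the code paths they check.

rand_rna <- function(len, rng_chars = c("A", "C", "G", "U")) {
  paste(sample(rng_chars, len, replace = TRUE), collapse = "")
}

# sequences with/without a planted consensus at a random position,
# background scrubbed of chance matches
planted_windows <- function(n, len, motif = "GGACU", plant = TRUE) {
  vapply(seq_len(n), function(i) {
    s <- strsplit(rand_rna(len), "")[[1L]]
    repeat {
      str <- paste(s, collapse = "")
      occ <- gregexpr(motif, str, fixed = TRUE)[[1L]]
      if (occ[1L] == -1L) break
      for (p in occ) s[p + 2L] <- sample(setdiff(c("A", "C", "G", "U"), s[p + 2L]), 1L)
    }
    if (plant) {
      at <- sample.int(len - nchar(motif) + 1L, 1L)
      s[at:(at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1L]]
    }
    paste(s, collapse = "")
  }, character(1))
}

# brute-force single-linkage clustering + lower-median representative
oracle_merge <- function(positions, d) {
  if (length(positions) == 0L) return(integer(0))
  reps <- integer(0)
  cluster <- positions[1L]
  for (p in positions[-1L]) {
    if (p - cluster[length(cluster)] <= d) {
      cluster <- c(cluster, p)
    } else {
      reps <- c(reps, cluster[ceiling(length(cluster) / 2)])
      cluster <- p
    }
  }
  c(reps, cluster[ceiling(length(cluster) / 2)])
}

# Mann-Whitney AUROC: P(pos > neg) + 0.5 P(tie), by explicit pair counts
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct evaluation of the five printed metric formulas
oracle_metrics <- function(TP, TN, FP, FN) {
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(accuracy = (TP + TN) / (TP + TN + FP + FN),
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       f1 = 2 * TP / (2 * TP + FP + FN),
       mcc = if (den == 0) 0 else (TP * TN - FP * FN) / den)
}

# Naive filter->motif conversion: scan every position of every sequence
# with explicit loops over the model's first-layer weights, batch-norm
# (running stats) and ReLU, take the per-sequence maximum, accumulate the
# activation-weighted one-hot subsequence, normalize rows.
oracle_filters_to_motifs <- function(model, sequences) {
  w1 <- model$config$filter_sizes[1L]
  n1 <- model$config$filter_counts[1L]
  W <- model$params$conv1$W
  b <- model$params$conv1$b
  g <- model$params$bn1$gamma
  be <- model$params$bn1$beta
  mu <- model$state$bn1$mean
  va <- model$state$bn1$var
  M <- lapply(seq_len(n1), function(k) matrix(0, w1, 4L))
  support <- integer(n1)
  for (s in sequences) {
    enc <- encode_onehot(s, w1)
    X <- enc$matrix
    L1 <- ncol(X) - w1 + 1L
    for (k in seq_len(n1)) {
      best <- -Inf; best_pos <- 1L
      for (p in seq_len(L1)) {
        conv <- b[k]
        for (j in seq_len(w1)) {
          for (ch in 1:4) {
            conv <- conv + W[k, (j - 1L) * 4L + ch] * X[ch, p + j - 1L]
          }
        }
        act <- max(0, g[k] * (conv - mu[k]) / sqrt(va[k] + 1e-5) + be[k])
        if (act > best) { best <- act; best_pos <- p }
      }
      if (best > 0) {
        M[[k]] <- M[[k]] + best * t(X[, best_pos:(best_pos + w1 - 1L), drop = FALSE])
        support[k] <- support[k] + 1L
      }
    }
  }
  lapply(seq_len(n1), function(k) {
    rs <- rowSums(M[[k]])
    pwm <- if (support[k] > 0L) {
      p <- M[[k]] / ifelse(rs > 0, rs, 1)
      p[rs == 0, ] <- 0.25
      p
    } else NULL
    list(filter_index = k, M = M[[k]], pwm = pwm, support = support[k])
  })
}

# tiny model configs used throughout the unit tests
nano_config <- function(...) {
  defaults <- list(filter_sizes = c(4L, 3L), filter_counts = c(4L, 3L),
                   blstm_units = 3L, fc_units = 4L, dropout_rate = 0,
                   maxpool = NULL, blstm_reduction = "final",
                   batch_size = 8L, max_epochs = 3L, patience = 3L,
                   window_size = 20L)
  do.call(tiny_config, utils::modifyList(defaults, list(...)))
}
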