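# A model whose first conv layer is fully engineered: batch norm is set to
# the identity (gamma 1, beta 0, running mean 0, var 1 - eps) so the
# post-ReLU first-layer activation equals ReLU(conv + bias) exactly.
engineered_model <- function(W1, b1 = NULL, filter_size = ncol(W1) / 4L) {
  n1 <- nrow(W1)
  cfg <- tiny_config(filter_sizes = c(as.integer(filter_size), 3L),
                     filter_counts = c(n1, 2L), blstm_units = 2L,
                     fc_units = 2L, dropout_rate = 0, maxpool = NULL,
                     blstm_reduction = "final", window_size = 20L, seed = 1L)
  model <- build_model(cfg)
  model$params$conv1$W <- W1
  model$params$conv1$b <- b1 %||% numeric(n1)
  model$params$bn1$gamma <- rep(1, n1)
  model$params$bn1$beta <- rep(0, n1)
  model$state$bn1$mean <- rep(0, n1)
  model$state$bn1$var <- rep(1 - 1e-5, n1)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# conv weight row matching a given subsequence exactly once (score =
# length at the match, strictly less elsewhere), with a bias shifting the
# maximum to `alpha`
matcher_row <- function(subseq, alpha) {
  enc <- encode_onehot(subseq, filter_size_1 = 1L)   # no pad
  w <- as.numeric(enc$matrix) * 2 - 1e-3             # reward match, mild else
  list(W = w, b = alpha - sum(as.numeric(enc$matrix) * w))
}

test_that("a single firing with alpha cancels in the normalized PWM", {
  sub <- "ACGUA"
  mr <- matcher_row(sub, alpha = 2)
  model <- engineered_model(matrix(mr$W, nrow = 1), mr$b, filter_size = 5L)
  seqs <- paste0("GG", sub, "GGGGGGGGGGGGG")
  motifs <- filters_to_motifs(model, seqs)
  expect_equal(motifs[[1]]$support, 1L)
  expect_equal(motifs[[1]]$pwm, consensus_pwm(sub), ignore_attr = TRUE)
})

test_that("activation weights combine as alpha-weighted averages", {
  # one filter that fires with alpha 1 on all-A and alpha 3 on all-C
  W <- matrix(0, 1, 4 * 3)
  W[1, seq(1, 12, by = 4)] <- 1      # A channel weight 1 per column
  W[1, seq(2, 12, by = 4)] <- 3      # C channel weight 3 per column
  model <- engineered_model(W / 3, filter_size = 3L)   # alphas 1 and 3
  motifs <- filters_to_motifs(model, c("AAAUUUUUUUUU", "CCCUUUUUUUUU"))
  expect_equal(motifs[[1]]$support, 2L)
  # each row accumulates 1 * A-one-hot + 3 * C-one-hot -> (0.25, 0.75, 0, 0)
  for (p in 1:3) {
    expect_equal(unname(motifs[[1]]$pwm[p, ]), c(0.25, 0.75, 0, 0),
                 tolerance = 1e-12)
  }
})

test_that("never-firing filters have zero support and no PWM", {
  W <- matrix(-1, 1, 4 * 3)          # always negative -> ReLU 0
  model <- engineered_model(W, filter_size = 3L)
  motifs <- filters_to_motifs(model, c("ACGUACGU", "GGGGCCCC"))
  expect_equal(motifs[[1]]$support, 0L)
  expect_null(motifs[[1]]$pwm)
  # and write_meme must not receive them
  keep <- Filter(function(m) m$support > 0, motifs)
  expect_length(keep, 0)
})

test_that("filters_to_motifs matches the brute-force scan oracle", {
  withr::local_seed(17)
  cfg <- tiny_config(filter_sizes = c(4L, 3L), filter_counts = c(2L, 2L),
                     blstm_units = 2L, fc_units = 2L, window_size = 20L,
                     maxpool = NULL, seed = 19L)
  model <- build_model(cfg)
  # move batch-norm state off the init values so the oracle must honor it
  model$state$bn1$mean <- rnorm(2, 0, 0.2)
  model$state$bn1$var <- runif(2, 0.5, 2)
  seqs <- replicate(10, rand_rna(sample(10:20, 1)))
  got <- filters_to_motifs(model, seqs)
  want <- oracle_filters_to_motifs(model, seqs)
  for (k in seq_along(got)) {
    expect_equal(got[[k]]$support, want[[k]]$support)
    expect_equal(got[[k]]$M, want[[k]]$M, tolerance = 1e-12)
    if (!is.null(want[[k]]$pwm)) {
      expect_equal(unname(got[[k]]$pwm), want[[k]]$pwm, tolerance = 1e-12)
    }
  }
})

test_that("saliency collapse is exact for a linear class score", {
  # S_c(X) = sum(W * X) + b  =>  w = W and S[j] = |W[base_j, j]|
  withr::local_seed(23)
  s <- "ACGUNACGGU"
  enc <- encode_onehot(s, filter_size_1 = 1L)   # pad 0: matrix is the core
  W <- matrix(rnorm(4 * nchar(s)), 4)
  S <- m6Ascan:::saliency_collapse(W, enc$matrix)
  chars <- strsplit(s, "")[[1]]
  for (j in seq_along(chars)) {
    if (chars[j] == "N") {
      expect_equal(S[j], 0)
    } else {
      ch <- c(A = 1, C = 2, G = 3, U = 4)[chars[j]]
      expect_equal(S[j], abs(W[ch, j]))
    }
  }
})

test_that("saliency gradient matches finite differences on a trained-ish model", {
  withr::local_seed(29)
  model <- build_model(nano_config(seed = 31L))
  s <- planted_windows(1, 20)
  trk <- saliency_map(model, s, window_id = "w1")
  expect_length(trk$score, 20L)
  expect_true(all(trk$score >= 0))
  enc <- encode_onehot(s, model$config$filter_sizes[1])
  eps <- 1e-4
  for (j in sample(which(trk$score > 1e-10), 5)) {
    ch <- which(enc$matrix[, enc$pad + j] == 1)
    Xp <- enc$matrix; Xp[ch, enc$pad + j] <- Xp[ch, enc$pad + j] + eps
    Xm <- enc$matrix; Xm[ch, enc$pad + j] <- Xm[ch, enc$pad + j] - eps
    lens <- enc$length + 2L * enc$pad
    num <- abs((m6Ascan:::nn_forward(model, array(Xp, c(4, ncol(Xp), 1)), lens)$logit -
                m6Ascan:::nn_forward(model, array(Xm, c(4, ncol(Xm), 1)), lens)$logit) /
               (2 * eps))
    expect_lt(abs(num - trk$score[j]) / max(num, 1e-12), 1e-3)
  }
})

test_that("N positions score zero and all-N windows give a zero track", {
  model <- build_model(nano_config(seed = 37L))
  trk <- saliency_map(model, "ACGUNNACGUACGU")
  expect_equal(trk$score[5:6], c(0, 0))
  trk0 <- saliency_map(model, strrep("N", 20))
  expect_true(all(trk0$score == 0))
  expect_null(most_salient_nucleotide(trk0))
})

test_that("most_salient_nucleotide takes the leftmost argmax", {
  trk <- structure(list(window_id = "w", sequence = "ACG",
                        score = c(0.1, 0.9, 0.3)), class = "m6a_saliency")
  expect_equal(most_salient_nucleotide(trk)$position, 1L)
  trk$score <- c(0.5, 0.5, 0.1)
  out <- most_salient_nucleotide(trk)
  expect_equal(out$position, 0L)
  expect_equal(out$base, "A")
})

test_that("site percentiles use mid-ranks among A positions", {
  seqs <- paste(rep("A", 10), collapse = "")
  trk <- structure(list(window_id = "w", sequence = seqs,
                        score = c(1:9 / 10, 5)), class = "m6a_saliency")
  # site on the unique max among 10 As
  expect_equal(site_saliency_percentile(trk, 9L)$percentile, 0.95)
  # full tie
  trk$score <- rep(0.3, 10)
  expect_equal(site_saliency_percentile(trk, 4L)$percentile, 0.5)
  # single A in the window (self-tie convention)
  trk2 <- structure(list(window_id = "w", sequence = "GGAGG",
                         score = c(0.1, 0.2, 0.9, 0.4, 0.3)),
                    class = "m6a_saliency")
  expect_equal(site_saliency_percentile(trk2, 2L)$percentile, 0.5)
  # site not on an A: warning + ranking among all positions, flagged
  expect_warning(out <- site_saliency_percentile(trk2, 1L), "not A")
  expect_true(out$flagged)
  expect_equal(out$percentile, (1 + 0.5) / 5)
})

test_that("distance_to_nearest_site is signed with the upstream tie-break", {
  expect_equal(distance_to_nearest_site(10L, c(7L, 30L)), 3L)
  expect_equal(distance_to_nearest_site(7L, 7L), 0L)
  expect_equal(distance_to_nearest_site(10L, c(5L, 15L)), -5L)
  expect_null(distance_to_nearest_site(10L, integer(0)))
})

test_that("pwm alignment and ranking helpers behave", {
  target <- consensus_pwm("GGACU")
  padded <- rbind(matrix(0.25, 3, 4), target, matrix(0.25, 2, 4))
  expect_equal(pwm_alignment_cor(padded, target), 1)
  m1 <- list(filter_index = 1L, support = 5L, total_activation = 10)
  m2 <- list(filter_index = 2L, support = 9L, total_activation = 3)
  expect_equal(rank_motifs(list(m1, m2))[[1]]$filter_index, 1L)
})
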