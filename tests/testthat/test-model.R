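test_that("model configs validate and builds are seed-deterministic", {
  expect_error(model_config(filter_counts = c(0L, 8L)))
  expect_error(model_config(dropout_rate = 1))
  expect_error(model_config(patience = 10L, max_epochs = 5L))
  m1 <- build_model(nano_config(seed = 3L))
  m2 <- build_model(nano_config(seed = 3L))
  expect_identical(m1$params, m2$params)
  m3 <- build_model(nano_config(seed = 4L))
  expect_false(identical(m1$params, m3$params))
})

test_that("forward pass returns scores in (0,1), deterministic and batch-invariant", {
  withr::local_seed(21)
  model <- build_model(nano_config(seed = 8L))
  seqs <- planted_windows(12, 20)
  s1 <- predict_scores(model, seqs)
  expect_true(all(s1 > 0 & s1 < 1))
  expect_identical(s1, predict_scores(model, seqs))
  # batch of 1 vs full batch
  s_one <- vapply(seqs, function(s) predict_scores(model, s), numeric(1))
  expect_equal(unname(s_one), s1, tolerance = 1e-12)
})

test_that("scores are invariant to batch-level zero padding (mixed lengths)", {
  withr::local_seed(22)
  model <- build_model(nano_config(seed = 9L))
  long <- planted_windows(1, 20)
  short <- planted_windows(1, 11)
  mixed <- predict_scores(model, c(long, short))   # short gets extra pad cols
  alone <- c(predict_scores(model, long), predict_scores(model, short))
  expect_equal(mixed, alone, tolerance = 1e-12)
})

test_that("maxpool halves the position dimension after each conv block", {
  cfg <- nano_config(maxpool = 2L)
  model <- build_model(cfg)
  be <- m6Ascan:::encode_batch(planted_windows(2, 20), cfg$filter_sizes[1])
  fw <- m6Ascan:::nn_forward(model, be$X, be$core_len + 2L * be$pad)
  # L1 = ceil((20 + 2*2 - 4 + 1)/2) = 11, L2 = ceil((11 - 3 + 1)/2) = 5
  expect_equal(dim(fw$caches$b1$A3)[2], 11L)
  expect_equal(dim(fw$caches$b2$A3)[2], 5L)
})

test_that("analytic gradients match central finite differences", {
  withr::local_seed(31)
  # training mode (batch-norm on batch stats), mixed lengths, pooling on
  cfg <- nano_config(maxpool = 2L, blstm_reduction = "flatten", seed = 13L)
  model <- build_model(cfg)
  seqs <- c(planted_windows(2, 20), planted_windows(1, 13), "ACGNNACGUACG")
  y <- c(1, 0, 1, 0)
  be <- m6Ascan:::encode_batch(seqs, cfg$filter_sizes[1])
  lens <- be$core_len + 2L * be$pad
  loss_fn <- function(m) {
    fw <- m6Ascan:::nn_forward(m, be$X, lens, training = TRUE)
    m6Ascan:::bce_with_logits(fw$logit, y)$loss
  }
  fw <- m6Ascan:::nn_forward(model, be$X, lens, training = TRUE)
  lo <- m6Ascan:::bce_with_logits(fw$logit, y)
  bw <- m6Ascan:::nn_backward(model, fw, lo$dlogit)
  eps <- 1e-5
  for (grp in names(model$params)) {
    for (nm in names(model$params[[grp]])) {
      P <- model$params[[grp]][[nm]]
      for (ii in sample(length(P), min(3, length(P)))) {
        mp <- model; mp$params[[grp]][[nm]][ii] <- P[ii] + eps
        mm <- model; mm$params[[grp]][[nm]][ii] <- P[ii] - eps
        num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
        ana <- bw$grads[[grp]][[nm]][ii]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4,
                  label = sprintf("grad %s$%s[%d]", grp, nm, ii))
      }
    }
  }
  # input gradient in eval mode (the saliency path)
  fw2 <- m6Ascan:::nn_forward(model, be$X, lens, training = FALSE)
  bw2 <- m6Ascan:::nn_backward(model, fw2, c(1, 0, 0, 0))
  for (ii in sample(seq_len(length(be$X[, , 1])), 5)) {
    Xp <- be$X; Xp[, , 1][ii] <- Xp[, , 1][ii] + eps
    Xm <- be$X; Xm[, , 1][ii] <- Xm[, , 1][ii] - eps
    num <- (m6Ascan:::nn_forward(model, Xp, lens, FALSE)$logit[1] -
            m6Ascan:::nn_forward(model, Xm, lens, FALSE)$logit[1]) / (2 * eps)
    expect_lt(abs(num - bw2$dX[, , 1][ii]) /
                max(1e-6, abs(num) + abs(bw2$dX[, , 1][ii])), 1e-4)
  }
})

test_that("training rejects single-class sets and triggers early stopping", {
  seqs <- planted_windows(20, 20)
  expect_error(train_model(nano_config(), seqs, rep(1, 20), seqs, rep(0:1, 10)),
               "both classes")
  expect_error(train_model(nano_config(), seqs, rep(0:1, 10), seqs, rep(1, 20)),
               "both classes")

  # constant-noise data with patience 1 stops well before max_epochs
  withr::local_seed(41)
  seqs <- replicate(24, rand_rna(20))
  y <- rep(0:1, 12)
  fit <- train_model(nano_config(max_epochs = 30L, patience = 1L, seed = 2L),
                     seqs, y, seqs, y)
  expect_lt(fit$record$stopped_epoch, 30L)
  expect_lte(fit$record$best_epoch, fit$record$stopped_epoch)
})

test_that("training is reproducible run-to-run under a fixed seed", {
  withr::local_seed(51)
  seqs <- planted_windows(30, 20)
  y <- rep(0:1, 15)
  cfg <- nano_config(seed = 6L, max_epochs = 2L, patience = 2L)
  f1 <- train_model(cfg, seqs, y, seqs[1:10], y[1:10])
  f2 <- train_model(cfg, seqs, y, seqs[1:10], y[1:10])
  expect_identical(f1$record$history, f2$record$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the model separates planted-motif data (capacity sanity)", {
  withr::local_seed(61)
  pos <- planted_windows(60, 25, plant = TRUE)
  neg <- planted_windows(60, 25, plant = FALSE)
  seqs <- c(pos, neg); y <- rep(1:0, each = 60)
  vi <- c(1:8, 61:68); ti <- setdiff(seq_along(y), vi)
  cfg <- tiny_config(filter_sizes = c(5L, 3L), filter_counts = c(8L, 4L),
                     blstm_units = 8L, fc_units = 8L, maxpool = 4L,
                     window_size = 25L, max_epochs = 15L, patience = 15L,
                     seed = 7L)
  fit <- train_model(cfg, seqs[ti], y[ti], seqs[vi], y[vi])
  tr_auroc <- roc_pr(predict_scores(fit$model, seqs[ti]), y[ti])$auroc
  expect_gte(tr_auroc, 0.99)
  # planted-motif positives score higher than negatives on average
  sc <- predict_scores(fit$model, seqs)
  expect_gt(mean(sc[y == 1]), mean(sc[y == 0]))
})

test_that("shuffled labels give chance-level validation AUROC", {
  withr::local_seed(71)
  pos <- planted_windows(30, 20, plant = TRUE)
  neg <- planted_windows(30, 20, plant = FALSE)
  seqs <- c(pos, neg)
  y <- sample(rep(0:1, 30))                 # labels independent of content
  ho <- c(1:10, 51:60)                      # held-out windows
  tr <- setdiff(seq_along(y), ho)
  fit <- train_model(nano_config(seed = 3L, max_epochs = 5L, patience = 5L),
                     seqs[tr], y[tr], seqs[ho], y[ho])
  auroc <- roc_pr(predict_scores(fit$model, seqs[ho]), y[ho])$auroc
  expect_gt(auroc, 0.2)   # chance level, wide band for n = 20
  expect_lt(auroc, 0.8)
})

test_that("grid_search_cv does stratified folds and ranks settings", {
  withr::local_seed(81)
  pos <- planted_windows(25, 20, plant = TRUE)
  neg <- planted_windows(25, 20, plant = FALSE)
  seqs <- c(pos, neg); y <- rep(1:0, each = 25)

  # fold arithmetic: k = 5 on 50 samples, each fold of size 10 used once
  folds <- m6Ascan:::stratified_folds(y, 5L)
  expect_equal(as.vector(table(folds)), rep(10L, 5))
  expect_equal(as.vector(table(folds[y == 1])), rep(5L, 5))

  base <- nano_config(max_epochs = 4L, patience = 4L, seed = 5L)
  one <- grid_search_cv(seqs, y, grid = list(list(blstm_units = 3L)),
                        k = 2L, base_config = base, seed = 2L)
  expect_equal(one$best_index, 1L)
  expect_equal(nrow(one$table), 1L)
  expect_true(is.finite(one$table$mean_auroc))

  # a setting that cannot learn (learning rate ~ 0) loses
  two <- grid_search_cv(seqs, y,
                        grid = list(list(learning_rate = 1e-12,
                                         max_epochs = 2L, patience = 2L),
                                    list(max_epochs = 6L, patience = 6L)),
                        k = 2L, base_config = base, seed = 2L)
  expect_equal(two$best_index, 2L)
})

test_that("a saved checkpoint predicts identically after reload", {
  withr::local_seed(91)
  model <- build_model(nano_config(seed = 12L))
  seqs <- planted_windows(6, 20)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, f)
  back <- load_checkpoint(f, expect_window_size = 20L)$model
  expect_identical(predict_scores(back, seqs), predict_scores(model, seqs))
})
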