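test_that("merge_sites follows chain-and-lower-median and matches the oracle", {
  expect_equal(merge_sites(c(100L, 130L, 160L), 50L), 130L)
  expect_equal(merge_sites(c(100L, 200L), 50L), c(100L, 200L))
  expect_equal(merge_sites(100L, 50L), 100L)
  expect_equal(merge_sites(integer(0), 50L), integer(0))
  expect_error(merge_sites(c(5L, 3L), 50L), "sorted")

  withr::local_seed(42)
  for (i in 1:50) {
    pos <- sort(sample.int(500L, sample(1:20, 1)))
    d <- sample(0:80, 1)
    expect_equal(merge_sites(pos, d), oracle_merge(pos, d))
  }
  # merge_distance 0 is the identity on unique sorted sites
  pos <- sort(sample.int(1000L, 30L))
  expect_equal(merge_sites(pos, 0L), pos)
})

test_that("place_positive_window places uniformly within the feasible range", {
  cfg <- builder_config(seed = 1L)
  # forced placement: window exactly covers the transcript
  w <- place_positive_window(101L, 50L, cfg)
  expect_equal(w$start, 0L)
  expect_equal(w$end, 101L)
  expect_equal(w$site_offsets, 50L)

  # terminal truncation
  w <- place_positive_window(60L, 10L, cfg)
  expect_equal(w$start, 0L)
  expect_equal(w$end, 60L)

  expect_error(place_positive_window(0L, 0L, cfg), "transcript_len")

  # uniform support over [site - 100, site] for a mid-transcript site
  withr::local_seed(7)
  starts <- replicate(1000, place_positive_window(10000L, 5000L, cfg)$start)
  expect_true(all(starts >= 4900L & starts <= 5000L))
  expect_true(all(starts <= 5000L))                       # site inside
  expect_gt(length(unique(starts)), 60)                   # spread out
  tab <- tabulate(starts - 4899L, 101L)
  expect_lt(max(tab), 1000 * 0.05)                        # no big atom
})

test_that("find_negative_window picks the closest valid candidate", {
  cfg <- builder_config(seed = 1L)
  pos <- list(start = 1000L, end = 1101L)
  # spacious, site-free transcript: both sides valid at distance 100,
  # tie broken ~ uniformly
  withr::local_seed(3)
  starts <- replicate(400, find_negative_window(pos, 10000L, 1050L, cfg)$start)
  expect_setequal(unique(starts), c(900L, 1100L))
  expect_gt(mean(starts == 900L), 0.4)
  expect_lt(mean(starts == 900L), 0.6)

  # no upstream room: first valid downstream candidate
  pos0 <- list(start = 0L, end = 101L)
  nw <- find_negative_window(pos0, 10000L, 50L, cfg)
  expect_equal(nw$start, 100L)

  # transcript too short for any candidate
  expect_null(find_negative_window(pos0, 150L, 50L, cfg))

  # candidates overlapping a site are skipped
  pos2 <- list(start = 500L, end = 601L)
  sites <- c(550L, seq(380L, 480L, by = 10L))  # upstream range at d=100..200 blocked
  nw2 <- find_negative_window(pos2, 10000L, sites, cfg)
  expect_equal(nw2$start, 600L)
})

test_that("build_dataset satisfies its invariants on simulated data", {
  sim <- simulate_dataset(sim_config(n_transcripts = 40L, seed = 5L))
  cfg <- builder_config(seed = 5L)
  ds <- build_dataset(sim$fasta, sim$sites, cfg, quiet = TRUE)
  w <- ds$windows
  lens <- nchar(sim$fasta)[w$transcript_id]

  expect_true(all(w$start >= 0L))
  expect_true(all(w$end <= lens))
  expect_true(all(w$end - w$start <= cfg$window_size))

  offs <- m6Ascan:::window_offsets(w)
  pos <- w$label == "positive"
  expect_true(all(lengths(offs[pos]) >= 1L))
  expect_true(all(lengths(offs[!pos]) == 0L))

  # every positive contains its generating site; no negative spans any site
  for (i in which(pos)) {
    on_tx <- sim$sites$position[sim$sites$transcript_id == w$transcript_id[i]]
    expect_true(all((w$start[i] + offs[[i]]) %in% on_tx))
  }
  for (i in which(!pos)) {
    on_tx <- sim$sites$position[sim$sites$transcript_id == w$transcript_id[i]]
    expect_false(any(on_tx >= w$start[i] & on_tx < w$end[i]))
  }

  # approx 1:1 ratio on spacious transcripts
  ratio <- sum(pos) / sum(!pos)
  expect_gte(ratio, 0.9)
  expect_lte(ratio, 1.1)

  # split fractions: 20% test, 1/8 of the rest validation
  expect_equal(sum(w$split == "test"), round(nrow(w) * 0.2))
  expect_setequal(unique(w$split), c("train", "val", "test"))
})

test_that("build_dataset is deterministic and handles empty input", {
  sim <- simulate_dataset(sim_config(n_transcripts = 10L, seed = 2L))
  cfg <- builder_config(seed = 9L)
  d1 <- build_dataset(sim$fasta, sim$sites, cfg, quiet = TRUE)
  d2 <- build_dataset(sim$fasta, sim$sites, cfg, quiet = TRUE)
  expect_identical(d1$windows, d2$windows)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_windows(d1$windows, f1); write_windows(d2$windows, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  empty <- build_dataset(sim$fasta, sim$sites[0, ], cfg, quiet = TRUE)
  expect_equal(nrow(empty$windows), 0L)
})

test_that("site beyond transcript end is reported with the offender", {
  fasta <- c(tx1 = rand_rna(300))
  sites <- data.frame(transcript_id = "tx1", position = 400L,
                      source_tag = "", stringsAsFactors = FALSE)
  expect_error(build_dataset(fasta, sites, builder_config(seed = 1L)),
               "tx1:400")
})

test_that("intersect_sites keeps exact (transcript, position) matches", {
  a <- data.frame(transcript_id = c("t1", "t1", "t2"),
                  position = c(5L, 9L, 5L), source_tag = "r1")
  b <- data.frame(transcript_id = c("t1", "t2"),
                  position = c(9L, 7L), source_tag = "r2")
  expect_equal(intersect_sites(a, b)$position, 9L)
})
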