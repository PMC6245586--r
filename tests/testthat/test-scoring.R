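# Independent word-count oracle: enumerate overlapping words by hand and
# apply the smoothing formula with plain arithmetic.
oracle_f <- function(positive, null, w = 6L, pc = 1) {
  count_all <- function(seqs) {
    words <- unlist(lapply(seqs, function(s) {
      substring(s, 1:(nchar(s) - w + 1L), w:nchar(s))
    }))
    table(words)
  }
  cm <- count_all(positive)
  cn <- count_all(null)
  tot_m <- sum(cm) + pc * 4^w
  tot_n <- sum(cn) + pc * 4^w
  function(word) {
    m <- if (word %in% names(cm)) cm[[word]] else 0
    n <- if (word %in% names(cn)) cn[[word]] else 0
    log2(((m + pc) / tot_m) / ((n + pc) / tot_n))
  }
}

test_that("identical training sets give an all-zero model", {
  seqs <- c("ACGTACGTAC", "GGGTTTCCCA")
  model <- train_model(seqs, seqs)
  expect_length(model$log_ratios, 4^6)
  expect_true(all(model$log_ratios == 0))
  expect_equal(score_sequence(model, "ACGTACGTACGT"), 0)
})

test_that("trained log-ratios match the hand-computed smoothing formula", {
  positive <- c("AAAAAAA", "ACGTACGTAC")
  null <- c("TTTTTTTT", "CCCCGGGG")
  model <- train_model(positive, null)
  f <- oracle_f(positive, null)
  for (word in c("AAAAAA", "ACGTAC", "TTTTTT", "CCCCGG", "GGGGGG")) {
    expect_equal(unname(model$log_ratios[word]), f(word), tolerance = 1e-12)
  }
  # word absent from both sets with equal smoothed totals scores 0
  eq_pos <- c("ACGTACGTAC")
  eq_null <- c("TTGCATTGCA")
  m2 <- train_model(eq_pos, eq_null)
  expect_equal(unname(m2$log_ratios["GGGGGG"]), 0)
})

test_that("a word twice as probable in M as in N scores F = 1", {
  model <- train_model("ACGTAC", "ACGTAC")
  model$log_ratios["ACGTAC"] <- log2(2) # construct the exact ratio
  expect_equal(score_sequence(model, "ACGTAC"), 1)
})

test_that("sequence score is the mean F over valid windows", {
  positive <- c("ACGTACGTACGTACG")
  null <- c("GGTTGGTTGGTT")
  model <- train_model(positive, null)
  s <- "ACGTACGTAC" # 5 windows
  words <- substring(s, 1:5, 6:10)
  expect_equal(score_sequence(model, s),
               mean(model$log_ratios[words]))
  # windows containing N are excluded from the divisor
  sn <- "ACGTACNGTACG"
  valid <- substring(sn, 1:7, 6:12)
  valid <- valid[!grepl("N", valid)]
  expect_equal(score_sequence(model, sn),
               sum(model$log_ratios[valid]) / length(valid))
  expect_error(score_sequence(model, "ACGT"), "shorter")
  expect_equal(score_sequence(model, "NNNNNNNN"), 0)
})

test_that("swapping positive and null sets negates all scores exactly", {
  set.seed(5)
  ts <- make_training_sets(30, 30, "TGCATG", enrichment = 50, seed = 5)
  m1 <- train_model(ts$positive, ts$null)
  m2 <- train_model(ts$null, ts$positive)
  expect_equal(m1$log_ratios, -m2$log_ratios)
  s <- ts$positive[1]
  expect_equal(score_sequence(m1, s), -score_sequence(m2, s))
})

test_that("duplicating training sequences leaves word probabilities unchanged", {
  # raw word frequencies are duplication-invariant; with a vanishing
  # pseudocount the log-ratios of observed words are too (the default
  # pseudocount of 1 perturbs them only at small sample sizes)
  ts <- make_training_sets(10, 10, "TGCATG", seed = 6)
  m1 <- train_model(ts$positive, ts$null, pseudocount = 1e-9)
  m2 <- train_model(rep(ts$positive, 3), rep(ts$null, 3), pseudocount = 1e-9)
  seen <- function(seqs) {
    unique(unlist(lapply(seqs, function(s) {
      substring(s, 1:(nchar(s) - 5L), 6:nchar(s))
    })))
  }
  both <- intersect(seen(ts$positive), seen(ts$null))
  expect_gt(length(both), 50L)
  expect_equal(m1$log_ratios[both], m2$log_ratios[both], tolerance = 1e-6)
})

test_that("score filtering is strict and order preserving", {
  cand <- data.frame(record_id = "c", start = c(0L, 100L), end = c(60L, 160L),
                     sequence = c("ACGTACGTAC", "GGTTGGTTGGTT"))
  model <- train_model("ACGTACGTACGTACG", "GGTTGGTTGGTT")
  scored <- filter_by_score(cand, model, threshold = -Inf)
  expect_equal(nrow(scored), 2L)
  expect_equal(scored$start, c(0L, 100L))
  s1 <- scored$score[1]
  expect_equal(nrow(filter_by_score(cand, model, threshold = s1 - 0.01)), 1L)
  # strictly-greater-than retention: a candidate at the threshold drops
  expect_equal(sum(filter_by_score(cand, model, threshold = s1)$score == s1), 0L)
})

test_that("model files round-trip bit-exactly and preserve scoring", {
  set.seed(8)
  ts <- make_training_sets(20, 20, "TGCATG", seed = 8)
  model <- train_model(ts$positive, ts$null)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_model(model, f1)
  loaded <- read_model(f1)
  write_model(loaded, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(loaded$word_length, 6L)
  s <- ts$positive[1]
  expect_equal(score_sequence(loaded, s), score_sequence(model, s),
               tolerance = 1e-5)
})

test_that("motif-enriched training separates motif-bearing from uniform sequences", {
  ts <- make_training_sets(200, 200, "TGCATG", seed = 12)
  model <- train_model(ts$positive, ts$null)
  expect_gt(unname(model$log_ratios["TGCATG"]), 0)
  fresh <- make_training_sets(50, 50, "TGCATG", seed = 13)
  pos_scores <- vapply(fresh$positive, function(s) score_sequence(model, s),
                       numeric(1))
  neg_scores <- vapply(fresh$null, function(s) score_sequence(model, s),
                       numeric(1))
  expect_gt(auc_scores(pos_scores, neg_scores), 0.9)
  # uniform sequences sit near zero (small negative offset from the
  # motif mass displacing background words in the positive set)
  expect_lt(abs(mean(neg_scores)), 0.3)
  expect_gt(mean(pos_scores), mean(neg_scores) + 0.2)
})
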