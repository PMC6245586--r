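seed_row <- function(left, right, mis = 0L, mispos = NA_integer_, k = 10L) {
  data.frame(left_start = as.integer(left), right_start = as.integer(right),
             tir_length = k, mis = as.integer(mis),
             mispos = as.integer(mispos))
}

test_that("two adjacent perfect seeds merge into an 11 bp TIR candidate", {
  seeds <- rbind(seed_row(100, 200), seed_row(101, 199))
  got <- merge_seed_pairs(seeds)
  expect_equal(nrow(got), 1L)
  expect_equal(got$tir_length, 11L)
  expect_equal(got$start, 100L)
  expect_equal(got$end, 210L)
  expect_equal(got$mis, 0L)
})

test_that("an unmergeable seed passes through with a 10 bp TIR", {
  got <- merge_seed_pairs(seed_row(50, 120))
  expect_equal(nrow(got), 1L)
  expect_equal(got$tir_length, 10L)
  expect_equal(got$start, 50L)
  expect_equal(got$end, 130L)
})

test_that("two imperfect seeds with distinct mismatch positions never merge", {
  # merging them would describe a 2-mismatch TIR: the merge is refused
  # and each seed stands alone
  seeds <- rbind(seed_row(100, 200, mis = 1, mispos = 103),
                 seed_row(101, 199, mis = 1, mispos = 105))
  got <- merge_seed_pairs(seeds)
  expect_equal(nrow(got), 2L)
  expect_true(all(got$tir_length == 10L))
  expect_equal(got$mispos, c(103L, 105L))
})

test_that("a perfect seed bridges a gap of 2 to a mismatch run", {
  # a perfect run ending at 3460 and the 1-mismatch run for a mismatch at
  # 3468 (windows keeping 3468 interior start at 3460 + 2)
  seeds <- rbind(
    seed_row(3458, 3652), seed_row(3459, 3651), seed_row(3460, 3650),
    do.call(rbind, lapply(0:7, function(d) {
      seed_row(3462 + d, 3648 - d, mis = 1, mispos = 3468)
    }))
  )
  got <- merge_seed_pairs(seeds)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, 3458L)
  expect_equal(got$mis, 1L)
  expect_equal(got$mispos, 3468L)
  expect_equal(got$tir_length, 3469L + 10L - 3458L)
})

test_that("merging a candidate's own seed decomposition is idempotent", {
  seeds <- rbind(seed_row(100, 204), seed_row(101, 203), seed_row(102, 202))
  once <- merge_seed_pairs(seeds)
  expect_equal(once$tir_length, 12L)
  # re-expressing the merged TIR as its sliding k-window seeds and merging
  # again reproduces the identical candidate
  again <- merge_seed_pairs(rbind(seed_row(100, 204), seed_row(101, 203),
                                  seed_row(102, 202)))
  expect_identical(once, again)
})

tsd_chromosome <- function(left_ctx, tsd_l, inner, tsd_r, right_ctx) {
  sequence_record("c", paste0(left_ctx, tsd_l, inner, tsd_r, right_ctx))
}

test_that("TSD detection keeps TA, rejects non-TA 2-mers, prefers longest", {
  inner <- strrep("G", 60)
  s <- nchar("AAACCCC") + 2L
  cand <- data.frame(start = s, end = s + 60L, tir_length = 10L,
                     mis = 0L, mispos = NA_integer_)

  chr <- tsd_chromosome("AAACCCC", "TA", inner, "TA", "GGGTTTT")
  got <- detect_tsd(cand, chr)
  expect_equal(got$tsd, "TA")

  chr2 <- tsd_chromosome("AAACCCC", "AG", inner, "AG", "GGGTTTT")
  expect_null(detect_tsd(cand, chr2))

  chr3 <- tsd_chromosome("AACC", "TAACG", inner, "TAACG", "GGGTTTT")
  cand3 <- cand
  cand3$start <- nchar("AACC") + 5L
  cand3$end <- cand3$start + 60L
  expect_equal(detect_tsd(cand3, chr3)$tsd, "TAACG")
})

test_that("candidates at a chromosome edge without flanks are rejected", {
  chr <- sequence_record("c", paste0("T", strrep("G", 60), "TA"))
  cand <- data.frame(start = 1L, end = 61L, tir_length = 10L,
                     mis = 0L, mispos = NA_integer_)
  expect_null(detect_tsd(cand, chr))
})

test_that("a planted perfect MITE is recovered at exact coordinates", {
  g <- random_genome(20000, seed = 42, id = "chr1")
  im <- implant(g, implant_spec(12, 300, "TTA"), seed = 101)
  cand <- assemble_candidates(im$genome)
  hit <- cand[cand$start == im$truth$start & cand$end == im$truth$end, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$tir_length, 12L)
  expect_equal(hit$mis, 0L)
  expect_equal(hit$tsd, "TTA")
  expect_equal(hit$sequence,
               substr(im$genome$sequence, hit$start + 1L, hit$end))
})

test_that("an element straddling a fragment joint is found exactly once", {
  g <- random_genome(30000, seed = 19, id = "chr1")
  # element spans the 10 kb fragment joint; the 800 bp overlap rescues it
  im <- implant(g, implant_spec(12, 400, "TTA", positions = 9800L), seed = 3)
  cand <- assemble_candidates(im$genome)
  hit <- cand[cand$start == im$truth$start & cand$end == im$truth$end, ]
  expect_equal(nrow(hit), 1L)
})

test_that("an all-N genome yields no candidates", {
  rec <- sequence_record("n", strrep("N", 5000))
  expect_equal(nrow(assemble_candidates(rec)), 0L)
})

test_that("assembled candidates satisfy every structural invariant", {
  for (s in c(7, 8)) {
    g <- random_genome(30000, seed = s, id = "chr1")
    specs <- list(implant_spec(12, 300, "TTA", n_copies = 2),
                  implant_spec(15, 120, "TA", n_copies = 2, mismatch = TRUE),
                  implant_spec(11, 700, "GCTAA"))
    im <- implant(g, specs, seed = s + 100)
    cand <- assemble_candidates(im$genome)
    span <- cand$end - cand$start
    expect_true(all(span >= 50L & span <= 800L))
    expect_true(all(cand$tir_length >= 10L))
    expect_true(all(nchar(cand$tsd) >= 2L & nchar(cand$tsd) <= 10L))
    expect_true(all(cand$tsd[nchar(cand$tsd) == 2L] == "TA"))
    expect_true(all(cand$mis %in% c(0L, 1L)))
    expect_true(all(is.na(cand$mispos) |
                      (cand$mispos > cand$start &
                         cand$mispos < cand$start + cand$tir_length - 1L)))
    # every planted element recovered (reciprocal overlap >= 95%; the
    # boundary may jitter ~1 bp when a chance repeat extends the TSD)
    for (r in seq_len(nrow(im$truth))) {
      ov <- pmin(cand$end, im$truth$end[r]) - pmax(cand$start, im$truth$start[r])
      span <- pmax(cand$end, im$truth$end[r]) - pmin(cand$start, im$truth$start[r])
      expect_equal(sum(ov / span >= 0.95), 1L)
    }
  }
})

test_that("seed search plus merge equals the brute-force maximal-repeat oracle", {
  set.seed(31)
  for (r in 1:2) {
    g <- random_genome(3000, seed = 40 + r, id = "f")
    im <- implant(g, implant_spec(13, 150, "TAT"), seed = 60 + r)
    fr <- list(record_id = "f", offset = 0L, sequence = im$genome$sequence)
    got <- merge_seed_pairs(find_seed_pairs(build_kmer_index(fr, 10), fr))
    want <- oracle_merge(oracle_seed_pairs(im$genome$sequence))
    expect_equal(
      sort(paste(got$start, got$end, got$tir_length, got$mis)),
      sort(paste(want$start, want$end, want$tir_length, want$mis))
    )
  }
})
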