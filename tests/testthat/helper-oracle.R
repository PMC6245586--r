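# Independent brute-force oracle for the seed search and merge stages.
# Works directly on character matrices of every k-window, never touching
# the package's hash-index code path.

# Simple-sequence check written independently of is_low_complexity():
# run lengths via rle(), alternation via positional comparison.
oracle_low_complexity <- function(w, run_min = 8L, comp_min = 20) {
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (max(rle(ch)$lengths) >= run_min) return(TRUE)
  # longest alternating XYXY... stretch of two distinct bases
  alt <- rep(1L, n)
  for (t in seq_len(n)) {
    if (t > 2 && ch[t] == ch[t - 2] && ch[t] != ch[t - 1]) {
      alt[t] <- alt[t - 1] + 1L
    } else if (t > 1 && ch[t] != ch[t - 1]) {
      alt[t] <- 2L
    }
  }
  if (max(alt) >= run_min) return(TRUE)
  gc <- mean(ch %in% c("G", "C")) * 100
  if (gc < comp_min || (100 - gc) < comp_min) return(TRUE)
  FALSE
}

# Every (left_start, right_start, mis, mispos) pair of k-windows, found by
# direct positional comparison of each left window's reverse complement
# against every in-range right window.
oracle_seed_pairs <- function(seq, k = 10L, min_len = 50L, max_len = 800L,
                              max_mismatch = 1L) {
  n <- nchar(seq)
  empty <- data.frame(left_start = integer(0), right_start = integer(0),
                      mis = integer(0), mispos = integer(0))
  if (n < k) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  nw <- n - k + 1L
  M <- vapply(1:k, function(off) ch[(1:nw) + off - 1L], character(nw))
  if (nw == 1L) M <- matrix(M, nrow = 1L)
  has_n <- apply(M, 1L, function(r) any(!r %in% c("A", "C", "G", "T")))
  words <- substring(seq, 1:nw, (1:nw) + k - 1L)
  lowc <- vapply(words, oracle_low_complexity, logical(1), USE.NAMES = FALSE)
  usable <- !has_n & !lowc
  compmap <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- vector("list", 0L)
  for (w in which(usable)) {
    i0 <- w - 1L # 0-based left start
    rc_row <- rev(compmap[M[w, ]]) # reverse complement, per position
    j0_lo <- max(i0 + k, i0 + min_len - k)
    j0_hi <- min(nw - 1L, i0 + max_len - k)
    if (j0_lo > j0_hi) next
    js <- (j0_lo:j0_hi) + 1L
    js <- js[usable[js]]
    if (!length(js)) next
    sub <- M[js, , drop = FALSE]
    diffs <- sub != matrix(rc_row, nrow = length(js), ncol = k, byrow = TRUE)
    cnt <- rowSums(diffs)
    hit_perfect <- js[cnt == 0L]
    for (j in hit_perfect) {
      rows[[length(rows) + 1L]] <- data.frame(left_start = i0,
                                              right_start = j - 1L,
                                              mis = 0L, mispos = NA_integer_)
    }
    if (max_mismatch >= 1L) {
      hit_one <- which(cnt == 1L)
      for (hi in hit_one) {
        col <- which(diffs[hi, ])
        if (col == 1L || col == k) next # terminal mismatch excluded
        rows[[length(rows) + 1L]] <- data.frame(
          left_start = i0, right_start = js[hi] - 1L,
          mis = 1L, mispos = i0 + (k - col))
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$left_start, out$right_start), , drop = FALSE]
}

# Walk-based chain merge, written against the chain rules directly:
# start from each unused seed in order and walk forward one seed at a
# time; a step of +1/-1 always links, a step of +2/-2 links only across a
# perfect/imperfect junction, and a step introducing a second distinct
# mismatch position is refused (a 2-mismatch TIR), cutting the chain.
oracle_merge <- function(seeds, k = 10L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      tir_length = integer(0), mis = integer(0),
                      mispos = integer(0))
  if (!nrow(seeds)) return(empty)
  seeds <- seeds[order(seeds$left_start, seeds$right_start), , drop = FALSE]
  key <- paste(seeds$left_start, seeds$right_start)
  lookup <- function(l, r) match(paste(l, r), key)
  used <- rep(FALSE, nrow(seeds))
  rows <- vector("list", 0L)
  for (s in seq_len(nrow(seeds))) {
    if (used[s]) next
    chain <- s
    used[s] <- TRUE
    mp <- seeds$mispos[s]
    repeat {
      cur <- chain[length(chain)]
      nxt <- NA
      for (d in 1:2) {
        cand <- lookup(seeds$left_start[cur] + d, seeds$right_start[cur] - d)
        if (is.na(cand) || used[cand]) next
        if (d == 2L && seeds$mis[cur] + seeds$mis[cand] != 1L) next
        if (!is.na(seeds$mispos[cand]) && !is.na(mp) &&
            seeds$mispos[cand] != mp) next
        nxt <- cand
        break
      }
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
      used[nxt] <- TRUE
      if (is.na(mp)) mp <- seeds$mispos[nxt]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = seeds$left_start[chain[1]],
      end = seeds$right_start[chain[1]] + k,
      tir_length = seeds$left_start[chain[length(chain)]] + k -
        seeds$left_start[chain[1]],
      mis = as.integer(!is.na(mp)),
      mispos = if (!is.na(mp)) mp else NA_integer_)
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# Rank-sum AUC for separating two score vectors.
auc_scores <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
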