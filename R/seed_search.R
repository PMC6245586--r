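#' Reverse complement of a DNA string
#'
#' Base-pairing complement, reversed. `N` maps to `N`.
#'
#' @param seq Character vector of DNA strings over `ACGTN`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GATTACA")
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) {
    stop("sequence contains characters outside ACGTN")
  }
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Vectorised reverse complement through Biostrings; used on large k-mer
# vectors where the character-level version would be slow.
rc_vec <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build the k-mer index of a fragment
#'
#' Indexes every overlapping window of length `k`; windows containing `N`
#' are skipped. The index is the associative map (k-mer text to sorted
#' 0-based start positions) used to retrieve inverted-repeat partners in
#' constant expected time.
#'
#' @param fragment A genome fragment (see [fragment_sequence()]), or any
#'   list with a `sequence` element.
#' @param k Word length in bp (default 10, the minimum TIR length).
#' @return An object of class `kmer_index`: a list with `k`, `positions`
#'   (named list, k-mer to integer vector of 0-based starts) and internal
#'   flat vectors used by [find_seed_pairs()].
#' @export
build_kmer_index <- function(fragment, k = 10L) {
  stopifnot(k >= 2L)
  seq <- fragment$sequence
  n <- nchar(seq)
  if (n < k) {
    return(structure(list(k = as.integer(k), positions = list(),
                          starts = integer(0), kmers = character(0)),
                     class = "kmer_index"))
  }
  starts0 <- 0:(n - k)
  kmers <- substring(seq, starts0 + 1L, starts0 + k)
  valid <- !grepl("[^ACGT]", kmers)
  positions <- split(starts0[valid], kmers[valid])
  structure(
    list(k = as.integer(k), positions = positions,
         starts = as.integer(starts0[valid]), kmers = kmers[valid]),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d indexed positions, %d distinct words\n",
              x$k, length(x$starts), length(x$positions)))
  invisible(x)
}

#' Low-complexity test for TIR sequences
#'
#' A TIR is flagged as low complexity when any of the following holds:
#' a homopolymer run of at least `homopolymer_min` bp, a dinucleotide
#' (alternating two-base) stretch of at least `homopolymer_min` bp, G+C
#' content below `composition_min_pct` percent, or A+T content below
#' `composition_min_pct` percent. Such repeats arise from simple-sequence
#' DNA rather than transposition and are dropped at the seed stage.
#'
#' @param tir Character vector of TIR sequences.
#' @param homopolymer_min Minimum run length (bp) that trips the
#'   homopolymer/dinucleotide arm (default 8).
#' @param composition_min_pct Minimum percentage of G+C (and of A+T)
#'   required to pass the composition arm (default 20); strictly lower
#'   content is flagged.
#' @return Logical vector, `TRUE` where the TIR is low complexity.
#' @examples
#' is_low_complexity(c("AAAAAAAAGT", "GATATATATC", "ACGTTGCAAC"))
#' @export
is_low_complexity <- function(tir, homopolymer_min = 8L, composition_min_pct = 20) {
  m <- as.integer(homopolymer_min)
  homo_pat <- paste(sprintf("%s{%d,}", c("A", "C", "G", "T"), m), collapse = "|")
  pairs <- c("AC", "AG", "AT", "CA", "CG", "CT",
             "GA", "GC", "GT", "TA", "TC", "TG")
  di_pat <- paste(vapply(pairs, function(p) {
    substr(strrep(p, ceiling(m / 2) + 1L), 1L, m)
  }, character(1)), collapse = "|")
  n <- nchar(tir)
  gc <- nchar(gsub("[^GC]", "", tir)) / n * 100
  at <- nchar(gsub("[^AT]", "", tir)) / n * 100
  grepl(homo_pat, tir) | grepl(di_pat, tir) |
    gc < composition_min_pct | at < composition_min_pct
}

#' Enumerate inverted-repeat seed pairs in a fragment
#'
#' Finds every pair of k-mer windows (left at `left_start`, right at
#' `right_start`, both 0-based fragment-relative) such that the right
#' window equals the reverse complement of the left window either exactly
#' (`mis = 0`) or at all but one interior position (`mis = 1`, with
#' `mispos` the 0-based fragment position of the mismatched base on the
#' left window). Terminal mismatches are excluded. Pairs whose element
#' span `right_start + k - left_start` falls outside
#' `[min_length, max_length]`, whose windows overlap
#' (`right_start < left_start + k`), or whose left or right window is low
#' complexity (see [is_low_complexity()]) are dropped.
#'
#' @param index A `kmer_index` built from `fragment` with the same `k`.
#' @param fragment The fragment the index was built from.
#' @param min_length,max_length Retained element span in bp
#'   (defaults 50 and 800).
#' @param max_mismatch 0 for perfect seeds only, 1 (default) to also
#'   report single-interior-mismatch seeds.
#' @param homopolymer_min,composition_min_pct Passed to
#'   [is_low_complexity()].
#' @return A data.frame with columns `left_start`, `right_start`,
#'   `tir_length` (= k), `mis`, `mispos`, ordered by
#'   (`left_start`, `right_start`).
#' @export
find_seed_pairs <- function(index, fragment, min_length = 50L, max_length = 800L,
                            max_mismatch = 1L, homopolymer_min = 8L,
                            composition_min_pct = 20) {
  k <- index$k
  empty <- data.frame(left_start = integer(0), right_start = integer(0),
                      tir_length = integer(0), mis = integer(0),
                      mispos = integer(0))
  if (!length(index$starts)) return(empty)

  ok <- !is_low_complexity(index$kmers, homopolymer_min, composition_min_pct)
  if (!any(ok)) return(empty)
  starts <- index$starts[ok]
  kmers <- index$kmers[ok]
  rc <- rc_vec(kmers)

  rights <- data.table::data.table(word = kmers, rs = starts)
  lefts <- list(data.table::data.table(word = rc, ls = starts,
                                       mis = 0L, mispos = NA_integer_))
  if (max_mismatch >= 1L) {
    # All interior single-substitution variants of the reverse complement:
    # position q (1-based) of the right window corresponds to position
    # k - q (0-based) on the left window, so q in 2..(k-1) keeps the
    # mismatch interior on both windows.
    for (q in 2:(k - 1L)) {
      cur <- substr(rc, q, q)
      head_ <- substr(rc, 1L, q - 1L)
      tail_ <- substr(rc, q + 1L, k)
      for (b in c("A", "C", "G", "T")) {
        sel <- cur != b
        if (!any(sel)) next
        lefts[[length(lefts) + 1L]] <- data.table::data.table(
          word = paste0(head_[sel], b, tail_[sel]),
          ls = starts[sel], mis = 1L,
          mispos = starts[sel] + (k - q)
        )
      }
    }
  }
  lefts <- data.table::rbindlist(lefts)
  hits <- rights[lefts, on = "word", allow.cartesian = TRUE, nomatch = NULL]
  keep <- hits$rs >= hits$ls + k
  hits <- hits[keep, ]
  span <- hits$rs + k - hits$ls
  hits <- hits[span >= min_length & span <= max_length, ]
  hits <- hits[order(hits$ls, hits$rs), ]
  data.frame(left_start = hits$ls, right_start = hits$rs,
             tir_length = rep.int(as.integer(k), nrow(hits)),
             mis = hits$mis, mispos = hits$mispos)
}
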