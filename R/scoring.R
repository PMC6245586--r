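#' Train the 6-mer log-ratio scoring model
#'
#' For every word `s` of length `word_length` the model stores
#' `F(s) = log2( Pr(s | M) / Pr(s | N) )`, where `M` is the positive
#' (true-MITE) training set and `N` the null (structural false positive)
#' set. Word probabilities are estimated from overlapping word counts with
#' add-`pseudocount` smoothing,
#' `Pr(s | M) = (count_M(s) + c) / (total_M + c * 4^w)`,
#' which keeps every `F(s)` finite even for words absent from one set.
#'
#' @param positive,null Character vectors of DNA sequences (each at least
#'   `word_length` bp) for the positive and null sets.
#' @param word_length Word size in bp (default 6).
#' @param pseudocount Smoothing constant added to every word count
#'   (default 1).
#' @return An object of class `log_ratio_model` with elements
#'   `word_length`, `pseudocount`, `log_ratios` (named numeric over all
#'   `4^word_length` words), `positive_total`, `null_total` (smoothed
#'   totals).
#' @export
train_model <- function(positive, null, word_length = 6L, pseudocount = 1) {
  for (set in list(positive, null)) {
    if (!length(set)) stop("training set is empty")
    if (any(nchar(set) < word_length)) {
      stop("every training sequence must be at least word_length bp")
    }
  }
  count_words <- function(seqs) {
    colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(seqs), width = word_length))
  }
  cm <- count_words(positive)
  cn <- count_words(null)
  nwords <- 4^word_length
  tot_m <- sum(cm) + pseudocount * nwords
  tot_n <- sum(cn) + pseudocount * nwords
  f <- log2((cm + pseudocount) / tot_m) - log2((cn + pseudocount) / tot_n)
  structure(
    list(word_length = as.integer(word_length), pseudocount = pseudocount,
         log_ratios = f, positive_total = tot_m, null_total = tot_n),
    class = "log_ratio_model"
  )
}

#' @export
print.log_ratio_model <- function(x, ...) {
  cat(sprintf("<log_ratio_model> %d-mer, %d words, pseudocount %g\n",
              x$word_length, length(x$log_ratios), x$pseudocount))
  cat(sprintf("  F(s) range: [%.3f, %.3f]\n",
              min(x$log_ratios), max(x$log_ratios)))
  invisible(x)
}

#' Score a sequence under a log-ratio model
#'
#' The score of a sequence of length `n` is the mean of `F` over its
#' `n - w + 1` overlapping words, which normalizes away the length of the
#' candidate. Windows containing `N` carry no evidence: they contribute 0
#' and are excluded from the divisor. A sequence with no scorable window
#' scores 0.
#'
#' @param model A `log_ratio_model`.
#' @param seq A single DNA string of length at least `model$word_length`.
#' @return The mean log2 likelihood ratio per word (a real number).
#' @export
score_sequence <- function(model, seq) {
  w <- model$word_length
  n <- nchar(seq)
  if (n < w) stop("sequence shorter than model word length")
  words <- substring(seq, 1:(n - w + 1L), w:n)
  ok <- !grepl("[^ACGT]", words)
  if (!any(ok)) return(0)
  sum(model$log_ratios[words[ok]]) / sum(ok)
}

#' Score candidates and drop low-scoring ones
#'
#' Sets each candidate's `score` (see [score_sequence()], applied to the
#' full element sequence, TIRs included) and retains only candidates whose
#' score is strictly greater than `threshold`. Order is preserved.
#'
#' @param candidates Candidate table with a `sequence` column.
#' @param model A `log_ratio_model`.
#' @param threshold Retention threshold (default 0); `-Inf` keeps all
#'   candidates while still annotating scores.
#' @return The filtered candidate table with a `score` column.
#' @export
filter_by_score <- function(candidates, model, threshold = 0) {
  if (!nrow(candidates)) {
    candidates$score <- numeric(0)
    return(candidates)
  }
  candidates$score <- vapply(candidates$sequence,
                             function(s) score_sequence(model, s),
                             numeric(1), USE.NAMES = FALSE)
  candidates[candidates$score > threshold, , drop = FALSE]
}

#' Write a log-ratio model to a plain-text file
#'
#' Format: header lines `#word_length<TAB>w` and `#pseudocount<TAB>c`,
#' then one `WORD<TAB>F` line per word in lexicographic order, `F` printed
#' with six decimals. A file read with [read_model()] and written back is
#' byte-identical.
#'
#' @param model A `log_ratio_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  words <- sort(names(model$log_ratios))
  lines <- c(
    sprintf("#word_length\t%d", model$word_length),
    sprintf("#pseudocount\t%g", model$pseudocount),
    sprintf("%s\t%.6f", words, model$log_ratios[words])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a log-ratio model written by [write_model()]
#'
#' @param path Model file path.
#' @return A `log_ratio_model` (totals are not stored in the file and are
#'   `NA` on a loaded model; scoring does not need them).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(ln) != 1L) stop("model file missing header: ", key)
    strsplit(ln, "\t", fixed = TRUE)[[1]][2]
  }
  w <- as.integer(get_hdr("word_length"))
  pc <- as.numeric(get_hdr("pseudocount"))
  parts <- strsplit(body, "\t", fixed = TRUE)
  f <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  names(f) <- vapply(parts, `[`, character(1), 1L)
  if (length(f) != 4^w) {
    stop("model file has ", length(f), " words, expected ", 4^w)
  }
  structure(
    list(word_length = w, pseudocount = pc, log_ratios = f,
         positive_total = NA_real_, null_total = NA_real_),
    class = "log_ratio_model"
  )
}
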