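#' Generate a seeded random chromosome
#'
#' Bases are drawn i.i.d. with the requested GC fraction (G and C
#' equiprobable, likewise A and T). The same seed always yields the same
#' sequence.
#'
#' @param length Chromosome length in bp (positive).
#' @param gc_fraction Target G+C fraction (default 0.5).
#' @param seed Optional integer seed.
#' @param id Record identifier (default `"synth_1"`).
#' @return A `sequence_record`.
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed = NULL, id = "synth_1") {
  if (length <= 0) stop("length must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  sequence_record(id = id, sequence = paste(bases, collapse = ""),
                  description = "synthetic")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Specification of a MITE implant
#'
#' Describes one family of elements to implant into a synthetic genome:
#' the structural parameters (TIR length, total element length, TSD), the
#' copy number, whether each copy carries a single interior TIR mismatch,
#' and the per-copy decay rate (substitutions per bp applied to the
#' internal region only, so the structural signals stay intact).
#'
#' @param tir_length TIR length in bp (>= 10 for a detectable element;
#'   smaller values are allowed to build negative controls).
#' @param total_length Element length in bp, left TIR start through right
#'   TIR end (TSD excluded).
#' @param tsd TSD text (length 2-10; a 2 bp TSD should be `"TA"` to
#'   survive validation).
#' @param n_copies Number of copies to implant (default 1).
#' @param mismatch Logical, recycled per copy: apply one interior TIR
#'   mismatch to that copy (default `FALSE`).
#' @param decay Substitutions per bp applied to each copy's internal
#'   region (default 0).
#' @param positions Optional vector of 0-based insertion points on the
#'   original genome; `NULL` (default) places copies at random,
#'   non-overlapping, at least 900 bp apart.
#' @param carry_flank If positive, a shared flanking context of this many
#'   bp is generated once and inserted around every copy, emulating
#'   segmental duplication of the element together with its neighborhood
#'   (the false-positive mode the flank filter removes). Default 0:
#'   copies land in unrelated background, as transposition does.
#' @param family Label recorded in the truth table.
#' @return A list of class `implant_spec`.
#' @export
implant_spec <- function(tir_length, total_length, tsd, n_copies = 1L,
                         mismatch = FALSE, decay = 0, positions = NULL,
                         carry_flank = 0L, family = "fam1") {
  if (total_length < 2L * tir_length) {
    stop("total_length too small to hold two TIRs of ", tir_length, " bp")
  }
  structure(
    list(tir_length = as.integer(tir_length),
         total_length = as.integer(total_length),
         tsd = tsd, n_copies = as.integer(n_copies),
         mismatch = rep_len(mismatch, n_copies),
         decay = decay, positions = positions,
         carry_flank = as.integer(carry_flank), family = family),
    class = "implant_spec"
  )
}

#' Build one MITE element from an implant specification
#'
#' Assembles `tsd + left_tir + internal + reverse_complement(left_tir) +
#' tsd`. The TIR is redrawn until it (and each of its 10 bp windows)
#' passes the low-complexity filter, so the element is detectable by
#' construction. When `mismatch` is requested, exactly one interior base
#' of the right TIR is substituted.
#'
#' @param spec An [implant_spec()].
#' @param seed Optional integer seed.
#' @param mismatch Override of the spec's per-copy mismatch flag (single
#'   logical).
#' @return A list with `sequence` (TSD-flanked insert), `element` (the
#'   TSD-free element), `tir` (left TIR), `mispos_rel` (0-based mismatch
#'   position relative to element start, or `NA`), and `tsd`.
#' @export
make_mite <- function(spec, seed = NULL, mismatch = spec$mismatch[1]) {
  if (!is.null(seed)) set.seed(seed)
  tl <- spec$tir_length
  tir <- draw_clean_tir(tl)
  internal <- if (spec$total_length > 2L * tl) {
    guard_internal(random_dna(spec$total_length - 2L * tl))
  } else ""
  right <- reverse_complement(tir)
  mispos_rel <- NA_integer_
  if (isTRUE(mismatch)) {
    # interior position of the LEFT TIR (0-based), mirrored onto the right
    p <- sample(1:(tl - 2L), 1L)
    q <- tl - 1L - p
    old <- substr(right, q + 1L, q + 1L)
    substr(right, q + 1L, q + 1L) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    mispos_rel <- p
  }
  element <- paste0(tir, internal, right)
  list(sequence = paste0(spec$tsd, element, spec$tsd),
       element = element, tir = tir,
       mispos_rel = mispos_rel, tsd = spec$tsd)
}

# Make the element's maximal inverted repeat equal its TIR: force the two
# innermost base pairs of the internal region to be non-complementary, so
# the inverted repeat cannot extend inward past the TIR (any window going
# deeper would carry two mismatches). Without this guard a planted
# "TIR 9" element can truly hold a 10 bp repeat and the truth table would
# misstate the structure it describes.
guard_internal <- function(internal) {
  n <- nchar(internal)
  if (n < 2L) return(internal)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (off in 0:1) {
    lpos <- 1L + off
    rpos <- n - off
    if (lpos >= rpos) break
    while (substr(internal, lpos, lpos) ==
             comp[[substr(internal, rpos, rpos)]]) {
      substr(internal, lpos, lpos) <- sample(c("A", "C", "G", "T"), 1L)
    }
  }
  internal
}

# Draw a TIR none of whose 10 bp windows is low complexity (nor the TIR
# itself), so seed-stage filtering cannot remove a deliberate implant.
draw_clean_tir <- function(tl, k = 10L) {
  for (try in 1:200) {
    tir <- random_dna(tl)
    win <- if (tl >= k) substring(tir, 1:(tl - k + 1L), k:tl) else tir
    if (!any(is_low_complexity(c(tir, win)))) return(tir)
  }
  stop("could not draw a high-complexity TIR of length ", tl)
}

#' Implant MITEs into a genome with a truth table
#'
#' Inserts every copy of every spec at non-overlapping positions at least
#' 900 bp apart (unless a spec pins positions), so fragment-overlap and
#' flank logic are exercised cleanly. Decayed copies of one spec share a
#' family element whose internal region is independently mutated per
#' copy.
#'
#' @param genome A `sequence_record`.
#' @param specs A list of [implant_spec()] objects (or a single one).
#' @param seed Optional integer seed.
#' @return A list with `genome` (the mutated `sequence_record`) and
#'   `truth`: a data.frame with `record_id`, `start`, `end` (0-based
#'   half-open element coordinates on the mutated genome), `tir_length`,
#'   `tsd`, `family`, `mismatch`.
#' @export
implant <- function(genome, specs, seed = NULL) {
  if (inherits(specs, "implant_spec")) specs <- list(specs)
  if (!is.null(seed)) set.seed(seed)
  empty_truth <- data.frame(record_id = character(0), start = integer(0),
                            end = integer(0), tir_length = integer(0),
                            tsd = character(0), family = character(0),
                            mismatch = logical(0))
  if (!length(specs)) return(list(genome = genome, truth = empty_truth))

  # one insert per copy, in spec order
  inserts <- list()
  for (sp in specs) {
    base <- make_mite(sp, mismatch = FALSE)
    cf <- if (is.null(sp$carry_flank)) 0L else sp$carry_flank
    fl <- if (cf > 0L) random_dna(cf) else ""
    fr <- if (cf > 0L) random_dna(cf) else ""
    for (cp in seq_len(sp$n_copies)) {
      el <- base$element
      if (isTRUE(sp$mismatch[cp])) {
        tl <- sp$tir_length
        p <- sample(1:(tl - 2L), 1L)
        q <- nchar(el) - tl + (tl - 1L - p)
        old <- substr(el, q + 1L, q + 1L)
        substr(el, q + 1L, q + 1L) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      if (sp$decay > 0 && sp$total_length > 2L * sp$tir_length) {
        el <- decay_internal(el, sp$tir_length, sp$decay)
      }
      inserts[[length(inserts) + 1L]] <- list(
        text = paste0(fl, sp$tsd, el, sp$tsd, fr), tsd = sp$tsd,
        lead = cf + nchar(sp$tsd), el_len = nchar(el),
        tir_length = sp$tir_length, family = sp$family,
        mismatch = isTRUE(sp$mismatch[cp]),
        position = if (!is.null(sp$positions)) sp$positions[cp] else NA_integer_
      )
    }
  }

  len <- nchar(genome$sequence)
  fixed <- vapply(inserts, function(x) as.integer(x$position), integer(1))
  need <- sum(is.na(fixed))
  pos <- fixed
  if (need > 0L) {
    placed <- FALSE
    for (try in 1:1000) {
      cand <- sort(sample(1000:(len - 1000L), need))
      all_pos <- sort(c(cand, fixed[!is.na(fixed)]))
      if (length(all_pos) == 1L || all(diff(all_pos) >= 900L)) {
        pos[is.na(fixed)] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("cannot place implants >= 900 bp apart; genome too small")
  }
  ord <- order(pos)
  inserts <- inserts[ord]
  pos <- pos[ord]
  if (any(diff(pos) < 900L)) stop("pinned implant positions closer than 900 bp")

  pieces <- character(2L * length(pos) + 1L)
  truth <- vector("list", length(pos))
  prev <- 0L
  shift <- 0L
  for (t in seq_along(pos)) {
    pieces[2L * t - 1L] <- substr(genome$sequence, prev + 1L, pos[t])
    pieces[2L * t] <- inserts[[t]]$text
    el_len <- inserts[[t]]$el_len
    start <- pos[t] + shift + inserts[[t]]$lead
    truth[[t]] <- data.frame(
      record_id = genome$id, start = start, end = start + el_len,
      tir_length = inserts[[t]]$tir_length, tsd = inserts[[t]]$tsd,
      family = inserts[[t]]$family, mismatch = inserts[[t]]$mismatch
    )
    shift <- shift + nchar(inserts[[t]]$text)
    prev <- pos[t]
  }
  pieces[2L * length(pos) + 1L] <- substr(genome$sequence, prev + 1L, len)
  mutated <- sequence_record(id = genome$id,
                             sequence = paste(pieces, collapse = ""),
                             description = genome$description)
  list(genome = mutated, truth = do.call(rbind, truth))
}

# Substitute internal bases at the given per-bp rate; TIRs, TSD and the
# two guarded innermost internal pairs are never touched so each
# structural filter can be tested in isolation.
decay_internal <- function(element, tir_length, rate) {
  n <- nchar(element)
  inner <- (tir_length + 3L):(n - tir_length - 2L)
  if (length(inner) == 0L || inner[1] > inner[length(inner)]) return(element)
  hit <- inner[stats::runif(length(inner)) < rate]
  for (pidx in hit) {
    old <- substr(element, pidx, pidx)
    substr(element, pidx, pidx) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  }
  element
}

#' Generate motif-enriched positive and uniform null training sets
#'
#' Positive sequences carry a 6-mer motif at `enrichment` times its
#' uniform per-window probability (`enrichment / 4096` per window,
#' occurrences placed without overlap); null sequences are uniform random
#' DNA. With the default enrichment of 100 a 200 bp positive sequence
#' carries about five motif copies, a realistic density for a conserved
#' family motif.
#'
#' @param n_pos,n_neg Number of sequences per set.
#' @param motif The 6-mer to enrich.
#' @param enrichment Fold enrichment over the uniform expectation
#'   (>= 1; default 100).
#' @param length Sequence length in bp (default 200).
#' @param seed Optional integer seed.
#' @return A list with `positive` and `null` character vectors.
#' @export
make_training_sets <- function(n_pos, n_neg, motif, enrichment = 100,
                               length = 200L, seed = NULL) {
  stopifnot(enrichment >= 1, nchar(motif) == 6L)
  if (!is.null(seed)) set.seed(seed)
  nwin <- length - nchar(motif) + 1L
  p_win <- enrichment / 4^nchar(motif)
  one_pos <- function() {
    s <- random_dna(length)
    n_occ <- stats::rbinom(1L, nwin, p_win)
    if (n_occ > 0L) {
      slots <- seq(1L, nwin, by = nchar(motif))
      for (at in sample(slots, min(n_occ, length(slots)))) {
        substr(s, at, at + nchar(motif) - 1L) <- motif
      }
    }
    s
  }
  list(positive = vapply(seq_len(n_pos), function(i) one_pos(), character(1)),
       null = vapply(seq_len(n_neg), function(i) random_dna(length), character(1)))
}
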