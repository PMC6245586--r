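#' Merge adjacent seed pairs into maximal TIR candidates
#'
#' Seeds whose left starts step by +1 while right starts step by -1 lie on
#' one diagonal (constant `left_start + right_start`) and describe the same
#' TIR read through a sliding k-window; a maximal run of such seeds
#' collapses into one candidate whose TIR length grows by one per extra
#' seed. A gap of 2 in left starts is bridged when it joins a perfect run
#' to a single-mismatch run (the two windows flanking a mismatched base are
#' excluded because the mismatch would sit on a window edge), producing a
#' merged candidate with `mis = 1`. A merge that would combine two
#' distinct mismatch positions would describe a 2-mismatch TIR and is
#' refused: the chain is cut there and the incoming seed opens a new
#' chain. Unmergeable seeds pass through unchanged.
#'
#' @param seeds Seed table from [find_seed_pairs()] (one fragment,
#'   deterministic order).
#' @return A data.frame of candidates with columns `start` (0-based left
#'   TIR start), `end` (0-based exclusive right TIR end), `tir_length`,
#'   `mis`, `mispos`, sorted by (`start`, `end`).
#' @export
merge_seed_pairs <- function(seeds) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      tir_length = integer(0), mis = integer(0),
                      mispos = integer(0))
  if (!nrow(seeds)) return(empty)
  k <- seeds$tir_length[1]
  diag <- seeds$left_start + seeds$right_start
  out <- vector("list", 0L)
  for (d in unique(diag)) {
    g <- seeds[diag == d, , drop = FALSE]
    g <- g[order(g$left_start), , drop = FALSE]
    m <- nrow(g)
    chain_id <- integer(m)
    chain_id[1] <- 1L
    chain_mispos <- g$mispos[1]
    for (t in seq_len(m - 1L) + 1L) {
      dl <- g$left_start[t] - g$left_start[t - 1L]
      linked <- dl == 1L ||
        (dl == 2L && (g$mis[t] + g$mis[t - 1L]) == 1L)
      # refuse a merge that would need two distinct mismatch positions
      if (linked && !is.na(g$mispos[t]) && !is.na(chain_mispos) &&
          g$mispos[t] != chain_mispos) {
        linked <- FALSE
      }
      if (linked) {
        chain_id[t] <- chain_id[t - 1L]
        if (is.na(chain_mispos)) chain_mispos <- g$mispos[t]
      } else {
        chain_id[t] <- chain_id[t - 1L] + 1L
        chain_mispos <- g$mispos[t]
      }
    }
    for (cid in unique(chain_id)) {
      ch <- g[chain_id == cid, , drop = FALSE]
      mp <- unique(ch$mispos[!is.na(ch$mispos)])
      out[[length(out) + 1L]] <- data.frame(
        start = ch$left_start[1],
        end = ch$right_start[1] + k,
        tir_length = ch$left_start[nrow(ch)] + k - ch$left_start[1],
        mis = as.integer(length(mp) > 0L),
        mispos = if (length(mp)) mp else NA_integer_
      )
    }
  }
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Validate a candidate's target-site duplication
#'
#' On insertion a MITE duplicates its target site, leaving an identical
#' direct repeat of 2-10 bp immediately on both sides of the element. For
#' lengths 10 down to 2 the bases just left of `start` are compared with
#' the bases just right of `end`; the longest exact `ACGT`-only match is
#' recorded as the TSD. Candidates with no match, or whose only match has
#' length 2 and is not `"TA"`, are rejected (`NULL`).
#'
#' @param candidate One-row candidate data.frame with 0-based half-open
#'   `start`/`end` absolute on the chromosome.
#' @param chromosome A `sequence_record`.
#' @return The candidate row with a `tsd` column added, or `NULL` when
#'   rejected.
#' @export
detect_tsd <- function(candidate, chromosome) {
  seq <- chromosome$sequence
  len <- nchar(seq)
  s <- candidate$start
  e <- candidate$end
  for (L in 10:2) {
    if (s - L < 0L || e + L > len) next
    left <- substr(seq, s - L + 1L, s)
    right <- substr(seq, e + 1L, e + L)
    if (left == right && !grepl("[^ACGT]", left)) {
      if (L == 2L && left != "TA") return(NULL)
      candidate$tsd <- left
      return(candidate)
    }
  }
  NULL
}

#' Detect MITE candidates on one chromosome
#'
#' Runs fragmentation, k-mer indexing, seed search with the low-complexity
#' filter, seed merging and TSD validation over a whole chromosome.
#' Fragment-relative coordinates are lifted to absolute chromosome
#' coordinates; candidates discovered in two overlapping fragments are
#' deduplicated by exact coordinate identity, and candidates nested inside
#' a longer candidate sharing the same right TIR end are suppressed in
#' favor of the maximal chain.
#'
#' @param record A `sequence_record`.
#' @param config A [pipeline_config()] list.
#' @return A data.frame of structurally validated candidates with columns
#'   `record_id`, `start`, `end` (0-based half-open), `tir_length`, `mis`,
#'   `mispos`, `tsd`, `sequence` (the element), sorted by
#'   (`start`, `end`).
#' @export
assemble_candidates <- function(record, config = pipeline_config()) {
  frags <- fragment_sequence(record, config$fragment_length, config$overlap)
  pieces <- lapply(frags, function(fr) {
    idx <- build_kmer_index(fr, config$k)
    seeds <- find_seed_pairs(idx, fr,
                             min_length = config$min_length,
                             max_length = config$max_length,
                             max_mismatch = config$max_mismatch,
                             homopolymer_min = config$homopolymer_min,
                             composition_min_pct = config$composition_min_pct)
    cand <- merge_seed_pairs(seeds)
    if (nrow(cand)) {
      cand$start <- cand$start + fr$offset
      cand$end <- cand$end + fr$offset
      cand$mispos <- cand$mispos + fr$offset
    }
    cand
  })
  cand <- do.call(rbind, pieces)
  if (is.null(cand) || !nrow(cand)) {
    return(empty_candidates())
  }
  cand <- cand[!duplicated(cand[, c("start", "end", "tir_length")]), , drop = FALSE]
  cand <- cand[cand$tir_length >= config$min_tir, , drop = FALSE]
  # same right TIR end: keep the maximal chain only
  cand <- cand[order(cand$end, -cand$tir_length, cand$start), , drop = FALSE]
  cand <- cand[!duplicated(cand$end), , drop = FALSE]

  kept <- vector("list", 0L)
  for (r in seq_len(nrow(cand))) {
    v <- validate_tsd_trimmed(cand[r, , drop = FALSE], record,
                              config$min_tir, config$min_length,
                              config$max_length, config$k)
    if (!is.null(v)) kept[[length(kept) + 1L]] <- v
  }
  if (!length(kept)) return(empty_candidates())
  out <- do.call(rbind, kept)
  # chains clipped differently by fragment edges can trim to the same
  # final element: dedup again on validated coordinates, keeping the
  # longest-TIR reading
  out <- out[order(out$start, out$end, -out$tir_length, out$mis), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out$record_id <- record$id
  out$sequence <- substring(record$sequence, out$start + 1L, out$end)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("record_id", "start", "end", "tir_length", "mis", "mispos",
          "tsd", "sequence")]
}

# TSD validation over symmetric trims of a maximal inverted repeat.
#
# When the two ends of a TSD are reverse-complementary (the Stowaway
# "TA" is the canonical case) the inverted repeat provably extends into
# the TSD itself, and chance or 1-mismatch seeds can push it further, so
# the maximal seed chain may overshoot the element and the TSD no longer
# flanks it. Symmetric trims d = 0, 1, ... of the maximal repeat are
# therefore tested outside-in (largest TIR first, subject to the trimmed
# TIR staying >= min_tir and the span >= min_length) and the first trim
# with a valid TSD is taken -- except that a boundary overshot by one
# base always sees an exact direct repeat made of the TSD's interior
# (its length minus 2), so after a hit the next trim is peeked at: when
# it shows exactly that signature (a valid TSD two bases longer whose
# interior equals the current one) the boundary hops one base inward,
# repeatedly. A mismatch position trimmed out of the TIR reverts the
# candidate to perfect.
validate_tsd_trimmed <- function(candidate, record, min_tir, min_length,
                                 max_length = 800L, k = 10L) {
  dmax <- candidate$tir_length - min_tir
  trim <- function(d) {
    trial <- candidate
    trial$start <- candidate$start + d
    trial$end <- candidate$end - d
    trial$tir_length <- candidate$tir_length - d
    span <- trial$end - trial$start
    if (span < min_length || span > max_length || trial$tir_length < min_tir) {
      return(NULL)
    }
    if (!is.na(trial$mispos) && trial$mispos < trial$start) {
      trial$mis <- 0L
      trial$mispos <- NA_integer_
    }
    detect_tsd(trial, record)
  }
  # A TIR mismatch at window offset k-1 makes the outermost seed window
  # terminal-excluded, so the chain starts one base inside the element;
  # that configuration is recognizable (observed mismatch at chain-TIR
  # offset k-2) and earns one outward extension trial.
  dmin <- if (candidate$mis == 1L &&
                !is.na(candidate$mispos) &&
                candidate$mispos - candidate$start == k - 2L) -1L else 0L
  scan <- function(perfect_only) {
    for (d in dmin:dmax) {
      v <- trim(d)
      if (is.null(v) || (perfect_only && v$mis == 1L)) next
      while (d < dmax) {
        v2 <- trim(d + 1L)
        if (is.null(v2) || nchar(v2$tsd) != nchar(v$tsd) + 2L ||
            substr(v2$tsd, 2L, nchar(v2$tsd) - 1L) != v$tsd) {
          break
        }
        v <- v2
        d <- d + 1L
      }
      return(v)
    }
    NULL
  }
  # Prefer readings that need no mismatch: a chance 1-mismatch window
  # absorbing flanking sequence extends the chain of a perfect element
  # outward, and in repeat-rich flanks the overshot boundary can present
  # a valid chance TSD; the true reading is the one where the trimmed
  # TIR is again perfect.
  if (candidate$mis == 1L) {
    v <- scan(perfect_only = TRUE)
    if (!is.null(v)) return(v)
  }
  scan(perfect_only = FALSE)
}

empty_candidates <- function() {
  data.frame(record_id = character(0), start = integer(0), end = integer(0),
             tir_length = integer(0), mis = integer(0), mispos = integer(0),
             tsd = character(0), sequence = character(0))
}
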