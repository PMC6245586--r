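#' Extract an element together with its genomic flanks
#'
#' Returns `flank_left + element + flank_right`, where each flank is up to
#' `flank` bp of chromosome sequence immediately outside the element
#' (truncated at chromosome edges). Flank similarity between two
#' candidates indicates segmental duplication rather than transposition,
#' which is what the downstream filter tests.
#'
#' @param candidate One-row candidate data.frame (0-based half-open
#'   `start`/`end`).
#' @param chromosome A `sequence_record`.
#' @param flank Flank length in bp (default 60).
#' @return A list with `sequence` (the flanked string), `flank_left`,
#'   `flank_right`, and `element_bounds` (0-based half-open position of
#'   the element within the flanked string).
#' @export
extract_with_flanks <- function(candidate, chromosome, flank = 60L) {
  seq <- chromosome$sequence
  len <- nchar(seq)
  s <- candidate$start
  e <- candidate$end
  fl <- substr(seq, max(1L, s - flank + 1L), s)
  fr <- substr(seq, e + 1L, min(len, e + flank))
  list(
    sequence = paste0(fl, substr(seq, s + 1L, e), fr),
    flank_left = fl,
    flank_right = fr,
    element_bounds = c(nchar(fl), nchar(fl) + (e - s))
  )
}

# Shared local-alignment core: match +1, mismatch -1, gap open -2,
# gap extend -1; N mismatches everything including N.
local_alignment <- function(a, b) {
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
  diag(mat) <- 1
  mat["N", "N"] <- -1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  columns <- length(pa)
  matches <- sum(pa == pb & pa != "-")
  list(
    identity_pct = if (columns) 100 * matches / columns else 0,
    align_length = columns,
    q_start = Biostrings::start(Biostrings::pattern(aln)),
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    s_start = Biostrings::start(Biostrings::subject(aln)),
    s_end = Biostrings::end(Biostrings::subject(aln))
  )
}

#' Best local-alignment similarity between two flanked candidates
#'
#' Computes the best local alignment (match +1, mismatch -1, gap open -2,
#' gap extend -1; identity = matches / alignment columns) between two
#' flanked candidate sequences. Alignments shorter than `min_len` aligned
#' columns or below `min_pident` percent identity fall under the reporting
#' floor and return `NULL`. When element bounds are supplied the hit
#' records whether the alignment extends into either 60 bp flank on either
#' sequence (`covers_flank`).
#'
#' @param a,b DNA strings (flanked candidate sequences).
#' @param bounds_a,bounds_b Optional 0-based half-open element intervals
#'   within `a` and `b` (see [extract_with_flanks()]).
#' @param min_len Minimum aligned columns to report (default 30).
#' @param min_pident Minimum percent identity to report (default 80).
#' @param slop Tolerated extension (bp) of the alignment beyond the
#'   element before it counts as covering the flank (default 15). Two
#'   copies of one family share their TSD (up to 10 bp) and the odd
#'   chance base immediately outside the element, so only extension past
#'   this margin is evidence of co-duplicated context.
#' @return A list (`identity_pct`, `align_length`, `covers_flank`,
#'   `q_start`, `q_end`, `s_start`, `s_end`; alignment coordinates
#'   1-based) or `NULL` below the reporting floor.
#' @export
pairwise_similarity <- function(a, b, bounds_a = NULL, bounds_b = NULL,
                                min_len = 30L, min_pident = 80, slop = 15L) {
  hit <- local_alignment(a, b)
  if (hit$align_length < min_len || hit$identity_pct < min_pident) {
    return(NULL)
  }
  covers <- FALSE
  if (!is.null(bounds_a)) {
    covers <- covers || hit$q_start - 1L < bounds_a[1] - slop ||
      hit$q_end > bounds_a[2] + slop
  }
  if (!is.null(bounds_b)) {
    covers <- covers || hit$s_start - 1L < bounds_b[1] - slop ||
      hit$s_end > bounds_b[2] + slop
  }
  hit$covers_flank <- covers
  hit
}

# All-by-all hits over a list of flanked candidates. Returns one row per
# unordered pair that reaches the reporting floor.
all_pairwise_hits <- function(flanked, min_len = 30L, min_pident = 80) {
  n <- length(flanked)
  rows <- vector("list", 0L)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        hit <- pairwise_similarity(flanked[[i]]$sequence, flanked[[j]]$sequence,
                                   flanked[[i]]$element_bounds,
                                   flanked[[j]]$element_bounds,
                                   min_len = min_len, min_pident = min_pident)
        if (!is.null(hit)) {
          rows[[length(rows) + 1L]] <- data.frame(
            query = i, subject = j,
            identity_pct = hit$identity_pct,
            align_length = hit$align_length,
            covers_flank = hit$covers_flank,
            q_start = hit$q_start, q_end = hit$q_end,
            s_start = hit$s_start, s_end = hit$s_end
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query = integer(0), subject = integer(0),
                      identity_pct = numeric(0), align_length = integer(0),
                      covers_flank = logical(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0)))
  }
  do.call(rbind, rows)
}

#' Remove candidates lacking transposition-style similarity evidence
#'
#' A genuine MITE family transposes the element but not its genomic
#' context, so a true candidate should match another candidate within the
#' element while their flanks diverge. A candidate is retained iff it has
#' at least one partner hit with identity above `pident_min` percent whose
#' alignment stays inside both elements (`covers_flank = FALSE`).
#' Candidates whose only similarity evidence extends into the flanks
#' (segmental duplications) and candidates with no qualifying partner at
#' all (singletons) are removed.
#'
#' @param candidates Candidate table (rows aligned with the hit indices).
#' @param hits Hit table from [all_pairwise_hits()].
#' @param pident_min Identity threshold in percent (default 80, strict).
#' @return The retained subset of `candidates`.
#' @export
flank_filter <- function(candidates, hits, pident_min = 80) {
  if (!nrow(candidates)) return(candidates)
  good <- hits[hits$identity_pct > pident_min & !hits$covers_flank, , drop = FALSE]
  keep <- seq_len(nrow(candidates)) %in% c(good$query, good$subject)
  candidates[keep, , drop = FALSE]
}

#' Build the family similarity network
#'
#' Nodes are retained candidates; an undirected edge joins two candidates
#' whose element sequences (without flanks) align at `pident_min` percent
#' identity or better over at least `coverage_min` of the shorter element.
#' Connected components of this network are the MITE families.
#'
#' @param candidates Candidate table with `sequence`, `record_id`, `start`.
#' @param pident_min Clustering identity threshold in percent (default 90).
#' @param coverage_min Minimum aligned fraction of the shorter element
#'   (default 0.9).
#' @return An `igraph` undirected graph whose vertices carry `record_id`
#'   and `start` attributes; vertex names are candidate identifiers.
#' @export
build_family_network <- function(candidates, pident_min = 90, coverage_min = 0.9) {
  n <- nrow(candidates)
  ids <- if (n) candidate_ids(candidates) else character(0)
  edges <- vector("list", 0L)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        floor_len <- ceiling(coverage_min *
                               min(nchar(candidates$sequence[i]),
                                   nchar(candidates$sequence[j])))
        hit <- pairwise_similarity(candidates$sequence[i],
                                   candidates$sequence[j],
                                   min_len = floor_len,
                                   min_pident = pident_min)
        if (!is.null(hit)) {
          edges[[length(edges) + 1L]] <- c(ids[i], ids[j])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = ids,
                            record_id = candidates$record_id,
                            start = candidates$start)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  g
}

#' Select MITE families and their representatives
#'
#' Connected components with at least `min_members` members become
#' families. The representative of a family is its member of maximal
#' network degree, ties broken by smallest (`record_id`, `start`).
#' Families are numbered in genome order (by their earliest member).
#'
#' @param graph Similarity network from [build_family_network()].
#' @param min_members Minimum family size (default 3).
#' @return A data.frame with one row per family member: `family_id`,
#'   `member_id`, `degree`, `is_representative`.
#' @export
select_families <- function(graph, min_members = 3L) {
  empty <- data.frame(family_id = integer(0), member_id = character(0),
                      degree = integer(0), is_representative = logical(0))
  if (igraph::vcount(graph) == 0L) return(empty)
  comp <- igraph::components(graph)
  deg <- igraph::degree(graph)
  rid <- igraph::vertex_attr(graph, "record_id")
  vstart <- igraph::vertex_attr(graph, "start")
  vname <- igraph::vertex_attr(graph, "name")

  keep <- which(comp$csize >= min_members)
  if (!length(keep)) return(empty)
  fams <- lapply(keep, function(ci) which(comp$membership == ci))
  ord <- order(vapply(fams, function(v) min(rid[v]), character(1)),
               vapply(fams, function(v) min(vstart[v]), numeric(1)))
  fams <- fams[ord]

  rows <- lapply(seq_along(fams), function(fi) {
    v <- fams[[fi]]
    # representative: max degree, ties by smallest (record_id, start)
    v <- v[order(-deg[v], rid[v], vstart[v])]
    data.frame(family_id = fi, member_id = vname[v],
               degree = as.integer(deg[v]),
               is_representative = seq_along(v) == 1L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Superfamily classification from the TSD
#'
#' MITE superfamilies leave characteristic target-site duplications:
#' Stowaway duplicates `TA`, Tourist `TAA`, hAT targets of 5, 6 or 8 bp
#' and Mutator targets of 9 or 10 bp. Other TSDs (length 3 other than
#' `TAA`, 4, or 7) are labelled `Unknown`.
#'
#' @param tsd Character vector of TSD sequences (lengths 2-10).
#' @return Character vector of labels in
#'   `c("Stowaway", "Tourist", "hAT", "Mutator", "Unknown")`.
#' @examples
#' classify_superfamily(c("TA", "TAA", "GTCCAG", "GATCGATCG", "GGCC"))
#' @export
classify_superfamily <- function(tsd) {
  len <- nchar(tsd)
  if (any(len < 2L | len > 10L)) stop("TSD length must be between 2 and 10 bp")
  out <- rep("Unknown", length(tsd))
  out[tsd == "TA"] <- "Stowaway"
  out[tsd == "TAA"] <- "Tourist"
  out[tsd != "TAA" & len %in% c(5L, 6L, 8L)] <- "hAT"
  out[len %in% c(9L, 10L)] <- "Mutator"
  out
}
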