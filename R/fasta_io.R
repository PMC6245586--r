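#' Read a genome from FASTA
#'
#' Reads every record of a FASTA file into a list of sequence records.
#' Sequences are uppercased and any character outside `A`, `C`, `G`, `T`,
#' `N` (for example soft-mask gaps or IUPAC ambiguity codes) is coerced to
#' `N` with a warning, so that real genome assemblies parse without
#' special-casing.
#'
#' @param path Path to a FASTA file.
#' @return A list of sequence records. Each record is a list with elements
#'   `id` (first whitespace-delimited token of the header), `description`
#'   (remainder of the header, possibly `""`) and `sequence` (uppercase
#'   string over `ACGTN`).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 demo", "acgt", "ACGT"), tf)
#' read_fasta(tf)[[1]]$sequence
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records")
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (n_bad > 0L) {
    warning(n_bad, " non-ACGTN base(s) coerced to N in '", path, "'")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (any(!nzchar(seqs))) {
    stop("FASTA record with empty sequence in '", path, "'")
  }
  lapply(seq_along(set), function(i) {
    id <- sub("\\s.*$", "", headers[i])
    desc <- sub("^\\S+\\s*", "", headers[i])
    sequence_record(id = id, description = desc, sequence = unname(seqs[i]))
  })
}

#' Construct a sequence record
#'
#' @param id Record identifier (no whitespace).
#' @param sequence Uppercase sequence over `ACGTN`.
#' @param description Free-text remainder of the FASTA header.
#' @return A list with class `sequence_record`.
#' @export
sequence_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(sequence))
  structure(
    list(id = id, description = description, sequence = sequence),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d bp)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Cut a chromosome into overlapping fragments
#'
#' Fragments a chromosome into windows of `fragment_length` bp stepping by
#' `fragment_length - overlap`, so that adjacent fragments share `overlap`
#' bp. With the default overlap of 800 bp (the maximum element length) any
#' MITE lies entirely inside at least one fragment, which makes detection
#' safe to run fragment by fragment.
#'
#' All fragment offsets are 0-based.
#'
#' @param record A `sequence_record` (see [read_fasta()]).
#' @param fragment_length Fragment size in bp (default 10000).
#' @param overlap Shared sequence between adjacent fragments in bp
#'   (default 800); must be smaller than `fragment_length`.
#' @return A list of genome fragments, each a list with `record_id`,
#'   `offset` (0-based start on the chromosome) and `sequence`.
#' @export
fragment_sequence <- function(record, fragment_length = 10000L, overlap = 800L) {
  if (fragment_length <= overlap) {
    stop("fragment_length (", fragment_length, ") must exceed overlap (", overlap, ")")
  }
  len <- nchar(record$sequence)
  step <- fragment_length - overlap
  offsets <- 0L
  while (utils::tail(offsets, 1L) + fragment_length < len) {
    offsets <- c(offsets, utils::tail(offsets, 1L) + step)
  }
  lapply(offsets, function(off) {
    list(
      record_id = record$id,
      offset = as.integer(off),
      sequence = substr(record$sequence, off + 1L, min(off + fragment_length, len))
    )
  })
}

#' Write detection results to an output directory
#'
#' Writes four artifacts: `mites.fa` (all retained MITE sequences),
#' `representatives.fa` (one exemplar per family), `report.tsv` (one row
#' per retained candidate) and `superfamily_counts.tsv` (per-chromosome
#' superfamily tallies). Coordinates in the report are 1-based inclusive;
#' internal 0-based half-open coordinates are converted on output.
#'
#' @param candidates Candidate table as produced by the pipeline: one row
#'   per retained MITE with columns `record_id`, `start`, `end` (0-based
#'   half-open), `tir_length`, `tsd`, `mis`, `mispos`, `score`, `sequence`,
#'   `family_id`, `superfamily`, `is_representative`.
#' @param families Family table from [select_families()] (may have zero rows).
#' @param out_dir Output directory; created if absent.
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_outputs <- function(candidates, families, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    mites = file.path(out_dir, "mites.fa"),
    representatives = file.path(out_dir, "representatives.fa"),
    report = file.path(out_dir, "report.tsv"),
    counts = file.path(out_dir, "superfamily_counts.tsv")
  )

  n <- nrow(candidates)
  cand_id <- if (n) candidate_ids(candidates) else character(0)

  seqs <- Biostrings::DNAStringSet(if (n) candidates$sequence else character(0))
  names(seqs) <- cand_id
  Biostrings::writeXStringSet(seqs, paths[["mites"]])

  is_rep <- if (n) candidates$is_representative else logical(0)
  Biostrings::writeXStringSet(seqs[is_rep], paths[["representatives"]])

  report <- data.frame(
    record_id = if (n) candidates$record_id else character(0),
    start = if (n) candidates$start + 1L else integer(0),
    end = if (n) candidates$end else integer(0),
    tir_length = if (n) candidates$tir_length else integer(0),
    tsd = if (n) candidates$tsd else character(0),
    mismatch_position = if (n) ifelse(is.na(candidates$mispos), NA_integer_,
                                      candidates$mispos + 1L) else integer(0),
    score = if (n) candidates$score else numeric(0),
    family_id = if (n) candidates$family_id else integer(0),
    superfamily = if (n) candidates$superfamily else character(0),
    is_representative = if (n) as.integer(candidates$is_representative) else integer(0),
    stringsAsFactors = FALSE
  )
  utils::write.table(report, paths[["report"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sf_levels <- c("Stowaway", "Tourist", "hAT", "Mutator", "Unknown")
  if (n) {
    tab <- table(factor(candidates$record_id, levels = unique(candidates$record_id)),
                 factor(candidates$superfamily, levels = sf_levels))
    counts <- data.frame(record_id = rownames(tab),
                         as.data.frame.matrix(tab),
                         row.names = NULL, check.names = FALSE)
  } else {
    counts <- data.frame(record_id = character(0))
    for (sf in sf_levels) counts[[sf]] <- integer(0)
  }
  utils::write.table(counts, paths[["counts"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

# Stable per-candidate identifier: chromosome plus 1-based inclusive span.
candidate_ids <- function(candidates) {
  sprintf("%s:%d-%d", candidates$record_id, candidates$start + 1L, candidates$end)
}
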