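#' Pipeline configuration
#'
#' Collects every tunable parameter of the detection pipeline with its
#' documented default: k-mer seed length 10 bp (= minimum TIR), element
#' span 50-800 bp, at most 1 interior TIR mismatch, 10 kb fragments
#' overlapping by 800 bp (the maximum element length), score threshold 0,
#' 60 bp flanks, 80% identity for the flank filter, 90% identity over 90%
#' of the shorter element for family clustering, minimum family size 3,
#' 8 bp homopolymer/dinucleotide and 20% composition bounds for the
#' low-complexity filter.
#'
#' @param k K-mer seed length in bp.
#' @param min_tir Minimum reported TIR length in bp.
#' @param min_length,max_length Element span bounds in bp.
#' @param max_mismatch Maximum interior TIR mismatches (0 or 1).
#' @param fragment_length,overlap Chromosome fragmentation in bp;
#'   `fragment_length` must exceed `overlap`, and `overlap` should be at
#'   least `max_length` so no element is split across all fragments.
#' @param score_threshold Retention threshold for the log-ratio score
#'   (strictly greater-than); `-Inf` disables score filtering.
#' @param flank Flank length in bp for the similarity filter.
#' @param pident_min Percent identity for the flank filter (strict).
#' @param cluster_pident,cluster_coverage Family-network edge thresholds.
#' @param min_family_size Minimum members per family.
#' @param homopolymer_min,composition_min_pct Low-complexity filter
#'   parameters (bp run length; percent).
#' @param model_path Optional path to a trained model file.
#' @param seed Integer seed for any synthetic fallback (default 1).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 10L, min_tir = 10L, min_length = 50L,
                            max_length = 800L, max_mismatch = 1L,
                            fragment_length = 10000L, overlap = 800L,
                            score_threshold = 0, flank = 60L,
                            pident_min = 80, cluster_pident = 90,
                            cluster_coverage = 0.9, min_family_size = 3L,
                            homopolymer_min = 8L, composition_min_pct = 20,
                            model_path = NULL, seed = 1L) {
  if (fragment_length <= overlap) {
    stop("fragment_length must exceed overlap")
  }
  if (overlap < max_length) {
    warning("overlap (", overlap, ") below max_length (", max_length,
            "): elements straddling fragment joints may be missed")
  }
  if (min_length > max_length) stop("min_length exceeds max_length")
  structure(
    list(k = as.integer(k), min_tir = as.integer(min_tir),
         min_length = as.integer(min_length),
         max_length = as.integer(max_length),
         max_mismatch = as.integer(max_mismatch),
         fragment_length = as.integer(fragment_length),
         overlap = as.integer(overlap),
         score_threshold = score_threshold, flank = as.integer(flank),
         pident_min = pident_min, cluster_pident = cluster_pident,
         cluster_coverage = cluster_coverage,
         min_family_size = as.integer(min_family_size),
         homopolymer_min = as.integer(homopolymer_min),
         composition_min_pct = composition_min_pct,
         model_path = model_path, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full MITE detection pipeline
#'
#' Executes detection end to end: FASTA input, per-chromosome candidate
#' assembly (seed search, merging, TSD validation), log-ratio score
#' filtering, flank-similarity false-positive removal, family selection
#' on the similarity network, superfamily classification, and report
#' writing. With identical inputs, configuration and seed the output
#' files are byte-identical.
#'
#' @param genome_path Path to the genome FASTA file.
#' @param out_dir Output directory (see [write_outputs()]).
#' @param config A [pipeline_config()].
#' @param model A `log_ratio_model`, a model file path, or `NULL`. With
#'   `NULL` a model trained on synthetic motif sets is used, with a
#'   warning: scores from it are not biologically meaningful and users
#'   should train on curated positive/null sets via [run_train()].
#' @return Invisibly, a list with `candidates` (final annotated table),
#'   `families` (family table), `paths` (output files) and `counts`
#'   (per-stage candidate counts).
#' @export
run_pipeline <- function(genome_path, out_dir, config = pipeline_config(),
                         model = NULL) {
  records <- read_fasta(genome_path)
  message("read ", length(records), " sequence record(s)")

  if (is.null(model)) {
    if (!is.null(config$model_path)) {
      model <- read_model(config$model_path)
    } else {
      warning("no scoring model supplied; training a synthetic default ",
              "model (train on curated sets for real genomes)")
      set.seed(config$seed)
      ts <- make_training_sets(200L, 200L, motif = "TGCATG")
      model <- train_model(ts$positive, ts$null)
    }
  } else if (is.character(model)) {
    model <- read_model(model)
  }

  cand <- do.call(rbind, lapply(records, assemble_candidates, config = config))
  if (is.null(cand)) cand <- empty_candidates()
  n_assembled <- nrow(cand)
  message("assembly: ", n_assembled, " structurally valid candidate(s)")

  cand <- filter_by_score(cand, model, config$score_threshold)
  n_scored <- nrow(cand)
  message("scoring: ", n_scored, " candidate(s) above threshold ",
          config$score_threshold)

  recmap <- stats::setNames(records, vapply(records, `[[`, character(1), "id"))
  if (nrow(cand)) {
    flanked <- lapply(seq_len(nrow(cand)), function(r) {
      extract_with_flanks(cand[r, , drop = FALSE],
                          recmap[[cand$record_id[r]]], config$flank)
    })
    cand$flank_left <- vapply(flanked, `[[`, character(1), "flank_left")
    cand$flank_right <- vapply(flanked, `[[`, character(1), "flank_right")
    hits <- all_pairwise_hits(flanked, min_pident = config$pident_min)
    cand <- flank_filter(cand, hits, config$pident_min)
  }
  n_flank <- nrow(cand)
  message("flank filter: ", n_flank, " candidate(s) retained")

  graph <- build_family_network(cand, config$cluster_pident,
                                config$cluster_coverage)
  families <- select_families(graph, config$min_family_size)
  message("families: ", length(unique(families$family_id)),
          " family/families of >= ", config$min_family_size, " members")

  # keep only family members, annotate, classify
  if (nrow(cand)) {
    cand$candidate_id <- candidate_ids(cand)
    cand <- merge(cand, families, by.x = "candidate_id", by.y = "member_id")
    if (nrow(cand)) {
      cand$superfamily <- classify_superfamily(cand$tsd)
      cand <- cand[order(cand$record_id, cand$start, cand$end), , drop = FALSE]
      rownames(cand) <- NULL
    }
  }
  if (!nrow(cand)) {
    cand <- empty_candidates()
    cand$score <- numeric(0)
    cand$family_id <- integer(0)
    cand$superfamily <- character(0)
    cand$is_representative <- logical(0)
  }
  paths <- write_outputs(cand, families, out_dir)
  message("wrote ", length(paths), " file(s) to ", out_dir)
  invisible(list(candidates = cand, families = families, paths = paths,
                 counts = c(assembled = n_assembled, scored = n_scored,
                            flank_filtered = n_flank,
                            final = nrow(cand))))
}

#' Train a scoring model from FASTA files and write it to disk
#'
#' @param positive_path,null_path FASTA files of positive (true-MITE) and
#'   null (structural false positive) training sequences.
#' @param out_model Output model file path (see [write_model()]).
#' @param word_length,pseudocount Passed to [train_model()].
#' @return Invisibly, the trained `log_ratio_model`.
#' @export
run_train <- function(positive_path, null_path, out_model,
                      word_length = 6L, pseudocount = 1) {
  pos <- vapply(read_fasta(positive_path), `[[`, character(1), "sequence")
  nul <- vapply(read_fasta(null_path), `[[`, character(1), "sequence")
  model <- train_model(pos, nul, word_length, pseudocount)
  message("trained on ", sum(nchar(pos)) - (word_length - 1) * length(pos),
          " positive and ", sum(nchar(nul)) - (word_length - 1) * length(nul),
          " null word(s)")
  write_model(model, out_model)
  invisible(model)
}
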