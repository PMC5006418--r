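#' Default run configuration
#'
#' All module thresholds in one place; any entry can be overridden via
#' the `config` argument of [run_annotation()] or a YAML file
#' ([read_run_config()]).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    strategies = strategy_ids(),
    min_query_cov = 0.40, min_hsp_len = 21L, min_identity = 0.75,
    merge_cap = 1.25, max_gap = 30L, flank = 10L,
    band = 40L, trigger_extra = 6L,
    hmm_e_max = 0.01, hmm_null_samples = 1000L,
    cm_e_max = 0.01, cm_min_coverage = 0.70, cm_calibration_n = 1000L,
    curation_flank = 300L,
    screen_contaminants = TRUE,
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys override [default_config()].
#' @return Merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' Run the full annotation pipeline
#'
#' Stage order: contamination screen, multi-strategy local search,
#' filter/merge/extend into candidate regions, profile-HMM search as an
#' independent candidate source, covariance-model validation of the
#' union of both candidate tracks, overlap resolution, final curation
#' with 300 nt flanks, and GFF3/TSV emission.  Every stage appends a
#' count line to the log; re-running with an identical configuration and
#' seed gives identical outputs.
#'
#' @param genome `DNAStringSet` of contigs (or FASTA path).
#' @param queries Query data.frame ([read_query_fasta()] layout) or path.
#' @param seeds Named list of `seed_alignment` objects, one per family
#'   appearing in `queries`.
#' @param contaminants Optional `DNAStringSet` (or FASTA path) of
#'   contaminant references.
#' @param config Configuration overrides (see [default_config()]).
#' @param output_dir Optional directory for GFF3/TSV/log emission.
#' @return List with `loci` (curated annotated loci), `summary`
#'   (families and loci per RNA class), `hsp_count`, `candidates`,
#'   `hmm_hits`, `cm_hits`, `contamination`, `log` (character vector),
#'   `rejected`.
#' @export
run_annotation <- function(genome, queries, seeds, contaminants = NULL,
                           config = list(), output_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- read_fasta(genome)
  if (!methods::is(genome, "XStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.character(queries)) queries <- read_query_fasta(queries)
  if (is.character(contaminants) && length(contaminants) == 1)
    contaminants <- read_fasta(contaminants)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  # 1) contamination screen
  contamination <- NULL
  if (!is.null(contaminants) && isTRUE(cfg$screen_contaminants)) {
    contamination <- screen_contamination(genome, contaminants,
                                          config = cfg)
    note("contamination: ", length(genome), " contigs in, ",
         length(contamination$clean_genome), " out (",
         nrow(contamination$calls), " flagged)")
    genome <- contamination$clean_genome
  }
  if (length(genome) == 0 || nrow(queries) == 0) {
    note("empty genome or query set; emitting empty annotation")
    loci <- locus_frame()
    res <- list(loci = loci, summary = summarize_annotation(loci),
                hsp_count = 0L, candidates = candidate_frame(),
                hmm_hits = hmm_hit_frame(), cm_hits = NULL,
                contamination = contamination, log = log,
                rejected = NULL)
    if (!is.null(output_dir)) emit_outputs(res, genome, output_dir)
    return(res)
  }
  bg <- base_frequencies(genome)
  # 2) multi-strategy search + 3) filter/merge/extend, per family
  families <- unique(queries$family_id)
  cand_blast <- list()
  hsp_count <- 0L
  for (fam in families) {
    qsub <- queries[queries$family_id == fam, , drop = FALSE]
    fam_cands <- list()
    for (sid in cfg$strategies) {
      scheme <- make_strategy(sid)
      stats <- solve_statistics(scheme, bg)
      for (qi in seq_len(nrow(qsub))) {
        hsps <- blast_search(qsub[qi, , drop = FALSE], genome, scheme, stats, cfg)
        hsp_count <- hsp_count + nrow(hsps)
        qlen <- nchar(qsub$sequence[qi])
        hsps <- filter_hsps(hsps, qlen, cfg$min_query_cov, cfg$min_hsp_len,
                            cfg$min_identity)
        if (!nrow(hsps)) next
        hsps <- merge_hsps(hsps, qlen, cfg$max_gap, cfg$merge_cap)
        hsps$species_tag <- qsub$species_tag[qi]
        hsps$strategy_id <- sid
        fam_cands[[length(fam_cands) + 1L]] <- cbind(hsps, qlen = qlen)
      }
    }
    if (!length(fam_cands)) next
    all_hsps <- do.call(rbind, fam_cands)
    cand <- build_candidates(all_hsps, genome, round(median(all_hsps$qlen)),
                             flank = cfg$flank, family_id = fam,
                             rna_class = qsub$rna_class[1])
    cand_blast[[fam]] <- cand
  }
  candidates <- if (length(cand_blast)) do.call(rbind, cand_blast) else candidate_frame()
  rownames(candidates) <- NULL
  note("blast track: ", hsp_count, " HSPs in, ", nrow(candidates),
       " candidate regions out")
  # 4) profile-HMM track
  hmm_hits <- list()
  models_hmm <- list()
  for (fam in families) {
    if (is.null(seeds[[fam]])) next
    phmm <- build_phmm(seeds[[fam]])
    models_hmm[[fam]] <- phmm
    hh <- search_phmm(phmm, genome, e_max = cfg$hmm_e_max,
                      null_samples = cfg$hmm_null_samples, seed = cfg$seed)
    if (nrow(hh)) {
      hh$rna_class <- queries$rna_class[match(fam, queries$family_id)]
      hmm_hits[[fam]] <- hh
    }
  }
  hmm_hits <- if (length(hmm_hits)) do.call(rbind, hmm_hits) else {
    h <- hmm_hit_frame(); h$rna_class <- character(); h
  }
  rownames(hmm_hits) <- NULL
  note("hmm track: ", nrow(hmm_hits), " envelope hits")
  # 5) CM validation of the union of candidate sources
  cm_hits <- list()
  rejected <- list()
  for (fam in families) {
    if (is.null(seeds[[fam]])) next
    cm <- calibrate_cm(build_cm(seeds[[fam]]), n = cfg$cm_calibration_n,
                       seed = cfg$seed)
    regions <- list()
    cb <- candidates[candidates$family_id == fam, , drop = FALSE]
    if (nrow(cb)) {
      cb$evidence <- "blast"
      regions[[length(regions) + 1L]] <-
        cb[, c("family_id", "rna_class", "contig_id", "start", "end",
               "strand", "sequence", "evidence")]
    }
    ch <- hmm_hits[hmm_hits$family_id == fam, , drop = FALSE]
    if (nrow(ch)) {
      ch$evidence <- "hmm"
      ch <- regions_with_sequence(ch, genome)
      regions[[length(regions) + 1L]] <-
        ch[, c("family_id", "rna_class", "contig_id", "start", "end",
               "strand", "sequence", "evidence")]
    }
    if (!length(regions)) next
    reg <- do.call(rbind, regions)
    hits <- search_cm(cm, reg, e_max = cfg$cm_e_max,
                      min_coverage = cfg$cm_min_coverage)
    note("cm validation [", fam, "]: ", nrow(reg), " regions in, ",
         sum(hits$status == "accepted"), " accepted")
    acc <- hits[hits$status == "accepted", , drop = FALSE]
    if (nrow(acc)) {
      acc <- resolve_overlaps(acc)
      cur <- curate_final(acc, genome, cm, flank = cfg$curation_flank,
                          e_max = cfg$cm_e_max)
      note("curation [", fam, "]: ", nrow(acc), " in, ",
           nrow(cur$loci), " curated loci")
      if (nrow(cur$loci)) cm_hits[[length(cm_hits) + 1L]] <- cur$loci
      if (nrow(cur$rejected)) rejected[[length(rejected) + 1L]] <- cur$rejected
    }
  }
  loci <- if (length(cm_hits)) do.call(rbind, cm_hits) else locus_frame()
  rownames(loci) <- NULL
  # cross-family overlap resolution on the curated set
  if (nrow(loci) > 1) loci <- resolve_overlaps(loci)
  summary <- summarize_annotation(loci)
  note("final: ", nrow(loci), " curated loci in ", nrow(summary), " classes")
  res <- list(loci = loci, summary = summary, hsp_count = hsp_count,
              candidates = candidates, hmm_hits = hmm_hits,
              cm_hits = if (length(cm_hits)) do.call(rbind, cm_hits) else NULL,
              contamination = contamination, log = log,
              rejected = if (length(rejected)) do.call(rbind, rejected) else NULL)
  if (!is.null(output_dir)) emit_outputs(res, genome, output_dir)
  res
}

#' Families and loci per RNA class
#'
#' @param loci Annotated locus data.frame.
#' @return Data.frame with `rna_class`, `families`, `loci`.
#' @export
summarize_annotation <- function(loci) {
  if (!nrow(loci)) {
    return(data.frame(rna_class = character(), families = integer(),
                      loci = integer(), stringsAsFactors = FALSE))
  }
  agg <- split(loci, loci$rna_class)
  out <- data.frame(
    rna_class = names(agg),
    families = vapply(agg, function(d) length(unique(d$family_id)), 0L),
    loci = vapply(agg, nrow, 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$rna_class), , drop = FALSE]
}

base_frequencies <- function(genome) {
  f <- Biostrings::alphabetFrequency(genome, baseOnly = TRUE, collapse = TRUE)
  f <- f[c("A", "C", "G", "T")]
  as.numeric(f / sum(f))
}

emit_outputs <- function(res, genome, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_annotations(res$loci, genome,
                    file.path(output_dir, "annotation.gff3"),
                    file.path(output_dir, "annotation.tsv"))
  writeLines(res$log, file.path(output_dir, "pipeline.log"))
  write.table(res$summary, file.path(output_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(output_dir)
}
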