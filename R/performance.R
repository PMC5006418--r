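#' Shuffle a sequence preserving composition
#'
#' `order = "mono"` draws Fisher-Yates permutations (mononucleotide
#' composition preserved); `order = "di"` uses the Altschul-Erickson
#' Eulerian-walk shuffle, preserving the exact dinucleotide count
#' vector.  Deterministic under a fixed seed.
#'
#' @param seq DNA string.
#' @param n Number of shuffles.
#' @param seed RNG seed.
#' @param order `"mono"` or `"di"`.
#' @return Character vector of `n` shuffled sequences.
#' @export
shuffle_sequence <- function(seq, n = 1000L, seed = 1L,
                             order = c("mono", "di")) {
  order <- match.arg(order)
  stopifnot(n >= 1)
  chars <- strsplit(toupper(seq), "")[[1]]
  with_seed(seed, {
    if (order == "mono") {
      vapply(seq_len(n), function(i) paste0(sample(chars), collapse = ""), "")
    } else {
      vapply(seq_len(n), function(i) dinucleotide_shuffle(chars), "")
    }
  })
}

# Altschul-Erickson dinucleotide shuffle: pick a random "last edge" per
# vertex forming an arborescence into the final vertex, shuffle the
# remaining out-edges, and walk the resulting Eulerian path.
dinucleotide_shuffle <- function(chars) {
  L <- length(chars)
  if (L <= 2) return(paste0(chars, collapse = ""))
  verts <- unique(chars)
  edges <- split(chars[-1], factor(chars[-L], levels = verts))
  last <- chars[L]
  repeat {
    last_edge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last || !length(edges[[v]])) next
      last_edge[[v]] <- edges[[v]][sample.int(length(edges[[v]]), 1)]
    }
    # the chosen last edges must connect every used vertex to `last`
    reach <- function(v, depth = 0) {
      if (v == last) return(TRUE)
      if (depth > length(verts)) return(FALSE)
      nx <- last_edge[[v]]
      if (is.null(nx)) return(FALSE)
      reach(nx, depth + 1)
    }
    for (v in verts) {
      if (v == last || !length(edges[[v]])) next
      if (!reach(v)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  pool <- list()
  for (v in verts) {
    e <- edges[[v]]
    if (v != last && length(e)) {
      drop <- match(last_edge[[v]], e)
      e <- c(sample(e[-drop]), e[drop])
    } else if (length(e) > 1) {
      e <- sample(e)
    }
    pool[[v]] <- e
  }
  used <- setNames(integer(length(verts)), verts)
  out <- character(L)
  out[1] <- chars[1]
  v <- chars[1]
  for (i in 2:L) {
    used[v] <- used[v] + 1L
    nx <- pool[[v]][used[v]]
    out[i] <- nx
    v <- nx
  }
  paste0(out, collapse = "")
}

#' Sensitivity and specificity from a confusion matrix
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (FP + TN).  An
#' undefined denominator yields `NA`.
#'
#' @param cm Data.frame (or list) with columns/fields `TP`, `FP`, `TN`,
#'   `FN`.
#' @return Data.frame with `sensitivity` and `specificity` (one row per
#'   input row).
#' @export
sens_spec <- function(cm) {
  cm <- as.data.frame(cm)
  sens <- ifelse(cm$TP + cm$FN > 0, cm$TP / (cm$TP + cm$FN), NA_real_)
  spec <- ifelse(cm$FP + cm$TN > 0, cm$TN / (cm$FP + cm$TN), NA_real_)
  data.frame(sensitivity = sens, specificity = spec)
}

#' Estimate a strategy's confusion matrix against planted truth
#'
#' TP counts truth loci recovered (at least 50 % reciprocal overlap,
#' same contig) by the strategy's filtered-and-merged candidates; FN is
#' the remainder.  FP counts shuffled query sequences that yield at
#' least one passing candidate; TN is the remainder of the nulls.
#'
#' @param strategy_id Strategy identifier (see [strategy_ids()]).
#' @param queries Query data.frame ([read_query_fasta()] layout) with a
#'   `family_id`/`rna_class` per row.
#' @param truth Truth table (data.frame with `family_id`, `rna_class`,
#'   `contig_id`, `start`, `end`).
#' @param genome `DNAStringSet`.
#' @param nulls_per_family Number of shuffled sequences per family.
#' @param seed RNG seed for the shuffles.
#' @param config Filter/merge/search configuration overrides.
#' @param validate Optional function(candidates, queries_row) applied to
#'   candidates before counting, e.g. CM validation for full-pipeline
#'   specificity; identity by default.
#' @return Data.frame, one row per RNA class: `strategy_id`,
#'   `rna_class`, `TP`, `FP`, `TN`, `FN`, `sensitivity`, `specificity`.
#' @export
evaluate_strategy <- function(strategy_id, queries, truth, genome,
                              nulls_per_family = 1000L, seed = 1L,
                              config = list(), validate = NULL) {
  scheme <- make_strategy(strategy_id)
  stats <- solve_statistics(scheme)
  out <- list()
  for (cls in unique(queries$rna_class)) {
    qsub <- queries[queries$rna_class == cls, , drop = FALSE]
    tsub <- truth[truth$rna_class == cls, , drop = FALSE]
    cands_all <- list()
    for (qi in seq_len(nrow(qsub))) {
      cand <- search_filter_candidates(qsub[qi, , drop = FALSE], genome,
                                       scheme, stats, config)
      if (!is.null(validate) && nrow(cand))
        cand <- validate(cand, qsub[qi, , drop = FALSE])
      if (nrow(cand)) cands_all[[length(cands_all) + 1L]] <- cand
    }
    cands <- if (length(cands_all)) do.call(rbind, cands_all) else candidate_frame()
    TP <- if (nrow(tsub)) sum(vapply(seq_len(nrow(tsub)), function(ti) {
      any_reciprocal_overlap(tsub[ti, , drop = FALSE], cands, 0.5)
    }, TRUE)) else 0L
    FN <- nrow(tsub) - TP
    FP <- 0L
    nulls_total <- 0L
    for (qi in seq_len(nrow(qsub))) {
      shufs <- shuffle_sequence(qsub$sequence[qi], nulls_per_family,
                                seed = seed + qi, order = config$shuffle_order %||% "mono")
      nulls_total <- nulls_total + length(shufs)
      FP <- FP + count_null_positives(shufs, qsub[qi, , drop = FALSE], genome,
                                      scheme, stats, config, validate)
    }
    TN <- nulls_total - FP
    row <- data.frame(strategy_id = strategy_id, rna_class = cls,
                      TP = TP, FP = FP, TN = TN, FN = FN,
                      stringsAsFactors = FALSE)
    row <- cbind(row, sens_spec(row))
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# number of shuffled sequences that yield >= 1 passing candidate; one
# batched genome pass for all shuffles of one family
count_null_positives <- function(shufs, qrow, genome, scheme, stats,
                                 config = list(), validate = NULL) {
  hits <- multi_blast_search(shufs, genome, scheme, stats, config)
  if (!nrow(hits)) return(0L)
  qlen <- nchar(qrow$sequence)
  hits <- filter_hsps(hits, qlen,
                      min_query_cov = config$min_query_cov %||% 0.40,
                      min_hsp_len = config$min_hsp_len %||% 21L,
                      min_identity = config$min_identity %||% 0.75)
  # every surviving filtered HSP yields a candidate region, so without
  # downstream validation FP is just the number of distinct shuffles left
  pass_idx <- unique(hits$query_index)
  if (is.null(validate)) return(length(pass_idx))
  fp <- 0L
  for (qi in pass_idx) {
    sub <- hits[hits$query_index == qi, , drop = FALSE]
    sub$query_id <- qrow$family_id
    sub <- merge_hsps(sub, qlen, max_gap = config$max_gap %||% 30L,
                      merge_cap = config$merge_cap %||% 1.25)
    sub$species_tag <- qrow$species_tag %||% NA_character_
    sub$strategy_id <- scheme$strategy_id
    cand <- build_candidates(sub, genome, qlen, flank = config$flank %||% 10L,
                             family_id = qrow$family_id,
                             rna_class = qrow$rna_class)
    if (nrow(cand)) cand <- validate(cand, qrow)
    if (nrow(cand)) fp <- fp + 1L
  }
  fp
}

# search -> filter -> merge -> extend for one query row
search_filter_candidates <- function(qrow, genome, scheme, stats, config = list()) {
  hsps <- blast_search(qrow, genome, scheme, stats, config)
  qlen <- nchar(qrow$sequence)
  hsps <- filter_hsps(hsps, qlen,
                      min_query_cov = config$min_query_cov %||% 0.40,
                      min_hsp_len = config$min_hsp_len %||% 21L,
                      min_identity = config$min_identity %||% 0.75)
  if (!nrow(hsps)) return(candidate_frame())
  hsps <- merge_hsps(hsps, qlen, max_gap = config$max_gap %||% 30L,
                     merge_cap = config$merge_cap %||% 1.25)
  hsps$species_tag <- qrow$species_tag %||% NA_character_
  hsps$strategy_id <- scheme$strategy_id
  build_candidates(hsps, genome, qlen, flank = config$flank %||% 10L,
                   family_id = qrow$family_id, rna_class = qrow$rna_class)
}

# does any row of `cands` overlap `locus` reciprocally by >= frac?
any_reciprocal_overlap <- function(locus, cands, frac = 0.5) {
  if (!nrow(cands)) return(FALSE)
  same <- cands$contig_id == locus$contig_id
  if (!any(same)) return(FALSE)
  sub <- cands[same, , drop = FALSE]
  ov <- pmin(sub$end, locus$end) - pmax(sub$start, locus$start)
  any(ov / (locus$end - locus$start) >= frac &
        ov / (sub$end - sub$start) >= frac)
}

#' Group strategies that share scoring parameters
#'
#' Strategies differing only in their expectation cutoff produce nested
#' HSP sets, so one search with the loosest cutoff serves the whole
#' group.
#'
#' @param strategies Character vector of strategy ids.
#' @return List of groups; each has `scheme` (loosest-cutoff scheme) and
#'   `members` (data.frame of id and e_cut).
#' @export
strategy_groups <- function(strategies = strategy_ids()) {
  schemes <- lapply(strategies, make_strategy)
  key <- vapply(schemes, function(s)
    paste(s$r, s$q, s$G, s$E_ext, s$W), "")
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    ecuts <- vapply(schemes[idx], `[[`, 0, "e_cut")
    loosest <- schemes[[idx[which.max(ecuts)]]]
    out[[length(out) + 1L]] <- list(
      scheme = loosest,
      members = data.frame(strategy_id = strategies[idx], e_cut = ecuts,
                           stringsAsFactors = FALSE))
  }
  out
}

#' Full-pipeline specificity against shuffled nulls
#'
#' For each family, `n` shuffled copies of the query are searched with
#' the whole strategy ensemble (one pass per distinct parameter set),
#' filtered, merged, extended, validated with the family's covariance
#' model and curated -- exactly the treatment of real queries.  A false
#' positive is a shuffled sequence yielding at least one curated locus.
#'
#' @param queries Query data.frame (one row per family).
#' @param seeds Named list of `seed_alignment`s per family.
#' @param genome `DNAStringSet`.
#' @param n Shuffles per family.
#' @param seed RNG seed.
#' @param strategies Strategy ids forming the ensemble.
#' @param config Threshold overrides (see [default_config()]).
#' @param cms Optional named list of pre-calibrated covariance models.
#' @return Data.frame per rna_class: `FP`, `TN`, `specificity`.
#' @export
pipeline_specificity <- function(queries, seeds, genome, n = 1000L,
                                 seed = 1L, strategies = strategy_ids(),
                                 config = list(), cms = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  groups <- strategy_groups(strategies)
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    qrow <- queries[qi, , drop = FALSE]
    fam <- qrow$family_id
    cm <- cms[[fam]] %||%
      calibrate_cm(build_cm(seeds[[fam]]), n = cfg$cm_calibration_n,
                   seed = seed)
    shufs <- shuffle_sequence(qrow$sequence, n, seed = seed + qi)
    qlen <- nchar(qrow$sequence)
    hits <- list()
    for (g in groups) {
      stats <- solve_statistics(g$scheme, base_frequencies(genome))
      h <- multi_blast_search(shufs, genome, g$scheme, stats, cfg)
      h <- filter_hsps(h, qlen, cfg$min_query_cov, cfg$min_hsp_len,
                       cfg$min_identity)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
    fp <- 0L
    if (length(hits)) {
      hits <- do.call(rbind, hits)
      for (idx in unique(hits$query_index)) {
        sub <- hits[hits$query_index == idx, , drop = FALSE]
        sub$query_id <- fam
        sub <- merge_hsps(sub, qlen, cfg$max_gap, cfg$merge_cap)
        sub$species_tag <- qrow$species_tag %||% NA_character_
        cand <- build_candidates(sub, genome, qlen, flank = cfg$flank,
                                 family_id = fam, rna_class = qrow$rna_class)
        if (!nrow(cand)) next
        val <- search_cm(cm, cand, e_max = cfg$cm_e_max,
                         min_coverage = cfg$cm_min_coverage)
        acc <- val[val$status == "accepted", , drop = FALSE]
        if (!nrow(acc)) next
        cur <- curate_final(acc, genome, cm, flank = cfg$curation_flank,
                            e_max = cfg$cm_e_max)
        if (nrow(cur$loci)) fp <- fp + 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      family_id = fam, rna_class = qrow$rna_class, FP = fp, TN = n - fp,
      specificity = (n - fp) / n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of truth loci recovered by an annotation
#'
#' A truth locus counts as recovered when some annotated locus overlaps
#' it reciprocally by at least `frac` on the same contig.
#'
#' @param truth Truth table (`contig_id`, `start`, `end`).
#' @param loci Annotated loci.
#' @param frac Reciprocal-overlap fraction.
#' @return List with `recovered`, `total`, `fraction`.
#' @export
recovery_fraction <- function(truth, loci, frac = 0.5) {
  if (!nrow(truth)) return(list(recovered = 0L, total = 0L, fraction = NA_real_))
  rec <- vapply(seq_len(nrow(truth)), function(i)
    any_reciprocal_overlap(truth[i, , drop = FALSE], loci, frac), TRUE)
  list(recovered = sum(rec), total = nrow(truth),
       fraction = mean(rec))
}

#' Per-strategy recovery of planted loci at the raw hit stage
#'
#' Counts, for each strategy, how many truth loci are overlapped
#' (reciprocally, at least 50 %) by any HSP of any query -- the
#' detection-sensitivity view, before identity filtering.
#'
#' @param queries Query data.frame.
#' @param truth Truth table.
#' @param genome `DNAStringSet`.
#' @param strategies Strategy ids.
#' @param config Search configuration.
#' @return Named integer vector of recovered counts, one per strategy,
#'   plus an attribute `union` with the count recovered by the union of
#'   all listed strategies.
#' @export
strategy_hsp_recovery <- function(queries, truth, genome,
                                  strategies = strategy_ids(),
                                  config = list()) {
  bg <- base_frequencies(genome)
  per <- setNames(integer(length(strategies)), strategies)
  union_hits <- list()
  for (sid in strategies) {
    scheme <- make_strategy(sid)
    stats <- solve_statistics(scheme, bg)
    hits <- list()
    for (qi in seq_len(nrow(queries))) {
      h <- blast_search(queries[qi, , drop = FALSE], genome, scheme, stats,
                        config)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
    hits <- if (length(hits)) do.call(rbind, hits) else hsp_frame()
    union_hits[[sid]] <- hits
    per[sid] <- if (nrow(truth)) sum(vapply(seq_len(nrow(truth)), function(i)
      any_reciprocal_overlap(truth[i, , drop = FALSE], hits, 0.5), TRUE)) else 0L
  }
  allh <- do.call(rbind, union_hits)
  attr(per, "union") <- if (nrow(truth)) sum(vapply(seq_len(nrow(truth)),
    function(i) any_reciprocal_overlap(truth[i, , drop = FALSE], allh, 0.5),
    TRUE)) else 0L
  per
}
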