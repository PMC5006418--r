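#' Rule-based HSP filtering
#'
#' An HSP is kept iff it covers at least 40 % of the query length
#' (inclusive), its alignment length strictly exceeds 20 columns, and its
#' identity is at least 75 % (inclusive).  Input order is preserved and
#' the filter is idempotent.
#'
#' @param hsps HSP data.frame from [blast_search()].
#' @param query_length Length of the query the HSPs belong to.
#' @param min_query_cov,min_hsp_len,min_identity Rule thresholds; the
#'   length rule keeps alignments with `length >= min_hsp_len`
#'   (default 21, i.e. strictly more than 20 columns).
#' @return Filtered HSP data.frame.
#' @export
filter_hsps <- function(hsps, query_length, min_query_cov = 0.40,
                        min_hsp_len = 21L, min_identity = 0.75) {
  stopifnot(query_length > 0)
  if (!nrow(hsps)) return(hsps)
  keep <- (hsps$qend - hsps$qstart) / query_length >= min_query_cov &
    hsps$length >= min_hsp_len &
    hsps$identity >= min_identity
  out <- hsps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby same-strand HSPs of one query
#'
#' HSPs on the same contig and strand whose genomic gap is at most
#' `max_gap` are merged greedily left-to-right into their coordinate
#' hull, but only when the hull does not exceed `merge_cap` (125 %) of
#' the query length.  A merged hit's score is the sum of its members'
#' scores and its identity the match-weighted mean.  Opposite strands are
#' never merged.
#'
#' @param hsps HSPs of a single query (data.frame).
#' @param query_length Query length in nt.
#' @param max_gap Maximum genomic gap between mergeable HSPs (nt).
#' @param merge_cap Maximum hull length as a fraction of the query.
#' @return Data.frame of merged hits.
#' @export
merge_hsps <- function(hsps, query_length, max_gap = 30L, merge_cap = 1.25) {
  if (!nrow(hsps)) return(hsps)
  stopifnot(length(unique(hsps$query_id)) == 1L)
  cap <- merge_cap * query_length
  out <- list()
  for (key in unique(paste(hsps$contig_id, hsps$strand))) {
    grp <- hsps[paste(hsps$contig_id, hsps$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    for (i in seq_len(nrow(grp))[-1]) {
      nxt <- grp[i, , drop = FALSE]
      gap <- nxt$start - cur$end
      hull_len <- max(cur$end, nxt$end) - cur$start
      if (gap <= max_gap && hull_len <= cap) {
        cur$end <- max(cur$end, nxt$end)
        cur$qstart <- min(cur$qstart, nxt$qstart)
        cur$qend <- max(cur$qend, nxt$qend)
        total_m <- cur$matches + nxt$matches
        cur$identity <- (cur$identity * cur$matches + nxt$identity * nxt$matches) /
          max(1, total_m)
        cur$matches <- total_m
        cur$length <- cur$length + nxt$length
        cur$score <- cur$score + nxt$score
        cur$evalue <- min(cur$evalue, nxt$evalue)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build extended candidate regions from filtered, merged hits
#'
#' Each hit is extended symmetrically to the length expected from the
#' query (centred on the hit, asymmetric when clipped by contig ends),
#' then `flank` nt are added on either side and the interval is clipped
#' to the contig.  Near-duplicate intervals (same contig and strand,
#' at least 90 % reciprocal overlap) arising from different queries of
#' the same family are collapsed into one region whose supporting
#' species/strategy sets accumulate.
#'
#' @param hsps Filtered and merged HSP data.frame; may carry
#'   `species_tag` and `strategy_id` provenance columns.
#' @param genome `DNAStringSet`.
#' @param query_length Query length in nt.
#' @param flank Flank added on either side (nt).
#' @param family_id Family the queries belong to.
#' @param rna_class RNA class tag.
#' @param min_reciprocal Reciprocal-overlap fraction for collapsing.
#' @return Data.frame of candidate regions with columns `family_id`,
#'   `rna_class`, `contig_id`, `start`, `end`, `strand`, `score`,
#'   `best_evalue`, `n_hsps`, `supporting_species`,
#'   `supporting_strategies` (comma-separated sets) and `sequence`.
#' @export
build_candidates <- function(hsps, genome, query_length, flank = 10L,
                             family_id = hsps$query_id[1],
                             rna_class = NA_character_,
                             min_reciprocal = 0.90) {
  if (!nrow(hsps)) return(candidate_frame())
  lens <- setNames(Biostrings::width(genome), names(genome))
  regions <- list()
  for (i in seq_len(nrow(hsps))) {
    h <- hsps[i, , drop = FALSE]
    clen <- lens[[h$contig_id]]
    hit_len <- h$end - h$start
    extra <- max(0, query_length - hit_len)
    left <- floor(extra / 2)
    right <- extra - left
    s <- h$start - left
    e <- h$end + right
    # clipping at a contig edge shifts the unused extension to the other side
    if (s < 0) { e <- min(clen, e - s); s <- 0 }
    if (e > clen) { s <- max(0, s - (e - clen)); e <- clen }
    s <- max(0, s - flank)
    e <- min(clen, e + flank)
    regions[[i]] <- data.frame(
      family_id = family_id, rna_class = rna_class,
      contig_id = h$contig_id, start = s, end = e, strand = h$strand,
      score = h$score, best_evalue = h$evalue, n_hsps = 1L,
      supporting_species = if ("species_tag" %in% names(h)) h$species_tag else NA_character_,
      supporting_strategies = if ("strategy_id" %in% names(h)) h$strategy_id else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, regions)
  df <- df[order(df$contig_id, df$strand, df$start, -df$score), , drop = FALSE]
  # collapse >=90 % reciprocal overlaps, accumulating provenance sets
  kept <- list()
  for (i in seq_len(nrow(df))) {
    cand <- df[i, , drop = FALSE]
    merged <- FALSE
    for (k in seq_along(kept)) {
      ex <- kept[[k]]
      if (ex$contig_id != cand$contig_id || ex$strand != cand$strand) next
      ov <- min(ex$end, cand$end) - max(ex$start, cand$start)
      if (ov <= 0) next
      if (ov / (ex$end - ex$start) >= min_reciprocal &&
          ov / (cand$end - cand$start) >= min_reciprocal) {
        ex$supporting_species <- union_set(ex$supporting_species, cand$supporting_species)
        ex$supporting_strategies <- union_set(ex$supporting_strategies, cand$supporting_strategies)
        ex$n_hsps <- ex$n_hsps + 1L
        ex$score <- max(ex$score, cand$score)
        ex$best_evalue <- min(ex$best_evalue, cand$best_evalue)
        kept[[k]] <- ex
        merged <- TRUE
        break
      }
    }
    if (!merged) kept[[length(kept) + 1L]] <- cand
  }
  res <- do.call(rbind, kept)
  res$sequence <- vapply(seq_len(nrow(res)), function(i) {
    interval_sequence(genome, res$contig_id[i], res$start[i], res$end[i],
                      res$strand[i])
  }, "")
  rownames(res) <- NULL
  res
}

union_set <- function(a, b) {
  vals <- unique(c(strsplit(a %||% "", ",")[[1]], strsplit(b %||% "", ",")[[1]]))
  vals <- sort(vals[nzchar(vals) & !is.na(vals)])
  if (!length(vals)) NA_character_ else paste(vals, collapse = ",")
}

candidate_frame <- function() {
  data.frame(family_id = character(), rna_class = character(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), best_evalue = numeric(),
             n_hsps = integer(), supporting_species = character(),
             supporting_strategies = character(), sequence = character(),
             stringsAsFactors = FALSE)
}
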