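#' Screen contigs for bacterial/archaeal contamination
#'
#' Two rules, applied from local-alignment hits of the contaminant
#' references against each contig:
#' * `hsp_rule`: any HSP with E-value below 1e-10, identity above 75 %
#'   and alignment length above 20 nt flags the contig;
#' * `genome_rule`: a contig is flagged when the merged HSP footprint
#'   covers at least 70 % of the contig at a (match-weighted) identity of
#'   at least 80 % ("similarity" is implemented as alignment identity).
#'
#' Calls are deduplicated per contig keeping the stronger rule
#' (`hsp_rule` first, being the more specific evidence).
#'
#' @param contigs `DNAStringSet` of genome contigs.
#' @param contaminant_db `DNAStringSet` of contaminant reference
#'   sequences.
#' @param scheme Scoring scheme for the search (default strategy).
#' @param config Passed to [blast_search()].
#' @param hsp_e,hsp_identity,hsp_len Rule-A thresholds (strict `<`, `>`,
#'   `>` respectively).
#' @param cov_min,cov_identity Rule-B thresholds (both inclusive).
#' @return List with `calls` (data.frame: `contig_id`, `rule`,
#'   `best_evalue`, `identity`, `coverage`, `source_id`) and
#'   `clean_genome` (contigs minus flagged ones).
#' @export
screen_contamination <- function(contigs, contaminant_db,
                                 scheme = make_strategy("default"),
                                 config = list(),
                                 hsp_e = 1e-10, hsp_identity = 0.75,
                                 hsp_len = 20L,
                                 cov_min = 0.70, cov_identity = 0.80) {
  if (!methods::is(contigs, "XStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (!methods::is(contaminant_db, "XStringSet"))
    contaminant_db <- Biostrings::DNAStringSet(contaminant_db)
  if (!length(contaminant_db)) stop("contaminant database is empty")
  stats <- solve_statistics(scheme)
  hits <- list()
  for (ri in seq_along(contaminant_db)) {
    h <- blast_search(as.character(contaminant_db[[ri]]), contigs, scheme,
                      stats, config, query_id = names(contaminant_db)[ri])
    if (nrow(h)) hits[[length(hits) + 1L]] <- h
  }
  calls <- list()
  if (length(hits)) {
    hsps <- do.call(rbind, hits)
    lens <- setNames(Biostrings::width(contigs), names(contigs))
    for (cid in unique(hsps$contig_id)) {
      sub <- hsps[hsps$contig_id == cid, , drop = FALSE]
      # rule A: a single strong HSP
      a <- sub$evalue < hsp_e & sub$identity > hsp_identity & sub$length > hsp_len
      # rule B: merged footprint coverage (overlaps counted once)
      iv <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
      cov <- sum(IRanges::width(iv)) / lens[[cid]]
      wid <- sum(sub$identity * sub$matches) / sum(sub$matches)
      best <- which.min(sub$evalue)
      if (any(a)) {
        ba <- which(a)[which.min(sub$evalue[a])]
        calls[[length(calls) + 1L]] <- data.frame(
          contig_id = cid, rule = "hsp_rule",
          best_evalue = sub$evalue[ba], identity = sub$identity[ba],
          coverage = cov, source_id = sub$query_id[ba],
          stringsAsFactors = FALSE)
      } else if (cov >= cov_min && wid >= cov_identity) {
        calls[[length(calls) + 1L]] <- data.frame(
          contig_id = cid, rule = "genome_rule",
          best_evalue = sub$evalue[best], identity = wid,
          coverage = cov, source_id = sub$query_id[best],
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(contig_id = character(), rule = character(),
               best_evalue = numeric(), identity = numeric(),
               coverage = numeric(), source_id = character(),
               stringsAsFactors = FALSE)
  flagged <- unique(calls$contig_id)
  list(calls = calls,
       clean_genome = contigs[!names(contigs) %in% flagged])
}
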