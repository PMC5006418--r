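#' Sensitivity-tuned local-alignment scoring strategies
#'
#' Eight preset parameterisations of word-seeded nucleotide local search,
#' spanning reward/penalty ratios and word sizes chosen to trade speed
#' for sensitivity at high divergence, plus the standard `blastn`
#' default.  Presets with no stated expectation cutoff fall back to the
#' default cutoff of 10.  The theoretical frequency `TF` (the expected
#' identity of optimal local alignments under the scheme) is carried as
#' informational metadata only.
#'
#' @param id One of `"1"`..`"8"` or `"default"` (integers accepted).
#' @param overrides Named list overriding any preset field
#'   (`r`, `q`, `G`, `E_ext`, `W`, `e_cut`).
#' @return A list of class `scoring_scheme` with fields `strategy_id`,
#'   `r` (match reward), `q` (mismatch penalty, negative), `G` (gap open),
#'   `E_ext` (gap extend), `W` (word size), `e_cut` (E-value cutoff),
#'   `TF` (informational).
#' @export
make_strategy <- function(id = "default", overrides = list()) {
  presets <- strategy_presets()
  id <- as.character(id)
  if (!id %in% names(presets))
    stop("unknown strategy '", id, "'; valid ids: ",
         paste(names(presets), collapse = ", "))
  s <- presets[[id]]
  for (nm in names(overrides)) {
    if (!nm %in% c("r", "q", "G", "E_ext", "W", "e_cut"))
      stop("unknown scoring-scheme field: ", nm)
    s[[nm]] <- overrides[[nm]]
  }
  stopifnot(s$r > 0, s$q < 0, s$W >= 4, s$e_cut > 0, s$G >= 0, s$E_ext >= 0)
  structure(s, class = "scoring_scheme")
}

strategy_presets <- function() {
  # e_cut "NA" rows use the default cutoff of 10
  mk <- function(id, r, q, G, e, E, W, TF) {
    list(strategy_id = id, r = r, q = q, G = G,
         e_cut = if (is.na(e)) 10 else e, E_ext = E, W = W, TF = TF)
  }
  list(
    "1" = mk("1", 5, -4, 10, NA, 6, 7, 0.69),
    "2" = mk("2", 4, -5, 3, NA, 5, 7, NA),
    "3" = mk("3", 5, -4, 25, NA, 10, 7, 0.69),
    "4" = mk("4", 4, -5, 12, NA, 8, 7, NA),
    "5" = mk("5", 4, -5, 3, 20, 5, 7, NA),
    "6" = mk("6", 5, -4, 25, 20, 10, 7, 0.69),
    "7" = mk("7", 4, -5, 3, 1000, 5, 7, NA),
    "8" = mk("8", 5, -4, 25, 1000, 10, 7, 0.69),
    "default" = mk("default", 1, -3, 5, 10, 2, 11, 0.99)
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("Scoring strategy %s: r=%d q=%d G=%d E=%d W=%d e_cut=%g\n",
              x$strategy_id, x$r, x$q, x$G, x$E_ext, x$W, x$e_cut))
  invisible(x)
}

#' All strategy identifiers
#' @return Character vector `c("1", ..., "8", "default")`.
#' @export
strategy_ids <- function() names(strategy_presets())

#' Solve Karlin-Altschul statistics for a scoring scheme
#'
#' `lambda` is the unique positive root of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}, found by bisection to
#' \eqn{|f| < 10^{-9}}.  `K` uses the standard ungapped geometric-series
#' approximation; since the gapped lambda is approximated by the ungapped
#' one, E-values serve ranking and thresholding rather than literal
#' probabilities.  `target_frequency` is the match-restricted sum
#' \eqn{\sum_i p_i^2 e^{\lambda r}}, the expected identity of optimal
#' local alignments under the scheme.
#'
#' @param scheme A [make_strategy()] scoring scheme.
#' @param background Length-4 base frequency vector (A,C,G,T).
#' @return List of class `scoring_statistics` with `lambda`, `K`,
#'   `target_frequency`, `background`.
#' @export
solve_statistics <- function(scheme, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4, all(background >= 0))
  background <- background / sum(background)
  p_match <- sum(background^2)
  r <- scheme$r; q <- scheme$q
  expected <- p_match * r + (1 - p_match) * q
  if (expected >= 0)
    stop("invalid scoring system: expected score ", signif(expected, 4),
         " >= 0 (no positive Karlin-Altschul root)")
  f <- function(lambda) p_match * exp(lambda * r) + (1 - p_match) * exp(lambda * q) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-12
  while (hi - lo > 1e-15 && abs(f((lo + hi) / 2)) >= 1e-9) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  lambda <- (lo + hi) / 2
  # geometric-series (renewal) approximation for K on the score lattice
  d <- gcd_int(r, abs(q))
  es_exp <- p_match * r * exp(lambda * r) + (1 - p_match) * q * exp(lambda * q)
  K <- (1 - exp(-lambda * d))^2 / (lambda * d * es_exp)
  structure(list(lambda = lambda, K = K,
                 target_frequency = p_match * exp(lambda * r),
                 background = background),
            class = "scoring_statistics")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' E-value of a raw local-alignment score
#'
#' Karlin-Altschul: \eqn{E = K m n e^{-\lambda S}} with `m` the query
#' length and `n` the searched length (both strands).
#'
#' @param score Raw score(s).
#' @param m Query length (nt).
#' @param n Search-space length (nt, both strands).
#' @param stats A [solve_statistics()] result.
#' @return Numeric E-value(s).
#' @export
karlin_evalue <- function(score, m, n, stats) {
  stats$K * m * n * exp(-stats$lambda * score)
}

#' Word-seeded local alignment of one query against a genome
#'
#' Exact W-mer seeding, ungapped X-drop extension, then banded affine-gap
#' local alignment around segments that reach the gapped trigger score.
#' Both strands are searched (the minus strand via the reverse-complemented
#' query) and reported in forward-strand coordinates with a strand flag.
#' Only HSPs with `evalue <= scheme$e_cut` are returned, in deterministic
#' order (contig, strand, start, score).
#'
#' @param query Query sequence (character) or a single-row data.frame as
#'   returned by [read_query_fasta()].
#' @param genome `DNAStringSet` (or named character vector) of contigs.
#' @param scheme Scoring scheme from [make_strategy()].
#' @param stats Optional precomputed [solve_statistics()]; solved on the
#'   uniform background when missing.
#' @param config List of tuning knobs: `xdrop` (ungapped X-drop, default
#'   `20 * r`), `band` (gapped band width in diagonals, default 40),
#'   `trigger_extra` (extra match-equivalents beyond a perfect word
#'   required to trigger gapped extension, default 6).
#' @param query_id Identifier used in the output.
#' @return Data.frame of HSPs with columns `query_id`, `strategy_id`,
#'   `contig_id`, `start`, `end` (0-based half-open, forward strand),
#'   `strand`, `qstart`, `qend`, `score`, `length`, `matches`,
#'   `identity`, `evalue`.
#' @export
blast_search <- function(query, genome, scheme = make_strategy(),
                         stats = NULL, config = list(), query_id = "query") {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1)
    query_id <- query$family_id
    query <- query$sequence
  }
  query <- chartr("U", "T", toupper(query))
  if (!methods::is(genome, "XStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  m <- nchar(query)
  empty <- hsp_frame()
  if (m < scheme$W) {
    warning("query '", query_id, "' shorter than word size ", scheme$W)
    return(empty)
  }
  if (is.null(stats)) stats <- solve_statistics(scheme)
  xdrop <- config$xdrop %||% (20 * scheme$r)
  band <- config$band %||% 40L
  trigger <- scheme$W * scheme$r + (config$trigger_extra %||% 6L) * scheme$r
  n_space <- 2 * sum(Biostrings::width(genome))
  # minimum raw score implied by the E-value cutoff (guard against junk)
  smin <- ceiling((log(stats$K * m * n_space) - log(scheme$e_cut)) / stats$lambda)
  smin <- max(1L, as.integer(smin))
  rc_query <- reverse_complement(query)
  out <- list()
  for (ci in seq_along(genome)) {
    subject <- as.character(genome[[ci]])
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") query else rc_query
      df <- cpp_seed_extend(qseq, subject, scheme$r, scheme$q, scheme$G,
                            scheme$E_ext, scheme$W, xdrop, band,
                            as.integer(trigger), smin)
      if (!nrow(df)) next
      if (strand == "-") {
        qs <- m - df$qend
        qe <- m - df$qstart
        df$qstart <- qs
        df$qend <- qe
      }
      df$contig_id <- names(genome)[ci]
      df$strand <- strand
      out[[length(out) + 1L]] <- df
    }
  }
  if (!length(out)) return(empty)
  df <- do.call(rbind, out)
  df$identity <- df$matches / df$length
  df$evalue <- karlin_evalue(df$score, m, n_space, stats)
  df <- df[df$evalue <= scheme$e_cut, , drop = FALSE]
  res <- data.frame(
    query_id = rep(query_id, nrow(df)),
    strategy_id = rep(scheme$strategy_id, nrow(df)),
    contig_id = df$contig_id,
    start = df$gstart, end = df$gend, strand = df$strand,
    qstart = df$qstart, qend = df$qend,
    score = df$score, length = df$length, matches = df$matches,
    identity = df$identity, evalue = df$evalue,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$contig_id, res$strand, res$start, -res$score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

hsp_frame <- function() {
  data.frame(query_id = character(), strategy_id = character(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), qstart = integer(), qend = integer(),
             score = integer(), length = integer(), matches = integer(),
             identity = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Search a set of queries under several strategies
#'
#' @param queries Data.frame from [read_query_fasta()].
#' @param genome `DNAStringSet`.
#' @param strategies Character vector of strategy ids.
#' @param config Passed to [blast_search()].
#' @param background Base frequencies for the Karlin-Altschul solve.
#' @return Combined HSP data.frame (one block per query x strategy).
#' @export
multi_strategy_search <- function(queries, genome,
                                  strategies = strategy_ids(),
                                  config = list(),
                                  background = rep(0.25, 4)) {
  out <- list()
  for (sid in strategies) {
    scheme <- make_strategy(sid, overrides = config$overrides[[sid]] %||% list())
    stats <- solve_statistics(scheme, background)
    for (qi in seq_len(nrow(queries))) {
      hits <- blast_search(queries[qi, , drop = FALSE], genome, scheme,
                           stats, config)
      if (nrow(hits)) {
        hits$rna_class <- queries$rna_class[qi]
        hits$species_tag <- queries$species_tag[qi]
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) {
    res <- hsp_frame()
    res$rna_class <- character()
    res$species_tag <- character()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Concatenate a genome into one subject string with N spacers (alignments
# cannot cross a spacer: N scores as mismatch and never seeds).
concat_genome <- function(genome, spacer = 60L) {
  seqs <- as.character(genome)
  lens <- nchar(seqs)
  gap <- strrep("N", spacer)
  offsets <- cumsum(c(0L, head(lens + spacer, -1L)))
  list(seq = paste(seqs, collapse = gap),
       map = data.frame(contig_id = names(genome), offset = offsets,
                        len = lens, stringsAsFactors = FALSE))
}

#' Search many queries under one scheme in a single genome pass
#'
#' Batched variant of [blast_search()] for shuffle-null evaluation: all
#' queries (both orientations) are hashed together and the genome is
#' scanned once.  Results are identical in content to per-query calls.
#'
#' @param qseqs Character vector of query sequences.
#' @param genome `DNAStringSet`.
#' @param scheme,stats,config As in [blast_search()].
#' @return HSP data.frame with a `query_index` column (1-based into
#'   `qseqs`) instead of `query_id`.
#' @export
multi_blast_search <- function(qseqs, genome, scheme, stats = NULL,
                               config = list()) {
  if (!methods::is(genome, "XStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(stats)) stats <- solve_statistics(scheme)
  qseqs <- chartr("U", "T", toupper(qseqs))
  nq <- length(qseqs)
  all_q <- c(qseqs, reverse_complement(qseqs))
  cg <- concat_genome(genome)
  xdrop <- config$xdrop %||% (20 * scheme$r)
  band <- config$band %||% 40L
  trigger <- scheme$W * scheme$r + (config$trigger_extra %||% 6L) * scheme$r
  n_space <- 2 * sum(Biostrings::width(genome))
  m_ref <- max(nchar(qseqs))
  smin <- ceiling((log(stats$K * m_ref * n_space) - log(scheme$e_cut)) / stats$lambda)
  smin <- max(1L, as.integer(smin))
  df <- cpp_seed_extend_multi(all_q, cg$seq, scheme$r, scheme$q, scheme$G,
                              scheme$E_ext, scheme$W, xdrop, band,
                              as.integer(trigger), smin)
  if (!nrow(df)) {
    out <- hsp_frame()
    out$query_index <- integer()
    out$query_id <- NULL
    return(out)
  }
  # map concatenated coordinates back to contigs
  ci <- findInterval(df$gstart, cg$map$offset)
  df$contig_id <- cg$map$contig_id[ci]
  off <- cg$map$offset[ci]
  df$gstart <- df$gstart - off
  df$gend <- df$gend - off
  keep <- df$gend <= cg$map$len[ci]  # drop anything touching a spacer
  df <- df[keep, , drop = FALSE]
  ci <- ci[keep]
  minus <- df$query_index > nq
  df$strand <- ifelse(minus, "-", "+")
  df$query_index <- ifelse(minus, df$query_index - nq, df$query_index)
  mlen <- nchar(qseqs)[df$query_index]
  qs <- ifelse(minus, mlen - df$qend, df$qstart)
  qe <- ifelse(minus, mlen - df$qstart, df$qend)
  df$qstart <- qs
  df$qend <- qe
  df$identity <- df$matches / df$length
  df$evalue <- karlin_evalue(df$score, mlen, n_space, stats)
  df <- df[df$evalue <= scheme$e_cut, , drop = FALSE]
  res <- data.frame(
    query_index = df$query_index,
    strategy_id = rep(scheme$strategy_id, nrow(df)),
    contig_id = df$contig_id,
    start = df$gstart, end = df$gend, strand = df$strand,
    qstart = df$qstart, qend = df$qend,
    score = df$score, length = df$length, matches = df$matches,
    identity = df$identity, evalue = df$evalue,
    stringsAsFactors = FALSE)
  res <- res[order(res$query_index, res$contig_id, res$strand, res$start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
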