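#' Build a miniature covariance model from a seed alignment
#'
#' The consensus secondary structure drives a guide tree of node kinds
#' MATP (paired match columns, 16-way pair emissions), MATL/MATR
#' (unpaired match columns, 4-way emissions) and BIF (multiloops).
#' Match columns are those with less than 50 % gaps; emissions use
#' Laplace (+1) pseudocounts; node ordering is deterministic
#' (leftmost-outermost first).  Rows outside `taxon_filter` (matched
#' against the sequence names of the seed) are dropped before counting,
#' mirroring clade-specific model construction; the topology always
#' comes from the consensus structure alone.
#'
#' @param seed A `seed_alignment`.
#' @param taxon_filter Optional character vector of row names to keep.
#' @return A list of class `covariance_model` with the flat guide-tree
#'   arrays (`kind`, `child1`, `child2`, per-node emissions and
#'   transitions), `clen` (consensus length), `consensus`, `null`
#'   background, and -- after [calibrate_cm()] -- `gumbel` and `GA`.
#' @export
build_cm <- function(seed, taxon_filter = NULL) {
  rows <- seed$rows
  if (!is.null(taxon_filter)) {
    rows <- rows[names(rows) %in% taxon_filter]
    if (!length(rows)) stop("no seed rows survive the taxon filter")
  }
  mat <- do.call(rbind, strsplit(chartr("U", "T", toupper(rows)), ""))
  is_gap <- mat %in% c("-", ".")
  dim(is_gap) <- dim(mat)
  match_cols <- which(colMeans(is_gap) < 0.5)
  if (!length(match_cols)) stop("alignment has no match columns")
  partner_all <- pair_table(seed$ss_cons)
  # structure pairs must survive the match-column projection intact
  in_match <- seq_len(seed$columns) %in% match_cols
  partner_ok <- in_match[ifelse(is.na(partner_all), 1L, partner_all)]
  broken <- which(in_match & !is.na(partner_all) & !partner_ok)
  if (length(broken))
    stop("consensus pairs span non-match (dropped) columns at alignment column ",
         broken[1])
  proj_partner <- rep(NA_integer_, length(match_cols))
  for (k in seq_along(match_cols)) {
    p <- partner_all[match_cols[k]]
    if (!is.na(p)) proj_partner[k] <- match(p, match_cols)
  }
  bases <- c("A", "C", "G", "T")
  res <- mat[!is_gap]
  null <- as.numeric((table(factor(res, levels = bases)) + 1) /
                       (sum(res %in% bases) + 4))
  null <- null / sum(null)

  nodes <- list()
  emit_node <- function(kind, c1 = -1L, c2 = -1L, colL = NA_integer_,
                        colR = NA_integer_) {
    nodes[[length(nodes) + 1L]] <<- list(kind = kind, child1 = c1, child2 = c2,
                                         colL = colL, colR = colR)
    length(nodes)
  }
  # recursive decomposition over match-column indices [a, b]
  decompose <- function(a, b) {
    if (a > b) return(emit_node(4L))
    if (is.na(proj_partner[a])) {
      idx <- emit_node(0L, colL = a)
      child <- decompose(a + 1L, b)
      nodes[[idx]]$child1 <<- child
      return(idx)
    }
    p <- proj_partner[a]
    if (p == b) {
      idx <- emit_node(2L, colL = a, colR = b)
      child <- decompose(a + 1L, b - 1L)
      nodes[[idx]]$child1 <<- child
      return(idx)
    }
    if (is.na(proj_partner[b])) {
      idx <- emit_node(1L, colR = b)
      child <- decompose(a, b - 1L)
      nodes[[idx]]$child1 <<- child
      return(idx)
    }
    # a pairs inside [a, b): bifurcation into [a, p] and [p+1, b]
    idx <- emit_node(3L)
    c1 <- decompose(a, p)
    c2 <- decompose(p + 1L, b)
    nodes[[idx]]$child1 <<- c1
    nodes[[idx]]$child2 <<- c2
    idx
  }
  decompose(1L, length(match_cols))
  nn <- length(nodes)
  kind <- vapply(nodes, `[[`, 0L, "kind")
  child1 <- vapply(nodes, `[[`, 0L, "child1") - 1L  # 0-based for C++
  child2 <- vapply(nodes, `[[`, 0L, "child2") - 1L
  emL <- matrix(0, nn, 4)
  emP <- matrix(0, nn, 16)
  tM <- tD <- numeric(nn)
  nrows <- nrow(mat)
  for (k in seq_len(nn)) {
    nd <- nodes[[k]]
    if (nd$kind %in% c(0L, 1L)) {
      col <- match_cols[if (nd$kind == 0L) nd$colL else nd$colR]
      cnt <- table(factor(mat[, col], levels = bases))
      emL[k, ] <- (cnt + 1) / (sum(cnt) + 4)
      used <- sum(!is_gap[, col])
      tM[k] <- (used + 1) / (nrows + 2)
    } else if (nd$kind == 2L) {
      cl <- match_cols[nd$colL]; cr <- match_cols[nd$colR]
      ok <- !is_gap[, cl] & !is_gap[, cr]
      pair <- paste0(mat[ok, cl], mat[ok, cr])
      lv <- paste0(rep(bases, each = 4), rep(bases, times = 4))  # left-major a*4+b
      cnt <- table(factor(pair, levels = lv))
      # row-major (left base * 4 + right base) to match the C++ lookup
      emP[k, ] <- as.numeric((cnt + 1) / (sum(cnt) + 16))
      tM[k] <- (sum(ok) + 1) / (nrows + 2)
    } else {
      tM[k] <- 1
    }
    tD[k] <- 1 - tM[k]
    if (kind[k] %in% c(3L, 4L)) { tM[k] <- 1; tD[k] <- 1 }  # unused; keep log finite
  }
  clen <- sum(kind == 0L) + sum(kind == 1L) + 2L * sum(kind == 2L)
  cons <- character(length(match_cols))
  for (k in seq_len(nn)) {
    nd <- nodes[[k]]
    if (nd$kind == 0L) cons[nd$colL] <- bases[which.max(emL[k, ])]
    if (nd$kind == 1L) cons[nd$colR] <- bases[which.max(emL[k, ])]
    if (nd$kind == 2L) {
      best <- which.max(emP[k, ]) - 1L
      cons[nd$colL] <- bases[best %/% 4L + 1L]
      cons[nd$colR] <- bases[best %% 4L + 1L]
    }
  }
  structure(list(family_id = seed$family_id, kind = kind, child1 = child1,
                 child2 = child2, emL = emL, emP = emP, tM = tM, tD = tD,
                 t_ins = 0.01, clen = clen, null = null,
                 consensus = paste0(cons, collapse = ""),
                 ss_cons_match = paste0(
                   ifelse(is.na(proj_partner), ".",
                          ifelse(proj_partner > seq_along(proj_partner), "(", ")")),
                   collapse = ""),
                 GA = NULL, gumbel = NULL),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("Covariance model '", x$family_id, "': clen=", x$clen, ", ",
      length(x$kind), " nodes",
      if (!is.null(x$gumbel)) sprintf(", calibrated (GA=%.1f bits)", x$GA) else
        " (uncalibrated)",
      "\n", sep = "")
  invisible(x)
}

cm_log_params <- function(cm) {
  lemL <- log(sweep(cm$emL, 2, cm$null, "/"))
  lemL[!is.finite(lemL)] <- 0
  pr_null <- cm$null[rep(1:4, each = 4)] * cm$null[rep(1:4, times = 4)]  # left-major a*4+b
  lemP <- log(sweep(cm$emP, 2, pr_null, "/"))
  lemP[!is.finite(lemP)] <- 0
  list(lemL = lemL, lemP = lemP, ltM = log(cm$tM), ltD = log(pmax(cm$tD, 1e-12)),
       ltI = rep(log(cm$t_ins), length(cm$kind)))
}

#' Score a sequence against a covariance model by CYK
#'
#' Global in the model (every consensus position is matched or deleted),
#' local in the sequence: the best-scoring parse of any substring is
#' reported, with residues outside the parse free, so scores are
#' comparable across window lengths.  `bitscore_global` is the strictly
#' global score in which every sequence residue must be emitted
#' (matched or inserted) -- the quantity the exhaustive parse
#' enumeration defines.  Log-odds are in bits against the background
#' null.  `matched_positions` counts the consensus columns aligned to
#' residues (MATP counts two), for model coverage;
#' `align_start`/`align_end` give the footprint of match-emitted
#' residues (0-based half-open).
#'
#' @param cm A [build_cm()] model.
#' @param seq DNA string; at most `max_mult * clen` long.
#' @param max_mult Window cap multiplier (default 4).
#' @return List with `bitscore`, `bitscore_global`, `matched_positions`,
#'   `align_start`, `align_end`.
#' @export
cm_cyk <- function(cm, seq, max_mult = 4) {
  n <- nchar(seq)
  if (n > max_mult * cm$clen)
    stop("sequence length ", n, " exceeds ", max_mult, " * clen = ",
         max_mult * cm$clen, "; use a windowed search (cm_score_window)")
  lp <- cm_log_params(cm)
  res <- cpp_cyk(encode_dna(seq), cm$kind, cm$child1, cm$child2,
                 lp$lemL, lp$lemP, lp$ltM, lp$ltD, lp$ltI)
  list(bitscore = res$bits, bitscore_global = res$bits_global,
       matched_positions = res$matched,
       align_start = res$align_start, align_end = res$align_end)
}

#' Best CYK score over sliding sub-windows of a longer sequence
#'
#' Scans windows of `2 * clen` (50 % overlap) so regions longer than the
#' CYK cap can be scored; returns the best-scoring window's result with
#' coordinates offset into the full sequence.
#'
#' @param cm Covariance model.
#' @param seq DNA string of any length.
#' @return As [cm_cyk()], plus `window_start` (0-based offset).
#' @export
cm_score_window <- function(cm, seq) {
  n <- nchar(seq)
  win <- 2L * cm$clen
  if (n <= win) {
    res <- cm_cyk(cm, seq)
    res$window_start <- 0L
    return(res)
  }
  starts <- unique(c(seq(0L, n - win, by = max(1L, cm$clen %/% 2L)), n - win))
  best <- NULL
  for (s in starts) {
    res <- cm_cyk(cm, substr(seq, s + 1L, s + win))
    if (is.null(best) || res$bitscore > best$bitscore) {
      res$window_start <- s
      best <- res
    }
  }
  best$align_start <- best$align_start + best$window_start
  best$align_end <- best$align_end + best$window_start
  best
}

#' Calibrate a covariance model on shuffled sequences
#'
#' Scores `n` mononucleotide shuffles of the model consensus and fits a
#' Gumbel distribution to the null bitscores by maximum likelihood.
#' E-values at search time use the exact Gumbel tail scaled by the
#' number of scoring trials.  Unless a gathering threshold is supplied,
#' `GA` is set to the maximum null score plus 2 bits.
#'
#' @param cm Covariance model.
#' @param n Number of shuffles (at least 100).
#' @param seed RNG seed.
#' @param GA Optional externally supplied gathering threshold (bits);
#'   when given, calibration leaves it untouched.
#' @return The model with `gumbel` (`mu`, `beta`, `lambda`) and `GA` set.
#' @export
calibrate_cm <- function(cm, n = 1000L, seed = 1L, GA = NULL) {
  if (n < 100) stop("calibration requires n >= 100")
  scores <- with_seed(seed, {
    chars <- strsplit(cm$consensus, "")[[1]]
    vapply(seq_len(n), function(i) {
      cm_cyk(cm, paste0(sample(chars), collapse = ""))$bitscore
    }, 0)
  })
  if (sd(scores) < 1e-9) stop("degenerate null score distribution")
  cm$gumbel <- fit_gumbel(scores)
  cm$gumbel$n_calibration <- n
  cm$GA <- GA %||% (max(scores) + 2)
  cm
}

#' E-value of a CM bitscore
#'
#' @param cm Calibrated model.
#' @param bitscore Score(s) in bits.
#' @param n_search Number of scoring trials in the search the E-value
#'   refers to.
#' @return Expected number of null trials at or above `bitscore`.
#' @export
cm_evalue <- function(cm, bitscore, n_search = 1) {
  if (is.null(cm$gumbel)) stop("model is not calibrated; run calibrate_cm()")
  n_search * gumbel_tail(bitscore, cm$gumbel)
}

#' Validate candidate regions with a covariance model
#'
#' Each region is CYK-scored on both strands (reported on the better
#' one, relative to the region's own orientation) and accepted iff its
#' bitscore is not lower than the gathering threshold, its E-value is
#' below 0.01, and the parse covers at least 70 % of the model's
#' consensus positions.
#'
#' @param cm Calibrated covariance model.
#' @param regions Candidate data.frame (from [build_candidates()] or
#'   [search_phmm()] envelopes equipped with a `sequence` column via
#'   [regions_with_sequence()]).
#' @param e_max E-value threshold (strict `<`).
#' @param min_coverage Minimum model coverage (inclusive).
#' @return Data.frame of CM hits: region columns plus `bitscore`,
#'   `evalue`, `model_coverage`, `cm_start`, `cm_end` (footprint in
#'   forward-strand genome coordinates) and `status`
#'   (`"accepted"`/`"raw"`).
#' @export
search_cm <- function(cm, regions, e_max = 0.01, min_coverage = 0.70) {
  if (is.null(cm$gumbel)) stop("model is not calibrated; run calibrate_cm()")
  if (!nrow(regions)) return(cbind(regions[0, , drop = FALSE],
                                   bitscore = numeric(), evalue = numeric(),
                                   model_coverage = numeric(),
                                   status = character()))
  n_search <- 2L * nrow(regions)
  out <- regions
  out$bitscore <- NA_real_
  out$model_coverage <- NA_real_
  out$cm_start <- NA_integer_
  out$cm_end <- NA_integer_
  flipped <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$sequence[i]
    fw <- cm_score_window(cm, s)
    rv <- cm_score_window(cm, reverse_complement(s))
    use_rv <- rv$bitscore > fw$bitscore
    res <- if (use_rv) rv else fw
    flipped[i] <- use_rv
    out$bitscore[i] <- res$bitscore
    out$model_coverage[i] <- res$matched_positions / cm$clen
    # footprint relative to the region's own (stranded) sequence
    a <- res$align_start; b <- res$align_end
    L <- nchar(s)
    if (use_rv) { tmp <- a; a <- L - b; b <- L - tmp }
    # map to forward-strand genome coordinates
    if (identical(regions$strand[i], "-")) {
      out$cm_start[i] <- regions$end[i] - b
      out$cm_end[i] <- regions$end[i] - a
    } else {
      out$cm_start[i] <- regions$start[i] + a
      out$cm_end[i] <- regions$start[i] + b
    }
  }
  out$strand <- ifelse(flipped, ifelse(regions$strand == "+", "-", "+"),
                       regions$strand)
  out$evalue <- cm_evalue(cm, out$bitscore, n_search)
  out$status <- ifelse(out$bitscore >= cm$GA & out$evalue < e_max &
                         out$model_coverage >= min_coverage,
                       "accepted", "raw")
  rownames(out) <- NULL
  out
}

#' Resolve overlapping CM hits
#'
#' Overlapping hits of the same family are merged to the coordinate hull
#' keeping the best bitscore; for overlapping hits of different families
#' the best hit wins (maximum bitscore, ties broken by smaller E-value,
#' then lexicographic family id).
#'
#' @param hits Data.frame with `family_id`, `contig_id`, `cm_start`,
#'   `cm_end` (or `start`/`end`), `bitscore`, `evalue`.
#' @return Data.frame with no overlapping intervals from different
#'   families.
#' @export
resolve_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  sc <- if ("cm_start" %in% names(hits)) "cm_start" else "start"
  ec <- if ("cm_end" %in% names(hits)) "cm_end" else "end"
  # 1) same-family merges to the hull
  merged <- list()
  for (key in unique(paste(hits$family_id, hits$contig_id))) {
    grp <- hits[paste(hits$family_id, hits$contig_id) == key, , drop = FALSE]
    grp <- grp[order(grp[[sc]], grp[[ec]]), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    for (i in seq_len(nrow(grp))[-1]) {
      nxt <- grp[i, , drop = FALSE]
      if (nxt[[sc]] < cur[[ec]]) {  # overlap
        cur[[ec]] <- max(cur[[ec]], nxt[[ec]])
        if (nxt$bitscore > cur$bitscore ||
            (nxt$bitscore == cur$bitscore && nxt$evalue < cur$evalue)) {
          keep_cols <- setdiff(names(cur), c(sc, ec))
          cur[keep_cols] <- nxt[keep_cols]
        }
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nxt
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  df <- do.call(rbind, merged)
  # 2) cross-family conflicts: best bitscore, then E-value, then family id
  df <- df[order(df$contig_id, -df$bitscore, df$evalue, df$family_id), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(df))) {
    cand <- df[i, , drop = FALSE]
    clash <- FALSE
    for (k in seq_along(kept)) {
      ex <- kept[[k]]
      if (ex$contig_id != cand$contig_id) next
      if (cand[[sc]] < ex[[ec]] && ex[[sc]] < cand[[ec]]) { clash <- TRUE; break }
    }
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  res <- do.call(rbind, kept)
  res <- res[order(res$contig_id, res[[sc]]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Final curation of accepted CM hits
#'
#' Each accepted hit is re-extracted with 300 nt of flanking sequence
#' (clipped at contig edges, with a `clipped` flag), re-scored against
#' the model, and emitted as an annotated locus iff the re-scored
#' E-value is below 0.01 and the bitscore is strictly greater than the
#' gathering threshold.  Coordinates are tightened to the re-scored
#' alignment footprint.
#'
#' @param hits Accepted CM hits (from [search_cm()]; rows with
#'   `status == "accepted"` are curated, others are returned as logged
#'   rejections).
#' @param genome `DNAStringSet`.
#' @param cm Calibrated model.
#' @param flank Flanking length (nt, default 300).
#' @param e_max Curation E-value threshold (strict `<`).
#' @return List with `loci` (curated annotated loci) and `rejected`
#'   (hits that failed curation, with a `reason` column).
#' @export
curate_final <- function(hits, genome, cm, flank = 300L, e_max = 0.01) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  sc <- if ("cm_start" %in% names(hits)) "cm_start" else "start"
  ec <- if ("cm_end" %in% names(hits)) "cm_end" else "end"
  loci <- list()
  rejected <- list()
  n_search <- 2L * max(1L, sum(hits$status == "accepted"))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    if (!identical(h$status, "accepted")) {
      h$reason <- "not accepted at screening"
      rejected[[length(rejected) + 1L]] <- h
      next
    }
    clen <- lens[[h$contig_id]]
    ws <- max(0L, h[[sc]] - flank)
    we <- min(clen, h[[ec]] + flank)
    clipped <- (h[[sc]] - flank < 0L) || (h[[ec]] + flank > clen)
    wseq <- interval_sequence(genome, h$contig_id, ws, we, h$strand)
    res <- cm_score_window(cm, wseq)
    ev <- cm_evalue(cm, res$bitscore, n_search)
    if (ev < e_max && res$bitscore > cm$GA) {
      a <- res$align_start; b <- res$align_end
      L <- nchar(wseq)
      if (identical(h$strand, "-")) {
        fs <- we - b; fe <- we - a
      } else {
        fs <- ws + a; fe <- ws + b
      }
      loci[[length(loci) + 1L]] <- data.frame(
        family_id = h$family_id,
        rna_class = h$rna_class %||% NA_character_,
        contig_id = h$contig_id, start = fs, end = fe, strand = h$strand,
        bitscore = res$bitscore, evalue = ev,
        evidence = h$evidence %||% "blast",
        clipped = clipped, curated = TRUE,
        stringsAsFactors = FALSE)
    } else {
      h$reason <- if (ev >= e_max) "curation E-value" else "curation bitscore <= GA"
      rejected[[length(rejected) + 1L]] <- h
    }
  }
  list(
    loci = if (length(loci)) do.call(rbind, loci) else locus_frame(),
    rejected = if (length(rejected)) do.call(rbind, rejected) else hits[0, , drop = FALSE]
  )
}

locus_frame <- function() {
  data.frame(family_id = character(), rna_class = character(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), bitscore = numeric(), evalue = numeric(),
             evidence = character(), clipped = logical(), curated = logical(),
             stringsAsFactors = FALSE)
}

#' Attach genomic sequences to hit/region tables
#'
#' @param regions Data.frame with `contig_id`, `start`, `end`, `strand`.
#' @param genome `DNAStringSet`.
#' @return The table with a `sequence` column (minus-strand regions are
#'   reverse-complemented).
#' @export
regions_with_sequence <- function(regions, genome) {
  regions$sequence <- vapply(seq_len(nrow(regions)), function(i) {
    interval_sequence(genome, regions$contig_id[i], regions$start[i],
                      regions$end[i], regions$strand[i])
  }, "")
  regions
}
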