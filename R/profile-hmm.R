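#' Build a profile HMM from a seed alignment
#'
#' Match columns are the alignment columns with less than 50 % gap
#' characters.  Emission and transition probabilities are estimated from
#' counts with Laplace (+1) pseudocounts; insert states emit the
#' background (null) distribution, which is taken from the seed's
#' residue frequencies.
#'
#' @param seed A `seed_alignment` (see [read_stockholm()]).
#' @return A list of class `profile_hmm` with fields `family_id`, `M`,
#'   `emissions` (M x 4 probability matrix), `transitions` (M x 7 matrix,
#'   columns `MM,MI,MD,IM,II,DM,DD`), `null` (background 4-vector),
#'   `match_columns` (indices into the alignment), `consensus`.
#' @export
build_phmm <- function(seed) {
  rows <- toupper(seed$rows)
  stopifnot(length(rows) >= 1)
  mat <- do.call(rbind, strsplit(chartr("U", "T", rows), ""))
  is_gap <- mat %in% c("-", ".")
  dim(is_gap) <- dim(mat)
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < 0.5)
  M <- length(match_cols)
  if (M == 0) stop("alignment has no match columns (all columns >=50% gaps)")
  bases <- c("A", "C", "G", "T")
  res <- mat[!is_gap]
  null <- (table(factor(res, levels = bases)) + 1) / (length(res[res %in% bases]) + 4)
  null <- as.numeric(null / sum(null))
  emis <- matrix(0, M, 4, dimnames = list(NULL, bases))
  for (k in seq_len(M)) {
    cnt <- table(factor(mat[, match_cols[k]], levels = bases))
    emis[k, ] <- (cnt + 1) / (sum(cnt) + 4)
  }
  # transition counts from each row's match/delete/insert path
  tc <- matrix(1, M, 7, dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  col_state <- rep("I", ncol(mat))
  col_state[match_cols] <- "M"
  node_of <- cumsum(col_state == "M")  # insert columns belong to the preceding node
  for (r in seq_len(nrow(mat))) {
    prev_state <- NULL; prev_node <- 0L
    for (cix in seq_len(ncol(mat))) {
      st <- if (col_state[cix] == "M") {
        if (is_gap[r, cix]) "D" else "M"
      } else {
        if (is_gap[r, cix]) NA else "I"
      }
      if (is.na(st)) next
      node <- node_of[cix]
      if (!is.null(prev_state) && prev_node >= 1 && prev_node < M) {
        key <- paste0(prev_state, st)
        if (key %in% colnames(tc)) tc[prev_node, key] <- tc[prev_node, key] + 1
      }
      prev_state <- st
      prev_node <- if (st == "I") node else node
    }
  }
  trans <- matrix(0, M, 7, dimnames = dimnames(tc))
  for (k in seq_len(M)) {
    trans[k, 1:3] <- tc[k, 1:3] / sum(tc[k, 1:3])
    trans[k, 4:5] <- tc[k, 4:5] / sum(tc[k, 4:5])
    trans[k, 6:7] <- tc[k, 6:7] / sum(tc[k, 6:7])
  }
  consensus <- paste0(bases[apply(emis, 1, which.max)], collapse = "")
  structure(list(family_id = seed$family_id, M = M, emissions = emis,
                 transitions = trans, null = null,
                 match_columns = match_cols, consensus = consensus),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM '", x$family_id, "': ", x$M, " match states\n", sep = "")
  invisible(x)
}

phmm_log_params <- function(phmm) {
  lodds <- log(sweep(phmm$emissions, 2, phmm$null, "/"))
  list(memis = lodds, trans = log(phmm$transitions))
}

#' Score a sequence against a profile HMM
#'
#' Local (free entry/exit) Viterbi and forward log-odds versus the null
#' model, in bits, plus the posterior envelope: the maximal contiguous
#' region where the posterior probability that a residue is emitted by
#' the model (rather than the flanking null) is at least 0.5, computed
#' by forward-backward.
#'
#' @param phmm A [build_phmm()] model.
#' @param seq DNA string.
#' @return List with `viterbi_bits`, `forward_bits`, `backward_bits`
#'   (forward-backward consistency check), `envelope` (0-based half-open
#'   `c(start, end)`, or `c(0, 0)` when no position reaches 0.5) and
#'   `posterior` (per-position model occupancy).
#' @export
score_sequence <- function(phmm, seq) {
  codes <- encode_dna(seq)
  stopifnot(length(codes) >= 1)
  lp <- phmm_log_params(phmm)
  res <- cpp_phmm_dp(codes, lp$memis, lp$trans, TRUE)
  post <- res$post
  env <- c(0L, 0L)
  hit <- which(post >= 0.5)
  if (length(hit)) {
    anchor <- which.max(post)
    lo <- anchor
    while (lo > 1 && post[lo - 1] >= 0.5) lo <- lo - 1
    hi <- anchor
    while (hi < length(post) && post[hi + 1] >= 0.5) hi <- hi + 1
    env <- c(lo - 1L, hi)
  }
  list(viterbi_bits = res$viterbi / log(2),
       forward_bits = res$forward / log(2),
       backward_bits = res$backward / log(2),
       envelope = env, posterior = post)
}

encode_dna <- function(seq) {
  codes <- match(strsplit(chartr("U", "T", toupper(seq)), "")[[1]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L
  as.integer(codes - 1L)
}

#' Scan a genome with a profile HMM
#'
#' Windows of length `2 * M` are scanned with stride `M` on both strands
#' and scored by the forward algorithm.  E-values come from a Gumbel fit
#' (maximum likelihood) to the forward bitscores of `null_samples`
#' mononucleotide-shuffled genome windows, scaled by the number of
#' windows scanned.  Overlapping passing windows are merged and the
#' posterior envelope of each merged region is reported as the candidate
#' interval.  Only hits with `evalue <= e_max` are returned.
#'
#' @param phmm A [build_phmm()] model.
#' @param genome `DNAStringSet`.
#' @param e_max E-value cutoff (default 0.01).
#' @param null_samples Number of shuffled windows for calibration
#'   (at least 100).
#' @param seed RNG seed for the calibration shuffles.
#' @return Data.frame of hits: `family_id`, `contig_id`, `start`, `end`,
#'   `strand`, `bitscore`, `evalue` (envelope coordinates, 0-based
#'   half-open, forward strand).
#' @export
search_phmm <- function(phmm, genome, e_max = 0.01, null_samples = 1000L,
                        seed = 1L) {
  if (null_samples < 100) stop("calibration requires null_samples >= 100")
  if (!methods::is(genome, "XStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  lp <- phmm_log_params(phmm)
  win <- 2L * phmm$M
  stride <- phmm$M
  # calibration: forward bitscores of shuffled genome windows
  null_bits <- with_seed(seed, {
    widths <- Biostrings::width(genome)
    ok <- which(widths >= win)
    if (!length(ok)) stop("no contig long enough for calibration window")
    vapply(seq_len(null_samples), function(i) {
      ci <- ok[sample.int(length(ok), 1)]
      s0 <- sample.int(widths[ci] - win + 1L, 1)
      w <- as.character(Biostrings::subseq(genome[[ci]], s0, s0 + win - 1L))
      shuf <- paste0(sample(strsplit(w, "")[[1]]), collapse = "")
      cpp_phmm_dp(encode_dna(shuf), lp$memis, lp$trans, FALSE)$forward / log(2)
    }, 0)
  })
  if (sd(null_bits) < 1e-9) stop("degenerate calibration score distribution")
  fit <- fit_gumbel(null_bits)
  hits <- list()
  for (ci in seq_along(genome)) {
    seq_fwd <- as.character(genome[[ci]])
    clen <- nchar(seq_fwd)
    if (clen < min(win, phmm$M)) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else reverse_complement(seq_fwd)
      sc <- cpp_phmm_scan(encode_dna(s), lp$memis, lp$trans, win, stride)
      if (!nrow(sc)) next
      bits <- sc[, 2] / log(2)
      hits[[length(hits) + 1L]] <- data.frame(
        contig_id = names(genome)[ci], strand = strand,
        wstart = as.integer(sc[, 1]), bits = bits,
        clen = clen, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(hmm_hit_frame())
  allw <- do.call(rbind, hits)
  n_search <- nrow(allw)
  allw$evalue <- n_search * gumbel_tail(allw$bits, fit)
  allw <- allw[allw$evalue <= e_max, , drop = FALSE]
  if (!nrow(allw)) return(hmm_hit_frame())
  # merge overlapping passing windows per contig/strand, then envelope
  out <- list()
  for (key in unique(paste(allw$contig_id, allw$strand))) {
    grp <- allw[paste(allw$contig_id, allw$strand) == key, , drop = FALSE]
    grp <- grp[order(grp$wstart), , drop = FALSE]
    runs <- split_runs(grp$wstart, win)
    for (run in runs) {
      sub <- grp[run, , drop = FALSE]
      rs <- min(sub$wstart)
      re <- min(sub$clen[1], max(sub$wstart) + win)
      cid <- sub$contig_id[1]
      strand <- sub$strand[1]
      region_fwd <- if (strand == "+") {
        c(rs, re)
      } else {
        c(sub$clen[1] - re, sub$clen[1] - rs)
      }
      rseq <- interval_sequence(genome, cid, region_fwd[1], region_fwd[2], strand)
      scr <- score_sequence(phmm, rseq)
      env <- scr$envelope
      if (env[2] <= env[1]) env <- c(0L, nchar(rseq))
      env_fwd <- if (strand == "+") {
        region_fwd[1] + env
      } else {
        c(region_fwd[2] - env[2], region_fwd[2] - env[1])
      }
      ev <- n_search * gumbel_tail(scr$forward_bits, fit)
      out[[length(out) + 1L]] <- data.frame(
        family_id = phmm$family_id, contig_id = cid,
        start = env_fwd[1], end = env_fwd[2], strand = strand,
        bitscore = scr$forward_bits, evalue = ev,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$evalue <= e_max, , drop = FALSE]
  res <- res[order(res$contig_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

hmm_hit_frame <- function() {
  data.frame(family_id = character(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             bitscore = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

# group sorted window starts into runs of mutually-overlapping windows
split_runs <- function(starts, win) {
  runs <- list()
  cur <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - starts[i - 1] <= win) {
      cur <- c(cur, i)
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- i
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location `mu` and scale `beta` of a Gumbel (type-I extreme value)
#' distribution by maximum likelihood (profile likelihood in `beta`
#' solved with [stats::uniroot()]).
#'
#' @param x Numeric sample.
#' @return List with `mu`, `beta`, `lambda` (= 1/beta).
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10)
  if (sd(x) < 1e-12) stop("degenerate sample: zero variance")
  g <- function(beta) {
    w <- exp(-(x - max(x)) / beta)
    beta - mean(x) + sum(x * w) / sum(w)
  }
  lo <- sd(x) / 50
  hi <- sd(x) * 50
  while (g(lo) > 0 && lo > 1e-12) lo <- lo / 4
  while (g(hi) < 0 && hi < 1e12) hi <- hi * 4
  beta <- uniroot(g, c(lo, hi), tol = 1e-10)$root
  mu <- -beta * log(mean(exp(-(x - max(x)) / beta))) + max(x)
  list(mu = mu, beta = beta, lambda = 1 / beta)
}

# P(X >= s) under a fitted Gumbel
gumbel_tail <- function(s, fit) {
  1 - exp(-exp(-(s - fit$mu) / fit$beta))
}
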