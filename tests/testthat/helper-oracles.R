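# Independent brute-force oracles.  These deliberately share no code
# with the package's compiled implementations: plain-R dynamic programs
# and exhaustive enumerations, usable only at toy scale.

# Full affine-gap local alignment (gap of length k costs G + k*E) with
# traceback; returns the optimal score and the longest run of exact
# diagonal matches on one optimal path.
sw_oracle <- function(a, b, r, q, G, E) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B); NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    X[i, j] <- max(H[i - 1, j] - (G + E), X[i - 1, j] - E)
    Y[i, j] <- max(H[i, j - 1] - (G + E), Y[i, j - 1] - E)
    s <- if (A[i - 1] == B[j - 1]) r else q
    H[i, j] <- max(0, H[i - 1, j - 1] + s, X[i, j], Y[i, j])
  }
  best <- max(H)
  hit <- which(H == best, arr.ind = TRUE)[1, ]
  # traceback one optimal path, recording match-run lengths
  i <- hit[1]; j <- hit[2]; state <- "H"
  run <- 0; maxrun <- 0
  while (i > 1 || j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      s <- if (A[i - 1] == B[j - 1]) r else q
      if (i > 1 && j > 1 && H[i, j] == H[i - 1, j - 1] + s) {
        if (A[i - 1] == B[j - 1]) { run <- run + 1; maxrun <- max(maxrun, run) }
        else run <- 0
        i <- i - 1; j <- j - 1
      } else if (H[i, j] == X[i, j]) { state <- "X"; run <- 0 }
      else { state <- "Y"; run <- 0 }
    } else if (state == "X") {
      if (X[i, j] == H[i - 1, j] - (G + E)) { i <- i - 1; state <- "H" }
      else { i <- i - 1 }
    } else {
      if (Y[i, j] == H[i, j - 1] - (G + E)) { j <- j - 1; state <- "H" }
      else { j <- j - 1 }
    }
  }
  list(score = best, max_match_run = maxrun)
}

# Exhaustive sum over all local alignment paths of a profile HMM
# (uniform 1/M entry and exit weights, free flanks), in bits.
enum_forward_phmm <- function(ph, seq) {
  codes <- rnahomology:::encode_dna(seq)
  L <- length(codes); M <- ph$M
  lo <- ph$emissions / matrix(ph$null, M, 4, byrow = TRUE)
  tr <- ph$transitions
  total <- 0
  walk <- function(kind, k, i, p) {
    if (kind == "M") {
      if (i > L) return()
      em <- if (codes[i] >= 4) 1 else lo[k, codes[i] + 1]
      p <- p * em
      total <<- total + p * (1 / M)
      if (k < M) {
        walk("M", k + 1, i + 1, p * tr[k, "MM"])
        walk("I", k, i + 1, p * tr[k, "MI"])
        walk("D", k + 1, i + 1, p * tr[k, "MD"])
      }
    } else if (kind == "I") {
      if (i > L) return()
      walk("M", k + 1, i + 1, p * tr[k, "IM"])
      walk("I", k, i + 1, p * tr[k, "II"])
    } else {
      if (k < M) {
        walk("M", k + 1, i, p * tr[k, "DM"])
        walk("D", k + 1, i, p * tr[k, "DD"])
      }
    }
  }
  for (start in seq_len(L)) for (k in seq_len(M)) walk("M", k, start, 1 / M)
  unname(log2(total))
}

# Memoised exhaustive maximisation over covariance-model parse trees,
# following the same grammar semantics as the package model but written
# as a direct recursion over the guide tree; strictly global in the
# sequence (the quantity cm_cyk() reports as bitscore_global).
cyk_enum_oracle <- function(cm, seq) {
  codes <- rnahomology:::encode_dna(seq)
  lp <- rnahomology:::cm_log_params(cm)
  n <- length(codes)
  memo <- new.env(hash = TRUE)
  V <- function(k, i, j) {
    key <- paste(k, i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    kd <- cm$kind[k + 1]; c1 <- cm$child1[k + 1]; c2 <- cm$child2[k + 1]
    len <- j - i
    best <- -Inf
    if (kd == 4L) {
      best <- len * lp$ltI[k + 1]
    } else if (kd == 3L) {
      for (m in i:j) best <- max(best, V(c1, i, m) + V(c2, m, j))
    } else {
      if (kd == 0L && len >= 1) {
        em <- if (codes[i + 1] >= 4) 0 else lp$lemL[k + 1, codes[i + 1] + 1]
        best <- max(best, lp$ltM[k + 1] + em + V(c1, i + 1, j))
      }
      if (kd == 1L && len >= 1) {
        em <- if (codes[j] >= 4) 0 else lp$lemL[k + 1, codes[j] + 1]
        best <- max(best, lp$ltM[k + 1] + em + V(c1, i, j - 1))
      }
      if (kd == 2L && len >= 2) {
        em <- if (codes[i + 1] >= 4 || codes[j] >= 4) 0 else
          lp$lemP[k + 1, codes[i + 1] * 4 + codes[j] + 1]
        best <- max(best, lp$ltM[k + 1] + em + V(c1, i + 1, j - 1))
      }
      best <- max(best, lp$ltD[k + 1] + V(c1, i, j))
      if (len >= 1 && kd %in% c(0L, 2L))
        best <- max(best, lp$ltI[k + 1] + V(k, i + 1, j))
      if (len >= 1 && kd %in% c(1L, 2L))
        best <- max(best, lp$ltI[k + 1] + V(k, i, j - 1))
    }
    memo[[key]] <- best
    best
  }
  V(0, 0, n) / log(2)
}

# Minimal loss count over all single-gain Dollo assignments, by
# exhaustive enumeration of the gain node.
dollo_loss_oracle <- function(tree, leaf_states) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  par <- rnahomology:::tree_parent(tree)
  tu <- rnahomology:::tips_under(tree)
  pres <- which(leaf_states[tree$tip.label] == 1)
  if (!length(pres)) return(0L)
  best <- Inf
  for (g in seq_len(nn)) {
    if (!all(pres %in% tu[[g]])) next
    present <- rep(FALSE, nn)
    for (v in pres) {
      p <- v
      repeat {
        present[p] <- TRUE
        if (p == g) break
        p <- par[p]
        if (is.na(p)) break
      }
    }
    losses <- sum(present[tree$edge[, 1]] & !present[tree$edge[, 2]])
    best <- min(best, losses)
  }
  as.integer(best)
}
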