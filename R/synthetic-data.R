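#' Generate an i.i.d. background sequence with a given GC content
#'
#' Bases are drawn independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`; the default GC of 0.36 matches the
#' AT-rich composition typical of tunicate draft assemblies.
#'
#' @param length Sequence length (nt).
#' @param gc GC content in `(0, 1)` (boundaries produce two-letter
#'   sequences).
#' @param seed RNG seed (NULL uses the current RNG stream).
#' @return DNA string.
#' @export
generate_background <- function(length, gc = 0.36, seed = NULL) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  with_seed(seed, {
    paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
           collapse = "")
  })
}

#' Mutate a sequence to a target pairwise identity
#'
#' Substitutions are placed uniformly (never twice at one site) until the
#' identity implied by the edit trace reaches the target; indels (single
#' nt, insertion or deletion with equal probability) are then added at
#' `indel_rate` per column.  Identity is measured on the true alignment
#' known from the trace: matches / alignment columns, so with no indels
#' it equals the Hamming identity exactly.
#'
#' @param seq Source DNA string.
#' @param target_identity Target identity in `[0, 1]`.
#' @param indel_rate Expected indels per column.
#' @param seed RNG seed.
#' @return List with `mutant` and `realized_identity`.
#' @export
mutate_to_identity <- function(seq, target_identity, indel_rate = 0,
                               seed = NULL) {
  stopifnot(target_identity >= 0, target_identity <= 1)
  with_seed(seed, {
    chars <- strsplit(toupper(seq), "")[[1]]
    L <- length(chars)
    bases <- c("A", "C", "G", "T")
    # plan indels first so substitutions can compensate for the identity
    # they consume (a deletion turns a match column into a gap column; an
    # insertion adds a non-match column)
    n_del <- 0L; n_ins <- 0L
    if (indel_rate > 0) {
      n_indel <- stats::rbinom(1, L, indel_rate)
      n_del <- sum(runif(n_indel) < 0.5)
      n_del <- min(n_del, L - 10L)  # keep a usable sequence
      n_ins <- n_indel - n_del
    }
    del_sites <- if (n_del > 0) sort(sample.int(L, n_del)) else integer(0)
    columns <- L + n_ins
    matches_now <- L - n_del
    matches_target <- round(target_identity * columns)
    n_sub <- max(0L, matches_now - matches_target)
    live <- setdiff(seq_len(L), del_sites)
    sub_sites <- if (n_sub > 0) sample(live, min(n_sub, length(live))) else integer(0)
    for (i in sub_sites) chars[i] <- sample(setdiff(bases, chars[i]), 1)
    if (n_del > 0) chars <- chars[-del_sites]
    for (k in seq_len(n_ins)) {
      ins <- sample.int(length(chars) + 1L, 1)
      chars <- append(chars, sample(bases, 1), after = ins - 1L)
    }
    list(mutant = paste0(chars, collapse = ""),
         realized_identity = (matches_now - length(sub_sites)) / columns)
  })
}

#' Specification of a synthetic benchmark genome
#'
#' Defaults emulate a highly fragmented, AT-rich draft assembly: log-normal
#' contig lengths truncated to `[200, 25000]` nt with most contigs below
#' 1 kb, GC 0.36, planted ncRNA homologs at controlled identity, optional
#' pseudogenised (truncated, extra-mutated) copies, and bacterial
#' contaminant contigs copied from a reference at 95-100 % identity.
#'
#' @param genome_length Total background length (nt).
#' @param contig_median,contig_sdlog Log-normal contig length parameters.
#' @param gc Background GC content.
#' @param families List of per-family specs: each a list with `seed_aln`
#'   (a `seed_alignment`), `rna_class`, `copies`, `target_identity`,
#'   `indel_rate`, `pseudogene_fraction`.
#' @param contaminants Optional `DNAStringSet` of contaminant references.
#' @param contaminant_contigs Number of contaminant contigs to plant.
#' @param seed RNG seed (recorded in the truth output).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(genome_length = 2e6, contig_median = 500,
                           contig_sdlog = 0.65, gc = 0.36,
                           families = list(), contaminants = NULL,
                           contaminant_contigs = 0L, seed = 1L) {
  stopifnot(gc > 0, gc < 1, genome_length >= 1000)
  structure(list(genome_length = genome_length, contig_median = contig_median,
                 contig_sdlog = contig_sdlog, gc = gc, families = families,
                 contaminants = contaminants,
                 contaminant_contigs = contaminant_contigs, seed = seed),
            class = "synthetic_spec")
}

#' Consensus sequence of a seed alignment
#'
#' Majority residue per match column (columns with <50 % gaps), ties
#' broken alphabetically.
#'
#' @param seed A `seed_alignment`.
#' @return DNA string.
#' @export
seed_consensus <- function(seed) {
  mat <- do.call(rbind, strsplit(chartr("U", "T", toupper(seed$rows)), ""))
  is_gap <- mat %in% c("-", ".")
  dim(is_gap) <- dim(mat)
  match_cols <- which(colMeans(is_gap) < 0.5)
  bases <- c("A", "C", "G", "T")
  paste0(vapply(match_cols, function(cix) {
    cnt <- table(factor(mat[, cix], levels = bases))
    bases[which.max(cnt)]
  }, ""), collapse = "")
}

#' Build a synthetic genome with planted ncRNA homologs
#'
#' Background sequence is fragmented per the contig-length distribution;
#' family instances are generated from the seed consensus via
#' [mutate_to_identity()] and planted on random strands at
#' non-overlapping positions.  Pseudogene copies are truncated to
#' 40-70 % of their length, receive extra substitutions (15 percentage
#' points below the target identity) and are flagged.  Contaminant
#' contigs are appended as copies of the contaminant references at
#' 95-100 % identity.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `genome` (`DNAStringSet`), `truth` (data.frame:
#'   `family_id`, `rna_class`, `contig_id`, `start`, `end`, `strand`,
#'   `realized_identity`, `is_pseudogene`), `contaminant_truth`
#'   (contig ids planted from the contaminant set) and `seed`.
#' @export
build_genome <- function(spec) {
  with_seed(spec$seed, {
    # contig length draws until the total is reached
    lens <- integer(0)
    total <- 0
    while (total < spec$genome_length) {
      l <- round(stats::rlnorm(1, log(spec$contig_median), spec$contig_sdlog))
      l <- min(25000L, max(200L, as.integer(l)))
      lens <- c(lens, l)
      total <- total + l
    }
    contigs <- vapply(lens, function(l) {
      generate_background(l, spec$gc, seed = NULL)
    }, "")
    names(contigs) <- sprintf("ctg%05d", seq_along(contigs))
    occupied <- setNames(vector("list", length(contigs)), names(contigs))
    truth <- list()
    for (fam in spec$families) {
      cons <- seed_consensus(fam$seed_aln)
      qlen <- nchar(cons)
      n_pseudo <- round((fam$pseudogene_fraction %||% 0) * fam$copies)
      for (ci in seq_len(fam$copies)) {
        is_pseudo <- ci <= n_pseudo
        if (is_pseudo) {
          keep <- runif(1, 0.40, 0.70)
          frag_len <- max(20L, as.integer(round(keep * qlen)))
          off <- sample.int(qlen - frag_len + 1L, 1)
          src <- substr(cons, off, off + frag_len - 1L)
          mut <- mutate_to_identity(src, max(0.4, fam$target_identity - 0.15),
                                    fam$indel_rate %||% 0, seed = NULL)
        } else {
          mut <- mutate_to_identity(cons, fam$target_identity,
                                    fam$indel_rate %||% 0, seed = NULL)
        }
        inst <- mut$mutant
        ilen <- nchar(inst)
        placed <- FALSE
        for (try in seq_len(500L)) {
          cix <- sample.int(length(contigs), 1)
          clen <- nchar(contigs[[cix]])
          if (clen < ilen + 2) next
          s0 <- sample.int(clen - ilen + 1L, 1) - 1L
          e0 <- s0 + ilen
          occ <- occupied[[cix]]
          clash <- any(vapply(occ, function(iv) s0 < iv[2] && iv[1] < e0, TRUE))
          if (clash) next
          strand <- sample(c("+", "-"), 1)
          planted <- if (strand == "+") inst else reverse_complement(inst)
          substr(contigs[[cix]], s0 + 1L, e0) <- planted
          occupied[[cix]] <- c(occ, list(c(s0, e0)))
          truth[[length(truth) + 1L]] <- data.frame(
            family_id = fam$seed_aln$family_id,
            rna_class = fam$rna_class,
            contig_id = names(contigs)[cix], start = s0, end = e0,
            strand = strand, realized_identity = mut$realized_identity,
            is_pseudogene = is_pseudo, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("genome too small to place all requested family copies")
      }
    }
    contam_ids <- character(0)
    if (spec$contaminant_contigs > 0) {
      if (is.null(spec$contaminants)) stop("contaminant_contigs > 0 but no contaminant references")
      refs <- as.character(spec$contaminants)
      for (k in seq_len(spec$contaminant_contigs)) {
        src <- refs[[((k - 1L) %% length(refs)) + 1L]]
        mut <- mutate_to_identity(src, runif(1, 0.95, 1.0), 0, seed = NULL)
        nm <- sprintf("contam%03d", k)
        contigs[nm] <- mut$mutant
        contam_ids <- c(contam_ids, nm)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      family_id = character(), rna_class = character(), contig_id = character(),
      start = integer(), end = integer(), strand = character(),
      realized_identity = numeric(), is_pseudogene = logical(),
      stringsAsFactors = FALSE)
    list(genome = Biostrings::DNAStringSet(contigs), truth = truth,
         contaminant_truth = contam_ids, seed = spec$seed)
  })
}

#' Build a toy ncRNA family seed alignment
#'
#' Generates a random consensus with an optional hairpin structure and
#' seed rows at about 90 % identity of the consensus; used for
#' self-contained benchmarks and tests.
#'
#' @param family_id Family name.
#' @param length Consensus length (nt).
#' @param n_rows Number of seed rows.
#' @param stem Hairpin stem length in bp (0 for unstructured families);
#'   the stem pairs the first/last `stem` positions.
#' @param gc GC content of the consensus.
#' @param seed RNG seed.
#' @param row_identity Identity of seed rows to the consensus.
#' @return A `seed_alignment`.
#' @export
make_seed_alignment <- function(family_id, length = 80L, n_rows = 5L,
                                stem = 10L, gc = 0.5, seed = 1L,
                                row_identity = 0.9) {
  stopifnot(length > 2 * stem + 3)
  with_seed(seed, {
    cons <- strsplit(generate_background(length, gc, seed = NULL), "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (stem > 0) {
      for (i in seq_len(stem)) cons[length - i + 1L] <- comp[[cons[i]]]
    }
    ss <- rep(".", length)
    if (stem > 0) {
      ss[seq_len(stem)] <- "("
      ss[seq(length - stem + 1L, length)] <- ")"
    }
    rows <- vapply(seq_len(n_rows), function(r) {
      chars <- cons
      n_mut <- round((1 - row_identity) * length)
      for (i in sample.int(length, n_mut)) {
        if (ss[i] == "." ) {
          chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
        }  # stem positions stay consensus so pairing survives in rows
      }
      paste0(chars, collapse = "")
    }, "")
    names(rows) <- paste0("seq", seq_len(n_rows))
    make_seed_alignment_obj(family_id, rows, paste0(ss, collapse = ""))
  })
}

#' Write a truth table as TSV and GFF3
#'
#' @param truth Truth data.frame from [build_genome()].
#' @param genome The matching `DNAStringSet`.
#' @param path_tsv,path_gff Output paths.
#' @export
write_truth <- function(truth, genome, path_tsv, path_gff) {
  write.table(truth, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  loci <- truth
  loci$evidence <- ifelse(loci$is_pseudogene, "pseudogene", "planted")
  loci$bitscore <- 0
  loci$evalue <- 0
  write_annotations(loci, genome, path_gff, tempfile(fileext = ".tsv"))
  invisible(path_tsv)
}
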