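#' Read a FASTA file of genome contigs
#'
#' Sequences are uppercased and U is mapped to T so a single DNA alphabet
#' flows through all scoring code.  Characters outside `{A,C,G,T,N,U}`
#' are rejected with an error naming the offending line.  N is allowed
#' (it scores as a mismatch everywhere and never seeds a word match).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record; names
#'   are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- parse_fasta_lines(lines, path)
  Biostrings::DNAStringSet(setNames(vapply(recs, `[[`, "", "seq"),
                                    vapply(recs, `[[`, "", "id")))
}

# Shared line-oriented FASTA scan: validates the grammar and alphabet and
# reports 1-based line numbers on failure.
parse_fasta_lines <- function(lines, path = "<fasta>") {
  lines <- sub("\r$", "", lines)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("malformed FASTA (no header line) in ", path)
  first_hdr <- which(hdr)[1]
  if (any(nzchar(trimws(lines[seq_len(first_hdr - 1)]))))
    stop("malformed FASTA: sequence before first header at line ",
         which(nzchar(trimws(lines[seq_len(first_hdr - 1)])))[1], " in ", path)
  idx <- which(hdr)
  ends <- c(idx[-1] - 1L, length(lines))
  recs <- vector("list", length(idx))
  for (r in seq_along(idx)) {
    header <- sub("^>", "", lines[idx[r]])
    id <- strsplit(trimws(header), "[ \t]")[[1]][1]
    if (is.na(id) || !nzchar(id))
      stop("malformed FASTA header at line ", idx[r], " in ", path)
    body_lines <- seq(idx[r] + 1L, length.out = max(0L, ends[r] - idx[r]))
    seq_parts <- character(0)
    for (ln in body_lines) {
      s <- toupper(gsub("[ \t]", "", lines[ln]))
      if (!nzchar(s)) next
      bad <- regmatches(s, regexpr("[^ACGTNU]", s))
      if (length(bad) && nzchar(bad))
        stop("invalid character '", bad, "' at line ", ln, " in ", path)
      seq_parts <- c(seq_parts, chartr("U", "T", s))
    }
    sq <- paste0(seq_parts, collapse = "")
    if (!nzchar(sq)) stop("empty record '", id, "' at line ", idx[r], " in ", path)
    recs[[r]] <- list(id = id, seq = sq, line = idx[r])
  }
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[duplicated(ids)][1], "' in ", path)
  recs
}

#' Read a query FASTA whose headers carry family, class and species tags
#'
#' The header grammar is `>family_id|rna_class|species_tag`; `rna_class`
#' must come from the fixed vocabulary (see [rna_classes()]).
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `family_id`, `rna_class`,
#'   `species_tag`, `sequence`.
#' @export
read_query_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- parse_fasta_lines(readLines(path, warn = FALSE), path)
  parts <- strsplit(vapply(recs, `[[`, "", "id"), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("query header at line ", recs[[bad[1]]]$line,
         " is not 'family|class|species' in ", path)
  df <- data.frame(
    family_id = vapply(parts, `[[`, "", 1L),
    rna_class = vapply(parts, `[[`, "", 2L),
    species_tag = vapply(parts, `[[`, "", 3L),
    sequence = vapply(recs, `[[`, "", "seq"),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(unique(df$rna_class), rna_classes())
  if (length(unknown))
    stop("unknown RNA class: ", paste(unknown, collapse = ", "),
         " (valid: ", paste(rna_classes(), collapse = ", "), ")")
  df
}

#' The fixed RNA class vocabulary
#' @return Character vector of valid `rna_class` values.
#' @export
rna_classes <- function() {
  c("miRNA", "rRNA", "snRNA", "snoRNA", "tRNA", "misc_RNA", "lncRNA")
}

#' Write sequences to FASTA
#'
#' @param x Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(nchar(s), starts + width - 1L)), con)
  }
  invisible(path)
}

#' Read a Stockholm 1.0 seed alignment
#'
#' Interleaved blocks are concatenated.  The consensus structure line
#' (`#=GC SS_cons`) is required (covariance-model construction is
#' impossible without it) and normalised to `( ) .`: the WUSS pair
#' symbols `<> [] {} ()` map to round brackets and every unpaired symbol
#' maps to a dot.  Unbalanced structures are rejected.
#'
#' @param path Path to a Stockholm file.
#' @param family_id Optional family identifier; defaults to the `#=GF ID`
#'   line if present, else the file name.
#' @return A list of class `seed_alignment` with elements `family_id`,
#'   `rows` (named character vector of aligned sequences), `ss_cons`,
#'   `columns`.
#' @export
read_stockholm <- function(path, family_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (!length(lines) || !grepl("^# STOCKHOLM 1.0", lines[1]))
    stop("missing '# STOCKHOLM 1.0' header in ", path)
  rows <- list()
  ss <- character(0)
  gf_id <- NULL
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GF\\s+ID\\s+", ln)) {
      gf_id <- trimws(sub("^#=GF\\s+ID\\s+", "", ln))
    } else if (grepl("^#=GC\\s+SS_cons\\s+", ln)) {
      ss <- c(ss, trimws(sub("^#=GC\\s+SS_cons\\s+", "", ln)))
    } else if (grepl("^#", ln)) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 2L) stop("malformed alignment line in ", path, ": ", ln)
      rows[[f[1]]] <- paste0(rows[[f[1]]] %||% "", f[2])
    }
  }
  if (!length(ss)) stop("missing #=GC SS_cons line in ", path)
  ss_cons <- normalize_ss_cons(paste0(ss, collapse = ""))
  rows <- vapply(rows, toupper, "")
  rows <- chartr("U", "T", rows)
  cols <- unique(nchar(c(rows, ss_cons)))
  if (length(cols) != 1L)
    stop("rows and SS_cons differ in length in ", path)
  make_seed_alignment_obj(
    family_id = family_id %||% gf_id %||% sub("\\.[^.]*$", "", basename(path)),
    rows = rows, ss_cons = ss_cons
  )
}

make_seed_alignment_obj <- function(family_id, rows, ss_cons) {
  structure(list(family_id = family_id, rows = rows, ss_cons = ss_cons,
                 columns = nchar(ss_cons)),
            class = "seed_alignment")
}

#' @export
print.seed_alignment <- function(x, ...) {
  cat("Seed alignment '", x$family_id, "': ", length(x$rows), " rows x ",
      x$columns, " columns\n", sep = "")
  invisible(x)
}

#' Normalise a WUSS consensus structure string to dot-bracket
#'
#' @param ss Structure string; `<> [] {} ()` become `()`, everything else
#'   becomes `.`.
#' @return Normalised string over `{'(', ')', '.'}`.
#' @export
normalize_ss_cons <- function(ss) {
  chars <- strsplit(ss, "")[[1]]
  out <- ifelse(chars %in% c("<", "[", "{", "("), "(",
         ifelse(chars %in% c(">", "]", "}", ")"), ")", "."))
  res <- paste0(out, collapse = "")
  depth <- cumsum(ifelse(out == "(", 1L, ifelse(out == ")", -1L, 0L)))
  if (length(depth) && (any(depth < 0L) || depth[length(depth)] != 0L))
    stop("unbalanced consensus structure: ", ss)
  res
}

# Partner index per column (NA when unpaired); input already normalised.
pair_table <- function(ss_cons) {
  chars <- strsplit(ss_cons, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

#' Write a seed alignment to Stockholm 1.0
#' @param aln A `seed_alignment`.
#' @param path Output path.
#' @export
write_stockholm <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# STOCKHOLM 1.0", con)
  writeLines(paste("#=GF ID", aln$family_id), con)
  wid <- max(nchar(names(aln$rows)), nchar("#=GC SS_cons"))
  for (nm in names(aln$rows))
    writeLines(sprintf("%-*s %s", wid, nm, aln$rows[[nm]]), con)
  writeLines(sprintf("%-*s %s", wid, "#=GC SS_cons", aln$ss_cons), con)
  writeLines("//", con)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' An involution over `{A,C,G,T,N}`; N maps to N.
#'
#' @param seq Character scalar (or vector) of DNA.
#' @return Reverse complement(s).
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# --- genomic interval helpers (internal convention: 0-based half-open,
#     forward-strand coordinates; minus-strand features carry strand "-") ---

validate_intervals <- function(df, genome) {
  lens <- Biostrings::width(genome)
  names(lens) <- names(genome)
  if (!all(df$contig_id %in% names(lens)))
    stop("interval on unknown contig: ",
         paste(setdiff(df$contig_id, names(lens)), collapse = ", "))
  bad <- df$start < 0 | df$end > lens[df$contig_id] | df$start >= df$end
  if (any(bad))
    stop("interval out of contig bounds: ",
         paste0(df$contig_id[bad][1], ":", df$start[bad][1], "-", df$end[bad][1]))
  invisible(TRUE)
}

# Extract the sequence of a 0-based half-open interval, reverse-complemented
# for minus-strand features.
interval_sequence <- function(genome, contig_id, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(genome[[contig_id]], start + 1L, end))
  if (identical(strand, "-")) s <- reverse_complement(s)
  s
}

#' Write annotated loci to GFF3 and TSV
#'
#' GFF3 uses 1-based inclusive coordinates (the internal convention is
#' 0-based half-open); column 3 carries the RNA class and the attributes
#' carry family, evidence method, bitscore and E-value.  Output is
#' deterministic: rows are sorted by contig, start and family.
#'
#' @param loci Data.frame with columns `contig_id`, `start`, `end`,
#'   `strand`, `family_id`, `rna_class`, `evidence`, `bitscore`, `evalue`.
#' @param genome `DNAStringSet` the coordinates refer to.
#' @param path_gff,path_tsv Output paths.
#' @return Invisibly, the sorted loci table.
#' @export
write_annotations <- function(loci, genome, path_gff, path_tsv) {
  cols <- c("contig_id", "start", "end", "strand", "family_id", "rna_class",
            "evidence", "bitscore", "evalue")
  if (nrow(loci) == 0) {
    loci <- data.frame(contig_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       family_id = character(), rna_class = character(),
                       evidence = character(), bitscore = numeric(),
                       evalue = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(cols %in% names(loci)))
  if (nrow(loci)) validate_intervals(loci, genome)
  loci <- loci[order(loci$contig_id, loci$start, loci$family_id), , drop = FALSE]
  if (!nrow(loci)) {  # header-only GFF3; rtracklayer rejects the empty case
    writeLines("##gff-version 3", path_gff)
    write.table(loci, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(loci))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(loci)) loci$contig_id else character(),
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = if (nrow(loci)) loci$strand else character()
  )
  S4Vectors::mcols(gr)$source <- rep("rnahomology", nrow(loci))
  S4Vectors::mcols(gr)$type <- loci$rna_class
  S4Vectors::mcols(gr)$score <- loci$bitscore
  S4Vectors::mcols(gr)$family_id <- loci$family_id
  S4Vectors::mcols(gr)$evidence <- loci$evidence
  S4Vectors::mcols(gr)$bitscore <- loci$bitscore
  S4Vectors::mcols(gr)$evalue <- loci$evalue
  rtracklayer::export(gr, path_gff, format = "gff3")
  write.table(loci, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(loci)
}

#' Read a locus annotation GFF3 back into the internal convention
#'
#' @param path_gff GFF3 file written by [write_annotations()].
#' @return Data.frame in internal 0-based half-open coordinates.
#' @export
read_annotations <- function(path_gff) {
  gr <- rtracklayer::import(path_gff, format = "gff3")
  data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family_id = S4Vectors::mcols(gr)$family_id,
    rna_class = S4Vectors::mcols(gr)$type,
    evidence = S4Vectors::mcols(gr)$evidence,
    bitscore = as.numeric(S4Vectors::mcols(gr)$bitscore),
    evalue = as.numeric(S4Vectors::mcols(gr)$evalue),
    stringsAsFactors = FALSE
  )
}
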