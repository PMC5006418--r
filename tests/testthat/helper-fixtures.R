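# Small fixtures built in code at test time.

toy_seed <- function(id = "toy", rows = c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT"),
                     ss = "....") {
  rnahomology:::make_seed_alignment_obj(id, rows, ss)
}

hairpin_seed <- function(id = "hairpin") {
  toy_seed(id, c(a = "GGGAAACCC", b = "GGGAAACCC", c = "GGCAAACCC"),
           "(((...)))")
}

twostem_seed <- function(id = "twostem") {
  toy_seed(id, c(a = "GGAACCGGAACC", b = "GGAACCGGAACC"), "((..))((..))")
}

tiny_genome <- function(n_contigs = 10, len = 800, gc = 0.36, seed = 1) {
  seqs <- vapply(seq_len(n_contigs), function(i)
    generate_background(len, gc, seed = seed + i), "")
  names(seqs) <- paste0("ctg", seq_len(n_contigs))
  Biostrings::DNAStringSet(seqs)
}

# a genome with one planted copy of `instance` at a known position
plant_in_genome <- function(instance, flank = 400, gc = 0.36, seed = 2,
                            strand = "+") {
  left <- generate_background(flank, gc, seed = seed)
  right <- generate_background(flank, gc, seed = seed + 1)
  ins <- if (strand == "+") instance else reverse_complement(instance)
  list(genome = Biostrings::DNAStringSet(c(ctgA = paste0(left, ins, right))),
       start = flank, end = flank + nchar(instance), strand = strand)
}

fake_hsp <- function(contig_id = "c1", start, end, strand = "+",
                     qstart = 0L, qend = end - start, score = (end - start),
                     length = end - start, matches = end - start,
                     identity = matches / length, evalue = 1e-5,
                     query_id = "q", strategy_id = "default") {
  data.frame(query_id = query_id, strategy_id = strategy_id,
             contig_id = contig_id, start = start, end = end,
             strand = strand, qstart = qstart, qend = qend, score = score,
             length = length, matches = matches, identity = identity,
             evalue = evalue, stringsAsFactors = FALSE)
}
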