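test_that("background sequences hit the requested composition", {
  s <- generate_background(1e5, 0.36, seed = 3)
  gc <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_equal(gc, 0.36, tolerance = 0.01)
  # boundary: gc = 0 uses only A/T
  expect_false(grepl("[GC]", generate_background(500, 0, seed = 1)))
  # determinism
  expect_identical(generate_background(1000, 0.36, seed = 9),
                   generate_background(1000, 0.36, seed = 9))
})

test_that("mutation to a target identity is exact without indels", {
  src <- generate_background(200, 0.5, seed = 11)
  m <- mutate_to_identity(src, 1.0, 0, seed = 1)
  expect_identical(m$mutant, src)
  expect_equal(m$realized_identity, 1)
  m2 <- mutate_to_identity(src, 0.7, 0, seed = 2)
  # Hamming identity of the no-indel mutant equals the reported identity
  a <- strsplit(src, "")[[1]]; b <- strsplit(m2$mutant, "")[[1]]
  expect_equal(mean(a == b), m2$realized_identity)
  expect_equal(m2$realized_identity, 0.7, tolerance = 0.02)
  # with indels the trace-based identity stays near target
  m3 <- mutate_to_identity(src, 0.7, 0.02, seed = 3)
  expect_equal(m3$realized_identity, 0.7, tolerance = 0.05)
  expect_false(nchar(m3$mutant) == 0)
})

test_that("generated genomes are fragmented, truthful and reproducible", {
  fam <- make_seed_alignment("famS", length = 80, stem = 10, seed = 81)
  spec <- synthetic_spec(
    genome_length = 3e5, seed = 82,
    families = list(list(seed_aln = fam, rna_class = "miRNA", copies = 10,
                         target_identity = 0.85, indel_rate = 0.01,
                         pseudogene_fraction = 0.5)))
  gen <- build_genome(spec)
  # fragmentation: most contigs below 1 kb, all within the truncation range
  w <- Biostrings::width(gen$genome)
  expect_gte(mean(w < 1000), 0.8)
  expect_true(all(w >= 200 & w <= 25000))
  # truth bookkeeping: 10 records, half flagged pseudogenes
  expect_equal(nrow(gen$truth), 10L)
  expect_equal(sum(gen$truth$is_pseudogene), 5L)
  # realized identity within the stated band for intact copies
  intact <- gen$truth[!gen$truth$is_pseudogene, ]
  expect_true(all(abs(intact$realized_identity - 0.85) <= 0.03))
  # intervals sit inside their contigs and never overlap each other
  lens <- setNames(Biostrings::width(gen$genome), names(gen$genome))
  expect_true(all(gen$truth$start >= 0 &
                    gen$truth$end <= lens[gen$truth$contig_id]))
  for (cid in unique(gen$truth$contig_id)) {
    iv <- gen$truth[gen$truth$contig_id == cid, , drop = FALSE]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1) expect_true(all(diff(iv$start) >= head(iv$end - iv$start, -1)))
  }
  # the planted sequence really sits at the recorded interval
  r <- gen$truth[!gen$truth$is_pseudogene, ][1, ]
  planted <- rnahomology:::interval_sequence(gen$genome, r$contig_id, r$start,
                                             r$end, r$strand)
  cons <- seed_consensus(fam)
  al <- sw_oracle(cons, planted, 1, -1, 2, 1)
  expect_gte(al$score, 30)  # clearly homologous to the consensus
  # same spec, same genome
  gen2 <- build_genome(spec)
  expect_identical(as.character(gen$genome), as.character(gen2$genome))
  expect_identical(gen$truth, gen2$truth)
})

test_that("an over-packed genome spec fails loudly", {
  fam <- make_seed_alignment("famT", length = 300, stem = 10, seed = 91)
  spec <- synthetic_spec(
    genome_length = 1200, seed = 92,
    families = list(list(seed_aln = fam, rna_class = "rRNA", copies = 50,
                         target_identity = 0.9, indel_rate = 0,
                         pseudogene_fraction = 0)))
  expect_error(build_genome(spec), "too small")
})

test_that("truth tables serialise to TSV and GFF3", {
  fam <- make_seed_alignment("famU", length = 60, stem = 8, seed = 93)
  spec <- synthetic_spec(
    genome_length = 50000, seed = 94,
    families = list(list(seed_aln = fam, rna_class = "snRNA", copies = 3,
                         target_identity = 0.9, indel_rate = 0,
                         pseudogene_fraction = 0)))
  gen <- build_genome(spec)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_truth(gen$truth, gen$genome, tsv, gff)
  back <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3L)
  expect_equal(nrow(read_annotations(gff)), 3L)
})
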