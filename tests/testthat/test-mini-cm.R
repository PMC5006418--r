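test_that("the guide tree is driven by the consensus structure alone", {
  aln <- toy_seed(rows = c(a = "GGAAAACC", b = "GGAAAACC", c = "GGAAAACC",
                           d = "GGAAAACC"), ss = "((....))")
  cm <- build_cm(aln)
  expect_equal(sum(cm$kind == 2L), 2L)  # 2 MATP
  expect_equal(sum(cm$kind == 0L) + sum(cm$kind == 1L), 4L)  # 4 unpaired
  expect_equal(cm$clen, 8L)
  # dropping rows by taxon changes counts, not topology
  cm2 <- build_cm(aln, taxon_filter = c("a", "b"))
  expect_equal(cm2$kind, cm$kind)
  expect_equal(cm2$child1, cm$child1)
  expect_error(build_cm(aln, taxon_filter = "nobody"), "no seed rows")
})

test_that("an all-GC outer pair concentrates the MATP emission on the GC cell", {
  aln <- toy_seed(rows = c(a = "GAAAC", b = "GAAAC", c = "GAAAC"),
                  ss = "(...)")
  cm <- build_cm(aln)
  k <- which(cm$kind == 2L)[1]
  # left-major 16-vector: GC cell is index G*4 + C = 2*4+1 (+1 for R)
  expect_equal(which.max(cm$emP[k, ]), 2L * 4L + 1L + 1L)
  expect_equal(sum(cm$emP[k, ]), 1, tolerance = 1e-9)
})

test_that("CYK equals exhaustive parse enumeration on toy grammars", {
  grammars <- list(hairpin_seed(), twostem_seed(),
                   toy_seed("bulge", c(a = "GGAAAACC", b = "GGAAAACC"),
                            "((....))"))
  set.seed(11)
  for (cm_seed in grammars) {
    cm <- build_cm(cm_seed)
    for (t in 1:8) {
      s <- paste0(sample(c("A", "C", "G", "T"), sample(2:12, 1),
                         replace = TRUE), collapse = "")
      got <- cm_cyk(cm, s)$bitscore_global
      expect_equal(got, cyk_enum_oracle(cm, s), tolerance = 1e-6,
                   info = paste(cm$family_id, s))
    }
  }
})

test_that("the ungapped consensus parses with full coverage and a stable score", {
  cm <- build_cm(hairpin_seed())
  r <- cm_cyk(cm, cm$consensus)
  expect_equal(r$matched_positions, cm$clen)
  expect_equal(c(r$align_start, r$align_end), c(0L, nchar(cm$consensus)))
  # pure function of the sequence: same input, same score
  expect_identical(cm_cyk(cm, cm$consensus)$bitscore, r$bitscore)
  # window cap
  long <- strrep("A", 4 * cm$clen + 1)
  expect_error(cm_cyk(cm, long), "windowed")
})

test_that("calibration fits a Gumbel null and respects a supplied GA", {
  cm <- build_cm(make_seed_alignment("famE", length = 60, stem = 8, seed = 3))
  cal <- calibrate_cm(cm, n = 300, seed = 7)
  expect_false(is.null(cal$gumbel))
  expect_true(is.finite(cal$GA))
  # E-value at the null median is about half the calibration trials
  scores <- vapply(shuffle_sequence(cm$consensus, 200, seed = 7), function(s)
    cm_cyk(cal, s)$bitscore, 0)
  e_med <- cm_evalue(cal, median(scores), n_search = 200)
  expect_equal(e_med, 100, tolerance = 0.25)
  # supplied GA is left untouched
  cal30 <- calibrate_cm(cm, n = 300, seed = 7, GA = 30)
  expect_equal(cal30$GA, 30)
  expect_error(calibrate_cm(cm, n = 50), "n >= 100")
  expect_error(cm_evalue(cm, 10), "not calibrated")
})

test_that("acceptance needs GA, E-value and 70 % model coverage together", {
  seed_aln <- make_seed_alignment("famF", length = 80, stem = 10, seed = 21)
  cm <- calibrate_cm(build_cm(seed_aln), n = 300, seed = 1)
  inst <- mutate_to_identity(cm$consensus, 0.9, 0, seed = 2)$mutant
  regions <- data.frame(
    family_id = "famF", rna_class = "miRNA", contig_id = "c",
    start = 0L, end = nchar(inst), strand = "+", sequence = inst,
    stringsAsFactors = FALSE)
  hits <- search_cm(cm, regions)
  expect_equal(hits$status, "accepted")
  expect_gte(hits$bitscore, cm$GA)
  expect_gte(hits$model_coverage, 0.70)
  # truncated instance: high identity but low model coverage -> rejected
  half <- substr(inst, 1, round(nchar(inst) * 0.5))
  regions$sequence <- half; regions$end <- nchar(half)
  hits2 <- search_cm(cm, regions)
  expect_equal(hits2$status, "raw")
  expect_lt(hits2$model_coverage, 0.70)
  # bitscore fractionally below GA -> rejected even with fine E and coverage
  cm_hi <- cm; cm_hi$GA <- hits$bitscore + 0.1
  regions$sequence <- inst; regions$end <- nchar(inst)
  expect_equal(search_cm(cm_hi, regions)$status, "raw")
  expect_error(search_cm(build_cm(seed_aln), regions), "not calibrated")
})

test_that("overlap resolution merges within and arbitrates across families", {
  mk <- function(fam, s, e, bits, ev) data.frame(
    family_id = fam, contig_id = "c1", cm_start = s, cm_end = e,
    bitscore = bits, evalue = ev, stringsAsFactors = FALSE)
  # same family: hull merge keeping the best score
  same <- rbind(mk("U6", 100, 160, 40, 1e-6), mk("U6", 150, 210, 35, 1e-5))
  r <- resolve_overlaps(same)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$cm_start, r$cm_end), c(100, 210))
  expect_equal(r$bitscore, 40)
  # different families: higher bitscore wins
  diff <- rbind(mk("U6", 100, 160, 40, 1e-6), mk("U5", 120, 180, 35, 1e-9))
  r2 <- resolve_overlaps(diff)
  expect_equal(r2$family_id, "U6")
  # bitscore tie: smaller E-value wins
  tie <- rbind(mk("U6", 100, 160, 40, 1e-4), mk("U5", 120, 180, 40, 1e-9))
  expect_equal(resolve_overlaps(tie)$family_id, "U5")
  # equal on both: lexicographic family id
  tie2 <- rbind(mk("U6", 100, 160, 40, 1e-4), mk("U5", 120, 180, 40, 1e-4))
  expect_equal(resolve_overlaps(tie2)$family_id, "U5")
  # output never contains cross-family overlaps
  set.seed(3)
  rnd <- do.call(rbind, lapply(1:20, function(i)
    mk(sample(c("A", "B", "C"), 1), s <- sample(1000, 1), s + 80,
       runif(1, 10, 50), 10^-runif(1, 2, 9))))
  rr <- resolve_overlaps(rnd)
  if (nrow(rr) > 1) for (i in 2:nrow(rr)) {
    prev <- rr[rr$family_id != rr$family_id[i], , drop = FALSE]
    if (!nrow(prev)) next
    ov <- pmin(prev$cm_end, rr$cm_end[i]) - pmax(prev$cm_start, rr$cm_start[i])
    expect_true(all(ov <= 0))
  }
})

test_that("curation re-scores with 300 nt flanks and applies the strict GA rule", {
  seed_aln <- make_seed_alignment("famG", length = 80, stem = 10, seed = 31)
  cm <- calibrate_cm(build_cm(seed_aln), n = 300, seed = 1)
  inst <- mutate_to_identity(cm$consensus, 0.9, 0.01, seed = 5)$mutant
  pg <- plant_in_genome(inst, flank = 600, seed = 12)
  regions <- regions_with_sequence(data.frame(
    family_id = "famG", rna_class = "miRNA", contig_id = "ctgA",
    start = pg$start, end = pg$end, strand = "+", stringsAsFactors = FALSE),
    pg$genome)
  hits <- search_cm(cm, regions)
  expect_equal(hits$status, "accepted")
  cur <- curate_final(hits, pg$genome, cm)
  expect_equal(nrow(cur$loci), 1L)
  # footprint lands within a few nt of the planted interval
  expect_lte(abs(cur$loci$start - pg$start), 5)
  expect_lte(abs(cur$loci$end - pg$end), 5)
  expect_false(cur$loci$clipped)
  # a hit at a contig edge is curated on the clipped window and flagged
  pg2 <- plant_in_genome(inst, flank = 100, seed = 13)
  regions2 <- regions_with_sequence(data.frame(
    family_id = "famG", rna_class = "miRNA", contig_id = "ctgA",
    start = pg2$start, end = pg2$end, strand = "+", stringsAsFactors = FALSE),
    pg2$genome)
  hits2 <- search_cm(cm, regions2)
  cur2 <- curate_final(hits2, pg2$genome, cm)
  expect_equal(nrow(cur2$loci), 1L)
  expect_true(cur2$loci$clipped)
  # borderline: a re-score exactly at GA fails the strict inequality
  cm_exact <- cm
  probe <- curate_final(hits, pg$genome, cm)
  cm_exact$GA <- probe$loci$bitscore
  cur3 <- curate_final(hits, pg$genome, cm_exact)
  expect_equal(nrow(cur3$loci), 0L)
  expect_match(cur3$rejected$reason, "bitscore")
})
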