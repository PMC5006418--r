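test_that("the four-rule filter applies its boundary semantics exactly", {
  # coverage 0.38 < 0.40 -> rejected despite high identity
  h <- fake_hsp(start = 100, end = 138, qstart = 0, qend = 38,
                length = 38, matches = 34)
  expect_equal(nrow(filter_hsps(h, 100)), 0L)
  # alignment length exactly 20 -> rejected ("exceeds 20" is strict)
  h <- fake_hsp(start = 100, end = 120, qstart = 0, qend = 20,
                length = 20, matches = 20)
  expect_equal(nrow(filter_hsps(h, 40)), 0L)
  h$length <- 21L; h$qend <- 21L; h$end <- 121L; h$matches <- 21L
  h$identity <- 1
  expect_equal(nrow(filter_hsps(h, 40)), 1L)
  # identity boundary: 0.74 rejected, 0.75 kept (inclusive)
  h <- fake_hsp(start = 0, end = 50, qstart = 0, qend = 50, length = 50,
                matches = 37)
  expect_equal(nrow(filter_hsps(h, 100)), 0L)
  h$matches <- 38L; h$identity <- 38 / 50  # 0.76 >= 0.75
  expect_equal(nrow(filter_hsps(h, 100)), 1L)
  h$matches <- 37.5; h$identity <- 0.75
  expect_equal(nrow(filter_hsps(h, 100)), 1L)
  # empty in, empty out; idempotence
  expect_equal(nrow(filter_hsps(h[0, ], 100)), 0L)
  once <- filter_hsps(h, 100)
  expect_equal(filter_hsps(once, 100), once)
})

test_that("same-strand merging respects the gap and the 125 % cap", {
  a <- fake_hsp(start = 100, end = 150, qstart = 0, qend = 50, length = 50,
                matches = 45)
  b <- fake_hsp(start = 160, end = 220, qstart = 55, qend = 100,
                length = 60, matches = 50)
  both <- rbind(a, b)
  m <- merge_hsps(both, query_length = 100, max_gap = 30)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100, 220))  # hull 120 <= 125
  expect_equal(m$score, a$score + b$score)
  # hull over the cap: kept separate
  b2 <- b; b2$start <- 185; b2$end <- 245
  m2 <- merge_hsps(rbind(a, b2), query_length = 100, max_gap = 40)
  expect_equal(nrow(m2), 2L)
  # opposite strands never merge
  b3 <- b; b3$strand <- "-"
  m3 <- merge_hsps(rbind(a, b3), query_length = 100, max_gap = 30)
  expect_equal(nrow(m3), 2L)
  # merge is idempotent on its own output
  expect_equal(merge_hsps(m, 100, 30), m)
})

test_that("merged identity is the match-weighted mean", {
  a <- fake_hsp(start = 0, end = 40, qstart = 0, qend = 40, length = 40,
                matches = 40, identity = 1.0)
  b <- fake_hsp(start = 50, end = 90, qstart = 45, qend = 85, length = 40,
                matches = 32, identity = 0.8)
  m <- merge_hsps(rbind(a, b), query_length = 100, max_gap = 30)
  expect_equal(m$identity, (1.0 * 40 + 0.8 * 32) / 72)
})

test_that("candidate extension centres, adds flanks, and clips at edges", {
  genome <- tiny_genome(1, 10000, seed = 5)
  h <- fake_hsp(contig_id = "ctg1", start = 100, end = 160, qstart = 10,
                qend = 70, length = 60, matches = 55)
  cand <- build_candidates(h, genome, query_length = 80, flank = 10)
  expect_equal(c(cand$start, cand$end), c(80, 180))
  expect_equal(nchar(cand$sequence), 100)
  # near the contig start the left extension is clipped, the leftover
  # shifts right, and the flank is clipped at zero
  h2 <- fake_hsp(contig_id = "ctg1", start = 5, end = 65, qstart = 10,
                 qend = 70, length = 60, matches = 55)
  cand2 <- build_candidates(h2, genome, query_length = 80, flank = 10)
  expect_equal(cand2$start, 0)
  expect_equal(cand2$end, 90)  # clipped left extension shifted right, then flank
  # minus strand: sequence is the reverse complement of the slice
  h3 <- fake_hsp(contig_id = "ctg1", start = 100, end = 160, strand = "-",
                 qstart = 10, qend = 70, length = 60, matches = 55)
  cand3 <- build_candidates(h3, genome, query_length = 60, flank = 0)
  expect_equal(cand3$sequence,
               reverse_complement(as.character(
                 Biostrings::subseq(genome[["ctg1"]], 101, 160))))
})

test_that("near-duplicate regions from different queries collapse, keeping provenance", {
  genome <- tiny_genome(1, 5000, seed = 6)
  h1 <- fake_hsp(contig_id = "ctg1", start = 1000, end = 1080, qstart = 0,
                 qend = 80, length = 80, matches = 75)
  h1$species_tag <- "CIN"; h1$strategy_id <- "1"
  h2 <- fake_hsp(contig_id = "ctg1", start = 1002, end = 1081, qstart = 0,
                 qend = 79, length = 79, matches = 70)
  h2$species_tag <- "DRE"; h2$strategy_id <- "7"
  cand <- build_candidates(rbind(h1, h2), genome, query_length = 80,
                           family_id = "mir-124")
  expect_equal(nrow(cand), 1L)
  expect_setequal(strsplit(cand$supporting_species, ",")[[1]], c("CIN", "DRE"))
  expect_setequal(strsplit(cand$supporting_strategies, ",")[[1]], c("1", "7"))
  # disjoint hits stay separate and provenance is not pooled
  h3 <- h2; h3$start <- 3000; h3$end <- 3079
  cand2 <- build_candidates(rbind(h1, h3), genome, query_length = 80,
                            family_id = "mir-124")
  expect_equal(nrow(cand2), 2L)
  expect_equal(sum(grepl("CIN", cand2$supporting_species)), 1L)
})
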