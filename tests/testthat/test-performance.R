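test_that("mononucleotide shuffles preserve composition and are seed-stable", {
  seq <- generate_background(120, 0.42, seed = 1)
  sh <- shuffle_sequence(seq, 20, seed = 5)
  comp <- function(s) table(factor(strsplit(s, "")[[1]],
                                   levels = c("A", "C", "G", "T")))
  for (s in sh) expect_equal(comp(s), comp(seq))
  expect_identical(sh, shuffle_sequence(seq, 20, seed = 5))
  expect_false(identical(sh, shuffle_sequence(seq, 20, seed = 6)))
})

test_that("dinucleotide shuffles preserve the dinucleotide count vector", {
  dicount <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(factor(paste0(head(ch, -1), tail(ch, -1)),
                 levels = as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0))))
  }
  set.seed(2)
  for (i in 1:5) {
    seq <- generate_background(80, runif(1, 0.3, 0.6))
    sh <- shuffle_sequence(seq, 5, seed = i, order = "di")
    for (s in sh) expect_equal(dicount(s), dicount(seq))
  }
  expect_identical(shuffle_sequence("ACGTACGT", 3, seed = 9, order = "di"),
                   shuffle_sequence("ACGTACGT", 3, seed = 9, order = "di"))
})

test_that("sensitivity and specificity follow the defining ratios", {
  cm <- data.frame(TP = 6, FN = 4, FP = 1, TN = 999)
  ss <- sens_spec(cm)
  expect_equal(ss$sensitivity, 0.6)
  expect_equal(ss$specificity, 0.999)
  # undefined denominators propagate NA
  ss0 <- sens_spec(data.frame(TP = 0, FN = 0, FP = 0, TN = 0))
  expect_true(is.na(ss0$sensitivity))
  expect_true(is.na(ss0$specificity))
  # vectorised over rows
  ss2 <- sens_spec(data.frame(TP = c(1, 3), FN = c(1, 1),
                              FP = c(0, 1), TN = c(10, 9)))
  expect_equal(ss2$sensitivity, c(0.5, 0.75))
  expect_equal(ss2$specificity, c(1, 0.9))
})

test_that("evaluate_strategy counts recovered loci and null positives", {
  fam <- make_seed_alignment("famH", length = 80, stem = 10, seed = 71)
  cons <- seed_consensus(fam)
  spec <- synthetic_spec(
    genome_length = 80000, seed = 72,
    families = list(list(seed_aln = fam, rna_class = "miRNA", copies = 6,
                         target_identity = 0.9, indel_rate = 0,
                         pseudogene_fraction = 0)))
  gen <- build_genome(spec)
  queries <- data.frame(family_id = "famH", rna_class = "miRNA",
                        species_tag = "CIN", sequence = cons,
                        stringsAsFactors = FALSE)
  res <- evaluate_strategy("1", queries, gen$truth, gen$genome,
                           nulls_per_family = 100, seed = 4)
  expect_equal(res$TP + res$FN, 6)
  expect_gte(res$TP, 5)  # 90 % identity copies are easy for strategy 1
  expect_equal(res$FP + res$TN, 100)
  expect_equal(res$sensitivity, res$TP / 6)
  # a class with no truth loci reports NA sensitivity
  res2 <- evaluate_strategy("1", queries, gen$truth[0, ], gen$genome,
                            nulls_per_family = 50, seed = 4)
  expect_true(is.na(res2$sensitivity))
})

test_that("strategy groups collapse shared parameter sets", {
  g <- strategy_groups()
  expect_equal(length(g), 5L)  # {1}, {2,5,7}, {3,6,8}, {4}, {default}
  members <- vapply(g, function(x) nrow(x$members), 0L)
  expect_setequal(members, c(1L, 3L, 3L, 1L, 1L))
  big <- g[[which(members == 3)[1]]]
  expect_equal(big$scheme$e_cut, 1000)
})
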