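test_that("strategy presets carry the tuned parameter table", {
  d <- make_strategy("default")
  expect_equal(unlist(d[c("r", "q", "G", "e_cut", "E_ext", "W")]),
               c(r = 1, q = -3, G = 5, e_cut = 10, E_ext = 2, W = 11))
  s8 <- make_strategy(8)
  expect_equal(unlist(s8[c("r", "q", "G", "e_cut", "E_ext", "W")]),
               c(r = 5, q = -4, G = 25, e_cut = 1000, E_ext = 10, W = 7))
  s2 <- make_strategy("2")
  expect_equal(unlist(s2[c("r", "q", "G", "e_cut", "E_ext", "W")]),
               c(r = 4, q = -5, G = 3, e_cut = 10, E_ext = 5, W = 7))
  expect_error(make_strategy("9"), "valid ids")
  over <- make_strategy("2", overrides = list(e_cut = 50))
  expect_equal(over$e_cut, 50)
  expect_error(make_strategy("2", overrides = list(bogus = 1)), "unknown")
})

test_that("Karlin-Altschul lambda solves the transcendental equation", {
  st <- solve_statistics(make_strategy("default"))
  # bisection oracle on (1/4) e^lambda + (3/4) e^{-3 lambda} = 1
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-3 * l) - 1
  expect_lt(abs(f(st$lambda)), 1e-9)
  expect_equal(st$lambda, 1.374, tolerance = 1e-3)
  # target frequency: expected identity of optimal alignments
  expect_equal(st$target_frequency, 0.99, tolerance = 0.005)
  st8 <- solve_statistics(make_strategy("8"))
  expect_equal(st8$target_frequency, 0.65, tolerance = 0.01)
  # root-defining invariant on a non-uniform background
  bg <- c(0.32, 0.18, 0.18, 0.32)
  sch <- make_strategy("1")
  stb <- solve_statistics(sch, bg)
  pm <- sum(bg^2)
  expect_lt(abs(pm * exp(stb$lambda * sch$r) +
                  (1 - pm) * exp(stb$lambda * sch$q) - 1), 1e-9)
})

test_that("a scoring system with non-negative expected score is rejected", {
  expect_error(solve_statistics(make_strategy("default",
                                              overrides = list(q = -1L, r = 1L))),
               NA)  # r=1,q=-1 expected score negative: fine
  sch <- make_strategy("default")
  sch$q <- 1  # bypass constructor to build the invalid system
  expect_error(solve_statistics(sch), "invalid scoring system")
})

test_that("a verbatim planted query is found with full identity on both strands", {
  g <- generate_background(4000, 0.36, seed = 11)
  q <- substr(g, 2001, 2040)
  genome <- Biostrings::DNAStringSet(c(c1 = g))
  for (sid in c("default", "1")) {
    sch <- make_strategy(sid)
    hits <- blast_search(q, genome, sch)
    top <- hits[which.max(hits$score), ]
    expect_equal(top$start, 2000)
    expect_equal(top$end, 2040)
    expect_equal(top$strand, "+")
    expect_equal(top$identity, 1.0)
    expect_equal(top$score, 40 * sch$r)
    expect_equal(c(top$qstart, top$qend), c(0, 40))
  }
  # strand symmetry: the reverse-complemented query gives the same score
  hits_rc <- blast_search(reverse_complement(q), genome, make_strategy("1"))
  top_rc <- hits_rc[which.max(hits_rc$score), ]
  expect_equal(top_rc$strand, "-")
  expect_equal(top_rc$score, 40 * make_strategy("1")$r)
  expect_equal(c(top_rc$start, top_rc$end), c(2000, 2040))
})

test_that("queries shorter than the word size warn and return nothing", {
  genome <- tiny_genome(1, 300, seed = 3)
  expect_warning(h <- blast_search("ACGTA", genome, make_strategy("default")),
                 "word size")
  expect_equal(nrow(h), 0L)
})

test_that("seeded aligner equals full Smith-Waterman when the optimum has a word", {
  set.seed(4242)
  checked <- 0
  for (rep in 1:80) {
    if (checked >= 50) break
    L <- sample(60:200, 1)
    a <- generate_background(L, 0.5)
    core <- mutate_to_identity(a, runif(1, 0.7, 0.95), 0.02)$mutant
    b <- paste0(generate_background(30, 0.5), core, generate_background(30, 0.5))
    sid <- sample(c("1", "2", "8", "default"), 1)
    sch <- make_strategy(sid, overrides = list(e_cut = 1e15))
    want <- sw_oracle(a, b, sch$r, sch$q, sch$G, sch$E_ext)
    if (want$max_match_run < sch$W) next  # optimum contains no exact W-mer
    checked <- checked + 1
    hits <- blast_search(a, Biostrings::DNAStringSet(c(x = b)), sch,
                         config = list(xdrop = 1e9, band = 2000,
                                       trigger_extra = 0))
    expect_equal(max(hits$score), want$score,
                 info = paste("strategy", sid, "rep", rep))
  }
  expect_gte(checked, 50)
})

test_that("relaxing the expectation cutoff never removes hits (3 vs 8)", {
  genome <- tiny_genome(5, 2000, seed = 21)
  set.seed(9)
  q <- generate_background(80, 0.4)
  h3 <- blast_search(q, genome, make_strategy("3"))
  h8 <- blast_search(q, genome, make_strategy("8"))
  key <- function(h) paste(h$contig_id, h$strand, h$start, h$end, h$score)
  expect_true(all(key(h3) %in% key(h8)))
})

test_that("multi-query search equals per-query search", {
  genome <- tiny_genome(6, 1500, seed = 31)
  set.seed(5)
  qs <- vapply(1:4, function(i) generate_background(70, 0.45), "")
  for (sid in c("1", "default")) {
    sch <- make_strategy(sid)
    st <- solve_statistics(sch)
    hm <- multi_blast_search(qs, genome, sch, st)
    for (i in seq_along(qs)) {
      h1 <- blast_search(qs[i], genome, sch, st)
      hmi <- hm[hm$query_index == i, , drop = FALSE]
      cols <- c("contig_id", "start", "end", "strand", "score", "matches",
                "length")
      expect_equal(
        h1[order(h1$contig_id, h1$strand, h1$start, h1$score), cols],
        hmi[order(hmi$contig_id, hmi$strand, hmi$start, hmi$score), cols],
        ignore_attr = TRUE)
    }
  }
})
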