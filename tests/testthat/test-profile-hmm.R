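test_that("profile construction counts emissions with +1 pseudocounts", {
  ph <- build_phmm(toy_seed())
  expect_equal(ph$M, 4L)
  # 3 identical gap-free rows of ACGT: state 1 sees 3 A's -> (3+1)/(3+4)
  expect_equal(unname(ph$emissions[1, ]), c(4, 1, 1, 1) / 7)
  expect_equal(rowSums(ph$emissions), rep(1, 4))
  # transition rows normalise within their state class
  expect_equal(unname(rowSums(ph$transitions[, 1:3])), rep(1, 4))
  expect_equal(unname(rowSums(ph$transitions[, 4:5])), rep(1, 4))
})

test_that("columns with a gap majority are not match columns", {
  aln <- toy_seed(rows = c(s1 = "A-CGT", s2 = "A-CGT", s3 = "AACGT"),
                  ss = ".....")
  ph <- build_phmm(aln)
  expect_equal(ph$M, 4L)  # column 2 has 2/3 gaps
  # single-row seed degenerates gracefully
  ph1 <- build_phmm(toy_seed(rows = c(only = "ACGTACGT"), ss = "........"))
  expect_equal(ph1$M, 8L)
  # all-gap-majority alignment is rejected
  expect_error(build_phmm(toy_seed(rows = c(a = "A-", b = "--", c = "--"),
                                   ss = "..")),
               "no match columns")
})

test_that("forward equals exhaustive path enumeration on toy models", {
  ph <- build_phmm(toy_seed())
  set.seed(7)
  for (i in 1:8) {
    s <- paste0(sample(c("A", "C", "G", "T"), sample(3:6, 1), replace = TRUE),
                collapse = "")
    sc <- score_sequence(ph, s)
    expect_equal(sc$forward_bits, enum_forward_phmm(ph, s), tolerance = 1e-9)
    expect_gte(sc$forward_bits, sc$viterbi_bits - 1e-9)  # sum >= max
    # forward-backward consistency
    expect_equal(sc$forward_bits, sc$backward_bits, tolerance = 1e-6)
  }
})

test_that("the seed consensus outscores its shuffles almost always", {
  seed_aln <- make_seed_alignment("famA", length = 60, stem = 8, seed = 77)
  ph <- build_phmm(seed_aln)
  cons <- ph$consensus
  cons_score <- score_sequence(ph, cons)$forward_bits
  shufs <- shuffle_sequence(cons, 100, seed = 123)
  wins <- sum(vapply(shufs, function(s)
    cons_score > score_sequence(ph, s)$forward_bits, TRUE))
  expect_gte(wins, 95)
})

test_that("the posterior envelope brackets a planted consensus copy", {
  seed_aln <- make_seed_alignment("famB", length = 70, stem = 0, seed = 5)
  ph <- build_phmm(seed_aln)
  win <- paste0(generate_background(60, 0.36, seed = 1), ph$consensus,
                generate_background(60, 0.36, seed = 2))
  sc <- score_sequence(ph, win)
  env <- sc$envelope
  ov <- min(env[2], 130) - max(env[1], 60)
  expect_gte(ov / 70, 0.5)  # envelope covers >= 50% of the planted copy
  expect_true(env[1] >= 0 && env[2] <= nchar(win))
})

test_that("genome scanning flags planted copies and respects the cutoff", {
  seed_aln <- make_seed_alignment("famC", length = 80, stem = 10, seed = 9)
  ph <- build_phmm(seed_aln)
  # pure random genome: no hits at E <= 0.01
  nullg <- tiny_genome(4, 3000, seed = 50)
  h0 <- search_phmm(ph, nullg, null_samples = 300, seed = 2)
  expect_equal(nrow(h0), 0L)
  # planted consensus copy: exactly that region comes back
  pg <- plant_in_genome(ph$consensus, flank = 1500, seed = 8)
  h1 <- search_phmm(ph, pg$genome, null_samples = 300, seed = 2)
  expect_gte(nrow(h1), 1L)
  best <- h1[which.min(h1$evalue), ]
  ov <- min(best$end, pg$end) - max(best$start, pg$start)
  expect_gte(ov / (pg$end - pg$start), 0.5)
  expect_lte(best$evalue, 0.01)
  # calibration refuses too few null samples
  expect_error(search_phmm(ph, pg$genome, null_samples = 50), "null_samples")
})

test_that("a planted copy on the minus strand is reported in forward coordinates", {
  seed_aln <- make_seed_alignment("famD", length = 80, stem = 10, seed = 13)
  ph <- build_phmm(seed_aln)
  pg <- plant_in_genome(ph$consensus, flank = 1200, seed = 4, strand = "-")
  h <- search_phmm(ph, pg$genome, null_samples = 300, seed = 2)
  expect_gte(nrow(h), 1L)
  best <- h[which.min(h$evalue), ]
  expect_equal(best$strand, "-")
  ov <- min(best$end, pg$end) - max(best$start, pg$start)
  expect_gte(ov / (pg$end - pg$start), 0.5)
})

test_that("Gumbel fitting recovers known parameters", {
  set.seed(99)
  x <- -log(-log(runif(5000))) * 2.5 + 7  # Gumbel(mu=7, beta=2.5)
  fit <- fit_gumbel(x)
  expect_equal(fit$mu, 7, tolerance = 0.15)
  expect_equal(fit$beta, 2.5, tolerance = 0.15)
  expect_error(fit_gumbel(rep(1, 100)), "zero variance")
})
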