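make_tree <- function(newick) ape::read.tree(text = newick)

test_that("forced reconstructions behave at the extremes", {
  tr <- make_tree("((A,B)ab,(C,D)cd)root;")
  m <- matrix(c(1, 1, 1, 1), 1, 4, dimnames = list("f1", c("A", "B", "C", "D")))
  rec <- dollo_reconstruct(tr, m)
  expect_true(all(rec$states["f1", ] == 1))
  expect_equal(unname(rec$gain_node["f1"]), "root")
  expect_equal(length(rec$loss_edges[["f1"]]), 0L)
  # single presence leaf: gain on the pendant edge, no losses
  m2 <- matrix(c(1, 0, 0, 0), 1, 4, dimnames = list("f2", c("A", "B", "C", "D")))
  rec2 <- dollo_reconstruct(tr, m2)
  expect_equal(unname(rec2$gain_node["f2"]), "A")
  expect_equal(length(rec2$loss_edges[["f2"]]), 0L)
  # absent everywhere: no gain, all zero
  m3 <- matrix(0L, 1, 4, dimnames = list("f3", c("A", "B", "C", "D")))
  rec3 <- dollo_reconstruct(tr, m3)
  expect_true(all(rec3$states == 0))
  expect_true(is.na(rec3$gain_node["f3"]))
})

test_that("loss counts equal the exhaustive single-gain minimum", {
  set.seed(17)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(5:8, 1))
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
    for (column in 1:20) {
      ls <- sample(0:1, ape::Ntip(tr), replace = TRUE)
      names(ls) <- tr$tip.label
      m <- matrix(ls, 1, dimnames = list("fam", tr$tip.label))
      rec <- dollo_reconstruct(tr, m)
      expect_equal(length(rec$loss_edges[["fam"]]),
                   dollo_loss_oracle(tr, ls))
      # leaves always match the matrix
      expect_equal(unname(rec$states["fam", tr$tip.label]), unname(ls))
    }
  }
})

test_that("every edge satisfies count(child) = count(parent) + gains - losses", {
  set.seed(23)
  tr <- ape::rtree(7)
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  m <- matrix(sample(0:1, 7 * 30, replace = TRUE), 30, 7,
              dimnames = list(paste0("f", 1:30), tr$tip.label))
  rec <- dollo_reconstruct(tr, m)
  e <- rec$summary$edges
  expect_equal(e$child_count, e$parent_count + e$gains - e$losses)
  # per family: at most one gain, and no edge is both gain and loss
  for (f in rownames(m)) {
    g <- rec$gain_node[f]
    if (!is.na(g)) expect_false(g %in% rec$loss_edges[[f]])
  }
  # determinism
  rec2 <- dollo_reconstruct(tr, m)
  expect_identical(rec$states, rec2$states)
})

test_that("hard constraints override parsimony placement or error out", {
  tr <- make_tree("((A,B)ab,(C,D)cd)root;")
  m <- matrix(c(1, 0, 0, 0), 1, 4, dimnames = list("f", c("A", "B", "C", "D")))
  # forcing presence at the root relocates the gain there, with losses below
  cons <- data.frame(node = "root", family_id = "f", state = 1L)
  rec <- dollo_reconstruct(tr, m, cons)
  expect_equal(unname(rec$gain_node["f"]), "root")
  expect_gte(length(rec$loss_edges[["f"]]), 1L)
  # a leaf constraint contradicting the matrix errors
  bad <- data.frame(node = "B", family_id = "f", state = 1L)
  expect_error(dollo_reconstruct(tr, m, bad), "contradicts leaf")
  # an absence constraint on a required path errors
  m2 <- matrix(c(1, 1, 0, 0), 1, 4, dimnames = list("f", c("A", "B", "C", "D")))
  bad2 <- data.frame(node = "ab", family_id = "f", state = 0L)
  expect_error(dollo_reconstruct(tr, m2, bad2), "contradicts required")
})

test_that("family sets partition presences between disjoint groups", {
  m <- matrix(c(1, 0, 0, 0,
                1, 1, 0, 0,
                0, 0, 1, 0,
                1, 0, 1, 0,
                0, 0, 0, 0), 5, 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:5), c("A", "B", "C", "D")))
  fs <- family_sets(m, c("A", "B"), c("C", "D"))
  expect_setequal(fs$a_specific, c("f1", "f2"))
  expect_setequal(fs$b_specific, "f3")
  expect_setequal(fs$shared, "f4")
  # absent-everywhere families appear in none of the sets
  expect_false("f5" %in% unlist(fs))
  # partition identity over families present in the union
  present <- rownames(m)[rowSums(m[, c("A", "B", "C", "D")]) > 0]
  expect_setequal(unlist(fs), present)
  expect_error(family_sets(m, c("A", "B"), c("B", "C")), "overlap")
})

test_that("count propagation reproduces published-style edge bookkeeping", {
  expect_equal(propagate_count(58, c(18, 6), c(1, 1)), c(75, 80))
  expect_equal(propagate_count(37, 50, 5), 82)
  expect_length(propagate_count(10, integer(0), integer(0)), 0)
})

test_that("the shipped species tree has the expected taxa and named clades", {
  tr <- default_species_tree()
  expect_setequal(tr$tip.label, c("Cel", "Bfl", "Odi", "Bsc", "Dvex", "Cin",
                                  "Csa", "Pma", "Dre", "Lch", "Xtr", "Aca"))
  expect_true(all(c("Bilateria", "Chordata", "Olfactores", "Tunicata",
                    "Craniata") %in% tr$node.label))
  # a colonial-vs-solitary miRNA comparison runs on it end to end
  m <- matrix(rbinom(12 * 6, 1, 0.5), 6, 12,
              dimnames = list(paste0("mir-", 1:6), tr$tip.label))
  rec <- dollo_reconstruct(tr, m)
  expect_equal(ncol(rec$states), 12 + tr$Nnode)
  fs <- family_sets(m, c("Dvex", "Bsc"), c("Odi", "Cin", "Csa"))
  expect_true(is.list(fs))
})
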