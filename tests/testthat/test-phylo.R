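test_that("alignment-identity distances are consistent with global_align", {
  set.seed(8)
  seqs <- c(a = random_peptide(60), c = random_peptide(60))
  seqs["b"] <- seqs[["a"]]  # identical pair
  x <- seq_set(seqs[c("a", "b", "c")], alphabet = "peptide")
  d <- pairwise_distances(x)
  expect_equal(d["a", "b"], 0)
  expect_equal(unclass(d), t(unclass(d)))
  expect_equal(diag(unclass(d)), c(a = 0, b = 0, c = 0))
  # consistency: every entry equals a fresh pairwise recomputation
  for (i in c("a", "b", "c")) for (j in c("a", "b", "c")) {
    if (i == j) next
    expect_equal(d[i, j],
                 1 - global_align(unclass(x)[[i]], unclass(x)[[j]])$identity)
  }
  expect_error(pairwise_distances(x[1:2]), "at least 3")
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.4,
                0.5, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  len <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(len[["a"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(len[["b"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(len[["c"]], (0.5 + 0.4 - 0.3) / 2)
})

test_that("NJ recovers topology and branch lengths exactly from additive matrices", {
  set.seed(31)
  for (i in 1:10) {
    case <- random_additive_case(sample(4:8, 1))
    tree <- nj_tree(case$d)
    expect_equal(phangorn::RF.dist(ape::unroot(case$tree), tree), 0)
    got <- stats::cophenetic(tree)[rownames(case$d), colnames(case$d)]
    expect_lt(max(abs(got - case$d)), 1e-9)
  }
})

test_that("NJ validates input and clamps negative branch lengths", {
  d <- matrix(c(0, NaN, 1, NaN, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "finite")
  d2 <- matrix(c(0, -0.1, 1, -0.1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d2), "non-negative")
  set.seed(4)
  for (i in 1:5) {  # noisy matrices: output must never carry negative edges
    case <- random_additive_case(6)
    noisy <- case$d + matrix(stats::runif(36, 0, 0.8), 6, 6)
    noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
    tr <- suppressWarnings(nj_tree(noisy))
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("NJ topology is invariant to taxon relabeling", {
  set.seed(12)
  case <- random_additive_case(6)
  perm <- sample(6)
  d2 <- case$d[perm, perm]
  expect_equal(phangorn::RF.dist(nj_tree(case$d), nj_tree(d2)), 0)
})

test_that("a candidate sister to an ingroup bait is called an ortholog", {
  tree <- read_newick("((cand:0.1,in1:0.1):1.0,(out1:0.1,out2:0.1):1.0);")
  call <- classify_ortholog(tree, "cand", "in1", c("out1", "out2"))
  expect_equal(call$ingroup_fraction, 1.0)
  expect_true(call$is_ortholog)
  expect_identical(call$n_neighbors_considered, 1L)
})

test_that("a candidate nested among outgroup baits is rejected", {
  tree <- read_newick(
    "((cand:0.1,out1:0.1):0.2,(out2:0.1,(in1:0.1,in2:0.1):0.2):0.2);")
  call <- classify_ortholog(tree, "cand", c("in1", "in2"),
                            c("out1", "out2"))
  expect_equal(call$ingroup_fraction, 0.0)
  expect_false(call$is_ortholog)
})

test_that("the ingroup-fraction boundary is inclusive at the default threshold", {
  nwk <- "((cand:0.1,((in1:0.1,in2:0.1):0.1,(out1:0.1,out2:0.1):0.1):0.1):0.5,(in3:0.1,out3:2.0):0.5);"
  tree <- read_newick(nwk)
  call <- classify_ortholog(tree, "cand", c("in1", "in2", "in3"),
                            c("out1", "out2", "out3"))
  expect_equal(call$ingroup_fraction, 0.5)  # 2 ingroup of 4 baits in the clade
  expect_identical(call$n_neighbors_considered, 4L)
  expect_true(call$is_ortholog)             # boundary inclusive
})

test_that("the ortholog call ignores leaves outside the deciding clade", {
  base <- "((cand:0.1,in1:0.1):1.0,(out1:0.1,out2:0.1):1.0);"
  more <- "((cand:0.1,in1:0.1):1.0,((out1:0.1,out2:0.1):0.5,(out3:0.1,out4:0.1):0.5):0.5);"
  c1 <- classify_ortholog(read_newick(base), "cand", "in1",
                          c("out1", "out2"))
  c2 <- classify_ortholog(read_newick(more), "cand", "in1",
                          c("out1", "out2", "out3", "out4"))
  expect_equal(c1$ingroup_fraction, c2$ingroup_fraction)
  expect_identical(c1$is_ortholog, c2$is_ortholog)
})

test_that("classify_ortholog validates its leaves", {
  tree <- read_newick("((cand:0.1,in1:0.1):1.0,(out1:0.1,out2:0.1):1.0);")
  expect_error(classify_ortholog(tree, "ghost", "in1", "out1"),
               "not a leaf")
  expect_error(classify_ortholog(tree, "cand", character(0), "out1"),
               "at least one ingroup")
})

test_that("newick writer emits the canonical three-leaf form", {
  tree <- nj_tree(matrix(c(0, 0.3, 0.5, 0.3, 0, 0.4, 0.5, 0.4, 0), 3, 3,
                         dimnames = list(c("A", "B", "C"),
                                         c("A", "B", "C"))))
  s <- write_newick(tree)
  expect_match(s, "^\\([A-C]:0\\.\\d+,[A-C]:0\\.\\d+,[A-C]:0\\.\\d+\\);$")
  back <- read_newick(s)
  expect_setequal(back$tip.label, c("A", "B", "C"))
  expect_equal(stats::cophenetic(back)[c("A", "B", "C"), c("A", "B", "C")],
               stats::cophenetic(tree)[c("A", "B", "C"), c("A", "B", "C")])
})

test_that("labels with reserved characters are quoted and re-parseable", {
  tree <- ape::rtree(4)
  tree$tip.label <- c("plain", "with(parens)", "semi;colon", "quo'te")
  s <- write_newick(tree)
  expect_match(s, "'with\\(parens\\)'", fixed = FALSE)
  back <- read_newick(s)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(phangorn::RF.dist(back, tree), 0)
})

test_that("write-then-read round-trips random trees within 1e-9", {
  set.seed(77)
  for (i in 1:10) {
    tree <- ape::rtree(sample(4:12, 1))
    f <- withr::local_tempfile()
    write_newick(tree, f)
    back <- read_newick(f)
    expect_equal(phangorn::RF.dist(back, tree), 0)
    got <- stats::cophenetic(back)[tree$tip.label, tree$tip.label]
    expect_lt(max(abs(got - stats::cophenetic(tree))), 1e-9)
    # independent parser agrees on plain-label trees
    via_ape <- ape::read.tree(f)
    expect_equal(phangorn::RF.dist(via_ape, tree), 0)
  }
})
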