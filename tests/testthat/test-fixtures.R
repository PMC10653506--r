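test_that("family simulation respects its parameter contract", {
  fam <- simulate_family(60, 3, 0, seed = 1)
  expect_true(all(unclass(fam$members) == fam$ancestor))  # divergence 0
  one <- simulate_family(60, 1, 0.2, seed = 2)
  expect_length(one$members, 1L)
  expect_error(simulate_family(20, 2, 0.1), ">= 50")
  expect_error(simulate_family(60, 2, 0.7), "divergence")
  # conserved sites never move
  fam2 <- simulate_family(100, 5, 0.5, seed = 3, conserved = c(10, 50))
  for (m in unclass(fam2$members)) {
    expect_identical(substr(m, 10, 10), substr(fam2$ancestor, 10, 10))
    expect_identical(substr(m, 50, 50), substr(fam2$ancestor, 50, 50))
  }
})

test_that("mean pairwise identity matches the closed-form expectation", {
  # two members match at a site w.p. (1-d)^2 + d^2/19
  d <- 0.1
  expected <- (1 - d)^2 + d^2 / 19
  idents <- unlist(lapply(1:6, function(s) {
    fam <- simulate_family(300, 4, d, seed = 400 + s)
    mem <- unclass(fam$members)
    sapply(combn(length(mem), 2, simplify = FALSE), function(p) {
      a <- strsplit(mem[[p[1]]], "")[[1]]
      b <- strsplit(mem[[p[2]]], "")[[1]]
      mean(a == b)
    })
  }))
  # Monte-Carlo tolerance: SE of the mean over 36 pairs x 300 sites
  expect_lt(abs(mean(idents) - expected), 0.01)
})

test_that("identical seeds reproduce byte-identical study files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(d1, n_steps = 2, n_decoys = 10, seq_length = 80,
                 n_samples = 5, seed = 123)
  simulate_study(d2, n_steps = 2, n_decoys = 10, seq_length = 80,
                 n_samples = 5, seed = 123)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
})

test_that("the planted ortholog outscores every decoy in identity to its bait", {
  for (s in 1:3) {
    dir <- withr::local_tempdir()
    truth <- simulate_study(dir, n_steps = 1, n_decoys = 15,
                            seq_length = 100, divergence = 0.2,
                            n_samples = 4, seed = 600 + s)
    subj <- read_fasta(file.path(dir, "subject.fasta"))
    step <- read_bait_step(list.files(file.path(dir, "baits"),
                                      full.names = TRUE)[1])
    ortho <- truth$steps$step01$ortholog
    best_ident <- function(id) {
      max(vapply(unclass(step$ingroup), function(b)
        global_align(unclass(subj)[[id]], b)$identity, numeric(1)))
    }
    oi <- best_ident(ortho)
    for (d in truth$decoys) expect_lt(best_ident(d), oi)
  }
})

test_that("study truth is internally consistent and id sets are disjoint", {
  dir <- withr::local_tempdir()
  truth <- simulate_study(dir, n_steps = 3, n_decoys = 8, seq_length = 80,
                          n_samples = 4, pseudogene_steps = 2, seed = 9)
  orthos <- vapply(truth$steps, function(s) s$ortholog, character(1))
  pseudos <- unlist(lapply(truth$steps, function(s) s$pseudogene))
  expect_length(pseudos, 1L)
  expect_length(intersect(orthos, truth$decoys), 0L)
  expect_length(intersect(pseudos, truth$decoys), 0L)
  subj <- read_fasta(file.path(dir, "subject.fasta"))
  expect_true(all(c(orthos, pseudos, truth$decoys) %in% names(subj)))
  # the pseudogene really is knocked out at the recorded rule position
  st <- truth$steps$step02
  ref <- unclass(read_bait_step(
    file.path(dir, "baits", "step02.fasta"))$ingroup)[[st$reference_id]]
  rules <- load_rules(file.path(dir, "rules", "step02_residues.tsv"))$residues
  rep <- check_residues(unclass(subj)[[st$pseudogene]], ref, rules,
                        reference_id = st$reference_id)
  bad <- rep$residues[rep$residues$outcome == "mismatch", ]
  expect_identical(bad$position, st$knocked_out_position)
})

test_that("zero decoys at zero divergence give perfect score ratios", {
  dir <- withr::local_tempdir()
  simulate_study(dir, n_steps = 2, n_decoys = 0, divergence = 0,
                 seq_length = 80, n_samples = 4,
                 pseudogene_steps = integer(0), seed = 44)
  subj <- read_fasta(file.path(dir, "subject.fasta"))
  for (bf in list.files(file.path(dir, "baits"), full.names = TRUE)) {
    step <- read_bait_step(bf)
    hits <- find_candidates(subj, step)
    expect_equal(hits$score_ratio, rep(1.0, nrow(hits)))
    expect_equal(hits$identity, rep(1.0, nrow(hits)))
  }
})

test_that("the optional indel mode changes lengths but spares conserved sites", {
  fam0 <- simulate_family(100, 4, 0.1, seed = 70)
  expect_true(all(nchar(unclass(fam0$members)) == 100))  # default: no indels
  fam <- simulate_family(100, 6, 0.1, seed = 70, indel_rate = 0.05,
                         conserved = c(40, 41))
  lens <- nchar(unclass(fam$members))
  expect_true(any(lens != 100))
  # the conserved block survives in every member (positions may shift)
  anc_block <- substr(fam$ancestor, 40, 41)
  for (m in unclass(fam$members))
    expect_true(grepl(anc_block, m, fixed = TRUE))
  expect_error(simulate_family(60, 2, 0.1, indel_rate = 0.5), "indel_rate")
})
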