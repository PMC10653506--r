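test_that("the bundled FLS rules carry the literature residues and motifs", {
  rules <- bundled_rules("fls")
  res <- rules$residues
  expect_setequal(res$position[res$role_tag == "ferrous iron binding"],
                  c(221, 223, 277))
  expect_setequal(res$position[res$role_tag == "2-oxoglutarate binding"],
                  c(287, 289))
  expect_setequal(res$position[res$role_tag == "folding"],
                  c(68, 75, 207, 261))
  expect_identical(res$expected[res$position == 287], "R")
  expect_identical(res$expected[res$position == 289], "S")
  expect_identical(res$expected[match(c(221, 223, 277), res$position)],
                   c("H", "D", "H"))
  expect_identical(res$expected[match(c(68, 75, 207, 261), res$position)],
                   c("G", "H", "P", "G"))
  expect_setequal(rules$motifs$pattern, c("PxxxIRxxxEQP", "SxxTxLVP"))
  lycb <- bundled_rules("lycb")
  expect_true(any(grepl("dinucleotide", lycb$domains$name)))
})

test_that("rule validation rejects malformed tables", {
  f <- withr::local_tempfile(lines = c(
    "reference_id\tposition\texpected\talternatives\trole_tag",
    "ref\t0\tR\t\tbinding"))
  expect_error(load_rules(residues_path = f), "line 2")
  m <- withr::local_tempfile(lines = c("name\tpattern", "m1\t"))
  expect_error(load_rules(motifs_path = m), "line 2")
  expect_error(residue_rules("ref", 5, "R", alternatives = "K,R"),
               "among its own alternatives")
  expect_error(motif_rules("m", "PX-3"), "letters")
})

test_that("position mapping is the identity on identity alignments", {
  s <- random_peptide(50)
  aln <- global_align(s, s)
  for (p in c(1, 10, 25, 50)) expect_identical(map_position(aln, p), as.integer(p))
  expect_error(map_position(aln, 51), "out of range")
  expect_error(map_position(aln, 0), "out of range")
})

test_that("an N-terminal extension shifts every mapped position by its length", {
  set.seed(2)
  ref <- random_peptide(120)
  cand <- paste0(random_peptide(10), ref)
  aln <- global_align(cand, ref)
  for (p in c(1, 7, 60, 120))
    expect_identical(map_position(aln, p), as.integer(p + 10))
})

test_that("reference positions deleted in the candidate map to NA", {
  ref <- paste0(strrep("A", 20), "WWWWW", strrep("A", 20))
  cand <- strrep("A", 40)  # middle block absent
  aln <- global_align(cand, ref)
  expect_true(is.na(map_position(aln, 23)))
})

test_that("position mapping is strictly increasing where defined", {
  set.seed(14)
  for (i in 1:5) {
    ref <- random_peptide(80)
    cand <- orthobait:::.mutate(ref, 0.2)
    aln <- global_align(cand, ref)
    mapped <- vapply(1:80, function(p) {
      v <- map_position(aln, p)
      if (is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
    mapped <- mapped[!is.na(mapped)]
    expect_true(all(diff(mapped) > 0))
  }
})

test_that("a candidate identical to the reference passes every rule", {
  ref <- unclass(fls_reference_fixture())[["FLS_reference"]]
  rules <- bundled_rules("fls")
  rep <- check_residues(ref, ref, rules$residues, rules$motifs,
                        reference_id = "FLS_reference")
  expect_true(all(rep$residues$outcome == "match"))
  expect_true(all(rep$motifs$present))
})

test_that("a 2-oxoglutarate arginine knockout yields exactly one mismatch", {
  ref <- unclass(fls_reference_fixture())[["FLS_reference"]]
  cand <- ref
  substr(cand, 287, 287) <- "K"  # R287K, K not an accepted alternative
  rules <- bundled_rules("fls")
  rep <- check_residues(cand, ref, rules$residues,
                        reference_id = "FLS_reference")
  mism <- rep$residues[rep$residues$outcome == "mismatch", ]
  expect_identical(nrow(mism), 1L)
  expect_identical(mism$position, 287L)
  expect_identical(mism$observed, "K")
  expect_identical(mism$role_tag, "2-oxoglutarate binding")
})

test_that("accepted alternatives rescue a substitution", {
  ref <- random_peptide(60)
  rules <- residue_rules("r", 30, substr(ref, 30, 30) , alternatives = "",
                         role_tag = "binding")
  cand <- ref
  substr(cand, 30, 30) <- if (substr(ref, 30, 30) == "K") "R" else "K"
  rules2 <- residue_rules("r", 30, substr(ref, 30, 30),
                          alternatives = substr(cand, 30, 30),
                          role_tag = "binding")
  strict <- check_residues(cand, ref, rules, reference_id = "r")
  lenient <- check_residues(cand, ref, rules2, reference_id = "r")
  expect_identical(strict$residues$outcome, "mismatch")
  expect_identical(lenient$residues$outcome, "accepted_alternative")
})

test_that("truncation before a rule position reports it unaligned", {
  ref <- unclass(fls_reference_fixture())[["FLS_reference"]]
  cand <- substr(ref, 1, 200)  # lost everything from 201 on
  rules <- bundled_rules("fls")
  rep <- check_residues(cand, ref, rules$residues,
                        reference_id = "FLS_reference")
  late <- rep$residues[rep$residues$position > 200, ]
  expect_true(all(late$outcome == "unaligned"))
  early <- rep$residues[rep$residues$position <= 200, ]
  expect_true(all(early$outcome == "match"))
})

test_that("check_residues refuses a reference id mismatch", {
  rules <- residue_rules("other_ref", 5, "A")
  expect_error(check_residues("MKVAA", "MKVAA", rules, reference_id = "r"),
               "reference")
})

test_that("motif scanning matches the hand-checked example and finds overlaps", {
  expect_identical(scan_motif("PAAAIRAAAEQP", "PxxxIRxxxEQP"), 1L)
  expect_identical(scan_motif("MKVPAAAIRAAAEQPW", "PxxxIRxxxEQP"), 4L)
  expect_identical(scan_motif("PAAAIRAAAAAA", "PxxxIRxxxEQP"), integer(0))
  expect_identical(scan_motif("AAAA", "AxA"), c(1L, 2L))  # overlapping hits
  expect_identical(scan_motif("mkvSaaTaLVPw", "SxxTxLVP"), 4L)  # case-insensitive
})

test_that("motif scanning agrees with the naive sliding-window oracle", {
  set.seed(55)
  aa <- c("A", "E", "P", "Q", "R", "S")  # small alphabet to force matches
  for (i in 1:200) {
    s <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    p <- paste(sample(c(aa, "x"), sample(2:6, 1), replace = TRUE),
               collapse = "")
    expect_identical(scan_motif(s, p), oracle_motif_scan(s, p))
  }
})

test_that("candidate classification follows the ortholog gate and rule failures", {
  ref <- unclass(fls_reference_fixture())[["FLS_reference"]]
  rules <- bundled_rules("fls")
  ok_rep <- check_residues(ref, ref, rules$residues,
                           reference_id = "FLS_reference")
  ko <- ref; substr(ko, 287, 287) <- "K"
  ko_rep <- check_residues(ko, ref, rules$residues,
                           reference_id = "FLS_reference")
  yes <- structure(list(is_ortholog = TRUE), class = "ortholog_call")
  no <- structure(list(is_ortholog = FALSE), class = "ortholog_call")
  expect_identical(as.character(classify_candidate(ok_rep, yes)), "functional")
  part <- classify_candidate(ko_rep, yes)
  expect_identical(as.character(part), "partial")
  expect_identical(attr(part, "failures")$position, 287L)
  expect_identical(as.character(classify_candidate(ok_rep, no)), "unlikely")
})

test_that("classification is monotone: adding a failure never upgrades", {
  ref <- unclass(fls_reference_fixture())[["FLS_reference"]]
  rules <- bundled_rules("fls")$residues
  yes <- structure(list(is_ortholog = TRUE), class = "ortholog_call")
  rank <- c(unlikely = 0, partial = 1, functional = 2)
  prev <- "functional"
  cand <- ref
  set.seed(9)
  for (pos in sample(rules$position)) {  # knock out one more rule each round
    substr(cand, pos, pos) <- if (substr(ref, pos, pos) == "A") "V" else "A"
    st <- as.character(classify_candidate(
      check_residues(cand, ref, rules, reference_id = "FLS_reference"), yes))
    expect_lte(rank[[st]], rank[[prev]])
    prev <- st
  }
})

test_that("a folding-only failure is reported but spared under a critical-tag policy", {
  ref <- unclass(fls_reference_fixture())[["FLS_reference"]]
  rules <- bundled_rules("fls")$residues
  cand <- ref; substr(cand, 68, 68) <- "W"  # folding G68W
  rep <- check_residues(cand, ref, rules, reference_id = "FLS_reference")
  yes <- structure(list(is_ortholog = TRUE), class = "ortholog_call")
  expect_identical(as.character(classify_candidate(rep, yes)), "partial")
  spared <- classify_candidate(rep, yes, critical_tags = c("binding"))
  expect_identical(as.character(spared), "functional")
})
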