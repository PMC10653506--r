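#' Residue and motif rules
#'
#' Functional-residue rules encode literature knowledge of the form
#' "position 287 of the reference must be an arginine (2-oxoglutarate
#' binding)". Positions are 1-based on the ungapped reference sequence,
#' matching the Arg287-style nomenclature of the enzyme literature. Motif
#' rules are short patterns over amino-acid letters where `x` matches any
#' residue (e.g. the flavonol synthase diagnostic `PxxxIRxxxEQP`).
#'
#' `residue_rules()` and `motif_rules()` validate and construct the rule
#' tables; [load_rules] reads them from TSV files.
#'
#' @param reference_id id of the reference sequence the positions refer to.
#' @param position 1-based residue positions on the ungapped reference.
#' @param expected expected one-letter residues.
#' @param alternatives accepted alternative residues per rule, as
#'   comma-separated strings (`""` = strict).
#' @param role_tag free-text functional role (e.g. `"2-oxoglutarate
#'   binding"`, `"ferrous iron binding"`, `"folding"`).
#' @return a data.frame of class `residue_rules` (or `motif_rules`).
#' @export
residue_rules <- function(reference_id, position, expected,
                          alternatives = "", role_tag = "") {
  n <- length(position)
  df <- data.frame(reference_id = rep_len(as.character(reference_id), n),
                   position = as.integer(position),
                   expected = toupper(as.character(expected)),
                   alternatives = rep_len(toupper(as.character(alternatives)), n),
                   role_tag = rep_len(as.character(role_tag), n),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$position) | df$position < 1L)
  if (length(bad))
    stop("residue rule position must be a 1-based integer (row ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  bad <- which(!grepl("^[A-Z]$", df$expected))
  if (length(bad))
    stop("expected residue must be a single letter (row ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  alts <- strsplit(gsub(" ", "", df$alternatives), ",", fixed = TRUE)
  bad <- which(mapply(function(e, a) e %in% a, df$expected, alts))
  if (length(bad))
    stop("expected residue listed among its own alternatives (row ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  class(df) <- c("residue_rules", "data.frame")
  df
}

#' @rdname residue_rules
#' @param name motif names.
#' @param pattern motif patterns over `[A-Z]` and the wildcard `x`.
#' @export
motif_rules <- function(name, pattern) {
  df <- data.frame(name = as.character(name),
                   pattern = as.character(pattern),
                   stringsAsFactors = FALSE)
  bad <- which(!nzchar(df$pattern) | !grepl("^[A-Za-z]+$", df$pattern))
  if (length(bad))
    stop("motif pattern must be non-empty and contain only letters and 'x' (row ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  class(df) <- c("motif_rules", "data.frame")
  df
}

#' Load residue and motif rules from TSV files
#'
#' The residue file is a TSV with header columns `reference_id`,
#' `position`, `expected`, `alternatives`, `role_tag`; the motif file has
#' `name` and `pattern`. Malformed rows are reported with their line
#' number. Rule files for flavonol synthase (FLS) and lycopene beta-cyclase
#' (LYC-b) ship with the package; see [bundled_rules].
#'
#' @param residues_path path to the residue-rule TSV (or `NULL`).
#' @param motifs_path path to the motif TSV (or `NULL`).
#' @return a list with elements `residues` ([residue_rules] or `NULL`) and
#'   `motifs` ([motif_rules] or `NULL`).
#' @export
load_rules <- function(residues_path = NULL, motifs_path = NULL) {
  res <- NULL
  mot <- NULL
  if (!is.null(residues_path)) {
    df <- utils::read.delim(residues_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("reference_id", "position", "expected", "alternatives",
              "role_tag")
    if (!all(need %in% names(df)))
      stop("residue rule file must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    pos <- suppressWarnings(as.integer(df$position))
    bad <- which(is.na(pos) | pos < 1L)
    if (length(bad))
      stop("invalid position in ", residues_path, " line ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    res <- residue_rules(df$reference_id, pos, df$expected,
                         df$alternatives, df$role_tag)
  }
  if (!is.null(motifs_path)) {
    df <- utils::read.delim(motifs_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("name", "pattern") %in% names(df)))
      stop("motif file must have columns: name, pattern", call. = FALSE)
    ok <- nzchar(df$pattern) & grepl("^[A-Za-z]+$", df$pattern)
    if (any(!ok))
      stop("invalid motif pattern in ", motifs_path, " line ",
           paste(which(!ok) + 1L, collapse = ", "), call. = FALSE)
    mot <- motif_rules(df$name, df$pattern)
  }
  list(residues = res, motifs = mot)
}

#' Bundled rule sets
#'
#' Returns the rule files shipped with the package. `"fls"` carries the
#' flavonol synthase functional residues (ferrous iron binding His221,
#' Asp223, His277; 2-oxoglutarate binding Arg287, Ser289; 2-ODD folding
#' Gly68, His75, Pro207, Gly261) and the two FLS-diagnostic motifs
#' `PxxxIRxxxEQP` and `SxxTxLVP`. `"lycb"` carries the named conserved
#' regions of lycopene beta-cyclase (dinucleotide binding motif, cyclase
#' motifs I and II, conserved region beta-LYC, beta-cyclase motif) as
#' annotations only, since residue-level catalytic knowledge for LYC-b is
#' not established; LYC-b candidates are therefore screened by tree
#' placement rather than by residues.
#'
#' @param set `"fls"` or `"lycb"`.
#' @return for `"fls"`, a list with `residues` and `motifs` rule tables;
#'   for `"lycb"`, a list with a `domains` annotation data.frame.
#' @export
bundled_rules <- function(set = c("fls", "lycb")) {
  set <- match.arg(set)
  ext <- function(f) system.file("extdata", f, package = "orthobait",
                                 mustWork = TRUE)
  if (set == "fls") {
    load_rules(ext("fls_residues.tsv"), ext("fls_motifs.tsv"))
  } else {
    list(domains = utils::read.delim(ext("lycb_domains.tsv"),
                                     stringsAsFactors = FALSE))
  }
}

#' Map a reference position through an alignment
#'
#' Walks the aligned columns counting ungapped reference positions and
#' returns the 1-based ungapped candidate position aligned to the column
#' holding reference position `ref_position`, or `NA` when that column
#' holds a candidate gap. The mapping is strictly increasing over reference
#' positions where defined.
#'
#' @param alignment a `pairwise_alignment` with the candidate as sequence
#'   `a` and the reference as sequence `b`.
#' @param ref_position 1-based position on the ungapped reference.
#' @return the candidate position, or `NA_integer_` when unaligned.
#' @export
map_position <- function(alignment, ref_position) {
  ca <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  ref_len <- sum(cb != "-")
  if (!is.numeric(ref_position) || ref_position < 1L ||
      ref_position > ref_len)
    stop("ref_position out of range 1..", ref_len, call. = FALSE)
  col <- which(cumsum(cb != "-") == ref_position & cb != "-")[1L]
  if (ca[col] == "-") return(NA_integer_)
  as.integer(sum(ca[seq_len(col)] != "-"))
}

#' Check functional residues and motifs of a candidate
#'
#' Globally aligns the candidate to the reference and evaluates every
#' residue rule through [map_position]: `match` when the candidate residue
#' equals the expected one, `accepted_alternative` when it is among the
#' rule's alternatives, `mismatch` otherwise, and `unaligned` when the
#' reference position falls in a candidate gap (e.g. a truncation). Motifs
#' are scanned over the full candidate sequence.
#'
#' @param candidate,reference peptide sequences (character scalars).
#' @param rules a [residue_rules] table referring to `reference_id`.
#' @param motifs an optional [motif_rules] table.
#' @param reference_id id of the reference; must match the rules'
#'   `reference_id`.
#' @param candidate_id id carried into the report.
#' @param scheme a [scoring_scheme].
#' @return a list of class `residue_report`: `residues` (rule table plus
#'   `candidate_position`, `observed`, `outcome`), `motifs` (per-motif
#'   `present` and start positions), and `counts`.
#' @export
check_residues <- function(candidate, reference, rules, motifs = NULL,
                           reference_id = NULL, candidate_id = NA_character_,
                           scheme = scoring_scheme()) {
  if (!is.null(rules)) {
    if (!is.null(reference_id) && !all(rules$reference_id == reference_id))
      stop("rules refer to reference '",
           paste(unique(rules$reference_id), collapse = ","),
           "' but reference '", reference_id, "' was given", call. = FALSE)
    if (any(rules$position > nchar(reference)))
      stop("rule position exceeds reference length ", nchar(reference),
           call. = FALSE)
  }
  aln <- global_align(candidate, reference, scheme,
                      id_a = candidate_id, id_b = reference_id)
  res <- NULL
  if (!is.null(rules) && nrow(rules) > 0L) {
    res <- as.data.frame(rules)
    res$candidate_position <- NA_integer_
    res$observed <- NA_character_
    res$outcome <- NA_character_
    for (i in seq_len(nrow(res))) {
      cp <- map_position(aln, res$position[i])
      if (is.na(cp)) {
        res$outcome[i] <- "unaligned"
        next
      }
      obs <- substr(candidate, cp, cp)
      alts <- strsplit(gsub(" ", "", res$alternatives[i]), ",",
                       fixed = TRUE)[[1]]
      res$candidate_position[i] <- cp
      res$observed[i] <- obs
      res$outcome[i] <- if (obs == res$expected[i]) "match"
        else if (obs %in% alts) "accepted_alternative"
        else "mismatch"
    }
  }
  mot <- NULL
  if (!is.null(motifs) && nrow(motifs) > 0L) {
    mot <- as.data.frame(motifs)
    starts <- lapply(mot$pattern, function(p) scan_motif(candidate, p))
    mot$present <- lengths(starts) > 0L
    mot$starts <- vapply(starts, paste, character(1), collapse = ",")
  }
  counts <- c(match = 0L, accepted_alternative = 0L, mismatch = 0L,
              unaligned = 0L)
  if (!is.null(res)) {
    tab <- table(res$outcome)
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(candidate_id = candidate_id, reference_id = reference_id,
                 residues = res, motifs = mot, counts = counts,
                 alignment = aln),
            class = "residue_report")
}

#' @export
print.residue_report <- function(x, ...) {
  cat(sprintf("residue report%s: %d match, %d alternative, %d mismatch, %d unaligned\n",
              if (!is.na(x$candidate_id)) paste0(" for ", x$candidate_id) else "",
              x$counts[["match"]], x$counts[["accepted_alternative"]],
              x$counts[["mismatch"]], x$counts[["unaligned"]]))
  if (!is.null(x$motifs))
    cat(sprintf("motifs present: %d of %d\n", sum(x$motifs$present),
                nrow(x$motifs)))
  invisible(x)
}

#' Scan a peptide for a wildcard motif
#'
#' Finds all (possibly overlapping) occurrences of a motif pattern in which
#' letters match exactly (case-insensitively) and `x` matches any residue.
#'
#' @param seq peptide sequence.
#' @param pattern motif pattern (string or single-row [motif_rules]).
#' @return integer vector of 1-based start positions (empty when absent).
#' @export
scan_motif <- function(seq, pattern) {
  if (is.data.frame(pattern)) pattern <- pattern$pattern[1L]
  if (!nzchar(pattern) || !grepl("^[A-Za-z]+$", pattern))
    stop("motif pattern must be non-empty letters/'x'", call. = FALSE)
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  # matching is case-insensitive, so 'x'/'X' both act as the wildcard
  rx <- paste(ifelse(chars == "X", ".", chars), collapse = "")
  m <- gregexpr(paste0("(?=", rx, ")"), toupper(seq), perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Classify a candidate from its evidence
#'
#' Combines the tree-based ortholog call with the residue report:
#' candidates that are not orthologs are `unlikely`; orthologs whose gating
#' rules all pass (outcome `match` or `accepted_alternative`) are
#' `functional`; orthologs with at least one gating-rule failure
#' (`mismatch` or `unaligned`) are `partial`, with the failures listed --
#' this is what separates intact genes from likely pseudogene products. By
#' default every residue rule gates the functional call; `critical_tags`
#' restricts gating to rules whose `role_tag` matches one of the given
#' regular expressions (e.g. `c("binding", "catalytic")`), in which case
#' non-critical failures are still reported but do not demote the
#' candidate.
#'
#' @param report a `residue_report` (or `NULL` when the step has no rules).
#' @param ortholog an `ortholog_call` for the same candidate.
#' @param hit optional `candidate_hits` row for the same candidate (carried
#'   into the result for reporting).
#' @param critical_tags optional character vector of regexes selecting the
#'   gating rules by `role_tag`; `NULL` gates on all rules.
#' @return a character scalar, one of `"functional"`, `"partial"`,
#'   `"unlikely"`, with the failing rules in attribute `"failures"`.
#' @export
classify_candidate <- function(report, ortholog, hit = NULL,
                               critical_tags = NULL) {
  fails <- data.frame()
  if (!is.null(report) && !is.null(report$residues)) {
    res <- report$residues
    gate <- rep(TRUE, nrow(res))
    if (!is.null(critical_tags))
      gate <- Reduce(`|`, lapply(critical_tags, grepl, x = res$role_tag,
                                 ignore.case = TRUE))
    fails <- res[gate & res$outcome %in% c("mismatch", "unaligned"), ,
                 drop = FALSE]
  }
  status <- if (!ortholog$is_ortholog) "unlikely"
    else if (nrow(fails) == 0L) "functional"
    else "partial"
  attr(status, "failures") <- fails
  status
}
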