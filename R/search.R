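#' Bait steps
#'
#' One pathway step: a collection of ingroup baits (characterized enzymes
#' with the step's function), outgroup baits (related but functionally
#' distinct sequences), a reference sequence id on which residue positions
#' are defined, and optional residue/motif rules.
#'
#' @param label step label (e.g. `"FLS"`).
#' @param ingroup,outgroup peptide [seq_set]s.
#' @param reference_id id of the reference sequence for residue rules; must
#'   be an ingroup bait. Defaults to the first ingroup bait.
#' @param residue_rules,motif_rules optional rule tables (see [load_rules]).
#' @return an object of class `bait_step`.
#' @export
bait_step <- function(label, ingroup, outgroup = NULL, reference_id = NULL,
                      residue_rules = NULL, motif_rules = NULL) {
  if (length(ingroup) == 0L)
    stop("bait step '", label, "' has no ingroup baits", call. = FALSE)
  if (is.null(reference_id)) reference_id <- names(ingroup)[1L]
  if (!reference_id %in% names(ingroup))
    stop("reference_id '", reference_id, "' is not an ingroup bait",
         call. = FALSE)
  structure(list(label = label, ingroup = ingroup,
                 outgroup = if (is.null(outgroup)) seq_set(character(0)) else outgroup,
                 reference_id = reference_id,
                 residue_rules = residue_rules, motif_rules = motif_rules),
            class = "bait_step")
}

#' @export
print.bait_step <- function(x, ...) {
  cat(sprintf("bait_step '%s': %d ingroup, %d outgroup baits, reference %s, %d residue rule(s), %d motif(s)\n",
              x$label, length(x$ingroup), length(x$outgroup), x$reference_id,
              if (is.null(x$residue_rules)) 0L else nrow(x$residue_rules),
              if (is.null(x$motif_rules)) 0L else nrow(x$motif_rules)))
  invisible(x)
}

#' Read a bait step from FASTA
#'
#' Headers carry the group membership as a `in=1` or `out=1` token in the
#' description (e.g. `>AtFLS1 in=1`); sequences without a token default to
#' ingroup.
#'
#' @param path FASTA file, one per pathway step.
#' @param label step label; defaults to the file name without extension.
#' @inheritParams bait_step
#' @return a [bait_step].
#' @export
read_bait_step <- function(path, label = NULL, residue_rules = NULL,
                           motif_rules = NULL, reference_id = NULL) {
  if (is.null(label))
    label <- sub("\\.(fa|fasta|faa)$", "", basename(path))
  recs <- read_fasta(path, alphabet = "peptide")
  desc <- attr(recs, "description")
  is_out <- grepl("(^|\\s)out=1(\\s|$)", desc)
  ing <- recs[!is_out]
  outg <- if (any(is_out)) recs[is_out] else NULL
  bait_step(label, ing, outg, reference_id = reference_id,
            residue_rules = residue_rules, motif_rules = motif_rules)
}

#' Build a k-mer index of subject sequences
#'
#' Exact k-mer postings used as a prefilter so that full global alignments
#' are only computed for plausible bait/subject pairs.
#'
#' @param x a peptide [seq_set].
#' @param k k-mer length (default 4).
#' @return an object of class `seed_index`: a list mapping each k-mer to the
#'   ids of subjects containing it.
#' @export
seed_index <- function(x, k = 4L) {
  stopifnot(k >= 1L)
  kmers <- lapply(names(x), function(id) {
    s <- unclass(x)[[id]]
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  ids <- rep(names(x), lengths(kmers))
  idx <- split(ids, unlist(kmers))
  structure(list(index = idx, k = k, ids = names(x)), class = "seed_index")
}

# distinct k-mers of `query` shared with each indexed subject
.shared_kmer_counts <- function(index, query) {
  k <- index$k
  n <- nchar(query)
  if (n < k) return(stats::setNames(integer(0), character(0)))
  qk <- unique(substring(query, 1:(n - k + 1L), k:n))
  hits <- unlist(index$index[intersect(qk, names(index$index))],
                 use.names = FALSE)
  if (is.null(hits)) return(stats::setNames(integer(0), character(0)))
  tab <- table(hits)
  stats::setNames(as.integer(tab), names(tab))
}

#' Find candidate homologs of a bait step
#'
#' Subjects passing the k-mer prefilter against any ingroup bait are
#' globally aligned against all ingroup baits. A hit is retained when its
#' score ratio (alignment score divided by the best bait's self-alignment
#' score) reaches `min_score_ratio` and its identity reaches
#' `min_identity`. Hits are ranked by score ratio (descending), ties broken
#' by subject id, and capped at `max_candidates`; the output order is fully
#' deterministic.
#'
#' @param subjects peptide [seq_set] of the species under study.
#' @param step a [bait_step].
#' @param scheme a [scoring_scheme].
#' @param min_score_ratio minimum score ratio (default 0.3).
#' @param min_identity minimum alignment identity (default 0.2).
#' @param max_candidates cap on candidates per step (default 10).
#' @param min_shared_kmers distinct shared k-mers (with any ingroup bait)
#'   required to pass the prefilter (default 2).
#' @param k k-mer length for the prefilter.
#' @param prefilter disable to align every subject against every bait.
#' @return a data.frame of class `candidate_hits` with columns
#'   `subject_id`, `step_label`, `best_bait_id`, `score`, `score_ratio`,
#'   `identity`, `coverage`, `rank`; the `"alignments"` attribute holds the
#'   subject-vs-best-bait `pairwise_alignment` objects.
#' @export
find_candidates <- function(subjects, step, scheme = scoring_scheme(),
                            min_score_ratio = 0.3, min_identity = 0.2,
                            max_candidates = 10L, min_shared_kmers = 2L,
                            k = 4L, prefilter = TRUE) {
  if (!inherits(step, "bait_step")) stop("step must be a bait_step", call. = FALSE)
  empty <- data.frame(subject_id = character(0), step_label = character(0),
                      best_bait_id = character(0), score = numeric(0),
                      score_ratio = numeric(0), identity = numeric(0),
                      coverage = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("candidate_hits", "data.frame")
  attr(empty, "alignments") <- list()
  if (length(subjects) == 0L) {
    warning("empty subject collection for step '", step$label, "'",
            call. = FALSE)
    return(empty)
  }
  baits <- unclass(step$ingroup)
  pass <- names(subjects)
  if (isTRUE(prefilter)) {
    idx <- seed_index(subjects, k = k)
    shared <- lapply(baits, function(b) .shared_kmer_counts(idx, b))
    best_shared <- Reduce(function(a, b) {
      ids <- union(names(a), names(b))
      stats::setNames(pmax(ifelse(is.na(a[ids]), 0L, a[ids]),
                           ifelse(is.na(b[ids]), 0L, b[ids])), ids)
    }, shared, init = stats::setNames(integer(0), character(0)))
    pass <- names(best_shared)[best_shared >= min_shared_kmers]
    pass <- pass[order(match(pass, names(subjects)))]
  }
  if (length(pass) == 0L) return(empty)
  self_scores <- vapply(baits, .self_score, numeric(1), scheme = scheme)
  rows <- list()
  alns <- list()
  for (sid in pass) {
    subj <- unclass(subjects)[[sid]]
    sc <- .scores_vs(baits, subj, scheme)
    best <- names(sc)[order(-sc, names(sc))][1L]
    aln <- global_align(subj, baits[[best]], scheme, id_a = sid, id_b = best)
    ratio <- aln$score / self_scores[[best]]
    if (ratio >= min_score_ratio && aln$identity >= min_identity) {
      rows[[sid]] <- data.frame(subject_id = sid, step_label = step$label,
                                best_bait_id = best, score = aln$score,
                                score_ratio = ratio, identity = aln$identity,
                                coverage = aln$coverage_a,
                                stringsAsFactors = FALSE)
      alns[[sid]] <- aln
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$score_ratio, out$subject_id), , drop = FALSE]
  out <- utils::head(out, max_candidates)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_hits", "data.frame")
  attr(out, "alignments") <- alns[out$subject_id]
  out
}

#' Import precomputed tabular similarity-search hits
#'
#' Optional hook for users who already ran an external similarity search:
#' reads the conventional 12-column tabular format (query, subject,
#' identity, alignment length, mismatches, gap opens, qstart, qend, sstart,
#' send, evalue, bitscore).
#'
#' @param path path to a tab-separated 12-column hit table without header.
#' @return a data.frame with the 12 standard columns.
#' @export
read_tabular_hits <- function(path) {
  cols <- c("query", "subject", "identity", "length", "mismatches",
            "gapopens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) != 12L)
    stop("expected 12 tab-separated columns, found ", ncol(x), call. = FALSE)
  names(x) <- cols
  x
}
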