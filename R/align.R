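#' Alignment scoring scheme
#'
#' Bundles a substitution matrix with affine gap penalties. A gap of length
#' L scores `gap_open + (L - 1) * gap_extend` (so the defaults -11/-1 give
#' -11 for a single-residue gap), the convention commonly used with
#' BLOSUM62.
#'
#' @param matrix substitution matrix name (currently `"BLOSUM62"`) or a
#'   symmetric numeric matrix with residue dimnames.
#' @param gap_open score for opening a gap (first gapped residue); negative.
#' @param gap_extend score for each further gapped residue; negative, with
#'   `gap_open <= gap_extend < 0`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -11, gap_extend = -1) {
  if (is.character(matrix)) {
    matrix <- match.arg(matrix, "BLOSUM62")
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62
  }
  if (!is.matrix(matrix) || is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)) ||
      !isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric with residue dimnames",
         call. = FALSE)
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("need gap_open <= gap_extend < 0", call. = FALSE)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

.check_alphabet <- function(s, scheme, what = "sequence") {
  chars <- unique(strsplit(s, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, rownames(scheme$matrix))
  if (length(bad))
    stop(sprintf("%s contains character(s) absent from the substitution matrix: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# Biostrings parameterization: a gap of length L costs gapOpening +
# L * gapExtension, so gapOpening = -(gap_open - gap_extend),
# gapExtension = -gap_extend reproduces our convention.
.pa_gap <- function(scheme) {
  list(opening = -(scheme$gap_open - scheme$gap_extend),
       extension = -scheme$gap_extend)
}

.alignment_result <- function(aligned_a, aligned_b, score,
                              id_a = NA_character_, id_b = NA_character_) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  both <- ca != "-" | cb != "-"  # columns that are not dual gaps
  ident <- sum(ca == cb & ca != "-" & cb != "-") / sum(both)
  la <- sum(ca != "-"); lb <- sum(cb != "-")
  cov_a <- sum(ca != "-" & cb != "-") / la
  cov_b <- sum(ca != "-" & cb != "-") / lb
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, identity = ident,
                 coverage_a = cov_a, coverage_b = cov_b,
                 id_a = id_a, id_b = id_b),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("global alignment%s: score %.1f, identity %.3f\n",
              if (!is.na(x$id_a)) sprintf(" %s vs %s", x$id_a, x$id_b) else "",
              x$score, x$identity))
  cat(" ", substr(x$aligned_a, 1, 70), "\n ", substr(x$aligned_b, 1, 70), "\n")
  invisible(x)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (Gotoh),
#' computed by `Biostrings::pairwiseAlignment`. Identity is the fraction of
#' matching residues over aligned columns (dual-gap columns excluded);
#' coverage is the aligned (non-gap-paired) fraction of each input.
#' Removing the gaps from either aligned string recovers the corresponding
#' input. The result is deterministic for a given pair of inputs.
#'
#' @param a,b peptide sequences (character scalars, optionally named via
#'   `id_a`/`id_b`).
#' @param scheme a [scoring_scheme].
#' @param id_a,id_b optional sequence identifiers carried into the result.
#' @return an object of class `pairwise_alignment` with elements
#'   `aligned_a`, `aligned_b`, `score`, `identity`, `coverage_a`,
#'   `coverage_b`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme(),
                         id_a = NA_character_, id_b = NA_character_) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || !nzchar(a) || !nzchar(b))
    stop("both sequences must be non-empty character scalars", call. = FALSE)
  .check_alphabet(a, scheme, "sequence a")
  .check_alphabet(b, scheme, "sequence b")
  gp <- .pa_gap(scheme)
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = scheme$matrix,
    gapOpening = gp$opening, gapExtension = gp$extension)
  .alignment_result(as.character(Biostrings::alignedPattern(pa)),
                    as.character(Biostrings::alignedSubject(pa)),
                    Biostrings::score(pa), id_a = id_a, id_b = id_b)
}

# score of a sequence aligned to itself (identity alignment is optimal for
# matrices whose diagonal dominates, as in BLOSUM62)
.self_score <- function(s, scheme) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  sum(scheme$matrix[cbind(chars, chars)])
}

# vectorized scores of one subject against many baits (no traceback)
.scores_vs <- function(baits, subject, scheme) {
  gp <- .pa_gap(scheme)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(baits), subject = subject,
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = gp$opening, gapExtension = gp$extension,
    scoreOnly = TRUE)
  stats::setNames(pa, names(baits))
}
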