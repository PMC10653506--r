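#' Sequence sets
#'
#' A `seq_set` is the package's light-weight container for named sequences:
#' a named character vector with per-record descriptions and a declared
#' alphabet (`"nucleotide"`, `"peptide"`, or `"unknown"`). Identifiers must
#' be unique and non-empty, sequences non-empty.
#'
#' @param seqs named character vector of sequences.
#' @param desc optional character vector of descriptions (recycled names of
#'   `seqs` are used when `NULL`).
#' @param alphabet declared alphabet.
#' @return an object of class `seq_set`.
#' @export
seq_set <- function(seqs, desc = NULL,
                    alphabet = c("unknown", "nucleotide", "peptide")) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) == 0L) {
    seqs <- character(0)
  }
  ids <- names(seqs)
  if (length(seqs) > 0L && (is.null(ids) || any(!nzchar(ids))))
    stop("every sequence must have a non-empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  if (is.null(desc)) desc <- rep("", length(seqs))
  structure(as.character(seqs),
            names = ids,
            description = as.character(desc),
            alphabet = alphabet,
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d sequence(s), alphabet: %s\n",
              length(x), attr(x, "alphabet")))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s  [%d] %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' @export
`[.seq_set` <- function(x, i) {
  y <- unclass(x)
  d <- attr(x, "description")
  names(d) <- names(y)
  y <- y[i]
  seq_set(y, desc = unname(d[names(y)]), alphabet = attr(x, "alphabet"))
}

# characters tolerated after cleaning (IUPAC nucleotide + amino acid codes,
# '*' for stop codons retained internally)
.legal_chars <- function() c(LETTERS, "*")

#' Read a FASTA file
#'
#' Reads a (multi-line) FASTA file into a [seq_set]. Sequences are
#' uppercased, whitespace and alignment gap characters (`-`, `.`) are
#' stripped, `U` is converted to `T`, and a single terminal `*` (stop) is
#' removed and recorded in the `"stripped_stop"` attribute. Record order is
#' preserved; duplicate identifiers and residual illegal characters are
#' rejected.
#'
#' @param path path to a FASTA file.
#' @param alphabet declared alphabet of the file, if known.
#' @return a [seq_set]; attribute `"stripped_stop"` is a named logical
#'   vector marking records whose terminal stop was removed.
#' @export
read_fasta <- function(path, alphabet = c("unknown", "nucleotide", "peptide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("FASTA parse error: empty file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1L])
    stop("FASTA parse error: first non-empty line is not a header", call. = FALSE)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("FASTA parse error: empty identifier in header", call. = FALSE)
  if (anyDuplicated(ids))
    stop("FASTA parse error: duplicate id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 paste, character(1), collapse = "")
  # groups with no sequence lines are absent from split(); refuse them
  if (length(seqs) != length(ids))
    stop("FASTA parse error: record without sequence lines", call. = FALSE)
  seqs <- toupper(gsub("[\\s.\\-]", "", seqs, perl = TRUE))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  stripped <- grepl("\\*$", seqs)
  seqs <- sub("\\*$", "", seqs)
  bad <- !grepl("^[A-Z*]*$", seqs)
  if (any(bad))
    stop("FASTA parse error: illegal characters in record ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  names(seqs) <- ids
  out <- seq_set(seqs, desc = desc, alphabet = alphabet)
  attr(out, "stripped_stop") <- stats::setNames(stripped, ids)
  out
}

#' Write a FASTA file
#'
#' @param x a [seq_set] (or named character vector).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  ids <- names(x)
  desc <- attr(x, "description")
  if (is.null(desc)) desc <- rep("", length(x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(x)) {
    hdr <- if (nzchar(desc[i])) paste(ids[i], desc[i]) else ids[i]
    writeLines(paste0(">", hdr), con)
    s <- unclass(x)[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Detect whether sequences are nucleotide or peptide
#'
#' Pools all residues of the collection and infers `nucleotide` when the
#' fraction of characters in `{A,C,G,T,U,N}` exceeds `threshold`. A user
#' declaration is never silently overridden: a disagreement sets
#' `conflict = TRUE` and raises a warning, leaving the responsibility for
#' the declared type with the user.
#'
#' @param x a [seq_set].
#' @param threshold nucleotide-character fraction above which the collection
#'   is called nucleotide. The default 0.9 tolerates IUPAC ambiguity codes
#'   while still catching peptide input.
#' @param user_declared optional user declaration
#'   (`"nucleotide"`/`"peptide"`).
#' @return a list of class `seq_type_report` with elements `inferred`,
#'   `fraction_nucleotide_chars`, `user_declared`, `conflict`.
#' @export
detect_sequence_type <- function(x, threshold = 0.9, user_declared = NULL) {
  if (length(x) == 0L) stop("need at least one sequence", call. = FALSE)
  pooled <- paste(unclass(x), collapse = "")
  chars <- strsplit(pooled, "", fixed = TRUE)[[1]]
  frac <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  inferred <- if (frac > threshold) "nucleotide" else "peptide"
  conflict <- FALSE
  if (!is.null(user_declared)) {
    user_declared <- match.arg(user_declared, c("nucleotide", "peptide"))
    conflict <- !identical(user_declared, inferred)
    if (conflict)
      warning(sprintf(
        "declared sequence type '%s' disagrees with inferred '%s' (%.3f nucleotide characters); the declaration is kept",
        user_declared, inferred, frac), call. = FALSE)
  }
  structure(list(inferred = inferred,
                 fraction_nucleotide_chars = frac,
                 user_declared = user_declared,
                 conflict = conflict),
            class = "seq_type_report")
}

#' @export
print.seq_type_report <- function(x, ...) {
  cat(sprintf("sequence type: %s (%.1f%% nucleotide characters)%s\n",
              x$inferred, 100 * x$fraction_nucleotide_chars,
              if (x$conflict) sprintf(" -- CONFLICTS with declared '%s'",
                                      x$user_declared) else ""))
  invisible(x)
}

#' Translate coding sequences
#'
#' Translates each nucleotide sequence from position 1 using the standard
#' genetic code. A trailing incomplete codon is dropped with a warning;
#' internal stop codons are rendered as `*` and flagged.
#'
#' @param x a nucleotide [seq_set].
#' @return a peptide [seq_set]; attribute `"internal_stop"` is a named
#'   logical vector.
#' @export
translate_cds <- function(x) {
  code <- Biostrings::GENETIC_CODE
  seqs <- unclass(x)
  if (any(nchar(seqs) < 3L))
    stop("coding sequence shorter than one codon: ",
         paste(names(x)[nchar(seqs) < 3L], collapse = ", "), call. = FALSE)
  partial <- nchar(seqs) %% 3L != 0L
  if (any(partial))
    warning("trailing incomplete codon dropped for: ",
            paste(names(x)[partial], collapse = ", "), call. = FALSE)
  pep <- vapply(seqs, function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))
  pep <- sub("\\*$", "", pep)          # a terminal stop is expected, drop it
  internal <- grepl("*", pep, fixed = TRUE)  # remaining stops are internal
  keep <- nzchar(pep)
  if (!all(keep))
    warning("translation empty after stop removal for: ",
            paste(names(x)[!keep], collapse = ", "), call. = FALSE)
  out <- seq_set(pep[keep], alphabet = "peptide")
  attr(out, "internal_stop") <- stats::setNames(unname(internal)[keep],
                                                names(x)[keep])
  out
}

.revcomp <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Extract open reading frames from all six frames
#'
#' A simplified genome mode: every ORF (methionine to the next stop codon,
#' or to the frame end) of at least `min_len` amino acids is reported from
#' all six frames. Identifiers are suffixed with the frame and 1-based
#' inclusive forward-strand coordinates of the ORF; the strand is stored in
#' the `"orf_table"` attribute. Intron-aware gene prediction is deliberately
#' not attempted; dedicated gene predictors should be used for genomes with
#' introns.
#'
#' @param x a nucleotide [seq_set].
#' @param min_len minimum ORF length in amino acids.
#' @return a peptide [seq_set] of ORFs; attribute `"orf_table"` is a
#'   data.frame with source id, frame, strand, start, end.
#' @export
six_frame_orfs <- function(x, min_len = 50L) {
  code <- Biostrings::GENETIC_CODE
  res <- list()
  tab <- list()
  for (id in names(x)) {
    s <- unclass(x)[[id]]
    L <- nchar(s)
    for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
      strand <- if (frame > 0) "+" else "-"
      src <- if (frame > 0) s else .revcomp(s)
      off <- abs(frame) - 1L
      n <- L - off
      n <- n - n %% 3L
      if (n < 3L) next
      codons <- substring(src, off + seq(1L, n, 3L), off + seq(3L, n, 3L))
      aa <- unname(code[codons])
      aa[is.na(aa)] <- "X"
      pep <- paste(aa, collapse = "")
      # ORFs: from each first M of a stop-delimited segment to the stop
      segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
      pos <- 1L  # 1-based aa offset of segment start within frame
      for (seg in segs) {
        m <- regexpr("M", seg, fixed = TRUE)
        if (m > 0L) {
          orf <- substring(seg, m)
          if (nchar(orf) >= min_len) {
            aa_start <- pos + m - 1L
            aa_end <- pos + nchar(seg) - 1L
            nt_start <- off + (aa_start - 1L) * 3L + 1L  # on src strand
            nt_end <- off + aa_end * 3L
            if (strand == "-") {  # map back to forward strand
              fs <- L - nt_end + 1L
              fe <- L - nt_start + 1L
              nt_start <- fs; nt_end <- fe
            }
            oid <- sprintf("%s_%s%d_%d-%d", id, strand, abs(frame),
                           nt_start, nt_end)
            res[[oid]] <- orf
            tab[[oid]] <- data.frame(source = id, frame = frame,
                                     strand = strand, start = nt_start,
                                     end = nt_end, stringsAsFactors = FALSE)
          }
        }
        pos <- pos + nchar(seg) + 1L
      }
    }
  }
  out <- seq_set(unlist(res), alphabet = "peptide")
  orf_table <- if (length(tab)) do.call(rbind, tab) else
    data.frame(source = character(0), frame = integer(0),
               strand = character(0), start = integer(0), end = integer(0))
  attr(out, "orf_table") <- orf_table
  out
}
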