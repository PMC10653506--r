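#' Load an expression matrix
#'
#' Reads a genes-by-samples expression table (e.g. TPM values) from a TSV
#' whose first column holds gene ids and whose header row holds sample ids.
#' Duplicate genes, missing values, and non-numeric cells are rejected with
#' their coordinates.
#'
#' @param path path to the TSV file.
#' @return a numeric matrix (genes in rows, samples in columns).
#' @export
load_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression table needs a gene column and at least one sample",
         call. = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene id: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  samples <- names(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing expression value at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]]), call. = FALSE)
  dimnames(num) <- list(genes, samples)
  num
}

#' All-vs-all co-expression network among candidates
#'
#' Computes the correlation of expression profiles for every unordered pair
#' of candidate genes and keeps edges whose coefficient reaches
#' `min_coefficient`. Spearman correlation (rank transform with average
#' ranks for ties, then Pearson on the ranks) is the default as it is
#' robust to non-linear but monotone expression relationships. Candidates
#' absent from the matrix are reported as warnings, not errors. The
#' resulting edge list is undirected with `source < target`
#' lexicographically, no self edges, and no duplicate pairs; it can be
#' loaded into standard network-visualization tools via [export_network].
#'
#' @param candidates character vector of candidate gene ids.
#' @param mat numeric expression matrix (genes x samples), see
#'   [load_expression].
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_coefficient minimum coefficient for an edge (default 0.7).
#' @return a data.frame of class `edge_list` with columns `source`,
#'   `target`, `coefficient`, `n_samples`.
#' @export
coexpression_network <- function(candidates, mat,
                                 method = c("spearman", "pearson"),
                                 min_coefficient = 0.7) {
  method <- match.arg(method)
  if (ncol(mat) < 3L)
    stop("at least 3 samples are required for correlation", call. = FALSE)
  candidates <- unique(candidates)
  missing <- setdiff(candidates, rownames(mat))
  if (length(missing))
    warning("candidate(s) absent from expression matrix: ",
            paste(missing, collapse = ", "), call. = FALSE)
  present <- sort(intersect(candidates, rownames(mat)))
  empty <- data.frame(source = character(0), target = character(0),
                      coefficient = numeric(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("edge_list", "data.frame")
  if (length(present) < 2L) {
    if (length(candidates) >= 2L)
      warning("fewer than 2 candidates present in the expression matrix",
              call. = FALSE)
    return(empty)
  }
  cc <- stats::cor(t(mat[present, , drop = FALSE]), method = method)
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  out <- data.frame(source = present[pairs[, 1L]],
                    target = present[pairs[, 2L]],
                    coefficient = cc[pairs],
                    n_samples = ncol(mat),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$coefficient) & out$coefficient >= min_coefficient, ,
             drop = FALSE]
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Export / read a co-expression edge list
#'
#' Writes the edge list as a TSV with header `source`, `target`,
#' `coefficient`, `n_samples`, directly importable as a network table by
#' visualization tools such as Cytoscape. `read_network` parses such a file
#' back; exporting and re-reading yields an identical edge list.
#'
#' @param edges an `edge_list` from [coexpression_network].
#' @param path output (input) path.
#' @return `path` invisibly (`read_network`: the `edge_list`).
#' @export
export_network <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "coefficient")
  if (!all(need %in% names(df)))
    stop("network file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$n_samples)) df$n_samples <- NA_integer_
  class(df) <- c("edge_list", "data.frame")
  df
}
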