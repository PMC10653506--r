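#' Pairwise alignment-identity distances
#'
#' Distance between two peptides is one minus the identity of their optimal
#' global alignment; the diagonal is zero. At least three sequences are
#' required (the matrix feeds tree construction).
#'
#' @param x a peptide [seq_set].
#' @param scheme a [scoring_scheme].
#' @return a symmetric numeric matrix with zero diagonal and the sequence
#'   ids as dimnames, of class `dist_matrix`.
#' @export
pairwise_distances <- function(x, scheme = scoring_scheme()) {
  if (length(x) < 3L) stop("need at least 3 sequences", call. = FALSE)
  ids <- names(x)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- global_align(unclass(x)[[i]], unclass(x)[[j]], scheme)
      d[i, j] <- d[j, i] <- 1 - aln$identity
    }
  }
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Neighbor-joining tree
#'
#' Standard neighbor-joining agglomeration on a distance matrix
#' (`ape::nj`). Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with a warning. On additive
#' matrices the source tree's topology and branch lengths are recovered
#' exactly. The agglomeration is deterministic for a given matrix.
#'
#' @param d a symmetric distance matrix with zero diagonal and unique
#'   labels as dimnames (e.g. from [pairwise_distances]).
#' @return an `ape` `phylo` tree whose tips are the matrix labels.
#' @export
nj_tree <- function(d) {
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3L)
    stop("d must be a square matrix with at least 3 taxa", call. = FALSE)
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    stop("d must have unique labels as dimnames", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d)))
    stop("distances must be finite and non-missing", call. = FALSE)
  if (any(d < 0))
    stop("distances must be non-negative", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12)
    stop("distance matrix must be symmetric", call. = FALSE)
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Classify a candidate as orthologous from its tree neighborhood
#'
#' The tree is midpoint-rooted, then the smallest clade containing the
#' candidate and at least one bait (ingroup or outgroup) is located by
#' walking from the candidate tip towards the root. The candidate is called
#' an ortholog when the fraction of ingroup baits among all baits in that
#' clade reaches `threshold` (boundary inclusive; the default 0.5 is a
#' majority rule).
#'
#' @param tree a `phylo` tree containing the candidate and bait tips.
#' @param candidate_id tip label of the candidate.
#' @param ingroup_ids,outgroup_ids tip labels of the ingroup and outgroup
#'   baits (at least one of each must be present in the tree).
#' @param threshold minimum ingroup fraction (default 0.5).
#' @return a list of class `ortholog_call` with `candidate_id`,
#'   `ingroup_fraction`, `n_neighbors_considered`, `is_ortholog`.
#' @export
classify_ortholog <- function(tree, candidate_id, ingroup_ids, outgroup_ids,
                              threshold = 0.5) {
  if (!candidate_id %in% tree$tip.label)
    stop("candidate '", candidate_id, "' is not a leaf of the tree",
         call. = FALSE)
  ingroup_ids <- intersect(ingroup_ids, tree$tip.label)
  outgroup_ids <- intersect(outgroup_ids, tree$tip.label)
  if (length(ingroup_ids) < 1L || length(outgroup_ids) < 1L)
    stop("need at least one ingroup and one outgroup bait in the tree",
         call. = FALSE)
  rooted <- phangorn::midpoint(tree)
  baits <- c(ingroup_ids, outgroup_ids)
  tip <- match(candidate_id, rooted$tip.label)
  root <- ape::Ntip(rooted) + 1L
  path <- rev(ape::nodepath(rooted, from = root, to = tip))  # tip -> root
  frac <- NA_real_
  n_baits <- 0L
  for (node in path[-1L]) {  # first element is the tip itself
    tips <- ape::extract.clade(rooted, node)$tip.label
    in_clade <- intersect(tips, baits)
    if (length(in_clade) > 0L) {
      n_baits <- length(in_clade)
      frac <- length(intersect(tips, ingroup_ids)) / n_baits
      break
    }
  }
  if (is.na(frac))  # candidate alone on its side of the root: use all baits
    stop("no clade containing the candidate and a bait was found",
         call. = FALSE)
  structure(list(candidate_id = candidate_id, ingroup_fraction = frac,
                 n_neighbors_considered = n_baits,
                 is_ortholog = frac >= threshold),
            class = "ortholog_call")
}

#' @export
print.ortholog_call <- function(x, ...) {
  cat(sprintf("%s: ingroup fraction %.2f over %d bait(s) -> %s\n",
              x$candidate_id, x$ingroup_fraction, x$n_neighbors_considered,
              if (x$is_ortholog) "ortholog" else "not an ortholog"))
  invisible(x)
}

.newick_quote <- function(label) {
  if (grepl("[][(){}:;,'\"\\s]", label, perl = TRUE))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

#' Write a tree in Newick format
#'
#' Serializes a `phylo` tree with branch lengths. Labels containing
#' Newick-reserved characters (parentheses, brackets, colons, semicolons,
#' commas, quotes, whitespace) are single-quoted with internal quotes
#' doubled, so any label round-trips through [read_newick].
#'
#' @param tree a `phylo` tree.
#' @param path optional output file; when `NULL` the string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL, digits = 10L) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  fmt <- function(x) sprintf("%.*g", digits, x)
  recurse <- function(node) {
    if (node <= ntip) {
      .newick_quote(tree$tip.label[node])
    } else {
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(ch, function(c2)
        paste0(recurse(c2), ":", fmt(elen[[as.character(c2)]])),
        character(1)), collapse = ","), ")")
    }
  }
  s <- paste0(recurse(ntip + 1L), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read a Newick tree
#'
#' Parses a Newick string or file into an `ape` `phylo` tree. Single-quoted
#' labels (with doubled internal quotes) are supported, so trees written by
#' [write_newick] round-trip exactly.
#'
#' @param x a file path or a Newick string (detected by the presence of a
#'   `(`).
#' @return a `phylo` tree.
#' @export
read_newick <- function(x) {
  s <- if (grepl("(", x, fixed = TRUE)) x else
    paste(readLines(x, warn = FALSE), collapse = "")
  s <- trimws(s)
  if (!endsWith(s, ";")) stop("Newick string must end with ';'", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[pos] else ""
  advance <- function() pos <<- pos + 1L
  read_label <- function() {
    if (peek() == "'") {
      advance()
      out <- character(0)
      repeat {
        if (pos > n) stop("unterminated quoted label", call. = FALSE)
        ch <- chars[pos]; advance()
        if (ch == "'") {
          if (peek() == "'") { out <- c(out, "'"); advance() } else break
        } else out <- c(out, ch)
      }
      paste(out, collapse = "")
    } else {
      start <- pos
      while (pos <= n && !chars[pos] %in% c(",", ")", ":", ";", "(")) advance()
      paste(chars[start:(pos - 1L)], collapse = "")
    }
  }
  tips <- character(0)
  edges <- list()   # (parent, child, length)
  next_internal <- 0L
  read_clade <- function() {
    # returns list(id = node key, ...); edges appended to enclosing state
    if (peek() == "(") {
      advance()
      next_internal <<- next_internal + 1L
      me <- paste0("I", next_internal)
      repeat {
        child <- read_clade()
        len <- NA_real_
        if (peek() == ":") {
          advance()
          start <- pos
          while (pos <= n && grepl("[-+0-9.eE]", chars[pos])) advance()
          len <- as.numeric(paste(chars[start:(pos - 1L)], collapse = ""))
        }
        edges[[length(edges) + 1L]] <<- list(parent = me, child = child,
                                             length = len)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick near position ", pos, call. = FALSE)
      }
      # optional internal node label, ignored for structure
      if (!peek() %in% c(":", ",", ")", ";")) read_label()
      me
    } else {
      lab <- read_label()
      if (!nzchar(lab)) stop("empty leaf label at position ", pos, call. = FALSE)
      tips <<- c(tips, lab)
      paste0("T", length(tips))
    }
  }
  root <- read_clade()
  if (peek() == ":") {  # tolerate and drop a root branch length
    advance()
    while (pos <= n && grepl("[-+0-9.eE]", chars[pos])) advance()
  }
  if (peek() != ";") stop("trailing characters after tree", call. = FALSE)
  ntip <- length(tips)
  ninternal <- next_internal
  key2num <- function(key) {
    num <- as.integer(substring(key, 2L))
    if (startsWith(key, "T")) num else ntip + num
  }
  edge <- t(vapply(edges, function(e) c(key2num(e$parent), key2num(e$child)),
                   integer(2)))
  lens <- vapply(edges, function(e) e$length, numeric(1))
  tree <- list(edge = edge, tip.label = tips, Nnode = ninternal)
  if (!all(is.na(lens))) tree$edge.length <- ifelse(is.na(lens), 0, lens)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}
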