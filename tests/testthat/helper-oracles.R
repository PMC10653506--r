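# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths under test.

# Affine-gap global alignment score by an exhaustive three-state dynamic
# program written in plain R (gap of length L scores go + (L-1)*ge).
oracle_global_score <- function(a, b, mat, go = -11, ge = -1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- go + (i - 1L) * ge
  for (j in seq_len(m)) Iy[1L, j + 1L] <- go + (j - 1L) * ge
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1L, j + 1L] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + go, Ix[i, j + 1L] + ge,
                                Iy[i, j + 1L] + go)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + go, Iy[i + 1L, j] + ge,
                                Ix[i + 1L, j] + go)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

# Naive sliding-window motif scan ('x'/'X' in the pattern matches anything).
oracle_motif_scan <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  hits <- integer(0)
  if (length(p) > length(s)) return(hits)
  for (start in 1:(length(s) - length(p) + 1L)) {
    ok <- TRUE
    for (k in seq_along(p)) {
      if (p[k] != "X" && s[start + k - 1L] != p[k]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, start)
  }
  hits
}

# Spearman as rank-transform (average ranks for ties) followed by Pearson.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Random peptide and random additive distance matrix from a known tree.
random_peptide <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_additive_case <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 2))
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  list(tree = tree, d = stats::cophenetic(tree)[tree$tip.label,
                                                tree$tip.label])
}

blosum62 <- function() orthobait::scoring_scheme()$matrix
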