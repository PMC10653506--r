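.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# evaluate `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

.random_peptide <- function(length) {
  paste(sample(.AA20, length, replace = TRUE), collapse = "")
}

# substitute each site independently with probability `rate`, drawing
# uniformly among the 19 alternative residues; `conserved` sites never move
.mutate <- function(seq, rate, conserved = integer(0)) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, conserved)
  for (i in hit)
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

# sprinkle insertions/deletions: events at rate `rate` per site, lengths
# 1 + Geometric(1/mean_len); events overlapping `conserved` sites (whose
# positions refer to the original sequence) are skipped
.apply_indels <- function(seq, rate, conserved = integer(0), mean_len = 3) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_events <- stats::rbinom(1L, length(chars), rate)
  if (n_events == 0L) return(seq)
  keep <- rep(TRUE, length(chars))
  insertions <- vector("list", length(chars))
  for (e in seq_len(n_events)) {
    at <- sample(length(chars), 1L)
    len <- 1L + stats::rgeom(1L, 1 / mean_len)
    if (stats::runif(1) < 0.5) {                     # deletion
      span <- at:min(at + len - 1L, length(chars))
      if (length(intersect(span, conserved))) next
      keep[span] <- FALSE
    } else {                                         # insertion after `at`
      if (at %in% conserved) next  # keep conserved blocks contiguous
      insertions[[at]] <- c(insertions[[at]],
                            sample(.AA20, len, replace = TRUE))
    }
  }
  out <- character(0)
  for (i in seq_along(chars)) {
    if (keep[i]) out <- c(out, chars[i])
    if (!is.null(insertions[[i]])) out <- c(out, insertions[[i]])
  }
  paste(out, collapse = "")
}

#' Simulate a protein family
#'
#' Draws a random ancestral peptide and derives `n_members` descendants by
#' independent substitutions: each site mutates with probability
#' `divergence` to a uniformly chosen alternative residue (substitution-only
#' evolution, so pairwise identities have a closed form: two members match
#' at a site with probability `(1-d)^2 + d^2/19`). Sites listed in
#' `conserved` never mutate, emulating purifying selection on functional
#' residues.
#'
#' @param length ancestor length in residues (>= 50).
#' @param n_members number of derived members.
#' @param divergence expected substitutions per site, in \[0, 0.5\].
#' @param seed optional RNG seed; the result is deterministic given a seed.
#' @param conserved integer positions exempt from substitution.
#' @param indel_rate per-site insertion/deletion event rate (default 0:
#'   substitution-only evolution, which keeps pairwise identity in closed
#'   form). When positive, events get geometric lengths (mean 3) and never
#'   touch conserved sites.
#' @param prefix member id prefix.
#' @return a list with `ancestor` (character scalar) and `members` (a
#'   peptide [seq_set] named `<prefix>1..n`).
#' @export
simulate_family <- function(length, n_members, divergence, seed = NULL,
                            conserved = integer(0), indel_rate = 0,
                            prefix = "m") {
  if (length < 50L) stop("length must be >= 50", call. = FALSE)
  if (divergence < 0 || divergence > 0.5)
    stop("divergence must be in [0, 0.5]", call. = FALSE)
  if (n_members < 1L) stop("n_members must be >= 1", call. = FALSE)
  if (indel_rate < 0 || indel_rate > 0.1)
    stop("indel_rate must be in [0, 0.1]", call. = FALSE)
  .with_seed(seed, {
    anc <- .random_peptide(length)
    members <- vapply(seq_len(n_members), function(i) {
      m <- .mutate(anc, divergence, conserved)
      if (indel_rate > 0) m <- .apply_indels(m, indel_rate, conserved)
      m
    }, character(1))
    names(members) <- paste0(prefix, seq_len(n_members))
    list(ancestor = anc, members = seq_set(members, alphabet = "peptide"))
  })
}

#' Simulate a complete annotation study with known ground truth
#'
#' Generates everything a pipeline run consumes -- per-step bait FASTA
#' files (ingroup plus an outgroup sister family), residue-rule TSVs, a
#' subject proteome with one planted ortholog per step, optional
#' residue-knockout pseudogene copies, random decoy proteins, and an
#' expression matrix in which the true pathway genes share a latent profile
#' while decoys vary independently -- together with a machine-readable
#' truth record.
#'
#' Per step, an ancestral enzyme is drawn; ingroup baits and the planted
#' ortholog descend from it at `divergence` with the rule positions held
#' fixed (purifying selection), while the outgroup descends from a sister
#' ancestor derived at `outgroup_divergence` without that constraint. A
#' pseudogene is an ortholog copy with one rule residue substituted.
#'
#' @param dir output directory (created if needed).
#' @param n_steps number of pathway steps (default 5).
#' @param n_ingroup,n_outgroup baits per group per step (default 4 each).
#' @param seq_length enzyme length in residues (default 300).
#' @param divergence within-family substitution rate (default 0.1).
#' @param outgroup_divergence divergence of the outgroup sister ancestor
#'   (default 0.3).
#' @param n_decoys unrelated random proteins in the subject set
#'   (default 100).
#' @param n_rules functional-residue rules per step (default 4).
#' @param pseudogene_steps indices of steps receiving a pseudogene copy
#'   (default 1; use `integer(0)` for none).
#' @param n_samples expression samples (default 12).
#' @param noise_sd standard deviation of the Gaussian noise around the
#'   shared latent expression profile (default 0.5; values truncated at 0).
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @return (invisibly) a list of class `simulation_truth`: per-step true
#'   ortholog ids, pseudogene ids with their knocked-out positions, decoy
#'   ids, file paths, and the seed.
#' @export
simulate_study <- function(dir, n_steps = 5L, n_ingroup = 4L, n_outgroup = 4L,
                           seq_length = 300L, divergence = 0.1,
                           outgroup_divergence = 0.3, n_decoys = 100L,
                           n_rules = 4L, pseudogene_steps = 1L,
                           n_samples = 12L, noise_sd = 0.5, seed = 1L) {
  stopifnot(n_steps >= 1L, n_rules >= 1L, n_samples >= 3L)
  dir.create(file.path(dir, "baits"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "rules"), recursive = TRUE, showWarnings = FALSE)
  .with_seed(seed, {
    subject <- character(0)
    truth_steps <- list()
    gene_no <- 0L
    next_gene <- function() {
      gene_no <<- gene_no + 1L
      sprintf("g%04d", gene_no)
    }
    for (i in seq_len(n_steps)) {
      label <- sprintf("step%02d", i)
      rule_pos <- sort(sample(30:(seq_length - 30L), n_rules))
      anc <- .random_peptide(seq_length)
      ing <- vapply(seq_len(n_ingroup), function(j)
        .mutate(anc, divergence, conserved = rule_pos), character(1))
      names(ing) <- sprintf("%s.in%d", label, seq_len(n_ingroup))
      out_anc <- .mutate(anc, outgroup_divergence)
      outg <- vapply(seq_len(n_outgroup), function(j)
        .mutate(out_anc, divergence), character(1))
      names(outg) <- sprintf("%s.out%d", label, seq_len(n_outgroup))
      ortho_id <- next_gene()
      ortho <- .mutate(anc, divergence, conserved = rule_pos)
      subject[ortho_id] <- ortho
      pseudo_id <- NULL
      knocked <- NULL
      if (i %in% pseudogene_steps) {
        pseudo_id <- next_gene()
        knocked <- rule_pos[1L]
        chars <- strsplit(ortho, "", fixed = TRUE)[[1]]
        chars[knocked] <- sample(setdiff(.AA20, substr(anc, knocked, knocked)), 1L)
        subject[pseudo_id] <- paste(chars, collapse = "")
      }
      bait_seqs <- seq_set(c(ing, outg), desc = c(rep("in=1", n_ingroup),
                                                  rep("out=1", n_outgroup)),
                           alphabet = "peptide")
      write_fasta(bait_seqs, file.path(dir, "baits", paste0(label, ".fasta")))
      rules <- residue_rules(reference_id = names(ing)[1L],
                             position = rule_pos,
                             expected = substring(anc, rule_pos, rule_pos),
                             alternatives = "",
                             role_tag = rep(c("cofactor binding", "folding"),
                                            length.out = n_rules))
      utils::write.table(as.data.frame(rules),
                         file.path(dir, "rules",
                                   paste0(label, "_residues.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      truth_steps[[label]] <- list(ortholog = ortho_id,
                                   pseudogene = pseudo_id,
                                   knocked_out_position = knocked,
                                   rule_positions = rule_pos,
                                   reference_id = names(ing)[1L])
    }
    decoy_ids <- character(0)
    for (j in seq_len(n_decoys)) {
      id <- next_gene()
      decoy_ids <- c(decoy_ids, id)
      len <- sample(round(seq_length * 0.8):round(seq_length * 1.2), 1L)
      subject[id] <- .random_peptide(len)
    }
    write_fasta(seq_set(subject, alphabet = "peptide"),
                file.path(dir, "subject.fasta"))
    # expression: true orthologs share a latent profile; everything else is
    # independent
    latent <- stats::runif(n_samples, 1, 100)
    ortho_ids <- vapply(truth_steps, function(s) s$ortholog, character(1))
    expr <- matrix(0, nrow = length(subject), ncol = n_samples,
                   dimnames = list(names(subject),
                                   sprintf("sample%02d", seq_len(n_samples))))
    for (id in names(subject)) {
      expr[id, ] <- if (id %in% ortho_ids)
        pmax(0, latent + stats::rnorm(n_samples, 0, noise_sd))
      else
        stats::runif(n_samples, 0, 100)
    }
    expr <- round(expr, 4)
    df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth <- structure(list(steps = truth_steps, decoys = decoy_ids,
                            dir = dir, seed = seed,
                            paths = list(
                              subject = file.path(dir, "subject.fasta"),
                              baits = file.path(dir, "baits"),
                              rules = file.path(dir, "rules"),
                              expression = file.path(dir, "expression.tsv"))),
                       class = "simulation_truth")
    jsonlite::write_json(truth[c("steps", "decoys", "seed")],
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(truth)
  })
}

#' Synthetic flavonol synthase reference fixture
#'
#' Builds a synthetic peptide that carries the bundled FLS residue rules
#' (iron binding H221/D223/H277, 2-oxoglutarate binding R287/S289, folding
#' G68/H75/P207/G261) at their literature positions and one instance of
#' each FLS-diagnostic motif (`PxxxIRxxxEQP` planted at position 100,
#' `SxxTxLVP` at position 150), on an otherwise random background. This is
#' a synthetic stand-in for a real FLS protein, intended for testing
#' residue mapping; it is not a biological sequence.
#'
#' @param length total length (default 320, past the last rule position).
#' @param seed RNG seed for the random background.
#' @return a peptide [seq_set] with the single record `FLS_reference`.
#' @export
fls_reference_fixture <- function(length = 320L, seed = 1L) {
  rules <- bundled_rules("fls")
  stopifnot(length >= max(rules$residues$position) + 10L)
  .with_seed(seed, {
    chars <- sample(.AA20, length, replace = TRUE)
    plant <- function(chars, pattern, at) {
      pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
      for (k in seq_along(pat))
        if (pat[k] != "X") chars[at + k - 1L] <- pat[k]
      chars
    }
    chars <- plant(chars, rules$motifs$pattern[1L], 100L)
    chars <- plant(chars, rules$motifs$pattern[2L], 150L)
    chars[rules$residues$position] <- rules$residues$expected
    seq_set(c(FLS_reference = paste(chars, collapse = "")),
            alphabet = "peptide")
  })
}
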