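#' Configure an annotation run
#'
#' Validates paths and thresholds for [run_pipeline]. The bait directory
#' holds one FASTA per pathway step (ingroup/outgroup encoded as
#' `in=1`/`out=1` header tokens); the rules directory may hold
#' `<step>_residues.tsv` and `<step>_motifs.tsv` files (see [load_rules]).
#'
#' @param subject path to the subject FASTA (peptide or coding sequences).
#' @param bait_dir directory of per-step bait FASTA files.
#' @param rules_dir optional directory of rule TSVs.
#' @param expression optional path to an expression TSV (see
#'   [load_expression]).
#' @param out_dir output directory.
#' @param min_score_ratio,min_identity,max_candidates,min_shared_kmers
#'   search thresholds, see [find_candidates].
#' @param ortholog_threshold minimum ingroup fraction, see
#'   [classify_ortholog].
#' @param min_coefficient co-expression edge threshold, see
#'   [coexpression_network].
#' @param coexpr_method correlation method.
#' @param critical_tags gating policy for [classify_candidate].
#' @param seed seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(subject, bait_dir, rules_dir = NULL,
                       expression = NULL, out_dir,
                       min_score_ratio = 0.3, min_identity = 0.2,
                       max_candidates = 10L, min_shared_kmers = 2L,
                       ortholog_threshold = 0.5, min_coefficient = 0.7,
                       coexpr_method = "spearman", critical_tags = NULL,
                       seed = 1L) {
  if (!file.exists(subject)) stop("subject not found: ", subject, call. = FALSE)
  if (!dir.exists(bait_dir)) stop("bait directory not found: ", bait_dir,
                                  call. = FALSE)
  if (!is.null(rules_dir) && !dir.exists(rules_dir))
    stop("rules directory not found: ", rules_dir, call. = FALSE)
  if (!is.null(expression) && !file.exists(expression))
    stop("expression file not found: ", expression, call. = FALSE)
  stopifnot(min_score_ratio >= 0, min_score_ratio <= 1,
            min_identity >= 0, min_identity <= 1,
            ortholog_threshold >= 0, ortholog_threshold <= 1,
            min_coefficient >= -1, min_coefficient <= 1,
            max_candidates >= 1L)
  structure(list(subject = subject, bait_dir = bait_dir,
                 rules_dir = rules_dir, expression = expression,
                 out_dir = out_dir, min_score_ratio = min_score_ratio,
                 min_identity = min_identity,
                 max_candidates = as.integer(max_candidates),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 ortholog_threshold = ortholog_threshold,
                 min_coefficient = min_coefficient,
                 coexpr_method = coexpr_method,
                 critical_tags = critical_tags,
                 seed = as.integer(seed)),
            class = "run_config")
}

.step_rules <- function(rules_dir, label) {
  if (is.null(rules_dir)) return(list(residues = NULL, motifs = NULL))
  rp <- file.path(rules_dir, paste0(label, "_residues.tsv"))
  mp <- file.path(rules_dir, paste0(label, "_motifs.tsv"))
  load_rules(if (file.exists(rp)) rp else NULL,
             if (file.exists(mp)) mp else NULL)
}

#' Run the full annotation pipeline
#'
#' For every pathway step: candidate search against the ingroup baits
#' ([find_candidates]), neighbor-joining tree of candidates plus all baits
#' with a tree-based ortholog call ([classify_ortholog]), functional
#' residue/motif verification against the step reference
#' ([check_residues]), and final classification ([classify_candidate]).
#' Subject coding sequences are translated automatically when the input is
#' detected as nucleotide. An error in one step is logged and isolates that
#' step; the remaining steps still run. Outputs under `out_dir`: per step a
#' directory with `candidates.fasta`, `summary.tsv`, `tree.nwk`, and
#' `residues.tsv`; a co-expression `network.tsv` over all final candidates
#' when an expression matrix is supplied; and a machine-readable `run.json`
#' with package version and parameters. Given an identical configuration
#' and seed, two runs produce byte-identical outputs.
#'
#' @param config a [run_config].
#' @return an object of class `annotation_run`: per-step summary
#'   data.frames, the network edge list (or `NULL`), and step errors.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- scoring_scheme()
  subjects <- read_fasta(config$subject)
  type <- detect_sequence_type(subjects)
  if (type$inferred == "nucleotide") subjects <- translate_cds(subjects)
  bait_files <- sort(list.files(config$bait_dir,
                                pattern = "\\.(fa|fasta|faa)$",
                                full.names = TRUE))
  if (length(bait_files) == 0L)
    stop("no bait FASTA files in ", config$bait_dir, call. = FALSE)
  steps <- list()
  errors <- list()
  all_candidates <- character(0)
  for (bf in bait_files) {
    label <- sub("\\.(fa|fasta|faa)$", "", basename(bf))
    step_dir <- file.path(config$out_dir, label)
    dir.create(step_dir, showWarnings = FALSE)
    result <- tryCatch({
      rules <- .step_rules(config$rules_dir, label)
      step <- read_bait_step(bf, label = label,
                             residue_rules = rules$residues,
                             motif_rules = rules$motifs)
      hits <- find_candidates(subjects, step, scheme,
                              min_score_ratio = config$min_score_ratio,
                              min_identity = config$min_identity,
                              max_candidates = config$max_candidates,
                              min_shared_kmers = config$min_shared_kmers)
      summary <- data.frame(subject_id = character(0), step = character(0),
                            best_bait_id = character(0),
                            score_ratio = numeric(0), identity = numeric(0),
                            ingroup_fraction = numeric(0),
                            is_ortholog = logical(0),
                            n_rule_failures = integer(0),
                            status = character(0), stringsAsFactors = FALSE)
      res_rows <- list()
      if (nrow(hits) > 0L) {
        ids <- hits$subject_id
        tree_seqs <- c(subjects[ids], step$ingroup, step$outgroup)
        dmat <- pairwise_distances(
          seq_set(stats::setNames(unclass(tree_seqs), names(tree_seqs)),
                  alphabet = "peptide"), scheme)
        tree <- nj_tree(dmat)
        write_newick(tree, file.path(step_dir, "tree.nwk"))
        write_fasta(subjects[ids], file.path(step_dir, "candidates.fasta"))
        refseq <- unclass(step$ingroup)[[step$reference_id]]
        for (j in seq_len(nrow(hits))) {
          cid <- hits$subject_id[j]
          call <- classify_ortholog(tree, cid, names(step$ingroup),
                                    names(step$outgroup),
                                    threshold = config$ortholog_threshold)
          rep <- check_residues(unclass(subjects)[[cid]], refseq,
                                rules = step$residue_rules,
                                motifs = step$motif_rules,
                                reference_id = step$reference_id,
                                candidate_id = cid, scheme = scheme)
          status <- classify_candidate(rep, call, hits[j, ],
                                       critical_tags = config$critical_tags)
          nfail <- if (is.null(rep$residues)) 0L else
            sum(rep$residues$outcome %in% c("mismatch", "unaligned"))
          summary <- rbind(summary, data.frame(
            subject_id = cid, step = label,
            best_bait_id = hits$best_bait_id[j],
            score_ratio = hits$score_ratio[j],
            identity = hits$identity[j],
            ingroup_fraction = call$ingroup_fraction,
            is_ortholog = call$is_ortholog,
            n_rule_failures = nfail,
            status = as.character(status), stringsAsFactors = FALSE))
          if (!is.null(rep$residues)) {
            rr <- rep$residues
            rr$candidate <- cid
            res_rows[[cid]] <- rr[, c("candidate", "reference_id", "position",
                                      "expected", "role_tag",
                                      "candidate_position", "observed",
                                      "outcome")]
          }
        }
      }
      utils::write.table(summary, file.path(step_dir, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(res_rows))
        utils::write.table(do.call(rbind, res_rows),
                           file.path(step_dir, "residues.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      all_candidates <- union(all_candidates, summary$subject_id)
      summary
    }, error = function(e) {
      errors[[label]] <<- conditionMessage(e)
      message("step '", label, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(result)) steps[[label]] <- result
  }
  network <- NULL
  if (!is.null(config$expression) && length(all_candidates) >= 2L) {
    expr <- load_expression(config$expression)
    network <- coexpression_network(all_candidates, expr,
                                    method = config$coexpr_method,
                                    min_coefficient = config$min_coefficient)
    export_network(network, file.path(config$out_dir, "network.tsv"))
  }
  run_info <- list(
    package = "orthobait",
    version = as.character(utils::packageVersion("orthobait")),
    parameters = config[setdiff(names(config), c("out_dir"))],
    steps_completed = names(steps),
    steps_failed = errors)
  jsonlite::write_json(run_info, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  structure(list(steps = steps, errors = errors, network = network,
                 config = config),
            class = "annotation_run")
}

#' @export
print.annotation_run <- function(x, ...) {
  cat(sprintf("annotation run: %d step(s) completed, %d failed\n",
              length(x$steps), length(x$errors)))
  for (label in names(x$steps)) {
    s <- x$steps[[label]]
    if (nrow(s) == 0L) {
      cat(sprintf("  %s: no candidate\n", label))
    } else {
      cat(sprintf("  %s: %d candidate(s) [%s]\n", label, nrow(s),
                  paste(sprintf("%s=%s", s$subject_id, s$status),
                        collapse = ", ")))
    }
  }
  for (label in names(x$errors))
    cat(sprintf("  %s: FAILED (%s)\n", label, x$errors[[label]]))
  if (!is.null(x$network))
    cat(sprintf("  network: %d edge(s)\n", nrow(x$network)))
  invisible(x)
}

#' Annotation benchmark metrics
#'
#' Specificity is the percentage of the true functional gene set that was
#' predicted (correct predictions / truth-set size); accuracy is the
#' percentage of predictions that are correct (correct predictions / total
#' predictions, defined as 0 for an empty prediction set); performance is
#' the mean of the two. All three are percentages in \[0, 100\]. Ids are
#' deduplicated, so the metrics are invariant to ordering and repetition.
#'
#' @param predicted character vector of predicted gene ids.
#' @param truth character vector of true functional gene ids (non-empty).
#' @return a list of class `evaluation_result` with `specificity`,
#'   `accuracy`, `performance`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  truth <- unique(as.character(truth))
  predicted <- unique(as.character(predicted))
  if (length(truth) == 0L) stop("truth set must be non-empty", call. = FALSE)
  correct <- length(intersect(predicted, truth))
  specificity <- 100 * correct / length(truth)
  accuracy <- if (length(predicted) == 0L) 0 else
    100 * correct / length(predicted)
  structure(list(specificity = specificity, accuracy = accuracy,
                 performance = (specificity + accuracy) / 2),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("specificity %.1f%%, accuracy %.1f%%, performance %.1f%%\n",
              x$specificity, x$accuracy, x$performance))
  invisible(x)
}
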