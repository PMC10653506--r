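---
title: "Methods: bait-based pathway gene annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bait-based pathway gene annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `orthobait`, the parameters that
matter, the synthetic-data generator used throughout the tests, and the
numerical and design choices a maintainer would want to know about.

## The annotation model

The package treats pathway annotation as a knowledge-transfer problem.
For a pathway step that is biochemically characterized in several species,
a curated *ingroup* of functional enzymes and an *outgroup* of close but
functionally distinct relatives define the step. A gene in the new species
is reported as a likely functional member of that step when three
independent lines of evidence agree:

1. **Sequence similarity** — the candidate aligns globally to an ingroup
   bait with a sufficiently high fraction of the bait's self-alignment
   score (the *score ratio*, a matrix-independent quantity in [0, 1]) and
   identity;
2. **Phylogenetic placement** — in a distance tree of the candidate with
   all baits, the candidate's local neighborhood is dominated by ingroup
   baits (orthology implies descent by speciation, and orthologs are the
   best predictors of conserved function);
3. **Functional residues** — amino acids known from the experimental
   literature to be required for catalysis, cofactor binding, or folding
   are present at the homologous positions, and family-diagnostic motifs
   are found.

The third line is what distinguishes a functional gene from the product of
a pseudogene: a recent pseudogene copy is nearly identical in sequence and
placed inside the ingroup clade, yet typically carries disabling
substitutions at exactly these positions. Orthologs failing residue rules
are therefore reported as `partial` rather than silently dropped.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `min_score_ratio` | 0.3 | score vs best-bait self-score; scale-free, tolerant of moderate divergence while excluding unrelated proteins |
| `min_identity` | 0.2 | guards against high-scoring but compositionally driven alignments |
| `max_candidates` | 10 | cap per step; pathway steps are small gene families |
| `min_shared_kmers` (k = 4) | 2 | prefilter: two distinct shared 4-mers before a full alignment is attempted |
| `ortholog_threshold` | 0.5 | minimum ingroup fraction in the deciding clade; majority rule, boundary inclusive |
| `min_coefficient` | 0.7 | Spearman threshold for a co-expression edge |
| gap penalties | −11 / −1 | affine gaps with BLOSUM62, the conventional pairing; a gap of length L scores −11 − (L − 1) |
| type-detection threshold | 0.9 | a pooled `{A,C,G,T,U,N}` character fraction above 0.9 calls the input nucleotide; tolerates IUPAC ambiguity codes while catching peptides |

These thresholds are package defaults, declared here rather than inherited
from any external tool; every one of them is exposed in `run_config()`.

## Procedure details and numerical choices

**Alignment.** Optimal global alignment under affine gaps is computed by
`Biostrings::pairwiseAlignment`, parameterized so that a length-L gap
scores `gap_open + (L−1)·gap_extend`. Identity is counted over aligned
columns (dual-gap columns excluded). Characters absent from the
substitution matrix are rejected by name before alignment. The test suite
checks the engine's scores exactly against an independently written
three-state dynamic program on hundreds of random short pairs, so the
scoring convention is pinned down, not assumed. Determinism of the aligned
strings comes from the engine's deterministic traceback.

**Trees.** Neighbor joining (`ape::nj`) was chosen over approximate
maximum likelihood deliberately: it is deterministic, closed-form,
assumption-light, and exact on additive matrices — at the desk scale of a
candidate set plus a dozen baits, the extra statistical efficiency of ML
buys little, while NJ's exact-recovery property gives the test suite a
sharp oracle (additive matrices constructed from known trees must be
recovered to 1e-9). Distances are `1 − identity` of the global alignment.
Negative NJ branch lengths (possible on non-additive input) are clamped to
zero with a warning, the standard practice. Trees are serialized in Newick
with single-quote escaping of reserved characters so that any label
round-trips; the package carries its own small reader/writer because the
available parsers mangle quoted labels.

**Ortholog call.** The tree is midpoint-rooted (rooting is otherwise
undefined for NJ), then the smallest clade containing the candidate and at
least one bait is found by walking from the candidate tip rootward. The
ingroup fraction among the baits of that clade, compared against an
inclusive 0.5 threshold, gives the call. Inclusive means a candidate in a
balanced 2-ingroup/2-outgroup clade passes — a deliberate
benefit-of-the-doubt choice, since downstream residue verification
provides the stricter filter. The clade rule makes the call invariant to
adding taxa outside the deciding clade.

**Residue mapping.** Residue positions are 1-based on the ungapped
reference, matching the His221-style nomenclature of the enzyme
literature. Mapping walks the aligned columns of the candidate–reference
*pairwise* alignment; a reference position opposite a candidate gap is
`unaligned` (truncations and internal deletions land here). Pairwise
mapping, rather than inspection of a full multiple alignment, keeps the
report deterministic, independent of which other candidates happen to be
present, and cheap; the cost is that a pairwise alignment can locally
differ from an MSA column assignment in low-identity regions, which is
acceptable at the identity levels where candidates survive the search
stage. Bundled rules are strict (no accepted alternatives) — whether
conservative substitutions at functional sites retain function is
enzyme-specific, so permissiveness is left to the user via the
`alternatives` column.

**Classification policy.** `functional` requires the ortholog call plus
zero failures among gating rules; by default *all* rules gate, so a
folding-residue failure also demotes to `partial`. A `critical_tags`
policy can restrict gating to, say, binding/catalytic rules. The default
is the stricter reading: residue evidence of any class is literature-level
knowledge, and `partial` still reports the candidate with its failure list
rather than discarding it. Classification is monotone — adding a rule
failure can never upgrade a status.

**Metrics.** Specificity, accuracy, and performance are percentages;
accuracy of an empty prediction set is defined as 0 (the ratio is
otherwise undefined), which makes an annotator that predicts nothing score
performance 50 at best, never 100. Ids are deduplicated before counting.

**Degenerate inputs.** Empty subject sets yield an empty, warned-about
hit list; a step whose bait file is malformed is aborted and logged
without stopping the run; distance matrices need ≥ 3 taxa; correlation
needs ≥ 3 samples; candidates missing from the expression matrix warn
rather than error.

## The synthetic-data generator

`simulate_family()` evolves a uniformly random ancestral peptide by
independent per-site substitution (probability `divergence`, uniform
choice among the 19 alternative residues). Substitution-only evolution is
a deliberate simplification: it gives closed-form expectations (two
members match at a site with probability `(1−d)² + d²/19`, so at the
default `d = 0.1` members are ~81 % identical) that the tests verify by
Monte Carlo. Sites under a residue rule are held fixed in ingroup baits
and planted orthologs, emulating purifying selection on functional
residues — without this, a 300-residue ortholog at `d = 0.1` would
randomly knock out one of its four rule residues in roughly one simulation
in three, which is not the biology the generator is meant to represent.

`simulate_study()` assembles the full study: per step, 4 ingroup baits and
a planted ortholog at divergence 0.1 from the step ancestor, 4 outgroup
baits from a sister ancestor at divergence 0.3 (far enough to be cleanly
separated on the tree, close enough to pass the search stage and exercise
the ortholog screen), one pseudogene copy (step 1) with a single
knocked-out rule residue, and 100 unrelated random decoys of comparable
length. Expression has 12 samples — a realistic small RNA-seq study —
with true pathway genes sharing a latent profile drawn uniform on
(1, 100) plus Gaussian noise (sd 0.5, truncated at 0) and all other genes
independent; at 12 samples the null Spearman distribution puts well under
5 % of independent pairs above the 0.7 edge threshold, so the network
recovered from the block is clean in expectation.

What the generator does *not* emulate by default: indels (an
indel-enabled mode with geometric event lengths exists via
`simulate_family(indel_rate = )` but is off by default, because
substitution-only evolution is what keeps the identity expectation in
closed form), codon-level evolution and selection, paralogs from recent
duplications, fragmented gene models, and compositional bias.
Passing the end-to-end tests therefore demonstrates the pipeline's logic
and determinism, not its performance on real proteomes, where bait-set
curation quality dominates.

## Problem sizes in the tests

The unit suite runs reduced studies (2–3 steps, 80–150 residue enzymes,
10–20 decoys) chosen so each stage is still exercised through the same
code paths as the defaults; the acceptance suite runs the full default
study (5 steps, 300-residue enzymes, 100 decoys) across three seeds, 500
alignment-oracle pairs, 100 NJ recovery matrices, and 1000 motif-oracle
cases. The oracle suites use exact-agreement assertions; the end-to-end
suite asserts complete recovery (all planted orthologs `functional`, all
pseudogenes `partial`, no decoy `functional`), which the default study
conditions are designed to support.

## Known limitations

- Six-frame ORF extraction is a convenience for prokaryote-like or
  intron-poor input; it is not gene prediction, and spliced genes will be
  missed or fragmented. Use a dedicated gene predictor upstream.
- The search stage is a full global alignment behind a k-mer prefilter;
  it is self-contained and deterministic but slower than heuristic local
  search tools on very large proteomes. A hook for importing precomputed
  12-column tabular hits exists (`read_tabular_hits`).
- NJ trees carry no support values; the ortholog call is a point estimate
  on a point tree.
- Co-expression uses a plain coefficient threshold with no multiple-testing
  control; the edge list is corroborating evidence for visualization, not
  an inference of regulatory structure.
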