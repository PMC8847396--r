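---
title: "Methods: paired-chain TCR repertoire analysis with clonoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-chain TCR repertoire analysis with clonoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoscope)
library(dplyr)
```

# The analysis

clonoscope analyzes paired alpha/beta T cell receptor (TCR) repertoires from
single-cell V(D)J sequencing, of the kind produced by 10x Genomics
`cellranger vdj`. The intended setting is a cohort of samples (e.g. mice
under different infection conditions) from which antigen-specific CD8 T
cells were sorted and sequenced, together with per-cell transcriptional
cluster labels computed upstream from gene expression. The pipeline answers
five questions: how clonally expanded is each repertoire, how much is shared
across individuals, whether non-identical receptors converge in sequence
space, which germline V genes are preferred, and whether expansion is
associated with particular transcriptional states.

## Cell assembly and quality filtering

A *cell* is a barcode carrying **exactly one TRA and one TRB** contig after
contig-level retention predicates (`productive`, `is_cell`,
`high_confidence`, each independently toggleable and on by default — the 10x
filtered contig file largely enforces them already). Barcodes failing the
rule are discarded and counted by reason (no/multiple TRA or TRB, all
contigs failing predicates), and the filter report reconciles exactly to the
input barcode count. Identical `(barcode, locus, cdr3_nt)` rows are treated
as duplicates, not as multi-chain evidence. Barcodes are sample-scoped: all
cross-sample operations key on `(sample_id, barcode)`.

Whether non-productive or low-confidence contigs should count toward the
"exactly one" rule is genuinely open; we apply the predicates *before*
counting chains (so a cell with one productive and one non-productive TRB
passes under the default), and expose the predicates as arguments for the
other reading.

## Clonotype definition

A clone is the set of cells with identical **paired CDR3 nucleotide
sequences**; the clone id is `cdr3b_nt + "_" + cdr3a_nt`. V/J gene calls are
recorded per member cell but deliberately not part of the key; a clone whose
members disagree on V calls stays one clone, with the disagreement kept in
its `v_pairs` table. Synonymous clones (same amino acids, different
nucleotides) are distinct. Clones with two or more cells are *expanded*;
singletons are *lowly expanded*. Ranking ties at equal size are broken by
clone id (lexicographic), making `top_clones()` deterministic.

## Diversity

Clonal-expansion structure is summarized by Shannon entropy
$H = -\sum_i p_i \ln p_i$ over clone-size proportions and by Pielou's
evenness $J = H / \ln S$ (natural log; the entropy base is configurable,
evenness is base-independent). $J = 1$ is a perfectly even repertoire;
values near 0 indicate domination by few clones. A monoclonal repertoire
($S = 1$) is assigned $J = 0$ with a warning, avoiding 0/0. Evenness is
computed on distinct-barcode clone counts, not UMI-weighted counts,
consistent with defining clonal frequency by counting cell barcodes.

A note on the concentration property we test: moving one cell from the
smallest to the largest clone strictly lowers evenness whenever the move
preserves the clone count (entropy is strictly Schur-concave). If the
smallest clone is a singleton the move *removes* it, $S$ drops, and the
renormalized evenness can increase (sizes `[1, 10, 10]` → `[11, 10]` raises
$J$ from 0.78 to 1.00), so the property test samples donor clones of size
at least 2.

## Overlap (public clones)

Sharing across repertoires is exact clonotype-key matching: entry $(i, j)$
of the overlap matrix is the number of identical paired-CDR3-nucleotide
keys in samples $i$ and $j$; the diagonal is NA. Restrictions: all clones,
expanded only (size ≥ 2), or the top $n$ most expanded clones per sample.
An amino-acid-level mode exists but is off by default, since nucleotide
matching is the primary definition.

## Similarity networks

Each (clone, sample) pair is one node — identical clonotypes in two samples
are distinct nodes joined at distance 0. Edit (Levenshtein) distances are
computed separately for the TRB and TRA CDR3 amino-acid sequences. The
default edge rule is `sum`: connect when `dist_b + dist_a <= threshold`
(default 7, inclusive); `per_chain` requires each chain to satisfy the
threshold independently. The combined-versus-per-chain rule and
strict-versus-inclusive comparison are both ambiguous in the source
procedure; we default to the combined inclusive rule ("7 amino acids or
less" reads as one number) and expose the alternative. Note `sum` at a
given threshold is always a subset of `per_chain` at the same threshold.
Connectivity is summarized by partitioning edges into within-group and
between-group counts; `threshold_sweep()` reports edge counts over a range
of thresholds, which are monotone non-decreasing by construction.

## Germline usage

V-gene usage is counted either **per cell** (default — pairing displays
count cells) or **per clone** (each clone votes its majority V pair, ties
lexicographic), the latter controlling expansion bias. Gene names are
canonicalized (allele suffixes `*01` stripped; dotted dialects `TRBV13.1`
mapped to `TRBV13-1`). The TRBV×TRAV pairing matrix underlies chord
displays; pairs at or above `label_threshold = 5` counts are flagged for
labeling. Usage vectors from different samples (or external reference
usage tables) are aligned on the union gene set with absent genes at 0,
re-normalized, and compared by Pearson correlation (Spearman optional);
samples are ordered by average-linkage hierarchical clustering on
$1 - r$. A zero-variance vector (e.g. exactly uniform usage) has no
defined Pearson correlation and is reported NA.

## Phenotype integration

Per-cell transcriptional cluster labels (from any upstream GEX clustering;
out of scope here) are joined to clones by `(sample_id, barcode)`.
Unannotated cells are dropped, never imputed. We report per-clone cluster
fractions (optionally for the top 15 or 30 most expanded clones — both
conventions appear in practice, so `top_n` is a parameter),
expansion-stratum compositions, and a formal cell-level association per
cluster: the 2×2 table of expanded/lowly-expanded × in/out-of-cluster, an
odds ratio in closed form ($ad/bc$, Haldane–Anscombe +0.5 on all cells when
any count is zero), Fisher's exact test (or chi-squared), and
Benjamini–Hochberg adjustment across clusters within a sample. The source
analysis shows these contrasts visually; the test is an explicit extension
that makes them assertable. Cells of one clone are not independent, so a
clone-level variant (`unit = "clone"`, majority-cluster voting) is provided
against pseudo-replication; the cell-level unit remains the default because
the displays it mirrors are cell-level.

CDR3 motifs are position-by-residue frequency matrices over (by default
unique) amino-acid sequences of one exact length — no alignment or padding;
positions are 1-based from the N-terminal cysteine. Contrasts between two
strata subtract matrices entrywise, so each position row sums to 0.

# The synthetic generator

`generate_cohort()` produces seeded cohorts with ground truth, in the same
file dialects the pipeline reads. It emulates the statistical structure the
analysis assumes:

- **Clone sizes**: i.i.d. from a truncated power law $P(k) \propto
  k^{-\alpha}$ on $[1, k_{max}]$ or a truncated geometric. The default
  cohort is six samples, two per group, 300 clones each, $k_{max} = 1500$:
  "acute-like" samples use $\alpha = 3.0$ (mostly singletons, high
  evenness), "chronic-/latent-like" $\alpha = 1.8$ (heavy tail, clones up
  to hundreds of cells). These presets are named for documentation only.
- **Germline usage**: each group has a fixed skewed base profile (geometric
  decay over 20 mouse TRBV / 20 TRAV names, rotated per group so groups are
  distinct); each sample draws its profile from a Dirichlet around its
  group's base with concentration $\kappa = 200$ — large enough that
  within-group correlation clearly exceeds between-group correlation at 300
  clones.
- **CDR3s**: amino-acid lengths uniform on 12–17 (TRB) and 10–16 (TRA),
  conserved `C…F` flanks, random interiors; nucleotide sequences are
  back-translated codon-by-codon, so `cdr3_aa` is always the standard-code
  translation of `cdr3_nt`. Clonotype keys are kept unique by resampling on
  collision (registry shared across the cohort), so the key is a perfect
  clone identifier in synthetic data — real-data nucleotide collisions are
  outside the generator's scope.
- **Cluster labels**: cell labels are drawn from a softmax over eight
  clusters whose target-cluster log-odds are shifted by
  $\beta_1 \log(\text{clone size})$ (default $\beta_1 = 0.8$; default
  targets: cluster 1 for acute, 5 for chronic, 2 for latent groups). The
  cell-level log odds ratio this implies depends on the realized clone
  sizes; `implied_association_logor()` computes it from expected counts and
  `calibrate_expansion_bias()` solves for the $\beta_1$ giving a desired
  value, which is how recovery is checked (the estimand is planted, not
  assumed).
- **Contamination**: per cell, TRA dropout (default 0.05), TRB dropout
  (0.05), and an extra random TRB contig (0.03) — each makes the cell fail
  the one-TRA-one-TRB filter, emulating dropout and doublets.
- **Public clones**: each clone is copied into one other random sample with
  probability `public_clone_rate` (default 0.01), with a freshly drawn size
  in the recipient; planted copies are recorded, and because non-public
  keys are globally unique, detected overlap equals the planted counts
  exactly under zero contamination.

What the generator does **not** emulate: realistic V(D)J recombination
junction statistics (no generative rearrangement model), sequencing errors
within CDR3s, UMI count structure, cell-type mixtures beyond the cluster
labels, or any mechanistic selection. Tests passing on synthetic data
therefore demonstrate the pipeline's correctness contracts (conservation,
oracle equivalence, parameter recovery) — not that real repertoires follow
these laws.

RNG: one base seed; each sample uses the substream `seed + 1009 * index`,
and public-clone planting uses `seed + 999`, so cohorts are reproducible
and byte-identical across runs, including under partial regeneration.

# Numerical and design choices

- Edit distances are unit-cost Levenshtein via R's native `adist()`, with
  input validated against the 20-letter amino-acid alphabet; the test suite
  checks it against an independent memoized recursive implementation.
- Network construction evaluates all pairs through two distance matrices
  (one per chain) and thresholds them — at repertoire scale (hundreds to a
  few thousand nodes) this is exact and fast, and it is verified against
  brute-force pair enumeration.
- Entropy sums use natural log throughout; evenness tolerance contracts are
  1e-12 in tests.
- Odds ratios use the closed form rather than Fisher's conditional MLE, so
  the reported value matches the planted cell-level estimand; the p-value
  still comes from `fisher.test()`.
- Hierarchical clustering uses average linkage on $1 - r$; leaf order comes
  from `hclust` on samples sorted by id, so it is deterministic.
- All tabular outputs are TSV with fixed column order and `NA` for missing
  values; the run report is JSON without timestamps, so reruns are
  byte-identical.

The validation suite exercises the default study-like conditions at sizes
chosen to keep a full run on one CPU within minutes: 6 × 300-clone cohorts
for end-to-end recovery, 100 replicates for the evenness and germline
grouping contrasts, and a single ~3000-cell sample (geometric sizes,
q = 0.5) for association recovery, where both expansion strata are well
populated.

# Limitations

- The clonotype key follows the stated nucleotide-CDR3 definition; if an
  upstream caller's clonotyping also required matched V/J genes, counts can
  differ for the (rare) clones that share CDR3s across V contexts.
- Cell-level association tests inherit the non-independence of cells within
  clones; use `unit = "clone"` when that matters.
- Motif matrices are per-exact-length; comparing motifs across lengths
  requires an alignment convention this package intentionally does not
  impose.
- The package consumes, but never computes, transcriptional clusters.

# A worked mini-example

```{r example}
cfg <- generator_config(
  seed = 7,
  samples = default_cohort_samples(n_clones = 60, max_size = 40)
)
cohort <- generate_cohort(cfg)

dir <- tempfile(); dir.create(dir)
paths <- vapply(names(cohort$contigs), function(sid) {
  f <- file.path(dir, paste0(sid, ".csv"))
  readr::write_csv(cohort$contigs[[sid]], f)
  f
}, character(1))

clones <- purrr::map2_dfr(names(paths), cfg$samples$group_label,
  function(sid, grp) {
    cells <- assemble_cells(read_contigs(paths[[sid]], "tenx_csv", sid))
    classify_expansion(build_clones(cells, grp))
  })

diversity_summary(clones)
overlap_matrix(clones)
glance(build_network(clones, threshold = 7))
```
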