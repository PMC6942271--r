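---
title: "Reconstructing subgenomes and classifying homeolog dominance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing subgenomes and classifying homeolog dominance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(homeologr)
library(dplyr)
```

## The problem

Maize went through a whole-genome duplication roughly 5–12 million years ago,
after its split from sorghum. The two ancestral genome complements — the
subgenomes conventionally called Maize1 and Maize2 — are still recognizable
today because each region of the sorghum genome is syntenic to up to two
regions of maize. Gene loss after the duplication (fractionation) was biased:
one subgenome lost genes faster, through many short deletions, leaving a
larger, less fractionated Maize1 and a smaller Maize2.

Where both copies of an ancestral gene survive (a *retained duplicate* or
*homeolog pair*), their expression and protein abundance across tissues
record how regulation diverged after duplication. homeologr implements the
whole chain:

1. **Subgenome reconstruction** from maize–sorghum syntenic anchor blocks
   with per-anchor Ks (synonymous substitution rate).
2. **Dominance classification** of homeolog pairs from a genes × tissues
   expression (FPKM) and protein-abundance (dNSAF) matrix.
3. **Correlation structure** between expression and abundance per tissue.
4. **Functional set comparisons** between subgenomes: GO terms, reactions
   and pathways, isoform counts.
5. A **synthetic study generator** that emulates all the above with known
   ground truth, so every stage is testable end to end with no downloads.

## Subgenome reconstruction

The unit of evidence is the *syntenic block*: a chained run of collinear
maize–sorghum gene matches (anchors). Blocks are first filtered:

* blocks with fewer than `min_anchors = 12` anchored genes are dropped —
  short chains are unreliable synteny evidence;
* blocks whose average anchor Ks exceeds `max_mean_ks = 1.0` are dropped —
  they reflect older duplications or spurious chains, not the post-speciation
  duplication of interest. A block sitting exactly on either boundary is
  kept; both boundary readings are configurable (`ks_inclusive`,
  and `drop_missing_ks` for blocks with no Ks estimates at all, which are
  kept and flagged by default).

Because each sorghum region corresponds to at most two maize regions, the
filtered blocks are greedily bipartitioned: visiting blocks by decreasing
anchor count (ties by lower mean Ks, then block id), each block joins the
first of two groups in which it shares no sorghum gene with an
already-placed block on the same sorghum chromosome; a block conflicting
with both groups is set aside as an orphan. The larger group (by retained
gene count) becomes `SUB1` — Maize1 in maize. Grouping and labeling are
global by default; a `scope = "per_chromosome"` mode repeats the procedure
within each sorghum chromosome, for the (unstated in the source protocols)
possibility that the assignment should be local. Block "size" is anchor
count — the only size measure an anchor file carries — and "overlap" is
sharing a sorghum gene identifier, not base pairs, matching the gene-model
phrasing of the protocol this follows.

A homeolog pair is then one sorghum gene anchored in both groups; within a
group, multiple anchors for one sorghum gene resolve to the lowest-Ks anchor
(ties to the lexicographically smallest gene id).

```{r}
study <- simulate_study(sim_config(seed = 1))
anchors <- filter_blocks(study$anchors)
bp <- greedy_bipartition(anchors)
bp
pairs <- extract_homeolog_pairs(bp)
head(pairs, 3)
```

`validate_bipartition()` re-checks the non-overlap invariants by a
brute-force pairwise scan that shares no code with the greedy construction.

## Dominance classification

Per tissue, a homeolog *dominates* when its value is at least `fold = 2`
times its partner's (boundary inclusive: exactly 2-fold counts). A positive
value dominates a zero at any fold — the limiting fold change is infinite —
and two zeros give no call. *Average dominance* applies the same rule to the
two tissue means (fold change of averages, not average of fold changes).

Pairs are classified into five mutually exclusive categories, applied in
precedence order:

| category | definition |
|---|---|
| `NO_SIGNAL` | nothing detected for either copy in any tissue |
| `ONE_SILENT` | exactly one copy undetected everywhere |
| `ALTERNATING` | each copy dominates (≥ fold) in at least one tissue |
| `CORRELATED` | correlation across tissues > `corr_threshold = 0.95` |
| `OTHER` | everything else |

The correlation is Pearson on untransformed per-tissue values by default
(`corr_method = "spearman"` is available): in the source analyses the one
correlation matrix that is explicitly rank-based is labeled as such, so the
unlabeled per-pair threshold is read as Pearson. `ALTERNATING` takes
precedence over `CORRELATED`, following the narrative order in which the
categories were defined ("of the remaining pairs…").

Missing cells (absent measurements) are distinct from zeros (nothing
detected): they are dropped tissue-wise from means and correlations, and a
copy missing everywhere counts as undetected. Pairs with fewer than three
complete tissues cannot reach `CORRELATED`; their number is reported.

The joint expression/abundance view gates on *data completeness* (all four
vectors detected somewhere), then counts pairs alternating in both data
kinds and, among the remaining complete pairs, pairs above the correlation
threshold in both. Whether joint alternation must happen in the *same*
tissues in both kinds is genuinely ambiguous; the default does not require
coincidence, `same_tissue = TRUE` does.

```{r}
expr_prof <- build_pair_profiles(pairs, study$quant$expr)
abun_prof <- build_pair_profiles(pairs, study$quant$abun)
count_categories(classify_pairs(expr_prof))
count_joint(joint_classification(expr_prof, abun_prof))
```

`spearman_rho()` (mid-ranks, p from the t approximation on n − 2 df) drives
`correlation_matrix()`, the 4 × tissues summary in which a pollen-like
tissue stands out as the one place protein abundance decouples from
transcript level.

## Functional comparisons

All subgenome-level comparisons reduce to a three-way set split (shared /
unique to SUB1 / unique to SUB2), with `tidy()` and `glance()` methods:

* **GO terms** after aspect and evidence filters. The "gold standard" uses
  molecular-function terms with the standard experimental evidence codes
  EXP/IDA/IPI/IMP/IGI/IEP (`go_experimental_codes`) — the usual reading of
  "experimentally determined", since no source names the codes. No ancestor
  propagation is performed: term sets are compared as annotated.
* **Per-pair GO assignments**, where the item is (pair, side, term): a term
  annotating both members of a pair is one shared assignment; the same term
  on genes of *different* pairs stays unique on both sides.
* **Reactions**, optionally restricted to pair genes and to reactions in at
  least one pathway, plus the count of pathways touched by each side's
  unique reactions.
* **Isoform counts** per gene from GFF3/GTF (via rtracklayer), compared
  within pairs as counts, differences and `log2(n1/n2)` — a log of a ratio,
  since a log of a signed difference is undefined; the raw difference is
  emitted alongside, and the ratio is `NA` when either count is 0.

## The synthetic study generator

`simulate_study()` emits a complete fake study — anchor file, FPKM and
dNSAF matrices, GAF, reaction links, GFF3, and the ground truth — from one
seed. Sub-streams are keyed by stage, so adding configuration fields never
reshuffles earlier draws, and byte-identical outputs per seed are a tested
contract.

**Genome.** An ancestral order of `n_sorghum_genes = 2000` genes over 3
chromosomes is cut into `n_blocks_per_subgenome = 10` contiguous templates;
each template is instantiated twice and fractionated by a two-state Markov
chain whose stationary retention is `retention_prob_sub1 = 0.8` versus
`retention_prob_sub2 = 0.5` and whose deletion runs are geometric with mean
`deletion_run_length = 2` — the short-deletion mechanism of biased
fractionation, at rates that give a SUB1:SUB2 gene ratio near the ~1.6
observed in maize. Anchor Ks is normal truncated at zero with mean 0.75
(the maize–sorghum divergence mode, safely under the 1.0 filter cutoff);
`n_noise_blocks = 4` decoy blocks carry Ks around 1.6 and must be removed
by the filter. Each template is *conditioned*, by rejection, on the
configured bias being realized (the SUB1 copy strictly larger) and on the
two copies sharing at least one ancestral gene: a template where, by
chance, the SUB2 copy survived better would make the planted labels
unrecoverable by any synteny method, i.e. the truth itself would be
ill-defined. Recovery of planted labels and pairs is therefore exact in the
absence of decoys — and tested as such.

**Quantification.** Each pair draws a category with fractions
`(NO_SIGNAL, ONE_SILENT, ALTERNATING, CORRELATED) = (0.01, 0.075, 0.25,
0.07)` — the proportions observed among maize retained duplicates — and
profiles over `n_tissues = 23` realise it:

* `ALTERNATING`: one tissue per direction planted at `fold_signal = 4`
  (comfortably above the classifier's 2), multiplicative lognormal
  measurement noise of cv `noise_cv = 0.2`;
* `CORRELATED`: exactly proportional vectors with ratio in (0.75, 1.3).
  They are emitted noise-free by design: independent multiplicative noise
  of cv 0.2 on both vectors caps the population Pearson near
  exp(−cv²) ≈ 0.96, and at 23 tissues sampling fluctuation would push much
  of the class under the 0.95 boundary — the archetype *is* "realized
  proportionality";
* `OTHER`: one-sided profiles (one copy uniformly 2.5–10× the other,
  random side, plus noise), rejection-resampled until the emitted vectors
  have Pearson ≤ 0.90 and the dominated side never comes within 2-fold.
  Two fully independent lognormal vectors would not do: they almost surely
  alternate at 2-fold, so an unconstrained "remainder" class would not be
  identifiable even without noise.

With `noise_cv = 0` the classifier reproduces the planted counts exactly;
at the default noise the only leakage is the occasional alternating pair
whose planted dominance tissue is eroded (≈ 1%), well within binomial
sampling bands — both tested properties.

**Abundance** is generated from expression by a Gaussian copula on pooled
normal scores of the detected values: the copula parameter is
2·sin(π·ρ_S/6) for a target Spearman `abun_coupling_rho = 0.55`, the
genome-wide transcript–protein correlation scale reported in maize (and
typical of the 0.4–0.5 range seen elsewhere). One tissue (`pollen`) is
decoupled to `decouple_rho = 0.2`, emulating the pollen effect. A fraction
`abun_shared_noise = 0.95` of the noise variance is shared between the two
members of a pair within a tissue: homeologs are near-identical proteins
quantified in the same sample, so most of what decouples protein from
transcript is common to both copies. Sharing leaves marginals — and hence
the Spearman target — untouched, while keeping within-pair abundance
ratios meaningful; with fully independent noise essentially every pair
would classify as abundance-alternating, which matches no observed
proteome. Undetected transcripts yield undetected protein (0 → 0); real
data violates this occasionally, which the generator does not emulate.

**Annotations** plant a SUB1:SUB2 rate asymmetry (`annotation_asym = 1.5`)
into GO terms (shared-within-pair component plus side-specific components,
IEA versus experimental evidence codes, aspects cycling MF/BP/CC),
gene–reaction links with 0–2 pathways per reaction, and isoform counts
(1 + Poisson). The planted per-subgenome term and reaction sets are
recorded and must round-trip exactly through the GAF/TSV/GFF3 writers and
readers — also a tested contract.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: inversions and transpositions within blocks,
tandem duplicates, three-plus-copy regions, Ks estimation error correlated
along chromosomes, replicate structure in the matrices, compositional
constraints of dNSAF, protein detected without transcript, and GO-graph
structure (terms are exchangeable tokens). The pipeline's behavior on real
inputs depends on upstream chaining and quantification quality in ways the
synthetic study cannot probe.

## Numerical and design choices

* Boundary inclusivity: "at least 2-fold" is `≥`; "fewer than 12 genes"
  removes 11 and keeps 12; "Ks higher than 1.0" removes strictly above.
* `a > 0, b = 0` is dominance of `a` at any fold.
* Ties in greedy ordering: mean Ks, then block id — deterministic output
  for identical input is a tested pipeline invariant.
* "12 genes" counts anchors (the only gene count an anchor file carries),
  not genes spanned.
* Missing Ks anchors are excluded from block means.
* Coordinates are 1-based inclusive (GFF convention) everywhere inside the
  package; the BED writer converts to 0-based half-open in one place.
* Problem sizes in the shipped property tests: 100 simulated genomes of
  500 ancestral genes for partition validity, 4000 planted pairs for
  classifier identifiability, 2000 pairs × 23 tissues for coupling
  recovery, 1000 random vectors for the rank-correlation oracle — sizes at
  which the binomial bands used are narrow enough to detect the failure
  modes described above.

## Limitations

Exactly two subgenomes are supported (no hexaploids), chaining and Ks
estimation are upstream concerns consumed as input, there is no enrichment
statistic on the set comparisons (counts only, as in the analyses this
mirrors), and no GO ancestor closure. The per-pair correlation threshold
compares raw values; heavy-tailed profiles make raw Pearson sensitive to
single tissues, which is faithful to the mirrored analysis but worth
remembering when interpreting `CORRELATED`.
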