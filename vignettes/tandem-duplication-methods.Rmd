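---
title: "Detecting and characterising co-localised duplicated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising co-localised duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemdup)
```

## The problem

Gene duplication comes in three broad flavours: whole-genome duplication,
dispersed duplication, and tandem duplication, where the copies stay close
together on one chromosome.  `tandemdup` targets the third class only.
Its unit of inference is the *duplicate group*: a set of two or more
co-localised genes whose peptides are similar enough that common descent
by duplication is the parsimonious explanation.  Detection works on any
genome for which gene coordinates and peptide sequences are available;
characterisation then asks whether group members retain correlated
expression and shared Gene Ontology annotation.

## The detection model

### One peptide per gene

Genes usually encode several isoforms.  Before any comparison, each gene
is reduced to its single longest peptide (`select_longest_peptides()`),
with length ties broken by the lexicographically smallest peptide id so
that re-runs are byte-identical.  Comparing all isoform pairs would count
the same locus several times and make group membership depend on
annotation depth rather than duplication history.

### Weighted identity

For an aligned peptide pair, let `L` be the aligned-region length in
columns (gap columns included), `identities` the identical aligned
positions, `n_i` the residues of sequence *i* inside the aligned region
and `L_i` its full length.  The raw identity is `I = identities / L`, and
the decision statistic is the coverage-weighted identity

$$I' = I \times \min(n_1/L_1,\; n_2/L_2).$$

The min-coverage factor is the guard against the classic false positive
of domain sharing: a 50-aa peptide identical to one domain of a 500-aa
multidomain protein has `I = 1` but `I' = 0.1` and is rejected at every
alignment length.  We treat the gap-inclusive reading of `I` as affecting
the denominator only — a gap column can never count as an identity in the
numerator.

### The length-dependent threshold

A pair passes when `I'` is at least 30 % for `L ≥ 150` aa, or at least
the twilight-zone curve

$$p(L) = 0.01\,n + 4.8\,L^{-0.32\,(1+\exp(-L/1000))}, \qquad n = 6$$

for shorter alignments (`rost_threshold()`).  The offset `n = 6` makes
the curve meet the 30 % cutoff at the 150-aa breakpoint (30.3 %, i.e.
30 % to the nearest percent), so the criterion is continuous in `L`;
`detection_params()` warns if a user-supplied combination breaks this.
Two numerical consequences are worth knowing: below roughly 15 aa the
curve exceeds 1, so no very short alignment can ever pass — this is what
keeps random spurious micro-alignments out; and the closed form is
strictly decreasing only up to `L ≈ 416`, beyond which it rises again
very slightly.  The non-monotone tail is irrelevant in practice because
the curve is only consulted for `L < 150`, and our monotonicity test is
scoped accordingly.

The published criterion states the long branch in terms of `I'` but
writes the short branch with `I`; since the source of the thresholds
defines both branches on the weighted statistic and the stated intent is
conservatism, the short branch compares `I'` by default
(`short_branch_stat = "I_prime"`), with the raw-identity reading
available as an option.

### Alignment

Internal alignments are Smith–Waterman local alignments with affine gaps
computed by `Biostrings::pairwiseAlignment()` under BLOSUM62 with gap
open 11 and extend 1 — the conventional protein-search defaults; no
parameters are prescribed by the method itself.  Unknown residues (X)
are scored 0 against everything.  The test suite checks the scores
against an exhaustive plain-R dynamic program on hundreds of short random
pairs.  Precomputed alignments in the standard 12-column tabular dialect
(optionally extended with qlen/slen) can be ingested instead
(`parse_alignment_tabular()`); identity counts are reconstructed from the
percent identity by half-up rounding, and decisions are identical
whichever route produced the alignment.  Internally computed alignments
carry no e-value and skip the e-value filter; the filter exists only to
discard irrelevant hits from external search tools, not as part of the
similarity model.

Aligning every pair in every window is wasteful: two random peptides
share essentially no 5-mers, while any pair above the identity thresholds
shares many.  `find_duplicate_pairs()` therefore screens candidate pairs
through a shared-k-mer index (k = 5) before aligning; pairs with a
peptide shorter than k bypass the screen.  The screen is a seed heuristic
in the spirit of word-based search tools, is configurable
(`prescreen = FALSE` disables it), and only skips alignments whose
identity could not plausibly reach the curve.

### Window, linking and grouping

Co-localisation is measured in gene ranks, not base pairs: candidate
partners lie within 100 genes on the same chromosome.  A rank window is
portable across genomes with very different gene densities, which is the
reason this parameterisation is standard for tandem-array detection.  The
window is two-sided around each query; among the passing hits downstream
(higher rank), the query links to the nearest one.  A gene whose passing
hits are all upstream is still captured, because the upstream partner's
own downstream link is the same unordered pair.  Genes without a peptide
are skipped with a warning but keep their ranks — the window describes
genomic context, not alignable genes.  The closest-downstream selection
is applied after threshold filtering (among passing hits); an `"all"`
linking mode that keeps every passing pair in the window is provided for
sensitivity analysis, and because groups are the connected components of
the link graph (union-find, `build_groups()`), the final grouping is
largely insensitive to this choice.  Group identifiers are deterministic
(chromosome plus the member with the smallest start), groups are reported
in (chromosome, min-start) order, and a group's genomic span is
`max(end) − min(start)` over its members, reported in kb.

## Characterisation

### Co-expression

For each group and each eligible expression dataset, all member pairs get
a Pearson correlation with a two-sided p-value from the t distribution on
n − 2 degrees of freedom (`stats::cor.test`).  Eligibility mirrors the
three classic filters: at least 3 samples, all members present, no member
profile constant or entirely missing.  Missing values are handled
pairwise-complete; a pair×dataset test with fewer than 3 complete
observations is skipped and counted.  The headline statistic is the
pooled proportion of significant tests over all pair×dataset
combinations (`by = "pair"` averages per-pair proportions instead —
both readings of "proportion per gene pair within a group" are
supported).  `alpha` defaults to 0.05; the method itself fixes no level.
No multiple-testing correction is applied by default because the
statistic is a raw proportion of significant tests, not a discovery set;
Benjamini–Hochberg is available as an option.  Expression analysis is
capped at groups of 5 genes, the published cap beyond which expression
data are typically too incomplete.

Two control classes calibrate the comparison: runs of adjacent-rank
non-duplicated genes (co-localised controls) and uniform draws of
non-duplicated genes genome-wide (random controls), with sizes matched to
the duplicated-group size distribution.  Class means are compared with a
Welch t-test — the unequal-variance form, since there is no reason to
expect equal variances between duplicated and control proportions, and
constant-sample degeneracies are resolved explicitly (identical constant
samples give t = 0, p = 1).

### GO semantic similarity

Similarity between annotated genes uses the Wang graph-based measure.
Each term's semantics are summarised by S-values over its ancestor DAG:
`S(term) = 1`, decaying along each child→parent edge by a contribution
factor and taking the best path where several exist.  Term similarity is
the S-value mass of shared ancestors relative to the two terms' total
semantic values — symmetric, 1 on identity, bounded in [0, 1].  The
contribution factors default to 0.8 (`is_a`) and 0.6 (`part_of`), the
values of the original measure (the method as applied prints none); both
are configurable.  Gene-level aggregation uses the best-match average,
with max-of-pairs as an option; the applied method does not state its
aggregation, so this choice is exposed rather than hidden.  A namespace
contributes only when at least two group members are annotated in it;
annotations with a NOT qualifier are dropped on read; IEA-coded
annotations are kept but tracked, and each group reports its IEA
proportion so electronic-annotation inflation is visible.  The
conventional 0.5 "fairly similar" boundary is exposed as the labelled
constant `wang_fairly_similar`.  GO analysis is capped at 15 genes per
group.  The ontology is read from OBO; obsolete terms are dropped, only
`is_a`/`part_of` edges are retained (other relationship types are
ignored, the terms kept), and a cycle is a hard error.

## Synthetic fixtures and what they show

`fixture_spec()` defaults define the standard test conditions: 5
chromosomes × 200 genes; 20 planted families of sizes 2–5 at adjacent
ranks, each member a copy of a family founder with 10 % of positions
substituted; background peptides uniform-random over the 20 residues
(pairwise identity far below any threshold); expression with a planted
within-group pairwise correlation of 0.9 across 20 datasets of 10
samples via a shared latent factor; ontologies as regular trees (depth 3,
branching 2, 15 terms per namespace) with duplicated-group genes
annotated inside a single depth-1 subtree and background genes uniformly.
These sizes keep the full pipeline's validation runs in the minutes
range on one core while leaving planted effects overwhelmingly clear of
their thresholds.

On these fixtures the detector recovers the planted truth with precision
and recall 1.0, the window boundary behaves exactly (rank gap 100 in, 101
out), the correlation stage is calibrated under the null (mean proportion
of significant tests within three binomial standard errors of alpha), and
both characterisation axes separate duplicated groups from random
controls in the expected direction.  What passing these tests does *not*
show: real proteomes have paralog families with indels, domain shuffling
and rate heterogeneity that a substitution-only mutator does not emulate;
real expression compendia have batch structure and heavy-tailed noise;
real GO annotation is biased and incomplete in ways a uniform/subtree
split is not.  The fixtures validate the machinery and its decision
boundaries, not the biological error rates on any particular genome —
genome-scale counts additionally depend on the annotation snapshot used.

## Degenerate inputs and tie-breaks

Empty local alignments (no positive-scoring region) never pass.  Ranks
tie-break by (start, end, gene id); equal-length peptides by peptide id;
multiple alignments for one pair by score, then aligned length, then
subject id.  Correlation tests on constant or too-short profiles are
skipped and counted rather than erroring.  All generators and samplers
take explicit seeds and restore the caller's RNG state.

## Known limitations

Inter-chromosomal and whole-genome duplication classes are out of scope
by design, as are running external search executables, live retrieval
from annotation/expression/GO services, probe-to-gene mapping and
expression normalisation, and information-content (Resnik/Lin)
similarity measures.  Chromosome labels are taken as given; scaffold
filtering is the caller's responsibility.
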