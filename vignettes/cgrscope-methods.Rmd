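---
title: "cgrscope: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgrscope: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrscope)
```

`cgrscope` implements the downstream analysis layer for whole-genome
characterization of genomically unstable tumors: estimating tumor purity,
converting relative copy-number ratios to absolute copies, filtering
tumor-only somatic calls against a panel of normals, detecting complex
genomic rearrangements (CGRs), calling gene-level alterations, building
multi-region clonal phylogenies, and computing the cohort statistics used
to compare an engineered mouse model with human high-grade osteosarcoma
cohorts. This vignette documents the models and the choices made where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## Purity from an engineered biallelic deletion

In the engineered model, Cre recombination deletes both copies of the
floxed locus in every tumor cell. Coverage over the edit site therefore
comes only from admixed normal cells, and with mean depths $d_e$ over the
edit site and $d_f$ over a flanking region of normal copy number,

$$\hat p \;=\; \mathrm{clamp}\!\left(1 - \frac{d_e}{d_f},\ 0,\ 1\right).$$

Assumptions, recorded in the output metadata: (i) the deletion is biallelic
in all tumor cells; (ii) the flank is copy-neutral in the tumor. The
estimator is undefined at $d_f = 0$ (error), clamps ratios above 1 to
purity 0 with a warning, and raises a QC flag when the ratio is within
Poisson noise of 1 (a purity estimate indistinguishable from zero).

One convention needed fixing: the broader window *encompasses* the edit
site. If the flank mean included the deleted interval, the estimate would
be biased low by roughly $p \cdot L_\text{edit}/L_\text{flank}$. Both the
estimator's documented convention and the simulator therefore define the
flank as the broad window *minus* the edit interval.

## Absolute copy number

The observed relative ratio is a purity-weighted mixture of tumor copy
number and the diploid normal genome:

$$\mathrm{CN} \;=\; \frac{\text{ploidy}\cdot 2^{\text{log2fc}} - 2(1-p)}{p},$$

with the exact algebraic inverse `log2fc_from_cn()` used by the simulator
and by the round-trip property test (reproducing the input log2 ratio to
1e-9 over 10^4 random draws). Negative copy numbers clamp to 0 with a
warning. Cohort-wide analyses assume `ploidy = 2`; a per-sample override
exists because whole-genome doubling cannot be inferred from an isogenic
strain with few heterozygous sites.

State thresholds are inclusive, matching their defining operators: gain at
$\ge 2.5$, loss at $\le 1.5$, amplification at $\ge 5$, homozygous loss at
$\le 0.5$ copies. The lenient single-copy bounds are deliberate: in a
genome-doubled tumor forced through a diploid assumption, a single-copy
gain/loss lands near 2.5/1.5. Amplification takes precedence over gain and
homozygous loss over loss, making `classify_cn_state` a total,
order-consistent partition of $[0,\infty)$ — property-tested on a grid.

Binning uses 1-Mb windows tiling every chromosome; the bin value is the
**length-weighted** mean copy number of overlapping segments (the weighting
is a package choice; an unweighted mean over segments would let a 1-kb
fragment swing a megabase bin). Bins without segment coverage are missing
(`NA`), never zero, and are excluded pairwise from cosine similarity rather
than imputed. Blacklist filtering removes a segment when $\ge 20\%$ of its
length overlaps the *union* of blacklist intervals (inclusive boundary,
union so adjacent blacklist entries are not double-counted).

## Somatic consensus for tumor-only samples

Two SV calls are the same event iff their types match and, after canonical
breakend ordering (genome order of the two breakpoints), both coordinate
distances are strictly below 10 bp — for translocations this implies the
unordered chromosome pair matches. Strictness follows the defining
wording ("less than 10 bp"; VAF "> 0.1"). Matching at a tolerance is not
transitive, so identity across the N tumor-vs-control comparisons uses
single-linkage grouping; a group is somatic iff it contains a somatic label
from *every* comparison and no germline label from any. This makes the
output anti-monotone in the number of controls, which is property-tested.
SNVs and indels match on exact `(chrom, pos, ref, alt)` keys; tumor-only
SNVs additionally require VAF strictly above 0.1. The VAF filter runs
after consensus; the order only matters for calls that would fail both,
and filtering last keeps the per-comparison bookkeeping intact.

## CGR detection and multi-chromosomal linkage

Two intrachromosomal SVs *interleave* when their breakpoint intervals
$[p_1, p_2]$ partially overlap: positive overlap, neither containing the
other. This is the one externally-sourced definition in the package (the
interleaving semantics of chromothripsis callers). Clusters are connected
components of the interleaving graph with $\ge 4$ members (8 breakpoints);
the footprint runs from the leftmost to the rightmost member breakpoint.
Detection is verified against a brute-force all-pairs + component-expansion
oracle on hundreds of random instances.

Multi-chromosomal CGRs are built by union-find closure over two linking
rules:

1. **Direct**: a translocation with one breakpoint inside each of two
   footprints on different chromosomes.
2. **Enrichment**: for each chromosome pair $(i,j)$ with at least one
   translocation, a one-sided Fisher exact test on
   $[t_{ij},\ t_{i\cdot}-t_{ij};\ t_{\cdot j}-t_{ij},\
   T-t_{i\cdot}-t_{\cdot j}+t_{ij}]$, where $t$ counts translocation
   *events* (not breakpoints) and $T$ is the tumor's total. P-values are
   BH-adjusted across the tested pairs within the tumor; pairs join at
   $q < 0.01$.

Testing a chromosome pair against the tumor's background translocation
rate admits several 2×2 constructions; this one is a package choice (each
margin is a chromosome's share of the tumor's translocation events). Pairs with $t_{ij} = 0$ are untested, which fixes
the BH family. Footprints of linked clusters are reported per chromosome,
not merged. Manual verification of CGRs is replaced by a machine-readable
report (cluster size, footprint span, member list).

The breakpoint fraction counts two breakpoints per SV, each independently
against the footprints on its chromosome; it is missing (not zero) for a
tumor with no breakpoints.

## Gene-level alterations

Per gene and sample: amplification iff the length-weighted gene-body copy
number is $\ge 5$; focal deletion iff it is $\le 0.5$ **and** at least 0.5
copies below the chromosome's length-weighted average (the focality
condition); SV disruption iff an intrachromosomal SV has a breakpoint in an
exon, or a translocation has a breakpoint anywhere in the gene body; small
variants iff impact is HIGH or MODERATE with a qualifying consequence,
where missense additionally requires the annotation table's deleteriousness
flag (no in-house prediction). Amplifications carry two CGR flags:
same-chromosome (the whole chromosome stands in for the chromosome arm,
since mouse chromosomes are acrocentric) and direct footprint overlap.

The cohort matrix keeps the highest-priority category per cell
(amplification > focal deletion > SV breakpoint > small variant — a fixed
display convention); frequencies count altered *mice* over eligible mice,
with multi-region mice contributing only their designated primary sample
and engineered cases excluded from the denominator of their engineered
gene. Multiple distinct small variants in one gene/sample count once in
the matrix; the calls table keeps all of them.

## Multi-region phylogenetics

A candidate site enters the presence matrix only with depth $\ge 40\times$
in **every** sample; presence in a sample means caller detection or the
rescue rule of $\ge 3$ high-quality alternate reads (mapping quality
$\ge 30$, base quality $\ge 20$). Clonality: truncal = present in all,
private = exactly one, shared = otherwise.

Trees are rooted by an implicit germline outgroup in the all-absent state
(somatic presence/absence is naturally rooted). Parsimony scoring is Fitch
small parsimony with the germline join counted at the root; every mutation
needs at least one change, so the score is bounded below by the row count,
with equality iff the matrix is a perfect phylogeny on that topology.
The search is exact up to 8 samples — branch and bound over rooted
topologies by stepwise insertion, pruning on the monotone partial score,
ties broken by the lexicographically smallest canonical newick — and
verified against full topology enumeration plus an independent
state-assignment-enumeration scorer. Above 8 samples a parsimony ratchet
runs: greedy stepwise addition, then iterations that double the weight of
a random 25% of mutations, hill-climb by leaf re-insertion under the
perturbed weights, and re-climb under unit weights (50 iterations by
default). Leaf re-insertion was chosen over nearest-neighbor interchange
as the rearrangement move: it is simpler, reaches every topology, and the
exact mode covers all in-scope scales anyway.

Branch lengths are mutation counts: a mutation whose presence set equals
the tip set below an edge increments that edge; truncal mutations count on
the root edge; presence sets matching no clade are reported as
*unassigned*, never forced onto a branch. Lengths plus unassigned always
sum to the matrix row count (asserted in tests).

SV trees use UPGMA (average-linkage `hclust`) on Hamming distance between
binary SV profiles; the metric is a package choice (Hamming is the
natural distance for binary presence profiles). SVs are grouped across samples by the same
single-linkage matching as the consensus module, and groups whose allele
fraction never strictly exceeds 0.1 are dropped (groups with no AF
information are kept). Bootstrap support resamples matrix rows with
replacement, rebuilds the topology, and reports per-clade replicate
fractions; it is seeded and reproducible.

## Cohort statistics

Welch's unequal-variance t with Satterthwaite degrees of freedom (p = 1 by
convention for degenerate zero-variance equal-mean input). The 2×2
chi-square is Pearson's without continuity correction on 1 df (Yates'
correction would give a different p for the 12/22-vs-11/46 worked
example); the same comparison is also available as Fisher's exact test,
whose two-sided p sums all tables at the observed margins with point
probability at most the observed table's (the minimum-likelihood
convention, stated explicitly because conventions differ). Fisher is
verified against full hypergeometric enumeration for small margins.
`bh_adjust` is the Benjamini–Hochberg step-up: monotone, order-preserving,
$q \ge p$, and equal to the reference implementation; note that the
step-up procedure is *not* idempotent (re-adjusting adjusted values can
increase them), so no such property is claimed. Cross-cohort enrichment
tests only genes altered in at least 10 cases of the reference cohort
(inclusive), then BH-adjusts across the tested genes.

## The synthetic world

`simulate_cohort()` states a world rather than exposing dials to tune:

* one mouse, `n_samples = 4` tumor regions by default, related by a
  balanced clone tree; 50 truncal mutations on the root branch, 20 shared
  per internal branch, 10 private per leaf — the scale of a multi-region
  design where most mutations are truncal;
* purity 0.7 and depth 100× (high-depth tumor WGS), variant allele
  fractions at $0.5 \times \text{purity}$ for heterozygous diploid somatic
  variants, depth summaries Poisson-sampled at base resolution;
* planted CGRs are truncal (complex rearrangements arise early, before
  clonal diversification): chromothripsis plants one interleaved chain with
  copy number oscillating between two states; BFB plants foldback
  (head-to-head) inversions, escalating amplification and a terminal loss;
  the multi-chromosomal style plants one chain per chromosome joined by
  translocations through the footprints. Planted chains are equal-length
  intervals shifted by half a length, so adjacent members interleave and
  the component is connected — verified at generation time;
* a panel of 17 normals sharing 200 common germline variants;
* noise knobs — breakpoint jitter, call dropout, germline leakage into
  tumor call sets — default to **0** so oracle tests run on a noise-free
  world, and are switched on individually by the tests that need them.

Background SVs are rejection-sampled so they neither partially overlap any
existing SV interval nor land within 1 Mb of a planted footprint. This is
what makes "planted cluster membership recovered with recall and precision
1.0" a designed property of the noise-free world, not an empirical
accident.

What the generator does **not** emulate — and hence what a green test does
not establish: read-level errors and mapping artifacts (no FASTQ/BAM),
subclonal structure within a sample (each region is one clone, so VAFs are
bimodal), consistency between planted SV types and the copy-number profile
(a DEL-type chain member does not deplete coverage), germline SNP phasing,
and realistic per-event allele-fraction distributions (the defaults are
placeholders, not calibrated against any real cohort). Recovery results on this
world demonstrate correctness of the algorithms' logic, not calibration
against real sequencing noise.

One validation tightening: a `multichromosomal` spec requires at least 4
SVs per named chromosome (not 4 total), because interleaving is
intrachromosomal and a smaller per-chromosome chain would plant an
undetectable cluster, contradicting the detectability invariant.

## Numerical conventions

* Coordinates are 0-based half-open everywhere inside the package;
  conversion to/from 1-based VCF `POS` happens only in the I/O layer.
* Breakend orientation encodes SV type: `+-` DEL-like, `-+` DUP-like,
  `++` head-to-head inversion, `--` tail-to-tail inversion, `TRA` iff the
  chromosomes differ. The mapping from typed `SVTYPE=INV` records uses the
  `STRANDS` tag and is cross-checked against the paired-breakend encoding
  of the same junction.
* `log2fc_from_cn()` floors the mixture ratio at $2^{-12}$ so a fully
  deleted segment in a pure tumor stays finite.
* Percentages recomputed from integer counts use half-up rounding
  (62.5 reports as 63).
* Ties in the exact parsimony search break on the lexicographically
  smallest canonical newick; clade keys sort tip labels as strings.
* All simulation randomness flows through R's RNG seeded once from the
  config; the ratchet and bootstrap document their seeding.

## Known limitations

Chromothripsis subtype classification, copy-number oscillation tests,
ecDNA amplicon reconstruction and allele-specific copy number are out of
scope. The purity estimator has no heterozygous-deletion model and does
not correct for copy-number changes overlapping the flank. `fitch_score`
expects binary rooted trees (multifurcations are folded pairwise, which
matches Fitch only for binary input). The enrichment 2×2 for translocation
linkage is one reading of an under-specified protocol; alternatives (e.g.
breakpoint-level counting) would change borderline links.
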