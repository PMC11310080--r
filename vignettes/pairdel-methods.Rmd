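---
title: "Models and methods behind pairdel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairdel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pairdel implements the analysis side of a dual-CRISPR deletion screen: a
pooled library in which every construct expresses two sgRNAs from convergent
U6 and H1 promoters, so that Cas9 excises the genomic interval between the
two cut sites. Deleting a whole non-coding regulatory element (NCRE) — an
enhancer, silencer or ultra-conserved element typically 50–300 bp long —
tests its function regardless of whether the element activates or represses
transcription, which one-guide CRISPRi/CRISPRa tiling cannot do without
prior knowledge of the element's sign of action. This vignette explains the
models, the defaults and the choices that were genuinely open.

## Library design

### Guide discovery and filtering

Candidate protospacers are every 20-mer 5' of an NGG PAM on either strand
(`scan_protospacers()`), with the blunt cut placed between protospacer
positions 17 and 18 (3 bp 5' of the PAM). Efficacy and off-target scores are
**inputs**, not computed here: practitioners obtain them from a dedicated
scorer, and the toolkit's contribution is the filter contract
(`filter_guides()`): efficacy > 0.15, top-5 off-target total < 47, top-10
off-target total < 50 (all strict), no overlap of the protospacer with
exclusion intervals (exons, repeats), and a cut site at least 10 bp from any
splice site. All coordinates are 0-based half-open (BED convention).

### Pairing strategies

`design_flanking_pairs()` selects up to five passing guides cutting in each
200-bp flank of the target region and emits their Cartesian product, so an
abundantly scannable region receives exactly 25 pairs whose expected
deletions all contain the region. Where a flank is unusable (genomic
repeats, no passing guide), `design_internal_pairs()` falls back to pairing
a 5'-proximal with a 3'-proximal in-region guide, keeping up to 14 pairs
whose deletion spans the region midpoint, widest deletion first. Two choices
here were open and are ours: when more than five guides pass per flank we
rank by efficacy, then by proximity to the region boundary, then by guide id
(deterministic); and the internal cap of 14 is a parameter whose default
matches the typical per-enhancer pair count of the second-strategy library.

### Oligo and cassette grammar

`assemble_oligo()` emits the exact synthesized-oligo string for either
cassette generation: both begin `ATCTTGTGGAAAGGACGAAACACCG` and end
`CGGGAAAGAGTGGTCTCATACAGAACTTAT`, embed the H1-side guide as its reverse
complement, and differ in the middle linker (v1: one BsmBI-bearing linker;
v2: two linkers around a 10-nt barcode). `parse_oligo()` inverts the
grammar exactly; the round trip is property-tested on 1,000 random pairs.
Protospacers containing BsmBI (`CGTCTC`/`GAGACG`) or BbsI
(`GAAGAC`/`GTCTTC`) recognition sequences are rejected: those enzymes open
the vector during the two-step cloning, so such guides cannot be
synthesized into a functional construct. The paper-facing rationale is
implicit in the cloning chemistry; enforcing it in software is our choice.

`build_expression_cassette()` returns the post-cloning cassette with two
full 76-nt tracrRNA scaffolds separated by a neutral spacer of exactly 50 bp
(v1) or 200 bp (v2); the wider v2 gap exists so that paired-end sequencing
of the two protospacers stays base-balanced and efficient. The spacer is a
fixed 200-nt sequence generated once under constraints (GC 40–60%, no
homopolymer of 4, no 6-mer shared with any promoter/scaffold/template
anchor, no type-IIS site) and frozen as a package constant; only "neutral
filler" is specified by the design, so any sequence meeting those
constraints is equivalent.

Barcodes (v2) are 10-nt, homopolymer-free, pairwise Hamming distance >= 2,
drawn by a seeded greedy sampler. The distance and homopolymer rules are
plumbing of this implementation, not a published constraint.

## Read processing

Amplicon read pairs are anchored on the promoter 3' ends — U6:
`ATATATCTTGTGGAAAGGACGAAA`, H1: `ATAAGTTCTGTATGAGACCACTCTT` — found anywhere
in the read with at most one mismatch (so variable-length stagger prefixes
phase-shift the reads without affecting extraction). After the fixed
junction bases (`CACCG` / `TCCCG`) the next 20 nt are the protospacer; the
following 20 bp must match the scaffold prefix `GTTTTAGAGCTAGAAATAGC` with
at most one mismatch, with the tracrRNA identifying sequence `AAGTTAAAAT`
(scaffold positions 21–30) as a fallback check when the prefix fails. The
published pipeline is ambiguous about whether the two downstream checks were
conjunctive or alternatives; we implement prefix-first with the identifier
as fallback, which accepts a superset of reads either single rule would.

A read-pair aligner is deliberately replaced by exact/near-exact matching
with a **unique-best** contract: a protospacer is assigned only when exactly
one reference guide attains the minimal Hamming distance (<= 1 by default).
This is the deterministic, dependency-free analogue of discarding multi-
mapping alignments by mapping quality. Both sides assigned to one designed
pair is `matched`; to different pairs, `recombinant` — the signature of PCR
or lentiviral template switching — and excluded from counting. Fates are
exhaustive and conserved: matched + recombinant + no_anchor + no_scaffold +
ambiguous + unmatched equals the number of read pairs.

One consequence worth knowing: recombination between two constructs that
share a U6 guide (common within a region designed as a Cartesian product)
regenerates another *designed* construct and is therefore undetectable in
principle; the recombinant-fraction meter is only interpretable on the
subset of the library with unique guides per pair.

`filter_low_coverage()` drops pairs below `min_count` (default 5) in the
day-0 reference sample; the published analysis filters low coverage without
stating a threshold, so 5 is our documented default.

## Screen statistics

Counts are normalized by median-ratio size factors (the screen-analysis
convention; the normalization method itself is unstated in the source
analysis). Guide-pair scores are log2 fold changes with pseudocount 1, day-15
versus day-0, ranked most-depleted-first; ties break by pair id.

### Region calls: alpha-RRA

For a region with $k$ scored pairs whose percentiles (rank/m) sorted are
$u_{(1)} \le \dots \le u_{(k)}$, only percentiles below $\alpha$ (default
0.25) are considered informative and

$$\rho = \min_{j:\, u_{(j)} < \alpha} P\!\left(\mathrm{Beta}(j,\,k-j+1) \le u_{(j)}\right),$$

the smallest Beta order-statistic tail probability. A region with no
percentile below $\alpha$ gets $\rho = 1$. Significance uses the published
cut-off $\rho < 0.01$. Permutation p-values compare each region against
seeded random $k$-subsets of the global percentile pool, with add-one
smoothing; the null set is shared across regions of equal $k$ (the standard
implementation trick — it changes nothing about the estimand and keeps
2,000-region screens fast), and BH correction is applied across regions.
On instances small enough to enumerate every subset, the permutation
p-values converge to the exhaustive values (tested).

### Beta scores and drug interactions

The cited maximum-likelihood beta estimation is deliberately replaced by a
robust median estimator: a region's beta per condition is the median over
its pairs of the log2 fold change versus day 0 (samples averaged within a
condition first — replicate handling inside the original MLE is
unreported). The classification rules, which are the substantive
contribution, operate identically on any consistent selection coefficient.
A region is *resistant* when its treated beta exceeds the treated
population mean by more than 2 s.d., its untreated beta stays within 1
s.d. of the untreated mean, and its differential beta (treated minus
untreated) exceeds the differential mean by more than 1 s.d.; *sensitizing*
mirrors this. The 2-s.d. treated rule follows the stated method; the 1-s.d.
differential rule follows the figure convention; both are parameters. Note
the control-arm gate (within 1 s.d.) excludes roughly a third of genuinely
drug-interacting regions by chance alone — a property of the rule, not of
the implementation — which is why the simulation guarantee is phrased over
regions exceeding every threshold by a clear margin (0.5 s.d.).

## Enhancer clusters

Many enhancers act redundantly inside super-enhancer clusters: each member
deletion shifts growth too little to call alone. `map_regions_to_clusters()`
assigns regions to annotation intervals by midpoint containment (overlapping
annotation intervals are rejected as ambiguous). Two tests run at cluster
granularity: a weighted Kolmogorov–Smirnov running-sum enrichment score
(weight 1, one-sided toward depletion, membership-permutation p-values) and
alpha-RRA with all member regions' guide pairs pooled. BH correction is
applied across clusters in both, with FDR < 0.25 as the reporting
convention. `select_shared_top()` intersects the top-20 clusters of both
methods, ordered by joint rank sum — the agreement criterion used to
nominate clusters for validation. The KS variant (weighted, one-sided) is
our choice; the method family is named but not the variant.

## Single-cell perturbation analysis

`assign_perturbations()` sums guide-capture UMIs to pair level and assigns
a cell to its top pair when it has >= 3 UMIs and >= 80% of the cell's pair
UMIs; two pairs above the UMI floor without dominance make a multiplet.
The thresholds are ours (the source states a low MOI of 0.2 and multiplet
filtering without numbers) and are parameters.

Expression is depth-normalized per cell to 10,000 counts and
natural-log-transformed (`ln(1 + 10^4 c / C)`). Differential expression per
target uses a two-part hurdle model on the log-normalized matrix with the
per-cell covariates log(genes detected) and log(guide UMIs): a logistic
model of detection and a Gaussian linear model of expression among detected
cells. The test statistic is the summed likelihood-ratio deviance drop from
removing the group term in both parts, chi-square with 2 df; complete
separation in the detection part (or an inestimable continuous part) falls
back to the remaining part with 1 df and a flag. Genes with mean normalized
expression below 0.01, or detected in fewer than 5% of cells in both groups,
are skipped (the 5% is our parameterized default for an unquantified
filter). Fold changes are reported as log2 ratios of group means of
*linear-scale* depth-normalized expression, so a 50% knockdown reads as
LFC -1. Cell-cycle regression is not performed; users can pass residualized
matrices if they need it.

`cis_window_report()` restricts candidate genes to the TAD containing the
region midpoint when TAD annotations are supplied, otherwise (or when the
region lies outside all TADs) to +/- 1 Mb around the region.

## Synthetic data: what it does and does not emulate

The `simulate_*` generators give every stage a ground truth:

- `simulate_design_inputs()` plants NGG PAMs at regular spacing so each
  flank is guaranteed its requested candidate count; scores are drawn so
  filter pass rates are predictable (efficacy ~ U(0,1) passes 85%;
  off-target scores ~ U(0,94) and U(0,100) pass 50% each).
- `simulate_screen_counts()` draws day-0 abundances Dirichlet-multinomial
  (concentration 3) and later samples negative-binomial (dispersion 0.05)
  around expected abundances scaled by $2^{\text{effect} \times \text{days}}$
  and renormalized — as in a real pooled screen, a depleted construct's
  sequencing share is redistributed, which shifts all null log fold changes
  by a small rank-invariant constant. Defaults mirror the screen conditions:
  15-day window, 400x coverage, 5% essential regions at 2-fold/day
  depletion, drug shifts of +/- 2 over the window.
- `simulate_amplicon_reads()` embeds the exact cassette grammar with
  staggers of length 0–7 (mirroring the staggered PCR design), per-base
  substitution errors, and H1-side swaps at the recombination rate.
- `simulate_single_cell()` draws baseline counts negative-binomially with
  log-normal gene means and per-cell depth factors, scales cis-target means
  by (1 - knockdown), and plants capture UMIs with sparse background noise
  and optional multiplets. Genes named in `cis_effects` are floored at 1
  count/cell: a knockdown planted on an undetectable gene is not a
  meaningful test condition. Default group sizes are 150 perturbed versus
  4,000 control cells.

What the generators do **not** emulate — and hence what green tests cannot
certify about real data: guide-specific efficacy differences within a
region, chromatin-context effects on cutting, PCR jackpotting beyond the NB
dispersion, base-quality structure, ambient RNA and doublet transcriptomes,
cell-cycle structure, or batch effects. They are calibrated for
correctness of the statistical machinery, not realism of every artifact.

## Numerical choices and degenerate inputs

- Seeds are explicit arguments everywhere randomness exists; seeded calls
  restore the caller's RNG state.
- Permutation p-values use add-one smoothing, so they are never 0.
- Rank ties break by pair id; selection ties in the designers break by
  guide id — all outputs are deterministic for fixed inputs.
- Degenerate inputs fail loudly and early: empty flanks and one-sided
  midpoints warn and return empty designs; a missing score names the guide;
  zero-total cells are dropped with a warning; a population s.d. of 0 makes
  every drug call `none` (strict inequalities).
- Problem sizes in the test-suite simulations (for example 2,000 regions
  with 25 pairs each at 400x depth, 10^5 read pairs, 150 vs 4,000 cells
  with 20 power replicates) are chosen as the smallest sizes at which the
  statistical guarantees are sharp.

## Known limitations

- The beta estimator is a median log-fold-change, not the cited MLE: point
  estimates agree in expectation under the simulated model, but shrinkage
  behaviour under very low counts differs.
- The recombinant-read meter undercounts recombination in libraries where
  pairs share guides (see above); report it per unique-guide stratum.
- The hurdle model's Gaussian continuous part is an approximation on
  log-normalized counts; its 2-df calibration is verified in simulation at
  the default group sizes, not proven for arbitrary designs.
- alpha-RRA precision at `rho < 0.01` depends on pairs-per-region: with
  very few pairs (k <= 5), the null rho distribution has appreciable mass
  below 0.01 and the cut-off alone over-calls; the screen design's
  redundancy (up to 25 pairs per region) is part of the statistical
  contract, and the permutation FDR column is provided for designs that
  cannot afford it.
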