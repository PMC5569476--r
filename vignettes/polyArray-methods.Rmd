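---
title: "Methods and design notes for polyArray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for polyArray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polyArray implements the computational pipeline around intraspecific SNP
genotyping arrays for polyploid crops: panel design from re-sequencing
candidates, genotype calling from two-channel intensities with polyploid
cluster adjustment, panel QC, distance-based phylogenetics and LD, and a
Q+K mixed-model association scan. This vignette records the models, the
tunable parameters, and the design choices made where conventions were
genuinely open — the things a maintainer would otherwise have to
reverse-engineer from the code.

## Panel design

Candidates arrive as a manifest (id, chromosome, 1-based position, alleles,
MAF, heterozygosity rate, re-sequencing genotype accuracy, probe design
score, multi-mapping flag). The cascade in `applyHardFilters()` runs in a
fixed order — MAF, accuracy, repeat regions, flanking variants,
heterozygosity, uniqueness — so that the per-stage attrition report is
reproducible; each rule is a per-candidate predicate, so the surviving set
itself does not depend on the order or on how the input is chunked.

Defaults in `filterConfig()`:

| parameter | default | meaning |
|---|---|---|
| `mafMin` | 0.10 | minimum minor allele frequency (inclusive) |
| `accuracyMin` | 0.9912 | genotype accuracy, consumed as an input field (exclusive) |
| `flankBp` | 50 bp | no other SNP/In-Del within this distance of the site |
| `hetMax` | 0.15 | heterozygosity rate bound (exclusive); high values suggest collapsed paralogs |
| `scoreGenicMin` / `scoreIntergenicMin` | 0.7 / 0.9 | probe design-score thresholds (exclusive) |
| `minGapBp` | 2100 bp | minimum distance between adjacent selected markers (exclusive) |

The genotype accuracy is a per-candidate input: how it was derived from
re-sequencing data is upstream of this package. The uniqueness step is
implemented as removal of multi-mapped candidates (flag in the manifest) —
markers whose flanking sequence hits homeologous or paralogous loci cannot
be assayed addressably on a polyploid.

The spacing rule is interpreted as a constraint on *adjacent selected
markers*: every adjacent same-chromosome pair must be more than `minGapBp`
apart (an alternative reading — probe-flank geometry — would give a
different constant but the same machinery). `selectSpacedMarkers()` offers
two modes: `max_count`, a left-to-right greedy sweep that provably retains
the maximum number of markers on a line, and `score_priority`, which admits
candidates in descending design score subject to the gap, with
deterministic (position, id) tie-breaks.

Reporting conventions in `summarizePanel()`: the average spacing of a
chromosome is its length divided by the marker count (not count − 1),
rounded to one decimal in Kb; both conventions agree at that rounding for
realistic panels and the simpler one is fixed. Percentage shares are
reported at two decimals. Gap histograms default to bins <10, 10–20,
20–30, 30–40, 40–50 and >50 Kb. Chromosomes with zero markers report an
undefined (`NA`) spacing rather than a division error. Coordinates are
1-based inclusive internally; BED input is converted at the reader
(`readBedMask()`).

Genic annotation (`annotateSnpContext()`) classifies a SNP inside any gene
span as genic, with feature precedence UTR > exon > intron; intron means
"inside a gene but in no exon/UTR interval". Exon/UTR intervals outside
every gene span are ignored with a warning.

## Genotype calling

The caller works marker by marker on normalized intensities: `theta`
(allele contrast, 0–1) and `normR` (total signal). The mixture is
one-dimensional in theta because the genotype classes of Infinium-style
data separate along the contrast axis; R carries presence/absence
information and is used only to exclude no-signal samples from fitting and
to gate `NG` calls. The upstream raw-to-normalized transform of the
scanner software is out of scope; this package starts from (theta, R).

`fitThetaClusters()` fits Gaussian mixtures with k = 1..5 components
(an allotetraploid locus can show AAAA, AAAB, AABB, ABBB, BBBB) and picks
k by minimum BIC (`−2·logL + (3k−1)·log n`). The EM is deterministic: two
fixed starts — component means equally spaced over the data range, and
means at data quantiles — and the better final likelihood wins. Two starts
matter: a single quantile start collapses onto the majority cluster when
class sizes are very uneven, which is the common case for loci with a rare
homozygote. A standard-deviation floor of 1e-3 keeps the likelihood finite
on noise-free (replicated-value) data. Components with weight below
`minClusterWeight` (default 0.02) are removed outright and the weights
renormalized; their samples then fall outside the assignment radius and
are called `--`. Removing rather than refitting is deliberate: refitting
with k−1 smears the removed mass into a neighboring component and turns a
conservative no-call into a confident miscall.

`adjustClusters()` is the polyploid adjustment: adjacent components closer
than `mergeDeltaTheta` (default 0.15) in mean theta are merged (weighted
mean, pooled second moment), iterating until no pair qualifies. The
default separates the five canonical cluster positions (≈0.23 apart)
while collapsing AAAA/AAAB- or ABBB/BBBB-type sub-clusters; it is
configurable because real arrays differ. Labels are then assigned by rank:
the increasing subset of anchor positions (0, 0.5, 1 for diploidized
labels; 0, 0.25, 0.5, 0.75, 1 for tetraploid classes) minimizing total
distance to the cluster means. This reproduces the standard manual
adjustments — a pair near 0 becomes {AA, AB} (AAAA/AAAB), a pair at
0.05/0.95 stays {AA, BB}, a lone cluster at 0.9 is BB. Models keeping more
than three clusters after merging are flagged complex; their calls are
diploidized from the tetraploid labels (AAAA/AAAB → AA, AABB → AB,
ABBB/BBBB → BB). The adjustment is idempotent.

Calling (`callGenotypes()`): `normR < ngRMin` (default 0.2) at a working
marker gives `NG` — the no-genotype state attributed to structural
variation or In-Dels, distinct from the failed call `--`. The direction of
the R rule (low signal = no call) is the implemented reading of an
ambiguous convention; it is a config knob. Samples farther than
`assignMaxDistance` (default 4) standardized deviations from every cluster
mean are `--`; everything else takes the nearest cluster's diploidized
label. Markers with fewer than two usable samples are failed (`--`
everywhere). Call rates count only AA/AB/BB; both `NG` and `--` reduce
them (the conservative reading of "uncalled").

`classifyLocusPattern()` reproduces the cluster-graph taxonomy seen on
polyploid arrays: monomorphic, two-cluster, three-cluster, partial-NG,
failed, polyploid-adjusted. The predicates overlap, so precedence is
fixed: failed > polyploid-adjusted (any merge, or >3 clusters) >
partial-NG > k-based.

## Panel QC

Definitions, all over definite calls only: MAF from allele counts
(AA → 2 reference alleles, AB → 1+1, BB → 2 alternate); a marker is
polymorphic when MAF > 0 in the sample set under consideration; pairwise
similarity is the percentage of identical calls over co-called loci and
the pairwise polymorphic rate is its complement (the two columns of a
replicate/distinguishability table are complements by construction).
Parent/F1 verification counts loci where the parents are opposite
homozygotes and all three samples are called; the verification percentage
is the share of those loci called heterozygous in the F1. Empty
denominators are flagged undefined rather than propagated as NaN.
Subpopulation summaries obey the nesting
MAF>0.1 ≤ MAF>0.05 ≤ polymorphic ≤ total by construction.

## Population genetics

Identity-by-state for a called pair at one locus is the shared-allele
fraction (1, 0.5, 0); the pairwise distance is 1 − mean IBS over co-called
loci. Neighbor joining uses the Saitou–Nei algorithm (via ape); on
additive matrices the reconstruction is exact. Negative branch lengths —
possible on non-additive input — are clamped to zero with the deficit
moved to the branches incident at the same node, preserving path lengths
through the node where possible.

PCA operates on marker-mean-centered dosages (0/1/2) with missing values
mean-imputed (centered zeros, so imputation is neutral); monomorphic
markers are dropped; component signs are fixed by making the
largest-magnitude loading positive.

LD: r² is the squared Pearson correlation of dosage vectors over co-called
samples — the composite estimator, appropriate because array genotypes are
unphased. D′ uses two-locus haplotype frequencies from an EM in which only
the double heterozygote is phase-ambiguous. The decay curve is the mean r²
per physical-distance bin (default width 10 kb); the decay distance is the
smallest bin midpoint at which the lightly smoothed curve (3-bin running
mean) falls to half its maximum. Half-maximum is a convention — decay
distances are only comparable under the same rule — and the bin width is a
parameter.

## GWAS

The scan fits `y = μ + Qv + xβ + u + e`, `u ~ N(0, σ²g K)`,
`e ~ N(0, σ²e I)`. K is the VanRaden kinship: centered-dosage
cross-product scaled by `Σ 2p(1−p)` over polymorphic markers (a Gram
matrix, hence PSD). Q defaults to an intercept plus the top k−1 principal
components — admixture proportions for k source populations sum to one and
span k−1 dimensions, so PCs are the rank-correct substitute for a
model-based structure matrix; an externally computed Q can be supplied.

Estimation follows the spectral approach: with K = U D Uᵀ, rotating by Uᵀ
makes the covariance diagonal in λ = σ²g/σ²e, and the REML profile in λ is
optimized on the log scale over [e⁻¹², e¹²]. By default the null-model λ
is reused for every marker (P3D), which makes each marker test a weighted
least-squares Wald t-test (df = n − p − 1); `exact = TRUE` re-estimates λ
per marker with the marker in the fixed effects. P3D is faster and
near-identical for small effects; the exact mode matters for strong
effects, whose contribution otherwise inflates the null λ and is partly
absorbed into the polygenic term. When K = I the model collapses to
ordinary least squares exactly — the weights are constant — which the
tests verify to 1e-8.

Markers are pre-filtered to MAF > 0.05 by default. The Bonferroni
threshold is reported as `1/n` at two significant figures (the
conventional presentation) alongside a fixed 1e-05 reporting threshold.
Significant SNPs are expanded ±500 Kb (configurable), overlapping windows
merged per chromosome (`GenomicRanges::reduce`), bounds clipped to [1,
chromosome length] and also reported in Mb at two decimals; genes whose
spans intersect a region are listed with it.

## Synthetic data

The generators emit everything the pipeline consumes plus truth tables
sufficient to score every module without external data, and are
deterministic under a seed.

Populations follow the Balding–Nichols model: ancestral frequency
p ~ Uniform(bounds), subpopulation frequency ~ Beta(p(1−Fst)/Fst,
(1−p)(1−Fst)/Fst), Hardy–Weinberg genotypes within subpopulations; the
Fst = 0 and Fst = 1 boundaries collapse to no drift and fixation. Optional
LD comes from a latent AR(1) process along each haplotype with correlation
exp(−rate × distance) between adjacent markers — enough to make decay
curves move monotonically with the rate, not a coalescent.

Intensities: theta ~ Normal at the class mean, truncated to [0, 1], with
defaults AA 0.05, AB 0.50, BB 0.95 and tetraploid-mode means 0.05, 0.275,
0.50, 0.725, 0.95 — cluster graphs in this field print no axis numbers, so
these are symmetric conventions, not measured values. normR is log-normal
(meanlog 0, sdlog 0.3); planted NG entries draw normR below the no-signal
threshold. In tetraploid mode homozygous samples split between the outer
and inner cluster of their side. Note the default tetraploid spacing
(0.225) exceeds the default merge window (0.15): fully separated 5-cluster
loci are classified polyploid-complex rather than merged, matching how
such loci look in practice; merge-path tests use a sub-cluster geometry
(e.g. means 0.05/0.15/0.5/0.85/0.95).

Phenotypes: `y = μ + β·dosage + g + e`, with g drawn with covariance
proportional to the VanRaden kinship of the input genotypes. Unless an
explicit β is given, g and e are made orthogonal in sample to the causal
dosage (and to each other) and each component is rescaled, so the realized
variance fractions equal the targets exactly. This is the faithful
implementation of "scaled to hit target h² components": the planted
ground truth is exact, recovery tests are sharp, and no power is spent on
the sampling covariance between components. Real phenotypes, of course,
carry that covariance — the generator validates the machinery, it does not
emulate field noise.

## Study conditions used by the validation suite

The test suite fixes these problem sizes as the package's reference
conditions: filter-cascade oracle equivalence on 1,000 random instances of
up to 20 candidates; caller recovery on 75 markers × 150 samples
(>10,000 calls) from a common-variant population (ancestral MAF 0.3–0.5,
so every genotype class clears the 2% component-weight floor) — exact at
sd 0, ≥99% at sd 0.05; NJ reconstruction on random additive trees of up to
12 taxa; MLM null calibration over >20,000 tests (10 phenotypes on
2,100 markers × 200 samples, 3 subpopulations at Fst 0.2); and
planted-causal power over 50 replicates of 1,000 markers × 300 samples at
h²snp = 0.1, polygenic h² = 0.3, causal MAF ≈ 0.3. In the power scenario
the causal SNP is planted with near-homogeneous subpopulation frequencies:
the polygenic background is then partly structure-confounded (which Q+K
absorbs) while the causal effect is not — the textbook situation the Q+K
design exists for. The exact-REML flag is used there because a strong
planted effect inflates the null-model λ under P3D and would be partly
absorbed into the polygenic term.

## Limitations

- The caller models theta as a Gaussian mixture; real cluster clouds are
  asymmetric near the rails (theta is a ratio-derived angle), and R-theta
  dependence is ignored beyond the NG gate. No batch/plate effects.
- The synthetic populations have exchangeable markers and no demographic
  history; passing recovery tests demonstrates correctness of the
  estimators, not their behavior on real germplasm.
- D′ assumes two alleles and random mating within the sample used.
- The decay distance depends on the binning and half-maximum conventions.
- P3D shares one λ across markers; use `exact = TRUE` when strong effects
  are expected.
- Admixture-style Q is approximated by principal components; supply an
  external Q matrix to use model-based ancestry fractions.
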