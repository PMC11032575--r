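---
title: "Haplotype-aware expression analysis for (B6 x CC)F1 mice: models and methods"
author: "ccf1tx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-aware expression analysis for (B6 x CC)F1 mice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccf1tx)
```

## The study system

The Collaborative Cross (CC) is a panel of recombinant inbred mouse strains
derived from eight founders (A/J, C57BL/6J, 129S1/SvImJ, NOD/ShiLtJ,
NZO/HlLtJ, CAST/EiJ, PWK/PhJ, WSB/EiJ; coded A-H throughout this package,
with B = C57BL/6J). Each CC genome is a mosaic of founder haplotype blocks.
Crossing a female C57BL/6J carrying a hemizygous transgene (e.g. the 5xFAD
amyloidosis construct) to a CC male yields F1 animals that are heterozygous
genome-wide - one B6 haplotype from the dam, one CC-mosaic haplotype from
the sire - and that carry the transgene with Mendelian probability 1/2.
Expression analysis of such animals needs a *diploid* reference (both
parental allele sequences), allele-aware quantification, and downstream
statistics that respect the crossed design. `ccf1tx` implements that
pipeline end to end at desk scale, together with a fully seeded synthetic
generator that produces every input with known ground truth.

## Synthetic data: what is emulated, what is not

`sim_config()` fixes all generator tunables; every generator is a pure
function of the configuration (seeded sub-streams per operation), so reruns
are byte-identical.

* **Founders** (`gen_founders`): a shared transcript skeleton - intron-free
  transcripts laid non-overlapping on each chromosome - with segregating
  sites planted at `snp_rate` per transcribed bp (default 0.005/bp, the
  order of the panel's variant density). Founder B carries the reference
  base; each other founder carries the alternate independently with
  probability 1/2. The SNP table is emitted as ground truth.
* **Mosaics** (`gen_mosaic`): `n_blocks_per_chrom` contiguous blocks with
  uniform-random breakpoints and uniform founder labels. The real CC
  funnel-breeding block-length distribution is not published for these
  lines, so no recombination-map realism is claimed.
* **Crosses** (`simulate_cross`): transgene carriage Bernoulli(0.5) by
  default, sex Bernoulli(0.5), age from {4, 12} months (the two harvest
  ages, coded 0/1 for regression), plus eight correlated sequencing-QC
  metrics per sample carrying a planted batch direction - the raw material
  for sequencing PCs.
* **Reads** (`simulate_reads`): single-end, fixed length (default 43 bp);
  an entry is drawn with probability proportional to
  `weight * (length - read_length + 1)` (weights are molar), the start is
  uniform, and per-base substitution errors are optional. Real library
  chemistry was paired-end; pairing adds no logic the equivalence-class EM
  needs at this scale, so it is out of scope.
* **Expression** (`gen_expression`): log2-scale matrices with planted
  module factors (`loading * factor + covariates + noise`), planted
  covariate effects, and full ground truth returned.

Not simulated: sex chromosomes (autosomes plus an optional maternal-only
chrMT), indels and structural variants, isoform diversity (one transcript
per gene), GC or positional bias, and count-level (negative binomial)
noise - simulated expression is Gaussian on the log2 scale. Passing tests
therefore demonstrate algorithmic correctness under clean conditions, not
robustness to every artifact of real libraries.

## Reference construction

`parse_mosaic()` enforces the mosaic TSV dialect (1-based inclusive
coordinates; per chromosome the blocks must start at 1 and tile without
gaps or overlaps). `build_strain_transcriptome()` assigns each transcript
whole to the founder whose blocks cover most of its base pairs, breaking
ties toward the block with the smaller start coordinate. The alternative -
stitching a chimeric sequence per segment - was rejected: it is not what
the haplotype files describe, and a single source founder per transcript is
what downstream allele-level quantification expects. Transcripts that
straddle a breakpoint are therefore attributed to the majority founder;
this choice is deterministic and is tested against a per-base-pair oracle.

`build_f1_diploid()` combines the stitched paternal set with the maternal
C57BL/6J copy, suffixing transcript IDs `_M`/`_P`. Mitochondrial
transcripts are emitted maternal-only, since all F1 animals inherit B6
mitochondria from the dam. CC strains are treated as fully inbred;
residual heterozygous founder states in real MRCA files are out of scope.

`founder_contribution()` reports, per gene locus, the fraction of base
pairs covered by each founder's blocks - rows sum to 1 and are one-hot
unless a locus straddles a breakpoint. An all-B6 mosaic yields 100%
C57BL/6J contribution at every locus.

## Equivalence classes and EM quantification

At desk scale, alignment is exact-substring compatibility: every window of
read length in the diploid reference is hashed, and a read's equivalence
class is the set of transcript-alleles containing it. A read overlapping a
maternal/paternal SNP is compatible with exactly one allele; a read from a
shared region is compatible with both.

The EM iterates in read-fraction coordinates `eta`: the E-step splits each
class count among members in proportion to `eta_t / l_t`, with
`l = length - read_length + 1` (floored at 1) the effective length, and
the M-step sets `eta_t` to the assigned read fraction. The per-class data
log-likelihood `sum_c n_c log(sum_{t in c} eta_t / l_t)` is non-decreasing
each sweep (asserted in tests). Initialization is uniform; convergence is
max-abs change in `eta` below `tol = 1e-8` within `max_iter = 1000` sweeps;
hitting the cap flags the result rather than erroring. The reported
abundance is the molar fraction `theta = (eta/l) / sum(eta/l)`: with
uniquely mapped reads this is direct count-over-effective-length
normalization after a single sweep. A `unique_only` switch drops ambiguous
classes first, reproducing a strict unique-read quantification.

`gene_tpm()` pools the two alleles of each gene *before* scaling the
column to 1e6 - whether pooling happened before or after scaling is not
observable from gene-level output, and pooling first keeps the
transcript-allele layer available unscaled. The hierarchical
allele/isoform/gene EM of full-size tools collapses to this flat
transcript-allele EM here because the toy model has one isoform per gene.

## Preprocessing

* `filter_low_expressed()`: a gene is kept iff TPM exceeds 0.1 in strictly
  more than 20% of samples. "Expressed" is operationalized as TPM > 0.1
  and exposed as a flag, since no universal definition exists.
* `compute_seq_pcs()`: QC metrics are z-scored and the top five principal
  component scores are returned (`seq_pc_1..5`), with the deterministic
  sign convention that each component's largest-magnitude loading is
  positive.
* `regress_covariates()`: per-gene OLS of log2(TPM+1) on the dummy-coded
  design, residuals plus gene grand mean returned. The full stated model is
  `expression ~ line + genotype + sex + age + seq_pc_1..5`, and that is the
  function's default. For stages that *test* line, genotype, sex or age
  downstream, regressing those same factors out first would nullify the
  test; the pipeline therefore passes only the sequencing PCs as the
  covariate set for the differential-expression and network stages, and the
  term set is an explicit argument so either reading is available.

## Differential expression

The per-gene test is a Welch two-sample t on log2 expression with
Benjamini-Hochberg control across genes. A negative-binomial count
framework is deliberately not replicated: the thresholds, divergence
matrices and intersections that sit on top of the test are test-agnostic,
and the interface isolates the test statistic so an NB variant can be
swapped in. `log2_fc` is the difference of group means on the log2 scale
(not the ratio of means). A gene is a DEG iff |log2FC| > 1 and FDR < 0.05;
the volcano classes `FC-only`, `FDR-only` and `NS` cover the remaining
quadrants. `deg_count_matrix()` computes symmetric line-by-line DEG counts
(optionally per sex); `conserved_degs()` intersects DEG sets across
comparisons and additionally requires a concordant fold-change sign -
whether the original conserved-DEG count imposed directional concordance is
unstated, so the stricter reading is implemented.

## Consensus co-expression networks

For each dataset (strain), the gene-gene similarity is the biweight
midcorrelation with `u = (x - med)/(9 MAD)` (MAD unscaled, the classical
biweight convention), weights `(1 - u^2)^2` inside |u| < 1. Genes with
MAD = 0 but non-constant values fall back to Pearson weighting for their
pairs; constant genes are dropped. The signed adjacency is
`((1 + bicor)/2)^beta` - beta = 16 for the age/sex network, 14 for the
genotype network, taken as given (the scale-free fit search that produced
them is out of scope) - and the topological overlap is

    tom_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij).

Consensus: each dataset's TOM is power-scaled so its 0.2 off-diagonal
quantile matches dataset 1's (`tom^(log q_1 / log q_s)`; plain ratio
scaling would push values above 1), then the element-wise minimum is
taken - co-expression must be present in every strain to survive.

**Dynamic cut.** The published hybrid tree-cut algorithm is not
re-specified by its users, so this package defines its own contract:
average-linkage clustering of `1 - TOM`; a static cut at
`cut_height = 0.999`; then recursive splitting of each branch at the
largest gap between consecutive sorted merge heights whenever that gap
exceeds a `deep_split`-mapped fraction of the branch's height range
(deep_split 0-4 maps to 0.5 down to 0.1; the default 4 is the most
sensitive). Final branches smaller than `min_module_size = 100` are
unassigned, as is a root branch that was never separated from anything -
that last rule is what sends pure-noise data entirely to grey. The
planted-module recovery and pure-noise tests are the behavioural contract
for this component.

Modules whose eigengene dissimilarity `1 - cor(ME)` falls below
`merge_thresh` (0.25 or 0.2 depending on the network) are merged
iteratively, closest pair first. The module eigengene is the first
principal component of the z-scored module submatrix over the per-dataset
z-scored, sample-concatenated expression (per-dataset z-scoring puts
strains on a common scale before a single PC is taken), unit-norm,
sign-anchored so the mean member-gene correlation is positive. kME is the
Pearson correlation of each gene with each eigengene; genes whose
own-module kME falls below 0.7 are returned to grey, and the reported kME
table is computed against the same eigengenes used for pruning, so the
retained-gene invariant (own kME >= 0.7) holds exactly. Labels are color
names in decreasing pre-prune size order (turquoise, blue, brown, ...).

`module_trait_cor()` correlates eigengenes with numeric-coded traits
(age 4/12 to 0/1, sex F/M to 0/1, genotype WT/5x to 0/1), with t-based
p-values and BH FDR over the whole table; a cell is significant iff
FDR < 0.05 and |r| >= 0.1. `synthetic_eigengenes()` re-applies fixed
module definitions to sample subsets to trace module trajectories.

## Enrichment and preservation

`fisher_enrich()` computes the two-sided Fisher exact p by summing
hypergeometric point probabilities no larger than the observed table's
(the same convention as `fisher.test`, which the test suite uses as an
independent oracle). Odds ratios use `ad/bc` with a 0.5 continuity
correction on all cells when any cell is zero; the correction never
touches the p-value. Confidence intervals are reported but not
interpreted. Note that exact conditional p-values are discrete and
super-uniform under the null - calibration checks must compare against the
exact discrete null law, not a continuous uniform.

`directional_overlap()` splits a DE result into up- and down-regulated
DEG sets before enrichment. `deg_module_correlation()` correlates the DE
log2FC vector with per-gene module signatures over shared genes (flagging
|r| >= 0.20, p < 0.05; fewer than 10 shared genes marks the row
unreliable); the alternative reading - correlating eigengene effects
instead of fold changes - is not implemented. `geneset_eigengene()` is the
PC1-of-a-gene-list summary with per-group means and SEMs.

`module_preservation()` uses exactly two statistics per module: density
(mean within-module signed adjacency in the test data) and connectivity
preservation (correlation of intramodular connectivity between reference
and test). Reference implementations aggregate many more statistics; the
reduced pair is this package's contract, validated by planted
self-preservation and independent-noise constructions. A permutation null
of `n_perm >= 50` random same-size gene sets gives
`Z = (obs - mean)/sd` per statistic and `Z_summary` as their mean, banded
as: < 2 not preserved, [2, 5) moderately preserved, [5, 10] preserved,
> 10 highly preserved. If a null has zero spread (connectivity when test
and reference coincide), its Z is 0 when the observed value equals the
null mean - no evidence either way - rather than an arbitrary large value.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive everywhere; nothing converts.
* All RNG flows from explicit seeds; operations draw from deterministic
  per-operation sub-streams of the master seed, so adding an operation
  does not shift another's stream.
* EM: uniform initialization, tolerance 1e-8 on read fractions, effective
  lengths floored at 1; non-convergence warns and flags.
* bicor clamps to [-1, 1]; TOM clamps to [0, 1]; a consensus scaling
  quantile of zero is an error (degenerate network).
* Ties in founder assignment break toward the earlier block; ties in
  module merging break toward the first-found closest pair.
* Welch t with zero variance in both groups: p = 1 when the means agree,
  p = 0 otherwise.

## Problem sizes used in the test suite

The suite exercises the pipeline at sizes chosen to make every oracle
exhaustively checkable while keeping a full run in tens of seconds:
reference construction on 20 mosaics x 200 transcripts against a per-bp
oracle; EM on 100,000 reads over 12 genes for 2%-relative-error TPM
recovery; networks on 600 genes x 50 samples x 2 strains for
planted-module recovery; preservation on 300 genes with 100 permutations;
enrichment nulls with 1,000 resamples over a 1,000-gene universe. The
end-to-end chain (simulate, build reference, quantify, preprocess, test,
network, enrich, preserve) runs on 2 strains x 8 samples at 30 genes.

## Known limitations

* The Gaussian log2-scale expression model has no mean-variance coupling;
  conclusions about count-level inference do not transfer.
* The dynamic cut is a defined alternative to the published hybrid
  algorithm, not a re-implementation; on data with gradual module
  boundaries the two will differ.
* Exact-substring compatibility has no mismatch tolerance, so sequencing
  errors reduce the mapped fraction rather than creating mismapping.
* Fisher odds-ratio continuity correction biases the OR toward 1 for
  sparse tables; p-values are unaffected.
* CC strains are modeled as fully inbred and mosaics as uniform-random;
  neither linkage structure nor real block-length distributions are
  reproduced.
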