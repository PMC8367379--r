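---
title: "Methods: allele-specific expression dynamics and CRE-seq analysis"
author: "asedyn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression dynamics and CRE-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asedyn)
```

# The problem

In a hybrid diploid, the two parental alleles of a gene share one nucleus
and one trans-acting environment, so a difference in their expression
isolates cis-acting regulatory variation. Over a timecourse — here modeled
on the yeast diauxic shift, the transition from glucose fermentation to
respiration — cis variation can change not only the *level* of allelic
imbalance but its *dynamics*: the timing or rate at which one allele is
activated or repressed relative to the other, or an imbalance present in
only one metabolic state. `asedyn` implements the statistical pipeline for
detecting both kinds of signal from allele-resolved RNA-seq counts,
clustering the resulting trajectories, associating ASE with promoter
variant burden, designing and analyzing a barcoded reporter (CRE-seq)
library that assigns effects to individual variants and promoter halves,
and annotating variants with conservation and binding-change scores. A
seeded synthetic-data module generates every input the pipeline consumes,
with known ground truth, so that calibration and power are testable.

# The two ASE tests

Counts are first normalized by median-of-ratios across all
timepoint-by-allele columns of a hybrid jointly (`medianOfRatios`,
`normalizeAlleleCounts`): the reference value for a gene is its geometric
mean across columns (genes with any zero are excluded from the reference
set) and a column's size factor is the median ratio to that reference,
taken in log space. Genes with a mean below 20 total reads per timepoint,
or with more than seven zero-coverage timepoints, are removed
(`filterGenes`); both boundaries are strict, so a mean of exactly 20 and
exactly seven zero timepoints survive.

For each gene the reference-allele frequency is
$f_i = \mathrm{ref}_i / (\mathrm{ref}_i + \mathrm{alt}_i)$ on normalized
counts, with weight $w_i$ equal to the raw total reads at timepoint $i$;
zero-coverage timepoints are undefined and drop out of both tests, with
the dynamics test requiring at least four defined points.

**Levels.** The model $f_i = 0.5 + \beta_0 + e_i$ is fit by weighted least
squares, so $\hat\beta_0 = \sum_i w_i (f_i - 0.5) / \sum_i w_i$ is the
read-weighted mean allelic imbalance; the p-value is a two-sided t test of
$\beta_0 = 0$ with the weighted residual variance and $T - 1$ degrees of
freedom (`testAseLevels`).

**Dynamics.** The statistic is the weighted Durbin–Watson form on the
residuals of the levels model,

$$\mathrm{dw} = \frac{\sum_{i=1}^{T-1} (w_{i+1} e_{i+1} - w_i e_i)^2}
                     {\sum_{i=1}^{T} (w_i e_i)^2},$$

which is 2 in expectation for exchangeable residuals, below 2 for smooth
(positively autocorrelated) allelic trajectories and above 2 for
alternation (`weightedDwStat`, `testAseDynamics`). With unit weights it
reduces exactly to the classical Durbin–Watson statistic, which is the
cross-check the test suite runs against `lmtest`.

**The dynamics null.** No analytic null is available for the weighted
statistic, so the p-value is computed by permutation of the timepoint
order: the default 1000 seeded permutations of $u_i = w_i e_i$ give a
reference distribution, and the p-value is the two-sided fraction of
permutations at least as far from the permutation mean as the observed
statistic, smoothed as $(b + 1)/(N + 1)$. Orderings are drawn
independently for every gene (vectorized as one two-key radix sort per
permutation round), which keeps per-gene p-values independent and
marginally uniform; a shared ordering set would make them conditionally
non-uniform in a way a Kolmogorov–Smirnov calibration check detects.
Permutation p-values have a floor of $1/(N+1)$; with Benjamini–Hochberg
control this matters when few genes carry signal, so
`testAseDynamics(pMethod = "normal")` optionally replaces the empirical
tail with a normal approximation of the permutation distribution when
continuous p-values are needed. The exact permutation form is the default
and is what the validation targets use.

Both families of p-values are adjusted by Benjamini–Hochberg (`bhAdjust`,
a validated wrapper over `p.adjust`) at a default FDR of 0.01.

**Known limitation: weight heteroskedasticity.** Weighting by read counts
assumes the sampling variance of $f_i$ scales as $1/w_i$, which is exact
for Poisson counting noise. Two features of real data bend this: negative
binomial overdispersion adds a variance term that grows with depth, and a
gene's expression trajectory makes $\mathrm{Var}(w_i e_i)$ itself follow a
smooth curve in time, so the timepoints of $u_i$ are not perfectly
exchangeable. Both make the dynamics test mildly anti-conservative. This
is a property of the read-count-weighted statistic, and it is exactly what
the permutation-based validation quantifies: the pipeline's own
timepoint-permutation audit (`permutationNullDynamics`) reports the
resulting false-positive counts rather than assuming them to be zero. The
test suite asserts strict p-value uniformity only under the exchangeable
null (flat trajectories, Poisson noise), where it holds.

**Validation of the cutoffs.** `permutationNullLevels` destroys the
allelic signal by swapping the allele labels with probability 0.5
independently at each gene and timepoint, re-normalizes, and counts
discoveries at FDR < 0.01; `permutationNullDynamics` applies one random
timepoint reordering to all genes per replicate and re-runs the dynamics
test. Defaults are 10 replicates. Destroying the signal "independently at each timepoint" could mean
swapping or resampling; the swap convention is used
because it preserves totals and per-timepoint depth exactly. Whether the
dynamics test should be one- or two-sided is equally unstated; two-sided
distance from the null center is used since both smooth trajectories and
alternation are departures from a constant allelic ratio.

# Trajectory clustering and the transition classifier

`clusterProfiles` removes genes with any missing timepoint (k-means cannot
use them), normalizes each gene's series — centered and scaled for
combined-expression profiles, centered only for allele-frequency profiles,
the two scaling modes — and runs Lloyd's k-means
with k-means++ seeding, keeping the best of 25 restarts by within-cluster
sum of squares. The default k = 12 is fixed; no model selection over k
is attempted. The distance is Euclidean, and the seeded
k-means++/restart policy is this package's choice for reproducibility.

`classifyTransition` operationalizes the distinction between
environment-dependent ASE (imbalance growing or shrinking toward the ends
of the timecourse) and a transition extremum (maximum deviation during the
shift): a centered ASE series is a `transition_extremum` iff its maximum
absolute value inside a window around the shift index strictly exceeds the
absolute values at both series endpoints by a configurable margin
(default 0). The endpoint-comparison rule is this package's
operationalization of an otherwise qualitative dichotomy.

# Variant-burden association

`defineRegions` builds, per gene: the upstream region as the sequence
between the gene's CDS and the adjacent CDS on its 5' side, extended past
any neighbor closer than 5 bp (or overlapping) to the next gene; the
coding region as the CDS span; and the downstream region as 80 bp 3' of
the stop codon, clipped and flagged at contig ends. Variants count in a
region iff their leftmost reference base lies inside it (deterministic and
strand-independent for InDels). `logisticAssociation` fits
$\mathrm{logit}\,P(\mathrm{ASE}) = b_0 + b_1 x$ by IRLS (`stats::glm`),
reporting the odds ratio per additional variant with a Wald 95% interval;
complete separation and constant predictors are flagged instead of
reported. `associationBattery` runs the full 6-predictor (SNP and InDel
counts in upstream/coding/downstream) by 10-response (levels and dynamics
status in five hybrids) battery — 60 regressions — with Bonferroni control
at $\alpha = 0.05/60$. Genes without variant counts are dropped from fits.

# CRE-seq library design

`makeWindows` tiles five 130 bp windows at a 30 bp step across the 250 bp
upstream of each TSS on the coding strand, numbered proximal (ending at
the TSS) to distal, and removes windows that leave the contig or overlap
the next upstream CDS. `buildAlleles` creates, per window with $k$
variants: one shared construct ($k = 0$), the two parental alleles
($k = 1$), or additionally $2k$ single-variant swaps ($k \ge 2$) — each
parental background with exactly one variant exchanged. `buildChimeras`
globally aligns the two parental alleles (Biostrings), splits at the
alignment midpoint column — "the center" is otherwise undefined under
InDels — and recombines left(distal) and right(proximal) halves both ways,
refusing alignments below 50% identity. Insertion-carrying alleles exceed
the 130 bp window and are trimmed at the distal end (each allele's CRE is
anchored at its TSS-proximal end); deletion-carrying alleles are shorter
and receive a deterministic, seeded pad between RS2 and RS3, screened
against restriction sites, so every assembled oligo is exactly 200 bp:
forward primer, RS1, CRE, RS2, pad, RS3, RS4, 10 bp barcode, RS5, reverse
primer. The restriction sites themselves are configurable placeholders
(EcoRI/BamHI/XbaI/SalI/PstI by default). `generateBarcodes` draws random 10-mers with pairwise
Hamming distance at least 2 (checked in O(length) per candidate via
one-position-wildcard hashing), no restriction site on either strand, and
per-base composition within 10 percentage points of uniform across the
set; four barcode replicates per construct is the default.

# CRE-seq analysis

`countBarcodes` tallies exact (perfect-match) barcode hits per
demultiplexed sample and discards everything else. `filterCres` removes
barcodes with zeros in more than a third of the RNA samples or a mean
below 100 reads in RNA or DNA (strict boundaries). `creExpression`
normalizes all RNA and DNA columns jointly by median-of-ratios and divides
each barcode's normalized RNA by its DNA reference — the mean of its
normalized DNA samples, which uses the first- and last-timepoint DNA
information symmetrically; zero RNA counts are missing data, zero DNA
drops the barcode with a flag. Note that joint normalization estimates
per-sample depth from the median barcode, which is identifiable only
because a real library mixes thousands of constructs with heterogeneous
trajectories; the round-trip test constructs such a mixture deliberately.

`correlateWithEndogenous` computes the Pearson correlation of a region's
barcode-mean expression with the endogenous RNA-seq series of its gene,
mapping a denser reporter clock onto the RNA-seq timepoints by nearest
sampling time with ties to the earlier sample. `testCreLevels` collapses
each barcode to the natural log of its across-timepoint mean — a
deliberately conservative design: a single barcode with a global offset
contributes one observation, not T — and fits a linear model with an
allele indicator on the (about eight) barcode means. The log transform is
a variance-stabilization choice of this package. `testCreDynamics` forms the per-timepoint
expression share of the first allele, weights by total raw counts, and
applies the same weighted Durbin–Watson machinery as the endogenous test.
`testVariant` pools parental and swap constructs by their genotype at the
focal variant (swap constructs for other variants carry their background's
allele there, maximizing replicates) and runs both tests per variant.
`mapChimera` groups constructs once by the origin of the proximal half and
once by the distal half; the parental difference maps to whichever half's
genotype is significant alone, else `both` or `neither`.
`classifyChimeraRange` calls a chimera `outside` the parental range iff
the mean of its Euclidean distances to the two parents (on barcode-mean
series over common defined timepoints) exceeds the distance between the
parents, and also counts timepoints strictly outside the parental
interval. Barcode-mean series are used for the distances; a per-barcode
variant would be equally defensible but is not what the summary reports.

# Variant annotation

`pwmScan` scores every placement of a position probability matrix on both
strands as $\sum_j \log_2 p_\mathrm{motif}(b_j)/p_\mathrm{bg}(b_j)$
against a background with 36% GC ($p_A = p_T = 0.32$,
$p_C = p_G = 0.18$), floors negative best scores to zero (no better than
background), and treats ambiguous bases as background. Motif
probabilities receive a pseudocount of $10^{-3}$ before scoring — a plain
regularization, not a reproduction of any particular scanner's scheme.
`bindingChangeScore` extracts the best score for each allele's 30 bp
variant context and reports the maximum absolute difference across the
motif set (the absolute-difference convention; a signed delta is also
returned). `phastconsAnnotate` gives SNPs their site score and InDels the
mean of the two flanking sites plus any interior sites.
`scoreGroupAnova` is a one-way ANOVA of annotation scores across variant
groups (e.g. reporter-positive, reporter-negative, other intergenic).
Motifs are read from MEME minimal text format; conservation tracks from
bedGraph.

# The synthetic-data module

`simulateAseCounts` draws, per gene, a trajectory from a small parametric
family — four-parameter logistic in time for monotone profiles, a
difference of two logistics for peaks and troughs, constant for flat —
with the shift midpoint near timepoint 7 of 19, emulating the cluster
shapes of a glucose-depletion timecourse. Allele 2's curve is allele 1's
transformed by the gene's effect: `level` multiplies it by
$2^{\mathrm{magnitude}}$, `delay` shifts the midpoint by `magnitude`
timepoints, `rate` multiplies the slope, and `condition` scales the shift
amplitude by $2^{\mathrm{magnitude}}$. Effect direction is randomized per
gene so the two alleles are exchangeable in aggregate; without this, a
one-sided effect mix biases the joint normalization and shifts null genes
off $f = 0.5$. Counts are negative binomial with variance
$\mu + \alpha\mu^2$ ($\alpha = 0$ is Poisson), at a default depth of 600
total allele reads per gene per timepoint — 2–3 million allele reads per
timepoint spread over ~4700 genes — with per-timepoint library sizes drawn
lognormal (sdlog 0.2) around that depth. The default dispersion of 0.01
is a convention for the technical overdispersion of single libraries
measured along a timecourse, not a fit to any deposited dataset.

`simulateCreCounts` draws one lognormal DNA abundance per barcode, holds
it across samples up to counting noise, and sets the RNA mean to abundance
times the construct's expression at each timepoint. `simulateGenomeFixture`
writes a two-haplotype toy genome (alternating intergenic and CDS blocks,
TSS annotations, anchored SNPs and InDels at stated per-bp rates) for
region definition and library design. `simulateVariantBurden` inverts the
association model: ASE status is Bernoulli with log-odds $b_0 + b_1 x$,
for parameter-recovery tests. One root seed drives everything; child
streams are derived per generator from fixed labels, so adding a generator
never perturbs another's stream, and identical seeds give bit-identical
outputs.

What the generator does *not* emulate: read sequences and mapping bias,
aneuploidy, cell-to-cell expression noise, PCR jackpotting, or correlated
dispersion structure across genes. Passing tests therefore demonstrate the
statistical machinery under the stated count models, not robustness to
those artifacts.

# Numerical choices and problem sizes

Float output is serialized at 6 significant digits for reproducible
diffs. GFF3 is 1-based closed on disk; in memory all intervals are
`IRanges`/`GRanges` (1-based closed). The dynamics permutation default is
1000 draws; the validation audits use 10 replicates. The test suite runs
its calibration checks at 2000 genes and its full-scale validation at
4703 genes by 19 timepoints (the post-filter gene count the defaults
emulate), sizes
chosen so the whole suite completes in a few minutes on one CPU. The
k-means restart count (25) and the chimera alignment identity floor (0.5)
are package choices.
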