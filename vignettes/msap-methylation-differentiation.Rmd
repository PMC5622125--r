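---
title: "Quantifying DNA methylation differentiation from MSAP data"
author: "msapDiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DNA methylation differentiation from MSAP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapDiff)
```

# The measurement model

Methylation-Sensitive Amplified Polymorphism (MSAP) assays global DNA
methylation at hundreds of anonymous genomic loci by running an AFLP-style
fingerprint twice per sample, once with each member of the HpaII/MspI
isoschizomer pair (plus EcoRI).  Both enzymes recognize CCGG but differ in
sensitivity to cytosine methylation, so the pair of band presence/absence
calls at a locus encodes its methylation state:

| HpaII band | MspI band | Type | Interpretation |
|---|---|---|---|
| 1 | 1 | I   | unmethylated |
| 0 | 1 | II  | internal cytosine methylation |
| 1 | 0 | III | hemi-methylated outer cytosine |
| 0 | 0 | IV  | hypermethylated — or the target is absent |

`callMethylationTypes()` applies exactly this map; a cell is missing iff
either enzyme call is missing.  Type IV is scored as methylated downstream
even though the double-absence pattern is confounded with restriction-site
loss; this is the standard convention for the marker system and the main
caveat to keep in mind when interpreting results (all analyses here are
dominant-marker analyses, not single-nucleotide measurements).

## Locus classification

A locus is *methylation-susceptible* (MSL) when the proportion of
non-missing samples showing a methylation-indicative type (II, III or IV)
strictly exceeds `errorThreshold`; otherwise it is non-methylated (NML) and
carries no methylation signal.  Among MSL, cells are binarized
(methylated = II/III/IV, unmethylated = I), and a locus is retained as
*polymorphic* only when each binary state occurs in strictly more than
`errorThreshold` of its non-missing samples.  Using the same threshold on
both sides, rather than a single discordant sample, makes the polymorphism
call robust to scoring error; the threshold default (0.05) is aligned with
per-primer genotyping error rates typically measured from technical
replicate pairs (`estimateGenotypingError()` implements the standard
replicate-discordance estimate, pooling both enzymes and excluding missing
calls pairwise).  Both rules use strict inequalities, so at threshold 0.05 a
locus with exactly 5% discordant samples is rejected.

# Differentiation between groups

## Distances

On the binary matrix of polymorphic MSL, the squared distance between
samples $i$ and $j$ is the mismatch count rescaled for missing data,

$$d^2_{ij} = \frac{L}{L_{ij}} \, m_{ij},$$

with $L$ the locus count, $L_{ij}$ the loci observed in both samples and
$m_{ij}$ the number of opposite binary states among them.  With complete
data this is the squared Euclidean distance on 0/1 vectors, the standard
choice for AMOVA on dominant markers; the multiplicative rescaling keeps
distances comparable across pairs with different missingness.  A pair with
$L_{ij} = 0$ is an error, not a silent imputation.

## AMOVA and $\Phi_{ST}$

`amova()` partitions squared deviations in the classic single-level layout:

$$SSD_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \qquad
  SSD_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij},$$

with $SSD_{among}$ their difference.  Mean squares are $SSD/df$
($df_{among} = G-1$, $df_{within} = N-G$), and with
$n_0 = (N - \sum_g n_g^2/N)/(G-1)$ the variance components are
$\sigma^2_{within} = MSD_{within}$ and
$\sigma^2_{among} = (MSD_{among} - MSD_{within})/n_0$.  The differentiation
index is $\Phi_{ST} = \sigma^2_{among}/(\sigma^2_{among} +
\sigma^2_{within})$.  Negative among-group components are deliberately
retained rather than truncated at zero: they are legitimate outcomes of the
moment estimator under weak differentiation, and truncation would bias
$\Phi_{ST}$ upward (the two-group worked example in
`?varianceComponents` yields $-0.032$).

Significance is assessed by shuffling the sample-to-group assignment
(preserving group sizes) and recomputing $\Phi_{ST}$; only the within-group
sum changes under a permutation, which is what makes $10^4$–$10^6$
permutations cheap.  The p-value uses the $(1+b)/(1+B)$ estimator, so it is
never exactly zero — a run with $B = 10^6$ and no exceedances is reported
as $p < 10^{-6}$.  Ties between a permuted and the observed statistic are
counted as exceedances, with a $10^{-10}$ relative tolerance because
floating-point summation order differs between permutations.  The default is
$B = 10^4$ (adequate to resolve $p \approx 10^{-3}$); raise
`nPermutations` for publication-grade resolution.

## Ordination and per-locus tests

`runPcoa()` performs classical metric scaling of the squared-distance
matrix (double-centering of $-d^2/2$ followed by eigendecomposition, axes
scaled by the square root of their eigenvalues).  Axes with negative
eigenvalues — possible because missing-data rescaling can make the matrix
slightly non-Euclidean — are dropped with a message, and the per-axis
percentage of variance is computed over the positive eigenvalues only.

`locusFisherTests()` tests each polymorphic MSL with a two-sided exact test
on the $2 \times G$ table of methylated/unmethylated counts.  For $G > 2$
the exact p-value sums the probabilities, under fixed margins, of all
tables at most as probable as the observed one; at the per-locus sample
sizes this is always enumerable, and a seeded Monte-Carlo fallback engages
(and is reported) only when the enumeration budget is exceeded.  A locus
with a degenerate margin carries no information and gets $p = 1$ with a
note.  P-values are adjusted jointly across loci by Benjamini–Hochberg;
`intersectSignificant()` intersects significant sets across two
comparisons (e.g. the two directions of a temperature switch).

For display ordering, significant loci are clustered on the *four-state*
type matrix — not the binary one — using the categorical Gower distance
(fraction of samples whose types differ, missing cells excluded pairwise)
and UPGMA.  UPGMA is implemented with the unweighted (leaf-averaged)
update and a deterministic lexicographic tie-break on the smallest leaf
label per cluster, so the merge sequence is reproducible across platforms;
exact ties are common with categorical distances, and `hclust`'s behaviour
under ties is unspecified, which is why the package carries its own
implementation (average-linkage `hclust` is used as an independent
cross-check in the test suite on tie-free matrices).  Merge heights are
cophenetic distances; serialized trees (`writeNewick()`) use the
ultrametric convention of node heights equal to half the merge distance.

# Relative gene expression

Quantification cycles are first rescaled to the perfect-doubling scale with
the per-primer amplification efficiency $E \in (0,1]$:

$$Cq_E = Cq \cdot \frac{\log(1+E)}{\log 2}.$$

Normalization uses two validated reference genes; on the expression scale
the geometric mean of the references is the correct average, and because
expression is $2^{-Cq_E}$ this is implemented exactly as the arithmetic
mean of the corrected reference Cq values:
$\Delta Cq = Cq_E(\text{target}) - \tfrac12\,(Cq_E(ref_1) + Cq_E(ref_2))$.

For a (treatment, control) pair,
$\Delta\Delta Cq = \overline{\Delta Cq}_t - \overline{\Delta Cq}_c$, the
log2 fold change is $-\Delta\Delta Cq$ and the fold change $2^{-\Delta\Delta
Cq}$.  The standard error combines the group standard errors in quadrature,
$SE = \sqrt{SE_t^2 + SE_c^2}$ (standard propagation of error).  The
confidence interval multiplies this SE by a Student-$t$ quantile with
Welch–Satterthwaite degrees of freedom rather than a normal quantile: at
the $n = 4$ replicates typical of qPCR designs a $z$-interval with an
estimated SE covers the truth only ~90% of the time, while the $t$-interval
is calibrated (the two coincide as $n$ grows).  This calibration is
verified by simulation in the test suite.

Group means are compared by a two-tailed Student $t$-test on the
$\Delta Cq$ values (pooled variance; Welch available via `varEqual =
FALSE`).  Shapiro–Wilk normality and Levene homoscedasticity checks are
evaluated and reported per comparison, but they gate nothing: the test is
reported unchanged, and the gate columns let the analyst judge.  FDR across
all comparisons reported together is controlled with Storey q-values:
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda = 0.05, \dots, 0.95$, cubic smoothing spline (3 df) evaluated at
$\lambda = 0.95$, clamped into $[1/m, 1]$ (a non-positive smoother estimate
can only arise when essentially every p-value is tiny, in which case at
most one test can plausibly be null), and
$q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \mathrm{rank}(p_j)$.
Forcing $\pi_0 = 1$ reproduces Benjamini–Hochberg exactly, which the tests
assert.  The `qvalue` smoother estimator is reimplemented here because the
whole q-value computation is a handful of lines and the package keeps its
multiple-testing arithmetic fully transparent.

Morphometric (weight/length) group differences use rank tests:
Kruskal–Wallis with tie correction for 3+ groups, two-sided Wilcoxon
rank-sum for two; with all observations tied the Kruskal–Wallis statistic
is defined as 0.

# The synthetic-data generator

`simulateMsap()` emulates the statistical structure of a multi-group MSAP
study, not its raw electropherograms: per-locus probability vectors over
types I–IV, group-specific shifts at a controlled fraction of loci,
independent per-band scoring errors and missing calls.  Defaults mirror a
three-group larval design — group sizes 21/15/12 and 300 loci, matching the
scale of the experiments this package was built to reanalyze — with 2%
per-band flip error and 2% missing calls, values in the range reported for
replicate-based genotyping error in AFLP/MSAP work.  Baseline state
probabilities are a free parameter of the method (field studies rarely
report per-locus state spectra); the default Dirichlet sampler with shape
$(5, 2, 1.5, 1.5)$ gives on average half the bands unmethylated with
realistic locus-to-locus heterogeneity, and any fixed vector, matrix or
sampler function can be substituted.

Differentiation is injected by moving `effectSize` total-variation mass at
the selected loci from type I toward types II/III/IV (proportionally to
their baseline mass) in every non-reference group — modelling an
environmental exposure that shifts loci between methylation states.  Flip
errors apply independently to each of the two enzyme-presence calls,
matching how genotyping error is actually measured (per primer and band).
One pooled larval sample is one statistical unit, as a pool is one
biological replicate.

`simulateQpcr()` writes Cq values as
$(baseCq - \text{log2FC} \cdot \mathbb{1}[\text{treatment}] +
\varepsilon)/\log_2(1+E)$ with $\varepsilon \sim N(0, \sigma)$: the
parameters are specified on the efficiency-corrected scale and then mapped
to the instrument scale, so downstream correction recovers the configured
truth at *every* efficiency, not only at $E = 1$ (at $E = 1$ the two scales
coincide).  Reference genes have true fold change 0 by construction.

What the simulators do **not** emulate — fragment sizes and binning,
comigration of distinct fragments, primer-specific band intensity,
locus-locus linkage, inter-batch (egg-batch) variation, and qPCR technical
replicate structure below the biological replicate.  Passing the recovery
tests therefore demonstrates that the statistical machinery is correct
under the declared generative model; it does not validate upstream
fragment scoring on real traces.

## What the validation studies run

The test suite and the acceptance script re-derive every stage from
scratch at desk scale, sizes chosen so the full suite completes in about a
minute: exhaustive AMOVA oracles at $N \le 8$ with complete permutation
enumeration; a 500-replicate null study (3 groups of 8, 60 loci, 999
permutations) whose rejection rate at $\alpha = 0.05$ must sit inside the
exact binomial 99% interval and whose p-values must pass a
Kolmogorov–Smirnov uniformity check; a 100-replicate-per-level dose
response showing mean $\Phi_{ST}$ strictly increasing in the differentiated
fraction (0, 0.2, 0.5); and a 500-replicate qPCR coverage study at
$\sigma = 0.3$, $n = 4$.

# Numerical and design notes

- All seeded APIs save and restore the caller's RNG state; every stage of
  a pipeline run derives its own stream from the single config seed, so
  reruns are byte-identical.
- Exact ties in UPGMA and in the permutation exceedance count are resolved
  by explicit rules (lexicographic; tolerance-counted) rather than left to
  floating-point accident.
- The exact r-by-c test can return $1 + \epsilon$ from its network
  algorithm; p-values are clamped into $[0, 1]$.
- A locus with all cells missing is excluded and reported, never imputed.
- Comparisons in a multi-round analysis are classified independently
  (polymorphic-MSL sets legitimately differ between rounds); group
  membership always comes from the input, never from assumptions about the
  design.

# Limitations

MSAP interrogates only CCGG sites reachable by the primer scheme, and a
dominant marker cannot distinguish homozygous absence from hypermethylation
(type IV).  $\Phi_{ST}$ summarizes differentiation of the methylation
profile as a whole; it says nothing about which genomic features moved.
The q-value smoother is unstable for very small batches of p-values; for a
handful of comparisons the BH-equivalent $\pi_0 = 1$ setting is the honest
choice.
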