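---
title: "Methods: network-based stratification of tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based stratification of tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(netstrat)
```

netstrat implements a network-based stratification workflow for small
clinical transcriptomic cohorts, anchored to a large reference cohort. This
vignette is the package's account of the underlying models, the parameters
that matter, the numerical choices made where the method leaves room, and
what the synthetic-data tests do and do not establish.

## The reference co-expression model

The workflow assumes a reference cohort large enough to estimate gene-gene
co-expression reliably (the intended scale is on the order of 150 samples
over the 2000 most variable genes, log2 scale). The network is *signed
hybrid*: pairwise biweight midcorrelations (`bicor()`, the robust 9-MAD
Tukey-weighted correlation, with a Pearson fallback for zero-MAD margins)
are truncated at zero and raised to a soft-threshold power,

a_ij = max(bicor_ij, 0)^beta,   beta = 5 by default,

so that only positively co-expressed genes are connected and weak
correlations are suppressed smoothly rather than by a hard cutoff. Gene
similarity for clustering is topological overlap,

TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij),

which rewards shared neighborhoods over single edges; modules are branches
of an average-linkage tree on 1 - TOM.

### Branch cutting

`detect_modules()` implements a deliberately simplified dynamic hybrid cut
rather than a port of the full published heuristic, whose many corner cases
are under-documented. The simplification has three deterministic stages:

1. a static cut at `cut_height` (default 0.995) defines coarse branches;
2. each branch is recursively split at a subtree root when both children
   can host a module (`min_size`, default 30) and the root merge height
   stands clear of its children's internal heights by a relative gap of
   `0.25 - 0.05 * deep_split` (so `deep_split = 2`, the default, requires a
   15% gap; larger values split more aggressively);
3. clusters below `min_size` dissolve to label 0, and an optional PAM-like
   stage reassigns unlabeled genes to the module with the smallest average
   dissimilarity when that average is below `cut_height`.

Module ids are contiguous integers ordered by decreasing size (ties broken
by the lexicographically smallest member gene), with 0 meaning unassigned;
colors are considered presentation, not data. The procedure is
permutation-equivariant in gene order and fully deterministic.

### Module validation

Two gates assess whether a module is more than a clustering artifact.
*Topological significance* compares density-based statistics of the module
subnetwork (weighted density and mean adjacency — which coincide for a
zero-diagonal network; both are reported for transparency, so the gate is
effectively a density Z-score) against 100 equally sized gene sets drawn
without replacement from the analysis universe, and requires a median
Z-score of at least 2. Under the null the Z is approximately standard
normal, so random gene sets pass rarely (about 2% of the time), while
planted modules at the default study conditions pass with Z in the tens.
*Stability* (`module_stability()`) repeats the full detection on 50 random
subsamples of 63.2% of samples and scores each reference module by its mean
best-Jaccard overlap across iterations; values near 1 indicate the module
does not depend on particular samples. Stability is exposed as a separate
step (not run inside `run_reference_build()`) because it multiplies the
cost of detection by the iteration count; the tests exercise it on small
cohorts.

## Eigengenes, projection, and harmonization

A module's *eigengene* is the first principal component of its standardized
(per-gene centered/scaled) expression; the per-sample PC1 score is the
module's one-number summary. Signs of singular vectors are arbitrary, so
PC1 is oriented to correlate non-negatively with the module's mean
standardized expression — a convention invariant to the decomposition's
internal sign choices. *kME*, the Pearson correlation of each gene with the
eigengene scores, measures module membership; constant genes get an
explicit `NA` rather than a silent zero.

A new cohort is made comparable by *reference-moment matching*
(`reference_batch_correct()`): each shared gene is location/scale
transformed so its cohort mean and SD equal the reference's. This
intentionally replaces empirical-Bayes batch shrinkage: with a single
target batch corrected toward a fixed reference, the shrinkage step mainly
matters for very small batches, and exact moment matching makes the
"reference batch unchanged" semantics literal. Output carries a
`harmonization` attribute naming the method so results are labeled as
moment-matched, not ComBat-corrected. Projection (`project_scores()`) then
standardizes each model gene by the *reference* mean/SD and multiplies into
the stored eigenvectors — no refitting, so a cohort of any size (even a
single sample) is scored on the reference axes. Projection is affine and
reproduces the reference's own scores exactly; genes missing from a cohort
are a hard error because a partial basis silently changes the score scale.

## Signatures and single-sample scoring

Modules are distilled into portable gene sets by kME: a threshold set
(kME > 0.9 by default) and a small top-n set (n = 3), plus a single
hub-gene "signature" realized as a mean score over a singleton set. Samples
are scored by an unnormalized single-sample enrichment walk: genes ranked
by expression per sample (descending, average ties), in-set steps weighted
by rank^0.25, out-of-set steps uniform, score = sum of the running
difference. The exponent is a config default, not a claim about the
original analysis, which does not state it. Because the statistic is
rank-based it is invariant to any strictly monotone per-sample transform.
Two numerical caveats are documented deliberately: at a positive exponent
the null mean of the raw score is slightly positive (the weighting
concentrates in-set mass at the top of the list); it is exactly zero in the
uniform-weight limit, and the tests check both facts. No cross-sample
rescaling is applied, matching the stated "no normalization" behavior.

`gsva_score()` provides the kernel-CDF variant used for immune cell-type
panels: per gene, a Gaussian-kernel cumulative density across samples
(bandwidth = population SD / 4; the population SD makes scores exactly
invariant to duplicating the cohort), then a per-sample
Kolmogorov-Smirnov-like walk with symmetric rank weights, scored as the
signed sum of the maximum and minimum deviations (`mx_diff = TRUE`). Note
the statistic is cross-sample *relative*: a gene set cannot be "high" in
every sample, and scores should be read as contrasts within the cohort.

Over-representation of modules in external collections uses the
hypergeometric upper tail within the stated universe with
Benjamini-Yekutieli adjustment (the conservative choice used for the
hallmark-style collections); differential tables elsewhere use
Benjamini-Hochberg.

## Response classification

`fit_threshold_classifier()` realizes a depth-1 conditional-inference tree:
a permutation test on the linear statistic sum(score_i * label_i) gates
splitting at alpha = 0.05 (exact enumeration of label assignments when
n <= 12, Monte-Carlo otherwise, seeded); if it passes, the cutoff maximizes
the standardized two-sample statistic over midpoints that leave at least
`min_leaf = 3` samples per side. A gate failure returns a majority-class
model flagged degenerate — never a spurious split. Ties at the cutoff
predict the "<= cutoff" side, a fixed convention for cross-platform
determinism. Metrics report MCC and F1 as explicit N/A (not 0) whenever a
confusion-matrix marginal vanishes, mirroring how degenerate single-class
predictors should be reported.

Subtype calls are nearest-centroid by Spearman correlation over the
centroid gene list (average ranks for ties, a documented assumption), with
calls closer than 0.1 between the top two centroids declared INDETERMINATE.
The rescue rule resolves indeterminates with a response classifier:
predicted non-responders get the poor-prognosis subtype, predicted
responders the good-prognosis one, with provenance recorded per call. One
subtlety: under Spearman the "exact midpoint of two centroids" with margin
0 is the midpoint of the *rank* profiles, not of the raw values; tests
plant indeterminates accordingly.

## Patient-specific networks

Each module is decomposed into per-sample networks by linear interpolation
against the reference: with e(S) the edge function over sample set S and N
the reference size, edges(q) = (N + 1) e(reference + q) - N e(reference).
The default edge function is the same biweight midcorrelation as the
reference network, for internal consistency; plain Pearson is available by
flag since the interpolation is conventionally stated for product-moment
correlation, and any symmetric matrix-valued function can be passed (the
tests exploit a linear aggregate, for which the interpolation returns the
held-in sample's contribution exactly). The leave-in term uses weight
N + 1; both N and the conversion constants are recorded in provenance
because the interpolation is not scale-free in N.

Signed interpolated edges become standard adjacencies by removing negative
edges and dividing by the maximum positive weight — a per-network scaling
(an alternative global clip is deliberately not the default, and the
constant is stored so either can be reconstructed). Gene-level wiring
statistics are connectivity (row sum), the maximum adjacency ratio
(sum of squared adjacencies over connectivity), and the weighted clustering
coefficient; whole-network summaries are density, centralization and
heterogeneity (population-SD coefficient of variation of connectivity).
Undefined values (isolated genes, zero denominators) propagate as explicit
flags, never as zeros, because zeros would bias differential wiring tests.

## Differential testing and sectors

Expression and network features are tested with an empirical-Bayes
moderated t: residual variances shrink toward a common or abundance-trend
prior with prior degrees of freedom estimated by moment matching on log
variances (trigamma inversion by Newton iteration); `prior_df = 0` recovers
the ordinary t exactly, and the estimated version is cross-checked against
the established empirical-Bayes implementation in the test suite. TMM
factors follow the standard trimmed-mean-of-M construction (30%/5% trims,
precision weights, geometric-mean-1 scaling) with the highest-depth library
as the default reference; note that a sample with a subset of genes shifted
up receives a factor *below* 1 under the effective-library convention.
Paired biopsy contrasts subtract within patient (Bx2 - Bx1) and test the
deltas.

Sector plots place each gene at (t_expression, t_wiring) and partition the
plane into six wedges: sectors 2 and 5 within 30 degrees of the positive
and negative wiring axes (wiring-dominant, sign-of-expression invariant),
flanked by mixed sectors 1/3 and 4/6. The wedge construction is a
reconstruction — the boundary angle is a config parameter, ties go to the
lower-numbered sector, and the origin is unassigned.

## Repertoire diversity

Clonotype tables (sample, clonotype, chain, isotype, reads) are summarized
per sample and class by Shannon entropy (nats), evenness (entropy / ln of
the clonotype count, undefined below two clonotypes), D50 (fewest top
clones holding half the reads), the Gini coefficient, and Gini-Simpson
(1 - sum p^2). The source analysis names a "Gini-Shannon" measure it never
defines; the package ships Gini-Simpson under its own name
(`gini_simpson`) and makes no fidelity claim for the undefined measure.
Depth confounding is handled by downsampling reads without replacement
(reads are a finite multiset, so the draw is multivariate hypergeometric)
with per-metric medians over 5 repetitions; shipped per-biopsy depths are
8500 (Bx1) and 400 (Bx2), and samples below depth are excluded rather than
padded, since treating shallow samples as high-evenness would manufacture
group differences.

## The synthetic study conditions

The generator implements the minimal model under which everything above is
well-defined and recoverable: per-module latent factors f ~ N(0,1), module
genes x = mu + lambda f + eps with lambda ~ U(0.5, 1.5) and eps ~ N(0,
0.5^2) on the log2 scale, background genes pure noise. These defaults were
calibrated once to the landscape the method expects: 150 samples x 2000
genes with modules of 469/323/190/48/42 genes, and true kME values spanning
roughly 0.7-0.95 with a minority of genes above 0.9 (so kME-threshold
signatures are non-trivial). The clinical cohort has 13 patients (8
responders, 5 progressors, a 61.5% majority rate) whose response labels
derive from the response module's latent factor with a gap of `effect = 2`
straddling the threshold; Bx2 factors correlate 0.8 within patient (a knob,
not an asserted value — the within-patient correlation of the real design
is uncharacterized) plus an additive on-treatment shift; both biopsies pass
through a gene-wise batch perturbation so harmonization is exercised.
Clonotype tables draw clone sizes from a discrete power law (exponent 1.5)
with totals scaling 2^factor, so abundance tracks the response module.

What passing tests show: the estimators recover the structure this linear
model plants, at these sizes and noise levels, and the machinery is
internally consistent against brute-force oracles. What they do not show:
robustness to the ways real tumors deviate — non-Gaussian expression,
overlapping modules, confounded batches, tissue composition, or
repertoire assembly artifacts. Headline accuracies on the synthetic cohort
(typically 100% at effect 2 with no label noise) characterize the planted
signal, not expected clinical performance.

## Problem sizes and determinism

Default problem sizes were chosen so a full reference build (2000 genes,
150 samples, 100-draw significance null) completes in seconds and the
demonstration pipeline (`run_demo()`, two biopsies x 13 patients, three
modules of interest, 78 patient networks, clonotype panel) in about a
minute on one core. Every stochastic step — generators, permutation tests,
subsampling, downsampling, significance nulls — flows from a named integer
seed through a local RNG that restores the caller's state, and reruns with
the same seed produce byte-identical artifacts.
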