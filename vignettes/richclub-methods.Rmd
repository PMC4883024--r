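---
title: "Methods: weighted rich-club analysis of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted rich-club analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(richclubnet)
```

## Data model

A subject is three symmetric, nonnegative 68 × 68 matrices over the
Desikan–Killiany cortical parcellation — fiber density (streamline-count
based, arbitrary count-like units), mean FA (dimensionless, in [0, 1])
and mean MD (mm²/s-scaled) along the connecting tracts — plus covariates
(age in years, sex, total brain volume in mm³, diagnostic group, MMSE).
Three invariants are enforced at construction:

* an edge exists iff its weight is strictly positive; no minimum-weight
  threshold is applied (tract-level filtering is assumed upstream);
* FA and MD can only be nonzero where fiber density is nonzero — a tract
  property is undefined without a tract;
* matrices are symmetrized by averaging when the asymmetry is within
  `1e-8` (tractography matrices are symmetric by construction; anything
  larger is treated as a corrupted input and rejected).

Node order is canonical — 34 left-hemisphere labels then 34
right-hemisphere labels, alphabetical within hemisphere — so edge indices
are reproducible across datasets. A cohort's *edge support* is the set of
node pairs connected in at least one subject; pairs never connected in
anyone are excluded from all edgewise inference, since a test on an
all-zero column is meaningless.

## The weighted rich club

The degree `k` of a node counts its distinct connections. At each level
`k`, `weighted_rich_club()` takes the subnetwork of nodes with degree
strictly greater than `k` (the strict inequality is deliberate and
matches the standard definition), sums the weights of the edges inside
it, and divides by the sum of the equally many strongest weights found
anywhere in the network. The coefficient is therefore in [0, 1],
scale-invariant under global weight rescaling, and *undefined* — carried
as `NA`, never as 0 — when the subnetwork has no edges. MD curves use
the identical formula with no inversion; the interpretation of a lower
MD-weighted coefficient is left to reporting.

**Null model.** The observed coefficient reflects both topology and the
placement of strong weights, so it is normalized by its mean over random
networks that preserve exactly the degree sequence *and* the weight
multiset: Maslov–Sneppen double-edge swaps on the binary support (10 × E
attempted swaps per replicate, delegated to `igraph::rewire()`), followed
by a random permutation of the original weights onto the rewired edges.
This is the convention of the weighted rich-club literature; both
conserved quantities are asserted exactly in the test suite. The
normalization uses the null *mean* (not median), with undefined entries
excluded pairwise, because the normalized coefficient is defined as a
ratio of coefficients. 500 replicates is the conventional default;
`n_random = 100` already gives a stable mean for 68-node networks and is
what the validation scripts use. Networks with fewer than two edges
cannot be rewired; they fall back to a weight-reshuffled copy with a
warning.

`k_max` defaults to 30 because with ~36% edge density the degree
distribution of a 68-node network rarely supports defined coefficients
much beyond that, and reported rich-club regimes for this resolution live
at k ≈ 4–30. Curves can be computed per subject (the default used for
statistics, keeping inference subject-level) or on a group-average
network for display; both are supported.

## Rich-club membership and the edge taxonomy

The rich-club *regime* (k > 15) and the rich-club *membership* are
different objects. Membership selection mixes, in published practice,
a degree criterion, a "top fraction of most consistently interconnected
nodes" target, and ad-hoc bilateral completions. `select_rich_nodes()`
implements this as an auditable cascade: group-mean fiber-density degree
≥ `degree_floor` (default 30) in *every* diagnostic group, bilateral
symmetrization (a qualifying region pulls in its homologue), and
explicit force-include overrides; the rule is stored with the result.
Because the exact published ranking procedure is not fully specified, the
previously reported membership of 13 bilateral regions (26 nodes) also
ships verbatim (`rich_club_regions()`), and is the pipeline default —
downstream stages can then be run exactly as published rather than on a
guessed reconstruction. Selection always uses fiber-density degrees; FA
and MD analyses reuse the same membership.

Edges are classed by endpoint membership — rich-club / feeder / local —
a partition of the support that depends only on topology, never on
weights. Per-subject class counts feed the group means that serve as
expected totals in the enrichment tests.

## Inference

* **Residualization.** Measures are residualized once on intercept +
  age + sex (0/1, M = 1; the coding affects nothing two-sided) + brain
  volume by OLS, pooled over the compared subjects; rank-deficient
  designs fail naming the collinear column. Labels are then permuted on
  the residuals (the simple permutation-of-residuals scheme; a
  Freedman–Lane refinement would permute residuals under the reduced
  model, but the simpler scheme is the one being reproduced and its
  type-I calibration is verified directly).
* **Permutation test.** Two-sided via statistic magnitudes, strict
  inequality for the exceedance count, P = (b+1)/(m+1), so the smallest
  attainable p is 1/(m+1) (1e-4 at the default m = 10,000). For itemwise
  (edge/node) families one permutation sequence is shared across items,
  which keeps the joint permutation distribution available. |t| is a
  monotone function of |cor| for a single regressor, so the engine counts
  exceedances on correlations computed by one matrix product; an epsilon
  of 1e-12 guards floating-point ties (the identity permutation must not
  count as an exceedance).
* **FDR.** Benjamini–Hochberg step-up at q = 0.05, applied per contrast
  per weight kind (not pooled across kinds), and across k within each
  weight kind for curve comparisons. Decisions are computed via
  `p.adjust(. , "BH")`, which is algebraically the step-up rule; the
  reported "FDR critical p" is the largest rejected p-value.
* **Chi-squared enrichment.** Pearson's test without continuity
  correction on the 2 × C affected/unaffected table — validated by exact
  reproduction of the published p-values from published counts (one of
  which, 0.013, turns out to be a truncation of 0.0135). Expected class
  totals are the disease group's mean per-subject class counts rounded
  to the nearest integer. Zero-total classes are dropped with a warning,
  reducing df. Degenerate measures (zero residual variance) yield p = 1
  with a warning rather than an error, since all-zero edges legitimately
  occur in contrast subsets.
* **MMSE.** Associations with cognition additionally covary for disease
  status (group indicators in the residualization design) and permute
  the MMSE values; subjects missing MMSE are dropped, with at least 80%
  coverage required.

One published inconsistency is deliberately not "corrected": for the
bvFTD-vs-EOAD fiber-density comparison the printed local-vs-rich and
local-vs-feeder p-values (0.016, 0.1) are swapped relative to what the
printed counts imply (0.108, 0.017). The implementation reports whatever
the counts give.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions; `generate_cohort()` is
bit-reproducible from its seed and emits exact ground truth (planted
core, lesioned edge list) for scoring.

* **Topology.** Node propensities θᵢ are drawn from the truncated power
  law s^(α−1)·e^(−s/s_c) (a Gamma(α = 1.2, scale = 12) draw — fat-tailed
  with an exponential cutoff, the documented shape of cortical strength
  distributions), the 26 largest assigned to the planted core. Edges
  appear with probability 1 − e^(−λθᵢθⱼ), λ calibrated by root-finding
  to the target density (0.36, ≈ 820 of 2278 pairs, typical of 68-node
  tractography networks); core-core pairs are present with probability
  one.
* **Weights.** Fiber density ∝ √(θᵢθⱼ) with log-normal scatter, core
  edges boosted ×2 (the heavy-weight club), normalized to unit mean. FA
  is a logistic squash of standardized log fiber density into
  (0.2, 0.8) — strong tracts are more anisotropic; MD falls linearly
  with FA around 9 × 10⁻⁴ mm²/s, giving the anticorrelation expected in
  white matter. All three kinds share one support.
* **Individuals.** Subjects apply multiplicative log-normal noise
  (σ = 0.15, i.e. ~15% edgewise variability) per weight kind,
  age/sex/volume effects on fiber density (−1%/year, +5% male, √volume
  scaling), and 5% dropout of non-core edges so supports differ across
  subjects. Group sizes default to 37/20/23 (control/bvFTD/EOAD); ages
  ~N(59.4, 9.6), N(60.7, 10.7), N(59.0, 5.0) per group.
* **Disease.** Lesions multiply class-restricted edge weights *before*
  noise, so the effect is the population mean shift: EOAD scales 50% of
  rich-club edges (fiber ×0.8, FA ×0.95, MD ×1.1); bvFTD scales 50% of
  feeder+local edges (fiber ×0.75, FA ×0.9, MD ×1.1) — FA down, MD up,
  as in degeneration. MMSE is drawn at
  29.1 − 10·√burden with sd 0.9 + 5.5·√burden (burden = mean over
  lesions of fraction × Σ|log₂ effect|), clamped to [0, 30]; this puts
  patient means near 23–24 against 29.1 ± 0.9 in controls.

**What the generator does not emulate.** Lesions rescale weights but do
not delete edges, so group differences in edge count E and nodal degree
are *not* planted (only dropout noise differentiates supports);
distance-dependent connection probabilities, hemispheric asymmetries,
scanner/site effects and tractography bias are absent; and the planted
core is complete, making the synthetic class totals (≈ 325 rich-club
edges) more core-heavy than typical measured networks (≈ 179). Passing
recovery tests therefore demonstrates that the statistical machinery
detects the structure it models — not that real acquisitions carry that
structure.

## Validation design and problem sizes

The suite cross-checks every stage against an independent route: the
rich-club coefficient against naive-loop brute force (exhaustively for
all supports on ≤ 4 nodes, randomized sweeps on 5–8 nodes); permutation
p-values against exhaustive enumeration at n ≤ 8; BH decisions against
an O(n²) threshold search on 1000 random p-vectors; the 2 × 2 chi-squared
against the two-proportion z-test and the df = 2 tail against its closed
form e^(−χ²/2). Calibration runs use 2000 null simulations at m = 500
permutations (type-I error must land in [0.03, 0.07]) and 50 replicate
cohorts for lesion-class recovery; rich-club null bands use 100 random
networks. These sizes keep each validation block in the seconds-to-
minutes range while leaving Monte-Carlo error well inside the asserted
margins; the interactive defaults (m = 10,000, n_random = 500) remain
the published operating point. Fast unit tests run on a 16-node
miniature of the generator with identical structure.

## Limitations

Subject-level results from the original patient cohorts (e.g. which 53 nodes
were affected) are not reproducible without the original scans; what is
reproducible — and reproduced — are the count-level chi-squared
findings, the closed-form identities, and the behaviour of the method
under known synthetic truth. Directed or signed networks, subcortical
nodes, topological (unweighted) rich-club variants, network-based
statistic corrections and longitudinal models are out of scope.
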