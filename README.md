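# richclubnet

Weighted rich-club analysis of structural brain connectomes, with
permutation-based group inference and a calibrated synthetic-cohort
generator.

## The problem

Diffusion-MRI tractography summarizes a brain as a 68-node cortical
network (Desikan–Killiany parcellation, 34 regions per hemisphere) whose
edges carry three kinds of weight: fiber density, mean fractional
anisotropy (FA) and mean diffusivity (MD) along the connecting tracts. In
such networks a small set of high-degree hubs — the *rich club* — is more
densely interconnected than chance predicts, and neurodegenerative
diseases are hypothesized to target either this core (as reported for
early-onset Alzheimer's disease, EOAD) or the periphery around it (as in
behavioral-variant frontotemporal dementia, bvFTD).

`richclubnet` implements the full analysis chain used to test such
hypotheses:

1. **Weighted rich-club curves.** At each degree level *k*, with
   *E₍₎* the edges among nodes of degree > *k* and *W₍₎* their total
   weight,

   Φʷ(k) = W₍₎ / Σₗ₌₁^{E₍₎} wₗ^ranked,

   the ratio of *W₍₎* to the sum of the *E₍₎* strongest weights anywhere
   in the network. Φʷ is normalized by its mean over degree-preserving
   random networks (Maslov–Sneppen rewiring with the weight multiset
   permuted onto the rewired support): Φₙ(k) = Φʷ(k) / ⟨Φʷ_rand(k)⟩, and
   a rich club is present where Φₙ > 1.
2. **Edge taxonomy.** Given a rich-club node set, every edge is
   *rich-club* (both endpoints rich), *feeder* (one), or *local*
   (neither).
3. **Group inference.** Measures are residualized on age, sex and total
   brain volume; group differences are tested by label permutation
   (P = (b+1)/(m+1) with two-sided statistic magnitudes, m = 10,000 by
   default) with Benjamini–Hochberg FDR across items; the class
   distribution of altered edges or nodes is tested against the expected
   class totals by Pearson chi-squared.
4. **Synthetic cohorts.** A generator plants all of this structure —
   truncated power-law strengths, a complete heavy core, anticorrelated
   FA/MD, covariate effects, group-specific lesions with exact ground
   truth — so the whole pipeline is testable without patient data.

## Worked example

```r
library(richclubnet)

ch <- generate_cohort(cohort_spec(), seed = 11)
ch
#> <cohort> 80 subjects (bvFTD: 20, control: 37, EOAD: 23), 798 supported edges

rc <- rich_club_curve(ch$subjects[[1]]$matrices$fiber_density,
                      k_max = 30, n_random = 100, seed = 1)
rc
#> <rich_club_curve> weight kind: fiber_density, k = 1..30, 100 null networks
#>   Phi_n defined at k = 1..30; Phi_n > 1 at 29 of 30 levels

et <- edgewise_group_test(ch, "fiber_density", c("EOAD", "control"),
                          m = 500, seed = 5)
et
#> <edgewise_test> EOAD vs control on fiber_density: 175/798 edges
#> FDR-significant (critical P_perm = 0.00998)

en <- class_enrichment(et, ch, rich_node_set(rich_club_regions()))
en$affected
#> rich_club    feeder     local
#>       166         7         2
en$chi2
#> <chi2_test> X-squared = 259.5, df = 2, p = 4.5e-57
```

The planted EOAD lesion (rich-club fiber density scaled by 0.8) is
recovered: the altered edges concentrate overwhelmingly in the rich-club
class, exactly the enrichment signature the chi-squared test quantifies.
`run_pipeline()` chains every stage (global, curve-wise, nodal, edgewise
tests, enrichment, MMSE associations) and `write_report()` saves the
result tables with a reproducibility manifest.

Published affected/total counts per class ship with the package; feeding
them through the same test reproduces the published findings:

```r
counts <- subset(reported_class_counts(),
                 contrast == "EOAD_vs_control" & measure == "fiber_density")
chi2_proportions(setNames(counts$affected, counts$class), counts$total)
#> <chi2_test> X-squared = 29.74, df = 2, p = 3.49e-07
```

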