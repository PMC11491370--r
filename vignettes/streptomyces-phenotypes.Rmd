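---
title: "Quantifying soil Streptomyces phenotypes in a nested richness/fungicide design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying soil Streptomyces phenotypes in a nested richness/fungicide design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strepniche)
```

## The experiment this package models

`strepniche` analyses a hierarchical field survey of root-associated
*Streptomyces*: two plots differing in plant richness (a grass monoculture
and a 16-species polyculture), each containing a foliar-fungicide-treated
and an untreated subplot, with six plants sampled per subplot. That gives
2 × 2 × 6 = 24 composite soil samples. Isolates are cultured from two
plants per subplot, ten isolates per plant, for 80 isolates in total. The
fungicide factor exists only *within* a richness plot, so every analysis
treats fungicide as nested within richness.

Four assay families feed the analysis:

* **Resource use.** Each isolate is grown on a 95-carbon-source phenotype
  array plus a water control; well absorbance (AU590) after three days
  measures growth on each substrate.
* **Densities and inhibition.** Soil suspensions (5 g soil in 25 mL
  water) are dilution-plated; colonies are counted, then plates are
  overlaid with an indicator strain and colonies producing clearing zones
  are counted as inhibitory.
* **Antibiotic resistance.** Disk diffusion against nine clinical
  antibiotics; a zone is the mean of two right-angle radial measurements
  from the colony edge to the clearing edge, replicated twice.
* **Phylogeny.** A rooted tree over the isolates (built elsewhere from
  16S sequences and consumed here as newick).

## Resource-use metrics

Raw well absorbances are blank-corrected by subtracting the water-control
well; negative differences are clamped to zero, since negative growth is
unphysical and the overlap statistic below requires non-negative values.
A substrate is **used** when the corrected absorbance strictly exceeds
0.01 AU590 — so 0.011 is a use and 0.010 is not. The threshold is a
parameter of `resource_profiles()` for sensitivity analysis, but 0.01
with a strict inequality is the default everywhere.

For isolate $a$ with corrected absorbances $od_a(i)$:

* **niche width** — the number of used substrates (0–95);
* **growth efficiency** — the mean of $od_a(i)$ over used substrates,
  *undefined* (`NA`) when the width is zero: an empty mean is not 0, and
  coding it as 0 would bias group means downward;
* **niche overlap** of $a$ onto $b$ —

$$\bar\omega_{a \to b} \;=\; \frac{1}{n}\sum_{i \in U(a)}
  \frac{\min\!\big(od_a(i),\, od_b(i)\big)}{od_a(i)},$$

where $U(a)$ is $a$'s used-substrate set and $n = |U(a)|$. The statistic
is the fraction of $a$'s realised niche that $b$ matches; it is
asymmetric ($\bar\omega_{a\to b} \ne \bar\omega_{b\to a}$ in general),
lies in $[0,1]$ term-wise, and equals 1 for self-overlap.

**Design choice — the summation domain.** The defining sum could run over
all 95 substrates or only over $a$'s used set, and the all-95 convention
needs an extra $0/0 \to 0$ rule. We sum over $U(a)$ only: it avoids
division by zero without a special case, preserves the asymmetry, and
gives the self-overlap identity $\bar\omega_{a\to a} = 1$ exactly. Wells
where $od_a$ is positive but below the use threshold are likewise
excluded, keeping the overlap consistent with the use calls.

Overlap is summarised within the group of isolates from the same plant —
the scale at which co-occurring isolates actually compete — as the mean
over all ordered pairs of distinct isolates (`overlap_matrix()`), and per
isolate as the mean overlap onto its plant-mates (`isolate_overlap()`),
which is the response analysed against the treatments.

**Group substrate profiles.** For figure-style "proportion of total
resource use" summaries, each isolate's absorbances are first normalised
to shares summing to 1, then shares are averaged across the group and
reported with the standard error of that mean. Normalising per isolate
before averaging weights isolates equally; pooling absorbances first
would weight fast growers more. Both are defensible, so
`group_substrate_profile(per_isolate = FALSE)` exposes the pooled
variant; per-isolate normalisation is the default.

## Densities, inhibition, resistance

Plate counts convert to CFU per gram of dry soil by standard plate-count
arithmetic,

$$\mathrm{CFU/g} = \frac{\text{count}}{\text{plated volume} \times
\text{dilution}} \times \frac{\text{suspension volume}}{\text{soil mass}},$$

with the 5 g / 25 mL suspension as the configurable default
(`suspension_spec()`). Every plate is converted *before* averaging so
mixed dilutions are handled correctly. The inhibitory proportion is the
inhibitor density over the total density, computed per indicator overlay
and also averaged over overlays — the two views answer slightly different
questions, so both are emitted. Because overlay counts and density counts
come from separate plate sets, sampling noise can push the ratio above 1;
such values are reported with a warning rather than clipped, so the
anomaly stays visible. Zone sizes are radii, never diameters, matching
how both assays are measured.

## Phylogenetic comparison

* `faith_pd()` sums the branch lengths of the minimal subtree spanning a
  tip set. The path to the root is **included by default**, matching the
  common default of community-phylogenetics software; since the choice is
  a convention, `include_root = FALSE` is available. Trees must arrive
  rooted — an unrooted tree is rejected rather than midpoint-rooted
  silently, precisely because this root dependence would otherwise be
  decided behind the user's back.
* `unweighted_unifrac()` is the presence/absence UniFrac: the branch
  length leading to tips of exactly one community divided by the branch
  length leading to tips of either. Each treatment cell's (or plant's)
  isolate set is one community.
* `permanova()` partitions the squared-distance matrix among sequential
  model terms via the Gower-centred inner-product matrix, forms a
  pseudo-F per term against the residual, and permutes observation
  labels. The p-value uses the add-one convention
  $(1 + \#\{F^* \ge F\})/(1 + N)$, so the smallest attainable p with 999
  permutations is 0.001. Labels are permuted freely by default; a
  `strata` argument restricts permutation to within richness plots for
  the nested term, since the right scheme for a split-plot layout is
  debatable and the free scheme is the common default. Numerical ties
  ($F^* = F$ up to rounding) count as exceedances, and a permutation with
  a residual sum of squares at rounding-noise scale gets an infinite
  pseudo-F when its term carries signal — otherwise the most-separated
  partitions would be dropped by sign noise.

The sample-level PERMANOVA input is the UniFrac matrix between the eight
plant communities (10 isolates each), with richness and
fungicide-within-richness as terms.

## Statistical layer

* `nested_anova()` fits `y ~ richness + richness:fungicide` with
  sequential (Type I) sums of squares — the classical nested
  decomposition, which for this ordering equals the group-mean projection
  arithmetic even in unbalanced data. Both terms are tested against the
  residual mean square, treating plants (or isolates) within subplots as
  replicates. With only one plot per richness level this inference is
  conditional on the plots themselves — a pseudo-replication caveat that
  belongs with any interpretation of the richness term; the package
  documents it rather than "fixing" it, since no within-study remedy
  exists. Terms whose sum of squares is at rounding-noise scale report
  F = 0, p = 1.
* `tukey_hsd()` uses the studentized range (Tukey–Kramer under unequal
  n) for all pairwise comparisons, and assigns compact letters by the
  insert-and-absorb algorithm: two groups share a letter exactly when
  they are not significantly different at the chosen level; ties are
  broken by first appearance order.
* `fdr_adjust()` is step-up Benjamini–Hochberg, or Benjamini–Yekutieli
  with the harmonic-sum factor (never smaller than BH).
* `per_substrate_tests()` runs, for each of the 95 substrates, a
  fungicide contrast within each richness level, a richness contrast, and
  the nested ANOVA, adjusting each family across substrates. The
  pairwise contrast is Welch's unequal-variance t test by default — the
  most defensible default when group variances are not known to be equal
  — with Student and Mann–Whitney variants exposed because the choice
  changes the pre-correction discovery count. Substrates with zero
  variance in a family are excluded from that family with a message and
  carry `NA`.
* `correlate_nutrients()` computes Pearson $R^2$ with its two-sided
  t-transform p-value between the per-sample density responses and each
  nutrient, within each richness plot (n = 12 samples per plot); the
  stratification column is a parameter because sample pairings across
  strata are a design decision, not a computation.

## The synthetic-data generator

`simulate_experiment()` draws a complete experiment from one seeded
stream, so every downstream stage is testable without the field data.
Its defaults *are* the study conditions: the 2 × 2 × 6 design, 80
isolates from 2 plants per subplot, three replicate plates per overlay
per sample (six per sample), nine antibiotics with two replicate disks,
and a 0.1 mL aliquot at a 10^-3^ dilution (chosen to put expected counts
in the 30–300 colony range of a countable plate).

Per-cell parameter magnitudes are realistic placeholders chosen once —
the field study reports no within-treatment distributions — with effect
*directions* following the field observations: polyculture soils richer
in C, N, P, K and organic matter; monoculture with a higher inhibitory
fraction, further raised under fungicide; niche width lowered by
fungicide in monoculture and raised in polyculture; larger
(more-susceptible) amoxicillin/erythromycin/chloramphenicol zones in
monoculture. Magnitudes are of the order of the field summaries without
claiming to match them.

Construction details that matter:

* **Use-call consistency.** A well generated as "used" gets absorbance
  `water + |N(mean, sd)| + threshold`, and an unused well gets noise
  truncated below the threshold, so the generated truth and
  `call_resource_use()` agree *exactly* on every well — width recovery is
  an identity, not an approximation.
* **Truncated normals** (inverse-CDF, no rejection loops) keep pH,
  percentages and radii inside their physical bounds.
* **Counts** are Poisson around the sample's latent density times the
  plating factor, with Binomial inhibitory subsets, so inhibitory counts
  can never exceed totals within a plate.
* **The tree** is grown by sequential attachment: each new tip splits the
  pendant edge of an existing tip, chosen from its own richness group
  with probability `tree_clustering` (default 0.8) and uniformly
  otherwise. This is deliberately not a birth–death model: the analysis
  only needs controllable clustering-by-group structure. Tips are
  inserted in a *randomised* order — inserting in design order would make
  early (repeatedly split) tips systematically deeper and leak block
  structure into the tree even with no clustering bias, which a
  permutation test then "detects". With random insertion order the labels
  are exchangeable under `tree_clustering = 0` by symmetry.
* `null_config()` equalises all cell parameters *and* sets
  `tree_clustering = 0`: the clustering bias is richness-linked
  structure, so a true null must remove it even though it is a global
  parameter.

What the generator does **not** emulate: spatial autocorrelation within
plots, seasonal drift, substrate–substrate correlation in resource use
(wells are independent Bernoulli given the width mean), measurement
drift between plates, and phylogenetic signal in phenotypes. Passing the
calibration tests therefore shows the *methods* are correct and
calibrated under the stated model, not that field data meet that model.

## Calibration and verification

The test suite checks, among other things:

* the worked overlap example $\bar\omega = 0.75$ and equality of the
  vectorised overlap matrix with a naive double loop (100 random
  instances, 10^-12^);
* Faith's PD and UniFrac against manual branch sums and against the
  independent `picante` implementations on 50 random trees (10^-9^);
* PERMANOVA's sums of squares against both a direct within/between
  partition and `vegan::adonis2`, uniformity of its null p (200 seeded
  replicates, KS at 0.01), and the 1/1000 permutation floor;
* nested-ANOVA sums of squares against the projection oracle, type-I
  error of both terms inside the binomial 99% interval of 0.05 over 400
  null replicates, and power ≥ 80% for the richness term when each cell
  deviates by one within-cell SD from the grand mean ("cell effect" here
  means that per-cell deviation, the standard ANOVA effect);
* BH step-up arithmetic against a naive O(m²) oracle, near-zero
  discoveries on null 95-substrate data, and recovery of a 7-substrate
  injected effect;
* byte-identical reruns of `run_simulate()` + `run_report()` under a
  fixed seed.

Replicate counts (200–400) keep every Monte-Carlo check inside a few
minutes on one CPU while leaving the binomial intervals tight enough to
be informative.

## A minimal session

```{r example, eval = FALSE}
library(strepniche)

run_simulate("experiment", seed = 1)
res <- run_report("experiment", "results", n_permutations = 999,
                  seed = 17)

res$permanova                      # richness / nested fungicide terms
head(res$isolates)                 # width, efficiency, overlap per isolate
subset(res$anova, response == "niche_width")
res$letters[res$letters$response == "niche_width", ]
```

## Known limitations

* One plot per richness level: the richness term's inference is
  conditional on those plots (see above).
* The overlap summation convention (used-set of $a$) is one of two
  defensible readings of the statistic's definition; results under the
  all-95 convention would differ for isolate pairs with small widths.
* Unweighted UniFrac and the free permutation scheme are defaults, not
  the only choices; weighted UniFrac and model-based alternatives are out
  of scope.
* The generator's independence assumptions (above) mean calibration
  results transfer to field data only insofar as those assumptions hold.
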