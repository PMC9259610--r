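---
title: "Partitioning N2O production in the plastisphere: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning N2O production in the plastisphere: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastiN2O)
library(dplyr)
```

## The scientific problem

Plastic debris in estuaries grows biofilms ("the plastisphere") whose
anoxic micro-niches favour denitrification, making them a candidate source
of the greenhouse gas N2O. Three processes can produce that N2O:
bacterial denitrification (BD), fungal denitrification (FD, whose agents
typically lack N2O reductase and so terminate at N2O), and abiotic
chemodenitrification (CD, e.g. Fe(II)-driven nitrite reduction). This
package quantifies their relative contributions from dual-isotope
measurements, and wraps the supporting quantitative stages — 15N isotope
pairing, acetylene blockage, qPCR, community ecology and single-cell Raman
microspectroscopy — so the full analysis runs end to end on data a seeded
generator can produce.

## The isotopocule mixing model

N2O is linear (N–N–O); the central (alpha) and terminal (beta) nitrogen
positions carry distinct delta-15N values. Two derived coordinates
diagnose sources:

* site preference, `SP = d15N_alpha - d15N_beta` (per mil), which is
  insensitive to the substrate's isotopic composition, and
* `d18O` on the N2O/H2O scale, obtained by subtracting ambient-water
  delta-18O (default 0.91 per mil for surface seawater, global span about
  -2.98 to 1) under the assumption of near-complete oxygen exchange with
  water during denitrification.

Each source occupies a characteristic region of this plane. The package's
defaults place the endmember points at BD (-1.5, 19), FD (37, 47) and
CD (16, 30), with literature ranges SP: BD -7.5 to 3.7, FD 27.2 to 39.9,
CD 10 to 22; d18O: BD 16.4 to 23.3, FD 42.0 to 55.1, CD 24.9 to 37.6 (all
per mil).

Partial reduction of N2O to N2 (by organisms that carry N2O reductase)
enriches the remaining N2O along a line of slope
`sp_epsilon / d18O_epsilon = (-6) / (-25) = 0.24` in this plane. Measured
values are therefore corrected back to pre-reduction ("NR") coordinates
with the linear form

```
SP_NR   = SP_measured   + f_R * sp_epsilon
d18O_NR = (d18O_measured - h2o_d18O) + f_R * d18O_epsilon
```

where `f_R` is the N2O reduction ratio, estimated experimentally as the
residual/total N2O concentration ratio of an acetylene-block pair
(`n2o_reduction_ratio()`; 0.75 with the default synthetic inputs). The
linear (first-order) form is used deliberately rather than a
Rayleigh/logarithmic form: it is how the correction enters the mixing
equations this package implements. Both corrections are pure shifts, so
their order is immaterial.

The corrected pair is then decomposed on the three endmembers by the exact
3-by-3 linear system

```
[ 1      1      1    ] [f_BD]   [ 1       ]
[ SP_BD  SP_FD  SP_CD] [f_FD] = [ SP_NR   ]
[ O_BD   O_FD   O_CD ] [f_CD]   [ d18O_NR ]
```

(`solve_fractions()`). When the corrected measurement falls outside the
endmember triangle the raw solution leaves the probability simplex; the
feasibility rule (`clip_fractions()`) zeroes negative components and
rescales the survivors proportionally so the fractions sum to one. A
least-squares re-solve of the two-endmember subsystem is a conceivable
alternative; the proportional rule is used because it is the transparent,
stated convention of this model family, and the `clipped` flag records
exactly when it fired.

## Uncertainty: Monte Carlo over endmembers, and why the point estimate is deterministic

Endmember signatures are literature ranges, not constants.
`monte_carlo_partition()` propagates that uncertainty by sampling each
endmember's SP and d18O independently from Gaussians centred on the point
values with SD = (range width)/4 (roughly 95% of mass inside the printed
range), re-solving and re-clipping per draw (10,000 draws by default), and
reporting per-source draw means, SDs, standard errors (SD/sqrt(n_draws))
and clip frequencies. SP and d18O are sampled independently because no
covariance information is available; measured sample values are held fixed
by default (endmember uncertainty dominates), with an optional
`measurement_sd` adding instrument noise (about 0.9 per mil per site
delta, 0.6 per mil for d18O).

One numerical property matters for interpretation: the endmember triangle
is thin (its three points are nearly collinear), so the inverse mixing map
is ill-conditioned. Perturbing endmembers by their literature spreads
produces raw fraction draws with very large dispersion, and per-draw
clipping then projects them back onto the simplex asymmetrically. The mean
of clipped draws is therefore a *biased* estimator of the generating
fractions — the bias is O(1) and does not vanish as draws increase — and
it systematically inflates the source whose raw fraction is most often
negative (typically CD). For this reason the package reports the
**deterministic clipped solution at the endmember point values** as the
point estimate, and uses the Monte Carlo layer only for dispersion (SE)
and clip diagnostics. This choice also reproduces the qualitative
behaviour expected of these systems (CD near zero rather than inflated to
a third of the total). The `tidy()` method exposes both quantities side by
side so users can see when they diverge; large divergence is itself a
warning that the measurement sits near or outside the endmember hull.

Whether clipping should be applied per draw or only to the summary is not
externally constrained; per-draw clipping is the default here because it
keeps every reported mean on the simplex.

## Isotope pairing, anammox and acetylene

With a nitrate pool enriched to 15N atom fraction `Fn` (0.99 by default),
true denitrification pairs two pool nitrogens, so its 30N2 production
implies a total rate `2*T30/Fn` — algebraically identical to the two-term
form `T30*2*(1-Fn)/Fn + 2*T30` (`denitrification_rate()`). Anammox pairs
one labelled with one ambient nitrogen and therefore produces only 29N2;
its rate is estimated as the 29N2 excess over the binomial expectation
`2*T30*(1-Fn)/Fn`, floored at zero and flagged when measurements fall
below that expectation (`denit_anammox_share()`). This excess convention
is the package's explicit choice of partition formula — it is the
standard revised isotope-pairing construction — since the split itself
admits no unique definition from 29/30N2 alone when codenitrification is
present. The `codenitrification_indicator()` (`t30/(t29+t30)`) makes the
qualitative check explicit: values near 1 mean the label emerged as 30N2,
i.e. genuine denitrification rather than codenitrification.

Cell-specific rates divide volumetric rates by cell numbers estimated as
absolute 16S rRNA gene copies / 4.1 (mean ribosomal operon copy number).
A CO2-equivalent multiplier is provided as configurable plumbing (default
298); it is not a package-specific estimate.

## qPCR transforms

Chip qPCR reports threshold cycles. Relative copy numbers use the
detection limit Ct = 31 as the unit anchor and a 100%-efficiency slope of
3.33 cycles per decade: `10^((31 - Ct)/3.33)`. Values above the limit
become explicit below-detection flags and propagate as `NA` — never as
imputed zeros, which would silently bias ratios. Normalisation divides by
the sample's 16S value, cancelling chip-level offsets (a property the
tests check directly). The (nirS+nirK)/nosZ ratio then indexes net N2O
production potential: nitrite reducers make N2O, nosZ carriers consume it.

## Community ecology

Niche metrics treat **samples as resource states**: a taxon's use
proportions `P_j` across samples give Levins breadth `B = 1/sum(P_j^2)`
(bounded by 1 and the number of states) and the asymmetric overlap
`alpha_ij = sum(P_ia P_ja) / sum(P_ia^2)`. Aggregation to community level
is left to the caller (e.g. averaging per-taxon values), since any
aggregation convention is defensible.

Shannon and Gini-Simpson come from vegan; Chao1 and ACE are computed
in-package because the classic Chao1 form `S_obs + F1^2/(2 F2)` (with the
bias-corrected `S_obs + F1(F1-1)/2` only when F2 = 0) and the standard
ACE with rare-abundance cutoff 10 are the conventions wanted here, while
vegan's `estimateR()` always applies the bias-corrected variant. vegan
also provides Bray-Curtis distances and ANOSIM (seeded permutations);
PCoA is classical scaling via `cmdscale`, with negative eigenvalues (a
normal consequence of semimetric input) reported rather than dropped.

Co-occurrence networks threshold pairwise correlations at r^2 > 0.90 and
p < 0.05. Spearman is the default (abundance data are non-normal and
compositional-ish); p-values come from a seeded joint-permutation null
(999 permutations) with a t-approximation alternative, and no
multiple-testing correction is applied by default so the thresholds mean
exactly what they say (Benjamini-Hochberg is available). "Keystone" taxa
are the top-degree nodes, ties broken by betweenness then label — a
topological convention made explicit and configurable because no unique
ecological definition exists.

## Raman processing

Spectra are axis-calibrated against the 520.6 cm^-1 silicon band, then
baseline-corrected with an asymmetric least squares (Whittaker smoother)
baseline: penalised least squares with a second-difference stiffness
`smoothness` and asymmetric weights `asymmetry` given to points above the
baseline. Defaults (`smoothness = 1e5`, `asymmetry = 0.02`, for 1-2 cm^-1
grids) were tuned on the package's synthetic fixtures to recover known
band areas: stiffer baselines fail to track curved fluorescence drift and
leak it into the wide C-D window, while laxer ones climb into the broad
C-H envelope. An iteratively peak-stripped polynomial baseline is the
alternative.

Band quantities integrate trapezoidally over the window (C-D 2040-2300,
C-H 2800-3100 cm^-1), flooring negative corrected intensities at zero;
peak-height mode exists because band maxima are the other common
convention, and the two agree in rank order on the fixtures. The activity
ratio `(C-D)/(C-D + C-H)` is computed on corrected, un-normalised
intensities (it is scale-invariant anyway); the five lipid band
intensities (972, 1032, 1080, 1250, 1735 cm^-1, half-window 10) are
reported after area normalisation over 600-3200 cm^-1 so they compare
across cells.

Residual limitations: a zero-floor plus the baseline's noise-level offset
add a small positive contamination to wide-window areas, which inflates
low C-D ratios by a few percent relative to truth; window truncation of
broad Gaussian envelopes removes 1-2%. Both effects are visible in the
tests' tolerance choices.

## The synthetic scenario

`scenario_config()` fixes the study conditions: four plastic types (PE,
PS, PP, PVC) plus bulk water, six samples per group. Measured isotope
values are drawn from per-group Gaussians calibrated to the observed
group ranges (plastisphere SP 15.56-26.21 and d18O 64.14-77.82 per mil;
bulk water 7.53-8.68 and 55.62-59.93), with the four plastic types
staggered at quantiles 1/8, 3/8, 5/8, 7/8 of the plastisphere range
(within-type SD = width/8) and bulk water at its mid-range (SD =
width/4). These ranges lie partly *outside* the endmember hull after
correction — the corrected group means solve to raw fractions far off the
simplex — which is precisely why the generator's default mode samples
measured values directly rather than forward-modelling from fractions:
no simplex point maps onto those ranges. The forward-model mode
(`true_fractions`) exists for parameter-recovery testing, where ground
truth must be known.

Communities are Dirichlet-multinomial (depth 5000, concentration 60) with
habitat-tilted centroids, 30% of taxa absent from bulk water (richness
contrast) and proportional "hub" blocks planted per habitat (bnirK-type
in the plastisphere, bnirS-type in bulk water) for the network stage. Ct
tables are Gaussian (SD 0.1 cycles) around targets that put
(nirS+nirK)/nosZ at 1.7-2.1 across plastic types and 0.37 in bulk water.
Raman cohorts use true C-D ratio means of 0.18/0.22/0.25/0.29
(plastisphere types) and 0.09 (bulk), per-cell SD 0.03, 40 cells per
group, log-normal intensity jitter and a linear-plus-curved drift.
Isotope-pairing rates encode a denitrification share of 0.80
(plastisphere) and 0.75 (bulk) with 5% log-normal noise shared between
t29 and t30, and acetylene pairs with residual/total exactly 0.75.

What the generator does **not** emulate: real amplicon workflows
(chimeras, compositional closure from sequencing depth, taxonomy error),
spatial structure within biofilms, instrument drift in isotope ratios,
cosmic-ray spikes in Raman spectra, or covariance between endmember SP
and d18O. Passing tests therefore demonstrate correctness of the
computations under the stated statistical structure, not robustness to
every artefact of field data.

## Problem sizes and determinism

Test and example runs use reduced sizes (hundreds to a few thousand Monte
Carlo draws, 199-999 permutations, 2-12 cells or samples per group) —
enough to pin every closed-form value exactly and every stochastic
property within its stated tolerance; the defaults users get are 10,000
draws and 999 permutations. Every stochastic function takes a seed, and
`run_pipeline()` fans one global seed out to per-stage seeds via a small
deterministic hash (`derive_seed()`), so reports are bit-reproducible and
single stages can be rerun standalone.

## Worked example

```{r pipeline, eval = FALSE}
res <- run_pipeline(scenario_config(), seed = 42)
res$group_fractions
tidy(monte_carlo_partition(16.3, 48.16, seed = 1))
```

On the default scenario the partition reports bacterial denitrification
as the dominant source in both habitats, a larger fungal contribution in
the plastisphere than in bulk water, and a negligible chemodenitrification
share — with the gene-ratio, network-keystone and Raman-activity stages
showing the concordant contrasts described above.
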