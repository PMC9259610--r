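# plastiN2O

Quantifying where the nitrous oxide comes from in the **plastisphere** —
the biofilm communities that colonise plastic debris in estuaries and
coastal waters. Plastic surfaces develop anoxic micro-niches that favour
denitrifiers, and the N2O they vent is a potent greenhouse gas. The
package is written for biogeochemists and microbial ecologists who have
(or want to simulate) the standard measurement bundle of such a study:
N2O isotopocule data, 15N isotope-pairing rates, acetylene-block N2O
pairs, qPCR threshold cycles, denitrifier OTU tables and D2O-labelled
single-cell Raman spectra.

## The core model

N2O is linear (N–N–O), and its two nitrogen sites are isotopically
distinct. From the site-specific values the package derives

- **site preference** SP = δ¹⁵Nᵅ − δ¹⁵Nᵝ, and
- **δ¹⁸O (N2O/H2O)** = δ¹⁸O − δ¹⁸O(H2O), assuming near-complete O
  exchange with ambient water (default water value 0.91 ‰).

Measured values are corrected for partial N2O reduction to N2,

SP_NR = SP + f_R·SPε,  δ¹⁸O_NR = δ¹⁸O(N2O/H2O) + f_R·δ¹⁸Oε,

with f_R the acetylene-block reduction ratio (residual/total N2O) and
(SPε, δ¹⁸Oε) = (−6, −25) ‰. The corrected pair is decomposed on three
endmembers — bacterial denitrification BD (−1.5, 19), fungal
denitrification FD (37, 47) and chemodenitrification CD (16, 30) — by the
exact linear system

```
f_BD + f_FD + f_CD                        = 1
f_BD·SP_BD + f_FD·SP_FD + f_CD·SP_CD      = SP_NR
f_BD·O_BD  + f_FD·O_FD  + f_CD·O_CD      = δ¹⁸O_NR
```

Negative fractions are clipped to zero and the survivors renormalised to
100 %. Endmember uncertainty (literature ranges, Gaussian SD =
range width/4) is propagated by seeded Monte Carlo (10,000 draws,
per-draw clipping) yielding standard errors and clip diagnostics; the
reported point estimate is the deterministic clipped solution (see the
methods vignette for why the mean of clipped draws is biased here).

Supporting stages: isotope-pairing denitrification rate 2·T₃₀/Fₙ and the
denitrification/anammox split via the ²⁹N₂-excess convention; qPCR
relative copies 10^((31−Ct)/3.33) with 16S normalisation and the
(nirS+nirK)/nosZ ratio; Levins niche breadth 1/ΣP², asymmetric niche
overlap, α-diversity, Bray-Curtis + PCoA + ANOSIM, correlation-threshold
co-occurrence networks (r² > 0.9, p < 0.05) with keystone extraction; and
Raman C–D/(C–D + C–H) activity ratios with asymmetric-least-squares
baseline correction. A seeded generator (`scenario_config()`, `gen_*()`)
produces every input table, so the whole pipeline runs with no external
data.

## Worked example

```r
library(plastiN2O)
res <- run_pipeline(scenario_config(), seed = 42)
res$group_fractions
#> # A tibble: 2 × 5
#>   habitat       f_BD  f_FD  f_CD     n
#>   <chr>        <dbl> <dbl> <dbl> <int>
#> 1 bulk_water   0.577 0.423     0     6
#> 2 plastisphere 0.546 0.454     0    24
```

Bacterial denitrification dominates N2O production in both habitats, the
fungal share is higher in the plastisphere than in bulk water, and
chemodenitrification is negligible — the expected ordering for this
system. The same report carries the concordant supporting contrasts:

```r
res$anosim
#> R = 0.981, p = 0.001        # plastisphere vs bulk communities separate
res$summary$nir_nos
#> plastisphere 1.90, bulk_water 0.367   # more N2O producers than consumers on plastic
res$raman_groups
#> mean C-D ratio 0.18-0.30 on plastics vs 0.096 in bulk water
```

A single measurement partitions with full uncertainty:

```r
tidy(monte_carlo_partition(16.3, 48.16, seed = 1))
#> # A tibble: 3 × 7
#>   sample_id source estimate  mean    sd      se clip_frequency
#> 1 sample_1  BD        0.6   0.432 0.231 0.00231          0.129
#> 2 sample_1  FD        0.3   0.217 0.152 0.00152          0.201
#> 3 sample_1  CD        0.100 0.351 0.370 0.00370          0.339
```

Here `estimate` is the deterministic clipped solution and the Monte Carlo
columns quantify endmember-driven uncertainty; the gap between the two is
itself a diagnostic (see the vignette).

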