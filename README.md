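# minscreen

Design and analysis tools for forward-genetic screens that hunt **dominant
quantitative modifiers** of an overdispersed count phenotype — the
motivating case is intestinal tumor multiplicity in *Apc^Min/+* mice
modified by ENU-induced point mutations. The package is aimed at
statistical geneticists planning such screens: it answers how many progeny
a kindred needs, how many kindreds a screen needs, what preselecting
extreme kindreds buys, what fraction of mutagenized kindreds carry
modifiers, and how to build and validate an isogenic SNV mapping panel for
the hits.

## The models at the core

**Segregating three-component mixture.** A kindred (the progeny cluster of
one mutagenized founder) is unaffected (probability π₀), carries a
dominant suppressor (π_s) or a dominant enhancer (π_e). Modifier kindreds
draw a multiplicative fold effect *f* from a class-specific distribution
(suppressors *f* < 1, enhancers *f* > 1); each progeny inherits the
modifier with probability ½. With baseline density f₀ (negative binomial,
mean μ = 99.8, shape k = 9.8; variance μ + μ²/k) the kindred likelihood is

    L = π₀ ∏ᵢ f₀(xᵢ) + Σ_c π_c E_f [ ∏ᵢ ( ½ f₀(xᵢ | f·μ) + ½ f₀(xᵢ) ) ]

and `fit_mixture()` maximises it over weights and effect distributions by
a monotone EM ascent with quasi-Newton polish.

**Power and screen design.** The kindred mean of n progeny is tested
against N(μ, (μ + μ²/k)/n); under a segregating fold *f* the alternative
mean is μ(1+f)/2 with between-genotype variance ¼μ²(f−1)²/n added to the
sampling variance. `screen_size_for_discovery()` sizes the screen so the
Benjamini–Hochberg list at q = 0.05 contains a true large-effect modifier
with probability ≥ 0.95, and `preselected_design()` does the same after
enriching the kindred mixture by selecting clusters with multiple extreme
animals.

**Inbreeding and panel construction.** Residual heterozygosity under sib
mating follows H_t = ½H_{t−1} + ¼H_{t−2} (14% at F10); multi-line variant
tables are depth-filtered, partitioned into line-specific / pair-shared /
remainder sites, summarised as mutation spectra and rates, and distilled
into a three-markers-per-autosome genotyping panel whose validation
results are classified into five outcome categories.

## Worked example

Simulate a screen at the estimated mixture (39% of kindreds modifier-free,
41% suppressor, 20% enhancer), refit it, and size the follow-up design —
this is what `analysis/01_simulate_cohorts.R` … `03_power_design.R` run:

```r
library(minscreen)

colony  <- colony_model()                 # NB(99.8, 9.8) + survival link
classes <- modifier_class_params()        # weights 0.39 / 0.41 / 0.20
cohort  <- simulate_kindreds(colony, classes, n_kindreds = 2000,
                             progeny_per_kindred = 10, seed = 20140417)

fit <- fit_mixture(cohort, baseline_nb(99.8, 9.8), n_restarts = 10, seed = 1)
print(fit)
#> Segregating three-component mixture fit (count channel)
#>   kindreds: 2000   log-likelihood: -101942.663   converged: TRUE (87 iterations)
#>   weights: none 0.359, suppressor 0.412, enhancer 0.229
#>   modifier induction rate: 0.641
#>   suppressor fold: median 0.606 (log-sd 0.201)
#>   enhancer fold:   median 1.773 (log-sd 0.203)
```

The fit recovers the generating weights (0.39/0.41/0.20) to within a few
points and the fold medians (0.6, 1.8) almost exactly; `posterior_class()`
then flags individual kindreds. Design questions:

```r
progeny_for_power(design_query(f = 2), power_target = 0.9)
#> [1] 10                      # progeny to detect a 2-fold enhancer kindred

screen_size_for_discovery(classes, n = 10, effect_threshold = 2,
                          mc_reps = 2000, seed = 7)
#> [1] 50                      # kindreds for a >=95% chance the FDR list
#>                             # contains a true >=2-fold enhancer

preselected_design(classes, selection_rule(2, 10, 0.05, "upper"),
                   effect_threshold = 2, mc_reps = 2000, seed = 7)[
  c("n_kindreds", "progeny_per_kindred", "enrichment")]
#> $n_kindreds [1] 9   $progeny_per_kindred [1] 10   $enrichment [1] 4.7
```

Preselecting kindreds with ≥2 of 10 first-pass animals in the top-5% tumor
tail enriches large enhancers 4.7-fold and cuts the deep-tested kindreds
from 50 to 9. On the inbreeding side:

```r
round(100 * heterozygosity_remaining(10:11))
#> [1] 14 11                   # % of induced variants still heterozygous
```

The numbered scripts under `analysis/` chain these steps end to end
(cohort simulation → mixture fit → power/design tables → heterozygosity
series → variant panel → genotyping validation), writing TSV/VCF/BED
artifacts under `results/`.

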