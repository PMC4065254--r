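---
title: "Models and methods behind minscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind minscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(minscreen)
```

# The problem

A forward-genetic screen for *dominant quantitative modifiers* asks whether
the progeny cluster ("kindred") of a single mutagenized founder deviates in
a quantitative phenotype. The motivating system is intestinal tumor
multiplicity in Apc^Min/+ mice: the baseline colony phenotype is an
overdispersed count (negative binomial with mean about 99.8 tumors and
shape 9.8, so variance is roughly 1116 rather than the Poisson 100), a
dominant modifier multiplies a carrier's expected count by a fold effect
`f` (suppressors `f < 1`, enhancers `f > 1`), and because the founder is
heterozygous the modifier segregates to each progeny with probability 1/2.
Lifespan is negatively linked to tumor burden, which is why survival can
serve as a first-pass phenotype.

`minscreen` implements the full statistical scaffolding of such a screen:
cohort simulation, mixture-model estimation of the modifier induction rate
and effect-size distribution, power and screen-size design, the
sib-mating heterozygosity recurrence, and the construction and validation
of an isogenic single-nucleotide-variant (SNV) mapping panel.

# The segregating three-component mixture

Each kindred belongs to a latent class: unaffected (probability
$\pi_0$), suppressor ($\pi_s$) or enhancer ($\pi_e$). A modifier kindred
draws a fold effect $f$ from its class's distribution; each of its $n$
progeny is a carrier independently with probability $s$ (default 1/2).
The likelihood of a kindred with phenotypes $x_1, \dots, x_n$ is

$$
L = \pi_0 \prod_i f_0(x_i) \;+\; \sum_{c \in \{s, e\}} \pi_c \,
    \mathbb{E}_{f \sim G_c} \prod_i \big[ s\, f_0(x_i \mid f) + (1 - s)\,
    f_0(x_i) \big],
$$

where $f_0(\cdot \mid f)$ is the baseline density with its mean multiplied
by $f$ (the negative-binomial shape is unchanged by the modifier).
Marginalising each animal's carrier status inside the product is exact and
equivalent to summing over all $2^n$ carrier configurations; the test
suite checks this equivalence against exhaustive enumeration to 1e-10.

Two phenotype channels sit behind one density interface: tumor counts
(negative binomial, `baseline_nb()`) and log lifespans (normal,
`baseline_loglifespan()`, with a fold effect shifting the mean by
$-\beta \log f$ through the survival link). The original screen read
survival first and counts second; the package treats counts as the primary
channel because the design calculations are stated on that scale.

## Effect distributions and their grid representation

The fold-effect distributions $G_s$, $G_e$ default to log-normals
truncated to $(0, 1)$ and $(1, \infty)$; the published analysis does not
state a parametric form, so this is the package's own choice, made for
its flexibility on a multiplicative scale (`effect_points()` provides an
explicit point-mass alternative). Inside the likelihood each log-normal is
discretized onto a fixed log-spaced grid of fold values (25 nodes per
class, suppressor nodes in [0.05, 0.995], enhancer nodes in [1.005, 20]).
Because the grid is fixed, the expensive per-kindred, per-fold evidence
matrix is computed once; EM iterations then cost almost nothing. Because
suppressor nodes stay below 1 and enhancer nodes above it, component
labels can never swap during estimation.

## Estimation

`fit_mixture()` runs an expectation-maximisation ascent: the E step
computes responsibilities over (class, fold node); the M step updates the
class weights in closed form and refits each class's (location, scale) by
numerically maximising the expected complete-data likelihood on the grid,
started from the current value so the observed log-likelihood never
decreases. Convergence is declared when the relative log-likelihood change
falls below 1e-8 (at most 2000 iterations); non-convergence is flagged,
not raised. Starts combine a method-of-moments classification of kindred
means (fold backed out from the segregation-diluted mean ratio
$\bar{x}/\mu \approx (1+f)/2$) with random perturbations; the best of
`n_restarts` is kept. EM's geometric tail can stall a few log-likelihood
units short when weak suppressors overlap the null component, so the best
run is finished with a quasi-Newton polish of the same discretized
likelihood, accepted only when it improves — this preserves the monotone
trace while reliably reaching the optimum.

At the study's scale (2,000 kindreds of 10 progeny, weights 0.39 / 0.41 /
0.20, fold medians 0.6 and 1.8 with log-sd 0.2) replicate simulations show
per-weight bias below about 0.015 and standard errors near 0.03: weak
suppressors with folds above roughly 0.85 are nearly indistinguishable
from unaffected kindreds at 10 progeny, which is the irreducible source of
that spread. Recovery of each weight to within ±0.05 is therefore a
high-probability, not certain, event per simulated cohort.

# Extreme-kindred enrichment

Selecting kindreds with at least $m$ of $c$ first-pass animals beyond an
extreme baseline quantile (default the 5th/95th percentile) enriches the
follow-up set for large effects. For a kindred of fold $f$ the probability
an animal is extreme is the segregation-weighted tail probability of the
fold-shifted negative binomial, selection is a binomial tail event, and

$$
\text{enrichment} =
\frac{P(\text{effect beyond threshold} \mid \text{selected})}
     {P(\text{effect beyond threshold})}
$$

is evaluated exactly on the (class, fold) atoms of the mixture
(`extreme_selection_enrichment()`). The published formula for this
quantity lives in supplementary material that the package does not
reproduce; the implementation is a reconstruction from the stated
selection procedure, and is validated against Monte-Carlo selection
frequencies to within 5% relative error. `min_extreme = 0` is the vacuous
rule (every kindred selected, enrichment exactly 1). Note the extreme
*count* tail maps to the opposite survival tail: short-lived kindreds are
the high-count, enhancer side.

# Power and screen design

The per-kindred test compares the kindred mean count against the null
normal approximation $N(\mu, (\mu + \mu^2/k)/n)$ at level $\alpha$
(two-sided by default; the screen direction is rarely known in advance).
Under the alternative the pooled mean is $\mu(1+f)/2$ with variance
$[\tfrac12(\mu f + (\mu f)^2/k) + \tfrac12(\mu + \mu^2/k) +
\tfrac14 \mu^2 (f-1)^2]/n$ — the last term is the between-genotype
variance contributed by segregation; `kindred_mean_distribution()` exposes
exactly these moments. For the power itself, `kindred_power()` conditions
on the binomial number of carriers and applies the normal approximation
within each carrier stratum: at small $n$ the carrier-count lumpiness
dominates the shape of the alternative, and the stratified form tracks an
exact negative-binomial Monte Carlo to better than 0.01 absolute across
folds 0.25–4 and $n$ = 5–30, where a single pooled normal errs by up to
0.03. `progeny_for_power()` inverts the monotone power curve by bisection.

A screen of $N$ kindreds reports the kindreds surviving Benjamini-Hochberg
at $q = 0.05$; the design criterion requires this list to contain at least
one *true* modifier beyond a stated fold with probability at least 0.95.
`screen_size_for_discovery()` estimates the discovery probability by Monte
Carlo — kindred (class, fold) from the mixture, carrier counts binomial,
count sums exact negative binomial, p-values from the null normal — and
finds the smallest $N$ by doubling and bisection. Common random numbers
(a screen of $N$ kindreds is the first $N$ columns of one simulated pool)
keep the estimated curve comparable across $N$. `preselected_design()`
chains the pieces: the selection rule reweights the mixture, the progeny
number comes from the power target at the threshold fold, and the screen
size is solved on the enriched mixture. The published supplementary screen
sizes depend on a fitted effect distribution that is not reproduced in the
main text, so the package exercises the procedure on its own documented
mixture rather than reproducing those particular numbers.

# Inbreeding

With repeated full-sib mating, the expected fraction of founder-
heterozygous loci still heterozygous follows
$H_t = \tfrac12 H_{t-1} + \tfrac14 H_{t-2}$, $H_0 = H_1 = 1$: about 14%
at generation 10 and 11% one generation later. The published account
attaches 11% to "12 generations"; under this recurrence the two reported
percentages correspond to adjacent indices (t = 10 and t = 11), an
inconsistency in generation labelling that the package documents rather
than resolves (the `t` index counts sib-mating generations with
$H_0 = H_1 = 1$). `1 - H_t` reproduces the classical inbreeding
coefficient series, and $H_{t+1}/H_t \to (1+\sqrt5)/4 \approx 0.809$.

# Mapping-panel construction

Variant processing follows the resequencing workflow: calls are kept with
read depth at least 3 and at most 2.5 times the line's mean coverage
(culling copy-number pile-ups); sites — keyed on (chrom, pos, alt),
zygosity ignored — are partitioned into line-specific (exactly one line),
related-pair-shared (exactly the two sibling lines, evidence of a common
founder mutation) and remainder; and the 12-category mutation spectrum
and per-bp rate are tabulated. Genotyping candidates require Phred quality
99 and a flank free of significant repeats, operationalized as no
homopolymer run of 8+ bases and no 4+ unit tandem dinucleotide — the
source states no definition, so these thresholds are package choices,
configurable in `flank_has_repeat()`. Candidates are ordered pair-shared
first, then by mutation type (A>T/T>A transversions, then A>G/T>C, then
G>A/C>T — ENU's elevated AT-to-TA rate makes those the most credible
induced mutations), then position. The panel takes the best candidate in
each third of each autosome (equal physical thirds approximate
centromere/middle/telomere on acrocentric mouse chromosomes; no published
bin boundaries exist), relaxing first mutation-type then specificity
criteria only in bins that would otherwise stay empty. Ties within a bin
go to the candidate nearer the bin midpoint, then to the lower position.
Marker spacing is summarised by within-chromosome adjacent-site distance
quantiles, and marker-free gaps of 30 Mbp or more are reported as 0-based
half-open intervals (a site at 1-based position $p$ occupies $[p-1, p)$,
so a gap between adjacent sites $p_1 < p_2$ is $[p_1, p_2 - 1)$).

# Genotyping validation

Assay results across reference-colony, SNV-line and F1 samples are
classified by ordered rules: all no-calls — assay failure; any alt allele
in the reference colony — reference divergence (colony-vs-assembly
divergence and assembly error are indistinguishable here and share one
label); SNV-line all ref/ref — call error; SNV-line mixed — residual
heterozygosity (which requires at least one alt allele and is consistent
with some line individuals being homozygous); otherwise validated
homozygous. Partial no-calls classify on the called subset; a site whose
SNV-line samples are all missing is an assay failure. The fixture
generator inverts the classifier, so requested category counts round-trip
exactly.

# Synthetic data: what it does and does not emulate

The generators reproduce the statistical structure the analyses assume:
negative-binomial counts with the stated moments, Mendelian carrier
segregation, multiplicative fold effects, a log-linear lifespan link
(`log(lifespan) = intercept − slope·log(count+1) + noise`; only a negative
correlation is documented, so the form and its defaults — intercept
log(600), slope 0.35, noise sd 0.2, giving roughly 120-day lifespans at
100 tumors — are package choices), Poisson variant counts placed uniformly
along chromosomes (no mutational hotspots), the published mutation
spectrum, a configurable shared-variant fraction for the related line pair
(default 792/4537, the observed shared-to-total ratio for that pair), and
a 14% residual heterozygosity rate (the F10 expectation). They do not
emulate real-data features such as litter effects, temporal drift in
colony phenotype, sequencing error structure, alignment artifacts or
mutational clustering; tests passing on synthetic cohorts therefore
validate the estimators' internal consistency, not robustness to those
features. One master seed spawns a named substream per generator
(`substream_seed()`), so modules stay decoupled and every output is
bit-reproducible per seed.

# Numerical choices and problem sizes

Likelihoods are computed in log space with log-sum-exp; truncated
log-normal sampling uses inverse-CDF so no rejection loop perturbs the
random stream; screen-size search doubles then bisects; the per-kindred
p-value under the screen Monte Carlo uses the same null normal as the
analytic power, so discreteness is treated identically on both paths.
The packaged analyses and tests run at 2,000 kindreds × 10 progeny for
mixture fits, 1e5 replicates for size checks, 4e4–1e5 for power and
enrichment oracles, and 1,000–2,000 Monte-Carlo screens for design
searches; these sizes give Monte-Carlo error comfortably inside the
tolerances being asserted while keeping a full run to a few minutes.

# Known limitations

The effect-distribution family and the enrichment formula are
reconstructions, labelled as such above. The mixture fit treats kindred
sizes as fixed. The per-kindred test is the normal-approximation z-test
throughout; an exact test would differ slightly at very small kindreds.
Published downstream numbers that depend on unavailable supplementary
inputs (specific screen-size tables, the observed inter-SNV distance
quantiles of the real lines, and the neutrality test's exact p-value,
which needs the raw counts) are exercised procedurally on synthetic data
rather than reproduced.
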