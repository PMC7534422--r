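---
title: "Models and simulation design for genomic selection in a biparental squash population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation design for genomic selection in a biparental squash population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squashgs)
```

# What this package models

`squashgs` re-creates, on fully synthetic data, the statistical machinery of
a recurrent genomic-selection program in a biparental winter squash
(*Cucurbita moschata*) population: an F2 base population derived from two
divergent purelines, repeated fruit-level measurements of quality traits,
GBS (genotyping-by-sequencing) marker data, GBLUP-based prediction, index
selection, and mixed-model estimation of realized gain across selection
cycles. All real-data inputs of the original program — raw reads, field
trials, colorimeter output — are out of scope; the synthetic-data module
generates populations with the same statistical structure the analysis
assumes, so every estimator in the package can be validated against known
truth.

# The population simulator

**Meiosis.** Gametes are simulated under the Haldane model: the crossover
count per chromosome is Poisson with mean equal to the map length in
Morgans, crossover positions are uniform, and there is no interference.
This is the simplest model consistent with a centimorgan map; squash has 20
chromosomes, but most analyses here use 5–10 chromosomes of ~90 cM, which
preserves the relatedness structure that matters for GBLUP while keeping
simulations fast.

**The cross.** The two founders are fully homozygous and carry opposite
alleles at every marker — the maximally informative configuration for a
biparental cross. The F1 is therefore heterozygous everywhere, and the F2
("C0") segregates 1:2:1 at every marker with expected allele frequency 1/2.

**Trait architecture.** Marker effects for all traits are drawn jointly from
a multivariate normal whose across-trait correlation is the target genetic
correlation matrix, then rescaled analytically so the F2 genic variance
$\sum_m 2p_mq_m\beta_m^2$ (with $p_m = 1/2$) equals the target additive
variance. All markers are causal by default (infinitesimal-style
architecture, matching the assumption behind GBLUP); `n_qtl` can restrict
the causal set. Total phenotypic variance is normalized to 1 per trait, so
heritability and repeatability targets are exact by construction:
$\sigma^2_u = h^2$, $\sigma^2_p = t - h^2$, $\sigma^2_e = 1 - t$.

**Records.** Each fruit record is
$y = \text{site} + u(\text{plant}) + p(\text{plant}) + e(\text{fruit})$:
$u$ the true breeding value, $p$ a per-plant permanent environment effect,
$e$ a fruit residual correlated across traits. Fruit counts are uniform on
4–6 per plant — the range the program's repeatability estimates identify as
sufficient; it is a configurable default, not a claim of fidelity to any
particular field season. Yield-type traits are measured once per plant and
carry no permanent-environment term. Site effects are N(0, 0.5²) in
phenotypic-SD units — environment is deliberately a major driver of
between-plant variation, as it is in the field.

**GBS degradation.** Read depth per call is Poisson; calls below a depth
threshold become missing (threshold 2 in the selection profile, 7 in the
cross-validation profile, the depth at which a caller can demand two reads
per allele of a heterozygote); heterozygous calls with depth $d < 7$ are
miscalled homozygous with probability $2 \cdot (1/2)^d$ — the probability
that all sampled reads carry the same allele. Uniform missingness is added
on top. The simulator does not model sequence reads, dominance, or
epistasis.

**Reproducibility.** Every driver consumes one global seed and derives
fixed-offset child seeds per stage (`child_seed`), so re-ordering stages
cannot silently change downstream draws, and all outputs are bit-identical
under a fixed seed.

# Genotype QC and the relationship matrix

Filters follow the standard GBS pipeline for a biparental cross: depth
masking first, then individuals with more than 40% missing calls are
dropped, then markers are dropped for missingness (> 20%) or minor allele
frequency (< 0.05), in that fixed order; a parent-informed filter retains
only markers homozygous-different between the founders with heterozygote
fraction below 0.9. Marker sets are merged on common marker ids. Remaining
missing dosages are mean-imputed — one deterministic, testable method used
throughout (model-based imputation such as EM or LD-kNN alternatives are
deliberately out of scope). The additive relationship matrix is VanRaden's
first method: $K = WW' / 2\sum p(1-p)$ with $W$ the column-centered dosage
matrix. $K$ from an F2 family is numerically singular (centering gives an
exact null direction), so model-fitting code adds a ridge of
$10^{-6}\,\overline{\mathrm{diag}(K)}$ before inversion.

# Mixed models

**Repeatability model.** For fruit-level records,
$y = X\beta + Zu + Zp + e$ with $u \sim N(0, \sigma^2_u K)$,
$p \sim N(0, \sigma^2_p I)$, $e \sim N(0, \sigma^2_e I)$ and site as a fixed
effect. Because the fixed effects are constant within plant, the restricted
likelihood factorizes exactly into a within-plant part — $(n - m)$ degrees
of freedom on $\sigma^2_e$ alone — and a plant-mean part whose covariance is
$\sigma^2_u K + \sigma^2_p I + \sigma^2_e\,\mathrm{diag}(1/n_i)$. The sum is
maximized directly by L-BFGS on log-variances with analytic gradients. This
is exact REML; the choice of a direct optimizer here (rather than the EM
engine used elsewhere) is purely computational — EM on the record-level
mixed-model equations converges too slowly at the 800-plant scales the
validation suite uses — and agreement between the two routes is enforced by
test to $10^{-4}$ in the variance ratio. From the components,
$t = (\sigma^2_u + \sigma^2_p)/(\sigma^2_u + \sigma^2_p + \sigma^2_e)$ and
$h^2 = \sigma^2_u/(\sigma^2_u + \sigma^2_p + \sigma^2_e)$.

**Generic univariate engine.** `reml_fit` is EM-REML on the mixed-model
equations for any set of random terms (kinship or identity structure) and
grouped residual variances. EM is monotone in the restricted likelihood and
respects the parameter cone; its slow tail is accelerated by Aitken
extrapolation of the log-variance sequence, with candidates accepted only
when they improve the likelihood (so the monotone trace is preserved), and
finished by a short bounded quasi-Newton polish plus an explicit
boundary test (a variance below $10^{-3}$ of the phenotypic variance is
pinned to the floor when pinning costs no likelihood — EM approaches a zero
variance only asymptotically). Estimates at the floor ($10^{-10}$ of the
phenotypic variance) are reported as 0. Convergence is declared when the
restricted log-likelihood changes by less than $10^{-8}$; hitting the
iteration cap flags the fit, never silently. For a single kinship term with
iid residual, an eigendecomposition-profiled likelihood (one-dimensional
search over the variance ratio) is used instead; the two routes agree by
test.

**Multi-trait GBLUP.** $y = X\beta + Zu + e$ with
$u \sim N(0, K \otimes G)$, $e \sim N(0, I \otimes R)$, a separate fixed
site effect per trait, and $G$ unstructured or constrained diagonal (the
reduced model of the genetic-covariance LRT). The EM runs in the eigenbasis
of $K$, where rows decouple into $T \times T$ problems — $O(mT^3)$ per
iteration (C++/RcppArmadillo core). Two record levels are supported: plant
means (the parameter-estimation model behind genetic correlations) and
fruit level (the selection model, which deliberately omits the
permanent-environment term). Fruit-level fits use an exact reduction:
scaling plant means by $\sqrt{n_i}$ turns the covariance into
$\tilde K \otimes G + I \otimes R$ with
$\tilde K = D^{1/2} K D^{1/2}$, plus an independent Wishart contribution to
$R$ from the within-plant contrasts — algebraically identical to the
record-level model at per-plant cost. When an EM step leaves the PSD cone,
$G$ is bent back by clipping eigenvalues at $10^{-6} \cdot \mathrm{tr}(G)$;
genetic correlations are clamped to $[-1, 1]$, and estimates at that
boundary (common for strongly correlated traits at $n \approx 200$) are
reported as boundary values rather than allowed outside the cone. Records
missing any requested trait are dropped for that fit.

One consequence worth knowing: fitting the fruit-level model (no
permanent-environment term) to data that *have* a permanent environment
effect inflates $G$, because the plant-level non-genetic covariance must be
absorbed somewhere and $K$'s diagonal lets $G$ act partly like an iid plant
effect. The package reproduces this deliberately — the selection model is
specified without the PE term — and it is harmless for selection, which
needs only the GEBV ranking; parameter estimation uses the plant-mean
bivariate model instead.

**Predictions.** GEBVs for any individual covered by $K$, including
unphenotyped selection candidates, come from the kinship rows against the
phenotyped set ($\hat u_{new} = K_{new,obs}\, \alpha$ with $\alpha$ the
prediction kernel at the REML optimum). This is the standard single-GRM
strategy for across-set prediction: one relationship matrix on the merged
marker set rather than separate per-set equations.

**Gain model.** Realized gain is the fixed slope on a numeric cycle
covariate (coded 1, 2, 3, 5 — the last cycle of selection is two
generations past the third code, hence the gap) in a mixed model with random
site, block-within-site and plot-within-block effects with one variance per
site (plots only at sites that declare intra-block replicates — implemented
as terms with zero incidence elsewhere), and residual variances grouped by
harvesting mode (plot means of fruit vs plot means of plant means).
Significance is a Wald F with denominator degrees of freedom by the
containment approximation $n - \mathrm{rank}(X) - q$; the exact algebraic
degrees-of-freedom computation of commercial mixed-model software is out of
scope.

# Quantitative-genetic summaries

$\mathrm{PA}_{max} = \sqrt{h^2}$ benchmarks genomic predictive ability
against phenotypic mass selection. The accuracy gain from $n$ repeated
measures is implemented as $\Delta r = \sqrt{1/(t + (1-t)/n)}$: the radical
is required for $\Delta r(1) = 1$ and for the interpretation as an accuracy
ratio with asymptote $1/\sqrt t$ (the squared variant is available behind a
flag for comparison). The record weight for heterogeneous error variance of
plant means is $w = (1-h^2)\,/\,(c h^2 + (1 + (n-1)t)/n - h^2)$, positive
and decreasing in the marker-variance proportion $c$. Index heritability is
$h^2_I = b'Gb / b'Pb$. Phenotypic correlations are Pearson correlations of
least-squares residuals after regressing each trait on environment
indicators, with t-tests and Bonferroni correction over the pairs tested in
the call; genetic correlations are $G_{12}/\sqrt{G_{11}G_{22}}$ from the
bivariate plant-mean model, tested by the diagonal-vs-unstructured LRT.
No standard errors are reported for $h^2$ and $t$; validation is
simulation-based instead.

# Selection

The Smith–Hazel coefficients are $b = P^{-1}Ga$; with equal economic
weights and GEBVs available, the index is simply the GEBV sum. Truncation
selection takes the top $\lceil fn \rceil$ with ties broken by ascending
individual id — a deterministic convention the original program did not
need to state. Independent culling (the phenotypic C0 step) uses inclusive
type-7 quantile thresholds ("top 20%" means at or above the 80th
percentile), which avoids empty eligible sets in small populations; when
more plants pass than the target, they are ranked by mean within-trait
rank, and when fewer pass, the driver tops the set up by the same ranking so
the scheme always advances the intended number of selections — both
conventions are this implementation's choices where the original procedure
was manual.

The recurrent driver runs: C0 phenotypic culling → three GS cycles of
predict–select–mate, with multi-trait models trained at the field
generations (C0 and C2 by default) and each model first used one generation
after its training data exist, matching the genotyping lag of greenhouse
selection. Random mating gives each dam a pool of 4–5 random sires (self
excluded whenever possible), seed-level paternity uniform within the pool,
and balanced half-sib family sizes. Greenhouse logistics (cuttings, lagged
transplanting) are not modeled beyond the training lag.

# Cross-validation

Within-set: random 80/20 partitions repeated 50 times, partitions shared
across traits, truth = plant mean of fruit records. Across-set: merge
marker sets on common markers, one joint kinship, train on all training
individuals, one PA per trait. Stratified: equal draws per population set
form the training composite, 25 per set form the test set, swept over
training sizes. Replicates whose test fold has no phenotypic variance yield
an undefined PA, which is recorded as missing and excluded from summaries,
never imputed. All schemes are bit-reproducible under a fixed seed and
invariant to input row order.

# What the validation suite does and does not show

The acceptance-style tests check: analytic identities (PAmax values,
Smith–Hazel identities, the single-marker GRM); agreement of EM-REML with a
brute-force restricted-likelihood grid on a 20-record instance; recovery of
$(h^2, t) = (0.25, 0.55)$ from 800 plants × 5 fruit within (0.07, 0.05) on
the mean of 20 seeds; recovery of $r_g = 0.7$ within 0.15 with the LRT
rejecting in at least 80% of seeds; type-I error of the covariance LRT and
the gain-model Wald F within 1–10% at nominal 5% over 200 null simulations;
a strictly increasing true-index trajectory over the GS cycles in at least
90% of 20 seeds against a drift-only control; and gain-slope recovery
within 2 SE in at least 90% of seeds. Problem sizes (800 plants for
recovery, 150 for null simulations, 200-plant populations with 250–400
markers for the driver) are chosen so the whole suite runs in minutes on
one core while keeping each check's sampling error well inside its
acceptance band.

Because the data are synthetic, passing these tests shows the estimators
and the scheme behave correctly *under the generative model* — it says
nothing about sequencing artifacts beyond the depth/missingness model,
genotype-by-environment interaction (not simulated, and not fit: the
original analysis discusses but never models it), non-additive genetic
variance, or the vagaries of real field trials.

# Known limitations

* Mean imputation only; no LD-aware imputation.
* No dominance or epistasis; no G×E terms.
* The Wald denominator degrees of freedom use containment, which is
  approximate for unbalanced multi-site designs.
* Genetic correlations at the PSD boundary (±1) are reported at the
  boundary; profile-likelihood intervals are not provided.
* The one-generation training lag is fixed; finer greenhouse timing is not
  modeled.
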