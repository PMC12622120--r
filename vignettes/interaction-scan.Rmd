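---
title: "Targeted estimation of variant-variant interaction effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted estimation of variant-variant interaction effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiescan)
```

## The estimands

`aiescan` detects epistasis between a *binding QTL* (bQTL, a variant that
changes a transcription factor's binding affinity, alleles b/B) and a
*facilitator QTL* (fQTL, a trans-acting variant that modulates the factor's
activity, alleles f/F) on a trait Y, adjusting for confounders W such as
population-stratification principal components plus sex and age.

The building blocks are model-independent causal contrasts. For a
single-allele change of one variant, the **average treatment effect** is

$$\mathrm{ATE}_{V_1:0\to 1}
  = E_W\big[\,E[Y\mid V_1{=}1, W] - E[Y\mid V_1{=}0, W]\,\big],$$

where the labels 0 and 1 denote two adjacent genotypes (e.g. bb and bB).
The **2-point average interaction effect** is the double difference over a
pair of single-allele changes,

$$\mathrm{AIE} = E_W\big[\,\mu(1,1,W) - \mu(0,1,W) - \mu(1,0,W)
  + \mu(0,0,W)\,\big], \qquad \mu(v_1,v_2,w) = E[Y\mid V_1{=}v_1,
  V_2{=}v_2, W{=}w],$$

positive for synergistic and negative for antagonistic epistasis. It is
algebraically the effect of changing both variants jointly minus the sum of
the two single-variant effects (`joint_minus_marginals_identity()` checks
this decomposition to machine precision). The **3-point AIE** is the
male-minus-female difference of sex-stratified 2-point AIEs, answering "does
the interaction differ by sex?"; a third variant could play the same
stratifying role.

These definitions impose no functional form. When the truth happens to be
linear, $Y = \alpha_0 + \alpha_1 V_1 + \alpha_2 V_2 + \gamma V_1 V_2 +
\delta' W + \varepsilon$, they collapse to familiar quantities: every
2-point AIE equals $\gamma$, and the marginal effect of $V_1$ equals
$\beta = \alpha_1 + \gamma\,E[V_2]$ — the interaction leaks into the
marginal coefficient in proportion to the partner's allele frequency. The
package's simulator and `oracle_effects()` expose exactly these identities
for validation, with $E[V_2] = 2\,\mathrm{maf}_2$ on the dosage scale.

## Transitions and positivity

Each variant pair contributes up to four interpretable components: the two
single-allele changes of the bQTL (bb→bB, bB→BB) crossed with the two of
the fQTL. A component is estimable only if all four joint-genotype corner
cells it touches have empirical frequency above a positivity threshold,
0.01 by default. `enumerate_transitions()` applies this minimum-genotype-
frequency rule to every corner cell of a candidate (the conservative
reading of a "minor genotype frequency" filter), returning the k ≤ 4
surviving components and a per-cell report. For 3-point components the
cell frequencies are computed within each sex stratum and both strata must
pass, so a sex-specific empty cell cannot slip through. We export k as the
number of sex-difference components (≤ 4); an 8-signed-component
representation of the same contrasts would give identical joint inference,
since the Hotelling statistic below is invariant to invertible linear
reparameterization.

## Estimation: TMLE with machine-learned nuisances

Estimation is semiparametric in two stages. First, two nuisance functions
are learned: the outcome regression $E[Y\mid V_1,V_2,S,\mathrm{age},W]$
and the joint genotype propensity $P(V_1,V_2\mid W)$. The default boosted
learner (gradient-boosted trees) cross-validates over tree depth and L2
regularization strength; a generalized-linear learner and a constant-mean
baseline are available behind the same interface, the latter doubling as a
misspecification probe. The propensity is modelled as a single 9-cell
conditional distribution rather than a product of per-variant models,
since the variants need not be independent given W; predicted cell
probabilities are clipped below at a floor (default 0.001, an order of
magnitude under the positivity threshold) and renormalized, so
inverse-propensity weights stay bounded without masking genuine positivity
violations, which are filtered upstream.

Second, each counterfactual cell mean $E[Y(v_1,v_2)]$ is *targeted*: the
outcome is mapped to $[0,1]$ (continuous traits are min–max scaled using
the observed range widened by 0.5% per side, recorded for
back-transformation), and a single weighted intercept-only logistic
fluctuation with clever-covariate weight
$\mathbf{1}\{V_1{=}v_1,V_2{=}v_2\}/\hat P(v_1,v_2\mid W)$ is applied to
the initial fit. The intercept fluctuation solves the efficient-influence-
curve (EIC) score equation exactly in one pass (a Newton solve, tolerance
1e-12), so no iteration is needed and the empirical mean of the EIC is
zero to solver precision. A 2-point component is the signed four-corner
sum of targeted cell means; cells shared between components are targeted
once. Its standard error is the EIC standard deviation over $\sqrt n$
(population-variance convention, so the covariance diagonal matches
exactly), and the estimator is asymptotically unbiased and normal when at
least one nuisance is consistently estimated — the double robustness that
the test suite probes by deliberately replacing one nuisance with the
constant baseline.

3-point components are male-minus-female differences of stratified 2-point
components, with nuisances refit within each stratum and each stratum's
EIC inflated by the inverse stratum proportion so the difference's EIC is
valid on the full sample.

## Joint testing and FDR

The k component estimates of one pair are correlated (they share corner
cells and samples), so they are tested jointly:
$T^2 = \hat\theta' \hat\Sigma^{-1} \hat\theta$ with $\hat\Sigma$ the
empirical EIC cross-covariance divided by n. Exploiting this correlation
structure is what makes the joint test more powerful than testing each
transition separately. The p-value $p_H$ uses the exact Hotelling F
reference $\frac{n-k}{k(n-1)}T^2 \sim F(k, n-k)$ — indistinguishable from
$\chi^2_k$ at biobank n but correct at the cohort sizes used in the test
suite; the $\chi^2$ p-value is reported alongside and selectable. A
numerically singular $\hat\Sigma$ (possible only far from biobank scale)
falls back to the Moore–Penrose pseudo-inverse with the effective rank as
test dimension, with a warning. Across a scan, Benjamini–Hochberg is
applied within each trait × TF group (`bh_adjust()`), and discoveries are
declared at $\mathrm{FDR}_H < 0.05$ by default.

## Power: why interactions are expensive

Under a working model in which each variant enters as a binary contrast
class with population frequency f, the marginal-effect estimator has
$\mathrm{SE} = \sigma/\sqrt{n f_1(1-f_1)}$ while the interaction estimator
pays a second variance factor:
$\mathrm{SE} = \sigma/\sqrt{n f_1(1-f_1) f_2(1-f_2)}$. Because
$f(1-f) \le 1/4$, equal-magnitude interactions are always harder to
detect. The parity factors are closed-form: matching the marginal test's
power requires multiplying the sample size by $1/(f_2(1-f_2))$ — 4 at
$f_2 = 0.5$, ≈ 21 at $f_2 = 0.05$ — or the effect by the square root of
that — 2 and ≈ 4.59 respectively. `mc_power_oracle()` verifies the closed
forms by brute-force simulation: the marginal arm fits the simple
regression `Y ~ V1` (whose slope SE is exactly the closed form's), the
interaction arm the saturated `Y ~ V1 * V2` via its equivalent cell-mean
contrast. Effects can be supplied in trait units or directly in
standard-error units.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes: biallelic genotypes in Hardy–Weinberg proportions; confounding in
which the first confounder coordinate shifts both the allele log-odds
(slope `confound_strength`) and the trait, making W a genuine common
cause; optional LD between the variants via a haplotype-copy mixture
(each allele copy of the template is retained with a probability solved in
closed form from the target dosage $R^2$ and marginal frequency, exact
under Hardy–Weinberg, with infeasible frequency/correlation combinations
rejected by name); sex Bernoulli(0.5) independent of genotype; age
uniform on 40–70 years, used only as an outcome-regression covariate; and
the linear structural trait model above, with an optional sex-modified
interaction coefficient `gamma_sex` for 3-point signal, a logistic link
for binary traits (a conventional choice keeping probabilities valid),
and an optional quadratic confounder effect to stress robustness to
outcome-model misspecification.

What the generator does **not** emulate — realistic LD blocks and
haplotype panels, multi-ancestry structure, genotyping error and
missingness, trait heritability from thousands of background loci —
bounds what passing tests show: they validate the estimation machinery
against its assumed data-generating class, not robustness to everything a
biobank contains.

Default study conditions used by the validation suite: interaction
recovery uses $\gamma = 0.3$ (and $\gamma_{sex} = 0.4$ for 3-point) at
n = 50,000 with allele frequencies 0.3, confounding slope 0.5 and unit
residual SD; confidence-interval coverage uses 500 replicates at
n = 5,000 with the generalized-linear nuisances (exactly specified for
this generator, the appropriate regime for a calibration check); null
calibration uses 1,000 replicates at n = 1,500 and a 200-entry null scan
at n = 2,000. These sizes are the package's choices for a desk-scale
validation of asymptotic guarantees.

## Numerical and design choices

* Dosages are always oriented as counts of the effect (B/F) allele; input
  orientation is normalized at load time and flipping is an involution.
* The marginal ATEs inside the joint-minus-sum decomposition hold the
  other variant at the transition's `from` level — the unique convention
  making the identity exact.
* Component ordering is fixed lexicographic (V1 change, then V2 change,
  then sex), so covariance layouts are reproducible.
* `mc_power_oracle`'s marginal arm uses `Y ~ V1` rather than the
  saturated fit because the closed form's SE is the marginal slope's; the
  saturated model's V1 coefficient would estimate a conditional effect
  with a different variance.
* Each manifest entry refits nuisances for its own variants and trait —
  simple and correct; caching across entries sharing a trait is left as
  an optimization.
* Cross-fitting of nuisances is not implemented; plain TMLE with in-sample
  nuisance fits is used throughout, which the coverage simulations support
  at the learner complexities shipped here.
* Per-entry failures in `run_scan()` are isolated into a status/error
  column, never aborting a scan; entries with k = 0 are reported as
  positivity skips.

## Known limitations

Binary-trait estimands are risk differences; odds-ratio-scale power is out
of scope. No BGEN/PLINK-binary readers and no biobank-scale performance
engineering: the scan loop is plain R over manifest entries. The
closed-form power expressions describe the continuous-trait working model
only. More than two variants plus a sex stratifier is not supported.
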