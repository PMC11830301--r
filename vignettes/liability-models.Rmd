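---
title: "Familial liability models for rare register phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial liability models for rare register phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famliab)
```

## The problem

Psychotic major depressive disorder is rare (lifetime prevalence around
0.2%) and its genetic epidemiology is therefore studied in national
registers, where millions of relative pairs compensate for the scarcity of
cases. The analyses this package implements are the standard register
toolkit for such a phenotype:

* **familial aggregation and coaggregation** — odds ratios for a relative
  carrying the same (or another) diagnosis when the proband is affected,
  estimated per kinship class with family-clustered robust standard
  errors;
* **liability-scale heritability** — an ACE/AE variance decomposition of a
  latent normal liability, identified by contrasting full siblings (who
  share half of the additive genetic variance A and all of the shared
  environment C) with first cousins (one eighth of A, none of C);
* **genetic correlations** between traits, including the awkward case of
  *mutually exclusive* diagnoses (a person is either psychotic or
  non-psychotic MDD, never both), where all cross-trait information lives
  in cross-relative contrasts;
* **case–case polygenic-score models** — per-SD odds ratios for being the
  psychotic rather than the non-psychotic subtype among diagnosed cases;
* **fixed-effect meta-analysis** pooling estimates across cohorts.

Because the real register data are access-restricted, the package pairs
every estimator with a synthetic register generator whose ground truth is
known exactly, so that each stage of the pipeline can be validated by
parameter recovery.

## The liability-threshold model and the generator

Each trait $t$ has a standard-normal liability
$\ell_t = g_t + c_t + e_t$ with variance shares $a^2_t + c^2_t + e^2_t =
1$; the person is diagnosed when $\ell_t$ exceeds
$z_t = \Phi^{-1}(1 - K_t)$ for prevalence $K_t$. Cross-trait structure
enters through correlation matrices for the genetic ($r_g$), shared
($r_c$) and unique environment ($r_e$) components.

`simulate_population()` builds three-generation families from a fixed
template: a grandparental couple, two of their children married to
unrelated founders, and the two resulting sibships — so full siblings,
maternal half siblings (via an optional second partner) and first cousins
all arise naturally, and kinship never needs general-graph computation.
Genetic values are *transmitted* (child = mid-parent plus a Mendelian
deviation with half the additive covariance), which yields the classical
expected liability correlations

| kinship | correlation |
|---|---|
| full siblings | $0.5\,a^2 + c^2$ |
| half siblings | $0.25\,a^2 + \kappa\,c^2$ |
| first cousins | $0.125\,a^2$ |

The half-sib shared-environment coefficient $\kappa$ defaults to 0: the
full-sib/cousin contrast used by the estimators leaves it unidentified, so
any default is a modelling convention rather than an estimable quantity.
`simulate_pairs()` is the vectorised pair-level counterpart: it draws
directly from the exact joint normal of one pair, in memory-bounded
chunks, and is what the recovery experiments use at millions of pairs.

Mutual exclusivity is applied as a masking rule — by default "psychotic
wins": a person whose psychotic and non-psychotic latent diagnoses both
fire is recorded as psychotic MDD, mirroring the register convention that
any F32.3/F33.3 code labels the person psychotic. Diagnosis ages are drawn
uniformly over an onset window (default 18–45 years), and comorbid
bipolar, schizophrenia/schizoaffective and other-psychotic codes are
placed before or after the first MDD code with configurable probabilities
(defaults 15.9%/17.4%/21.9% for the psychotic subtype, with 30% placed
before), so that conversion tables are non-trivial. Treatment events
(antipsychotics, ECT) are emitted with subtype-specific probabilities.
Polygenic-score columns are normal scores mean-shifted in psychotic cases
by the configured per-SD log odds ratio; for a binary outcome and normal
scores this mean-shift construction makes the logistic model hold exactly
with coefficient equal to the shift.

What the generator deliberately does **not** emulate: calendar-time
censoring processes correlated with diagnosis, diagnostic drift across
ICD revisions, assortative mating, sibling-environment interactions, and
genotype-level structure (scores are simulated directly, not built from
variants). Passing recovery tests therefore demonstrates the estimators
are correct under the generating model, not that the model captures every
feature of register data.

## Phenotype definitions

`classify_mdd()` implements two definitions. The *main* definition labels
any carrier of F32.3/F33.3 as psychotic MDD and any other F32/F33 carrier
as non-psychotic MDD, without excluding bipolar or schizophrenia
diagnoses (so diagnostic conversion remains observable). The
*restrictive* definition removes bipolar-disorder carriers from all MDD
and schizophrenia/schizoaffective carriers from psychotic MDD. The
shipped `codes.yaml` also carries the alternative "severe-episode"
psychotic code set (F32.2/F32.3), because both conventions appear in the
literature for these sub-codes; the choice is surfaced as configuration
rather than resolved silently. The sibling birth-gap filter (10 years)
applies to full- and half-sibling pairs only — it exists to limit cohort
effects between siblings, and cousinship is derived from the unfiltered
pedigree.

## Familial aggregation

`fit_cluster_logit()` fits ordinary logistic maximum likelihood — the
point estimates of a GEE with independence working correlation — and
reports the cluster sandwich variance over families with no small-sample
adjustment. Each unordered pair enters in both orderings (each member once
as proband, once as relative), which is exactly why family clustering is
required. Two identities pin the implementation down: with one
independent pair per family the sandwich collapses to the classical
Woolf/model-based SE (asserted to 1e-8; the IRLS convergence tolerance is
tightened to make this hold), and duplicating every family under new ids
leaves the OR untouched while scaling the SE by exactly $1/\sqrt{2}$.
Covariates follow the "sex- and birth-year-adjusted" convention: relative
sex as an indicator and a centred linear birth-year term.

## Tetrachoric correlations and ACE/AE fits

`tetrachoric()` inverts the bivariate-normal orthant probability
$P(\ell_1 > z_1, \ell_2 > z_2; \rho)$ at the observed concordance by
bracketed root finding (tolerance 1e-12 on $\rho$). The bivariate normal
CDF is implemented in-package (`pbvn()`): Drezner–Wesolowsky quadrature
with Genz's expansion above $|\rho| = 0.925$, accurate to near machine
precision, vectorised over limits. Zero concordant cells return the
boundary estimate ($\rho = \pm 1$) with a flag instead of failing, which
matters for bootstrap replicates of rare traits. The delta-method SE
$\sqrt{p_{11}(1-p_{11})/n}\,/\,\phi_2(z_1, z_2; \rho)$ ignores threshold
uncertainty — appropriate when prevalences are (optionally) constrained,
and a second-order effect otherwise. One caveat discovered while
validating against adaptive quadrature: when the thresholds are far apart
and $|\rho|$ is high, $\partial P_{11}/\partial\rho$ underflows (e.g.
$\approx 5\times10^{-14}$ at $z = (-2, 1.5)$, $\rho = 0.9$) and *no*
double-precision method can resolve $\rho$ finely there; the oracle tests
restrict themselves to cells where the derivative exceeds 1e-6.

`fit_ace_wls()` minimises the inverse-variance-weighted distance between
the observed full-sib and cousin tetrachorics and their structural values
$(0.5a^2 + c^2,\ 0.125a^2)$. The AE model leaves a 1-df fit statistic;
the just-identified ACE model is solved exactly
($a^2 = 8 r_C$, $c^2 = r_{FS} - 4 r_C$) with boundary projection and a
flag when the unconstrained solution leaves $[0,1]$ — for example when
the cousin correlation exceeds a quarter of the sibling one. Model
comparison (`compare_models()`) uses the difference of fit statistics
(WLS) or the likelihood ratio (ML); when the constrained parameter sits on
its boundary, as in testing $C = 0$, the 50:50 mixture p-value (half the
chi-square tail) is reported alongside the conservative default.

## Genetic correlation, including mutually exclusive traits

For a trait pair the model adds three structural quantities: the
within-person cross-trait correlation
$r_w = r_g\sqrt{a^2_1 a^2_2} + r_e\sqrt{e^2_1 e^2_2}$ (with $r_e = 0$ by
default, configurable), the cross-person same-trait correlations
$\phi\,a^2_t$, and the cross-person cross-trait correlation
$\phi\,r_g\sqrt{a^2_1 a^2_2}$, where $\phi$ is the kinship's additive
sharing. This is the simplest AE structure consistent with the estimators'
symbols and is stated prominently as an assumption.

`fit_rg_ml()` maximises a multinomial likelihood over the pair outcome
categories — 3 per person for an exclusive pair (none / psychotic /
non-psychotic), 4 otherwise — with cell probabilities from
`pair_category_probs()`. Rather than a 4-dimensional rectangle algorithm,
the probabilities use an exact conditional factorization: conditional on
the pair's *shared* bivariate factor (the family-level component, with
covariance equal to the cross-person block), the two relatives' liability
vectors are independent bivariate normals, so each cell is a 2-D
Gauss–Hermite average (48 nodes per dimension) of closed-form
bivariate-normal rectangle probabilities. Both residual blocks
$W \pm B$ are PSD whenever the input correlation matrices are, the
computation is deterministic, and each node's person-category vector sums
to one, so the 3×3/4×4 probability table sums to one by construction
(asserted to 1e-8); a candidate point that violates PSD is rejected with
a penalty rather than crashing the optimiser.

Thresholds are calibrated to the *observed* person-category margins: the
winning trait's threshold directly ($z_1 = \Phi^{-1}(1-\hat p_1)$, exact
because masking never hides the winner), and the masked trait's threshold
by solving $\Phi(z_1) - \Phi_2(z_1, z_2; r_w) = \hat p_2$ inside every
likelihood evaluation, so the margins are matched exactly at any $r_g$.
Marginal heritabilities are fixed at their univariate AE-WLS estimates
(two-stage estimation, the common practice); a joint-ML experiment over
$(r_g, a^2_1, a^2_2)$ gave the same spread (SD 0.057 vs 0.057 over ten
replicates at register scale), so the two-stage default stands. The
likelihood is optimised over $r_g \in (-1, 1)$ by golden-section search —
it is smooth and unimodal in all profiled cases examined — and
likelihood-ratio tests against $r_g = 0$ and $r_g = 1$ are reported
(Wald-style bootstrap tests are available via the bootstrap replicates).
One asymmetry is intentional: the exclusive model's masking rule is
directional, so label-swap invariance holds exactly only for the
non-exclusive model.

## Bootstrap and meta-analysis

`bootstrap_ci()` resamples *families* with replacement and reweights the
per-pair rows by the family multiplicities, so cross tables are rebuilt in
O(pairs) per replicate without copying data; percentile 95% intervals
follow the register convention (1000 replicates there; tests use 200 at
reduced designs, where measured coverage sits in the low-to-mid 90s, the
expected mild undercoverage of percentile intervals). `rg_difference_test()`
compares two genetic correlations on the paired bootstrap distribution of
their difference. `meta_fixed()` pools log odds ratios with inverse-variance
weights; heritabilities are pooled on the raw scale with weights from
bootstrap SEs, since the register convention reports fixed-effect pooling
without a scale specification.

## Case–case polygenic-score models

`fit_prs_models()` standardizes each score within the analysis sample
(sample SD, idempotent, zero-variance columns are errors) and fits
univariate or mutually-adjusted logistic models for psychotic versus
non-psychotic cases, adjusted by default for sex, age and any PC1–PC5
columns present. An aggregate bipolar score is barred from entering a
joint model with its subtype scores (a deliberate collinearity guard).
The generator reproduces the characteristic sign flip: an MDD score that
is marginally null turns protective once positively correlated
schizophrenia/bipolar scores are adjusted for. Upstream score
construction — effect rescaling, MAF/INFO filters, MHC exclusion — is out
of scope; the module consumes ready-made scores.

## Numerical choices and problem sizes

* `pbvn()`: 24-node Gauss–Legendre on the Drezner–Wesolowsky integrand;
  high-correlation branch above $|\rho| = 0.925$; validated against nested
  adaptive quadrature to ~1e-9.
* Quadrature for pair categories: 48 Gauss–Hermite nodes per dimension;
  category tables sum to 1 within 1e-8 across the tested parameter grid.
* Root finding: `uniroot` at tolerance 1e-12 ($\rho$, thresholds);
  logistic fits at IRLS epsilon 1e-14 so closed-form identities hold.
* Ties between a comorbid code and the first MDD code count as "before"
  (conversion-to-MDD reading), configurable.
* The recovery experiments run at the register-scale design: 2.5 million
  full-sib and 6.3 million cousin pairs for heritability and genetic
  correlations, 500,000 pairs for aggregation, 50,000 cases for the
  score models; the full suite completes in a few minutes on one core.

## Known limitations

At a 0.2% prevalence, even millions of pairs contain only tens of
concordant affected pairs, so single-run recovery estimates of
heritability, the exclusive-trait genetic correlation and the aggregation
OR carry substantial Monte-Carlo spread (measured SDs of about 5.7
percentage points, 0.057 and 1.0 respectively at the design sizes above —
the genetic-correlation spread matching the width implied by the register
study's own bootstrap interval). Recovery assertions are therefore made
against multiple-of-SE tolerances or confidence-interval coverage, not
point equality. The exclusive-trait parameterization is an assumption, not
an estimate; half-sib shared environment is a convention; and no
dominance, gene–environment interaction or twin-specific structure is
modelled.
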