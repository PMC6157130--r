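---
title: "Path models for direct and indirect SNP effects on triglycerides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path models for direct and indirect SNP effects on triglycerides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsem)
```

## The scientific problem

Genome-wide association studies have mapped many loci for fasting
triglycerides (TG), but a marginal SNP-TG association says nothing about the
route: a variant may act on TG directly, through earlier TG measurements that
track forward in time, through a correlated lipid such as HDL cholesterol, or
through methylation at a nearby CpG (an mQTL acting as a mediator). With
longitudinal lipids (four clinic visits), genotypes, and array methylation
measured in families, an observed-variable structural equation model (path
analysis) can estimate all these routes *simultaneously*, so each pathway
estimate is conditional on every other modeled route.

`lipidsem` implements that analysis for one tag SNP at a time: the a priori
model structure, maximum-likelihood estimation, family-clustered sandwich
inference, fit-index gating, CpG pruning, and the decomposition of the SNP's
effect on visit-4 TG (TG4) into direct and indirect pathway contributions. A
calibrated synthetic cohort generator stands in for the restricted family
study the design emulates, so every statistical property of the pipeline is
testable end to end.

## The model

For endogenous variables $y$ (TG1-TG4, HDL1-HDL4, one variable per modeled
CpG) and exogenous variables $x$ (SNP dosage plus covariates),

$$ y = \nu + B\,y + \Gamma x + \varepsilon, \qquad
   \varepsilon \sim N(0, \Psi), \ \Psi \text{ diagonal}, $$

with $B$ strictly lower-triangular in a topological order (a recursive
system). The default edge set is:

* lag (tracking) effects $TG_{t-1} \to TG_t$ and $HDL_{t-1} \to HDL_t$;
* contemporaneous $HDL_t \to TG_t$ (carrying the inverse TG-HDL dependence);
* $SNP \to TG_t$ and $SNP \to HDL_t$ at every visit;
* $SNP \to CpG_j$ and $CpG_j \to TG2$ for each CpG — methylation was measured
  at visit 2, so CpGs act only there, and each extra CpG adds exactly four
  free parameters (two edges, an intercept, a residual variance);
* every covariate on every lipid visit. Covariates do not point at CpGs:
  technical methylation confounding is removed upstream by principal-component
  residualization, and giving CpGs covariate parents would break the
  4-parameters-per-CpG structure.

Estimation conditions on the exogenous variables; their moments are not
modeled. Because the system is recursive with diagonal $\Psi$, the
conditional likelihood factorises over equations, and the ML solution equals
per-equation least squares with variance divisor $n$. Both routes are
implemented — `method = "ols"` (closed form) and `method = "ml"` (BFGS plus a
monotone Newton polish on each equation's Gaussian likelihood) — and the test
suite requires them to agree to $10^{-6}$ on random recursive systems; the
closed form is the oracle for the optimizer, never its implementation.

### Family-clustered inference

Families induce within-cluster correlation that the per-equation model
ignores. All inference therefore uses the Huber-White sandwich
$A^{-1} B A^{-1}$, where $A$ is the expected information of the stacked
per-equation likelihood (block-diagonal; inverted blockwise, which also
avoids mixing mg/dL-scale lipid blocks with beta-value-scale CpG blocks in
one ill-conditioned solve) and $B$ sums outer products of per-family score
sums. With singleton clusters this reduces exactly to HC0. No small-sample
degrees-of-freedom correction is applied by default; a $G/(G-1)$ factor is
available via `small_sample = TRUE`. At the design's 172 families the
correction is a 0.3% SE change, and simulated 95% robust intervals cover true
parameters at ~94% (inside the 93-97% acceptance band).

### Fit indices and gating

The likelihood-ratio statistic is $T = 2(\ell_{sat} - \ell_{model})$ against
the saturated conditional Gaussian (full multivariate regression of all
endogenous on all exogenous variables with free residual covariance); the
$(n-1) \times F$ variant would differ only at small $n$ and the
likelihood-ratio form was chosen and documented. The independence baseline
(all endogenous mutually independent with free means and variances — the
conventional null, since the source analysis does not define its baseline)
feeds CFI and TLI:

$$ \mathrm{RMSEA} = \sqrt{\frac{\max(T - df, 0)}{df \cdot n}}, \quad
   \mathrm{CFI} = 1 - \frac{\max(T - df, 0)}{\max(T_b - df_b,\, T - df,\, 0)}, \quad
   \mathrm{TLI} = \frac{T_b/df_b - T/df}{T_b/df_b - 1}. $$

A model fits poorly when RMSEA $\ge 0.10$ *or* CFI $\le 0.9$ *or* TLI
$\le 0.9$. The gating sentence in the source is grammatically ambiguous
between "and" and "or"; the disjunctive reading is the conservative one and
is the default (`rule = "any"`), with the conjunctive variant behind a flag.
Indices use the unadjusted ML statistic, not a robustness-scaled one — a
documented divergence risk against software that defaults to scaled
estimators.

### CpG pruning

If the full model fails the gates, CpGs whose two paths (SNP→CpG and
CpG→TG2) are **both** nonsignificant at robust $p > 0.2$ are removed in one
pass and the model is refit once (`iterate_prune = TRUE` enables repetition;
the source analysis needed a single pass). "Nonsignificant CpG" is not
defined precisely in the source; the conjunction reading was chosen because
a CpG with *either* path active still carries a candidate mediation route.
Under the conjunction rule a fully null CpG has removal probability
$\approx 0.8^2 = 0.64$ (two roughly uniform p-values), not $\ge 0.9$; the
`"either"` variant removes it with probability $\approx 0.96$. The tests
assert these analytically derived rates rather than a folk expectation. A
locus whose pruned model still fails the gates yields **no** pathway claims.

### Pathway effects

Every simple directed path from SNP to TG4 is enumerated (deterministic
lexicographic order; checked against an adjacency-matrix-power counting
oracle). A chain's effect is the product of its edge coefficients; its SE is
the multivariate delta method $g^\top V g$ with $g_k = \prod_{j \ne k}
\hat\beta_j$ and $V$ the robust covariance of the chain coefficients
*including cross-equation covariances* (the stacked sandwich makes these
non-zero, so this is strictly more faithful than the independence-assuming
Sobel formula, to which it reduces for two independent coefficients). The
total effect is read off the reduced form $(I-B)^{-1}\Gamma$ and equals the
direct edge plus the sum of all chain products exactly — an identity the
tests verify to $10^{-10}$.

Reported pathways must reach nominal $p < 0.05$ (two-sided normal, the
conventional ML default) *and* be directionally consistent with the locus's
expected TG direction from prior GWAS. For multi-edge chains "direction" is
evaluated on the sign of the whole product (the product-sign convention —
the source does not define the rule for chains whose segments have mixed
signs). Across loci, a Bonferroni threshold $0.05/n_{loci}$ is applied
(0.05/12 reported as 0.004 at one significant digit). Under a locus with no
SNP effects, nominal $p<0.05$ rates per chain sit at $\alpha$ because only
the SNP edge of each chain is null; the directional filter then halves the
retained rate by sign symmetry.

## The synthetic cohort generator

The generator is a first-class, tested module that emulates the family study
the models were built for: 172 nuclear families totalling 810 genotyped
adults, 707 with complete methylation; ~50% women; mean baseline age 48;
two centers; fenofibrate given to everyone between visits 2 and 3, dropping
both the mean and the variance of TG.

Design choices, in the package's own words:

* **Lognormal lipids, exact two-moment calibration.** TG is strictly positive
  and right-skewed and only per-visit means/SDs are published, so each
  visit's marginal is lognormal with moments matched to the targets. The
  structural model lives on the log scale — effects are proportional
  (per log-unit) rather than additive mg/dL, the one coherent choice given
  positivity plus moment calibration. Every log-lipid is a linear
  combination of independent primitives (dosage, binary/normal covariates,
  CpG noise, family intercepts, visit residuals), so each visit's intercept
  and residual variance are solved *exactly* from products of primitive
  moment-generating functions; sample moments converge to the printed
  targets as $n$ grows (the acceptance suite checks 2-3% agreement at
  $n = 50{,}000$).
* **Visit targets.** TG1 106.35[106.35] and TG2 140.16[99.34]. The printed
  TG1 SD exactly equals its mean — a suspected transcription artifact — so
  TG1 is kept as-is as a default but excluded from calibration-accuracy
  acceptance targets. Visit 3-4 targets are *constructed* as the visit-2
  target times fenofibrate mean/SD multipliers whose defaults are the
  printed post/pre ratios (hence defaults reproduce 92.26[57.41] and
  90.14[55.07] exactly, and multiplier 1 makes visits 3-4 match visit 2 —
  the "no drug" invariant). Fenofibrate is a pure mean/variance shift; no
  pharmacokinetics.
* **HDL moments are not published**: mean 47, SD 13 mg/dL are invented,
  flagged defaults, excluded from acceptance targets.
* **Pedigrees** are nuclear (two founders, Mendelian allele transmission,
  Hardy-Weinberg founders at the tag SNP's EAF); the real study's extended
  pedigrees are out of scope since nuclear structure suffices to exercise
  clustered inference. The family-size distribution is unpublished; the
  default (sizes 2-8, mean 4.71) is a documented guess that makes 172
  families average 810 members, and totals are adjusted to hit the target
  count exactly.
* **Methylation**: each CpG's beta value is a clamped linear mQTL model
  `base + slope * dosage + noise` in [0,1]; by default the first CpG at a
  locus is an active mQTL (0.04 beta-units/allele) that also shifts visit-2
  log-TG, and the remaining CpGs are null — giving the pruning rule real
  targets. With only a handful of locus CpGs the genome-wide PC adjustment
  would regress the biology on itself, so the pipeline skips PC
  residualization unless the supplied beta matrix is wide (> 5 x `n_pcs`
  columns); the PC module itself is fully exercised on wide matrices.
* **Missingness** is completely at random; by default exactly
  `round(707/810 * n)` individuals are flagged complete-case (707 at the
  default size), or a plain MCAR rate can be supplied.
* **Remaining invented rates** (not published anywhere in the source):
  smoking prevalence 0.18, equal center split, age SD 12 years, family
  intercept SDs 0.12 (log-TG) and 0.05 (log-HDL), lag coefficients 0.5/0.6,
  HDL-to-TG elasticity -0.35, SNP effects 0.04/-0.05 log-units per allele.
  Chosen once as field-plausible values and not revisited.

**What a green test does and does not establish.** The generator reproduces
the published *marginal* moments, demographic mix, family clustering, and
the qualitative structure the model assumes (tracking, inverse TG-HDL
coupling, an mQTL-mediated route, the fenofibrate shift). It does not
reproduce real LD structure, array measurement error, cell-type mixture,
extended-pedigree kinship, or the real study's joint distributions — so
passing tests validate the *statistical machinery*, not any biological claim
about a specific locus.

## Numerical choices

* ML optimization: per-equation BFGS (analytic gradient, internally
  standardized columns) then Newton-Raphson with step-halving; the
  likelihood is non-decreasing across iterations and the gradient norm must
  fall below `tol * n` (`tol = 1e-10`). A supplied `init` starts Newton
  directly, so initialization at the optimum converges immediately.
* Rank-deficient equation designs raise an error naming the equation;
  missing data are an error (complete-case analysis only; full-information
  ML for missingness is out of scope).
* The CpG selection window around a tag SNP is a *closed* interval (a CpG at
  exactly 10 kb is included); positions are 1-based hg19. An empty 10 kb
  window triggers a single 20 kb fallback.
* Methylation PC signs are fixed by making each component's
  largest-magnitude loading positive, so results are machine-deterministic.
  Residualized beta values may leave [0,1]; downstream modeling treats them
  as continuous, which is consistent with the linear SEM.
* `simulate_from_theta()` draws its optional family intercept independently
  per endogenous equation. A single intercept shared across equations would
  correlate with endogenous parents and bias the coefficient estimands —
  the package's coverage simulations depend on this distinction.
* Degenerate fit-index inputs: `df = 0` yields RMSEA 0/CFI 1 (saturated
  model); a degenerate baseline ($T_b \le df_b$) reports both incremental
  indices as 1 with a warning.

## Design decisions on genuinely open points

* The exact arrow set of the source's model figure is not recoverable from
  text; the default structure is reconstructed from the methods description
  and the reported pathway chains, and every assumption can be overridden
  through `structure_overrides` (subject to acyclicity).
* The published per-locus "Parameters" counts follow an unstated software
  convention that the text does not determine; this package counts one
  parameter per edge plus an intercept and a residual variance per
  endogenous variable, which reproduces the published +4-per-CpG increments
  but not the absolute counts. Those counts are not acceptance targets.
* The published locus table implies six exogenous variables per model; only
  four covariates (sex, baseline age, center, baseline smoking) are
  identifiable from the text, and a filler column would be collinear, so the
  default covariate list has four entries and the builder accepts any list.
* Expected TG directions per locus are not published; for the five loci with
  reported pathways the direction is set from the sign of the reported chain
  products, and the remaining seven carry a +1 convention, flagged in the
  packaged table's `direction_source` column.
* Whether published chain SEs came from the delta method or a bootstrap is
  unstated; the delta method is implemented, with a 10,000-draw parametric
  bootstrap as a test oracle (agreement within 5% required).

## Known limitations

* Linear SEM on raw mg/dL lipids applied to lognormal data is (mildly)
  misspecified; at the design sample size the fit gates pass comfortably
  (typical RMSEA ≈ 0.03), but the fitted coefficients are linear
  approximations of a multiplicative world — exactly the situation a real
  analysis of skewed lipids faces.
* The sandwich is HC0-style; with few clusters it is anti-conservative (a
  warning fires when clusters ≤ parameters, and the G/(G-1) option exists).
* No latent variables, non-recursive structures, correlated residuals,
  FIML, LD-aware multi-SNP models, or methylation-on-HDL routes.

## A worked example

```{r example, eval = FALSE}
coh <- simulate_cohort(cohort_config(), seed = 5)   # 810 members, 707 complete
rep1 <- run_locus(coh)                              # fit, gate, decompose
print(rep1)
write_locus_report(rep1, "locus_out")               # Table-2-style TSV + JSON
multi <- run_all_loci(goldn_loci(), n_individuals = 810, seed = 1)
```
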