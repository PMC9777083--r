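---
title: "Building rank-based gene-pair survival signatures with reosurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building rank-based gene-pair survival signatures with reosurv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosurv)
```

## Why orderings instead of expression values

A prognostic gene-expression model that thresholds a weighted risk score
inherits every systematic bias of the measurement pipeline: platform
chemistry, normalization, batch. The threshold learned on one cohort does not
transfer, and re-normalizing a new sample against a reference set makes the
prediction depend on which other samples happen to be at hand — the opposite
of an individualized test.

`reosurv` instead uses only the *relative expression ordering* (REO) of gene
pairs within one sample: the indicator that gene $G_a$ is expressed above
gene $G_b$. Any strictly increasing distortion of a sample's values — scale,
shift, log, platform response curve — leaves every one of its REOs unchanged.
A classifier built from REOs can therefore be applied to a single sample on
any platform that measures its genes, with no normalization step.

The assumptions are the standard ones of the component models: proportional
hazards for the Cox screens (a pair's ordering shifts the hazard by a
constant factor over time), non-informative right-censoring, and — implicit
in any cross-cohort screen — that the direction of a gene's survival
association is a property of the disease rather than of one platform.

## The training cascade

1. **Gene screen** (`screen_genes`). For every gene in the common universe of
   the training cohorts, a univariate Cox model is fitted per cohort on the
   expression values. A gene survives when its Wald $p < \alpha$ (default
   0.05) in at least one cohort and its coefficient has the same sign in
   every cohort where the fit converged. The sign-consistency requirement is
   the strict reading of cross-platform agreement: a gene whose hazard
   direction flips between platforms cannot give a transferable orientation.
   Cohorts where the fit did not converge are treated as abstentions rather
   than contradictions.
2. **Pair screen** (`enumerate_pairs`, `build_reo_matrix`, `screen_pairs`).
   All $g(g-1)/2$ pairs of surviving genes are formed (canonical order:
   lexicographically smaller gene first). The REO matrix is binary with
   $x_{ij}=1$ iff $E_a > E_b$ strictly; ties fall into the $\le$ state. Pair
   Cox models are fitted on the *pooled* training samples: the gene screen is
   per-cohort because expression values are not cross-platform comparable,
   but REO indicators are, and pooling gives one Benjamini–Hochberg family
   and maximal power for the pair stage. Pairs with a constant indicator
   carry no information and are dropped *before* the BH adjustment, so the
   family is the set of pairs actually tested. Significant pairs (adjusted
   $p < 0.05$) are oriented: the risky state is the indicator value with the
   positive coefficient, so each oriented pair's concordance index is at
   least one half on the training data.
3. **Greedy combination search** (`greedy_build`). The score of a combination
   is its *risky-vote fraction* — the share of member pairs sitting in their
   risky state. The search seeds one combination from each of the top
   `n_seeds` (default 10) candidates and makes a single pass over the
   remaining candidates in decreasing individual-concordance order, accepting
   a candidate when it increases the combination's training concordance by
   more than $10^{-12}$ (a strict-improvement rule; the tolerance only
   absorbs floating-point noise). One deterministic pass, rather than
   iterating to convergence, keeps the procedure order-stated and cheap; the
   objective is non-decreasing along accepted additions, so every final
   combination scores at least its seed. The same genes may appear in several
   pairs of one combination.
4. **Test-set selection** (`select_final`). Each combination's vote fraction
   is evaluated on an independent test cohort with a univariate Cox model.
   Among combinations with test $p < 0.05$ — significance is a gate, not a
   ranking — the one with the largest test concordance of the *continuous*
   score becomes the signature. The continuous score is used (rather than the
   dichotomized label) because it carries strictly more ranking information.
5. **Classification** (`classify`). A sample is high-risk when at least half
   of the signature pairs detected on its platform are in their risky state.
   Undetected pairs are removed before voting, which is what lets the
   signature cross platforms with partial gene coverage. An exact tie is
   called high-risk — the conservative direction for a triage tool — and the
   call is flagged in the output. A call never uses another sample's values.

## Statistical kernel

* **Cox fits** (`cox_fit`) wrap `survival::coxph` with Breslow tie handling
  (the simplest consistent choice) and Wald p-values and 95% CIs, matching
  what forest-plot software reports. Screening loops need fits that never
  throw: a constant covariate, fewer than two events, a failed fit, or a
  runaway coefficient ($|\hat\beta| > 15$, the signature of a monotone
  partial likelihood under perfect separation) all return a flagged
  non-converged row with $p = 1$, which screens treat as "skip".
* **Concordance** (`concordance_index`) uses Harrell's rule with the strict
  comparability definition: pair $(i,j)$ is comparable iff $t_i < t_j$ and
  sample $i$'s event was observed; censored–censored pairs and pairs tied on
  time are not comparable; score ties count one half. Note one consequence:
  a binary score that separates early from late deaths perfectly still has
  $C < 1$, because within-group comparable pairs are score ties.
* **Time-dependent AUC** (`td_auc`) is the cumulative-case / dynamic-control
  estimator with inverse-probability-of-censoring weights from the
  Kaplan–Meier estimate of the censoring distribution ($G(t^-)$ for cases,
  $G(t)$ for controls), written in-package. Without censoring it reduces
  exactly to the Mann–Whitney AUC of the dichotomized outcome, which is how
  the tests pin it down. Horizons with no case or no control, or with a zero
  censoring-survival weight, are reported as not computable and excluded
  from the mean AUC rather than extrapolated.
* **Fisher tests** (`fisher_2x2`) report the exact two-sided p-value (sum of
  hypergeometric probabilities at most as likely as the observed table) and
  the *sample* odds ratio $ad/bc$ — not the conditional MLE that
  `fisher.test` prints — so published contingency tables reproduce digit for
  digit. `drug_response_analysis` collapses RECIST CR/PR to sensitive and
  SD/PD to resistant, and reports the low-risk sensitivity odds ratio with
  its exact reciprocal for resistance.
* **Multiple testing** is Benjamini–Hochberg throughout (`bh_adjust`, a
  validating wrapper over `stats::p.adjust`).

## Preprocessing rules

`preprocess_cohort` applies, in order: removal of samples lacking survival
fields or with non-positive survival time; collapsing of duplicate gene IDs
by the element-wise mean over non-missing cells; removal of genes whose value
is missing or exactly zero in strictly more than half the samples (the
"more than half" rule is a strict inequality: 2 missing out of 4 is kept,
3 out of 5 is dropped). The low-expression fraction is configurable. Only
survival fields are required — age, stage, grade and drug response stay
optional, and downstream multivariate models use whichever are present.
Tumor/normal annotation is the caller's responsibility, since it is an input
annotation, not something inferable from the matrix. Survival is stored in
months; the reader converts days with the mean month length 30.44.

## What the generator emulates — and what it does not

`sim_config()` defaults define the reference study conditions: five cohorts
(three training, one test, one validation) of 150 samples, a 300-gene shared
universe with 30 prognostic genes (half up with risk, half down), unit
log-hazard per unit latent risk ($\beta = 1$), unit expression signal against
unit noise on an intensity-like baseline (mean 6, SD 2), exponential survival
with baseline median 40 months — inside the 35–60 month range of median
follow-up typical for serous ovarian cancer cohorts — and a 30% censoring
target, calibrated by root-finding the exponential censoring rate against the
realized hazards. Each cohort receives its own strictly increasing cubic
distortion and per-sample log-normal gains, emulating platform response and
scaling differences while preserving every within-sample ordering exactly
(the distortion parameters are drawn from the RNG stream whether or not the
distortion is applied, so distorted and undistorted runs of the same seed
share the same underlying data). Survival times are rounded to two decimals
as clinical tables report them; an `exact_times` flag disables this for
oracle tests. Optional covariates (age/stage/grade) and RECIST drug response
are weakly coupled to the latent risk.

The generator does **not** emulate: heavy-tailed or platform-specific
intensity distributions, probe-level noise or missingness patterns,
correlated gene modules (genes are conditionally independent given the latent
risk), non-proportional hazards, informative censoring, or cohort-specific
case mix. Passing tests on these cohorts therefore demonstrates correctness
of the machinery and recoverability of a planted qualitative signal under
monotone platform distortion — not clinical performance on real data.

Problem sizes used in the test suite are deliberately desk-scale: null
calibrations run at 40–60 genes and cohorts of 60–100 samples over 10–20
replicates, and the parameter-recovery run uses the reference configuration
above. These sizes give stable Monte-Carlo levels (pilot runs put the null
gene-screen retention near 0.04 against the 0.05 bound) while keeping the
whole suite in the low minutes.

## Numerical and degenerate-input choices

* Strict improvement ($> 10^{-12}$) for greedy acceptance; candidate order is
  descending concordance with lexicographic gene-ID tie-breaks, so the search
  is fully deterministic.
* Cox Newton iterations are capped at 50; non-convergence is a flagged
  result, never an exception.
* `concordance_index` errors on data with no comparable pair (everything
  censored, or all times tied) instead of returning 0.5: an uninformative
  dataset should be visible, not averaged away.
* An exact vote tie classifies as high-risk and is flagged.
* Empty 2×2 margins make the Fisher p degenerate (reported as 1 with a flag);
  negative cells are hard errors.
* A cohort left empty by preprocessing, a zero gene-universe intersection,
  and a signature with no detected pair on a platform are hard errors naming
  the cohort or platform.

## Invariance: what is guaranteed where

Everything downstream of the REO construction — pair screening, the greedy
search, classification — is *bitwise* invariant under arbitrary strictly
increasing per-sample transforms of expression, and the test suite asserts
this by running the stages twice and comparing outputs exactly. The
gene-level screen, however, is fitted on expression values (orderings of one
gene across samples are exactly what REOs discard), so its invariance is
narrower: per-cohort positive affine rescaling leaves coefficients' signs and
Wald p-values unchanged and hence the screened gene set and the whole
downstream result; an arbitrary per-sample monotone map can in principle
change which genes pass. This is an inherent property of screening on values,
not an implementation artifact; the distortions the generator applies are
exactly the kind the end-to-end pipeline is guaranteed against from the pair
stage onward.

## Known limitations

* Qualitative by design: collapsing expression to orderings discards
  magnitude information, and a pair whose genes sit far apart in baseline
  level is constant in every sample, hence uninformative.
* The pair-level Cox pools training cohorts; if cohorts differ grossly in
  baseline hazard, pooling mixes them (a stratified pooled fit is a natural
  extension, deliberately not implemented).
* Wald inference degrades under perfect separation (monotone likelihood);
  such fits are excluded from screens rather than rescued with penalized
  likelihood.
* The greedy search makes one pass and does not revisit accepted pairs; it
  is bounded by the exhaustive-subset optimum (asserted on small instances)
  but not guaranteed to reach it.
* No competing risks, interval censoring, stratified or penalized Cox.
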