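---
title: "Methods: matched screening of pre-injury diagnosis histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched screening of pre-injury diagnosis histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population-wide administrative claims record every emergency-department and
acute-care encounter with up to 25 ICD-10-style diagnosis codes. For a
case-defining event such as a first traumatic brain injury (TBI), the years of
coded history *before* the event hold a phenome-wide picture of the health
states that precede it. `preinjury` implements a screening pipeline for 1:1
matched case-reference designs built on such data: which three-character
diagnosis blocks are over-represented in cases' pre-event histories, how do
those blocks cluster into interpretable comorbidity factors, and how strongly
is each factor associated with case status?

Because real claims registries are access-restricted, the package ships a
synthetic claims generator with planted ground truth. The generator is a
first-class, tested module: every downstream stage is validated against known
carrier status, known per-code prevalences, and closed-form odds ratios.

## Pipeline model

For each patient an *index date* anchors the analysis: cases use the date of
their earliest visit carrying an event block; references use the middle
element of their date-sorted visit list (for even counts, the earlier of the
two middle visits, so the index is always an actual visit date). Diagnoses are
normalized to three-character blocks (punctuation stripped, uppercased,
truncated; the provisional research blocks U98/U99 excluded) and binarized
over the half-open window

$$[\,\text{index} - L,\ \text{index} - E\,),$$

with lookback $L = 1825$ days (five years) and exclusion $E$ either
configured or detected from the peri-index visit histogram. Matched pairs are
randomized to training/validation/testing splits (50/25/25 by default,
largest-remainder apportionment, pairs never broken).

Screening then proceeds per block $b$ with discordant counts $n_{10}$ (case
only) and $n_{01}$ (reference only):

* **McNemar test.** Asymptotic statistic
  $(n_{10}-n_{01})^2/(n_{10}+n_{01}) \sim \chi^2_1$ without continuity
  correction; exact two-sided binomial test of $n_{10}$ in $n_{10}+n_{01}$
  trials at $p = \tfrac12$ when the discordant total is below 25 (the `auto`
  variant). The statistic's symmetric asymptotics are the textbook default;
  the exact branch guards rare codes.
* **Benjamini–Yekutieli step-up** across all tested blocks at FDR
  $q = 0.05$: reject the $k^*$ smallest p-values with
  $k^* = \max\{i : p_{(i)} \le i\,q / (m\,c(m))\}$, $c(m)=\sum_{k\le m} 1/k$.
  BY is valid under arbitrary dependence, which matters because comorbid
  blocks are correlated. The decision is implemented through
  `stats::p.adjust(method = "BY")`; an independent step-up enumeration serves
  as the test-suite oracle.
* **Direction filter.** Screened blocks must also be over-represented in
  cases ($\hat{OR} = n_{10}/n_{01} > 1$; an infinite estimate qualifies). BY
  is applied first and the filter second; the retained flag requires both.
* **Split-sample validation.** Screened blocks are re-tested on the
  validation split with the same procedure, with the multiplicity
  denominator equal to the number of carried-forward candidates. That is the
  natural reading of a train-then-validate design; re-testing against the
  full original denominator would only make validation harder in a way the
  design does not require.

Validated blocks enter a principal-component factor model computed on the
training split (both arms; the factor structure describes the cohort's
comorbidity, not the cases alone): the Pearson (phi) correlation matrix of
the binary columns is eigendecomposed, loadings are eigenvectors scaled by
$\sqrt{\lambda_j}$ with each column's dominant sign forced positive, and a
block joins factor $j$ when its loading is $\ge 0.2$ (boundary inclusive,
signed, with no restriction on multiple membership). Retention diagnostics
report (i) the count of eigenvalues above 1, (ii) the scree elbow as the
interior index maximizing the centred second difference of the eigenvalue
sequence, and (iii) the cumulative-variance profile; the default arbiter is
(iv) validation-split AUC, described next. A configuration override exists
for the judgment call a human analyst may wish to impose.

For criterion (iv) the package fits, for each candidate $k$, one joint
conditional logistic model on the training pairs using the $k$ binary
factor-based scores as covariates, evaluates the fitted linear predictor on
validation-split patients, and selects the $k$ maximizing the rank (Wilcoxon)
AUC for case-vs-reference discrimination, breaking ties toward the smaller
$k$. A per-factor (marginal) loop would also be defensible; the joint model
is used because candidate factor sets overlap and the joint likelihood
accounts for that overlap when ranking candidate partitions.

Finally, each retained factor is scored on the held-out testing split
(score 1 iff any member block is present) and its matched odds ratio is
estimated. For a single binary covariate under 1:1 matching the conditional
maximum-likelihood estimate is the discordant ratio $n_{10}/n_{01}$ with
95% Wald interval $\exp(\ln \hat{OR} \pm 1.96\sqrt{1/n_{10}+1/n_{01}})$;
the general-purpose fitter (damped Newton ascent on the pair-difference
likelihood, gradient tolerance $10^{-8}$, 100 iterations) backs the joint
models and agrees with the closed form to $10^{-6}$ on every single-covariate
instance, a property the test suite asserts. Wald intervals on the log scale
reproduce the checkable published-style worked examples exactly at two
decimals, which is why they are the default over exact conditional
intervals. Models are fit on the testing split itself, matching the reported
frequencies' frame.

### Zero cells and degenerate inputs

* $n_{10}+n_{01}=0$: a degenerate test result ($p = 1$, OR undefined) during
  screening; an explicit `no_information` flag during effect estimation.
* $n_{01}=0 < n_{10}$: the point estimate is reported as infinite and
  flagged, with an exact one-sided binomial bound in place of the missing
  Wald limit. No continuity correction is applied anywhere: silent smoothing
  would corrupt printed-value checks and bias small-count factors.
* Separation in the joint fitter (a covariate whose nonzero pair differences
  share one sign) is flagged per coefficient and the fit is reported as
  non-converged; AUC-based selection skips such candidates.
* Constant code columns are dropped (with a warning) before correlation; a
  flat scree returns elbow 1 with a degenerate-scree warning.

## Peri-index window detection

The event-window half-width is detected from the histogram of visit counts by
day offset from the index date: counts are smoothed with a centred 7-day
moving average, a baseline is taken from offsets beyond ±90 days, and the
returned half-width is the smallest $w$ such that the smoothed series within
$w \le |\text{offset}| \le 90$ stays inside the tolerance band
$\text{median} \pm 2\max(\text{MAD},\ \sqrt{\text{median}/7})$, where median
and MAD (unscaled) are computed from the raw baseline counts. The
$\sqrt{\text{median}/7}$ term is a Poisson count-noise floor — the standard
deviation of a 7-day average of counts at the baseline level — without which
a noiseless constructed histogram would face a zero-width band and the rule
would be unusable on clean inputs. A peak still outside the band at ±90
raises a window-not-found error, and the exclusion can then be set by
configuration. On noisy histograms a single baseline blip beyond the band
widens the detected window (the rule is deliberately literal about "stays
within"); this errs toward a conservative, larger exclusion, which only
discards peri-index information and never biases case-reference symmetry.

## The synthetic generator

`generate_cohort()` emulates the *structure* of matched claims extracts —
matched pairs, multi-year visit histories, multi-field coding, a peri-index
visit spike for cases, latent comorbidity factors, case-vs-reference effects
expressed as odds ratios — with no attempt at real ICD frequency
distributions or care-pathway realism. Design choices that matter:

* **Visit skeleton.** Every patient receives
  $K = 1 + \mathrm{Poisson}(\text{visit\_rate}\times 5 - 1)$ history visits
  uniformly inside the lookback window, so each patient has at least one
  in-window visit and the mean in-window count equals
  $\text{visit\_rate}\times 5$ whenever that product is at least 1 (the
  package's cohort summaries report in-window visit means, the study frame).
  References additionally receive one anchor visit on the intended index
  date and $K$ mirrored post-index visits, which pins the visit-midpoint
  rule to the anchor *exactly* — the ingestion module provably recovers the
  generator's intended index dates, and active codes are always observable.
  Cases receive the anchor (carrying the event block), spike visits within
  ±30 days at `spike_multiplier` times the baseline intensity (carrying only
  a peri-event filler block), and a one-year post-index baseline tail so the
  offset histogram has both shoulders.
* **Code content.** Each patient activates each vocabulary code with the
  background probability; carriers of a planted factor (reference-arm
  prevalence $p_0$, case-arm prevalence derived on the odds scale from the
  planted OR) additionally activate each member code with probability $q$.
  Active codes are scattered uniformly over the patient's in-window history
  visits — the simplest process satisfying the binarized downstream
  contract. Per-code prevalence therefore has the closed form
  $1-(1-\text{bg})\prod_f(1-p_f q_f)$, exposed as
  `expected_code_prevalence()`, and the factor-score odds ratio has a closed
  form exposed as `true_factor_or()`; both are the estimands of the
  calibration and coverage tests.
* **Null cohorts.** `generate_null_cohort()` forces every planted OR to 1.
  Because code content lives only on in-window history visits and those are
  generated identically in both arms, case and reference code content is
  exactly exchangeable under the null — the property the FDR study relies
  on. The spike remains (it is a timing feature, not a content feature).
* **Matching covariates** (age, sex, income quintile, rurality) are shared
  within a pair but do not influence code generation: matching is fixed
  upstream of the statistics being tested, so building covariate effects
  into the generator would test nothing the pipeline uses.
* **Ground truth** (carrier flags, intended index dates, true ORs) is always
  returned alongside the data so recovery tests never need re-simulation.

What passing tests on this generator do *not* show: robustness to real ICD
coding practice (code choice varies by site and specialty), to informative
visit timing (real pre-injury visits cluster before the event), to
imperfect matching, or to secular trends. The generator's factors are
block-structured and conditionally independent given carrier status; real
comorbidity has overlapping, hierarchical structure.

## Problem sizes and numerical tolerances

The test suite exercises: determinism and configuration validation at tiny
sizes; marginal calibration and exchangeability at 5,000 pairs (4-standard-
error bands); FDR control with 500 replicates of 2,000 pairs × 500 codes
under the global null (one-sided 99% binomial bound around the nominal 5%);
CI coverage for planted ORs of 2 and 5 with 200 replicates each at 1,000
pairs; block-membership recovery with 20 replicates at 20,000 pairs (mean
matched Jaccard ≥ 0.8 after exhaustive factor-to-truth matching); and
spectral identities (trace, reconstruction, orthogonality) at $10^{-8}$.
These sizes were chosen so each Monte-Carlo bound has conventional slack at
its replicate count. `scripts/acceptance.R` recomputes the headline
quantities (worked-example ORs, window half-widths, null-screen FDR,
coverage, recovery, and a demonstration pipeline) from scratch at the seed
given on its command line.

## Known limitations

* The discordant-ratio estimator and Wald interval are undefined or one-sided
  at zero cells; the package flags rather than smooths these.
* Scree-elbow detection by second differences is a convention; other
  operationalizations (profile likelihood, acceleration factor) can suggest
  different counts on shallow screes.
* Unrotated principal components are used throughout (rotation is never
  applied); with highly overlapping factors, varimax-style rotations could
  yield cleaner memberships but would change the loading cutoff's meaning.
* Validation-split re-testing restricted to candidates is one reading of a
  train-validate design; re-testing against the full code universe is
  stricter and supported by passing the full matrix with a configured
  candidate list.
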