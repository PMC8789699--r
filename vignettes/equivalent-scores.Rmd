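---
title: "Equivalent Score norms: method, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent Score norms: method, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esnorms)
```

## The problem

Raw neuropsychological test scores cannot be judged directly: performance
depends on age, education and sometimes sex, and the score distributions of
healthy people are typically skewed, bounded and tie-ridden, so normal-theory
percentiles are unreliable. The Equivalent Score (ES) method, the standard
norming approach in Italian neuropsychology, solves this in two stages:

1. **Demographic adjustment.** Raw scores from a healthy normative sample are
   corrected by a regression equation so that a 70-year-old with 5 years of
   education and a 30-year-old graduate are judged against the same yardstick.
2. **Non-parametric standardization.** The *ranked* adjusted scores are mapped
   to a 5-point ordinal scale — ES 0 "defective", ES 1 "borderline", ES 2
   "low-end normal", ES 3 and 4 "normal" — using exact order-statistic
   tolerance limits rather than distributional assumptions.

`esnorms` implements the whole pipeline behind one fitting function,
`es_norm()`, plus exported building blocks for each stage.

## Tolerance limits from the Beta distribution of order statistics

If $X_{(1)} \le \dots \le X_{(n)}$ are the ordered adjusted scores of $n$
healthy participants, the population CDF value at the $r$-th order statistic
follows $F(X_{(r)}) \sim \mathrm{Beta}(r,\, n - r + 1)$. The *safety level* of
a candidate cut-off rank $r$ is therefore exact and distribution-free:

$$p_{\text{outer}}(r) = P\!\left[F(X_{(r)}) \le q\right] = I_q(r,\, n-r+1)
  = \sum_{k=r}^{n} \binom{n}{k} q^k (1-q)^{n-k},$$

the regularized incomplete Beta function at the tail proportion $q$
(default 0.05). The **outer tolerance limit (oTL)** is the *largest* rank whose
safety level still reaches the confidence level (default 0.95): with 95%
confidence, no more than 5% of the healthy population scores below that
observation, so it defines the clinical cut-off (ES = 0 at or below it). The
**inner tolerance limit (iTL)** uses the complementary condition
$P[F(X_{(r)}) \ge q] \ge 0.95$ and is the *smallest* qualifying rank. Scores
between the two limits form the **gray area**: nominally ES 1, but the 5%
error guarantee does not hold there.

```{r}
tol_limits(300)
```

`find_outer_tl()` scans every rank exhaustively (the closed-form counterpart
of the trial-and-error search older norming studies used). Below $n = 59$ not
even rank 1 reaches 95% confidence ($1 - 0.95^{58} < 0.95$); the function then
refuses with an error naming the minimum qualifying size, computed from the
closed form rather than hard-coded. Safety levels are kept at full floating
precision; display rounds to 3 decimals (half away from zero).

## The z-deviate partition into ES 1–3

Ranks above the oTL and up to the median are split into ES 1, 2, 3 by equal
thirds of the standard-normal deviate interval. With $cd_1 = r_{\mathrm{oTL}}/n$
and $z_1 = \Phi^{-1}(cd_1)$, the segment boundaries are $2z_1/3$, $z_1/3$ and
$0$; each segment's expected count is $n$ times the normal mass it covers,
rounded to an integer and accumulated on top of the oTL rank:

```{r}
es_partition(9, 300)
```

Everything above the last ES 3 rank — the median observation included — is
ES 4. Two numerical choices matter here:

* **Rounding is explicit half-up** (`round_half_up()`), not R's banker's
  rounding, matching the convention of the reference procedure; `half_down`
  is available, and a per-category `adjust` of ±1 propagates to every
  downstream cumulative rank, mirroring the manual judgment call the method
  traditionally required.
* **Near-half flags.** A raw count whose fractional part is within 0.05 of .5
  (the 22.48 above, for instance) is flagged so the analyst can see where
  rounding direction was debatable. The 0.05 window is our choice — the
  procedure's description gives an example but no numeric rule — and is
  configurable.

Because the rounded counts each err by at most 0.5 and sum against an exact
total of $n/2 - r_{\mathrm{oTL}}$, the last ES 3 rank always lands within 2 of
$n/2$; the test suite checks this for every $n$ from 60 to 5000.

## Regression-based adjustment

The adjustment stage follows the field's five-step paradigm:

1. *Screening*: each predictor is regressed alone on the raw score
   (`screen_predictors()`; for sex this is the two-group comparison on the
   0/1 dummy).
2. *Transform search* (`search_transform()`): for each continuous predictor,
   the catalogue {identity, $\ln(100-x)$, $\sqrt{x}$, $\ln x$, $x^2$} is
   fitted and the highest-$R^2$ candidate kept; ties break toward identity,
   then catalogue order. Transforms undefined on the observed range are
   skipped with a warning. The catalogue is fixed but replaceable — the
   method's literature names $\ln(100-\text{age})$ and
   $\sqrt{\text{education}}$ as the customary shapes.
3. *Selection* (`select_model()`): forward stepwise multiple regression with
   Bonferroni-corrected entry and removal at $\alpha/k$, $k$ being the number
   of distinct candidate predictors entering selection (counted after
   transform choice, one per predictor). Forward direction was chosen because
   $k$ is small and the entry criterion is explicit; the procedure is
   deterministic and may legitimately return an *empty* model, in which case
   the adjusted score is the raw score.
4. *Adjustment*: $AS = RS + \sum_i\left[-b_i\,(x_i - M_{x_i})\right]$, each
   covariate on its transformed scale and centered at its sample mean; sex
   contributes $-b_{sex}(sex - 0.5)$ with male = 0, female = 1 — the constant
   0.5, not the sample proportion, per the method's printed equation. Scores
   at the instrument floor or ceiling are **exempt**: they keep their raw
   score but remain in the ranking and count toward $n$ (they are real
   normative observations).
5. *Ranking*: ascending, stable on subject id within ties; equal adjusted
   scores share a tie-group id, which is what the tied-rank rules consume.

Two identities pin the implementation down: because the model is fit (and
centered) on the non-exempt rows, the OLS residual orthogonality makes a
regression of adjusted scores on any retained transformed predictor exactly
flat, and the mean of adjusted scores equals the mean of raw scores on those
rows. The latter holds exactly only for covariates centered at their sample
means — the fixed 0.5 sex centering shifts the mean when the sexes are
unbalanced, which is a property of the method, not a bug.

## Tied ranks and the norm table

A tolerance limit or ES threshold is a *rank*, but clinicians apply the norm
table to *scores*; when the score at a formal rank recurs in a run of ties,
the rank-based guarantee breaks. `resolve_ties()` applies the conservative
correction: the oTL moves **down** to the highest rank below the run (keeping
the false-positive risk under the nominal level), while the iTL and the ES
thresholds move **up** to the lowest rank above the run (assigning the more
severe category more generously is the safe direction when passing upward).
A formal rank already at the safe edge of its run needs no correction; a run
reaching rank 1 (oTL) or rank $n$ (iTL/threshold) makes correction
impossible and raises an error for manual review. The method literature
states the downward rule for the oTL and the upward rule for the iTL and
thresholds but contains one self-contradictory sentence; we follow the
conservative reading throughout and log every shift in the table's
`tie_corrections` so the analyst can audit it.

`build_norm_table()` then reads the adjusted scores at the effective ranks
and lays out the deliverable: the cut-off is one unit *at the instrument's
reporting precision* (default 3 decimals, an explicit parameter) above the
oTL score, bands are closed at their printed upper bounds, and the next band
starts one precision unit higher, so the five ES ranges tile the real line.
`classify_scores()` is monotone and total; gray-area membership is reported
as a flag on ES 1 results, never as a sixth category.

```{r}
d <- simulate_norm_sample(n = 300, seed = 7)
fit <- es_norm(raw_score ~ age + education + sex, d, test_min = 0, test_max = 15)
fit$table
```

## The synthetic generator

`simulate_norm_sample()` is first-class, tested code, not a fixture: it draws
demographics uniformly (age 20–90, education 5–18 years by default, optional
Gaussian-copula age–education correlation), sex from a Bernoulli(0.5), and
scores from

$$RS = \beta_0 + b_{age}\ln(100-\text{age}) + b_{edu}\sqrt{\text{education}}
      + b_{sex}(\text{sex}-0.5) + \varepsilon,$$

clipped to the instrument range and rounded to a configurable number of
decimals. Defaults ($\beta_0 = -1$, $b_{age} = 1.5$, $b_{edu} = 1$,
$b_{sex} = 0.3$, $\sigma = 1.5$, range 0–15, 2-decimal scores) emulate a
mid-sized normative study of a bounded cognitive screening test with mild
demographic gradients: mean near 8, demographic signal comparable to the
noise, occasional floor/ceiling rows. Clipping deliberately produces exempt
rows, and coarse `score_rounding` produces tie runs, so both special-case
paths are exercised by realistic inputs. What the generator does *not*
emulate: real population demography (ages are uniform, not census-weighted),
item-level measurement structure, and non-Gaussian residuals — so passing
tests demonstrate correctness of the pipeline's logic, not robustness of the
regression step to every real-world violation.

## Problem sizes and determinism

The package is deterministic everywhere except the generator, which is fully
seed-controlled (identical configuration and seed give byte-identical CSV).
The test suite validates the safety levels against a brute-force binomial
summation for every rank at all $n \le 50$, the median-landing property of
the partition for all $n$ in 60–5000, coefficient recovery on one synthetic
sample of $n = 5000$, and the family-wise null inclusion rate of the
Bonferroni stepwise over 1000 replicates of $n = 100$ — sizes chosen so the
whole suite runs in well under a minute while the Monte-Carlo standard errors
stay small relative to the tolerances checked.

## Known limitations

* The tied-rank corrections are the field's empirical "thumb rules"; they
  lack a formal optimality result, and the package surfaces every applied
  correction rather than hiding it.
* Only one criterion variable is supported; polynomial transform discovery
  and alternative variable-selection schemes are out of scope.
* The safety levels reported are exact Beta tail probabilities at full
  precision; published worked examples elsewhere occasionally differ in the
  third decimal, which traces to the older calculator-based workflow rather
  than to the order-statistic condition itself.
* Two-sided and parametric (normal-theory) tolerance intervals are
  deliberately not provided.
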