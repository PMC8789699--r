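# esnorms

Equivalent Score (ES) norms for neuropsychological tests: exact
non-parametric tolerance limits, z-deviate ES thresholds, and
regression-based demographic adjustment, in one tested R package with a
command-line interface.

## Who this is for

Neuropsychologists and psychometricians norming a cognitive test from a
healthy normative sample. The ES method — the standard approach in Italian
neuropsychology — classifies a demographically adjusted score on a 5-point
ordinal scale (ES 0 "defective", 1 "borderline", 2 "low-end normal", 3–4
"normal") while keeping the inferential error risk of a "defective" call
below 5%. Deriving the cut-offs has traditionally been a manual, error-prone
procedure; `esnorms` computes every step exactly and audits the judgment
calls (rounding near .5, tied ranks) instead of hiding them.

## The statistics in brief

For ordered adjusted scores $X_{(1)} \le \dots \le X_{(n)}$, the population
CDF value at the $r$-th order statistic is $\mathrm{Beta}(r, n-r+1)$, so the
confidence that no more than a proportion $q$ of the population scores below
$X_{(r)}$ is the exact tail
$I_q(r, n-r+1) = \sum_{k=r}^{n}\binom{n}{k}q^k(1-q)^{n-k}$.
The **outer tolerance limit** is the largest rank with $I_q \ge 0.95$
(the clinical cut-off, $q = 0.05$); the **inner tolerance limit** is the
smallest rank with $1 - I_q \ge 0.95$; scores between them form the **gray
area**. Ranks from the cut-off to the median are split into ES 1–3 by equal
thirds of the z-deviate interval $[\Phi^{-1}(r_{oTL}/n),\, 0]$. Before any of
this, raw scores are adjusted as
$AS = RS + \sum_i[-b_i(x_i - M_{x_i})]$ using a Bonferroni-corrected stepwise
regression on transformed demographic predictors (floor/ceiling scores are
exempt). See the methods vignette (`vignettes/equivalent-scores.Rmd`) for
assumptions, tie rules and design choices.

## Worked example

```r
library(esnorms)

tol_limits(300)
#> Outer tolerance limit: rank 9 of n = 300 (safety level 0.966; q = 0.05, confidence = 0.95)
#> Inner tolerance limit: rank 22 of n = 300 (safety level 0.951; q = 0.05, confidence = 0.95)

es_partition(9, 300)
#> Equivalent Score partition (n = 300, outer TL rank = 9)
#>   cd1 = 0.03; z1 = -1.880794; boundaries 2z1/3 = -1.253862, z1/3 = -0.626931
#>   ES 1: raw count 22.4838 -> 22 [near .5 - inspect]; last rank 31
#>   ES 2: raw count 48.1218 -> 48; last rank 79
#>   ES 3: raw count 70.3944 -> 70; last rank 149
```

For a normative sample of 300, the cut-off is the 9th-worst adjusted score
(95%+ confidence that at most 5% of healthy people score below it), the gray
area extends to the 22nd, and the last observations holding ES 1, 2, 3 are
the 31st, 79th and 149th — everything above, median included, is ES 4. The
ES 1 count is flagged because its unrounded value (22.48) sits near the
rounding threshold, the judgment call the manual procedure leaves to the
analyst.

The full pipeline on a sample (here synthetic) with one fitting call:

```r
d <- simulate_norm_sample(n = 300, seed = 7)
fit <- es_norm(raw_score ~ age + education + sex, d, test_min = 0, test_max = 15)
fit$table
#> Equivalent Score norm table (n = 300, reporting precision 3 d.p.)
#>   Outer TL 4.963 | Inner TL 5.503 | cut-off 4.964 | gray area 4.964-5.503
#>   ES 0: <= 4.963
#>   ES 1: 4.964-5.981
#>   ES 2: 5.982-6.786
#>   ES 3: 6.787-7.684
#>   ES 4: >= 7.685

predict(fit, newdata = data.frame(raw_score = 6, age = 74, education = 8, sex = "F"))
#>   adjusted_score es in_gray_area
#> 1       7.046716  3        FALSE
```

A raw score of 6 from a 74-year-old woman with 8 years of education adjusts
upward to about 7.05 (her demographics predict lower performance, so her
score is credited back) and lands in ES 3: a normal performance.

`print`, `summary`, `coef`, `predict`, `plot` and `residuals` methods are
provided. The same operations are scriptable from a shell:

```sh
Rscript inst/cli/esnorms.R tl --n 300
Rscript inst/cli/esnorms.R thresholds --n 300 --otl 9 --json
Rscript inst/cli/esnorms.R norm --input sample.csv --test-min 0 --test-max 15 --out norms.json
Rscript inst/cli/esnorms.R classify --table norms.json --score 5.0
```

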