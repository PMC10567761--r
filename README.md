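# mixri

Indirect estimation of clinical reference intervals from routine laboratory
data, by Gaussian mixture decomposition.

## The problem

A reference interval (RI) is the central 95% range of an analyte in a
healthy population — the basis of the normal/abnormal flags on every lab
report. Establishing RIs *directly* requires sampling at least 120 vetted
healthy volunteers per population segment and analyte, so the intervals
used in practice are frequently outdated, unverified, and identical across
sex and age even where physiology clearly is not. Routine lab databases, by
contrast, hold millions of results — but mixed healthy and pathological,
with no labels.

`mixri` is for biostatisticians and laboratory-medicine researchers who
want to estimate sex- and age-stratified RIs *indirectly* from such
unlabeled routine data. It is built around the renal-panel analytes serum
creatinine (LOINC 2160-0) and blood urea nitrogen (LOINC 3094-0), both in
mg/dl, and generalizes to other analytes and to multi-analyte panels.

## The method

Within each (gender, age) segment the value distribution is modeled as a
two-component Gaussian mixture

    p(x) = Σₖ aₖ N(x | μₖ, Σₖ),   k = 1, 2

fitted by expectation–maximization (or variational Bayes). The dominant
**principal Gaussian** is taken as the healthy subpopulation — healthy
physiology produces a narrow, approximately Gaussian spread, while disease
overlays a thick tail — and the RI is its central 95%: μ ± 1.96 σ. The
second component absorbs the tail; its weight estimates the pathological
fraction of the segment. On top of this the package provides:

* **Age trends** of the limits: linear over adulthood, cubic for the
  accelerating widening after 60, and the implied annual deterioration
  rate (`annual_deterioration_rate`).
* **Bootstrap errors** for the limits (100 half-size resamples).
* **Bivariate generalization**: the 95% highest-density ellipse of the
  joint creatinine–urea principal Gaussian, and conditional "chord"
  intervals for one analyte at a fixed value of the other — which can be
  empty when the fixed reading alone is already outside the joint region.
* **Continuous abnormal flags**: the highest-density percentile of a
  reading under its segment's principal Gaussian (0 at the center, 0.95 at
  the RI limit), for single readings and panels, backed by a persisted
  population model.
* **A synthetic cohort generator** encoding the reported structure of a
  real four-million-result renal cohort (age-widening healthy component,
  age-ramped outlier weight, correlated joint values, repeat visits, entry
  errors), so the whole pipeline is testable without licensed data.

## Worked example

Generate a small synthetic cohort (two ages, 5,000 results per analyte and
segment), filter implausible entries, and estimate the per-segment RIs:

```r
library(mixri)

sp <- default_spec()
sp$ages <- c(30L, 65L)
sp$n_per_segment <- 5000L
cohort <- generate_cohort(sp, seed = 42)

filt <- filter_plausible(cohort$results)   # removes 84 of 40,000 readings
rit <- ri_table(filt$table, ri_config(seed = 42))
rit[, c("analyte", "gender", "age", "n", "low", "high", "outlier_fraction")]
#>   analyte gender age    n   low   high outlier_fraction
#> 1  2160-0 female  30 4988 0.453  0.924           0.0173
#> 2  2160-0 female  65 4988 0.451  1.029           0.0716
#> 3  2160-0   male  30 4990 0.548  1.222           0.0268
#> 4  2160-0   male  65 4991 0.559  1.364           0.0727
#> 5  3094-0 female  30 4986 5.927 18.296           0.0200
#> 6  3094-0 female  65 4988 5.867 21.936           0.1087
#> 7  3094-0   male  30 4991 6.896 21.194           0.0361
#> 8  3094-0   male  65 4994 7.256 25.756           0.1129
```

Reading the table: `low`/`high` are the 2.5th/97.5th percentiles of the
fitted healthy Gaussian in mg/dl — male limits sit above female limits,
every limit widens from age 30 to 65, and the low limits stay nearly
constant. `outlier_fraction` is the estimated pathological share, rising
with age as chronic conditions accumulate.

Score a new patient's panel against the population model:

```r
pm <- build_population_model(filt$table, ri_config(seed = 42))
predict(pm, gender = "male", age = 65,
        readings = c("2160-0" = 1.40, "3094-0" = 22))
#> Abnormal flags (male, age 65, threshold 0.95):
#>   2160-0 = 1.4: 96.7% range (abnormal)
#>   3094-0 = 22: 75.6% range (normal)
#>   joint: 89.8% range (normal)
```

The creatinine reading alone is just outside its RI (96.7% range), but the
urea reading is concordantly elevated, so the pair is *jointly* within the
normal 95% region (89.8%) — the joint model uses the correlation between
the analytes, which the marginal flags cannot.

The same pipeline is available from the shell via the installed
`exec/mixri` script:

```sh
mixri simulate --seed 7 -o cohort.csv
mixri fit cohort.csv -o ri.csv
mixri trends ri.csv --age-min 20 --age-max 60 -o trends.json
mixri model cohort.csv -o model.json
mixri predict --model model.json --gender male --age 30 \
      --creatinine 1.3 --urea 10.0
```

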