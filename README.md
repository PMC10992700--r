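# omatraj

Longitudinal treatment-response phenotyping for omalizumab add-on therapy
in antihistamine-refractory chronic urticaria (CU), working purely from
prescription records.

About half of CU patients remain symptomatic on H1-antihistamines (H1AH);
for them, omalizumab is the standard add-on, but responses range from
rapid antihistamine tapering to none at all. When the only longitudinal
signal is the dispensing record, response must be *defined* from
medication changes. `omatraj` implements that definition end to end:

* **Medication score** per assessment window, in loratadine/prednisolone
  equivalents: 1 point per 10 mg/day H1AH, oral corticosteroids banded
  5/10/15 points (< 11, 11–25, > 25 mg/day), cyclosporine 8, leukotriene
  receptor antagonists 2, H2-antihistamines 2; omalizumab excluded.
* **Rule-based response classification** at months 1, 3, 6, 9, 12, 15,
  18, 21, 24 after the first omalizumab injection, into nonresponse /
  partial / complete / remission (priority rules: escalation to
  cyclosporine or methotrexate, long oral-steroid courses or any IV
  steroid mean nonresponse; a >= 10 mg H1AH reduction without oral
  steroids under maintained omalizumab is a complete response).
* **Shape-respecting trajectory clustering**: K-means under the discrete
  Fréchet distance

  `d(A, B) = min over monotone couplings C of max_(i,j) in C ||a_i - b_j||`

  computed by dynamic programming on the (rescaled time, ordinal value)
  point sequences, with medoid centers and deterministic farthest-point
  initialisation. Clusters are ordered 1 (favorable) to k (poor).
* **Survival and agreement statistics**: Kaplan–Meier and log-rank for
  time to first complete response; Fleiss kappa between trajectory
  clusters and early/late/nonresponder timing groups.
* **Predictor screening**: logit-link GLMs (nonresponder vs responder,
  early vs late) over baseline labs — total IgE percentile flags, SIRI
  `(neutrophils x monocytes) / lymphocytes`, platelet-to-lymphocyte
  ratio, basophil and C4 flags — reported as odds ratios with Wald 95%
  CIs.
* **A synthetic EMR generator** with known latent responder classes
  (favorable / intermediate / poor) driving dose-reduction dynamics and
  class-shifted lab distributions, so the whole pipeline is testable
  without any protected data.

Everything is tibble-in / tibble-out and chains with the pipe; fitted
objects have `tidy()` / `glance()` / `augment()` methods and
`autoplot()` / `plot_*()` displays.

## Worked example

```r
library(omatraj)
library(dplyr)

cohort <- generate_cohort(cohort_spec(n_patients = 300, seed = 1))
traj   <- response_trajectories(cohort$events)

cumulative_response_rate(traj, months = c(3, 6, 9))
#> # A tibble: 3 × 2
#>   month  rate
#>   <dbl> <dbl>
#> 1     3 0.547
#> 2     6 0.687
#> 3     9 0.74

fit <- shape_kmeans(traj, k = 3, seed = 1)
tidy(fit)
#> # A tibble: 3 × 4
#>   cluster  size medoid_id terminal_mean
#>     <int> <int> <chr>             <int>
#> 1       1   165 P0014                 3
#> 2       2    80 P0060                 2
#> 3       3    55 P0283                 0

rg <- responder_groups(traj)
count(rg, group)
#> # A tibble: 3 × 2
#>   group            n
#>   <chr>        <int>
#> 1 EARLY          164
#> 2 LATE            98
#> 3 NONRESPONDER    38

rec <- first_complete_response(traj) |> inner_join(fit$assignments, "patient_id")
log_rank(rec, rec$cluster)
#> # A tibble: 1 × 3
#>   statistic    df  p_value
#>       <dbl> <int>    <dbl>
#> 1      141.     2 2.26e-31
```

Here 54.7% of the synthetic cohort achieves a complete response or
remission within 3 months, rising to 74% by month 9; the three recovered
trajectory clusters (sizes 165/80/55, ordered favorable to poor) separate
strongly on time-to-response (log-rank chi-square 141 on 2 df). The
`EARLY`/`LATE`/`NONRESPONDER` split is 164/98/38.

The whole analysis also runs as one pipeline that writes plain CSV/JSON
artifacts and a reproducibility manifest:

```r
run_pipeline("all", pipeline_config(n_patients = 300, seed = 1), "out/")
```

or from a shell via `inst/scripts/run_pipeline.R` (flags `--config`,
`--out`, `--seed`, `--k`, `--n`, `--stratify-by-maintenance`,
`--pin-paper-cutoffs`).

## Package layout

| Where | What |
|---|---|
| `R/cohort-spec.R`, `R/generate-cohort.R`, `R/cohort-io.R` | synthetic EMR cohort generator and delimited-text round-trip |
| `R/dosing.R` | dose expansion and the medication score |
| `R/response.R` | response rules, trajectories, timing groups |
| `R/frechet.R`, `src/frechet.cpp`, `R/shape-kmeans.R` | shape-respecting distance and clustering |
| `R/survstats.R` | Kaplan–Meier, log-rank, Fleiss kappa, cross-tabs |
| `R/markers.R` | derived lab markers, group comparisons, logit GLMs |
| `R/pipeline.R` | end-to-end runner with manifests |
| `vignettes/omalizumab-response-phenotyping.Rmd` | methods and design rationale |
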