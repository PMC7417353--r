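# groomnet

Dynamic social-network analysis of allogrooming in dairy herds.

Allogrooming (social licking) is the behaviour through which cows build
and maintain affiliative bonds. When a postpartum group is assembled over
several weeks — new cows joining after calving — the directed grooming
network reorganizes week by week, shaped by reciprocity, triadic closure,
age, dominance rank and how recently a cow entered the group. `groomnet`
implements the full analysis chain for observational studies of this kind,
for behavioural scientists and veterinary epidemiologists:

* **Event-log processing**: validated dyadic behavioural event logs
  (groom / headbutt), the 20-second bout-merging rule, weekly weighted and
  binary directed network waves with joiner/leaver composition tracking.
* **Descriptives**: density, reciprocity, directed diameter and average
  path length per wave; created/dissolved/stable tie counts and the
  Jaccard stability index between waves.
* **Dominance**: the Lamprecht dominance index DI = subordinates /
  interaction partners from weekly headbutt matrices, rank classes
  (low < 0.40 ≤ medium < 0.60 ≤ high), and ICC(A,k) — the two-way
  absolute-agreement, mean-rating intraclass correlation — for rank
  stability and inter-observer reliability.
* **A stochastic actor-oriented model (SAOM) engine, written from
  scratch**: actors receive change opportunities at rate
  `rho_m * exp(alpha * outdeg_i)` and toggle at most one outgoing tie per
  micro-step by multinomial logit on an evaluation function
  `f_i(x) = sum_k beta_k s_ik(x)` (reciprocity, transitive triplets,
  popularity/activity, covariate ego/alter/homophily effects, ...).
  Parameters are estimated by Method of Moments with Robbins–Monro
  stochastic approximation, with convergence t-ratios and the overall
  maximum convergence ratio, Mahalanobis goodness of fit on degree, triad
  census and geodesic distributions, a time-heterogeneity score test, and
  forward model selection.
* **A synthetic-herd generator** reproducing the design of a 38-cow,
  6-week staggered-entry study from known ground truth, so the whole
  pipeline is testable by parameter recovery without access to raw field
  data.

The compute-heavy micro-step chain is in compiled code (Rcpp); everything
else is plain R over matrices and data frames, with igraph behind the
graph-theoretic utilities.

## A worked example

Generate a synthetic herd study, run the whole pipeline, and fit the
two-effect dynamics model:

```r
library(groomnet)

cfg <- list(
  synth = list(n_actors = 20, n_waves = 4, entry_schedule = c(16, 2, 2, 0),
               beta_true = c(outdegree = -1.9, reciprocity = 1.1),
               rate_true = rep(4, 3)),
  model = list(effects = list("outdegree", "reciprocity"), rates = 4),
  estimation = list(n3 = 500, gof_nsim = 200),
  seed = 1)
res <- run_study(cfg, "study_out")

res$summary$waves
#>   week n_nodes n_ties density diameter average_path_length reciprocity
#> 1    1      16     70    0.29        4                1.93        0.31
#> 2    2      18     45    0.15        6                2.57        0.44
#> 3    3      20     35    0.09       10                3.69        0.29
#> 4    4      20     24    0.06        6                2.52        0.50

res$fit
#> <saom_fit> converged
#>             estimate     se  t_conv
#> rate_1        3.4362 0.5917 -0.0439
#> rate_2        3.0476 0.7568 -0.0162
#> rate_3        3.1369 0.8982 -0.0262
#> outdegree    -1.9593 0.1669  0.0159
#> reciprocity   1.5158 0.2756  0.0711
#> max convergence ratio: 0.1023 (phase-3 n = 500)
```

The `density` column is the share of possible directed ties present (the
seed network dilutes as the process relaxes and joiners enter), and the
`estimate` column recovers the generating parameters `outdegree = -1.9`
and `reciprocity = 1.1` well within sampling error on a panel this small.
All convergence t-ratios are inside |t| < 0.1 and the maximum convergence
ratio 0.10 is inside the 0.25 threshold, so the fit counts as converged.

Goodness of fit and parameter stability over time:

```r
res$gof$p_values
#>    outdegree     indegree triad_census     geodesic
#>        0.025        0.400        0.735        0.635
res$heterogeneity[c("chi2", "df", "p")]
#> $chi2 [1] 4.84   $df [1] 4   $p [1] 0.30
```

p-values above 0.05 mean the fitted process reproduces the observed
structure; here the triad and geodesic distributions fit comfortably while
the cumulative outdegree distribution is flagged at p = 0.025 — on a
20-cow, 4-wave panel a single auxiliary will occasionally sit below the
line, and this is exactly the signal a practitioner would follow up (for
example with an activity or popularity effect). The non-significant
heterogeneity test says the parameters are stable across the three
periods.

The artifacts (`summary.csv`, `changes.csv`, `ranks.csv`, `fit.json`,
`gof.json`, `run.log`) land in the output directory. A thin command-line
wrapper lives at `inst/scripts/groomnet.R`
(`Rscript groomnet.R run --config study.yaml --out results/`).

## Package layout

| file | contents |
| --- | --- |
| `R/event_log.R`, `R/wave_panel.R` | event-log validation, bout rule, wave construction, serialization |
| `R/descriptives.R` | density, reciprocity, geodesics, tie changes |
| `R/dominance.R`, `R/icc.R` | dominance index, rank classes, ICC(A,k) |
| `R/effects.R`, `R/targets.R` | effect statistics, model specification, MoM targets |
| `R/simulate.R`, `src/saom_core.cpp` | micro-step chain (R reference + compiled core) |
| `R/estimate.R`, `R/gof.R`, `R/heterogeneity.R`, `R/selection.R` | estimation, diagnostics, GOF, heterogeneity test, forward selection |
| `R/synth.R` | synthetic-herd generator |
| `R/pipeline.R` | `run_study()` orchestration |

The methods vignette (`vignettes/groomnet-methods.Rmd`) documents the
model, the estimation scheme, the generator's design choices and the
scaled study designs used by the validation suite.
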