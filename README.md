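# coalrank

Tools for analysing how male–male coalitions shape dominance-rank
trajectories — and how rank, in turn, predicts reproductive success — in
wild primate groups with dynamic male hierarchies (the motivating system is
the crested macaque, *Macaca nigra*, living in groups with 7–18 co-resident
adult males and frequent migration).

## What it computes

Given five tabular inputs (decided dyadic agonistic interactions, coalition
events, male presence/demography, focal observation effort, conception
records), the package:

1. **Elo-rating trajectories.** Each decided contest updates winner and
   loser ratings by $k\,(1 - E(R_w - R_l))$, where $E$ is the expected
   score for the pre-contest rating difference (logistic with scale 400 by
   default, a normal-CDF variant is provided). Ratings start at 1000,
   $k = 100$; both are configurable.
2. **Coalition metrics.** Each event (≥ 2 participants jointly attacking a
   target) is classified by the rank relation of the target to the
   participants — *all-down* (target below all participants), *all-up*
   (target above all), *bridging* (in between) — and scored for
   **feasibility** $f = \sum_i s_i - s_t$, the participants' summed
   standardized ratings minus the target's, with ratings min–max
   standardized to $[0,1]$ among all males present in the group that day.
3. **Model tables.** Every event is represented 12 times — once for each
   future offset 10, 20, …, 120 days — with the male's rating at that
   future date as the response and role, configuration, feasibility, time
   distance and controls (current rank, age, aggression rate, hierarchy
   stability, male competition, optional residual autocorrelation term) as
   predictors. Conceptions yield one row per candidate male present during
   the 11-day window centred on the conception date, with his window-mean
   standardized rating.
4. **Inference.** A Gaussian LMM of future rating (crossed random
   intercepts for male and event, random slopes for time distance and
   feasibility) and a binomial GLMM of siring probability (male random
   intercept, adaptive Gauss–Hermite quadrature), compared full-vs-null by
   likelihood-ratio tests, with parametric-bootstrap prediction bands.
5. **Synthetic data.** An agent-based generator with known ground truth —
   latent-strength-driven contests, coalition events whose transient rank
   consequences decay linearly over a 120-day horizon, and conceptions with
   logit-linear rank dependence — so the full pipeline is testable end to
   end and parameter recovery can be measured.

## Worked example

```r
library(coalrank)

study <- simulate_study(seed = 42)             # two groups, two years

met <- coalition_metrics(study$coalitions, study$trajectories)
configuration_share_table(met$configuration)
#>   configuration  n percent
#> 1      all-down 75      75
#> 2      bridging 15      15
#> 3        all-up 10      10

rt <- build_rank_dataset(study$coalitions, study$trajectories,
                         focal = study$focal)
rl <- rank_lrt(rt)
rl$lrt
#> LRT: chi-squared = 799.216, df = 13, p = 2.034e-162

predicted_role_gap(rl$full, rt)[c(1, 3, 12), ]
#>    days_since participant   target      gap
#> 1          10    1161.161 808.2777 352.8832
#> 5          30    1147.126 830.6695 316.4568
#> 23        120    1083.970 931.4324 152.5378

pt <- build_paternity_dataset(study$conceptions, study$trajectories)
full <- fit_paternity_model(pt)
null <- fit_paternity_model(pt, include_rating = FALSE)
likelihood_ratio_test(full, null)
#> LRT: chi-squared = 3.792, df = 1, p = 0.0515
subset(full$coefficients, term == "rating")
#>     term estimate        se     stat
#> 2 rating 1.924808 0.9878349 1.948512
```

Reading the output: this synthetic study produced 100 coalition events,
three quarters of them all-down. The 13-df likelihood-ratio test says the
coalition predictors (role, configuration, feasibility, time distance and
their interactions) explain substantial variation in future rating. The
predicted participant-minus-target gap is largest 10 days after an event
(≈ 353 rating points, reflecting the injected transient effects) and
shrinks by 120 days, when the injected perturbation has decayed away. The
paternity model recovers a positive rating–siring slope (the generator's
true value is 1.43 log-odds per unit standardized rating); with only 19
conceptions the single-cohort estimate is noisy, which is why recovery is
assessed over replicate cohorts (below).

`run_pipeline(pipeline_config(synthetic = list(), seed = 1))` runs the same
chain end to end, writing tables, fit JSONs, bootstrap bands, figures and a
report with full provenance.

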