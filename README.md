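# ssgvalidity

Quantifies individual in-game soccer performance from event-coded match
logs and asks two questions about 7-vs-7 small-sided games (SSGs) as an
assessment context for youth academy players: are they **representative**
of 11-vs-11 games in the frequency structure of on-ball events, and does
individual SSG performance **predict** 11-vs-11 performance better than
isolated physiological and motor tests?

Intended users: sports scientists and performance analysts working with
notational (event-coded) match data, and methodologists interested in
continuous in-game criterion measures for talent identification.

## What the package computes

* **Rate statistics** for count-type indicators (chances created, shots on
  target, applying pressure, pass interceptions): events per six-minute
  bout, `6 * count / minutes`.
* **Posterior player scores** for success/failure indicators (forward
  passes, offensive duels, defensive duels) from a random-intercept
  multilevel logistic regression with team as a categorical covariate:

  logit P(success) = β₀ + β_team + u_player,  u_player ~ N(0, σ_u²).

  The empirical-Bayes player modes shrink noisy records towards the team
  mean, so players with few attempts are not over- or under-rated.
* **Indicator weights** as the team-wise Spearman correlation of each
  indicator with an in-game success proxy (shots on target; shots
  conceded for defense), aggregated by DerSimonian–Laird random-effects
  meta-analysis on the Fisher-z scale (variance 1/(n−3)).
* **Composite offensive/defensive scores**: within-team z-scores times the
  weights, summed; defense negated so higher is always better. Published
  default weights: offense 0.21·z(pass) + 0.17·z(duel) + 0.50·z(chance)
  + 1·z(shot); defense −(−0.14·z(duel) − 0.06·z(interception) −
  0.11·z(pressure)).
* **Representativeness**: a chi-square goodness-of-fit test of the SSG
  event distribution against the 11-vs-11 relative frequencies, with
  adjusted standardized residuals (O−E)/√(E(1−p)), plus a Spearman
  correlation between the two per-indicator total distributions with a
  Fisher-z CI.
* **Predictive validity**: team-wise Spearman correlations of player
  scores across formats (and of test scores against the composites),
  DL-aggregated, with Cohen magnitude labels.
* **A seedful synthetic-study generator** with known ground truth for
  every latent quantity, used for the calibration and parameter-recovery
  experiments; its defaults emulate the original study's design (4 teams,
  63 players, six-minute SSGs, six 11-vs-11 halves per team).

## Worked example

The representativeness analysis runs directly from the published
per-format event totals shipped with the package:

```r
library(ssgvalidity)
rep <- representativeness_report(published_event_counts())
print(rep$gof)
#> Chi-square goodness of fit: chi2(10, N = 6060) = 923.79, p < 0.01
#> # A tibble: 11 x 7
#>    indicator    observed_m11 prop_m11 observed_ssg prop_ssg expected_ssg
#>  1 pass_forward         2167  0.416           2526  0.417         2519.
#>  2 tackle                619  0.119            758  0.125          720.
#>  ...                                            (std_residual column: 0.18,
#>  1.53, 3.07, ..., -17.14 for defensive aerial duels, 16.18 for shots)
rep$distribution_cor
#> $r 0.784  $ci_low 0.347  $ci_high 0.941
```

Reading: the SSG event mix deviates from the 11-vs-11 reference
(χ²(10, N = 6060) = 923.79) mainly through missing aerial duels (residual
−17.1) and extra shots on target (+16.2), yet the two distributions are
strongly rank-concordant (r_s = 0.78, and 0.98 once aerial duels are
removed) — SSGs are faster paced but representative.

A full scoring run on synthetic data:

```r
study <- generate_study(generator_config(seed = 2024))
res <- run_pipeline(study$events, study$roster, study$games,
                    out_dir = "results/pipeline")
res$weights              # derived indicator weights with CIs
res$validity_indicators  # SSG vs 11-vs-11, aggregated over the 4 teams
```

With the generator's default cross-format consistency (ρ = 0.6) the
aggregated validity coefficients come out small-to-moderate (for seed
2024: pass interceptions 0.37, forward passing 0.33, applying pressure
0.44), mirroring the magnitudes such a design can support.

The numbered scripts under `analysis/` narrate the full sequence:
`01_representativeness.R`, `02_simulate_study.R`, `03_score_players.R`,
`04_validity.R`, `05_calibration.R`. Each prints its findings and writes
tables under `results/`.

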