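---
title: "Quantifying in-game soccer performance and the validity of small-sided games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in-game soccer performance and the validity of small-sided games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgvalidity)
```

## The problem

Talent researchers increasingly want *in-game* performance, measured on a
continuous scale, both as the criterion to predict and as the basis of
representative assessments. `ssgvalidity` implements a complete pipeline
for that purpose around event-coded match data from a youth soccer academy
setting: four age-category teams (U15–U23), six-minute 7-vs-7 small-sided
games (SSGs) with sides re-shuffled every game, and halves of competitive
11-vs-11 games coded with the same scheme. The package answers three
questions:

1. **Representativeness** — does the frequency structure of coded on-ball
   events in SSGs match that of 11-vs-11 games?
2. **Predictive validity of SSG performance** — do players who perform
   well in SSGs also perform well in 11-vs-11 games?
3. **Predictive validity of isolated tests** — how do sprint, endurance
   and agility tests compare as predictors of 11-vs-11 performance?

## The coding scheme and data model

Events arrive as one row per coded on-ball action: game, format
(`SSG`/`M11`), age-category team, within-game side, player, indicator,
and a success/failure outcome where the indicator has one. Eleven raw
indicators are modelled (`indicator_taxonomy()`). Four are *count-type*
(chances created, shots on target, applying pressure, pass interceptions):
they are counted when they occur and carry no outcome. The rest are
*binary-outcome*. Two merge rules produce the player-quantification view:
dribbles + take-ons = offensive duels; tackles + staying-in-front =
defensive duels. The representativeness analysis keeps the raw labels, so
both views derive from one input file. Aerial duels are read and validated
but excluded from individual quantification — in SSGs most players record
none, so a per-player aerial score would be mostly noise.

Players with no 11-vs-11 minutes, or with an SSG count more than 2 sample
standard deviations below their team's mean, are excluded
(`exclude_players()`). The threshold is strict ("more than"), computed per
team; a boundary player is retained. Coding reliability can be audited
with `cohens_kappa()`.

## Quantifying individual performance

**Count indicators** become rate statistics: events per six-minute bout,
`6 * count / minutes`, with the player's total minutes in the format as
exposure (`events_per_bout()`). Exposure is pooled over a player's games
because all downstream use is rank-based across players, not per-game.

**Binary indicators** are scored with a random-intercept multilevel
logistic regression (`fit_success_model()`):

$$\mathrm{logit}\,P(\text{success}_{ij}) = \beta_0 + \beta_{\text{team}(i)} + u_i,
\qquad u_i \sim N(0, \sigma_u^2).$$

A naive success fraction over- or under-rates players with few attempts;
the empirical-Bayes modes $u_i$ shrink towards the team mean in proportion
to how little data a player has. The player score is the logit-scale
linear predictor $\beta_0 + \beta_{\text{team}} + u_i$
(`player_posterior_scores()`); a retained player with zero attempts gets
full shrinkage, $\beta_0 + \beta_{\text{team}}$. Because every downstream
use is Spearman correlation, any strictly monotone transform of the score
(logit or probability scale) gives identical results; the logit scale is
kept for numerical symmetry. Estimation is marginal maximum likelihood via
`lme4::glmer` — Laplace by default, adaptive Gauss–Hermite on request —
and the method used is recorded in the fit object so a run is reproducible
bit for bit. Two guards handle degenerate data: a fit where *all* outcomes
are identical is refused (no interior maximum exists), and a team whose
outcomes are all identical receives a weakly-informative data-augmentation
penalty (one pseudo-player with one success and one failure) that keeps
its effect finite; this is flagged in the diagnostics and pseudo-players
never receive scores.

## Weights and composite scores

Indicator weights come from the data: for each game side, the
per-indicator performance (count of events, or of successful events for
binary indicators) is paired with that side's in-game success proxy — its
own shots on target for offensive indicators, the shots it conceded for
defensive ones (`team_game_indicator_totals()`). Spearman correlations are
computed within each team-by-format group of game sides and aggregated by
random-effects meta-analysis; the aggregated coefficient is the weight
(`derive_weights()`). Published weights are available as defaults via
`table_weights()` (0.21, 0.17, 0.50, shots fixed at 1; −0.14, −0.11,
−0.06).

Composites standardise each indicator score to a z-score within the
player's team (sample SD; a zero-spread indicator maps to z = 0 with a
warning, a single-player team is an error), multiply by the weights, and
sum; the defensive sum is negated so that higher always means better
(`composite_scores()`). A player missing any formula indicator gets `NA`
for that composite rather than a silently incomplete sum.

Whether the per-game binary-indicator team performance should be a success
count or a success proportion is not decidable from the published
description; the count is the default (it parallels the count-based
representativeness accounting) and the proportion sits behind
`binary_stat = "success_prop"`. Similarly, shots on target entering the
offensive composite are z-scored like every other term — the formula's
footnote treats all terms as standardized scores.

## Meta-analytic aggregation

All correlation aggregation uses one code path (`meta_spearman()`,
`meta_fisher_dl()`): Fisher z-transform $z_i = \operatorname{atanh} r_i$
with variance $1/(n_i - 3)$, DerSimonian–Laird moment estimate of the
between-group variance $\tau^2$ (non-iterative, hence deterministic; REML
would be a defensible alternative but adds an iterative fit for no
downstream benefit), inverse-variance weights $1/(v_i + \tau^2)$, and a
normal-theory 95% CI and two-sided p on the aggregate, back-transformed
with $\tanh$. With one group the aggregate reduces to that group's
coefficient. Groups with fewer than `min_n = 4` complete pairs or zero
variance are skipped with a warning. A perfectly concordant group
($r = 1$) is handled by clamping the transform just inside $\pm 1$;
exactly homogeneous inputs return the common coefficient unchanged.

## Representativeness

`gof_chi_square()` tests the SSG event-type distribution against the
11-vs-11 relative frequencies taken as the theoretical distribution:
$E_i = N p_i$ with $p_i$ the exact 11-vs-11 count ratios (not rounded
proportions), so $\sum E_i = N$ to machine precision. Cell deviations are
*adjusted* standardized residuals,

$$s_i = \frac{O_i - E_i}{\sqrt{E_i (1 - p_i)}},$$

the multinomial form whose denominator accounts for the size of the cell
proportion; the package deliberately asserts this convention in its tests
because the plain Pearson form $\,(O_i-E_i)/\sqrt{E_i}\,$ yields visibly
different residuals on the same counts. The association between the two
frequency distributions is summarised by a Spearman correlation over the
per-indicator totals with a Fisher-z CI (SE $1/\sqrt{k-3}$, computed on
the unrounded coefficient). Removing the two aerial-duel categories is an
explicit re-run on the reduced indicator set (df drops by 2, N by the
removed events), never an in-place patch. p-values below 0.01 are
displayed as "< 0.01".

## The synthetic-study generator

No raw data accompany the original study, so the package carries a
first-class generator (`generate_study()`) whose defaults *are* the study
conditions: teams of 17/15/16/15 players; 19/12/20/16 SSGs per team
(back-computed so that the mean number of SSGs played per player matches
the published 16/11.5/17.8/14.8 when 14 of each team's players are drawn
per game); six 45-minute 11-vs-11 halves per team with eleven players
drawn per half and only the academy side coded; per-player per-bout event
rates calibrated as the published per-format totals divided by the nominal
exposure (82 × 14 SSG player-bouts; 4 × 6 × 45 × 11 player-minutes), which
reproduces the qualitative pattern of faster-paced SSGs and suppressed
aerial duels.

The latent structure is deliberately low-dimensional: each player has one
offensive and one defensive ability per format, linked across formats by a
Gaussian copula with correlation $\rho$ (default 0.6, echoing the
moderate cross-format validity the design anticipates). Count rates are
modulated by $\exp(\sigma_r \cdot \text{ability})$ with $\sigma_r = 0.4$;
binary success probabilities by
$\mathrm{plogis}(\beta_0 + \beta_{\text{team}} + \sigma_u \cdot
\text{ability})$ with $\sigma_u = 0.5$ and mildly increasing team effects
(0, 0.1, 0.2, 0.3 on the logit scale) so that the team covariate earns its
place. Each game side draws offensive and defensive strengths
(SD 0.3); a side's offensive rates — shots included, which is what makes
shots on target a *common factor* with the other offensive indicators —
scale with its own offensive strength and are suppressed by 0.5 times the
opponent's defensive strength, which links defensive ability negatively to
shots conceded. All log-normal modulators are mean-corrected so expected
totals recover the configured rates. Test scores load weakly on the
11-vs-11 latents (sprints −0.2, ISRT +0.15/−0.10, agility ∓0.1), with
MCAR missingness of 10% (sprint and agility jointly, as injuries remove
both) and 2% (ISRT). Shots on target per side are exactly the side's
generated shot events, so the games table is consistent with the event
log by construction.

What the generator does *not* emulate: positions and position breadth in
the side shuffling, within-game fatigue or momentum, correlated abilities
across indicators beyond the single offense/defense pair, partial
substitutions (minutes are whole games/halves), and non-random
missingness. Passing tests therefore show that the *pipeline* behaves
correctly under a plausible generative model, not that real coded data
would yield the published coefficients.

## Calibration experiments and problem sizes

Three seeded experiments back the statistical machinery, each sized to
run comfortably on a single CPU:

* **Null coverage** (`null_validity_coverage()`): 200 replicate studies at
  $\rho = 0$; about 95% of the aggregated rate-indicator validity CIs
  should contain 0. The rate-only path is used so the replicate loop needs
  no mixed-model fits.
* **Target recovery** (`validity_recovery()`): 30 replicates under a
  high-consistency, low-noise configuration — $\rho = 0.9$,
  $\sigma_r = 1$, event rates scaled ×25 so the rarest indicator yields
  enough events for Poisson noise to be negligible, game-strength wobble
  off. The mean aggregated coefficient should recover the population
  Spearman of the Gaussian copula, $(6/\pi)\arcsin(\rho/2) \approx 0.89$,
  within 0.1. The small residual gap (~0.04) that remains at any rate
  scale is small-sample Fisher-z aggregation bias at ~15 players per team.
* **Success-model recovery** (`success_model_recovery()`): 60 players ×
  50 trials with $\sigma_u = 1$ and team effects (0, 0.3, −0.3, 0.5);
  $\hat\sigma_u$ lands within ±0.35 and the player modes rank-correlate
  with the truth above 0.7. A two-player toy problem additionally checks
  that the fit maximises the same marginal likelihood as a brute-force
  120-node Gauss–Hermite evaluation, to four decimals.

## Numerical choices and limitations

Ties in all rank correlations use mid-ranks. Fisher-z CIs require group
sizes above 3; the meta-analysis refuses to run with no usable group. The
DL estimator is truncated at $\tau^2 = 0$. Optimizer settings for the
mixed models are pinned (`bobyqa`), so identical inputs reproduce
identical outputs; the determinism contract extends to the generator,
which derives all replicate seeds from one master seed and regenerates
byte-identical CSVs.

Known limitations: no positional stratification, no off-ball or
spatio-temporal indicators, per-game validity is not modelled (exposure is
pooled per player), and the published Tables 4–5 coefficient values cannot
be reproduced without the unpublished raw data — the validity machinery is
instead validated by the calibration experiments above.
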