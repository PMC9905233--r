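---
title: "Models and methods: cohesion incentives, exploration, and group decision quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cohesion incentives, exploration, and group decision quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesim)
```

This vignette documents the models implemented in `cohesim`, the
assumptions behind them, the parameters that matter, and the design
choices made where the underlying methodology is underdetermined. The
package has four layers: a multi-agent bandit simulator, behavioral
metrics for choice and movement logs, synthetic session generators with
planted ground truth, and the statistical pipeline that analyzes their
output.

## 1. The multi-agent ε-greedy bandit

A run consists of `n_agents` (default 6) agents repeatedly choosing among
`k` options (default 4) for `n_iterations` rounds (default 30). Option
*j* pays `payout_cent[j]` with probability `success_prob[j]` each round,
independently across rounds and agents, so the task is a stationary
multi-armed bandit — until a cohesion bonus couples payoffs across
agents.

Each agent keeps a per-option value estimate and chooses by the ε-greedy
rule: draw `p ~ U(0,1)`; explore uniformly if `p < ε`, otherwise exploit
the argmax of the estimates. Three choices the rule itself leaves open
are fixed as follows:

* **Boundary `p = ε`** counts as exploitation. The event has probability
  zero; the convention only matters for documentation.
* **Argmax ties** are broken uniformly at random. A deterministic
  tie-break (e.g., lowest index) would systematically favor one option
  during early rounds when many estimates are equal.
* **Update rule**: incremental sample average, `Q ← Q + (r − Q)/n`.
  This is the standard estimator for stationary bandits; the simulation
  design does not call for recency weighting.

Estimates start at 0 for every option, encoding the assumption that all
options look equally profitable before any feedback; the first
`forced_exploration_iterations` (default 3) rounds are uniform random
for every agent, so real estimates exist before greedy play starts.

Within an iteration all agents commit their choices simultaneously;
payouts are then drawn independently per agent, and bonuses are computed
from the joint choice vector. This mirrors the round structure of the
experimental paradigms (everyone chooses, then everyone is paid).

### Cohesion bonuses

With `m` agents on the same option (including the focal agent, so a lone
chooser is never inflated):

| scheme | bonus on top of payout `x` |
|---|---|
| `none` | 0 |
| `additive` | `3 · (m − 1)` cents (amount configurable) |
| `multiplicative` | `x · (m − 1)` (total received `x · m`) |

`bonus_in_update` controls whether the bonus is folded into the reward
used for the value update. The default is `TRUE`: the agent cannot
separate option feedback from cohesion feedback, which is precisely the
mechanism by which a multiplicative bonus creates non-stationary,
obfuscated reward distributions and impairs collective induction.
Setting it to `FALSE` models designs that report the bonus separately.

### Reproducibility and scale

One master seed generates a deterministic vector of per-run substream
seeds, so runs are mutually independent and the full log is reproducible
bit-for-bit. The full study configuration — 3 schemes × 1,000 runs × 30
iterations × 6 agents — simulates in a few seconds; the Poisson mixed
model on the resulting 90,000 counts dominates the runtime (about a
minute). Unit tests use 100–200 runs, which is ample for the qualitative
properties they check.

## 2. Behavioral metrics

**Choice score.** 3 points for the profitable option, 2 for a neutral
one, 1 for the unprofitable one, 0 for a missed round, summed over the
game (0–90 for 30 rounds). It quantifies decision quality for analysis
and is deliberately not the player's earnings.

**Half-change round.** A change occurs when a round's choice differs
from the *most recent prior actual choice*; missed rounds are skipped,
so a change is only ever counted between two real choices. The statistic
is the earliest round at which the cumulative number of changes reaches
`ceiling(total/2)`. A player with zero changes is assigned round 1
(immediate exploitation); because that value is a convention rather than
an observation, the result carries a `no_changes` attribute so analyses
can exclude such players.

**L-F score.** Movement logs are sequences of single-player move events
on a hexagonal board in axial coordinates, with distance
`(|Δq| + |Δr| + |Δq+Δr|)/2`. When a player moves, every (mover, other)
pair is scored: distance increased → mover +1, other −1; decreased →
mover −1, other +1; unchanged → nothing. We apply the increments *per
pair* rather than once per move: in the canonical two-move illustration
of the scoring (A steps away from B and C, then B steps toward A but
away from C), the second mover's net zero (−1 for approaching A, +1 for
leaving C) only balances under the pairwise rule, and the rule makes
increments exactly zero-sum across players — a conservation property the
test suite asserts on every generated session. The mover's first-move
tally is +2 under this rule where the narrated shorthand says "+1"; the
non-movers' −1 each and every subsequent increment agree exactly.

**Spatial cohesion.** Two field-distribution percentages: cells ever
used by anyone over the game, and the mean per-move-snapshot count of
simultaneously occupied cells, both relative to board size. The board is
a regular hexagon of configurable radius, default 5 (91 cells): the
original playing field's size is not published, so all percentages are
parameterized by board size, and the default was chosen so that six
players produce move-level occupancies in the empirically reported 4–5 %
range. Transitivity is the global clustering coefficient of the
complete weighted player graph. Closeness weights are `1/(1 + d)` by
default — finite for co-located players, unlike raw `1/d`; a clamped
`1/max(d, 1)` variant is available. "Weighted global clustering" is
underdetermined for complete graphs, so the variant is configurable:
geometric-mean triangle intensity (Onnela) by default, Zhang–Horvath as
the alternative. Both attain 1 exactly when all pairwise distances are
equal (in particular for a fully stacked group) and decrease with
unequal dispersion.

## 3. Synthetic sessions with ground truth

The generators exist to make every metric and model testable with known
answers, not to simulate human psychology.

**Card sessions.** Each of the players follows an `agent_profile`:
scheduled switchers change option at exactly the listed rounds (so the
half-change round of the log is known by construction); goal-directed
agents stay on their goal option except on ε-exploration rounds; pure
learners run the same ε-greedy machinery as the simulator. Payouts are
drawn from the option distributions; the additive bonus is computed from
co-choices and reported separately (it never enters anyone's updates,
matching the separated-feedback experimental design).

**Movement sessions.** Players start on distinct cells of the central
ring (configurable, e.g. stacked starts). Each round consists of up to
`moves_per_round` turns; within a turn agents move one cell each, in an
order sampled with probability proportional to `leader_bias + 0.1`, so
designated leaders tend to move first. An agent steps toward the point
interpolating between its goal field and the current group centroid
with weight `cohesion_weight` (`target = (goal + w·centroid)/(1 + w)`),
and stops when no neighboring cell improves its distance to that
target. The round's option is the reward field occupied at round end;
off-field players earn nothing that round. Positions persist across
rounds. The per-round move cap defaults to 10, a value chosen to let
agents reach any field from the center on the default board with slack;
the original paradigm's cap is not published and the parameter is
configurable.

This minimal rule suffices to plant recoverable signal: a high-bias
agent with centroid-attracted followers earns the top L-F score in well
over 90 % of seeded sessions, and raising `cohesion_weight` from 0 to 5
shrinks field distribution in essentially every paired seed — both
properties are asserted in the acceptance tests at 100 seeds each. What
the generator does *not* emulate: human memory and strategy, visual
radii, communication conventions, or round timeouts (the cap replaces
the wall clock, which a generator cannot meaningfully reproduce).
Passing recovery tests therefore demonstrates that the metrics measure
what they claim on data with known structure — not that human sessions
will behave like the generator.

## 4. Statistical pipeline

The pipeline reproduces the analysis computations on simulator or
generator output, delegating estimation to `lme4`.

* **Profitable-count model**: Poisson mixed regression of per-run,
  per-iteration counts of agents on the profitable option, on bonus
  scheme × iteration with a run random intercept. The scheme factor uses
  sum-to-zero (deviation) contrasts so each coefficient reads "this
  scheme against the average" — the coding the verbal description of
  the published coefficients implies, and documented here because the
  estimates are meaningless without knowing it. The deviation
  coefficient of the level dropped by the coding is reconstructed with a
  delta-method standard error so all three schemes are always reported.
* **Learning curve**: logistic mixed model `profitable ~ −1 + round`
  with a random round slope at the player level plus player and group
  intercepts (the published random-effects phrasing is ambiguous between
  slope and intercept for round; the slope variant is the default and
  the intercept-only variant is available). A constant outcome has no
  interior ML solution (complete separation), so the fit is guarded: the
  function returns the degenerate fitted probability with a note.
* **Exploration–quality**: `choice_score ~ hcr + hcr²` with group random
  intercept versus the linear-only model, compared by likelihood ratio
  (both ML). With fewer than two groups the random effect is dropped
  with a warning.
* **Mediation**: product of coefficients on linear models, percentile
  bootstrap CIs (seeded), `total = direct + indirect` exactly for
  continuous outcomes. Binary outcomes are decomposed on the
  linear-probability scale — an approximation, flagged as such, chosen
  because effect decomposition on the odds scale is not additive.
  Following common reporting practice the proportion mediated is set to
  0 when the indirect effect's CI spans zero.
* **Group comparisons**: thin wrappers around Welch's t (Cohen's d),
  Wilcoxon rank-sum with continuity correction (rank-biserial), and the
  χ² test (Cramér's V).

Mixed-model fit quality is reported as marginal/conditional pseudo-R²
by the usual variance-decomposition definition, with distribution-
specific residual variance (σ² gaussian, π²/3 logit, lognormal
approximation for the Poisson log link).

### Replication behavior of the simulation study

Running the full three-scheme study and the count model recovers an
iteration (round) main effect of ≈ 0.0206 on the log scale — agents
learn to choose the profitable option — with the no-bonus × iteration
interaction ≈ +0.001 (fastest learning) and the multiplicative ×
iteration interaction negative (≈ −0.001 to −0.002 across master seeds,
p < 0.001): the multiplicative bonus measurably slows collective
induction, and late-round profitable-choice shares order
none > additive > multiplicative. The Wald standard error of the
interaction understates its across-simulation variability, so the
interaction's magnitude moves more between master seeds than within-fit
uncertainty suggests; the sign and ordering are stable.

## 5. Numerical conventions and limitations

Currency is integer cents end-to-end; rounds and event indices are
1-based; axial coordinates have the origin at the board center. All
stochastic stages take explicit seeds and derive substreams
deterministically; identical config + seed reproduces byte-identical
logs, which the run-manifest utilities checksum and verify.

Known limitations: the simulator implements only the ε-greedy rule (no
soft-max, uncertainty bonus, or decaying ε) and stationary base rewards;
the movement generator's strategy is a two-point interpolation, not a
behavioral model; weighted transitivity and board size are conventions
(configurable) rather than published values; and the binary-outcome
mediation decomposition is a linear-probability approximation.
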