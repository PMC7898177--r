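---
title: "Emotion-based social norms in the iterated prisoner's dilemma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion-based social norms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emonorm)
```

This vignette is the package's own account of the science it implements:
the game-theoretic model, the emotion-signaling layer, the synthetic
participant population, the statistical pipeline, and the derivation of
emotion-based social-norm tables. It also records every numerically or
scientifically consequential design choice, so that a reader can judge
what passing tests do — and do not — establish.

## 1. The game and memory-one strategies

Two players repeatedly face a prisoner's dilemma with per-round payoffs
T > R > P > S and 2R > T + S (default (T, R, P, S) = (5, 3, 1, 0), the
standard matrix of the zero-determinant literature). Outcomes are ordered
(CC, CD, DC, DD), first letter the focal player's move; all serialization
uses these labels, never indices, and the perspective swap exchanges CD
and DC.

A *memory-one* strategy is a vector p = (p_CC, p_CD, p_DC, p_DD) of
cooperation probabilities conditioned on the previous outcome (own
perspective), plus a first-round probability p0. A strategy pair induces
a Markov chain on the four outcomes whose transition matrix
`build_transition_matrix()` composes entrywise; the stationary
distribution v gives expected per-round payoffs s_X = v·f_X and
s_Y = v·f_Y with f_X = (R, S, T, P), f_Y = (R, T, S, P).

**Numerical choices.** The stationary solve replaces one row of
M' − I with the normalization constraint and solves the 4×4 linear
system. When the unit eigenvalue is not simple (absorbing sets, e.g. two
tit-for-tats), there is no unique stationary distribution; rather than
return NaNs the package computes the Cesàro (running-average) limit from
a configurable initial distribution (uniform by default) and flags the
result with a `non_ergodic` attribute, which `expected_payoffs()`
surfaces as a warning. Press–Dyson theory assumes ergodicity, so every
downstream ZD claim is conditional on that flag being clean. The Cesàro
iteration stops when the running mean moves by < 1e−13 (at most 1e5
steps); for a 4-state chain this is far past convergence.

## 2. Zero-determinant strategies

`press_dyson_payoff()` evaluates v·f as a ratio of two 4×4 determinants
whose second column depends only on the focal strategy,
p̃ = p − (1, 1, 0, 0). This is the zero-determinant mechanism: choosing
p̃ = α f_X + β f_Y + γ·1 forces α s_X + β s_Y + γ = 0 against *every*
opponent. `zd_certificate()` solves that decomposition by least squares
(QR) and certifies the strategy as ZD when the L2 residual is below a
tolerance (default 1e−9, configurable; the shipped vectors decompose to
~1e−16). Writing the enforced relation as
s_X − pivot = χ(s_Y − pivot), with χ = −β/α and
pivot = −γ/(α + β):

* **extortion**: pivot = P and χ > 1 — the focal surplus over the
  punishment point is χ times the opponent's, so the extortionist can
  never fall behind (s_X ≥ s_Y whenever s_Y ≥ P);
* **generous**: pivot = R and χ > 1 — the focal player absorbs the
  larger share of any shortfall from mutual cooperation
  (s_X ≤ s_Y whenever s_Y ≤ R).

Degenerate branches are handled explicitly rather than by division:
α ≈ 0 with β ≠ 0 (equalizer strategies that pin the opponent's score)
and α + β ≈ 0 (χ = 1, "fair" relations with no pivot) both report
`other-ZD` with χ or pivot undefined. Signs are normalized so α ≥ 0,
which is harmless because the relation is sign-invariant. Pivot matching
uses a relative tolerance of 1e−6 times the payoff scale.

**Shipped strategy vectors.** The extortionate counterpart is the
canonical χ = 3 strategy (11/13, 1/2, 7/26, 0) for these payoffs. For
the generous counterpart the package constructs the pivot-R member of
the same family at the same χ = 3 and the largest feasible scale
φ = 1/11, giving (1, 2/11, 1, 4/11). Both are configuration values
(`strategies.extortion`, `strategies.generous`), so a user who wants
different published vectors can substitute them and re-certify; the
certificate operation validates whatever is configured. The first-round
probability p0 defaults to 1 (cooperate) for both: each family is a
"nice" variant that starts cooperatively, and round-1 variation in the
experimental design is attributed to the reputation prior alone.

## 3. Emotion display policies and the valence signal

Each counterpart profile maps the outcome *from the displayer's
perspective* to an expression:

| profile | CC | CD (was exploited) | DC (exploited other) | DD |
|---|---|---|---|---|
| cooperative | joy | anger | regret | neutral |
| neutral | neutral | neutral | neutral | neutral |
| competitive | regret | anger | joy | neutral |

The cooperative pattern signals an appraisal aligned with mutual
cooperation; the competitive pattern inverts it on the two
cooperation-discriminating cells (mutual cooperation is a missed chance
to exploit, hence regret; exploiting brings joy). The two emotive
profiles share the CD (anger) and DD (neutral) cells, so only CC and DC
outcomes discriminate between them.

`emotion_valence()` reduces an observed (outcome, expression) pair to
the minimal signed signal carrying that contrast: +1 for cells unique to
the cooperative policy, −1 for cells unique to the competitive policy, 0
for shared cells and neutral displays. Magnitude differences between
emotions (joy vs regret intensity) are deliberately not modeled: the
factorial design manipulates the *pattern*, not the intensity, and a
three-level code keeps the participant model identifiable.
`classify_profile()` scores agreement with each policy table and breaks
exact ties deterministically in the order cooperative < neutral <
competitive (random tie-breaks would make classification
non-reproducible). The policy tables are defined generically over the
displayer's perspective and are overridable cell-by-cell in the
configuration for ablation experiments.

## 4. The synthetic participant population

The generator is a controllable stand-in for human participants, not a
cognitive theory: it exists so that the pipeline (design → trials →
ANOVA → norm table) can be exercised end-to-end with known ground truth.
Each participant cooperates with probability

logit P(C at round t) = b0 + b_rep·rep + b_recip·last + b_emo·v̄(t) + b_round·(t−1)

where `rep` is the reputation code, `last` is the counterpart's previous
move (+1/−1, 0 at round 1), and v̄(t) is the running mean of the valence
signals observed before round t (0 at round 1). Round 1 is therefore
structurally blind to strategy and emotion — only the reputation prior
moves the first choice, matching the experimental observation that
first-round cooperation varied with reputation only.

Ratings live on the −50..+50 slider. The initial rating is
a_rep · 30 · rep_sym + ε, with rep_sym the *symmetric* code (−1, 0, +1),
so an unknown counterpart starts at the scale midpoint; Gaussian noise
(σ_a = 8) is clipped to the slider range, because that is how a bounded
slider behaves (clipping, not truncation-aware inference). The final
rating is w_rep·rep + w_coop·(c̄ − 0.5) + w_emo·v̄ + ε with c̄ the
counterpart's observed cooperation frequency and σ_w = 12.

Behavioral terms use an *asymmetric* reputation code (−1, +0.5, +1) by
default: behavior toward unknown counterparts empirically resembles
behavior toward positively-reputed ones, and the asymmetric option
encodes that; the symmetric coding remains available
(`participant.rep_coding`).

**Default population (the shipped scenario).** Coefficients were
calibrated once, from the model's predicted cell means (per-cell
counterpart cooperation frequencies and mean valence measured at
n = 200/cell), and then frozen:

| parameter | value | between-participant SD | role |
|---|---|---|---|
| b0 | 0.2 | 0.25 | slight baseline cooperativeness |
| b_rep | 0.4 | 0.15 | reputation prior (log-odds per code unit) |
| b_recip | 1.1 | 0.25 | direct reciprocity — the dominant behavioral force |
| b_emo | 0.3 | 0.15 | emotion-signal effect |
| b_round | 0 | 0 | no secular drift |
| a_rep | 1 | 0.1 | initial rating = ±30 for ±1 reputation |
| w_rep, w_coop, w_emo | 10, 40, 22 | 1.5, 3, 2 | final-rating weights (points) |

With these values the derived norm table reproduces the three headline
patterns of the phenomenon the package models: a well-reputed
extortionist keeps a significantly positive final reputation when it
displays cooperative emotion; a badly-reputed generous counterpart is
rehabilitated to positive reputation when generosity is confirmed by
cooperative emotion; and generosity alone — with a neutral face — is not
sufficient (predicted cell means +22, +11, −2 rating points
respectively, against a cell-mean sampling SD of about 2 at 40
participants per cell).

**What the generator does not emulate.** (i) Human effect-size ratios:
in the synthetic scenario the reputation and strategy effects are of
comparable magnitude, whereas in human data strategy dominates by a
factor of ~3 in partial η²; passing tests therefore certify directions
and pipeline correctness, not human effect sizes. (ii) The fourth,
symmetric "as long as" nuance — a well-reputed extortionist with a
*neutral* face dropping to non-positive status — is not reproduced: with
a single w_coop weight the generous and extortion cooperation-frequency
offsets from 0.5 (about +0.19 vs −0.08) cannot both cancel the
reputation term, so that cell's predicted mean stays positive (+7). A
rating model with asymmetric behavioral weighting could capture it; that
is deliberately out of scope. (iii) Learning, fatigue, demographics,
dropout, and attention are absent; coefficients are fixed per participant.
(iv) The expression is assumed available to the participant model from
the round it follows (shown with the outcome feedback), and full payoff
feedback is assumed each round.

**Reproducibility.** All randomness flows from one root seed through
named substreams (`population`, `participant-<id>`), so regeneration is
bit-identical and enlarging one component never perturbs another's
stream. Sub-seeds are derived by a fixed integer hash and stay below
2^31.

## 5. The statistical pipeline

The response for the cooperation analysis is the per-participant
cooperation rate averaged over the 20 rounds; rating analyses use the
final rating and the change (final − initial).

`factorial_anova()` computes **Type III sums of squares** from first
principles: the fully-crossed model is built with effect (sum-to-zero)
coding, and each effect's SS is the residual-SS increase when its
columns are dropped from the full model (all other effects, including
interactions, retained). The choice is deliberate: real cell sizes in a
711-participant 18-cell study are necessarily unbalanced (711/18 =
39.5), yet the reported error df (N − 18 = 693) implies the full
factorial model; Type III with effect coding is the standard convention
for exactly that situation, and on balanced data it provably coincides
with the sequential decomposition (asserted to 1e−9 in the tests,
alongside an independent cross-check against `car::Anova`). F =
MS_effect/MS_error, p from the F distribution, and partial η² =
SS_effect/(SS_effect + SS_error), which is invariant to affine
rescaling of the response. Degenerate inputs error explicitly: empty
cells are listed by name, and a residual SS below 1e−10 of the total is
reported as zero residual variance rather than producing infinite F.
The design machinery (QR factorizations of the full and each reduced
model) is built once and reused, which makes the 10,000-replicate
type-I-error calibration run in seconds.

`bonferroni_pairwise()` performs all k(k−1)/2 comparisons within one
factor using the pooled one-way error term (MS_error on N − k df) and
multiplies raw p by the number of comparisons, capped at 1. The family
is the comparisons within one factor — three for a 3-level factor — not
all effects jointly. Whether the original analyses pooled the omnibus
error term or used per-pair variances is not recoverable from the
reported statistics; the pooled version is implemented and flagged here.

`one_sample_t()` is the textbook statistic t = (x̄ − μ0)/(s/√n) with
two-sided p; a zero-variance sample raises an error rather than
returning ±∞. p-values are reported at full precision; significance
thresholds are applied downstream, never inside the test.

## 6. Norm tables

`derive_norm_table()` reconstructs the per-cell classification: for each
of the 18 cells, one-sample t-tests of final ratings and of rating
changes against 0 at α = 0.05 (uncorrected across cells by default —
per-cell significance is conventionally reported without a cross-cell
correction, and a Bonferroni flag over the 18 cells is available). A
cell is G when its mean is significantly positive, B when significantly
negative, N otherwise; change direction up/neutral/down analogously.
Classification is monotone in shifts of the ratings, and under a null
generator each cell is non-N with probability ≈ α.

`apply_norm()` turns a derived table into deterministic reputation
dynamics by mapping the final class {B, N, G} onto the labels {negative,
unknown, positive}. That mapping extrapolates beyond the original
factorial design (which never re-assigned reputations); it exists to
let users iterate a derived norm, e.g. to check that constant generous
behavior with cooperative emotion absorbs at the positive label within
two steps. The strategy class fed to the norm is the assigned design
cell, not inferred from behavior, matching the experimental
manipulation.

## 7. Configuration, I/O, and the CLI

Everything tunable lives in one JSON configuration (payoffs, strategy
vectors, p0, display-policy overrides, population means/SDs, design
sizes, seed, analysis options) with schema validation that rejects
unknown keys and names the offending field path. Trial and rating data
are plain CSV in documented schemas; reading validates label sets and
the consistency of every outcome with its two moves, and a
column-mapping adapter accommodates externally formatted files (the
layout of any external deposit is not hard-coded). The
`emonorm` CLI (`verify-zd`, `simulate`, `analyze`, `derive-norms`) is a
thin wrapper over the same functions; `simulate` is byte-reproducible
under a fixed seed.

## 8. Problem sizes used in the checks

The shipped test-and-acceptance surface uses: 1,000 random strategy
pairs for row-stochasticity; 1,000 random opponents per certified
strategy for the enforced payoff relation (tolerance 1e−8); 50 random
ergodic pairs × 10^6 Monte-Carlo rounds against the stationary solve
(tolerance 0.005 per outcome; entries kept in [0.05, 0.95] so chains mix
well); 10,000 null replicates at 10 observations/cell for the ANOVA and
t-test size calibration (band 0.05 ± 0.01); ten independent n = 720
datasets for coefficient recovery (unbiasedness and nominal 2-SE
coverage — a single 2-SE check is itself a 95%-probability event, so the
property is certified at the replicate level); and the default scenario
at 40 participants/cell for the norm-table patterns. These sizes were
chosen so every claim is tested at the scale the underlying statistics
require.

## 9. Known limitations

* The participant model is a minimal logistic reciprocity model;
  reinforcement learning, belief updating, and richer appraisal dynamics
  are out of scope by design.
* Higher-order norms conditioning on the *judge's own* reputation are
  not modeled (the judged player's reputation is a design factor; the
  participant's own reputation is always unknown to the counterpart).
* Longer-memory strategies, implementation noise in the counterpart
  scripts, evolutionary tournaments, and population dynamics are
  non-goals.
* Human cell means are not reproducible from the generator; see §4 for
  exactly which qualitative patterns the default scenario does and does
  not reproduce.
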