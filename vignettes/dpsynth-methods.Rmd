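---
title: "Differentially private synthetic cohorts: models and methods"
author: "dpsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentially private synthetic cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpsynth)
```

# The problem

Individual-level records from clinical studies — say twelve visits of
systolic blood pressure (SBP), diastolic blood pressure (DBP) and
medication count per participant of a two-arm hypertension trial — cannot
normally be shared without data-use agreements, because the records
identify people. `dpsynth` takes the generative route: fit a model of the
joint distribution of participant records under differential privacy, then
release synthetic participants sampled from it. Differential privacy makes
the release quantitative: an (ε, δ) guarantee bounds, up to a factor eᵉ
with failure probability δ, how much any observer's beliefs about a single
participant can change because that participant joined the study. The
`dpProbabilityBound()` / `premiumBound()` helpers express this bound on the
probability-and-cost scale (a prior event probability p is bounded by
p(1+ε) in the small-ε linearised convention, or p·eᵉ exactly — the
linearised form is the default because it is the convention used in
nontechnical presentations of the guarantee; both cap at 1).

# The generative model

The synthesiser is an auxiliary-classifier GAN over the flattened
participant record (36 values for the default trial schema), conditioned
on treatment arm:

* **Generator** G(z, a): z ∈ R¹⁰⁰ standard normal, arm a embedded by a
  learned 2×8 table concatenated to z; two fully connected ReLU layers of
  width 128; tanh output, so records live in [−1, 1] per coordinate.
* **Discriminator** D(x): two leaky-ReLU(0.2) layers of width 128 with two
  sigmoid heads — a *source* head (real vs generated) and an *arm* head.

The arm head is what distinguishes an AC-GAN from a plain GAN: both
networks are additionally penalised by arm-classification cross-entropy
(on real and fake records for D, on fakes for G), so G is rewarded for
fakes that carry their requested arm's structure. All losses are binary
cross-entropies computed from logits.

Records enter the network through a fixed affine normalisation per
variable: x ↦ (x − mid)/half over a-priori physiologic ranges — SBP
(60, 250) mmHg, DBP (30, 150) mmHg, medications (0, 10). The ranges are
deliberately *not* data-derived: estimating a min/max from the data would
itself consume privacy budget. Denormalisation clamps to the range and
rounds count variables to non-negative integers; out-of-range inputs clamp
with a warning rather than erroring, because a synthetic record slightly
outside a physiologic range is a modelling blemish, not a pipeline fault.

Both networks are trained with Adam at learning rate 2 × 10⁻⁴ and
β₁ = 0.5. The β₁ choice matters: with standard momentum (β₁ = 0.9) or with
plain SGD on the discriminator the adversarial game on the trial fixture
is unbalanced — the discriminator wins and its held-out real-vs-fake
accuracy sits at 65–80% — whereas the damped setting lets the two players
track each other and the game settles near the 50% indifference point.
This is the standard configuration in the GAN literature, and it is
compatible with the privacy analysis below because the optimizer only ever
consumes the already-privatised gradient.

# Training with differential privacy

Only the discriminator touches real data, so only its updates are
privatised. One private update:

1. **Poisson lot sampling.** Each of the n training records enters the lot
   independently with probability q = L/n (`sampleLot()`), so the lot size
   is Binomial(n, q) with mean L. Poisson sampling — not fixed-size
   shuffling — is used because the accountant's subsampling amplification
   bound assumes exactly this mechanism.
2. **Per-participant clipping.** The gradient of each lot member's loss
   (source + arm terms) is clipped to ‖g‖₂ ≤ C (`clipGradient()` states
   the rule; training uses the factorised form below). Clipping is on the
   *global* norm across all discriminator parameters, not per layer.
3. **Noise on the sum.** The clipped gradients are summed, Gaussian noise
   N(0, σ²C²) is added per coordinate, and the result is divided by L
   (`noisyLotGradient()`): the Abadi convention of noising the sum rather
   than the mean, documented because both appear in the literature.
4. The fake-batch half of the discriminator loss involves no real data and
   enters as an ordinary mean gradient; the generator's update is pure
   post-processing of discriminator feedback and is never clipped, noised
   or accounted.

Because the networks are fully connected, the per-example gradient of a
dense layer factorises as outer(input, delta), so its squared norm is
|input|²·|delta|² and the whole per-example clipping step reduces to one
backward pass plus a row-scaled matrix product — no per-example loop. A
finite-difference test pins the backward pass to the loss, and a
degenerate-parameter test (σ = 0, q = 1, C = ∞) verifies that the private
code path reproduces the vanilla gradient exactly.

# Privacy accounting

Each noisy step is one invocation of the subsampled Gaussian mechanism
with parameters (q, σ). The accountant tracks, for integer moment orders
λ = 1…32, the log moment of the privacy-loss random variable

α(λ) = log E₍z∼ν₎[(ν(z)/μ₀(z))^λ],  μ₀ = N(0, σ²), μ₁ = N(1, σ²),
ν = (1−q)μ₀ + qμ₁,

whose binomial expansion for integer λ is exact:

α(λ) = logsumexp over k = 0…λ+1 of [log C(λ+1, k) + (λ+1−k)·log(1−q) +
k·log q + k(k−1)/(2σ²)].

At q = 1 only the k = λ+1 term survives and the plain Gaussian closed form
λ(λ+1)/(2σ²) is recovered. Log moments are additive under composition, so
T steps cost T·α(λ), and the tail bound converts the ledger to
δ(ε) = min_λ exp(α(λ) − λε), with ε(δ) obtained by bisection to 10⁻⁴.
A ledger with zero steps reports δ = 0 (no mechanism ever ran), and σ = 0
with q > 0 is rejected as an infinite-moment configuration. The expansion
is evaluated in log space throughout; the test suite checks it against an
independent numerical-quadrature oracle to 10⁻⁶ across q ∈ {0.001, 0.01,
0.05} × σ ∈ {1, 2, 4, 8}.

The default private configuration is lots of L = 60 from n = 6000
(q = 0.01, 100 lots per epoch) with σ = 5 and C = 1. These defaults were
fixed so that a full 1000-epoch run stays within the budget the package
targets — ε = 3.5 at δ < 10⁻⁵ (`epsilonAtDelta()` gives 3.28 for these
defaults). `privacyCurve()` tabulates δ against
epoch for several ε to make the spend visible while choosing a run length.

# Private checkpoint selection

A GAN has no single best epoch; sampling several checkpoints improves the
released cohort. Checkpoints are scored by a *bounded* downstream utility:
generate a small synthetic cohort from the checkpoint, fit a lightweight
arm classifier on it (nearest centroid by default), and record its
agreement in [0, 1] with the real training arms. Because the score reads
real data, selection must be private: k = 10 checkpoints are drawn without
replacement by the exponential mechanism, each draw picking index i with
probability ∝ exp(ε·uᵢ/(2Δu)) at ε = 0.05 — a (0.05, 0) guarantee per
selected model, (0.5, 0) in total by basic composition. The agreement
utility changes by at most 1/n when one participant changes, so
Δu = 1/n_train by default; both the utility and its sensitivity are
configurable. The exponential mechanism is used because it is the standard
(ε, 0) selection primitive whose cost is a fixed per-model budget;
k = 10 at 0.05 each gives a selection total of (0.5, 0). Composed with
training at ε = 3.5, δ = 10⁻⁵ this yields the single-digit overall budget
(4, 10⁻⁵) that `composeBudgets()` reproduces.

`poolGenerate()` splits the requested cohort as evenly as possible across
the selected checkpoints (remainder to the earliest) with deterministic
per-checkpoint seeds. Arm counts in generation are exact
(round(n·armMix)), not Bernoulli draws, for reproducibility.

# Evaluating synthetic-cohort utility

* `pairwisePearson()` — correlation of all 36 columns in variable-major
  order; zero-variance columns yield 0 with a warning.
* `structureSimilarity()` — Spearman rank correlation of the strictly
  lower triangles (diagonal excluded, since it is 1 by construction) of
  two correlation matrices.
* `summaryStats()` — per-arm, per-visit, per-variable mean (SD) tables.
* `medAdditionRate()` — among visit transitions whose starting SBP exceeds
  the arm's goal (120 mmHg intensive / 140 standard), the proportion where
  the medication count increases. Transition-level counting is used
  (each above-goal transition is one trial) rather than per-participant
  aggregation, matching a "proportion of times" reading; per-arm rates are
  also emitted, and an empty denominator yields NA rather than 0.
* `transferLearningEval()` — TSTR: classifiers (logistic regression via
  `glm`, linear-kernel SVM via e1071, random forest, k-NN) trained on real
  or synthetic data, all scored by AUROC on the same held-out real test
  set; coefficient/importance vectors are returned and
  `coefficientConcordance()` correlates them (Pearson and Spearman, raw
  p-values, no multiplicity correction). Features are identically
  normalised for every training source so coefficients are comparable.
  Classifier hyperparameters are library defaults with fixed seeds.
* `scoreComparison()` — Mann-Whitney U with exact enumeration of all
  label assignments when n₁+n₂ ≤ 12 and the tie-corrected,
  continuity-corrected normal approximation otherwise (checked against
  `wilcox.test` in the tests).

# The fixture simulators

The real data targeted by this class of method are access-restricted, so
the package ships generative fixtures whose *structure* matches the
analysis targets while every numeric default is a declared fixture
constant, not an estimate of any real study.

`simulateTrial()`: arm ∼ Bernoulli(0.5); baseline SBP ∼ N(140, 15²)
truncated to [90, 200]; baseline medications ∼ Poisson(2) truncated to
[0, 6]; per visit transition, a medication is added with probability 0.3
while above the arm's goal (counts capped at 10), and SBP mean-reverts
towards the arm target with rate κ = 0.4 plus N(0, 8²) innovations; DBP =
0.5·SBP + 8 + N(0, 6²). The titration *goals* (120/140) are kept distinct
from the reversion *targets* (120/135): the goals are protocol thresholds,
the targets describe how tightly the simulated physician actually controls
each arm, and separating them produces above-goal titration events at a
controllable rate. Mean reversion gives the qualitative signature of real
longitudinal BP data — cross-visit correlation that decays with lag — and
the titration rule makes the medication-addition rate an exact
parameter-recovery target (the estimator recovers p_add up to the rare
censoring at the 10-medication cap).

`simulateEhr()` emulates the EHR task: nine vital signs with ≥ 5
timestamped measurements for a configurable fraction of patients (default
0.95; the remainder get 4 of one vital and are dropped by the
complete-case rule), case probability 2110/8260 by default, and case means
shifted by a configurable number of SDs. Heart-failure labels come from an
ICD-9 code list; matching is exact on the trimmed code string ("428"
matches only the literal "428", never "428.x") because the list already
enumerates its decimal children — prefix semantics would silently
over-match, and users who want them can expand the list.

What the fixtures do *not* emulate: real marginal shapes (skew, mixed
discrete/continuous patterns, digit preference), informative missingness,
measurement batch effects, or any real event rates beyond order of
magnitude. Tests passing on fixtures therefore demonstrate that the
machinery is correct and that the method preserves the kinds of structure
it is designed to preserve — not that any particular real-data result is
reproduced.

# Numerical and design choices

* **Split.** `splitTrainTest()` is a seeded uniform shuffle; the
  train/test partition of the motivating studies was not documented, so a
  reproducible random split is used.
* **Checkpoint cadence.** A uniform `checkpointEvery` grid (default every
  10 epochs) plus the final epoch. A denser tail was considered and
  rejected: a uniform grid serves epoch selection equally well and keeps
  memory proportional to epochs/cadence.
* **Ledger for nonprivate runs.** Real-data steps are still counted but
  the log moments are infinite — δ(ε) = 1 for every ε, i.e. explicitly no
  guarantee — rather than pretending a nonprivate run has a budget.
* **Worked-example conventions.** The premium bound adds the full bounded
  expected event cost to the stated base premium (base + cost·p), and the
  probability bound defaults to the linearised (1+ε) factor; both follow
  the conventions such worked examples conventionally print (a $3000
  premium, a $30,000 event and a 0.18% bound give $3054), with the exact
  eᵉ variant behind a flag.
* **Determinism.** Every stochastic entry point takes a seed and restores
  the caller's RNG state; the pipeline fans one seed out to stages through
  a fixed affine counter scheme. Bit-reproducibility holds for fixed
  BLAS/thread settings.
* **Problem sizes in the shipped tests.** The adversarial-training checks
  run at n = 2000 training records for 200 epochs (three seeds), the
  parameter-recovery check at n = 6000, and Monte-Carlo checks at 10⁴–10⁵
  draws — sizes at which the verified quantities (equilibrium accuracy
  bands, recovery tolerances, 3·SE Monte-Carlo bounds) are statistically
  meaningful on a desktop machine.

# Limitations

The networks are fully connected and the data model is a fixed-width
continuous matrix with one binary condition label: no recurrent or
convolutional variants, no native handling of categorical/ordinal
variables (counts are handled by rounding), and no discrete-data GAN
extensions. The accountant implements the single moments-accountant tail
bound — no Rényi-DP conversions, advanced composition theorems, or
auditing attacks. Private training degrades utility by design; at the
default σ the synthetic cohorts from short private runs are visibly
noisier than nonprivate ones, and closing that gap requires larger cohorts
(larger n lowers q, and privacy amplification does the rest).
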