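---
title: "An entropic simulator of insistence on sameness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An entropic simulator of insistence on sameness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrosim)
```

## The model

entrosim simulates a cognitive agent whose only abilities are
discrimination, memorization and prediction of concrete stimuli. The
agent's relationship to its world is summarized by the entropy distance
(variation of information) between two random variables: the environment
$R$, a mixture of stimulus sequences, and the memory $M$, a growing graph
of classified stimulus prototypes:

$$D_H(R, M) = H(R \mid M) + H(M \mid R).$$

The two conditional entropies are read as *surprise* (how unpredictable the
incoming stimulus is given what is remembered) and *uncertainty* (how
ambiguous the memorized continuations are given the current stimulus). The
distance is a metric on random variables: it is zero exactly when each
variable determines the other, equals $H(R) + H(M)$ under independence, and
satisfies the identity $D_H = H(R,M) - I(R;M)$, which links distance
reduction to mutual-information maximization. The test suite verifies the
identity to $10^{-9}$ on random joints and the triangle inequality by brute
force over all three-variable ternary joints on a $1/4$ probability grid.

Each simulated step runs a three-phase processing loop:

1. **Perception.** Before the stimulus is fully integrated, the memorized
   context predicts what should come next. If the stimulus is known, the
   surprise is the entropy of the memorized option set (0 bits on a
   deterministic continuation, $\log_2 \nu$ bits at a $\nu$-way uniform
   branch); if it is new, the memorized context carries no information
   about it and the surprise falls back to a baseline standing in for
   $H(R)$. The configured *event rule* decides which quantity is compared
   against the sensory-overload threshold $T_{so}$: the set entropy itself,
   or the realized surprisal $-\log_2 p(\text{observed})$ under a smoothed
   predictive distribution (the default, since a threshold crossing is
   triggered by a concrete stimulus rather than by an expectation).
2. **Classification.** A nearest-neighbour map $\rho$ assigns the stimulus
   to the closest stored prototype under Euclidean distance — always, no
   matter how far it is; a novelty radius $\varepsilon$ decides whether the
   match counts as a (noisy) re-occurrence or as something new. Ties break
   to the lowest item id so runs are reproducible.
3. **Prediction.** The uncertainty about what comes next — option-set
   entropy for known stimuli with registered continuations, the full
   memory entropy $H(M)$ for novel ones — is compared against the anxiety
   threshold $T_a$.

Both thresholds are positive random variables (lognormal by default,
resampled each step), reflecting that they are unknown, individually
specific and varying in time. A step below both thresholds is inside the
*comfort zone*.

## Policies and emergent sameness

Two routes reduce $D_H$: learn about $R$ (store new stimuli in $M$), or
constrain $R$ to what $M$ already contains. The package's three policies
operationalize this choice:

* `learn` inserts every observation into the memory graph;
* `constrain` rejects novel stimuli (and known stimuli arriving outside
  any memorized continuation) and immediately redraws the environment step
  restricted to states whose prototypes classify as known — the
  insistence-on-sameness mechanism. The redraw happens within the step:
  recording the novel stimulus's events and constraining only later would
  leave the agent exposed to novelty at the injection rate, which is
  precisely what the behavior avoids;
* `passive` observes without acting, the baseline for twin comparisons.

The headline emergent property, checked on twenty matched seeds in the
acceptance suite, is that with learning disabled in a novelty-injecting
environment the constrain policy produces strictly fewer overload and
anxiety events and a lower empirical $D_H$ than the passive policy, at the
price of visible rejection behavior and reduced route diversity.

Under sensory deprivation the environment emits pure endogenous noise, so
every percept is novel and surprisal is high. With self-stimulation
enabled, a novel ambient stimulus whose surprisal exceeds
$\min(T_{so}, \text{floor})$ is displaced by the prototype of the most
frequent memorized item, and the step's measures are computed on the
substituted stimulus with a fresh context (the stim routine restarts a
known sequence). Self-stimulation therefore requires a non-empty memory;
experiments seed it by memorizing a small chain first.

## Synthetic environments

All inputs are synthetic. `env_spec()` + `generate_environment()` build
branching sequence graphs: `n_sequences` trunks of `seq_length` states
whose prototypes are drawn by rejection sampling until every pair is at
least `min_separation` apart (error if the dimension cannot host them);
sequences share a prefix up to each branch position and diverge into
`branch_arity` suffixes, so a branch is a set of memorized possibilities
after a common context. Emission adds isotropic Gaussian noise of sd
`noise_sd`; with probability `novelty_rate` a brand-new, separation-
respecting prototype is injected (persistent by default: it becomes an
environment state with a recorded resume successor; a transient mode
labels it uniquely in the trace without persisting it).

Sensory noise is drawn from a private RNG stream seeded independently of
the episode seed (`set_noise_seed()`). This makes the noise-invariance
property testable in its sharp form: with prototype separation above
$2\varepsilon$ and noise kept below $\varepsilon$, varying only the noise
seed leaves every classification, measure and event bit-identical.
Gaussian noise is unbounded, so the regime used in the tests sets
$\sigma = 0.02$ against $\varepsilon = 0.5$, where the chi-square tail
probability of a noise norm exceeding $\varepsilon$ is far below what any
feasible run length could sample.

Three guideline-inspired transforms reshape environments the way a
therapist would reshape activities:

* `transform_amulets()` appends a per-sequence indicator coordinate (an
  "amulet" distinguishing otherwise identical activities) and splits
  shared states, driving memorized branch uncertainty to zero;
* `transform_branch_to_start()` reorders each sequence so its
  distinguishing states come first — the choice is made at index 0 and
  the remainder is deterministic;
* `transform_limit_options()` prunes branch alternatives to at most
  $\nu_{max}$, cutting memorized branch entropy from $\log_2 \nu$ to
  $\log_2 \nu_{max}$.

What the generator deliberately does **not** emulate: naturalistic sensory
statistics (stimuli are abstract separated vectors, so classification is
almost noiseless by construction), semantic or hierarchical structure
(excluded by the model's own assumptions), non-stationary drift of
prototypes, and correlated or heavy-tailed noise. Passing tests therefore
show internal consistency of the framework under its stated assumptions,
not ecological validity on real sensory data.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| novelty radius $\varepsilon$ | $0.45 \cdot$ `min_separation` | stimulus space | below half the separation, so sub-radius noise can never flip a classification |
| `baseline_bits` | $\log_2(\max(2, \text{n states}))$ | bits | stand-in for $H(R)$, which the agent cannot know; the environment alphabet size is the natural scale |
| `novelty_mass` | $2^{-10}$ | probability | smoothing mass reserved for unseen continuations; keeps realized surprisal finite while making deviations expensive (~10 bits) |
| `context_depth` | `Inf` | items | sequences are memorized as wholes; depth 1 gives the Markov ablation |
| threshold model | lognormal, meanlog $\log 4$, sdlog 0.25, per step | bits | positive support, moderate variability around a threshold a few bits above routine surprise |
| H(M) weighting | counts | — | the agent's exposure frequencies; `uniform` available since the choice is genuinely open |
| noise sd (presets) | 0.02 | stimulus space | two orders of magnitude under the separation: known stimuli stay known |
| novelty rate (nonstationary preset) | 0.05 | per step | rare enough that routines dominate, frequent enough that policies diverge measurably |

## The therapy planner

Therapy is the constrained optimization: choose what to present next to
maximize $I(R;M)$ while predicted surprise and uncertainty stay below the
thresholds. Since the thresholds are latent, `estimate_thresholds()` treats
every step as an interval-censored observation — an event step brackets the
sampled threshold from above, a quiet step from below — and fits the
Turnbull NPMLE (via the survival package), reading off a conservative
$q$-quantile ($q = 0.1$ by default). A channel that never produced events
yields only lower bounds; the estimate then falls back to the maximum
observed measure plus a margin and is flagged.

`plan_therapy()` is greedy over a finite candidate set of complete
environment sequences (never fragments): each round it simulates presenting
every remaining candidate to the current simulated memory, discards those
whose per-step maximum surprise or uncertainty reaches the estimates (the
constraints are stated per step; the max-over-steps reading is the
conservative resolution of their per-candidate aggregation), and schedules
the feasible candidate with the largest estimated MI gain. Gains are
estimated by classifying one seeded rollout stream under the memory before
and after hypothetically learning the candidate, so the difference isolates
the candidate's effect. Planning stops when no candidate is feasible ("no
safe entry point" at round one), when gains fall below a floor, or when
candidates run out. The planner may apply the branch-to-start transform
when it unlocks infeasible candidates (it preserves the stimulus
dimension); the amulet transform changes the stimulus encoding itself, so
it is recorded as a recommendation rather than applied silently.

For planning and executed therapy the set-entropy event rule is the
default: the optimization problem's constraints are the conditional-entropy
levels themselves, and using one measure end to end keeps calibration,
planning and execution coherent. Greedy scheduling is compared against the
exhaustive-ordering optimum on four-candidate instances in the tests; the
achieved predicted-gain ratio is printed by the acceptance suite rather
than claimed here.

## Numerical choices and degenerate inputs

* Logarithms are base 2 throughout; all quantities are bits. A $\nu$-way
  uniform branch is worth exactly $\log_2 \nu$.
* $0 \log 0 = 0$; probability vectors must sum to 1 within $10^{-9}$;
  exact-arithmetic tests run at $10^{-12}$.
* Plug-in entropy estimation by default; the Miller–Madow correction is
  available behind a `correction` flag for empirical joints (which carry
  their observation count).
* An empty option set is a legitimate zero-length distribution signalling
  the novel case; an empty memory has $H(M) = 0$ with a warning;
  `surprisal_of()` falls back to `baseline_bits` whenever the memory
  offers no continuation, so scores are finite everywhere.
* A sequence's terminal step has no registered continuation, so its
  predictive uncertainty falls back to $H(M)$ by design; analytic-zero
  checks therefore read interior steps.
* Classification ties, option-pruning ties and start-state ties all break
  to the lowest id.
* Environments are pure functions of their spec (the generator uses a
  private RNG stream and restores the caller's RNG); episodes are pure
  functions of (config, environment, threshold model, seed).

## Problem sizes

The shipped experiments are sized for a single CPU: preset environments of
6–18 states in 8–16 dimensions; episodes of 100–500 steps; twin and
self-stimulation experiments over 20 matched seeds; threshold recovery at
500 censored step records; exhaustive-ordering comparisons on 4-candidate
instances (24 orderings); the triangle-inequality enumeration over 27,405
grid joints. These sizes were chosen so each property is measured well
clear of its decision boundary while the whole suite stays fast.

## Known limitations

* The memory never forgets and never abstracts; both are faithful to the
  modeled cognitive restrictions, but they mean memory size grows linearly
  with distinct novel stimuli.
* The $H(R)$ baseline is a configured proxy; an agent cannot estimate the
  true environment entropy it has refused to sample.
* The constrain policy's redraw uses the simulator's knowledge of which
  environment states are known to the agent; a physical agent would
  implement the restriction through action, which is outside scope.
* Threshold estimation assumes the event rule used to generate the traces
  is known; mixing traces recorded under different rules would bias the
  censoring directions.
* Validation here is internal (identities, invariants, emergent-behavior
  contrasts on synthetic worlds) — the digital-twin comparison surface is
  an instrument for expert judgement, not a clinical claim.
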