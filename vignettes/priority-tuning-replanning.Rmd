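---
title: "Priority-tuning replanning: models, scoring, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Priority-tuning replanning: models, scoring, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`replanRL` turns the manual priority-tuning loop of IMPT inverse planning
into a Markov decision process and trains value-based (DQN) and
policy-gradient (PPO) agents on it. This vignette explains each model in
the pipeline, the parameters that matter, what the synthetic generator does
and does not emulate, and the design choices made where the design was
genuinely open.

## 1. The dose model

A phantom is a voxel grid (default $64 \times 64 \times 1$ at 2 mm
spacing, i.e. a single axial slice with 0.008 cc voxels) carrying binary
masks for up to three clinical target volumes (CTV1/2/3, prescribed
70 / 59.85 / 53.90 GyRBE by default) and twelve head-and-neck OARs. The
default layout places a primary target inside a larger secondary target —
the nested-target geometry typical of head-and-neck plans — with the
pharynx overlapping the targets and the remaining OARs at anatomically
motivated bearings. Placement can also be randomized per seed.

Dose is linear in the beamlet intensities, $d = Dx$. The dose-influence
matrix $D$ is built from a parallel-ray pencil-beam model: each of 5
coplanar gantry angles carries 13 lateral spot positions (4 mm apart,
3 mm Gaussian penumbra) times 9 energy layers whose Bragg peaks sit at
depths 36–92 mm. The depth dose is a parameterized Bragg-like curve: a
0.35 entrance plateau rising to a unit Gaussian peak (proximal width 5 mm)
with a sharper 2 mm distal falloff. Entries below 0.5 % of a column's
maximum are zeroed and the matrix stored sparse; all-zero columns from rays
that miss the grid are kept so beamlet indexing is stable across anatomies.

This model is intentionally simple: any smooth, nonnegative linear dose
operator supports the method, and the Bragg-peaked layers preserve what
makes the proton setting distinctive (dose that can be *placed* in depth,
hence a meaningful trade-off space for the optimizer). It is not a
transport calculation: no heterogeneity, scatter, or range straggling.

## 2. Inverse planning

Fluence is optimized by projected gradient descent on
$$\mathcal{L}(x) = \sum_m \omega_m \lVert D_m x - d_{Rx,m}\rVert^2
 + \sum_k \omega_k \lVert D_k x \rVert^2,\qquad x \ge 0,$$
with one scalar prescription per target (uniform target vector) and
per-structure priorities $\omega \in [0,1]$. Voxels belonging to several
structures contribute to every term that indexes them; there is no mask
exclusivity, so target–OAR overlap produces the genuine competition the
tuning agent must resolve.

Numerical choices:

* **Step size.** Fixed $\eta = 1/L$ with $L$ estimated by 30 power
  iterations on the weighted normal operator $D^\top \mathrm{diag}(w) D$
  from a deterministic start; an Armijo backtracking rule is available as
  an alternative. A safeguard halves any step that fails to decrease the
  objective, so the objective trace is non-increasing under either rule.
* **Stopping.** Relative objective change below $10^{-5}$ (default) or 200
  iterations. The iteration cap is a per-transition budget: inside an
  episode each re-optimization is warm-started from the previous fluence,
  so convergence accumulates across steps.
* **Degenerate inputs.** All-zero weights return the start point with a
  zero objective; non-finite objectives or gradients abort with the
  iteration index; zero-dose beamlet columns are tolerated.

**Planning margin.** The quadratic penalizes deviation from the
prescription symmetrically, so a converged plan centers target dose *at*
the prescription and the coverage metric $V_{d_{Rx}}$ would saturate near
50 %. Clinical practice plans a few percent above prescription so that the
cold tail still clears it. The environment therefore passes
`rx_boost` × prescription (default 1.08) to the optimizer as the planning
target, while every metric and score is evaluated at the clinical
prescription. This is a deliberate package choice; set `rx_boost = 1` to
recover the unmargined objective.

## 3. Plan scoring

Sixteen clinical objectives are scored: $V_{d_{Rx}} \ge 98\%$ per target,
$D_{0\%} \le 110\%$ of prescription for CTV1, near-maximum limits
$D_{0.03cc} \le 30$ GyRBE for brainstem and spinal cord, $V_{70} \le 10\%$
for the mandible, and mean-dose limits for the remaining OARs. $D_v$ is
computed by descending sort at rank $\lceil v / \text{voxel volume}\rceil$;
$D_{0\%}$ is the maximum.

Per-goal scores are piecewise linear: full points when the goal is met,
zero at a configurable zero-score level, linear between. Defaults: the
zero level is goal × 1.25 for upper limits and goal − 5 percentage points
for coverage. Points are allocated 15 per target objective (4 objectives)
and 7.5 per OAR objective (12 objectives), summing to exactly 150 — the
allocation preserves the published total and the dominance of target
objectives while remaining overridable per goal. The per-goal curve shapes
and the allocation are package defaults, not reproductions of any
proprietary scoring table.

## 4. The MDP

* **State**: the $15 \times 100$ cumulative DVH matrix (dose axis 0 to
  1.2 × the highest prescription), flattened to 1500 dimensions.
* **Actions**: 22 = 2 directions × 11 tuning targets — each CTV
  individually plus 8 OAR groups (brainstem, spinal cord, mandible,
  larynx+pharynx, parotids, cochleae, submandibular glands, esophagus).
  Bilateral organs move together; each action adds ±0.1 and clips to
  $[0,1]$. The grouping, the ±0.1 magnitude, and the initial priorities
  $\omega_0$ (0.8 for targets, 0.2 for OARs) are package defaults chosen so
  that both directions are initially non-trivial and the full range is
  traversable within an episode.
* **Transition**: warm-started re-optimization under the updated weights.
* **Reward**: the plan-score difference, which telescopes to
  (final − initial) over an episode.
* **Termination**: 15 steps, or early once the score reaches the goal
  table's ceiling. At evaluation the horizon may be extended, and the
  best-scoring *intermediate* plan is reported alongside the final one —
  a planner would keep the best plan seen, not the last.

The environment is deterministic: replaying an action sequence reproduces
rewards bitwise. All randomness lives in the agents.

## 5. Agents

Both learners operate on the flattened DVH state with 2-hidden-layer
fully-connected networks (256 and 128 units, ReLU), written in base R with
manual backpropagation and Adam, and verified against finite-difference
gradients in the test suite.

* **DQN**: experience replay (capacity 10 000), minibatch 64, target
  network synced every 100 gradient steps, ε-greedy linearly annealed
  1.0 → 0.05 over 1000 env steps, γ = 0.99, learning rate $10^{-3}$.
  The TD target is $r + \gamma \max_{a'} Q_{\text{target}}(s', a')$,
  reducing to $r$ at terminal steps.
* **PPO**: separate policy and value networks, rollouts of 60 steps,
  4 epochs of minibatch 32, clip ε = 0.2, GAE λ = 0.95, value coefficient
  0.5, entropy coefficient 0.01, learning rate $3 \times 10^{-4}$,
  advantages normalized per rollout. The critic regresses on discounted
  returns; the actor maximizes the clipped surrogate.

All hyperparameters are conventional desk-scale defaults, configurable
through `dqn_config()` / `ppo_config()`; none are reproductions of any
published configuration.

**Patient-specific vs population training.** `train_agent()` cycles
episodes round-robin over whatever environments it is given: the
original + progression + regression anatomies of one phantom
(patient-specific mode) or a pool of different phantoms (population mode).
Across-episode warm starting of fluence is off; warm starts apply only
within an episode, where successive problems differ by one priority nudge.

## 6. What the generator emulates — and what it does not

The synthetic pipeline stands in for a planning CT with contours plus an
external dose engine: structure masks play the contours, the pencil-beam
matrix plays the precalculated dose influence, CTV dilation by 2 mm /
erosion by 3 mm plays tumor progression/regression, and a held-out anatomy
with an anisotropic CTV change (3 mm / 1 mm per axis) plus a 4 mm parotid
shift plays the replanning CT. The structuring element is a discrete ball
with per-axis radius `round(margin / spacing)`.

It does **not** emulate: CT numbers or density heterogeneity, deformable
soft-tissue motion (changes are morphological or rigid), weight loss,
3-D out-of-plane geometry in the default configuration, or inter-patient
anatomical diversity beyond sphere placement. Consequently, passing tests
show that the method — optimization, scoring, credit assignment, learning —
behaves correctly and that agents can learn to improve plans on anatomies
with these controlled changes; they do not show clinical performance on
real patients.

## 7. Problem sizes and verification

The test suite runs everything at the scale it documents: the default
64 × 64 phantom (4096 voxels, 585 beamlets), 100-bin DVHs, and training
runs of 30 episodes across 3 seeds for the improvement check (the full
protocol default is 100 episodes). The optimizer is checked against
brute-force active-set enumeration on 100 random problems with ≤ 5 voxels
and ≤ 3 beamlets; DVH and metrics against sort-and-count oracles on random
~1000-voxel structures; GAE against direct double-sum evaluation; DQN
against exhaustive search on a deterministic 3-state MDP; and the
morphological augmentation against an independent imaging library's
dilate/erode. The acceptance script reruns a complete experiment from a
single seed.

## 8. Known limitations

* The 2-D default keeps every computation interactive but understates the
  degrees of freedom (and difficulty) of volumetric planning; 3-D grids are
  supported by the same code paths but slower.
* Projected gradient descent is first-order: on the ill-conditioned
  planning quadratic the default iteration budget reaches planning-grade,
  not machine-precision, optima. Warm starting mitigates this inside
  episodes; test oracles use higher budgets on tiny problems.
* The score landscape under the default phantom tops out well below 150:
  with genuinely overlapping structures some goals are mutually
  unsatisfiable, which is realistic but means "score 150" early termination
  is effectively never triggered there.
* Rewards are dense but small (fractions of a point per step is common),
  so training benefits from more episodes than the desk-scale defaults.
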