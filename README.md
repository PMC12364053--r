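# replanRL

Automated replanning for intensity-modulated proton therapy (IMPT) by deep
reinforcement learning, as a fully self-contained R simulator and library.

When a head-and-neck cancer patient's anatomy changes mid-treatment (tumor
progression or regression, weight loss), the proton Bragg peak shifts and
the original plan can underdose the tumor or overdose organs at risk
(OARs). Replanning is an iterative, manual tuning loop: a planner adjusts
per-structure priority weights, re-runs the inverse optimizer, inspects the
dose-volume histograms (DVHs), and repeats. `replanRL` automates that loop:
a reinforcement-learning agent observes the plan's DVHs and learns which
priority to nudge next so that a 150-point clinical plan-quality score is
maximized. It is aimed at medical-physics and RL researchers who want a
desk-scale, fully reproducible testbed for priority-tuning agents — no
patient data, no external treatment-planning system.

## The model

**Dose.** Anatomy is voxelized; each structure is a binary mask. A sparse
dose-influence matrix `D` maps beamlet intensities `x ≥ 0` to voxel doses,

    d_i = Σ_j D_ij x_j .

The package generates `D` itself from a pencil-beam model: coplanar beams,
lateral spot positions × Bragg-curve energy layers, Gaussian penumbra.

**Inverse planning.** Fluence is found by projected gradient descent on the
weighted multi-objective loss

    L(x) = Σ_m ω_CTVm ‖D_CTVm x − d_Rx,m‖² + Σ_k ω_OARk ‖D_OARk x‖² ,  x ≥ 0,

where the weights ω ∈ [0,1] are the treatment-planning priorities (TPPs).

**Scoring.** Plans are scored against a 16-objective clinical goal table
(target coverage V_dRx ≥ 98%, a CTV1 hot-spot limit D0% ≤ 110% of
prescription, and 12 OAR limits on D0.03cc, V70 or Dmean) with
piecewise-linear per-goal ramps summing to a 150-point maximum.

**The MDP.** State: the 15 × 100 normalized cumulative DVH matrix. Actions:
22 clipped priority adjustments (±0.1 on each CTV and on 8 OAR groups).
Transition: warm-started re-optimization under the updated priorities.
Reward: the change in plan score. Episodes run up to 15 steps or until the
score reaches 150. Two learners are provided: DQN (replay buffer, target
network, ε-greedy) and PPO (clipped surrogate, generalized advantage
estimation, entropy bonus), both on small fully-connected networks written
in base R.

**Patient-specific training.** Agents train on a phantom's baseline anatomy
plus two augmented variants (CTVs dilated 2 mm / eroded 3 mm) and are
evaluated on a held-out "replan" anatomy with a different, anisotropic
change — the synthetic analogue of training on a planning CT and testing on
a later replanning CT.

## Worked example

```r
library(replanRL)

geom <- generate_phantom(phantom_config(), seed = 7)
geom
#> Synthetic phantom anatomy
#>   grid: 64 x 64 x 1 voxels at 2 x 2 x 2 mm (0.0080 cc/voxel)
#>   structures: 15 (3 targets, 12 OARs)
#>     CTV1   CTV1   156 voxels (1.25 cc)  Rx 70.00 GyRBE
#>     CTV2   CTV2   316 voxels (2.53 cc)  Rx 59.85 GyRBE
#>     ...

dinf <- compute_dose_influence(geom)
dinf
#> Dose-influence matrix
#>   4096 voxels x 585 beamlets, 151350 nonzeros (6.3% dense)

env <- planning_env(geom, dinf)
state <- env_reset(env)   # optimizes the default-priority plan
env$score
#> Plan quality score: 101.21 / 150.0
#>  structure               label value points max_points
#>       CTV1       V70.00 >= 98% 40.38   0.00       15.0
#>       CTV2       V59.85 >= 98% 84.49   0.00       15.0
#>       ...
#>        PHY   Dmean <= 50 GyRBE 56.31   3.71        7.5
#>       PARL   Dmean <= 26 GyRBE 14.23   7.50        7.5
#>       ...
```

The default-priority plan leaves points on the table: coverage of all three
targets is below the 98% goal and the pharynx (which overlaps the targets)
exceeds its mean-dose limit. Each `env_step(env, a)` nudges one priority,
re-optimizes, and returns the score change as the reward. Training and
evaluating agents end to end:

```r
spec <- experiment_spec(episodes = 30L, seed = 1L)
report <- run_experiment(spec)
report
#> Replanning experiment report
#>   initial plan score (default priorities): 99.62
#>   DQN  best 101.72 (step 6), final 100.88
#>   PPO  best 104.92 (step 7), final 104.70
```

Both agents improve on the default-priority plan of the held-out replan
anatomy; `report$dosimetric_table` breaks the comparison down per clinical
goal, and `plot(report$agents$ppo$agent)` shows the learning curve.

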