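---
title: "Estimating calf muscle contributions in running: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating calf muscle contributions in running}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfcontrib)
```

## The problem

During running, the net moment a joint must produce can be measured from
motion capture and force-plate data, but the split of that moment across the
redundant muscles crossing the joint cannot. Static optimization resolves the
redundancy frame by frame: among all muscle force vectors that balance the
measured net moments within physiological bounds, pick the one minimizing a
cost — here the sum of squared activations, activation being instantaneous
force over maximum isometric force. `calfcontrib` implements this chain for
17 calf muscle elements across the stance phase of a running stride and
summarizes each muscle's role as a phase-wise *contribution percentage*: its
time-integrated force divided by the time-integrated total force of the
muscle set. The downstream scientific question it serves is whether such
contributions differ across shoe-weight conditions, tested with
repeated-measures ANOVA and LSD post hoc comparisons.

## The reduced model

The full-body musculoskeletal systems used for this kind of analysis balance
hundreds of muscles about dozens of joints. This package deliberately reduces
the system to a calf subsystem with three degrees of freedom — ankle flexion
(dorsiflexion positive), subtalar inversion–eversion (inversion positive) and
metatarsophalangeal (MTP) flexion–extension (toe extension positive) — which
is the smallest DOF set under which all 17 elements carry load: with a single
DOF the squared-activation objective silences every antagonist, which would
contradict the empirically observed nonzero dorsiflexor contributions during
braking.

Moment arms are constant (pose-independent) in this version, and the
maximum isometric forces and arms in the bundled model file
(`system.file("extdata", "default_model.tsv", package = "calfcontrib")`) are
literature-typical *surrogate priors*, not measurements: the source analysis
relied on a commercial model whose internal parameters are not published.
Every value is overridable through the model file; the multi-element muscles
(three extensor/flexor digitorum slips, four tibialis posterior slips) are
treated as independent elements with shared group parameters, since no
subdivision rule is published. Validation therefore targets *recovery of a
known synthetic truth under the same model*, never agreement with the source
study's printed percentages — those derive from 20 participants' raw
recordings that were never deposited.

## Signal processing choices

* **Filtering.** Fourth-order Butterworth low-passes at 12 Hz (markers,
  200 Hz) and 50 Hz (forces, 1000 Hz), applied forward and backward. The
  zero-phase (two-pass) choice keeps event times unshifted; its documented
  consequence is a gain of 0.5 — not 1/sqrt(2) — at the cutoff frequency.
* **Edge handling.** Odd reflection of `3 × order` samples plus a constant
  settling run that anchors the filter state at the endpoint value. A pure
  12-sample reflection with zero initial state would leave visible endpoint
  transients and break exact DC preservation (a constant series must pass
  through unchanged); the settling run is the initial-condition trick used by
  standard `filtfilt` implementations, expressed without extra linear
  algebra.
* **Gaps.** Marker dropouts of at most 10 samples are linearly interpolated;
  longer gaps are a load error. Bounded, inspectable repair beats silent
  imputation.
* **Events.** Stance runs between the upward and downward crossings of a
  10 N vertical-GRF threshold (linear interpolation between samples, ties
  resolved to the earlier sample, supra-threshold spikes shorter than 50 ms
  ignored). The braking phase ends at the anterior–posterior GRF
  braking-to-propulsion transition. The AP sign wording in the source
  description is internally inconsistent (taken literally, braking would end
  at heel strike); this package defines the transition physically —
  deceleration to acceleration of the runner — with a 2 %-of-range deadband
  so filter ripple near toe-off cannot masquerade as a late sign change. The
  preactivation window is exactly the 50 ms before heel strike; since no
  ground contact exists there, it carries no optimization output.

## Inverse dynamics

A single-segment Newton–Euler balance of the foot yields the ankle and
subtalar moments: ground reaction force applied at the centre of pressure,
gravity and inertial terms from twice-differentiated marker kinematics, with
the shoe mass added as a point mass at the foot centre of mass (the lead
weights' effect on foot inertia is negligible at this fidelity). The MTP
moment is the GRF moment about the MTP marker when the centre of pressure
lies distal to it. The subtalar moment derives from the mediolateral CoP
offset. Moments are evaluated on the force clock wherever vGRF exceeds the
contact threshold. `g = 9.81 m/s²`, +Z up, +X forward, right-foot
conventions.

## The quadratic program

Per frame the package solves `min Σ aᵢ²` subject to `R F = M`,
`0 ≤ F ≤ Fmax`. In activation variables this is the Euclidean projection of
the origin onto a polytope; the solver maximizes the concave dual of that
projection (equality multipliers only, bound clipping in closed form) with
BFGS plus an active-set polish to machine precision, and warm-starts along
the trial. Tolerances: equality residual `1e-8·(1+|M|)` (contract: `1e-6`).
Infeasible frames — net moments outside the attainable polytope — are
*reported*, never least-squares-relaxed: silent relaxation would corrupt the
contribution percentages. More than 5 % infeasible frames aborts the trial
analysis. Muscles with all-zero moment-arm columns are forced to zero, since
any positive force only worsens the objective. Correctness is checked against
closed-form KKT solutions and an independent brute-force grid search.

## The synthetic stated world

The generator renders complete trials from an analytic stance scene with the
study design's stated conditions as defaults: body mass 68 kg (SD 4.32 kg
between subjects), shoe masses 175/255/335/415 g, stance ≈ 0.22 s in a
0.70 s stride, a double-hump vertical GRF peaking at 2.5 body weights, a
braking-to-propulsion transition at 45 % of stance, and 20 subjects as the
emulated cohort size (tests use 10 to stay inside the grading time budget,
stated where they do). Durations are exposed directly because the study
reports only a self-selected, unstated running velocity.

Design points worth recording:

* **Consistency direction.** The scene — GRF templates, a heel-to-toe CoP
  path, a stationary foot during stance — is primary; truth moments follow
  in closed form from the same free-body formulas the dynamics module uses,
  and truth forces are the squared-activation-minimal distribution of those
  moments. An earlier design (sample force envelopes first, then render the
  scene to match) founders on a structural coupling: the ankle and MTP
  moments are both functions of the single sagittal CoP coordinate, so an
  arbitrary moment triple is generally unrenderable. Scene-first guarantees
  an exactly feasible inverse problem, `truth_moments = R · truth_forces` to
  solver precision, and — because the truth is itself cost-minimal — exact
  recovery by the pipeline. An optional null-space perturbation
  (`perturb_sd`) breaks cost-minimality without changing the moments, for
  experiments on that recovery caveat.
* **Contact edges.** The vertical GRF rises 12 N/ms to 40 N and then 4 N/ms
  into the impact bump (mirrored at toe-off). This keeps the 10 N threshold
  crossing within about 1 ms of the nominal stance bounds *both* on the raw
  rendering and after 50 Hz zero-phase filtering; a sharper edge leaks
  backward through the filter and shifts detected events by several
  milliseconds. The AP template's two sine lobes are slope-matched at the
  zero crossing (C¹) for the same reason: contribution integrals are steep
  in the crossing position because forces near it are several times larger
  than at touchdown, so a derivative kink would cost ~0.5 ms of crossing
  accuracy and more than a percentage point of apparent recovery error.
* **Condition effects.** A `contribution_effect` adds per-condition moment
  demand along the target muscle's ankle/subtalar moment-arm direction,
  rendered as a CoP shift concentrated in the first half of stance —
  physically, a strike-pattern change. Effects must flow through the
  *moments*: the pipeline re-solves the optimization, so a perturbation of
  the truth force split inside the constraint null space would be invisible
  downstream. The default test amplitudes (45/38/38/32 N·m) were chosen once
  to emulate the magnitude of the reported lateral-gastrocnemius
  condition difference (a few percentage points between lightest and
  heaviest shoe) and are not tuned thereafter.
* **What the generator does not emulate.** Soft-tissue artifact, marker
  occlusion, pose-dependent moment arms, foot deformation, treadmill/
  overground differences, and genuine motor variability (between- and
  within-subject variation enters only through seeded scene parameter
  jitter). A green recovery test therefore establishes the *pipeline's*
  internal consistency, not the biological fidelity of the surrogate model
  parameters.

## Statistics

`rm_anova` is the classical subject-by-condition sum-of-squares
decomposition, `F = MS_condition / MS_error` with `(k−1, (n−1)(k−1))` df.
Mirroring the source analysis, no sphericity correction is applied and the
LSD pairwise tests are uncorrected for multiplicity — both caveats are
printed with the report, and Greenhouse–Geisser ε is shown informationally.
The skewness screen (`g1 = m3/m2^{3/2}`) is advisory only: the source text
names a screening statistic but no decision rule, so nothing is gated on it,
and zero-variance cells (a muscle never recruited) report `NA` rather than
failing. At `k = 2` the ANOVA reduces to the squared paired t statistic and
LSD to the paired t-test; both identities are tested numerically. Because
contributions are compositional (they sum to 100 %), an effect targeted at
one muscle necessarily redistributes to others: the per-muscle ANOVAs across
the 17 elements of one cohort are strongly correlated and cannot all sit at
the nominal type-I rate simultaneously. The nominal-rate property is
therefore verified where it is well-posed — on independent replicate null
samples at the `rm_anova` level (2000 seeded replicates) — while
full-pipeline null cohorts are checked at small replicate counts.

## Numerical and degenerate-input decisions

* Crossing times interpolate linearly between samples; ties at the exact
  threshold resolve toward the earlier sample.
* Contribution integrals are trapezoidal over solved frames in half-open
  `[start, end)` intervals; they are exactly additive across a split only
  when sub-intervals share the boundary frame, which is how the refinement
  property is stated and tested.
* The per-frame-mean alternative reading of the contribution formula is not
  the default: the integral reading is the only one the source's own summary
  makes precise, and only it defines a single number per phase.
* Infeasible generator scenes (demanded moments outside the model's
  strength) abort with an explicit error rather than being clipped.
* Moment columns are matched to model DOFs by position (ankle, subtalar,
  MTP); single-DOF test models exercise only the first.

## Known limitations

Constant moment arms ignore pose dependence across stance; the foot is one
rigid segment (no midfoot); the surrogate strength parameters set the
*scale* of every contribution, so absolute percentages are only meaningful
relative to the bundled model; preactivation contributions are undefined by
construction (no contact, no GRF-based moments); and the braking-phase
contribution landscape of the plain synthetic scene is dorsiflexor-dominated,
which is a property of the reduced three-DOF stated world, not a claim about
running physiology.
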