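# calfcontrib

Muscle-force inference for the stance phase of running: from marker
trajectories and force-plate records, `calfcontrib` estimates the forces of 17
calf muscle elements by inverse dynamics plus static optimization, converts
them into phase-wise *individual muscle contribution* percentages, and
compares shoe-weight conditions with repeated-measures ANOVA and Fisher LSD
post hoc tests. It is aimed at biomechanics researchers who want a small,
fully testable re-implementation of this analysis chain, with a synthetic gait
generator providing ground truth where participant data are unavailable.

## The method

For each force-plate frame inside stance, net internal moments
`M = (M_ankle, M_subtalar, M_mtp)` are computed by a Newton–Euler free-body
balance of the foot segment (ground reaction force at the centre of pressure,
gravity and inertial terms; the shoe mass is added to the anthropometric foot
mass). The net moments are distributed across the `n = 17` muscle elements by
solving, per frame, the convex bounded quadratic program

```
minimize   Σᵢ aᵢ²,      aᵢ = Fᵢ / Fmaxᵢ          (activation)
subject to R F = M,     0 ≤ Fᵢ ≤ Fmaxᵢ
```

where `R` is the constant 3 × 17 signed moment-arm matrix of the model. A
muscle's contribution to a gait phase (preactivation, braking, push-off; the
braking phase runs from heel strike, vGRF > 10 N, to the anterior–posterior
GRF braking→propulsion transition) is

```
contributionᵢ = 100 · ∫phase Fᵢ dt / ∫phase Σⱼ Fⱼ dt     [%]
```

so each phase's contribution vector sums to 100. Signals are filtered with
4th-order zero-phase Butterworth low-passes (12 Hz kinematics at 200 Hz,
50 Hz forces at 1000 Hz). Condition comparisons use one-way repeated-measures
ANOVA (no sphericity correction; Greenhouse–Geisser ε reported
informationally) with uncorrected LSD pairwise tests, α = 0.05.

## Worked example

```r
library(calfcontrib)
model <- load_model()                       # bundled 17-muscle calf model

trial <- generate_trial(model, trial_params(seed = 7, shoe_mass = 0.255))
analysis <- analyze_trial(trial$recording, model)
print(analysis)
#> <gait_phases>
#>   preactivation [0.0559, 0.1059) s  (50.0 ms)
#>   stance        [0.1059, 0.3259) s  (220.0 ms)
#>   braking       [0.1059, 0.2040) s  (98.1 ms)
#>   push_off      [0.2040, 0.3259) s  (121.9 ms)
#>   top braking contributors (%):
#>         Tibialis anterior                    Soleus Fibularis peroneus brevis
#>                      60.3                      19.4                       8.5
```

The detected stance (220 ms) and braking fraction round-trip the generator's
parameters; braking is dorsiflexor-dominated in this plain scene because the
centre of pressure stays behind the ankle early in stance.

A cohort with an induced shoe-mass effect on the lateral gastrocnemius
(lighter shoes shift the centre-of-pressure path the way a more
forefoot-oriented strike would, loading that muscle during braking):

```r
eff <- contribution_effect("Gastrocnemius lateralis", c(45, 38, 38, 32))
cohort <- generate_cohort(model, n_subjects = 10, effect = eff, seed = 21)
table <- analyze_cohort(cohort, model, phases = "braking")
contribution_wide(aggregate_cohort(table))[7, ]
#>                    muscle  0.175 kg  0.255 kg  0.335 kg  0.415 kg
#> 7 Gastrocnemius lateralis 5.7 ± 1.1 3.2 ± 0.8 3.3 ± 0.7 1.6 ± 0.6

cmp <- compare_conditions(table, phase = "braking")
subset(cmp$anova, muscle == "Gastrocnemius lateralis")[, c("F", "df1", "df2", "p")]
#>          F df1 df2        p
#> 7 322.8924   3  27  2.97e-21
```

The lateral gastrocnemius contribution falls from 5.7 % (175 g shoes) to
1.6 % (415 g shoes) and the repeated-measures ANOVA flags it
(F(3, 27) = 322.9); LSD post hoc tests identify which condition pairs differ.
All 80 trials carry per-frame ground-truth forces, and the pipeline recovers
every muscle's braking contribution within 1 percentage point of that truth
on noiseless cohorts (within 3 with 1 mm marker / 2 N force noise).

## Command line

```sh
Rscript -e 'calfcontrib::calfcontrib_cli()' simulate --seed 1 --out sim/
Rscript -e 'calfcontrib::calfcontrib_cli()' contributions \
  --markers sim/markers.tsv --forces sim/forces.tsv --meta sim/meta.tsv \
  --phase braking --out contrib.tsv
Rscript -e 'calfcontrib::calfcontrib_cli()' stats --table table.tsv --alpha 0.05
```

File formats (tab-separated, UTF-8, documented in the function help): marker
TSV in mm with `<marker>_X/_Y/_Z` columns, force TSV in N / m with
`time, Fx, Fy, Fz, CoPx, CoPy`, and a `key<TAB>value` metadata file.
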