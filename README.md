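# dopaPET

Kinetic analysis of dynamic ^18^F-DOPA PET for small-animal studies of
presynaptic dopaminergic function, written for the genotype-by-age design of
a CRISPR G51D α-synuclein (SNCA) rat model of Parkinson's disease.

^18^F-DOPA is taken up into striatal dopaminergic terminals, decarboxylated
by AADC and trapped as ^18^F-dopamine, which is then slowly lost from the
tissue. With the cerebellum as a reference region (no specific dopaminergic
signal), a 2-h dynamic scan supports three endpoints without blood sampling,
all obtained here as ordinary least-squares slopes of graphical transforms
over frames whose mid-times lie in a fit window:

- **Ki** (1/min) — Patlak reference-tissue influx:
  slope of `C_T/C_R` vs `∫C_R/C_R`, fitted over 10–60 min;
- **DVR** — Logan reference-tissue distribution volume ratio:
  slope of `∫C_T/C_T` vs `∫C_R/C_T`, fitted over 30–120 min;
- **EDVR** — effective DVR: the same Logan analysis applied after
  subtracting the cerebellar TAC from the striatal TAC; `1/EDVR` estimates
  the effective dopamine turnover, and the left–right asymmetry index
  `(EDVR_contra − EDVR_ipsi)/EDVR_contra` quantifies lateralization.

For the two-tissue target model
`dC1/dt = K1·Cp − (k2+k3)·C1`, `dC2/dt = k3·C1 − k_loss·C2` with a
one-tissue reference, the large-time limits are
`Ki = K1·k3/(k2+k3) · k2r/K1r`,
`DVR = K1/(k2+k3) · (1 + k3/k_loss) · k2r/K1r`, and `EDVR = DVR − 1`.

The package also ships the surrounding study machinery: frame schedules and
TACs with decay-correction tracking, SUV/SUVr and pseudo-equilibrium
detection, a closed-form compartment-model cohort simulator (tri-exponential
bolus input, exact per-frame integrals, decay-weighted noise) for
parameter-recovery validation, VOI-based TAC extraction from 4D images with
spherical voxel phantoms and NIfTI I/O, group statistics (one-way ANOVA with
Tukey HSD, paired t tests, Q–Q diagnostics), and in-silico BspHI-digest
genotyping of the G51D allele.

## Worked example

Simulate one noise-free animal at the study protocol (33 frames over 2 h)
and fit the three endpoints:

```r
library(dopaPET)

sched      <- studyFrameSchedule()
input      <- defaultPlasmaInput()
striatum   <- simulateRegion(defaultTissueKinetics(), input, sched)
cerebellum <- simulateRegion(defaultReferenceKinetics(), input, sched)

patlakReference(striatum, cerebellum)
#> Patlak reference-tissue analysis: Ki = 0.01929 /min (R^2 0.9959)
loganReference(striatum, cerebellum)
#> Logan reference-tissue analysis: DVR = 2.7262 (R^2 0.9952)
edvr(striatum, cerebellum)
#> EDVR analysis: EDVR = 2.9553, effective turnover = 0.3384 (R^2 0.9968)
```

The default kinetics have asymptotic DVR 3.64 and EDVR 2.64
(`analyticTargets(defaultTissueKinetics(), defaultReferenceKinetics())`);
the differences above are the documented finite-scan behaviour of the
graphical methods at a 2-h protocol (see the methods vignette), shared by
all subjects and hence common mode in group comparisons.

A full study-like cohort — 3 genotypes × 3 ages × 4 rats with the default
effect map (EDVR ×0.7 and left–right turnover asymmetry in aged
homozygotes) — runs through the pipeline in a few seconds:

```r
cohort    <- simulateCohort(cohortDesign(seed = 1))
endpoints <- fitCohort(cohort)
reportGroups(endpoints)
#> == age_16m ==
#>   Ki_per_min: F = 0.183, p = 0.836; significant pairs: none
#>   DVR: F = 0.662, p = 0.539; significant pairs: none
#>   EDVR: F = 3.58, p = 0.0717; significant pairs: none
#>   L/R EDVR WT: t(3) = 1.98, p = 0.143
#>   L/R EDVR G51D/+: t(3) = -0.0483, p = 0.964
#>   L/R EDVR G51D/G51D: t(3) = -26, p = 0.000124
#> ...
```

At this seed the homozygote left–right EDVR asymmetry is strongly detected
at 16 months (and at 5 months), while the 16-month EDVR ANOVA only trends —
with n = 4 per group a ~30% EDVR effect is detected by the ANOVA in roughly
nine out of ten cohorts, not all of them.

Genotyping logic, from the shipped donor-oligo fixture:

```r
digestSequence(g51dOligos()[["donor"]], "TCATGA")
#> $cut_positions
#> [1] 40
#> $fragment_lengths
#> [1] 41 39
```

The 2-bp GGA→GAT codon edit creates the single BspHI site; the reverted
wild-type sequence has none — the basis of the PCR–digest assay.

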