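---
title: "Reference-tissue kinetic modelling of dynamic 18F-DOPA PET with dopaPET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-tissue kinetic modelling of dynamic 18F-DOPA PET with dopaPET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopaPET)
```

## The measurement problem

6-[^18^F]fluoro-L-DOPA (^18^F-DOPA) PET probes presynaptic dopaminergic
function. The tracer is carried into tissue, decarboxylated by aromatic
L-amino acid decarboxylase (AADC) in dopaminergic terminals, and the
resulting ^18^F-dopamine is stored in vesicles and slowly lost from the
tissue. In a rat, a 2-h dynamic scan of striatum (the dopaminergic target)
and cerebellum (a reference tissue devoid of specific signal) supports three
standard endpoints without arterial sampling:

* **Ki** — the net influx rate constant from the Patlak reference-tissue
  plot, treating trapping as irreversible;
* **DVR** — the striatum-to-cerebellum distribution volume ratio from the
  Logan reference-tissue plot, acknowledging that trapping is reversible
  on the 2-h scale;
* **EDVR** — the *effective* DVR: the Logan slope after subtracting the
  cerebellar TAC from the striatal TAC, whose inverse estimates the
  effective dopamine turnover. A *lower* EDVR means *faster* turnover.

dopaPET implements this pipeline (TACs, SUV/SUVr, the three graphical
estimators, left–right asymmetry, and the group statistics of a
genotype-by-age rat study) together with a compartment-model simulator rich
enough to validate every stage by parameter recovery.

## Kinetic model

The simulator and the closed-form endpoint oracles share one linear model.
With plasma concentration $C_p(t)$:

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3)\,C_1, \qquad
  \frac{dC_2}{dt} = k_3 C_1 - k_{loss} C_2,$$

where $C_1$ is the free/precursor pool ($K_1$ delivery, $k_2$ efflux),
$k_3$ the AADC trapping step, and $k_{loss}$ the slow egress from the
specific pool; the measured striatal activity is $C_T = C_1 + C_2$. The
cerebellum is one-tissue: $dC_r/dt = K_{1r} C_p - k_{2r} C_r$.

The large-time limits of the three estimators for this model are

$$K_i = \frac{K_1 k_3}{k_2 + k_3}\cdot\frac{k_{2r}}{K_{1r}}, \qquad
  DVR = \frac{K_1}{k_2 + k_3}\Bigl(1 + \frac{k_3}{k_{loss}}\Bigr)
        \cdot\frac{k_{2r}}{K_{1r}}, \qquad EDVR = DVR - 1,$$

the last identity because distribution volumes are additive under TAC
subtraction. `analyticTargets()` returns exactly these. When the reference
matches the target's nondisplaceable uptake ($K_{1r}/k_{2r} = K_1/k_2$) and
$k_{loss} \ll k_2$, the EDVR reduces to the familiar reading
$(k_3/k_{loss})\cdot k_2/(k_2+k_3)$ — the ratio of specific to precursor
distribution volumes reduced by the factor $k_2/(k_2+k_3)$. We deliberately
use the exact asymptotes rather than that approximation as recovery targets:
at the corners of the validation grid ($k_{loss}$ up to 0.05/min against
$k_2$ down to 0.1/min) the approximation is off by tens of percent and would
make "oracle recovery" untestable.

## The graphical estimators

All three estimators are ordinary least squares on transformed coordinates,
restricted to frames whose **mid-times** fall in a window $[t^*, T]$
(inclusive; mid-times are the standard abscissa for frame-averaged data and
match the quadrature grid). Running integrals use the trapezoid on
mid-times with a zero-anchored first segment — exact for piecewise-linear
curves. Fits are unweighted. Defaults follow the study protocol:

| endpoint | transform | window (defaults) |
|---|---|---|
| Ki (1/min) | $C_T/C_R$ vs $\int_0^t C_R / C_R$ | 10–60 min |
| DVR | $\int_0^t C_T / C_T$ vs $\int_0^t C_R / C_T$ | 30–120 min |
| EDVR | Logan on $C_T - C_R$ vs $C_R$ | 30–120 min |

The Logan form omits the reference-efflux ($k_2'$) correction term by
default; `k2PrimePerMin` adds the standard $C_R/(k_2' C_T)$ term as an
opt-in. Internally all transforms work in seconds; Ki alone is converted to
1/min at the boundary.

Negative activities (simulated noise) pass through SUV and the transforms
unclipped — clipping would bias the slopes. The transforms do require
positive denominators *inside the fit window* (reference for Patlak, target
for Logan, the subtracted specific curve for EDVR) and refuse to fit
otherwise, naming the offending frames; pre-equilibrium negative frames of
the specific curve *before* the window are expected and harmless.

### Known finite-scan bias

The Logan slope converges to the DVR only once both tissues track plasma
quasi-statically. With $k_{loss}$ at 0.005–0.01/min the transient has a
half-time of 1–2 h, so at the 2-h protocol the Logan DVR underestimates its
asymptote by up to tens of percent, and EDVR carries a bias of order +10%
at the default kinetics; Patlak applied to reversible data underestimates
the irreversible-limit Ki by 30–40% because the trapped pool leaks during
the 10–60-min window. These are properties of the estimators at this
protocol, not defects: group comparisons share the protocol, so the bias is
common mode. The test suite therefore checks estimator-against-oracle
agreement in the asymptotic regime (16-h simulated scans with 5-min frames,
$t^* = T/4$, a distribution-volume-matched reference, 108 parameter sets
over $K_1 \in [0.05,0.2]$, $k_2 \in [0.1,0.5]$, $k_3 \in [0.01,0.1]$,
$k_{loss} \in [0.005,0.05]$ /min; all three estimators land within 5%/5%/10%,
measured <1%), and separately asserts the *sign and envelope* of the 2-h
biases at the study windows.

## The synthetic cohort

`simulateCohort()` emulates the study design: 3 genotypes (WT, G51D/+,
G51D/G51D) × 3 ages (5, 11, 16 months) × 4 rats, three regions per rat
(left striatum, right striatum, cerebellum), the study's 33-frame 2-h
schedule (6×30 s, 3×60 s, 2×120 s, 22×300 s), body weight 0.37 kg (10% CV)
and injected dose 18.5 MBq with the study's reported 38% spread (SUV
normalizes dose out, so its spread is inert downstream).

**Input function.** A Feng-type tri-exponential bolus
(`defaultPlasmaInput()`: $A_1$=600 kBq/mL/min, $A_2$=30, $A_3$=25 kBq/mL,
$\lambda_1$=4, $\lambda_2$=0.5, $\lambda_3$=0.004 /min, delay 0.5 min),
continuous at onset, peaking near 90 kBq/mL ~45 s after appearance with a
slow terminal tail — the shape of a tail-vein bolus under peripheral enzyme
blockade. Validity requires $C_p \ge 0$ over a 4-h horizon.

**Solution.** TACs are computed from the exact exponential-polynomial
closed form of the linear system (an internal convolution algebra over
terms $c\,t^p e^{-rt}$), including *exact per-frame integrals*, so
frame-averaged activities carry no solver or quadrature error and are fully
deterministic (validated against an adaptive ODE solver at 2×10⁻⁵). Rates
closer than 10⁻⁹ are merged into the confluent limit to avoid catastrophic
cancellation; with continuous parameter jitter such collisions have measure
zero.

**Default kinetics.** $K_1$=0.1, $k_2$=0.3, $k_3$=0.03, $k_{loss}$=0.01,
$K_{1r}$=0.1, $k_{2r}$=0.3 /min — configuration, not constants. They give a
striatum:cerebellum SUVr of about 2.0–2.7 over 50–85 min that flattens
slowly through the late scan (the curve drifts by ~0.02 SUVr/min there,
which is also the default tolerance of the plateau detector
`findPseudoEquilibrium()`), Ki ≈ 0.027/min, DVR ≈ 3.6 and EDVR ≈ 2.6 in the
asymptotic limit.

**Between-animal variability.** One log-normal *delivery* multiplier shared
by $K_1$ and $K_{1r}$, one *nonspecific-efflux* multiplier shared by $k_2$
and $k_{2r}$, and independent multipliers on the dopaminergic rates $k_3$
and $k_{loss}$, each with CV 10% (configurable). Within an animal the
nonspecific kinetics of striatum and cerebellum co-vary — blood flow and
peripheral tracer handling are animal-level quantities — and the
reference-tissue method exists precisely to cancel that shared part.
Jittering all six rates independently would triple the between-animal CV of
the endpoints relative to the nominal value and no longer represent a
reference-region-valid animal. With this structure the realized
between-animal EDVR CV is ≈ 16%.

**Effects.** The effect map assigns each genotype-by-age cell a
multiplicative EDVR effect (implemented by dividing $k_{loss}$, since EDVR
scales essentially inversely with it) and a left/right $k_{loss}$ ratio
(split symmetrically as $\sqrt{ratio}$ up on the left and down on the
right). The default map encodes the study-like phenotype: EDVR ×0.7 in
16-month homozygotes and a left/right ratio of 1.2 (left striatum turning
over faster → positive right-referenced asymmetry ≈ 0.15) in 5- and
16-month homozygotes. `nullEffectMap()` clears all effects.

**Noise.** Zero-mean Gaussian per frame with
$\sigma_i = s\sqrt{\max(A_i,0)\,2^{t_i/T_{1/2}}/\Delta_i}$ — simulated
activities are decay-corrected as scanner output is, and the
$2^{t/T_{1/2}}$ factor reinstates the count loss from physical decay, so
late frames are noisier. Default scale $s$ = 0.1. All randomness flows from
the single design seed; identical designs produce byte-identical cohort
directories.

What the generator does **not** emulate: partial-volume and spill-over
effects, motion, attenuation/scatter residuals, plasma metabolites, frame
count statistics beyond the Gaussian approximation, or anatomical
variability in VOI placement. Passing recovery tests therefore demonstrates
correctness of the estimators and pipeline plumbing, not robustness of the
method to those real-data effects.

## Group statistics

`fitCohort()` produces per-subject endpoints for left, right and whole
striatum (for simulated cohorts the whole-striatum TAC is the unweighted
mean of the two sides; for image-derived data a union-mask VOI mean is the
volume-weighted analogue and not generally equal to the L/R average).
`reportGroups()` then runs, per age: one-way ANOVA with Tukey HSD across
genotypes on whole-striatum Ki, DVR and EDVR; a paired t test of left vs
right EDVR within each genotype; and normal Q–Q points at plotting positions
$(i-0.5)/n$. The asymmetry index is
$(EDVR_{contra} - EDVR_{ipsi})/EDVR_{contra}$; since the animals are
unlesioned the side mapping is a convention — the default takes the right
striatum as contralateral, making indices positive when the left EDVR is
lower, and the choice is echoed in every report. Subjects whose specific
TAC has no positive signal in the EDVR window (possible under strong
turnover with unfavourable biology, ~0.4% of simulated fits) are skipped
with a warning and counted, as are subjects with missing regions.

Calibration, measured by the acceptance suite on simulated cohorts
(200 seeds): per-family type-I error of the EDVR ANOVA ≈ 4–6% at nominal
5%; detection of the 0.7× EDVR effect at 16 months by the ANOVA in ~90% of
seeds (the Tukey-adjusted WT-vs-homozygote pair flags in ~75–85%, the usual
price of multiplicity at n = 4). Note that with three independent per-age
families at $\alpha$ = 0.05, some family is expected to flag in ~14% of
null cohorts — nominal behaviour, not an inflation.

## Images and phantoms

`makePhantom()` paints spherical regions carrying prescribed TACs into a 4D
voxel grid with exactly matching masks, so `extractTAC()` is an exact round
trip; this anchors the VOI machinery (per-frame masked means,
duration-weighted frame averaging, SUV images). Gaussian display smoothing
interprets "1 mm × 1 mm × 1 mm" as FWHM (the convention of the analysis
software used in such studies; `kind = "sigma"` is available), is separable
with zero-padded borders, and is *never* applied before TAC extraction.
Masks must share the image grid exactly — registration and resampling are
out of scope, as is VOI placement itself. NIfTI-1 I/O (gzipped accepted)
carries the frame schedule in a JSON sidecar.

## Genotyping utilities

The G51D knock-in turns the rat SNCA glycine-51 codon GGA into GAT (a 2-bp
edit) and thereby creates a BspHI site (TCATGA — palindromic, so
single-strand scanning suffices) absent from the wild-type allele.
`findSites()` (0-based, overlapping matches), `digestSequence()` (default
cut offset 1, T^CATGA; fragment lengths always sum to the input length),
`hammingDistance()` and `mendelianChisq()` (1:2:1 intercross default)
reproduce the assay logic in silico. The printed 20-nt gRNA protospacer and
80-nt donor oligonucleotide ship as a FASTA fixture with the edit in lower
case. Absolute gel fragment sizes are not reproducible without the genomic
amplicon coordinates, so fragment arithmetic is exposed generically.

## Numerical and design choices, in brief

* F-18 half-life fixed at 109.77 min (`F18_HALF_LIFE_S`).
* Decay-correction state is tracked on the TAC and double correction is an
  error; the correction reference time is always explicit.
* Frames are contiguous from injection in everything we generate; the data
  model tolerates gaps but the generator never makes them.
* Fit windows are inclusive of boundary mid-times; window selection and
  integration share the same grid by construction.
* Tukey HSD uses the studentized range (Tukey–Kramer for unbalanced cells),
  via the standard R implementations throughout (`aov`, `TukeyHSD`,
  `t.test`, `chisq.test`); the package's own contribution is the kinetic
  layer, not the classical statistics.
* Problem sizes in the shipped tests: 108-point oracle grid at 16 h
  simulated scans; 100 noise replicates; 200 null cohorts and 200
  effect cohorts for calibration — sizes chosen so the whole suite stays
  comfortably interactive while leaving Monte-Carlo error well below the
  asserted margins.

## Limitations

VOI-level only (no voxelwise parametric maps); no arterial-input or full
nonlinear compartmental fitting of real data; no metabolite, partial-volume
or motion handling; the k2′-corrected Logan variant is opt-in and untested
against real data; EDVR's subtraction step is intrinsically fragile when
specific binding is weak — the pipeline surfaces those subjects rather than
guessing.

## A worked run

```{r example, eval = FALSE}
sched <- studyFrameSchedule()
input <- defaultPlasmaInput()
striatum <- simulateRegion(defaultTissueKinetics(), input, sched)
cerebellum <- simulateRegion(defaultReferenceKinetics(), input, sched)

patlakReference(striatum, cerebellum)   # Ki at 10-60 min
loganReference(striatum, cerebellum)    # DVR at 30-120 min
edvr(striatum, cerebellum)              # EDVR and turnover

cohort <- simulateCohort(cohortDesign(seed = 1))
endpoints <- fitCohort(cohort)
reportGroups(endpoints)
```
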