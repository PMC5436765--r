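---
title: "Modelling rat HPA axis dynamics under lateral hypothalamic kindling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rat HPA axis dynamics under lateral hypothalamic kindling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hpaxis` implements a stoichiometric network model of the
hypothalamic–pituitary–adrenal (HPA) axis in the rat, and the *in silico*
experiment built around it: circadian forcing of CRH production, a "sham"
stress potentiation, lateral-hypothalamic-kindling (LHK) emulated as a train
of instantaneous CRH pulses, oscillation analytics for the resulting
corticosterone time courses, a synthetic blood-sampling/ELISA measurement
generator, and least-squares recovery of the perturbation parameters from
the synthetic measurements. This vignette records the model, the design
decisions that were genuinely open, and the limits of what the synthetic
experiments can show.

## The reaction network

The model tracks 11 species in molar units — cholesterol (CHOL), CRH,
aldosterone (ALDO), ACTH, pregnenolone (PNN), progesterone (PGS),
deoxycorticosterone (DCTS), corticosterone (CTS),
17α-hydroxypregnenolone (HPNN), 17α-hydroxyprogesterone (HPGS) and cortisol
(CORT) — coupled by 25 reaction steps with published rate constants
(`hpa_rate_constants()`). The steps are not elementary reactions but
condensed pathway summaries; their mass-action rate laws nevertheless define
the ODE system exactly:

* R1–R3: zeroth-order production of CHOL, CRH and ALDO. The CRH step (R2)
  is modulated by the circadian drive, so its rate is $k_2 D(t)$.
* R4: CRH-stimulated ACTH production.
* R5–R13: adrenal steroidogenesis — ACTH-mediated conversion of cholesterol
  to pregnenolone, the chain to corticosterone, and the 17α-hydroxylated
  branch ending in cortisol.
* R14: cubic autocatalysis of corticosterone
  (DCTS + 2 CTS → 3 CTS), the positive feedback mediated by hippocampal
  receptors; R15: corticosterone autoinhibition via aldosterone
  (ALDO + 2 CTS → CTS).
* R16–R17: negative feedback of corticosterone on CRH and ACTH.
* R18–R25: first-order elimination. Products of elimination and of the
  feedback steps never re-enter as reactants; receptor concentrations are
  folded into the rate constants.

```{r}
library(hpaxis)
build_rat_network()
```

### The one structural decision: R4 is catalytic

The printed stoichiometric relation for ACTH production reads
"CRH → ACTH". Taken literally under mass action it would convert CRH into
ACTH, consuming CRH at rate $k_4[\mathrm{CRH}]$. Physiologically that is not
what the step describes — CRH *stimulates* ACTH secretion from the
pituitary; the two peptides are distinct molecules and CRH is not consumed
by the act of stimulation. The two readings differ dynamically, and only
one of them reproduces the documented behaviour of the model:

* Literal reading: with $k_4 \approx 1.08\times10^4\,\mathrm{min}^{-1}$
  dominating CRH removal, the corticosterone feedback on CRH (R16) becomes
  irrelevant, and the integrated system relaxes to a smooth circadian wave
  with **no ultradian oscillations** and a mean corticosterone of
  ~17 ng/mL.
* Catalytic reading (CRH → CRH + ACTH; rate $k_4[\mathrm{CRH}]$, net CRH
  change zero): CRH removal is then dominated by the R16 feedback, closing
  the delayed negative-feedback loop. The system oscillates with an
  inter-peak interval near an hour inside a circadian envelope, and control
  corticosterone averages tens of ng/mL — the documented behaviour.

`mass_action_rhs()` therefore implements R4 catalytically, and
`build_rat_network()` records R4 with CRH on both sides so that the
stoichiometry matrix, the rate law and the hand-written balance equations
stay mutually consistent (the test suite checks their equivalence on 1,000
random states to a relative error of 1e-12). The fixed-point analysis
(`hpa_fixed_point()`) confirms the oscillatory mechanism independently of
any integration: at the frozen period-mean drive the steady state is an
unstable focus whose rotation period lies in the ultradian band.

R5 (ACTH + CHOL → PNN) is kept literal — ACTH is consumed. The
alternative catalytic reading of R5 was also examined and rejected: it
inflates steroid production so that corticosterone settles near
$10^{-6}$ M (~900 ng/mL), an order of magnitude above the physiological
range the model is tuned to.

## Circadian forcing

The drive is the asymmetric, strictly positive, 24-h periodic function

$$D(t) = d_1 - 0.079145093\,d_2 + \left\{0.064\sin\!\frac{2\pi(t-840)}{1440}
 + 0.12\left|\sin\!\frac{\pi(t-840)}{1440}\right|\right\} d_2$$

with $d_1 = 0.2662$, $d_2 = 2.5$, $t$ in minutes since midnight of day 1.
The printed form of the rectified term has an unbalanced bracket
("abs[sin(π(t−840)/1440]"); it is read as
$|\sin(\pi(t-840)/1440)|$ — the only interpretation that is 1440-min
periodic and produces the documented asymmetric day/night profile. The
phase of 840 min anchors the reference point at 14:00, consistent with
clock-labelled results. With default parameters $D$ stays above 0.065
(minimum near $t \approx 747$), so CRH production never switches off.

## Scenarios and the pulse protocol

* **control** — the constants as printed.
* **sham** — $k_2$ multiplied by 1.1765 for the whole span, representing
  surgery/handling potentiation. The multiplier is applied to the forced
  rate $k_2 D(t)$.
* **lhk** — the sham multiplier plus kindling: integration is stopped,
  CRH is incremented by the pulse intensity (5×10⁻⁸ M by default), and
  integration restarts from the perturbed state; repeated every 40 s for
  50 min. The first pulse fires at the kindling start and no pulse fires
  at or after start + 50 min, giving 75 pulses with the last at
  start + 49 min 20 s. This endpoint convention is a choice (the protocol
  is stated only as "every 40 s during 50 min"); it keeps the whole train
  inside the stated 21:12–22:02 window.

Whether the sham multiplier acts during the whole LHK span or only around
kindling is not stated; it is applied to the whole span, which matches the
statement that the sham parameter set was used for the LHK simulations.

Long continuous kindling (up to 72 h, i.e. 6,480 restarts) uses the same
stop-and-restart mechanism; output sampling can be coarsened but pulse
timing never is.

## Numerical integration

The system is stiff (rate constants span 17 orders of magnitude), so
trajectories are computed with `deSolve`'s backward-differentiation (BDF,
i.e. Gear) method, the algorithm family the original simulations used.
At strict tolerances the BDF and lsoda solutions agree to ~1e-12 on daily
means, but BDF tracks the strict solution far better when tolerances are
relaxed, which is what makes the batch runs cheap. Three tolerance presets
are exposed:

| preset | atol | rtol | role |
|---|---|---|---|
| `strict` | 3e-20 | 1e-14 | published pair; rules out numerical artefacts; the configuration default |
| `standard` | 1e-15 | 1e-8 | working preset for batch runs; atol below the smallest species scale (~1e-12 M), so trajectories stay positive |
| `relaxed` | 1e-9 | 3e-6 | published robustness pair; same corticosterone-scale behaviour at a fraction of the cost |

The acceptance suite verifies that strict and relaxed runs agree on
day-2–5 daily corticosterone means to better than 1%. Note one caveat of
the relaxed pair: its absolute tolerance sits *above* the CRH/ACTH scale,
so those two species can drift a few times $10^{-12}$ M below zero —
harmless for corticosterone-scale metrics, which is the only use the
package makes of relaxed runs (the calibration grids). Magnitudes below 1e-30 M are floored to zero. Simulations start at
00:00 of day 1 from the published initial concentrations; day 1 is an
entrainment transient and is excluded from all metrics by default.

## Oscillation metrics

Corticosterone analytics work on a 1-min resampled series. The circadian
baseline is removed by subtracting a 6-h running median — long against the
20 min–2 h ultradian band, short against the 24-h envelope. Peaks and
troughs are local extrema with topographic prominence of at least 5% of
the detrended window's interquartile range; both the window length and the
threshold are exposed as arguments, and neither comes from the source
experiment (they were chosen once so that a synthetic 80-min sinusoid
fixture and the control scenario are both detected cleanly, and are
deliberately relative quantities so detection is scale-invariant).
Reported metrics: median inter-peak interval, peaks per 24 h, median
peak-minus-following-trough amplitude on the raw series, the highest
peak/lowest trough pair, a circadian modulation index
$(\max - \min)/(\max + \min)$ of the hourly maxima (the daily upper
envelope), and per-day means. Fewer than two detected peaks yields `NA`
metrics flagged absent, never zeros. The circadian period is estimated as
the lag of the autocorrelation maximum searched between 18 h and 30 h,
which requires at least four full analysed days.

Unit bridges: ng/mL = M × molar mass × 10⁶, with corticosterone at
346.46 g/mol and CRH at 4758 g/mol (41-residue peptide) — physical
constants supplied as defaults, not fitted. The CRH stimulation-test
calculator converts an intravenous dose to a peripheral blood
concentration under either a total blood volume (litres, with body mass)
or a per-kg blood volume (mL/kg).

## The synthetic measurement generator

The generator emulates the blood-sampling protocol of the source
experiment: 31 samples of 50 μL over ~24 h (1.55 mL total) in two
interval layouts — variant A (23 hourly samples, six 10-min samples during
kindling, two 30-min samples after) and variant B (one sample 50 min
before kindling, six 10-min samples during, 24 hourly samples after).
The in-kindling samples are anchored to the 21:12–22:02 window; the clock
position of variant A's hourly run-in is not pinned by the protocol and is
configurable. Measurement error is multiplicative log-normal with median 1
and CV 4.1% (the inter-assay CV of the corticosterone ELISA); a log-normal
was chosen because only a CV is stated and it guarantees nonnegative
"assay" values while being median-unbiased. Sample loss is i.i.d.
Bernoulli and removes a value, never its schedule row. Cohorts derive
per-animal seeds deterministically from one master seed and regenerate
bit-identically.

What the generator does *not* emulate: genuine inter-animal parameter
variability (all animals of a group share one trajectory unless per-animal
trajectories are supplied), hypovolemia feedback from repeated sampling
(reported to be mild), serial correlation of assay errors, and
detection-limit censoring. Passing tests therefore show that the
*pipeline* recovers what it put in under honest assay noise — not that it
would survive every pathology of live-animal data.

## Calibration

"Best agreement" is operationalised as least squares in ng/mL — the assay
scale, shared with the noise model — between noiseless model predictions
at the sample times and the measured values, pooled across animals.

* **Pulse intensity**: grid search over a log-spaced candidate grid
  (reference: 9 points from 10⁻⁸ to 10⁻⁶ M); one simulation per candidate,
  reusable across repeated fits. A failed candidate simulation is flagged
  in the trace and excluded from the argmin, never silently dropped.
* **Stress multiplier**: linear grid over [1, 1.4] followed by bounded
  scalar refinement. The pointwise objective decorrelates once the
  ultradian phase drifts by a large fraction of a cycle, leaving an
  attraction basin only a few hundredths wide around the optimum; the
  default 33-point grid (spacing 0.0125) is chosen to land inside it, and
  the refined value is reported only if it improves on the grid optimum.
  Near the minimum the objective bottoms out at a solver-tolerance noise
  floor, so recovery is reliable to ±0.01 rather than machine precision.
  A flat grid objective raises a non-identifiability warning.
* **Group comparison**: classical one-way ANOVA on samples pooled per
  group (the pooled form is implied by the degrees of freedom reported for
  the animal experiment; nothing quantitative here depends on that
  choice).

## Problem sizes

The analysis scripts and tests use: 5-day integrations for the three
scenarios (standard tolerances); 72-h continuous kindling at three
intensities (relaxed tolerances, 6,480 restarts each); 20 seeded
parameter-recovery repeats over 4-animal cohorts at CV 4.1% reusing nine
candidate simulations; and 1,000 null cohorts for the ANOVA calibration.
These sizes were chosen as the smallest that make the monotonicity and
recovery claims statistically meaningful.

## Known limitations

* The model inherits every simplification of the source network: no AVP,
  angiotensin II or monoamine inputs, no receptor dynamics, continuous
  (deterministic) kinetics, spatial homogeneity, and condensed pathway
  steps whose constants are not individually interpretable.
* CRH release is continuous through R2; real CRH is secreted in discrete
  pulses. The kindling pulses are instantaneous concentration jumps, an
  idealisation of 10-s stimulation trains.
* The ultradian detector is a time-domain peak picker; no spectral or
  deconvolution machinery is provided, so closely spaced secretory events
  merge.
* Calibration identifies the two perturbation parameters only; the 25 rate
  constants are taken as given and are not identifiable from a single
  corticosterone series.
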