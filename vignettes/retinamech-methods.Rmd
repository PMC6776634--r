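---
title: "Methods: indentation rheology and mechanically evoked spiking analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indentation rheology and mechanically evoked spiking analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinamech)
```

This vignette documents the models, conventions and design choices behind
the package: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generators do and do not
emulate, and where genuinely open choices were settled.

## Dynamic micro-indentation rheology

A ferrule-top probe indents the tissue with a spherical tip (radius *R*)
while an interferometer reads the cantilever deflection; load is
`spring_constant × deflection`. In depth-controlled mode the indentation
depth is the piezo travel minus the deflection, both referenced to the
contact point:

$$h(t) = \big(z_{piezo}(t) - z_{contact}\big) - \big(d(t) - d_{baseline}\big).$$

**Contact detection.** Contact is the first sample at which the load
exceeds the pre-contact baseline mean by 3 baseline SDs and stays above for
at least 50 ms. The instrument does not mark contact, so some criterion is
needed; a sustained 3σ crossing is the standard change-point heuristic and
the hold window rejects isolated noise excursions. On a noise-free trace
the rule degenerates to the first loaded sample. Because a Hertzian load
rises as $h^{3/2}$, detection on a soft sample is systematically slightly
late — about 0.2 µm of depth at the default noise level — which biases the
contact radius by roughly 1% at a 15 µm working depth; this is the dominant
systematic in the noisy closed-loop recovery and stays well inside the 5%
envelope.

**Oscillation extraction.** Each oscillation segment is fit, at its known
drive frequency, by least squares on $c + A\sin\omega t + B\cos\omega t$
for both depth and load; amplitudes are $\sqrt{A^2+B^2}$ and the phase lag
$\Phi$ is the load phase minus the depth phase wrapped to $[-\pi,\pi]$.
At a known single frequency this is the maximum-likelihood (lock-in)
estimator under white noise, and on integer-period noise-free segments it
agrees with the FFT-bin value to machine precision (the test suite holds it
to $10^{-6}$). Segments must span at least 3 full periods. A fitted
$\Phi \notin [0, \pi/2]$ is physically inadmissible for a passive material
and is flagged on the fit, never clipped — clipping would silently bias the
loss modulus toward zero.

**Moduli.** With Hertzian contact radius $a=\sqrt{R\bar h}$ at the
segment's mean depth and $A = \pi a^2$,

$$K' = \frac{F_0}{h_0}\cos\Phi\,\frac{\sqrt\pi}{2\sqrt A},\qquad
  K'' = \frac{F_0}{h_0}\sin\Phi\,\frac{\sqrt\pi}{2\sqrt A},\qquad
  \tan\Phi = K''/K'.$$

These are the dynamic-stiffness forms (equivalently $(F_0/h_0)\cos\Phi/2a$)
in the $E/(1-\nu^2)$ normalization with $\nu=0.5$ (incompressible tissue).
The oscillation is at most 2% of the working depth, so the contact area is
treated as constant within a segment. All file I/O stays in the recorded
µm/µN units; modulus arithmetic converts to SI internally.

**Strain and pressure.** Per-trial indentation strain is $\epsilon = a/R =
\sqrt{h/R}$ and pressure is the maximal load over the contact area,
$F_{max}/(\pi R h)$. The strain convention follows the usual spherical-
indentation definition; where a source uses $0.2\,a/R$ instead, thresholds
on strain scale accordingly.

**Statistics.** Per-frequency modulus samples across map locations are
tested for normality (Shapiro–Wilk); distributional comparison across
frequencies uses Kruskal–Wallis, with significance flagged at 0.01 and
0.0005. When all observations are identical the ties-corrected statistic is
degenerate; the package reports H = 0, p = 1 by convention.

## The synthetic indentation generator

The generator inverts the moduli equations: given a tissue model
($K'(f), K''(f)$), the load oscillation at drive frequency $f$ has
amplitude $F_0 = h_0\,2a\,|K^*|$ and phase $\Phi=\mathrm{atan2}(K'',K')$,
so the downstream analysis must return exactly the planted moduli. Ramp and
relaxation segments are qualitative scaffolding (Hertzian loading with the
instantaneous modulus, exponential relaxation to the equilibrium modulus):
they exercise contact detection and set the mean load but carry no graded
quantity. Measurement noise is Gaussian on the deflection channel only,
which is where interferometric readout noise lives; the load inherits it
through the spring constant, and the depth channel is unaffected because
depth is piezo minus deflection.

The default tissue is a standard linear solid with the relaxation frequency
placed at 30 Hz — above the 0.1–10 Hz measurement band — calibrated so the
storage modulus rises from 0.7 kPa at 0.1 Hz to 1.7 kPa at 10 Hz. With the
relaxation above the band, both moduli increase with frequency and the loss
tangent is largest at 10 Hz, the qualitative behaviour reported for retinal
tissue. A single SLS cannot make $K''$ rise monotonically *and* peak inside
the band; placing the relaxation outside it resolves the choice in favour
of the observed trend.

Oscillation segments default to at least 4 periods and at least 5 s
(`min_oscillation_s`): at 10 Hz the loss angle is estimated from
phase differences of order $10^{-2}$ rad, and five seconds at the 1 kHz
default sampling rate is what keeps the noisy phase error a few times
smaller than the 5% recovery envelope. These durations are realistic for
dynamic indentation practice.

## The synthetic retina generator

Units fire as inhomogeneous Poisson processes on a 10 ms rate grid
(piecewise-constant intensity; counts per bin with uniform placement, which
is an exact simulation). Three rate components:

* **Basal**: constant per-unit rate, 5 Hz default — a typical spontaneous
  RGC rate in darkness.
* **Flash responses**: a 200 ms half-cosine transient per preferred flash
  (ON: white, OFF: black, ON-OFF: both, NC: none) peaking at
  `flash_gain × basal` (default 4). The kernel shape is a modelling choice;
  nothing downstream depends on it beyond producing a clear peak within the
  response window.
* **Mechanically evoked modulation**: per planted cluster, a box-car gain
  with exponential rise (τ = 1 s) starting `latency_s` after stimulation
  onset and/or offset and lasting `duration_s` (defaults 2 s and 5 s; gain
  3). Suppressive kinds divide the rate by the gain; `rebound` suppresses
  during the stimulus and excites after release. Reported response
  kinetics are only "slow, lasting a few seconds", so the exact kinetics
  here are declared, not inferred. Per-unit latency grows with electrode
  distance from the indentation center at 0.5 s/mm, reflecting the
  observation that response delays track distance from the probe.

Poisson spiking (no refractoriness) is the simplest model sufficient to
exercise the pipeline; an optional absolute refractory period is available.
All randomness flows from one explicit integer seed through a local RNG
stream that never touches the caller's global state. What the generator
does **not** emulate: bursting, adaptation, receptive-field structure,
photoreceptor transduction dynamics, Müller-cell calcium waves, spike-sorting
artifacts, or electrode crosstalk — so passing tests demonstrate the
correctness of the analysis chain, not biological realism of the input.

## Spike-train analysis conventions

* **Rates**: spikes counted in a 2 s window sliding in 10 ms steps
  (left-closed, right-open); bin centers are placed so every window lies
  fully inside the analysis interval — edge windows are never padded.
* **Z-scoring**: per unit over the matrix's own bins, population-SD
  (divisor *n*) convention. Constant-rate rows are flagged and excluded
  from correlation and clustering rather than propagating NaNs.
* **Clustering**: average-linkage agglomeration on $d = 1-|\rho|$, a
  monotone transform of the absolute-Pearson similarity, so correlated and
  anti-correlated units merge — intended, since suppression is as much a
  response as excitation. For each candidate k the dendrogram is cut and
  the mean silhouette width on the same precomputed distance scores it;
  ties select the smallest k, making selection deterministic. If all
  pairwise distances vanish (identical signals) the silhouette is undefined
  for every k and a single cluster is returned with a warning.
* **Windows**: the basal reference is the 120 s preceding stimulation
  onset; the indentation correlation window runs from onset to offset plus
  a 10 s margin, since offset-locked responses would otherwise be cut.
  Both phases use identical window/step parameters for comparability.

## ON/OFF classification

Peak amplitudes come from the trial-averaged peri-stimulus rate around
each flash color, baseline-subtracted and floored at zero (the bias index
presumes non-negative amplitudes; suppressive flash responses are not
signed). The response window is the flash duration plus 0.5 s. Flash
analysis should use a short rate window (0.2 s default in the pipeline):
a 2 s window would dilute a 200 ms transient tenfold. The NC criterion is
applied first: a unit whose peak rate stays below
`basal_mean + 1 × basal_sd` — no excursion beyond baseline variability —
is non-classified regardless of its bias index. The literal alternative
("peak below mean − SD") would make NC nearly unreachable for any active
cell, so this package uses the variability-threshold reading and documents
it as a convention. `basal_sd` is the SD of the single-window baseline rate
trace, not the trial-averaged SE; this keeps chance peaks of non-responders
below threshold.

## Probe localization

The probe shadow is the largest 4-connected component of non-saturating
electrodes (4- rather than 8-connectivity resists diagonal noise bridges);
isolated flipped electrodes fall below `min_region` and are ignored. The
center estimate is the component centroid snapped to the nearest electrode,
half-way ties toward smaller indices — deterministic and, by convexity,
always inside the shadow's hull. Manual localization on the rig is
replaced by this automated rule; a `manual_override` escape hatch remains.
With several frames, the frame with the most saturating electrodes (light
fully on, crispest shadow) is selected. A disk fit is deliberately not the
default: the probe stem also shadows electrodes, and the raw centroid is
robust to moderate stem contamination while a disk fit would need an
outlier model.

## Decision-tree predictors

The feature table holds, per trial: contact area, strain, pressure, depth,
d5 (units within five electrode distances of the center, inclusive
Euclidean) and r5 (their mean basal rate; undefined when d5 = 0). A binary
classification tree (Gini criterion, unlimited depth, minimum leaf size 1,
no surrogate or competitor splits) is fit 1000 times; each repeat draws a
stratified 80/20 training split from a repeat-specific seed. A tree on a
fixed table is deterministic, so resampling is the only meaningful
"different initial condition"; a `seed_only` mode that refits the full
table is provided for completeness and produces zero variance. Importances
are the normalized per-tree Gini impurity decreases (summing to 1; unused
features score 0), reported as mean ± SD over repeats. Features are
processed in a canonical (alphabetical) order before fitting so that split
tie-breaking — and hence the result — cannot depend on the arrangement of
input columns; a duplicated feature therefore splits its importance with
its copy rather than inflating the pair.

## Numerical and degenerate-input policy

Typed conditions (`retinamech_invalid_parameter`,
`retinamech_insufficient_data`, `retinamech_no_contact`, …) separate user
errors from degenerate data. Degeneracies that are legitimate outcomes —
constant-rate units, empty composition groups, single-unit clusters,
all-identical statistic groups — are flagged or given documented
conventions rather than raised as errors. Oscillation fits require ≥ 3
periods counting whole samples (n·Δt), so a nominal 3-period segment is not
rejected for being one sample short.

## Problem sizes and verification scope

The test suite and the acceptance script run everything at desk scale,
chosen to keep the full verification pass in a few minutes: closed-loop
recovery on single traces plus five noisy replicates; 1000-case identity
checks; 200-seed calibration of the Kruskal–Wallis size and power at the
observed 0.7/1.2/1.7 kPa effect; 50-seed recovery of four 75-unit planted
clusters among 300 units (120 s basal + 60 s indentation); three 200-unit
synthetic retinas for classification; 100 noisy saturation frames; 1000
tree repeats on 200 trials; and two full pipeline runs compared byte for
byte. The end-to-end demo pipeline uses 300 units and 16 trials over a
~40-minute synthetic recording.

## Known limitations

* Ramp/relaxation segments of the synthetic traces are qualitative; the
  package does not fit stress-relaxation models, adhesion corrections, or
  substrate-thickness corrections.
* The Hertzian contact expressions assume small strain and a flat,
  laterally infinite sample; at 60 µm depth with a 125 µm bead the strain
  reaches ~0.7, where the apparent moduli are effective, not constitutive,
  quantities.
* Cluster-count selection by silhouette is reliable when planted structure
  is orthogonal in time; temporally overlapping response families merge
  under the $|\rho|$ metric by design.
* The reported pressure uses $A=\pi R h$; minimum-pressure thresholds
  quoted under other contact-area conventions differ by a constant factor
  and are not reconciled here.
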