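# retinamech

Combined analysis of tissue micro-mechanics and large-scale retinal
electrophysiology, for experiments in which a ferrule-top micro-indenter
stimulates the photoreceptor layer of an explanted retina while a
high-density multi-electrode array (HD-MEA, a 64 × 64 grid of electrodes at
42 µm pitch) records the spiking of hundreds of retinal ganglion cells
(RGCs). The package is aimed at labs doing mechanobiology or
mechano-electrophysiology on soft neural tissue who need a tested, scriptable
version of the full analysis chain — and a synthetic-data generator that
makes every stage verifiable without instrument data.

## What it computes

**Viscoelastic characterization from oscillatory indentation.** During a
depth-controlled protocol (2 µm/s ramp, stress-relaxation hold, then 0.3 µm
sinusoidal oscillations at 0.1, 1 and 10 Hz) the load *F(t)* and indentation
*h(t)* oscillations are fit at the known drive frequency by linear least
squares. With oscillation amplitudes F₀ and h₀, phase lag Φ, and Hertzian
contact area A = πa², a = √(Rh̄) for a spherical tip of radius R at mean
depth h̄, the apparent storage and loss moduli (E/(1−ν²) normalization,
ν = 0.5) are

    K′ = (F₀/h₀) · cos Φ · √π / (2√A)
    K″ = (F₀/h₀) · sin Φ · √π / (2√A)

and the loss tangent is tan Φ = K″/K′. Per-frequency samples across map
locations are compared with Shapiro–Wilk normality tests and a
Kruskal–Wallis test.

**Mechanically evoked spiking structure.** Spike trains (units ≥ 0.1 Hz) are
converted to sliding-window firing rates (2 s window, 10 ms steps),
z-scored, and correlated across units separately for the 120 s basal window
and the indentation window. Units are clustered hierarchically (average
linkage) on the distance 1 − |ρ| so correlated and anti-correlated units
group together; the cluster count k ∈ [4, 60] is selected by maximizing the
mean silhouette width. Reordering the basal correlation matrix by the
indentation-phase clusters quantifies how much of the correlation structure
is stimulus-induced.

**Cell-type attribution.** Units are typed from full-field white/black
flash responses via the bias index BI = (A_w − A_b)/(A_w + A_b) (ON if
BI > 0.3, OFF if BI < −0.3, ON-OFF otherwise; non-responsive units are NC),
and the ON/OFF/ON-OFF/NC composition of mechanically responsive vs
unresponsive clusters is tabulated.

**Probe localization.** The probe shadow in a far-red-light saturation
frame is segmented as the largest 4-connected non-saturating component and
its centroid gives the indentation-center electrode.

**Trial-outcome predictors.** Per indentation trial, physical features
(contact area, strain ε = √(h/R), pressure = F_max/A, depth) and local
electrophysiological features (d5 = units within five electrode distances
of the center, r5 = their mean basal rate) feed a decision-tree classifier
(Gini criterion); normalized Gini importances averaged over 1000
stratified-split repeats rank the predictors of successful stimulation.

## Worked example

```r
library(retinamech)

# synthetic tissue whose storage modulus rises 0.7 -> 1.7 kPa over 0.1 -> 10 Hz
tissue <- sls_tissue_preset()
trace  <- simulate_indentation_trace(indentation_protocol("map_sweep"), tissue, seed = 1)
round(analyze_indentation_trace(trace)[, c("freq_hz", "k_storage_pa", "k_loss_pa", "tan_phi")], 3)
#>  freq_hz k_storage_pa k_loss_pa tan_phi
#>      0.1      706.577    34.571   0.049
#>      1.0      716.839   335.000   0.467
#>     10.0     1715.268  3028.132   1.765
```

The recovered moduli at 5 nm deflection noise sit within a few percent of
the planted model: 706.6 Pa at 0.1 Hz and 1715.3 Pa at 10 Hz against the
planted 700 and 1700 Pa, with the loss tangent rising from 0.049 to 1.765
across the band — tissue damping grows with stimulation frequency.

```r
# four planted response clusters among 300 RGCs, 60 s indentation at t = 120 s
members <- split(1:300, rep(1:4, each = 75))
pcs <- list(planted_cluster(members[[1]], "onset_excited",  latency_s = 1,  duration_s = 8),
            planted_cluster(members[[2]], "onset_excited",  latency_s = 20, duration_s = 8),
            planted_cluster(members[[3]], "onset_excited",  latency_s = 40, duration_s = 8),
            planted_cluster(members[[4]], "offset_excited", latency_s = 1,  duration_s = 8))
cfg <- retina_config(n_units = 300, basal_rates_hz = 5, planted_clusters = pcs, seed = 1)
sts <- simulate_spike_trains(cfg, stim = stim_schedule(120, 180), duration_s = 200, seed = 2)

aligned <- align_stimulation_window(sts, cbind(120, 180))
ind <- zscore_rates(compute_firing_rate(aligned, c(120, 190), 2, 0.01))
bas <- zscore_rates(compute_firing_rate(aligned, c(0, 120), 2, 0.01))
ca  <- cluster_units(correlation_matrix(ind), c(4, 60))
ca
#> <cluster_assignment: 300 units in 4 clusters (avg linkage, 1-|rho|)>
#>   silhouette at k = 4: 0.675
#> cluster
#>  1  2  3  4
#> 75 75 75 75

reorder_basal(correlation_matrix(bas), ca, indent_corr = correlation_matrix(ind))$summary
#>         phase mean_within_abs_rho mean_between_abs_rho
#> 1       basal          0.08544167           0.08456485
#> 2 indentation          0.72717585           0.11397840
```

The silhouette-selected k equals the planted 4 and membership is exact;
within-cluster |ρ| is ~0.73 during indentation but ~0.085 in the basal
window — the correlation structure is created by the mechanical stimulus,
not present at rest.

`run_full_pipeline(out_dir, seed)` chains every stage (mechanics map →
probe localization → clustering → classification → predictors) on a
self-generated dataset and writes CSV/JSON artifacts plus a run report;
identical config and seed reproduce all outputs byte for byte. A thin
command-line wrapper is installed at `inst/scripts/retinamech-cli.R`.

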