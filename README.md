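# neurokernel

Kernel methods for decoding and controlling multiscale neural activity.

Simultaneous recordings carry the same population signal at two scales:
**spike trains** (sparse, precisely timed point processes) and **local field
potentials** (continuous, robust, temporally sloppy averages). `neurokernel`
puts both into one reproducing-kernel Hilbert space so that a single linear
filter in that space can

* **decode** a stimulus from joint spike/LFP windows, and
* **control** a neural population: an adaptive inverse controller computes
  multichannel microstimulation patterns whose evoked activity mimics a
  target response — a *virtual touch*.

## The model

A windowed spike train enters through the Schoenberg kernel on smoothed
intensity functions,

    k_s(a, b) = exp( - ∫ (λ̂_a(t) - λ̂_b(t))² dt / σ_s² ),

with λ̂ the spike train convolved with a rectangular smoother (evaluated in
closed form from rectangle overlaps — no binning). An LFP window enters
through the Gaussian-type kernel on the sampled trace,
`k_x = exp(-||x_a - x_b||² / σ_x²)`. Direct-sum kernels pool units and
channels; the **tensor product** `k = k_s · k_x` fuses the modalities into a
strict joint similarity. On top of this sits

* **Q-KLMS** (`qklms()`, `qklms_train()`): quantized kernel least mean
  squares — an online dictionary filter `y_m = Σ_n a_mn k(c_n, u)` whose
  dictionary grows only when an input is farther than a quantization radius
  from every center; and
* **filtered-error adaptive inverse control** (`initialize_controller()`,
  `run_control_loop()`): a Q-KLMS inverse plant model doubles as the
  controller, adapted with ε = P̂⁻¹φ(x) − P̂⁻¹φ(z), with constraint
  post-processing (`constrain_stimulation()`) that turns raw amplitude
  traces into deliverable pulse sequences (≥10 ms per-channel spacing, one
  channel at a time, 8–30 µA).

A seeded synthetic thalamocortical plant (`synthetic_plant_config()`,
`simulate_plant()`) — inhomogeneous-Poisson spiking plus damped-sinusoid
LFP responses with latency jitter — makes every experiment runnable without
recorded data.

## Worked example

One decoding trial: simulate 20 s of touch-driven activity plus a held-out
2.5 s test segment, set the kernel sizes from the data, and compare the
tensor-product decoder against its single-modality ablations.

```r
library(neurokernel)

cfg  <- synthetic_plant_config(seed = 7)
stim <- generate_touch_stimulus(20, touch_rate = 0.5, n_sites = 1, seed = 7)
rec  <- simulate_plant(stim, cfg, seed = 7)
rec
#> <recording> 20.000 s, 10 units (1508 spikes), 4 LFP ch @ 1000 Hz, 1 stim ch @ 200 Hz

compare_decoders(seed = 1)[, c("rule", "nmse")]
#>          rule  nmse
#> 1     product 0.807
#> 2 spikes_only 0.991
#> 3    lfp_only 0.769
```

The numbers are held-out NMSE (0 = perfect, 1 = predicting the mean) for
decoding the derivative of the touch-force envelope. Spike windows alone
barely decode (≈1): 9 ms Poisson windows are nearly orthogonal in the
RKHS. Individual seeds vary — on this one the LFP decoder edges out the
product — but across repeated trials the tensor-product decoder's *median*
NMSE is at or below both ablations, because the spike factor vetoes the
LFP's jittered timing (see the vignette for the mechanism, and
`run_control_experiment()` for the control counterpart).

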