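---
title: "Tensor-product kernels for multiscale neural decoding and control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-product kernels for multiscale neural decoding and control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurokernel)
```

## The problem

Simultaneously recorded spike trains and local field potentials (LFPs)
describe the same neural population at two scales: spikes carry precise
event timing from a handful of units, LFPs carry a robust but temporally
sloppy population average. `neurokernel` fuses the two through
reproducing-kernel methods so that one linear-in-RKHS model can decode a
stimulus from both, and — run in reverse as an adaptive inverse controller —
can compute multichannel microstimulation patterns whose evoked activity
mimics a target response ("virtual touch").

## Kernels

A window of a single spike train is compared through its smoothed intensity
function. With the rectangular smoother $g(t) = \tfrac1{\mathcal T}
(U(t)-U(t-\mathcal T))$ the estimate $\hat\lambda(t)=\sum_m g(t-t_m)$ is a
step function, and the Schoenberg kernel

$$\kappa_s(a,b)=\exp\!\Big(-\tfrac1{\sigma_s^2}\int_0^{T_s}
(\hat\lambda_a-\hat\lambda_b)^2\,dt\Big)$$

is evaluated exactly from rectangle overlaps — no time grid is involved.
The default smoothing width equals the window length $T_s$ (so the
intensity is a cumulative spike-count profile), honouring the requirement
that the smoother be much wider than the interspike interval; it is
configurable. Integration is restricted to the analysis window $[0,T_s]$,
with rectangles truncated at the right edge, so windows are self-contained.

An LFP window is compared directly as a sampled trace,
$\kappa_x(a,b)=\exp(-\|x_a-x_b\|^2/\sigma_x^2)$, with the squared distance
taken as a left Riemann sum scaled by the sampling period, so $\sigma_x^2$
has time-integral units and is stable under resampling.

Units and channels are pooled by direct-sum kernels (unweighted averages by
default — the `normalize_channels` flag divides by the count so
self-similarity is 1 and the distance shortcut $d=\sqrt{2-2\kappa}$
applies; the unnormalized literal sum is one flag away). The two modalities
are fused by the tensor product $\kappa = \kappa_s \cdot \kappa_x$, a
*strict* joint similarity: if either factor vanishes, so does the product.
A direct-sum alternative and single-modality rules are available through
`composite_kernel_spec()`.

### Kernel sizes

The field's usual prescription — set $\sigma$ from the average pairwise RKHS
distance of the training samples — is circular, because the RKHS distance
already depends on $\sigma$. We therefore set $\sigma^2$ to the mean
*pre-exponential* squared distance (the integral inside the exponent),
which is what the kernel actually scales. Two further choices matter:

* The mean is taken over *non-identical* single-unit (or single-channel)
  comparisons. Sparse 9 ms windows make most unit pairs empty-vs-empty
  with distance exactly zero; including them shrinks $\sigma_s$ an order of
  magnitude below the scale of any real spike difference and collapses the
  spike kernel into an exact-match indicator. For LFPs no two windows are
  identical and the definition coincides with the plain all-pairs mean.
* For long window sequences the pair mean is estimated on an evenly spaced
  subsample of at most 600 windows (~180k pairs), which is statistically
  indistinguishable from the full quadratic scan.

## Q-KLMS

`qklms()` implements the quantized kernel least-mean-square filter: an
online dictionary of center samples and an outputs-by-centers coefficient
matrix. Each update computes the a-priori error, finds the nearest center
in RKHS distance (general form $\sqrt{\kappa_{aa}+\kappa_{bb}-2\kappa_{ab}}$
with cached self-similarities; ties go to the lowest index), and either
nudges that center's coefficients by $\eta e$ (distance within the
quantization radius $\varepsilon_q$) or appends a new center. With
$\varepsilon_q=0$ — the decoding default — only exact repeats merge and the
filter is plain KLMS; repeated passes over the data refine the
coefficients.

Two engines give the same result: a step-by-step online reference path, and
a fast path that precomputes the kernel matrix of the training inputs in
compiled code and replays the identical recursion. The equivalence is
pinned by tests to 1e-12 and, against a naive KLMS reference, bit for bit.

## Windowing and decoding

`slide_windows()` builds causal windows that end at the prediction time:
spikes from $(t_k-T_s, t_k]$ (shifted to window coordinates), LFP samples
from $(t_k-T_x, t_k]$, and the stimulus value at $t_k$ by nearest sample —
the target alignment is the window's right edge, with an optional
`target_delay_ms` for inverse models (below). Defaults follow the
autocorrelation analysis of the experimental preparation: $T_s = 9$ ms,
$T_x = 20$ ms, step 5 ms (the stimulus discretization).
`estimate_window_length()` reproduces that analysis: the window length is
the smallest lag from which the autocorrelation stays inside its $\pm 2
SE$ band (cumulative Bartlett SE), channel-averaged.

Decoding quality is scored by NMSE normalized by the variance of the
desired signal (the normalization is stated nowhere upstream, so it is
documented here): 0 is perfect, 1 is the mean predictor.

## The synthetic plant

No recordings are shipped; `synthetic_plant_config()` + `simulate_plant()`
generate a seeded stand-in for an anesthetized thalamocortical preparation:

* **Spiking**: each unit is an inhomogeneous Poisson process
  (Lewis–Shedler thinning on a 1 ms grid), rate = 5 sp/s baseline plus
  gain-weighted stimulus drive. Touch drive mixes the sustained pressure
  envelope with its rectified positive derivative (`phasic_weight` 0.6):
  cortical touch responses are phasic and onset-dominated. A strongly
  driven multiunit reaches ~120 sp/s (`stim_gain_rate`).
* **LFPs**: the stimulus drive convolved with per-channel damped sinusoids
  (20–40 Hz, 8–15 ms decay — a ~20 ms correlation time) plus Gaussian
  noise (sd 0.4). Each stimulus event's LFP deflection is jittered in
  latency (sd 10 ms) while the spike volley stays precise. This implements
  the complementarity the decoders rely on: the LFP carries the smooth
  envelope with good SNR but is blind to fine timing; spikes are sparse
  but precisely timed.
* **Touches**: non-overlapping 100 ms raised-cosine pulses at
  Poisson-thinned times. A *decoding* trial touches a single site, which
  recruits the whole recorded population (one digit pad per trial);
  multi-site stimuli (used by the control experiment) have sharp receptive
  fields — a strong preferred block of units and a weak (0.05–0.2×)
  surround — because per-unit Pearson correlations are scale-invariant and
  site identity is only visible as presence/absence differences.
* **Microstimulation**: pulses with exponential inter-stimulus intervals
  (mean 100 ms) over 8 sites at 10/20/30 µA. A pulse evokes a ~25 ms burst
  (urethane-like cortical response), recruiting all units weakly with one
  or two strongly preferred units per channel.

All randomness flows from one seed through named substreams, so stimulus,
spikes and noise are independently reproducible. What the generator does
*not* emulate: biophysical membrane dynamics, volume conduction, 1/f
background, state fluctuations, electrode artifacts. Tests passing on this
plant show the estimators and the control loop behave as designed under
the stated model, not that they meet any particular accuracy on real
tissue.

## Decoder comparison

`compare_decoders()` is the packaged experiment: 20 s of training and
2.5 s of held-out test data per seed (the durations used with the real
preparation), the decoded
target being the normalized derivative of the touch force envelope (the
"desired stimulation" signal). The tensor-product decoder is compared with
spike-only and LFP-only decoders sharing the same kernel sizes, learning
rate (0.2), three epochs and presentation order. Across seeds the product
kernel's median NMSE is at or below both single-modality decoders: the LFP
factor supplies the envelope, the spike factor vetoes the LFP's jittered
timing. The spike-only decoder hovers near NMSE 1 — sparse 9 ms windows
of Poisson spikes are mutually near-orthogonal in the Schoenberg RKHS,
so single-window spike decoding barely generalizes; that is also why it
was the weakest decoder in the experimental ranking this reproduces.

## Adaptive inverse control

`initialize_controller()` trains the inverse plant model $\hat P^{-1}$:
Q-KLMS from response windows to delivered per-channel amplitudes. Three
alignment choices proved load-bearing:

* **Modeling delay.** A causal window ending at $t$ cannot contain the
  response to a pulse delivered *at* $t$; the inverse target is the
  stimulation at $t - \Delta$ with $\Delta = \max(T_s, T_x) = 20$ ms.
* **Target hold.** The 5 ms-binned amplitude series is sparse while the
  evoked burst lasts ~25 ms; the inverse target is held over a trailing
  15 ms window (rolling max) so readouts calibrate to the µA scale rather
  than being diluted across bins.
* **Emission threshold.** The controller inherits a per-channel noise
  floor — the 95th percentile of the inverse readout on zero-amplitude
  training windows. Outputs below it are not delivered; without this, the
  8 µA legal floor turns sub-µA readout noise into continuous stimulation.

The controller is a copy of the inverse model with its dictionary frozen.
`run_control_loop()` feeds target windows through it, schedules the output
with a delivery look-ahead of $\Delta$ plus one step (which time-locks the
evoked response to the target at lag 0), constrains it to deliverable
pulses, and — in closed loop — adapts: the inverse model updates online on
(response window, delivered amplitude), and each frozen controller center
moves by the *mean* filtered error
$\varepsilon = \hat P^{-1}\phi(x) - \hat P^{-1}\phi(z)$ of the windows
quantized onto it that epoch. The per-center mean (rather than summed
per-step increments) keeps the effective step size independent of how many
windows share a center; summed updates concentrate hundreds of increments
on a few centers and ring. `update_controller()` retains the classic
single-update semantics.

Constraint processing (`constrain_stimulation()`) enforces the delivery
rules: per channel, positive candidates survive a greedy amplitude-descending
non-maximum suppression with a 10 ms exclusion window (a deterministic
stand-in for flat-kernel mode seeking, whose bandwidth and initialization
are unstated upstream); at each time point only the largest-amplitude
channel keeps its pulse (ties to the lowest channel index); surviving
amplitudes are clipped into 8–30 µA, with sub-minimum survivors raised to
8 µA and non-positive candidates discarded. `validate_stimulation()`
audits any sequence against these invariants independently.

`run_control_experiment()` packages one trial: 8 s of random-stimulation
pretraining, a 5 s closed-loop run (5 epochs) for the filtered-error
trajectory, then a 10 s open-loop pass — the controller generates the
whole stimulation sequence offline and it is delivered once, exactly the
open-loop protocol the evaluation mirrors. The evoked response is scored
by unit-averaged 5 ms-binned correlations in 300 ms post-onset windows
against the matched-site and the other-site target, and by the lag of the
full-series cross-correlation peak.

## Problem sizes and numerics

Defaults were chosen once so a full trial battery (20 seeded decoder
comparisons, 20 control trials) completes in minutes on one core: 10
units, 4 LFP channels, 8 stimulation channels, 20 s/2.5 s decoding splits,
8 s/5 s/10 s control segments. Kernel evaluations and the Gram-replayed
Q-KLMS recursion are compiled (Rcpp); accumulations use extended
precision; square-root arguments are clipped at zero; nearest-center ties
break to the lowest index for deterministic replay. Units are matched by
index across samples (no re-matching or drift handling). Presentation
order is data order, no shuffling.

## Limitations

The spike-only decoder is close to uninformative at realistic sparseness —
a property of single-window Schoenberg decoding, not a bug. Virtual-touch
correlations are far smaller in absolute terms than on real recordings,
because matched and mismatched targets share the same post-onset burst
shape and Poisson noise dominates per-unit correlations at these rates;
the *ordering* (matched above mismatched, peak at lag zero) is the
reproducible claim. Frequency-domain LFP features, learned kernel weights,
and alternatives to KLMS (KRLS, SVR, sliding-window forgetting) are out of
scope.
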