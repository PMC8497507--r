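---
title: "Modelling the UBC temporal-response continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the UBC temporal-response continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubcontinuum)
```

## The scientific problem

Cerebellar unipolar brush cells (UBCs) each receive a single mossy-fiber
(MF) input and transform a brief burst of MF stimuli (the reference
protocol is 20 pulses at 100 Hz) into firing-rate responses whose durations
span two orders of magnitude — from a few hundred milliseconds to tens of
seconds. Rather than discrete "ON" and "OFF" subtypes, the population forms
a single continuum: graded expression of the excitatory mGluR1 pathway
(PLCβ → DAG → TRPC3, terminated by DAG kinases) against the inhibitory
mGluR2/3 → GIRK pathway produces a graded family of synaptic currents, and
those currents, through a supra-linear f-I relation, set the time course of
spiking. This package implements that account end to end:

1. a **synthetic population generator** (latent continuum → per-cell
   parameters → biphasic synaptic currents → supra-linear f-I → stochastic
   spike trains, with pharmacology emulation),
2. **rate estimation** from spike trains (reciprocal-ISI instantaneous
   rates, trial averaging, baseline statistics, latency-based pauses),
3. **per-cell feature extraction** by fitting a log-Gaussian temporal
   response model,
4. **population statistics** (sorted heatmaps, rank regressions, an
   inverted soft-plus amplitude law, log-uniformity tests, and the
   1/√N-normalized population amplitude with its shifted power-law decay),
5. a **latent-gradient expression module** (synthetic counts with an
   inverse mGluR1-vs-mGluR2/3 gradient, NNMF on log counts, factor
   selection, gene/cell ordering).

## The temporal response model

Each cell's post-offset excitatory response (time zeroed at stimulus
offset) is modelled as Gaussian in log time,

$$ r(t) = r_b + A\,e^{-\left(\frac{\ln t - \mu}{\sigma}\right)^2}, $$

with baseline rate $r_b$ (Hz), amplitude $A$ (Hz), log peak location $\mu$
(ln s) and log-time width $\sigma$ (dimensionless). Closed forms follow:

* peak time $t_{pk} = e^{\mu}$,
* half-width $= 2 e^{\mu} \sinh(\sigma\sqrt{\ln 2})$,
* half-decay (peak to half, post-peak) $= e^{\mu}(e^{\sigma\sqrt{\ln 2}}-1)$,
* half-width / peak-time $= 2\sinh(\sigma\sqrt{\ln 2})$ — independent of
  $\mu$: a constant log-time width across cells yields a constant ratio
  across the whole continuum.

The default width $\sigma_0 = 1.787$ is the unique width whose ratio is
4.2, the value the population exhibits.

## The generator

`sample_population()` draws a population (default 84 cells: 28 pure-ON,
42 biphasic, 14 OFF) as follows.

**Peak times.** Excitatory (pure-ON + biphasic) log10 peak times are drawn
on $[-1.50,\,0.363]$ (0.032–2.31 s) with one uniform draw per equal
log-width stratum. The draw is marginally log-uniform, but reproduces the
tight uniform progression of peak times the recorded population shows
(rank regressions with $R^2_{adj}$ near 1); it also makes the
Kolmogorov–Smirnov log-uniformity test conservative (p near 1 rather than
Uniform(0,1) under an i.i.d. null).

**Widths.** $\sigma_i = \sigma_0 + \mathcal N(0, 0.05)$.

**Amplitudes.** The amplitude–duration tradeoff is a soft minimum of a
saturation plateau and a spike-count-conserving $1/t_{pk}$ line,
$$ A(t_{pk}) = A_{sat}\bigl(1 + (t_{pk}/t_c)^s\bigr)^{-1/s}, $$
with $A_{sat} = 200$ Hz, knee $t_c = 0.09$ s, $s = 2$, and 0.03 dex
lognormal scatter. On log axes this is an inverted-soft-plus-shaped curve:
flat near 200 Hz for fast cells, then decaying as $1/t$ so that the evoked
spike count $\propto A \cdot t_{pk}$ is approximately conserved. The knee
and exponent were calibrated from two closed-form constraints: the
coefficient of variation of the extra evoked spikes stays below 0.3, and
the slowest cell's amplitude stays above the 5 Hz classification floor.

**Classes and pauses.** The fastest 28 excitatory cells are pure-ON, the
slower 42 biphasic: pauses are briefer in cells with shorter-lived
excitation, and the pause trend continues along the half-decay sort into
the OFF group. Biphasic pauses are $0.19\,t_{pk}$ (the proportionality
implied by the matched slopes of the pause and peak-time rank regressions),
floored at 85 ms; OFF pauses are log-uniform on 0.4–1.05 s. A pause is only
measurable if it clearly exceeds the cell's own inter-spike interval, so
pausing cells' baseline rates are drawn coupled to their pause
($r_b = (5/p)\,U(1.1, 1.6)$, clamped to 8–65 Hz for biphasic cells;
Uniform(20, 60) Hz for OFF cells, which fire spontaneously at high rates).
Pure-ON baselines are Uniform(0, 15) Hz. These couplings are the package's
own design: the source data constrain only the measured pause distribution
and the fact that suppressed cells fire at high rates.

**Currents.** Each cell's current has three components (inward positive):

* *mGluR1* — a log-Gaussian inward current for $t > 0$. Inverting the f-I
  power law $r = r_b + k I^p$ maps the target rate onto the current
  exactly: $\sigma_I = \sigma_r \sqrt p$, $\mu_I = \mu_r$,
  $A_I = (A_r/k)^{1/p}$. Under DGK inhibition only the decay limb widens
  (the width for $\ln t > \mu$ is multiplied by `dgk_scale`), leaving the
  peak unchanged.
* *mGluR2/3* — an outward current that rises with a 50 ms saturating
  exponential from the first pulse (transmitter present throughout the
  burst) and decays as a Gaussian in time from offset
  ($\tau_{out} = p_{dur}/1.4$), reflecting accelerating G-protein
  deactivation. The accelerating decay is what lets the outward current
  dominate the (already substantial) inward log-Gaussian throughout the
  pause and still terminate before the inward peak; an exponential tail
  cannot do both at physiological amplitudes. The amplitude is 1.2× the
  minimum that keeps the net current outward through the pause (the
  empirical pause–amplitude relation, log10 pause = −0.42 + 0.01·A_out, is
  used when it is larger); outward currents exceed the subsequent inward
  current, as observed.
* *ionotropic* — 5 ms AMPA/NMDA transients at each pulse, calibrated so the
  fast component carries 9% of the excitatory charge (the complement of the
  91% mGluR1 share). In biphasic cells the amplitude is capped so the last
  pulse's post-offset tail cannot cut the pause short; OFF cells have none.

**f-I transform.** For net inward current, $r = r_b + k I^{p}$ capped at
500 Hz (the power law extrapolated to the brief burst transients is
unphysiological; the cap never binds after offset). The default exponent
is not a free constant but the calibration
`calibrate_fi_exponent(sigma0, target_ratio = 2)` ≈ 1.92: the unique $p$
for which the current outlasts the rate by a factor 2.0 in half-decay at
$\sigma_0$, matching the measured 2.0 ± 0.6. The gain maps a 100 pA peak
to 200 Hz. For net outward current the rate falls linearly to zero at a
per-cell suppression scale $I_0$, calibrated from the synthesized current
so the simulated pause matches the drawn pause duration.

**Spikes.** Inhomogeneous Poisson thinning (segment-wise local envelopes)
with a 2 ms absolute refractory period; the spike RNG stream is separate
from the population-sampling stream.

## Measurement pipeline and numerical choices

**Instantaneous rate.** The reciprocal-ISI step function (1/ISI between
consecutive spikes, 0 outside the train), sampled on a grid that is
uniform (10 ms) over a 5 s pre-onset window and log-spaced (600 points,
5 ms–60 s) after offset so every decade carries equal weight. No kernel
smoothing — the log-Gaussian fit is the smoother.

**Fitting.** `fit_log_gaussian()` has two modes. On smooth traces it is
bounded nonlinear least squares on the log-spaced samples
($\sigma \in [0.1, 5]$, $\mu \in [\ln 5\,\mathrm{ms}, \ln 60\,\mathrm{s}]$,
multi-start). On spike trains it switches to a count-based fit: the
pointwise reciprocal-ISI estimator has *infinite variance* (the interval
covering a fixed time is length-biased, so $E[1/\mathrm{ISI}^2]$
diverges), which makes plain least squares on a fine grid unstable at 3–5
trials. Spike counts in 80 log-spaced bins are well behaved, so the fit
minimizes their Poisson deviance — equivalently, iteratively reweighted
(inverse-variance) least squares — against the model
$b + A e^{-((\ln t - \mu)/\sigma)^2}$ with three numerical refinements:
the absolute refractory dead-time enters the forward model
($r \mapsto r/(1+r\tau_{ref})$, which otherwise compresses a 200 Hz peak
to 143 Hz and inflates the fitted width), expected counts integrate the
model over each bin (Simpson's rule), and the fitted baseline $b$ is
bounded within 20% of the precisely measured pre-onset baseline (removing
a wide-width/low-baseline degeneracy). Parameter standard errors come from
the deviance curvature.

**Pauses and censoring.** The pause is the mean first post-offset spike
latency minus the baseline mean ISI, floored at zero; trials without a
post-offset spike are censored at the recording end and counted. For cells
with a detected pause (≥ 3 baseline ISIs), samples below 1.75× the pause
are censored from the fit — the observed rate there is floored at zero by
mGluR2/3 suppression while the model describes the mGluR1 component — and
$\mu$ is bounded below by the censoring point, since with the left flank
removed an extrapolated below-window peak is a degenerate solution. Fits
narrower than three count bins are flagged unresolved: they are single
noise bumps, not temporal responses.

**Width pooling.** The model holds that all cells share a common log-time
width up to small variation, while five-trial width estimates carry large
sampling error; because the half-width/peak-time ratio
$2\sinh(\sigma\sqrt{\ln2})$ is convex, unpooled width noise would bias the
population mean ratio upward. The pipeline therefore applies
DerSimonian–Laird random-effects shrinkage (`pool_log_widths()`): the
between-cell variance is estimated from the per-cell estimates and their
Fisher standard errors, and each width is shrunk toward a 10%-trimmed
unweighted mean. The target is unweighted because the standard error
scales with the fitted width, so precision weighting would overweight
cells that underestimate it. Width-derived features are recomputed from
the pooled widths; `pool_widths = FALSE` disables this.

**Classification.** Excitation requires a fitted amplitude of at least
max(5 Hz, 0.2 × baseline) from a trustworthy fit (resolved width, and
$A > 2\,\mathrm{SE}_A$); a pause requires at least 3 baseline ISIs. Both →
biphasic, excitation only → excited, pause only → suppressed, neither →
unresponsive.

## Population statistics

Excited and biphasic cells are sorted by half-decay (ties by peak time,
then id) and normalized by peak rate; suppressed cells are appended sorted
by pause and normalized by baseline. Rank regressions report slope,
intercept and $R^2_{adj}$ (computed with the stated formula; $p$ = 1) for
log10 peak time, half-width and pause, and for the raw ratio and width.
The amplitude decline is fitted with the inverted soft-plus
$a - \ln(1+e^{x/b})$. The population amplitude is the L2 norm of the
population rate vector normalized by $1/\sqrt N$ (the RMS rate across
cells), and its post-offset tail (0.1–30 s by default) is fitted jointly
across stimulus counts with the shifted power law
$C n (t + t_{min} n^{\beta})^{\alpha}$, in log-log space, with a
cell-resampling bootstrap CI for the critical exponent $\alpha$. Under
exact spike-count conservation without saturation the analytic limit is
$\alpha = -1$ (the integral of squared log-Gaussians against $A \propto
1/t_{pk}$ scales as $1/t^2$ inside the continuum, so the L2 norm scales as
$1/t$); the saturating amplitude law steepens it, the direction in which
the recorded population's −1.47 lies.

## The expression module

Synthetic counts are Poisson with log-mean $b_g + w_g f_c$: $f_c \sim
U(0,1)$ is the latent gradient, group-1 mGluR-pathway genes have $w = +2$,
group-2 genes $w = -2$, ionotropic and null genes $w = 0$ (uniform AMPAR
expression). NNMF uses classical multiplicative updates on $\log(1+x)$
counts (the pseudocount keeps zero counts finite and non-negative), rank 3,
seeded non-negative initialization, stopping at $10^{-6}$ relative
improvement or 500 iterations, with the objective asserted non-increasing.
The gradient factor is selected by marker correlation (the criterion the
source analysis leaves unstated) and sign-canonicalized so positive markers
load positively; genes are ordered by Pearson correlation with the
loadings and the top 1% by |r| flagged.

## What the generator does and does not emulate

It reproduces the population's *statistical* structure: composition,
log-uniform multi-scale timing, constant log-width, amplitude–duration
tradeoff, pause–speed coupling, current-outlasts-rate factor, and the 91/9
metabotropic/ionotropic charge split. It does **not** simulate receptor
kinetics mechanistically (no G-protein cascade ODEs — DGK inhibition is a
phenomenological width knob), has no short-term plasticity (bursts sum
linearly, consistent with profiles independent of stimulus number), uses
Poisson spiking (real UBC trains are more regular, so real data would be
*less* noisy than these tests), and draws biphasic pauses deterministically
coupled to peak time rather than from the measured pause scatter. Passing
tests therefore certify the analysis pipeline against a faithful
statistical surrogate, not against biological recordings.

## Problem sizes

The test suite and acceptance script use the full 84-cell population with
5 trials per cell (one simulation ≈ 20 s), 6 cells for the charge
bookkeeping, 300-cell noiseless populations for the power-law properties,
and 300 genes × 200 cells over several seeds for the NNMF recovery — sizes
chosen so the statistical assertions are well powered while the whole
suite runs in about a minute.

## Known limitations

* Width estimates for the weakest slow biphasic cells (amplitude ≈ 6–10 Hz
  on a 10–20 Hz baseline) are information-limited at five trials; the
  random-effects pooling handles this honestly but per-cell widths there
  should not be over-interpreted.
* The latency-based pause cannot resolve pauses shorter than about one
  baseline ISI; measured sub-10 ms pauses in real data are best read as a
  noise floor.
* The shifted power-law exponent depends on the fitted tail window when the
  continuum is truncated; the window is exposed in the fitting interface.
* `adjusted_r2` for the count-mode fit is computed on binned rates and is
  descriptive, not the fit's objective.
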