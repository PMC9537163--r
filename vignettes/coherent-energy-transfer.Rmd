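---
title: "Modeling time-resolved coherent energy transfer between mid-IR fields and solvated molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling time-resolved coherent energy transfer between mid-IR fields and solvated molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetscope)
```

## The physical picture

A broadband mid-infrared pulse transmitted through a thin cuvette of a
dilute molecular solution exchanges energy with the vibrational modes of
the solute. In a field-resolved (electro-optic-sampling-style) measurement
both the reference field $E_{ref}(t)$ and the transmitted field
$E_{sam}(t)$ are known with sub-cycle resolution, so the energy exchange
can be followed in time rather than only integrated over the pulse. The
central quantity is the coherent energy transfer

$$\mathrm{CET}(t) = \int_{t_0}^{t}\left[I^{inst}_{ref}(t') -
I^{inst}_{sam}(t')\right]\,dt', \qquad
I^{inst}(t) = c\,\varepsilon_0\,E(t)^2 ,$$

the running integral of the instantaneous-intensity difference. Its
maximum is the transiently absorbed energy per area; its asymptotic end
value is the energy dissipated in the sample (equal, by Parseval's
theorem, to the integrated energy-spectral-density deficit that a
frequency-domain spectrometer would report); and the difference between
maximum and end value is the energy the ringing molecular polarization
coherently re-emits after (or during) the excitation — the free-induction
decay.

For a pulse much shorter than the dephasing time, absorption and coherent
re-emission separate cleanly in time (few-cycle excitation, FCE). A
chirped pulse (CPE) stretched beyond the dephasing time instead overlaps
with the molecular ringing, and the swept instantaneous frequency beats
against the resonantly oscillating polarization, producing alternating
absorption/emission episodes — coherent transients — plus a step-like
sub-cycle structure in which each half-cycle of the field exchanges a
single-signed parcel of energy.

## The linear-response model

Each vibrational mode $k$ is a homogeneously broadened Lorentz oscillator
with center frequency $\omega_k$, transition dipole $\mu_{0k}$ and
dephasing rate $\Gamma_k$. The susceptibility of the solution with number
density $N = \beta N_A / M$ is

$$\chi^{(1)}(\omega) = \sum_k \frac{2}{3}\,
\frac{\beta}{m\,\hbar\,\varepsilon_0}\,
\frac{\mu_{0k}^2\,\omega_k}{\omega_k^2 - (\omega - i\Gamma_k)^2},$$

where $\beta/m = N$ and the factor $2/3$ is the isotropic orientational
average $\langle\cos^2\theta\rangle = 1/3$ applied to the two
(co- and counter-rotating) poles. `susceptibility()` evaluates this sum;
`transfer_function()` turns it into the propagation factor
$H(\omega) = \exp[-i(n-1)\,\omega L/c]$, $n = \sqrt{1+\chi}$, of the
solute layer (the solvent background is part of the reference waveform by
construction), and `propagate()` applies it by FFT.

In the time domain the same physics is first-order perturbation theory:
each mode acquires a coherence

$$\rho_{0k}(t) = \frac{i}{\hbar}\,\mu_{0k}\int_0^\infty
E(t-t_1)\,e^{-i\omega_k t_1} e^{-\Gamma_k t_1}\,dt_1,$$

which drives a macroscopic polarization
$P(t) = \sum_k \tfrac{2}{3} N \mu_{0k}\,\mathrm{Re}\,\rho_{0k}(t)
= F^{-1}\{\varepsilon_0\chi^{(1)}(\omega)E(\omega)\}$. The identity of
the two routes is exercised as a standing internal cross-check
(`polarization(..., verify = TRUE)`, tolerance 0.5% RMS). The
rotating-wave approximation drops the terms oscillating at the *sum* of
field and vibrational frequencies; `coherence_trajectory(rwa = TRUE)`
implements it by replacing the real field with its co-rotating
analytic-signal half (factor ½ retained, so resonant driving is
identical). Removing the RWA reveals one cycloid bump of the
rotating-frame coherence per field half-cycle — the microscopic
counterpart of the CET steps.

### Conventions (fixed package-wide)

* **Fourier sign.** The forward transform kernel is $e^{-i\omega t}$
  (`stats::fft`). Under this convention the susceptibility written with
  the $(\omega - i\Gamma)$ pole has $\mathrm{Im}\,\chi < 0$ at resonance,
  which *is* the absorbing sign, and the coherence kernel carries
  $e^{-i\omega_k t_1}$. The physical contract is convention-free and is
  what the tests pin down: transmission $\le 1$ at resonance, causal
  impulse response, and positive dissipated energy. With the opposite
  transform convention the conjugate expressions would be required; only
  the relative sign between the transform and the pole matters.
* **Linewidth.** A Lorentzian FWHM of $\tilde\nu$ cm⁻¹ corresponds to
  $\Gamma = \pi c \tilde\nu$; the coherence amplitude decays as
  $e^{-\Gamma t}$. The study's typical 19.4 cm⁻¹ gives
  $\Gamma^{-1} = 547$ fs. All conversions live in one place
  (`fwhm_to_gamma()` and friends).
* **Absorbance.** Amplitude-logarithm convention,
  $A = \log_{10}|E_{ref}(\omega)| - \log_{10}|E_{sam}(\omega)|$. The
  Lorentzian fitter follows the same convention (an intensity-convention
  switch is provided, since fitted literature values may use either; it
  simply doubles the model).

## Impulsive-regime closed forms

For a Dirac-delta excitation of area $A$ the CET bookkeeping collapses to
three one-sided frequency integrals over the transfer function,

$$W_{max} = \frac{c\varepsilon_0 A^2}{\pi}\int 2\,(1-\mathrm{Re}\,H)\,
d\omega,\quad
W_{re} = \frac{c\varepsilon_0 A^2}{\pi}\int |H-1|^2\, d\omega,\quad
W_{end} = \frac{c\varepsilon_0 A^2}{\pi}\int (1-|H|^2)\, d\omega,$$

with $W_{max} = W_{end} + W_{re}$ identically (the cross-work at the
impulse takes the half-value of the jump of the re-radiated field — the
same half that makes the deposited energy equal the quantum tally
$\sum_k \tfrac13 N L\,\hbar\omega_k\,|\mu_{0k}A/\hbar|^2$). In the
thin-sample, narrow-line limit the integrals reduce to the analytic
expressions implemented in `impulsive_budget(closed_form = TRUE)`,
including the mode cross terms of the free-decay emission; the analytic
and quadrature routes agree to better than 0.5% and serve as each other's
oracle. The default uses the exact exponential slab, consistent with the
default propagation — at 10 mg/ml and 30 µm the strongest band reaches a
peak absorbance near 0.5 (intensity), where reabsorption of the
free-induction field inside the layer is no longer negligible and the
strict thin-sample form overestimates the re-emitted fraction by roughly
one part in eight.

A finite pulse enters the impulsive model through its energy spectral
density: each mode is kicked in proportion to $|E(\omega_k)|$, so the
delta-limit integrals are weighted by the pulse's own ESD and normalized
by its own fluence. This is the only reading under which "deviation from
the impulsive values" is meaningful for ratios taken against the pulse
energy: at fixed fluence the resonant spectral density — and with it both
energy fractions — vanishes linearly as $\tau \to 0$, so the comparison
must be made against the impulsive prediction *for the same pulse*.
`duration_scan()` reports exactly that deviation; it vanishes in the
short-pulse limit and reaches ≈30% when the duration is one tenth of the
dephasing time, with the re-emitted fraction the more sensitive of the
two ratios.

### Thin-sample energy tally

`cet_coherence_check()` reconstructs CET(t) microscopically as the energy
currently stored in the coherences plus the energy already dissipated,

$$\mathrm{CET}(t) \approx \sum_k w_k\left[|\rho_{0k}(t)|^2 +
2\Gamma_k \int_{-\infty}^{t} |\rho_{0k}|^2\, dt'\right],\qquad
w_k = \tfrac13\, N L\, \hbar \omega_k ,$$

per unit area. The weight follows from the same $1/3$ orientational
average that builds the susceptibility — the $2/3$ prefactor of
$\chi$ belongs to the polarization, not to the energy per coherence
quantum — and is validated against the propagation pipeline in the test
suite rather than assumed. Without the dissipation integral the identity
would hold only while $t \ll \Gamma^{-1}$; with it, the residual is below
2% for thin samples and grows with absorbance, as the statement is
genuinely a thin-sample one.

## Parameters and presets

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| mode centers / dipoles | four printed parameter sets (`sample_preset()`) | cm⁻¹, D | fitted values and three solvation treatments for the two SO₂ stretching modes of DMSO₂ |
| linewidth | 19.4 (both modes) | cm⁻¹ FWHM | the study's typical homogeneous width; per-mode values are not published |
| concentration, path | 10 mg/ml, 30 µm | — | stated sample cell |
| molar mass | 94.13 | g/mol | DMSO₂, standard atomic masses |
| pulse duration | 62.5 (FCE preset), 30 (model-absorber preset) | fs, intensity FWHM | stated durations; "duration" read as intensity-envelope FWHM (standard ultrafast usage) |
| pulse center | 1260 | cm⁻¹ | midpoint of the stated 850–1670 cm⁻¹ coverage; the experimental spectral shape is unpublished |
| CEP | 0 | rad | waveform-stable but unstated |
| CPE chirp | −13500 | fs² | stretches 62.5 fs to ≈600 fs ≳ Γ⁻¹, the regime in which coherent transients appear; the dispersion actually applied by the 5-mm CaF₂ substrate to the super-octave pulse is not stated, so the chirp is modeled as a Taylor spectral phase with a documented preset value rather than by ray tracing |
| model-absorber dipole | 0.33 | D | the single-mode absorber's line strength is unprinted; the explicit-solvation symmetric-stretch value is used |
| grid | −2 ps … +6 ps, 0.5 fs | — | ≥12 samples per cycle at 1670 cm⁻¹ (sub-cycle analysis) and >10 Γ⁻¹ of post-pulse decay (CET convergence); FFTs are zero-padded to ≥2× with 5-smooth lengths |

## What the synthetic data emulate — and what they do not

The generator produces waveform-stable Gaussian (optionally chirped)
fields plus measurement-like trace ensembles: additive white field noise
and per-trace field-scale jitter (pulse energy jitter ≈ twice the field
jitter), reproducible from a seed. The trace-normalization stage rescales
each trace on the 984–1051 cm⁻¹ band, where no significant molecular
resonances are expected, and the error corridor propagates the field
standard errors through the CET integral in first order — mirroring the
protocol of three repeats of twenty averaged scans.

What is *not* emulated: the true super-octave spectral shape of the
experimental waveform (a transform-limited Gaussian of the same duration
is far narrower), the detector gating response, phase-matching, or the
water-vapor background. Consequently, passing tests demonstrate the
correctness of the response model and of the energy bookkeeping — not
that a Gaussian surrogate reproduces every measured number (see
Limitations).

## Numerical choices

* Cumulative trapezoid on the shared grid for CET; inputs are never
  resampled, so sub-cycle structure is preserved.
* The coherence convolution kernel is sampled with a half-weight at
  $t_1 = 0$ (trapezoid end correction) and truncated where
  $e^{-\Gamma t} < 10^{-8}$; near the kernel pole the discrete transfer
  function deviates from the analytic one only at $O((\Gamma\,dt)^2)$,
  which keeps the dual-route polarization agreement well inside 0.5% at
  $dt = 0.5$ fs.
* The impulsive-budget quadrature uses a composite frequency grid: a
  1 cm⁻¹ global grid to 20000 cm⁻¹ plus windows of ±50 FWHM at FWHM/100
  around each line (Lorentzian tails are fat; the windows alone would
  miss ~1% of the line integral).
* Peak picking for fit initialization: local maxima above 3× the median
  absolute deviation, seeded in descending height, widths at 20 cm⁻¹;
  per-mode widths float independently (whether the published fits shared
  a width is unstated).
* Degenerate inputs are errors, not guesses: zero-amplitude spectra,
  non-uniform grids, chirps that overflow the window, boxes that leak
  eigenfunctions, bands outside the spectral support.
* The sub-cycle step detector ignores half-cycles whose CET increment is
  below $10^{-4}$ of the CET maximum. During an FCE absorption phase
  essentially all half-cycles are monotone; during a chirped passage the
  quadrature (reactive) episodes legitimately are not, and only the
  dominant steps are.

## Design decisions that were genuinely open

* **Exact slab vs thin sample.** Both are implemented; the exact
  exponential is the default everywhere (including the impulsive budget)
  because the sample is thin but not infinitesimally so. The thin-sample
  closed forms are kept as oracles and for the dilute scans.
* **Impulsive reference for finite pulses.** Weighted by the pulse ESD
  and fluence, as derived above. The alternative — fixed delta-pulse
  numbers — makes the duration-scan comparison ill-defined at fixed
  fluence.
* **Energy weight $w_k$.** Derived as $\tfrac13 N L \hbar\omega_k$ and
  validated numerically; a $2/3$ prefactor here would double-count the
  orientational average already spent in $\chi$.
* **Coherent-transient marking.** CET maxima lag the corresponding
  $|\rho|^2$ maxima by the dissipation tally (CET is flat where
  $d|\rho|^2/dt = -2\Gamma|\rho|^2$, i.e. slightly *after* the coherence
  peak); the association test therefore uses a tolerance of a fraction of
  the transient beat period rather than a few fs.

## Limitations

* With the documented study conditions — a transform-limited 62.5 fs
  Gaussian and 19.4 cm⁻¹ for both modes — the simulated FCE budget puts
  the re-emitted fraction of the impinging energy at ≈0.44% (measured:
  0.4%), but the re-emitted fraction of the maximum absorbed energy at
  ≈6.7%, below the measured 11%. The model's own impulsive ceiling for
  the fitted parameters is ≈9% (computed by `impulsive_budget()`), and a
  62.5 fs pulse sits ≈30% below its impulsive value, so no Gaussian
  surrogate reaches the measured ratio: that number reflects the
  unpublished near-impulsive structure of the real super-octave waveform
  and the unpublished per-mode fitted linewidths (the ceiling scales as
  $1/\Gamma$). The acceptance script reports the simulated value as is.
* The delta-limit oracle equivalence is exact only in the limit: at 1 fs
  the global CET maximum still rides on the physical sub-cycle absorption
  steps, an $O(\tau/T_k)$ overshoot (≈2% on the re-emitted/max ratio at
  1 fs, <1% at 0.25 fs, linear in $\tau$).
* First order only: no Rabi cycling, no $T_1$ relaxation distinct from
  dephasing, no inhomogeneous (Voigt) broadening, no nonlinear
  susceptibility — all negligible at the sub-$10^{-3}$ excited-state
  populations of the studied field strengths.
* The eigensolver is one-dimensional (one normal coordinate per
  problem); mode-pair coupling surfaces are out of scope.

## Problem sizes

The default pipeline uses 16001 samples (0.5 fs over 8 ps) and runs in
well under a second; the full test suite — including the 13-point
duration scan, a 10000-trace ensemble statistic and the eigensolver
oracles — completes in a few seconds. These sizes were chosen so that
every reported quantity is converged (halving $dt$ or extending the
window changes the energy ratios by less than $10^{-3}$ relative), not to
economize.
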