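---
title: "Simulating and reconstructing compressed-sensing accelerated single-shot FSE"
author: "ssfseSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing compressed-sensing accelerated single-shot FSE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfseSim)
```

## The problem

Single-shot fast spin-echo (SSFSE) acquires all phase-encode lines of a
T2-weighted slice in one echo train after a single excitation, which makes it
robust to respiratory and bowel motion — but the long train suffers T2 decay
along the way (phase-encode blurring and signal loss), and the sequential
acquisition caps how much the train can be shortened. Compressed sensing (CS)
shortens the train by undersampling phase encodes with a variable-density
random pattern and recovering the image by sparsity-regularized inversion.
This package is a desk-scale simulator and reconstruction library for that
acquisition chain: digital phantoms with known tissue maps, multi-coil
Cartesian k-space simulation with per-echo T2 decay and complex Gaussian
noise, the CS solver and the two conventional baselines (homodyne
partial-Fourier synthesis and the coil-combined zero-filled adjoint), plus the
ordinal reader-study statistics such protocols are judged by clinically.

## Reconstruction model

The CS reconstruction solves

$$ \hat I = \arg\min_I \tfrac12 \lVert A I - D \rVert_2^2
   + \lambda \lVert W I \rVert_1, $$

where $D$ is the acquired multi-coil k-space, $W$ is the orthonormal
multilevel Haar wavelet transform, and the system operator
$A = M \circ F \circ S$ is coil-sensitivity multiplication $S$, the centered
unitary 2D Fourier transform $F$, and phase-encode masking $M$. Coil maps are
estimated from a separate fully sampled calibration (reference) scan of 24
center lines, acquired as a second echo train.

Because the FFT is unitary, the maps are RSS-normalized and masking is an
orthogonal projection, the operator norm of $A$ is at most 1, which fixes the
gradient step at $1/L$ with $L = \lambda_{\max}(A^H A)$ estimated by power
iteration. Because $W$ is orthonormal, the proximal map of the penalty is
exact — soft-threshold in the coefficient domain, transform back — so plain
proximal-gradient iteration applies with no inner loops. Two solvers are
provided: ISTA (monotone for steps up to $1/L$) and the default FISTA with a
function-value restart, which re-starts the momentum whenever a step would
increase the objective, so the recorded objective trace is non-increasing by
construction. The best (lowest-objective) iterate is returned together with
the trace.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `lam` | auto | penalty weight $\lambda$; auto = `max(1e-3 * max|A^H D|, 2 * sigma * sqrt(m/nPE))` |
| `nIter` | 100 | iteration cap |
| `tol` | 1e-5 | relative iterate change at which to stop |
| `step` | auto | gradient step, auto = $1/L$ by power iteration |
| `levels` | 3 | Haar decomposition depth |

The automatic $\lambda$ combines a data-scaled floor (`1e-3 * max|A^H D|`,
which transfers across image scales and keeps near-noiseless problems
essentially unregularized, so exact-recovery limits hold) with a
noise-proportional term: under the adjoint, i.i.d. complex k-space noise of
per-component standard deviation $\sigma$ becomes image-domain noise of
standard deviation $\sigma\sqrt{m/n_{PE}}$ ($m$ sampled of $n_{PE}$ lines),
and the per-iteration soft threshold should sit a small factor above that
level for the penalty to actually denoise. A fixed data-scaled fraction alone
under-regularizes noisy data: the solver then converges toward a
noise-fitting least-squares solution and loses to the zero-filled baseline.

## Acquisition model

Each sampled line $j$, acquired at echo index $e(j)$ under the chosen
ordering, is the matching row of the unitary 2D FFT of

$$ S_c \cdot \rho \cdot e^{-\mathrm{TE}_{\mathrm{eff}}(j)/T_2}\cdot e^{i\varphi},
\qquad \mathrm{TE}_{\mathrm{eff}}(j) = \mathrm{TE} + (e(j) - e_\mathrm{ctr})\,
\mathrm{esp}, $$

with the center-most sampled line pinned to the protocol's nominal TE; i.i.d.
complex Gaussian noise (standard deviation `noiseSigma` per real/imaginary
component, identical across coils) is added to every sampled entry. The
ground-truth image all metrics compare against is the static object at the
nominal TE, $\rho\, e^{-\mathrm{TE}/T_2} e^{i\varphi}$, so the acquisition's
line-to-line decay modulation is exactly the T2-blurring mechanism of long
trains.

Two orderings are offered. `linear` (bottom-to-top) is the default; with the
default echo spacing of 3 ms the nominal TE of 99 ms equals the 33rd echo, so
a 6/8 partial-Fourier train reaches its center line with all effective echo
times positive. `center_out` starts the train at the center line
(`TE_eff >= TE` everywhere) and is what the bundled experiment uses for its
fully sampled arm, whose 128-echo train would otherwise extend to negative
effective echo times under linear ordering. Echo spacing, TE/TR, matrix,
acceleration, partial-Fourier factor, calibration-line count, slice count and
slice increment are carried by `ProtocolParams`; `protocolPreset()` provides
the six sequence/scanner cards of the emulated study design, and
`echoTrainLength()` implements the single-shot budget
`floor(matrixPE / acceleration)` (84 lines at 253/3; 125 at 250/2; 128 at
256/2). Multishot TSE is represented by its protocol record only — its
segmented acquisition is out of scope and `echoTrainLength()` refuses it.

### Sampling patterns

* **Variable density** (`buildVDMask`): exactly `budget` lines; a fully
  sampled contiguous center block of `round(centerFraction * budget)` lines
  (default 24/84, so the imaging scan covers the usual calibration region),
  with the rest drawn without replacement under a density that falls off
  linearly from center to edge; `accelIncrement` sets the slope, since only
  the existence of such an increment — not its functional form or value — is
  part of the emulated protocol. Deterministic given a seed.
* **Uniform** (`buildUniformMask`): every `r`-th line — parallel-imaging
  (GRAPPA-style) geometry only; its baseline reconstruction here is the
  coil-combined zero-filled adjoint, not kernel interpolation.
* **Partial Fourier** (`buildPFMask`): `ceiling(fraction * nPE)` contiguous
  lines, one full half plus the symmetric margin, center line always
  retained; 6/8 = 75% coverage is the usual single-shot choice.

### Slice ordering

`sliceOrder()` visits slices in strides of the protocol's slice increment
(four for the CS protocol versus two conventionally), separating temporally
adjacent slices to reduce crosstalk and magnetization-transfer effects at
short TR.

## Homodyne partial-Fourier reconstruction

The conventional SSFSE baseline acquires 75% of k-space and synthesizes the
rest from conjugate symmetry. The implementation coil-combines first
(conjugate-map-weighted zero-filled adjoint), re-transforms the combined
image to a single virtual k-space, and then applies standard homodyne there:
a pre-weight that is 0 on unacquired lines, a linear ramp from 0 to 2 across
the symmetric band (1 at DC, antisymmetric about it, so conjugate pairs
always sum to weight 2, the self-conjugate Nyquist line on even grids getting
weight 1), and 2 where only one conjugate copy exists; phase correction with
the low-resolution phase from the symmetric center band under a cosine taper
that is symmetric about the DC line; then real-part projection with negatives
clipped. Two choices matter for correctness and are easy to get subtly wrong:
demodulating the coil phase *before* the asymmetric weighting, and using
*conjugate-symmetric* tapers — both are required for the method to be exact
on zero-phase objects with full data, which the tests verify at 1e-8. The
phase estimate is applied only where the low-resolution magnitude exceeds
1e-6 of its peak; at numerically-zero pixels an arbitrary phase would
otherwise leak the antisymmetric ramp component into the output. Homodyne
assumes slowly varying object phase; the phantom's polynomial phase map with
adjustable amplitude exists precisely to probe that assumption.

## What the phantom emulates — and what it does not

`makePhantom()` composes an abdominal-like slice from ellipses: a body, a
large parenchymal (liver-like) organ, a secondary organ, a native bright
fluid structure, and non-overlapping focal lesions inside the parenchyma —
fluid (cyst-like) lesions with T2 of 500–1200 ms and solid lesions at
60–120 ms against 40–60 ms parenchyma, the contrast regime in which
T2-weighted single-shot imaging is read. Proton density is piecewise
constant per tissue with a smooth multiplicative texture; the phase map is a
low-order polynomial. Coil sensitivities (`simulateCoils`) are Gaussian
profiles centered on a ring of coils with smooth polynomial phases,
RSS-normalized to exactly 1. Defaults: 128 x 128 grid, 1.5 mm pixels, 8
coils, complex noise sigma 0.02 (image-domain SNR of roughly 10–70 across
tissues at the default geometry).

This is deliberately *not* an anatomical atlas: there is no respiratory or
cardiac motion, no flow or chemical shift, no B0/B1 inhomogeneity, no coil
noise correlation, and tissue boundaries are geometric. Passing tests
therefore certify the reconstruction and statistics machinery — operator
identities, solver convergence, method orderings under controlled
degradation — not clinical image quality; the subjective reading scores of an
actual patient study depend on artifact phenomenology this generator does not
model, which is also why the ratings workflow ships with its own synthetic
ordinal-score generator rather than a claim to reproduce reader scores.

## Reader-study statistics

Scores live on the five-point scale (1 unacceptable … 5 excellent); a case is
*insufficient* when rated 1 or 2, and `insufficientRate()` reports the count
and one-decimal percentage. `descriptiveStats()` gives mean with sample
(n-1) SD, median, inclusive-interpolation quartiles and range.
`wilcoxonSignedRank()` is built for heavily tied ordinal data: midranks,
Pratt zero handling by default (zeros ranked, then dropped; `wilcox` mode
discards zeros first), an exact mode that enumerates the null distribution of
the positive-rank sum over all $2^m$ sign assignments via its generating
polynomial (used automatically up to 25 nonzero differences), and a normal
approximation with tie correction, Pratt zero correction and continuity
correction above that. `compareSequences()` runs the three pairwise tests of
the three-sequence design on complete pairs, declares significance on the raw
p at the configured threshold (default 0.025, the convention of this design),
and reports Bonferroni-adjusted p-values for the three-test family alongside
— the threshold is exposed as a parameter because fixing 0.025 while
reporting three comparisons per criterion is a convention, not something the
package can derive.

## Numerical choices

* k-space convention: DC at index `floor(n/2) + 1` (1-based), unitary FFT
  everywhere; one convention for all adjoint and Parseval identities.
* Haar with periodic boundary and orthonormal scaling; images whose sides are
  not divisible by `2^levels` are zero-padded for the transform and cropped
  back (the prox is then applied in the padded domain — exact for divisible
  shapes, a standard approximation otherwise; all shipped geometries are
  divisible).
* Coil-map support threshold: 5% of the peak RSS magnitude of the
  low-resolution calibration images, avoiding division blow-up outside the
  object; maps are 0 outside the support.
* Complex images are reconstructed throughout; magnitude is taken only at
  metric and export time, and reported metrics rescale the test image to the
  reference l2 norm because reconstruction arms differ by global scale.
* Ties in `softThreshold` at exactly zero magnitude shrink to zero; the
  complex prox shrinks magnitude and preserves phase.
* All stochastic stages accept a seed and restore the caller's RNG state;
  `runExperiment()` derives all stage seeds deterministically from one
  experiment seed (`(seed * 1009 + stage * 9973) mod 2^31-1`).

## Problem sizes

The bundled experiment and the test suite run the study geometry scaled to a
128-line phase-encode axis (echo-train budget 42–43 of 128 at acceleration 3,
24 calibration lines, 6/8 partial Fourier, uniform R = 2, 8 coils), which
preserves every ratio of the full 253-line protocol while keeping a complete
simulate-reconstruct-evaluate cycle in seconds; protocol arithmetic itself
(echo-train lengths, mask counts, acceleration ratios) is checked at the
native 253/250/256-line sizes. The small convex-solver certification runs a
16 x 16 problem against a 1e5-iteration small-step reference solve of the
same objective; the power analysis of the sequence comparison uses 200
replicates of 101 cases.

## Known limitations

* No GRAPPA/ESPIRiT calibration, non-Cartesian or wave trajectories, or
  learned regularizers; the uniform arm is geometry-only.
* No variable refocusing flip angles; the flip angle is carried in the
  protocol record but does not enter the signal model.
* The per-echo decay model treats each line's modulation as purely
  exponential in effective TE with a global pin at the center line; stimulated
  echoes, fat suppression and relaxation during refocusing are not modeled.
* Scan-time arithmetic is not computed: acquisition clock time depends on
  scanner scheduling (pauses, SAR limits) that a desk model cannot derive
  from TR and slice count alone.
* Metrics are full-reference and magnitude-based; they are quantitative
  surrogates for — not predictors of — subjective reading criteria.
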