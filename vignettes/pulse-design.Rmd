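---
title: "Joint pTx RF and gradient pulse design: models, cost, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint pTx RF and gradient pulse design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ptxpulse)
```

## The problem

At ultra-high field (7 T and above) the transmit RF field of a head coil is
strongly inhomogeneous: a circularly-polarised (CP) drive produces flip
angles that vary severalfold across the brain. Parallel transmission (pTx)
drives each coil element with its own complex voltage waveform, and playing
a gradient waveform during excitation adds spatial encoding, so that the
achieved flip-angle (FA) pattern can be shaped. `ptxpulse` designs such
pulses by descending, with an adaptive gradient method, through a
differentiable simulation of the excitation: every RF sample of every
channel and every sample of the three gradient axes is a free parameter.

## Forward models

**Bloch model.** Magnetization evolves in the rotating frame as
$\dot{\vec M} = \gamma \,\vec M \times \vec B(t)$ plus relaxation, with the
effective field per voxel
$\vec B = (\mathrm{Re}\,S,\ \mathrm{Im}\,S,\ \vec g \cdot \vec r + 2\pi b_0/\gamma)$,
where $S = \sum_c B_{1,c}^+(\vec r)\, p_c(t)$ is the sensitivity-weighted
channel sum (B1+ maps in nT/V, RF in V), $\vec g$ the gradient vector in
T/m and $b_0$ the off-resonance in Hz. The integrator applies one exact
axis–angle rotation per raster step (hard-pulse approximation), which is
unconditionally norm-preserving; T1/T2 relaxation, when enabled, is applied
as a separable exponential decay/regrowth per step. Relaxation is disabled
during design — pulses here are two orders of magnitude shorter than
tissue relaxation times.

**Small-tip-angle (STA) model.** Linearising around $M_z \approx M_0$
makes the transverse magnetization linear in the RF, $\vec m = A\vec b$,
with the spatial-domain system matrix element for voxel $\vec r$, channel
$c$, sample $t$:
$$A_{\vec r,(c,t)} = i\gamma\, B^+_{1,c}(\vec r)\,\Delta t\,
\exp\!\big(i[\vec k(t)\cdot\vec r + 2\pi b_0 (t - T)]\big),\qquad
\vec k(t) = -\gamma \int_t^T \vec g(s)\,ds,$$
so the phase reference sits at the pulse end and $\vec k(T)=0$. The matrix
is reassembled from the current gradients on every evaluation, which keeps
the model differentiable in the gradient waveforms.

**Sign conventions.** Both models use the same rotating-frame convention:
positive $B_z$ (positive off-resonance) precesses the transverse
magnetization clockwise, i.e. its phase decreases at $\gamma B_z$. This is
the convention under which the STA phase factor above is the first-order
limit of the Bloch model, so the two agree including phase. The gyromagnetic
ratio is fixed at $\gamma = 267.522\times 10^6$ rad/s/T.

On representative 10° pulses the two models agree to an FA NRMSE well below
2 %; pulses with strong, high-voltage sub-pulse structure (e.g. fresh
kT-point seeds) can reach a few percent because transient rotations are no
longer small — the Bloch refinement phase exists for exactly this regime.

## The design cost

The cost is a sum of eight terms. One science term:

* `pen_rmse` — root-mean-square deviation of the simulated FA map from the
  target, in **degrees**, averaged over subjects when several map sets are
  given (universal-pulse design).

Five hinge ("error") terms that are exactly zero while the pulse is
feasible and grow quadratically past the limit, with fixed weights that
make any violation dominate the cost: per-channel voltage
($\times 10^6$, limit 185 V), gradient magnitude ($\times 10^{15}$, limit
65 mT/m), slew rate ($\times 10^6$, limit 185 T/m/s, with the ramps from
and to the implicit zero before the first and after the last sample
included), non-zero first-plus-last gradient samples ($\times 10^6$ after
mT/m scaling), and maximum local SAR excess ($\times 10^2$ against the
VOP-predicted SAR time-averaged over the repetition time, default limit
2.3 W/kg at TR 19.7 ms). Two mild regularisers are always active: mean RF
power $\overline{(|p|\cdot 10^{-2})^2}$ and mean squared slew
$\overline{|\dot g|^2}\cdot 10^{-6}$.

The hinge terms reduce by a **sum** over violating samples so every
violating sample receives gradient; `options(ptxpulse.err_reduction =
"mean")` switches to a mean reduction. The FA deviation is taken in
degrees: at these weights a typical working point balances `pen_rmse` of a
few degrees against `pen_power` of order one.

The edge term penalises the *sum* of the first and last gradient samples,
which cannot see an equal-and-opposite pair; because the scanner constraint
is structural, the design recipes additionally keep those two samples
frozen at zero (`zero_edge_grad` in `design_problem()`), so converged
designs satisfy the constraint exactly rather than asymptotically.

## Optimization

Gradients of the full cost with respect to all parameters are computed by
hand-derived reverse-mode (adjoint) differentiation: through the STA model
via the linearity in RF and a right-aligned cumulative sum for the k-space
dependence on the gradients, and through the Bloch model by
backpropagating through the rotation chain using the closed-form derivative
of a rotation with respect to its rotation vector. Both are verified
against central finite differences in the test suite (relative agreement
better than $10^{-6}$ on small problems).

The descent is AdamW with learning rate $4\times10^{-4}$, momentum
constants 0.9/0.999, and decoupled weight decay 0 by default. Parameters
are normalised by their hardware limits (RF by the voltage limit,
gradients by the amplitude limit) so one learning rate is meaningful for
both groups; in these units the printed learning rate moves an RF sample by
at most ~0.07 V per iteration. Every `restart_period` (default 1000)
iterations the optimizer state is reinitialised and the parameters reload
from the best-cost pulse seen so far; the best pulse is also what is
returned, so the reported cost trace is non-increasing in its running
minimum.

**Initialisation.** The generic `optimize_pulse()` starts from a 1 V
complex-Gaussian RF with zero gradients when no pulse is supplied. The
non-selective recipe `design_small_fa()` instead warm-starts, by default,
from a coarse 3-kT-point solution: a random search over k-space position
pairs scored by magnitude-least-squares residual on a voxel subsample,
followed by a ridge-regularised variable-exchange solve whose ridge weight
is bisected so the seed stays just inside the voltage limit, assembled with
triangular blips and padded to the design duration. A cold start at this
learning rate spends its whole iteration budget rebuilding bulk amplitude;
seeding from the standard shim/kT-points operating point lets the free
optimization do the work it is actually for. `init = "cp"` (CP mode scaled
to the target mean FA) and `init = "random"` remain available.

**Recipes.**

* `design_small_fa()` — STA phase (default 7500 iterations) jointly over RF
  and gradients, then optional Bloch refinement (default 2500) from the STA
  result; a tailored single-subject pulse conventionally uses the STA phase
  only (2500 iterations). Because the STA is linear, the result can be
  rescaled to any smaller flip angle by scaling the voltage.
* `design_large_fa()` — designs at one tenth of the target FA under a
  tenfold-reduced voltage limit, scales the RF by 10, then refines with the
  Bloch model updating the RF only; no SAR term (preparation-pulse use).
* `design_slab()` — target pattern `fa` inside the slab and 0 outside,
  seeded from a CP-mode sinc (time-bandwidth product 8 by default) under a
  trapezoidal slice-selection gradient with a triangular refocusing lobe.
* `design_kt_pulse()` — the 3-kT-point benchmark: 5000 random position
  pairs by default within ±14 rad/m (the unit in which the system-matrix
  phase consumes k), scored at sub-pulse granularity, solved unregularised
  with 20 variable-exchange iterations, assembled as 3×130 µs rectangles
  with 60 µs gaps (510 µs total). No SAR constraint, matching common
  benchmark practice.

## The synthetic phantom

`synth_fieldmaps()` emulates the features of measured ultra-high-field
head data that the design code is sensitive to, without electromagnetic
simulation:

* an ellipsoidal "brain" mask with semi-axes 45 % of the grid extent;
* per-channel sensitivities from coil elements equally spaced in azimuth
  around the mask, alternating between two sub-rows (±15 % of the extent in
  z) as in dual-row 16-channel arrays — without the z-stagger all channels
  share one superior–inferior profile and FA homogenisation along z is
  impossible at feasible voltage, which misrepresents real arrays;
* Gaussian magnitude decay with distance from each element
  (σ = 22 % of the extent, near/centre ratio ≈ 15, loop-like), scaled so
  the CP-mode combination gives ≈ 25 nT/V at the centre;
* a propagation-like phase slope of 2.5 rad per extent plus a small smooth
  per-channel perturbation, anchored so that the CP-mode combination is
  provably non-zero everywhere inside the mask;
* a low-order polynomial B0 field scaled to a peak of `b0_range`
  (default 300 Hz, plausible at 9.4 T).

On 32³ maps these choices give a CP-mode FA error around 35 % NRMSE at a
10° target — comparable to measured-map CP behaviour at 9.4 T. What the
phantom does **not** reproduce: wavelength-scale interference nulls,
tissue-dependent amplitude structure, and the strong per-channel phase
diversity of real arrays (the CP-positivity guarantee bounds the phase
spread). Passing tests on the phantom therefore demonstrate correctness of
the machinery and realistic relative behaviour (free design ≪ CP; free
design better than kT points), not absolute error levels on in-vivo maps.

`synth_vops()` produces rank-2 Hermitian PSD matrices with largest
eigenvalue of order `scale` (default $10^{-3}$ W/kg/V², which puts the SAR
of a ~10° CP pulse at a TR of 19.7 ms near 1 W/kg, the scale reported for
comparable scanned protocols).

## Numerical choices and degenerate inputs

* Rotation angles below $10^{-14}$ rad fall back to the identity; the
  rotation-derivative formula switches to its small-angle limit below
  $10^{-8}$ rad.
* `pen_rmse` at exactly zero error has an undefined gradient; the adjoint
  returns zero there (a global minimum).
* Voxels with $|m_{xy}| = 0$ report phase 0 by convention, and the
  FA adjoint treats the non-differentiable point as having zero transverse
  gradient.
* The FA of the Bloch model is `atan2(|mxy|, mz)`; the STA reports `|mxy|`
  in radians (its `mz` is the equilibrium value by assumption). Near 90°
  these definitions diverge; comparisons between models are made on FA
  maps, where the difference is absorbed by the stated tolerances.
* Even grid axes have no centre voxel; coordinates place the origin midway
  between the two central voxels so k-space phases stay symmetric.
* Variable exchange is an alternating minimisation: its magnitude residual
  is non-increasing but the problem is non-convex; the returned weights
  depend on the (deterministic, seeded) start.
* The MAT-container layer supports uncompressed MATLAB v5 numeric, complex
  and logical arrays only; files from other writers are cross-checked in
  the tests against an independent reader/writer.

## Problem sizes used in the tests

The test-suite study runs 16 channels on 32³ maps (≈ 12 600 masked voxels)
with 500 STA iterations for the scaled-down design experiment and 2500 for
the converged tailored pulse, 208 VOPs, and 500 kT-point candidates;
smaller grids (3³–12³) back the unit and gradient-check tests. These sizes
were chosen so the whole suite exercises every code path at full fidelity
while completing in minutes on one core; the recipes' defaults
(7500 + 2500 iterations, 5000 candidates) reflect standard practice at
full scale.

## Known limitations

* No explicit Jacobians beyond the ones derived here; second-order methods
  are out of scope.
* The SAR model is the VOP upper bound; no global-SAR or field-level model.
* Universal-pulse aggregation is the unweighted mean of per-subject costs.
* The ini pulse dialect is this package's own documented text format;
  vendor formats need a converter.
* No GPU path: the hot loops are vectorised BLAS-backed R, adequate for the
  problem sizes above.
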