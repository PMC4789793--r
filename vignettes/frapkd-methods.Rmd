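---
title: "Models and methods behind frapkd"
author: "frapkd maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind frapkd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frapkd)
```

`frapkd` quantifies how secreted signalling proteins move through the
intercellular space (IS) of embryonic tissue, and what their mobility
implies about binding. The measurement it is built around is FRAP in a
*single* linear IS: a short stripe (typically `w = 7.5` µm) of the thin
fluid gap between two adjacent ectodermal cells is photobleached and the
return of fluorescence is recorded. Because the gap is effectively a
one-dimensional channel, recovery can be modelled in 1D, which avoids the
fractal-dimension ambiguities of conventional multi-cell square-region
FRAP and keeps acquisitions short.

This vignette explains the forward models, the numerical choices, and
what the synthetic-data generators do and do not emulate. Everything
quantitative stated here is recomputed by the test-suite or by
`scripts/acceptance.R`; the vignette itself asserts nothing the code does
not check.

## Free diffusion in a 1D gap

For a tracer that does not interact with the intercellular matrix, the
post-bleach concentration field is the heat-kernel evolution of a step
profile. Averaging the solution over the bleach stripe $[-w/2, w/2]$
gives the closed form used throughout
(`freeRecoveryCurve()`):

$$
I_N(t) = 1 - d \cdot B(a), \qquad
B(a) = \operatorname{erf}(a) + \frac{e^{-a^2} - 1}{a\sqrt{\pi}}, \qquad
a = \frac{w}{2\sqrt{D t}},
$$

where $d$ is the bleach depth, $D$ the Fickian diffusion coefficient
(µm²/s) and $I_N$ the window-averaged intensity normalized to the
pre-bleach level. $B$ decreases from 1 at $t=0$ to 0 as $t \to \infty$:
recovery is complete, monotone, with the characteristic $\sqrt{t}$ onset
and $t^{-1/2}$ tail of one-dimensional transport.

The printed source of this model family gives its equations as images, so
the implementation pins the reconstruction to an independent ground
truth: a finite-difference reaction–diffusion simulator
(`simulateFrap()`, below) run with zero binding must agree with the
closed form to better than 1% sup-norm across
$D \in \{0.05, 1, 3.75, 8\}$ µm²/s and $w \in \{5, 7.5, 10\}$ µm. That
test is part of the suite.

### The two-thirds recovery time and $D_E$

Comparing proteins whose recovery is *not* free diffusion requires a
model-free mobility scale. The package uses the time $\tau_{2/3}$ at
which the recovery reaches two thirds of its plateau, and defines the
**effective diffusion coefficient** as the diffusivity of the virtual
free-diffusion process with the same $\tau_{2/3}$:

$$ D_E = c\, w^2 / \tau_{2/3}. $$

The dimensionless constant $c$ is *defined* by the identity $D_E = D$
for pure free diffusion — i.e. $B(a^\ast) = 1/3$ with
$c = 1/(4 a^{\ast 2})$ — computed once at first use by root finding and
cached (`cTwoThirds()`, ≈ 0.631325; frozen to six digits in the tests).
$\tau_{2/3}$ is always taken from a *fitted* model curve, never from the
last sample, because the plateau of an incomplete recovery is otherwise
unidentified.

## Diffusion hindered by reversible adsorption

Heparin-binding proteins adsorb on immobile matrix components (HSPGs),
and their single-IS FRAP curves are not fit by the free model. With
association rate $k_{on}$ (1/(nM·s)), dissociation rate $k_{off}$ (1/s),
free binding-centre concentration $\sigma_{free}$ (nM) and binding
constant $K = k_{on}/k_{off}$, the recovery is described by a sum of two
exponentials (`twoExpCurve()`):

$$ I_N(t) = \text{plateau} - A_1 e^{-t/\tau_1} - A_2 e^{-t/\tau_2}, $$

a fast *diffusion-driven* component and a slow *adsorption-driven*
component, with the weight of the fast exponent
$\alpha = A_1/A_2$. `characteristicTimes()` returns the standard limit
predictions

$$
\tau_1 = c\,w^2\,(1 + K\sigma_{free})/D_{free}, \qquad
\tau_2 = 1/k_{off}, \qquad
\alpha = 1/(K \sigma_{free}),
$$

and the package treats them as what they are — *regime limits*, not
exact results:

* $\alpha$ is the mass-action free/bound pool ratio and holds exactly at
  equilibrium (asserted exactly in the tests);
* $\tau_2 = 1/k_{off}$ and the amplitude split are quantitative in the
  **slow-exchange regime** $k_{off} \ll D_{free}/(c w^2)$, where the fast
  phase is free diffusion of the unbound pool and the slow phase is
  exchange with the bound pool (validated against the simulator within
  30%; observed agreement ~5%);
* $\tau_1$ with the retardation factor $(1+K\sigma_{free})$ is the
  recovery time in the **fast-exchange regime**, where binding and
  release are much faster than transport and the whole system behaves as
  one species with $D_{eff} = D_{free}/(1+K\sigma_{free})$ (validated via
  the $D_E \to D_{eff}$ limit within 20%).

In the *intermediate* regime the recovery is a single
effective-diffusion-like curve: a two-exponential fit still achieves
$R^2 > 0.999$, but the individual $(A_i, \tau_i)$ are not identifiable —
the optimiser can trade amplitude between components almost freely. The
package therefore never interprets two-exponential parameters outside the
slow-exchange regime, and the affinity method below is explicitly an
upper-bound method.

## The reaction–diffusion simulator

`simulateFrap()` integrates, for fluorescent and bleached pools,

$$
\partial_t a = D\, \partial_x^2 a - k_{on}\, a\, \sigma_{free} + k_{off} c,
\qquad
\partial_t c = k_{on}\, a\, \sigma_{free} - k_{off} c,
$$

with the complex $c$ immobile, on a 1D domain of 10 bleach-window lengths
(configurable) with reflecting boundaries, starting from the mass-action
steady state; at $t=0$ the fluorophores inside the stripe are converted
to bleached counterparts. Bleached molecules obey identical dynamics and,
in saturating mode, compete for the same binding centres — as they
physically must.

Numerical choices:

* **Transport** uses a conservative flux-form explicit update under the
  stability bound $\Delta t \le 0.4\,\Delta x^2 / D$ (enforced; an
  explicit `dt` violating it is rejected).
* **Binding** is advanced by the *exact* closed-form solution of the
  per-cell linear two-species ODE (the default, linearised
  $\sigma_{free}$-constant mode), so stiffness of fast exchange costs
  accuracy, not stability; splitting accuracy is protected by an
  additional $\Delta t \le 0.2/(k_{on}\sigma_{free}+k_{off})$ cap. The
  saturating mode (sites depleted by occupancy, pre-bleach state from the
  quadratic 1:1 equilibrium) steps the reaction explicitly with a
  correspondingly smaller step.
* The bleach stripe is represented with **fractional-overlap weights** on
  edge cells, for both the initial bleach and the read-out average, so
  the discretised stripe is exactly `w` long at any resolution; with
  whole-cell windows the recovered $D$ is biased by several percent at
  coarse $\Delta x$.
* Total label is conserved to machine precision under reflecting
  boundaries (asserted at 1e-6 in the tests), concentrations are checked
  for negativity, and halving $\Delta x$ (with the induced $\Delta t$
  refinement) moves the window-averaged trace by well under 0.5%.
* The default domain truncation (10–20 windows) means the asymptotic
  plateau is $1 - d\,w/L$ rather than 1 — the reflecting walls make the
  label reservoir finite. Fits leave the plateau free for exactly this
  reason (and because real recoveries are rarely complete).

A deliberately plain, fully explicit R re-implementation of the same
system lives in the test helpers and cross-checks the compiled stepper.

## Fitting and model selection

`normalizeTrace()` maps the pre-bleach mean to 1 and a user-supplied
background to 0, and re-zeroes time at the first post-bleach frame (at
least 2 pre-bleach and 10 post-bleach frames are required).

`fitFreeDiffusion()` estimates $(D, d)$ by Levenberg–Marquardt least
squares, with $D$ initialised from the 50%-recovery time. For this model
$D_E \equiv D$ by construction, which the tests assert as a calibration
identity.

`fitTwoExponential()` estimates $(A_1, A_2, \tau_1, \tau_2,
\text{plateau})$ with bounds ($A_i \ge 0$, plateau in $[0.5, 1.2]$) from
a fixed schedule of five log-spaced $(\tau_1, \tau_2)$ starts; the best
final sum of squares wins, which makes the fit deterministic. Label
switching is resolved by the convention $\tau_1 < \tau_2$. If the slow
amplitude collapses below 2% of the total the fit falls back to a single
exponential with a warning.

`modelSelect()` compares the two models by small-sample-corrected AICc
(the source analysis reports only $R^2$, which cannot penalise the three
extra parameters); ties within 2 units go to the free model.

`poolResults()` reports per-condition mean, SD and SEM with no silent
exclusions — published per-condition spreads do not state whether they
are SD or SEM, so both are available — and `foldChange()` reports
ratios of pooled means with a one-significant-figure "approximately
n-fold" rendering.

## Affinity estimation

Three independent routes to a dissociation constant are implemented.

**Equilibrium isotherms** (`fitIsotherm()`): nonlinear least squares of
the 1:1 Langmuir model $y = R_{max} x/(K_d + x)$, unweighted (no
weighting scheme is given in the source protocols), with a seeded
residual bootstrap for intervals and an explicit flag — never a silent
number — when the sampled range shows no curvature. Both free- and
fixed-$R_{max}$ modes exist because the original bound-fraction fits do
not state which was used. `wbToConcentration()` converts quantified
band densities to nM through a linear standard series, the reaction
volume, the dilution factor and the molecular weight.

**In-vivo amplitude ratio** (`kdFromAmplitudeRatio()`): when a fast
tracer (the inhibitor) binds a partner (the ligand) that is itself
quasi-immobile on the matrix, the two-exponential amplitude split of the
tracer's recovery reports the free/bound partition: free fraction
$f = \alpha/(1+\alpha)$, complex $C = N_{tot}(1-f)$, and

$$ K_d = (N_{tot}-C)(W_{tot}-C)/C. $$

This inverts the quadratic 1:1 equilibrium exactly (round-trip identity
to 1e-6 over $K_d \in [1, 10^4]$ nM in the tests) and returns an
infeasibility error when the implied complex exceeds either total. Its
accuracy through the *full* chain (simulate → fit → invert) is limited
by the exponential approximation of the diffusive fast phase: part of
the $t^{-1/2}$ diffusion tail is absorbed by the slow component, which
lowers $\alpha$ and hence $K_d$. The bias is always downward, so the
chain is conservative for an upper-bound statement ("does not exceed
100 nM"); with the generator's default timescale separation it recovers
a 90 nM truth within ~6%.

**Receptor competition** (`competitionEquilibrium()`): the
ligand–receptor–inhibitor equilibrium is solved on the free-ligand
concentration as the single unknown of a strictly monotone scalar
equation, bracketed on $[0, W_{tot}]$ — robust for any totals — followed
by one Newton polish step; conservation holds to 1e-9 and each pairwise
$K_d$ residual to 1e-7. A brute-force residual-grid search serves as the
independent oracle in the tests.

## The signalling-gradient model

`gradientScenario()` describes the anterior neural-plate midline as a
300 µm axis with $x = 0$ posterior (the ligand maximum at the
hind–midbrain border) and $x = L$ anterior. Total ligand follows a
posterior-normalized logistic sigmoid

$$ W(x) = W_{max}\, \frac{s(x)}{s(0)}, \qquad
   s(x) = \frac{1}{1 + e^{k (x - m)}}, $$

with defaults $W_{max} = 50$ nM, receptor and inhibitor totals 50 nM
each, $K_d^{WF} = 10$ nM, $K_d^{WN} = 100$ nM — the stated biological
operating point. The sigmoid midpoint ($m = L/2$) and steepness
($k = 0.04$ /µm) are *not* printed in the source; the defaults are the
package's own choice, made once: midpoint at mid-axis for symmetry, and
the steepness set so the profile falls below 2% of $W_{max}$ at the
anterior end (a validation warning fires otherwise), as the stated
boundary behaviour requires. Both are exposed in the scenario because
only the endpoints and the shape family are fixed by the biology.

`signalProfile()` partitions $W(x)$ pointwise among receptor and
inhibitor; `thresholdPosition()` finds, by linear interpolation, the
anterior-most position where the signalling complex still meets a
threshold; `shiftAnalysis()` sweeps inhibitor levels. The default
threshold is the wild-type complex concentration at mid-axis (the
"arbitrary threshold" of a thresholded readout), and the default
perturbations model knockdown as 0 nM and overexpression as 10× the
wild-type 50 nM — labelled assumptions, both sweepable, since the
perturbed concentrations appear only in unprinted supplementary
material. Under these choices the threshold moves monotonically toward
the posterior as inhibitor rises, with a total range of roughly 80 µm —
inside the order-of-magnitude 30–300 µm band the tests assert. The
large shift arises because the mid-axis threshold under strong
inhibition requires near-maximal total ligand, which pushes the crossing
deep into the flat posterior shoulder of the sigmoid.

The gradient itself is an initial condition, not a solved
reaction–diffusion steady state: conclusions are independent of how the
gradient forms, and no transport dynamics are modelled on the axis.

## Imaging helpers

Collective ectodermal cell movement displaces the bleached region between
frames, so `registerFrames()` estimates per-frame rigid *translations*
(rotation is deliberately out of scope, matching the original
drift-correction script's purpose) by FFT cross-correlation against the
first frame, refined to subpixel precision with a five-point
least-squares parabola per axis; frames whose correlation peak is too low
carry the previous shift forward with a warning. `extractIsTrace()`
averages a pixel band along the IS segment into a raw trace whose bleach
window is the segment length. `calibrationCurve()` /
`intensityToConcentration()` implement the linear
fluorescence-to-concentration calibration with a mandatory blank and
extrapolation warnings. `diffusionPath()` measures, on six equally
spaced rays from a graft centre, the distance from the graft boundary to
where the (3-sample moving-mean smoothed, first-crossing convention)
intensity reaches background; rays that never decay are censored, not
imputed. Pixel coordinates are 0-based (row, col); physical positions
are µm.

## Synthetic data: what it does and does not emulate

The generators (`generateDataset()` and the `sim*()` family) produce
every input the pipeline consumes, with multiplicative Gaussian noise
(10–15% is typical of in-vivo confocal intensities) and full
determinism: replicate *k* of a call runs under a child seed derived from
(seed, k), so any subset regenerates byte-identically.

* `frap_free` samples the analytic free curve (default: 1 pre-bleach +
  100 frames over ten $\tau_{2/3}$, mirroring a short single-IS
  acquisition).
* `frap_adsorption` samples the simulator with dense early and sparse
  late frames covering both phases.
* `frap_quasi_immobile_partner` builds the in-vivo affinity experiment:
  totals 1 µM/1 µM (the calibrated expression level), the free-partner
  concentration at equilibrium supplying the binding-centre pool, and a
  default $k_{off} = 2\times10^{-4}$/s placing $\tau_2$ two orders of
  magnitude above the diffusion time — the separation the
  amplitude-ratio method assumes. Sampling is one frame per 30 s out to
  $2.4\,\tau_2$; that horizon is longer than a practical acquisition,
  which is exactly why the in-vivo method should be read as bounding,
  not measuring, the affinity.
* `spr` / `isotherm` generate Langmuir responses and quadratic
  bound/free dilution series; `calibration` a known line with a blank;
  `image_stack` a drifting two-cell scene with granular cytoplasmic
  texture (drift would be unidentifiable along a featureless IS line)
  and a recovering bleached segment.

What the generators do **not** emulate: photofading and blinking, z-drift,
detector shot-noise statistics, IS-network geometry (the 1D gap is an
idealisation), secretion and degradation during acquisition, and
developmental changes in expression level. Passing the recovery tests
therefore shows the estimators are correct *for the stated generative
models*, not that real embryos satisfy those models.

## Problem sizes and runtime

The test-suite and the acceptance script are sized for a single CPU:
oracle grids of 128–800 cells (1600 for the headline $D$ recovery, where
the first-order spatial bias of the fitted $D$ is driven below 1%),
recovery horizons of 2–2.5 characteristic times, 200 replicates for the
stochastic recovery studies, and 25 replicates for the pooled-bias
check. The full suite runs in well under a minute; the acceptance script
in a few seconds.

## Known limitations

* The two-exponential parameters are reported for any trace but are only
  physically interpretable under slow exchange; `modelSelect()` guards
  against over-fitting free traces but cannot rescue intermediate-regime
  identifiability.
* The in-vivo $K_d$ chain is downward-biased by design (upper-bound
  method); do not read its point estimate as unbiased.
* Registration models translation only, on whole frames; rotating or
  deforming tissue will degrade extraction silently up to the 50%-overlap
  guard.
* The gradient model is an equilibrium partition along a postulated
  profile; it says nothing about gradient formation kinetics or
  cytoneme-mediated transport.
* Saturating-site dynamics use an explicit reaction step and are intended
  for moderate stiffness; the linearised mode is the validated default.
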