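---
title: "Compartmental modelling of dynamic FMISO PET: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental modelling of dynamic FMISO PET: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
kinetic model and its assumptions, the numerical method, the statistical
conventions, and — importantly — the identifiability structure of the model,
which dictates how parameter-recovery studies must be run.

## The tracer and the question

¹⁸F-fluoromisonidazole (FMISO) is a nitroimidazole PET tracer that diffuses
freely into tissue and, under hypoxia, is enzymatically reduced and trapped in
viable cells. Static imaging 2 h after injection summarises total uptake; a
tumour-to-blood activity ratio above 1.2 is the conventional hypoxia
criterion (`static_summary()`). Dynamic imaging over the full 2 h, analysed
with compartment models, separates the *specific trapping rate* from
non-specific delivery and washout — the distinction static imaging cannot
make when uptake is driven by transient perfusion.

## The two-tissue compartment model

Tissue tracer is split into a non-specific diffusive pool $C_d$ and a
specifically trapped pool $C_a$, exchanging with arterial plasma $C_p$:

$$
\frac{dC_d}{dt} = K_1 C_p(t) - (k_2 + k_3)\,C_d + k_4 C_a,\qquad
\frac{dC_a}{dt} = k_3 C_d - k_4 C_a .
$$

$K_1$ (mL/g/min) is plasma-to-tissue transport, $k_2$ washout, $k_3$ the
hypoxia-specific trapping rate and $k_4$ the release rate; $k_4 = 0$ is the
irreversible model, appropriate when trapped tracer effectively never leaves
on the scan time scale. Transport is modelled as purely diffusive: there are
no saturable or active-transport terms. The measured ROI signal is the
weighted sum

$$
C_\mathrm{ROI}(t) = w_p C_p(t) + w_d C_d(t) + w_a C_a(t),\qquad
w_p + w_d + w_a = 1,
$$

with $w_p$ the fractional blood volume. The plasma curve is taken from a
left-ventricle image ROI without metabolite, dispersion or delay correction —
the image-derived input-function convention for small-animal work
(`lv_input_function()`); no such corrections are added here.

The net (macro) influx rate of the irreversible model is
$K_i = K_1 k_3/(k_2+k_3)$ (`macro_influx_rate()`), which is also the
asymptotic slope of the Patlak plot of the **total tissue concentration**.

## Exact solution for a piecewise-linear input

`solve_two_tissue()` does not integrate the ODEs numerically. The sampled
input is interpreted as piecewise linear; on each segment the linear 2×2
system has a closed-form solution by convolution with its matrix-exponential
kernel, expressed through the two eigen-rates
$\alpha_{1,2} = \tfrac12\big(s \mp \sqrt{s^2 - 4k_2k_4}\big)$, $s=k_2+k_3+k_4$
(in 1/s internally; rate constants are stored in 1/min, the reporting unit).
The convolution state is advanced segment by segment with the exact
$\varphi$-functions of each eigenvalue, so results are independent of any
step size; the tests verify agreement with a stiff `deSolve` integration at
`rtol = 1e-10` to within the 0.1 % accuracy contract (the closed form is
exact up to floating point, so the margin is wide). Numerical care: $\varphi_1 = \mathrm{expm1}(\lambda h)/\lambda$, a
series expansion of $\varphi_2$ below $|\lambda h| < 10^{-4}$, a
cancellation-free discriminant $(a-k_4)^2 + 4k_3k_4$, the eigenvalue product
relation for the small root, and a blocked, rescaled cumulative-sum scan so
long decays neither underflow nor overflow. PET frames integrate counts, so
the model prediction compared against measured TACs is the exact *frame
average* of $C_\mathrm{ROI}$ (`frame_average_signal()`), not a midpoint
sample; frame averaging is exact for linear signals and matches fine-grid
quadrature to <0.1 % elsewhere.

Times are half-open frames $[t_0, t_1)$ in seconds from injection at $t=0$;
$C_p$ is ramped linearly from $(0,0)$ when its first sample is later.
Inputs are assumed decay-corrected (scanner convention); `decay_correct()`
exists for uncorrected data and is never applied implicitly (F-18 half-life
109.77 min).

## Fitting and the goodness-of-fit convention

`fit_tac()` minimises $\sum_i w_i\,(\mathrm{TAC}_i - \mathrm{model}_i)^2$
with bounded Levenberg–Marquardt (minpack.lm), free parameters
$K_1,k_2,k_3,(k_4),w_p,w_d$, $w_a = 1-w_p-w_d$ eliminated by construction
(internally $w_d$ is fitted as a fraction of $1-w_p$, so box constraints
suffice). Bounds are $[0,1]$ for every rate and weight; initial values are
the conventional $K_1=k_2=k_3=0.01$, $w_p=w_d=0.1$ (and $k_4=0.001$).
Residual weights are uniform by default; frame-duration weighting, the
natural inverse-variance surrogate under counting statistics, is available
(`weighting = "duration"`).

Goodness of fit is the residual percentage

$$
\varepsilon = 100 \cdot \frac{\mathrm{mean}_i\,|\mathrm{TAC}_i -
\mathrm{model}_i|}{\max_i \mathrm{TAC}_i},
$$

a fixed package convention: scale-free, robust to near-zero early frames,
and on the scale on which the conventional "accept below 5 %" rule is
quoted. A pointwise-relative alternative (frames above 10 % of the maximum)
is available via `epsilon_method = "relative"`. Because the exact formula
behind published $\varepsilon$ tables is not standardised, cross-study
$\varepsilon$ values should be compared only qualitatively (orderings, e.g.
irreversible < reversible on irreversible-like data).

When the single standard initialisation fails (non-convergence, or
$\varepsilon$ above `restart_epsilon`, default 2 %), up to `restarts`
jittered initialisations are tried under a fixed seed and the best SSE kept.
TACs indistinguishable from background are refused rather than noise-fitted
when the caller provides a background level (`background`,
`min_signal_ratio = 3`): this mirrors the convention of setting rates to
zero for tumours invisible above background, and it is opt-in because early
frames of a genuine TAC legitimately carry blood signal.

## Structural identifiability: the central caveat

For the irreversible model the fitted signal can be written

$$
C_\mathrm{ROI} = w_p C_p + \Big[\underbrace{w_d K_1}_{A}\,e^{-(k_2+k_3)t}
 + \underbrace{w_a K_1 k_3/(k_2+k_3)}_{B}\,\big(1-e^{-(k_2+k_3)t}\big)\Big]
 \otimes C_p ,
$$

so a noiseless TAC determines only **four** functionals —
$w_p$, $a=k_2+k_3$, $A$ and $B$ — against **five** free parameters. There is
a one-dimensional manifold of parameter sets that fit exactly (e.g. for the
MDA-MB-435 1 h scenario, $K_1$ anywhere above ≈0.0248 fits noiselessly with
compensating $w_d, k_3, k_2$); the reversible variant has the same
one-dimensional deficiency, plus a $k_2=0$ alias branch on which
$\alpha_1=0$ for *any* $k_4$. Consequences drawn in this package:

* The fully-free fit (the conventional protocol) reproduces the curve but
  its individual rate estimates are not unique and should be interpreted
  with care. This is a property of the weighted-sum model itself, not of the
  optimiser.
* **Recovery and comparison studies pin $w_d$** (`fixed = c(wd = 0.6)`),
  which removes exactly the deficient dimension: with $w_d$ known, $K_1 =
  A/w_d$, then $k_3$ and $k_2$ follow uniquely. Weights are treated as
  nuisance parameters throughout. Under this protocol noiseless fits recover
  all rates to ~1e-10, and the reversible fit of irreversible data drives
  $k_4$ below $10^{-4}$ min⁻¹ instead of wandering on the alias branch.
* `k3_map()` pins $w_d$ at the package's reference tissue composition
  ($w_d = 0.60$) by default for the same reason: free-weight voxel fits
  would return arbitrary manifold points and the map would be meaningless.
* Some corners of the parameter space (very small $k_2$) are *practically*
  ill-conditioned even with $w_d$ pinned: local minima exist whose
  $\varepsilon$ is a fraction of a percent. Recovery studies therefore run
  with aggressive multi-start (`restarts = 8, restart_epsilon = 1e-5`).

## Patlak analysis and what its slope estimates

`patlak_transform()` plots $y = C_t/C_p$ against the normalised time
$x = \int_0^t C_p\,ds / C_p(t)$ (minutes) at frame midpoints, with the
plasma integral computed exactly on the piecewise-linear input; frames with
$C_p$ below 1 % of its peak are excluded for division stability.
`patlak_fit()` is ordinary least squares over valid points at
$t \ge t^*$; $t^* = 30$ min by default — past the fast exponentials implied
by the reference rate constants, and standard for this slow-circulating
tracer (weighting options are deliberately not defaulted on).

One subtlety matters: only the $w_a C_a$ term grows like $\int C_p$, so the
asymptotic Patlak slope of the **weighted ROI signal** is $w_a K_i$, not
$K_i$. Applied to the **total tissue concentration** $C_d + C_a$
(`frame_average_tissue()`), the slope is $K_i$ itself; that is the curve the
package's Patlak↔compartment consistency checks use (agreement within 5 % at
$t^*=30$, 2 % at $t^*=60$ on noiseless scenarios). Phantom truth maps store
the *observable* slope $w_a K_i$ for each region. For slowly equilibrating
tissue ($k_2+k_3 \lesssim 0.005$ min⁻¹) a residual drift of the diffusive
term inflates voxel slopes above the asymptote; Ki maps are therefore most
quantitative where trapping dominates, and remain useful as contrast images
elsewhere. `reference_patlak()` substitutes a muscle TAC for plasma for
whole-body mapping when no blood curve is reliable.

## Parametric maps and overlap summaries

`ki_map()` runs the Patlak regression per voxel (closed-form OLS across the
voxel matrix; negative slopes clamped to 0, per-voxel failures recorded in a
validity mask, never a global error). `k3_map()` fits the irreversible model
per tumour voxel, warm-started from the whole-ROI fit, which cuts both
non-convergence and run time; non-converged voxels are invalid.
`map_positive_fraction()` reports the percentage of tumour voxels whose map
value reaches a level. The display default (`map_level()`) is 20 % of the
within-tumour maximum — configurable, and deliberately treated as a display
convention because overlap percentages are threshold-dependent; for
phantom validation the level is placed midway between the designed rim and
core $k_3$, which makes the recovered hypoxic fraction directly comparable
to the designed one. A robustness note: the 20 %-of-maximum default is
sensitive to single-voxel outliers under noise, which is one more reason
overlap figures should be read qualitatively.

## The synthetic generator: what it emulates, and what not

All testing runs on synthetic data built to the statistical structure the
analysis assumes:

* **Acquisition**: 2 h, 52 frames (10×30 s, 10×60 s, 10×120 s, 10×150 s,
  12×300 s), injection at acquisition start.
* **Input function**: linear rise from 0 to 100 Bq/mL at 30 s, then a
  tri-exponential tail with rates 4, 0.25, 0.005 min⁻¹ and amplitude
  fractions 0.55/0.25/0.20 — a fast distribution phase and a slow plateau
  (~11 % of peak at 2 h), matching the long circulation of this tracer.
  Sampled at 1 s. The absolute scale is arbitrary (every analysis quantity
  is a ratio or normalised slope).
* **Noise**: zero-mean Gaussian per frame with
  $\mathrm{sd}_i = \sigma_0\sqrt{\max(v_i,0)/\Delta t_i}$ — variance
  proportional to activity over frame duration, the standard surrogate for
  reconstructed-PET counting noise. Named levels: none/low/moderate/high =
  $\sigma_0$ 0/0.5/3/8, i.e. roughly 0/0.6/4/10 % relative noise on late
  300 s tumour frames. True Poisson sinogram simulation, PSF, attenuation,
  scatter and motion are out of scope, so passing tests demonstrate
  correctness of the estimators under the assumed noise model, not
  robustness to reconstruction artefacts.
* **Phantom** (`phantom_spec()`): 32³ voxels of 0.8 mm — sized so the full
  voxelwise study runs in minutes on one CPU — with a tumour sphere (radius
  0.2× the grid), a hypoxic core comprising exactly 30 % of tumour voxels
  (the voxels nearest the tumour centre), a normoxic rim
  ($k_3 = 0.002$ min⁻¹), a separated blood pool ($w_p = 1$, the
  left-ventricle stand-in), and muscle elsewhere
  ($K_1=0.03, k_2=0.06, k_3=5\times10^{-4}$). Tumour presets carry the
  reference scenario means with $w_p=0.05, w_d=0.60, w_a=0.35$ — fitted
  weight values are never published for these scenarios, so one plausible
  composition is fixed and used consistently for generation and for the
  pinned-weight fitting protocol. Default $\sigma_0 = 1$ (low counting
  noise of a reconstructed frame).

Every simulator output is bit-reproducible given the spec and seed, and the
global RNG stream is left untouched.

## Problem sizes and run times

The shipped studies are sized for a single CPU: the 20-point noiseless
recovery grid (~1 min), 50 noisy replicate fits (~20 s), and one 32³
phantom with ~1100 voxelwise $k_3$ fits (~1 min) — small enough to re-run
routinely, large enough that the voxelwise statistics (medians, overlap
fractions) are stable.

## Known limitations

* The weighted-sum signal model is structurally non-identifiable with free
  weights (above); absolute micro-parameter values from the free protocol
  carry a manifold ambiguity that no optimiser can resolve.
* The image-derived input function is used uncorrected; plasma metabolites,
  dispersion and delay would bias $K_1$ and $w_p$ on real data.
* No partial-volume or spill-over correction: small structures inherit the
  usual quantification bias.
* Patlak mapping of slowly equilibrating tissue overestimates the
  asymptotic slope (drift term above).
* The hypoxia T/B cutoff (1.2, strict) and the threshold-ROI fraction
  (default 0.5 of the in-box maximum, largest connected component kept) are
  conventions, exposed as parameters.
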