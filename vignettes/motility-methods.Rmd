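---
title: "Models and methods in motilitykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in motilitykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(motilitykit)
```

`motilitykit` measures bacterial swimming behaviour at two levels: per-cell
trajectory statistics in quasi-2D, and population-averaged motility from
movies in 3D. This vignette explains the models behind each estimator, the
parameters that matter, what the built-in simulator does and does not
emulate, and the numerical choices that were genuinely open.

## The circular run-and-tumble model

Bacteria swimming close to a surface experience hydrodynamic torques that
curve their runs into circular arcs. The package's core single-cell model
is therefore a cell moving on a circle of radius $s$ with angular velocity
$\psi$, at tangential speed $v = \psi s$, which reorients completely at
tumbles occurring at exponential waiting times with rate $\lambda_T$.

Closed forms implemented (and unit-tested against quadrature and
Monte-Carlo simulation):

* direction autocorrelation of pure circular motion:
  $\langle \hat c(0)\cdot\hat c(t)\rangle = \cos(\psi t)$
  (`acf_circular()`);
* mean square displacement:
  $\langle r^2(t)\rangle = 2 s^2\left[1 - \cos(\psi t)\right]$, which is
  $v^2 t^2$ at short times and bounded by the squared diameter $4s^2$
  (`msd_circular()`);
* with tumbling and full decorrelation at each tumble:
  $e^{-\lambda_T t}\cos(\psi t)$ (`acf_circular_rt()`). The exponential
  factor is the probability that no tumble occurred in the interval; the
  test suite gates this form against the ensemble ACF of 2000 simulated
  tracks at three standard errors per lag;
* population averaging over curvature heterogeneity
  $P(\psi) = \lambda e^{-\lambda\psi}$:
  $\int_0^\infty \cos(\psi t)\,\lambda e^{-\lambda\psi}\,d\psi =
  \lambda^2/(\lambda^2 + t^2)$ (`acf_population_exponential()`), an
  algebraically decaying curve that never crosses zero, unlike the
  single-curvature cosine. Whether a real population is better described
  by a single $\psi$ or the exponential mixture is an empirical question;
  the fitting routine exposes both (`mode = "single"` / `"population"`).

`fit_circular_rt()` fits the chosen ACF form by weighted least squares
(weights $\sqrt{n_\text{pairs}}$, downweighting noisy long lags) with a
20-point multistart over $\psi \in [0, \pi/\Delta]$ — the cosine makes the
objective multimodal, and $\pi/\Delta$ is the largest curvature
identifiable at lag spacing $\Delta$. The tangential speed is read off the
first MSD point as $v = \sqrt{\text{MSD}(\Delta)}/\Delta$ (ballistic
short-time assumption); a three-point quadratic through the origin is
available (`v_method = "quadratic"`) when the first lag is noisy. The
radius follows as $s = v/\psi$. Parameters are optimized on a log scale to
enforce positivity; the zero-tumble limit is reachable as
$\lambda_T \to 0$.

## Trajectory statistics

**Features.** From positions on a uniform grid $\Delta t$ (default 10
frames per second): speed from frame displacements; headings from
displacement vectors; angular velocity as the wrapped heading change per
unit time. "Relative acceleration" is defined here as the frame-to-frame
speed change normalized by the track-mean speed per unit time
(dimension 1/s), which makes the feature scale-free across slow and fast
cells; angular acceleration is the frame difference of angular velocity.

**Tumble detection.** A two-state hidden Markov model ("swimming",
"tumbling") with bivariate Gaussian emissions over (relative acceleration,
|angular acceleration|) is trained by Baum–Welch on a pooled reference
population (convergence at $10^{-6}$ log-likelihood gain per frame, cap
500 iterations; covariance diagonals floored at $10^{-8}$ with a warning
if degenerate). The absolute angular acceleration makes left and right
turns equivalent. States are labeled by their mean |angular acceleration|;
an exact tie keeps state 1 as swimming. Decoding uses Viterbi rather than
posterior thresholding so tumble events come out as contiguous runs,
matching the event semantics of a "sudden change in direction".

One bias deserves explanation: both emission features are (second)
differences spanning three consecutive displacements, so the emissions
around a true tumble are anomalous for about one extra frame on each
side, and raw Viterbi occupancy overestimates time-in-tumble accordingly.
`classify_tumbles()` therefore trims one frame from each end of every
detected run (never below one frame) — a deterministic compensation for
the known width of the feature kernel, controllable via `trim`.

**Diffusion and persistence.** The diffusion coefficient uses the
covariance-based estimator on positions subsampled at
`resample_interval = 10` s, beyond the timescale of rotational diffusion:
$\hat D = \langle\delta^2\rangle/2\Delta +
\langle\delta_n\delta_{n+1}\rangle/\Delta$ per axis, averaged over axes.
The covariance term cancels static localization noise exactly in
expectation. A 100 s track yields only ~10 subsampled displacements, so
single-track estimates are noisy and may be negative; they are reported
as-is (flagged), because truncating at zero would bias ensemble averages.
Persistence is $\tau = 2D/v_0^2$. For run-and-tumble with uniform
reorientation in the plane this gives $\tau = 1/\lambda_T$, which the
suite verifies by simulation.

**Filters.** Population summaries retain tracks of at least 10 s duration
and 5 µm/s mean speed — configurable defaults chosen to exclude
non-motile and barely-tracked cells.

## DDM and DFM

**Structure function.** `image_structure_function()` computes
$g(q,\tau) = \langle |\hat I(t+\tau) - \hat I(t)|^2 \rangle / N_{px}$,
radially averaged into annular bins one FFT pixel wide; bins with fewer
than 8 Fourier modes are discarded, as is the DC mode. With this
normalization a stack of i.i.d. noise of variance $s^2$ has a flat
$g = 2s^2$, a convenient absolute check. Time origins are capped at 60
per lag (evenly strided) — beyond that the origins are strongly
correlated and add little.

**ISF model.** Per $q$, $g = A(q)[1 - f(q,\tau)] + B(q)$ with
$$f(q,\tau) = e^{-Dq^2\tau}\left[(1-\alpha) + \alpha\,
W_s(q\bar v\tau; Z)\right],$$
where $W_s$ is the closed-form intermediate scattering function of
straight swimmers with Schulz-distributed speeds,
$Z = (\bar v/\sigma)^2 - 1$. $W_s(x;Z) \to \operatorname{sinc}(x)$ as
$\sigma \to 0$; the suite checks this limit to $10^{-3}$ and the closed
form against direct quadrature over the Schulz density to $10^{-8}$.
Fitting is bounded Levenberg–Marquardt with plateau-based initialization
of $A, B$ and a multistart over $\bar v \in \{5, 15, 30\}$ µm/s; $\sigma$
is parameterized as a fraction of $\bar v$ in $[0.02, 0.7]$ so the Schulz
parameterization stays valid. When the swimming fraction is known a
priori (e.g. a pure diffuser control), `alpha_fixed` removes the
degeneracy between slow swimming and diffusion. Failed bins are flagged
and excluded from averages, never silently dropped.

**Summary metrics.** $v$ and $\sigma$ are averaged over
$0.5 \le q \le 2$ µm⁻¹ (length scales 3–13 µm); $S = \sigma/v$; the path
straightness $R = v(L_1)/v(L_2)$ uses the fitted speeds at the bins
nearest $q = 2\pi/L$ for $L_1 = 3$, $L_2 = 13$ µm (nearest bin, not
interpolation, and the bins used are reported). Straight paths give
$R = 1$; reorientation depresses the apparent speed at large length
scales and pushes $R$ above 1.

**Flicker spectroscopy.** Cells are segmented on the temporal-mean image
(Otsu threshold, connected components, minimum area 4 px — the simplest
reproducible choice for high-contrast fixtures); each cell's integrated
intensity is mean-subtracted, Hann-windowed and periodogrammed, spectra
are averaged across cells, and the body angular velocity is
$\Omega = 2\pi f_\text{peak}$ at the lowest-frequency local maximum
exceeding 4× the median-smoothed background. Taking the lowest qualifying
peak makes the estimate robust to harmonics. Integrated intensity is the
flicker observable; it is validated against the virtual microscope, where
the modulation is known by construction. Processivity is $P = v/\Omega$
(µm/rad; $2\pi P$ per revolution), optionally normalized to a reference
condition.

## The simulator and virtual microscope

`simulate_circular_rt()` generates the study conditions for every test:

* per-cell speeds from a Schulz (gamma) distribution with mean
  `speed_mean` (default 25 µm/s) and relative width `speed_rel_width`
  (default 0.2) — the same family the ISF fit assumes, so speed-recovery
  tests are exact in principle;
* per-cell curvature fixed or exponential; all-positive by default (a
  single handedness, as for surface swimming), with a mixed-sign option;
* heading updates by exact rotation $\psi\,\Delta t$ (not Euler
  integration of velocity components), so noiseless trajectories are
  exact circles and the analytic oracles are sharp; rotational diffusion
  adds Gaussian heading noise of variance $2D_r\Delta t$;
* tumble waiting times drawn in continuous time (exact exponentials,
  stored in the ground truth), with the uniform heading redraw taking
  effect at the next frame boundary, since positions are reported at
  frame times only. With this convention the displacement-heading ACF of
  the simulated process equals $e^{-\lambda_T t}\cos(\psi t)$ exactly in
  expectation, with no chord-straddling bias — which is what lets the
  Monte-Carlo gate on `acf_circular_rt()` be set at 3 SE;
* an optional finite-duration tumble mode (speed drops to 0.3 of the run
  speed for an exponential duration of mean 0.15 s while the heading
  scrambles) for training and scoring the tumble classifier;
* a `geometry = "isotropic3d"` mode: straight runs with directions
  uniform on the sphere, positions reported in 2D projection. This is the
  right fixture for DDM: for isotropic 3D swimmers the in-plane ISF is
  exactly $\operatorname{sinc}(qv\tau)$, whereas purely in-plane swimmers
  would give a Bessel $J_0$ form and a sinc-model fit would overestimate
  their speed by a geometry factor. Planar mode remains the default for
  the quasi-2D tracking analyses;
* periodic boundaries with unwrapped coordinates kept in the ground
  truth, so MSD and ACF are computed without wrap artifacts. Brownian
  controls (`simulate_brownian()`) take a `box_size` so that rendered
  populations start spatially uniform — a clustered start would add
  coherent collective dynamics to $g(q,\tau)$.

`render_movie()` images each cell as a Gaussian spot (width `psf_sigma`,
default 0.6 µm) with per-pixel Gaussian read noise, clipped at zero; in
dark-field mode the per-cell intensity is modulated as
$1 + d\sin(2\pi f t + \varphi_i)$ at the body-rotation frequency with
random phases. Wobble frequencies at or above Nyquist are rejected.

What the simulator does **not** emulate: hydrodynamic cell–cell or
cell–surface interactions, flagellar mechanics, 3D defocus blur,
phase-contrast halos, cell shape, photobleaching, or tracking failures
(linking errors, lost cells). Passing the recovery tests therefore shows
the estimators are correct on their own model classes and robust to the
noise sources modeled (read noise, localization error, speed and
curvature heterogeneity) — it does not certify performance on real
microscopy, where segmentation and linking dominate the error budget.

## Problem sizes and numerical choices

The test suite runs deterministic, seeded simulations sized so the whole
suite completes in about a minute: 2000 tracks for the Monte-Carlo ACF
gate, 1000 tracks for parameter recovery (curvature within 10%, tumble
rate within 20%, speed within 5%), 1000 × 100 s Brownian tracks for the
diffusion estimator (within 5%), and a 2000-frame 256×256 movie at 100
fps for the DDM straight-path check ($|R - 1| < 5\%$). The acceptance
script re-runs the movie pipeline at the same size.

Other numerical choices: angle wrapping maps to $(-\pi, \pi]$; the Schulz
term switches to its $x \to 0$ limit below $10^{-8}$ to avoid 0/0;
correlation curves record the number of pairs per lag so fits can weight
by information content; TIFF stacks are stored scaled to $[0,1]$ with the
scale in a YAML sidecar (the structure function is quadratic under
intensity scaling, so derived quantities are unaffected); and all
generators and the renderer consume explicit integer seeds, making every
pipeline — including the condition sweep `hook_sweep()`, which writes a
JSON manifest of command, config, seed and package version — bit-for-bit
reproducible.

## Known limitations

* The ACF fit estimates a single effective $(\psi, \lambda_T)$ per
  population; strongly heterogeneous curvature is better served by the
  population mode, and rotational diffusion is not a separate fit
  parameter (it folds into the apparent tumble rate).
* Single-track covariance-based diffusion estimates at 10 s subsampling
  have large variance by construction; only ensembles are quantitative.
* The DDM fit assumes the Schulz speed family and a common diffusive
  envelope; it does not model body-wobble oscillations inside the ISF
  (wobble is measured separately by the flicker spectrum).
* The tumble classifier's occupancy correction assumes isolated events;
  at tumble rates high enough for events to merge (biases above ~0.3 at
  10 fps), detected event counts undercount true events.
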