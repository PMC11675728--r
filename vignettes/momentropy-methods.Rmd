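---
title: "Metastable oscillatory modes and system entropy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metastable oscillatory modes and system entropy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(momentropy)
```

# The model

`momentropy` simulates a network of N Stuart–Landau oscillators — the normal
form of the Andronov–Hopf bifurcation — coupled through a weighted structural
connectome with pairwise conduction delays:

$$
\frac{dZ_n}{dt} = Z_n\,(a + i\omega - |Z_n|^2)
  + K \sum_{p \ne n} C_{np}\,[Z_p(t-\tau_{np}) - Z_n(t)]
  + \beta\eta_1 + i\beta\eta_2 .
$$

Each complex unit $Z_n$ stands for one brain region. With the bifurcation
parameter $a = -5$ every region is subcritical: it does not oscillate on its
own, but rings at its intrinsic frequency $\omega = 2\pi \cdot 40$ Hz
(gamma-band) when perturbed, with amplitude decaying over a few hundred
milliseconds. Independent complex white noise of scale $\beta = 0.001$
perturbs every unit continuously. $C_{np}$ are non-negative connection
weights (zero diagonal, symmetric), and each connection carries a delay
$\tau_{np}$ proportional to the fiber distance $D_{np}$, rescaled so the mean
delay over connected pairs equals $\langle\tau\rangle$.

Two free parameters span the dynamical regimes: the global coupling strength
$K$ and the mean conduction delay $\langle\tau\rangle$. The reference setting
is $K = 10$, $\langle\tau\rangle = 3$ ms.

A useful fact about this diffusive delay coupling: the zero fixed point is
linearly stable for *every* $K$ and $\langle\tau\rangle$ (for any phase factor
$c = \cos\nu\tau \in [-1, 1]$ the matrix $cC - \mathrm{diag}(\sum_p C_{np})$
is diagonally dominant, hence negative semi-definite, so no characteristic
root can cross the imaginary axis). The observed dynamics are therefore
noise-sustained ringing of collective eigenmodes. Delays lower both the
frequency and the damping of the slowest collective modes; when a mode comes
close to criticality it amplifies the noise into intermittent, band-limited
bursts of collective oscillation — the metastable oscillatory modes (MOMs).

## Coupling normalization

The scale of $C$ decides which $K$ is "strong". `scaled_coupling()` defaults
to dividing $C$ by the mean over all off-diagonal entries (`normalize =
"mean_all"`), so the summed input weight per node averages $N$ and the
effective coupling mass is $K \cdot N$ independent of connection density.
Solving the characteristic equation
$\lambda = a + i\omega + KN(e^{-\lambda\tau} - 1)$ of the mean-field mode
under this convention places the slowest collective mode near 10.7 Hz at
$K = 10$, $\langle\tau\rangle = 3$ ms — the alpha band, where MOMs are
expected at the reference parameters — with delta-band modes appearing at
$K = 50$. The alternative `"mean_nonzero"` (mean over nonzero weights = 1)
makes the coupling mass density-dependent; on the synthetic connectomes used
here it leaves every regime of the $3 \times 3$ grid overdamped, with no
supra-threshold coalitions anywhere, which contradicts the phenomenology the
model is meant to exhibit. Both conventions plus `"none"` are exposed.

## Numerical integration

`simulate_network()` uses an exponential (splitting) Euler–Maruyama scheme:
per step the cubic, coupling and noise terms advance by an explicit Euler
substep, then the exact linear flow $e^{(a + i\omega)\,dt}$ is applied. A
plain Euler step is unusable here: at $\omega dt = 2\pi\cdot 40 \cdot 10^{-4}
\approx 0.025$ rad the rotation inflates the radius by $(\omega dt)^2/2$ per
step, an artificial anti-damping of $\approx +3.2\,\mathrm{s}^{-1}$ that
would cancel most of the $a = -5$ decay. The splitting scheme reproduces the
closed-form radial decay $r(t)^2 = a r_0^2 e^{2at} / (a + r_0^2(e^{2at}-1))$
of an uncoupled unit to $2.4\times10^{-6}$ at $dt = 10^{-4}$ s over 1 s
(tested), and the phase advances at exactly $\omega$.

Other integration choices:

* $dt = 10^{-4}$ s (250 steps per gamma cycle); delays are rounded to the
  nearest integer step and delayed states are read from a ring-buffer
  history of length max-delay.
* The history ($t \le 0$) is initialized at the fixed point plus noise of
  the per-step noise scale; the first second (`transient`) is discarded.
* Noise convention (`noise_mode`): default `"sqrt_dt"` adds
  $\beta\sqrt{dt}\,\eta$ per step — the diffusion is invariant under step
  refinement. `"per_step"` ($\beta\eta$ per step) is provided for
  compatibility with fixed-step readings of the noise term.
* The real part of $Z_n$ is stored every 2 ms (500 Hz), giving
  $T = 20{,}000$ samples for a 40 s run.
* Divergence (non-finite state or $|Z| > 10^6$) aborts with the step index.

# MOM detection

`run_pipeline()` detects MOMs as in the reference procedure:

1. **Band-pass filtering** into delta (0.5–4), theta (4–8), alpha (8–13) and
   beta (13–30 Hz) by FFT, zeroing all bins outside the band (DC included),
   and inverting. Filtering is applied to the full record once; the first
   and last ~100 ms are edge-affected, which at 40 s is negligible.
2. **Amplitude envelopes** as the magnitude of the analytic signal (Hilbert
   transform) per node and band.
3. **Baseline calibration**: a twin simulation with `mean_delay = 0` and all
   other parameters (including the seed, by default) unchanged. Without
   delays the network generates no sub-gamma collective oscillation, so
   these envelopes measure the noise floor. Per node and band the threshold
   is mean + 5 SD of the baseline envelope (`threshold_formula =
   "mean_plus_sd"`; the `"sd_only"` variant, 5 SD without the mean, is also
   available since both readings appear in descriptions of the procedure).
   The SD is computed per node, not pooled.
4. **Coalitions**: at each sample, the number of nodes whose envelope
   exceeds their threshold, per band; the total series sums the four bands.
   The correlation analysis uses these *raw* counts — the minimum coalition
   size of 5 only classifies discrete MOM *events*
   (`detect_mom_events()`), which are maximal contiguous runs with at least
   5 supra-threshold nodes. (Window-averaged raw counts between 0 and 1 in
   quiet regimes are meaningful; masking would zero them.)

# System entropy

`entropy_timeseries()` quantifies how ordered the collective state is:

1. Low-pass the signals below 30 Hz (FFT zeroing) and take instantaneous
   phases $\theta_n(t)$ from the analytic signal. The sub-30 Hz range is
   where delay-induced collective oscillations live; the cutoff is
   configurable, and `f_cut = NULL` skips filtering (useful when the
   synchronized rhythm itself sits at the intrinsic 40 Hz, as in the
   order/disorder contrast test).
2. Slice into 200 ms windows with 50% overlap (left-aligned, wholly inside
   the record; a 40 s record gives exactly $(20000-100)/50 + 1 = 399$
   windows).
3. Per window, compute the phase covariance. "Covariance of phase angles" is
   ambiguous for circular data, so the default forms the Hermitian
   covariance of the unit-modulus phase factors $e^{i\theta_n(t)}$ with
   within-window means subtracted — bounded, wrap-around-safe, positive
   semi-definite with real eigenvalues. `method = "cosine_phase"` (real
   covariance of $\cos\theta_n$) is the alternative.
4. Eigendecompose, clip numerically negative eigenvalues to zero, normalize
   to sum 1, and take Shannon entropy $H = -\sum_n p_n \ln p_n$ (natural
   log; $0\ln 0 \equiv 0$). $H$ ranges from 0 (all variance in one
   collective mode) to $\ln N \approx 4.4998$ for $N = 90$ (flat spectrum,
   full disorder).

**Known resolution limit.** The windowed phase covariance only sees a
collective rhythm whose period is comparable to or shorter than the window:
the within-window variance of $e^{i\theta}$ carried by a locked rhythm of
frequency $f$ scales like $(f \cdot \mathrm{window})^2$ for slow $f$. At
$K = 50$, $\langle\tau\rangle = 10$ ms the collective mode slows to roughly
1 Hz, a 200 ms window holds a fifth of a cycle, and window entropy no longer
drops during MOMs — the measured coalition–entropy correlation in that cell
turns weakly positive, while 600 ms windows (the upper end of the robustness
range) restore a strong anti-correlation. This is a property of the
windowed estimator, not of the underlying coupling between coalitions and
order.

# Coupling coalitions to entropy

The total coalition size is averaged over exactly the entropy windows
(`window_average()`), and the two window series are correlated
(Pearson, two-sided t-test on $W - 2$ degrees of freedom). Overlapping
windows are autocorrelated, so the naive p-value is anti-conservative; it is
reported as such, and `permutation_pvalue()` offers a circular-shift
permutation test (1,000 shifts by default) that preserves autocorrelation
for honest inference. `run_parameter_sweep()` runs the pipeline over the
$3\times3$ grid $K \in \{0.1, 10, 50\}$, $\langle\tau\rangle \in \{0, 3,
10\}$ ms with per-cell seeds derived deterministically from a master seed,
and Bonferroni-corrects with family size $m = 9$ (the grid is the natural
family). Zero-variance cells report `NA` with a reason code rather than
$r = 0$.

# The synthetic connectome

`synthetic_connectome()` stands in for a diffusion-MRI structural connectome
(no imaging data is downloaded or processed). It emulates the features that
matter for the dynamics:

* symmetric, zero-diagonal, non-negative weights;
* heavy-tailed weight distribution: nonzero weights are log-normal
  (`sdlog = 1`, spanning ~2 orders of magnitude, as streamline counts do);
* distances are Euclidean separations of uniform random 3-D positions in a
  brain-sized box (140 × 170 × 120 mm), guaranteeing metric consistency and
  a right-skewed, unimodal delay distribution;
* connection probability decays with distance (nearer pairs connect
  preferentially), with overall density 0.35 of all pairs.

What it does **not** emulate: hemispheric/homotopic block structure, hub
topology, and the exact weight–distance joint distribution of a real
tractography connectome. Consequences observed in this package: the
full-length anti-correlation at the reference parameters lands near
$r \approx -0.75$ to $-0.81$ across seeds rather than exactly at a value
measured on a specific released connectome, and the weakly excitable
$K = 10$, $\langle\tau\rangle = 10$ ms cell produces few MOMs at 10–20 s
durations. Passing tests therefore demonstrate the mechanism and its
statistical signature, not region-level anatomical detail.

# Problem sizes used by tests

Unit tests use 2–30-node networks and 1–8 s records; the end-to-end checks
use the 90-node synthetic connectome with 20 s records for the multi-seed
sign reproduction (199 windows each), the full 40 s record (399 windows) for
the reference-run check, and 20 s per cell for the $3\times3$ sweep. The
demonstration in `run_demo()` writes every artifact (connectome, window
series, events, summary, manifest) and reruns byte-identically under a fixed
seed.

# Worked example

```{r demo, eval = FALSE}
conn <- synthetic_connectome(90, density = 0.35, seed = 1)
params <- sl_params(K = 10, mean_delay = 0.003, duration = 40, seed = 1)
fit <- run_pipeline(params, conn)
glance(fit)
autoplot(fit)

sweep <- run_parameter_sweep(conn, base_params = sl_params(duration = 20),
                             master_seed = 1)
autoplot(sweep)
```

# Limitations

* p-values from overlapping windows are anti-conservative (use the
  permutation test for inference).
* The entropy estimator is blind to rhythms much slower than the window
  (see above); window length should be chosen with the expected collective
  frequency in mind.
* The integrator is first-order in the nonlinear and coupling terms;
  waveform-level agreement between step sizes is not expected, only
  statistical reproduction.
* Only delimited text connectome matrices are read.
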