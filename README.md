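# momentropy

Coupled-oscillator whole-brain modelling: simulate a network of
Stuart–Landau oscillators on a structural connectome with conduction
delays, detect **Metastable Oscillatory Modes (MOMs)** — transient
coalitions of regions whose band-limited amplitude surges far above a
no-delay baseline — and track system-level order through the **Shannon
entropy of the eigenvalue spectrum of sliding-window phase covariance**.
The package is for computational neuroscientists studying how transient
synchronization shapes the entropy of large oscillator networks.

## The model

Each of N brain regions is a Stuart–Landau unit (the Hopf normal form) in
the subcritical regime, coupled diffusively through connectome weights
C with delays proportional to fiber distance:

```
dZn/dt = Zn (a + iω − |Zn|²) + K Σp Cnp [Zp(t − τnp) − Zn(t)] + β(η₁ + iη₂)
```

with a = −5, ω = 2π·40 Hz, β = 0.001, τnp ∝ Dnp rescaled to a mean delay
⟨τ⟩. Delays slow and de-damp collective eigenmodes; near criticality these
modes amplify the noise into intermittent sub-gamma bursts (MOMs). A node
joins a coalition when its band-limited Hilbert envelope exceeds
mean + 5 SD of a zero-delay twin run; events need ≥ 5 simultaneous nodes.
System entropy per 200 ms window (50% overlap) is H = −Σ p ln p over the
normalized eigenvalues of the phase covariance: 0 when one collective mode
dominates, ln N when all modes are equal. The headline analysis correlates
window-averaged total coalition size with H(t).

## Worked example

```r
library(momentropy)

conn   <- synthetic_connectome(90, density = 0.35, seed = 1)
params <- sl_params(K = 10, mean_delay = 0.003, duration = 40, seed = 1)
fit    <- run_pipeline(params, conn)
glance(fit)
#> # A tibble: 1 × 6
#>        r  p_value n_windows mean_coalition mean_entropy n_events
#>    <dbl>    <dbl>     <int>          <dbl>        <dbl>    <int>
#> 1 -0.796 1.36e-88       399           2.67         1.94       46
```

At the reference regime (K = 10, ⟨τ⟩ = 3 ms) the 40 s run yields 399
analysis windows, 46 classified MOM events, and a strong anti-correlation
(r = −0.80) between coalition size and entropy: when many regions surge
together, the system's variance concentrates in few eigenmodes and entropy
drops. `autoplot(fit)` overlays the two standardized window series;
`tidy(fit)` returns them as a tibble.

The regime sweep:

```r
sweep <- run_parameter_sweep(conn, base_params = sl_params(duration = 20),
                             master_seed = 1)
sweep[, c("K", "tau_ms", "r", "p_adj")]
#> # A tibble: 9 × 4
#>        K tau_ms        r     p_adj
#>    <dbl>  <dbl>    <dbl>     <dbl>
#> 1    0.1      0  0.119   8.53e-  1
#> 2    0.1      3 -0.0203  1   e+  0
#> 3    0.1     10  0.0319  1   e+  0
#> 4   10        0  0.0247  1   e+  0
#> 5   10        3 -0.780   4.75e- 41
#> 6   10       10 -0.0737  1   e+  0
#> 7   50        0 -0.190   6.55e-  2
#> 8   50        3 -0.947   1.67e- 98
#> 9   50        10  0.484   3.88e- 12
```

Low coupling or zero delay leaves both series nearly flat (no MOMs); the
strongly metastable cells (⟨τ⟩ = 3 ms, K ∈ {10, 50}) show large coalitions
and strong, Bonferroni-significant anti-correlations. At K = 50,
⟨τ⟩ = 10 ms the collective rhythm slows to ~1 Hz, below what a 200 ms
window resolves — see the methods vignette
(`vignettes/momentropy-methods.Rmd`) for this estimator limit and all
modelling choices.

`run_demo("out", seed = 1)` runs the whole chain on a synthetic connectome
and writes connectome CSVs, window series, MOM events, a summary and a
re-run manifest.

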