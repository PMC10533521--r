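# flagellaRD

Eukaryotic flagella and cilia beat because thousands of dynein motors,
engaged in a tug-of-war across the elastic axoneme, destabilise the
straight configuration and saturate into travelling waves. `flagellaRD`
implements a minimal, geometrically exact reaction–diffusion (RD) model
of this process for people who want to simulate beating patterns, test
the sliding-control hypothesis against waveform data, or study Hopf
bifurcations and pattern formation on an animated elastic structure.

The state is the shear angle $\gamma(s,t) = \theta(s,t) - \theta(0,t)$
and the bound motor fractions $n^\pm(s,t)$ on the two filaments, with
nondimensional dynamics

$$\mu_a \zeta\,\bar n\,\gamma_t = \gamma_{ss} - \mu\gamma + \mu_a\tilde n,
\qquad
n^\pm_t = \eta(1 - n^\pm) - (1-\eta)\,n^\pm e^{f^*(1 \pm \zeta\gamma_t)},$$

$\tilde n = n^- - n^+$, $\bar n = n^- + n^+$, $\gamma(0)=0$,
$\gamma_s(1)=0$. Only the shear "diffuses" (via bending elasticity
against motor friction); the motors react in place. The quiescent state
loses stability at

$$\mu_a^{\rm crit} = \frac{\pi^2 + 4\mu}{8 n_0 \bar\zeta\,\omega_0^2},
\qquad n_0 = \frac{\eta}{\eta + (1-\eta)e^{f^*}},\quad
\omega_0^2 = (1-n_0)f^* - 1,\quad
\bar\zeta = \zeta\,(\eta + (1-\eta)e^{f^*}),$$

and $\epsilon = (\mu_a - \mu_a^{\rm crit})/\mu_a^{\rm crit}$ measures
distance to the bifurcation: standing waves just above onset, base-to-tip
travelling waves at $\epsilon = O(1)$ and beyond.

The package provides:

- closed-form linear stability (`stability_summary`, `critical_activity`,
  `bifurcation_distance`, `linear_growth_and_frequency`);
- stiff simulators for the isolated shearing element
  (`simulate_element`) and the full PDE (`simulate_rd`, compiled
  method-of-lines RHS, optional DAE path), plus the no-feedback
  diffusion limit and its series solution (`diffusion_closed_form`);
- waveform analysis: fundamental Fourier modes of kymographs
  (`fundamental_mode`), phase alignment and the $R^2$ fit score
  (`r_squared`), wavenumber from spatial autocorrelation
  (`wavenumber`), centerline reconstruction;
- a grid-search fit of the three motor parameters $(\mu_a,\eta,\zeta)$
  to a target mode (`fit_beat`, returning a classed object with
  `print`/`summary`/`coef`/`plot` methods);
- a seeded synthetic-data generator (`synthesize_beat_record`)
  emulating the two experimental recording dialects (tangent angle,
  19 points / 1 ms; curvature, 30 points / 4 ms), so the whole pipeline
  runs without downloads.

A thin command-line front end (`inst/cli/flagellard`) exposes
`stability`, `simulate-element`, `simulate-rd`, `analyze`, `synth` and
`fit` subcommands over the same functions.

## Worked example

Stability of the mean fitted wild-type *C. reinhardtii* parameters, a
simulation near onset, and its fundamental mode:

```r
library(flagellaRD)

print(stability_summary(rd_params(1570, 10, 0.096, 0.96, fstar = 2)))
#> Linear stability of the flagellar RD model
#>   parameters: mu_a = 1570, mu = 10, eta = 0.096, zeta = 0.96, f* = 2
#>   n0 = 0.014168   omega0^2 = 0.97166   zeta_bar = 6.5047
#>   mu_a_crit = 69.613   (single element nu_a_crit = 5.5836)
#>   epsilon = 21.55  (supercritical: spontaneous oscillations)
#>   linear frequency undefined at this epsilon (overdamped branch)

crit <- critical_activity(100, 0.14, 0.3, 2)   # 1274.8
sim <- simulate_rd(rd_params(1.2 * crit, 100, 0.14, 0.3, 2),
                   t_end = 140, dt_out = 0.02)
gm <- measure_growth_rate(as_kymograph(sim))
round(c(alpha = gm$alpha, omega = gm$omega), 4)
#>  alpha  omega
#> 0.5152 5.7821
```

The measured growth rate and frequency sit within 1% of the linear
prediction at this $\epsilon = 0.2$ (0.5179 and 5.7763 after converting
the closed forms to simulation time units). Fitting a noisy synthetic
record back to its generating parameters:

```r
truth <- rd_params(2500, 100, 0.14, 0.3, 2)
rec <- synthesize_beat_record(truth, "chlamy_theta_19pt_1ms",
                              noise_sigma = 0.02, seed = 1)
grid <- parameter_grid(100, mu_a = c(2000, 2500, 3000),
                       eta = c(0.10, 0.14), zeta = c(0.3, 0.4))
fit <- fit_beat(rec, grid, mu = 100)
print(fit)
#> RD beat fit (grid search)
#>   mu fixed at 100, f* = 2; 12 candidates evaluated
#>   best (mu_a, eta, zeta) = (2500, 0.14, 0.3), R^2 = 1.0000
#>   target omega = 314.2, fitted-model omega = 4.775 (frequencies reported, not matched)
```

The generator's parameters are recovered exactly and the aligned mode
overlap $R^2$ is essentially 1; the target frequency is in rad/s (the
record carries physical time), the simulated one in inverse motor time
units — shapes, not frequencies, are scored.

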