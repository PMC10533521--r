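---
title: "A reaction-diffusion model of the flagellar beat: methods and design"
author: "flagellaRD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reaction-diffusion model of the flagellar beat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagellaRD)
```

## The model

The axoneme of a eukaryotic flagellum is modelled in its bending plane
as two filaments at fixed spacing $a$, cross-linked by passive elastic
elements (stiffness $K$ per unit length) and by two antagonistic teams
of dynein motors. Bound motors obey a linear force--velocity relation
with stall force $f_0$ and zero-load velocity $v_0$, so each motor acts
as a force generator with internal drag $\xi^m = f_0/v_0$. Writing
$n^\pm(s,t)$ for the bound fractions of the two teams and
$\gamma(s,t) = \theta(s) - \theta(0)$ for the shear angle (sliding
$\Delta = a\gamma$), the tangential force from the cross-linkers is

$$f^t = \rho f_0\left[\tilde n - \bar n\,\frac{\Delta_t}{v_0}\right] - K\Delta,
\qquad \tilde n = n^- - n^+,\ \ \bar n = n^- + n^+ .$$

Motor kinetics follow a two-state tug-of-war with load-dependent
detachment: attachment at base rate $\pi_0$ proportional to the unbound
fraction, detachment at base rate $\epsilon_0$ amplified exponentially
by the motor load relative to a characteristic unbinding force $f_c$.
When the team driving the current sliding direction gains members its
load per motor drops, detaching fewer motors — the positive feedback
that destabilises the quiescent state.

Balancing the active moment against bending elasticity only (bending
rigidity $B$; the regime where external viscous moments are negligible
compared to internal shear moments) gives, after nondimensionalising
lengths by $L$ and time by $\tau = (\pi_0+\epsilon_0)^{-1}$,

$$\mu_a \zeta\, \bar n\, \gamma_t = \gamma_{ss} - \mu\gamma + \mu_a \tilde n,
\qquad
n^\pm_t = \eta(1-n^\pm) - (1-\eta)\,n^\pm
  e^{f^*(1\pm\zeta\gamma_t)},$$

with boundary conditions $\gamma(0)=0$ (clamped base) and
$\gamma_s(1)=0$ (free tip). This is a reaction--diffusion system in
$(\gamma, n^+, n^-)$: only the shear diffuses (through bending
elasticity combined with motor friction), while the motors are anchored
in place. Five dimensionless groups control everything:

| parameter | meaning | typical values used here |
|---|---|---|
| $\mu_a = a\rho f_0 L^2/B$ | motor activity vs bending stiffness | $10^2$–$10^4$ |
| $\mu = a^2 K L^2/B$ | shear vs bending stiffness | 10 (chlamydomonas-like), 100 (sperm-like) |
| $\eta = \pi_0\tau$ | motor duty parameter, $(0,1)$ | 0.05–0.5 |
| $\zeta = a/(v_0\tau)$ | motor friction parameter | 0.1–1.3 |
| $f^* = f_0/f_c$ | stall force vs unbinding force | 2 |

$f^*$ defaults to 2: this single choice reproduces all three published
bifurcation distances (21.6, 19.1, 5.92--5.93; see below)
simultaneously, and it is exposed as a configurable field everywhere
rather than hard-coded.

## Linear stability and its time units

The quiescent state has bound fractions
$n_0 = \eta/(\eta + (1-\eta)e^{f^*})$. An isolated shearing element
($f^t = 0$ plus the kinetics) undergoes a Hopf bifurcation at
$\nu_a^{\rm crit} = (2\bar\zeta n_0 \omega_0^2)^{-1}$ where
$\omega_0^2 = (1-n_0)f^* - 1$ and
$\bar\zeta = \zeta(\eta + (1-\eta)e^{f^*})$ is the friction parameter
rescaled by the equilibrium motor time
$\bar\tau = (\pi_0 + \epsilon_0 e^{f^*})^{-1}$ (the identity follows
from $\bar\zeta/\zeta = \tau/\bar\tau$). The spatially extended system
bifurcates at

$$\mu_a^{\rm crit} = \frac{\pi^2 + 4\mu}{8 n_0 \bar\zeta \omega_0^2},$$

whose $\pi^2\to 0$ limit recovers $\mu\,\nu_a^{\rm crit}$. Distance to
the bifurcation is $\epsilon = (\mu_a - \mu_a^{\rm crit})/\mu_a^{\rm crit}$,
and near onset the growth rate and frequency are

$$\alpha = \frac{\epsilon\,\omega_0^2}{2(1+\epsilon)}, \qquad
\omega^2 = \frac{1+\epsilon - \tfrac14\omega_0^2\epsilon^2}{(1+\epsilon)^2}\,
\omega_0^2 .$$

One unit subtlety matters in practice: these closed forms are expressed
per $\bar\tau$, while the governing equations (and hence simulation
time) run in $\tau$. Multiplying $\alpha$ and $\omega$ by
$\bar\zeta/\zeta$ converts them to simulation units;
`stability_summary()` does this, and with the conversion the simulated
growth rate and frequency agree with the formulas to well under 1% for
$\epsilon \le 0.4$ (the package's acceptance tests check 5%). Without
it the two disagree by a factor of $\approx 6.5$ at $f^*=2$, which is a
useful diagnostic that an implementation has mixed the two clocks.

When $\omega_0^2 \le 0$ (no oscillatory regime) the stability
operations raise typed errors rather than returning complex numbers:
the linear theory is only meaningful on the oscillatory branch. The
same policy applies far from onset where the bracket in $\omega^2$
turns negative ("overdamped" error).

Near onset the unstable mode is a standing wave
$\gamma = A\,e^{(\alpha + i\omega)t}\sin(\pi s/2)$ — in-phase shear
oscillation along the whole flagellum with a quarter-sine envelope. As
$\epsilon$ grows to order one, the oscillation develops a monotone
base-to-tip phase gradient: a travelling wave, which is what propels.

## Numerics

**Discretization.** $m$ equally spaced arclength points (default
$m = 101$), second-order centred differences in the interior, a ghost
node for the free tip, and a penalization equation
$\gamma_{t,0} = -\gamma_0$ (coefficient exactly 1) at the base. The
Laplacian prefactor is the squared inverse spacing $(m-1)^2$; the
variant $m^2$ is selectable via `grid_factor = "m2"` for
exact-replication studies (at $m = 101$ the two differ by 2% in the
discrete prefactor only). Shear rate is solvable in closed form at
every node, so the method of lines applies directly.

**Time stepping.** A stiff BDF integrator (deSolve's `lsode`,
`mf = 25`) with a banded numeric Jacobian over the interleaved state
$(\gamma_i, n^+_i, n^-_i)$ and a compiled right-hand side. Default
tolerances are `rtol = 1e-8`, `atol = 1e-10`: the detachment exponent
$e^{f^*(1\pm\zeta\gamma_t)}$ is violently stiff whenever
$|\zeta\gamma_t|$ is large, which happens routinely at the fitted
parameter regimes ($\epsilon \approx 20$) where the motor populations
nearly empty during each relaxation-like cycle. Two numerical guards
keep the implicit solver stable without altering reachable dynamics:
$\bar n$ is floored at $10^{-10}$ and the detachment exponent clipped
at 500 — both only ever active for non-physical Newton iterates. A DAE
path (`method = "daspk"`, residual form) is available behind the same
interface for very high activity. Candidate sweeps in the fitter run at
`rtol = 1e-6`, `atol = 1e-8`: extracted fundamental modes agree with
the tight-tolerance reference to $R^2 = 1$ within $10^{-6}$, at half
the cost.

**Initial condition.** A Gaussian bump
$\gamma(s,0) = 0.001\,e^{-((s-0.5)/0.1)^2}$ with motors at $n_0$. (The
positive exponent sometimes seen in print is a typo: it is unbounded
and contradicts "small perturbation".)

**Diffusion limit.** With detachment frozen at its equilibrium value
the system reduces to $\gamma_t = D\gamma_{ss} - E\gamma$ with
$D = (2 n_0 \mu_a \zeta)^{-1}$, $E = \mu D$, solved in closed form in
the half-integer sine basis; `diffusion_closed_form()` truncates at a
configurable order (default 400, tail coefficient reported) and the
solver matches it to better than $10^{-4}$ absolute over five decay
times at $m = 101$.

## Waveform analysis

`fundamental_mode()` removes the per-point time mean, estimates the
dominant frequency from the raw spatially averaged periodogram (no
window, no peak interpolation — peak-picking on the bare bin), truncates
to an integer number of estimated periods to limit leakage, and returns
the complex one-sided mode $\tilde\gamma(s)$ at the peak bin. A
20-period minimum record is required by default; candidate simulations
in the fitter analyse the final 50 time units of a 100-unit run, which
near onset holds fewer than 20 periods, so the sweep relaxes the
requirement to 5 periods — synthetic records destined for the
"experimental" side are always generated with at least 20.

Phase alignment between two modes uses the closed form
$\phi = \arg\sum_i \tilde\gamma_{\rm exp}(s_i)
\overline{\tilde\gamma_{\rm sim}(s_i)}$, which minimizes
$\sum_i |\tilde\gamma_{\rm exp} - e^{i\phi}\tilde\gamma_{\rm sim}|^2$
(expand the square: the $\phi$-dependent term is
$-2\,\mathrm{Re}[e^{-i\phi}\sum \tilde\gamma_{\rm exp}
\overline{\tilde\gamma_{\rm sim}}]$). The fit score is

$$R^2 = 1 - \frac{\sum_i |\tilde\gamma_{\rm exp}(s_i) -
e^{i\phi}\tilde\gamma_{\rm sim}(s_i)|^2}{\sum_i
|\tilde\gamma_{\rm exp}(s_i)|^2}.$$

The dominant wavenumber comes from the spatial autocorrelation of the
detrended field averaged over time. The lag sum is normalized by the
number of valid pairs at each lag: an unnormalized sum weights small
lags by their larger overlap, which biases extremum locations by up to
~10% of the domain and breaks the exact identities $q = 2\pi$ and
$4\pi$ for one- and two-wavelength test signals; with pair
normalization those identities hold to within one lag bin. When the
beat holds less than one full spatial oscillation, the wavelength is
twice the lag of the deepest valley. Ties between equal-magnitude peaks
(exactly periodic signals) are broken toward the smallest lag, i.e. the
fundamental period.

A static (asymmetric) beat component enters as
$\gamma \to \gamma - Cs$: it shifts neither $\gamma_t$ nor
$\gamma_{ss}$, so the oscillatory dynamics superpose on it and the
fitter works on the mean-subtracted oscillatory part only.

## Fitting

`fit_beat()` grid-searches $(\mu_a, \eta, \zeta)$ at fixed $\mu$
(order-of-magnitude estimates: 10 for *C. reinhardtii*, 100 for bull
sperm, the difference mostly the $L^2$ scaling of $\mu$). Default axis
steps are $(100, 0.04, 0.1)$ at $\mu = 10$ and $(1000, 0.04, 0.1)$ at
$\mu = 100$; the published sweep totals cannot be reconstructed from
the printed steps alone, so the default bounds
($\mu_a \in [100, 3000]$ resp. $[1000, 10^4]$, $\eta \in [0.02, 0.5]$,
$\zeta \in [0.1, 1.3]$) are chosen to bracket all published estimates
with margin, and every axis is configurable. Candidates that are
subcritical in closed form decay to a zero mode and score 0 with a
logged reason — they are not simulated and never abort a sweep; ties in
$R^2$ break toward the lexicographically smallest parameters. Only the
mode *shape* enters the score; simulated and target frequencies are
reported side by side but not matched, since simulation time is
nondimensional. There is deliberately no continuous optimizer: the
grid is the model space.

## Synthetic data

`synthesize_beat_record()` emulates the two recording dialects the
preprocessing supports: tangent angle at 19 arclength points every
1 ms, and curvature at 30 points every 4 ms. It runs the model through
a 100-unit transient, measures the limit-cycle period, continues for
`n_periods` beats (default 24), optionally superposes a static
curvature, converts to the dialect field (curvature by central
differences on the fine grid before downsampling), downsamples to the
dialect geometry, and finally adds seeded i.i.d. Gaussian noise
(default 0.02 rad, small against the O(1) rad beat) — noise after
downsampling, matching measurement semantics. The tau-to-seconds
factor is fixed by a nominal beat frequency (50 Hz chlamydomonas-like,
20 Hz sperm-like). Everything needed to regenerate the record bitwise
is stored as ground truth, in a sidecar the fitter never reads.

What the generator does *not* emulate: cell-body yaw and lab-frame
drift, tracking artifacts, non-Gaussian or spatially correlated noise,
basal sliding, and any real biological variability between beats.
Passing parameter-recovery tests on these records therefore
demonstrates that the pipeline is self-consistent and robust to
measurement-scale noise — not that the model fits any particular real
cell.

## Problem sizes used by the tests and acceptance script

The acceptance targets themselves are closed-form (the three fitted
parameter sets' $\epsilon$). The simulation-backed checks use: three
runs to $t \le 180$ for growth/frequency; two runs for the
standing/travelling wave contrast; one no-feedback run over five decay
times; a bisection of about a dozen element runs for the Hopf point;
and a 27-candidate sweep (the published $\mu = 100$ steps
$(1000, 0.04, 0.1)$ around the fitted bull-sperm parameter set as
ground truth, $\le 200$ candidates by design) shared across ten noise
seeds for parameter recovery. These sizes were chosen as the smallest
that exercise each claim cleanly; at the chosen conditions the
noiseless on-grid target is recovered exactly, so the noisy-recovery
criterion tests robustness to the noise level, not grid resolution.

## Known limitations

- No hydrodynamic coupling: the model describes beat *shaping* in the
  regime where external viscous moments are small; swimming kinematics
  and any moderate-to-high viscosity regime are out of scope.
- Basal sliding is fixed at zero; basal compliance is known to matter
  for some datasets and is not representable here.
- Planar beating only.
- The mean-field motor kinetics are deterministic; stochastic motor
  number fluctuations are absent.
- Far from onset ($\epsilon \gtrsim 10$) the dynamics are
  relaxation-like and expensive to integrate at tight tolerance; the
  implementation is robust there, but individual runs take seconds
  rather than fractions of a second.
- Deep in that regime the motor parameters also become partially
  degenerate: at a wild-type-like point ($\mu_a = 1500$,
  $\eta = 0.10$, $\zeta = 0.9$, $\mu = 10$, $\epsilon \approx 20$)
  the neighbour $(\mu_a, \eta) = (1300, 0.14)$ reproduces the
  fundamental mode to $R^2 = 0.9995$ — beyond the 19-point recording
  dialect's own round-trip fidelity — so $\mu_a$ and $\eta$ are only
  *jointly* identifiable there, with or without measurement noise.
  Fits in this regime should be read as constraining a ridge in
  $(\mu_a, \eta)$ rather than each parameter to one grid step; the
  package's recovery validation therefore uses the moderately
  supercritical bull-sperm point, where one-step identifiability
  holds.
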