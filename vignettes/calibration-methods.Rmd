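---
title: "Calibrating optical traps by Kramers-Moyal reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating optical traps by Kramers-Moyal reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otcalib)
```

## The model

A micron-sized bead held in an optical trap at low Reynolds number follows
an overdamped Langevin equation. In the classical linear picture the
restoring force is Hookean, $F = -kx$, the thermal noise is white, and

$$\gamma \dot x + k x = \sqrt{2 k_B T \gamma}\,\Gamma(t),
\qquad \gamma = 6\pi\eta a ,$$

with $\Gamma$ zero-mean, delta-correlated Gaussian noise. Dividing by the
drag $\gamma$ puts this into the general diffusion form this package works
with throughout,

$$\dot x = D^{(1)}(x) + \sqrt{2 D^{(2)}(x)}\,\Gamma(t)
\qquad \text{(Itô convention)},$$

where the linear theory corresponds to a linear drift and a constant
diffusion coefficient:

$$D^{(1)}(x) = -\tfrac{k}{\gamma}\,x \equiv -Qx, \qquad
D^{(2)}(x) = \tfrac{k_B T}{\gamma}.$$

The classical power-spectrum (PS) calibration rests on both assumptions:
the position spectrum is then the Lorentzian
$p(f) = D/(2\pi^2(f^2 + f_c^2))$ with corner frequency
$f_c = k/(2\pi\gamma)$, and fitting $(f_c, D)$ yields the stiffness and,
through $\beta = \sqrt{D_{SI}/D_V}$, the volt-to-metre conversion factor of
the detector.

The point of the nonlinear analysis implemented here is that neither
assumption needs to be taken on faith: for a Markov process, drift and
diffusion can be read off the data directly as the zero-lag limits of
conditional moments,

$$D^{(k)}(x) = \frac{1}{k!}\lim_{\Delta t\to 0}
  \frac{1}{\Delta t}\left\langle (x(t+\Delta t)-x)^k \,\middle|\, x(t)=x
  \right\rangle, \qquad k = 1, 2, 4,$$

which makes the position dependence of $D^{(2)}$ an empirical question.
Detector records of trapped beads show a nearly quadratic
$D^{(2)}(x) = a + b x^2$, and when $b > 0$ the PS method, which has no
room for it, overestimates the stiffness and underestimates $\beta$. The
package provides both branches side by side so the discrepancy is visible
record by record.

## Workflow

1. **Markov check** (`scan_me_timescale`): the Kramers-Moyal (KM) limit
   only makes sense above the Markov-Einstein time scale. Empirical
   three-point statistics at spacing $\Delta$ are compared with their
   Chapman-Kolmogorov reconstruction
   $p_{\mathrm{Mar}}(x_1,x_2,x_3) = p(x_3|x_2)\,p(x_2,x_1)$ through a
   reduced $\chi^2$; the spacing minimizing $\chi^2_\nu$ estimates
   $\tau_M$.
2. **Pawula check** (`pawula_ratio`): the median of $|D^{(4)}|/D^{(2)}$
   over bins, conventionally on the variance-standardized series. Small
   values justify truncating the KM expansion to a Fokker-Planck equation,
   i.e. treating the record as a diffusion.
3. **KM estimation** (`km_coefficients`, `fit_drift`, `fit_diffusion`):
   binned conditional moments at several lags, extrapolated per bin to
   zero lag, then weighted straight-line and quadratic fits give
   $\hat Q$, $\hat a$, $\hat b$.
4. **PS branch** (`periodogram`, `fit_lorentzian`): blocked periodogram
   and an iterated weighted Lorentzian fit give $(\hat f_c, \hat D)$.
5. **Report** (`calibrate`): stiffnesses $k = \gamma Q$, conversion
   factors $\beta$, and percent relative differences with the PS value as
   reference.

## Estimator details and numerical choices

**Simulator.** `simulate_langevin` integrates the Itô equation with the
explicit Euler-Maruyama scheme, the diffusion evaluated at the
pre-increment state. Normals come from a counter-based generator
(splitmix64 + Box-Muller), so a seed fully determines a trajectory
without touching R's global RNG. The default burn-in of $10/(Q\,dt)$
steps (ten relaxation times) erases the initial condition; `x0` defaults
to the trap centre. A warning is emitted when $Q\,dt > 0.01$, where the
scheme's $O(Q\,dt/2)$ drift bias passes half a percent. For $b > 0$ the
stationary variance is $D_0/(Q-b)$ (finite only for $Q > b$), which the
simulator reproduces and the test suite checks against numerical
quadrature of the stationary density
$p(x)\propto (D_0 + b x^2)^{-(1 + Q/2b)}$.

**Binning.** The default grid is 50 equal-width bins spanning the sample
mean ± 4 standard deviations with at least 100 pairs per bin at every
lag; bins failing the threshold are excluded and reported. With
$10^7$-sample records this keeps per-bin standard errors at the percent
level while resolving the curvature of $D^{(2)}$.

**Zero-lag extrapolation.** At finite lag $\tau$ the scaled moments carry
an $O(\tau)$ bias; for a harmonic trap the single-lag diffusion estimate
acquires a spurious quadratic term $(1-e^{-Q\tau})^2/(2\tau)\,x^2$, which
for $Q = 5000$ and $\tau = 1\,\mu s$ equals $12.4$ — easily mistaken for
real position dependence. The default therefore fits $M_k(x,\tau)/\tau$
against $\tau$ over lags $\{1,\dots,5\}\,dt$ per bin (weighted by the
within-bin standard errors) and uses the intercept. The leading
correction is linear in $\tau$, so a straight line suffices over short
lags; the residual $O(\tau^2)$ curvature biases the diffusion intercept
by only $\sim 0.5\%$ at the synthetic study conditions. A flag falls back
to the smallest lag for users who want the raw (biased) estimate.

**Standard errors.** Conditional SEs come from the within-bin sample
standard deviation of the $k$-th powered increments. Because every
overlapping pair along the record enters the averages, increments from
neighbouring time points share most of their path and the nominal SEs
understate the true sampling scatter; seed-replication experiments at the
synthetic study conditions show the drift-slope and quadratic-coefficient
errors exceed the nominal fit SEs by a factor of roughly 2-3 (about 2.5
on average). The suite's recovery checks therefore use three standard
deviations of the *measured* sampling law, e.g.
$3 \times 2.5\sqrt{2/(QT)}$ for the relative drift-slope error on a
record of length $T$. The nominal SEs are still reported — they are the
right relative weights across bins — but should not be read as marginal
1-sigma errors at small lags.

**Lorentzian fit.** The blocked periodogram averages per-segment
two-sided periodograms $|x(f)|^2/L$ after per-block mean removal; its
normalization satisfies Parseval (spectral mass = demeaned block
variance, within 1% whenever blocks span many relaxation times). The fit
minimizes weighted squared residuals with weights
$n_{\mathrm{blocks}}/p_{\mathrm{model}}^2$, iterated until the weights
are evaluated at the converged model. The one-shot closed-form variant
(regressing 1 on $(p, p f^2)$) is used only as the initializer: its
normal equations are quadratic in the data, which biases $D$ upward by
$O(1/n_{\mathrm{blocks}})$, whereas the iterated fit's estimating
equations are unbiased. The default window is $[3/L, f_{Nyq}/4]$: the
quarter-Nyquist cap keeps the discrete-sampling (aliasing) flattening of
the sampled spectrum — a universal factor $\pi^2/4$ at Nyquist relative
to the continuous Lorentzian — from inflating the fit by more than
$\sim 2\%$. Fits on exact Lorentzian input recover the generating
parameters to numerical precision.

**Markov test.** Probabilities are estimated as densities (counts over
cell volume), and the $\chi^2$ denominators use multinomial counting
variances: $\sigma^2 = c/(T V)^2$ for the three-point density and a
delta-method propagation $p_{\mathrm{Mar}}^2(1/c_{23}+1/c_{12}+1/c_2)$
for the reconstruction. Cells with Markov-expected triple counts below 5
are excluded; equal spacing $\Delta = t_2-t_1 = t_3-t_2$ is enforced. The
statistic is invariant under affine rescaling of data and grid together.
The default 12-bins-per-axis grid over mean ± 3 SD keeps expected counts
above the threshold for records of $10^5$ samples and up. Two caveats are
worth knowing. First, the error model neglects the covariance between the
empirical and reconstructed densities and the correlation of overlapping
triples, so when the sampling interval is much shorter than the
relaxation time the reduced $\chi^2$ at the smallest spacings rises above
one even for exactly Markov records; the scan is a diagnostic for
*structure* in $\Delta$, not an absolute goodness-of-fit. Second, a
Wilcoxon-type alternative exists but is not implemented. On records
band-limited by a moving-average filter the profile is large below the
filter window and drops to the noise floor above it, which is the
behaviour the estimator of $\tau_M$ keys on; ties prefer the smallest
spacing, so an everywhere-Markov record reports the smallest scanned
$\Delta$.

**Pawula diagnostic.** For a diffusion sampled at lag $\tau$, Gaussian
transition statistics force $D^{(4)}/D^{(2)} = D^{(2)}\tau/2$ at the
smallest lag, which on the variance-standardized series is about
$Q\tau/2$ — e.g. $5\times10^{-4}$ for $Q=1000$ at $\tau=1\,\mu s$. After
zero-lag extrapolation the ratio collapses to its noise floor
($\sim 10^{-5}$–$10^{-4}$ at the study conditions), well under the
$10^{-3}$ level conventionally taken to justify the Fokker-Planck
truncation. `calibrate` reports the extrapolated, variance-normalized
ratio.

## What the synthetic generator does and does not emulate

The generator reproduces the study conditions used for validation:
records of $10^7$ points at $dt = 10^{-6}$ (simulation units), linear
traps with $Q \in \{1000, 3000, 5000\}$, $D_0 = 50$, and
multiplicative-noise traps with $(Q, D_0, b) = (7100, 52, 1040)$,
$(4100, 24, 506)$, $(1500, 2, 28)$. These numbers are dimensionless
stand-ins chosen to be comparable with experimental values; `preset_models`
exposes them and `run_synthetic_suite` runs both branches over all six.

It does *not* emulate detector physics: no measurement noise floor, no
low-pass filtering of the photodiode, no aliasing from a finite
acquisition bandwidth beyond what discrete sampling itself introduces, no
drift of the trap centre, and no laser-power fluctuations. Passing the
synthetic suite therefore demonstrates the correctness of the estimators
on ideal diffusions, not robustness to instrumentation artifacts — on
real records the Markov scan exists precisely to detect the scale below
which such artifacts (e.g. filtering) break the diffusion picture.

On linear synthetic data the two branches agree: the Lorentzian fit
recovers $Q$ and $D_0$ to within a couple of percent and the KM branch
recovers them within its sampling error. On multiplicative-noise data the
KM branch recovers $(Q, D_0, b)$, while the Lorentzian fit returns an
inflated force constant and a diffusion value near the count-weighted
stationary average $D_0 Q/(Q-b)$ of $D^{(2)}(x)$ — the expected behaviour
of a constant-diffusion model confronted with state-dependent noise. A
quantitative note for reproducers: because the drift is linear, the
stationary autocovariance of the simulated record is exactly
$\mathrm{var}\cdot(1-Q\,dt)^k$ *regardless of* $b$, so the expected
periodogram of a multiplicative-noise record is that of a linear trap
with effective diffusion $D_0 Q/(Q-b)$; the PS stiffness inflation from
this pipeline is correspondingly a few percent (it comes from the sampled
spectrum's shape, not from $b$ directly), e.g. about $7.3\times10^3$
fitted for the $(7100, 52, 1040)$ set.

## Problem sizes in the tests

The test suite exercises the full study conditions ($10^7$ samples) for
the parameter-recovery and acceptance checks, and smaller records
($2\times10^5$–$2\times10^6$) for distributional properties where the
extra length adds nothing; the Markov fixtures use $4\times10^5$ samples
at two samples per relaxation time so that neighbouring triples
decorrelate. The acceptance script regenerates every quantity from
scratch at the full study conditions in about a minute.

## Known limitations

* Nominal per-bin SEs are anti-conservative at small lags (overlapping
  pairs), as quantified above.
* The zero-lag extrapolation is linear; records sampled so coarsely that
  $Q\tau_{\max} \gtrsim 0.3$ need either shorter lag lists or a quadratic
  extrapolant.
* The PS branch implements the plain Lorentzian only — no
  hydrodynamic-memory, detector-filter or aliasing corrections; a user
  wanting them can fit the periodogram object with any model function.
* One-dimensional records only; dual-axis traps are analyzed per axis.
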