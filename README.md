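# otcalib

Nonlinear calibration of optical tweezers from bead-position time series.

Optical traps are calibrated so that the detector signal (volts) can be
converted into displacement and force. The standard power-spectrum (PS)
method fits a Lorentzian

$$p(f) = \frac{D}{2\pi^2 (f^2 + f_c^2)}$$

to the position spectrum, reads the stiffness off the corner frequency
($k = 2\pi\gamma f_c$, with Stokes drag $\gamma = 6\pi\eta a$) and the
volt-to-metre factor off the fitted diffusion coefficient
($\beta = \sqrt{D_{SI}/D_V}$, $D_{SI} = k_B T/\gamma$). This assumes the
bead's diffusion coefficient is constant across the trap. In practice it is
not: detector records show a nearly quadratic
$D^{(2)}(x) = a + b\,x^2$, in which case the PS method overestimates the
stiffness and underestimates $\beta$ — a direct error on any force
measurement made with the trap.

`otcalib` implements the data-driven alternative: treating the record as a
Markov diffusion, it estimates the drift function $D^{(1)}(x)$ and
diffusion function $D^{(2)}(x)$ non-parametrically from binned
Kramers-Moyal conditional moments,

$$D^{(k)}(x) = \frac{1}{k!}\lim_{\Delta t \to 0} \frac{1}{\Delta t}
\big\langle (x(t{+}\Delta t) - x)^k \,\big|\, x(t) = x \big\rangle ,$$

with per-bin extrapolation to zero lag, and reconstructs the Langevin
equation $\dot x = D^{(1)}(x) + \sqrt{2 D^{(2)}(x)}\,\Gamma(t)$ (Itô). It
also provides the supporting checks — a three-point $\chi^2$ test for the
Markov-Einstein time scale and the Pawula ratio $D^{(4)}/D^{(2)}$ — the
classical PS branch for comparison, and an Euler-Maruyama simulator of
multiplicative-noise traps used to validate the whole pipeline end to end.

Intended users: single-molecule biophysicists calibrating optical tweezers,
and more generally anyone reconstructing drift/diffusion laws from uniformly
sampled time series.

## Worked example

Simulate a multiplicative-noise trap at the validation study conditions
(scaled down to 2×10⁶ samples) and calibrate it with both branches:

```r
library(otcalib)
model <- langevin_model(Q = 7100, D0 = 52, b = 1040)  # D2(x) = 52 + 1040 x^2
ts <- simulate_langevin(model, n = 2e6, dt = 1e-6, seed = 1)
report <- calibrate(ts, calibration_config(markov = list(deltas = c(1, 2, 5, 10, 20))))
print(report)
#> Calibration report
#>   record: n = 2000000, dt = 1e-06 (sim-unit)
#>   Markov-Einstein time scale: 20 samples (2e-05 s)
#>   PS branch: Q = 7345.6 +/- 87, D = 62.513 +/- 0.13
#>   KM branch: Q = 7396.4 +/- 90, D(0) = 52.389 +/- 0.082, b = 1066.4 +/- 9.2
#>   RelDif (%): Q = 0.7, D_V = 16.2
```

Reading the numbers: the Kramers-Moyal branch recovers the generating
parameters — drift slope `Q` near 7100, trap-centre diffusion `D(0)` near
52, quadratic coefficient `b` near 1040. The Lorentzian fit has no room
for position-dependent diffusion: its `D` lands near the *stationary
average* of $D^{(2)}(x)$, here $D_0 Q/(Q-b) = 60.9$, which is 20% above
the trap-centre value that calibration actually needs — the 16% `RelDif`
in the last line is exactly the discrepancy a PS-only calibration would
silently absorb into $\beta$. (At this dense sampling the Markov scan
reports the largest scanned spacing; see the methods vignette for the
caveat on reading the scan when the sampling interval is far below the
relaxation time.)

With a physical context the report also carries stiffness and conversion
factors in SI units:

```r
ctx <- physical_context(radius = 0.5e-6, viscosity = 0.95e-3, temperature = 295)
conversion_factor(einstein_diffusion(ctx), 8.8) * 1e9   # D_V in volt^2/s -> nm/V
#> [1] 227.3599
```

A thin command-line front end covers the same operations
(`simulate`, `km-estimate`, `markov-scan`, `ps-calibrate`, `calibrate`,
`synthetic-suite`):

```sh
Rscript inst/cli/otcalib.R simulate --Q 1000 --D0 50 --dt 1e-6 --n 1000000 \
    --seed 1 --out traj.txt
Rscript inst/cli/otcalib.R ps-calibrate --input traj.txt --out fit.json
```

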