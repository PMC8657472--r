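---
title: "Fractal ladder-circuit hemodynamics: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal ladder-circuit hemodynamics: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalflow)
library(ggplot2)
```

## The model

Lumped-parameter (Windkessel) models describe an arterial segment as an
electrical circuit under the mechanical–electrical analogy: pressure is
voltage, flow is current, blood inertia is an inductance
$L = c_L \rho / (\pi r^2)$, wall compliance a capacitance
$C = 3\pi r^2/(2 E h)$, and viscous loss a Poiseuille-type resistance
$R = 8 c_R \mu / (\pi r^4)$. Classical Windkessel models stop at a handful
of such compartments. `fractalflow` implements the limiting construction
instead: the segment is split into infinitely many micro-compartments, each
level of the resulting ladder repeating the previous one. The minimal
repeating unit (the *hypercell*) pairs a shunt admittance $T_1$ with a
series admittance $T_2$; in the aorta $(T_1, T_2) = (C p,\ 1/(L p))$
because inertia dominates there, in the arteriole
$(T_1, T_2) = (C p,\ 1/R)$ because viscosity does ($p$ is the Heaviside
differentiation symbol).

Because the ladder is self-similar, its input admittance $\hat T$ satisfies
the fixed-point equation

$$\hat T^2 - T_1 \hat T - T_1 T_2 = 0,
\qquad
\hat T = \frac{T_1 \pm \sqrt{T_1^2 + 4 T_1 T_2}}{2},$$

the *fractal admittance operator*. Everything the package computes flows
from this root:

* **Frequency domain** (`fao()`, `fao_frequency_response()`): the closed
  forms $\hat T_a(s) = \tfrac{C}{2}(s \pm \sqrt{s^2 + 4/\tau^2})$ and
  $\hat T_{ar}(s) = \tfrac12 (C s \pm \sqrt{C^2 s^2 + 4 C s/\tau})$, with
  the single time scale $\tau = \sqrt{LC}$ (aorta) or $\tau = RC$
  (arteriole).
* **Finite-ladder oracle** (`ladder_admittance()`): the continued-fraction
  recursion $T_{k+1} = T_1 + T_2 T_k/(T_2 + T_k)$, the brute-force check
  that the closed form really is the infinite-ladder limit. Four hypercell
  repetitions already agree with the fixed point to under 0.02 %
  (`ladder_relative_error()`), which is what makes finite physical
  realisations of the circuit practical.
* **Time domain** (`gkf_qq()`, `bkf_nef()`, `flow_response()`): the
  modulation part of the root acts on a pressure input as a Volterra
  convolution with a closed-form kernel, giving the governing equation
  $$ i(t) = \frac{C}{2}\,\frac{du}{dt} \ \pm\ \int_0^t f(t-s)\,u(s)\,ds. $$

The aortic kernel is a Gaussian-type kernel with quadratic quotient,
$f_a(t) = C\,(1-e^{-2t^2/\tau^2})/(2t^2)$; the arteriolar kernel is an
exponentially weighted modified-Bessel kernel,
$f_{ar}(t) = C e^{-2t/\tau}/\tau^2\,[I_0(2t/\tau) - I_2(2t/\tau)]$. Both
start at the plateau value $C/\tau^2$, decay monotonically, and are exactly
linear in $C$ — compliance scales the flow amplitude, the characteristic
time shapes its decay and moves the inflection point.

```{r kernels, fig.width = 6, fig.height = 3.5}
kernel_sweep("gkf_qq", tau = c(1.5, 2.5, 5), C = 1,
             t = seq(0, 8, 0.02)) |>
  plot_kernel_sweep()
```

## Conventions worth stating explicitly

**The aortic characteristic time is $\sqrt{LC}$.** The product $LC$ has
units of s$^2$; only its square root is a time, and only with
$\tau_a = \sqrt{LC}$ do the closed-form root and the kernel have consistent
units. The package uses the square root throughout, which is the standard
transmission-line convention; sources sometimes abbreviate the relation as
$\tau_a = LC_a$.

**Two variants of the simplified aortic kernel.** Substituting $C = 2$,
$\tau = 2$ into $f_a$ gives $(1 - e^{-t^2/2})/t^2$, while the widely quoted
dimensionless reference curve is $g(t) = (1 - e^{-t^2})/t^2$. These differ
(the exponent rate differs by a factor 2), so the package keeps both: the
parameterised kernel `gkf_qq(t, C, tau)` is always the exact closed form,
and `gauss_family(t, "gauss_qq")` is the dimensionless reference curve used
for shape comparisons and the inflection benchmarks ($g$ inflects near
0.90 s, the basic Gaussian $e^{-t^2}$ at $1/\sqrt2 \approx 0.71$ s).

**Branch signs.** The quadratic has two roots. The `+` root is passive
(non-negative real part for $\mathrm{Re}(s) > 0$) and is the default
everywhere in the frequency domain. In the time domain the modulation term
enters with `+` for the aorta and `-` for the arteriole, the convention
under which both segments reproduce the physiological reflux and
hysteresis phenomenology.

**Pulse-wave continuity.** The two-harmonic pressure input splits the
cardiac period $t_0$ into three equal segments: primary harmonic, primary
plus reflected, reflected alone. Writing the middle-segment baseline as
$2P_0$ makes the wave jump by exactly $P_0$ at both interior junctions,
which contradicts the idea of superposing harmonics on one baseline. The
default mode therefore uses a $P_0$ baseline in all three segments, which
makes the wave exactly continuous ($P(0) = P(t_0) = P_0$, aortic peak
$P_0 + 2P_{0\sin} = 62$ mmHg at $t_0/3$); the discontinuous variant
remains available as `mode = "as_printed"` for comparison.

## Default parameters

| parameter | aorta | arteriole | meaning |
|---|---|---|---|
| $C$ | 1 | 0.1 | compliance, cm·mmHg$^{-1}$ |
| $\tau$ | 2.5 s | 5 s | characteristic time (ascending aorta / arm arteriole) |
| sign | `+` | `-` | modulation branch |
| $P_0$, $P_{0\sin}$, $k$ | 22, 20 mmHg, 0.7 | 20, 35 mmHg, 0.5 | pulse baseline, harmonic amplitude, reflection weight |
| $t_0$ | 0.8 s | 0.8 s | cardiac period |
| `dt` | 0.001 s | 0.001 s | solver step (800 nodes per period) |

The dimensionless shape coefficients $c_L$ and $c_R$ of the vessel-to-
circuit map are not fixed by the analogy and default to 1; both are
overridable. Units are "model units" as stated — pressures in mmHg, times
in seconds, flow in the mmHg·cm·s$^{-1}$ implied by $C\,dP/dt$ — and no
unit-conversion layer is attempted (the per-unit-length compliance unit
cm·mmHg$^{-1}$ is used as conventionally quoted).

## Numerical choices

* **Convolution quadrature.** Uniform-grid trapezoid rule on the Volterra
  integral with the kernel evaluated at node differences; the pressure
  derivative by central differences (one-sided at the ends). For smooth
  inputs the response converges at second order in `dt`; the suite
  verifies the ratio directly. `dt = 0.001` s resolves the 0.8 s period by
  800 nodes and keeps a multi-period simulation in the
  tens-of-milliseconds range.
* **Removable singularities.** Kernel values at $t = 0$ are the analytic
  limits ($C/\tau^2$); for $2t^2/\tau^2 < 10^{-8}$ the aortic kernel uses a
  two-term Taylor expansion to avoid catastrophic cancellation.
* **Scaled Bessel evaluation.** $e^{-x} I_n(x)$ is computed with
  `besselI(..., expon.scaled = TRUE)`; the kernel stays finite out to
  $t = 10^6$ s and decays algebraically like $t^{-3/2}$. The recurrence
  $I_0 - I_2 = 2 I_1 / x$ serves as an independent oracle in the tests.
* **Complex square root.** Principal branch everywhere, so frequency
  responses are bit-for-bit reproducible.
* **Ladder evaluation frequencies.** Oracle comparisons use
  $s = \sigma + i\omega$ with a small positive real part
  ($\sigma = 0.01|\omega|$): on the pure imaginary axis the lossless
  aortic LC ladder's continued fraction need not converge.
* **Ladder boundary.** The grounded seed $T_0 = T_1 + T_2$ (tail at zero
  potential, the segment's outlet condition) is the default; the open seed
  $T_0 = T_1$ is kept as an option since truncation-depth conventions
  vary. With the grounded seed and equal unit elements, depth 4 gives a
  relative error of 0.0091 %.
* **Half-order operators.** The modulated Riemann–Liouville half
  derivative $D^{0.5,A} f = e^{-At} D^{0.5}[e^{At} f]$ is discretised with
  Grünwald–Letnikov weights (first-order accurate). Two passes with the
  same $A$ compose *exactly* into the backward difference of
  $e^{At} f$ — the discrete counterpart of
  $\sqrt{p+A}\,\sqrt{p+A} = p + A$ — which is how the suite checks the
  semigroup property; with the conjugate pair $A = \pm 2i/\tau$ the
  composed weights are exactly real. The $t = 0$ endpoint of a half
  derivative is singular for $f(0) \neq 0$ and is returned flagged;
  accuracy is only asserted for $t \ge 5\,dt$. This module verifies the
  apparent-fractional-order rewritings; the canonical solver path is the
  convolution kernel, not these operators.
* **Bisection for inflection points.** The second derivative is taken by
  central differences ($h = 10^{-4}$) and bisected to $10^{-6}$ s. A
  bracket whose second derivative lies within the differencing noise floor
  ($\sim \varepsilon |f| / h^2$) is reported as "no inflection" rather
  than chasing roundoff sign flips.

## Flow analytics

`detect_reflux()` returns the maximal negative-flow intervals with
endpoints interpolated at sign changes; with the two-harmonic input both
segments show at least one reflux episode per period, appearing with the
reflected pressure component. `hysteresis_loop()` pairs pressure with flow
over the final simulated period (at least two earlier periods are treated
as transient by default), reports the signed shoelace area, the circular
distance between the flow and pressure peaks (the peak phase lag), and a
closure gap quantifying how much transient remains.

Two monotonicity facts about the characteristic time are worth separating.
The *net* modulated flow — the period mean of $i(t)$, i.e. the volume
throughput per cardiac cycle contributed by the convolution term — shrinks
monotonically as $\tau$ grows for both segments, because the kernel
integral scales like $C/\tau$. The *pointwise extremes* behave differently
by segment: the aortic flow peak falls with $\tau$ (the positive
modulation adds less), while the arteriolar positive peak actually rises
slightly (the subtracted modulation shrinks). Summaries report peak,
trough, peak-to-peak and mean so both effects are visible;
`stable_modulation_interval()` sweeps $\tau$ and finds where the response
stops changing faster than a stated accuracy percentage. That threshold is
input- and accuracy-dependent by construction — with the default aortic
pulse and a 5 % accuracy it lands in the low single-digit seconds — and is
reported as a diagnostic, not asserted against any fixed interval.

`fao_consistency()` compares the time-domain steady-state gain at the
input's harmonics with $|\hat T(i\omega)|$ from the closed-form root. The
operational-calculus kernels are *not* the classical inverse Laplace
transforms of the frequency-domain roots (the classical inverse of
$\sqrt{s^2 + a^2} - s$ is an oscillatory Bessel-$J$ kernel), so the two
calculi genuinely disagree; the function reports the observed deviation as
data and the package asserts nothing about it. This is a property of the
underlying operational calculus, not a numerical artifact.

## What the built-in scenarios do and do not show

The built-in input is the idealised two-harmonic pulse with representative
parameters; it reproduces the qualitative physiology (reflux with the
reflected wave, closed pressure–flow loops, delayed flow peaks) and the
quantitative kernel benchmarks. It does not capture measured waveform
morphology, beat-to-beat variability, nonlinear wall mechanics, tapered or
branching geometry, closed-loop heart coupling, peripheral-resistance
termination or venous return — the segment is homogeneous and the outlet
is held at zero potential. Passing tests therefore demonstrate the model's
internal consistency and its stated phenomenology, not agreement with any
particular patient measurement. External measured waveforms can be driven
through the same solver via `read_waveform_csv()`.

## Reference scenarios

`generate_fixtures()` writes YAML configurations for the standard runs:
the dimensionless kernel family, kernel sweeps over $\tau$ and $C$ for
both segments, the two pulse-driven simulations, and the ladder-truncation
study. `run_scenario()` executes a configuration deterministically (same
config, byte-identical CSV/JSON outputs; floating-point output uses 17
significant digits so round trips are exact). A thin command-line wrapper
with subcommands `kernels`, `pulse`, `ladder`, `simulate`, `sweep` and
`fixtures` ships in `inst/cli/fractalflow.R`.

```{r pipeline, fig.width = 6, fig.height = 4}
resp <- pulse_params("aorta") |>
  sample_waveform(dt = 0.002, n_periods = 4) |>
  flow_response()
glance(resp)
autoplot(hysteresis_loop(resp))
```
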