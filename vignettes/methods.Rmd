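---
title: "Methods: map neuron, rate reduction, and augmented neural field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: map neuron, rate reduction, and augmented neural field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rulkovfield)
```

This vignette documents the models implemented by **rulkovfield**, the
numerical choices behind them, and the design decisions taken where more
than one reasonable convention exists. It states no empirical numbers beyond
those the test suite and `scripts/acceptance.R` themselves compute.

## 1. The single-neuron map

The neuron is a two-dimensional map: a fast membrane potential $v$ updated
through the piecewise function $f$, and a slow adaptation variable $a$
driven solely by a binary spike flag $s$,

$$
v_{n+1} = f(v_n, v_{n-1}, \kappa u_n - a_n - \theta), \qquad
a_{n+1} = a_n - \varepsilon\bigl(a_n + (1-\kappa)u_n - \gamma s_n\bigr).
$$

Because $a$ sees the potential only through $s$, the subthreshold adaptation
dynamics is *linear* — the key property enabling both the closed-form
frequency responses and the rate reduction. The price is the loss of
subthreshold oscillations, which the model deliberately does not support.

**Spike-flag timing.** The spike flag $s_n$ is evaluated from the *current*
potential pair: $s_n = 1$ iff $v_n \ge 0$ and ($v_n \ge 50 + 50(\kappa u_n -
a_n - \theta)$ or $v_{n-1} \ge 0$). This is precisely the condition under
which $f$ takes its reset branch, so $s_n = 1$ iff $v_{n+1} = -50$ exactly
(the reset contract, asserted in the tests). That same $s_n$ enters the
update producing $a_{n+1}$, keeping the step one-pass. Trace rows align
$u_n, v_n, a_n, s_n$ at the same index.

**Exact comparisons.** All branch and spike comparisons use the literal
$\ge$ / $<$ of the defining formulas with no tolerance: limit-cycle periods
are integer counts that depend on exact branch logic, and a tolerance would
blur the staircase discontinuities that the rest of the package is built on.

**Initialization.** The default state is the reset point $v_0 = v_{-1} =
-50$, $a_0 = 0$ — always a valid state of the map. The first iteration needs
$v_{-1}$; it defaults to $v_0$.

**Parameters.** $\theta$ (spiking threshold, dimensionless drive units):
constant input $\varphi$ elicits persistent spiking iff $\varphi > \theta$.
$\kappa$ (input partition): fraction of input applied to the fast subsystem;
$\kappa > 1$ yields postinhibitory rebound and accommodation, $\kappa = 0$
first-spike latency, $\kappa < 0$ inhibition-induced spiking. The asymptotic
response to constant input is independent of $\kappa$ (tested).
$\varepsilon \in (0,1)$ (adaptation rate per iteration): small values give
the slow–fast separation on which the rate reduction rests. $\gamma$
(adaptation strength, drive units per spike). One iteration corresponds to
about 0.5 ms; all internal bookkeeping is in iteration units, and only
reporting may convert.

## 2. Fast subsystem and the staircase rate function

Freezing the drive at $\varsigma$ gives a one-dimensional map with a
saddle-node bifurcation at $\varsigma = 0$: for $\varsigma < 0$ stable and
unstable fixed points $25(\varsigma - 2 \mp \sqrt{\varsigma^2 -
8\varsigma})$, for $\varsigma > 0$ a unique limit cycle. Since the reset
value $-50$ lies on the cycle, the period is found by iterating from $-50$
and counting left-interval ($v<0$) visits, plus one peak and one reset
iteration. The rate function $S(\varsigma) = 1/P(\varsigma)$ (0 for
$\varsigma \le 0$) is a nondecreasing staircase with maximal rate $1/3$.

**Discontinuity points.** $\varsigma_k$ (where $P$ drops from $k+3$ to
$k+2$) are located by bisection on the integer-valued period function. Each
bisection is run until the bracket collapses at double resolution, so
$\varsigma_k$ is the smallest representable double with period $k+2$. This
matters for the boundary convention $S(\varsigma_k) = 1/(k+2)$
(right-continuity, $H(0)=1$): with a finitely-toleranced bisection the
returned knot can land a hair above the true boundary and put the exact
point $\varsigma = 1$ on the wrong plateau. The first two points are checked
against their closed forms $1$ and $(5-\sqrt{17})/2$ in the tests.

**Truncation.** The packaged staircase keeps $K = 200$ knots. Below
$\varsigma_{200}$ (order $10^{-4}$) the truncated staircase returns 0, an
error of at most $1/(K+3)$; an `exact_tail` option evaluates that region by
direct period iteration instead. The rate model uses the truncated default —
the affected drive interval is crossed in a vanishing fraction of
integration time.

## 3. Frequency responses and quiescence

In the subthreshold regime the adaptation recursion is linear, and harmonic
input $u_n = \varphi\cos(\omega\pi n/1000 + \vartheta)$ produces a
steady-state drive $|F(\omega)|\varphi\cos(\cdot + \arg F)$ with

$$
F(\omega) = \kappa + \frac{\varepsilon(1-\kappa)}
{e^{i\omega\pi/1000} + \varepsilon - 1}, \qquad
G(\omega) = \kappa + \frac{\varepsilon(1-\kappa)}
{\varepsilon + i\omega\pi/1000}
$$

for the map and the rate model respectively. $\omega$ is treated as a
continuous parameter in Hz; $F$ is defined on $[0, 1000]$ only (the Nyquist
frequency of the 0.5 ms step), $G$ on $[0, \infty)$. Arguments are taken in
$(-\pi, \pi]$. $|F|$ is strictly decreasing iff $\kappa \in
(-1+\varepsilon, 1)$; $|G|$ iff $|\kappa| < 1$ (at $|\kappa| = 1$, $|G|
\equiv 1$, so the tests probe strictly inside/outside the boundary).

$|F(\omega)|\varphi \le \theta$ is *sufficient* for map quiescence (the map
needs a few iterations on its periodic orbit before it can spike, so the
condition is not necessary); $|G(\omega)|\varphi \le \theta$ is *exact* for
the rate model. The default phase is $\vartheta = 0$: steady-state
per-period quantities are phase-independent, so nothing downstream depends
on this choice.

**Verification tolerances.** The closed forms are compared against
simulation at $10^{-9}$ (adaptation) and $10^{-8}$ (drive). The analytic
form assumes an infinite input history; the tests therefore either discard a
burn-in long enough that the geometric transient $(1-\varepsilon)^n$ is
below the comparison tolerance, or start the rate model directly on the
analytic periodic orbit. A burn-in of $10/\varepsilon$ (transient
$\approx e^{-10}$) is *not* sufficient at these tolerances; the tests use
what the tolerance requires.

## 4. Rate model integration

The scalar ODE is integrated with the classical fixed-step 4th-order
Runge–Kutta scheme (`deSolve::rk4`), default $dt = 0.1$ iteration units.
Fixed step is a deliberate choice: with the staircase $S$ the right-hand
side is discontinuous, and adaptive error control would chatter at the
jumps. Step sensitivity is assessed by halving $dt$ (the refinement test
requires $< 10^{-6}$ drift for smooth $S$). With the staircase $S$ a
constant-input equilibrium can fall *between* plateaus; the trajectory then
slides along the jump, which is why the equilibrium identity
$\varphi - \theta = r^* + \gamma S(r^*)$ is verified with the smooth
two-term rate function.

Per-period rate integrals (the rate model's analogue of spikes per period)
are trapezoidal integrals over the final full forcing period, after
discarding a transient of at least $\max(5\ \text{periods},
10/\varepsilon)$. For the harmonic-response experiments the integrations run
to $t = 12000$ (1 Hz, period 2000) and $t = 6000$ (2 Hz, period 1000).

## 5. Expected rate under threshold noise and erf fits

With Gaussian threshold noise of variance $\sigma^2$, the expected rate
$\langle S\rangle(\varsigma)$ is computed two independent ways:

* **Quadrature:** composite Gauss–Legendre (12 nodes per panel) of the
  Gaussian-weighted staircase over $\pm 8\sigma$, with panels split at every
  staircase knot inside the window (the integrand is piecewise smooth) and
  capped at width $\sigma/2$ so the Gaussian factor is resolved. The
  staircase is evaluated exactly (direct period iteration) below its last
  knot.
* **Series:** $1/6 + \sum_{k\le K} \mathrm{erf}\bigl((\varsigma -
  \varsigma_k)/\sqrt{2\sigma^2}\bigr)/(2(k+2)(k+3))$ plus a closing term
  $\mathrm{erf}(\varsigma/\sqrt{2\sigma^2})/(2(K+3))$ that collapses the
  $k > K$ tail at its limit $\varsigma_k \to 0$. The closing term keeps both
  limits (0 and 1/3) exact; a plain truncation would leave an error of order
  $1/(2(K+3))$, which at $K = 200$ would exceed the $10^{-6}$ agreement the
  two routes are required to show. The crude bound $1/(2(K+3))$ on the
  collapsed tail is attached as an attribute.

The $N$-term approximation $1/6 + \frac{1}{6N}\sum_i
\mathrm{erf}((\varsigma-\nu_i)/\chi_i)$ is fitted by least squares on the
grid $\varsigma \in [-3, 4]$, step 0.01 (covering the sigmoid's support for
the noise levels of interest), using Levenberg–Marquardt from 8
deterministic seeded starts, widths parameterized on the log scale, terms
sorted by center. The norm's grid and domain are a package choice — refit
constants can differ from any particular reference in late digits. The
packaged two-term rate function for field work uses the fixed constants
$(\nu, \chi) = (0.0335, 0.7099, 0.6890, 0.8213)$ at $\sigma^2 = 1/4$.

## 6. The two-population field and the matched network

The field on $\Omega = (-1, 1)$ couples two populations through
$J_{ij}(x,x') = \rho_j \eta_{ij} e^{-\mu_{ij}|x-x'|}$ and evolves, per
population, a synaptic input $u_i$ (exponential synapse, decay $\alpha_i$)
and an adaptation field $a_i$ (the rate model pointwise). Discretization:
$M = 201$ uniform points including endpoints, trapezoidal quadrature for the
coupling integrals (the kernel's kink sits on grid nodes, preserving
$O(1/M^2)$), and the same fixed-step RK4 in time. Snapshots are recorded
every `record_every` steps to bound memory; integration proceeds in chunks
between snapshots. The refinement check doubles resolution,
$(M, dt) = (201, 0.1) \to (401, 0.05)$, and requires the final rate field to
move by less than $10^{-3}$ in maximum norm at moderate horizon ($t = 50$)
from a smooth deterministic initial bump — chosen smooth and
grid-representable precisely so that the two resolutions solve the same
initial-value problem.

The showcase initial condition is $u_i = a_i = 0$ plus seeded uniform noise
of amplitude 0.01 to break spatial symmetry (the homogeneous state is an
approximate equilibrium; without a perturbation nothing patterns). Whether
the field itself should carry stochastic forcing is left out: the field is
deterministic, noise lives in the spiking network.

The matched network places two subpopulations of $n$ neurons each
equidistantly on $[-1,1]$ (both on the same layout, endpoints included),
all-to-all coupled by $c_{ij} = \eta_{p_ip_j}e^{-\mu_{p_ip_j}|x_i-x_j|}$.
Self-connections are kept — the coupling is stated as all-to-all, and at
these scales one self-term among $2n$ inputs is negligible. Updates are
synchronous: spikes are evaluated from the pre-update state, then synapses,
then the single-neuron maps. Threshold noise $\xi \sim N(0, \sigma^2)$ is
redrawn independently per neuron *and* per iteration (uncorrelated in space
and time), and the same draw enters both the spike condition and the
membrane update of that iteration. With $n = 300$ per population the implied
density $n/2 = 150$ per unit length matches the field's $\rho$; the config
builder asserts this correspondence. Zero coupling plus zero noise reduces
every neuron *exactly* to the single-neuron simulator, and zero field
coupling reduces every grid point *exactly* to the rate model (identical
steppers) — the two anchor equivalences of the test suite.

## 7. Scenario presets: what they emulate and what they don't

Six presets pair the canonical parameter tuples for tonic spiking
$(\tfrac1{10},\tfrac12,\tfrac12,\tfrac12)$, spike-frequency adaptation
$(\tfrac1{10},1,\tfrac1{1000},5)$, rebound $(\tfrac1{50},2,\tfrac1{100},
\tfrac15)$, accommodation $(\tfrac3{25},3,\tfrac1{50},\tfrac25)$, latency
$(\tfrac1{10},0,\tfrac1{200},\tfrac25)$, and inhibition-induced spiking
$(\tfrac1{50},-1,\tfrac1{500},\tfrac25)$ with package-chosen stimuli (step
of amplitude 0.3 on iterations [200, 1200); hyperpolarizing pulse −0.4 for
500 iterations; fast 50-iteration ramp to the subthreshold level 0.1;
inhibitory step −0.3). The stimulus choices are the package's own — only
the parameter tuples are canonical — and were fixed once for qualitative
plausibility: amplitudes comfortably clear the relevant thresholds and
windows are long enough for the slow adaptation variables to express each
behavior. The tests assert the defining signature of each pattern (spikes
only after pulse offset, delayed first spike, spiking only during
inhibition, lengthening inter-spike intervals, transient spiking under held
subthreshold input) and, for the strongly time-scale-separated cases
($\varepsilon \le 1/50$), that the rate model's integrated rate matches the
map's spike count within 15%. For tonic spiking ($\varepsilon = 1/2$) the
forward-Euler correspondence between map and ODE is coarse and no
quantitative agreement is claimed.

What passing these scenarios does *not* show: the stimuli are clean steps
and ramps, not synaptic bombardment; agreement is in integrated counts, not
spike timing; and a single neuron's behavior does not certify network-level
pattern formation, which is exercised separately (and only qualitatively)
by the field/network showcase.

## 8. Problem sizes and degenerate inputs

The test suite runs map simulations of $2\times 10^4$ iterations, rate
integrations up to $1.2\times 10^4$ time units at $dt = 0.1$, a $K = 200$
staircase, field runs up to $M = 401$, and networks of up to 60 neurons —
sizes chosen so the whole suite completes in about a minute on one CPU
while leaving every convergence margin (trapezoid order, RK4 refinement,
quadrature-vs-series agreement) clearly resolved. Degenerate inputs are
rejected with diagnostics: empty stimuli, non-finite values in `f`,
$dt \le 0$, drives without a limit cycle, traces shorter than one period,
malformed or non-finite CSV rows (with line numbers), and configuration
files with missing keys or $\varepsilon \notin (0,1)$. Unknown config keys
warn rather than error.

## 9. Known limitations

* No subthreshold oscillations (by construction of the modified map), no
  bistable fast subsystem ("chattering" variants are out of scope).
* The rate reduction is heuristic; its quantitative fidelity degrades as
  $\varepsilon$ grows toward 1.
* The field solver supports the 1-D domain $(-1,1)$ without transmission
  delays or periodic boundaries.
* Map frequency responses are subthreshold constructs; no empirical
  transfer function of the spiking regime is estimated.
* The spiking network is dense (all-to-all); no sparse or conductance-based
  synapses.
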