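---
title: "Models and methods behind ClampKinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ClampKinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ClampKinetics)
```

# The experimental system

8-oxoguanine (oxoG) is the most common oxidative DNA lesion and is excised
in human cells by the bifunctional glycosylase OGG1, which first hydrolyzes
the N-glycosidic bond (N-glycosylase activity, leaving an abasic AP site)
and then nicks the backbone 3' of that site (AP-lyase activity). The
oxoG-clamp is a fluorescent phenoxazine-based cytosine analog whose
emission is selectively quenched when it pairs with oxoG; placing it
opposite a lesion turns base-pairing status into an optical signal.

ClampKinetics implements the quantitative analyses such a study runs:

* **mechanisms** — mass-action kinetic schemes compiled to stiff ODE
  systems, with equilibrium algebra for derived binding constants;
* **globalfit** — global nonlinear least-squares fitting of stopped-flow
  fluorescence concentration series and stepwise selection of the minimal
  mechanism;
* **melting** — melting temperatures from multi-wavelength UV denaturation
  curves via smoothed differentiation;
* **hybridization** — the equilibrium quenching isotherm of clamp/partner
  titrations;
* **cleavage** — closed-form consecutive-reaction analysis of
  single-turnover gel time courses;
* **synthetic data** — seeded generators emulating all four instruments, so
  every estimator is exercised against known ground truth.

# Binding kinetics

## The two-step scheme

Enzyme–substrate association is modeled as two reversible stages,

$$E + S \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} ES
      \underset{k_{-2}}{\overset{k_2}{\rightleftharpoons}} ES^*,$$

with $k_1$ in M$^{-1}$s$^{-1}$ and the rest in s$^{-1}$. `KineticScheme`
objects accept arbitrary mass-action steps up to bimolecular; the compiled
right-hand side and its analytic Jacobian are handed to a stiff-capable
integrator (`deSolve::ode`, lsoda) because the bimolecular and unimolecular
rates differ by ~$10^6$ in natural units. Default tolerances are
`rtol = 1e-8`, `atol = 1e-12` M; trajectories conserve enzyme and DNA
totals to well below one part in $10^9$ (in practice, machine precision,
since the conservation laws lie in the left null space of the stoichiometry
matrix and the integrator's error is made orthogonal to them only up to its
tolerance — the tests check the $10^{-9}$ bound). Concentrations down to
$-10^{-12}$ M are clipped to zero; anything more negative raises an error.

The overall association constant reported by such experiments lumps every
bound state over the free ones. For a binding chain,

$$K_a = \frac{[ES] + [ES^*]}{[E][S]} = K_1 (1 + K_2), \qquad
  K_i = k_i / k_{-i},$$

which `derivedConstants()` computes and the test suite verifies against
long-time numerical equilibration to 0.1%. $K_a$ is the robust quantity
here: $K_1$ and $K_2$ are anti-correlated along the fit's flat direction,
while their combination $K_1(1+K_2)$ is pinned by the equilibrium
amplitudes.

## The stopped-flow generator

`simulateTraceSet()` integrates a scheme from mixing (t = 0) for each
(enzyme, duplex) pair of a concentration design, evaluates a linear
fluorescence response
$F(t) = b + \sum_s r_s [s](t)$, samples it on 400 log-spaced points between
the 1.4 ms instrument dead time and 1 s, and adds seeded Gaussian noise.
Defaults mirror the study conditions: 1 µM enzyme against duplex at 0.4,
0.8, 1.2, 1.6 µM (the complementary fixed-duplex design is available via
`fixedDuplexDesign()`). The default response (`clampResponseModel()`) makes
the enzyme-bound states slightly dimmer than the free duplex, reproducing
the modest signal decrease observed for clamp-containing duplexes; the
enzyme itself is dark at the clamp emission wavelengths.

**Noise convention.** `noiseSd` is a fraction of the *recorded dynamic
range* — the largest within-trace signal change of the set — not of the
absolute fluorescence level. A stopped-flow acquisition is gain-adjusted so
the kinetic change spans the digitizer range, which makes this the natural
meaning of "1% noise"; defined against the absolute level instead, the
few-percent binding-induced dip would carry a per-point signal-to-noise
ratio near 1 and no concentration series of this size could constrain
$K_a$ usefully. For kinetics-free (flat) signals the full scale falls back
to the absolute level so noise never vanishes spuriously.

## Global fitting

`globalFit()` shares the rate constants across all traces of a set and
minimizes the summed squared residuals. Two structural choices matter:

* **Log-scale trust-region optimization with multi-start.** Rates are
  positive and span decades, so the nonlinear parameters are the log rates,
  optimized with `minpack.lm::nls.lm` inside a wide positivity box
  ($10^3$–$10^{11}$ M$^{-1}$s$^{-1}$ bimolecular, $10^{-5}$–$10^6$ s$^{-1}$
  unimolecular; the box mainly keeps hill-climbing out of the degenerate
  fast-equilibrium ridge where all rates diverge jointly). Five starting
  points by default: the template scheme's own values, a heuristic from a
  single-exponential pre-fit of the largest-amplitude trace, and seeded
  log-uniform draws; the best final SSR is kept.
* **Variable projection of the linear response.** For fixed rates the model
  is linear in the background and per-species responses, so these are
  profiled out exactly by least squares at every function evaluation. Only
  the (2 or 4) log rates are iterated, which makes each fit both fast and
  far less start-dependent.

By default one background and one response per DNA-containing species are
shared across the whole set: a concentration series is recorded in a single
optical session, so the dependence of the absolute signal level on total
duplex is real information and is what pins the equilibrium constants. The
alternative `backgroundPerTrace = TRUE` floats one background per trace;
duplex conservation then absorbs the free-duplex response into the
backgrounds and $K_a$ must be inferred from kinetic shapes alone — its
uncertainty grows several-fold, which is why the shared-background variant
is the default rather than the other way round.

The model is always integrated from t = 0 but residuals are evaluated only
at the sampled times (all at or after the dead time), so the unobserved
pre-dead-time evolution is absorbed correctly rather than re-zeroed.
Standard errors come from the profiled Jacobian at the optimum (delta
method back to the natural scale, and onto $K_a$); a numerically singular
Jacobian produces a warning naming the flattest parameter combination.

## Mechanism selection

`selectMechanism()` mirrors the stepwise practice of pre-steady-state
analysis: fitting starts on the initial part of the curves (which a single
exponential describes), and the fitted time window is expanded step by
step. At each window the current candidate is compared with the candidate
one reversible step larger by the extra-sum-of-squares F test; a step is
added only when the smaller model is rejected at $\alpha = 0.01$ (AIC is
reported alongside but does not drive the decision). The chosen mechanism
is the smallest candidate never rejected at the full window. Degenerate
inputs are flagged rather than failed on: kinetics-free data carry a
`zeroAmplitude` flag, and a final fit whose RMS residual stays more than
three times above the noise floor (estimated from first differences) is
flagged `noSatisfactoryScheme`.

# Melting analysis

## Model and generator

Thermal denaturation of a non-self-complementary duplex at equal strand
totals $C_s$ is modeled as two-state, $A + B \rightleftharpoons AB$, with a
van't Hoff association constant anchored so half the strands are paired at
the anchor temperature $T_m$:

$$K(T) = \frac{2}{C_s}\,
  \exp\!\left[\frac{-\Delta H}{R}\left(\frac1T - \frac1{T_m}\right)\right],$$

and the paired fraction is the exact root of the binding quadratic,
evaluated in the cancellation-free form
$\theta = 2u / (u + 1 + \sqrt{2u + 1})$ with $u = 2 K C_s$. Absorbance at
260 and 270 nm interpolates between linear duplex and single-strand
baselines (melting is hyperchromic); the 330 nm channel carries baseline
only and serves as the drift reference for `baselineCorrect()`. The default
enthalpy is $\Delta H = -400$ kJ/mol, a realistic van't Hoff value for a
13-mer duplex; neither the melting protocol nor the observed temperatures
determine it, so it is a fixed generator convention, not a fitted quantity.

## The derivative-maximum estimator and its bias

`differentialMelting()` smooths each analysis channel with a
Savitzky–Golay filter (order 2, 11-point window ≈ 5 °C on the 0.5 °C grid)
and differentiates it; the melting temperature is the maximum of the
differential curve. Sub-grid resolution comes from fitting a quadratic to
the *top of the peak* — the contiguous points above 70% of the peak
prominence, at least 13 points — and taking its vertex. A 3-point parabola
on adjacent grid points was tried first and discarded: at 0.2% absorbance
noise its vertex scatters by 0.6–0.8 °C between replicates, while the
peak-top fit scatters by ~0.2 °C, because it averages noise over the whole
peak cap. A channel whose peak prominence does not exceed three estimated
derivative-noise standard deviations (plus a small float-jitter floor) is
declared transition-free; if no channel shows a transition the estimator
stops with "no transition detected". The consensus Tm is the unweighted
mean of the 260 and 270 nm estimates, which are always reported
individually as well.

One genuine property of the bimolecular two-state model deserves emphasis:
**the derivative maximum does not sit at the half-pairing temperature**.
At $\Delta H = -400$ kJ/mol the exact offset is about +1 °C (computable to
arbitrary precision from the model; `derivativeMaxTm()` does exactly
that). Since melting experiments *define* Tm operationally as the
derivative maximum, the reference temperatures the package carries are of
that kind, and `meltingFixtures()` converts them into generator anchors by
numerically inverting the offset (`anchorForDerivativeMax()`). Recovery
tests therefore compare the estimator against the curve's true derivative
maximum, not against the anchor. The estimator degrades for broad
transitions: below roughly $|\Delta H| \approx 300$ kJ/mol the peak becomes
wide enough that 0.2% noise occasionally moves the estimate by more than
1 °C, a limitation documented by the recovery tests' enthalpy range
(−450 to −350 kJ/mol).

# Hybridization quenching

The titration model is static two-state quenching: the clamp strand is
fully bright when free and loses the fraction $Q$ of its fluorescence when
paired with an oxoG partner, so the relative signal is
$1 - Q \cdot f_{AB}$, where $f_{AB}$ follows the exact two-component
binding quadratic (`fractionDuplex()`, written in the numerically stable
root form so it remains accurate for $K_d$ far below the strand totals). A
partner carrying normal G does not quench; the model forces $Q = 0$ there.
No dynamic-quenching term is included — the equilibrium titration data
shape cannot distinguish one — and buffer or ionic-strength effects are
absorbed into $K_d$ and $Q$ rather than parameterized. The reference
fixture uses $K_d = 0.1$ µM with $Q$ calibrated so that the equimolar
point of a 10 µM titration shows a 20% signal decrease. When every
titration point is saturating, $K_d$ and $Q$ become weakly separable;
`fitQuenchTitration()` flags this and the $K_d$ estimate should then be
read only as an upper bound.

# Cleavage kinetics

Under single-turnover conditions (enzyme at or above substrate, each
substrate processed at most once) the two chemical steps are lumped into
first-order rates acting on a pre-bound substrate:
substrate $\xrightarrow{k_g}$ AP $\xrightarrow{k_l}$ nicked, within an
*active fraction* $a$ of the substrate; the remaining $1-a$ never reacts,
which is how the sub-unity plateaus of single-turnover gels are
represented (an amplitude limit, not a reversible step). The closed forms
are the standard consecutive-reaction solutions, with the AP intermediate
written as
$a\,k_g\,t\,e^{-\min(k_g,k_l)t}\,\varphi(|k_l-k_g|t)$,
$\varphi(x) = (1-e^{-x})/x$ via `expm1`, which is continuous through the
removable singularity at $k_l = k_g$ and overflow-free for either rate
ordering; the tests verify agreement with direct ODE integration to
$10^{-9}$. The untreated gel aliquot scores only the nicked product; the
alkali-treated aliquot (NaOH converts surviving AP sites to strand breaks)
scores AP + nicked, i.e. the pure glycosylase progress curve
$a(1 - e^{-k_g t})$. Lyase stimulation by added 8-bromoguanine is a plain
multiplier on $k_l$ — no product-assisted-catalysis mechanism is modeled,
since the data forms handled here cannot discriminate one. The exact
half-plateau advancement under a stimulation factor $f$ is
$(\ln 2/k_l + 1/k_g)\,/\,(\ln 2/(f k_l) + 1/k_g)$, which approaches $f$
from below as $k_l/k_g \to 0$; it never reaches $f$ because the
glycosylase step delays both curves equally.

`fitCleavage()` fits both readouts jointly with shared parameters,
returning flagged rather than failed results on degenerate data: an
all-zero pair (the clamp-opposed null result) returns $k_g = 0$ with the
active fraction marked unidentifiable, and a flat untreated readout marks
$k_l$ unidentifiable.

# Reference fixtures

The study's printed summary values — overall binding constants of
$5 \times 10^6$, $0.45 \times 10^6$ and $0.25 \times 10^6$ M$^{-1}$ for
the oxoG/C, G/C and oxoG/oxoG-clamp duplexes, melting temperatures of
48/35 °C (oxoG pair) and 49/33 °C (G pair), a ~20% equimolar quench, and
2 h cleavage plateaus of ~55% (alkali) / ~46% (untreated) — do not include
the underlying elementary parameters. `conditionFixtures()`,
`meltingFixtures()`, `quenchFixture()` and `cleavageFixtures()` therefore
carry *synthetic* parameter sets, each chosen once so the summary quantity
it implies matches the reference value (e.g. $k_1 = 5 \times 10^6$
M$^{-1}$s$^{-1}$, $k_{-1} = 50$ s$^{-1}$, $k_2 = 15$ s$^{-1}$,
$k_{-2} = 10$ s$^{-1}$ gives exactly $K_a = 2.5 \times 10^5$ M$^{-1}$).
They are documented as such and exist to drive the generators; nothing in
the estimation path reads them.

# What the synthetic data do and do not establish

The generators reproduce the statistical structure the estimators care
about: dead-time truncation, additive Gaussian instrument noise, linear
baselines and shared drift, saturating isotherms, amplitude-limited
plateaus, seeded reproducibility. They deliberately omit photobleaching,
inner-filter effects, instrument drift over a titration, gel-image
artifacts, temperature dependence of rate constants, and any hysteresis
between heating and cooling. Passing recovery tests therefore demonstrate
that the estimators are correct and well-conditioned *under the stated
noise model* — they do not certify robustness to systematic errors real
instruments add, and fits to real data should always inspect the residual
structure the `FitResult` carries.

# Problem sizes

The test suite and demo run at sizes chosen to exercise every code path at
full fidelity where it matters (the acceptance-style checks use the full
400-point, 4-trace, 1% noise design) and reduced sizes elsewhere (150–200
point grids, 2–3 multi-starts, 10-seed Monte-Carlo batches) so the whole
suite completes in a few minutes on one CPU. The Monte-Carlo batch sizes
are small enough that their pass thresholds are set at ≥ 9/10 seeds rather
than tight percentages; the underlying estimator errors measured there are
a few percent for $K_a$ at 1% trace noise and well under 10% for $k_g$ at
3% densitometry noise.
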