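---
title: "The two-step model of second-gas elimination during N2O washout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-step model of second-gas elimination during N2O washout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgewash)
```

## The physiological question

During emergence from anesthesia a high alveolar concentration of nitrous
oxide is washed out of the body. Of the order of half a litre of N2O per
minute crosses from pulmonary blood into alveolar gas, expanding the
expired gas volume. Any trace inert gas simultaneously being eliminated is
diluted by that expansion, which lowers its alveolar partial pressure,
steepens its blood-to-gas gradient, and increases its elimination — the
second gas effect in the elimination direction. `sgewash` asks how large
that extra elimination is, how it depends on the blood solubility of the
trace gas, and how it interacts with ventilation-perfusion mismatch.

## Model and assumptions

The lung is a set of parallel, steady-state gas-exchanging compartments.
The model makes the standard inert-gas assumptions:

* every gas has a linear dissociation curve characterized by an Ostwald
  blood/gas partition coefficient $\lambda$;
* exchange is alveolar and perfusion-limited (no diffusion limitation, no
  airway exchange — which is why the solubility series stops at
  methoxyflurane, $\lambda = 13$: above $\lambda \approx 10$–$100$ a
  growing share of real exchange moves into the conducting airways, which
  this model does not represent);
* the inspired mixture contains none of the eliminated gases
  ($F_I = 0$) and the diluent is completely insoluble;
* ventilation follows the *constant inflow* pattern: inspired alveolar
  ventilation $\dot V_I$ is fixed per compartment and expired ventilation
  $\dot V_A$ floats with net transfer. (The opposite idealization,
  constant outflow, is implemented too; it produces no second gas effect
  at all, and the package proves that identity in its tests.)

For a single unit, eliminating a gas with mixed-venous dry-gas fraction
$F_{\bar v}$:

$$\dot V_A F_A = \lambda \dot Q (F_{\bar v} - F_A), \qquad
  \dot V_A = \frac{\dot V_I}{1 - F_A},$$

which collapses to the closed form

$$F_A = 1 - \tfrac12\!\left(\alpha + \sqrt{\alpha^2 + 4\psi}\right),
  \qquad \psi = \frac{\dot V_I}{\lambda \dot Q},
  \quad \alpha = 1 - F_{\bar v} - \psi.$$

This is applied to N2O ($\lambda = 0.47$) to get $F_A$, $\dot V_A$ and the
N2O efflux $\dot V_A F_A$ per compartment. A trace second gas at venous
fraction $F_{\bar v}^{SG}$ is then a passive tracer (its own volume change
is negligible) with outflow

$$\text{flux} = \frac{\lambda_{SG}\, \dot V_A\, F_{\bar v}^{SG}}
  {\lambda_{SG} + \dot V_A / \dot Q}.$$

**The two steps.** Step 1 evaluates this outflow at constant volume,
$\dot V_A = \dot V_I$; Step 2 is the increment when $\dot V_A$ expands to
$\dot V_I/(1-F_A^{N_2O})$. Because both steps use the same law, Step 1 +
Step 2 reproduces the classical one-step flux *exactly* — the
decomposition isolates the volume-expansion contribution without changing
any total.

## The heterogeneous lung

Whole-lung behaviour depends only on the perfusion-weighted distribution
of $\ln(\dot V/\dot Q)$, which `build_lung()` takes to be Normal with
standard deviation $\sigma$, the mismatch index. $\sigma$ is in
natural-log units: 0.25–0.5 in awake adults, 0.75–1.75 after induction of
anesthesia; $\sigma = 2$ represents severe mismatch. Compartments sit on
an equally spaced grid of $x = \ln(\dot V_I/\dot Q)$ over
$\mu \pm \mathrm{span}\cdot\sigma$, with perfusion weights proportional to
the normal density and $\dot V_{I,i} = Q_i e^{x_i}$.

Numerical choices:

* **Totals.** $\dot V_I = 4$ L/min and $\dot Q_t = 5$ L/min (overall
  $\dot V/\dot Q = 0.8$), typical resting adult values; both are exact
  constraints on the discretized lung.
* **Centering.** Because the grid is centred on $\mu$, the discrete sum
  $\sum_i Q_i e^{x_i}$ factors as $e^{\mu}$ times a $\mu$-independent
  constant, so $\mu$ is solved in closed form to make the discretized
  ventilation total exact — no iteration and no discretization bias at
  large $\sigma$. As $N, \mathrm{span} \to \infty$ this recovers the
  analytic $\mu = \ln(\dot V_I/\dot Q_t) - \sigma^2/2$.
* **Resolution.** Defaults $N = 1001$ compartments, span $= 5$ SDs. The
  test suite shows every whole-lung flux moves by well under 0.1% when $N$
  doubles at $\sigma = 2$, so results are grid-converged at the reported
  precision; the whole suite runs in seconds.
* **Robustness.** The closed-form quadratic is guarded: the discriminant
  is clamped at zero against floating-point underflow, every root is
  checked against the original mass balance, and any failure falls back to
  bisection. At extreme $\psi$ (very insoluble gas, very high
  $\dot V/\dot Q$) the closed form suffers catastrophic cancellation and
  the bisection path carries the answer.
* **Degenerate inputs.** $\sigma = 0$ returns a single compartment and
  every pipeline quantity reduces to the single-unit closed forms exactly;
  $F_{\bar v} = 0$ gives zero flux; a target elimination of 0 calibrates
  to a venous fraction of 0.

## Calibration of venous N2O

The mixed-venous N2O fraction is not free: it is chosen so that the
whole-lung N2O elimination rate equals a target, 0.5 L/min by default —
the washout rate characteristic of early emergence. Whole-lung output is
strictly increasing in the venous fraction, so bisection on $[0, 0.7]$
converges unconditionally; the tolerance is $10^{-10}$ L/min on the
target. The 0.7 cap is the highest N2O fraction clinically usable without
hypoxia, and an unreachable target raises a typed error carrying the
achievable maximum rather than silently clamping. The same 0.5 L/min
calibration is applied to the distribution profiles and both sweeps for
consistency (every piece of it is config-overridable).

The venous second-gas fraction defaults to 0.01 — a 1% inspired mixture
previously equilibrated with the body has a mixed-venous dry-gas fraction
equal to the former inspired fraction. All reported outputs are fractions
of incoming second gas and the transfer law is linear in
$F_{\bar v}^{SG}$, so results are invariant to this choice; a test asserts
the invariance.

## What the model shows

```{r sweeps}
sol <- sweep_solubility(log10_lambda_grid = seq(-2.5, 1.5, by = 0.01),
                        sigma_set = c(0, 2))
find_max_gap(sol, "step1")$log10_lambda
find_max_gap(sol, "net")$log10_lambda
```

Step-1 (constant-volume) elimination always falls as mismatch increases,
most steeply for solubilities near $\lambda \approx 0.2$
($\log_{10}\lambda = -0.75$). The Step-2 extra elimination behaves
*paradoxically*: it grows with mismatch for low-solubility gases, because
those gases retain proportionately more of their incoming amount after
Step 1 in a mismatched lung, leaving more to be taken by the dilution.
The net effect still falls with mismatch, but less than Step 1 alone, and
the most mismatch-sensitive solubility shifts to $\lambda \approx 0.3$
($\log_{10}\lambda = -0.5$). The peak-gap locator evaluates the gap on a
0.01 grid of $\log_{10}\lambda$ and reports the argmax rounded to the
nearest 0.25 (ties and exact halfway points resolve toward the lower
solubility), matching the natural reporting resolution of the sweep.

Two fine points the discrete gas series makes visible. First, among the
thirteen named gases the largest Step-1 sensitivity to $\sigma$ belongs to
xenon ($\lambda = 0.115$, nearest the $\lambda \approx 0.2$ peak), not to
sulfur hexafluoride: SF6 is *so* insoluble that it is almost fully
eliminated even under severe mismatch. Second, the Step-2 reversal
(mismatch helping elimination) holds strictly for $\lambda \le 1$ and
decays to crossings of order $10^{-3}$ and below beyond that — the effect
virtually disappears once $\lambda > 1$, and the tests bound it there
rather than asserting a strict ordering that does not hold.

## What the model does not show

The model is a steady-state snapshot. In a real emergence the venous N2O
fraction decays within minutes as body stores deplete, so the volume
expansion — and with it every Step-2 effect — is transient. Tissue
stores, time-resolved washout kinetics, O2/CO2 interaction, cyclic tidal
ventilation, diffusion limitation, airway exchange of very soluble vapors,
and bimodal or measured (MIGET-type) $\dot V/\dot Q$ distributions are all
out of scope. Shunt and dead space exist only as the extreme tails of the
log-normal distribution. Passing tests therefore demonstrate internal
consistency of the steady-state theory and its closed forms, not the
magnitude of the effect in any particular patient.

## Parameter summary

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `sigma` | scenario-dependent | ln units | SD of $\ln(\dot V/\dot Q)$ over perfusion |
| `VI_total` | 4 | L/min | total inspired alveolar ventilation |
| `Q_total` | 5 | L/min | total pulmonary blood flow |
| `N` | 1001 | — | compartment count (odd) |
| `span` | 5 | SD | half-width of the $x$ grid |
| `lambda_n2o` | 0.47 | — | N2O blood/gas partition coefficient |
| `target_elimination` | 0.5 | L/min | whole-lung N2O washout rate |
| `Fv_n2o_cap` | 0.7 | — | ceiling on venous N2O fraction |
| `Fv_sg` | 0.01 | — | venous second-gas fraction (results invariant) |
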