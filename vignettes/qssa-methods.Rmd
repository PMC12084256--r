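---
title: "Methods: accuracy and predominance of quasi-steady-state reductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accuracy and predominance of quasi-steady-state reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qssa)
```

## The model and the reductions

The package studies the planar mass-action kinetics of the irreversible
Michaelis–Menten mechanism $S + E \rightleftharpoons C \rightarrow E + P$,

$$\dot s = -k_1(e_0 - c)s + k_{-1}c, \qquad
  \dot c = k_1(e_0 - c)s - (k_{-1} + k_2)c,$$

with free enzyme eliminated through $e = e_0 - c$. Three derived
constants organize everything: the equilibrium constant
$K_S = k_{-1}/k_1$, the Van Slyke–Cullen constant $K = k_2/k_1$, and the
Michaelis constant $K_M = K_S + K$. All quantities are treated as
consistent arbitrary units; no non-dimensionalization is imposed,
because validity conditions are expressed directly through dimensionless
ratios of the parameters.

Five reduced models are implemented as closed one-dimensional substrate
dynamics (`reduction_model()`), each paired with the phase-plane curve
that reconstructs the complex coordinate:

* **sQSSA** $\dot s = -k_2 e_0 s/(K_M + s)$, paired with the
  c-nullcline $\gamma_c(s) = e_0 s/(K_M+s)$;
* **slow-product QSSA** (the singular limit of small $k_2$), paired
  with its QSS curve $\gamma_{SP}$;
* **Kumar–Josić** refinement
  $\dot s = \mathrm{sQSSA}(s)/(1+\varphi(s))$ with
  $\varphi(s) = K_M e_0/(K_M+s)^2$, paired with $\gamma_c$;
* **Calder–Siegel** reduction built from the slow eigenvector slope
  $m$ at the origin, paired with the fence
  $\alpha_{cs}(s) = m e_0 s/(e_0 + m s)$;
* the piecewise **reverse QSSA**: constant-rate depletion
  $\dot s = -k_2 e_0$ right of the transcritical point $(0, e_0)$, and
  exponential complex decay $\dot c = -k_2 c$ on the vertical branch.
  A high-enzyme launch from the s-axis must be shifted to
  $(s_0 - e_0,\, e_0)$ (`shifted_initial_condition()`), reflecting the
  substrate consumed during the collapse onto $c = e_0$. The two pieces
  are exposed separately with the hand-off at $s = 0^+$ (the outer
  solution is clipped at zero); no matching rule beyond the clip is
  attempted because the theory supplies none, and only outer-regime
  substrate depletion is compared against the full model.

## Fences, anti-funnels and rate envelopes

A curve $c = \gamma(s)$ is a *fence* when the planar vector field
crosses it in one direction only, measured by the signed residual
$r(s) = \dot c(s, \gamma(s)) - \gamma'(s)\,\dot s(s, \gamma(s))$
(`fence_residual()`). An *anti-funnel* is the region between two fences
that trap a distinguished solution — here the slow invariant manifold —
and it is *narrowing* when the fence separation vanishes. Four named
regions are constructed (`anti_funnel()`): the nullcline trapping region
`Gamma`, the Calder–Siegel region `Gamma_cs`, the refined region
`Gamma_0` between $\gamma_c$ and
$\gamma(s) = \gamma_s(s) - k_2 e_0 s (K_M+s) /
\bigl(k_1 (K_S+s)(K_M e_0 + (K_M+s)^2)\bigr)$, and `Gamma_SP` between
$\gamma_{SP}$ and $\gamma$, whose fence property requires
$e_0 < 8K_S$ (the constructor refuses the region otherwise; for
$e_0 \ge 8K_S$ the property is *unproven*, not false — the condition is
sufficient only).

One documented orientation choice: the literature states the
Calder–Siegel region with $\gamma_c$ and $\alpha_{cs}$ in both orders in
different places; the package adopts $\gamma_c \le c \le \alpha_{cs}$,
consistent with the direction of the rate bound below.

Trapping the slow manifold yields rigorous envelopes on the substrate
rate in the slow regime, checked pointwise along trajectories by
`rate_bound_check()`: the sQSSA/Calder–Siegel envelope and the
sQSSA/Kumar–Josić envelope after the c-nullcline crossing
($t \ge t_{\mathrm{cross}}$), and the four-term chain inserting the
slow-product rate after the $\gamma_{SP}$ crossing while $s \le s^*$,
where $s^* = (k_{-1}/k_2)(e_0 - K)$ is the $\gamma_{SP}$/$\gamma_c$
intersection. A slack of $10^{-8}$ of the local envelope width absorbs
floating-point rounding; the envelopes themselves are theorems, so any
genuine violation indicates a solver failure.

## Dimensionless indicators and verdicts

`indicators()` reports: the Reich–Sel'kov ratio
$\varepsilon_{RS} = e_0/K_M$ (accuracy), the predominance ratio $e_0/K$,
the leading-order slow/fast eigenvalue ratio
$\delta = \varepsilon_{RS}\, k_2/(k_{-1}+k_2)$ alongside the exact ratio
$\lambda_+/\lambda_-$ (the truncation drops an $O(e_0^2)$ remainder that
the theory does not bound, so $\delta$ is reported but never used for
verdicts), the node discriminant deficit $4Ke_0/(K_M+e_0)^2$, and the
high-enzyme factor $\mu = \varepsilon_{RS}/(1+\varepsilon_{RS})^2$.

"Much less than" is not a number; `validity_report()` therefore applies
a configurable threshold $\theta$ (default 0.1) to every sharp
condition and always reports the raw ratio next to the verdict, and the
strict inequality $e_0 < K$ is kept separate from its thresholded
version $e_0/K \le \theta$ throughout — they are different claims and
the package never conflates them.

## Numerical methods

**Integrators.** No ODE solver package is available in the deployment
environment, so `src/` implements two classical steppers for this
specific 2-dimensional problem: an explicit Dormand–Prince 5(4) pair
with FSAL, PI step control and the pair's standard 4th-order dense
output, and an L-stable Rosenbrock 2(3) pair (the ode23s coefficient
set) using the analytic Jacobian, for parameter regimes where the fast
eigenvalue $\lambda_- \approx -k_1(K_M + e_0)$ times the slow horizon
makes an explicit method impractical (`method = "auto"` switches at
$k_1(K_M+e_0)\,T > 2\times 10^5$). Default tolerances are
`rtol = 1e-8`, `atol = 1e-10`; the test suite verifies that tightening
them tenfold moves reported error metrics by less than 1%, and that the
two steppers agree on a stiff reference problem.

**Dense output and events.** Crossing times of QSS curves are located
on the dense interpolant (never on raw steps, so they are independent
of step-size placement): a sign change is bracketed on the accepted-step
skeleton and refined by `uniroot` to $10^{-9}$ of the horizon.
Rosenbrock trajectories use cubic Hermite interpolation instead, which
matches that stepper's order.

**Horizons and stopping.** Integration stops at $s \le 10^{-3} s_0$ by
default (the late-time regime where predominance claims live), with a
horizon of 20 times the closed-form sQSSA depletion time
$t(s) = (K_M \ln(s_0/s) + s_0 - s)/(k_2 e_0)$ as a safety cap.

**Floating-point honesty.** Several asserted inequalities are strict in
exact arithmetic but have gaps that fall below double precision at
extreme parameter draws: the slope ordering $\gamma_{SP}'(0) < m$, and
fence residual signs at large $s$ where both fences converge to the
slow manifold and the residual decays orders of magnitude faster than
the terms composing it. Property tests therefore allow a relative slack
of $10^{-10}$ on slopes and $10^{-12}$ of the residual's conditioning
scale (returned by `fence_residual(detail = TRUE)`); 50-digit spot
checks confirmed the true signs in the cases where double precision
flips. The reference-parameter acceptance grids pass strictly with no
slack. Similarly, $\lambda_+$ is computed by the determinant (product)
form and the eigenvector slope $m$ by a branch between the rationalized
conjugate form (accurate for $k_1 e_0 \ll k_{-1}+k_2$) and the direct
form (accurate otherwise); without these forms the spectral identities
cannot be met at the $10^{-10}$ level the tests demand.

## The predominance experiment

The empirical protocol (`predominance_experiment()`) integrates the full
system from $(s_0, 0)$, launches each reduction from the same $s_0$ at
$t = 0$ (the convention of the reference depletion-curve comparisons; a
launch from the full model's state at $t_{\mathrm{cross}}$ is also
exposed for bound checks), and ranks reductions by maximum relative
substrate error over $[t_{\mathrm{cross}}, \mathrm{end}]$ — or
$[t_{\mathrm{cross\_sp}}, \mathrm{end}]$ for late-window comparisons.
The theory does not prescribe an error norm for "better approximation";
maximum relative error on $s(t)$ was chosen because predominance claims
concern small substrate concentrations, where absolute errors vanish
for every model. The maximum-absolute and RMS metrics are reported
alongside, and for the reference comparison pair the ranking is
insensitive to the choice.

`predominance_map()` sweeps a log grid of the two governing ratios
$(e_0/K_M,\, e_0/K)$ with $k_1$ and $e_0$ fixed and compares the
empirical winner with the rule "the sQSSA predominates iff $e_0 < K$"
inside the rule's stated domain ($e_0/K_M < 0.3$, $e_0/K$ at least a
factor 2 from 1). Cells needing $K > K_M$ are infeasible by
construction and skipped. The 90% agreement threshold and the factor-2
exclusion band are package-level acceptance constants, not results from
the theory.

## Synthetic scenarios

`figure_fixtures()` registers the verbatim reference parameter sets
(the large-$k_{-1}$ ambiguity pair, the trapping-region launches, the
four $s^*$ panels, the slow-product trapping launches, and the
predominance pair). The $s^*$ panels are phase-plane illustrations with
no stated $s_0$; fixtures carry a nominal $s_0 = 10$ so they remain
runnable.

`sample_regime()` draws rate constants log-uniformly on
$[10^{-2}, 10^2]$ and keeps draws satisfying a regime's defining
inequalities by rejection, with a margin factor of 10 operationalizing
"much less than" at sampling time (deliberately distinct from the
reporting threshold $\theta$). `noisy_progress_curve()` applies
multiplicative log-normal noise to subsampled substrate curves; the
noise model is a package convention for exercising downstream tooling —
the theory is deterministic and prescribes none — so a green test on
noisy data establishes only that the generator is calibrated and
seeded, nothing about real measurement error.

What the generator does *not* emulate: measurement noise structure of
real progress-curve assays, enzyme inactivation, product inhibition, or
reversibility of the catalytic step. Green tests on synthetic scenarios
establish internal consistency of the reductions against the mass-action
model, not agreement with any experimental system.

## Known limitations

* Initial-layer (fast-transient) asymptotics and a priori
  $t_{\mathrm{cross}}$ estimates are out of scope; crossing times are
  always measured from the computed trajectory.
* The rQSSA inner piece has no time parameterization comparable to the
  full model; comparisons are restricted to outer-regime substrate
  depletion.
* $\delta$ is reported with its leading term only; the dropped
  $O(e_0^2)$ remainder is unbounded by the available theory, which is
  why verdicts never rely on $\delta$.
* The predominance ranking compares the implemented reductions only;
  "predominant" always means predominant within that class.
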