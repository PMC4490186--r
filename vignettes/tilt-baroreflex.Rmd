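---
title: "A closed-loop 0D model of the systemic circulation with baroreflex control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop 0D model of the systemic circulation with baroreflex control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baroloop)
```

# The model

`baroloop` simulates short-term arterial pressure regulation during a
head-up tilt test in a closed-loop, lumped-parameter (0D) model of the
systemic circulation. The loop runs: left ventricle → large-artery
surrogate → per-outlet small-artery Windkessels → arterioles → venules →
veins → left atrium → left ventricle. The pulmonary circulation is omitted:
the baroreflex predominantly alters the systemic side, and the venous
compartment returns directly to the atrium. All internal quantities are CGS
(dyn, cm, s); reported pressures are mmHg (1 mmHg = 1333.22 dyn cm⁻²).

## Left heart

The ventricle is a time-varying elastance chamber,

$$P_{LV}(t) = \big[E_{min} + (E_{max}\,x_E - E_{min})\,e_n(t)\big]\,
  (V_{LV} - V_{u,LV}),$$

where $e_n$ is a normalized activation curve and $x_E$ the baroreflex
scaling of maximum elastance. The activation is the smooth piecewise
half-cosine

$$e_n(s) = \tfrac12\!\left(1 - \cos\tfrac{\pi s}{f_{max}}\right)
  \;\; (0 \le s \le f_{max}), \qquad
  e_n(s) = \tfrac12\!\left(1 + \cos\tfrac{\pi (s - f_{max})}{f_{relax}}\right)
  \;\; (f_{max} < s \le f_{max}+f_{relax}),$$

and zero otherwise, with $s$ the beat-phase fraction. The anchors are the
fixed fractions $f_{max} = T_{max}/T_{baseline} = 0.5$ and
$f_{relax} = T_{relax}/T_{baseline} = 0.25$: the curve is *universal in
normalized time*, so when the baroreflex shortens the period, systole and
relaxation shorten proportionally and the diastolic filling fraction is
preserved. This choice matters: anchoring the timing in absolute seconds
instead makes a 15–20 % tachycardia consume the entire filling window
(0.8 s → 0.53 s < $T_{max}+T_{relax}$ = 0.6 s), which collapses stroke
volume and drives the control loop into an unphysical runaway. The curve is
a documented stand-in with the correct (0, 1, 0) anchors; any alternative
shape can be substituted through `normalized_elastance()`.

Ejection is governed by the aortic-valve ODE pair

$$L_{AV}\dot Q_{AV} + (R_{AV} + R_{LV})\,Q_{AV} = P_{LV} - P_{AV},
  \qquad \dot V_{LV} = -Q_{AV},$$

with the nonlinear internal resistance $R_{LV} = k_{LV} P_{LV}$ (clamped at
zero for negative pressures, which only occur with both valves shut). The
mitral branch has the same diode + series $R$–$L$ structure. Valves open on
a favorable pressure gradient and close on retrograde flow, regardless of
the gradient; transitions are detected after an accepted step and applied
before the next one (no sub-step event localization). At the default step
the regurgitant volume per closure is below 10⁻⁴ cm³, asserted in the
tests against a 0.01 cm³ bound. The atrium is passive:
$P_{LA} = E_{LA}(V_{LA} - V_{u,LA})$.

## Large-artery surrogate

The large arteries are ten R–L–C segments (ascending aorta → arch →
subclavians, common → internal/external carotids, descending aorta). Per
segment: Poiseuille resistance $8\mu\ell/\pi R^4$, inertance $\rho\ell/A$,
and a compliance from the Bramwell–Hill relation
$C = \ell A / (\rho c^2)$ using the empirical pulse wave velocity
$c(R) = 13.3/(2R)^{0.3}$ (read as m/s for $R$ in cm and converted to CGS
internally; `pulse_wave_velocity()` returns the literal value and exposes
the unit switch). The corresponding wall modulus
$E = E^{*}\,3\rho R c^{2}/(2\zeta)$ with $\zeta = 0.1R$ and $E^{*} = 2$
reduces to $E = 30\rho c^2$, independent of radius; it is reported as the
wall-property summary, while $c$ itself parameterizes the compliance (the
membrane-formulation modulus and the Moens–Korteweg velocity differ by a
3/2 factor, so deriving $C$ from $E$ would double-count that factor).

Each outlet couples to a three-element Windkessel
($R_1$ from the characteristic impedance $\rho c/A$, compliance chamber
$C$, distal $R_2$), all of which drain into a shared arteriole–venule–vein
chain and back to the atrium with explicit flow gathering, so continuity is
exact by construction. Default outlet areas invert $R_1 = \rho c/A$ against
the published proximal resistances, which lands on plausible anatomical
radii (descending aorta ≈ 1.7 cm, carotid branches 0.18–0.27 cm) and makes
the characteristic-impedance rule self-consistent.

## Gravity and the tilt protocol

Posture changes act through a rotating gravity vector
$\mathbf g(\theta) = [g\sin\theta,\,0,\,-g\cos\theta]$ ($g = 981$ cm s⁻²),
realized in 0D as a hydrostatic pressure source
$\rho\,(\mathbf g \cdot \Delta\mathbf r)$ in series with every surrogate
segment, where $\Delta\mathbf r$ is the segment's body-frame end-to-start
offset. Literally, a positive rotation tips gravity toward the head; the
protocol's `head_up = TRUE` default flips the rotation sense so the upright
stage raises the carotids above the heart — the sign is explicit
configuration, not a hidden convention. Gravity acts only on the surrogate
segments (the distal 0D compartments see no hydrostatic offsets; a
configuration flag can extend them). Default upright elevations: carotid
outlets +25 cm above the aortic root, subclavians +5 cm, descending-aorta
outlet −15 cm; these are configuration, not constants. The default protocol
is 10 s supine, 5 s linear rotation to 90°, 10 s upright; a smoothstep ramp
is available.

## Baroreflex

The afferent index is the ratio of the cardiac-cycle-average carotid
pressure to its target, $\delta = \bar p / p_{target}$, evaluated at the
four carotid outlets; the site deviating most from 1 drives the response.
$p_{target}$ is frozen per site as the beat mean of the last completed
supine beat, and $\delta$ is held at exactly 1 before then, so control and
no-control runs are bit-identical until the rotation starts. Efferent
activities are the complementary sigmoids
$n_s = 1/(1+\delta^{\nu})$, $n_p = 1/(1+\delta^{-\nu})$ with $\nu = 5$.
Five normalized variables (heart rate $H$, maximum elastance $E_{max}$,
arterial resistance $R$, venous compliance $C_V$, venous unstressed volume
$V_U$) follow

$$\tau_i \dot x_i + x_i = \alpha_i n_s - \beta_i n_p + \gamma_i,$$

with the published gains used literally (including the negative $\beta_H$);
at $\delta = 1$ every steady state is exactly 1. Controls apply
multiplicatively at beat boundaries: the period is
$T_{baseline}/x_H$ (heart *rate* scaling), $x_R$ scales every distal
Windkessel resistance and the arteriole resistance (never the
characteristic $R_1$), and $x_{C_V}$, $x_{V_U}$ scale both venous
compartments' compliances and unstressed volumes. Because $\delta$ is a
per-cycle quantity, the control ODEs are advanced across each beat with
the exact closed form of the per-step backward-Euler recursion,
$x_n = s + (x_0 - s)\,(\tau/(\tau+\Delta t))^n$ — identical (to rounding)
to stepping every $\Delta t$. When $C_V$ or $V_U$ change, the venous state
pressures are re-partitioned at constant compartment volume
($P \leftarrow (V - V_u')/C'$), so unstressed-volume control moves blood
between stressed and unstressed pools without creating or destroying it.

# Numerics

Every first-order element ODE is discretized with backward Euler and
collected into $A x^{n+1} = B x^n + C q^{n+1} + D$; $A$ is LU-factorized
once per configuration and reused. The ventricle and valves are the only
nonlinearity; they are solved *monolithically* against the linear circuit
through its boundary-flow response $x = x_{free} + G q$ with
$G = A^{-1}C$, which reduces each step to one back-substitution plus a
2×2 damped Newton on the open-valve flows (relative residual < 10⁻¹⁰,
50-iteration cap with a reported residual history). The step is therefore
fully implicit, and $A$ is independent of valve state: refactorization
happens only at beat boundaries when the controls rescale parameters. In
the generic circuit module, diode branches are removed from the topology
when closed and the matrices are reassembled if and only if a valve
changes state.

Conservation is built in rather than monitored: capacitor volumes obey
$V = V_u + CP$, internal flows cancel node-by-node, and the only boundary
fluxes are the aortic and mitral flows, which the ventricle integrates with
opposite sign. The measured relative drift over a 25 s experiment with
active volume control is ~10⁻¹².

Choices and tie-breaks:

* `dt = 1e-4` s by default (the convergence tests double/halve it; the
  scheme is first order). Beat boundaries are quantized to the step.
* Valve transitions apply at the next step; the retrograde sample that
  triggers closure is the only negative flow a diode branch ever carries.
* Degenerate inputs error early: non-positive element values, `dt <= 0`,
  ventricular collapse ($V_{LV} \le V_{u,LV}$), circuits without a
  pressure reference (named in the error), Newton non-convergence.
* Initialization: default chamber volumes (ventricle 120 cm³, atrium
  60 cm³) and compartment pressures are only a starting guess; `spin_up()`
  iterates supine beats until stroke volume and mean aortic pressure change
  by < 0.1 % per beat. Because the loop conserves volume, the limit cycle
  is selected by the total blood volume implied by the initial state (about
  4.1 L by default); the distribution across compartments is forgotten.

## Windkessel tuning

`tune_windkessels()` calibrates the boundaries to a beat-mean aortic
pressure of 120 mmHg, an aortic pulse pressure of 30 mmHg, and a flow
division proportional to outlet area. Each outer iteration re-runs the
closed loop to its periodic supine beat (warm-started), then

1. assigns per-outlet total resistances $\propto 1/A_i$ at a controlled
   total conductance (flow split),
2. moves the total conductance by a secant iteration in log space on the
   mean-pressure target — a secant is needed because cardiac output is
   venous-return-buffered, making the mean pressure's elasticity to distal
   resistance well below one, and
3. scales the compliances by a damped fixed point on the pulse-pressure
   target.

The compliance scale applies uniformly to the Windkessel chambers *and*
the surrogate segment compliances (`surrogate$c_scale`, ≈ 1.4 after
tuning). This is deliberate: a lumped surrogate concentrates the
distributed storage of the large arteries, and with segment compliances
fixed the aortic pulse has a floor of about 31.5 mmHg set by the fixed
characteristic resistances times peak flow — the 30 mmHg target is then
unreachable by Windkessel compliance alone. Characteristic resistances and
the resistive assignments are never touched by the compliance step.
Convergence (all three targets within tolerance) typically takes 8
iterations; non-convergence within the cap is an error that prints the
iteration log.

# What the defaults emulate — and what they do not

The default configuration reproduces the *conditions* of a virtual tilt
test: a supine periodic circulation calibrated to 120/30 mmHg, then a 5 s
rotation to upright with and without reflex control. Passing tests show
that the circuit mathematics, the control law, conservation and the
calibration loop behave as specified. They do not show fidelity to any
patient: the surrogate has no wave propagation or reflection, no 3D
pressure field, the elevations are nominal stand-ins, there is no
pulmonary loop or dedicated vena cava, the baroreceptor model has no
hysteresis, adaptation or resetting, and rotation inertia is ignored
(gravity rotates, the body does not move).

One consequence deserves emphasis: with the default +25 cm carotid
elevation, the hydrostatic head at the carotids is ≈ 19.4 mmHg, and the
upright no-control carotid pressures fall by ≈ 26 mmHg (the extra
~7 mmHg is systemic: the descending aorta gains hydrostatic assist,
raising its flow and draining arterial volume). That stimulus is larger
than in tilt-table observations of pressure at heart level, so the
simulated reflex excursions (peak heart-rate control, time-to-peak,
stroke-work response) are correspondingly stronger and slower to recover
than the mid-teens-percent responses typically reported. Reducing the
configured carotid elevation weakens the stimulus proportionally; the
defaults are kept as stated and results are reported as computed.

# Problem sizes

The test suite and the acceptance script use the sizes the package is
designed around: 33 circuit states, 25 s experiments at `dt = 1e-4`
(250 000 steps, ~10 s of wall time each), spin-ups of at most 30–40 beats,
and a tuning loop of ~8 outer iterations of up to 20 beats each. Analytic
fixtures (RC, RLC, static column, driven three-compartment loop) run in
fractions of a second; the brute-force references use an adaptive
integrator at 10⁻¹⁰–10⁻¹¹ tolerances.
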