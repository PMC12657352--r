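---
title: "Methods: 0D estimation of branch flow division in diseased aortas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 0D estimation of branch flow division in diseased aortas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowdiv)
```

## The problem

Computational hemodynamics of the aorta needs one boundary condition per
branch outlet, and branch flow rates are rarely measured clinically. The
usual fallback — empirical healthy-subject flow fractions — misallocates
flow in diseased aortas: a branch behind a tight ostial stenosis cannot
physically carry its healthy share. `flowdiv` estimates a patient-specific
flow division by exploiting the one robust clinical measurement that is
always available, brachial cuff pressure, together with a digitally
"repaired" reference anatomy that anchors the healthy-state outlet
behaviour.

This package replaces the 3D CFD forward model such frameworks are usually
built on with a lumped-parameter (0D) network solver, so every stage of the
pipeline — repair, estimation loop, Windkessel tuning, transient simulation,
metric extraction — is exercisable in seconds on synthetic vascular trees.

## Forward model

A vascular network is a directed graph of cylindrical segments. Each
segment obeys

$$\Delta P = R_\mathrm{pois}\,Q + K\,Q\,|Q|, \qquad
  R_\mathrm{pois} = \frac{8\mu L}{\pi r^4},$$

the linear term being fully developed Poiseuille resistance. Stenosed
segments add the classical quadratic expansion-loss term

$$K = K_t\,\frac{\rho}{2A_s^2}\left(\frac{A_0}{A_s}-1\right)^2,
  \qquad A_s = \text{area\_ratio}\times A_0,$$

with $K_t = 1.52$ by default, the classical empirical coefficient for blunt
stenoses. A 3D solver needs no such constitutive law; a 0D model must posit
one, and this is the standard choice in lumped arterial modelling. The
quadratic term is what makes stenosis behaviour flow-dependent, which is in
turn what the estimation loop detects.

Mass conservation at every node closes the system, which is solved by
Newton iteration on nodal pressures (analytic Jacobian; conductance of a
segment is $1/(R + 2K|Q|)$). Internally everything is SI; user-facing units
are mmHg, mL/s, mmHg·s/mL and mL/mmHg (1 mmHg = 133.322 Pa).

Outlet conditions:

* `PRESCRIBED_FRACTION` — outlet flows fixed at a fraction of inlet flow;
  pressures reported against a datum chosen so the inlet pressure equals
  the supplied reference (drops are datum-independent, which the tests
  verify by re-solving under a shifted datum).
* `RESISTANCE` — $P_{out} = P_{ven} + R\,Q$ against a venous reference
  pressure (default 0 mmHg; the implied distal reference is not stated in
  the framework this follows, so it is configurable and documented).
* `ZERO_PRESSURE` — outlet pinned at the venous reference; included as the
  comparison mode whose purely geometry-driven splits are known to grossly
  overfeed the low-resistance supra-aortic branches.

## Estimation loop

1. $Q_{in}$ = mean systolic flow of the inlet waveform (steady solves at
   mean systolic inflow are the established way to recover mean pressure and
   resistance from a single simulation).
2. One steady solve of the **reference** geometry under the empirical
   division fixes geometric drops $\Delta P_i$ and flows $Q_i$. This solve
   is done once: in $R_i = (P_\mathrm{mean} - \Delta P_i)/Q_i$ the geometry
   enters only through $\Delta P_i$, which is independent of the pressure
   level.
3. Starting from the target $P_\mathrm{mean,ao}$ (exact for lesion-free
   anatomy — see the identity property below), iterate: convert to
   resistances, solve the **diseased** geometry at the same inlet flow,
   compare predicted inlet pressure with the target. Below a 1 % relative
   discrepancy the loop stops; otherwise
   $P_\mathrm{mean} \leftarrow P_\mathrm{mean} + \omega\,(P_\mathrm{target} - P_\mathrm{pred})$
   with $\omega = 1$.

The update scheme is deliberately the simplest monotone fixed-point
correction: the predicted inlet pressure is strictly increasing in
$P_\mathrm{mean}$ (a property test sweeps a pressure grid to confirm), so
the additive update converges for $\omega \le 1$ on these networks.

Two structural properties pin the implementation down:

* **Identity recovery.** For a lesion-free pair (diseased = reference),
  substituting the derived resistances back into the same network
  reproduces the prescribed flows and the target pressure exactly, so the
  loop converges at the first check with the empirical division recovered
  to better than 1e-8 per branch. This is a parameter-recovery test of the
  whole pipeline.
* **Stenosis steal.** Tightening a branch's stenosis strictly lowers its
  converged fraction, with the displaced flow redistributed so fractions
  still sum to one.

If the target pressure lies below a branch's geometric drop, the required
resistance would be negative; this is raised as a non-convergence condition
(`fd_negative_resistance_error`) since no iterate can repair it, and the
command-line interface maps it to exit code 3.

## Empirical division rules

The healthy-subject allocation: 30 % of cardiac output to the supra-aortic
branches in proportion to their inlet areas; celiac trunk 15.5 %; superior
mesenteric and both renals 10.5 % each; inferior mesenteric 0.5 % when
present; the remainder split equally between the two iliac systems and
70 %/30 % between external and internal iliac per side. With all twelve
branches present this yields 7.875 % per external iliac (printing as 7.9 %)
and 3.375 % per internal iliac (3.4 %), independent of the supra-aortic
areas.

## Pressure targets

Brachial cuff readings are converted with the empirical transfer
$P_\mathrm{sys,ao} = 0.83\,P_\mathrm{sys,bra} + 0.15\,P_\mathrm{dia,bra}$,
$P_\mathrm{dia,ao} = P_\mathrm{dia,bra}$, and
$P_\mathrm{mean,ao} = 0.4\,P_\mathrm{sys,ao} + 0.6\,P_\mathrm{dia,ao}$.

## Windkessel tuning and transient simulation

`tune_windkessel()` uses the single-steady-solve ("fast") strategy: the
diseased network is solved once at mean systolic inflow with the estimated
division prescribed; outlet $i$'s total resistance is
$(P_\mathrm{mean,ao} - \Delta P_i)/\bar Q_i$ with
$\bar Q_i = \mathrm{division}_i \times \bar Q$. Whether $\bar Q$ should be
the cycle-mean or mean-systolic inlet flow is genuinely open; both are
exposed (`flow_basis`), cycle-mean being the default since the tuned
resistances must balance the cycle-mean operating point of the transient
run. The split $R_c = f_c R_i$, $R_p = (1-f_c) R_i$ uses $f_c = 0.056$
(characteristic impedance is a few percent of total arterial resistance),
and compliance follows from a single global decay constant,
$C_i = \tau / R_{p,i}$ with $\tau = 1.79$ s, a typical aortic
pressure-decay time. Both are configurable; the delegated tuning literature
does not print universal values.

`solve_transient()` integrates with backward Euler (first-order implicit),
$\Delta t = T/1000$ and five cycles by default. The Windkessel capacitor
states are unknowns of the same Newton system as the nodal pressures
(monolithic coupling): outlet flow $Q_i = (P_{out,i} - P_{c,i})/R_{c,i}$
and $C_i\,(P_c^{n+1}-P_c^n)/\Delta t = Q_i^{n+1} - P_c^{n+1}/R_{p,i}$.
Capacitors initialize from a steady solve at cycle-mean inflow with
equivalent resistances $R_c + R_p$ (i.e. $P_c = R_p Q_i$), which starts the
run near the periodic regime.

One honest caveat, verified numerically: with $\tau = 1.79$ s and a 1 s
cycle, the distance to the periodic regime decays by
$e^{-T/\tau} \approx 0.578$ per cycle, so five cycles still leave roughly
1.4 % cycle-to-cycle variation in inlet pressure; ten cycles bring it below
0.5 %. The `periodicity()` diagnostic reports this value so users can judge
whether their final cycle is converged; the test suite asserts the
geometric decay at the analytic rate rather than an arbitrary threshold.

## Metric suite

All cycle integrals use trapezoidal quadrature on the given samples
(quadrature is not specified in the source formulations; trapezoid is the
natural choice for periodic sampled data and makes the
$RRT\,(1-2\,OSI)\,TAWSS = 1$ identity hold exactly under shared
quadrature).

* TAWSS $= \frac1T\int_0^T|\tau_w|\,dt$; OSI
  $= \frac12\left(1 - |\int\tau_w\,dt| / \int|\tau_w|\,dt\right)$, clipped
  to $[0, 0.5]$ against round-off; RRT $= 1/((1-2\,OSI)\,TAWSS)$ with an
  `Inf` sentinel at OSI = 0.5; AFI = cosine between the instantaneous shear
  at the observation instant and the cycle-integrated shear.
* "Mid-systolic deceleration" for AFI is operationalized as the time of
  most negative inlet-flow derivative within systole (the phase is named in
  the literature but not defined); it is overridable.
* Wall shear from 0D flows uses the Poiseuille relation
  $\tau = 4\mu Q/(\pi r^3)$ per segment — a signed axial scalar, which is
  what a 1D-profile model can support.
* LNH $= \mathbf v\cdot(\nabla\times\mathbf v)/(|\mathbf v||\nabla\times\mathbf v|)$
  with central-difference curl, one-sided at grid boundaries. On an ABC
  (Beltrami) test field every central-difference derivative scales the
  analytic one by the same $\mathrm{sinc}$ factor, so interior LNH is exact
  to machine precision; one-sided boundary stencils perturb the direction
  by $O(h)$, so accuracy statements are made on the interior (and on the
  grid mean, which the boundary shells barely move).
* Degenerate points (zero shear, zero velocity or vorticity below 1e-12)
  carry `NA` flags rather than raising, so field summaries remain
  computable.
* Temporal statistics conventionally thin to every tenth step of the final
  cycle; `sample_every_tenth()` implements exactly that decimation.

## Synthetic anatomy: what it does and does not emulate

The healthy template is a ten-station tapering trunk (ascending aorta,
radius 1.5 cm, to iliac bifurcation, 0.8 cm) with the twelve canonical
branches at typical adult radii and lengths, fixed in a documented
morphometry table; real patient geometries are CTA meshes that a desk-scale
artifact cannot ship. A multiplicative log-normal jitter (sd 3 %, a
conservative figure for inter-subject calibre variability) makes cohorts
anatomically distinct while keeping every network solvable.

Lesions are reduced-order analogues: ostial stenosis attaches the loss law
to a branch's first segment (the geometric radius is untouched — the
stenosis descriptor carries the constriction); fusiform aneurysm multiplies
radii over a station range and records the factor; dissection splits a
trunk extent into parallel true/false-lumen chains (area fractions 0.43/0.57
of a 1.2-fold expanded lumen, matching the usual observation that the false
lumen is the larger channel) cross-linked by tear segments, with selected
branches re-anchorable onto the false lumen. Repair merges the chains back,
interpolating radii linearly in station index between the bounding
unaffected stations, and applies a configurable contraction factor
(default 1.0: the quantitative degree of post-merge contraction has no
published prescription, so none is imposed).

Passing tests on these networks demonstrate the *logic* of the method —
identity recovery, steal direction, conservation, convergence — not its
clinical accuracy: the 0D model has no secondary flow, no turbulence, no
wall compliance or flap motion, a plug-equivalent velocity profile, and its
stenosis law is an empirical scalar correlation. Those are exactly the
features a 3D solver on patient geometry would add back.

## Numerical choices

* Newton tolerance: max nodal mass imbalance ≤ 1e-10 of inlet flow;
  damping 0.7 on the first 5 iterations stabilizes the quadratic term.
* The initial iterate is the linearized (pure-Poiseuille) nodal solve — for
  lesion-free networks it is already the solution, and it dominates any
  flat or equal-split guess on stenosed ones.
* Flow from a pressure drop inverts the segment law in closed form,
  $Q = \mathrm{sign}(\Delta P)\,(-R + \sqrt{R^2 + 4K|\Delta P|})/(2K)$;
  the test oracle instead brackets the forward law with scalar root finding
  and solves the nodal system with an unrelated root finder, keeping the
  two routes independent.
* Ties/degeneracies: the steady system is smooth and monotone, so no
  tie-breaking arises; dead-end (false-lumen) segments carry exactly zero
  flow and are handled naturally by the nodal formulation.
* Problem sizes in tests: networks of 3–31 segments; transient runs of
  100–2000 steps/cycle and 1–10 cycles; one 64³ helicity grid. These sizes
  keep the full suite under ten seconds while still exercising every code
  path at the protocol's native resolution (1000 steps/cycle) where the
  check depends on it.

## Known limitations

* The estimation loop inherits the steady-tuning bias: compliance is absent
  from the steady solves, so transient runs underestimate mean pressure
  relative to the steady target; this is a property of the tuning strategy,
  not of the implementation.
* Five cycles do not fully reach periodicity at the default time constant
  (see above); use `periodicity()` and extend `n_cycles` when sub-percent
  cycle convergence matters.
* The dissection analogue reproduces topology (two lumina, tears, branch
  provenance), not the pressure field of a real flap; transmural-pressure
  outputs are therefore qualitative.
* Empirical division rules assume the twelve-branch anatomy; accessory
  renals or bovine arches are out of scope.
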