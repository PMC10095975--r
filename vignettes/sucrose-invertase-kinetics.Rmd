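---
title: "Kinetic analysis of invertase-driven sucrose cleavage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of invertase-driven sucrose cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metfun)
```

## The model

Invertases hydrolyse sucrose into glucose and fructose. In leaves this
reaction sits inside a cycle of sucrose synthesis and breakdown, which makes
its net contribution hard to measure directly; `metfun` instead analyses it
through *metabolic functions* — the right-hand sides of the sugar ODEs.
With a constant sucrose biosynthesis rate $r_{in}$, the invertase rate
$r_{inv}$, and hexose-consuming effluxes $r_{out,Glc}$, $r_{out,Frc}$
(e.g. hexokinase phosphorylation):

$$
\frac{d\,Suc}{dt} = f(Suc) = r_{in} - r_{inv}, \qquad
\frac{d\,Glc}{dt} = f(Glc) = r_{inv} - r_{out,Glc}, \qquad
\frac{d\,Frc}{dt} = f(Frc) = r_{inv} - r_{out,Frc}.
$$

Plant invertases are product inhibited: glucose acts non-competitively,
fructose competitively. `metfun` encodes exactly those two mechanisms in the
textbook mixed-inhibition form

$$
r_{inv} = \frac{V_{max}\, S}
  {\bigl(K_M (1 + F/K_{i,F}) + S\bigr)\,\bigl(1 + G/K_{i,G}\bigr)},
$$

where the competitive term scales the apparent $K_M$ and the non-competitive
term scales the whole rate. This algebraic form is a design choice of the
package (the standard encoding of the two stated inhibition types); users
with an independent derivation of the rate law should verify against
`invertase_rate()` before reusing downstream conclusions. The rate is
bounded by $V_{max}$, strictly increasing in sucrose and strictly decreasing
in each hexose — properties asserted by the test suite over random states.

**Units.** Everything internal is mM and hours. Whole-tissue amounts in
µmol gFW⁻¹ convert one-to-one to mM under the convention that 1 g fresh
weight corresponds to about 1 ml of water; `tissue_amounts()` exposes the
conversion factor for tissues where that assumption fails.

## Sensitivity surfaces: Jacobian and Hessian

Local regulation is read off the derivatives of the metabolic functions in
the fixed variable ordering (Suc, Glc, Frc):

* $j_{11} = \partial f(Suc)/\partial Suc \le 0$ — substrate drives cleavage;
* $j_{12} = \partial f(Suc)/\partial Glc \ge 0$ — glucose relieves the drain
  on sucrose by inhibiting invertase;
* $j_{13} = \partial f(Suc)/\partial Frc \ge 0$ — likewise for fructose;

with the Hessian entries $h_{f(Suc),1k}$ quantifying the curvature of the
$f(Suc)$ surface. All first and second derivatives are hand-derived closed
forms (`analytic_jacobian()`, `analytic_hessian()`), not runtime numeric
differentiation: the analysis hinges on exact surfaces, closed forms make
the sign claims provable, and Hessian symmetry is exact by construction.

An independent central-difference oracle (`finite_difference_oracle()`,
`derivative_report()`) cross-checks every analytic expression. Numerical
choices: relative step $10^{-6}$ for gradients; $10^{-3}$ for Hessians. The
larger second-order step matters: in strongly inhibited corners the
curvature can sit five orders of magnitude below the function value, and at
a $10^{-4}$ step float cancellation in the second difference leaves a
relative error of order $10^{-4}$, while $10^{-3}$ is near the optimum of
the truncation/cancellation trade-off (discrepancies around $10^{-6}$).
Steps that would cross the non-negativity boundary of a concentration fall
back to a one-sided second-order stencil and flag the result.

Discrepancies are measured as the maximum absolute entry difference divided
by the largest entry magnitude of the matrix pair. A plain entrywise
relative error would be dominated by entries that are structurally tiny;
the scale-relative form asks the question that matters — whether the
surfaces agree at the scale on which they are used.

## Grids and the ambient/cold contrast

`scan()` evaluates functions, Jacobian and Hessians over a
glucose × fructose grid on a set of sucrose planes (sucrose-plane major,
fructose fastest; byte-deterministic output). Default resolution is 50 × 50
hexose points on 3 planes (endpoints plus midpoint of each sucrose range) —
the surfaces are smooth and monotone, and the refinement test shows the
extrema are already stable at this resolution.

The bundled whole-cell grids place sucrose planes at 1–3 µmol gFW⁻¹ for the
ambient (22 °C) scenario and 4–8 µmol gFW⁻¹ for the cold (4 °C) scenario
(cold-acclimated tissue accumulates sucrose up to 8-fold above the ambient
minimum). The hexose axes have no fixed reference range; the package
uses 1–3 µmol gFW⁻¹ at 22 °C and 5–15 µmol gFW⁻¹ at 4 °C. The high ends
are the glucose levels at which the fructose sensitivity $j_{13}$
becomes minimal in the respective condition; the low ends reflect
that leaf hexose pools do not approach zero physiologically — a roughly
3-fold span is what diurnal-scale variation supports. These are
configuration defaults, overridable per scenario.

The `dynamic_range_summary()` / `compare_scenarios()` pair operationalises
the ambient/cold comparison: ranges (max − min), order-of-magnitude spans of
nonzero magnitudes, and the overlap between the $j_{12}$ and $j_{13}$ value
intervals as a Jaccard fraction of their [min, max] ranges. The overlap
measure is an *interpretation* — the underlying observation is described
only qualitatively — and, unlike the dynamic-range
contrasts, its direction is not reproduced by generic synthetic parameter
sets: it depends on the particular experimental parameter values, which are
not transcribed here. It is therefore reported as a diagnostic, not asserted
as a population property.

## Subcellular resolution

`effective_concentration()` converts a whole-tissue amount into a
compartment-local molar concentration:
$c = \mathrm{fraction} \cdot \mathrm{amount} /
(\mathrm{volume\ fraction} \cdot \mathrm{fw\_to\_volume})$,
with the cytosol taken as 5 % and the vacuole as 80 % of cell volume — hence
a 16-fold dilution for equal amounts and shares. Default distribution
shares (sucrose 50 %/25 % cytosol/vacuole at 22 °C, 40 %/33 % at 4 °C;
hexoses 30 %/55 % and 30 %/50 %) live in the bundled configuration.

One asymmetry is kept deliberately. The subcellular sucrose plane ranges
used by the packaged subcellular analyses (cytosol 22 °C: 8–24 mM; vacuole 22 °C:
0.25–0.75 mM; cytosol 4 °C: 25.6–51.2 mM; vacuole 4 °C: 1.32–2.64 mM) are
*not* all reproducible from the distribution shares under any single
formula — e.g. the 8–24 mM cytosolic range follows from a 40 % share where the
stated distribution gives 50 %, and the vacuolar ranges equal share × amount with no
volume division. Which convention was applied per compartment is not
recoverable, so `build_subcellular_scenarios()` treats those sucrose
ranges as authoritative grid inputs, while the hexose axes (which have no
fixed reference) are derived from the formula. Users with their own subcellular data get the
formula path via `effective_concentration()`.

Because vacuolar concentrations sit far below the inhibition constants, the
vacuolar surfaces keep a strong separation between substrate and product
sensitivities, while cytosolic entries compress towards each other — the
pooled $|j_{11}|,|j_{12}|,|j_{13}|$ magnitudes span more decades in the
vacuole. That pooled order-of-magnitude span is the package's reading of
the compartments' "wider relative range" of Jacobian entries; it is what
`analysis/02_subcellular_scan.R` and the acceptance checks compute.

## Time courses, steady states, transport

`simulate()` integrates the ODEs with `deSolve` (`lsoda`, stiff-capable)
using the analytic Jacobian; defaults `rtol = 1e-8`, `atol = 1e-10` mM,
because inhibition constants can be small against cold-accumulated
concentrations and make the system stiff. Rates are evaluated at
`max(x, 0)` so the tiny negative excursions any tolerance-bounded solver
produces cannot feed negative concentrations into the rate laws. The
conserved quantity of a closed system, $2\,Suc + Glc + Frc$ (hexose units;
sucrose counts twice), is exposed by `hexose_units()` and is conserved to
well below $10^{-8}$ relative over 100 h in the tests.

The two-compartment model (`coupled_scenarios()`, `simulate_coupled()`)
runs each compartment's kinetics on its local concentrations and exchanges
sugars across the tonoplast — sucrose cytosol → vacuole, hexoses
vacuole → cytosol — first-order in the donor concentration by default
(Michaelis–Menten selectable). Transfers are volume-consistent: removing
$k \cdot c$ from the donor adds $k\,c\,\phi_{donor}/\phi_{acceptor}$ to the
acceptor, so the volume-weighted hexose units of a closed pair are
conserved exactly. The independent-compartment scans remain the default
analysis mode; coupling exists for simulation studies.

`find_steady_state()` is a damped Newton iteration on the RHS with the
analytic Jacobian (tolerance $10^{-10}$ on the max residual), constrained
to non-negative concentrations, with an explicit non-convergence report —
never a silent wrong root. Steady states are cross-validated against long
simulations in the tests.

## Synthetic scenarios and parameter recovery

The experimentally determined parameter values that motivated this kind of
analysis are not numerically available here, so `scenario_template()` /
`generate_scenario_pair()` generate parameter sets with the same
*structure*: an ambient set ($V_{max} \sim U[1,10]$ µmol h⁻¹ gFW⁻¹,
$K_M \sim U[1,10]$ mM — the low-millimolar range typical of invertases,
$K_i \sim U[0.5,20]$ mM, $r_{in} \sim U[0.1,1]$), and a cold set derived by
attenuating $V_{max}$ and $r_{in}$ by independent factors $\sim U[0.2,0.8]$
with binding constants held temperature-stable, grids shifted upward as
above. All draws are seed-deterministic, and every artefact embeds its seed
and template. These distributions emulate the *contrast structure* of the
study conditions — they do not emulate correlations between parameters,
isoform-specific pH effects, or measurement error in experimentally
determined kinetic constants, so passing contrast tests demonstrates that the pipeline
reproduces the mechanism, not any particular experimental numbers.

`generate_time_course_data()` adds multiplicative log-normal noise
(metabolite measurements are positive and heteroscedastic).
`fit_parameters()` recovers parameters by least squares on the log scale,
optimised in log-parameter space under box constraints
(`minpack.lm::nls.lm`) with multi-start (default 10 starts, 3-fold
log-uniform perturbations). With trajectories of all three sugars,
$V_{max}$, $K_M$ and $r_{in}$ are well identified; the inhibition constants
are only weakly identifiable unless initial conditions perturb the hexoses,
which is why they are not fitted by default.

## Problem sizes and limitations

The packaged analyses use 50 × 50 × 3 grids (7 500 points per scenario),
100 random states per scenario for derivative verification, 50 synthetic
pairs for the ambient/cold contrast, and 10–20 noise replicates at 50 time
points for recovery — sizes at which every check runs in seconds to a
couple of minutes on one core while leaving the Monte-Carlo conclusions
stable.

Known limitations: sucrose re-synthesis (the other half of the cycle) is
not modelled — $r_{in}$ is a constant; temperature enters only as discrete
named scenarios; no chloroplast/apoplast compartments or extracellular
invertase; no eigen-analysis of the system Jacobian; and all bundled
kinetic constants are labelled synthetic stand-ins for the unavailable
experimental values.
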