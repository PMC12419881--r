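---
title: "Hybrid master-equation models with mean-field limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid master-equation models with mean-field limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meanflame)
```

## The modelling problem

Deterministic (mean-field) population models track expected counts with a
few ODEs, but they cannot represent absorbing states: a birth--death
population with births at rate $\mu n$ and deaths at rate $\nu n^2$ has an
unstable extinction state at $n = 0$ in the mean-field picture, so any
positive start drifts to the metastable state $n^{**} = \mu/\nu$ and stays
there forever. The master equation -- one ODE per discrete state $n$,

$$\frac{d}{dt}P_n = (n+1)^2\nu P_{n+1} + (n-1)\mu P_{n-1}
  - (n\mu + n^2\nu) P_n,$$

is exact and captures stochastic extinction, but needs as many equations as
there are reachable states, which is hopeless for large or spatial systems.

This package implements the hybrid in between. States close to the
absorbing state (counts $0,\dots,n_c-1$) are tracked explicitly; all states
with $n \ge n_c$ are collapsed into a *mean-field limit* described by two
quantities: the probability $P_{I}(t)$ of being anywhere in the limit, and
the expected count $I(t)$ of systems inside it. Four kinds of equations
result: interior master-equation states, the edge state at $n_c - 1$, the
limit occupation $P_I$, and the limit value $I$, whose ODE is exactly the
classic mean-field equation. With $n_c = 0$ the build *is* the mean-field
model; pushing $n_c$ past the truncation recovers the exact master
equation.

## The boundary coupling

Probability enters the limit when the edge state takes one step up. It
leaves when a system inside the limit, sitting exactly on the boundary
count $n_c$, takes one step down. The probability of sitting on the
boundary is modelled by a Poisson distribution with mean $I(t)$ truncated
to $[n_c,\infty)$:

$$\rho[n_c, I(t)] = \frac{e^{-I} I^{n_c}/n_c!}{\sum_{k \ge n_c} e^{-I}
I^{k}/k!},$$

so the exit rate is (rate evaluated at $n = n_c$) $\times\ \rho \times
P_I$. `rho()` computes this in log space; it is exact to $10^{-10}$
relative error against direct summation over the whole range used here
($n_c \le 50$, means up to $10^3$), and saturates at 1 as the value
collapses onto the boundary. The truncated Poisson is a modelling choice,
not a theorem: for the quadratic-death birth--death process the true
quasi-stationary distribution is narrower, and the limitations section
below quantifies what that costs.

## Multiple dimensions, subsystems and space

In $d$ dimensions every dimension carries its own cutoff and sentinel, so a
subsystem with $n$ explicit states per dimension has $(n+1)^d$ occupation
states, and every dimension with a limit carries one value equation per
state of the other dimensions (the value of the double limit conditions on
the partner's own limit value). The builder (`build_system()`) enumerates
states dimension-major (first declared dimension fastest, explicit
coordinates ascending, sentinel last, values after occupations, subsystems
in order), which makes enumeration reproducible and serialisable
(`equation_table()`).

Events are declared as `transition()` rules -- a stoichiometry plus a rate
function of effective counts. The builder derives all flows mechanically:

* explicit $\to$ explicit: the standard master-equation pattern;
* a +1 step out of the edge state enters the limit;
* a $-1$ step of a limited dimension exits at the $\rho$-weighted boundary
  rate;
* a *diagonal* event (predation: prey down, predator up) out of a prey
  limit splits into an exit branch (prey drop to the edge, weight $\rho$)
  and a stay branch (predator moves, prey limit retained, weight
  $1-\rho$);
* events that only move limited dimensions upward cause no occupation flow
  -- the value ODEs carry them;
* in the double limit the two dimensions are treated as independent
  truncated Poissons, each exit evaluated with the partner at its mean
  value.

Value ODEs are the deterministic rate balance of the same rules with the
limited coordinate replaced by its value and the conditioning coordinates
held fixed; they are autonomous (occupation flows never reset them), which
is also what makes staged integration possible (below). Rates feeding
occupation flows are floored at zero; value ODE terms are not (the
logistic pull-back $\mu F(K - F)$ may legitimately turn negative when a
prey value transiently exceeds the carrying capacity).

Subsystems (lattice sites) are joined by an expected-influx field
$\theta$: a factor times the weighted sum of the neighbours' expected
counts (`expected_count()` weighs explicit coordinates and limit values by
occupation). This is the approximate-master-equation closure: it scales
linearly in the number of sites but discards inter-site correlations, so a
locally extinct site is re-seeded at the *average* neighbour rate even when
its actual neighbours are extinct too. The cost of that closure is visible
in the coupled birth--death study below.

## Case studies and their conditions

All study parameters live in `get_fixture()`; tests and scripts never
hand-enter them.

* **fig2** -- single birth--death, $\mu = 1$, $\nu = 0.05$ (metastable
  state 20), cutoff 8, exact reference truncated at 100 states, start at
  $n = 1$, horizon $t = 400$. The initial point mass at one individual is a
  package choice (the natural "one founder" experiment); it is recorded in
  every manifest.
* **fig3** -- two coupled subsystems, $\mu = 1$, $\nu = 0.1$,
  migration factor $\lambda = 0.004$, cutoff 8 each (20 equations), joint
  exact reference with $50 \times 50$ states, horizon $t = 100$.
* **fig5 / fig6** -- predator--prey with logistic prey growth, prey birth
  rate $\mu F (K_F - F)$, predation $\beta F S$, predator death $\nu S$,
  $K_F = 20$, exact reference $(K_F+1)^2 = 441$ states (the prey dimension
  is naturally capped by the vanishing birth rate at $K_F$; the predator
  truncation is set to the same width). fig6 uses $\mu = 0.005$,
  $\nu = \beta = 0.1$, one prey and one predator, horizon $t = 100$ (the
  package's choice of window; extinction is still slowly accruing there).
  fig5 starts at 12 prey and 8 predators with $\beta = 0.04$,
  $\nu = 0.4$ and the quoted birth rate 0.4 applied *per capita*
  (coefficient $0.4/K_F$ in the rate above, horizon 150). The raw
  coefficient would make prey births outpace predation roughly forty-fold,
  pinning predators at the truncation cap with extinction probabilities of
  order $10^{-13}$ -- no cycling, no extinction, nothing to study. The
  per-capita reading restores the regime this case study is about
  (stochastic cycles ending in extinction while the deterministic model
  persists), and is the interpretation the package adopts.
* **fig8** -- spatial SIRS on a $50\times50$ von Neumann lattice with
  populations $N(x,y) = \lceil 10 + 100\cos^2(x/5)\sin^2(y/2)\rceil$,
  $\beta = 0.025$, $\alpha = 1$, $\gamma = 0.01$, $\lambda = 0.1$, cutoff
  10 per dimension ($n_c^2 + 4n_c + 3 = 143$ equations per site, 357,500
  in total), one initial case in the 25 sites with $x,y < 5$, cases read at
  $t = 9$. "Cases" means $i + r$; with $\gamma = 0.01$ and $t = 9$ barely
  any immunity has waned, so this approximates cumulative infections
  without carrying an extra counter dimension.
* **fig10** -- four-stage tree lifecycle (seeds and seedlings as *pure*
  mean-field dimensions, one value per occupation state; saplings and
  adults with explicit states, cutoff 5) on a climate landscape
  $K(x,y,t) = 20(\sin((x+t)/2)\cos((y+t)/5))^2$. Growth from sapling to
  adult is nonlinear, $\mu_y \sqrt{y}\, \max(K - a, 0)$: the square root
  uses the integer coordinate in explicit states and $\sqrt{\text{value}}$
  in the limit -- exactly the nonlinearity a continuous mean-field model
  gets wrong, because $\sqrt{y} \gg y$ for $y \ll 1$. Seeds disperse
  uniformly over a site and its von Neumann neighbours with
  source-normalised weights ($1/5$ in the interior; the kernel's support is
  given, its weights are a package choice). The per-site enumeration is
  36 occupation states, 12 sapling/adult values and $2 \times 36$
  seed/seedling values -- 120 equations; published per-cell and total
  counts for this configuration are mutually inconsistent, so the package
  documents its own enumeration and does not chase either number.

## Numerical choices

* Default integrator: `lsoda` with `rtol = 1e-8`, `atol = 1e-10`.
  Occupation entries are never clipped -- clipping silently destroys the
  conservation property that the assembled right-hand side satisfies
  exactly ($\sum_y \dot P_y = 0$ by construction, asserted symbolically in
  the tests and to integrator tolerance along trajectories).
* The predator--prey hybrids at larger $n$ trip `lsoda`'s corrector near
  sharp value collapses; `radau` integrates them cleanly and is used for
  the extinction sweeps.
* The $10\times10$ tree landscape (12,000 equations) uses `adams`
  (Jacobian-free) at `rtol = 1e-6`; its 400-equation mean-field comparator
  is integrated with fixed-step `rk4` (`hini = 0.01`) because the
  $\sqrt{Y}$ growth term has unbounded slope at $Y \to 0$, which defeats
  Jacobian-based step control while being harmless to a fixed-step scheme.
* Mean-field values are initialised at their cutoff $n_c$ -- the entry
  point of any trajectory into the limit -- except for $n_c = 0$
  dimensions, which start at the requested count. Values are not clamped;
  only the argument of `rho()` is floored at zero.
* Problem sizes: the spatial studies are exercised at reduced scale --
  SIRS on a $3\times3$ grid against a $10^4$-run Gillespie ensemble, trees
  on a $10\times10$ grid to $t = 30$ -- which keeps every boundary
  mechanism (limits, couplings, dispersal) active while the full
  $50\times50$ builds are exercised for enumeration and are runnable
  through `run_from_config()`.
* Staged integration (`integrate_staged()`) solves the autonomous value
  ODEs first and feeds the stored time course into the occupation
  equations; it refuses $\theta$-coupled systems, whose values depend on
  occupations. It exists because occupations ($\le 1$) and values
  (possibly huge) can sit at very different scales in one system.

## What the comparisons show -- and what they cannot

The synthetic conditions above are closed, well-specified Markov processes;
the exact references (sparse-generator master equations, checked against
`Matrix::expm`, and seeded Gillespie ensembles) are *exact* for them. A
passing suite therefore shows that the hybrid construction approximates
its own target process well; it says nothing about how well any of these
processes describe field data -- real epidemics have contact structure,
seasonality and reporting noise that none of these models carry.

Known limitations, measured rather than hidden:

* The truncated-Poisson boundary shape is wrong for the quadratic-death
  birth--death process. Where the metastable state sits well inside the
  limit (fig2: $\mu/\nu = 20$, cutoff 8) the error is negligible -- the
  hybrid's extinction mass at $t = 400$ matches the 100-state exact build
  to $\sim 10^{-5}$. Where the metastable state sits *on* the boundary
  (fig3: $\mu/\nu = 10$, cutoff 8) the true edge mass exceeds the Poisson
  edge mass, the limit over-fills, and marginal distributions are off by
  $\sim 0.14$--$0.20$ in L1 even though extinction probabilities stay
  within $0.015$. Choosing the cutoff relative to the metastable state
  matters more than its absolute size.
* The hybrid's expected count conditional on survival converges to exactly
  $\mu/\nu$ (the value ODE's fixed point), while the exact
  quasi-stationary mean is slightly lower (18.94 vs 20 at fig2
  conditions); the survival-conditional mean inherits a few-percent bias
  from the Poisson closure.
* The $\theta$ closure ignores correlations between subsystems, so joint
  extinctions are under-predicted (locally extinct sites are re-seeded at
  the average rate).
* With a single explicit state per species ($n = 1$) the predator--prey
  extinction curve is sensitive to the double-limit closure: it
  over-predicts extinction at early and intermediate times and settles
  slightly below the exact curve. From $n = 3$ the curve matches the
  441-equation exact build to better than $0.02$ everywhere on the
  window, at a quarter of the equations.

## Interfaces

Models are declarative: `dimension()` + `transition()` + optional
`coupling()` into `build_system()`, or the ready-made constructors
(`build_birth_death*()`, `build_lotka_volterra*()`, `build_sirs_*()`,
`build_tree_*()`). Config files (YAML) drive `run_from_config()` with
actions `build`, `integrate`, `simulate`, `compare`; every run writes CSV
tables plus a JSON manifest holding the config snapshot, seed, equation
counts and integrator diagnostics, and `fixture_config()` exports any
study fixture as such a config. A command-line front end over the same
runner ships in `inst/cli/meanflame.R`.
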