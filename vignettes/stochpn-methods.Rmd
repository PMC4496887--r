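---
title: "Stochastic Petri-net simulation: models, modes and numerical choices"
author: "stochpn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic Petri-net simulation: models, modes and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochpn)
```

# The model: place/transition nets with constant places

A Petri net is a directed bipartite graph of *places* (chemical species,
complexes, or states) and *transitions* (reactions) joined by weighted
arcs.  A *marking* assigns a non-negative integer token count to each
place; tokens are molecules.  A transition is *enabled* when every
pre-place holds at least the weight of the connecting arc, and *firing* it
consumes tokens from the pre-places and produces tokens on the post-places
according to the weights.

Note on the marking's range: the classical definition speaks of positive
token counts, but chemically meaningful models start species at zero (the
receptor-insulin complex before any binding event, for example), so this
package allows zero throughout.

`stochpn` extends the plain formalism with **constant places**: places
whose token count is never changed by firing but is set by a user-defined
mathematical expression after every simulation step.  Constant places still
count towards enablement and propensities, which makes them the natural way
to model boundary conditions — an externally regulated hormone level, a
buffered metabolite, a clamped input.  In the packaged insulin-receptor
model the external insulin pool is such a place.

Construction normalises the net: duplicate arcs between the same ordered
pair merge by summing weights (the arc set is a set), place and transition
identifiers must be disjoint, and `validate_net()` reports structural
problems (dangling arcs, non-positive weights, name collisions) as
diagnostics rather than errors so a model under construction can be
inspected.

# The four simulation engines

**Asynchronous.**  One uniformly chosen enabled transition fires per step.
No time is consumed; the trajectory is indexed by step count.

**Synchronous.**  Per step, a uniformly random subset of
`ceiling(fraction * |enabled|)` of the enabled transitions is selected and
fired in a uniformly random order, each re-checked against the evolving
marking and skipped if an earlier firing within the same step disabled it.
With `fraction = 1` the simulator tries to fire every enabled transition at
once; transitions competing for a shared pre-place are thereby resolved
uniformly at random until the tokens are exhausted.  The permutation-with-
re-check realisation was a design choice: it implements "randomly chosen
with equal probability until all tokens are consumed" without ever
re-drawing the selected subset mid-step (selected transitions that lose
their tokens are skipped, not replaced).

**Constant-rate stochastic.**  Every enabled transition carries a pending
firing time `clock + Exp(lambda)` with a modeler-specified rate `lambda`;
the transition with the smallest pending time fires and the clock jumps to
it (ties broken uniformly).  By the memorylessness of the exponential,
pending times are *kept* for transitions whose pre-place counts did not
change and redrawn only for the fired transition, transitions whose
pre-place counts changed, newly enabled transitions, and all
post-transitions of constant places (whose counts may have been moved by an
expression).  Pending times are stored as absolute times, which makes the
clock advance O(1); this is equivalent to storing waiting intervals, again
by memorylessness.  The test suite verifies the equivalence of this lazy
caching with full per-step resampling by comparing inter-event-time
distributions (Kolmogorov–Smirnov at alpha = 0.01) and firing fractions.
In this mode `lambda` is a constant per transition; marking-dependent
kinetics belong to the SSA modes.

**Exact SSA (direct method).**  Per step: (i) propensities
`r_j = c_j * prod(choose(m(p), f(p, j)))` are computed from the stochastic
rate constants and the reactant counts — binomial coefficients count the
distinct reactant combinations, the convention that together with the
factorial correction in the unit conversion (below) reproduces
deterministic mass action in the large-count limit; (ii) the waiting time
is `dt = -ln(1 - U1) / a0` with `a0` the propensity sum; (iii) reaction `i`
is the unique index with
`sum(r[1:(i-1)]) < U2 * a0 <= sum(r[1:i])` in the (stable, documented)
transition ordering of the net definition; (iv) the state is updated and
the clock advances by `dt`.  A dependency graph — for each transition, the
set of transitions with a pre-place whose count its firing changes — limits
propensity recomputation to the affected reactions; transitions fed by
expression-driven constant places, and transitions whose own rate is an
expression, are re-evaluated every step.  Switching the dependency graph
off changes no random draw and therefore yields bitwise-identical
trajectories, which the tests assert.

**Tau-leaping (approximate SSA).**  Reactions whose reactants allow fewer
than 20 consecutive firings are *critical* and simulated exactly; the
threshold is configurable via `leap_config()`.  Each step computes a leap
candidate `tau1` for the non-critical reactions and draws
`tau2 ~ Exp(sum of critical propensities)`.  If `tau1 < tau2` no critical
reaction occurs and each non-critical reaction fires `Poisson(r * tau1)`
times; otherwise one critical reaction chosen by the direct method fires
once and the non-critical reactions fire `Poisson(r * tau2)` times.  The
`tau1` selection bounds the expected relative change of any propensity
during the leap by `epsilon` (default 0.03) through the standard
mean/variance criterion on the per-species state change: for each reactant
species `i`,
`tau <= min(max(eps*x_i/g_i, 1)/|mu_i|, max(eps*x_i/g_i, 1)^2 / sigma2_i)`,
where `mu_i` and `sigma2_i` are the first two moments of the net change of
`i` per unit time over the non-critical reactions and `g_i` is the highest
order of reaction consuming `i` (with the usual small-count correction for
reactions consuming two copies of the same species).  Ties `tau1 == tau2`
(measure zero) resolve to the critical branch.  A leap that would drive any
count negative is rejected and retried with half the leap length, at most
ten times, after which a single exact step is taken — the critical-reaction
threshold reduces but does not eliminate the risk of negative populations,
and this guard removes it entirely (property-tested on a stiff
dimerisation net).  Whether the critical waiting time should be re-drawn
each step is not fixed by the algorithm's description; this implementation
re-draws `tau2` every step.

All exponential draws in every engine use inversion of a single uniform
(`-log1p(-U)/rate`), so engines that coincide mathematically also coincide
bitwise: a net in which every reaction is critical consumes the identical
RNG stream under tau-leaping and under the exact SSA, and the tests assert
trajectory equality.

# Converting biological input

Stochastic simulation operates on molecule counts.  With reaction volume
`V` (liters) and Avogadro constant `N_A`, concentrations convert as
`n = round(N_A * [X] * V)` (nearest integer, ties to even — the direction
of rounding is not fixed by convention, so the unbiased choice is used and
documented).  `N_A` defaults to the rounded `6e23` conventionally used with
this parameter set, so that published molecule counts are reproduced
exactly; pass the CODATA value if preferred.

A mass-action rate constant `k` of a reaction of order `x` (units
`M^-(x-1) s^-1`) converts to the stochastic rate constant

    c = k * prod(f!) / (V * N_A)^(x-1)

with `f` the pre-arc weights.  The familiar specialisations follow:
`c = k V N_A` (order 0), `c = k` (order 1), `c = k/(V N_A)` (`A+B -> C`),
`c = 2k/(V N_A)` (`2A -> B`).  Rate constants given as expressions or
conditional expressions in mass-action units are converted by applying the
same factor to each evaluated value at evaluation time, which keeps
published deterministic parameters (such as a conditional zero-order
synthesis rate in `M s^-1`) usable verbatim.

# The expression language

Rate constants and constant-place token counts may be textual expressions
over numeric literals (standard or scientific notation), the constant
`pi`, the variable `Time` (simulated seconds) and the names of
*non-constant* places, which bind to current token counts.  Operators:
`+ - * / ^ %` and unary sign; functions: `abs acos asin atan cbrt ceil cos
cosh exp floor log sin sinh sqrt tan tanh` and two-argument `div(x, y)`.

Numerical conventions, each of which had to be fixed one way:

* `div(x, y)` is integer division towards the nearest lower integer
  (floor), so `div(28, 24) = 1` and negative arguments are well defined.
* `%` is the remainder with the sign of the dividend
  (`x - trunc(x/y) * y`), the common expression-library convention.
* Division (and `div`/`%`) by zero is an error, never a silent `Inf`.
* Implicit multiplication by juxtaposition (`1400 cos(...)`, `2 pi`) is
  **not** accepted — the grammar requires explicit `*`.  Display forms of
  expressions in the literature must be rewritten accordingly
  (`1400*cos(Time/300*2*pi)+1600`).
* Constant-place expression values are rounded to the nearest integer
  token count; a negative value clamps to zero with a warning (once per
  run).
* In the timed engines `Time` is the clock in seconds; in the async and
  sync token-game engines, which consume no time, `Time` binds to the step
  count.
* Place-name variables bind to token *counts*, the simulator's native
  state, not to concentrations.  Thresholds stated as concentrations are
  converted once with `concentration_to_molecules()` when the expression
  text is built (the packaged model does exactly that for its synthesis
  switch).

**Conditional expressions** are ordered case lists with the concrete
grammar

    [cond , cond , ... :] value ; [cond , ... :] value ; ...

Cases are separated by `;`.  Each case is either a bare value expression
(always satisfied) or a comma-separated conjunction of conditions
`expr OP expr` — `OP` one of `=`, `<`, `>`, `<=`, `>=` — followed by `:`
and the value.  Evaluation returns the value of the **first** case whose
conditions all hold, and 0 when none holds.  Because published renderings
of this syntax are typographically lossy, the grammar above (separators
`;`, `,`, `:`) is this package's own concrete serialisation; it is used
identically in the XML setup format.  `=` compares with absolute tolerance
1e-9: the operator is defined between real-valued expressions, where exact
float equality would be fragile.

Expressions are evaluated **after each simulation step**.  Combined with
the Gillespie algorithm this discretisation can, in principle, skip over a
fast variation of a time-dependent expression when waiting times are very
large on the same time scale; the artifact is negligible for ordinary
parameterisations and is documented here rather than patched, the rigorous
treatment being a rejection method for non-homogeneous processes, which is
out of scope.

# Runs, replicates, persistence

`run()` seeds R's RNG from the setup seed and executes one trajectory;
identical setup and seed give bitwise-identical trajectories.
`run_replicates()` derives one seed per replicate from the master seed (a
single `sample.int()` draw of distinct integers), so each replicate is a
pure function of (setup, master seed, index) and results cannot depend on
any execution order; hundreds of replicates of a small model run in
seconds.  Trajectories record every event by default (time, fired
transition, full marking) and export as tab-separated text with
locale-independent decimal points.  Setups (marking, concentrations plus
volume, rate specifications including expression texts, end condition,
seed, leap parameters, replicate count) persist to a small documented XML
schema (`save_setup()`/`load_setup()`, schema in the `R/io.R` header and
the shipped `inst/extdata/ir_model_setup.xml`); models persist to the
PNML place/transition subset with constant-place flags and expressions in
a `toolspecific` annotation.  Unknown XML elements are errors, never
silently ignored.  All persisted artifacts use the shortest decimal
representation that parses back to the same double, so files are
byte-stable across runs.

# The insulin-receptor recycling case study

The packaged model describes activation and recycling of the insulin
receptor in a single cell of volume 1e-9 l: 6 places, 11 transitions, all
arc weights 1.  Free insulin (`Insulin`, a constant place regulated by
external processes) binds the free membrane receptor (`IR`) to form the
complex `IR_I`, which can dissociate again or be phosphorylated to
`IR_I_P`.  The phosphorylated complex can dephosphorylate or internalise
(`IR_I_P_Int`), the internalised complex can return to the membrane or
dephosphorylate into the internal receptor pool `IR_Int`, from which
receptors recycle to the membrane or are degraded; synthesis replenishes
the pool.  Initial concentrations: `IR` 9e-13 M (540 molecules), `IR_Int`
1e-13 M (60), the three complex states 0.  Rate constants are mass-action
values spanning binding at 1e6 M^-1 s^-1 through degradation at
2.783e-6 s^-1; the two constants published without units
(`Dephos_IR_I_P_Int` 7.68e-3, `Degradation` 2.783e-6) are taken as s^-1
since both steps are unimolecular.  Synthesis is a conditional zero-order
rate: 2.78e-19 M/s while the internal pool `IR_Int + IR_I_P_Int` is at or
above its steady-state value of 1e-13 M (60 molecules), and 1.67e-18 M/s
below it — the conditional text compares token counts against the
converted threshold.

Two wiring details are ambiguous in the prose description and were fixed as
follows: dephosphorylation of the membrane complex returns it to `IR_I`
(the alternative reading — that it also releases the ligand, yielding `IR`
directly — would merge two mechanistic steps); and no return arcs to the
constant `Insulin` place are drawn for dissociation or internal
dephosphorylation, since arcs into a constant place have no dynamic effect.

The daily insulin profile is a four-case conditional: one time-gated case
per meal (09:00, 13:00, 18:00) and a final condition-free basal case
(6e-11 M, 36000 molecules).  Within a meal window the count decays from the
peak (3.6e-10 M, 216000 molecules) as
`basal + (peak - basal) * exp(-(t - t_meal)/tau)`.  Only the boundary data
are published — basal, peak, meal times, a return to basal "within 3
hours", and the negative-exponential shape — so the time constant is
derived from them: `tau = dur / log((peak - basal)/(tol * basal))`, about
2345 s with the default 5% tolerance, which lands the profile within 5% of
basal exactly at the end of the 3 h window.  (A time constant as large as
3600 s would still sit 25% above basal after 3 h and would contradict the
stated return time.)  `Time % 86400` makes the profile repeat daily, so a
two-day simulation needs no duplicated cases.

```{r ir-example}
model <- build_ir_model()
length(model$net$places); length(model$net$transitions)
tr <- run_ir_simulation(hours = 2, seed = 1)
tail(tr$records, 3)
```

# What the test models emulate — and what they do not

The synthetic fixtures are chosen for closed-form behaviour: the
immigration–death net (`build_birth_death()`) has stationary occupancy
Poisson(`c_birth/c_death`), the pure-death chain has extinction time mean
`sum_{j<=n0} 1/(c j)`, and a two-transition race has firing fractions
`lambda_i / sum(lambda)`.  Statistical assertions compare *time-weighted*
trajectory averages against these values (event-count averages are biased
towards high-propensity states) at 3 standard errors with an effective
sample size discounted for autocorrelation.  Passing these tests shows the
samplers target the right continuous-time Markov process; it does not
validate any biological parameterisation, nor does the packaged IR model
claim predictive accuracy — it is a workflow demonstration whose stochastic
trajectories vary between seeds by design.

Problem sizes used by the suite: stationary-mean checks run 1e5 events,
tau-vs-exact comparisons 5e4–6e4 events each, replicate checks 100–500
replicates of 1000–2000 events, distributional KS checks 5e3–1e4 events,
and the full two-day IR simulation runs once.

# Known limitations

* No inhibitor arcs, capacities, colored or timed-arc extensions.
* Marking-dependent rates in the constant-rate stochastic mode are
  deliberately unsupported (use the SSA).
* The post-step evaluation of time-dependent expressions carries the
  discretisation caveat described above.
* Tau-leaping assumes the leap condition is meaningful, i.e. reasonably
  large counts among non-critical reactions; for very small systems it
  degenerates (correctly, and by construction) to the exact SSA.
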