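---
title: "Binary choice dynamics under in-group love and out-group hate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary choice dynamics under in-group love and out-group hate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affpol)
```

## The model

`affpol` studies how a binary choice (mask or not, vaccinate or not, adopt
a product or not) spreads through a society split into two antagonistic
groups, blue and red. Each node $v$ of an undirected graph carries a
static group label $R(v) \in \{0, 1\}$ and a dynamic choice
$H_k(v) \in \{0, 1\}$. At each discrete step one node, chosen uniformly at
random, looks at its neighbourhood. With $d^{\mathrm{in},1}$,
$d^{\mathrm{in},0}$, $d^{\mathrm{out},1}$, $d^{\mathrm{out},0}$ the
fractions of its neighbours in each (group match, choice) cell, the net
social drive is

$$ f = \alpha\,(d^{\mathrm{in},1} - d^{\mathrm{in},0})
     - \beta\,(d^{\mathrm{out},1} - d^{\mathrm{out},0}), $$

and the node adopts choice 1 if $f > \delta$, choice 0 if $f < -\delta$,
and otherwise keeps its current choice. The three behavioural constants
are all unitless and live in $[0, 1]$:

* $\alpha$ (*in-group love*): the pull towards conforming with same-group
  neighbours;
* $\beta$ (*out-group hate*): the push away from what the other group
  does;
* $\delta$ (*inertia*): the net drive needed before anyone changes their
  mind. $\delta = 0$ describes a maximally reactive population and is the
  setting in which the sharp analytic results below hold.

Only differences of normalized counts enter $f$: what matters within each
group is the surplus of neighbours at one choice over the other, not
their ratio.

The group-level state is $\theta = (\theta_B, \theta_R)$, the fractions
of blue and red nodes currently at choice 1 — always in that order.

## The mean-field limit

On a complete graph (or any graph where everyone effectively observes the
population statistics) the random sequential dynamics are approximated,
for large $N$ and with time rescaled as $t = k / N$, by the
piecewise-smooth ODE

$$ \dot\theta_g = (1 - \theta_g)\,\mathbf 1[f_g > \delta]
   - \theta_g\,\mathbf 1[f_g < -\delta], \qquad g \in \{B, R\}, $$

with the group drives

$$ f_B = \alpha(1-r)(2\theta_B - 1) - \beta r (2\theta_R - 1), \qquad
   f_R = \alpha r (2\theta_R - 1) - \beta (1-r)(2\theta_B - 1), $$

where $r$ is the red-group fraction. Note the factor $r$ on the red
in-group term: on a complete graph a red node's in-group neighbour
fraction at choice 1 is $r\,\theta_R$, exactly mirroring the
$(1-r)\theta_B$ of a blue node. `affpol` uses this symmetric form; a
variant omitting the factor (`red_drive = "unscaled"`) is retained purely
for comparison, because only the symmetric form produces the diagonal
phase boundaries below (at $r = 0.5$ the two groups must behave
identically, which the unscaled variant violates — see
`test-meanfield.R`).

### Exact event-driven integration

Within a region where both indicator values are constant, each component
relaxes exponentially with unit rate towards its target (1, 0, or frozen):
$\theta_g(t_0 + s) = T_g + (\theta_g(t_0) - T_g)e^{-s}$. Because every
component shares the time constant 1, each drive along the flow has the
exact form $f(s) = A + B e^{-s}$, so the next switching time is a
logarithm, not a root-finding problem. `mf_integrate()` therefore
advances from event to event in closed form; the only floating-point
error is in evaluating `exp` and `log`, and the property tests hold it to
below $10^{-3}$ against a $10^{-4}$-step Euler integrator over random
configurations (the discrepancy is dominated by the Euler scheme's own
first-order error at switching times).

States that land exactly on a threshold $f = \pm\delta$ are
disambiguated by flow consistency: the frozen branch is preferred when it
is self-consistent (which keeps the exact centre $(0.5, 0.5)$ stationary,
the behaviour the strict inequalities dictate), a moving branch is chosen
when the drive demonstrably departs the threshold in that direction, and
if no branch is consistent the pinned component is frozen and a `slide`
event recorded. These conventions only matter on a measure-zero set; all
generic trajectories consist of transversal crossings, recorded as
`cross` events with $10^{-12}$-level placement.

### Regimes

With $\delta = 0$ and a group-independent start
$\theta_B(0) = \theta_R(0) \ne 0.5$, the long-run outcome depends only on
how the group-size ratio $r/(1-r)$ compares with $\alpha/\beta$ and
$\beta/\alpha$ (`classify_regime()`, evaluated by cross-multiplication so
$\beta = 0$ needs no special casing):

| case | condition | limit from $\theta(0) > 0.5$ |
|------|-----------|------------------------------|
| 1 consensus | $\beta/\alpha < r/(1-r) < \alpha/\beta$ | $(1, 1)$ |
| 2 partisan | $r/(1-r)$ above both ratios | $(0, 1)$ |
| 3 partisan | $r/(1-r)$ below both ratios | $(1, 0)$ |
| 4 nonpartisan | $\beta/\alpha > r/(1-r) > \alpha/\beta$ | $(0.5, 0.5)$ |

In the partisan cases the majority group keeps the initially popular
choice and the minority adopts the opposite one; integration of the ODE
confirms this orientation. The case-4 rest point is unstable: any
one-sided perturbation sends the system to a partisan corner, and the
case-4 diagonal trajectory itself is $\theta(t) = \theta(0)e^{-t}$ until
it reaches the centre at $t = \ln(2\theta(0))$, frozen afterwards.

More hate than love ($\beta > \alpha$) makes consensus impossible
regardless of group sizes; more love than hate is necessary but not
sufficient, since a large enough group imbalance still forces a partisan
split.

### Homophily

On a two-block stochastic block model where a node links to same-group
nodes with probability proportional to $\rho$ and to the other group
proportional to $1 - \rho$, the same ODE applies with
$\alpha \to \alpha\rho$ and $\beta \to \beta(1-\rho)$. At $\rho = 0.5$
both drives are scaled by $0.5$, so with $\delta = 0$ the trajectory is
*identical* to the fully connected one (the acceptance suite checks
bit-identity). Lowering $\rho$ amplifies out-group hate: with
$\alpha = 0.8$, $\beta = 0.7$, $r = 0.65$, the society is in the
consensus regime at $\rho = 0.7$ but flips to the red-majority partisan
regime at $\rho = 0.5$ — breaking echo chambers can create polarization.
(With these parameters the flipped regime is case 2, the red-majority
side; descriptions elsewhere that label the same flip case 3 differ only
in which group is taken as the majority.) For $\delta > 0$ the
substitution is applied before the $\delta$ comparison; since the
rescaling shrinks both drives while $\delta$ is fixed, this is an
approximation for inert populations, adequate at the desk scales used
here.

### Consensus from group-dependent starts

From $\theta_B(0) \ne \theta_R(0)$, consensus emerges iff (i) the
configuration is in case 1 and (ii) both drives at $\theta(0)$ share a
nonzero sign (`consensus_reachable()`). Condition (ii) is the geometric
form of a ratio bound on $(2\theta_B(0)-1)/(2\theta_R(0)-1)$; we evaluate
the signs directly, which avoids dividing by $2\theta_R(0)-1 = 0$.
Sufficiency is immediate from the closed form: within the common-sign
cone each drive is monotone along the flow and ends at the corner value,
whose sign condition is exactly case 1, so neither drive can cross zero
en route. The checker is validated cell by cell against
integrate-to-convergence on a $21\times 21$ grid for 20 random case-1
configurations (a $10^{-3}$ band around the switching manifolds is
excluded, where the binary question itself is ill-conditioned).

When condition (ii) fails, one group reverses its trend exactly where the
trajectory crosses the corresponding switching manifold
$f_g = \pm\delta$ (`switching_manifolds()`, `detect_reversal()`): the
tipping points of the opinion landscape. The three scenario recipes in
`reproduce_figure("fig3", ...)` were chosen by solving the drive-sign
requirements by hand: (i) both groups rise towards consensus until the
minority blue group flips just short of it; (ii) both groups initially
abandon the popular choice until the blue minority flips back; (iii) the
mirror image in which the red majority flips.

## The stochastic model and the synthetic data it runs on

`abm_run()` performs the literal sequential dynamics on any labelled
graph, in compiled code, consuming one uniform draw per step so that runs
are bit-reproducible from the seed (a reference R loop in the test
helpers reproduces trajectories bit for bit). Complete graphs are stored
implicitly and updated in O(1) per step from group counters. Absorption
is detected by a full stability sweep every $N$ steps — "no node would
change if selected" — rather than "no recent flips", which would
misclassify frozen-but-mixed states under $\delta > 0$.

The generators define the study conditions used throughout the tests:

* ensembles default to 50 independent runs with empirical 2.5/97.5
  percentile bands (the 95% convention; percentile rather than normal
  bands because 50 runs is small). Band calibration is checked against
  exact binomial quantiles: the bands carry about 92–95% true coverage at
  that ensemble size, the accuracy expected of raw percentile bands;
* initial choices place exactly $\mathrm{round}(\theta_0 N_g)$ adopters
  per group; label assignments place exactly $\mathrm{round}(r N)$ red
  nodes;
* block-model graphs default to a density multiplier giving mean degree
  about 20. With $\delta = 0$ the dynamics depend on neighbourhood
  composition, not density, so sparse graphs carry the same semantics at
  a fraction of the cost; the multiplier is exposed (`density`) for
  studies where absolute degree matters;
* ABM horizons default to $30N$ steps ($t = 30$), far beyond the
  $\sim$5 e-foldings that decide every stable outcome; the heavier
  verification runs in the acceptance suite use $N = 5000$, 20 runs and
  $t \in [0, 10]$, and the real-network recipes run on generated SBM
  stand-ins of $N = 600$–1000 when no edge-list file is supplied.

What the synthetic graphs do **not** emulate: degree heterogeneity,
clustering, and community structure beyond two blocks. On real networks
the adoption fractions approach but do not exactly reach 0 or 1 (nodes in
unusual neighbourhoods can stick), so passing tests on generated graphs
demonstrate the mechanism, not quantitative endpoints for any particular
empirical network. The `fig4`–`fig6` recipes accept SNAP-format edge
lists to run the same protocols on real data, assigning groups either
uniformly (neutral assortativity) or by annealed label swaps targeting a
party assortativity (Newman's categorical coefficient; swaps preserve
group counts exactly, the objective is `|achieved - target|` with
geometric cooling and $2\times 10^5$ proposals by default). Targets of
$0.58$, $0.00$ and $-0.13$ — homophilic, unbiased, heterophilic — are
reached within $0.02$ on a two-community graph of $N = 2000$.

## Known limitations

* The mean-field ODE describes the large-$N$ limit. Near the unstable
  nonpartisan rest point the approximation breaks down qualitatively: the
  stochastic model reaches the centre, and $O(1/\sqrt N)$ fluctuations
  then select an escape direction essentially at random, so individual
  runs polarize while the deterministic trajectory stays frozen at the
  centre. A finite ensemble mean therefore deviates from the ODE by the
  binomial spread of escape directions (about $0.11$ for 20 runs); no
  ensemble of practical size tracks the ODE through an unstable regime,
  and the corresponding check in the acceptance suite records this
  honestly rather than averaging it away.
* Exact-threshold states are resolved by the documented conventions;
  these are measure-zero and irrelevant for generic parameters.
* The homophily rescaling is the main-text approximation for block
  models; it is exact in distribution only for the drives' expectations,
  and for $\delta > 0$ it interacts with the fixed threshold as noted
  above.
* Two groups, binary choices, undirected unweighted graphs, static
  parameters. Isolated nodes have no defined update and are rejected
  unless explicitly tolerated (then skipped with a warning).

## A worked example

```{r example}
params <- model_params(alpha = 0.8, beta = 0.7, rho = 0.5)
cfg <- mf_config(params, r = 0.65, mode = "sbm")
classify_regime(cfg)
tr <- mf_integrate(c(0.8, 0.8), cfg)
attr(tr, "theta_final")

g <- sbm_graph(500, r = 0.65, rho = 0.5, seed = 1)
ens <- abm_ensemble(g, params, c(0.8, 0.8), n_runs = 20, seed = 1)
ens
```

The stochastic ensemble on a neutral block model reproduces the
mean-field partisan split: the red majority keeps the initially popular
choice and the blue minority adopts the opposite one.
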