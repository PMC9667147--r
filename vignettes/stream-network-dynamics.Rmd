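---
title: "Simulating expansion and retraction of temporary stream networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating expansion and retraction of temporary stream networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamdyn)
library(ggplot2)
```

## The model

More than half of the global river network is temporary: reaches alternate
between flowing (active) and dry states as the catchment wets and dries.
`streamdyn` simulates these expansion/contraction cycles with a stochastic
framework that separates the *temporal* dimension of the dynamics — driven by
catchment streamflow — from the *spatial* dimension — encoded in a static map
of local persistency.

**Nodes and persistency.** The potential (geomorphic) network is a rooted
tree of $N$ nodes, each representing a uniform reach of length
$\Delta l_i$ with a binary state $X_i(t)$. The local persistency $P_i$ is
the marginal probability that node $i$ is active. Under *hierarchical
structuring*, nodes always activate from the most to the least persistent
and deactivate in the reverse order, so every configuration is a threshold
set: there is a time-varying persistency threshold $P^*(t)$ with

$$X_i(t) = \mathbf{1}\{P_i \ge P^*(t)\},$$

and the active length is $L(t) = \sum_i \Delta l_i\, X_i(t)$, counting
active reaches whether or not they are connected to the outlet. Equality is
inclusive: a node whose persistency exactly equals the threshold is active.

**Streamflow.** Daily discharge follows the jump--decay process
$\mathrm{d}Q/\mathrm{d}t = -kQ + \xi(t)$: effective rainfall is a marked
Poisson process with frequency $\lambda$ whose events add exponential jumps,
and flow recedes at rate $k$ between events. The stationary marginal of $Q$
is a gamma distribution with shape $\lambda/k$ and scale $\alpha k$. The
jump magnitudes are exponential with mean $\alpha k$ *in discharge units*:
this is the only scale compatible with that stationary law, and it makes
the long-run mean discharge equal to the effective precipitation
$\alpha\lambda$, closing the water balance.

**From flow to threshold.** The flow duration curve maps each discharge to
the fraction of time it is equalled or exceeded, $D(Q) = 1 -
\mathrm{CDF}_Q(Q)$, and the persistency threshold is exactly that duration:
$P^*(t) = D(Q(t))$. High flows mean low thresholds (expanded network), low
flows high thresholds (contracted network).

**Climate to parameters.** Only four independent climate parameters are
needed: mean daily rainfall depth $\alpha$, rainfall frequency
$\lambda_P$, potential evapotranspiration $E_p$ and the recession rate $k$.
The derivation chain is: total precipitation $P_t = \alpha\lambda_P$; actual
evapotranspiration from the Budyko curve
$E_a/P_t = [\,(E_p/P_t)\tanh(P_t/E_p)(1 - e^{-E_p/P_t})\,]^{1/2}$; effective
frequency $\lambda = \lambda_P - E_a/\alpha$ (Poisson thinning of rainfall
by the soil-moisture deficit); and mean network persistency from the
empirical relation $\bar P = 0.0527 + 0.1951\,(P_t - E_p)$. All chaining is
done at full precision; printed two-decimal parameter tables are reproduced
by rounding the final values only.

**Spatial persistency field.** Local persistency follows a one-parameter
beta law, $\mathrm{CDF}_P(P) = 1 - (1-P)^\beta$ with $\beta = 1/\bar P - 1$
(so its mean is exactly $\bar P$), optionally mixed with an atom at $P = 1$
for perennial reaches (default none). One sorted sample of $N$ values is
drawn by inverse transform, then arranged over nodes under one of three
schemes sharing that same sample: `random` (uncorrelated, a seeded
permutation), `twi` (quantile transformation against the topographic
wetness index) or `area` (quantile transformation against contributing
area, making persistency increase monotonically downstream). Sharing the
sample across schemes means scenario variants differ *only* in spatial
arrangement — exactly the comparison the three schemes are meant to
support. Ties in the covariate are broken by ascending node id.

## Duration curves and connectivity

The stream length duration curve (SLDC) follows in closed form from the
persistency law: $L/L_g = 1 - \mathrm{CDF}_P(D) = (1-D)^\beta$. Its
empirical counterpart is built from the daily $L(t)$ with Weibull plotting
positions $j/(n+1)$ (ties share the largest position). The same ranking
applied to discharge gives the empirical flow duration curve.

Connectivity is summarised by the largest connected patch (LCP): at a given
threshold, the summed reach length of the largest component of the subgraph
induced by active nodes (adjacency along the tree, treated as undirected).
Because configurations are nested, the package computes LCP for all $N+1$
configurations in a single sweep: nodes are activated in order of
decreasing persistency while an incremental union--find merges components;
each day (or grid threshold) is then mapped to its configuration by its
active-node count. Under the `area` scheme the active network is always one
patch, so the LCP curve coincides with the SLDC; under `random` allocation
the network fragments into many small patches and the LCP stays low even
when most of the network is flowing.

## Tunable parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `alpha` | mm/d | 15 (D), 10 (W) | mean daily rainfall depth |
| `lambda_p` | 1/d | 0.25 (D), 0.55 (W) | rainfall frequency |
| `e_p` | mm/d | 3 (D), 2 (W) | potential evapotranspiration |
| `k` | 1/d | 0.35 | recession rate |
| `n_nodes` | — | 1215 | network size (reference network size) |
| `n_years` | yr | 100 | run length; a year is 365 days, no leap days |
| `perennial_fraction` | — | 0 | probability atom at `P = 1` |
| `fdc_mode` | — | `"empirical"` | FDC used in the threshold transform |

The two presets `D` (dry) and `W` (wet) bracket erratic
($\lambda/k < 1$) and persistent ($\lambda/k > 1$) flow regimes. The six
standard scenarios combine them with the three allocation schemes
(`D1`..`W3`).

```{r presets}
preset_table()
```

## The synthetic network generator

Real applications take a node--link table extracted from a DEM
(`read_network_table()`). For self-contained experiments,
`generate_network()` grows a random rooted tree by sequential uniform
attachment (or a lattice-embedded variant for more river-like planforms),
with unit reach lengths and unit node areas: the model is scale-free in
space, so only relative lengths matter. Slopes follow a noisy slope--area
scaling $s_i = 0.1\,A_i^{-1/2} e^{\varepsilon_i}$,
$\varepsilon_i \sim N(0, 0.5^2)$, chosen so the TWI
$\ln(A_i/s_i)$ is correlated with — but not a monotone function of —
contributing area; without that noise the `twi` and `area` schemes would
coincide. Coordinates are decorative.

What the generator does **not** emulate: real drainage-network branching
statistics (Horton ratios, width functions), spatially organised slope
patterns, variable reach spacing, or any geologic heterogeneity. Passing
tests on synthetic trees therefore demonstrates the correctness of the
machinery and the climate-driven statistics (which do not depend on
topology), but the *shape* of LCP curves on a real extracted network will
differ quantitatively from the synthetic ones.

## Numerical choices

- **Exact event-time simulation.** Each day draws a Poisson number of
  events, uniform event times within the day and exponential jump sizes;
  each jump is decayed by $e^{-k\Delta}$ to the day's end. The day-end
  sample thus has exactly the stationary gamma marginal — no
  discretisation bias for any $k$.
- **Initial condition.** `q0 = "stationary"` draws $Q(0)$ from the
  stationary gamma, eliminating burn-in; `"zero"` and numeric values
  support recession tests.
- **Threshold mode.** The default `empirical` mode is two-pass: the full
  series is simulated, ranked, and each day given its Weibull position
  $\mathrm{rank}/(n+1)$ — thresholds are then exactly uniform on the
  discrete grid and each node's realized persistency is within $1/n$ of its
  nominal $P_i$. The `analytic` mode evaluates $1 - \mathrm{CDF}_Q$ and is
  used by distribution-level tests (probability integral transform).
- **Ties and clamping.** Tied values in any duration curve share the
  largest position among their ranks; empirical FDC queries outside the
  observed range clamp to $[1/(n+1), n/(n+1)]$, never erroring.
- **Saturation of the persistency relation.** $\bar P \le 0$ (hyper-arid)
  is always an error; $\bar P \ge 1$ (very humid) errors by default with an
  opt-in clamp to $1 - 10^{-6}$, since the linear climate relation is not
  meant to extrapolate there.
- **CV convention.** The coefficient of variation of $L(t)$ uses the
  population (n-denominator) standard deviation; immaterial at
  $n = 36\,500$ but fixed for reproducibility.
- **Seeds.** A run takes four independent sub-seeds (network, persistency
  sample, allocation, streamflow), derived from one master seed by fixed
  offsets, so scenario families (e.g. `D1`/`D2`/`D3`) share the network and
  sample while varying only the arrangement.

An analytic cross-check used in the tests: with $P^*$ uniform and the
plotting-position field, $L/L_g \mid P^* = (1-P^*)^\beta$, so the CV of the
relative length has the closed form $\sqrt{\beta^2/(2\beta+1)}$ — about
1.34 for the dry preset and 0.27 for the wet one, which the 100-year
simulations reproduce.

## A worked run

A full factorial at reference size (1215 nodes, 100 years) takes on the
order of a second per scenario; the vignette uses a smaller network for
the figures.

```{r run, fig.width = 7, fig.height = 5}
run <- run_scenario("W2", n_years = 10, n_nodes = 300, seed = 7)
glance(run)
autoplot(run, days = 1:365)
```

```{r curves, fig.width = 6, fig.height = 4}
plot_sldc(run)
plot_lcp(run)
```

```{r network-map, fig.width = 5, fig.height = 5}
autoplot(run$network)
```

## Limitations

- Climate is statistically stationary; seasonality would require
  period-specific parameter sets (not provided).
- The persistency field is statistical, not mechanistic: where subsurface
  heterogeneity dominates activation order, the three schemes may all
  misrepresent the true spatial pattern, and field-surveyed persistencies
  should be supplied instead (`read_persistency_field()`).
- The empirical persistency--climate relation is calibrated for temperate
  catchments and saturates in extreme climates (see above).
- Hierarchical structuring forces perfectly synchronised activation among
  equal-persistency nodes and a strict one-to-one relation between
  discharge and configuration; hysteresis between expansion and
  contraction phases is outside the model class.
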