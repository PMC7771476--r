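---
title: "Priority setting for crop research under foresight scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Priority setting for crop research under foresight scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agsurplus)
library(dplyr)
```

## The question the package answers

Agricultural research funders must rank candidate research options — say,
breeding potatoes for late-blight resistance versus improving seed systems —
before any of them exists. The standard tool is the comparative-static
economic surplus model: a technology shifts the supply curve of one
commodity in the target countries, and the discounted producer and consumer
surplus changes, net of research and dissemination costs, yield an NPV, an
IRR and an MIRR per option. That tool is static (no population, income or
climate dynamics), single-market, and usually limited to target countries.

`agsurplus` implements the richer alternative: a stylized recursive-dynamic,
multi-region, multi-commodity partial-equilibrium simulator in which
technologies enter as shifts of the exogenous yield trend, world prices clear
all markets endogenously every year, and welfare is measured against
scenario baselines. Running the same technology portfolio under a *static*
counterfactual (all dynamic drivers frozen) and under SSP-RCP-style
foresight scenarios, and aggregating welfare over *target countries only*
versus *all countries*, quantifies how much the standard tool's assumptions
matter for a priority-setting exercise.

## Market model

For each region $n$ and commodity $j$, per-year supply is the product of a
yield response and a harvested-area response, both constant-elasticity forms
calibrated at the base year:

$$Y_{j,n} = YInt_{j,n}\; YInt2_{j,n,t}\; YWat_{j,n,t}\; YClim_{j,n,t}\;
  (P_j/P^0_j)^{\varepsilon_{j,n}}\; (PF/PF^0)^{\eta_{j,n}} \; m_{j,n,t},$$

$$A_{j,n} = A^0_{j,n} \prod_i (P_i/P^0_i)^{\gamma_{j,i,n}}, \qquad
  D_{j,n} = D^0_{j,n}\; pop_{n,t}\; inc_{n,t}^{\,\epsilon^I_{j,n}}
  \prod_i (P_i/P^0_i)^{\delta_{j,i,n}},$$

where $YInt$ is the base yield, $YInt2$ the exogenous yield trend, $YWat$
and $YClim$ exogenous water and climate multipliers, $m$ the technology
shock multiplier, $\varepsilon \ge 0$ the yield own-price elasticity,
$\eta$ the (inert by default) input-price elasticity, $\gamma$ and
$\delta$ area and demand price elasticities, and $\epsilon^I$ the income
elasticity. Regions trade a homogeneous commodity at a single world price;
domestic prices equal world prices (perfect transmission — a per-region
margin would be a multiplicative constant and is omitted). Every year the
solver finds world prices at which global demand equals global supply per
commodity (damped Newton iteration on log prices, warm-started at the
previous year's solution, converged to $10^{-8}$ relative excess demand),
and net trade closes each region's balance.

Several features of the full-scale models this emulates are deliberately
simplified: land allocation is an unconstrained log-linear area response
rather than a land-market equilibrium; food, feed and other demand
components are collapsed into one demand function; there is no sub-national
(irrigated/rainfed, basin-level) disaggregation; input prices never move.
None of these affects the welfare comparisons the package is built to make,
which operate on the focus-crop market at the country level.

## Technology shocks

A technology option is a research lag $L_r$, an adoption lag $L_a$, and
per-target-country parameters: adoption ceiling $A_{max}$, maximum expected
yield change $\Delta Y$, production-cost change $\Delta C$, and probability
of research success $p$. Adoption follows the logistic curve
$A(t) = A_{max}/(1 + e^{-(\alpha + \beta t)})$, with $(\alpha,\beta)$
solved in closed form from two anchors: the initial rate $A_0$ at the
release year $t_0$ (first horizon year plus $L_r$) and $A_{max}/2$ at
$t_{mid}$. The source material specifies neither $A_0$ nor the mapping from
the adoption lag to $t_{mid}$; the package defaults to $A_0 = 0.5\%$ of the
ceiling and $t_{mid} = t_0 + L_a/2$, so the ceiling is effectively reached
by the end of the adoption lag. Both are configurable.

The success-weighted, fully adopted yield-trend shift is
$$\Delta YInt2 = \left(\Delta Y - \frac{\Delta C}{1+\Delta Y}\right) p,$$
and the region's yield multiplier in year $t$ is
$m_t = 1 + \Delta YInt2 \cdot A(t)$: the shift is read as the effect on
fully converted area and the adoption rate as the area share under the new
technology (area-weighted-average reading; the alternative — full-strength
shift from release with adoption handled elsewhere — is not what a diffusion
curve models). Non-target regions receive no shock: technology spillovers
are assumed away, so any non-target impact is a pure world-price effect.

Costs: the annual R&D cost accrues in each year of the research lag;
dissemination costs a fixed amount per hectare of *newly* adopted area
(clamped at zero when total area shrinks), with the adopted area taken from
the shocked run's realized harvested areas. Dissemination is not scaled by
$p$: the adoption curve describes the planned dissemination effort, while
$p$ discounts the uncertain yield benefit.

## Welfare accounting

Welfare is measured on the focus-crop market only. In a multi-market
equilibrium the focus market's price and quantity changes already embody the
feedback from related markets, and summing surplus over all markets would
double-count. For each region and year the demand and supply curves are
linearized at the equilibrium points and the changes between the baseline
($P_0, D_0, S_0$) and shocked ($P_1, D_1, S_1$) equilibria are

$$\Delta CS = (P_0 - P_1)\,\tfrac{D_0 + D_1}{2}, \qquad
  \Delta PS = \bigl(P_1 - (1-k)\,P_0\bigr)\,\tfrac{S_0 + S_1}{2},$$

where $k = 1 - m^{-1/\varepsilon_s}$ is the vertical supply-shift
proportion implied by the region's shock multiplier on a
constant-elasticity supply with elasticity $\varepsilon_s$ (the yield plus
area own-price elasticities), and $k = 0$ for non-target regions. In a
linear closed economy these formulas reproduce the textbook surplus-change
results exactly; note that they are *changes integrated between the two
equilibria under a common linearization*, not differences of separately
re-linearized surplus triangles — the latter disagrees with the
comparative-static results at first order in $k$ and can even flip sign.
The level functions `consumer_surplus()` / `producer_surplus()` are provided
as linearized level measures, while `welfare_change()` implements the change
formulas above.

Group results (`target`, `non_target`, `all`) are additive by construction.
Net benefits per aggregation are the surplus changes minus the cost stream,
discounted at 10% (configurable) with $t=0$ at the first simulation year;
`irr()` returns the smallest real root above $-100\%$ of the NPV polynomial
and `mirr()` uses finance and reinvestment rates that default to the
discount rate (unstated in the source material).

`alston_surplus()` is the independent closed-form oracle
($Z = k\varepsilon_s/(\varepsilon_s + \eta)$,
$\Delta CS = P_0 Q_0 Z (1 + 0.5 Z \eta)$,
$\Delta PS = P_0 Q_0 (k - Z)(1 + 0.5 Z \eta)$). The test suite verifies
that a one-region closed economy run through the full simulator reproduces
the oracle within 2% for shifts $k \le 0.05$. The residual discrepancy is
the genuine $O(k^2)$ difference between constant-elasticity and linear
curves; for the elasticity range sampled in the tests ($\eta, \varepsilon_s
\in [0.3, 0.8]$, typical of staple food crops) the worst corner stays below
2%. Outside that range (very inelastic supply with elastic-end demand) the
model difference can slightly exceed 2% at $k = 0.05$ — a property of the
two functional forms, not a solver error.

## The synthetic world generator

No public calibration exists for the original study (its market data are
proprietary, and the country-level technology parameters live in
supplementary material), so `generate_world()` draws a self-consistent
stand-in: 12 regions by default, a focus root crop plus two cereal staples,
FAOSTAT-like magnitudes (potato yields 10–25 t/ha, prices 150–350 US$/t,
region areas from tens of kha to several Mha), and elasticities from
documented ranges (demand own-price $[-0.8,-0.2]$, cross-price $[0,0.1]$,
income $[0.1,0.7]$, yield price response $[0.05,0.3]$, area own-price
$[0.1,0.5]$). Three structural choices encode the study conditions:

* the focus crop is a small sector — 15% of three-crop production value —
  so cross-price feedback onto cereals is small;
* target regions are mostly small producers with at most one larger one,
  and are tilted to be net *importers* of the focus crop (demand 1.35 times
  supply before the clearing rescale), so the non-target group is a net
  exporter and bears producer-surplus losses when the world price falls;
* base-year clearing is exact: demands are rescaled proportionally per
  commodity to equal global supply (a residual-region assignment would do
  the same less smoothly).

Scenario drivers map a common per-region uniform draw into per-pathway
ranges so that orderings hold region-by-region for every seed: annual
population growth 0.2–0.8% (SSP1), 0.6–1.2% (SSP2), 1.0–1.8% (SSP3); income
growth reverse-ordered at 1.5–2.0% / 1.0–1.5% / 0.5–1.0% (chosen so the
population effect dominates food-demand growth for all income-elasticity
draws); exogenous yield-trend growth 0.3–1.0% per year under any foresight
pathway; climate multipliers declining linearly to 2040 endpoints in
$[0.98,1.00]$ (RCP4.5), $[0.95,0.99]$ (RCP6.0), $[0.90,0.97]$ (RCP8.5).
Adoption ceilings are scaled by 1.10 under SSP1 and 0.90 under SSP3,
reflecting assumed differences in R&D investment climates. The static
pathway freezes every path at 1. Water multipliers are present but unity:
crop-growth modeling is out of scope, so climate enters only through these
exogenous multipliers.

`potato_technologies()` reproduces the published summary of the four potato
research options — research lags 3/10/2/2 years, adoption lags 5/10/10/10,
annual R&D costs 8/4/8/16 million US$, dissemination 80/50/50/50 US$/ha,
and the printed ranges for ceilings, yield changes, cost changes and
success probabilities — drawing per-country values uniformly within ranges
under a fixed seed. Target sets are assigned by harvested-area rank to
emulate the adopted-area ordering of the original study (seed systems and
late blight target everything, bacterial wilt all but the largest producer,
virus resistance the smallest $n_t - 2$).

## What the fixture study does and does not show

On the default fixture (world seed 1, technology seed 1) the qualitative
findings reproduce: the NPV ranking — late blight > virus > bacterial wilt
> seed systems — is identical across the static and all three foresight
scenarios and both aggregations; target-only net benefits exceed
all-countries net benefits in every cell; non-target producer surplus falls
and global consumer surplus rises everywhere; the world focus-crop price
falls under every technology (about $-1\%$ for late blight in the static
scenario); and the static counterfactual understates consumer-surplus gains
relative to every foresight scenario.

Because per-country technology parameters are uniform draws within the
published ranges, the ranking is a property of the fixture study
conditions, not a theorem: across random generator seeds roughly 3% of
worlds swap the two weakest options (bacterial wilt, burdened by its
10-year research lag, against improved seed systems). That mirrors the
source study's own observation that technology rankings are driven by the
specification data. The synthetic worlds reproduce directions, not
magnitudes: in particular the target/global overestimation ratio here is
modest (median about 1.02), whereas with a real-world calibration —
where target countries hold a far smaller share of world production value —
it can approach a factor of two.

## Numerical choices

* Solver: Newton on log world prices with a finite-difference Jacobian and
  step-halving damping; tolerance $10^{-8}$ relative excess demand; at the
  calibration point the residual is exactly zero, so static baselines
  return base prices without iteration and runs are bit-reproducible.
* Horizon: the study period is "25 years until 2040" from 2015, which read
  inclusively is 26 annual steps; the package treats the horizon as
  configuration and defaults to 2015–2040 inclusive.
* IRR: roots of the NPV polynomial via `polyroot()`, filtered to real
  rates above $-100\%$, smallest returned, Newton-polished; `NA` in reports
  when the net stream never changes sign.
* Ties in rankings break alphabetically by technology name.
* All randomness flows from explicit seeds; the same seed reproduces
  worlds, drivers, technologies and study outputs exactly.
* Problem sizes in the shipped tests (12 regions, 3 commodities, 26 years,
  a 4x4 study grid, 100-draw oracle comparisons) solve in seconds and were
  chosen to exercise every property at full fidelity.

## Limitations

Beyond the simplifications listed above: no technology spillovers between
regions; no stochastic treatment of adoption ceilings or success
probabilities (point estimates only, as in the source study's higher
adoption scenario); no poverty, nutrition or economy-wide (general
equilibrium) indicators; welfare on vertically related input markets is out
of scope. The generator emulates magnitudes and orderings, not any real
country's data; conclusions about real research portfolios require a real
calibration.
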