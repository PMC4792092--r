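---
title: "Price indices and catastrophic expenditure for branded medicines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Price indices and catastrophic expenditure for branded medicines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medafford)
```

## The problem

When patients buy prescribed medicines out of pocket, two questions decide
whether care is accessible: how a country's retail prices compare with a
relevant reference market, and whether acquiring a single treatment pushes a
low-income household past a catastrophic spending level. `medafford`
implements both analyses as one reproducible pipeline over plain CSV inputs:
a bilateral, sales-value-weighted Laspeyres price index with a purchasing
power adjustment, and a per-treatment catastrophic-expenditure
classification with population-share estimation. Branded (on-patent)
products are the motivating case — no generic substitute exists, so the
retail price is the price the patient pays.

## The price index

All comparisons are bilateral against one reference country (default `CY`).
For product $i$, let $p_{c,i}$ be its retail price in country $c$,
$p_{\mathrm{ref},i}$ its price in the reference country, and $w_i$ its sales
value in the reference market. With expenditure shares
$s_i = w_i / \sum_j w_j$, the index for country $c$ is

$$ I_c \;=\; 100 \times \sum_i s_i \,
   \frac{p_{c,i}}{p_{\mathrm{ref},i}} . $$

This is a Laspeyres index: with implicit base-period quantities
$q_i = w_i / p_{\mathrm{ref},i}$ it equals
$100 \sum_i p_{c,i} q_i / \sum_i p_{\mathrm{ref},i} q_i$, the cost of the
reference basket at the comparator's prices. Weighting by sales *value*
rather than volume makes a product's influence proportional to its budget
impact in the reference market. The index is a weighted mean of price
relatives, so it always lies between the smallest and largest relative;
scaling all weights by a constant leaves it unchanged, and scaling one
country's prices by $k$ scales its index by exactly $k$. These algebraic
laws — plus the equivalence of the two formulations to $10^{-9}$ on random
small baskets — are enforced in the test suite.

Weights are interpreted as sales values *of the reference country*. When the
index is re-rooted at another country, the weights file must be expressed in
that country's sales values; re-expressing the same quantities at the new
base prices ($w_i' = w_i \, p_{\mathrm{new},i}/p_{\mathrm{old},i}$)
reproduces the classical rebasing identity
$I^{new}_c = 100\, I_c / I_{new}$, which the CLI tests check.

### Basket matching

Products enter a bilateral comparison only when they are priced in both
countries and carry a weight (pairwise basket reduction; no imputation) —
the same mechanism by which a cross-country sample shrinks when identical
presentations cannot be matched everywhere. `build_index_report()` reports
`n_products` and `coverage` (the share of total reference sales value
actually compared) so incomparability is visible rather than silent. Baskets
are sorted lexicographically, making every result independent of input row
order.

### Affordability adjustment

A price index says nothing about what residents can afford. The adjusted
index divides by relative income,

$$ I^{adj}_c = I_c \times
   \frac{\mathrm{GDP^{PPP}_{pc}}(\mathrm{ref})}{\mathrm{GDP^{PPP}_{pc}}(c)}, $$

using GDP at purchasing power parity per capita. A country richer than the
reference sees its adjusted index fall (the same prices weigh less on local
incomes); a poorer one sees it rise. The reference country is pinned at 100
on both scales.

## Treatment costing

Prices of different presentations are made comparable through the defined
daily dose (DDD): a pack holds `pack_size * strength_mg / ddd_mg` DDDs, and
`price_per_ddd()` divides the pack price by that count. Monthly treatment
cost then follows the product's regimen:

* `standard_30d` — chronic daily dosing; a month is fixed at 30 DDDs. The
  30-day convention is deliberately not configurable so that published
  monthly figures remain exactly reproducible.
* `pack_cycle_28d` — the pack covers a 28-day cycle, so a calendar month
  requires opening a second pack: two pack prices. This rule is attached to
  products as a regimen attribute rather than hard-coded to the three
  treatments (a proton-pump inhibitor, a COX-2 inhibitor, an SSRI) it
  classically describes, so any 28-day-cycle product gets it.
* `yearly` — one pack a year (an annual osteoporosis infusion is the worked
  example); the monthly cost is one twelfth of the pack price.

When a data source publishes monthly costs directly, a `monthly_cost`
column in the price table overrides computation cell by cell
(`monthly_cost_table()`), which is how the worked-example fixture is stored.

## Catastrophic pharmaceutical expenditure

With income basis $W$ (we use the lowest official monthly wage of an
unskilled government worker, an explicit input rather than a guess at
household disposable income) and fraction $f$ (default 0.05 for medicines
alone; 0.40 expresses the total-health-expenditure rule):

* allowance $= fW$ — spending above this on one treatment is catastrophic;
* residual threshold $= (1-f)W$ — the income left at the threshold;
* a treatment is catastrophic iff its monthly cost **strictly** exceeds the
  allowance ("exceeds" in the catastrophic-expenditure literature; the exact
  boundary case is not catastrophic).

The two quantities always sum to the wage exactly, and both are emitted to
avoid ambiguity about which one a report prints. Display convention for the
residual threshold: truncate to whole euros when the wage is an integer,
round half-up to one decimal when it carries decimals — the rule consistent
with how such tables are conventionally printed, and locked by tests.

### Population shares

A wage comparison is all-or-nothing; to estimate *how many* people a
treatment would tip past the threshold, an income distribution is needed.
The share facing catastrophic expenditure from a treatment costing $m$ per
month is $F(m/f)$: the income-CDF mass below the level at which the
treatment costs exactly the fraction $f$. Two distribution kinds are
supported:

* **Parametric lognormal** (`income_lognormal(mu, sigma)`, log-EUR/month) —
  the conventional shape for household income; the share has the closed form
  $\Phi\!\big((\ln(m/f) - \mu)/\sigma\big)$.
* **Empirical quantile tables** (`income_empirical()`) — ascending
  (probability, income) pairs, evaluated by linear interpolation.

The empirical CDF is evaluated *left-continuously* (mass strictly below the
evaluation point; ties collapse to their lowest tabulated probability).
This choice makes the degenerate point-mass distribution (everyone earns
$W$) agree exactly with the strict boolean classifier: a cost of exactly
$fW$ yields share 0, anything above yields share 1. Below the first
tabulated quantile the CDF is 0 and above the last it is 1; for a fine
table (the generator uses $10^4$–$10^5$ draws) the truncation error is far
below the Monte-Carlo error. Affected counts are `round-half-up(share ×
count)`.

## The synthetic-data generator

Real price panels of this kind are built from national price lists and
commercial sales data that cannot be redistributed, and published income
extracts rarely accompany them. The generator therefore produces inputs
with the statistical structure the analysis assumes, so every stage is
testable end to end:

* **Prices** (`simulate_price_panel()`): reference prices log-uniform on
  [1, 600] EUR — spanning the two-and-a-half orders of magnitude between a
  cheap chronic tablet and an annual infusion in the worked example — and
  comparator prices $p_{c,i} = m_c\, p_{\mathrm{ref},i}\, e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$, the multiplicative country-effect ×
  product-noise structure a bilateral index presumes. Note
  $E[e^{\varepsilon}] = e^{\sigma^2/2}$, so a consistency check against
  $100\,m_c$ must divide out that bias (about 0.5% at $\sigma = 0.1$).
* **Weights** (`simulate_weights()`): Pareto sales values with tail index
  `alpha` (default 1.2), reproducing the concentration of pharmaceutical
  markets where a top-sellers list holds much of total value — at
  `alpha = 1.2` the top decile of products carries a majority of weight.
  `alpha = Inf` is a uniform-weights sentinel.
* **Incomes** (`simulate_income_distribution()`): a lognormal parameterized
  by its median, returned both parametrically and as a seeded empirical
  quantile table, mirroring the two inputs the share estimator accepts.

One integer seed drives a *named stream per generator* (a 31-bit hash of
seed and stream label), so adding a generator or reordering calls never
perturbs another's draws, and every output is reproducible from
(parameters, seed).

What the generator does **not** emulate: correlated product-level country
effects (therapeutic-class pricing policies), missingness mechanisms tied
to price levels, non-lognormal income shapes (bunching at minimum wages,
top-coding). Passing tests on synthetic data therefore validate the
*machinery* — estimator algebra, classification logic, I/O — not any claim
about a particular real market.

### The worked-example fixture

`worked_example_fixture()` ships an 8-product × 5-country table of monthly retail
treatment costs (EUR, 2011 private-sector price lists of Italy, Greece,
Portugal, Cyprus and Spain) for one branded product per major chronic
condition, with the five lowest monthly wages. It is stored as plain CSV
under `inst/extdata/` and is the package's end-to-end worked example: with
equal weights it yields indices of 92.10 (IT), 74.96 (GR), 77.20 (PT) and
85.90 (ES) against Cyprus = 100, and at the 5% fraction it flags 12 of the
40 country-treatment pairs as catastrophic (the annual osteoporosis
infusion and the branded antidiabetic in all five countries; the combined
asthma inhaler in Portugal and Spain). The fixture's GDP column is a unit
placeholder: the example's published context reports only the wage-based
analysis, and the placeholder keeps the adjusted index equal to the raw
one rather than inventing GDP figures.

## Numerical and design choices

* **Decimal-comma input.** Southern-European price lists are printed with
  decimal commas. Input locale is an explicit flag (`decimal_style`),
  never auto-detected; internal representation is always point-decimal.
  In semicolon-separated files this is plain locale parsing. In
  comma-separated files the decimal comma splits the numeric field, so a
  row is reconstructed only when the token count is unambiguous (numeric
  columns are trailing; either no field or every numeric field is split);
  anything else is a parse error naming the line.
* **Exact round-trips.** Writers emit doubles with 17 significant digits
  and readers convert through base R's correctly-rounded parser, so
  write-then-read reproduces values bit for bit (the bundled fast CSV
  parser is not correctly rounded in the last ulp).
* **Index precision.** `index.csv` is written at two decimals, the
  conventional reporting precision; full precision is kept in memory. The
  reference row is pinned to exactly 100 against floating-point residue.
* **Degenerate inputs.** An empty bilateral basket or a zero total weight
  is an error (the index is undefined), not a silent NA; a zero monthly
  cost has population share 0 by convention.
* **Problem sizes.** The property tests run dozens of random baskets of
  2–6 products (where the two Laspeyres formulations are compared to
  $10^{-9}$), multiplier-recovery panels of 48–500 products at
  $\sigma \in \{0, 0.1\}$, and Monte-Carlo income checks at $10^4$–$10^5$
  draws against 3-standard-error bands — sizes at which the law-of-large-
  numbers bounds involved are comfortably diagnostic while the whole suite
  runs in a few seconds.

## Limitations

* Bilateral indices only: every comparison is star-shaped around one
  reference; there is no multilateral chaining and no
  Paasche/Fisher/Törnqvist variant, and a reference-country weighting
  assumes comparator markets share its consumption pattern.
* Single currency: no exchange-rate handling (the motivating countries all
  use the euro).
* One treatment at a time: no household equivalence scales, no cumulative
  multi-treatment expenditure, no co-payment tier modelling.
* DDD values are user-supplied inputs; there is no dosing-registry lookup.
* Published headline percentages of populations facing catastrophic
  expenditure depend on income microdata that is not redistributable;
  the package validates its share estimator against closed forms and
  simulation instead.
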