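---
title: "Eccentricity-based indices and QSPR regression: methods and design"
author: "eccQSPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eccentricity-based indices and QSPR regression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccQSPR)
```

## The model

A drug molecule enters the package as its hydrogen-suppressed skeleton: a
simple, connected, undirected graph whose vertices are the heavy atoms and
whose edges are covalent bonds with bond order and aromaticity discarded.
That abstraction is deliberate — every index below depends only on
shortest-path distances, which bond order does not change — and it is the
convention under which the shipped chlorpromazine structure has exactly 21
vertices and 23 edges.

The central quantity is the vertex eccentricity ξ(v), the largest
shortest-path distance from v to any other vertex. Distances come from one
breadth-first search per source vertex (via `igraph`); an independently
written Floyd–Warshall dynamic program (`floydWarshallOracle()`) exists
purely as a cross-check and shares no code with the production path. From
the eccentricities the package forms two multiplicity summaries — the vertex
partition (how many vertices have each eccentricity value) and the edge
partition (how many edges have each unordered pair of endpoint
eccentricities) — and evaluates all eight indices on those partitions. This
is both faster than per-edge evaluation and matches how such calculations
are presented in the QSPR literature. Useful structural facts follow
directly: endpoint eccentricities of an edge differ by at most one, the
partition keys form a contiguous range from radius to diameter, and
diameter ≤ 2 · radius. All are asserted as property tests on generated
graphs.

## The two conventions

Published tables of these indices for the thirteen anti-schizophrenia drugs
were computed with two departures from the literature definitions, and the
package preserves both behaviours rather than silently "fixing" either:

* **M₁\*\*** — the literature defines the second Zagreb eccentricity index
  as the vertex sum of squared eccentricities (its stated summation domain
  over "edges" is a well-known typo for vertices). The published worked
  example instead squares each *class total*: Σ_k (n_k · k)² over
  eccentricity classes, giving 5978 instead of 1192 for chlorpromazine.
* **ABC** — the literature form takes the square root of the whole per-edge
  ratio, √((ξ_u + ξ_v − 2)/(ξ_u ξ_v)); the published arithmetic roots the
  numerator only, giving 1.6352 instead of 11.335 for chlorpromazine.

`convention = "standard"` (the default) implements the literature
definitions; `convention = "paper_faithful"` implements the published
arithmetic, and is what the reproduction pipeline pins. The other six
indices agree under both. Whether the published variants were intended or
accidental cannot be decided from the source tables; keeping both makes the
dataset reproducible without endorsing the nonstandard forms. Note that the
paper-faithful M₁\*\* is a function of the eccentricity *partition*, not a
vertex-additive index, which is why `secondZagrebEcc()` takes the partition
as an argument.

A related published claim — that M₁\* equals ζ(G) because each ξ(u) appears
d(u) times in the edge sum — is half right: the degree identity
M₁\* = Σ_v d(v) ξ(v) holds and is property-tested here, but it equals ζ(G)
only for 2-regular graphs (the worked example itself has 332 ≠ 156). The
package asserts the identity and not the false equality.

## The regression layer

The QSPR layer fits ordinary least squares of one property on one index,
linear or quadratic, via `stats::lm`, and reports:

* r = √r², the multiple correlation, always non-negative. Published QSPR
  tables print positive r even for negative slopes, so the package does the
  same; the signed slope stays available as β.
* F = (r²/k) / ((1−r²)/(n−k−1)), the overall-model statistic, with its
  upper-tail p-value from the F(k, n−k−1) distribution.
* the screening flags p ≤ 0.05, F > 2.5 (strict) and r > 0.7 (strict).

A numerically perfect fit (1 − r² below 1e−12) reports r² = 1 with F = Inf
and p = 0 instead of erroring, so that synthetic noise-free data flows
through the pipeline. Constant or rank-deficient predictors are an error in
`fitPropertyModel()` but are downgraded to NA rows in the batch driver
`fitAllModels()`, so one degenerate column cannot abort a 128-fit run.
No multiple-testing correction is applied, matching the published analysis.

Published quadratic equations list their coefficients in scrambled term
positions; they are interpreted via the table column headers as
α = intercept, β = linear, γ = quadratic. The complexity ~ GA₄ fit validates
this reading: it reproduces α = 1276.795, β = −74.313, γ = 1.629,
r = 0.6831 and F = 4.376 exactly.

## The embedded dataset and its audit

The thirteen-drug property table (boiling point, melting point, enthalpy,
flash point, molar refractivity, complexity, molecular weight, refractive
index) and the published index table are stored verbatim, anomalies
included. `validateConsistency()` reports, without correcting:

* drug c's ζ = 218 with avec = 8.75 implies n = 24.91 — not an integer
  vertex count, so at least one of the two printed values is wrong;
* one published quadratic correlation (avec ~ BP) below its linear
  counterpart, impossible for nested OLS models and hence a transcription
  error.

A few cells whose digit grouping was ambiguous in the available rendering of
the source tables are flagged in `fixtureFlags()` with the transcription
chosen; the choices maximize internal consistency (integer vertex counts,
the M₁\* ≈ 2·avec·m identity) and none of them touches the columns used in
the reproduction tests. The complexity column is additionally
cross-validated by reproducing the published r = 0.6602 of the
complexity ~ GA₄ fit. Published decimals occasionally truncate rather than
round the last digit (GA₄ = 22.9450 printed for a true 22.94507; quadratic
r = 0.6831 for 0.68317), so reproduction tests compare at the printed
precision with a one-unit-in-the-last-place allowance.

Only chlorpromazine's structure is recoverable from the source (the other
twelve appear solely as drawings), so it is the one structural fixture; it
ships both as an edge list and as a SMILES string, and tests require the
two entry paths to agree with each other and with the published partitions.

## Synthetic data: what it emulates and what it does not

`randomMolecularGraph()` grows a random spanning tree by uniform attachment
under a degree cap (default 4, mimicking carbon valence) and then adds up to
five ring-closing edges between non-adjacent vertices still under the cap.
This emulates the size range (up to 60 heavy atoms), branching and modest
ring content of drug skeletons — enough to exercise every index formula and
the distance machinery. It does not emulate chemistry: no valence rules
beyond the cap, no aromatic systems, no element identities. Passing property
tests on these graphs therefore certifies the graph algorithms and index
algebra, not any pharmacological claim.

`randomRegressionData()` draws x uniformly on (0, 35) — the span of the GA₄
column across the drug set — and adds Gaussian noise to a stated
linear-or-quadratic truth, for parameter-recovery tests (n = 200, recovery
within three standard errors) and for the Pearson-oracle checks.

Both generators take an explicit integer seed, restore the caller's RNG
state on exit, and are deterministic given the seed.

## Numerical choices and problem sizes

* Eccentricities and the classical indices are exact integer arithmetic in
  doubles (values ≪ 2⁵³); GA₄, ABC and Hₑ accumulate at double precision
  with no rescaling — partitioned evaluation keeps the term count at the
  number of eccentricity classes, typically < 10.
* Test problem sizes: 200 random graphs of up to 60 vertices for the
  BFS-versus-Floyd–Warshall equality, 150 generator-contract seeds, 60
  additional oracle comparisons, and n = 200 for regression recovery. These
  sizes give the property suite good coverage while the whole test run
  stays around ten seconds.
* The avec audit tolerance is 0.01: zeta/avec must sit within 0.01 of an
  integer, generous for 4-decimal rounding of avec yet far below the 0.09
  discrepancy it flags for drug c.

## Known limitations

* Graphs must be connected; infinite eccentricities are refused, not
  propagated, because every index formula assumes finite values.
* The SMILES reader depends on an optional ChemmineR/ChemmineOB backend and
  collapses everything to the skeleton — stereochemistry, charges and
  tautomers are out of scope.
* Only linear and quadratic property models are provided; cubic and
  regularized models, cross-validation and multivariate QSPR are not goals.
* The published comparison tables are reproduced as data, but full
  row-by-row reproduction of every published regression table is not
  asserted: several printed rows are internally inconsistent (see the
  audit), and the package prefers an honest anomaly report to a forced
  match.
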