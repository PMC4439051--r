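---
title: "Methods: case-control point-pattern inference in ccspat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control point-pattern inference in ccspat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccspat)
```

## The problem

Geocoded disease registries pose two distinct spatial questions. *Overall
clustering* asks whether cases, as a set, sit closer to one another than a
sample of the population at risk does — anywhere in the region, at which
distances. *Cluster detection* asks whether some specific circular
neighbourhood holds more cases than constant risk would predict, and where.
`ccspat` implements the standard answer to each for case-control point data:
the difference of K functions with random-labeling Monte Carlo envelopes,
and the purely spatial Bernoulli scan statistic. Both operate on a
`cc_pattern`: planar projected coordinates in meters (e.g. ETRS89 / UTM),
a case/control label, and the matching strata (region of residence, year of
birth, sex) of a matched design.

The motivating application is childhood-cancer surveillance, where the
population at risk is strongly inhomogeneous (a few dominant cities), cases
are rare, and controls are drawn from a birth registry matched 1:6 — so the
control pattern, not a homogeneous Poisson benchmark, carries the null
spatial structure.

## K functions and D(s)

For a pattern of $n$ points in a window of area $A$, the K function is
estimated as

$$\hat K(s) = \frac{1}{\hat\lambda\, n} \sum_i \sum_{j \ne i}
  w_{ij}\, \mathbf 1[d_{ij} \le s], \qquad \hat\lambda = n/A .$$

Without edge correction $w_{ij} = 1$; under complete spatial randomness
$K(s) = \pi s^2$, and points near the boundary bias $\hat K$ downward
because part of their distance-$s$ neighbourhood is unobserved. Ripley's
isotropic correction repairs this by weighting each pair by the reciprocal
of the fraction of the circle centred at $i$ through $j$ whose circumference
lies inside the window. The weight is computed by exact circular-arc/polygon
intersection: the circle's intersection angles with every polygon edge are
the roots of a quadratic along the edge, the circle is cut into arcs at
those angles, and each arc is classified by testing its midpoint against the
polygon. This is exact for any simple polygon, convex or not; a
discretised-circle evaluation exists in the test suite as an independent
oracle and agrees to well under 0.5%.

The clustering statistic is $D(s) = \hat K_{\text{cases}}(s) -
\hat K_{\text{controls}}(s)$, each K on its own sub-pattern over the shared
window. Its null distribution is simulated by *random labeling*: case and
control labels are permuted over the pooled coordinates, holding the number
of cases fixed, and D recomputed per replicate. Pair distances and edge
weights depend only on geometry, so they are computed once and every
relabeling reduces to re-summing weights over case-case and control-control
pairs (done in compiled code). Envelopes are pointwise: with the min/max
rule over $m$ replicates, the probability that the observed D exits the
envelope at one pre-fixed distance is $2/(m+1)$ under the null. A pointwise
band says nothing simultaneous about the whole curve — neighbouring
distances are strongly correlated because $\hat K$ is cumulative, and a
single dataset can sit near one envelope limit across a wide range of
distances without that being stronger evidence than one exceedance. We
report verdicts per distance (`cases_aggregated`, `controls_aggregated`,
`null_consistent`) and deliberately do not aggregate them into a global
test; the integrated Diggle–Chetwynd statistic would be the natural
extension but is out of scope.

Defaults: distances up to 8 km on a 64-point grid (125 m resolution), 999
relabelings, min/max envelopes, isotropic correction. The quantile rule
(2.5%/97.5%) is available for large replicate counts; the stratified
permutation option (permuting within matching strata) is provided for
sensitivity analysis of the matched design, not as the primary test.

## The Bernoulli scan statistic

Circular windows are centred at case addresses, the radius growing from zero
to a 5 km cap; the candidate radii at a centre are the sorted distances to
every at-risk point within reach, so each distinct inside-set is scored
once. Discs are closed: points exactly at the boundary distance are inside,
and ties in distance enter together. With $n_i$ cases of $N_i$ at-risk
inside and $m_i$ of $M_i$ outside, the default kernel is

$$\log LR_i = n_i \log\frac{n_i}{N_i} + m_i \log\frac{m_i}{M_i},
  \qquad \text{scored only when } \frac{n_i}{N_i} > \frac{m_i}{M_i},$$

with $0\log 0 = 0$. This is the case-count kernel of the case-control scan
literature; the full Bernoulli log likelihood ratio (adding the
$(N_i - n_i)$ and $(M_i - m_i)$ terms and subtracting the null likelihood)
is available as `kernel = "bernoulli"` and ranks windows near-identically.
The most likely cluster maximises the kernel, with ties broken by smaller
radius and then lower centre index so reports are deterministic. Secondary
clusters are the best window per centre, ranked after discarding discs that
geometrically overlap a higher-ranked reported disc.

Significance is by Monte Carlo: each replicate redraws the case labels
uniformly over all at-risk locations (constant-risk null), windows centred
at the *replicate's* case locations so observed and replicate statistics are
exchangeable, and $p = (1 + \#\{T_{rep} \ge T_{obs}\})/(R+1)$ with $R =
9999$ replications by default. This guarantees $p \ge 1/(R+1)$ and validity
(super-uniformity) under the null, which the test suite verifies empirically
at a reduced problem size (140 at-risk points, 999 replications, 200 outer
runs).

Two design points were genuinely open. First, the window cap: the study
design this package mirrors states 5 km in its methods and 8 km in its
discussion; we default to 5 km (the methods value) and expose
`max_radius`. Second, whether windows may also be centred at control
addresses: the default follows the case-centred description, and
`centers = "all"` gives the variant, which can only raise the maximum
statistic. No population-fraction cap is applied beyond the distance cap.

Expected cases inside a window are $E_i = C\,N_i/(N_i + M_i)$ — total cases
times the at-risk fraction inside — and sum to $C$ over any partition of
the at-risk set.

## The synthetic generator

Real registry addresses are confidential, so every analysis stage is
exercised on synthetic matched data. A `synthetic_scenario` draws an
at-risk pool from a Gaussian-mixture intensity truncated to the window by
rejection sampling — the simplest controllable stand-in for regions
dominated by a few cities; it is not fit to any real map. Cases are drawn
from the pool uniformly (or with selection weight multiplied by a relative
risk inside an injected disc), strata are assigned independently of
location, and each case receives `matching_ratio` same-stratum controls
drawn without replacement (default 6, the matched design of the motivating
study). The default pool holds $8 \times n_{cases}(ratio+1)$ locations; if
a rare stratum still cannot supply its controls, `generate_cc_data` tops the
pool up from the same intensity and retries — the same remedy a registry
study applies when sampled controls fall through — while `assign_cases` on
a fixed pool reports the exhausted stratum by name. The default scenarios
(`study_scenarios()`) mirror the published case counts of the motivating
study, e.g. 638 cases and 3828 controls for leukemia in the North-East
group.

Privacy jitter reproduces the coordinate-anonymisation applied to the real
data: the trailing $d$ integer digits of each coordinate are replaced by a
uniform random number, so with $d = 1$ every point moves by less than 10 m.
The number of digits actually randomised in the motivating study is not
public; $d = 1$ is the most conservative reading and the default. Jittered
points that would leave the window are redrawn, then kept at their original
position after 100 attempts (only possible within $10^d$ m of the
boundary). A perturbation test confirms meter-scale jitter changes
$\hat K(2000\,\text{m})$ by well under 1% — the anonymisation is harmless at
analysis distances.

Deliberately absent from the generator: spatial confounding by stratum
(strata are independent of location, so stratified and plain permutation
agree in distribution), real population rasters, and any space-time
structure. Passing tests therefore validate the inferential machinery, not
the realism of any particular map.

## Numerical choices

* Points exactly on the window boundary are inside; duplicate coordinates
  are allowed and zero-distance pairs count as neighbours at every
  $s > 0$ (post-jitter data can share addresses).
* The circumference fraction of an isotropic weight is floored at $10^{-6}$
  (weight cap $10^6$) against the measure-zero case of a point sitting
  exactly on the boundary.
* Polygon point-in-polygon tolerance scales with the coordinate magnitude
  ($10^{-9}\times$), so UTM-scale coordinates keep sub-micrometer
  effective tolerance.
* Monte Carlo p-values count replicates with $T_{rep} \ge T_{obs}$ under a
  relative tolerance of $10^{-7}$, so bitwise-equal count configurations tie
  rather than split on floating-point noise.
* All randomness flows through R's RNG (including inside compiled code),
  so a seed pins every envelope, scan and synthetic dataset exactly.

## Problem sizes used in the checks

The test suite validates the estimators against independent brute-force
oracles on 50 random instances of up to 50 points; the CSR benchmark uses
200 simulations of 500 points in a 1 km square (mean $\hat K$ within 5% of
$\pi s^2$ at 50–200 m); scan calibration uses 200 datasets of 140 at-risk
points with 999 replications each; envelope calibration uses 500 datasets
over 99 relabelings. The analysis scripts run the eight full-size study
datasets with 199 relabelings and 999 scan replications — sizes chosen so a
full sweep stays interactive; a single confirmatory analysis would use the
package defaults (999 and 9999).

## Power, honestly

Detection power is governed almost entirely by how many at-risk individuals
the true cluster disc contains. With 600 at-risk points spread over a
20 km square, a 500 m disc contains on average
$600\,\pi 500^2/20000^2 \approx 1.2$ individuals and is empty more than a
third of the time — no detector can localise risk carried by a window that
usually holds at most one person, however large the relative risk. The
package's power regression test therefore injects a 2 km disc (expected
occupancy ≈ 19), where the scan recovers the centre to within 1 km in well
over 60% of seeded runs. Users planning simulations should size the disc,
or the population density, so the expected occupancy is at least a handful
of individuals.

## Limitations

Windows are circular only; coordinates must be planar meters (no lon/lat);
the D(s) envelopes are pointwise, not simultaneous; no covariate adjustment
or space-time extension; and the Gaussian-mixture population is a
deliberately stylised stand-in — conclusions about any real region require
its real population pattern.
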