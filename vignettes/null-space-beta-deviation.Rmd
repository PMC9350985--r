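---
title: "Beta-diversity deviations across a bidimensional null space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-diversity deviations across a bidimensional null space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(betanull)
library(dplyr)
```

## The problem

β-diversity — the compositional variation among sites that links local (α)
to regional (γ) richness — can arise from two very different processes:
*turnover* (species replacement between sites) and *nestedness* (ordered
species loss, where poor sites hold subsets of rich sites' assemblages).
Telling them apart matters: a turnover-dominated region is best conserved
through networks of many small reserves, a nestedness-dominated one through
its richest sites.

But raw index values are not evidence of process: even randomly assembled
communities show nonzero turnover and nestedness. The standard remedy is a
null model — randomize the incidence matrix, recompute the index, and read
the deviation from the null mean as the effect size of nonrandom structure.
The catch is that the conclusion can hinge on which null model one picks:
constraining both marginal totals of the site × taxon matrix (the
"fixed-fixed" model) is conservative, while placing occurrences in cells
equiprobably is liberal. This package operationalizes the full continuum
between those extremes as a bidimensional null space, so the robustness of
a conclusion can be read across the whole constraint landscape instead of
at one arbitrary point.

## The indices

All computation runs on a binary site × taxon matrix (a `pa_matrix`).
For site richness $S_i$, pooled richness $S_T$ (γ), and pairwise exclusive
counts $b_{ij}$ (taxa in site $i$ but not $j$), the multiple-site
Sørensen-family dissimilarity and its Simpson-family turnover component are

$$
\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
 {\sum_i S_i - S_T + \sum_{i<j}\min(b_{ij},b_{ji})},\qquad
\beta_{SOR} = \frac{\sum_{i<j}\min + \sum_{i<j}\max}
 {2\left(\sum_i S_i - S_T\right) + \sum_{i<j}\min + \sum_{i<j}\max},
$$

with the nestedness component defined by the additive partition
$\beta_{SNE} = \beta_{SOR} - \beta_{SIM}$. Pairwise counterparts (and their
unweighted means) are provided for supplementary analyses, but the
multiple-site forms are primary: they account for co-occurrence patterns
involving more than two sites.

```{r}
nested <- make_nested(3, 4)   # strict subset chain: all nestedness
beta_multi(nested)
beta_multi(make_turnover(3, 2)) # disjoint blocks: all turnover
```

### A structural fact worth knowing

The multiple-site partition is **fully determined by the matrix's marginal
totals**: the sum of shared-taxon counts over site pairs equals
$\sum_t \binom{f_t}{2}$ (a function of the taxon frequencies $f_t$ alone),
and $\min(b_{ij}, b_{ji}) = \min(S_i, S_j) - a_{ij}$, so every term in the
formulas above reduces to row totals, column totals, and γ. Two
consequences thread through the whole package:

* Under the fixed-fixed null model the null distribution of every index is
  a point mass at the observed value — the deviation at the most
  constrained node of the null space is identically zero. (Empirically,
  deviations near that corner are tiny and non-significant; here the limit
  is exact.)
* All deviation signal across the null space is carried by how far the
  randomization moves the marginals, which is precisely what the null
  space's two axes measure.

The pairwise indices do *not* share this property (they depend on the
individual $a_{ij}$), which is one more reason the multiple-site and
pairwise analyses can disagree.

## The null space

Every null matrix conserves the fill $F$ (total occurrences) exactly. The
two axes of the null space measure how far the randomized matrix's row and
column marginal totals stray from the observed ones, as a Bray–Curtis
discrepancy $\sum_i |m_i - m'_i| / 2F$, normalized by the Monte-Carlo mean
discrepancy under full equiprobable refills so that 0 = preserved exactly
and 1 = typical of the equiprobable ensemble. The default grid has 11
equally spaced levels per axis — 121 nodes — anchored by the fixed-fixed
model at (0, 0) and the equiprobable model at (1, 1); the nine classical
presence-absence null-model algorithms (fixed / proportional /
equiprobable per axis) map onto its corners, mid-edges and centre
(`null_model_presets()`).

A sample at node $(d_r, d_c)$ is generated in three phases:

1. **Mixing** — `mix_factor * F` curveball trades (an elementary move that
   swaps exclusive taxa between two random sites, preserving both marginal
   vectors; its closure samples the fixed-fixed ensemble uniformly). Node
   (0, 0) stops here.
2. **Steering** — single occurrences are relocated within columns (moving
   only the row-axis discrepancy) and within rows (only the column-axis
   discrepancy); a move is accepted only if it brings that axis's
   normalized discrepancy strictly closer to target without overshooting
   `target + eps`. Because the two move types act on disjoint marginal
   vectors, the axes are steered independently.
3. **Re-mixing** — curveball trades again; these preserve the *achieved*
   marginals, hence the achieved discrepancies, while randomizing the
   structure reached by steering.

The corner (1, 1) is drawn directly from the equiprobable ensemble (its
achieved discrepancies scatter around 1 by construction, so the tolerance
contract is waived there). Nodes on the axes preserve the untouched
marginal vector *exactly* — an integer identity, not an approximation.

### Numerical choices

* **Tolerance.** `eps = 0.02` normalized units (one fifth of a grid step).
  A single relocation moves the normalized discrepancy by $1/(F D_{ref})$,
  so the effective tolerance is floored at half that lattice spacing —
  without this floor, small matrices could never converge.
* **Budgets.** Steering proposals are capped at `budget_factor * F`
  (default 50·F); an unconverged sample is regenerated once and then
  errors. Mixing defaults to 10·F trades.
* **Normalization.** `n_ref = 1000` equiprobable refills estimate the
  per-axis reference discrepancy $D_{ref}$; the all-ones matrix (no free
  cells) makes the normalization degenerate and errors with an explicit
  message.
* **Ties.** p-values count null scores *strictly* greater than observed
  (the reported convention). At marginal-preserving nodes every null ties
  the observed value exactly (see above), which yields p = 0; the
  `ties = "midrank"` option counts ties as ½ and yields p = 0.5 there.
  Strict counting stays the default for fidelity; midrank is the robust
  opt-in.
* **RNG.** One root seed; every (repetition × stage × node) task derives
  its own stream through a documented integer-folding rule
  (`derive_seed()`), so results are bitwise reproducible and independent
  of execution order.

## Deviation landscapes and conservativeness

At each node, `beta_deviation()` draws `n_null` samples and reports the raw
deviation $\Delta\beta = \beta_{obs} - \overline{\beta_{null}}$ per index —
raw rather than standardized, which keeps the three indices on their common
[0, 1] scale and preserves additivity
($\Delta\beta_{SOR} = \Delta\beta_{SIM} + \Delta\beta_{SNE}$, exactly) — and
a p-value as the fraction of null scores strictly above the observed. A
deviation is significant when p < α or p > 1 − α (α = 0.05 by default,
strict inequalities).

```{r, eval = FALSE}
m <- make_random(32, 78, 0.33)
land <- beta_landscape(m, null_space_grid(11), n_null = 100, seed = 1)
autoplot(land)                  # deviation heatmaps
autoplot(land, what = "p_value") # significance landscapes
```

The bottom-left quarter of the grid (both indices 0–4 on the default
11-level grid: 25 nodes strictly below the midline) is read as the
*conservative* regime, the top-right quarter (6–10) as *liberal*, and the
full 121-node landscape as *moderate*. On coarser grids the same
strict-half rule applies; note that on a 3-level grid the quarters
degenerate to single nodes — and the conservative one is the fixed-fixed
node, where deviations are identically zero by the marginal-determination
property. Desk-scale runs should read the moderate level, or use ≥ 7
levels if per-quarter statistics matter.

## The study pipeline

`run_study()` reproduces the full design: sites are binned into four
bioclimatic stages by mean annual temperature (foothill > 8 °C, montane
4–8 °C, subalpine 0 to < 4 °C, alpine < 0 °C; the printed range "4–8" is
closed, the outer bounds strict), an equal number of sites (the minimum
stage size; 32 in the emulated design) is drawn per stage to remove
sampling-effort bias, and per-stage raw profiles (βsor, βsim, βsne, γ,
fill) and deviation landscapes are computed. The whole procedure is
repeated `n_repetitions` times and averaged per node — deviations as the
quantity of interest, p-values as a *descriptive* summary only. Stage
pairs are then compared per index and conservativeness level with
two-sided Wilcoxon rank-sum tests on the per-node deviations
(exact for small untied samples, normal approximation with tie and
continuity correction otherwise), Holm-corrected within each
(index, level) family over all pairs by default (`family =
"consecutive"` restricts to adjacent stages; a paired signed-rank variant
is available since cells are matched across stages, but the unpaired test
is the default as pairing is a modelling choice, not a given). Star
symbols follow the conventional four-band scale.

The two repetition loops (subsampling; null sampling per node) are
implemented as independent counts — `n_repetitions` outer, `n_null` inner —
which is the simplest reading consistent with averaging deviations per
node.

## The synthetic metacommunity

`make_gradient()` emulates the kind of data the analysis was designed for:
309 sites in four temperature stages (84/110/83/32 sites — peaking at mid
elevation, 32-site minimum), 78 taxa, overall fill ≈ 0.33. Site
temperatures are uniform within each stage's band; occupancy is
independent Bernoulli per site × taxon with probabilities from a niche
model with two taxon guilds:

* a fraction `lambda` (default 0.5) of **core taxa** whose occupancy
  decays monotonically toward the cold end (warm-centred Gaussian with
  taxon-specific width 3–10 °C) — ordered species loss, the nestedness
  driver;
* the rest with **staggered narrow optima** (width 0.8–2.5 °C), drawn with
  a warm skew (`warm_skew = 0.5`) so replacement concentrates at the warm
  stages and regional richness declines toward the cold end — the turnover
  driver.

Two further choices give the generator the qualitative structure the
analysis expects. First, a `determinism` dial (default 3) tempers
occupancy probabilities toward 0/1 increasingly toward the cold end
(`p^s / (p^s + (1-p)^s)`, s rising from 1 at the warm end): cold-stage
assembly is filtering-dominated, warm-stage assembly stochastic. Without
it, independent Bernoulli noise swamps sparse cold assemblages with
apparent turnover. Second, a single global occupancy scale is calibrated
by root-finding so the *expected* fill matches the target; realized fill
lands within a few hundredths of 0.33.

What the generator deliberately omits: spatial autocorrelation, dispersal
kernels, and abundance. Sites are exchangeable within a stage — matching
the analysis's own exchangeability assumption — so passing tests show the
pipeline recovers structure *of the kind it models*, not that real stream
networks lack spatial effects.

```{r}
set.seed(5)
g <- make_gradient()
g$matrix
raw_profile(subsample_equal(g$matrix, g$metadata, 32)) |>
  mutate(across(where(is.numeric), ~ round(.x, 3)))
```

## Calibration, and what the tests do and do not show

When the observed matrix is itself a draw from a node's null ensemble, Δβ
should be ~0 and the two-tailed significance rule should fire ≈ 10% of the
time. The test suite checks this at the equiprobable corner — the one node
where the observed matrix and its null samples come from *exactly* the
same ensemble, making the p-value distribution uniform by exchangeability.
At interior nodes the ensemble is anchored on the observed matrix's own
marginals, so exchangeability is only approximate; and at
marginal-preserving nodes the null distribution is the degenerate point
mass discussed above, where no calibration rate is defined.

Verification scales used by the suite and the acceptance script (chosen as
desk-scale versions of the full design): 1,000 random matrices up to 8×10
against a brute-force pairwise-loop oracle; 20,000 fixed-fixed draws
against the enumerated 3×3 marginal class (χ², α = 0.01); constraint
checks at all 121 nodes of a 12×16 matrix; 200 calibration replicates at
32×78 with 99 nulls each; and a 5-repetition, 3-level, 20-null gradient
study. The full-scale defaults (11 levels, 100 repetitions, 100 nulls)
are the documented study configuration.

## Known limitations

* The multiple-site deviation analysis inherits the
  marginal-determination property: it measures how nonrandom the
  *marginal structure* is relative to each constraint regime, and is
  silent exactly at the fixed-fixed point.
* Steering targets a scalar discrepancy, not a specific marginal vector;
  two samples at the same node can have very different marginal shapes.
* The conservativeness quarters are only meaningful on grids fine enough
  to contain several nodes per quarter.
* No spatial distances, no abundance, no taxonomy above the modelled
  labels.
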