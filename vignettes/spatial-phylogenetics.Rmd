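---
title: "Spatial phylogenetics of endemism: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial phylogenetics of endemism: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloendemix)
```

## The problem

National floras are unevenly distributed: a small number of grid cells —
mountain massifs, old islands, climatically stable refugia — concentrate
a disproportionate share of range-restricted and evolutionarily isolated
taxa. `phyloendemix` implements the full analysis chain used to find and
characterize such cells on a regular planar grid: taxonomic and
range-weighted endemism metrics, phylogenetic endemism with a
randomization-based classification of endemism centres, percentile
hotspot mapping, protected-area gap analysis, and spatially explicit
regression of the metrics on environmental predictors.

All spatial inputs are planar: geographic coordinates must be projected
before gridding (the grid records only a free-text CRS label). Cell ids
are 0-based, row-major from the lower-left corner.

## Metrics

For a binary cells × taxa matrix with per-taxon range $r_i$ (occupied
cell count):

* **SR / ER** — native and endemic richness (row sums).
* **WE** $= \sum_{i \in \text{cell}} 1/r_i$ — weighted endemism; each
  taxon distributes one unit of weight across its range, so
  $\sum_\text{cells} \text{WE} = $ number of taxa exactly (a conservation
  identity the tests exploit).
* **CWE** $= \text{WE}/\text{richness}$ — the mean inverse range of the
  cell's taxa; with ranges in cells it is bounded by 1 and reaches 1
  only when every taxon is a single-cell occupant. Published CWE values
  above 1 arise when ranges are expressed in area units smaller than a
  cell; the `range_unit` argument reproduces that scaling, but the
  default keeps the canonical bounded form.
* **PE** $= \sum_{b} \ell_b / r_b$ over the branches $b$ spanning the
  cell's taxa, where $r_b$ is the branch range (cells holding at least
  one descendant tip) and $\ell_b$ the branch length. The full root path
  is included; `drop_root` removes the basal branches if wanted. PE also
  obeys a conservation identity: summed over cells it equals the
  retained tree length.
* **RPE** — PE on the observed tree divided by PE on a comparison tree
  with identical topology and every branch set to $T/N$ (total length
  over branch count, preserving total length). RPE above 1 flags cells
  whose restricted branches are unusually long (old, isolated lineages),
  below 1 unusually short (recent radiations). The $T/N$ comparison tree
  makes RPE invariant to rescaling all branch lengths.

Richness-independent metrics for *all* taxa (`SR`, `WE`, `CWE_NAT`) are
computed on the full matrix; the endemism-centre machinery (`PE`, `RPE`
and their significance) runs on the endemic subset only, which is the
set the classification is about.

## Null model and significance

Observed metrics are compared with `reps` randomized communities.
The default null is the **curveball** (fixed–fixed) Markov chain: a
trade picks two taxa and reshuffles the cells unique to each, so every
cell's richness *and* every taxon's range are preserved exactly. This is
deliberately stricter than a richness-only reallocation null (also
provided, `null = "richness"`): WE, CWE and PE all weight by range, so a
null that lets ranges drift confounds range-size effects with placement
effects.

Chain settings are the package's own: burn-in of `5 × fill` trades from
the observed matrix, then one rep every `5 × fill` trades without
restarting (a thinned chain). Rank p-values use the add-one convention
$p_\text{high} = (\#\{\text{null} \ge \text{obs}\} + 1)/(R + 1)$, ties
counting toward significance on both tails, so $p$ is never 0 and
$p_\text{high} + p_\text{low} \ge 1 + 1/(R+1)$.

Calibration is checked, not assumed: on a landscape drawn from the null
ensemble itself, the fraction of cells with $p_\text{high}(\text{PE}) <
0.05$ must sit in the 99% binomial band around 0.05, and the p-value
distribution must pass a Kolmogorov–Smirnov uniformity check at the 1%
level. Because a cell is a CANAPE *candidate* when either of two
strongly correlated tests (PE on the observed and on the comparison
tree) fires, the candidate rate under the null lies between $\alpha/2$
and $2\alpha$; the tests use that a-priori band rather than the
single-test one.

## CANAPE classification

With $\alpha_\text{primary} = 0.05$, $\alpha_\text{tail} = 0.025$ and
$\alpha_\text{super} = 0.01$:

1. candidate iff $p_\text{high}(\text{PE}_\text{obs}) < \alpha$ **or**
   $p_\text{high}(\text{PE}_\text{alt}) < \alpha$;
2. candidates split by the RPE tails: high → **paleo**, low → **neo**,
   neither → **mixed**;
3. mixed cells significant on both PE tests at $\alpha_\text{super}$
   are promoted to **super**.

The super threshold follows the protocol's 0.01 rather than the looser
0.1 sometimes quoted: at 0.1 super-centres would outnumber mixed ones,
contradicting every published application. Both thresholds are
arguments. Super is restricted to the mixed branch (it is defined as a
subdivision of mixed endemism); whether it may overlay neo/paleo is
genuinely ambiguous in the literature, and the restriction is the
reading consistent with "subdivision".

## Hotspots, refugia, gaps

Percentile sets use the nearest-rank quantile with
$k = \lceil f\,n \rceil$ tail cells and *ties included*: an equally
scoring cell is never silently dropped, which is the conservative
choice for conservation ranking (membership can exceed $f\,n$ under
ties). L1/L2/L3 = 1/5/10%, both tails; nestedness L1 ⊆ L2 ⊆ L3 is exact
by construction and tested. Priority Hotspots intersect the high tails
of CWE (endemics) and PE at one level.

Climate stability per variable is the inverse of the mean
elapsed-time-weighted absolute change across consecutive time slices,
rescaled to a maximum of 1; constant-through-time cells are capped at
the largest finite stability (they are the most stable, not an error).
The combined index is the rescaled product of the temperature and
precipitation stabilities — "interaction" is read as the product, the
convention of the deviation-based stability method the index follows.
Refugia are its top 10%.

Protected-area coverage is the exact planar area fraction of each cell
square inside the union of the (non-marine) polygons, computed by a
vertical slab sweep with even-odd ring semantics, so overlapping
polygons never double-count and holes subtract. Coverage below 10%
marks a conservation gap; the area-fraction reading (rather than
centroid-in-polygon) is implied by a percentage threshold.

## SAR error models

Per-cell responses are regressed on standardized predictors under
$y = X\beta + u$, $u = \lambda W u + \varepsilon$, with $W$ a
k-nearest-neighbour adjacency symmetrized by union and row-standardized.
$\lambda$ maximizes the profile log-likelihood with the exact
log-determinant $\sum_j \log(1 - \lambda\,\mu_j)$ from the eigenvalues
$\mu_j$ of $W$ (computed once per $W$); $\beta$ and $\sigma^2$ follow by
GLS. At $\lambda = 0$ the fit reproduces OLS exactly. AICc uses
$q = p + 2$ parameters; the neighbour count is AICc-selected over a
candidate list (default 1–8, ties to the smaller k). Goodness of fit is
the Nagelkerke pseudo-$R^2$ against the intercept-only non-spatial
Gaussian model, rescaled to its attainable maximum, so the intercept-only
model scores exactly 0. Responses are fitted untransformed by default —
counts included — matching the usual SAR practice; a log1p transform can
be applied by the caller. Residual spatial structure is inspected with a
Moran's I correlogram over equal-width distance bins (binary in-bin
weights; expectation $-1/(n-1)$ under independence).

The collinearity screen mirrors the two-stage convention: repeatedly
drop the larger-VIF member of the worst pair with |Spearman ρ| ≥ 0.7,
then drop VIFs ≥ 10. Exact duplicates make the correlation matrix
singular; a tiny ridge keeps their VIFs finite (and enormous), so one of
them is dropped deterministically.

## The synthetic landscape

Because the original occurrence database is proprietary, every pipeline
stage is exercised on generated landscapes with *planted, recoverable*
structure (`synthetic_scenario()` and the `simulate_*` functions). The
standard scenario uses a 25 × 20 grid (500 cells; the 5 km national-grid
analogue at desk scale), 300 taxa with log-normal ranges (median 15
cells, σ = 0.75 on the log scale — right-skewed, as range-size
distributions are), the narrowest-ranged half flagged endemic, and
ranges realized as contiguous spreading-dye patches (hotspot geometry in
real floras is spatially coherent; a scatter mode exists for
comparison).

Planted structure:

* ten **paleo** lineages confined to a five-cell block, pendant branches
  stretched to 8× the median pendant of a Yule backbone — old, isolated,
  range-restricted;
* a twelve-taxon **neo** radiation confined to another five-cell block,
  crown depth 10% of its anchor branch — young, short-branched,
  range-restricted;
* within each block, every other planted taxon spans the whole block and
  the rest get random narrower patches, so each planted cell is
  guaranteed several planted lineages (recoverability) while range
  variation among them preserves the weighted-endemism contrast;
* environmental predictors as Gaussian random fields (exponential
  covariance, range 4 cell widths) with known effects
  $\beta = (1, -0.5)$ and error autocorrelation $\lambda = 0.6$ on k = 4
  weights;
* protected-area rectangles covering 80% of target cells at 36% of each
  cell's area (comfortably above the 10% gap rule), plus decoys.

What the planted taxa make true — and what passing tests therefore show —
is that cells concentrating range-restricted long branches classify as
paleo-endemism centres, cells concentrating a restricted recent
radiation as neo-centres, and that both kinds of planted cell top the
CWE ranking. What the generator does *not* emulate: taxonomically
structured sampling effort, spatially varying detectability, realistic
niche-driven range placement (ranges are placed independently of the
environmental fields), or coastline/irregular study regions. Results on
real data depend on those aspects; the tests certify the machinery, not
the biology.

The collinear-predictor generator deserves a note: its 34 redundant
columns mix a primary core (Pearson ≈ 0.8), a second core, a per-group
latent factor and a factor common to all derived columns. The latent
factors (not exposed as columns) are what make the construction
screen-stable: siblings cannot be combined to reconstruct their core, so
core VIFs stay bounded, while every derived column remains far better
predicted than any core at every stage of the iterative screen, whatever
the drop order. Without them, the iterative rule exhibits an exact
core/derived VIF symmetry and the screen's outcome is a coin flip.

## Numerical choices and problem sizes

* λ search: `optimize()` on the feasible eigen-interval, tolerance 1e-8;
  estimates within 1e-7 of zero snap to exactly 0 when the likelihood
  allows.
* Tie handling in rank p-values uses a 1e-12 relative tolerance so
  recomputed floating-point equalities still count as ties.
* Zero-length branches carry incidence but no PE weight; cells with zero
  comparison-tree PE or zero richness are excluded from ratios with a
  message, never NaN-propagated.
* Polygon geometry is exact up to floating point (slab sweep); coverage
  agreement to 1e-9 is asserted for cells wholly inside a polygon.
* Default problem sizes in tests and the acceptance script — 500-cell
  landscapes, 199 null reps, 100 SAR replicates at n = 400 — are chosen
  so each property is measured with comfortable statistical margin while
  a full run stays in the minutes range on a laptop; the study analogue
  of 999 reps is the package default for real analyses.

## Worked example

```{r example, eval = FALSE}
sc  <- synthetic_scenario(seed = 7)
com <- simulate_grid_community(sc)
tre <- simulate_endemism_tree(sc, com)

met <- cell_metrics(com$matrix, tre$tree)
em  <- subset_taxa(com$matrix, com$matrix$taxon_id[com$matrix$endemic])
nul <- null_pvalues(em, tre$tree, reps = 199, seed = 8)
cls <- classify_cells(nul)
glance(cls)

pri <- priority_hotspots(met[!is.na(met$CWE_END), c("cell", "CWE_END")],
                         met[!is.na(met$PE_obs), c("cell", "PE_obs")], "L3")
pa  <- simulate_protected_areas(sc$grid, pri$cells, 0.8, seed = 9)
glance(conservation_gaps(pri, cell_coverage(sc$grid, pri$cells,
                                            pa$polygons)))

autoplot(cls, sc$grid)
```

Or end to end, with every table written to disk and a hashed manifest:

```{r pipeline, eval = FALSE}
run_pipeline(list(reps = 199, seed = 7), out_dir = "run1")
```

## Known limitations

* The curveball null is stricter than a richness-only reallocation null;
  on real data the two can disagree for metrics dominated by very
  widespread taxa (use `null = "richness"` to compare).
* The SAR fit is maximum likelihood with dense eigendecomposition:
  appropriate to a few thousand cells, not to 10^5-cell rasters.
* Shapefile input is not supported; polygons are read from GeoJSON.
* Grafting places missing taxa uniformly among congeners at the terminal
  branch midpoint; no placement information beyond genus membership is
  used.
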