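---
title: "Size, shape and allometry from linear measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size, shape and allometry from linear measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsrmorph)
```

## The problem

Traditional morphometrics describes anatomical structures by sets of linear
distances (and sometimes angles). In studies of size evolution — insular
dwarfing being the classic case — the scientific question is rarely about raw
measurements: it is about *shape*, what remains of the geometry once overall
size is factored out, and about *allometry*, the part of shape variation that
is statistically predictable from size. `lsrmorph` implements this workflow
for wide-format measurement tables: one row per specimen, one column per
variable, linear distances in mm and angles in degrees.

The package was developed around equid cranial and endocranial data — it
ships variable catalogs for the horse cranium (9 linear measurements), the
bony labyrinth of the inner ear (7 linear measurements) and the brain
endocast (13 measurements: 9 linear, 4 angles) — but every function is
catalog-driven and applies to any measurement set.

## The model and the three treatments

With no body-mass datum per specimen and no reason to privilege one
measurement as "the" size variable, overall size is proxied by the
**geometric mean** of the specimen's linear measurements,

$$\mathrm{GM}_i = \Big(\prod_{j=1}^{n} x_{ij}\Big)^{1/n},$$

computed in log space for numerical stability. Angles do not scale with size
and never enter the GM.

Three data treatments feed the ordinations:

* **form** — the raw values; size and shape together.
* **log shape ratios** (Mosimann) — each linear variable becomes
  $\log(x_{ij}/\mathrm{GM}_i)$. Within each specimen these sum to zero
  exactly ($\sum_j \log(x_{ij}/\mathrm{GM}_i) = \log\prod_j x_{ij} -
  n\log \mathrm{GM}_i = 0$), and they are invariant to uniform rescaling of
  the specimen. Angle variables pass through unchanged.
* **allometry-free shape** — ordinary least-squares residuals of each raw
  variable on GM (intercept and slope). Residualizing each response
  separately is identical to taking the residual matrix of the multivariate
  linear model of all variables on GM, so no multivariate test machinery is
  needed to define it. Each residual column is exactly zero-mean and has
  zero sample covariance with GM.

Each treatment is ordinated by **covariance PCA** (centering, no unit
variance scaling — within a treatment the variables are commensurate),
computed by singular value decomposition of the centered matrix with the
$n-1$ covariance divisor. All components are retained; reporting usually
shows PC1–PC2, but truncation is presentation-only.

**Allometry** is then assessed in the multivariate tradition of Jolicoeur:
the PC1 scores of the *log-shape-ratio* PCA — the dominant direction of
size-corrected shape variation — are regressed on $\log(\mathrm{GM})$, the
slope is tested with the single-covariate ANOVA F-test on $(1, n-2)$ degrees
of freedom, and $R^2$ (the squared correlation of PC1 scores with log size)
quantifies how much of that shape axis size explains. $R^2$, $F$ and the
p-value are invariant to the log base and to the arbitrary sign of PC1; the
package always reports $R^2$ together with the significance flag, so a
convention of quoting $R^2$ only when the test is significant is a view on
the output, not an information loss.

## Sampling rules

Two filters encode the inclusion rules of a careful comparative design:

* `filter_mature()` keeps only specimens whose maturity is positively
  recorded as `mature`. Specimens with unknown maturity are dropped by
  default — maturity must be established, not assumed — with
  `unknown = "keep"` as an explicit override.
* `filter_complete()` applies listwise deletion: a specimen missing any
  catalog variable is excluded. No imputation is offered; with the small
  samples typical of this field, an imputed cranium is a fabricated cranium.
  Consistently with this, `read_measurements()` coerces unparseable cells,
  non-positive lengths and out-of-range angles to missing with a warning,
  so one bad cell costs at most one specimen, never the run.

## Deterministic axis orientation

The sign of every principal axis is arbitrary. To make outputs
bit-reproducible across runs and platforms — and because published loading
plots are only interpretable relative to a sign convention —
`orient_axes()` flips each component, when needed, so that its largest
absolute loading is positive (ties broken by lowest variable index). Scores
are flipped consistently; variance decompositions, and the allometry
$R^2$ downstream, are unaffected.

## The synthetic generator

`simulate_measurements()` draws tables from the standard log-linear
allometric model

$$\log x_{ij} = \alpha_j + \beta_j \log s_i + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma_j^2),$$

with a log-normal latent size $s_i$ per group (so all measurements are
positive by construction), optional group-specific log-scale shape offsets,
and size-independent truncated-normal angles. $\beta_j = 1$ for all $j$ is
isometry; under it the linear log-shape-ratio columns reduce to
$\alpha_j - \bar\alpha$ plus centered noise, carrying no size signal. With a
spread of exponents and no noise, the shape matrix is exactly rank one in
$\log s$: the log-shape-ratio PC1 explains 100% of the variance, its
loadings are proportional to $\beta_j - \bar\beta$, and the allometry test
returns $R^2 = 1$. These closed-form corners anchor the test suite; the
stochastic middle ground is covered by seeded recovery and calibration
checks.

Ground truth (latent sizes, exponents, group labels) travels in a sidecar
record, never inside the table, so synthetic and real tables are
format-identical.

Three canned scenarios document the design space:

* `isometric_null` — one population of 60, all $\beta_j = 1$,
  $\sigma_j = 0.05$: the null of the allometry test.
* `island_dwarf` — a comparative sample of 138 (typical GM around 170 mm,
  log-size SD 0.15) against an island group of 35 (around 125 mm, SD 0.08),
  with rostrum-style exponents: facial lengths positively allometric
  ($\beta$ up to 1.25), transverse widths negatively ($\beta$ down to
  0.80), so small specimens are relatively wide-snouted. Group sizes mirror
  the sampling scale of published comparative cranial datasets in this
  field while keeping the whole test suite fast.
* `two_archipelago` — two independently dwarfed island groups of distinct
  sizes plus the comparative sample.

What the generator does **not** emulate: measurement error correlated
across variables, within-group breed substructure, non-linear (curvilinear)
allometry, sexual dimorphism, and missingness mechanisms. Passing the
recovery and calibration checks therefore demonstrates that the pipeline's
algebra and inference behave correctly under the model the analysis itself
assumes — not that any particular empirical dataset satisfies that model.

```{r example}
sim <- simulate_measurements(make_scenario("island_dwarf"))
tab <- filter_complete(filter_mature(sim$table))
model <- fit_pca(log_shape_ratios(tab))
fit <- allometry_test(model$scores[, 1], model$size)
fit
```

## Numerical choices and degenerate inputs

* Natural logs throughout; the allometry $R^2$ and p-value are log-base
  invariant, so the choice is consequence-free (tested to 1e-10).
* GM in log space (`exp(mean(log(x)))`): immune to overflow of the raw
  product.
* Residualization regresses raw variables on raw GM, not log on log — the
  allometry-free treatment removes the linear size trend from the variables
  as measured.
* PCA refuses constant matrices (zero total variance), fewer than 2
  specimens or variables, and any missing cell. `allometry_free()` requires
  at least 3 specimens (a two-parameter fit on 2 points leaves identically
  zero residuals) and non-constant GM. `allometry_test()` requires
  $n \ge 3$ and non-constant log size.
* Test tolerances: exact algebraic identities (zero sums, orthogonality,
  eigen-vs-SVD agreement) are asserted at 1e-8 to 1e-12; stochastic checks
  are seeded and asserted inside pre-registered bands (e.g. the null
  rejection rate across 200 replicates within [0.02, 0.09], a 99% binomial
  band around 0.05).

## Open design points, resolved

* **GM variable set.** The cranial GM uses all nine cranial measurements.
  For structures whose catalogs mix kinds, the GM is computed over the
  *linear* variables only: angles are dimensionless and size-free, and a
  "mean size" that averaged millimetres with degrees would be physically
  meaningless.
* **Angles in residualization.** Whether angles should be residualized on
  size is a genuine modelling choice: an angle can correlate with size even
  though it does not scale. The default residualizes the full raw variable
  set (`include_angles = TRUE`); `FALSE` passes angles through raw, as the
  log-shape-ratio treatment always does.
* **The endocast angle count.** The shipped endocast catalog carries 13
  variables, 9 linear and 4 angles (IHA, HPA, CSA, OFA). Descriptions of
  this measurement set sometimes state "three angle measurements" while
  defining four; the catalog follows the defined set of 13, and this
  discrepancy is surfaced here rather than silently resolved.
* **Group assignment** lives entirely in configuration
  (`assign_groups()`, `group_map`): any division of breeds into analysis
  groups is an interpretive choice, and the package refuses to hard-code
  one.

## Limitations

* Traditional linear measurements only: no landmark/Procrustes mode, no 3D
  mesh input, no measurement acquisition.
* The allometry test regresses a PCA summary, PC1, on size; when size-related
  shape variation is spread across several components, PC1-based $R^2$
  understates total allometry.
* Listwise deletion can discard many specimens from sparsely measured
  tables; that is by design, but it is a real cost.
* Monte-Carlo checks in the test suite use moderate problem sizes (tables of
  15–173 specimens, 200 calibration replicates, 50-seed recovery sweeps),
  chosen as the package's own compromise between statistical resolution and
  a fast, fully reproducible suite.
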