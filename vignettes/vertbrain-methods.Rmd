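---
title: "Methods: comparative models of vertebrate brain-size evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative models of vertebrate brain-size evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`vertbrain` implements a comparative-phylogenetics workflow for studying
encephalization across vertebrate classes: why relative brain size varies
by orders of magnitude among lineages, and how parental provisioning
(measured through newborn or hatchling size) and body temperature jointly
predict it. The package covers five stages:

1. **Trait harmonization** — converting heterogeneous newborn-size records
   (hatchling lengths, egg diameters, egg masses) to grams, allometric
   quality control of specimen-level brain data, BMR averaging, and
   transformation/scaling for modeling.
2. **Dated supertree assembly** — grafting class-level chronograms at
   calibrated last-common-ancestor (LCA) ages.
3. **PGLS** with Pagel's lambda estimated by REML or ML.
4. **A Bayesian phylogenetic mixed model** (animal model) fit by Gibbs
   sampling with parameter-expanded variance priors.
5. **Phylogenetic path analysis** over candidate causal graphs
   (d-separation tests, Fisher's C, CICc ranking and averaging).

A synthetic trait-evolution generator produces data with the statistical
structure these stages assume, so the entire pipeline is validated by
parameter-recovery experiments without any external download.

# Models and assumptions

## Phylogenetic covariance and Pagel's lambda

For an ultrametric tree, `shared_path_covariance()` builds the Brownian
expectation: entry (i, j) is the age-depth of the most recent common
ancestor of tips i and j; the diagonal is the root age. Multifurcations
are left unresolved — the covariance represents them naturally. Pagel's
lambda multiplies the off-diagonal entries only; lambda = 0 is a star
phylogeny (independent tips), lambda = 1 the full Brownian structure.

All fitting routines normalize the covariance to correlation form (unit
diagonal) first and let the residual variance absorb the scale. On trees
more than 500 Myr deep this is a numerical-conditioning decision: raw
entries span hundreds of Myr while the model's variances are order one.
A convenient consequence is that the lambda transform of a unit-diagonal
matrix, `lambda * C + (1 - lambda) * I`, shares the eigenvectors of `C`,
so the lambda profile costs one eigendecomposition regardless of how many
lambda values are visited. `precompute_eigen()` exposes the cache for
workflows (path analysis) that fit hundreds of small models against one
tree.

## Supertree grafting

`graft_supertree()` consumes a schedule of `(clade_a, clade_b, age)`
steps; each step joins the running components containing the two clades
under a new root at the stated age, with stem branches making the result
ultrametric. The packaged default schedule holds the eight vertebrate
calibrations (Aves+Crocodylia 244.8 Myr through Agnatha 563.4 Myr) as
data, not code, so updated calibrations are a file edit. Serialization
uses 17 significant digits, which round-trips IEEE doubles exactly;
within-clade patristic distances therefore survive grafting bit-for-bit.

## PGLS

`fit_pgls()` computes the GLS estimator with `V(lambda)` and maximizes
the restricted likelihood over lambda in [0, 1] by bounded scalar search
(tolerance 1e-6) with explicit endpoint checks, since the optimum is
frequently at a boundary. REML is the default because at comparative
sample sizes ML's variance-component bias propagates into lambda; ML
remains available (`method = "ML"`) and is what external references such
as `nlme::gls` + `corPagel` use, which the test suite exploits as an
independent cross-check. d-separation p-values use the t distribution
with n - p degrees of freedom.

## The animal model and its sampler

The mixed model is `y = X beta + u + e`, `u ~ N(0, sigma2_phylo * A)`,
`e ~ N(0, sigma2_res * I)`, with `A` the phylogenetic correlation matrix.
The Gibbs sampler works in the eigenbasis of `A`, where the rotated
random effects have a diagonal covariance and every full conditional is
cheap; the inner loop is compiled (Rcpp) and draws through R's RNG, so
`set.seed()`/`chain_spec(seed=)` makes chains exactly reproducible.
Ancestral (node) effects are never sampled — only tip effects with
covariance `A` — which leaves the likelihood identical with a smaller
state.

Priors follow the usual animal-model conventions: the residual variance
is inverse-gamma, written as a one-dimensional inverse-Wishart with
V = 1 and nu = 0.002 (shape nu/2, rate nu*V/2 — nearly flat); the
phylogenetic variance uses parameter expansion (`u = alpha * eta`,
`alpha ~ N(0, 100000)`, nu = 1 on the expanded variance), whose marginal
prior on the phylogenetic standard deviation is a weakly informative
half-Cauchy. Parameter expansion is not cosmetic: it keeps the chain
mixing when `sigma2_phylo` is near zero, exactly where a plain
inverse-gamma Gibbs step stalls. Fixed effects get an (effectively) flat
normal prior whose precision is exposed because the suite's
simulation-based calibration check needs a proper prior to draw from.

Chain defaults are 500,000 iterations, 100,000 burn-in, thinning every
40 — hence 10,000 stored draws. Summaries report the posterior mean, a
central 95% quantile interval (chosen over HPD because it needs no
density estimation and is exactly reproducible), the effective sample
size by the initial-positive-sequence rule, and pMCMC = twice the smaller
tail fraction of the coefficient's sign, floored at one over the stored
draw count and printed as `<0.001` below that threshold. The
phylogenetic signal reported as lambda is the per-draw ratio
`sigma2_phylo / (sigma2_phylo + sigma2_res)`, summarized by its posterior
mean and interval; being a ratio it is invariant to rescaling the
response. Coefficients are reported on the scale of the model frame; see
the scaling conventions below for mapping back to raw log10 units.

## Phylogenetic path analysis

Candidate causal structures are DAGs over six traits: ambient
temperature (Ta), body temperature (Tb), residual BMR, residual newborn
size (NM), adult body mass and residual brain size. BMR, newborn and
brain sizes enter as residuals from a regression on body mass because
BMR and body mass are nearly collinear, and `residualize()` implements
that step. For each DAG, `basis_set()` emits one independence claim per
nonadjacent pair, conditioned on the union of both nodes' parents — the
standard convention of PGLS-based path analysis — with the later node in
the causal order as the regression response. Claims are tested by PGLS;
Fisher's C = -2 * sum(log p) aggregates them (chi-squared, 2k df).
Models passing the C test (p > 0.05, configurable) are ranked by
CICc = C + 2qn/(n - 1 - q) with q = edges + nodes (each node contributes
a residual variance); models within Delta-CICc < 2 are averaged with
weights proportional to `exp(-Delta/2)`. Averaging is "full" by default
(an edge absent from a model contributes zero), with conditional
averaging behind a flag; full averaging had to be pinned down for
reproducibility and shrinks weakly supported paths toward zero, which is
the conservative direction.

The packaged set of 10 candidates is a **declared placeholder**: the
topologies cross the orientation of the temperature-metabolism link
(Tb -> BMR with Ta -> Tb, versus BMR -> Tb) with five direct-to-brain
parent sets drawn from {Ta, Tb, BMR}, on a common backbone
(body -> NM, NM -> brain, Ta -> BMR). Any candidate family can be
supplied as JSON.

# Scaling conventions

Masses are log10-transformed first, then z-scored; the order matters and
is fixed. z-scoring uses the **population** SD (root-mean-square
deviation), so {1, 2, 3} maps to (-1.2247, 0, 1.2247). Temperatures are
handled in degrees Celsius and z-scored without a log. Egg-care levels
form an ordered vocabulary (abandon < guard < bear < provision) but are
modeled as an unordered factor with "abandon" as reference, because the
analyses interpret per-level contrasts; the ordering is kept for
presentation. Missing data are handled per model (complete cases), with
the dropped-row count attached to every model frame, since different
analyses legitimately use differently sized subsets.

# Quality-control filters

The brain-data filter applies two tiers. Species with at least five
specimens are judged within-species: log10 brain is regressed on log10
body across the species' specimens and the species is removed if any
specimen's ratio of observed to predicted log10 brain leaves
[0.8, 1.2]. Smaller species are judged against their genus with the
wider band [0.6, 1.7]. Two implementation decisions matter here. First,
the bounds are read literally as ratios of log10 values, which makes the
filter scale-dependent (a fixed multiplicative error moves the ratio by
`log10(factor) / predicted`); the QC report exposes every ratio so a
residual-based alternative can be audited. Second, the genus reference
regression holds the focal species out: if the species under test is
itself grossly erroneous, including it would drag the reference fit and
flag clean congeners. The genus rule needs at least three other species
with data; below that the species is passed through flagged
"unfilterable" rather than silently dropped. A two-point regression fits
perfectly and filters nothing, which is why the threshold is three.

BMR records are averaged only within +/-20% of the species mean body
mass, and the conversion helpers implement the unit chain: length-weight
allometries (`a * L^b`), sphere-volume egg masses at density 1 g/cm^3,
and the log10-linear egg-to-hatchling regression (slope 0.936, intercept
-0.158 for birds). Turtle and crocodile egg masses pass through an
`identity` conversion unchanged.

# The synthetic generator: what it emulates and what it does not

`simulate_traits()` generates, on an ultrametric tree: Brownian log10
body mass (rate 0.01 per Myr around a 1 kg ancestor, giving roughly
vertebrate-scale spread at 100 Myr); an egg-care state evolving by a
stepwise Markov process between adjacent levels (rate 0.02 per Myr, so
roughly one or two transitions per root-to-tip lineage); log10 newborn
mass as an allometry on body mass (slope 0.75) shifted upward by care
level (0, 0.25, 0.5, 0.8 log10 units — monotone, emulating the observed
ordering of relative newborn size across care categories); body
temperature drawn per class around class means with a 50% heritable
(phylogenetically structured) component; and the brain response built
from the configured coefficients on the z-scored predictors plus a
phylogenetic residual with tunable lambda. Default truths are the
headline estimates of the among-vertebrate analysis (body 0.648,
newborn 0.286, temperature 0.187, interaction 0.109;
sigma2_phylo = 0.97, sigma2_res = 0.03, hence signal 0.97). When the
tree comes from `graft_supertree()`, tips carry their clade of origin
and classes are clades, so among-class analyses see realistic
deep-phylogeny confounding.

Because predictors are standardized inside the generator, the configured
betas are the exact estimands a refit recovers when the model frame
z-scores the predictors and leaves the response unscaled. What passing
recovery tests on these data shows is that the estimation machinery is
correct and calibrated **under the generating model**; it does not show
robustness to the many features of real comparative data the generator
omits: intraspecific variation and measurement error (beyond planted
multiplicative outliers), sampling biases across clades, non-Brownian
trait evolution, correlated predictor noise, or taxonomic error.

The specimen-level QC generator emulates a small-bodied ray-finned-fish
assemblage: genera sharing a tight allometry (slope 0.5, residual SD
0.05 log10 units), body masses around 100-2000 g and brain masses around
0.1-0.6 g. That regime is where the ratio-of-logs filter is sharp: with
predicted log10 brain between about -1.1 and -0.3, a 3x brain-mass error
moves the genus-rule ratio far outside [0.6, 1.7] while clean species
stay inside. For much larger brains (predicted log10 brain near or above
1) the same multiplicative error moves the ratio only slightly — a
documented property of the published filter, not of this implementation.

# Validation experiment sizes

The recovery experiments the package ships run at sizes chosen to
estimate the quantities they report with useful precision: coefficient
and signal recovery uses 300-tip trees with reduced chains (50,000
iterations, 10,000 burn-in, thin 40) across 100 replicates in the test
suite (60 in the acceptance script); path-model selection uses 100
replicates at n = 300; simulation-based calibration uses 120 prior-draw
datasets on 50-tip trees with short proper-prior chains; the QC
experiment plants 3x errors in 5% of 320 species. The null-calibration
check for d-separation p-values uses 200 simulations at n = 500 on a
star phylogeny, where the PGLS test reduces to OLS and uniformity is
exact.

# Numerical choices and degenerate inputs

- Ultrametricity tolerance: relative 1e-6 on root-to-tip depth
  (published chronograms carry rounded branch lengths).
- Covariance admissibility: smallest eigenvalue >= -1e-8 times the
  largest; tiny negative eigenvalues are clamped to zero.
- A graft step younger than a joined subtree's root age is an error
  (negative stem); an age exactly equal to the root age gives a
  zero-length stem and stays ultrametric.
- Zero-variance predictors error out everywhere (z-scoring, OLS,
  residualization) rather than propagating NaN.
- A saturated path model (no nonadjacent pairs) gets C = 0, df = 0,
  p = 1 and is flagged, not silently ranked; a p-value of exactly zero
  in Fisher's C is an error telling the caller to floor upstream.
- Divergent variance draws abort the sampler with the iteration and
  state in the message.
- The pMCMC floor is 1/(stored draws); the printed form `<0.001`
  matches the reporting convention of comparative tables.

# Known limitations

- Gaussian responses only; no multi-response models, no within-species
  repeated measures (species means are assumed).
- Lambda is the only correlation transform (no OU or kappa).
- The candidate DAG family is a placeholder where the original ten
  topologies are not published; conclusions about model selection apply
  to the family actually supplied.
- The QC filter inherits the scale dependence of its published
  definition (see above).
- Single-chain inference by default; a multi-chain R-hat workflow can be
  built from the exposed draws but is not automated.
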