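---
title: "Inferring subterranean connectivity and conservation priorities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring subterranean connectivity and conservation priorities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavenet)
```

## The model in one paragraph

Troglobites cannot maintain surface populations, so when two caves share
troglobitic species — or host closely related ones — the most parsimonious
explanation is dispersal through the subterranean void network. `cavenet`
operationalizes this: community similarity between caves is modeled as a
function of geographic distance and environmental contrasts; the distance
range of significant spatial autocorrelation and the per-predictor
difference thresholds (breakpoints) below which pairs remain similar define
*potential pairwise connectivity* (CPC); the resulting weighted graph is
mined for clusters, bridges, and singular caves that anchor conservation
priorities.

## Similarity representations

Abundances are transformed as `log(x + 1)` (natural log; the base is
configurable). The phrase "standardized and log-transformed" admits two
readings; the package logs first and makes per-species maximum
standardization an explicit switch, **off** by default — reproducibility
needs one default, and the off position follows the only transformation
defined exactly (`log(x + 1)`).

*Composition* uses Bray–Curtis dissimilarity,
`BC = Σ|x_i − x_j| / Σ(x_i + x_j)`; percent similarity is `100(1 − BC)`. A
pair of caves both lacking the focal species set has no defined value; the
pipeline assigns BC = 1 (maximally dissimilar) with a warning, since for
troglobite-only analyses empty caves are common and must stay in the graph
node set.

*Phylogenetic* similarity uses taxonomic distances: ranks form an
ultrametric tree, and the species-to-species distance is the number of rank
steps climbed to the lowest shared taxon, divided by the number of ranks, so
congeners sit at `1/L` and species sharing nothing at 1. Between-community
distance is the mean pairwise distance (MPD) across the two species sets,
unweighted by default (matching the common between-community MPD default);
abundance weighting is available. Pairs involving an empty community are
imputed at the observed maximum (configurable to an error): an empty cave
carries no evidence of relatedness.

Two ordination inputs are supported for the phylogenetic approaches: PCoA of
the MPD matrix treated directly as distances (default) or of Euclidean
distances among MPD row vectors (the literal two-step construction). The
MPD matrix can be non-Euclidean; negative PCoA eigenvalues are reported, and
no Lingoes/Cailliez correction is applied — only real positive axes are
used downstream, and DistLM works on the (always Euclidean-behaved)
Gower-centered traces regardless.

## Spatial autocorrelation

Moran's I is computed per distance class with symmetric binary weights;
classes are equal-width over the observed pairwise distances, with the
count defaulting to Sturges' rule on the number of pairs. Significance is by
Monte-Carlo permutation of the values (999 by default, two-sided around the
null expectation `−1/(n−1)`), chosen over the normal approximation because
ordination scores are routinely skewed; the normal option remains available.
Progressive Bonferroni tests the k-th class at `α/k`, each class
independently — isolated significant classes at large distance are
therefore possible.

The *significant range* — the CPC distance criterion — is the upper bound
of the largest corrected-significant class with **positive** I (similarity,
not dispersion). A caveat discovered while validating this rule on fields
with a known planted range: when short-range autocorrelation is strong, the
per-class permutation tests at unstructured long-range classes are
anticonservative (the exchangeable null is false globally), and the
"largest significant class" occasionally jumps to an isolated long-range
false positive even after progressive correction. The default follows the
stated rule; `significant_range(x, rule = "contiguous")` returns the end of
the initial contiguous run of significant positive classes, which in
simulations recovers a planted range within one class width in ≥ 90% of
runs. Users zoning landscapes should compare both.

By default only MDS1 is tested per similarity approach (one correlogram per
approach); a multi-axis policy taking the maximum range over axes is
available.

## Distance-based linear modeling

The pseudo-F statistic is the trace form on the Gower-centered matrix
`G = C(−D²/2)C`: explained traces under the hat matrices of the added and
conditioned designs, residual trace in the denominator with `n − q − 1`
degrees of freedom. On Euclidean distances of univariate data this equals
the classical regression F exactly (tested to 1e-8), which is the main
correctness anchor.

Permutation p-values use Freedman–Lane residuals of the reduced model
(`G* = H₀GH₀ + P((I−H₀)G(I−H₀))Pᵀ`); with nothing conditioned this is an
exact relabeling of observations, verified against full enumeration at
n = 4. Forward selection maximizes the cumulative adjusted R²
`1 − (1−R²)(n−1)/(n−q−1)` over predictor *sets* (categorical levels enter
as indicator blocks, ordinal predictors as integer level codes, the
coordinate pair as a single "Distance" set) and stops when no candidate
improves adjusted R² or the best candidate's permutation p reaches α.
Exact p-values from a proprietary implementation of the same model will
differ slightly — permutation schemes and tie handling vary — so
selection *order* is the comparable output, not the third decimal of p.

## Breakpoints

Pair-level responses (percent similarity for composition, MPD for
phylogeny) are modeled against pairwise predictor differences with a
Gaussian GLM under a logistic link, so responses are first mapped into
(0, 1): percent / 100, MPD min-max scaled to `(ε, 1−ε)`, `ε = 1e-6`,
parameters stored for inversion. MPD is a distance, so the pipeline models
`1 −` scaled MPD; one orientation convention ("similarity decreases with
difference; the favored region lies below ψ") then covers all responses,
with a warning if a fitted pre-break slope is positive.

The breakpoint ψ is estimated by iterative linearization: fit
`y ~ x + U + V` with `U = (x−ψ)1[x>ψ]`, `V = −1[x>ψ]`, update
`ψ ← ψ + γ̂_V/β̂_U`, stop when the working coefficient vanishes
(tol 1e-6, max 50 iterations). Because the iteration is
initialization-sensitive, it multi-starts from the quartiles of x and keeps
the best-AICc fit. The segmented model (k counts the breakpoint as a
parameter) is chosen over the linear GLM iff its AICc is lower, and is
*significant* when additionally the 95% CI of ψ stays inside the observed
predictor range. Ordinal thresholds are floored to whole level steps.
Against an independent profile-RSS grid search the iteration agrees to
< 0.1 on simulated data; its 2·SE interval covers the true knot at
approximately the nominal 95%.

Categorical predictors get contrasts of each pair-category combination mean
against the grand mean of combination means. With the single-step (max-t)
machinery unavailable here, adjustment is Bonferroni — conservative, which
errs against declaring favored combinations. Favored = significantly
*above* the grand mean (higher similarity).

## Graphs, weighting, exclusion

Four CPC graphs are built for the troglobite approaches only: distance-rule
graphs (edge iff `d ≤` significant range — boundary inclusive) and
breakpoint-rule graphs (edge iff the pair satisfies **all** favored-region
rules; thresholds are inclusive, mirroring the distance rule; an empty rule
set yields the complete graph as a vacuous conjunction). Edges are
validated when supported by at least one composition and one phylogeny
graph — identity and dispersal capability respectively — and weighted 2–4
by support count. Edges between two troglobite-free caves are removed
(joint absence suggests unsuitable habitat); mixed edges stay (absence may
be a sampling false negative).

Clustering is Girvan–Newman edge betweenness with the partition chosen at
maximum modularity, run unweighted by default: the weight semantics passed
to a shortest-path-based algorithm are ambiguous (weight-as-distance would
invert meaning), so the default ignores weights and a `1/weight` distance
mode is opt-in. Bridge caves are ranked by unweighted betweenness; the full
ranking is reported with a configurable top-k, since any published cutoff
of "the top few" is arbitrary.

## Singularity and priorities

`Sc = (STR_Ω/STR_TOT)/(D_Ω/D_MAX)` with `D_MAX = n − 1` by default (the
maximum number of possible distinct connections; an observed-max-degree
mode exists) and degree taken on the final parsimonious graph. An isolated
cave hosting troglobites gets `Sc = +∞` — an isolated endemic habitat is
the strongest possible priority — serialized as the string `"inf"` with an
explicit flag. Priorities are `Sc > 1`, strictly. Influence of neighbors on
a priority cave is graded by distinct incident edge weights (highest =
high, then medium, low); secondary priorities are high-influence neighbors
hosting at least one troglobite ("significant presence" is unquantified in
the source; ≥ 1 is the default, configurable) that are not priorities
themselves.

## The synthetic world

`synth_generate()` produces what the analysis assumes: 69 caves in 6
spatial clusters (grid spacing 2000 m, within-cluster jitter sd 250 m —
kilometer-scale geometry typical of canga plateaus); 8 numeric predictors
with between-cluster contrast plus exponential-covariance spatial noise
(range 800 m), an ordinal granulometry and a categorical hydric regime with
cluster-dominant levels; 9 troglobites whose occupancy is a 600 m dispersal
radius around cluster-center home points, with 2 pinned to single caves
(planted `Sc > 1` targets); 60 surface species with logistic occupancy
along the forest-cover gradient; negative-binomial abundances (mean 20,
dispersion 1 — strongly overdispersed, as arthropod counts are); taxonomy
by recursive random grouping over six ranks. Counts and scales not fixed by
the motivating system were chosen once as field-plausible and are not
tuned.

What a green end-to-end test establishes: with cluster-structured
communities and env fields, the pipeline's detected graph clusters match
the planted spatial clusters (median ARI ≥ 0.8 over 20 seeds) and planted
endemic caves are recovered as priorities (median recall ≥ 0.8). What it
does **not** establish: behavior under gradual (non-clustered) spatial
structure, unbalanced sampling effort, taxonomically structured endemism,
or detection/identification error — none of which the generator emulates.

## Numerical choices and degenerate inputs

Permutation p-values are `(1 + #{T* ≥ T})/(1 + n_perm)` with fixed,
recorded seeds; permutation counts are 999 by default and deliberately
smaller in tests (run-time budget; the tested effects do not hinge on p
resolution). Dissimilarity symmetry is enforced to 1e-12; PCoA axes below
`1e-10 ×` the leading eigenvalue are treated as null. Constant variables,
empty distance classes, all-coincident caves, rank-deficient designs and
`n_perm < 1` raise errors naming the offender; empty classes are flagged
and excluded from testing rather than silently dropped. The pipeline seeds
every stochastic stage from one master seed, so reruns are bit-identical.

## Known limitations

- The "largest significant class" range rule inherits the long-range
  anticonservativeness of per-class correlogram tests (see above).
- DistLM p-values are implementation-specific; only selection order and
  magnitudes transfer across implementations.
- Taxonomic MPD is a coarse proxy for phylogeny: no branch lengths, and
  rank steps are treated as equidistant.
- One breakpoint per predictor; thresholds from pair-level models are
  marginal, not joint, so conjoining all rules into edges is conservative.
- Singularity treats all troglobitic species as exchangeable; rarity
  weighting is out of scope.
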