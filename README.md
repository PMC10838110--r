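# cavenet

Subterranean connectivity networks and conservation priorities for cave
communities.

## The problem

Iron-ore (canga) caves harbor troglobites — obligate subterranean species
that cannot survive at the surface and disperse only through the void
network of the ferruginous matrix. Conservation decisions are usually made
cave by cave, ignoring that cave communities interact through this hidden
matrix. `cavenet` infers *potential pairwise connectivity* (CPC) between
caves from community similarity and turns it into a weighted graph that
supports reserve-design decisions: which clusters of caves function as one
system, which singular caves deserve individual protection, and which
neighbors influence them.

It is aimed at community ecologists and conservation planners holding three
tables: a cave table (coordinates + environmental predictors), a cave ×
morphospecies abundance table, and a species table (taxonomy + troglobite
flags).

## The method

1. **Similarity.** Four views of between-cave similarity: Bray–Curtis
   dissimilarity of `log(x+1)` abundances (all species / troglobites only),
   and taxonomic mean pairwise distance (MPD) on a rank-tree metric
   normalized to [0, 1] (all species / troglobites only), each ordinated by
   PCoA.
2. **Spatial range.** Moran's I correlograms on the ordination axes with
   progressive Bonferroni correction (class *k* tested at α/k) give the
   distance range over which communities are significantly similar.
3. **Drivers.** Distance-based linear models (DistLM): pseudo-F via Gower
   centering, Freedman–Lane permutation p-values, and forward selection of
   predictor sets by adjusted R².
4. **Thresholds.** Segmented (breakpoint) Gaussian-logit GLMs of pairwise
   similarity against pairwise predictor differences estimate the
   difference ψ below which a pair of caves counts as similar; model choice
   by AICc against the linear fit; categorical predictors via contrasts of
   favored category combinations.
5. **Graphs.** Four CPC graphs (composition/phylogeny × autocorrelation
   range/breakpoint rules) for the troglobite similarity. An edge is
   validated if supported by ≥ 1 composition *and* ≥ 1 phylogeny graph;
   its weight (2–4) counts the supporting graphs; edges joining two
   troglobite-free caves are excluded. On this parsimonious graph:
   density, Girvan–Newman edge-betweenness clusters with modularity, and
   betweenness "bridge" caves.
6. **Priorities.** Singularity
   `Sc = (STR_cave / STR_total) / (degree / D_max)`; caves with `Sc > 1`
   are top conservation priorities; their neighbors are graded
   high/medium/low influence by edge weight; high-influence
   troglobite-hosting neighbors become secondary priorities.

A synthetic cave-system generator (`synth_generate()`) with known ground
truth (spatial clusters, planted endemic caves, dispersal radius) makes the
whole pipeline testable end to end.

## Worked example

```r
library(cavenet)
sys <- synth_generate(synthetic_config(seed = 7))   # 69 caves, 6 clusters
res <- run_cave_pipeline(sys$caves, sys$community,
                         pipeline_config(n_perm = 199, seed = 7))
print(res$distlm$comp_troglobites)
#> distlm forward selection (alpha = 0.05 , n_perm = 199 )
#>               set  adjR2     R2 pseudo_F     p
#>          Distance 0.3034 0.3239   15.808 0.005
#>      Scarp height 0.4754 0.4985   22.632 0.005
#>  Maximum humidity 0.6318 0.6534   28.615 0.005
#>  ...
#> stop: best candidate 'Bat guano' p = 0.1 >= alpha
cat(sprintf("density = %.3f, clusters = %d, modularity = %.3f\n",
            res$density, res$clusters$n_clusters, res$clusters$modularity))
#> density = 0.146, clusters = 6, modularity = 0.832
print(res$report)
#> priority_report: 69 caves, STR_TOT = 9, D_MAX = 68
#>   11 priority caves (Sc > 1): CV001, ..., CV057
#>   7 secondary priorities: CV049, ..., CV058
str(recovery_metrics(res, sys$truth))
#> $ cluster_ari    : num 1      # planted spatial clusters recovered exactly
#> $ priority_recall: num 1      # both planted endemic caves flagged
#> $ range_error_m  : num 245    # detected range vs planted dispersal radius
```

Reading: the forward selection finds geographic distance plus habitat
predictors driving troglobite-composition similarity (cumulative adjusted
R² 0.80); the parsimonious graph keeps 14.6% of possible connections and
splits into the 6 planted clusters (modularity 0.83); 11 caves have
`Sc > 1` — the cave's share of the 9 troglobitic species exceeds its share
of possible connections — including both planted endemic caves.

### Input schemas

- `caves.csv`: `cave_id, easting_m, northing_m, <predictor columns>`
  (planar UTM meters, one zone).
- `community.csv` (long): `cave_id, species_id, season, abundance`
  (seasons are pooled by default).
- `species.csv`: `species_id, <rank columns coarse→fine>, troglobite`
  (0/1).
- `predictor_meta.csv` (optional): `name, kind, unit, group, levels` —
  declares each predictor `numeric`, `ordinal` (with `|`-separated level
  order) or `categorical`, and groups predictors into DistLM sets.

Outputs per run: correlogram/DistLM/breakpoint/cluster/metric TSV tables,
GraphML + edge-list CSV of the parsimonious graph, `priorities.json`, and a
provenance log.

### Command line

```sh
Rscript inst/cli/cavenet.R synth --out mysystem
Rscript inst/cli/cavenet.R run --caves mysystem/caves.csv \
    --community mysystem/community.csv --species mysystem/species.csv \
    --meta mysystem/predictor_meta.csv --out myrun
Rscript inst/cli/cavenet.R report myrun
```

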