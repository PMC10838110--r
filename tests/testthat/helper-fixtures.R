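# shared fixtures, built in code

toy_cave_df <- function() {
  data.frame(
    cave_id = c("A", "B", "C"),
    easting_m = c(0, 500, 1300),
    northing_m = c(0, 0, 0),
    scarp_height_m = c(10, 12, 20),
    granulometry = c("sand", "sand", "silt"),
    hydric_features = c("dry", "perennial", "perennial"),
    stringsAsFactors = FALSE
  )
}

toy_predictor_meta <- function() {
  data.frame(
    name = c("scarp_height_m", "granulometry", "hydric_features"),
    kind = c("numeric", "ordinal", "categorical"),
    unit = c("m", "level", "category"),
    group = c("Scarp height", "Granulometry", "Hydric features"),
    levels = c(NA, "silt|sand|granule", "dry|intermittent|perennial"),
    stringsAsFactors = FALSE
  )
}

toy_caves <- function() cave_table(toy_cave_df(), toy_predictor_meta())

toy_taxonomy <- function() {
  data.frame(
    species_id = paste0("s", 1:5),
    phylum = c("p1", "p1", "p1", "p1", "p2"),
    class = c("c1", "c1", "c1", "c2", "c3"),
    order = c("o1", "o1", "o2", "o3", "o4"),
    family = c("f1", "f1", "f2", "f3", "f4"),
    genus = c("g1", "g1", "g2", "g3", "g4"),
    stringsAsFactors = FALSE
  )
}

toy_community <- function() {
  ab <- matrix(
    c(3L, 1L, 0L, 2L, 0L,
      0L, 2L, 5L, 1L, 0L,
      1L, 0L, 0L, 4L, 6L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("A", "B", "C"), paste0("s", 1:5)))
  trog <- c(s1 = FALSE, s2 = FALSE, s3 = FALSE, s4 = TRUE, s5 = TRUE)
  community_matrix(ab, toy_taxonomy(), trog)
}

write_toy_inputs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(toy_cave_df(), file.path(dir, "caves.csv"), row.names = FALSE)
  comm <- toy_community()
  ab <- comm$abundance
  long <- data.frame(
    cave_id = rownames(ab)[row(ab)[ab > 0]],
    species_id = colnames(ab)[col(ab)[ab > 0]],
    season = "all", abundance = ab[ab > 0])
  utils::write.csv(long, file.path(dir, "community.csv"), row.names = FALSE)
  spt <- toy_taxonomy()
  spt$troglobite <- as.integer(comm$troglobite[spt$species_id])
  utils::write.csv(spt, file.path(dir, "species.csv"), row.names = FALSE)
  dir
}

# graph of two triangles joined by a single bridge edge
two_triangle_graph <- function() {
  igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, a - d)
}

# build one CPC igraph over a node set from an edge list given as pairs
mk_cpc <- function(ids, edges, provenance) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(edges)) g <- igraph::add_edges(g, unlist(edges))
  g$provenance <- provenance
  g
}

# a small synthetic system shared by slow-ish tests
small_synth <- function(seed = 11) {
  synth_generate(synthetic_config(
    n_caves = 30, n_clusters = 3, n_surface_species = 25, n_troglobites = 5,
    n_endemic = 1, seed = seed))
}

fast_config <- function(seed = 11, n_perm = 49)
  pipeline_config(n_perm = n_perm, seed = seed)
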