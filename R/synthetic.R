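#' Configuration for the synthetic cave-system generator
#'
#' The generated world mirrors the structure the connectivity analysis
#' assumes: caves clumped into spatial clusters embedded in a ferruginous
#' matrix, environmental predictors with between-cluster contrast plus
#' spatially autocorrelated noise (exponential covariance), troglobites
#' shared among caves within a dispersal radius of their home point
#' (cluster centers by default, with optional endemics pinned to a single
#' cave to plant Sc > 1 targets), surface species responding to a landscape
#' gradient, and overdispersed (negative binomial) counts. Defaults follow
#' the scale of the motivating system: 69 caves, 6 clusters, 9 troglobitic
#' species.
#'
#' @param n_caves,n_clusters counts.
#' @param cluster_spread_m Gaussian jitter (sd, meters) of caves around
#'   their cluster center.
#' @param inter_cluster_distance_m spacing of cluster centers on a grid.
#' @param n_surface_species,n_troglobites species counts.
#' @param n_endemic how many troglobites are pinned each to a single cave
#'   (planted priority caves).
#' @param dispersal_radius_m troglobite occupancy radius around its home.
#' @param nb_mu,nb_size negative-binomial abundance mean and dispersion.
#' @param env_spatial_range_m range of the exponential-covariance noise on
#'   numeric predictors.
#' @param env_between_sd,env_within_sd between-cluster and within-cluster
#'   standard deviations of numeric predictors (on their natural scales the
#'   predictors are rescaled by typical magnitudes).
#' @param seed RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_caves = 69, n_clusters = 6,
                             cluster_spread_m = 250,
                             inter_cluster_distance_m = 2000,
                             n_surface_species = 60, n_troglobites = 9,
                             n_endemic = 2, dispersal_radius_m = 600,
                             nb_mu = 20, nb_size = 1,
                             env_spatial_range_m = 800,
                             env_between_sd = 1.5, env_within_sd = 0.5,
                             seed = 1L) {
  stopifnot(n_caves > 0, n_clusters > 0, n_surface_species > 0,
            n_troglobites > 0, dispersal_radius_m >= 0,
            n_endemic >= 0, n_endemic <= n_troglobites,
            nb_mu > 0, nb_size > 0)
  cfg <- list(n_caves = n_caves, n_clusters = n_clusters,
              cluster_spread_m = cluster_spread_m,
              inter_cluster_distance_m = inter_cluster_distance_m,
              n_surface_species = n_surface_species,
              n_troglobites = n_troglobites, n_endemic = n_endemic,
              dispersal_radius_m = dispersal_radius_m,
              nb_mu = nb_mu, nb_size = nb_size,
              env_spatial_range_m = env_spatial_range_m,
              env_between_sd = env_between_sd,
              env_within_sd = env_within_sd, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# numeric predictors of the default synthetic world: name, unit, group,
# base level and scale factor mapping the unit-variance latent field onto a
# plausible natural range
synth_numeric_spec <- function() {
  data.frame(
    name = c("scarp_height_m", "area_m2", "max_humidity_pct",
             "min_humidity_pct", "mean_temperature_c", "forest_cover_ha",
             "altitude_m", "guano_m2"),
    unit = c("m", "m2", "%RH", "%RH", "degC", "ha", "m", "m2"),
    group = c("Scarp height", "Area", "Maximum humidity", "Minimum humidity",
              "Mean temperature", "Forest cover", "Altitude", "Bat guano"),
    base = c(10, 120, 85, 55, 24, 20, 700, 0.5),
    scale = c(4, 60, 5, 8, 0.5, 8, 40, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cave system
#'
#' @param config a [synthetic_config()].
#' @return list: `caves` ([cave_table]), `community`
#'   ([community_matrix]), `truth` (list: `cluster` named integer vector,
#'   `occupancy` list of cave-id sets per troglobite, `planted_priorities`,
#'   `dispersal_radius_m`).
#' @export
synth_generate <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  if (config$cluster_spread_m > config$inter_cluster_distance_m / 2)
    warning("cluster spread exceeds half the inter-cluster distance; clusters will overlap")

  n <- config$n_caves; k <- config$n_clusters
  ids <- sprintf("CV%03d", seq_len(n))
  # cluster centers on a grid
  ncol_grid <- ceiling(sqrt(k))
  centers <- cbind(
    ((seq_len(k) - 1) %% ncol_grid) * config$inter_cluster_distance_m,
    ((seq_len(k) - 1) %/% ncol_grid) * config$inter_cluster_distance_m
  )
  cl <- sort(rep_len(seq_len(k), n))
  coords <- centers[cl, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, config$cluster_spread_m), n, 2)

  # numeric predictors: cluster mean + spatially correlated noise
  dmat <- as.matrix(stats::dist(coords))
  Sigma <- exp(-dmat / config$env_spatial_range_m)
  L <- chol(Sigma + diag(1e-8, n))
  spec <- synth_numeric_spec()
  env <- list()
  for (r in seq_len(nrow(spec))) {
    mu_cl <- stats::rnorm(k, 0, config$env_between_sd)
    field <- as.numeric(t(L) %*% stats::rnorm(n)) * config$env_within_sd
    latent <- mu_cl[cl] + field
    env[[spec$name[r]]] <- spec$base[r] + spec$scale[r] * latent
  }
  # ordinal granulometry: cluster-dominant level + noise
  gran_levels <- c("silt", "sand", "granule", "pebble", "block")
  dom <- sample(seq_along(gran_levels), k, replace = TRUE)
  gran_code <- pmin(pmax(dom[cl] + sample(c(-1, 0, 0, 0, 1), n, replace = TRUE), 1),
                    length(gran_levels))
  env$granulometry <- gran_levels[gran_code]
  # categorical hydric features: cluster-dominant category
  hyd_levels <- c("dry", "intermittent", "perennial")
  dom_h <- sample(seq_along(hyd_levels), k, replace = TRUE)
  hyd <- vapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.75) dom_h[cl[i]] else sample(seq_along(hyd_levels), 1)
  }, 0L)
  env$hydric_features <- hyd_levels[hyd]

  predictor_meta <- data.frame(
    name = c(spec$name, "granulometry", "hydric_features"),
    kind = c(rep("numeric", nrow(spec)), "ordinal", "categorical"),
    unit = c(spec$unit, "level", "category"),
    group = c(spec$group, "Granulometry", "Hydric features"),
    levels = c(rep(NA_character_, nrow(spec)),
               paste(gran_levels, collapse = "|"),
               paste(hyd_levels, collapse = "|")),
    stringsAsFactors = FALSE
  )
  caves <- cave_table(
    data.frame(cave_id = ids, easting_m = coords[, 1], northing_m = coords[, 2],
               env, stringsAsFactors = FALSE),
    predictor_meta
  )

  # troglobites: home points at cluster centers (round-robin); the last
  # n_endemic species are pinned each to one cave, planting Sc > 1 targets
  nt <- config$n_troglobites
  n_end <- config$n_endemic
  trog_ids <- sprintf("TR%02d", seq_len(nt))
  occupancy <- vector("list", nt); names(occupancy) <- trog_ids
  planted <- character(0)
  free_idx <- seq_len(nt - n_end)
  for (t in free_idx) {
    home <- centers[((t - 1) %% k) + 1, ]
    d <- sqrt((coords[, 1] - home[1])^2 + (coords[, 2] - home[2])^2)
    occ <- which(d <= config$dispersal_radius_m)
    if (!length(occ)) occ <- which.min(d)
    occupancy[[t]] <- ids[occ]
  }
  if (n_end > 0) {
    host <- sample(seq_len(n), n_end)
    for (e in seq_len(n_end)) {
      occupancy[[nt - n_end + e]] <- ids[host[e]]
      planted <- c(planted, ids[host[e]])
    }
  }

  # surface species: logistic occupancy along the forest-cover gradient
  ns <- config$n_surface_species
  surf_ids <- sprintf("SP%03d", seq_len(ns))
  z <- as.numeric(scale(env$forest_cover_ha))
  ab <- matrix(0L, n, ns + nt, dimnames = list(ids, c(surf_ids, trog_ids)))
  rnb <- function(m) stats::rnbinom(m, mu = config$nb_mu, size = config$nb_size)
  for (s in seq_len(ns)) {
    a <- stats::rnorm(1, 0, 1); b <- stats::rnorm(1, 1, 0.5)
    occ <- stats::runif(n) < stats::plogis(a + b * z)
    ab[occ, s] <- pmax(1L, rnb(sum(occ)))
  }
  for (t in seq_len(nt)) {
    occ <- match(occupancy[[t]], ids)
    ab[occ, ns + t] <- pmax(1L, rnb(length(occ)))
  }

  taxonomy <- synth_taxonomy(c(surf_ids, trog_ids))
  trog_flag <- stats::setNames(c(rep(FALSE, ns), rep(TRUE, nt)),
                               c(surf_ids, trog_ids))
  community <- community_matrix(ab, taxonomy, trog_flag)
  truth <- list(cluster = stats::setNames(cl, ids),
                occupancy = occupancy,
                planted_priorities = unique(planted),
                dispersal_radius_m = config$dispersal_radius_m)
  list(caves = caves, community = community, truth = truth)
}

# recursive random grouping across 6 ranks (phylum..genus above species)
synth_taxonomy <- function(species_ids) {
  ranks <- c("phylum", "class", "order", "family", "genus")
  n <- length(species_ids)
  sizes <- pmax(2, round(n / c(24, 12, 6, 4, 2.5)))
  labels <- vector("list", length(ranks))
  # genus upward: group children randomly into parents
  child <- seq_len(n)
  assign_up <- function(n_child, n_parent)
    sample(rep_len(seq_len(n_parent), n_child))
  out <- data.frame(species_id = species_ids, stringsAsFactors = FALSE)
  parent_of <- assign_up(n, sizes[5])
  out$genus <- sprintf("gen%03d", parent_of)
  for (r in 4:1) {
    n_child <- length(unique(parent_of))
    up <- assign_up(n_child, min(sizes[r], n_child))
    parent_of <- up[match(parent_of, sort(unique(parent_of)))]
    out[[ranks[r]]] <- sprintf("%s%03d", substr(ranks[r], 1, 3), parent_of)
  }
  out[, c("species_id", ranks)]
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b integer/character membership vectors over the same elements.
#' @return ARI in \[-1, 1\]; 1 for identical partitions, ~0 for independent
#'   ones.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

#' Recovery metrics of a pipeline run against the generator's ground truth
#'
#' @param result a [run_cave_pipeline()] result.
#' @param truth the `truth` element of [synth_generate()].
#' @return list: `cluster_ari`, `priority_precision`, `priority_recall`,
#'   `range_error_m` (|significant range - dispersal radius|, `NA` when no
#'   range was found).
#' @export
recovery_metrics <- function(result, truth) {
  memb <- result$clusters$membership
  ids <- names(truth$cluster)
  if (!setequal(names(memb), ids)) stop("cave id mismatch between result and truth")
  ari <- adjusted_rand_index(as.integer(memb[ids]), as.integer(truth$cluster))
  detected <- result$report$priorities
  planted <- truth$planted_priorities
  prec <- if (length(detected)) mean(detected %in% planted) else NA_real_
  rec <- if (length(planted)) mean(planted %in% detected) else NA_real_
  rng <- result$ranges[["comp_troglobites"]]
  list(cluster_ari = ari,
       priority_precision = prec,
       priority_recall = rec,
       range_error_m = if (is.na(rng)) NA_real_ else
         abs(rng - truth$dispersal_radius_m))
}
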