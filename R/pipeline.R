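#' Pipeline configuration
#'
#' Collects every stage tunable in one place; no stage has hidden defaults
#' outside this object.
#'
#' @param alpha significance level used by correlograms, DistLM stop rule,
#'   breakpoint significance and categorical contrasts.
#' @param n_perm permutations for Moran's I and DistLM tests.
#' @param seed master seed; stage seeds are derived from it.
#' @param axes ordination axes fed to the correlograms (default `"MDS1"`).
#' @param log_base abundance log-transform base.
#' @param standardize per-species max-standardization after the log
#'   transform (default off).
#' @param mpd_weighted abundance-weighted MPD (default unweighted).
#' @param ordination_input `"mpd"` (default: PCoA of the MPD matrix treated
#'   as distances) or `"euclidean_of_mpd"` (PCoA of Euclidean distances
#'   among MPD row vectors).
#' @param cluster_weighted pass CPC weights (as inverse distances) to the
#'   clustering (default off).
#' @param d_max_mode see [build_report()].
#' @param min_troglobites see [secondary_priorities()].
#' @param bc_zero_policy,mpd_na_policy degenerate-community handling for
#'   [bray_curtis()] / [mpd_matrix()]; the pipeline defaults keep all caves
#'   in the analysis (empty pairs maximally dissimilar).
#' @param grouping predictor-set grouping mode (see [predictor_sets()]).
#' @param top_k_bridges length of the bridge report (default: all caves
#'   with positive betweenness).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, n_perm = 999, seed = 1L,
                            axes = "MDS1", log_base = exp(1),
                            standardize = FALSE, mpd_weighted = FALSE,
                            ordination_input = c("mpd", "euclidean_of_mpd"),
                            cluster_weighted = FALSE,
                            d_max_mode = "n_minus_1", min_troglobites = 1,
                            bc_zero_policy = "one", mpd_na_policy = "max",
                            grouping = "group", top_k_bridges = NULL) {
  cfg <- list(alpha = alpha, n_perm = n_perm, seed = as.integer(seed),
              axes = axes, log_base = log_base, standardize = standardize,
              mpd_weighted = mpd_weighted,
              ordination_input = match.arg(ordination_input),
              cluster_weighted = cluster_weighted,
              d_max_mode = d_max_mode, min_troglobites = min_troglobites,
              bc_zero_policy = bc_zero_policy,
              mpd_na_policy = mpd_na_policy, grouping = grouping,
              top_k_bridges = top_k_bridges)
  class(cfg) <- "pipeline_config"
  cfg
}

APPROACHES <- c("comp_all", "comp_troglobites", "phy_all", "phy_troglobites")

#' Run the full connectivity pipeline
#'
#' Executes: similarity matrices (Bray-Curtis composition; taxonomic MPD)
#' for all species and troglobites only; ordination; Moran's I correlograms
#' with progressive Bonferroni; DistLM forward selection per approach;
#' segmented breakpoint fits on the selected predictors; the four CPC
#' graphs for the troglobite approaches; edge validation, weighting and the
#' troglobite-free-pair exclusion; edge-betweenness clustering, betweenness
#' bridges; and the singularity-based priority report. When `out_dir` is
#' given all artifacts (TSV tables, GraphML/CSV graphs, `priorities.json`,
#' provenance log) are written there.
#'
#' @param caves a [cave_table()].
#' @param community a [community_matrix()] aligned with `caves`.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with elements `dissim`, `ordinations`, `correlograms`,
#'   `ranges`, `distlm`, `breakpoints`, `rules`, `graphs`, `combined`,
#'   `parsimonious`, `density`, `clusters`, `betweenness`, `report`,
#'   `pairs`, `config`.
#' @export
run_cave_pipeline <- function(caves, community, config = pipeline_config(),
                              out_dir = NULL) {
  stopifnot(inherits(caves, "cave_table"), inherits(community, "community_matrix"))
  if (!identical(caves$cave_id, rownames(community$abundance)))
    stop("cave table and community matrix are not aligned")
  coords <- cave_coords(caves)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## similarity -------------------------------------------------------------
  trog <- troglobite_species(community)
  if (length(trog) == 0) stop("no troglobitic species in the community")
  dissim <- stage("similarity", {
    ab <- community$abundance
    la <- log_transform(ab, base = config$log_base,
                        standardize = config$standardize)
    lt <- la[, trog, drop = FALSE]
    bc_all <- bray_curtis(la, zero_policy = config$bc_zero_policy)
    bc_trog <- suppressWarnings(
      bray_curtis(lt, zero_policy = config$bc_zero_policy))
    d_all <- taxonomic_distances(community$taxonomy)
    d_trog <- taxonomic_distances(
      community$taxonomy[community$taxonomy$species_id %in% trog, , drop = FALSE])
    mpd_all <- suppressWarnings(
      mpd_matrix(ab, d_all, weighted = config$mpd_weighted,
                 na_policy = config$mpd_na_policy))
    mpd_trog <- suppressWarnings(
      mpd_matrix(ab, d_trog, weighted = config$mpd_weighted,
                 na_policy = config$mpd_na_policy))
    list(comp_all = bc_all, comp_troglobites = bc_trog,
         phy_all = mpd_all, phy_troglobites = mpd_trog)
  })
  # DistLM / ordination input for the phylogenetic approaches
  resp <- dissim
  for (a in c("phy_all", "phy_troglobites"))
    resp[[a]] <- as_dissim(as.matrix(stats::dist(dissim[[a]])), "euclidean_of_mpd")

  ## ordination -------------------------------------------------------------
  ordinations <- stage("ordination", {
    lapply(stats::setNames(APPROACHES, APPROACHES), function(a) {
      d <- if (startsWith(a, "phy") && config$ordination_input == "euclidean_of_mpd")
        resp[[a]] else dissim[[a]]
      pcoa(d)
    })
  })

  ## correlograms -----------------------------------------------------------
  correlograms <- stage("correlogram", {
    out <- list()
    for (i in seq_along(APPROACHES)) {
      a <- APPROACHES[i]
      out[[a]] <- axes_correlogram(
        ordinations[[a]], coords, axes = config$axes, alpha = config$alpha,
        n_perm = config$n_perm, seed = (config$seed + 100 + i) %% .Machine$integer.max)
    }
    out
  })
  ranges <- vapply(correlograms, function(x) x$significant_range_m, 0)

  ## DistLM -----------------------------------------------------------------
  sets <- predictor_sets(caves, grouping = config$grouping)
  distlm_fits <- stage("distlm", {
    out <- list()
    for (i in seq_along(APPROACHES)) {
      a <- APPROACHES[i]
      out[[a]] <- forward_select(resp[[a]], sets, alpha = config$alpha,
                                 n_perm = config$n_perm,
                                 seed = (config$seed + 200 + 10 * i) %% .Machine$integer.max)
    }
    out
  })

  ## breakpoints ------------------------------------------------------------
  pairs <- build_pair_table(
    caves,
    responses = list(
      sim_comp_all = similarity_percent(dissim$comp_all),
      sim_comp_troglobites = similarity_percent(dissim$comp_troglobites),
      mpd_all = dissim$phy_all,
      mpd_troglobites = dissim$phy_troglobites))
  pm <- attr(caves, "predictor_meta")
  breakpoints <- stage("segmented", {
    out <- list()
    for (a in APPROACHES) {
      y <- if (startsWith(a, "comp")) {
        v <- pairs[[paste0("sim_", a)]]
        scale_response(pmin(pmax(v, 1e-4), 100 - 1e-4), "similarity_pct")
      } else {
        # MPD is a distance: invert so that larger = more similar and the
        # favored-region orientation (below psi) is uniform
        1 - as.numeric(scale_response(pairs[[paste0("mpd_",
          sub("phy_", "", a))]], "mpd"))
      }
      out[[a]] <- fit_breakpoints_for(distlm_fits[[a]], pairs, pm, y,
                                      alpha = config$alpha)
    }
    out
  })
  rules <- lapply(breakpoints, significant_rules)

  ## CPC graphs (troglobite approaches) -------------------------------------
  graphs <- stage("cpc_graphs", list(
    comp_autocorr = cpc_from_range(coords, ranges[["comp_troglobites"]],
                                   "comp_autocorr"),
    comp_breakpoint = cpc_from_rules(pairs, rules$comp_troglobites,
                                     "comp_breakpoint"),
    phy_autocorr = cpc_from_range(coords, ranges[["phy_troglobites"]],
                                  "phy_autocorr"),
    phy_breakpoint = cpc_from_rules(pairs, rules$phy_troglobites,
                                    "phy_breakpoint")))

  combined <- stage("combine", combine_and_weight(graphs))
  counts <- troglobite_counts(community)
  parsimonious <- stage("exclusion", drop_troglobite_free_edges(combined, counts))
  parsimonious$str_total <- length(trog)

  ## clustering, betweenness, priorities ------------------------------------
  clusters <- stage("clustering", {
    if (igraph::ecount(parsimonious) == 0) {
      memb <- stats::setNames(seq_len(igraph::vcount(parsimonious)),
                              igraph::V(parsimonious)$name)
      list(membership = memb, n_clusters = length(memb),
           modularity = NA_real_, communities = NULL)
    } else {
      edge_betweenness_clusters(parsimonious,
                                weighted = config$cluster_weighted)
    }
  })
  btw <- stage("betweenness", node_betweenness(parsimonious,
                                               top_k = config$top_k_bridges))
  igraph::V(parsimonious)$cluster <- as.integer(clusters$membership[
    igraph::V(parsimonious)$name])
  report <- stage("prioritization",
                  build_report(parsimonious, str_total = length(trog),
                               d_max_mode = config$d_max_mode,
                               min_troglobites = config$min_troglobites))
  igraph::V(parsimonious)$singularity <-
    report$caves$singularity[match(igraph::V(parsimonious)$name,
                                   report$caves$cave_id)]

  result <- list(dissim = dissim, ordinations = ordinations,
                 correlograms = correlograms, ranges = ranges,
                 distlm = distlm_fits, breakpoints = breakpoints,
                 rules = rules, graphs = graphs, combined = combined,
                 parsimonious = parsimonious,
                 density = graph_density(parsimonious),
                 clusters = clusters, betweenness = btw, report = report,
                 pairs = pairs, config = config)
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

# fit one breakpoint model per member predictor of each selected set
fit_breakpoints_for <- function(distlm_fit, pairs, pm, y, alpha) {
  out <- list()
  for (set_name in distlm_fit$steps$set) {
    if (set_name == "Distance") {
      out[["distance_m"]] <- try_breakpoint(y, pairs$distance_m, "distance_m")
      next
    }
    for (i in which(pm$group == set_name | pm$name == set_name)) {
      nm <- pm$name[i]
      if (pm$kind[i] == "categorical") {
        out[[nm]] <- tryCatch(
          categorical_rule(pmin(pmax(y, 1e-6), 1 - 1e-6), pairs[[nm]],
                           alpha = alpha),
          error = function(e) NULL)
        if (!is.null(out[[nm]])) out[[nm]]$predictor <- nm
      } else {
        out[[nm]] <- try_breakpoint(y, pairs[[nm]], nm,
                                    ordinal = pm$kind[i] == "ordinal")
      }
    }
  }
  out[!vapply(out, is.null, TRUE)]
}

try_breakpoint <- function(y, x, nm, ordinal = FALSE) {
  y <- pmin(pmax(as.numeric(y), 1e-6), 1 - 1e-6)
  tryCatch(suppressWarnings(
    fit_segmented(y, x, predictor = nm, ordinal = ordinal)),
    error = function(e) NULL)
}

# keep only rules usable for edge construction
significant_rules <- function(fits) {
  keep <- list()
  for (f in fits) {
    if (inherits(f, "breakpoint_fit")) {
      if (f$chosen == "segmented" && f$significant && !is.na(f$threshold))
        keep[[f$predictor]] <- f
    } else if (inherits(f, "categorical_rule")) {
      if (length(f$favored)) keep[[f$predictor]] <- f
    }
  }
  keep
}

write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  # correlogram tables
  ct <- do.call(rbind, lapply(names(result$correlograms), function(a) {
    x <- result$correlograms[[a]]$per_axis[[1]]
    cbind(approach = a, axis = names(result$correlograms[[a]]$per_axis)[1],
          as.data.frame(x))
  }))
  tsv(ct, "correlograms.tsv")
  tsv(data.frame(approach = names(result$ranges),
                 significant_range_m = unname(result$ranges)), "ranges.tsv")
  dl <- do.call(rbind, lapply(names(result$distlm), function(a) {
    s <- result$distlm[[a]]$steps
    if (!nrow(s)) return(NULL)
    cbind(approach = a, s)
  }))
  if (!is.null(dl)) tsv(dl, "distlm.tsv") else
    tsv(data.frame(approach = character(), set = character()), "distlm.tsv")
  bp <- do.call(rbind, lapply(names(result$breakpoints), function(a) {
    rows <- lapply(result$breakpoints[[a]], function(f) {
      if (inherits(f, "breakpoint_fit"))
        data.frame(approach = a, predictor = f$predictor, psi = f$psi,
                   psi_se = f$psi_se, delta_aicc = f$delta_aicc,
                   chosen = f$chosen, rule = f$rule)
      else
        data.frame(approach = a, predictor = f$predictor, psi = NA,
                   psi_se = NA, delta_aicc = NA, chosen = "categorical",
                   rule = f$rule)
    })
    do.call(rbind, rows)
  }))
  if (!is.null(bp)) tsv(bp, "breakpoints.tsv") else
    tsv(data.frame(approach = character(), predictor = character()),
        "breakpoints.tsv")
  write_graph_file(result$parsimonious,
                   file.path(out_dir, "parsimonious.graphml"), "graphml")
  write_graph_file(result$parsimonious,
                   file.path(out_dir, "parsimonious_edges.csv"), "edgelist_csv")
  tsv(data.frame(cave_id = names(result$clusters$membership),
                 cluster = as.integer(result$clusters$membership)),
      "clusters.tsv")
  tsv(result$report$caves, "cave_metrics.tsv")
  write_report_json(result$report, file.path(out_dir, "priorities.json"))
  prov <- list(package = "cavenet",
               version = as.character(utils::packageVersion("cavenet")),
               r_version = R.version.string,
               config = unclass(result$config),
               density = result$density,
               modularity = result$clusters$modularity,
               n_clusters = result$clusters$n_clusters,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write the three input CSV files
#'
#' Inverse of [read_inputs()]; used to persist synthetic systems in the
#' documented schemas.
#'
#' @param caves a [cave_table()].
#' @param community a [community_matrix()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_inputs <- function(caves, community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(caves), file.path(dir, "caves.csv"),
                   row.names = FALSE)
  ab <- community$abundance
  long <- data.frame(
    cave_id = rownames(ab)[row(ab)[ab > 0]],
    species_id = colnames(ab)[col(ab)[ab > 0]],
    season = "all",
    abundance = ab[ab > 0])
  utils::write.csv(long, file.path(dir, "community.csv"), row.names = FALSE)
  spt <- community$taxonomy
  spt$troglobite <- as.integer(community$troglobite[spt$species_id])
  utils::write.csv(spt, file.path(dir, "species.csv"), row.names = FALSE)
  pm <- attr(caves, "predictor_meta")
  utils::write.csv(pm, file.path(dir, "predictor_meta.csv"), row.names = FALSE)
  invisible(dir)
}
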