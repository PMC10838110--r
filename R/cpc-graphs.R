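#' Potential pairwise connectivity graph from a distance range
#'
#' Connects every pair of caves whose Euclidean distance is less than or
#' equal to the significant autocorrelation range.
#'
#' @param coords cave coordinate matrix (rownames = cave ids).
#' @param range_m significant range in meters (`NA` yields an empty graph).
#' @param provenance label, one of `comp_autocorr`, `comp_breakpoint`,
#'   `phy_autocorr`, `phy_breakpoint`.
#' @return an [igraph::igraph] with a `provenance` graph attribute.
#' @export
cpc_from_range <- function(coords, range_m,
                           provenance = c("comp_autocorr", "phy_autocorr",
                                          "comp_breakpoint", "phy_breakpoint")) {
  provenance <- match.arg(provenance)
  ids <- rownames(coords)
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  igraph::V(g)$name <- ids
  if (!is.na(range_m) && range_m >= 0) {
    dm <- as.matrix(stats::dist(coords))
    adj <- dm <= range_m & upper.tri(dm)
    ep <- which(adj, arr.ind = TRUE)
    if (nrow(ep)) g <- igraph::add_edges(g, as.vector(t(cbind(ids[ep[, 1]], ids[ep[, 2]]))))
  }
  g$provenance <- provenance
  g
}

#' Potential pairwise connectivity graph from breakpoint rules
#'
#' Connects a pair when it satisfies **all** supplied favored-region rules:
#' numeric rules require `|delta| <= threshold` (boundary inclusive),
#' ordinal rules at most the allowed number of level steps, categorical
#' rules membership of the pair's category combination in the favored set.
#' An empty rule list yields the complete graph (vacuous conjunction).
#'
#' @param pairs a [build_pair_table()] result.
#' @param rules list of rules; each either a [fit_segmented()]
#'   `breakpoint_fit` (with a non-`NA` threshold), a [categorical_rule()],
#'   or a bare `list(predictor =, threshold =)` /
#'   `list(predictor =, favored =)`.
#' @inheritParams cpc_from_range
#' @return an [igraph::igraph] over all caves in the pair table.
#' @export
cpc_from_rules <- function(pairs, rules,
                           provenance = c("comp_breakpoint", "phy_breakpoint",
                                          "comp_autocorr", "phy_autocorr")) {
  provenance <- match.arg(provenance)
  ids <- unique(c(pairs$cave_a, pairs$cave_b))
  keep <- rep(TRUE, nrow(pairs))
  for (r in rules) {
    nm <- r$predictor
    if (is.null(nm) || !nm %in% names(pairs))
      stop("rule predictor missing from pair table: ", nm)
    if (!is.null(r$favored)) {
      keep <- keep & pairs[[nm]] %in% r$favored
    } else {
      thr <- r$threshold
      if (is.null(thr) || is.na(thr))
        stop("rule for '", nm, "' has no threshold")
      keep <- keep & pairs[[nm]] <= thr
    }
  }
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (any(keep))
    g <- igraph::add_edges(g, as.vector(t(cbind(pairs$cave_a[keep],
                                                pairs$cave_b[keep]))))
  g$provenance <- provenance
  g
}

PROVENANCES <- c("comp_autocorr", "comp_breakpoint", "phy_autocorr", "phy_breakpoint")

#' Combine the four CPC graphs into a validated, weighted graph
#'
#' The candidate edge set is the union of the four graphs' edges. An edge is
#' **validated** when it appears in at least one composition graph *and* at
#' least one phylogeny graph; its weight is the number of graphs containing
#' it (2-4). Each edge carries the four provenance booleans.
#'
#' @param graphs named list with elements `comp_autocorr`,
#'   `comp_breakpoint`, `phy_autocorr`, `phy_breakpoint` (built on the same
#'   node set).
#' @return weighted undirected igraph with edge attributes `weight` and the
#'   four provenance flags.
#' @export
combine_and_weight <- function(graphs) {
  miss <- setdiff(PROVENANCES, names(graphs))
  if (length(miss)) stop("missing graphs: ", paste(miss, collapse = ", "))
  graphs <- graphs[PROVENANCES]
  ids <- sort(igraph::V(graphs[[1]])$name)
  for (g in graphs[-1])
    if (!identical(sort(igraph::V(g)$name), ids)) stop("node-set mismatch")
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) return(character(0))
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  }
  keys <- lapply(graphs, key)
  all_keys <- unique(unlist(keys))
  flags <- vapply(keys, function(k) all_keys %in% k,
                  logical(length(all_keys)))
  flags <- matrix(flags, nrow = length(all_keys),
                  dimnames = list(all_keys, PROVENANCES))
  valid <- (flags[, "comp_autocorr"] | flags[, "comp_breakpoint"]) &
    (flags[, "phy_autocorr"] | flags[, "phy_breakpoint"])
  flags <- flags[valid, , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(flags)) {
    ends <- do.call(rbind, strsplit(rownames(flags), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, as.vector(t(ends)))
    igraph::E(g)$weight <- as.integer(rowSums(flags))
    for (pv in PROVENANCES) igraph::edge_attr(g, pv) <- unname(flags[, pv])
  } else {
    igraph::E(g)$weight <- integer(0)
    for (pv in PROVENANCES) igraph::edge_attr(g, pv) <- logical(0)
  }
  g
}

#' Drop edges joining two troglobite-free caves
#'
#' Edges whose *both* endpoints host zero troglobitic species are removed
#' (absence at both ends suggests unsuitable habitat); edges with exactly
#' one troglobite-free endpoint are retained. Nodes are never removed. The
#' counts are stored as the `troglobites` vertex attribute.
#'
#' @param g igraph over caves.
#' @param counts named integer vector of troglobite species counts per cave.
#' @return the filtered graph.
#' @export
drop_troglobite_free_edges <- function(g, counts) {
  ids <- igraph::V(g)$name
  miss <- setdiff(ids, names(counts))
  if (length(miss)) stop("missing troglobite counts for: ", paste(miss, collapse = ", "))
  igraph::V(g)$troglobites <- as.integer(counts[ids])
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    dead <- counts[el[, 1]] == 0 & counts[el[, 2]] == 0
    g <- igraph::delete_edges(g, which(dead))
  }
  g
}

#' Density of connections
#'
#' Proportion of existing edges among all `n(n-1)/2` possible ones.
#'
#' @param g undirected igraph.
#' @return a number in \[0, 1\].
#' @export
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  igraph::ecount(g) / (n * (n - 1) / 2)
}

#' Edge-betweenness (Girvan-Newman) clustering
#'
#' Repeatedly removes the edge of highest edge betweenness and keeps, among
#' the nested partitions generated, the one maximizing Newman-Girvan
#' modularity. Runs unweighted by default; `weighted = TRUE` converts CPC
#' weights to distances (`1/weight`) so that stronger links are "shorter".
#'
#' @param g igraph with at least one edge.
#' @param weighted use edge weights (as inverse distances).
#' @return list: `membership` (named integer vector), `n_clusters`,
#'   `modularity`, `communities` (the igraph communities object, carrying
#'   the dendrogram).
#' @export
edge_betweenness_clusters <- function(g, weighted = FALSE) {
  if (igraph::ecount(g) == 0) stop("empty graph")
  w <- if (weighted) 1 / igraph::E(g)$weight else NULL
  # igraph warns that membership is picked at the modularity maximum; that
  # is precisely the intended behavior
  cm <- withCallingHandlers(
    igraph::cluster_edge_betweenness(g, weights = w, directed = FALSE,
                                     modularity = TRUE),
    warning = function(w_) {
      if (grepl("Membership vector", conditionMessage(w_)))
        invokeRestart("muffleWarning")
    })
  memb <- igraph::membership(cm)
  list(membership = memb,
       n_clusters = length(unique(memb)),
       modularity = igraph::modularity(g, memb),
       communities = cm)
}

#' Node betweenness and bridge ranking
#'
#' Unweighted shortest-path betweenness centrality; the bridge report ranks
#' caves by score.
#'
#' @param g igraph.
#' @param top_k how many top-ranked caves to flag as bridges (default all
#'   with positive score).
#' @return list: `scores` (named vector), `bridges` (data frame `cave`,
#'   `betweenness`, ranked decreasing).
#' @export
node_betweenness <- function(g, top_k = NULL) {
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  ord <- order(-b, igraph::V(g)$name)
  rank_df <- data.frame(cave = igraph::V(g)$name[ord], betweenness = b[ord],
                        row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(top_k)) {
    bridges <- rank_df[rank_df$betweenness > 0, , drop = FALSE]
  } else {
    bridges <- utils::head(rank_df, top_k)
  }
  list(scores = b, bridges = bridges)
}

#' Serialize a connectivity graph
#'
#' GraphML keeps all node attributes (troglobite count, singularity,
#' cluster id, ...) and edge attributes (weight, provenance flags); the
#' edge-list CSV has columns `cave_a, cave_b, weight` plus the four
#' provenance flags.
#'
#' @param g igraph.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @export
write_graph_file <- function(g, path, format = c("graphml", "edgelist_csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    df <- data.frame(cave_a = el[, 1], cave_b = el[, 2],
                     stringsAsFactors = FALSE)
    for (a in igraph::edge_attr_names(g)) df[[a]] <- igraph::edge_attr(g, a)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path, format = c("graphml", "edgelist_csv")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g
}
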