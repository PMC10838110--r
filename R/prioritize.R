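#' Singularity index of a cave
#'
#' `Sc = (STR_cave / STR_total) / (degree / D_max)`: the cave's share of
#' the area's troglobitic species divided by its share of the maximum
#' possible number of connections. An isolated cave (degree 0) that hosts
#' troglobites is an isolated endemic habitat and gets `Inf` (maximal
#' priority); an isolated cave without troglobites gets 0.
#'
#' @param str_cave troglobite species count in the cave.
#' @param str_total total troglobite species count in the study area (> 0).
#' @param degree number of connections of the cave.
#' @param d_max maximum possible number of connections (> 0).
#' @return singularity value (possibly `Inf`).
#' @export
singularity <- function(str_cave, str_total, degree, d_max) {
  if (any(str_total <= 0)) stop("str_total must be positive")
  if (any(d_max <= 0)) stop("d_max must be positive")
  if (any(degree > d_max)) stop("degree exceeds d_max")
  if (any(str_cave < 0) || any(degree < 0)) stop("negative counts")
  out <- ifelse(degree == 0,
                ifelse(str_cave > 0, Inf, 0),
                (str_cave / str_total) / (degree / d_max))
  unname(out)
}

#' Priority caves: singularity strictly above one
#'
#' @param sc named vector of singularity values.
#' @return character vector of cave ids with `Sc > 1` (`Inf` included).
#' @export
select_priorities <- function(sc) names(sc)[!is.na(sc) & sc > 1]

#' Influence levels of a priority cave's neighbors
#'
#' Neighbors are graded by the CPC weight of their edge to the priority
#' cave: the highest distinct incident weight maps to `"high"`, the second
#' to `"medium"`, the third to `"low"`.
#'
#' @param g weighted connectivity graph (edge attribute `weight`).
#' @param cave priority cave id.
#' @return named character vector (neighbor -> level); empty with a warning
#'   for an isolated cave.
#' @export
influence_levels <- function(g, cave) {
  stopifnot(cave %in% igraph::V(g)$name)
  inc <- igraph::incident(g, cave)
  if (length(inc) == 0) {
    warning("priority cave '", cave, "' is isolated")
    return(stats::setNames(character(0), character(0)))
  }
  nb <- igraph::V(g)$name[igraph::ends(g, inc, names = FALSE)]
  nb <- matrix(nb, ncol = 2)
  other <- ifelse(nb[, 1] == cave, nb[, 2], nb[, 1])
  w <- igraph::E(g)$weight[as.integer(inc)]
  tiers <- sort(unique(w), decreasing = TRUE)
  lvl <- c("high", "medium", "low")[match(w, tiers)]
  lvl[is.na(lvl)] <- "low"    # beyond third distinct weight (not expected for 2..4)
  stats::setNames(lvl, other)
}

#' Secondary priority caves
#'
#' Union over the priority caves of their high-influence neighbors that host
#' at least `min_troglobites` troglobitic species and are not themselves
#' priorities.
#'
#' @param g weighted connectivity graph.
#' @param priorities character vector of priority cave ids.
#' @param counts named troglobite counts.
#' @param min_troglobites minimum troglobite count (default 1).
#' @return character vector of secondary priority cave ids.
#' @export
secondary_priorities <- function(g, priorities, counts, min_troglobites = 1) {
  out <- character(0)
  for (p in priorities) {
    lv <- suppressWarnings(influence_levels(g, p))
    hi <- names(lv)[lv == "high"]
    out <- union(out, hi[counts[hi] >= min_troglobites])
  }
  setdiff(out, priorities)
}

#' Full conservation-priority report
#'
#' Computes, on the final (parsimonious) connectivity graph: per-cave
#' troglobite count, degree, betweenness and singularity; the priority set
#' (`Sc > 1`); per-priority influence maps; and the secondary priority set.
#'
#' @param g parsimonious weighted graph (vertex attribute `troglobites`).
#' @param str_total total number of distinct troglobitic species in the
#'   study area; defaults to the graph attribute `str_total` set by the
#'   pipeline, falling back (with a warning) to the maximum per-cave count.
#' @param d_max_mode `"n_minus_1"` (default: the maximum number of possible
#'   distinct connections) or `"observed"` (the maximum observed degree).
#' @param min_troglobites threshold for secondary priorities.
#' @return object of class `priority_report`: `caves` (data frame),
#'   `priorities`, `influence` (named list), `secondary`, `constants`.
#' @export
build_report <- function(g, str_total = NULL,
                         d_max_mode = c("n_minus_1", "observed"),
                         min_troglobites = 1) {
  d_max_mode <- match.arg(d_max_mode)
  ids <- igraph::V(g)$name
  if (is.null(igraph::V(g)$troglobites))
    stop("graph lacks the 'troglobites' vertex attribute")
  counts <- stats::setNames(igraph::V(g)$troglobites, ids)
  deg <- igraph::degree(g)
  if (is.null(str_total)) str_total <- g$str_total
  if (is.null(str_total)) {
    warning("str_total not supplied; using the maximum per-cave count")
    str_total <- max(counts)
  }
  d_max <- if (d_max_mode == "n_minus_1") length(ids) - 1 else max(deg)
  sc <- stats::setNames(
    singularity(counts, str_total, deg, d_max), ids)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  pri <- select_priorities(sc)
  infl <- lapply(stats::setNames(pri, pri), function(p)
    suppressWarnings(influence_levels(g, p)))
  sec <- secondary_priorities(g, pri, counts, min_troglobites)
  caves <- data.frame(cave_id = ids, troglobites = unname(counts),
                      degree = unname(deg), betweenness = unname(btw),
                      singularity = unname(sc),
                      priority = ids %in% pri,
                      stringsAsFactors = FALSE)
  structure(list(caves = caves, priorities = pri, influence = infl,
                 secondary = sec,
                 constants = list(str_total = str_total, d_max = d_max,
                                  d_max_mode = d_max_mode,
                                  min_troglobites = min_troglobites)),
            class = "priority_report")
}

#' @export
print.priority_report <- function(x, ...) {
  cat(sprintf("priority_report: %d caves, STR_TOT = %d, D_MAX = %d\n",
              nrow(x$caves), x$constants$str_total, x$constants$d_max))
  cat(sprintf("  %d priority caves (Sc > 1): %s\n", length(x$priorities),
              paste(x$priorities, collapse = ", ")))
  cat(sprintf("  %d secondary priorities: %s\n", length(x$secondary),
              paste(x$secondary, collapse = ", ")))
  invisible(x)
}

#' Serialize a priority report to JSON
#'
#' `Inf` singularities are serialized as the string `"inf"` together with an
#' `is_infinite` flag.
#'
#' @param report a [build_report()] result.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  caves <- report$caves
  caves$singularity_is_infinite <- is.infinite(caves$singularity)
  caves$singularity <- ifelse(is.infinite(caves$singularity), "inf",
                              as.character(caves$singularity))
  obj <- list(constants = report$constants,
              caves = caves,
              priorities = report$priorities,
              influence = lapply(report$influence, as.list),
              secondary = report$secondary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  caves <- as.data.frame(obj$caves, stringsAsFactors = FALSE)
  caves$singularity <- ifelse(caves$singularity_is_infinite, Inf,
                              suppressWarnings(as.numeric(caves$singularity)))
  caves$singularity_is_infinite <- NULL
  structure(list(caves = caves,
                 priorities = as.character(unlist(obj$priorities)),
                 influence = lapply(obj$influence, function(m)
                   stats::setNames(as.character(unlist(m)), names(m))),
                 secondary = as.character(unlist(obj$secondary)),
                 constants = obj$constants),
            class = "priority_report")
}
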