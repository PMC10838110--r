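#' Cave table: coordinates and environmental predictors
#'
#' A `cave_table` is a data frame with one row per cave holding its id, planar
#' UTM coordinates in meters, and a set of environmental predictors. Each
#' predictor is declared as `numeric`, `ordinal` (with an explicit level
#' order, e.g. sediment granulometry) or `categorical` (unordered levels,
#' e.g. hydric features), and carries a group label used to form predictor
#' sets for distance-based modeling (`"Distance"` is reserved for the
#' coordinate pair).
#'
#' @param df data frame with columns `cave_id`, `easting_m`, `northing_m`
#'   and one column per predictor.
#' @param predictor_meta data frame with columns `name`, `kind`
#'   (`numeric`/`ordinal`/`categorical`), `unit`, `group`, and `levels`
#'   (`|`-separated ordered levels for non-numeric predictors; `NA` for
#'   numeric). When `NULL`, numeric columns are declared numeric and
#'   character/factor columns categorical, each in its own group.
#' @return a `cave_table` object (a validated data frame with a
#'   `predictor_meta` attribute).
#' @export
cave_table <- function(df, predictor_meta = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("cave_id", "easting_m", "northing_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cave table lacks columns: ", paste(miss, collapse = ", "))
  df$cave_id <- as.character(df$cave_id)
  if (anyDuplicated(df$cave_id))
    stop("duplicate cave_id: ", paste(unique(df$cave_id[duplicated(df$cave_id)]), collapse = ", "))
  if (!all(is.finite(df$easting_m)) || !all(is.finite(df$northing_m)))
    stop("cave coordinates must be finite")
  pred_cols <- setdiff(names(df), need)
  if (is.null(predictor_meta)) {
    predictor_meta <- data.frame(
      name = pred_cols,
      kind = vapply(df[pred_cols], function(x)
        if (is.numeric(x)) "numeric" else "categorical", ""),
      unit = NA_character_, group = pred_cols,
      levels = NA_character_, stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("name", "kind", "group") %in% names(predictor_meta)))
  if (!"unit" %in% names(predictor_meta)) predictor_meta$unit <- NA_character_
  if (!"levels" %in% names(predictor_meta)) predictor_meta$levels <- NA_character_
  bad_kind <- setdiff(predictor_meta$kind, c("numeric", "ordinal", "categorical"))
  if (length(bad_kind)) stop("unknown predictor kind: ", paste(bad_kind, collapse = ", "))
  miss <- setdiff(predictor_meta$name, pred_cols)
  if (length(miss)) stop("predictor_meta names absent from table: ", paste(miss, collapse = ", "))
  extra <- setdiff(pred_cols, predictor_meta$name)
  if (length(extra)) stop("predictors lacking metadata: ", paste(extra, collapse = ", "))
  for (i in seq_len(nrow(predictor_meta))) {
    nm <- predictor_meta$name[i]; kind <- predictor_meta$kind[i]
    x <- df[[nm]]
    if (anyNA(x)) stop("missing values in predictor '", nm, "' (imputation not supported)")
    if (kind == "numeric") {
      if (!is.numeric(x)) stop("predictor '", nm, "' declared numeric but is not")
    } else {
      lv <- predictor_levels(predictor_meta$levels[i])
      if (kind == "ordinal" && is.null(lv))
        stop("ordinal predictor '", nm, "' must declare its level order")
      if (is.null(lv)) {
        lv <- sort(unique(as.character(x)))
        predictor_meta$levels[i] <- paste(lv, collapse = "|")
      }
      bad <- setdiff(as.character(x), lv)
      if (length(bad))
        stop("predictor '", nm, "' has undeclared levels: ", paste(bad, collapse = ", "))
      df[[nm]] <- as.character(x)
    }
  }
  structure(df,
    predictor_meta = predictor_meta,
    class = c("cave_table", class(df))
  )
}

predictor_levels <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(NULL)
  strsplit(spec, "|", fixed = TRUE)[[1]]
}

#' @export
print.cave_table <- function(x, ...) {
  pm <- attr(x, "predictor_meta")
  cat(sprintf("cave_table: %d caves, %d predictors (%s)\n", nrow(x), nrow(pm),
              paste(sprintf("%d %s", table(pm$kind), names(table(pm$kind))),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname cave_table
#' @param x a `cave_table`.
#' @export
cave_coords <- function(x) {
  m <- cbind(easting_m = x$easting_m, northing_m = x$northing_m)
  rownames(m) <- x$cave_id
  m
}

#' Community matrix: cave-by-species abundances with taxonomy
#'
#' Holds non-negative integer counts for each cave and morphospecies,
#' per-species taxonomy (ordered ranks, coarsest first) and a troglobite
#' flag. Taxonomy must be a tree: a label at one rank may not appear under
#' two different parents at the next coarser rank.
#'
#' @param abundance integer matrix, caves in rows (rownames = cave ids),
#'   species in columns (colnames = species ids).
#' @param taxonomy data frame with column `species_id` plus one column per
#'   rank, ordered coarsest (e.g. phylum) to finest (the morphospecies
#'   itself is not a column).
#' @param troglobite named logical vector over species ids.
#' @return a `community_matrix` object.
#' @export
community_matrix <- function(abundance, taxonomy, troglobite) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)),
            !is.null(colnames(abundance)))
  if (any(abundance < 0)) stop("negative abundance")
  if (any(abundance != round(abundance))) stop("abundance must be integer counts")
  sp <- colnames(abundance)
  stopifnot(is.data.frame(taxonomy), "species_id" %in% names(taxonomy))
  taxonomy$species_id <- as.character(taxonomy$species_id)
  miss <- setdiff(sp, taxonomy$species_id)
  if (length(miss)) stop("species lacking taxonomy: ", paste(miss, collapse = ", "))
  taxonomy <- taxonomy[match(sp, taxonomy$species_id), , drop = FALSE]
  ranks <- setdiff(names(taxonomy), "species_id")
  check_taxonomy_tree(taxonomy, ranks)
  miss <- setdiff(sp, names(troglobite))
  if (length(miss)) stop("species lacking troglobite flag: ", paste(miss, collapse = ", "))
  troglobite <- as.logical(troglobite[sp]); names(troglobite) <- sp
  if (anyNA(troglobite)) stop("troglobite flags must be TRUE/FALSE")
  structure(
    list(abundance = abundance, taxonomy = taxonomy,
         troglobite = troglobite, ranks = ranks),
    class = "community_matrix"
  )
}

# every label at rank r must have a single parent label at rank r-1
check_taxonomy_tree <- function(taxonomy, ranks) {
  if (length(ranks) < 1) stop("taxonomy needs at least one rank")
  for (r in seq_along(ranks)[-1]) {
    child <- as.character(taxonomy[[ranks[r]]])
    parent <- as.character(taxonomy[[ranks[r - 1]]])
    tab <- unique(data.frame(child, parent))
    dup <- tab$child[duplicated(tab$child)]
    if (length(dup))
      stop("taxonomy is not a tree: rank '", ranks[r], "' label(s) ",
           paste(unique(dup), collapse = ", "), " have multiple parents")
  }
  invisible(TRUE)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d caves x %d species (%d troglobites), ranks: %s\n",
              nrow(x$abundance), ncol(x$abundance), sum(x$troglobite),
              paste(x$ranks, collapse = " > ")))
  invisible(x)
}

#' @rdname community_matrix
#' @param x a `community_matrix`.
#' @param species character vector of species ids to keep.
#' @export
subset_species <- function(x, species) {
  stopifnot(inherits(x, "community_matrix"))
  miss <- setdiff(species, colnames(x$abundance))
  if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
  community_matrix(x$abundance[, species, drop = FALSE],
                   x$taxonomy[x$taxonomy$species_id %in% species, , drop = FALSE],
                   x$troglobite[species])
}

#' @rdname community_matrix
#' @export
troglobite_species <- function(x) names(x$troglobite)[x$troglobite]

#' @rdname community_matrix
#' @export
troglobite_counts <- function(x) {
  tr <- troglobite_species(x)
  cnt <- rowSums(x$abundance[, tr, drop = FALSE] > 0)
  names(cnt) <- rownames(x$abundance)
  cnt
}

#' Read the cave, community and species tables
#'
#' Reads the three documented CSV schemas and returns validated, aligned
#' objects. `caves.csv`: `cave_id, easting_m, northing_m, <predictors>`.
#' `community.csv` (long): `cave_id, species_id, season, abundance`.
#' `species.csv`: `species_id, <rank columns>, troglobite` (0/1). Caves or
#' species present in one table but missing from another raise an error
#' naming the offender; nothing is silently dropped.
#'
#' @param cave_csv,community_csv,species_csv file paths.
#' @param predictor_meta optional predictor metadata (see [cave_table()]).
#' @param pool_seasons sum the seasonal samples of each cave into a single
#'   community (default `TRUE`); when `FALSE` each cave/season pair becomes
#'   a row labelled `<cave_id>@<season>`.
#' @return list with elements `caves` ([cave_table]) and `community`
#'   ([community_matrix]), rows aligned on cave id.
#' @export
read_inputs <- function(cave_csv, community_csv, species_csv,
                        predictor_meta = NULL, pool_seasons = TRUE) {
  for (f in c(cave_csv, community_csv, species_csv))
    if (!file.exists(f)) stop("file not found: ", f)
  caves <- cave_table(utils::read.csv(cave_csv, stringsAsFactors = FALSE),
                      predictor_meta)
  comm <- utils::read.csv(community_csv, stringsAsFactors = FALSE)
  need <- c("cave_id", "species_id", "abundance")
  miss <- setdiff(need, names(comm))
  if (length(miss)) stop("community table lacks columns: ", paste(miss, collapse = ", "))
  if (!"season" %in% names(comm)) comm$season <- "all"
  if (any(comm$abundance < 0)) stop("negative abundance in community table")
  spt <- utils::read.csv(species_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("species_id", "troglobite") %in% names(spt)))

  unknown_caves <- setdiff(comm$cave_id, caves$cave_id)
  if (length(unknown_caves))
    stop("community table lists cave(s) absent from cave table: ",
         paste(unique(unknown_caves), collapse = ", "))
  orphan_caves <- setdiff(caves$cave_id, comm$cave_id)
  if (length(orphan_caves))
    stop("cave(s) absent from community table: ", paste(orphan_caves, collapse = ", "))
  unknown_sp <- setdiff(comm$species_id, spt$species_id)
  if (length(unknown_sp))
    stop("community table lists species absent from species table: ",
         paste(unique(unknown_sp), collapse = ", "))

  if (!pool_seasons)
    comm$cave_id <- paste(comm$cave_id, comm$season, sep = "@")
  sp_ids <- sort(unique(spt$species_id))
  row_ids <- if (pool_seasons) caves$cave_id else sort(unique(comm$cave_id))
  ab <- matrix(0L, length(row_ids), length(sp_ids),
               dimnames = list(row_ids, sp_ids))
  agg <- stats::aggregate(abundance ~ cave_id + species_id, comm, sum)
  ab[cbind(match(agg$cave_id, row_ids), match(agg$species_id, sp_ids))] <-
    as.integer(agg$abundance)
  ranks <- setdiff(names(spt), c("species_id", "troglobite"))
  taxonomy <- spt[, c("species_id", ranks), drop = FALSE]
  trog <- as.logical(spt$troglobite); names(trog) <- spt$species_id
  list(caves = caves, community = community_matrix(ab, taxonomy, trog))
}
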