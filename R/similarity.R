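#' Log-transform abundance counts
#'
#' Elementwise `log(x + 1)` (natural log by default). Optionally followed by
#' per-species maximum standardization (each column divided by its maximum
#' transformed value), off by default.
#'
#' @param x non-negative abundance matrix.
#' @param base log base (default `exp(1)`).
#' @param standardize divide each species column by its maximum after the
#'   log transform (columns with all zeros are left untouched).
#' @return real matrix with the same dimnames.
#' @export
log_transform <- function(x, base = exp(1), standardize = FALSE) {
  if (any(x < 0)) stop("negative input")
  out <- log1p(x) / log(base)
  if (standardize) {
    mx <- apply(out, 2, max)
    mx[mx == 0] <- 1
    out <- sweep(out, 2, mx, "/")
  }
  out
}

#' Bray-Curtis dissimilarity between cave communities
#'
#' `BC_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`, bounded in
#' \[0, 1\]. A pair in which both rows are all zero has no defined value;
#' by default this is an error, `zero_policy = "one"` assigns 1 (maximally
#' dissimilar) with a warning.
#'
#' @param x non-negative cave-by-species matrix (at least 2 rows).
#' @param zero_policy `"error"` (default) or `"one"`.
#' @return square symmetric dissimilarity matrix with a `metric` attribute.
#' @export
bray_curtis <- function(x, zero_policy = c("error", "one")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (any(x < 0)) stop("negative input")
  n <- nrow(x)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num[i, j] <- num[j, i] <- sum(abs(x[i, ] - x[j, ]))
      den[i, j] <- den[j, i] <- sum(x[i, ] + x[j, ])
    }
  }
  bad <- den == 0 & row(den) != col(den)
  if (any(bad)) {
    if (zero_policy == "error") {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop("pair with both communities empty: ",
           rownames(x)[idx[1]], " / ", rownames(x)[idx[2]],
           " (use zero_policy = \"one\" to assign BC = 1)")
    }
    warning(sum(bad) / 2, " empty-empty pair(s) assigned BC = 1")
    num[bad] <- 1; den[bad] <- 1
  }
  den[den == 0] <- 1 # diagonal
  d <- num / den
  dimnames(d) <- list(rownames(x), rownames(x))
  as_dissim(d, "bray_curtis")
}

as_dissim <- function(d, metric) {
  validate_dissim(d)
  attr(d, "metric") <- metric
  d
}

validate_dissim <- function(d, tol = 1e-12) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (!all(is.finite(d))) stop("dissimilarity values must be finite")
  if (any(abs(diag(d)) > tol)) stop("dissimilarity diagonal must be zero")
  if (max(abs(d - t(d))) > tol) stop("dissimilarity matrix must be symmetric")
  if (any(d < -tol)) stop("dissimilarity values must be non-negative")
  invisible(d)
}

#' Normalized taxonomic distances between species
#'
#' The rank hierarchy is read as an ultrametric tree. The distance between
#' two morphospecies is the number of rank steps climbed from the species
#' level until a shared taxon is reached, divided by the total number of
#' ranks above species, so two congeners are 1/L apart and species sharing
#' only the root (coarsest rank disagreeing too) are at distance 1.
#'
#' @param taxonomy data frame with `species_id` plus rank columns ordered
#'   coarsest to finest.
#' @return square symmetric matrix over species, values in \[0, 1\].
#' @export
taxonomic_distances <- function(taxonomy) {
  ranks <- setdiff(names(taxonomy), "species_id")
  if (length(ranks) < 1) stop("need at least one rank above species")
  check_taxonomy_tree(taxonomy, ranks)
  sp <- as.character(taxonomy$species_id)
  L <- length(ranks)
  # path: coarsest..finest labels, then species id as the leaf
  lab <- as.matrix(taxonomy[, ranks, drop = FALSE])
  n <- length(sp)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- which(lab[i, ] == lab[j, ])
      deepest <- if (length(shared)) max(shared) else 0L
      # rank steps from species level up to the lowest shared taxon; species
      # sharing no rank at all are capped at the maximum distance 1
      d[i, j] <- d[j, i] <- min(1, (L + 1 - max(deepest, 1L)) / L)
    }
  }
  as_dissim(d, "taxonomic")
}

#' Mean pairwise taxonomic distance between two communities
#'
#' Unweighted (default): the mean of `d(i, j)` over species `i` present in
#' community A and `j` present in community B. Weighted: the
#' abundance-weighted mean using relative abundances within each community.
#'
#' @param a,b abundance vectors named by species.
#' @param d species-by-species distance matrix.
#' @param weighted use relative-abundance weights.
#' @return a single MPD value, or `NA` with a warning when either community
#'   is empty on the species of `d`.
#' @export
mean_pairwise_distance <- function(a, b, d, weighted = FALSE) {
  sp <- rownames(d)
  a <- a[sp]; b <- b[sp]
  ia <- which(!is.na(a) & a > 0); ib <- which(!is.na(b) & b > 0)
  if (!length(ia) || !length(ib)) {
    warning("empty community: MPD undefined, returning NA")
    return(NA_real_)
  }
  sub <- d[ia, ib, drop = FALSE]
  if (!weighted) return(mean(sub))
  f <- a[ia] / sum(a[ia]); g <- b[ib] / sum(b[ib])
  as.numeric(f %*% sub %*% g)
}

#' All-pairs MPD matrix between cave communities
#'
#' @param x abundance matrix (caves x species).
#' @param d species distance matrix (e.g. [taxonomic_distances()]).
#' @param weighted see [mean_pairwise_distance()].
#' @param na_policy what to do with pairs involving an empty community:
#'   `"error"` (default), or `"max"` to impute the maximum observed MPD
#'   (treat an empty community as maximally distant) with a warning.
#' @return square symmetric matrix of MPD values over caves.
#' @export
mpd_matrix <- function(x, d, weighted = FALSE, na_policy = c("error", "max")) {
  na_policy <- match.arg(na_policy)
  n <- nrow(x)
  out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  empty <- rowSums(x[, rownames(d), drop = FALSE]) == 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- if (empty[i] || empty[j]) NA_real_ else
        suppressWarnings(mean_pairwise_distance(x[i, ], x[j, ], d, weighted))
      out[i, j] <- out[j, i] <- v
    }
  }
  if (anyNA(out)) {
    if (na_policy == "error")
      stop("empty communities: ", paste(rownames(x)[empty], collapse = ", "),
           " (use na_policy = \"max\" to impute)")
    warning(sum(empty), " empty communit(ies): MPD pairs imputed at the observed maximum")
    out[is.na(out)] <- max(out, na.rm = TRUE)
  }
  as_dissim(out, if (weighted) "mpd_weighted" else "mpd")
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Eigen-decomposition of the Gower-centered matrix
#' `G = C(-D^2/2)C`, `C = I - 11'/n`. Scores are eigenvectors scaled by the
#' square roots of positive eigenvalues; negative eigenvalues (possible for
#' non-Euclidean inputs such as raw MPD matrices) are reported, not
#' corrected.
#'
#' @param d dissimilarity matrix.
#' @param n_axes number of axes to return (default: all positive).
#' @return list of class `cave_pcoa`: `scores` (caves x axes, columns
#'   `MDS1`, `MDS2`, ...), `eigenvalues` (all, decreasing),
#'   `negative_magnitude` (sum of |negative eigenvalues|), `labels`.
#' @export
pcoa <- function(d, n_axes = NULL) {
  validate_dissim(d)
  n <- nrow(d)
  G <- gower_center(d)
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > max(e$values, 0) * 1e-10 & e$values > 1e-12)
  if (is.null(n_axes)) n_axes <- length(pos)
  if (n_axes > length(pos))
    stop("n_axes (", n_axes, ") exceeds positive-eigenvalue count (", length(pos), ")")
  if (n_axes == 0) {
    scores <- matrix(0, n, 0, dimnames = list(rownames(d), NULL))
  } else {
    idx <- pos[seq_len(n_axes)]
    scores <- e$vectors[, idx, drop = FALSE] %*%
      diag(sqrt(e$values[idx]), n_axes, n_axes)
    dimnames(scores) <- list(rownames(d), paste0("MDS", seq_len(n_axes)))
  }
  structure(list(
    scores = scores,
    eigenvalues = e$values,
    negative_magnitude = sum(abs(e$values[e$values < 0])),
    labels = rownames(d)
  ), class = "cave_pcoa")
}

#' @export
print.cave_pcoa <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("cave_pcoa: %d caves, %d positive axes", length(x$labels),
              ncol(x$scores)))
  rel <- ev[seq_len(min(2, ncol(x$scores)))] / sum(ev[ev > 0])
  if (length(rel)) cat(sprintf(" (first axes: %s)",
                               paste(sprintf("%.1f%%", 100 * rel), collapse = ", ")))
  if (x$negative_magnitude > 0)
    cat(sprintf("; |negative eigenvalues| = %.4g", x$negative_magnitude))
  cat("\n")
  invisible(x)
}

#' Spearman correlation between subset and total cave richness
#'
#' Checks how well a taxonomic subset (e.g. the genus-level-identified
#' species used for phylogenetic distance) represents the full community:
#' Spearman rank correlation between per-cave richness on the subset and
#' total richness.
#'
#' @param community a [community_matrix()].
#' @param species character vector, the subset.
#' @return list with `rho` and `p`.
#' @export
subset_richness_correlation <- function(community, species) {
  ab <- community$abundance
  if (nrow(ab) < 3) stop("need at least 3 caves")
  s_tot <- rowSums(ab > 0)
  s_sub <- rowSums(ab[, species, drop = FALSE] > 0)
  if (stats::var(s_tot) == 0 || stats::var(s_sub) == 0)
    stop("constant richness vector: rho undefined")
  ct <- suppressWarnings(stats::cor.test(s_sub, s_tot, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Percent similarity from a dissimilarity matrix
#'
#' @param d dissimilarity matrix on a \[0, 1\] scale.
#' @return matrix of `100 * (1 - d)`.
#' @export
similarity_percent <- function(d) 100 * (1 - d)
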