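#' Equal-width distance classes over the observed pairwise distances
#'
#' Bins span the range of observed pairwise Euclidean distances. The default
#' class count follows Sturges' rule on the number of pairs. Classes left
#' empty by sparse data are flagged (`n_pairs == 0`) and excluded from
#' significance testing downstream.
#'
#' @param coords cave coordinate matrix (meters, planar).
#' @param n_classes number of classes; default `ceiling(log2(n_pairs)) + 1`.
#' @return data frame: `low_m`, `high_m` (class is `(low, high]`, the first
#'   class closed at its lower bound), `center_m`, `n_pairs`.
#' @export
distance_classes <- function(coords, n_classes = NULL) {
  stopifnot(nrow(coords) >= 2)
  dist_m <- as.matrix(stats::dist(coords))
  dv <- dist_m[lower.tri(dist_m)]
  if (max(dv) == 0) stop("all caves coincident")
  if (is.null(n_classes)) n_classes <- ceiling(log2(length(dv))) + 1
  if (length(dv) == 1 || diff(range(dv)) == 0) {
    br <- c(min(dv) - 1e-9, max(dv))
    n_classes <- 1
  } else {
    br <- seq(min(dv), max(dv), length.out = n_classes + 1)
  }
  cls <- cut(dv, breaks = br, include.lowest = TRUE)
  data.frame(
    low_m = br[-length(br)],
    high_m = br[-1],
    center_m = (br[-length(br)] + br[-1]) / 2,
    n_pairs = as.integer(table(cls))
  )
}

#' Moran's I with a binary pair-membership weight matrix
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `w` symmetric binary (1 when the pair falls in the distance class)
#' and `S0 = sum(w)`.
#'
#' @param values per-cave numeric vector.
#' @param w symmetric binary weight matrix, zero diagonal.
#' @return Moran's I.
#' @export
morans_i <- function(values, w) {
  n <- length(values)
  stopifnot(nrow(w) == n, ncol(w) == n)
  if (sum(w) == 0) stop("no pairs in class")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("constant variable")
  (n / sum(w)) * as.numeric(z %*% w %*% z) / ss
}

#' Moran's I correlogram with progressive Bonferroni correction
#'
#' Computes Moran's I per distance class with two-sided p-values from a
#' Monte-Carlo permutation of the values (default) or the normal
#' approximation under randomization. Progressive Bonferroni tests the k-th
#' class (ordered by increasing distance, 1-indexed among non-empty classes)
#' at `alpha / k`. The significant range is the upper bound of the largest
#' class that is corrected-significant with positive I (similarity, not
#' dispersion).
#'
#' @param values per-cave numeric vector.
#' @param coords cave coordinates (meters).
#' @param classes output of [distance_classes()] (computed if `NULL`).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations (default 999); ignored for `method = "normal"`.
#' @param seed RNG seed for the permutation null.
#' @param method `"permutation"` (default) or `"normal"`.
#' @return object of class `correlogram`: the class table augmented with
#'   `I`, `expected_I`, `p`, `sig_raw`, `sig_corrected`, plus
#'   `significant_range_m` (`NA` when no class qualifies).
#' @export
correlogram <- function(values, coords, classes = NULL, alpha = 0.05,
                        n_perm = 999, seed = NULL,
                        method = c("permutation", "normal")) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 3) stop("need at least 3 caves")
  if (stats::var(values) == 0) stop("constant variable")
  if (is.null(classes)) classes <- distance_classes(coords)
  dist_m <- as.matrix(stats::dist(coords))
  ws <- lapply(seq_len(nrow(classes)), function(k) {
    w <- (dist_m > classes$low_m[k] | (k == 1 & dist_m >= classes$low_m[k])) &
      dist_m <= classes$high_m[k]
    diag(w) <- FALSE
    storage.mode(w) <- "double"
    w
  })
  usable <- classes$n_pairs > 0
  e_i <- -1 / (n - 1)
  I <- rep(NA_real_, nrow(classes))
  p <- rep(NA_real_, nrow(classes))
  I[usable] <- vapply(which(usable), function(k) morans_i(values, ws[[k]]), 0)
  if (method == "normal") {
    for (k in which(usable)) {
      v <- moran_var_randomization(values, ws[[k]])
      z <- (I[k] - e_i) / sqrt(v)
      p[k] <- 2 * stats::pnorm(-abs(z))
    }
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    ge <- matrix(0, n_perm, sum(usable))
    for (b in seq_len(n_perm)) {
      vp <- sample(values)
      ge[b, ] <- vapply(which(usable), function(k) morans_i(vp, ws[[k]]), 0)
    }
    obs_dev <- abs(I[usable] - e_i)
    p[usable] <- (1 + colSums(abs(sweep(ge, 2, e_i)) >= rep(obs_dev, each = n_perm))) /
      (1 + n_perm)
  }
  sig_raw <- !is.na(p) & p <= alpha
  rank_k <- cumsum(usable)          # 1-indexed among non-empty classes
  sig_corr <- progressive_bonferroni(p, alpha, rank_k)
  out <- cbind(classes, I = I, expected_I = e_i, p = p,
               sig_raw = sig_raw, sig_corrected = sig_corr)
  hit <- which(sig_corr & !is.na(I) & I > 0)
  attr(out, "significant_range_m") <-
    if (length(hit)) classes$high_m[max(hit)] else NA_real_
  # robust variant: end of the initial contiguous run of significant
  # positive classes (immune to isolated long-range false positives)
  pos <- sig_corr & !is.na(I) & I > 0
  attr(out, "contiguous_range_m") <-
    if (length(pos) && pos[1]) classes$high_m[max(which(cumsum(!pos) == 0))]
    else NA_real_
  attr(out, "alpha") <- alpha
  class(out) <- c("correlogram", class(out))
  out
}

#' Progressive Bonferroni correction
#'
#' The k-th test (classes ordered by increasing distance, 1-indexed) is
#' significant iff `p_k <= alpha / k`; each class is corrected
#' independently (no stop-at-first-failure), so non-consecutive significant
#' patterns are possible. Never declares significance where the
#' uncorrected test would not.
#'
#' @param p p-values in distance-class order (`NA` for untested classes).
#' @param alpha significance level.
#' @param k test ranks (default `seq_along(p)`).
#' @return logical vector.
#' @export
progressive_bonferroni <- function(p, alpha = 0.05, k = seq_along(p)) {
  !is.na(p) & p <= alpha / k
}

# variance of Moran's I under randomization (Cliff & Ord)
moran_var_randomization <- function(x, w) {
  n <- length(x)
  s0 <- sum(w)
  s1 <- sum((w + t(w))^2) / 2
  s2 <- sum((rowSums(w) + colSums(w))^2)
  z <- x - mean(x)
  b2 <- n * sum(z^4) / sum(z^2)^2
  num <- n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
    b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)
  num / ((n - 1) * (n - 2) * (n - 3) * s0^2) - 1 / (n - 1)^2
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("correlogram: %d classes, significant range %s m\n",
              nrow(x),
              format(attr(x, "significant_range_m"))))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @rdname correlogram
#' @param x a `correlogram`.
#' @param rule `"largest"` (default; upper bound of the largest
#'   corrected-significant positive class) or `"contiguous"` (upper bound of
#'   the initial contiguous run of such classes, robust to isolated
#'   long-range false positives of the per-class tests).
#' @export
significant_range <- function(x, rule = c("largest", "contiguous")) {
  rule <- match.arg(rule)
  if (rule == "largest") attr(x, "significant_range_m")
  else attr(x, "contiguous_range_m")
}

#' Correlograms over ordination axes
#'
#' Runs [correlogram()] on each requested ordination axis and combines the
#' per-axis significant ranges (policy `"max"`: largest range over the
#' axes). The default tests MDS1 only.
#'
#' @param ordination a [pcoa()] result.
#' @param coords cave coordinates (meters).
#' @param axes axis names (default `"MDS1"`).
#' @param ... passed to [correlogram()].
#' @return list with `per_axis` (named list of correlograms) and
#'   `significant_range_m` (the combined range; `NA` if no axis yields one).
#' @export
axes_correlogram <- function(ordination, coords, axes = "MDS1", ...) {
  miss <- setdiff(axes, colnames(ordination$scores))
  if (length(miss)) stop("unknown axes: ", paste(miss, collapse = ", "))
  per <- lapply(axes, function(a)
    correlogram(ordination$scores[, a], coords, ...))
  names(per) <- axes
  ranges <- vapply(per, significant_range, 0)
  comb <- if (all(is.na(ranges))) NA_real_ else max(ranges, na.rm = TRUE)
  list(per_axis = per, significant_range_m = comb)
}
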