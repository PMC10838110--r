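#' Gower-center a dissimilarity matrix
#'
#' `G = C A C` with `A = -D^2 / 2` and `C = I - 11'/n`. This inner-product
#' form is the core of distance-based linear modeling and of principal
#' coordinate analysis.
#'
#' @param d square symmetric dissimilarity matrix.
#' @return centered inner-product matrix `G` (row/column sums zero).
#' @export
gower_center <- function(d) {
  n <- nrow(d)
  A <- -d^2 / 2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  dimnames(G) <- dimnames(d)
  G
}

#' Predictor sets for distance-based modeling
#'
#' Builds the design columns for a named set of predictors: numeric
#' predictors enter as-is, ordinal predictors as integer level codes, and
#' categorical predictors as one binary indicator column per level (the
#' hat-matrix formulation is insensitive to the resulting redundancy with
#' the intercept; columns are reduced to a full-rank basis when fitted).
#'
#' @param caves a [cave_table()].
#' @param grouping how to group predictors into sets: `"group"` (default,
#'   use the `group` label from the predictor metadata, with the coordinate
#'   pair always forming the `"Distance"` set) or `"predictor"` (one set per
#'   predictor, plus `"Distance"`).
#' @return named list of numeric matrices (one per set, caves in rows).
#' @export
predictor_sets <- function(caves, grouping = c("group", "predictor")) {
  grouping <- match.arg(grouping)
  pm <- attr(caves, "predictor_meta")
  sets <- list(Distance = cave_coords(caves))
  key <- if (grouping == "group") pm$group else pm$name
  for (g in unique(key)) {
    cols <- list()
    for (i in which(key == g)) {
      nm <- pm$name[i]; x <- caves[[nm]]
      if (pm$kind[i] == "numeric") {
        cols[[nm]] <- as.numeric(x)
      } else if (pm$kind[i] == "ordinal") {
        lv <- predictor_levels(pm$levels[i])
        cols[[nm]] <- match(as.character(x), lv)
      } else {
        lv <- predictor_levels(pm$levels[i])
        for (l in lv) cols[[paste(nm, l, sep = ".")]] <-
            as.numeric(as.character(x) == l)
      }
    }
    sets[[g]] <- do.call(cbind, cols)
    rownames(sets[[g]]) <- caves$cave_id
  }
  sets
}

# centered full-column-rank design; drops collinear columns via QR
center_design <- function(X) {
  X <- as.matrix(X)
  X <- sweep(X, 2, colMeans(X))
  qr_ <- qr(X)
  keep <- qr_$pivot[seq_len(qr_$rank)]
  X[, sort(keep), drop = FALSE]
}

hat_matrix <- function(X) {
  if (is.null(X) || ncol(X) == 0) return(NULL)
  X %*% solve(crossprod(X), t(X))
}

#' Pseudo-F for predictor sets on a dissimilarity matrix
#'
#' McArdle-Anderson trace statistic. With `H` the hat matrix of the centered
#' `[X_cond, X_add]` design and `H0` that of `X_cond`:
#' `F = (tr(HGH) - tr(H0 G H0)) / m  /  (tr((I-H)G(I-H)) / (n - q - 1))`
#' where `m` is the number of added (independent) columns and `q` the total
#' number of fitted columns. R-squared values are trace ratios against
#' `tr(G)`.
#'
#' @param G Gower-centered matrix (from [gower_center()]).
#' @param X_add matrix of columns being tested.
#' @param X_cond matrix of columns conditioned on (or `NULL`).
#' @return list: `F`, `R2_partial` (added), `R2_cumulative` (full model),
#'   `m`, `q`, `df_resid`.
#' @export
pseudo_f <- function(G, X_add, X_cond = NULL) {
  n <- nrow(G)
  Xa <- center_design(X_add)
  Xc <- if (!is.null(X_cond) && NCOL(X_cond) > 0) center_design(X_cond) else NULL
  Xfull <- center_design(cbind(Xc, Xa))
  q <- ncol(Xfull)
  qc <- if (is.null(Xc)) 0L else ncol(Xc)
  m <- q - qc
  if (m == 0) stop("added columns are collinear with the conditioned set: ",
                   paste(colnames(X_add), collapse = ", "))
  if (n <= q + 1) stop("too few caves for ", q, " fitted columns")
  H <- hat_matrix(Xfull)
  tr_full <- sum(H * G)            # tr(HGH) = tr(HG) for projection H
  tr_cond <- if (is.null(Xc)) 0 else sum(hat_matrix(Xc) * G)
  tr_tot <- sum(diag(G))
  # the residual trace is non-negative in exact arithmetic; clamp the
  # floating-point remainder so perfect predictors yield F = +Inf, not noise
  tr_res <- max(tr_tot - tr_full, 0)
  Fstat <- ((tr_full - tr_cond) / m) / (tr_res / (n - q - 1))
  list(F = Fstat,
       R2_partial = (tr_full - tr_cond) / tr_tot,
       R2_cumulative = tr_full / tr_tot,
       m = m, q = q, df_resid = n - q - 1)
}

#' Permutation p-value for a pseudo-F test
#'
#' Freedman-Lane style: the Gower matrix is split into the part fitted by
#' the conditioned design and the residual part
#' `E = (I - H0) G (I - H0)`; permuted statistics are computed on
#' `H0 G H0 + P E P'`. With no conditioning this reduces to permuting the
#' rows/columns of `G`, i.e. permuting the observations.
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams pseudo_f
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param scheme `"freedman_lane"` (default) or `"raw"` (permute `G`
#'   directly even under conditioning).
#' @param perms optional matrix of explicit permutations (one per row,
#'   excluding the identity), e.g. the full enumeration on tiny designs;
#'   overrides `n_perm` and `seed`.
#' @return list: `p`, `F_obs`, `n_perm`, `seed`.
#' @export
permutation_p <- function(G, X_add, X_cond = NULL, n_perm = 999, seed = NULL,
                          scheme = c("freedman_lane", "raw"), perms = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(perms)) n_perm <- nrow(perms)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(G)
  obs <- pseudo_f(G, X_add, X_cond)
  has_cond <- !is.null(X_cond) && NCOL(X_cond) > 0
  if (has_cond && scheme == "freedman_lane") {
    H0 <- hat_matrix(center_design(X_cond))
    R0 <- diag(n) - H0
    E <- R0 %*% G %*% R0
    Gfit <- H0 %*% G %*% H0
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- if (is.null(perms)) sample.int(n) else perms[b, ]
    Gp <- if (has_cond && scheme == "freedman_lane")
      Gfit + E[perm, perm] else G[perm, perm]
    Fp <- pseudo_f(Gp, X_add, X_cond)$F
    if (Fp >= obs$F - 1e-12) count <- count + 1L
  }
  list(p = (1 + count) / (1 + n_perm), F_obs = obs$F,
       n_perm = n_perm, seed = seed)
}

#' Forward selection of predictor sets by adjusted R-squared
#'
#' Starts from the null model and at each step adds the candidate set that
#' maximizes the cumulative adjusted R-squared
#' `adjR2 = 1 - (1 - R2)(n - 1)/(n - q - 1)`. The added set's pseudo-F is
#' tested by permutation conditioned on the sets already selected; selection
#' stops when no candidate improves the adjusted R-squared or the best
#' candidate's p-value reaches `alpha`.
#'
#' @param d dissimilarity matrix.
#' @param sets named list of predictor matrices (see [predictor_sets()]).
#' @param alpha stopping level (default 0.05).
#' @param n_perm permutations per step (default 999).
#' @param seed RNG seed (per-step seeds are derived from it).
#' @return object of class `distlm`: data frame `steps` (`set`, `adjR2`,
#'   `R2`, `pseudo_F`, `p`), `stop_reason`, `alpha`, `n_perm`, `seed`.
#' @export
forward_select <- function(d, sets, alpha = 0.05, n_perm = 999, seed = NULL) {
  if (length(sets) < 1) stop("need at least one candidate set")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  G <- gower_center(d)
  n <- nrow(G)
  adj_r2 <- function(R2, q) 1 - (1 - R2) * (n - 1) / (n - q - 1)
  selected <- character(0)
  steps <- list()
  cur_adj <- 0
  stop_reason <- "no candidates left"
  step_i <- 0L
  while (length(selected) < length(sets)) {
    step_i <- step_i + 1L
    Xc <- if (length(selected))
      do.call(cbind, unname(sets[selected])) else NULL
    cands <- setdiff(names(sets), selected)
    best <- NULL
    for (nm in cands) {
      fit <- tryCatch(pseudo_f(G, sets[[nm]], Xc), error = function(e) NULL)
      if (is.null(fit)) next
      a <- adj_r2(fit$R2_cumulative, fit$q)
      if (is.null(best) || a > best$adj) best <- list(name = nm, fit = fit, adj = a)
    }
    if (is.null(best)) { stop_reason <- "no estimable candidate"; break }
    if (best$adj <= cur_adj && length(selected)) {
      stop_reason <- "no adjusted R2 improvement"; break
    }
    step_seed <- if (is.null(seed)) NULL else (seed + step_i) %% .Machine$integer.max
    pt <- permutation_p(G, sets[[best$name]], Xc, n_perm = n_perm,
                        seed = step_seed)
    if (pt$p >= alpha) {
      stop_reason <- sprintf("best candidate '%s' p = %.4g >= alpha", best$name, pt$p)
      break
    }
    selected <- c(selected, best$name)
    cur_adj <- best$adj
    steps[[length(steps) + 1L]] <- data.frame(
      set = best$name, adjR2 = best$adj, R2 = best$fit$R2_cumulative,
      pseudo_F = best$fit$F, p = pt$p, stringsAsFactors = FALSE
    )
  }
  if (length(selected) == length(sets)) stop_reason <- "all sets selected"
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(set = character(), adjR2 = numeric(), R2 = numeric(),
                 pseudo_F = numeric(), p = numeric()),
    stop_reason = stop_reason, alpha = alpha, n_perm = n_perm, seed = seed
  ), class = "distlm")
}

#' @export
print.distlm <- function(x, ...) {
  cat("distlm forward selection (alpha =", x$alpha, ", n_perm =", x$n_perm, ")\n")
  if (nrow(x$steps)) print(x$steps, digits = 4, row.names = FALSE)
  cat("stop:", x$stop_reason, "\n")
  invisible(x)
}
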