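#' Scale a pairwise response onto (0, 1)
#'
#' Breakpoint models use a Gaussian GLM with a logistic link, so responses
#' must live strictly inside (0, 1). Percent similarity is divided by 100;
#' MPD values are min-max scaled onto `(eps, 1 - eps)`. The transform
#' parameters are stored so the mapping can be inverted.
#'
#' @param values numeric vector.
#' @param kind `"similarity_pct"` or `"mpd"`.
#' @param eps boundary offset for min-max scaling (default 1e-6).
#' @return numeric vector with attribute `transform` (list with `kind` and,
#'   for MPD, `min`, `max`, `eps`).
#' @export
scale_response <- function(values, kind = c("similarity_pct", "mpd"),
                           eps = 1e-6) {
  kind <- match.arg(kind)
  if (!all(is.finite(values))) stop("non-finite response values")
  if (diff(range(values)) == 0) stop("constant response")
  if (kind == "similarity_pct") {
    out <- values / 100
    tr <- list(kind = kind)
  } else {
    lo <- min(values); hi <- max(values)
    out <- eps + (values - lo) / (hi - lo) * (1 - 2 * eps)
    tr <- list(kind = kind, min = lo, max = hi, eps = eps)
  }
  attr(out, "transform") <- tr
  out
}

#' @rdname scale_response
#' @param scaled output of `scale_response()`.
#' @export
unscale_response <- function(scaled) {
  tr <- attr(scaled, "transform")
  if (is.null(tr)) stop("no transform attribute")
  if (tr$kind == "similarity_pct") return(as.numeric(scaled) * 100)
  tr$min + (as.numeric(scaled) - tr$eps) / (1 - 2 * tr$eps) * (tr$max - tr$min)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)`.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size (`n > k + 1`).
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

glm_logit_gaussian <- function(formula, data) {
  mu0 <- pmin(pmax(data$y, 1e-3), 1 - 1e-3)
  # do.call so mustart is passed by value (glm evaluates arguments lazily in
  # the formula environment)
  do.call(stats::glm, list(formula, data = data,
                           family = stats::gaussian(link = "logit"),
                           mustart = mu0))
}

#' Segmented (breakpoint) GLM on pairwise data
#'
#' Fits a piecewise-linear model on the link scale by iterative
#' linearization: at the current breakpoint `psi` the working model
#' `y ~ x + U + V` is fitted with `U = (x - psi) * 1[x > psi]` and
#' `V = -1[x > psi]`, and `psi` is updated by `gamma_V / beta_U` until the
#' `V` coefficient vanishes. The model uses Gaussian errors with a logistic
#' link, so `y` must be strictly inside (0, 1) (see [scale_response()]).
#' The segmented fit is compared with the plain linear GLM by AICc; it is
#' chosen when its AICc is lower, and flagged significant when, in
#' addition, the 95% CI of `psi` stays inside the observed range of `x`.
#'
#' @param y response in (0, 1).
#' @param x pairwise predictor values (e.g. absolute differences).
#' @param psi_init starting breakpoint(s); default multi-start at the
#'   quartiles `q25, q50, q75` of `x`, keeping the best-AICc fit.
#' @param tol convergence tolerance on the `V` coefficient (default 1e-6).
#' @param max_iter maximum iterations per start (default 50).
#' @param predictor predictor name carried into the result.
#' @param ordinal when `TRUE` the favored-region threshold is reported as
#'   `floor(psi)` level steps.
#' @return object of class `breakpoint_fit`: `predictor`, `psi`, `psi_se`,
#'   `slope_before`, `slope_after` (link scale), `aicc_linear`,
#'   `aicc_segmented`, `delta_aicc`, `chosen` (`"segmented"`/`"linear"`),
#'   `significant`, `converged`, `rule` (favored-region description),
#'   `threshold` (the rule threshold on the predictor scale, `NA` for
#'   linear).
#' @export
fit_segmented <- function(y, x, psi_init = NULL, tol = 1e-6, max_iter = 50,
                          predictor = "x", ordinal = FALSE) {
  stopifnot(length(y) == length(x))
  if (length(y) < 20) stop("need at least 20 pairs")
  if (diff(range(x)) == 0) stop("constant predictor")
  if (any(y <= 0 | y >= 1)) stop("response must be strictly inside (0, 1)")
  dat <- data.frame(y = y, x = x)
  lin <- glm_logit_gaussian(y ~ x, dat)
  k_lin <- attr(stats::logLik(lin), "df")            # intercept, slope, sigma
  aicc_lin <- aicc(as.numeric(stats::logLik(lin)), k_lin, length(y))
  if (is.null(psi_init))
    psi_init <- unname(stats::quantile(x, c(0.25, 0.5, 0.75)))
  psi_init <- unique(psi_init)

  best <- NULL
  for (psi0 in psi_init) {
    fit <- muggeo_iterate(dat, psi0, tol, max_iter)
    if (is.null(fit)) next
    if (is.null(best) || fit$aicc < best$aicc) best <- fit
  }
  if (is.null(best)) {
    res <- list(predictor = predictor, psi = NA_real_, psi_se = NA_real_,
                slope_before = unname(stats::coef(lin)["x"]),
                slope_after = unname(stats::coef(lin)["x"]),
                aicc_linear = aicc_lin, aicc_segmented = NA_real_,
                delta_aicc = NA_real_, chosen = "linear", significant = FALSE,
                converged = FALSE, rule = "none (linear model preferred)",
                threshold = NA_real_, ordinal = ordinal)
    class(res) <- "breakpoint_fit"
    return(res)
  }
  delta <- best$aicc - aicc_lin
  ci <- best$psi + c(-1, 1) * 1.96 * best$psi_se
  within <- is.finite(best$psi_se) &&
    ci[1] > min(x) && ci[2] < max(x)
  chosen <- if (!is.na(delta) && delta < 0) "segmented" else "linear"
  significant <- chosen == "segmented" && within
  thr <- if (chosen == "segmented") {
    if (ordinal) floor(best$psi) else best$psi
  } else NA_real_
  rule <- if (chosen == "segmented") {
    if (best$slope_before > 0)
      warning("pre-break slope is positive; favored-region rule assumes ",
              "similarity decreases with the pairwise difference")
    sprintf("pair similar iff |delta %s| <= %s", predictor, format(thr))
  } else "none (linear model preferred)"
  res <- list(predictor = predictor, psi = best$psi, psi_se = best$psi_se,
              slope_before = best$slope_before, slope_after = best$slope_after,
              aicc_linear = aicc_lin, aicc_segmented = best$aicc,
              delta_aicc = delta, chosen = chosen, significant = significant,
              converged = best$converged, rule = rule, threshold = thr,
              ordinal = ordinal)
  class(res) <- "breakpoint_fit"
  res
}

muggeo_iterate <- function(dat, psi, tol, max_iter) {
  x <- dat$x
  n <- length(x)
  lo <- min(x); hi <- max(x)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- (x - psi) * (x > psi)
    V <- -as.numeric(x > psi)
    if (sum(x > psi) < 2 || sum(x <= psi) < 2) return(NULL)
    dat$U <- U; dat$V <- V
    fit <- tryCatch(glm_logit_gaussian(y ~ x + U + V, dat),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) return(NULL)
    gamma_v <- stats::coef(fit)["V"]
    beta_u <- stats::coef(fit)["U"]
    if (abs(beta_u) < 1e-12) return(NULL)
    step <- gamma_v / beta_u
    psi_new <- min(max(psi + step, lo + 1e-9), hi - 1e-9)
    if (abs(gamma_v) < tol || abs(psi_new - psi) < tol * max(1, hi - lo)) {
      psi <- psi_new
      converged <- TRUE
      break
    }
    psi <- psi_new
  }
  # final refit at the converged breakpoint, without the V working column
  U <- (x - psi) * (x > psi)
  if (sum(x > psi) < 2 || sum(x <= psi) < 2) return(NULL)
  datf <- data.frame(y = dat$y, x = x, U = U)
  fit <- tryCatch(glm_logit_gaussian(y ~ x + U, datf), error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit))) return(NULL)
  # delta-method SE of psi from the working model at convergence
  dat$U <- U; dat$V <- -as.numeric(x > psi)
  wfit <- tryCatch(glm_logit_gaussian(y ~ x + U + V, dat), error = function(e) NULL)
  psi_se <- NA_real_
  if (!is.null(wfit) && !anyNA(stats::coef(wfit))) {
    sm <- summary(wfit)$coefficients
    if (all(c("U", "V") %in% rownames(sm)) && abs(sm["U", 1]) > 1e-12)
      psi_se <- abs(sm["V", 2] / sm["U", 1])
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df") + 1          # + the breakpoint itself
  co <- stats::coef(fit)
  list(psi = psi, psi_se = psi_se,
       slope_before = unname(co["x"]),
       slope_after = unname(co["x"] + co["U"]),
       aicc = aicc(ll, k, n), converged = converged)
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("breakpoint_fit[%s]: chosen = %s", x$predictor, x$chosen))
  if (x$chosen == "segmented")
    cat(sprintf(", psi = %.4g (se %.3g), dAICc = %.3g, significant = %s",
                x$psi, x$psi_se, x$delta_aicc, x$significant))
  cat("\n  rule:", x$rule, "\n")
  invisible(x)
}

#' Favored category combinations for a categorical pairwise predictor
#'
#' Fits a Gaussian-logit GLM of the scaled response on the pair-category
#' combination factor and contrasts each combination mean against the grand
#' mean (Bonferroni-adjusted z tests). Combinations whose mean response is
#' significantly *higher* than the grand mean favor similarity; the emitted
#' rule declares a pair similar when its combination is in the favored set.
#'
#' @param y response in (0, 1).
#' @param combo character/factor of pair-category combinations (e.g.
#'   `"perennial|perennial"`).
#' @param alpha significance level (default 0.05).
#' @param min_n minimum pairs per combination (default 5); smaller
#'   combinations are excluded from testing.
#' @return object of class `categorical_rule`: `favored` (character),
#'   `table` (per-combination mean, se, z, p_adj), `rule`.
#' @export
categorical_rule <- function(y, combo, alpha = 0.05, min_n = 5) {
  combo <- as.character(combo)
  tab <- table(combo)
  keep <- names(tab)[tab >= min_n]
  if (length(unique(combo)) < 2) stop("single category combination")
  if (length(keep) < 2) stop("need >= 2 combinations with >= ", min_n, " pairs")
  sel <- combo %in% keep
  y <- y[sel]; combo <- factor(combo[sel])
  dat <- data.frame(y = y, combo = combo)
  fit <- glm_logit_gaussian(y ~ 0 + combo, dat)
  co <- summary(fit)$coefficients
  means <- co[, 1]; ses <- co[, 2]
  names(means) <- names(ses) <- levels(combo)
  grand <- mean(means)
  # each level vs the grand mean of level means (link scale)
  k <- length(means)
  cvec <- rep(-1 / k, k)
  z <- p <- numeric(k)
  V <- stats::vcov(fit)
  for (i in seq_len(k)) {
    ci <- cvec; ci[i] <- ci[i] + 1
    est <- sum(ci * means)
    se <- sqrt(as.numeric(t(ci) %*% V %*% ci))
    z[i] <- est / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  p_adj <- pmin(1, p * k)
  favored <- levels(combo)[p_adj <= alpha & z > 0]
  structure(list(
    favored = favored,
    table = data.frame(combination = levels(combo), mean_link = means,
                       se = ses, z = z, p_adj = p_adj, row.names = NULL),
    rule = if (length(favored))
      paste("pair similar iff combination in {",
            paste(favored, collapse = ", "), "}")
    else "none (no favored combination)"
  ), class = "categorical_rule")
}
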