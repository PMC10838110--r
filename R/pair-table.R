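#' Pairwise table of responses and predictor differences
#'
#' One row per unordered cave pair (`i < j` in cave-table order):
#' geographic distance in meters, any supplied pairwise responses (values
#' pulled from square matrices, e.g. percent similarity or MPD), and per
#' predictor the pairwise contrast — `|delta|` for numeric predictors,
#' level-step count for ordinal ones, and the sorted category combination
#' (`"a|b"`) for categorical ones.
#'
#' @param caves a [cave_table()].
#' @param responses named list of square matrices over the caves (optional).
#' @return data frame of class `pair_table` with `n(n-1)/2` rows.
#' @export
build_pair_table <- function(caves, responses = list()) {
  ids <- caves$cave_id
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  i <- idx[, 1]; j <- idx[, 2]
  out <- data.frame(cave_a = ids[i], cave_b = ids[j],
                    stringsAsFactors = FALSE)
  dm <- as.matrix(stats::dist(cave_coords(caves)))
  out$distance_m <- dm[cbind(i, j)]
  for (nm in names(responses)) {
    m <- responses[[nm]]
    stopifnot(nrow(m) == n, ncol(m) == n)
    out[[nm]] <- m[cbind(i, j)]
  }
  pm <- attr(caves, "predictor_meta")
  for (r in seq_len(nrow(pm))) {
    nm <- pm$name[r]; x <- caves[[nm]]
    if (pm$kind[r] == "numeric") {
      out[[nm]] <- abs(x[i] - x[j])
    } else if (pm$kind[r] == "ordinal") {
      lv <- predictor_levels(pm$levels[r])
      code <- match(as.character(x), lv)
      out[[nm]] <- abs(code[i] - code[j])
    } else {
      a <- as.character(x[i]); b <- as.character(x[j])
      out[[nm]] <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
    }
  }
  attr(out, "predictor_meta") <- pm
  class(out) <- c("pair_table", class(out))
  out
}
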