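test_that("log_transform matches direct evaluation", {
  expect_equal(log_transform(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(log_transform(matrix(9))[1, 1], log(10), tolerance = 1e-12)
  expect_equal(log_transform(matrix(9), base = 10)[1, 1], 1)
  expect_error(log_transform(matrix(-1)), "negative")
  # max-standardization caps each species at 1
  m <- matrix(c(1, 9, 0, 3), 2, 2)
  s <- log_transform(m, standardize = TRUE)
  expect_equal(apply(s, 2, max), c(1, 1))
})

test_that("bray_curtis matches hand values and the vegan oracle", {
  x <- rbind(a = c(1, 2), b = c(2, 1))
  expect_equal(bray_curtis(x)["a", "b"], 2 / 6)
  x2 <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(x2)["a", "b"], 1)
  x3 <- rbind(a = c(3, 1), b = c(3, 1))
  expect_equal(bray_curtis(x3)["a", "b"], 0)
  # random matrices: agree with vegan::vegdist and satisfy the matrix invariants
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rpois(6 * 8, 3) + 1, 6, 8,
                dimnames = list(paste0("c", 1:6), NULL))
    d <- bray_curtis(m)
    expect_equal(max(abs(d - t(d))), 0)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(diag(d)), rep(0, 6))
    ref <- as.matrix(vegan::vegdist(m, "bray"))
    expect_equal(unname(d), unname(ref), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("bray_curtis empty-pair policy", {
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_error(bray_curtis(x), "empty")
  expect_warning(d <- bray_curtis(x, zero_policy = "one"), "BC = 1")
  expect_equal(d["a", "b"], 1)
})

test_that("taxonomic distances follow the normalized rank-step rule", {
  tax <- data.frame(
    species_id = c("x1", "x2", "x3", "x4"),
    phylum = c("P", "P", "P", "Q"),
    class = c("C", "C", "C", "D"),
    order = c("O", "O", "O2", "O3"),
    family = c("F", "F", "F2", "F3"),
    genus = c("G", "G", "G2", "G3"),
    stringsAsFactors = FALSE)
  d <- taxonomic_distances(tax)
  L <- 5
  expect_equal(d["x1", "x1"], 0)
  expect_equal(d["x1", "x2"], 1 / L)   # congeners: one step to the shared genus
  # x1/x3 share their class: climb species->genus->family->order->class = 4 steps
  expect_equal(d["x1", "x3"], 4 / L)
  expect_equal(d["x1", "x4"], 1)       # nothing shared: maximum distance
  # six ranks: congeners at 1/6
  tax6 <- cbind(tax[, 1:2], subphylum = c("S", "S", "S", "T"), tax[, 3:6])
  expect_equal(taxonomic_distances(tax6)["x1", "x2"], 1 / 6)
  # invariant to rank-label renaming and species order
  tax_r <- tax[c(3, 1, 4, 2), ]
  tax_r$genus <- paste0("zz_", tax_r$genus)
  tax_r$family <- paste0("yy_", tax_r$family)
  d2 <- taxonomic_distances(tax_r)
  expect_equal(d2["x1", "x3"], d["x1", "x3"])
  expect_equal(d2["x2", "x4"], d["x2", "x4"])
  # ultrametric: d(a,c) <= max(d(a,b), d(b,c)) for all triples
  sp <- rownames(d)
  for (a in sp) for (b in sp) for (ch in sp)
    expect_lte(d[a, ch], max(d[a, b], d[b, ch]) + 1e-12)
})

test_that("taxonomic_distances rejects tree violations", {
  tax <- toy_taxonomy()
  tax$genus[3] <- "g1" # same genus under family f2 and f1
  expect_error(taxonomic_distances(tax), "not a tree")
})

test_that("mean pairwise distance: hand examples and properties", {
  d <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  d["s1", "s3"] <- d["s3", "s1"] <- 0.4
  d["s2", "s1"] <- d["s1", "s2"] <- 0.2
  d["s2", "s3"] <- d["s3", "s2"] <- 0.6
  A <- c(s1 = 1, s2 = 1, s3 = 0)
  B <- c(s1 = 1, s2 = 0, s3 = 1)
  expect_equal(mean_pairwise_distance(A, B, d), (0 + 0.4 + 0.2 + 0.6) / 4)
  expect_equal(mean_pairwise_distance(c(s1 = 2, s2 = 0, s3 = 0),
                                      c(s1 = 5, s2 = 0, s3 = 0), d), 0)
  expect_equal(mean_pairwise_distance(c(s1 = 1, s2 = 0, s3 = 0),
                                      c(s1 = 0, s2 = 0, s3 = 1), d), 0.4)
  # MPD(A, A) equals the mean within-community pairwise distance
  expect_equal(mean_pairwise_distance(A, A, d), mean(c(0, 0.2, 0.2, 0)))
  expect_warning(v <- mean_pairwise_distance(A, c(s1 = 0, s2 = 0, s3 = 0), d),
                 "empty")
  expect_true(is.na(v))
})

test_that("mpd_matrix imputes or errors on empty communities", {
  d <- taxonomic_distances(toy_taxonomy())
  ab <- toy_community()$abundance
  ab["B", ] <- 0L
  expect_error(mpd_matrix(ab, d), "empty")
  expect_warning(m <- mpd_matrix(ab, d, na_policy = "max"), "imputed")
  expect_equal(m["A", "B"], max(m))
  expect_equal(max(abs(m - t(m))), 0)
})

test_that("pcoa reproduces hand and round-trip cases", {
  # two caves at dissimilarity 2: scores +/-1 on axis 1, eigenvalue 2
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa(d)
  expect_equal(sort(p$scores[, "MDS1"]), c(-1, 1), ignore_attr = TRUE)
  expect_equal(p$eigenvalues[1], 2)
  # all-zero dissimilarity: no positive axes
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p0 <- pcoa(d0)
  expect_equal(ncol(p0$scores), 0)
  expect_error(pcoa(d0, n_axes = 1), "exceeds")
  # Euclidean-embeddable distances are reproduced by full-rank scores
  set.seed(7)
  X <- matrix(rnorm(5 * 3), 5, 3)
  de <- as.matrix(dist(X)); dimnames(de) <- list(letters[1:5], letters[1:5])
  pe <- pcoa(de)
  expect_equal(as.matrix(dist(pe$scores)), de, tolerance = 1e-8,
               ignore_attr = TRUE)
  # column means ~ 0, eigenvalue sum = trace of the centered matrix
  expect_lt(max(abs(colMeans(pe$scores))), 1e-10)
  expect_equal(sum(pe$eigenvalues), sum(diag(gower_center(de))),
               tolerance = 1e-8)
  # axes ordered by non-increasing eigenvalue
  expect_true(all(diff(pe$eigenvalues) <= 1e-12))
})

test_that("pcoa agrees with the classical scaling oracle", {
  set.seed(9)
  X <- matrix(rnorm(6 * 2), 6, 2)
  de <- as.matrix(dist(X)); dimnames(de) <- list(letters[1:6], letters[1:6])
  ours <- pcoa(de, n_axes = 2)$scores
  ref <- stats::cmdscale(de, k = 2)
  # equal up to per-axis sign
  for (j in 1:2)
    expect_equal(abs(ours[, j]), abs(ref[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("subset richness correlation", {
  comm <- small_synth()$community
  all_sp <- colnames(comm$abundance)
  expect_equal(subset_richness_correlation(comm, all_sp)$rho, 1)
  r <- subset_richness_correlation(comm, sample(all_sp, 20))
  expect_true(r$rho >= -1 && r$rho <= 1)
  # constant richness is an explicit error
  ab <- matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tax <- data.frame(species_id = c("s1", "s2"), genus = c("g1", "g2"))
  cm <- community_matrix(ab, tax, c(s1 = FALSE, s2 = FALSE))
  expect_error(subset_richness_correlation(cm, "s1"), "constant")
})
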