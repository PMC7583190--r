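## small helper: matrix + metadata for two batches
make_pmx <- function(values, arms = NULL, times = NULL) {
  n <- ncol(values)
  meta <- data.frame(
    arm = arms %||% rep("control", n),
    time_h = times %||% rep(6, n),
    replicate = seq_len(n),
    batch = rep(c(1L, 2L), length.out = n))
  proteomics_matrix(values, meta)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("quantile normalization equalizes sample distributions and
           preserves ranks", {
  set.seed(5)
  m <- matrix(2^rnorm(600, 10, 1), 100, 6,
              dimnames = list(sprintf("p%03d", 1:100), NULL))
  pmx <- make_pmx(m)
  qn <- quantile_normalize(pmx)
  srt <- apply(qn$values, 2, sort)
  expect_equal(max(apply(srt, 1, function(r) diff(range(r)))), 0,
               tolerance = 1e-10)
  for (j in 1:6) {
    expect_identical(rank(qn$values[, j]), rank(m[, j]))
  }
  ## scaling a sample by 10 is rank-invariant: the sample keeps exactly
  ## the same ordering after normalization, and its values differ from
  ## the unscaled run only through the shift of the pooled reference
  m2 <- m
  m2[, 3] <- 10 * m2[, 3]
  qn2 <- quantile_normalize(make_pmx(m2))
  expect_identical(rank(qn2$values[, 3]), rank(qn$values[, 3]))
  ref1 <- rowMeans(apply(m, 2, sort))
  ref2 <- rowMeans(apply(m2, 2, sort))
  expect_equal(unname(sort(qn2$values[, 3]) - sort(qn$values[, 3])),
               unname(ref2 - ref1), tolerance = 1e-8)
  ## idempotence
  qn_twice <- quantile_normalize(qn)
  expect_equal(qn_twice$values, qn$values, tolerance = 1e-10)
})

test_that("rank-identical samples map exactly onto the reference
           distribution", {
  base <- sort(2^rnorm(50, 10, 1))
  m <- cbind(base, base * 3)
  rownames(m) <- sprintf("p%02d", 1:50)
  qn <- quantile_normalize(make_pmx(m))
  ref <- unname(rowMeans(apply(m, 2, sort)))
  expect_equal(unname(qn$values[, 1]), ref, tolerance = 1e-10)
  expect_equal(unname(qn$values[, 2]), ref, tolerance = 1e-10)
})

test_that("log2 fold-changes are control-matched per timepoint", {
  vals <- matrix(100, 4, 6,
                 dimnames = list(paste0("p", 1:4), NULL))
  arms <- c("control", "control", "B", "B", "P", "P")
  times <- rep(6, 6)
  vals[, 3:4] <- 200       # B arm doubled
  vals[1, 5:6] <- 280      # p1 in P arm: 2.8-fold
  pmx <- make_pmx(vals, arms = arms, times = times)
  fc <- log2_fold_change(pmx)
  expect_equal(fc$value[fc$arm == "B"], rep(1, 4), tolerance = 1e-12)
  expect_equal(fc$value[fc$arm == "P" & fc$protein == "p1"], 1.485,
               tolerance = 1e-3)
  ## the control arm against itself is identically zero
  fc0 <- log2_fold_change(pmx, arms = "control")
  expect_true(all(fc0$value == 0))
  pmx_noctrl <- make_pmx(vals[, 3:6], arms = arms[3:6],
                         times = times[3:6])
  expect_error(log2_fold_change(pmx_noctrl), "control arm absent")
})

test_that("k-means clustering is deterministic and self-consistent", {
  set.seed(8)
  m <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(sprintf("p%03d", 1:200), NULL))
  c1 <- cluster_temporal(m, k_range = 4, seed = 42)
  c2 <- cluster_temporal(m, k_range = 4, seed = 42)
  expect_identical(c1$assignments, c2$assignments)
  expect_identical(c1$centroids, c2$centroids)
  ## fixed point: every profile is nearest its own centroid
  mu <- m / ifelse(sqrt(rowSums(m^2)) > 0, sqrt(rowSums(m^2)), 1)
  d <- as.matrix(dist(rbind(c1$centroids, mu)))[-(1:4), 1:4]
  expect_true(all(c1$assignments == apply(d, 1, which.min)))
})

test_that("identical profiles collapse to a single zero-deviation
           cluster", {
  m <- matrix(rep(c(0, 1, 2, 1), each = 40), 40, 4,
              dimnames = list(sprintf("p%02d", 1:40), NULL))
  cl <- cluster_temporal(m, k_range = 1, seed = 1)
  expect_identical(cl$k, 1L)
  expect_equal(max(cl$max_deviation), 0, tolerance = 1e-10)
  expect_error(cluster_temporal(m[1:3, ], k_range = 5), "exceeds")
})

test_that("planted archetypes are recovered and k is selected by the
           deviation elbow", {
  set.seed(13)
  arch <- synergypd:::.archetypes(c(6, 24, 48, 72))
  shp <- t(sapply(arch, function(a) as.vector(outer(a$arms, a$shape))))
  m90 <- shp[rep(1:9, each = 10), ] +
    matrix(rnorm(90 * 12, 0, 0.08), 90)
  rownames(m90) <- sprintf("p%02d", 1:90)
  cl <- cluster_temporal(m90, k_range = 2:12, seed = 3)
  expect_identical(cl$k, 9L)
  expect_gt(cluster_agreement(cl$assignments, rep(1:9, each = 10)), 0.9)
  ## the deviation criterion is (weakly) improving with k
  expect_lt(min(cl$criterion), cl$criterion[[1]])
})

test_that("representative profiles are centroids or named members", {
  m <- rbind(a = c(0, 1, 2, 1), b = c(0, 3, 4, 1))
  cl <- cluster_temporal(m, k_range = 1, seed = 1,
                         scale_profiles = "none")
  expect_equal(unname(representative_profile(cl, 1)), c(0, 2, 3, 1))
  expect_equal(unname(representative_profile(cl, 1, m,
                                             named_member = "b")),
               c(0, 3, 4, 1))
  expect_error(representative_profile(cl, 2), "unknown cluster")
  expect_error(representative_profile(cl, 1, m, named_member = "zz"),
               "unknown member")
  m2 <- rbind(a = c(0, 1, 2, 1), b = c(5, -3, 4, 1),
              c = c(0, 1.1, 2, 1), d = c(5.2, -3, 4, 1))
  cl2 <- cluster_temporal(m2, k_range = 2, seed = 2,
                          scale_profiles = "none")
  other <- names(cl2$assignments)[cl2$assignments !=
                                    cl2$assignments[["a"]]][1]
  expect_error(representative_profile(cl2, cl2$assignments[["a"]], m2,
                                      named_member = other),
               "belongs to cluster")
})

test_that("the adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(17)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- a
    flip <- sample(60, 12)
    b[flip] <- sample(1:4, 12, replace = TRUE)
    expect_equal(cluster_agreement(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(cluster_agreement(1:10, 1:10), 1)
})
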