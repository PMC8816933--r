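test_that("parallel analysis retains nothing under the null and one under a single factor", {
  # iid noise: mean retained components well below the quantile flip rate
  ret <- vapply(1:100, function(s) {
    X <- with_stream(s, "null-X", matrix(rnorm(80 * 12), 80, 12))
    parallel_analysis(X, n_sim = 200, seed = s)$n_retained
  }, integer(1))
  expect_lt(mean(ret), 0.3)

  # one dominant factor, loading 0.9 on all columns
  set.seed(42)
  f <- rnorm(500)
  X1 <- 0.9 * matrix(f, 500, 8) + sqrt(1 - 0.81) * matrix(rnorm(500 * 8), 500, 8)
  expect_identical(parallel_analysis(X1, n_sim = 200, seed = 1)$n_retained, 1L)

  Xc <- cbind(X1, constant = 1)
  expect_error(parallel_analysis(Xc, seed = 1), "constant")
})

test_that("oblimin rotation matches an external quartimin oracle", {
  # expected values computed once with statsmodels' rotate_factors(A, 'quartimin')
  A <- matrix(c(0.8, 0.75, 0.7, 0.65, 0.2, 0.1, 0.15, 0.05,
                0.1, 0.2, 0.05, 0.15, 0.7, 0.75, 0.65, 0.8), ncol = 2)
  rot <- wmhbullseye:::oblimin_rotate(A)
  expected_pattern <- matrix(c(
    0.8152006574, 0.7480056347, 0.7190340982, 0.6518390755,
    0.1005967517, -0.0108592020, 0.0563358207, -0.0704095275,
    -0.0314663389, 0.0805377954, -0.0663698071, 0.0456343272,
    0.6911951046, 0.7598563312, 0.6478521969, 0.8200781182), ncol = 2)
  expect_equal(unname(rot$pattern), expected_pattern, tolerance = 1e-4)
  expect_equal(rot$phi[1, 2], 0.3029513861, tolerance = 1e-4)
})

test_that("unrotated eigenvalues match the characteristic-polynomial oracle", {
  set.seed(3)
  for (i in 1:3) {
    X <- matrix(rnorm(50 * 4), 50, 4)
    R <- cor(X)
    ours <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(ours, charpoly_eigenvalues(R), tolerance = 1e-8)
  }
})

test_that("fit_components obeys its algebraic invariants", {
  co <- simulate_cohort(n = 108, seed = 1)
  X <- cohort_log_matrix(co)
  cm <- fit_components(X, k = 3)
  expect_true(all(cm$communalities >= -1e-8 & cm$communalities <= 1 + 1e-8))
  expect_true(isSymmetric(cm$phi))
  expect_equal(unname(diag(cm$phi)), rep(1, 3))
  expect_equal(unname(cm$structure), unname(cm$pattern %*% cm$phi))
  expect_equal(sum(cm$eigenvalues), 36)  # correlation-matrix PCA
  # rotation redistributes but never creates explained variance
  expect_equal(sum(cm$communalities), sum(cm$eigenvalues[1:3]))
  # sign convention: dominant pattern loading positive per component
  for (j in 1:3) expect_gt(cm$pattern[which.max(abs(cm$pattern[, j])), j], 0)
  # regression scores are centered
  expect_equal(unname(colMeans(cm$scores)), rep(0, 3), tolerance = 1e-10)
})

test_that("two identical columns share the maximal loading under k = 1", {
  set.seed(8)
  base <- matrix(rnorm(200 * 4), 200, 4)
  X <- cbind(base, dup1 = base[, 1], noise = rnorm(200))
  X[, 1] <- X[, 5]
  cm <- fit_components(X, k = 1)
  l <- as.numeric(abs(cm$pattern[, 1]))
  expect_equal(l[1], l[5], tolerance = 1e-10)
  expect_equal(max(l), l[1], tolerance = 1e-10)
})

test_that("rotated components recover a block-diagonal generating structure", {
  # population correlation: 3 blocks of sizes 4/4/4, within-block r = 0.6
  p <- 12L
  R <- diag(p)
  blocks <- rep(1:3, each = 4L)
  for (i in 1:p) for (j in 1:p)
    if (i != j && blocks[i] == blocks[j]) R[i, j] <- 0.6
  set.seed(12)
  X <- matrix(rnorm(4000 * p), 4000, p) %*% chol(R)
  cm <- fit_components(X, k = 3)
  assigned <- apply(abs(cm$pattern), 1L, which.max)
  expect_identical(partition_match_rate(assigned, blocks), 1)

  # a variable uncorrelated with all others has low communality
  Xu <- cbind(X, lone = rnorm(4000))
  cmu <- fit_components(Xu, k = 3)
  expect_lt(cmu$communalities[["lone"]], 0.4)
})

test_that("interpret_loadings thresholds structure loadings", {
  co <- simulate_cohort(n = 108, seed = 1)
  cm <- fit_components(cohort_log_matrix(co), k = 3)
  sets <- interpret_loadings(cm, threshold = 0.4)
  expect_length(sets, 3L)
  # threshold 0: every parcel in every component; huge threshold: none
  expect_true(all(lengths(interpret_loadings(cm, threshold = 0)) == 36L))
  expect_true(all(lengths(interpret_loadings(cm, threshold = 10)) == 0L))
  # ordering by decreasing |structure loading|
  s1 <- sets[[1]]
  mags <- abs(cm$structure[s1, 1])
  expect_true(all(diff(mags) <= 1e-12))
  # the temporal/juxtacortical component includes temporal layers 2-4
  blk <- attr(co, "block")
  names(blk) <- paste0("p", parcel_codes())
  block3_parcels <- names(blk)[blk == 3]
  overlap <- vapply(sets, function(s) mean(block3_parcels %in% s), numeric(1))
  best <- which.max(overlap)
  expect_true(all(c("p52", "p53", "p54", "p62", "p63", "p64") %in% sets[[best]]))
})

test_that("default simulated cohort reproduces a 3-component solution", {
  co <- simulate_cohort(n = 108, seed = 20)
  X <- cohort_log_matrix(co)
  pa <- parallel_analysis(X, n_sim = 500, seed = 20)
  expect_identical(pa$n_retained, 3L)
  cm <- fit_components(X, k = pa$n_retained)
  expect_gt(cm$total_var_explained, 0.35)
  expect_true(all(cm$phi[upper.tri(cm$phi)] > 0))  # positively correlated components
})
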