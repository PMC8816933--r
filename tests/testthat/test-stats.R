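test_that("standardize_scores builds re-standardized, reversible composites", {
  set.seed(31)
  n <- 120
  latent <- rnorm(n)
  tasks <- data.frame(
    a1 = latent + rnorm(n, 0, 0.5), a2 = latent + rnorm(n, 0, 0.5),
    a3 = latent + rnorm(n, 0, 0.5),
    b1 = rnorm(n), b2 = rnorm(n), b3 = rnorm(n)
  )
  dmap <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  sc <- standardize_scores(tasks, dmap)
  expect_equal(mean(sc$A), 0, tolerance = 1e-10)
  expect_equal(sd(sc$A), 1, tolerance = 1e-10)
  # reversing a domain flips the sign of its correlation with anything external
  scr <- standardize_scores(tasks, dmap, reverse = "A")
  expect_equal(cor(scr$A, latent), -cor(sc$A, latent), tolerance = 1e-12)
  # missing task -> missing domain score for that subject
  tasks$a2[3] <- NA
  expect_true(is.na(standardize_scores(tasks, dmap)$A[3]))
  tasks$b1 <- 7
  expect_error(standardize_scores(tasks, dmap), "zero variance")
})

test_that("bh_fdr equals the exhaustive step-up oracle and p.adjust", {
  expect_equal(bh_fdr(0.03)$q, 0.03)                      # m = 1
  expect_equal(bh_fdr(rep(0.2, 6))$q, rep(0.2, 6))        # all equal
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))$q, rep(0.05, 5))
  set.seed(14)
  grid <- c(0.001, 0.01, 0.02, 0.04, 0.05, 0.1, 0.25, 0.5, 0.8, 1)
  for (i in 1:200) {
    m <- sample(1:8, 1)
    p <- sample(grid, m, replace = TRUE)
    q <- bh_fdr(p)$q
    expect_equal(q, bh_oracle_q(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("vif matches the 1/(1 - R^2) closed form", {
  set.seed(4)
  n <- 400
  # mutually orthogonal predictors -> VIF 1
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  Qc <- scale(Q, scale = FALSE)
  v1 <- vif(Qc)
  expect_equal(as.numeric(v1), rep(1, 3), tolerance = 0.05)
  # two predictors with known correlation r: VIF = 1/(1 - r^2)
  x1 <- rnorm(1e5)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(1e5)
  v2 <- vif(cbind(x1, x2))
  expect_equal(as.numeric(v2), rep(1 / (1 - 0.36), 2), tolerance = 0.02)
  # duplicated predictor flagged infinite
  v3 <- vif(cbind(x1, x1, x2))
  expect_true(any(!is.finite(v3)))
  expect_true(attr(v3, "collinear"))
  expect_error(vif(cbind(x1)), "two predictors")
})

test_that("parcel models recover an injected effect and match normal equations", {
  # direct parameter recovery: beta* = -0.3, n = 500, 100 replicates
  betas <- vapply(1:100, function(r) {
    set.seed(r)
    n <- 500
    covs <- data.frame(subject_id = as.character(1:n), age = rnorm(n, 70, 6),
                       sex = sample(c("female", "male"), n, TRUE))
    x <- rnorm(n)
    parcels <- as.data.frame(matrix(rnorm(n * 36), n, 36,
                                    dimnames = list(NULL, paste0("p", parcel_codes()))))
    parcels$p11 <- x
    parcels$subject_id <- covs$subject_id
    y <- -0.3 * x + 0.02 * (covs$age - 70) + rnorm(n)
    scores <- data.frame(subject_id = covs$subject_id, memory = y)
    fit <- fit_parcel_models(parcels, scores, covs)
    fit$beta[fit$parcel == 11][1]
  }, numeric(1))
  expect_lt(abs(mean(betas) - (-0.3)), 0.05)

  # null predictor: mean estimate near zero
  null_betas <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    n <- 200
    d <- data.frame(y = rnorm(n), x = rnorm(n), z = rnorm(n))
    f <- wmhbullseye:::fit_ols(y ~ x + z, d)
    unname(f$coef["x"])
  }, numeric(1))
  expect_lt(abs(mean(null_betas)), 0.05)

  # OLS equals the normal-equations solution to 1e-10
  set.seed(77)
  n <- 150
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  f <- wmhbullseye:::fit_ols(y ~ a + b + c, d)
  X <- cbind(1, d$a, d$b, d$c)
  beta_ne <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(f$coef), drop(beta_ne), tolerance = 1e-10)

  # aliased covariate -> rank-deficiency error
  d$b2 <- d$b
  expect_error(wmhbullseye:::fit_ols(y ~ a + b + b2, d), "alias")
})

test_that("fit_parcel_models applies per-domain FDR over 36 tests", {
  co <- simulate_cohort(n = 108, seed = 2)
  tab <- log_transform(adjust_etiv(parcel_table(co)))
  scores <- co[, c("subject_id", "memory", "speed")]
  covs <- co[, c("subject_id", "age", "sex", "education", "bpf", "hypertension")]
  res <- fit_parcel_models(tab, scores, covs)
  expect_identical(nrow(res), 72L)
  expect_true(all(res$q >= res$p - 1e-15))
  for (d in c("memory", "speed")) {
    sub <- res[res$domain == d, ]
    expect_equal(sub$q, bh_fdr(sub$p)$q)
    expect_true(all(sub$n <= 108))
  }
})

test_that("bootstrap_ci is deterministic, degenerate-exact and calibrated in rank", {
  # zero-noise linear data: every resample refits the same line exactly
  d0 <- data.frame(x = 1:30)
  d0$y <- 2 + 3 * d0$x
  bs0 <- bootstrap_ci(y ~ x, d0, B = 50, seed = 1)
  expect_equal(unname(bs0$ci[, "lower"]), unname(bs0$ci[, "upper"]), tolerance = 1e-10)
  expect_equal(unname(bs0$ci["x", "lower"]), 3, tolerance = 1e-10)

  set.seed(10)
  d <- data.frame(x = rnorm(80), z = rnorm(80))
  d$y <- 1 + 0.5 * d$x + rnorm(80)
  a <- bootstrap_ci(y ~ x + z, d, B = 200, seed = 5)
  b <- bootstrap_ci(y ~ x + z, d, B = 200, seed = 5)
  expect_identical(a$ci, b$ci)
  expect_true(all(a$ci[, "lower"] <= a$ci[, "upper"]))
  expect_error(bootstrap_ci(y ~ x + z, d, B = 1), "B must be")

  # endpoint stabilization: B = 5000 vs B = 1000 endpoints agree to within
  # Monte-Carlo error of the percentile estimator (~0.09 SE at B = 1000)
  f1 <- bootstrap_ci(y ~ x + z, d, B = 1000, seed = 11)
  f2 <- bootstrap_ci(y ~ x + z, d, B = 5000, seed = 12)
  se_x <- summary(lm(y ~ x + z, d))$coefficients["x", "Std. Error"]
  expect_lt(max(abs(f1$ci["x", ] - f2$ci["x", ])), 0.3 * se_x)
})

test_that("component models report VIF, bootstrap CIs and detect the right component", {
  # effect injected only through component 3
  hits <- vapply(1:50, function(r) {
    set.seed(r)
    n <- 150
    comp <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("C", 1:3)))
    covs <- data.frame(subject_id = as.character(1:n), age = rnorm(n, 70, 6))
    y <- -0.4 * comp[, 3] + rnorm(n)
    fit <- fit_component_models(
      data.frame(subject_id = covs$subject_id, memory = y),
      data.frame(subject_id = covs$subject_id, comp), covs, B = 50, seed = r)
    c(fit$beta[fit$predictor == "C1"], fit$beta[fit$predictor == "C2"],
      fit$beta[fit$predictor == "C3"], fit$p[fit$predictor == "C3"])
  }, numeric(4))
  expect_lt(abs(mean(hits[1, ])), 0.05)
  expect_lt(abs(mean(hits[2, ])), 0.05)
  expect_lt(abs(mean(hits[3, ]) - (-0.4)), 0.05)
  expect_gt(mean(hits[4, ] < 0.05), 0.9)

  # null components: p-values uniform (KS not rejected at 1%)
  pnull <- vapply(1:100, function(r) {
    set.seed(5000 + r)
    n <- 120
    comp <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("C", 1:3)))
    covs <- data.frame(subject_id = as.character(1:n), age = rnorm(n, 70, 6))
    fit <- fit_component_models(
      data.frame(subject_id = covs$subject_id, memory = rnorm(n)),
      data.frame(subject_id = covs$subject_id, comp), covs, B = 2, seed = r)
    fit$p[fit$predictor == "C1"]
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pnull, "punif")$p.value), 0.01)

  # perfectly collinear components abort
  n <- 60
  comp <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("C1", "C2")))
  comp <- cbind(comp, C3 = comp[, 1])
  covs <- data.frame(subject_id = as.character(1:n), age = rnorm(n))
  expect_error(fit_component_models(
    data.frame(subject_id = covs$subject_id, memory = rnorm(n)),
    data.frame(subject_id = covs$subject_id, comp), covs, B = 10, seed = 1),
    "alias|rank")
})

test_that("age_tertiles cut at empirical terciles with ties going lower", {
  g <- age_tertiles(1:9)
  expect_identical(as.integer(table(g)), c(3L, 3L, 3L))
  expect_identical(as.character(g[1:3]), rep("T1", 3))
  ages <- c(60, 60, 60, 60, 70, 80, 81, 82, 83)
  g2 <- age_tertiles(ages)
  expect_identical(sum(as.integer(table(g2))), length(ages))
  # all values tied at the first cut point land in the lower group
  q1 <- quantile(ages, 1 / 3, names = FALSE)
  expect_true(all(g2[ages == q1] == "T1" | ages[ages == q1] > q1))
  expect_error(age_tertiles(c(1, 1, 1)), "distinct")
})

test_that("gamma GLM contrasts recover group mean ratios", {
  # identical groups: log-ratio near zero on average
  coefs <- vapply(1:50, function(r) {
    set.seed(r)
    v <- rgamma(400, shape = 2, scale = 50)
    g <- rep(c("A", "B"), each = 200)
    gamma_glm_compare(v, g)$estimate
  }, numeric(1))
  expect_lt(abs(mean(coefs)), 0.05)

  # true ratio 2 recovered at n = 500/group
  set.seed(33)
  v <- c(rgamma(500, 2, scale = 50), rgamma(500, 2, scale = 100))
  g <- rep(c("A", "B"), each = 500)
  res <- gamma_glm_compare(v, g)
  expect_true(res$ratio > 1.8 && res$ratio < 2.2)
  expect_lt(res$p, 0.001)

  expect_error(gamma_glm_compare(rgamma(10, 2), rep("A", 10)), "2 groups")
  expect_error(gamma_glm_compare(c(-1, 2, 3), c("A", "B", "A")), "positive")
})

test_that("demographic associations report r and Welch t", {
  set.seed(9)
  n <- 500
  age <- rnorm(n, 70, 6)
  sex <- sample(c("female", "male"), n, TRUE)
  comps <- cbind(C1 = as.numeric(scale(age)), C2 = rnorm(n))
  res <- demographic_associations(comps, age, sex)
  expect_equal(res$estimate[res$component == "C1" & res$variable == "age"], 1)
  # independent vectors: mean |r| small over replicates
  rs <- vapply(1:100, function(r) {
    set.seed(r)
    cor(rnorm(500), rnorm(500))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  # equal group means: t near 0
  x <- rep(c(1, 2), 250)
  res2 <- demographic_associations(cbind(C1 = x), age, rep(c("f", "m"), each = 250))
  expect_lt(abs(res2$stat[res2$variable == "sex"]), 2.5)
  expect_error(demographic_associations(cbind(C1 = rep(1, n)), age, sex), "variance")
})
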