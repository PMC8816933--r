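## Association stage: composite cognitive scores, mass-univariate parcel
## models, BH-FDR, component models with VIF and bootstrap percentile CIs,
## age-tertile gamma GLMs, and demographic correlations.

#' Standardized cognitive domain scores from task scores
#'
#' Each task is z-scored, tasks belonging to reverse-scored domains (e.g.
#' reaction-time based speed of processing) are negated, the (typically 3)
#' tasks of a domain are averaged, and the composite is re-standardized to
#' mean 0 / SD 1. A subject's domain score is missing if any of the domain's
#' tasks is missing.
#'
#' @param task_scores data.frame or matrix of task scores (n x tasks).
#' @param domain_map named character vector mapping task column name to
#'   domain name.
#' @param reverse character vector of reverse-scored domains.
#' @return data.frame of standardized domain scores (one column per domain).
#' @export
standardize_scores <- function(task_scores, domain_map, reverse = character()) {
  ts <- as.data.frame(task_scores)
  missing_tasks <- setdiff(names(domain_map), names(ts))
  if (length(missing_tasks))
    stop("task columns not found: ", paste(missing_tasks, collapse = ", "))
  zs <- lapply(names(domain_map), function(task) {
    x <- ts[[task]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("task '", task, "' has zero variance")
    z <- (x - mean(x, na.rm = TRUE)) / s
    if (domain_map[[task]] %in% reverse) -z else z
  })
  names(zs) <- names(domain_map)
  domains <- unique(unname(domain_map))
  out <- lapply(domains, function(d) {
    tasks <- names(domain_map)[domain_map == d]
    comp <- rowMeans(do.call(cbind, zs[tasks]))  # NA if any task missing
    (comp - mean(comp, na.rm = TRUE)) / sd(comp, na.rm = TRUE)
  })
  names(out) <- domains
  as.data.frame(out)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1;
#' rejections where `q <= level`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param level FDR level (default 0.05).
#' @return list with `q` (same order as `p`) and logical `reject`.
#' @export
bh_fdr <- function(p, level = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, reject = q <= level)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the remaining
#' predictors (with intercept). Exactly collinear predictors are reported as
#' `Inf` with attribute `collinear = TRUE`.
#'
#' @param design numeric matrix or data.frame of predictors (no intercept
#'   column), at least two columns.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  p <- ncol(X)
  if (p < 2L) stop("vif needs at least two predictors")
  out <- vapply(seq_len(p), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "collinear") <- any(!is.finite(out))
  out
}

## internal: OLS with full diagnostics for one model; errors on aliasing
fit_ols <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("too few complete cases (n = ", n, ") for ", p, " parameters")
  qx <- qr(X)
  if (qx$rank < p)
    stop("rank-deficient design (aliased predictors): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1L):p]], collapse = ", "))
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  list(coef = beta, se = se, t = tval, p = pval, n = n, df = n - p,
       X = X, y = y, formula = formula)
}

#' Mass-univariate parcel-cognition models
#'
#' For every cognitive domain and every parcel, fits an ordinary
#' least-squares model `domain score ~ log parcel volume + covariates` on
#' complete cases, and applies BH-FDR within each domain's 36 tests (one
#' family per domain).
#'
#' @param parcels a log-transformed `parcel_volume_table` (see
#'   [log_transform()]), or any data.frame with `subject_id` and `p11..p94`.
#' @param scores data.frame with `subject_id` and one column per domain.
#' @param covariates data.frame with `subject_id` and adjustment variables
#'   (all non-id columns are entered in every model).
#' @param fdr_level FDR level (default 0.05).
#' @return data.frame with one row per domain x parcel: `domain`, `parcel`,
#'   `beta`, `se`, `t`, `p`, `q`, `reject`, `n`.
#' @export
fit_parcel_models <- function(parcels, scores, covariates, fdr_level = 0.05) {
  pcols <- paste0("p", parcel_codes())
  dat <- merge(merge(as.data.frame(parcels)[, c("subject_id", pcols)],
                     scores, by = "subject_id"),
               covariates, by = "subject_id")
  domains <- setdiff(names(scores), "subject_id")
  covs <- setdiff(names(covariates), "subject_id")
  out <- list()
  for (d in domains) {
    rows <- lapply(pcols, function(pc) {
      f <- stats::reformulate(c(pc, covs), response = d)
      fit <- fit_ols(f, dat)
      data.frame(domain = d, parcel = as.integer(sub("^p", "", pc)),
                 beta = unname(fit$coef[pc]), se = unname(fit$se[pc]),
                 t = unname(fit$t[pc]), p = unname(fit$p[pc]), n = fit$n,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    fdr <- bh_fdr(res$p, fdr_level)
    res$q <- fdr$q
    res$reject <- fdr$reject
    out[[d]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Bootstrap percentile confidence intervals for regression coefficients
#'
#' Case (subject-level) resampling with replacement; for each of `B`
#' resamples the model is refit and the 2.5th and 97.5th percentiles of each
#' coefficient's bootstrap distribution form its interval. Resamples with a
#' rank-deficient design are redrawn and counted; more than 10\% redraws is
#' an error.
#'
#' @param formula model formula.
#' @param data data.frame (complete cases used).
#' @param B number of resamples (default 1000).
#' @param seed integer RNG seed.
#' @param probs interval percentiles (default `c(0.025, 0.975)`).
#' @return list with `ci` (coefficients x 2 matrix), `boot` (B x coefficients
#'   matrix of resampled estimates), `n_redraws`, `B`.
#' @export
bootstrap_ci <- function(formula, data, B = 1000L, seed = 1L,
                         probs = c(0.025, 0.975)) {
  if (B < 2L) stop("B must be >= 2")
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design in the original data")
  boot <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(X)))
  n_redraws <- 0L
  with_stream(seed, "bootstrap", {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        fit <- stats::.lm.fit(X[idx, , drop = FALSE], y[idx])
        if (fit$rank == p) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 0.1 * B)
          stop("more than 10% of bootstrap resamples were rank-deficient")
      }
      boot[b, ] <- fit$coefficients
    }
  })
  ci <- t(apply(boot, 2L, stats::quantile, probs = probs, names = FALSE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, boot = boot, n_redraws = n_redraws, B = B)
}

#' Component-cognition models with VIF and bootstrap intervals
#'
#' For each cognitive domain, fits one multiple regression with all latent
#' component scores entered simultaneously alongside the covariates, reports
#' per-predictor coefficients, analytic 95\% CIs, VIFs and bootstrap
#' percentile CIs. VIFs above `vif_warn` trigger a warning (not an abort).
#'
#' @param scores data.frame with `subject_id` and one column per domain.
#' @param components data.frame with `subject_id` and component-score columns
#'   (e.g. `C1..C3`).
#' @param covariates data.frame with `subject_id` and adjustment variables.
#' @param B bootstrap resamples (default 1000).
#' @param seed integer RNG seed.
#' @param vif_warn VIF warning threshold (default 10).
#' @return data.frame with one row per domain x predictor: `domain`,
#'   `predictor`, `beta`, `se`, `t`, `p`, `ci_lower`, `ci_upper`, `vif`,
#'   `bs_lower`, `bs_upper`, `n`.
#' @export
fit_component_models <- function(scores, components, covariates, B = 1000L,
                                 seed = 1L, vif_warn = 10) {
  dat <- merge(merge(components, scores, by = "subject_id"),
               covariates, by = "subject_id")
  comp_cols <- setdiff(names(components), "subject_id")
  covs <- setdiff(names(covariates), "subject_id")
  domains <- setdiff(names(scores), "subject_id")
  preds <- c(comp_cols, covs)
  out <- list()
  for (d in domains) {
    f <- stats::reformulate(preds, response = d)
    fit <- fit_ols(f, dat)
    mm <- fit$X[, -1L, drop = FALSE]     # drop intercept for VIF
    v <- vif(mm)
    if (any(is.finite(v) & v > vif_warn))
      warning("VIF above ", vif_warn, " in model for ", d)
    bs <- bootstrap_ci(f, dat, B = B, seed = stream_seed(seed, d))
    keep <- colnames(mm)
    tcrit <- stats::qt(0.975, df = fit$df)
    out[[d]] <- data.frame(
      domain = d, predictor = keep,
      beta = unname(fit$coef[keep]), se = unname(fit$se[keep]),
      t = unname(fit$t[keep]), p = unname(fit$p[keep]),
      ci_lower = unname(fit$coef[keep] - tcrit * fit$se[keep]),
      ci_upper = unname(fit$coef[keep] + tcrit * fit$se[keep]),
      vif = unname(v[keep]),
      bs_lower = bs$ci[keep, "lower"], bs_upper = bs$ci[keep, "upper"],
      n = fit$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Split a sample into age tertiles
#'
#' Cut points are the empirical 1/3 and 2/3 quantiles; ties at a cut point go
#' to the lower group.
#'
#' @param ages numeric vector, at least 3 distinct values.
#' @return factor with levels `T1`, `T2`, `T3`.
#' @export
age_tertiles <- function(ages) {
  if (length(unique(ages)) < 3L) stop("need at least 3 distinct ages")
  qs <- quantile(ages, probs = c(1 / 3, 2 / 3), names = FALSE)
  factor(ifelse(ages <= qs[1], "T1", ifelse(ages <= qs[2], "T2", "T3")),
         levels = c("T1", "T2", "T3"))
}

#' Pairwise group comparisons of WMH volumes with a gamma GLM
#'
#' Fits `volume ~ group` under a gamma distribution with a log link (volumes
#' must be strictly positive, e.g. after the +1 mm^3 offset) and reports all
#' pairwise contrasts as mean ratios `exp(coef difference)` with Wald
#' p-values.
#'
#' @param volumes positive numeric vector.
#' @param groups factor/character of group labels (>= 2 groups).
#' @return data.frame with `group1`, `group2`, `ratio` (mean of group2 over
#'   group1), `estimate` (log ratio), `se`, `p`.
#' @export
gamma_glm_compare <- function(volumes, groups) {
  if (any(volumes <= 0))
    stop("gamma GLM requires strictly positive volumes (apply the log offset first)")
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  fit <- glm(volumes ~ g, family = stats::Gamma(link = "log"))
  b <- coef(fit)
  V <- vcov(fit)
  levs <- levels(g)
  cmb <- utils::combn(seq_along(levs), 2L)
  rows <- apply(cmb, 2L, function(pr) {
    cvec <- numeric(length(b))
    if (pr[1] > 1L) cvec[pr[1]] <- -1
    cvec[pr[2]] <- 1
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    data.frame(group1 = levs[pr[1]], group2 = levs[pr[2]],
               ratio = exp(est), estimate = est, se = se,
               p = 2 * pnorm(-abs(est / se)), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Associations between component scores and demographics
#'
#' Pearson correlation (with p-value) for continuous variables, Welch t-test
#' for the binary sex grouping.
#'
#' @param components data.frame or matrix of component scores (n x k).
#' @param age numeric vector.
#' @param sex character/factor with two levels.
#' @return data.frame with one row per component x variable: `component`,
#'   `variable`, `method`, `estimate` (r, or mean difference group2 - group1),
#'   `stat`, `p`.
#' @export
demographic_associations <- function(components, age, sex) {
  cm <- as.matrix(components)
  if (sd(age) == 0) stop("age has zero variance")
  sx <- factor(sex)
  if (nlevels(sx) != 2L) stop("sex must have exactly two levels")
  rows <- list()
  for (j in seq_len(ncol(cm))) {
    comp <- colnames(cm)[j]
    if (sd(cm[, j]) == 0) stop("component ", comp, " has zero variance")
    ct <- cor.test(cm[, j], age)
    tt <- t.test(cm[, j] ~ sx)
    rows[[length(rows) + 1L]] <- data.frame(
      component = comp, variable = "age", method = "pearson",
      estimate = unname(ct$estimate), stat = unname(ct$statistic),
      p = ct$p.value, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      component = comp, variable = "sex", method = "welch_t",
      estimate = unname(diff(rev(tt$estimate))) * -1,
      stat = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
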