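## Latent-structure stage: PCA on the parcel correlation matrix, Horn
## parallel analysis for component retention, and direct oblimin (quartimin)
## rotation via the oblique gradient-projection algorithm.

#' Horn parallel analysis for component retention
#'
#' Compares the observed eigenvalues of `cor(X)` with the per-position
#' quantiles of eigenvalues from `n_sim` iid standard-normal datasets of the
#' same size. Components are retained from the first until the first observed
#' eigenvalue at or below its simulated quantile.
#'
#' @param X numeric n x p matrix (complete cases used).
#' @param n_sim number of null simulations (default 500).
#' @param quantile quantile of the null eigenvalue distribution (default 0.95).
#' @param seed integer RNG seed for the null simulations.
#' @return list of class `parallel_analysis` with `observed`, `simulated`
#'   (the quantile curve), `n_retained`, `n_sim`, `quantile`, `seed`, `n`, `p`.
#' @export
parallel_analysis <- function(X, n_sim = 500L, quantile = 0.95, seed = 1L) {
  X <- as.matrix(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) warning("parallel_analysis: n <= p; retention may be unstable")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    nm <- if (is.null(colnames(X))) which(sds == 0) else colnames(X)[sds == 0]
    stop("constant column(s): ", paste(nm, collapse = ", "))
  }
  observed <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  sim <- with_stream(seed, "parallel-analysis", {
    e <- matrix(0, n_sim, p)
    for (b in seq_len(n_sim)) {
      Z <- matrix(rnorm(n * p), n, p)
      e[b, ] <- eigen(cor(Z), symmetric = TRUE, only.values = TRUE)$values
    }
    e
  })
  qcurve <- apply(sim, 2L, stats::quantile, probs = quantile, names = FALSE)
  above <- observed > qcurve
  n_retained <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  structure(
    list(observed = observed, simulated = qcurve,
         n_retained = as.integer(n_retained), n_sim = n_sim,
         quantile = quantile, seed = seed, n = n, p = p),
    class = "parallel_analysis"
  )
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat("parallel analysis: retained ", x$n_retained, " component(s)\n",
      "  n = ", x$n, ", p = ", x$p, ", ", x$n_sim, " simulations, ",
      x$quantile * 100, "th percentile\n",
      "  first eigenvalues (observed | null): ",
      paste(sprintf("%.2f|%.2f", head(x$observed, 5), head(x$simulated, 5)),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}

## solve R x = B for symmetric PSD R, falling back to the eigen-pseudoinverse
## when R is singular (e.g. duplicated variables)
sym_solve <- function(R, B, tol = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    ((t(e$vectors[, pos, drop = FALSE]) %*% B) / e$values[pos])
}

## quartimin criterion value and gradient (gamma = 0 direct oblimin)
quartimin_fg <- function(L) {
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  L2 <- L * L
  M <- L2 %*% N
  list(f = sum(L2 * M) / 4, G = L * M)
}

## Oblique gradient-projection rotation (Jennrich 2002) minimizing the
## quartimin criterion. A is the unrotated loading matrix; returns the
## rotated pattern, the factor correlation Phi, and convergence metadata.
oblimin_rotate <- function(A, maxit = 1000L, tol = 1e-6) {
  k <- ncol(A)
  Tm <- diag(k)
  L <- A %*% t(solve(Tm))
  fg <- quartimin_fg(L)
  f <- fg$f
  G <- -t(t(L) %*% fg$G %*% solve(Tm))
  al <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)  # project onto the oblique manifold
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (half in 1:20) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Lt <- A %*% t(solve(Tt))
      fg <- quartimin_fg(Lt)
      if (fg$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; L <- Lt; f <- fg$f
    G <- -t(t(L) %*% fg$G %*% solve(Tm))
  }
  if (!converged)
    stop(sprintf("oblimin rotation failed to converge in %d iterations (|grad| = %.2e, f = %.4g)",
                 maxit, s, f))
  list(pattern = L, phi = t(Tm) %*% Tm, iterations = iter, criterion = f)
}

#' Principal components of the parcel correlation matrix with oblimin rotation
#'
#' Extracts the first `k` principal components of `cor(X)` and applies a
#' direct oblimin (quartimin) oblique rotation. Each rotated component is
#' sign-flipped so its largest-magnitude pattern loading is positive. Subject
#' scores are regression (Thurstone) scores of the standardized data.
#' Variance explained is reported two ways: from the unrotated eigenvalues
#' (additive) and as sums of squared structure loadings per rotated component
#' (non-additive under oblique rotation, labeled as such).
#'
#' @param X numeric n x p matrix (complete cases used).
#' @param k number of components to retain (e.g. from [parallel_analysis()]).
#' @param gamma oblimin gamma; only 0 (direct quartimin) is supported.
#' @param maxit,tol rotation convergence controls.
#' @return object of class `component_model`: `pattern` and `structure`
#'   loadings (p x k), `phi` (k x k component correlations), `communalities`,
#'   `eigenvalues` (all p), `var_explained` (per retained component,
#'   unrotated), `var_explained_rotated` (SS structure loadings / p),
#'   `total_var_explained`, `scores` (n x k), `rotation` metadata.
#' @export
fit_components <- function(X, k, gamma = 0, maxit = 1000L, tol = 1e-6) {
  X <- as.matrix(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (k < 1L) stop("k must be >= 1")
  if (n <= k) stop("need more observations than components")
  if (gamma != 0) stop("only direct quartimin (gamma = 0) is implemented")
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE)
  A <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev$values[seq_len(k)]), k)
  rownames(A) <- colnames(X)

  if (k == 1L) {
    rot <- list(pattern = A, phi = diag(1), iterations = 0L, criterion = 0)
  } else {
    rot <- oblimin_rotate(A, maxit = maxit, tol = tol)
  }
  P <- rot$pattern
  phi <- rot$phi

  # sign convention: dominant loading of each component positive
  flip <- vapply(seq_len(k), function(j) {
    sign(P[which.max(abs(P[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  P <- sweep(P, 2L, flip, `*`)
  phi <- diag(flip, k) %*% phi %*% diag(flip, k)
  S <- P %*% phi

  communal <- rowSums(P * S)   # = diag(P Phi P'), variance reproduced per variable
  Z <- scale(X)
  W <- sym_solve(R, S)         # regression-method score weights
  scores <- Z %*% W
  dimnames(P) <- dimnames(S) <- list(colnames(X), paste0("C", seq_len(k)))
  colnames(scores) <- paste0("C", seq_len(k))

  structure(
    list(k = k, pattern = P, structure = S, phi = phi,
         communalities = setNames(communal, colnames(X)),
         eigenvalues = ev$values,
         var_explained = ev$values[seq_len(k)] / p,
         var_explained_rotated = colSums(S^2) / p,
         total_var_explained = sum(ev$values[seq_len(k)]) / p,
         scores = scores, n = n,
         rotation = list(method = "oblimin", gamma = gamma,
                         iterations = rot$iterations,
                         criterion = rot$criterion, tol = tol)),
    class = "component_model"
  )
}

#' @export
print.component_model <- function(x, ...) {
  cat("component_model: ", x$k, " oblimin-rotated principal components (n = ",
      x$n, ")\n  total variance explained (unrotated eigenvalues): ",
      sprintf("%.1f%%", 100 * x$total_var_explained), "\n", sep = "")
  cat("  per component (unrotated): ",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Parcels loading on each component above a threshold
#'
#' @param model a `component_model`.
#' @param threshold absolute structure-loading threshold (default 0.4, the
#'   conventional display cutoff).
#' @return named list, one character vector of variable names per component,
#'   ordered by decreasing |loading|.
#' @export
interpret_loadings <- function(model, threshold = 0.4) {
  stopifnot(inherits(model, "component_model"))
  S <- model$structure
  out <- lapply(seq_len(ncol(S)), function(j) {
    sel <- abs(S[, j]) > threshold
    v <- rownames(S)[sel]
    v[order(abs(S[sel, j]), decreasing = TRUE)]
  })
  names(out) <- colnames(S)
  out
}
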