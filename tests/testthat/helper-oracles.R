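# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# all-pairs minimum distance (mm) to the mask, brute force
brute_force_distance <- function(mask, spacing) {
  dims <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  src_mm <- sweep(src - 1, 2L, spacing, `*`)
  out <- array(NA_real_, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    p <- c((i - 1) * spacing[1], (j - 1) * spacing[2], (k - 1) * spacing[3])
    out[i, j, k] <- sqrt(min(colSums((t(src_mm) - p)^2)))
  }
  out
}

# literal Benjamini-Hochberg step-up: q_i is the smallest candidate level at
# which hypothesis i is rejected by the procedure run from scratch
bh_oracle_q <- function(p) {
  m <- length(p)
  o <- order(p)
  levels_ <- sort(unique(pmin(1, p[o] * m / seq_len(m))))
  q <- rep(1, m)
  for (a in rev(levels_)) {
    ps <- p[o]
    ok <- ps <= a * seq_len(m) / m + 1e-12
    jmax <- if (any(ok)) max(which(ok)) else 0L
    rejected <- o[seq_len(jmax)]
    q[rejected] <- pmin(q[rejected], a)
  }
  q
}

# eigenvalues via the characteristic polynomial (Faddeev-LeVerrier + polyroot)
charpoly_eigenvalues <- function(A) {
  n <- nrow(A)
  M <- diag(n)
  cs <- numeric(n)
  for (k in seq_len(n)) {
    AM <- A %*% M
    cs[k] <- -sum(diag(AM)) / k
    M <- AM + cs[k] * diag(n)
  }
  roots <- polyroot(c(rev(cs), 1))
  sort(Re(roots), decreasing = TRUE)
}

# best block-partition agreement between a component assignment and the
# generating blocks, maximized over component relabelings
partition_match_rate <- function(assigned, blocks, k = 3L) {
  perms <- if (k == 3L) {
    list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  } else stop("k != 3 not needed here")
  tb <- table(factor(assigned, seq_len(k)), factor(blocks, seq_len(k)))
  max(vapply(perms, function(pm) sum(diag(tb[pm, ])), numeric(1))) / length(assigned)
}

# shared small phantom fixture (built once per test run)
phantom48 <- make_phantom_brain(shape = c(48L, 48L, 48L))
bullseye48 <- parcellate_phantom(phantom48)

cohort_log_matrix <- function(cohort) {
  tab <- log_transform(adjust_etiv(parcel_table(cohort)))
  as.matrix(as.data.frame(tab)[, paste0("p", parcel_codes())])
}
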