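test_that("phantom satisfies its structural invariants", {
  pb <- phantom48
  expect_false(any(pb$ventricle_mask & pb$wm_mask))
  expect_false(any(pb$ventricle_mask & pb$cortex_mask))
  expect_false(any(pb$wm_mask & pb$cortex_mask))
  bg <- pb$lobar_labels == 9L
  expect_false(any(pb$wm_mask & bg))
  # every wm and BG voxel carries exactly one lobar code
  expect_true(all(pb$lobar_labels[pb$wm_mask] %in% 1:8))
  expect_identical(sum(pb$lobar_labels > 0L), sum(pb$wm_mask) + sum(bg))
  # all masks inside the intracranial mask
  expect_true(all(pb$intracranial_mask[pb$ventricle_mask | pb$wm_mask |
                                       pb$cortex_mask | bg]))
  expect_identical(pb$etiv_mm3, sum(pb$intracranial_mask) * prod(pb$spacing))
  parench <- (sum(pb$wm_mask) + sum(pb$cortex_mask) + sum(bg)) * prod(pb$spacing)
  bpf <- compute_bpf(parench, pb$etiv_mm3)
  expect_true(bpf > 0 && bpf <= 100)
})

test_that("phantom generation is deterministic and rejects bad geometry", {
  a <- make_phantom_brain(shape = c(36, 36, 36), seed = 5)
  b <- make_phantom_brain(shape = c(36, 36, 36), seed = 5)
  expect_identical(a$wm_mask, b$wm_mask)
  expect_identical(a$lobar_labels, b$lobar_labels)
  expect_error(make_phantom_brain(geometry = phantom_geometry(ventricle_axes = c(0, 0, 0))),
               "invalid geometry")
  expect_error(make_phantom_brain(geometry = phantom_geometry(wm_frac = 0.9, cortex_frac = 0.8)),
               "invalid geometry")
  expect_error(make_phantom_brain(shape = c(16, 64, 64)), "32")
})

test_that("lesion seeding hits exact per-parcel voxel counts", {
  empty <- seed_wmh_lesions(bullseye48, setNames(numeric(0), character(0)))
  expect_identical(sum(empty$lesion_mask), 0L)

  gt <- seed_wmh_lesions(bullseye48, c(`11` = 50), seed = 3)
  expect_identical(sum(gt$lesion_mask), 50L)
  expect_true(all(bullseye48$values[gt$lesion_mask] == 11L))
  expect_identical(unname(gt$per_parcel_mm3[["11"]]), 50)

  gt2 <- seed_wmh_lesions(bullseye48, c(`11` = 50), seed = 3)
  expect_identical(gt$lesion_mask, gt2$lesion_mask)  # deterministic

  cap <- sum(bullseye48$values == 23L)
  expect_error(seed_wmh_lesions(bullseye48, setNames(cap + 10, "23")),
               "parcel 23")
  expect_error(seed_wmh_lesions(bullseye48, c(`11` = 0.5)), "multiple")
  expect_error(seed_wmh_lesions(bullseye48, c(`99` = 1)), "unknown")
})

test_that("seeded lesions round-trip through parcel volumetry", {
  set.seed(21)
  caps <- table(factor(bullseye48$values[bullseye48$values > 0],
                       levels = parcel_codes()))
  for (rep in 1:5) {
    targets <- setNames(pmin(rpois(36, 25), as.integer(caps)),
                        as.character(parcel_codes()))
    gt <- seed_wmh_lesions(bullseye48, targets, seed = rep)
    pv <- parcel_volumes(bullseye48, gt$lesion_mask)
    expect_identical(unname(pv$per_parcel_mm3), as.numeric(targets))
    expect_identical(pv$unassigned_mm3, 0)
    expect_equal(sum(pv$per_parcel_mm3), sum(gt$lesion_mask) * prod(gt$spacing))
  }
})

test_that("cohort generation is deterministic with skewed, block-structured volumes", {
  a <- simulate_cohort(n = 40, seed = 9)
  b <- simulate_cohort(n = 40, seed = 9)
  expect_identical(a, b)

  co <- simulate_cohort(n = 500, seed = 2)
  vols <- as.matrix(co[, paste0("p", parcel_codes())])
  expect_true(all(vols >= 0))
  skews <- apply(vols, 2L, function(x) {
    m <- mean(x); mean((x - m)^3) / mean((x - m)^2)^1.5
  })
  expect_true(all(skews > 0))  # lognormal marginals are right-skewed

  # 3-block structure on the log scale
  lv <- log(vols + 1)
  r <- cor(lv)
  blk <- attr(co, "block")
  same <- outer(blk, blk, `==`) & !diag(36)
  expect_gt(mean(abs(r[same])), mean(abs(r[!same & !diag(36)])))
})

test_that("cohort degenerate configurations behave as specified", {
  # noiseless single factor: all log-volumes perfectly correlated
  L1 <- matrix(0.7, 36, 1)
  co <- simulate_cohort(n = 30, loading_pattern = L1, factor_corr = matrix(1, 1, 1),
                        unique_sd = 0, covariate_model = list(age_factor_r = 0,
                                                              sex_factor_b = 0),
                        seed = 4)
  lv <- log(as.matrix(co[, paste0("p", parcel_codes())]))
  expect_true(all(abs(cor(lv) - 1) < 1e-12))

  bad_phi <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_cohort(n = 20, loading_pattern = matrix(0.5, 36, 2),
                               factor_corr = bad_phi, seed = 1),
               "positive-definite")
})

test_that("cohort domain scores are standardized with the stated missingness", {
  co <- simulate_cohort(n = 108, seed = 6)
  for (d in c("memory", "speed", "reasoning", "vocabulary")) {
    x <- co[[d]]
    expect_true(mean(is.na(x)) > 0.1 && mean(is.na(x)) < 0.5)
  }
  # scores were standardized over the full sample before missingness
  full <- simulate_cohort(n = 2000, seed = 6,
                          covariate_model = list(missing_rate = c(memory = 0,
                            speed = 0, reasoning = 0, vocabulary = 0)))
  expect_equal(mean(full$memory), 0, tolerance = 1e-10)
  expect_equal(sd(full$memory), 1, tolerance = 1e-10)
})
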