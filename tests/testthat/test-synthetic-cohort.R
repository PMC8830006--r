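test_that("cohort generation is deterministic and honours the block counts", {
  cfg <- cohort_config(seed = 123)
  c1 <- generate_cohort(cfg, compute_indices = FALSE)
  c2 <- generate_cohort(cfg, compute_indices = FALSE)
  expect_identical(c1$records, c2$records)
  counts <- dplyr::count(c1$records, group, site)
  blocks <- default_cohort_blocks()
  expect_equal(nrow(c1$records), sum(blocks$n))
  merged <- merge(counts, blocks[, c("group", "site", "n")],
                  by = c("group", "site"))
  expect_equal(merged$n.x, merged$n.y)
  # one record per (subject, site)
  expect_equal(anyDuplicated(paste(c1$records$subject_id, c1$records$site)), 0)
})

test_that("a config without a seed is rejected", {
  expect_error(cohort_config(), "seed")
})

test_that("sampled parameters track the configured means", {
  blocks <- default_cohort_blocks()
  blk <- blocks[blocks$group == "MCA_an" & blocks$site == "MCA_an", ]
  blk$n <- 500
  cfg <- cohort_config(seed = 321, blocks = blk)
  co <- generate_cohort(cfg, compute_indices = FALSE)
  # alpha mean 128.2, sd 24.2: sample mean within 3 SEs
  expect_lt(abs(mean(co$records$alpha_deg) - 128.2), 3 * 24.2 / sqrt(500))
  expect_lt(abs(mean(co$records$r0_mm) - 1.40), 3 * 0.18 / sqrt(500))
  # ordering enforced everywhere
  expect_true(all(co$records$r0_mm > co$records$r1_mm))
  expect_true(all(co$records$r1_mm >= co$records$r2_mm))
  expect_true(all(co$records$alpha_deg > 0 & co$records$alpha_deg < 180))
})

test_that("every generated record passes the type validation downstream", {
  cfg <- two_arm_config(seed = 9, n_per_arm = 40)
  co <- generate_cohort(cfg)
  m <- co$records
  expect_true(all(m$asymmetry_ratio > 0 & m$asymmetry_ratio <= 1))
  expect_true(all(m$area_ratio > 0))
  ok <- !is.na(m$junction_exponent)
  resid <- abs(m$r1_mm[ok]^m$junction_exponent[ok] +
                 m$r2_mm[ok]^m$junction_exponent[ok] -
                 m$r0_mm[ok]^m$junction_exponent[ok]) /
    m$r0_mm[ok]^m$junction_exponent[ok]
  expect_true(all(resid < 1e-9))
  defined <- m$domain_status %in% c("valid", "exponent_undefined")
  expect_equal(defined, !is.na(m$total_opt_deg))
})

test_that("unreachable ordering constraints fail with an informative error", {
  blk <- default_cohort_blocks()[1, ]
  blk$r0_mean <- 0.5  # parent mean far below branch means, tiny SDs
  blk$r0_sd <- 0.01; blk$r1_sd <- 0.01; blk$r2_sd <- 0.01
  cfg <- cohort_config(seed = 1, blocks = blk, max_attempts = 5)
  expect_error(generate_cohort(cfg), "r0 > r1 >= r2")
})

test_that("landmark synthesis round-trips the target angles", {
  set.seed(31)
  lm <- generate_landmarks(105, 60, 45)
  ang <- compute_observed_angles(lm)
  expect_equal(ang$alpha_deg, 105, tolerance = 1e-6)
  expect_equal(ang$phi1_obs_deg, 60, tolerance = 1e-6)
  expect_equal(ang$phi2_obs_deg, 45, tolerance = 1e-6)
  # arms honour the 5 mm rule
  expect_gte(sqrt(sum((lm$A - lm$O)^2)), 5)
  expect_gte(sqrt(sum((lm$B - lm$O)^2)), 5)

  # random non-coplanar targets, many poses, identical recovered angles
  for (k in 1:50) {
    p1 <- runif(1, 20, 90); p2 <- runif(1, 20, 90)
    a <- runif(1, abs(p1 - p2) + 1, min(p1 + p2, 179) - 0.5)
    lm_k <- generate_landmarks(a, p1, p2)
    ang_k <- compute_observed_angles(lm_k)
    expect_equal(ang_k$alpha_deg, a, tolerance = 1e-6)
    expect_equal(ang_k$phi1_obs_deg, p1, tolerance = 1e-6)
    expect_equal(ang_k$phi2_obs_deg, p2, tolerance = 1e-6)
  }
})

test_that("geometrically impossible angle targets are refused", {
  expect_error(generate_landmarks(120, 40, 50), "exceeds phi1 \\+ phi2")
  expect_error(generate_landmarks(5, 80, 20), "below \\|phi1 - phi2\\|")
  expect_error(generate_landmarks(190, 60, 45), "inside \\(0, 180\\)")
})

test_that("landmark-mode cohorts re-measure to the sampled angles", {
  blk <- default_cohort_blocks()
  blk <- blk[blk$site == "BA" & blk$group == "control", ]
  blk$n <- 25
  cfg <- cohort_config(seed = 77, blocks = blk, output = "landmarks")
  co <- generate_cohort(cfg)
  lm_df <- co$landmarks
  lm_df$branch_swapped <- FALSE
  m <- measure_landmarks(lm_df)
  expect_equal(m$alpha_deg, co$records$alpha_deg, tolerance = 1e-6)
  expect_equal(m$phi1_obs_deg, co$records$phi1_obs_deg, tolerance = 1e-6)
  expect_equal(m$r0_mm, co$records$r0_mm, tolerance = 1e-12)
})

test_that("coupled mode ties observed angles to the optimal angles", {
  blk <- default_cohort_blocks()
  blk <- blk[blk$site == "MCA_an", ]
  blk$n <- 120
  cfg <- cohort_config(seed = 15, blocks = blk, pmw_coupled = TRUE,
                       angle_noise_sd = 5)
  co <- generate_cohort(cfg)
  m <- co$records
  expect_true(all(m$domain_status %in% c("valid", "exponent_undefined")))
  # deviations should scatter around zero with roughly the noise SD
  expect_lt(abs(mean(m$dev_phi1_deg)), 2.5)
  expect_lt(sd(m$dev_phi1_deg), 12)
})

test_that("an injected aneurysm effect propagates through the full pipeline", {
  cfg <- two_arm_config(seed = 2024, n_per_arm = 120,
                        alpha_shift = 25, r0_shift = 0.15)
  co <- generate_cohort(cfg)
  m <- co$records
  gc <- compare_groups(m, "alpha_deg")
  expect_lt(gc$omnibus_p, 0.001)
  fit <- univariate_logistic(m, "alpha_deg", coding = "tertile")
  t3 <- fit$or_table[grepl("T3", fit$or_table$term), ]
  expect_gt(t3$or, 1)
  expect_gt(t3$ci_low, 1)
  roc <- roc_analysis(m, "alpha_deg")
  expect_gt(roc$auc, 0.7)
})

test_that("a zero-shift cohort shows no spurious signal", {
  cfg <- two_arm_config(seed = 404, n_per_arm = 120,
                        alpha_shift = 0, r0_shift = 0)
  co <- generate_cohort(cfg, compute_indices = FALSE)
  roc <- roc_analysis(co$records, "alpha_deg")
  expect_lt(abs(roc$auc - 0.5), 0.05)
})
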