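test_that("asymmetry and area ratios follow their definitions", {
  expect_equal(asymmetry_ratio(1, 1), 1)
  expect_equal(asymmetry_ratio(2, 1), 0.25)
  expect_equal(asymmetry_ratio(1.31, 1.01), 0.5944, tolerance = 1e-4)
  expect_error(asymmetry_ratio(1, 1.2), "r1 must be >= r2")

  expect_equal(area_ratio(sqrt(2), 1, 1), 1)
  expect_equal(area_ratio(2^(1/3), 1, 1), 2^(1/3), tolerance = 1e-12)
  expect_equal(area_ratio(1.58, 1.12, 0.92), 0.8416, tolerance = 1e-4)
  expect_error(area_ratio(-1, 1, 1), "positive")
})

test_that("junction exponent solves the radius power law", {
  expect_equal(as.numeric(junction_exponent(1.259921, 1, 1)), 3,
               tolerance = 1e-6)
  expect_equal(as.numeric(junction_exponent(2, 1, 1)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(junction_exponent(1.76, 1.31, 1.01)), 1.686,
               tolerance = 1e-3)
  n_undef <- junction_exponent(1.0, 1.0, 0.8)
  expect_true(is.na(n_undef))
  expect_match(attr(n_undef, "reason")[1], "no unique positive root")
})

test_that("junction exponent matches an independent grid+bisection oracle", {
  set.seed(42)
  for (k in 1:60) {
    r <- random_triple()
    n <- as.numeric(junction_exponent(r[1], r[2], r[3]))
    expect_equal(n, oracle_junction_exponent(r[1], r[2], r[3]),
                 tolerance = 1e-6)
    # residual of the power law, relative to r0^n
    expect_lt(abs(r[2]^n + r[3]^n - r[1]^n) / r[1]^n, 1e-9)
  }
})

test_that("junction exponent handles extreme roots via bracket expansion", {
  # nearly equal parent and branch pushes the root far above 50
  n <- as.numeric(junction_exponent(1.0001, 1, 1))
  expect_equal(n, log(2) / log(1.0001), tolerance = 1e-6)
})

test_that("junction exponent decreases as the parent radius grows", {
  r0s <- seq(1.3, 3, by = 0.1)
  ns <- as.numeric(junction_exponent(r0s, rep(1.2, length(r0s)),
                                     rep(0.9, length(r0s))))
  expect_true(all(diff(ns) < 0))
})

test_that("indices are invariant under uniform scaling of the radii", {
  set.seed(7)
  for (k in 1:20) {
    r <- random_triple()
    s <- runif(1, 0.1, 10)
    expect_equal(asymmetry_ratio(r[2], r[3]),
                 asymmetry_ratio(s * r[2], s * r[3]), tolerance = 1e-12)
    expect_equal(area_ratio(r[1], r[2], r[3]),
                 area_ratio(s * r[1], s * r[2], s * r[3]), tolerance = 1e-12)
    expect_equal(as.numeric(junction_exponent(r[1], r[2], r[3])),
                 as.numeric(junction_exponent(s * r[1], s * r[2], s * r[3])),
                 tolerance = 1e-9)
    a1 <- optimal_angles(r[1], r[2], r[3])
    a2 <- optimal_angles(s * r[1], s * r[2], s * r[3])
    expect_equal(a1$total_opt_deg, a2$total_opt_deg, tolerance = 1e-9)
  }
})

test_that("optimal angles obey the closed forms and the triangle identity", {
  a <- optimal_angles(2^(1/3), 1, 1)
  expect_equal(a$phi1_opt_deg, acos(2^(-1/3)) * 180 / pi, tolerance = 1e-9)
  expect_equal(a$phi1_opt_deg, 37.467, tolerance = 1e-3)
  expect_equal(a$total_opt_deg, 74.934, tolerance = 1e-3)
  expect_equal(a$phi1_opt_deg + a$phi2_opt_deg, a$total_opt_deg,
               tolerance = 1e-8)
  # boundary: all three cosines exactly 1
  b <- optimal_angles(sqrt(2), 1, 1)
  expect_equal(b$total_opt_deg, 0)
  expect_true(b$angles_defined)
})

test_that("out-of-domain radii are flagged, and clamp mode is explicit", {
  # control basilar-tip mean radii: cos(phi1) = 1.132 > 1
  r <- c(1.58, 1.12, 0.92)
  cos1 <- (r[1]^4 + r[2]^4 - r[3]^4) / (2 * r[1]^2 * r[2]^2)
  expect_gt(cos1, 1)
  a <- optimal_angles(r[1], r[2], r[3])
  expect_false(a$angles_defined)
  expect_true(is.na(a$phi1_opt_deg))
  ac <- optimal_angles(r[1], r[2], r[3], clamp = TRUE)
  expect_true(ac$clamped)
  expect_equal(ac$phi1_opt_deg, 0)
})

test_that("angle domain coincides with the squared-radius triangle inequality", {
  set.seed(13)
  for (k in 1:200) {
    r <- random_triple()
    s <- r^2
    tri <- (s[2] + s[3] > s[1]) && (s[1] + s[3] > s[2]) && (s[1] + s[2] > s[3])
    a <- optimal_angles(r[1], r[2], r[3])
    expect_identical(a$angles_defined, tri)
  }
})

test_that("deviations are signed predicted-minus-observed and propagate NA", {
  d <- deviations(74.9, 40, 34.9, 40, 34.9, 74.9)
  expect_equal(d$dev_total_deg, 0)
  d2 <- deviations(128.2, 59.6, 81.5, NA, NA, 62.2)
  expect_equal(d2$dev_total_deg, -66, tolerance = 1e-9)
  expect_true(is.na(d2$dev_phi1_deg))
  d3 <- deviations(100, 50, 50, NA_real_, NA_real_, NA_real_)
  expect_true(all(is.na(unlist(d3))))
})

test_that("compute_morphometry assembles the canonical table", {
  df <- tibble::tibble(
    subject_id = c("s1", "s2"), site = c("MCA_an", "BA"),
    group = c("MCA_an", "control"), aneurysm = c(1L, 0L),
    r0_mm = c(1.4, 1.58), r1_mm = c(1.16, 1.12), r2_mm = c(0.87, 0.92),
    alpha_deg = c(128.2, 107.0), phi1_obs_deg = c(59.6, 55.7),
    phi2_obs_deg = c(81.5, 58.2)
  )
  m <- compute_morphometry(df)
  expect_true(all(c("junction_exponent", "dev_total_deg", "domain_status")
                  %in% names(m)))
  # second row has no real optimal angles but a defined exponent
  expect_equal(m$domain_status[2], "angles_undefined")
  expect_false(is.na(m$junction_exponent[2]))
  expect_true(is.na(m$dev_total_deg[2]))
  expect_error(compute_morphometry(df[, -5]), "missing required column")
})
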