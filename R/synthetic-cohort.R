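# Synthetic case-control cohorts with the three-group, five-site structure
# of the CTA morphometry study design: a group with middle-cerebral-artery
# (MCA) aneurysms, a group with basilar-artery (BA) aneurysms, and controls,
# each contributing internal-carotid (ICA), MCA and BA bifurcations.
#
# Radii are drawn from a truncated trivariate normal with exchangeable
# correlation and the anatomical ordering r0 > r1 >= r2 enforced by
# resampling; angles from truncated normals. A configurable "aneurysm effect"
# adds an angle widening and a parent-radius enlargement at aneurysmal sites.

#' Default per-block calibration of the synthetic cohort
#'
#' One block per (group, site) combination with the group sizes and the
#' mean +/- SD of each radius and angle taken from published cohort tables of
#' cerebral-bifurcation morphometry (ICA, MCA and BA bifurcations of patients
#' with MCA aneurysms, patients with BA aneurysms, and controls). In the
#' MCA-aneurysm group the contralateral (non-aneurysmal) MCA is stored under
#' site `MCA_L`.
#'
#' @return Tibble with columns `group`, `site`, `aneurysm`, `n`, and
#'   mean/sd pairs for `r0`, `r1`, `r2` (mm) and `alpha`, `phi1`, `phi2`
#'   (degrees).
#' @export
default_cohort_blocks <- function() {
  blk <- function(group, site, an, n, r0m, r0s, r1m, r1s, r2m, r2s,
                  am, as_, p1m, p1s, p2m, p2s) {
    tibble::tibble(
      group = group, site = site, aneurysm = an, n = n,
      r0_mean = r0m, r0_sd = r0s, r1_mean = r1m, r1_sd = r1s,
      r2_mean = r2m, r2_sd = r2s,
      alpha_mean = am, alpha_sd = as_,
      phi1_mean = p1m, phi1_sd = p1s, phi2_mean = p2m, phi2_sd = p2s
    )
  }
  dplyr::bind_rows(
    # --- MCA-aneurysm group ---
    blk("MCA_an", "MCA_an", 1L, 119, 1.40, 0.18, 1.16, 0.17, 0.87, 0.20,
        128.2, 24.2, 59.6, 25.2, 81.5, 21.7),
    blk("MCA_an", "MCA_L", 0L, 92, 1.42, 0.18, 1.17, 0.19, 0.91, 0.19,
        105.9, 19.1, 47.3, 20.9, 68.2, 20.4),
    blk("MCA_an", "ICA_R", 0L, 107, 1.86, 0.24, 1.48, 0.21, 1.12, 0.22,
        116.4, 18.7, 44.9, 31.3, 88.2, 28.2),
    blk("MCA_an", "ICA_L", 0L, 108, 1.85, 0.20, 1.48, 0.18, 1.13, 0.17,
        114.8, 15.4, 39.9, 30.3, 86.8, 27.4),
    blk("MCA_an", "BA", 0L, 93, 1.57, 0.22, 1.17, 0.21, 0.96, 0.24,
        107.37, 19.27, 54.60, 20.23, 60.51, 17.87),
    # --- BA-aneurysm group ---
    blk("BA_an", "BA", 1L, 32, 1.76, 0.36, 1.31, 0.25, 1.01, 0.23,
        136.68, 22.98, 71.70, 18.95, 77.07, 24.00),
    blk("BA_an", "MCA_R", 0L, 23, 1.54, 0.21, 1.24, 0.23, 0.95, 0.22,
        103.4, 25.8, 47.7, 23.0, 66.4, 20.5),
    blk("BA_an", "MCA_L", 0L, 23, 1.49, 0.25, 1.21, 0.23, 0.94, 0.18,
        93.3, 18.0, 49.9, 27.0, 57.8, 25.2),
    blk("BA_an", "ICA_R", 0L, 28, 1.92, 0.23, 1.53, 0.19, 1.16, 0.21,
        119.4, 18.4, 35.6, 16.8, 96.0, 13.8),
    blk("BA_an", "ICA_L", 0L, 29, 1.91, 0.23, 1.48, 0.23, 1.17, 0.24,
        120.7, 26.4, 45.6, 19.2, 93.2, 15.6),
    # --- control group ---
    blk("control", "MCA_R", 0L, 91, 1.35, 0.16, 1.15, 0.18, 0.86, 0.17,
        97.1, 20.5, 46.8, 23.1, 61.0, 19.4),
    blk("control", "MCA_L", 0L, 91, 1.31, 0.20, 1.11, 0.21, 0.84, 0.18,
        93.2, 19.6, 42.4, 23.0, 65.3, 18.2),
    blk("control", "ICA_R", 0L, 99, 1.85, 0.23, 1.49, 0.22, 1.15, 0.25,
        120.2, 14.8, 41.7, 20.4, 95.0, 17.4),
    blk("control", "ICA_L", 0L, 100, 1.82, 0.22, 1.46, 0.23, 1.13, 0.26,
        119.1, 14.7, 40.4, 20.6, 92.5, 19.1),
    blk("control", "BA", 0L, 91, 1.58, 0.25, 1.12, 0.22, 0.92, 0.27,
        107.02, 23.55, 55.73, 19.19, 58.23, 20.82)
  )
}

#' Build a simulation configuration
#'
#' @param seed Integer seed; mandatory so every cohort is reproducible.
#' @param blocks Per-(group, site) calibration tibble, see
#'   [default_cohort_blocks()].
#' @param rho Exchangeable correlation of the radius triple (anatomical sizes
#'   co-vary; an assumption, configurable).
#' @param alpha_shift,r0_shift Aneurysm effect: additive shift of the alpha
#'   mean (degrees) and the r0 mean (mm) applied to aneurysmal blocks on top
#'   of their calibrated means.
#' @param radius_trunc,angle_trunc Truncation limits (radii mm, angles
#'   degrees) applied by resampling.
#' @param output `"morphometry"` (radii + angles table) or `"landmarks"`
#'   (additionally synthesises 3D landmark points per record).
#' @param pmw_coupled If `TRUE`, observed angles are the minimum-work optimal
#'   angles of the drawn radii plus Gaussian noise (`angle_noise_sd`),
#'   yielding cohorts consistent with the optimality model; radii are then
#'   additionally resampled into the optimal-angle domain.
#' @param angle_noise_sd Noise SD (degrees) for `pmw_coupled` mode.
#' @param max_attempts Resampling rounds before giving up on the ordering /
#'   truncation constraints.
#' @return List of class `sim_config`.
#' @export
cohort_config <- function(seed,
                          blocks = default_cohort_blocks(),
                          rho = 0.5,
                          alpha_shift = 0,
                          r0_shift = 0,
                          radius_trunc = c(0.05, Inf),
                          angle_trunc = c(1, 179),
                          output = c("morphometry", "landmarks"),
                          pmw_coupled = FALSE,
                          angle_noise_sd = 10,
                          max_attempts = 1000) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("a single integer 'seed' is mandatory", call. = FALSE)
  }
  output <- match.arg(output)
  stopifnot(nrow(blocks) >= 1, all(blocks$n >= 1),
            all(blocks$r0_sd > 0), all(blocks$alpha_sd > 0),
            rho > -0.5, rho < 1,
            radius_trunc[1] > 0, angle_trunc[1] > 0, angle_trunc[2] < 180)
  bad_site <- setdiff(blocks$site, VALID_SITES)
  if (length(bad_site) > 0) {
    stop("unknown site(s): ", paste(bad_site, collapse = ", "), call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), blocks = blocks, rho = rho,
         alpha_shift = alpha_shift, r0_shift = r0_shift,
         radius_trunc = radius_trunc, angle_trunc = angle_trunc,
         output = output, pmw_coupled = pmw_coupled,
         angle_noise_sd = angle_noise_sd, max_attempts = max_attempts),
    class = "sim_config"
  )
}

#' Minimal two-arm configuration for effect-recovery experiments
#'
#' A single aneurysmal MCA site per case against a control MCA site, both
#' arms sharing the control-group MCA calibration; the case arm differs only
#' by the configured aneurysm effect. Used for parameter-recovery and null
#' (zero-shift) simulations.
#'
#' @param seed Integer seed.
#' @param n_per_arm Records per arm.
#' @param alpha_shift,r0_shift Aneurysm effect applied to the case arm.
#' @param ... Passed on to [cohort_config()].
#' @return A `sim_config`.
#' @export
two_arm_config <- function(seed, n_per_arm = 120, alpha_shift = 25,
                           r0_shift = 0.15, ...) {
  base <- default_cohort_blocks()
  ctrl <- base[base$group == "control" & base$site == "MCA_R", ]
  case_blk <- ctrl
  case_blk$group <- "MCA_an"
  case_blk$site <- "MCA_an"
  case_blk$aneurysm <- 1L
  case_blk$n <- n_per_arm
  ctrl_blk <- ctrl
  ctrl_blk$n <- n_per_arm
  cohort_config(seed = seed,
                blocks = dplyr::bind_rows(case_blk, ctrl_blk),
                alpha_shift = alpha_shift, r0_shift = r0_shift, ...)
}

# Draw n radius triples for one block honouring truncation and ordering.
sample_radii_block <- function(n, mu, sds, rho, trunc, max_attempts,
                               block_label) {
  R <- matrix(rho, 3, 3); diag(R) <- 1
  Sigma <- diag(sds) %*% R %*% diag(sds)
  out <- matrix(NA_real_, n, 3)
  need <- seq_len(n)
  for (attempt in seq_len(max_attempts)) {
    draw <- MASS::mvrnorm(length(need), mu = mu, Sigma = Sigma)
    if (length(need) == 1) draw <- matrix(draw, nrow = 1)
    ok <- draw[, 1] > draw[, 2] & draw[, 2] >= draw[, 3] &
      apply(draw, 1, function(z) all(z > trunc[1] & z < trunc[2]))
    out[need[ok], ] <- draw[ok, , drop = FALSE]
    need <- need[!ok]
    if (length(need) == 0) break
  }
  if (length(need) > 0) {
    stop(sprintf(
      "block %s: could not satisfy r0 > r1 >= r2 within truncation after %d resampling rounds; check the configured means/SDs",
      block_label, max_attempts), call. = FALSE)
  }
  out
}

# Truncated-normal draws by resampling.
sample_truncnorm <- function(n, mean, sd, lower, upper, max_attempts,
                             block_label) {
  x <- rep(NA_real_, n)
  need <- seq_len(n)
  for (attempt in seq_len(max_attempts)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lower & draw < upper
    x[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (length(need) == 0) break
  }
  if (length(need) > 0) {
    stop(sprintf("block %s: truncated-normal sampling failed after %d rounds",
                 block_label, max_attempts), call. = FALSE)
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws one record per (subject, site) for every configured block:
#' radius triples from a truncated trivariate normal with exchangeable
#' correlation and the ordering `r0 > r1 >= r2` enforced by resampling, angles
#' from truncated normals (independent of the radii unless `pmw_coupled`),
#' with the configured aneurysm effect added to aneurysmal blocks. The full
#' morphometry table (minimum-work indices and deviations) is computed for
#' every record. Regeneration with the same config is bit-identical.
#'
#' @param cfg A `sim_config` from [cohort_config()].
#' @param compute_indices Compute the minimum-work indices (set `FALSE` to
#'   skip the per-record root-finding when only radii/angles are needed).
#' @return List of class `synthetic_cohort`: `records` (morphometry tibble),
#'   `landmarks` (landmark tibble or `NULL`), `ground_truth` (applied
#'   effects, seed, assumptions), `config`.
#' @export
generate_cohort <- function(cfg, compute_indices = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  blocks <- cfg$blocks
  rec_list <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    blk <- blocks[b, ]
    label <- paste(blk$group, blk$site, sep = "/")
    an <- blk$aneurysm == 1L
    mu_r <- c(blk$r0_mean + if (an) cfg$r0_shift else 0,
              blk$r1_mean, blk$r2_mean)
    radii <- sample_radii_block(
      blk$n, mu_r, c(blk$r0_sd, blk$r1_sd, blk$r2_sd), cfg$rho,
      cfg$radius_trunc, cfg$max_attempts, label)
    if (cfg$pmw_coupled) {
      # resample radii that have no optimal-angle solution, then derive
      # angles from the optimum plus noise
      for (attempt in seq_len(cfg$max_attempts)) {
        ang <- optimal_angles(radii[, 1], radii[, 2], radii[, 3])
        bad <- which(!ang$angles_defined)
        if (length(bad) == 0) break
        radii[bad, ] <- sample_radii_block(
          length(bad), mu_r, c(blk$r0_sd, blk$r1_sd, blk$r2_sd), cfg$rho,
          cfg$radius_trunc, cfg$max_attempts, label)
      }
      ang <- optimal_angles(radii[, 1], radii[, 2], radii[, 3])
      if (any(!ang$angles_defined)) {
        stop(sprintf(
          "block %s: could not draw radii inside the optimal-angle domain",
          label), call. = FALSE)
      }
      clamp_ang <- function(x) pmin(pmax(x, cfg$angle_trunc[1]),
                                    cfg$angle_trunc[2])
      phi1 <- clamp_ang(ang$phi1_opt_deg + rnorm(blk$n, 0, cfg$angle_noise_sd))
      phi2 <- clamp_ang(ang$phi2_opt_deg + rnorm(blk$n, 0, cfg$angle_noise_sd))
      alpha_mu_extra <- if (an) cfg$alpha_shift else 0
      alpha <- clamp_ang(ang$total_opt_deg + alpha_mu_extra +
                           rnorm(blk$n, 0, cfg$angle_noise_sd))
    } else {
      alpha_mu <- blk$alpha_mean + if (an) cfg$alpha_shift else 0
      alpha <- sample_truncnorm(blk$n, alpha_mu, blk$alpha_sd,
                                cfg$angle_trunc[1], cfg$angle_trunc[2],
                                cfg$max_attempts, label)
      phi1 <- sample_truncnorm(blk$n, blk$phi1_mean, blk$phi1_sd,
                               cfg$angle_trunc[1], cfg$angle_trunc[2],
                               cfg$max_attempts, label)
      phi2 <- sample_truncnorm(blk$n, blk$phi2_mean, blk$phi2_sd,
                               cfg$angle_trunc[1], cfg$angle_trunc[2],
                               cfg$max_attempts, label)
    }
    if (cfg$output == "landmarks") {
      # a 3D pose exists only when |phi1 - phi2| <= alpha <= phi1 + phi2;
      # resample angle triples until realisable
      for (attempt in seq_len(cfg$max_attempts)) {
        bad <- which(alpha > phi1 + phi2 | alpha < abs(phi1 - phi2) |
                       alpha > 360 - (phi1 + phi2))
        if (length(bad) == 0) break
        if (cfg$pmw_coupled) {
          stop(sprintf("block %s: coupled angles not 3D-realisable", label),
               call. = FALSE)
        }
        alpha_mu <- blk$alpha_mean + if (an) cfg$alpha_shift else 0
        alpha[bad] <- sample_truncnorm(length(bad), alpha_mu, blk$alpha_sd,
                                       cfg$angle_trunc[1], cfg$angle_trunc[2],
                                       cfg$max_attempts, label)
        phi1[bad] <- sample_truncnorm(length(bad), blk$phi1_mean, blk$phi1_sd,
                                      cfg$angle_trunc[1], cfg$angle_trunc[2],
                                      cfg$max_attempts, label)
        phi2[bad] <- sample_truncnorm(length(bad), blk$phi2_mean, blk$phi2_sd,
                                      cfg$angle_trunc[1], cfg$angle_trunc[2],
                                      cfg$max_attempts, label)
      }
      if (any(alpha > phi1 + phi2 | alpha < abs(phi1 - phi2) |
                alpha > 360 - (phi1 + phi2))) {
        stop(sprintf("block %s: could not draw 3D-realisable angle triples",
                     label), call. = FALSE)
      }
    }
    rec_list[[b]] <- tibble::tibble(
      subject_id = sprintf("%s_%03d", blk$group, seq_len(blk$n)),
      site = blk$site, group = blk$group, aneurysm = blk$aneurysm,
      r0_mm = radii[, 1], r1_mm = radii[, 2], r2_mm = radii[, 3],
      alpha_deg = alpha, phi1_obs_deg = phi1, phi2_obs_deg = phi2
    )
  }
  records <- dplyr::bind_rows(rec_list)

  landmarks <- NULL
  if (cfg$output == "landmarks") {
    lm_rows <- lapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      lm <- generate_landmarks(
        alpha_deg = r$alpha_deg, phi1_deg = r$phi1_obs_deg,
        phi2_deg = r$phi2_obs_deg,
        r0 = r$r0_mm, r1 = r$r1_mm, r2 = r$r2_mm)
      tibble::tibble(
        subject_id = r$subject_id, site = r$site, group = r$group,
        aneurysm = r$aneurysm,
        Ax = lm$A[1], Ay = lm$A[2], Az = lm$A[3],
        Bx = lm$B[1], By = lm$B[2], Bz = lm$B[3],
        Cx = lm$C[1], Cy = lm$C[2], Cz = lm$C[3],
        Ox = lm$O[1], Oy = lm$O[2], Oz = lm$O[3],
        d0_mm = lm$d0, d1_mm = lm$d1, d2_mm = lm$d2
      )
    })
    landmarks <- dplyr::bind_rows(lm_rows)
  }

  if (compute_indices) {
    records <- compute_morphometry(records)
  }
  structure(
    list(records = records,
         landmarks = landmarks,
         ground_truth = list(
           seed = cfg$seed,
           alpha_shift = cfg$alpha_shift,
           r0_shift = cfg$r0_shift,
           rho = cfg$rho,
           pmw_coupled = cfg$pmw_coupled,
           distribution = "truncated normal (assumed, not published)",
           n_records = nrow(records)),
         config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d records, %d blocks, seed %d\n",
              nrow(x$records), nrow(x$config$blocks), x$config$seed))
  print(dplyr::count(x$records, .data$group, .data$site, .data$aneurysm))
  invisible(x)
}

# Random rotation matrix (uniform via QR of a Gaussian matrix, det +1)
# drawn from the current RNG stream.
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Synthesise 3D landmarks realising target bifurcation angles
#'
#' Inverts the angle construction: places the apex O, a parent point A and
#' branch points B and C so that the measured total angle equals
#' `alpha_deg` and the branch angles relative to the extended parent axis
#' equal `phi1_deg` and `phi2_deg`. A 3D pose exists iff
#' `|phi1 - phi2| <= alpha <= phi1 + phi2`; the dihedral angle between the
#' two branch half-planes is solved from the spherical law of cosines. The
#' construction is built in a canonical frame and then mapped through a
#' random rigid motion (rotation + translation) drawn from the current RNG
#' stream; arm lengths honour the 5 mm minimum distance of curvature points
#' from the apex.
#'
#' @param alpha_deg,phi1_deg,phi2_deg Target angles in degrees, each in
#'   (0, 180).
#' @param r0,r1,r2 Radii (mm); stored as diameters `2 r`.
#' @param arm_parent,arm_branch Arm lengths in mm (>= 5).
#' @return A `bifurcation_landmarks` object whose measured angles reproduce
#'   the targets to ~1e-6 degrees.
#' @export
generate_landmarks <- function(alpha_deg, phi1_deg, phi2_deg,
                               r0 = 1.5, r1 = 1.2, r2 = 1.0,
                               arm_parent = 10, arm_branch = 7) {
  for (v in c(alpha_deg, phi1_deg, phi2_deg)) {
    if (!is.finite(v) || v <= 0 || v >= 180) {
      stop("target angles must lie strictly inside (0, 180) degrees",
           call. = FALSE)
    }
  }
  if (alpha_deg > phi1_deg + phi2_deg + 1e-9) {
    stop(sprintf(
      "infeasible targets: alpha (%.3f) exceeds phi1 + phi2 (%.3f); no 3D pose exists",
      alpha_deg, phi1_deg + phi2_deg), call. = FALSE)
  }
  # when the branch angles wrap past the anti-axis the attainable maximum of
  # alpha is 360 - (phi1 + phi2), reached with both branches coplanar
  if (alpha_deg > 360 - (phi1_deg + phi2_deg) + 1e-9) {
    stop(sprintf(
      "infeasible targets: alpha (%.3f) exceeds 360 - (phi1 + phi2) (%.3f); no 3D pose exists",
      alpha_deg, 360 - (phi1_deg + phi2_deg)), call. = FALSE)
  }
  if (alpha_deg < abs(phi1_deg - phi2_deg) - 1e-9) {
    stop(sprintf(
      "infeasible targets: alpha (%.3f) is below |phi1 - phi2| (%.3f); no 3D pose exists",
      alpha_deg, abs(phi1_deg - phi2_deg)), call. = FALSE)
  }
  if (arm_parent < MIN_ARM_MM || arm_branch < MIN_ARM_MM) {
    stop(sprintf("arm lengths must be at least %g mm", MIN_ARM_MM),
         call. = FALSE)
  }
  d2r <- pi / 180
  a <- alpha_deg * d2r; p1 <- phi1_deg * d2r; p2 <- phi2_deg * d2r
  # dihedral angle psi between branch half-planes about the parent axis:
  # cos a = cos p1 cos p2 + sin p1 sin p2 cos psi
  cpsi <- (cos(a) - cos(p1) * cos(p2)) / (sin(p1) * sin(p2))
  cpsi <- clamp_cosine(cpsi)
  psi <- acos(cpsi)
  # canonical frame: extended parent axis along +x, A behind the apex
  e <- c(1, 0, 0)
  A0 <- -arm_parent * e
  B0 <- arm_branch * c(cos(p1), sin(p1), 0)
  C0 <- arm_branch * c(cos(p2),
                       sin(p2) * cos(psi),
                       sin(p2) * sin(psi))
  R <- random_rotation()
  t <- rnorm(3, 0, 20)
  pose <- function(p) as.numeric(R %*% p + t)
  bifurcation_landmarks(
    A = pose(A0), B = pose(B0), C = pose(C0), O = pose(c(0, 0, 0)),
    d0 = 2 * r0, d1 = 2 * r1, d2 = 2 * r2, quiet = TRUE
  )
}
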