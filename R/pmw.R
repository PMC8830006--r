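# Minimum-work optimality indices for a bifurcation radius triple
# (r0 parent, r1 larger branch, r2 smaller branch, all mm, r0/r1/r2 > 0,
# r1 >= r2).
#
# The principle of minimum work predicts that an energetically optimal
# bifurcation satisfies the cube law r0^3 = r1^3 + r2^3 and branches at angles
# fixed by law-of-cosines relations in the squared radii. The junction
# exponent n — the exponent actually solving r0^n = r1^n + r2^n — measures how
# far a measured bifurcation sits from that optimum (n = 3 at the optimum).

JUNCTION_BRACKET <- c(0.05, 50)
JUNCTION_MAX_EXPANSIONS <- 3L
JUNCTION_TOL <- 1e-9  # relative residual tolerance on r0^n - r1^n - r2^n

check_radii <- function(r0, r1, r2) {
  n <- length(r0)
  if (length(r1) != n || length(r2) != n) {
    stop("r0, r1, r2 must have equal length", call. = FALSE)
  }
  bad <- !is.finite(r0) | !is.finite(r1) | !is.finite(r2) |
    r0 <= 0 | r1 <= 0 | r2 <= 0
  if (any(bad)) {
    stop(sprintf("radii must be positive and finite (first bad element: %d)",
                 which(bad)[1]), call. = FALSE)
  }
  if (any(r1 < r2)) {
    stop(sprintf(
      "r1 must be >= r2 (larger branch first); violated at element %d",
      which(r1 < r2)[1]), call. = FALSE)
  }
  invisible(NULL)
}

#' Branch asymmetry ratio
#'
#' `r2^2 / r1^2`: 1 for perfectly symmetric daughter branches, smaller as the
#' branches become more unequal.
#'
#' @param r1,r2 Radii of the larger and smaller branch (mm), `r1 >= r2`.
#' @return Dimensionless ratio in (0, 1].
#' @export
asymmetry_ratio <- function(r1, r2) {
  check_radii(r1, r1, r2)
  r2^2 / r1^2
}

#' Area ratio of a bifurcation
#'
#' `(r1^2 + r2^2) / r0^2`: combined daughter cross-sectional area relative to
#' the parent. Values above 1 indicate an expansion across the bifurcation.
#'
#' @param r0 Parent radius (mm).
#' @param r1,r2 Branch radii (mm), `r1 >= r2`.
#' @return Dimensionless positive ratio.
#' @export
area_ratio <- function(r0, r1, r2) {
  check_radii(r0, r1, r2)
  (r1^2 + r2^2) / r0^2
}

#' Junction exponent of a bifurcation
#'
#' Solves \eqn{r_0^n = r_1^n + r_2^n} for the junction exponent n by bracketed
#' root-finding on \eqn{f(n) = (r_1/r_0)^n + (r_2/r_0)^n - 1}, which is
#' strictly decreasing from f(0) = 1 towards -1 whenever `r0 > r1` strictly, so
#' a unique positive root exists. When `r0 <= r1` the equation has no positive
#' solution and `NA` is returned with an attribute explaining why (never an
#' error): undefined exponents are first-class and are counted, not dropped
#' silently, by downstream summaries.
#'
#' @param r0 Parent radius (mm); may be a vector.
#' @param r1,r2 Branch radii (mm), `r1 >= r2`; recycled against `r0` must not
#'   be needed — equal lengths required.
#' @param bracket Initial search interval for n.
#' @param tol Relative residual tolerance: the returned n satisfies
#'   \eqn{|r_0^n - r_1^n - r_2^n| < tol \cdot r_0^n}.
#' @return Numeric vector of junction exponents, `NA` where undefined; the
#'   attribute `reason` (character vector, `NA` where defined) records why.
#' @examples
#' junction_exponent(1.259921, 1, 1) # ~3, the minimum-work optimum
#' junction_exponent(2, 1, 1)        # 1
#' @export
junction_exponent <- function(r0, r1, r2, bracket = JUNCTION_BRACKET,
                              tol = JUNCTION_TOL) {
  check_radii(r0, r1, r2)
  n_out <- rep(NA_real_, length(r0))
  reason <- rep(NA_character_, length(r0))
  for (i in seq_along(r0)) {
    res <- junction_exponent_one(r0[i], r1[i], r2[i], bracket, tol)
    n_out[i] <- res$n
    reason[i] <- res$reason
  }
  attr(n_out, "reason") <- reason
  n_out
}

junction_exponent_one <- function(r0, r1, r2, bracket, tol) {
  if (r0 <= r1) {
    return(list(n = NA_real_,
                reason = "no unique positive root: r0 <= r1"))
  }
  a <- r1 / r0
  b <- r2 / r0
  f <- function(n) a^n + b^n - 1
  lo <- bracket[1]
  hi <- bracket[2]
  expansions <- 0L
  while (f(lo) < 0 || f(hi) > 0) {
    if (expansions >= JUNCTION_MAX_EXPANSIONS) {
      return(list(n = NA_real_,
                  reason = "root outside bracket after adaptive expansion"))
    }
    if (f(lo) < 0) lo <- lo / 10
    if (f(hi) > 0) hi <- hi * 10
    expansions <- expansions + 1L
  }
  root <- stats::uniroot(f, lower = lo, upper = hi, tol = 1e-14)$root
  # f(n) is the residual already scaled by r0^n
  if (abs(f(root)) >= tol) {
    # polish by bisection; f is monotone decreasing
    lo2 <- lo; hi2 <- hi
    for (k in 1:200) {
      mid <- (lo2 + hi2) / 2
      if (f(mid) > 0) lo2 <- mid else hi2 <- mid
      if (abs(f(mid)) < tol) break
    }
    root <- (lo2 + hi2) / 2
    if (abs(f(root)) >= tol) {
      return(list(n = NA_real_, reason = "root refinement failed"))
    }
  }
  list(n = root, reason = NA_character_)
}

#' Predicted optimal branching angles under the principle of minimum work
#'
#' Evaluates the three law-of-cosines relations
#' \deqn{\cos\phi_1 = (r_0^4 + r_1^4 - r_2^4) / (2 r_0^2 r_1^2)}
#' \deqn{\cos\phi_2 = (r_0^4 + r_2^4 - r_1^4) / (2 r_0^2 r_2^2)}
#' \deqn{\cos(\phi_1+\phi_2) = (r_0^4 - r_1^4 - r_2^4) / (2 r_1^2 r_2^2)}
#' which have a solution precisely when the squared radii satisfy the triangle
#' inequality. For measured radii this can fail (the cosine falls outside
#' \eqn{[-1, 1]}); by default such triples are flagged `angles_undefined` and
#' returned as `NA` rather than silently forced into range. With
#' `clamp = TRUE` the cosines are clamped to \eqn{\pm 1} and the row is marked
#' `clamped` — an explicit opt-in for users who want boundary-case angles.
#'
#' @param r0,r1,r2 Radii (mm), equal-length vectors, `r1 >= r2`.
#' @param clamp Clamp out-of-range cosines to the domain boundary instead of
#'   returning `NA` (flagged in the `clamped` column).
#' @return Tibble with columns `phi1_opt_deg`, `phi2_opt_deg`,
#'   `total_opt_deg`, `angles_defined` (logical), `clamped` (logical).
#' @export
optimal_angles <- function(r0, r1, r2, clamp = FALSE) {
  check_radii(r0, r1, r2)
  cos1 <- (r0^4 + r1^4 - r2^4) / (2 * r0^2 * r1^2)
  cos2 <- (r0^4 + r2^4 - r1^4) / (2 * r0^2 * r2^2)
  cos12 <- (r0^4 - r1^4 - r2^4) / (2 * r1^2 * r2^2)
  # floating-point overshoot at the domain boundary is numerical, not a
  # domain violation
  soften <- function(x) ifelse(abs(x) > 1 & abs(x) <= 1 + COS_CLAMP_TOL,
                               sign(x), x)
  cos1 <- soften(cos1); cos2 <- soften(cos2); cos12 <- soften(cos12)
  in_domain <- abs(cos1) <= 1 & abs(cos2) <= 1 & abs(cos12) <= 1
  clamped <- rep(FALSE, length(r0))
  if (clamp) {
    clamped <- !in_domain
    cos1 <- pmax(-1, pmin(1, cos1))
    cos2 <- pmax(-1, pmin(1, cos2))
    cos12 <- pmax(-1, pmin(1, cos12))
    usable <- rep(TRUE, length(r0))
  } else {
    usable <- in_domain
  }
  phi1 <- ifelse(usable, acos_deg(pmax(-1, pmin(1, cos1))), NA_real_)
  phi2 <- ifelse(usable, acos_deg(pmax(-1, pmin(1, cos2))), NA_real_)
  total <- ifelse(usable, acos_deg(pmax(-1, pmin(1, cos12))), NA_real_)
  tibble::tibble(
    phi1_opt_deg = phi1,
    phi2_opt_deg = phi2,
    total_opt_deg = total,
    angles_defined = usable,
    clamped = clamped
  )
}

#' All minimum-work indices for radius triples
#'
#' Convenience wrapper computing asymmetry and area ratios, the junction
#' exponent and the predicted optimal angles in one pass, with a
#' `domain_status` column summarising which quantities are defined:
#' `"valid"`, `"exponent_undefined"`, `"angles_undefined"` or
#' `"both_undefined"`.
#'
#' @inheritParams optimal_angles
#' @return Tibble with one row per triple.
#' @export
pmw_indices <- function(r0, r1, r2, clamp = FALSE) {
  check_radii(r0, r1, r2)
  n <- junction_exponent(r0, r1, r2)
  ang <- optimal_angles(r0, r1, r2, clamp = clamp)
  exp_ok <- !is.na(n)
  ang_ok <- !is.na(ang$phi1_opt_deg)
  status <- dplyr::case_when(
    exp_ok & ang_ok ~ "valid",
    !exp_ok & ang_ok ~ "exponent_undefined",
    exp_ok & !ang_ok ~ "angles_undefined",
    TRUE ~ "both_undefined"
  )
  tibble::tibble(
    asymmetry_ratio = asymmetry_ratio(r1, r2),
    area_ratio = area_ratio(r0, r1, r2),
    junction_exponent = as.numeric(n),
    exponent_reason = attr(n, "reason"),
    phi1_opt_deg = ang$phi1_opt_deg,
    phi2_opt_deg = ang$phi2_opt_deg,
    total_opt_deg = ang$total_opt_deg,
    clamped = ang$clamped,
    domain_status = status
  )
}

#' Deviations of observed angles from the predicted optimum
#'
#' Signed differences predicted minus observed: `total_opt - alpha`,
#' `phi1_opt - Phi1`, `phi2_opt - Phi2`. Undefined predictions propagate as
#' `NA`.
#'
#' @param alpha_deg,phi1_obs_deg,phi2_obs_deg Observed angles (degrees).
#' @param phi1_opt_deg,phi2_opt_deg,total_opt_deg Predicted optimal angles
#'   (degrees), possibly `NA`.
#' @return Tibble with `dev_total_deg`, `dev_phi1_deg`, `dev_phi2_deg`.
#' @export
deviations <- function(alpha_deg, phi1_obs_deg, phi2_obs_deg,
                       phi1_opt_deg, phi2_opt_deg, total_opt_deg) {
  tibble::tibble(
    dev_total_deg = total_opt_deg - alpha_deg,
    dev_phi1_deg = phi1_opt_deg - phi1_obs_deg,
    dev_phi2_deg = phi2_opt_deg - phi2_obs_deg
  )
}

# Canonical column order of the morphometry table / CSV dialect.
MORPHOMETRY_COLS <- c(
  "subject_id", "site", "group", "aneurysm",
  "r0_mm", "r1_mm", "r2_mm",
  "alpha_deg", "phi1_obs_deg", "phi2_obs_deg",
  "asymmetry_ratio", "area_ratio", "junction_exponent",
  "phi1_opt_deg", "phi2_opt_deg", "total_opt_deg",
  "dev_total_deg", "dev_phi1_deg", "dev_phi2_deg",
  "domain_status"
)

#' Complete the morphometry table for a cohort
#'
#' Takes per-bifurcation radii and observed angles (with identifiers) and adds
#' every minimum-work index and deviation, producing the canonical morphometry
#' table consumed by the statistical layer.
#'
#' @param df Data frame with at least `subject_id`, `site`, `group`,
#'   `aneurysm`, `r0_mm`, `r1_mm`, `r2_mm`, `alpha_deg`, `phi1_obs_deg`,
#'   `phi2_obs_deg`.
#' @param clamp Passed to [optimal_angles()].
#' @return Tibble in canonical morphometry column order (extra input columns
#'   are preserved at the end).
#' @export
compute_morphometry <- function(df, clamp = FALSE) {
  need <- c("subject_id", "site", "group", "aneurysm",
            "r0_mm", "r1_mm", "r2_mm",
            "alpha_deg", "phi1_obs_deg", "phi2_obs_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  idx <- pmw_indices(df$r0_mm, df$r1_mm, df$r2_mm, clamp = clamp)
  dev <- deviations(df$alpha_deg, df$phi1_obs_deg, df$phi2_obs_deg,
                    idx$phi1_opt_deg, idx$phi2_opt_deg, idx$total_opt_deg)
  out <- dplyr::bind_cols(tibble::as_tibble(df),
                          idx[setdiff(names(idx), "exponent_reason")], dev)
  extra <- setdiff(names(out), MORPHOMETRY_COLS)
  out[, c(MORPHOMETRY_COLS, extra)]
}

#' Measure a landmark table
#'
#' Runs the geometry stage over a validated landmark table (as returned by
#' [read_landmark_csv()]): observed angles at the apex O, radii from the
#' best-fit diameters, then the full morphometry table via
#' [compute_morphometry()].
#'
#' @param lm_df Landmark tibble with columns `subject_id`, `site`, `group`,
#'   `aneurysm`, `Ax..Oz`, `d0_mm`, `d1_mm`, `d2_mm` (and optionally
#'   `branch_swapped`).
#' @param clamp Passed to [compute_morphometry()].
#' @return Morphometry tibble, one row per landmark row.
#' @export
measure_landmarks <- function(lm_df, clamp = FALSE) {
  rows <- lapply(seq_len(nrow(lm_df)), function(i) {
    r <- lm_df[i, ]
    lm <- bifurcation_landmarks(
      A = c(r$Ax, r$Ay, r$Az), B = c(r$Bx, r$By, r$Bz),
      C = c(r$Cx, r$Cy, r$Cz), O = c(r$Ox, r$Oy, r$Oz),
      d0 = r$d0_mm, d1 = r$d1_mm, d2 = r$d2_mm, quiet = TRUE
    )
    ang <- compute_observed_angles(lm)
    tibble::tibble(
      subject_id = r$subject_id, site = r$site, group = r$group,
      aneurysm = r$aneurysm,
      r0_mm = radius_from_diameter(lm$d0),
      r1_mm = radius_from_diameter(lm$d1),
      r2_mm = radius_from_diameter(lm$d2),
      alpha_deg = ang$alpha_deg,
      phi1_obs_deg = ang$phi1_obs_deg,
      phi2_obs_deg = ang$phi2_obs_deg,
      branch_swapped = lm$branch_swapped | isTRUE(r$branch_swapped)
    )
  })
  compute_morphometry(dplyr::bind_rows(rows), clamp = clamp)
}
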