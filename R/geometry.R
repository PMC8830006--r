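# Landmark geometry: observed bifurcation angles from 3D points.
#
# A bifurcation is described by four 3D points in millimetres:
#   A — point of largest curvature on the parent vessel,
#   B — point of largest curvature on the larger branch,
#   C — point of largest curvature on the smaller branch,
#   O — intersection of the parent and branch centrelines (angle apex),
# plus best-fit diameters d0, d1, d2 of parent, larger and smaller branch.
# All angles are measured in 3D at the apex O and reported in degrees.

# Cosines may overshoot |1| by floating-point noise; anything within this
# relative tolerance is clamped, larger overshoot is treated as a real error.
COS_CLAMP_TOL <- 1e-12

# Landmark points should sit at least this far from the apex (mm). Violations
# are warned about, not rejected: upstream extraction is outside our control.
MIN_ARM_MM <- 5

#' Angle at an apex between two points, in degrees
#'
#' Computes the angle subtended at `apex` by the arms `apex -> p` and
#' `apex -> q` via the arc-cosine of the normalised dot product. The cosine is
#' clamped against floating-point overshoot of at most `1e-12` beyond
#' \eqn{[-1, 1]}; larger overshoot raises an error.
#'
#' @param apex,p,q Numeric 3-vectors (same units; typically mm).
#' @return Angle in degrees, in \eqn{[0, 180]}.
#' @examples
#' angle_between(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) # 90
#' @export
angle_between <- function(apex, p, q) {
  check_point(apex, "apex")
  check_point(p, "p")
  check_point(q, "q")
  u <- p - apex
  v <- q - apex
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0) {
    stop("degenerate geometry: point 'p' coincides with the apex", call. = FALSE)
  }
  if (nv == 0) {
    stop("degenerate geometry: point 'q' coincides with the apex", call. = FALSE)
  }
  cosang <- sum(u * v) / (nu * nv)
  acos_deg(clamp_cosine(cosang))
}

clamp_cosine <- function(x) {
  if (is.na(x)) {
    stop("degenerate geometry: cosine is not a number", call. = FALSE)
  }
  if (abs(x) > 1 + COS_CLAMP_TOL) {
    stop(sprintf("cosine %.17g overshoots [-1, 1] beyond tolerance", x),
         call. = FALSE)
  }
  max(-1, min(1, x))
}

acos_deg <- function(x) acos(x) * 180 / pi

check_point <- function(x, name) {
  if (!is.numeric(x) || length(x) != 3L || !all(is.finite(x))) {
    stop(sprintf("'%s' must be a finite numeric 3-vector", name), call. = FALSE)
  }
  invisible(x)
}

#' Construct and validate a set of bifurcation landmarks
#'
#' Bundles the four landmark points and the three best-fit diameters after
#' validating them. The larger branch must carry the larger diameter
#' (`d1 >= d2`); if the input violates this, B/C and d1/d2 are swapped and the
#' swap is recorded in the `branch_swapped` field (and reported as a message),
#' never performed silently. Arms shorter than 5 mm trigger a warning because
#' the landmark-extraction protocol places curvature points at least 5 mm from
#' the bifurcation.
#'
#' @param A,B,C,O Numeric 3-vectors, mm. `A` on the parent vessel, `B` on the
#'   larger branch, `C` on the smaller branch, `O` the centreline intersection.
#' @param d0,d1,d2 Best-fit diameters (mm) of parent, larger, smaller branch.
#' @param quiet Suppress the branch-swap message (the flag is still set).
#' @return An object of class `bifurcation_landmarks`: a list with fields
#'   `A`, `B`, `C`, `O`, `d0`, `d1`, `d2`, `branch_swapped`.
#' @export
bifurcation_landmarks <- function(A, B, C, O, d0, d1, d2, quiet = FALSE) {
  check_point(A, "A"); check_point(B, "B"); check_point(C, "C")
  check_point(O, "O")
  for (nm in c("d0", "d1", "d2")) {
    d <- get(nm)
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
      stop(sprintf("diameter '%s' must be a single positive number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("A", "B", "C")) {
    if (all(get(nm) == O)) {
      stop(sprintf("degenerate geometry: point '%s' coincides with O", nm),
           call. = FALSE)
    }
  }
  swapped <- FALSE
  if (d1 < d2) {
    tmp <- B; B <- C; C <- tmp
    tmp <- d1; d1 <- d2; d2 <- tmp
    swapped <- TRUE
    if (!quiet) {
      message("branch swap: d1 < d2 on input; relabelled so the larger branch is B")
    }
  }
  arms <- c(A = sqrt(sum((A - O)^2)), B = sqrt(sum((B - O)^2)),
            C = sqrt(sum((C - O)^2)))
  short <- names(arms)[arms < MIN_ARM_MM]
  if (length(short) > 0) {
    warning(sprintf(
      "landmark arm(s) %s shorter than %g mm; curvature points should sit at least %g mm from the apex",
      paste(short, collapse = ", "), MIN_ARM_MM, MIN_ARM_MM), call. = FALSE)
  }
  structure(
    list(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C),
         O = as.numeric(O), d0 = d0, d1 = d1, d2 = d2,
         branch_swapped = swapped),
    class = "bifurcation_landmarks"
  )
}

#' Observed bifurcation angles from landmarks
#'
#' The total bifurcation angle alpha is subtended at O by the two branch
#' points B and C; beta and gamma are subtended by the parent point A and the
#' larger/smaller branch point respectively. The branch angles relative to the
#' extended parent axis follow as `Phi1 = 180 - beta` and `Phi2 = 180 - gamma`.
#'
#' @param lm A `bifurcation_landmarks` object.
#' @return A one-row tibble with columns `alpha_deg`, `beta_deg`, `gamma_deg`,
#'   `phi1_obs_deg`, `phi2_obs_deg` (degrees).
#' @export
compute_observed_angles <- function(lm) {
  stopifnot(inherits(lm, "bifurcation_landmarks"))
  alpha <- angle_between(lm$O, lm$B, lm$C)
  beta  <- angle_between(lm$O, lm$A, lm$B)
  gamma <- angle_between(lm$O, lm$A, lm$C)
  tibble::tibble(
    alpha_deg = alpha,
    beta_deg = beta,
    gamma_deg = gamma,
    phi1_obs_deg = 180 - beta,
    phi2_obs_deg = 180 - gamma
  )
}

#' Vessel radius from best-fit diameter
#'
#' @param d Diameter(s), mm; must be positive.
#' @return `d / 2`, mm.
#' @examples
#' radius_from_diameter(3.52) # 1.76
#' @export
radius_from_diameter <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("diameters must be finite and positive", call. = FALSE)
  }
  d / 2
}
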