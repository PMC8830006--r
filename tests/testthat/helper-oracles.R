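# Independent oracles used to cross-check the implementation.

# Junction exponent by coarse grid scan + plain bisection (no uniroot).
oracle_junction_exponent <- function(r0, r1, r2, tol = 1e-12) {
  f <- function(n) (r1 / r0)^n + (r2 / r0)^n - 1
  grid <- seq(1e-3, 100, length.out = 2000)
  fg <- vapply(grid, f, numeric(1))
  i <- which(fg[-length(fg)] > 0 & fg[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  lo <- grid[i]; hi <- grid[i + 1]
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# AUC by exhaustive pair counting (ties count half).
oracle_auc_paircount <- function(cases, controls) {
  wins <- 0
  for (x in cases) {
    wins <- wins + sum(x > controls) + 0.5 * sum(x == controls)
  }
  wins / (length(cases) * length(controls))
}

# Random radius triple with r0 > r1 >= r2, optionally restricted to the
# optimal-angle domain (squared radii satisfy the strict triangle inequality).
random_triple <- function(domain_valid = FALSE) {
  repeat {
    r <- sort(runif(3, 0.3, 2.5), decreasing = TRUE)
    if (r[1] <= r[2]) next
    if (domain_valid) {
      s <- r^2
      if (!(s[2] + s[3] > s[1] && s[1] + s[3] > s[2] && s[1] + s[2] > s[3])) next
    }
    return(r)
  }
}

# Rigid motion applied to a landmark set.
apply_rigid <- function(lm, R, t) {
  bifurcation_landmarks(
    A = as.numeric(R %*% lm$A + t), B = as.numeric(R %*% lm$B + t),
    C = as.numeric(R %*% lm$C + t), O = as.numeric(R %*% lm$O + t),
    d0 = lm$d0, d1 = lm$d1, d2 = lm$d2, quiet = TRUE
  )
}

rotation_about <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
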