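# Case-control statistical layer: normality-gated group comparisons,
# tertile coding, univariate and stepwise multivariate logistic regression,
# ROC with Youden-index cut-offs.

#' Compare a morphometric parameter across groups
#'
#' Per-group normality is checked with the Shapiro-Wilk test. If every group
#' passes at p >= 0.05 the omnibus test is one-way ANOVA with Tukey-Kramer
#' post-hoc comparisons (valid for unequal group sizes); otherwise the
#' Kruskal-Wallis test with Dunn's multiple comparisons (Bonferroni-adjusted).
#' Post-hoc results are reported only when the omnibus test rejects at 0.05.
#' Undefined (`NA`) parameter values are excluded pairwise and counted.
#'
#' @param data Data frame (typically a morphometry table).
#' @param parameter Name of the numeric column to compare.
#' @param grouping Name of the grouping column (default `"group"`).
#' @return A `group_comparison` object: list with `parameter`, `summary`
#'   (per-group n, n_undefined, mean, sd, shapiro_p), `test_used`
#'   (`"anova_tukey"` or `"kruskal_wallis_mc"`), `omnibus_p`, and `posthoc`
#'   (tibble of pairwise p-values, `NULL` unless omnibus p < 0.05).
#' @export
compare_groups <- function(data, parameter, grouping = "group") {
  if (!parameter %in% names(data)) {
    stop("unknown parameter column: ", parameter, call. = FALSE)
  }
  if (!grouping %in% names(data)) {
    stop("unknown grouping column: ", grouping, call. = FALSE)
  }
  g_all <- as.character(data[[grouping]])
  x_all <- data[[parameter]]
  keep <- !is.na(x_all) & !is.na(g_all)
  x <- x_all[keep]
  g <- factor(g_all[keep])
  undef <- table(factor(g_all[!is.na(g_all) & !keep], levels = levels(g)))
  counts <- table(g)
  if (nlevels(g) < 2) {
    stop("need at least two groups with defined values", call. = FALSE)
  }
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    stop(sprintf("group(s) %s have fewer than 3 defined values for '%s'",
                 paste(small, collapse = ", "), parameter), call. = FALSE)
  }
  sw <- vapply(levels(g), function(lv) {
    xi <- x[g == lv]
    if (length(unique(xi)) < 2) return(0) # constant: not plausibly normal
    shapiro.test(xi)$p.value
  }, numeric(1))
  summary_tbl <- tibble::tibble(
    group = levels(g),
    n = as.integer(counts),
    n_undefined = as.integer(undef),
    mean = vapply(levels(g), function(lv) mean(x[g == lv]), numeric(1)),
    sd = vapply(levels(g), function(lv) sd(x[g == lv]), numeric(1)),
    shapiro_p = sw
  )
  all_normal <- all(sw >= 0.05)
  if (all_normal) {
    fit <- aov(x ~ g)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    test_used <- "anova_tukey"
    ph_all <- TukeyHSD(fit)$g
    posthoc <- tibble::tibble(
      group_pair = rownames(ph_all),
      p = unname(ph_all[, "p adj"])
    )
  } else {
    kw <- kruskal.test(x, g)
    omnibus_p <- kw$p.value
    test_used <- "kruskal_wallis_mc"
    posthoc <- dunn_posthoc(x, g)
  }
  structure(
    list(parameter = parameter, summary = summary_tbl, test_used = test_used,
         omnibus_p = omnibus_p,
         posthoc = if (omnibus_p < 0.05) posthoc else NULL),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' (%s), omnibus p = %.4g\n",
              x$parameter, x$test_used, x$omnibus_p))
  print(x$summary)
  if (!is.null(x$posthoc)) {
    cat("Post-hoc pairwise comparisons:\n")
    print(x$posthoc)
  } else {
    cat("No post-hoc comparisons (omnibus p >= 0.05).\n")
  }
  invisible(x)
}

#' Dunn's multiple-comparison test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the usual tie correction;
#' two-sided p-values are Bonferroni-adjusted over the number of pairs.
#'
#' @param x Numeric vector.
#' @param g Grouping factor, same length.
#' @return Tibble with `group_pair`, `z`, `p` (adjusted, capped at 1).
#' @export
dunn_posthoc <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    ni <- sum(g == pr[1]); nj <- sum(g == pr[2])
    ri <- mean(r[g == pr[1]]); rj <- mean(r[g == pr[2]])
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    z <- (ri - rj) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  m <- ncol(pairs)
  tibble::tibble(
    group_pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
    z = unname(res["z", ]),
    p = pmin(1, unname(res["p", ]) * m)
  )
}

#' Split a continuous variable into tertiles
#'
#' Boundaries are the empirical 33.33rd and 66.67th percentiles computed by
#' linear interpolation between order statistics (quantile type 7). A value
#' exactly on a boundary is assigned to the lower tertile.
#'
#' @param values Numeric vector; `NA`s are carried through as `NA`
#'   assignments.
#' @return List of class `tertile_spec`: `boundaries` (length 2, strictly
#'   increasing), `ranges` (observed min/max per tertile), `assignment`
#'   (integer vector 1/2/3 aligned with `values`), `counts`.
#' @export
tertile_split <- function(values) {
  x <- values[!is.na(values)]
  if (length(unique(x)) < 3) {
    stop("tertile split needs at least 3 distinct defined values",
         call. = FALSE)
  }
  b <- unname(quantile(x, probs = c(1, 2) / 3, type = 7))
  if (b[1] >= b[2]) {
    stop("degenerate tertile boundaries (heavy ties); cannot code in tertiles",
         call. = FALSE)
  }
  assignment <- ifelse(is.na(values), NA_integer_,
                       ifelse(values <= b[1], 1L,
                              ifelse(values <= b[2], 2L, 3L)))
  ranges <- lapply(1:3, function(k) {
    xk <- values[!is.na(assignment) & assignment == k]
    if (length(xk) == 0) c(NA_real_, NA_real_) else range(xk)
  })
  structure(
    list(boundaries = b,
         ranges = ranges,
         assignment = assignment,
         counts = as.integer(table(factor(assignment, levels = 1:3)))),
    class = "tertile_spec"
  )
}

#' @export
print.tertile_spec <- function(x, ...) {
  cat(sprintf("Tertile boundaries: %.4g, %.4g\n",
              x$boundaries[1], x$boundaries[2]))
  for (k in 1:3) {
    cat(sprintf("  %s tertile (%.4g-%.4g): n = %d\n",
                c("1st", "2nd", "3rd")[k],
                x$ranges[[k]][1], x$ranges[[k]][2], x$counts[k]))
  }
  invisible(x)
}

# Wald OR rows from a fitted binomial glm, for the non-intercept terms.
or_rows_from_glm <- function(fit, conf_level = 0.95) {
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  terms_keep <- setdiff(names(cf), "(Intercept)")
  zval <- cf[terms_keep] / se[terms_keep]
  tibble::tibble(
    term = terms_keep,
    or = unname(exp(cf[terms_keep])),
    ci_low = unname(exp(cf[terms_keep] - z * se[terms_keep])),
    ci_high = unname(exp(cf[terms_keep] + z * se[terms_keep])),
    p = unname(2 * pnorm(-abs(zval)))
  )
}

# Fit glm while capturing the separation warning.
fit_logistic <- function(formula, data) {
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # complete separation can converge silently to a saturated fit
  if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) ||
      stats::deviance(fit) < 1e-6) {
    separation <- TRUE
  }
  list(fit = fit, separation = separation)
}

#' Univariate logistic regression for aneurysm presence
#'
#' Fits a maximum-likelihood binary logistic model of the aneurysm flag on one
#' predictor, either continuous (one OR row per unit of the predictor) or
#' tertile-coded (1st tertile as reference; OR rows for the 2nd and 3rd).
#' Confidence intervals are Wald-type. Perfect separation is flagged in the
#' output, not raised as an error.
#'
#' @param data Data frame containing `predictor` and the outcome column.
#' @param predictor Name of the predictor column.
#' @param coding `"continuous"` or `"tertile"`.
#' @param outcome Name of the 0/1 outcome column (default `"aneurysm"`).
#' @return A `logistic_fit` object: list with `predictor`, `coding`,
#'   `or_table` (term, or, ci_low, ci_high, p, separation), `model_p`
#'   (likelihood-ratio p of the whole predictor), `tertiles`
#'   (a `tertile_spec` or `NULL`), `n_case`, `n_control`, and `fit`.
#' @export
univariate_logistic <- function(data, predictor,
                                coding = c("continuous", "tertile"),
                                outcome = "aneurysm") {
  coding <- match.arg(coding)
  if (!predictor %in% names(data)) {
    stop("unknown predictor column: ", predictor, call. = FALSE)
  }
  y <- data[[outcome]]
  x <- data[[predictor]]
  keep <- !is.na(y) & !is.na(x)
  y <- as.integer(y[keep]); x <- x[keep]
  if (length(unique(y)) < 2) {
    stop("outcome has a single class after exclusions", call. = FALSE)
  }
  if (min(table(y)) < 10) {
    stop(sprintf("predictor '%s' defined for fewer than 10 records in one outcome class",
                 predictor), call. = FALSE)
  }
  tert <- NULL
  if (coding == "tertile") {
    tert <- tertile_split(x)
    xf <- factor(tert$assignment, levels = 1:3,
                 labels = c("T1", "T2", "T3"))
    if (nlevels(droplevels(xf)) < 2) {
      stop("predictor varies only within the reference tertile", call. = FALSE)
    }
    dd <- data.frame(y = y, x = xf)
  } else {
    if (length(unique(x)) < 2) {
      stop(sprintf("predictor '%s' has no variation", predictor), call. = FALSE)
    }
    dd <- data.frame(y = y, x = x)
  }
  fl <- fit_logistic(y ~ x, dd)
  rows <- or_rows_from_glm(fl$fit)
  rows$term <- sub("^x", paste0(predictor, if (coding == "tertile") " " else ""),
                   rows$term)
  rows$separation <- fl$separation
  null_fit <- glm(y ~ 1, data = dd, family = binomial())
  model_p <- anova(null_fit, fl$fit, test = "LRT")[2, "Pr(>Chi)"]
  structure(
    list(predictor = predictor, coding = coding, or_table = rows,
         model_p = model_p, tertiles = tert,
         n_case = sum(y == 1), n_control = sum(y == 0), fit = fl$fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression: aneurysm ~ %s (%s coding), LRT p = %.4g\n",
              x$predictor, x$coding, x$model_p))
  print(x$or_table)
  invisible(x)
}

#' Multivariate logistic regression by stepwise addition
#'
#' Reproduces the two-stage selection used in case-control morphometry
#' studies: candidates must pass the univariate entry gate (`model_p <
#' entry_p`); among pairs of candidates whose underlying values correlate
#' beyond `correlation_exclusion_r` in absolute Pearson r, only the one with
#' the smaller univariate p is kept; the survivors enter a forward stepwise
#' addition (likelihood-ratio test, add while the best addition is
#' significant at `add_p`), and the final joint model is reported as OR rows.
#'
#' @param data Data frame.
#' @param candidates Named character vector mapping predictor column names to
#'   codings, e.g. `c(alpha_deg = "tertile", r0_mm = "continuous")`.
#' @param entry_p Univariate entry threshold for the candidate set.
#' @param add_p Significance-to-add threshold of the stepwise addition
#'   (default 0.05, the overall significance level).
#' @param correlation_exclusion_r Absolute Pearson correlation above which two
#'   candidates are considered redundant.
#' @param outcome Name of the 0/1 outcome column.
#' @param force_all Skip the entry gate and stepwise selection and fit all
#'   candidates jointly (used for pre-specified model templates).
#' @return A `logistic_model` object: list with `or_table`, `retained`,
#'   `dropped` (tibble: predictor, reason), `tertiles` (named list), `fit`.
#' @export
multivariate_logistic <- function(data, candidates, entry_p = 0.1,
                                  add_p = 0.05,
                                  correlation_exclusion_r = 0.7,
                                  outcome = "aneurysm", force_all = FALSE) {
  stopifnot(length(candidates) > 0, !is.null(names(candidates)))
  preds <- names(candidates)
  uni <- lapply(preds, function(p) {
    univariate_logistic(data, p, coding = candidates[[p]], outcome = outcome)
  })
  names(uni) <- preds
  uni_p <- vapply(uni, function(u) u$model_p, numeric(1))

  dropped <- tibble::tibble(predictor = character(), reason = character())
  surv <- preds
  if (!force_all) {
    fail <- surv[uni_p[surv] >= entry_p]
    if (length(fail) > 0) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        predictor = fail,
        reason = sprintf("univariate p = %.3g >= entry threshold %.3g",
                         uni_p[fail], entry_p)))
      surv <- setdiff(surv, fail)
    }
    # correlation exclusion on the raw values, pairwise-complete
    if (length(surv) > 1) {
      ord <- surv[order(uni_p[surv])]
      kept <- character()
      for (p in ord) {
        redundant <- FALSE
        for (q in kept) {
          r <- suppressWarnings(
            cor(data[[p]], data[[q]], use = "pairwise.complete.obs"))
          if (!is.na(r) && abs(r) > correlation_exclusion_r) {
            dropped <- dplyr::bind_rows(dropped, tibble::tibble(
              predictor = p,
              reason = sprintf("|r| = %.2f with '%s' exceeds %.2f",
                               abs(r), q, correlation_exclusion_r)))
            redundant <- TRUE
            break
          }
        }
        if (!redundant) kept <- c(kept, p)
      }
      surv <- kept
    }
    if (length(surv) == 0) {
      stop("no candidate predictors survive the entry and correlation filters",
           call. = FALSE)
    }
  }

  # build model frame: tertile-coded candidates become factors
  keep_rows <- !is.na(data[[outcome]])
  for (p in surv) keep_rows <- keep_rows & !is.na(data[[p]])
  dd <- data.frame(y = as.integer(data[[outcome]][keep_rows]))
  tert_specs <- list()
  for (p in surv) {
    xv <- data[[p]][keep_rows]
    if (candidates[[p]] == "tertile") {
      ts <- tertile_split(xv)
      tert_specs[[p]] <- ts
      dd[[p]] <- factor(ts$assignment, levels = 1:3,
                        labels = c("T1", "T2", "T3"))
    } else {
      dd[[p]] <- xv
    }
  }

  if (force_all) {
    selected <- surv
  } else {
    # forward stepwise addition by LRT
    selected <- character()
    remaining <- surv
    current <- glm(y ~ 1, data = dd, family = binomial())
    repeat {
      if (length(remaining) == 0) break
      step_p <- vapply(remaining, function(p) {
        f2 <- stats::update(current, stats::as.formula(paste(". ~ . +", p)))
        anova(current, f2, test = "LRT")[2, "Pr(>Chi)"]
      }, numeric(1))
      best <- names(which.min(step_p))
      if (step_p[best] >= add_p) {
        dropped <- dplyr::bind_rows(dropped, tibble::tibble(
          predictor = remaining,
          reason = sprintf("stepwise addition p = %.3g >= %.3g",
                           step_p[remaining], add_p)))
        break
      }
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
      current <- stats::update(current, stats::as.formula(paste(". ~ . +", best)))
    }
    if (length(selected) == 0) {
      stop("stepwise addition selected no predictors", call. = FALSE)
    }
  }

  fl <- fit_logistic(
    stats::as.formula(paste("y ~", paste(selected, collapse = " + "))), dd)
  rows <- or_rows_from_glm(fl$fit)
  rows$separation <- fl$separation
  structure(
    list(or_table = rows, retained = selected, dropped = dropped,
         tertiles = tert_specs, univariate_p = uni_p, fit = fl$fit),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Multivariate logistic model; retained predictors:",
      paste(x$retained, collapse = ", "), "\n")
  print(x$or_table)
  if (nrow(x$dropped) > 0) {
    cat("Dropped candidates:\n")
    print(x$dropped)
  }
  invisible(x)
}

#' ROC analysis with a Youden-index cut-off
#'
#' Builds the empirical ROC curve treating higher predictor values as
#' indicating a case. The AUC is the trapezoidal area over the full curve
#' (identical to the tie-corrected Mann-Whitney pair-counting statistic).
#' Candidate cut-offs are the midpoints between consecutive sorted unique
#' values; the reported cut-off maximises the Youden index
#' J = sensitivity + specificity - 1, ties broken by the lowest cut-off. A
#' record is called positive when its value exceeds the cut-off.
#'
#' @param data Data frame.
#' @param predictor Name of the numeric predictor column.
#' @param outcome Name of the 0/1 outcome column.
#' @return A `roc_result` object: list with `predictor`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `curve` (tibble of cutoff, fpr,
#'   tpr), `n_case`, `n_control`.
#' @export
roc_analysis <- function(data, predictor, outcome = "aneurysm") {
  y <- data[[outcome]]
  x <- data[[predictor]]
  keep <- !is.na(y) & !is.na(x)
  y <- as.integer(y[keep]); x <- x[keep]
  cases <- x[y == 1]
  controls <- x[y == 0]
  if (length(cases) == 0 || length(controls) == 0) {
    stop("ROC analysis needs both outcome classes non-empty", call. = FALSE)
  }
  v <- sort(unique(x))
  mids <- if (length(v) > 1) (v[-length(v)] + v[-1]) / 2 else numeric()
  thresholds <- c(-Inf, mids, Inf)
  tpr <- vapply(thresholds, function(t) mean(cases > t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(controls > t), numeric(1))
  # thresholds ascend, so fpr/tpr descend from (1,1) to (0,0)
  auc <- sum(-diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  j <- tpr - fpr # Youden J at each threshold
  cand <- seq_along(thresholds)[is.finite(thresholds)]
  if (length(cand) == 0) {
    stop("predictor has a single distinct value; no usable cut-off",
         call. = FALSE)
  }
  best <- cand[j[cand] == max(j[cand])][1] # ties -> lowest cut-off
  structure(
    list(predictor = predictor,
         auc = auc,
         cutoff = thresholds[best],
         sensitivity = tpr[best],
         specificity = 1 - fpr[best],
         youden = j[best],
         curve = tibble::tibble(cutoff = thresholds, fpr = fpr, tpr = tpr),
         n_case = length(cases), n_control = length(controls)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC for '%s': AUC = %.3f; Youden cut-off = %.4g (sens %.2f, spec %.2f)\n",
    x$predictor, x$auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Plot an empirical ROC curve
#'
#' @param roc A `roc_result` from [roc_analysis()].
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s (AUC = %.3f)", roc$predictor, roc$auc)
    ) +
    ggplot2::theme_minimal()
}
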