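# End-to-end analysis of a morphometry table and deterministic report files.

# Site families compared against each other, mirroring the per-artery layout
# of cohort tables (ICA, MCA and BA bifurcations analysed separately).
SITE_FAMILIES <- list(
  ICA = c("ICA_L", "ICA_R"),
  MCA = c("MCA_L", "MCA_R", "MCA_an"),
  BA = "BA"
)

COMPARED_PARAMETERS <- c(
  "alpha_deg", "phi1_obs_deg", "phi2_obs_deg",
  "r0_mm", "r1_mm", "r2_mm",
  "asymmetry_ratio", "area_ratio", "junction_exponent",
  "dev_total_deg", "dev_phi1_deg", "dev_phi2_deg"
)

#' Run the full case-control analysis on a morphometry table
#'
#' For each artery family (ICA, MCA, BA) every morphometric parameter is
#' compared across the (group, site) cells present, using the normality-gated
#' omnibus test of [compare_groups()]. Aneurysm presence is then modelled:
#' univariate logistic fits for all parameters (continuous, plus
#' tertile-coded angles), the two pre-specified multivariate templates
#' (model A: branch-angle tertiles + parent/larger-branch radii; model B:
#' total-angle tertiles + radii), and ROC analyses with Youden cut-offs for
#' the angle and parent-radius predictors.
#'
#' @param morph Morphometry tibble (see [compute_morphometry()]).
#' @param entry_p,correlation_exclusion_r Passed to
#'   [multivariate_logistic()].
#' @param meta Optional named list recorded in reports (e.g. seed, config).
#' @return A `cohort_analysis` object.
#' @export
analyze_cohort <- function(morph, entry_p = 0.1,
                           correlation_exclusion_r = 0.7, meta = list()) {
  if (nrow(morph) == 0) stop("empty morphometry table", call. = FALSE)
  morph$cell <- paste(morph$group, morph$site, sep = "/")

  comparisons <- list()
  skipped <- tibble::tibble(family = character(), parameter = character(),
                            reason = character())
  for (fam in names(SITE_FAMILIES)) {
    sub <- morph[morph$site %in% SITE_FAMILIES[[fam]], ]
    if (nrow(sub) == 0 || length(unique(sub$cell)) < 2) next
    fam_res <- list()
    for (par in intersect(COMPARED_PARAMETERS, names(sub))) {
      res <- tryCatch(compare_groups(sub, par, grouping = "cell"),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped <- dplyr::bind_rows(skipped, tibble::tibble(
          family = fam, parameter = par, reason = res))
      } else {
        fam_res[[par]] <- res
      }
    }
    comparisons[[fam]] <- fam_res
  }

  uni_specs <- c(
    r0_mm = "continuous", r1_mm = "continuous", r2_mm = "continuous",
    area_ratio = "continuous", asymmetry_ratio = "continuous",
    junction_exponent = "continuous",
    alpha_deg = "continuous", phi1_obs_deg = "continuous",
    phi2_obs_deg = "continuous"
  )
  uni <- list()
  for (p in names(uni_specs)) {
    uni[[p]] <- tryCatch(
      univariate_logistic(morph, p, coding = uni_specs[[p]]),
      error = function(e) NULL)
  }
  for (p in c("alpha_deg", "phi1_obs_deg", "phi2_obs_deg")) {
    uni[[paste0(p, "_tertile")]] <- tryCatch(
      univariate_logistic(morph, p, coding = "tertile"),
      error = function(e) NULL)
  }
  uni <- Filter(Negate(is.null), uni)

  model_a <- tryCatch(multivariate_logistic(
    morph,
    c(phi1_obs_deg = "tertile", phi2_obs_deg = "tertile",
      r0_mm = "continuous", r1_mm = "continuous"),
    entry_p = entry_p, correlation_exclusion_r = correlation_exclusion_r),
    error = function(e) conditionMessage(e))
  model_b <- tryCatch(multivariate_logistic(
    morph,
    c(alpha_deg = "tertile", r0_mm = "continuous", r1_mm = "continuous"),
    entry_p = entry_p, correlation_exclusion_r = correlation_exclusion_r),
    error = function(e) conditionMessage(e))

  roc <- list()
  for (p in c("alpha_deg", "phi1_obs_deg", "phi2_obs_deg", "r0_mm")) {
    roc[[p]] <- tryCatch(roc_analysis(morph, p), error = function(e) NULL)
  }
  roc <- Filter(Negate(is.null), roc)

  structure(
    list(comparisons = comparisons, skipped = skipped,
         univariate = uni, model_a = model_a, model_b = model_b,
         roc = roc,
         n_records = nrow(morph),
         n_undefined_angles = sum(morph$domain_status %in%
                                    c("angles_undefined", "both_undefined")),
         n_undefined_exponent = sum(morph$domain_status %in%
                                      c("exponent_undefined", "both_undefined")),
         entry_p = entry_p,
         correlation_exclusion_r = correlation_exclusion_r,
         meta = meta),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("Cohort analysis of %d records (%d with undefined optimal angles, %d with undefined junction exponent)\n",
              x$n_records, x$n_undefined_angles, x$n_undefined_exponent))
  for (fam in names(x$comparisons)) {
    cat(sprintf("-- %s bifurcations: %d parameters compared\n",
                fam, length(x$comparisons[[fam]])))
  }
  cat(sprintf("-- %d univariate logistic fits; ROC for: %s\n",
              length(x$univariate), paste(names(x$roc), collapse = ", ")))
  invisible(x)
}

comparison_table <- function(fam_res) {
  rows <- lapply(names(fam_res), function(par) {
    gc <- fam_res[[par]]
    s <- gc$summary
    s$parameter <- par
    s$test_used <- gc$test_used
    s$omnibus_p <- gc$omnibus_p
    s
  })
  out <- dplyr::bind_rows(rows)
  out[, c("parameter", "group", "n", "n_undefined", "mean", "sd",
          "shapiro_p", "test_used", "omnibus_p")]
}

or_table_of <- function(fits) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tb <- f$or_table
    tb$predictor <- nm
    tb$model_p <- f$model_p
    tb
  })
  out <- dplyr::bind_rows(rows)
  out[, c("predictor", "term", "or", "ci_low", "ci_high", "p", "separation",
          "model_p")]
}

roc_table_of <- function(rocs) {
  dplyr::bind_rows(lapply(rocs, function(r) tibble::tibble(
    predictor = r$predictor, auc = r$auc, cutoff = r$cutoff,
    sensitivity = r$sensitivity, specificity = r$specificity,
    n_case = r$n_case, n_control = r$n_control)))
}

#' Write a deterministic report file set
#'
#' Writes per-artery group-comparison tables (CSV and formatted text), the
#' univariate and multivariate odds-ratio tables, a ROC summary CSV and a
#' JSON run manifest (meta + configuration hash + package version). Identical
#' inputs produce byte-identical files; no timestamps are embedded.
#'
#' @param results A `cohort_analysis` object.
#' @param outdir Output directory, created if needed; must be writable (this
#'   is checked before anything is computed or written).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(results, outdir) {
  stopifnot(inherits(results, "cohort_analysis"))
  if (length(results$comparisons) == 0 && length(results$univariate) == 0 &&
      length(results$roc) == 0) {
    stop("empty results: nothing to report", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  files <- character()
  for (fam in names(results$comparisons)) {
    if (length(results$comparisons[[fam]]) == 0) next
    tb <- comparison_table(results$comparisons[[fam]])
    f_csv <- file.path(outdir, sprintf("group_comparison_%s.csv", fam))
    readr::write_csv(tb, f_csv, na = "")
    f_txt <- file.path(outdir, sprintf("group_comparison_%s.txt", fam))
    con <- file(f_txt, "w")
    for (par in names(results$comparisons[[fam]])) {
      gc <- results$comparisons[[fam]][[par]]
      writeLines(sprintf("%s [%s] omnibus p = %.4g", par, gc$test_used,
                         gc$omnibus_p), con)
      writeLines(sprintf("  %-24s n=%3d (undef %d)  %8.3f +/- %.3f",
                         gc$summary$group, gc$summary$n,
                         gc$summary$n_undefined, gc$summary$mean,
                         gc$summary$sd), con)
      if (!is.null(gc$posthoc)) {
        writeLines(sprintf("  post-hoc %-40s p = %.4g",
                           gc$posthoc$group_pair, gc$posthoc$p), con)
      }
      writeLines("", con)
    }
    close(con)
    files <- c(files, f_csv, f_txt)
  }
  if (length(results$univariate) > 0) {
    f <- file.path(outdir, "univariate_or.csv")
    readr::write_csv(or_table_of(results$univariate), f, na = "")
    files <- c(files, f)
  }
  for (mdl in c("model_a", "model_b")) {
    m <- results[[mdl]]
    if (inherits(m, "logistic_model")) {
      f <- file.path(outdir, paste0(mdl, "_or.csv"))
      readr::write_csv(m$or_table, f, na = "")
      files <- c(files, f)
    }
  }
  if (length(results$roc) > 0) {
    f <- file.path(outdir, "roc_summary.csv")
    readr::write_csv(roc_table_of(results$roc), f, na = "")
    files <- c(files, f)
  }
  manifest <- list(
    package = "pmwmorph",
    version = as.character(utils::packageVersion("pmwmorph")),
    meta = results$meta,
    entry_p = results$entry_p,
    correlation_exclusion_r = results$correlation_exclusion_r,
    n_records = results$n_records,
    n_undefined_angles = results$n_undefined_angles,
    n_undefined_exponent = results$n_undefined_exponent,
    meta_hash = config_hash(results$meta)
  )
  f_man <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, f_man)
  invisible(files)
}

# Stable md5 of an R object via its canonical JSON rendering.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline: simulate, measure, analyse, report
#'
#' @param cfg A `sim_config`.
#' @param outdir Report directory.
#' @param entry_p,correlation_exclusion_r Passed to [analyze_cohort()].
#' @return The `cohort_analysis`, invisibly; report files are written to
#'   `outdir` along with the simulated morphometry table and a ground-truth
#'   sidecar JSON.
#' @export
run_full_pipeline <- function(cfg, outdir, entry_p = 0.1,
                              correlation_exclusion_r = 0.7) {
  cohort <- generate_cohort(cfg)
  morph <- cohort$records
  if (cfg$output == "landmarks") {
    lm_df <- cohort$landmarks
    lm_df$branch_swapped <- FALSE
    morph <- measure_landmarks(lm_df)
  }
  res <- analyze_cohort(morph, entry_p = entry_p,
                        correlation_exclusion_r = correlation_exclusion_r,
                        meta = list(seed = cfg$seed,
                                    alpha_shift = cfg$alpha_shift,
                                    r0_shift = cfg$r0_shift))
  write_report(res, outdir)
  write_morphometry_csv(morph, file.path(outdir, "morphometry.csv"))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
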