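# CSV / YAML interchange. Undefined numeric values are serialised as empty
# fields, never sentinel numbers; every rejected or flagged row produces one
# structured diagnostic line.

LANDMARK_COLS <- c(
  "subject_id", "site", "group", "aneurysm",
  "Ax", "Ay", "Az", "Bx", "By", "Bz", "Cx", "Cy", "Cz", "Ox", "Oy", "Oz",
  "d0_mm", "d1_mm", "d2_mm"
)

#' Read a landmark CSV
#'
#' Expected columns: `subject_id, site, group, aneurysm, Ax..Oz, d0_mm,
#' d1_mm, d2_mm` (header required, one row per bifurcation). Every row is
#' validated: coordinates must be finite, diameters positive, and the points
#' A, B, C distinct from O. Rows failing validation are dropped with one
#' diagnostic message each (row number + reason); a row with `d1_mm < d2_mm`
#' is loaded with B/C and d1/d2 swapped and `branch_swapped = TRUE`.
#'
#' @param path Path to the CSV file.
#' @return Tibble of validated landmark rows with a `branch_swapped` column;
#'   the attribute `rejected` holds a tibble (row, reason) of dropped rows.
#' @export
read_landmark_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) stop("empty landmark file: ", path, call. = FALSE)
  missing_cols <- setdiff(LANDMARK_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("landmark CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(LANDMARK_COLS, c("subject_id", "site", "group"))
  rejected <- tibble::tibble(row = integer(), reason = character())
  keep <- rep(TRUE, nrow(df))
  swapped <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    reason <- NULL
    vals <- suppressWarnings(vapply(num_cols, function(cn) {
      as.numeric(df[[cn]][i])
    }, numeric(1)))
    if (any(!is.finite(vals))) {
      reason <- paste("non-numeric or missing value in",
                      paste(num_cols[!is.finite(vals)], collapse = ", "))
    } else if (any(vals[c("d0_mm", "d1_mm", "d2_mm")] <= 0)) {
      reason <- "nonpositive diameter"
    } else {
      O <- vals[c("Ox", "Oy", "Oz")]
      for (pt in c("A", "B", "C")) {
        if (all(vals[paste0(pt, c("x", "y", "z"))] == O)) {
          reason <- sprintf("point %s coincides with O", pt)
          break
        }
      }
    }
    if (!is.null(reason)) {
      message(sprintf("row %d rejected: %s", i, reason))
      rejected <- dplyr::bind_rows(rejected,
                                   tibble::tibble(row = i, reason = reason))
      keep[i] <- FALSE
      next
    }
    if (vals["d1_mm"] < vals["d2_mm"]) {
      message(sprintf(
        "row %d: d1 < d2; branches relabelled so the larger branch is B", i))
      for (co in c("x", "y", "z")) {
        tmp <- df[[paste0("B", co)]][i]
        df[[paste0("B", co)]][i] <- df[[paste0("C", co)]][i]
        df[[paste0("C", co)]][i] <- tmp
      }
      tmp <- df$d1_mm[i]; df$d1_mm[i] <- df$d2_mm[i]; df$d2_mm[i] <- tmp
      swapped[i] <- TRUE
    }
  }
  out <- df[keep, LANDMARK_COLS]
  out$branch_swapped <- swapped[keep]
  if (nrow(out) == 0) {
    stop("no valid rows in landmark file: ", path, call. = FALSE)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Write / read a morphometry table
#'
#' The morphometry CSV round-trips all numeric values at full precision;
#' undefined values are written as empty fields.
#'
#' @param df Morphometry tibble (see [compute_morphometry()]).
#' @param path Output path.
#' @return `path`, invisibly (writer); tibble (reader).
#' @export
write_morphometry_csv <- function(df, path) {
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' @rdname write_morphometry_csv
#' @export
read_morphometry_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  missing_cols <- setdiff(MORPHOMETRY_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("morphometry CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors the arguments of [cohort_config()]; a `blocks` list (one
#' mapping per group/site block) overrides the default calibration.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file's `seed` entry.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  blocks <- if (!is.null(y$blocks)) {
    bl <- lapply(y$blocks, function(b) {
      # YAML 1.1 reads a bare key `n` as boolean FALSE; map it back
      names(b)[names(b) == "FALSE"] <- "n"
      tibble::as_tibble(b)
    })
    dplyr::bind_rows(bl)
  } else {
    default_cohort_blocks()
  }
  cohort_config(
    seed = seed %||% y$seed,
    blocks = blocks,
    rho = y$rho %||% 0.5,
    alpha_shift = y$alpha_shift %||% 0,
    r0_shift = y$r0_shift %||% 0,
    radius_trunc = unlist(y$radius_trunc) %||% c(0.05, Inf),
    angle_trunc = unlist(y$angle_trunc) %||% c(1, 179),
    output = y$output %||% "morphometry",
    pmw_coupled = y$pmw_coupled %||% FALSE,
    angle_noise_sd = y$angle_noise_sd %||% 10,
    max_attempts = y$max_attempts %||% 1000
  )
}
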