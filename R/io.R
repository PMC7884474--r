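# CSV readers/writers, the analysis pipeline, and the JSON report.
#
# CSV dialects (all UTF-8, header row required):
#   vulnerability observations: sample_id, psi_mpa, lc
#   injection series:           sample_id, step_index, pressure_mpa,
#                               time_s, reference_time_s
#   conductivity measurements:  sample_id, length_m, area_m2, mass_kg,
#                               time_s, pressure_mpa
#   validation groups:          group, sample_id, variable (psi|lc), value

REPORT_SCHEMA_VERSION <- "1.0"

read_checked_csv <- function(path, required) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra))
    message("ignoring extra column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  df
}

# Data line number of row i (header is line 1).
row_line <- function(i) i + 1L

validate_rows <- function(df, col, path, check, what) {
  bad <- which(!check(df[[col]]))
  if (length(bad))
    stop("file ", path, ", line ", row_line(bad[1L]), ": column `", col,
         "` ", what, call. = FALSE)
  invisible(df)
}

#' Read a vulnerability-observation CSV
#'
#' Reads columns `sample_id`, `psi_mpa` (positive tension magnitude, MPa)
#' and `lc` (fraction in `[0, 1]`).  Extra columns are ignored with a
#' message; invalid rows raise an error naming the offending line.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return Data frame with columns `sample_id`, `psi`, `lc`, ready for
#'   [fit_weibull()].
#' @export
read_vc_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "psi_mpa", "lc"))
  num <- function(x) is.numeric(x) & is.finite(x)
  validate_rows(df, "psi_mpa", path,
                function(x) num(x) & x >= 0,
                "must be numeric >= 0 (tension magnitude)")
  validate_rows(df, "lc", path,
                function(x) num(x) & x >= 0 & x <= 1,
                "must be a fraction in [0, 1]")
  data.frame(sample_id = as.character(df$sample_id), psi = df$psi_mpa,
             lc = df$lc, stringsAsFactors = FALSE)
}

#' Write vulnerability observations to CSV
#'
#' Inverse of [read_vc_csv()]; writes columns `sample_id`, `psi_mpa`, `lc`.
#'
#' @param observations Data frame with columns `sample_id`, `psi`, `lc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vc_csv <- function(observations, path) {
  check_observations(observations, min_obs = 1L)
  out <- data.frame(
    sample_id = if (is.null(observations$sample_id)) "S01"
                else observations$sample_id,
    psi_mpa = observations$psi, lc = observations$lc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an air-injection series CSV
#'
#' Columns: `sample_id`, `step_index`, `pressure_mpa`, `time_s`,
#' `reference_time_s` (the flushed-maximum conductance time, repeated on
#' every row of a sample).  Steps with conductance time below the
#' reference are accepted (they flag as supra-maximal downstream).
#'
#' @inheritParams read_vc_csv
#' @return Named list of `injection_series` objects, one per sample.
#' @export
read_injection_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "step_index", "pressure_mpa",
                                 "time_s", "reference_time_s"))
  num <- function(x) is.numeric(x) & is.finite(x)
  validate_rows(df, "time_s", path, function(x) num(x) & x > 0,
                "must be numeric > 0")
  validate_rows(df, "reference_time_s", path, function(x) num(x) & x > 0,
                "must be numeric > 0")
  validate_rows(df, "pressure_mpa", path, function(x) num(x) & x >= 0,
                "must be numeric >= 0")
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$step_index), , drop = FALSE]
    ref <- unique(d$reference_time_s)
    if (length(ref) != 1L)
      stop("sample ", d$sample_id[1L], " in ", path,
           " has conflicting reference_time_s values", call. = FALSE)
    structure(
      list(sample_id = as.character(d$sample_id[1L]),
           reference_time_s = ref,
           steps = data.frame(step_index = d$step_index,
                              pressure_mpa = d$pressure_mpa,
                              time_s = d$time_s)),
      class = "injection_series")
  })
}

#' Read a conductivity-measurement CSV
#'
#' Columns: `sample_id`, `length_m`, `area_m2`, `mass_kg`, `time_s`,
#' `pressure_mpa`.  Returns the table with a computed `k_s` column
#' (stem-specific conductivity, kg m^-1 s^-1 MPa^-1).
#'
#' @inheritParams read_vc_csv
#' @return Data frame with the input columns plus `k_s`.
#' @export
read_conductivity_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "length_m", "area_m2",
                                 "mass_kg", "time_s", "pressure_mpa"))
  df$k_s <- specific_conductivity(df$length_m, df$area_m2, df$mass_kg,
                                  df$time_s, df$pressure_mpa)
  df
}

#' Read a validation-groups CSV
#'
#' Columns: `group`, `sample_id`, `variable` (`"psi"` or `"lc"`),
#' `value`.
#'
#' @inheritParams read_vc_csv
#' @return Data frame with those four columns.
#' @export
read_groups_csv <- function(path) {
  df <- read_checked_csv(path, c("group", "sample_id", "variable", "value"))
  validate_rows(df, "variable", path, function(x) x %in% c("psi", "lc"),
                "must be 'psi' or 'lc'")
  validate_rows(df, "value", path,
                function(x) is.numeric(x) & is.finite(x),
                "must be numeric and finite")
  df
}

keypoints_to_list <- function(kp) {
  out <- list(psi_m = kp$psi_m, psi_l = kp$psi_l,
              lc_m = kp$lc_m, lc_l = kp$lc_l)
  if (!is.na(kp$psi_e)) {
    out$psi_e <- kp$psi_e
    out$lc_e <- kp$lc_e
  }
  out
}

#' Run the full vulnerability-curve analysis pipeline
#'
#' Reads observations, fits the Weibull curve, computes differential- and
#' traditional-method key points, optionally bootstraps parameter
#' confidence intervals, classifies query tensions into the four curve
#' periods, and (when a groups file is supplied) runs the validation
#' statistics: a method-comparison report over groups named `air_entry`,
#' `fastest_drop` and `lethal`, and a bracketing test of the lethal point
#' when groups `lethal_lower` and `lethal_upper` are present.
#'
#' @param vc_path Path to a vulnerability-observation CSV (see
#'   [read_vc_csv()]).
#' @param groups_path Optional path to a validation-groups CSV; only rows
#'   with `variable == "psi"` are used.
#' @param method `"both"` (default), `"dm"` or `"tm"`: which key-point
#'   blocks to include in the report.
#' @param alpha Significance level for the validation tests.
#' @param seed Optional integer seed; required when `n_boot > 0`.
#' @param n_boot Bootstrap resamples for parameter CIs; 0 (default) skips
#'   the bootstrap.
#' @param classify_psi Optional tensions (MPa) to classify into curve
#'   periods (requires the differential method and shape `b > 2`).
#' @return Object of class `hvc_report`: a nested list with blocks
#'   `schema_version`, `generated` (timestamp), `provenance` (paths, MD5
#'   hashes, seed, package version), `fit`, `dm`, `tm`, `periods`,
#'   `stats`.  Serialise with [write_report()].
#' @export
run_pipeline <- function(vc_path, groups_path = NULL,
                         method = c("both", "dm", "tm"), alpha = 0.05,
                         seed = NULL, n_boot = 0L, classify_psi = NULL) {
  method <- match.arg(method)
  observations <- read_vc_csv(vc_path)
  fit <- if (n_boot > 0L) {
    if (is.null(seed))
      stop("`seed` is required when n_boot > 0", call. = FALSE)
    bootstrap_ci(observations, n_boot = n_boot, seed = seed)
  } else {
    fit_weibull(observations)
  }
  report <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    provenance = list(
      vc_path = vc_path,
      vc_md5 = unname(tools::md5sum(vc_path)),
      groups_path = groups_path,
      groups_md5 = if (!is.null(groups_path))
        unname(tools::md5sum(groups_path)),
      seed = seed,
      alpha = alpha,
      package_version = as.character(utils::packageVersion("hvcdm"))),
    fit = list(a = fit$params$a, b = fit$params$b,
               r_squared = fit$r_squared, n_obs = fit$n_obs,
               ci_a = fit$ci_a, ci_b = fit$ci_b))
  dm <- if (method != "tm") dm_key_points(fit$params)
  tm <- if (method != "dm") tm_points(fit$params)
  if (!is.null(dm)) report$dm <- keypoints_to_list(dm)
  if (!is.null(tm))
    report$tm <- list(psi_12 = tm$psi_12, psi_50 = tm$psi_50,
                      psi_88 = tm$psi_88)
  if (!is.null(classify_psi) && !is.null(dm))
    report$periods <- data.frame(
      psi = classify_psi,
      period = as.character(classify_period(dm, classify_psi)))
  if (!is.null(groups_path)) {
    gdf <- read_groups_csv(groups_path)
    gdf <- gdf[gdf$variable == "psi", , drop = FALSE]
    groups <- split(gdf$value, gdf$group)
    stats_block <- list()
    if (!is.null(dm) && !is.null(tm)) {
      cmp_names <- intersect(names(groups),
                             c("air_entry", "fastest_drop", "lethal"))
      if (length(cmp_names))
        stats_block$method_comparison <-
          method_comparison_report(groups[cmp_names], dm, tm, alpha = alpha)
    }
    if (!is.null(dm) &&
        all(c("lethal_lower", "lethal_upper") %in% names(groups))) {
      br <- bracket_test(groups$lethal_lower, groups$lethal_upper,
                         dm$psi_l, alpha = alpha)
      stats_block$lethal_bracket <- list(
        point = br$point, bracketed = br$bracketed,
        p_lower = br$lower_test$p_value, p_upper = br$upper_test$p_value)
    }
    report$stats <- stats_block
  }
  structure(report, class = "hvc_report")
}

#' @export
print.hvc_report <- function(x, ...) {
  cat("HVC analysis report (schema ", x$schema_version, ")\n", sep = "")
  cat(sprintf("  fit: a = %.2f MPa, b = %.2f, R^2 = %.4f (n = %d)\n",
              x$fit$a, x$fit$b, x$fit$r_squared, x$fit$n_obs))
  if (!is.null(x$dm))
    cat(sprintf("  DM:  psi_e = %s, psi_m = %.2f, psi_l = %.2f MPa\n",
                if (is.null(x$dm$psi_e)) "absent"
                else sprintf("%.2f", x$dm$psi_e),
                x$dm$psi_m, x$dm$psi_l))
  if (!is.null(x$tm))
    cat(sprintf("  TM:  psi_12 = %.2f, psi_50 = %.2f, psi_88 = %.2f MPa\n",
                x$tm$psi_12, x$tm$psi_50, x$tm$psi_88))
  if (!is.null(x$stats$lethal_bracket))
    cat(sprintf("  lethal point bracketed: %s\n",
                x$stats$lethal_bracket$bracketed))
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Numbers are written at full precision; the human-facing 2-decimal
#' rounding happens only in `print()` methods.
#'
#' @param report An `hvc_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "hvc_report"))
    stop("`report` must come from run_pipeline()", call. = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}

#' Read an analysis report back from JSON
#'
#' Rejects reports written under a different major schema version.
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return An `hvc_report` object.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  major <- function(v) strsplit(as.character(v), ".", fixed = TRUE)[[1L]][1L]
  if (is.null(rep$schema_version) ||
      major(rep$schema_version) != major(REPORT_SCHEMA_VERSION))
    stop("unsupported report schema version: ",
         rep$schema_version %||% "<missing>", call. = FALSE)
  structure(rep, class = "hvc_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
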