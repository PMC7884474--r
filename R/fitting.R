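# Estimation of Weibull HVC parameters from vulnerability observations.

# Validate a table of vulnerability observations: columns psi (MPa tension)
# and lc (fraction), optional sample_id.
check_observations <- function(observations, min_obs = 3L) {
  if (!is.data.frame(observations))
    stop("`observations` must be a data frame", call. = FALSE)
  need <- c("psi", "lc")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("`observations` is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  psi <- observations$psi
  lc <- observations$lc
  if (!is.numeric(psi) || anyNA(psi) || any(psi < 0))
    stop("`psi` must be numeric, non-missing and >= 0 (MPa tension)",
         call. = FALSE)
  if (!is.numeric(lc) || anyNA(lc) || any(lc < 0) || any(lc > 1))
    stop("`lc` must be a fraction in [0, 1]", call. = FALSE)
  if (nrow(observations) < min_obs)
    stop("need at least ", min_obs, " observations", call. = FALSE)
  invisible(observations)
}

#' Starting values for the Weibull fit by linearisation
#'
#' On noiseless data the Weibull CDF linearises exactly:
#' `log(-log(1 - lc))` is linear in `log(psi)` with slope `b` and intercept
#' `-b log(a)`.  Ordinary least squares on that transform gives starting
#' values for the nonlinear fit.  Observations with `lc` equal to 0 or 1,
#' or `psi == 0`, are singular under the transform and are excluded here
#' (they remain part of the nonlinear objective).
#'
#' @param observations Data frame with numeric columns `psi` (MPa tension,
#'   `>= 0`) and `lc` (fraction in `[0, 1]`).
#' @return A [weibull_params()] object.
#' @export
initial_guess <- function(observations) {
  check_observations(observations, min_obs = 2L)
  usable <- observations$psi > 0 & observations$lc > 0 & observations$lc < 1
  obs <- observations[usable, , drop = FALSE]
  if (nrow(obs) < 2L)
    stop("need at least 2 observations with psi > 0 and 0 < lc < 1 for ",
         "the linearised guess", call. = FALSE)
  x <- log(obs$psi)
  if (length(unique(x)) < 2L)
    stop("degenerate observations: all usable psi values identical",
         call. = FALSE)
  y <- log(-log1p(-obs$lc))
  co <- stats::coef(stats::lm.fit(cbind(1, x), y))
  b <- unname(co[2L])
  if (!is.finite(b) || b <= 0)
    stop("linearised guess failed: loss of conductivity does not increase ",
         "with tension", call. = FALSE)
  weibull_params(a = exp(-unname(co[1L]) / b), b = b)
}

#' Fit the Weibull vulnerability curve
#'
#' Estimates the scale and shape of the Weibull HVC by unweighted nonlinear
#' least squares on the loss-of-conductivity fraction, started from
#' [initial_guess()].  Fitting is performed with the Levenberg--Marquardt
#' algorithm ([minpack.lm::nlsLM()]) under positivity bounds on both
#' parameters; the result is deterministic given the data and options.
#'
#' By default all observations are pooled into a single fit.  With
#' `by_sample = TRUE` each `sample_id` is fitted separately and the
#' per-sample parameter estimates are summarised by their mean and standard
#' error.
#'
#' @inheritParams initial_guess
#' @param start Optional [weibull_params()] starting values; default
#'   [initial_guess()].
#' @param max_iter Maximum optimiser iterations.
#' @param tol Relative convergence tolerance on the objective and
#'   parameters.
#' @param by_sample Fit each `sample_id` separately instead of pooling.
#' @return For a pooled fit, an object of class `hvc_fit`: a list with
#'   `params` ([weibull_params()]), `r_squared` (computed as
#'   `1 - SS_res/SS_tot` on `lc`), `residuals` (observed minus fitted),
#'   `n_obs`, and `NULL` placeholders `ci_a`, `ci_b`, `seed` filled by
#'   [bootstrap_ci()].  For `by_sample = TRUE`, a list of class
#'   `hvc_fit_grouped` with per-sample fits and a `summary` data frame
#'   (mean and SE of each parameter).
#' @examples
#' obs <- generate_vc_observations(weibull_params(2.23, 2.5),
#'                                 n_samples = 1, noise_sd = 0)
#' fit_weibull(obs)
#' @export
fit_weibull <- function(observations, start = NULL, max_iter = 200L,
                        tol = 1e-10, by_sample = FALSE) {
  check_observations(observations)
  if (isTRUE(by_sample)) {
    if (is.null(observations$sample_id))
      stop("`by_sample = TRUE` requires a sample_id column", call. = FALSE)
    fits <- lapply(split(observations, observations$sample_id),
                   fit_weibull, start = start, max_iter = max_iter,
                   tol = tol)
    ab <- vapply(fits, function(f) c(f$params$a, f$params$b), numeric(2))
    summ <- data.frame(
      parameter = c("a", "b"),
      mean = rowMeans(ab),
      se = apply(ab, 1L, stats::sd) / sqrt(ncol(ab)))
    return(structure(list(fits = fits, summary = summ),
                     class = "hvc_fit_grouped"))
  }
  if (all(observations$lc == 0))
    stop("curve degenerate: all observations have zero loss of conductivity",
         call. = FALSE)
  if (length(unique(observations$psi)) < 2L)
    stop("need at least 2 distinct psi values", call. = FALSE)
  start <- if (is.null(start)) initial_guess(observations)
           else as_weibull_params(start)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      lc ~ -expm1(-(psi / a)^b),
      data = observations[, c("psi", "lc")],
      start = list(a = start$a, b = start$b),
      lower = c(a = 1e-10, b = 1e-10),
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iter), ftol = tol, ptol = tol)),
    error = function(e)
      stop("Weibull fit did not converge from start (a = ",
           signif(start$a, 6), ", b = ", signif(start$b, 6), "): ",
           conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  params <- weibull_params(co[["a"]], co[["b"]])
  res <- observations$lc - weibull_lc(params, observations$psi)
  ss_tot <- sum((observations$lc - mean(observations$lc))^2)
  structure(
    list(params = params,
         r_squared = 1 - sum(res^2) / ss_tot,
         residuals = res,
         n_obs = nrow(observations),
         ci_a = NULL, ci_b = NULL, seed = NULL),
    class = "hvc_fit")
}

#' @export
print.hvc_fit <- function(x, ...) {
  cat(sprintf("Weibull HVC fit (n = %d): a = %.4g MPa, b = %.4g, R^2 = %.4f\n",
              x$n_obs, x$params$a, x$params$b, x$r_squared))
  if (!is.null(x$ci_a))
    cat(sprintf("  bootstrap %d%% CI: a in [%.4g, %.4g], b in [%.4g, %.4g]\n",
                round(100 * x$level), x$ci_a[1], x$ci_a[2],
                x$ci_b[1], x$ci_b[2]))
  invisible(x)
}

#' @export
print.hvc_fit_grouped <- function(x, ...) {
  cat(sprintf("Per-sample Weibull HVC fits (%d samples)\n", length(x$fits)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Bootstrap confidence intervals for the Weibull parameters
#'
#' Case-resampling bootstrap: observations are resampled with replacement
#' and refitted `n_boot` times; percentile intervals at the requested level
#' are attached to the full-data fit.  Case resampling is used (rather than
#' residual resampling) because the LC error model is unknown and
#' heteroscedastic near the 0 and 1 boundaries.  Resamples with fewer than
#' 3 usable points, fewer than 2 distinct tensions, or a failed refit are
#' redrawn; the redraw count is recorded.
#'
#' @inheritParams initial_guess
#' @param n_boot Number of bootstrap resamples, at least 100.
#' @param seed Integer seed; all randomness is reproducible from it.
#' @param level Confidence level, default 0.95.
#' @return The full-data `hvc_fit` with `ci_a`, `ci_b` (each
#'   `c(lower, upper)`), `level`, `seed`, `n_boot`, `n_redraws`, and the
#'   resampled parameter draws in `boot_params`.
#' @export
bootstrap_ci <- function(observations, n_boot = 1000L, seed = 1L,
                         level = 0.95) {
  if (n_boot < 100L)
    stop("`n_boot` must be at least 100", call. = FALSE)
  fit <- fit_weibull(observations)
  n <- nrow(observations)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 2L,
                  dimnames = list(NULL, c("a", "b")))
  redraws <- 0L
  attempts <- 0L
  max_attempts <- 50L * n_boot
  k <- 1L
  while (k <= n_boot) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("bootstrap exceeded ", max_attempts, " resampling attempts",
           call. = FALSE)
    idx <- sample.int(n, n, replace = TRUE)
    rs <- observations[idx, , drop = FALSE]
    usable <- sum(rs$psi > 0 & rs$lc > 0 & rs$lc < 1)
    if (usable < 3L || length(unique(rs$psi)) < 2L || all(rs$lc == 0)) {
      redraws <- redraws + 1L
      next
    }
    bf <- tryCatch(fit_weibull(rs), error = function(e) NULL)
    if (is.null(bf)) {
      redraws <- redraws + 1L
      next
    }
    draws[k, ] <- c(bf$params$a, bf$params$b)
    k <- k + 1L
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  fit$ci_a <- unname(stats::quantile(draws[, "a"], probs))
  fit$ci_b <- unname(stats::quantile(draws[, "b"], probs))
  fit$level <- level
  fit$seed <- as.integer(seed)
  fit$n_boot <- as.integer(n_boot)
  fit$n_redraws <- redraws
  fit$boot_params <- draws
  fit
}
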