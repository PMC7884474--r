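# Weibull model of the hydraulic vulnerability curve and its key points.
#
# Sign convention, stated once for the whole package: water potentials are
# stored as positive tension magnitudes in MPa (the absolute value of stem
# water potential).  Negative inputs are rejected, never silently negated.

#' Weibull vulnerability-curve parameters
#'
#' Constructs the parameter pair of the Weibull cumulative distribution
#' function used throughout this package to model a hydraulic vulnerability
#' curve (HVC),
#' \deqn{LC(\Psi) = 1 - \exp[-(\Psi/a)^b],}
#' where \eqn{LC} is the fractional loss of hydraulic conductivity and
#' \eqn{\Psi} is xylem water potential expressed as a positive tension
#' magnitude (MPa).
#'
#' @param a Scale parameter, MPa tension; must be strictly positive.
#' @param b Shape parameter, dimensionless; must be strictly positive.
#'   Interior key points additionally require `b > 1` (inflection and lethal
#'   points) and `b > 2` (air-entry point); see [dm_key_points()].
#' @return An object of class `weibull_params`: a list with elements `a`
#'   and `b`.
#' @examples
#' p <- weibull_params(a = 2.23, b = 2.50)
#' weibull_lc(p, c(0, 1, 2, 3))
#' @seealso [weibull_lc()], [dm_key_points()], [tm_points()]
#' @export
weibull_params <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("`a` must be a single finite number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("`b` must be a single finite number", call. = FALSE)
  if (a <= 0)
    stop("scale parameter `a` must be > 0 (MPa tension)", call. = FALSE)
  if (b <= 0)
    stop("shape parameter `b` must be > 0", call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull HVC parameters: a = %.4g MPa, b = %.4g\n", x$a, x$b))
  invisible(x)
}

# Accept a weibull_params object or a plain numeric c(a, b).
as_weibull_params <- function(params) {
  if (inherits(params, "weibull_params")) return(params)
  if (is.numeric(params) && length(params) == 2L)
    return(weibull_params(params[[1L]], params[[2L]]))
  stop("`params` must be a weibull_params object or numeric c(a, b)",
       call. = FALSE)
}

check_psi <- function(psi, positive = FALSE) {
  if (!is.numeric(psi) || anyNA(psi))
    stop("`psi` must be numeric with no missing values", call. = FALSE)
  if (positive) {
    if (any(psi <= 0))
      stop("`psi` must be > 0 MPa tension", call. = FALSE)
  } else if (any(psi < 0)) {
    stop("`psi` must be >= 0: water potentials are positive tension ",
         "magnitudes (MPa)", call. = FALSE)
  }
  invisible(psi)
}

#' Loss of conductivity predicted by the Weibull HVC
#'
#' Evaluates the Weibull cumulative distribution function
#' \eqn{LC = 1 - \exp[-(\Psi/a)^b]} at the given tensions.
#'
#' @param params A [weibull_params()] object (or numeric `c(a, b)`).
#' @param psi Numeric vector of water-potential tensions, MPa, `>= 0`.
#' @return Numeric vector of loss-of-conductivity fractions in `[0, 1)`.
#' @examples
#' weibull_lc(weibull_params(2.23, 2.50), c(0, 2.23))  # 0 and 1 - exp(-1)
#' @export
weibull_lc <- function(params, psi) {
  params <- as_weibull_params(params)
  check_psi(psi)
  -expm1(-(psi / params$a)^params$b)
}

#' First three derivatives of the Weibull HVC
#'
#' Analytic first, second and third derivatives of the Weibull CDF with
#' respect to tension.  The second derivative vanishes at the fastest-drop
#' (inflection) point; the third derivative vanishes at the air-entry and
#' lethal (turning) points.
#'
#' @inheritParams weibull_lc
#' @param psi Numeric vector of tensions, MPa, strictly positive (the
#'   closed forms contain \eqn{\Psi^{b-k}} terms singular at 0 for small
#'   `b`).
#' @return A list with numeric vectors `d1`, `d2`, `d3`, the same length
#'   as `psi`.
#' @examples
#' p <- weibull_params(2.23, 2.50)
#' kp <- dm_key_points(p)
#' weibull_derivatives(p, kp$psi_m)$d2  # ~0: inflection point
#' @export
weibull_derivatives <- function(params, psi) {
  params <- as_weibull_params(params)
  check_psi(psi, positive = TRUE)
  a <- params$a
  b <- params$b
  u <- (psi / a)^b
  e <- exp(-u)
  list(
    d1 = (b / a) * e * (psi / a)^(b - 1),
    d2 = (b / a^2) * e * (psi / a)^(b - 2) * ((b - 1) - b * u),
    # cubic-in-u factorisation of the third derivative
    d3 = (b / a^3) * e * (psi / a)^(b - 3) *
      (b^2 * u^2 - 3 * b * (b - 1) * u + (b - 1) * (b - 2))
  )
}

new_keypoints <- function(psi_e, psi_m, psi_l, params, method) {
  lc_at <- function(psi) if (is.na(psi)) NA_real_ else weibull_lc(params, psi)
  structure(
    list(psi_e = psi_e, psi_m = psi_m, psi_l = psi_l,
         lc_e = lc_at(psi_e), lc_m = lc_at(psi_m), lc_l = lc_at(psi_l),
         params = params, method = method),
    class = "hvc_keypoints")
}

#' Differential-method key points of the vulnerability curve
#'
#' Locates the three key points of the Weibull HVC by the differential
#' method (DM): the fastest-drop point \eqn{\Psi_m} is the root of the
#' second derivative (inflection), and the air-entry point \eqn{\Psi_e} and
#' lethal point \eqn{\Psi_l} are the lower and upper positive roots of the
#' third derivative.  In closed form, with \eqn{u = (\Psi/a)^b},
#' \deqn{\Psi_m = a\left(\frac{b-1}{b}\right)^{1/b}, \qquad
#'       \Psi_{e,l} = a\left(\frac{3(b-1) \mp \sqrt{(b-1)(5b-1)}}{2b}
#'       \right)^{1/b}.}
#'
#' The inflection and lethal points exist only for `b > 1`; the lower root
#' of the third derivative is positive only for `b > 2`, so for
#' `1 < b <= 2` the air-entry point is reported as `NA` (absent), never a
#' silent zero.
#'
#' @inheritParams weibull_lc
#' @return An object of class `hvc_keypoints`: a list with tensions
#'   `psi_e`, `psi_m`, `psi_l` (MPa; `psi_e` may be `NA`), the
#'   corresponding loss-of-conductivity fractions `lc_e`, `lc_m`, `lc_l`,
#'   and the generating `params`.
#' @examples
#' dm_key_points(weibull_params(2.23, 2.50))  # psi_l ~ 2.78 MPa, lc_l ~ 0.82
#' @seealso [numeric_key_points()] for the root-finding cross-check,
#'   [tm_points()] for the traditional quantile readings.
#' @export
dm_key_points <- function(params) {
  params <- as_weibull_params(params)
  a <- params$a
  b <- params$b
  if (b <= 1)
    stop("no interior inflection point: differential-method key points ",
         "require shape b > 1", call. = FALSE)
  u_m <- (b - 1) / b
  disc <- sqrt((b - 1) * (5 * b - 1))
  u_lo <- (3 * (b - 1) - disc) / (2 * b)
  u_hi <- (3 * (b - 1) + disc) / (2 * b)
  psi_e <- if (u_lo > 0) a * u_lo^(1 / b) else NA_real_
  new_keypoints(psi_e,
                a * u_m^(1 / b),
                a * u_hi^(1 / b),
                params, method = "closed-form")
}

#' Traditional-method quantile points
#'
#' The traditional method (TM) reads key points off the fitted curve as the
#' tensions producing 12, 50 and 88 percent loss of conductivity:
#' \eqn{\Psi_p = a(-\ln(1-p))^{1/b}}.
#'
#' @inheritParams weibull_lc
#' @return An object of class `hvc_tm_points`: a list with `psi_12`,
#'   `psi_50`, `psi_88` (MPa) and `params`.
#' @examples
#' tm_points(weibull_params(2.23, 2.50))
#' @export
tm_points <- function(params) {
  params <- as_weibull_params(params)
  structure(
    list(psi_12 = lc_quantile(params, 0.12),
         psi_50 = lc_quantile(params, 0.50),
         psi_88 = lc_quantile(params, 0.88),
         params = params),
    class = "hvc_tm_points")
}

#' Tension producing a given loss of conductivity
#'
#' Inverts the Weibull HVC: returns the tension at which the curve reaches
#' loss fraction `p`.  Generalises the traditional-method readings to any
#' quantile.
#'
#' @inheritParams weibull_lc
#' @param p Loss-of-conductivity fraction(s), strictly inside `(0, 1)`.
#' @return Tension(s) in MPa; satisfies
#'   `weibull_lc(params, lc_quantile(params, p)) == p` to numerical
#'   precision.
#' @export
lc_quantile <- function(params, p) {
  params <- as_weibull_params(params)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  params$a * (-log1p(-p))^(1 / params$b)
}

#' Key points by numeric root-finding
#'
#' Locates the same three key points as [dm_key_points()] but by bracketed
#' root-finding on the analytic second and third derivatives, with the
#' search interval `(0, 2 * lc_quantile(params, 0.9999)]` adapted to the
#' parameters.  Serves as an independent cross-check of the closed forms;
#' the two agree to well below 1e-8 MPa.
#'
#' @inheritParams weibull_lc
#' @param tol Absolute root-finding tolerance passed to [stats::uniroot()].
#' @return An `hvc_keypoints` object (see [dm_key_points()]).
#' @export
numeric_key_points <- function(params, tol = 1e-12) {
  params <- as_weibull_params(params)
  b <- params$b
  if (b <= 1)
    stop("no interior inflection point: key points require shape b > 1",
         call. = FALSE)
  psi_max <- 2 * lc_quantile(params, 0.9999)
  d2 <- function(psi) weibull_derivatives(params, psi)$d2
  d3 <- function(psi) weibull_derivatives(params, psi)$d3

  find_roots <- function(f, expected) {
    # log-spaced scan catches roots close to the origin
    grid <- psi_max * exp(seq(log(1e-7), 0, length.out = 4096L))
    fv <- f(grid)
    flips <- which(fv[-1L] * fv[-length(fv)] < 0)
    if (length(flips) != expected)
      stop("internal error: expected ", expected, " sign change(s) of the ",
           "derivative but found ", length(flips),
           " (signals a derivative bug)", call. = FALSE)
    vapply(flips, function(i)
      stats::uniroot(f, lower = grid[i], upper = grid[i + 1L],
                     tol = tol)$root, numeric(1))
  }

  psi_m <- find_roots(d2, 1L)
  n3 <- if (b > 2) 2L else 1L
  r3 <- find_roots(d3, n3)
  psi_e <- if (n3 == 2L) r3[[1L]] else NA_real_
  psi_l <- r3[[n3]]
  new_keypoints(psi_e, psi_m, psi_l, params, method = "root-finding")
}

#' @export
print.hvc_keypoints <- function(x, ...) {
  # human-readable output rounds to 2 decimals; the object keeps full precision
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.2f", v)
  cat("Differential-method key points (", x$method, ")\n", sep = "")
  cat(sprintf("  air-entry    psi_e = %s MPa   LC_e = %s\n",
              fmt(x$psi_e), fmt(x$lc_e)))
  cat(sprintf("  fastest drop psi_m = %s MPa   LC_m = %s\n",
              fmt(x$psi_m), fmt(x$lc_m)))
  cat(sprintf("  lethal       psi_l = %s MPa   LC_l = %s\n",
              fmt(x$psi_l), fmt(x$lc_l)))
  invisible(x)
}

#' @export
print.hvc_tm_points <- function(x, ...) {
  cat("Traditional-method points\n")
  cat(sprintf("  psi_12 = %.2f MPa  psi_50 = %.2f MPa  psi_88 = %.2f MPa\n",
              x$psi_12, x$psi_50, x$psi_88))
  invisible(x)
}

#' Classify tensions into the four periods of the vulnerability curve
#'
#' The key points partition the tension axis into four half-open periods:
#' stationary `[0, psi_e)`, accelerated decline `[psi_e, psi_m)`,
#' decelerated decline `[psi_m, psi_l)`, and platform `[psi_l, Inf)`.
#' A tension equal to a key point belongs to the higher period.
#'
#' @param keypoints An `hvc_keypoints` object with all three points present
#'   (air-entry requires shape `b > 2`).
#' @param psi Numeric vector of tensions, MPa, `>= 0`.
#' @return A factor with levels `stationary`, `accelerated_decline`,
#'   `decelerated_decline`, `platform`.
#' @examples
#' kp <- dm_key_points(weibull_params(2.23, 2.50))
#' classify_period(kp, c(0, 1, 2, 3.5))
#' @export
classify_period <- function(keypoints, psi) {
  if (!inherits(keypoints, "hvc_keypoints"))
    stop("`keypoints` must be an hvc_keypoints object", call. = FALSE)
  if (is.na(keypoints$psi_e))
    stop("four-period classification requires the air-entry point, which ",
         "exists only for shape b > 2", call. = FALSE)
  check_psi(psi)
  lv <- c("stationary", "accelerated_decline", "decelerated_decline",
          "platform")
  idx <- findInterval(psi, c(keypoints$psi_e, keypoints$psi_m,
                             keypoints$psi_l)) + 1L
  factor(lv[idx], levels = lv)
}
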