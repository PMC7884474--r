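# Shared fixtures and independent oracles.

paper_params <- function() weibull_params(a = 2.23, b = 2.50)

# Independent derivative oracles, never touching weibull_derivatives():
# repeated symbolic differentiation of the curve formula by stats::D(),
# evaluated at machine precision.
sym_derivatives <- local({
  f <- quote(1 - exp(-(psi / a)^b))
  d1e <- stats::D(f, "psi")
  d2e <- stats::D(d1e, "psi")
  d3e <- stats::D(d2e, "psi")
  function(params, psi) {
    env <- list(a = params$a, b = params$b, psi = psi)
    list(d1 = eval(d1e, env), d2 = eval(d2e, env), d3 = eval(d3e, env))
  }
})

# 4th-order central finite difference of weibull_lc for the first
# derivative (higher orders are round-off limited in double precision).
fd_first_derivative <- function(params, psi, h = 1e-4 * params$a) {
  f <- function(x) weibull_lc(params, x)
  (-f(psi + 2 * h) + 8 * f(psi + h) - 8 * f(psi - h) + f(psi - 2 * h)) /
    (12 * h)
}

# Numeric CDF inversion by bisection: oracle for lc_quantile/tm_points.
bisect_quantile <- function(params, p) {
  stats::uniroot(function(psi) weibull_lc(params, psi) - p,
                 lower = 1e-12, upper = 1e3, tol = 1e-13)$root
}

noiseless_obs <- function(params = paper_params(), n_samples = 1L) {
  generate_vc_observations(params, n_samples = n_samples, noise_sd = 0)
}
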