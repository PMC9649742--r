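#' Rupture-force probability density under a constant loading rate
#'
#' Evaluates the Evans-Ritchie (Bell-model) rupture-force density for a slip
#' bond loaded at a constant rate,
#' \deqn{p(F) = a_1 e^{a_2 F} \exp\{(a_1/a_2)(1 - e^{a_2 F})\},}
#' with \eqn{a_1 = k_{off}/\dot F} and \eqn{a_2 = \Delta X / k_B T}.
#' The density is computed in log space so it underflows gracefully (to 0)
#' rather than overflowing at large forces.
#'
#' @param force Rupture force in pN; vectorized, must be `>= 0`.
#' @param landscape An [energy_landscape()].
#' @param f_dot Loading rate in pN/s.
#' @param env A [flow_environment()].
#' @param log If `TRUE`, return the log density.
#'
#' @return Probability density in 1/pN (or its log), same length as `force`.
#' @examples
#' dig <- energy_landscape(k_off = 4.0e-4, delta_x = 0.76)
#' rupture_density(seq(0, 50, by = 10), dig, f_dot = 0.5)
#' @export
rupture_density <- function(force, landscape, f_dot, env = flow_environment(),
                            log = FALSE) {
  env <- as_flow_environment(env)
  check_force_domain(force)
  rp <- reduced_params(landscape, f_dot, env)
  lp <- base::log(rp$a1) + rp$a2 * force - (rp$a1 / rp$a2) * expm1(rp$a2 * force)
  if (log) lp else exp(lp)
}

#' Cumulative rupture probability
#'
#' The probability that a bond loaded at a constant rate has ruptured by
#' force `F`. Two evaluations are provided:
#' \describe{
#'   \item{`exact`}{the closed-form integral of the rupture density,
#'     \eqn{P(F) = 1 - \exp\{(a_1/a_2)(1 - e^{a_2 F})\}}, a true CDF
#'     (0 at F = 0, increasing, tending to 1);}
#'   \item{`series`}{the truncated series expansion
#'     \eqn{[\sum_{n=1}^{N} a_1^n/(n!\,a_2^n)\, e^{n a_2 F}]
#'     \exp\{(a_1/a_2)(1 - e^{a_2 F})\}}, evaluated term-wise in log space.
#'     Its converged limit exceeds the exact form by the constant
#'     \eqn{e^{a_1/a_2} - 1}, which is negligible (< 0.5\%) in typical
#'     slip-bond regimes.}
#' }
#'
#' @inheritParams rupture_density
#' @param method `"exact"` (default) or `"series"`.
#' @param n_terms Number of series terms when `method = "series"`; default 50.
#'
#' @return Cumulative probability, same length as `force`.
#' @examples
#' dig <- energy_landscape(k_off = 4.0e-4, delta_x = 0.76)
#' rupture_cdf(c(10, 25, 40), dig, f_dot = 0.5)
#' @export
rupture_cdf <- function(force, landscape, f_dot, env = flow_environment(),
                        method = c("exact", "series"), n_terms = 50L) {
  env <- as_flow_environment(env)
  method <- match.arg(method)
  check_force_domain(force)
  rp <- reduced_params(landscape, f_dot, env)
  if (method == "exact") {
    return(-expm1(-(rp$a1 / rp$a2) * expm1(rp$a2 * force)))
  }
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 1L) {
    stop("`n_terms` must be at least 1", call. = FALSE)
  }
  n <- seq_len(n_terms)
  lead <- -(rp$a1 / rp$a2) * expm1(rp$a2 * force)
  out <- vapply(seq_along(force), function(i) {
    lt <- n * (base::log(rp$a1 / rp$a2) + rp$a2 * force[i]) - lfactorial(n)
    exp(logsumexp(lt) + lead[i])
  }, numeric(1))
  if (any(!is.finite(out))) {
    stop("series evaluation of the cumulative rupture probability overflowed; ",
         "use method = \"exact\"", call. = FALSE)
  }
  out
}

#' Most probable rupture force
#'
#' The mode of the rupture-force density at a given loading rate,
#' \deqn{F^* = \frac{k_B T}{\Delta X}\,
#'   \ln\frac{\dot F\, \Delta X}{N\, k_B T\, k_{off}},}
#' where `N` identical bonds loaded in series rupture `N`-fold faster and so
#' lower the most probable force by \eqn{(k_B T/\Delta X)\ln N}.
#'
#' When the logarithm's argument is at or below 1 the bond is effectively at
#' equilibrium at this loading rate and the formula leaves its domain of
#' validity; the (non-positive) value is still returned, carrying attribute
#' `flagged = TRUE`, with a warning.
#'
#' @inheritParams rupture_density
#' @param n_serial Number of identical serially connected bonds (default 1).
#'
#' @return Most probable rupture force in pN.
#' @examples
#' dig <- energy_landscape(k_off = 4.0e-4, delta_x = 0.76)
#' most_probable_force(dig, f_dot = 0.5)
#' @export
most_probable_force <- function(landscape, f_dot, env = flow_environment(),
                                n_serial = 1L) {
  env <- as_flow_environment(env)
  check_loading_rate(f_dot)
  stopifnot(is.numeric(n_serial), length(n_serial) == 1L, n_serial >= 1)
  kbt <- env$thermal_energy
  arg <- f_dot * landscape$delta_x / (n_serial * kbt * landscape$k_off)
  f_star <- kbt / landscape$delta_x * base::log(arg)
  if (arg <= 1) {
    warning("loading rate too low for this landscape: most probable force is ",
            "non-positive (near-equilibrium regime); value flagged",
            call. = FALSE)
    attr(f_star, "flagged") <- TRUE
  }
  f_star
}

#' Sample rupture forces by exact inverse-CDF sampling
#'
#' Draws rupture forces from the Evans-Ritchie density by inverting the exact
#' cumulative distribution:
#' \deqn{F = \frac{1}{a_2}\ln\Big[1 - \frac{a_2}{a_1}\ln(1 - u)\Big],
#'   \quad u \sim U[0, 1).}
#'
#' @inheritParams rupture_density
#' @param n Number of samples.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Numeric vector of `n` rupture forces in pN, all `>= 0`.
#' @examples
#' dig <- energy_landscape(k_off = 4.0e-4, delta_x = 0.76)
#' sample_rupture_forces(dig, f_dot = 0.5, n = 5, seed = 1)
#' @export
sample_rupture_forces <- function(landscape, f_dot, env = flow_environment(),
                                  n, seed = NULL) {
  env <- as_flow_environment(env)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  quantile_rupture(u, landscape, f_dot, env)
}

#' Quantile function of the rupture-force distribution
#'
#' @param p Probabilities in `[0, 1)`; vectorized.
#' @inheritParams rupture_density
#' @return Rupture forces in pN.
#' @export
quantile_rupture <- function(p, landscape, f_dot, env = flow_environment()) {
  env <- as_flow_environment(env)
  stopifnot(all(p >= 0 & p < 1))
  rp <- reduced_params(landscape, f_dot, env)
  log1p(-(rp$a2 / rp$a1) * log1p(-p)) / rp$a2
}

check_force_domain <- function(force) {
  if (!is.numeric(force) || any(!is.finite(force))) {
    stop("`force` must be finite numeric (pN)", call. = FALSE)
  }
  if (any(force < 0)) {
    stop("`force` must be non-negative: the rupture model is defined on F >= 0",
         call. = FALSE)
  }
  invisible(force)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + base::log(sum(exp(x - m)))
}
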