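#' Worm-like-chain parameters
#'
#' @param persistence_length_nm Persistence length P in nm (> 0).
#' @param contour_length_nm Contour length Lc in nm (> 0).
#' @return An object of class `wlc_params`.
#' @examples
#' wlc_params(56, 1800)
#' @export
wlc_params <- function(persistence_length_nm, contour_length_nm) {
  stopifnot(persistence_length_nm > 0, contour_length_nm > 0)
  structure(list(persistence_length_nm = persistence_length_nm,
                 contour_length_nm = contour_length_nm),
            class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("<wlc_params> P = %.3g nm, Lc = %.4g nm\n",
              x$persistence_length_nm, x$contour_length_nm))
  invisible(x)
}

#' Worm-like-chain force at a given extension
#'
#' The Marko-Siggia interpolation formula for the entropic elasticity of a
#' semiflexible polymer,
#' \deqn{F = \frac{k_B T}{P}\left[\frac{1}{4(1 - l/L_c)^2} - \frac14 +
#'   \frac{l}{L_c}\right],}
#' monotone increasing in `l` and divergent as `l` approaches the contour
#' length.
#'
#' @param extension_nm End-to-end extension l in nm; vectorized, must satisfy
#'   `0 <= l < Lc`.
#' @param wlc A [wlc_params()].
#' @param env A [flow_environment()].
#' @return Force in pN.
#' @examples
#' wlc_force(900, wlc_params(56, 1800))
#' @export
wlc_force <- function(extension_nm, wlc, env = flow_environment()) {
  env <- as_flow_environment(env)
  stopifnot(inherits(wlc, "wlc_params"))
  if (any(extension_nm < 0) || any(extension_nm >= wlc$contour_length_nm)) {
    stop("extension must satisfy 0 <= l < Lc", call. = FALSE)
  }
  x <- extension_nm / wlc$contour_length_nm
  env$thermal_energy / wlc$persistence_length_nm *
    (1 / (4 * (1 - x)^2) - 0.25 + x)
}

#' Worm-like-chain extension at a given force (numerical inverse)
#'
#' Inverts [wlc_force()] by bisection on the relative extension. The
#' interpolation formula is strictly increasing, so the inverse is unique.
#'
#' @param force_pn Force in pN; vectorized, >= 0.
#' @param wlc A [wlc_params()].
#' @param env A [flow_environment()].
#' @param tol Relative root tolerance (default 1e-12).
#' @return Extension in nm.
#' @export
wlc_extension <- function(force_pn, wlc, env = flow_environment(),
                          tol = 1e-12) {
  env <- as_flow_environment(env)
  stopifnot(inherits(wlc, "wlc_params"), all(force_pn >= 0))
  scale <- env$thermal_energy / wlc$persistence_length_nm
  vapply(force_pn, function(f) {
    if (f == 0) return(0)
    g <- function(x) scale * (1 / (4 * (1 - x)^2) - 0.25 + x) - f
    upper <- 1 - 1e-15
    if (g(upper) < 0) stop("force too high: extension would reach Lc",
                           call. = FALSE)
    stats::uniroot(g, c(0, upper), tol = tol)$root * wlc$contour_length_nm
  }, numeric(1))
}

#' Fit the worm-like-chain model to a force-extension curve
#'
#' Nonlinear least squares with residuals in extension (force is the
#' controlled variable in a flow-stretching assay; extension is the measured
#' one): observed `l` against the numerical inverse of the interpolation
#' force law. Parameters are bounded, with the contour length constrained to
#' exceed the largest observed extension.
#'
#' @param curve A data frame with columns `force_pn` and `extension_nm`
#'   (at least 4 points; a warning is issued when the forces span less than a
#'   5-fold range).
#' @param env A [flow_environment()].
#' @param init Optional [wlc_params()] starting values.
#'
#' @return An object of class `wlc_fit` with `$params` (a [wlc_params()]),
#'   `$vcov`, `$fit` (the underlying `nlsLM` object) and `$data`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' truth <- wlc_params(56, 1800)
#' curve <- simulate_force_extension(truth, forces_pn = c(0.1, 0.3, 1, 3),
#'                                   noise_sd_extension_nm = 0, seed = 1)
#' fit_wlc(curve)
#' @export
fit_wlc <- function(curve, env = flow_environment(), init = NULL) {
  env <- as_flow_environment(env)
  stopifnot(is.data.frame(curve),
            all(c("force_pn", "extension_nm") %in% names(curve)))
  if (nrow(curve) < 4L) {
    stop("worm-like-chain fitting needs at least 4 force-extension points",
         call. = FALSE)
  }
  if (any(curve$force_pn <= 0)) {
    stop("forces must be positive", call. = FALSE)
  }
  if (max(curve$force_pn) / min(curve$force_pn) < 5) {
    warning("force range spans less than 5-fold; persistence and contour ",
            "length may be poorly constrained", call. = FALSE)
  }
  lmax <- max(curve$extension_nm)
  lower <- c(P = 1, Lc = lmax * 1.001)
  upper <- c(P = 500, Lc = 10 * lmax)
  if (is.null(init)) {
    start <- c(P = 50, Lc = max(lmax * 1.05, lower[["Lc"]] * 1.01))
  } else {
    stopifnot(inherits(init, "wlc_params"))
    start <- c(P = init$persistence_length_nm, Lc = init$contour_length_nm)
  }
  start <- pmin(pmax(start, lower), upper)
  fit <- minpack.lm::nlsLM(
    extension_nm ~ wlc_extension(force_pn, wlc_params(P, Lc), env),
    data = curve, start = as.list(start),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  est <- stats::coef(fit)
  structure(
    list(params = wlc_params(est[["P"]], est[["Lc"]]),
         vcov = stats::vcov(fit), fit = fit,
         data = tibble::as_tibble(curve), env = env),
    class = "wlc_fit"
  )
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("<wlc_fit> P = %.3g nm, Lc = %.4g nm (n = %d points)\n",
              x$params$persistence_length_nm, x$params$contour_length_nm,
              nrow(x$data)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wlc_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = c("persistence_length_nm", "contour_length_nm"),
    estimate = c(x$params$persistence_length_nm, x$params$contour_length_nm),
    std.error = unname(se[c("P", "Lc")])
  )
}

#' @exportS3Method generics::glance
glance.wlc_fit <- function(x, ...) {
  r <- stats::resid(x$fit)
  tibble::tibble(sigma = sqrt(sum(r^2) / max(1, length(r) - 2)),
                 n = nrow(x$data),
                 converged = x$fit$convInfo$isConv)
}

#' @exportS3Method ggplot2::autoplot
autoplot.wlc_fit <- function(object, n_grid = 200, ...) {
  fmax <- max(object$data$force_pn)
  grid <- tibble::tibble(
    force_pn = exp(seq(log(min(object$data$force_pn)), log(fmax),
                       length.out = n_grid))
  )
  grid$extension_nm <- wlc_extension(grid$force_pn, object$params, object$env)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$extension_nm, y = .data$force_pn)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Extension (nm)", y = "Force (pN)",
                  title = sprintf("WLC fit: P = %.1f nm, Lc = %.0f nm",
                                  object$params$persistence_length_nm,
                                  object$params$contour_length_nm)) +
    ggplot2::theme_minimal()
}
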