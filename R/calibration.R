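#' Equipartition force estimate from transverse bead fluctuations
#'
#' A bead on a tether under a constant drag force behaves, transverse to the
#' flow, like an inverted pendulum of length `l + r`; the equipartition
#' theorem then relates its positional variance to the tether tension,
#' \deqn{F = \frac{k_B T\,(l + r)}{\langle \delta y^2 \rangle}.}
#'
#' @param variance_nm2 Variance of the bead-center position transverse to the
#'   flow, in nm^2; vectorized, must be > 0.
#' @param tether A [tether_geometry()] (supplies `l` and `r`).
#' @param env A [flow_environment()].
#'
#' @return Force in pN.
#' @examples
#' g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 900)
#' equipartition_force(8228, g)  # l + r = 2000 nm -> 1 pN
#' @export
equipartition_force <- function(variance_nm2, tether, env = flow_environment()) {
  env <- as_flow_environment(env)
  stopifnot(inherits(tether, "tether_geometry"))
  if (!is.numeric(variance_nm2) || any(!is.finite(variance_nm2)) ||
      any(variance_nm2 <= 0)) {
    stop("`variance_nm2` must be positive and finite", call. = FALSE)
  }
  env$thermal_energy * (tether$extension_nm + tether$bead_radius_nm) /
    variance_nm2
}

#' Transverse fluctuation variance of a recorded track
#'
#' Sample variance of the transverse position series after discarding an
#' initial burn-in (by default two relaxation times' worth of data when the
#' record carries its relaxation time, else nothing), so a non-equilibrium
#' start does not bias the equipartition estimate.
#'
#' @param record A fluctuation record from [simulate_tethered_bead()] (a
#'   tibble with columns `time_s`, `dy_nm`).
#' @param burn_in_s Burn-in to discard, in seconds. `NULL` (default) uses
#'   `2 * tau` from the record's `relaxation_time_s` attribute if present,
#'   else 0.
#' @return Unbiased sample variance in nm^2.
#' @export
fluctuation_variance <- function(record, burn_in_s = NULL) {
  stopifnot(is.data.frame(record), all(c("time_s", "dy_nm") %in% names(record)))
  if (is.null(burn_in_s)) {
    tau <- attr(record, "relaxation_time_s")
    burn_in_s <- if (is.null(tau)) 0 else 2 * tau
  }
  keep <- record$time_s >= burn_in_s
  if (sum(keep) < 2L) stop("burn-in leaves fewer than 2 samples", call. = FALSE)
  stats::var(record$dy_nm[keep])
}

#' Force-versus-velocity calibration model
#'
#' The empirical linear law `F = c V` relating the drag force on a tethered
#' bead to the mean flow velocity, together with the geometry it is valid
#' for. The calibration must be redone if the bead radius, tether length or
#' channel height change.
#'
#' @param slope_pn_s_mm Calibration slope c in pN s/mm.
#' @param valid_bead_radius_nm,valid_tether_length_nm,valid_channel_height_um
#'   Geometry the calibration applies to (recorded for provenance checks).
#' @return An object of class `calibration_model`.
#' @examples
#' calibration_model(1.4, 1100, 1900, 120)
#' @export
calibration_model <- function(slope_pn_s_mm, valid_bead_radius_nm = NA_real_,
                              valid_tether_length_nm = NA_real_,
                              valid_channel_height_um = NA_real_) {
  stopifnot(is.numeric(slope_pn_s_mm), length(slope_pn_s_mm) == 1L,
            is.finite(slope_pn_s_mm), slope_pn_s_mm > 0)
  structure(
    list(slope_pn_s_mm = slope_pn_s_mm,
         valid_bead_radius_nm = valid_bead_radius_nm,
         valid_tether_length_nm = valid_tether_length_nm,
         valid_channel_height_um = valid_channel_height_um),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> F = %.3g pN s/mm x V\n", x$slope_pn_s_mm))
  invisible(x)
}

#' Fit the force-versus-velocity calibration line
#'
#' Least-squares fit of per-condition equipartition force estimates against
#' mean flow velocities. The default is a through-origin fit (zero flow
#' exerts zero force); a free intercept is available as a diagnostic for
#' systematic offsets.
#'
#' @param data A data frame with columns `force_pn` and `velocity_mm_s`.
#' @param intercept If `TRUE`, fit a free intercept and report it as a
#'   diagnostic; the slope is still the calibration coefficient.
#' @param valid_bead_radius_nm,valid_tether_length_nm,valid_channel_height_um
#'   Geometry metadata forwarded to the resulting [calibration_model()].
#'
#' @return An object of class `calibration_fit`: contains `$model` (a
#'   [calibration_model()]), `$fit` (the underlying `lm`), and the data.
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(velocity_mm_s = c(1, 2, 3, 4),
#'                     force_pn = 1.4 * velocity_mm_s)
#' fit_calibration(d)
#' @export
fit_calibration <- function(data, intercept = FALSE,
                            valid_bead_radius_nm = NA_real_,
                            valid_tether_length_nm = NA_real_,
                            valid_channel_height_um = NA_real_) {
  stopifnot(is.data.frame(data),
            all(c("force_pn", "velocity_mm_s") %in% names(data)))
  v <- data$velocity_mm_s
  n_distinct_v <- length(unique(v))
  if (nrow(data) >= 2L && n_distinct_v < 2L && !intercept && all(v == 0)) {
    stop("degenerate design: all velocities zero", call. = FALSE)
  }
  if (nrow(data) < 1L || (intercept && n_distinct_v < 2L)) {
    stop("degenerate design: need at least two distinct velocities",
         call. = FALSE)
  }
  fml <- if (intercept) force_pn ~ velocity_mm_s else force_pn ~ velocity_mm_s + 0
  fit <- stats::lm(fml, data = data)
  slope <- unname(stats::coef(fit)[["velocity_mm_s"]])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration fit produced a non-positive slope", call. = FALSE)
  }
  structure(
    list(model = calibration_model(slope, valid_bead_radius_nm,
                                   valid_tether_length_nm,
                                   valid_channel_height_um),
         fit = fit, data = tibble::as_tibble(data), intercept = intercept),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope = %.4g pN s/mm (%s), n = %d\n",
              x$model$slope_pn_s_mm,
              if (x$intercept) "free intercept" else "through origin",
              nrow(x$data)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2])
}

#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(slope_pn_s_mm = x$model$slope_pn_s_mm,
                 sigma = s$sigma, n = nrow(x$data),
                 r.squared = s$r.squared)
}

#' @exportS3Method ggplot2::autoplot
autoplot.calibration_fit <- function(object, ...) {
  b0 <- if (object$intercept) stats::coef(object$fit)[["(Intercept)"]] else 0
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$velocity_mm_s, y = .data$force_pn)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$model$slope_pn_s_mm, intercept = b0,
                         linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Mean flow velocity (mm/s)", y = "Force (pN)",
                  title = sprintf("Calibration: F = %.3g pN s/mm x V",
                                  object$model$slope_pn_s_mm)) +
    ggplot2::theme_minimal()
}

#' Lorentzian corner frequency of a tethered bead
#'
#' Characteristic frequency of the transverse fluctuation spectrum,
#' `f_c = kappa / (2 pi gamma)` with stiffness `kappa = F / (l + r)` and
#' Stokes drag `gamma = 6 pi eta r`. Sampling below roughly `2 f_c`
#' underestimates the fluctuation variance (aliasing), which is why
#' equipartition calibration is restricted to low forces.
#'
#' @param force Tether tension in pN; vectorized.
#' @param tether A [tether_geometry()].
#' @param env A [flow_environment()] (supplies the viscosity).
#' @return Corner frequency in Hz.
#' @export
lorentzian_corner_frequency <- function(force, tether,
                                        env = flow_environment()) {
  env <- as_flow_environment(env)
  stopifnot(inherits(tether, "tether_geometry"), all(force > 0))
  kappa <- force / (tether$extension_nm + tether$bead_radius_nm)  # pN/nm
  gamma <- stokes_drag(tether$bead_radius_nm, env)                # pN s/nm
  kappa / (2 * pi * gamma)
}

# Stokes drag 6 pi eta r, converted from SI to pN s / nm
# (1 Pa s * 1 nm = 1e-6 pN s / nm)
stokes_drag <- function(bead_radius_nm, env) {
  6 * pi * env$viscosity * bead_radius_nm * 1e-6
}
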