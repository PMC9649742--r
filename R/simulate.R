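#' Simulate transverse fluctuations of a tethered bead under flow
#'
#' Forward model for the equipartition calibration: the bead-center position
#' transverse to the flow follows an overdamped mean-reverting
#' (Ornstein-Uhlenbeck) process with pendulum stiffness
#' `kappa = F / (l + r)`, Stokes drag `gamma = 6 pi eta r` and relaxation
#' time `tau = gamma / kappa`. The update uses the exact discretization
#' \deqn{y_{t+\Delta t} = y_t e^{-\Delta t/\tau} +
#'   \sigma\sqrt{1 - e^{-2\Delta t/\tau}}\,\xi,}
#' so the equilibrium variance `sigma^2 = kB T (l + r) / F` is honoured for
#' any step size. The series starts from an equilibrium draw.
#'
#' @param force_pn Constant tether tension in pN (> 0).
#' @param tether A [tether_geometry()].
#' @param env A [flow_environment()].
#' @param sampling_frequency_hz Camera sampling frequency in Hz.
#' @param duration_s Record duration in s (`duration * frequency >= 100`).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `time_s`, `dy_nm` carrying attributes
#'   `sampling_frequency_hz`, `variance_nm2` (the realized sample variance),
#'   `relaxation_time_s`, `force_pn` and, when the sampling frequency is
#'   below twice the Lorentzian corner frequency, `aliasing = TRUE` (with a
#'   warning).
#' @examples
#' g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 900)
#' rec <- simulate_tethered_bead(1, g, sampling_frequency_hz = 50,
#'                               duration_s = 20, seed = 1)
#' fluctuation_variance(rec)
#' @export
simulate_tethered_bead <- function(force_pn, tether, env = flow_environment(),
                                   sampling_frequency_hz, duration_s,
                                   seed = NULL) {
  env <- as_flow_environment(env)
  stopifnot(inherits(tether, "tether_geometry"),
            is.numeric(force_pn), length(force_pn) == 1L, force_pn > 0,
            sampling_frequency_hz > 0, duration_s > 0)
  n <- floor(duration_s * sampling_frequency_hz)
  if (n < 100L) {
    stop("record too short: need duration * sampling_frequency >= 100 samples",
         call. = FALSE)
  }
  l_plus_r <- tether$extension_nm + tether$bead_radius_nm
  kappa <- force_pn / l_plus_r
  gamma <- stokes_drag(tether$bead_radius_nm, env)
  tau <- gamma / kappa
  sigma2 <- env$thermal_energy * l_plus_r / force_pn
  dt <- 1 / sampling_frequency_hz
  a <- exp(-dt / tau)
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(n)
  y <- numeric(n)
  y[1] <- sqrt(sigma2) * eps[1]
  innov_sd <- sqrt(sigma2 * (1 - a^2))
  for (i in 2:n) y[i] <- a * y[i - 1] + innov_sd * eps[i]
  rec <- tibble::tibble(time_s = (seq_len(n) - 1) * dt, dy_nm = y)
  attr(rec, "sampling_frequency_hz") <- sampling_frequency_hz
  attr(rec, "variance_nm2") <- stats::var(y)
  attr(rec, "relaxation_time_s") <- tau
  attr(rec, "force_pn") <- force_pn
  fc <- lorentzian_corner_frequency(force_pn, tether, env)
  if (sampling_frequency_hz < 2 * fc) {
    warning(sprintf(paste0("sampling frequency %.3g Hz is below twice the ",
                           "Lorentzian corner frequency (%.3g Hz): variance ",
                           "will be aliased"),
                    sampling_frequency_hz, fc), call. = FALSE)
    attr(rec, "aliasing") <- TRUE
  }
  rec
}

#' Simulate a noisy worm-like-chain force-extension curve
#'
#' Fixture generator for [fit_wlc()]: extensions from the numerical inverse
#' of the interpolation force law, plus additive Gaussian extension noise.
#'
#' @param wlc A [wlc_params()] (the generating truth).
#' @param forces_pn Positive force grid in pN.
#' @param noise_sd_extension_nm Gaussian extension noise SD in nm (>= 0).
#' @param seed Optional integer seed.
#' @param env A [flow_environment()].
#' @return A tibble with columns `force_pn`, `extension_nm`.
#' @export
simulate_force_extension <- function(wlc, forces_pn, noise_sd_extension_nm = 0,
                                     seed = NULL, env = flow_environment()) {
  env <- as_flow_environment(env)
  stopifnot(inherits(wlc, "wlc_params"), all(forces_pn > 0),
            noise_sd_extension_nm >= 0)
  if (!is.null(seed)) set.seed(seed)
  l <- wlc_extension(forces_pn, wlc, env)
  if (noise_sd_extension_nm > 0) {
    l <- l + stats::rnorm(length(l), sd = noise_sd_extension_nm)
  }
  tibble::tibble(force_pn = forces_pn, extension_nm = l)
}

#' Simulate a multi-channel rupture experiment
#'
#' The forward model of a multiplexed flow-ramp experiment on a serial
#' multi-width chip. A linear inlet ramp `Q(t) = Q0 + beta t` produces, in
#' channel `i` of width `w_i` and height `h`, a force loading rate
#' \deqn{\dot F_i = c\,\beta / (w_i h)} (with `c` the calibration slope), so
#' loading rate scales inversely with channel width. Rupture forces are drawn
#' per bead by exact inverse-CDF sampling at the channel's loading rate and
#' converted back to rupture flow rates `Q_i = F w_i h / c`. Beads whose
#' sampled rupture flow rate exceeds the ramp maximum are right-censored.
#'
#' @param chip A [chip_layout()].
#' @param calibration A [calibration_model()].
#' @param protocol A [loading_protocol()] with a strictly positive ramp slope.
#' @param landscape An [energy_landscape()] (the generating truth).
#' @param env A [flow_environment()].
#' @param n_beads_per_channel Beads per channel.
#' @param seed Optional integer seed.
#'
#' @return A tibble with one row per bead: `bead_id`, `channel_index`,
#'   `width_um`, `loading_rate_pn_s`, `rupture_force_pn`,
#'   `rupture_flow_rate_mm3_s`, `censored`.
#' @examples
#' chip <- chip_layout(c(250, 500, 750, 1000), 60)
#' cal <- calibration_model(3.0)
#' prot <- loading_protocol(ramp_mm3_s2 = 0.02, duration_s = 300)
#' dig <- energy_landscape(4.0e-4, 0.76)
#' simulate_rupture_experiment(chip, cal, prot, dig,
#'                             n_beads_per_channel = 3, seed = 1)
#' @export
simulate_rupture_experiment <- function(chip, calibration, protocol, landscape,
                                        env = flow_environment(),
                                        n_beads_per_channel, seed = NULL) {
  env <- as_flow_environment(env)
  stopifnot(inherits(chip, "chip_layout"),
            inherits(calibration, "calibration_model"),
            inherits(protocol, "loading_protocol"),
            inherits(landscape, "energy_landscape"),
            n_beads_per_channel >= 1)
  if (protocol$ramp_mm3_s2 <= 0) {
    stop("zero ramp slope: no loading rate is defined for this protocol",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  c_pn_s_mm <- calibration$slope_pn_s_mm
  h_mm <- chip$height_um / 1000
  q_max <- protocol$flow_rate(protocol$duration_s)
  purrr::map_dfr(seq_len(nrow(chip$channels)), function(i) {
    w_mm <- chip$channels$width_um[i] / 1000
    f_dot <- c_pn_s_mm * protocol$ramp_mm3_s2 / (w_mm * h_mm)
    forces <- sample_rupture_forces(landscape, f_dot, env,
                                    n = n_beads_per_channel)
    q_rupt <- forces * w_mm * h_mm / c_pn_s_mm
    censored <- q_rupt > q_max
    tibble::tibble(
      bead_id = sprintf("ch%d_b%04d", i, seq_len(n_beads_per_channel)),
      channel_index = i,
      width_um = chip$channels$width_um[i],
      loading_rate_pn_s = f_dot,
      rupture_force_pn = forces,
      rupture_flow_rate_mm3_s = pmin(q_rupt, q_max),
      censored = censored
    )
  })
}

#' Simulate bead-survival data under constant force
#'
#' Competing independent exponential removal processes: background anchor
#' dissociation at rate `k_b` and strand displacement at rate `k_s`. Each
#' bead's removal time is exponential with total rate `k_b + k_s`; times
#' beyond the observation window are right-censored at the horizon.
#'
#' @param rate_background_s Background removal rate k_b in 1/s (>= 0).
#' @param rate_sd_s Strand-displacement rate k_s in 1/s (>= 0).
#' @param n_beads Number of beads (0 allowed: returns an empty record).
#' @param observation_time_s Observation horizon in s (> 0).
#' @param seed Optional integer seed.
#' @param applied_force_pn Optional force label attached to the record.
#'
#' @return A tibble with columns `bead_id`, `removal_time_s`, `censored`,
#'   carrying attributes `observation_time_s` and `applied_force_pn`.
#' @export
simulate_survival <- function(rate_background_s, rate_sd_s, n_beads,
                              observation_time_s, seed = NULL,
                              applied_force_pn = NA_real_) {
  stopifnot(rate_background_s >= 0, rate_sd_s >= 0, n_beads >= 0,
            observation_time_s > 0)
  if (!is.null(seed)) set.seed(seed)
  total <- rate_background_s + rate_sd_s
  if (n_beads == 0) {
    times <- numeric(0); censored <- logical(0)
  } else if (total == 0) {
    warning("both rates are zero: all beads censored at the horizon",
            call. = FALSE)
    times <- rep(observation_time_s, n_beads)
    censored <- rep(TRUE, n_beads)
  } else {
    raw <- stats::rexp(n_beads, rate = total)
    censored <- raw > observation_time_s
    times <- pmin(raw, observation_time_s)
  }
  rec <- tibble::tibble(bead_id = seq_len(n_beads),
                        removal_time_s = times, censored = censored)
  attr(rec, "observation_time_s") <- observation_time_s
  attr(rec, "applied_force_pn") <- applied_force_pn
  rec
}
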