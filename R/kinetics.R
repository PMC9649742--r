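#' Censored-exponential removal-rate fit
#'
#' Maximum-likelihood rate for exponentially distributed bead-removal times
#' with right censoring: `k = (number of events) / (total observed time)`,
#' where censored beads contribute their observation horizon to the
#' denominator. The confidence interval comes from the chi-square
#' (event-count) interval for a Poisson exposure.
#'
#' @param record A data frame with columns `removal_time_s` and `censored`
#'   (as produced by [simulate_survival()] or read from a survival CSV).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A list of class `removal_rate_fit`: `$rate` (1/s), `$lower`,
#'   `$upper`, `$n_events`, `$exposure_s`, `$flagged` (TRUE when there were
#'   zero events, in which case `$rate` is 0 and only the upper bound is
#'   meaningful).
#' @examples
#' rec <- simulate_survival(1e-3, 0, n_beads = 200,
#'                          observation_time_s = 5000, seed = 1)
#' fit_removal_rate(rec)
#' @export
fit_removal_rate <- function(record, conf_level = 0.95) {
  stopifnot(is.data.frame(record),
            all(c("removal_time_s", "censored") %in% names(record)),
            all(record$removal_time_s >= 0))
  d <- sum(!record$censored)
  exposure <- sum(record$removal_time_s)
  if (exposure <= 0) stop("total observed time is zero", call. = FALSE)
  alpha <- 1 - conf_level
  flagged <- d == 0
  if (flagged) {
    warning("no removal events observed: only the upper rate bound is ",
            "informative", call. = FALSE)
  }
  rate <- d / exposure
  lower <- if (d == 0) 0 else stats::qchisq(alpha / 2, 2 * d) / (2 * exposure)
  upper <- stats::qchisq(1 - alpha / 2, 2 * d + 2) / (2 * exposure)
  structure(
    list(rate = rate, lower = lower, upper = upper, n_events = d,
         exposure_s = exposure, flagged = flagged,
         se = if (d > 0) rate / sqrt(d) else NA_real_,
         applied_force_pn = attr(record, "applied_force_pn")),
    class = "removal_rate_fit"
  )
}

#' @export
print.removal_rate_fit <- function(x, ...) {
  cat(sprintf("<removal_rate_fit> k = %.3g 1/s [%.3g, %.3g], %d events / %.3g s\n",
              x$rate, x$lower, x$upper, x$n_events, x$exposure_s))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.removal_rate_fit <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate, std.error = x$se,
                 conf.low = x$lower, conf.high = x$upper)
}

#' Strand-displacement rate by background subtraction
#'
#' Anchor dissociation and toehold-mediated strand displacement remove beads
#' independently, so the total removal rate with the invader strand present
#' is the sum of the two processes' rates and the displacement rate is
#' recovered by subtracting the invader-free background:
#' `k_sd = k_total - k_background`. A (noise-driven) negative difference is
#' clipped to zero with a warning. Uncertainties add in quadrature.
#'
#' @param with_invader,background Survival records (see
#'   [fit_removal_rate()]) for the invader-present and invader-free
#'   conditions at the same applied force.
#' @param force_tol_pn Tolerated mismatch between the two records'
#'   `applied_force_pn` attributes (default 0.1 pN; `NA` forces skip the
#'   check).
#'
#' @return A list of class `sd_rate`: `$rate` (1/s), `$se`, `$rate_total`,
#'   `$rate_background`, `$clipped`.
#' @export
strand_displacement_rate <- function(with_invader, background,
                                     force_tol_pn = 0.1) {
  f1 <- attr(with_invader, "applied_force_pn")
  f2 <- attr(background, "applied_force_pn")
  if (!is.null(f1) && !is.null(f2) && !is.na(f1) && !is.na(f2) &&
      abs(f1 - f2) > force_tol_pn) {
    stop(sprintf("applied forces differ (%.3g vs %.3g pN): records are not a matched pair",
                 f1, f2), call. = FALSE)
  }
  kw <- fit_removal_rate(with_invader)
  kb <- fit_removal_rate(background)
  rate <- kw$rate - kb$rate
  clipped <- rate < 0
  if (clipped) {
    warning("background rate exceeds the total rate: strand-displacement ",
            "rate clipped to 0", call. = FALSE)
    rate <- 0
  }
  se <- sqrt(sum(c(kw$se, kb$se)^2, na.rm = TRUE))
  structure(
    list(rate = rate, se = se, rate_total = kw$rate,
         rate_background = kb$rate, clipped = clipped,
         applied_force_pn = if (!is.null(f1)) f1 else NA_real_),
    class = "sd_rate"
  )
}

#' @export
print.sd_rate <- function(x, ...) {
  cat(sprintf("<sd_rate> k_sd = %.3g +/- %.3g 1/s (total %.3g, background %.3g)\n",
              x$rate, x$se, x$rate_total, x$rate_background))
  invisible(x)
}

#' Strand-displacement rate versus force profile
#'
#' For each force level, partitions the invader-present and invader-free
#' records into `n_groups` random subgroups (the same rule as the rupture
#' subgroup statistics), computes the background-subtracted
#' strand-displacement rate in each, and reports the per-force mean and SD.
#' Force levels missing either condition (or with no beads) are omitted with
#' a message.
#'
#' @param records A data frame with columns `force_pn`, `condition` (values
#'   `"with_invader"` / `"background"`), `removal_time_s`, `censored`.
#' @param n_groups Subgroups per force level (default 3).
#' @param seed Optional integer seed for the partitions.
#'
#' @return A tibble with columns `force_pn`, `k_sd`, `k_sd_sd`,
#'   `k_total`, `k_background`, `n_with`, `n_background`.
#' @export
rate_vs_force_profile <- function(records, n_groups = 3L, seed = NULL) {
  stopifnot(is.data.frame(records),
            all(c("force_pn", "condition", "removal_time_s", "censored")
                %in% names(records)),
            all(records$condition %in% c("with_invader", "background")))
  if (!is.null(seed)) set.seed(seed)
  forces <- sort(unique(records$force_pn))
  rows <- lapply(forces, function(f) {
    wi <- records[records$force_pn == f &
                    records$condition == "with_invader", , drop = FALSE]
    bg <- records[records$force_pn == f &
                    records$condition == "background", , drop = FALSE]
    if (nrow(wi) < n_groups || nrow(bg) < n_groups) {
      message(sprintf("force level %.3g pN omitted: too few beads", f))
      return(NULL)
    }
    gw <- sample(rep_len(seq_len(n_groups), nrow(wi)))
    gb <- sample(rep_len(seq_len(n_groups), nrow(bg)))
    ks <- vapply(seq_len(n_groups), function(g) {
      r <- suppressWarnings(
        strand_displacement_rate(wi[gw == g, , drop = FALSE],
                                 bg[gb == g, , drop = FALSE],
                                 force_tol_pn = Inf)
      )
      r$rate
    }, numeric(1))
    full <- suppressWarnings(
      strand_displacement_rate(wi, bg, force_tol_pn = Inf)
    )
    tibble::tibble(force_pn = f, k_sd = mean(ks), k_sd_sd = stats::sd(ks),
                   k_total = full$rate_total,
                   k_background = full$rate_background,
                   n_with = nrow(wi), n_background = nrow(bg))
  })
  dplyr::bind_rows(rows)
}

#' Plot a strand-displacement rate-versus-force profile
#'
#' @param profile Output of [rate_vs_force_profile()].
#' @return A ggplot.
#' @export
plot_rate_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$force_pn, y = .data$k_sd)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$k_sd - .data$k_sd_sd,
                                                    .Machine$double.xmin),
                                        ymax = .data$k_sd + .data$k_sd_sd),
                           width = 0.1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Applied force (pN)",
                  y = "Strand-displacement rate (1/s)") +
    ggplot2::theme_minimal()
}
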