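#' Rupture-force dataset for one loading condition
#'
#' @param forces_pn Positive rupture forces in pN.
#' @param f_dot Loading rate in pN/s for this condition.
#' @param condition Optional condition label.
#' @param channel Optional channel provenance.
#' @return An object of class `rupture_dataset`.
#' @export
rupture_dataset <- function(forces_pn, f_dot, condition = NA_character_,
                            channel = NA_integer_) {
  check_loading_rate(f_dot)
  stopifnot(is.numeric(forces_pn), all(is.finite(forces_pn)),
            all(forces_pn > 0))
  structure(
    list(forces_pn = as.numeric(forces_pn), f_dot = f_dot,
         condition = condition, channel = channel),
    class = "rupture_dataset"
  )
}

#' @export
print.rupture_dataset <- function(x, ...) {
  cat(sprintf("<rupture_dataset> n = %d forces at f_dot = %.3g pN/s%s\n",
              length(x$forces_pn), x$f_dot,
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")")))
  invisible(x)
}

#' Empirical cumulative distribution of rupture forces
#'
#' Sorted forces with plotting positions `i/n`; tied forces share the
#' highest position of their run. Alternatively fixed-width cumulative
#' binning.
#'
#' @param forces_pn Rupture forces (n >= 2).
#' @param binned If `TRUE`, accumulate counts in fixed-width bins instead of
#'   using the sorted points directly.
#' @param bin_width_pn Bin width in pN when `binned = TRUE`.
#' @return A tibble with columns `force_pn`, `prob`.
#' @examples
#' empirical_cdf(c(1, 2, 3))
#' @export
empirical_cdf <- function(forces_pn, binned = FALSE, bin_width_pn = 1) {
  stopifnot(is.numeric(forces_pn), length(forces_pn) >= 2L)
  n <- length(forces_pn)
  if (binned) {
    breaks <- seq(0, max(forces_pn) + bin_width_pn, by = bin_width_pn)
    cnt <- table(cut(forces_pn, breaks, right = TRUE))
    return(tibble::tibble(force_pn = breaks[-1],
                          prob = cumsum(as.numeric(cnt)) / n))
  }
  s <- sort(forces_pn)
  prob <- seq_len(n) / n
  keep <- !duplicated(s, fromLast = TRUE)  # ties share the highest position
  tibble::tibble(force_pn = s[keep], prob = prob[keep])
}

#' Fit the rupture-force cumulative distribution
#'
#' Nonlinear least squares of the model cumulative rupture probability (at
#' the known loading rate) against the empirical CDF, over
#' `(log10 k_off, delta_x)`. Initialization uses `delta_x0 = kB T / SD(F)`
#' (the Bell-model width-SD relation) and inverts the most-probable-force
#' formula at the sample mode for `k_off0`. The fitted landscape is
#' converted to a most probable rupture force.
#'
#' @param data A [rupture_dataset()] (or a numeric force vector plus
#'   `f_dot`).
#' @param env A [flow_environment()].
#' @param method CDF evaluation passed to [rupture_cdf()] (`"exact"` or
#'   `"series"`).
#' @param n_terms Series length when `method = "series"`.
#' @param n_floor Minimum number of forces required (default 20).
#' @param f_dot Loading rate, only when `data` is a bare numeric vector.
#' @param probs Optional vector of cumulative probabilities overriding the
#'   empirical plotting positions (must match `data` in length and order
#'   after sorting); used for noiseless quantile-based fits.
#'
#' @return An object of class `rupture_cdf_fit`: `$landscape`, `$f_star`,
#'   `$f_dot`, `$sse`, `$boundary` (TRUE when the solution pinned a bound),
#'   `$data`. Supports [generics::tidy()] and [ggplot2::autoplot()].
#' @export
fit_rupture_cdf <- function(data, env = flow_environment(),
                            method = c("exact", "series"), n_terms = 50L,
                            n_floor = 20L, f_dot = NULL, probs = NULL) {
  env <- as_flow_environment(env)
  method <- match.arg(method)
  if (is.numeric(data)) {
    check_loading_rate(f_dot)
    data <- rupture_dataset(data, f_dot)
  }
  stopifnot(inherits(data, "rupture_dataset"))
  forces <- sort(data$forces_pn)
  n <- length(forces)
  if (n < n_floor) {
    stop(sprintf("need at least %d rupture forces to fit the CDF (got %d)",
                 n_floor, n), call. = FALSE)
  }
  if (is.null(probs)) {
    probs <- seq_len(n) / n
  } else {
    stopifnot(length(probs) == n, all(probs >= 0 & probs <= 1))
    probs <- sort(probs)  # paired with the sorted forces
  }
  kbt <- env$thermal_energy
  lo <- c(log10_koff = -12, delta_x = 0.01)
  hi <- c(log10_koff = 3, delta_x = 100)
  dx0 <- min(max(kbt / stats::sd(forces), lo[2]), hi[2])
  dens <- stats::density(forces)
  f_mode <- dens$x[which.max(dens$y)]
  koff0 <- data$f_dot * dx0 / kbt * exp(-dx0 * f_mode / kbt)
  th0 <- c(min(max(log10(koff0), lo[1]), hi[1]), dx0)
  obj <- function(th) {
    ls <- energy_landscape(10^th[1], th[2])
    p <- rupture_cdf(forces, ls, data$f_dot, env, method = method,
                     n_terms = n_terms)
    sum((p - probs)^2)
  }
  opt <- stats::nlminb(th0, obj, lower = lo, upper = hi,
                       control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                      iter.max = 500, eval.max = 1000))
  if (!opt$convergence %in% c(0, 1)) {
    stop("rupture CDF fit did not converge: ", opt$message, call. = FALSE)
  }
  opt$par <- stats::setNames(opt$par, names(lo))
  opt$value <- opt$objective
  at_bound <- any(abs(opt$par - lo) < 1e-8) || any(abs(opt$par - hi) < 1e-8)
  if (at_bound) {
    warning("rupture CDF fit pinned a parameter bound; estimates unreliable",
            call. = FALSE)
  }
  landscape <- energy_landscape(10^opt$par[[1]], opt$par[[2]])
  f_star <- most_probable_force(landscape, data$f_dot, env)
  structure(
    list(landscape = landscape, f_star = as.numeric(f_star),
         f_dot = data$f_dot, sse = opt$value, boundary = at_bound,
         method = method, data = data, env = env),
    class = "rupture_cdf_fit"
  )
}

#' @export
print.rupture_cdf_fit <- function(x, ...) {
  cat(sprintf(paste0("<rupture_cdf_fit> f_dot = %.3g pN/s: k_off = %.3g 1/s, ",
                     "delta_x = %.3g nm, F* = %.3g pN\n"),
              x$f_dot, x$landscape$k_off, x$landscape$delta_x, x$f_star))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rupture_cdf_fit <- function(x, ...) {
  tibble::tibble(term = c("k_off", "delta_x", "f_star"),
                 estimate = c(x$landscape$k_off, x$landscape$delta_x,
                              x$f_star))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rupture_cdf_fit <- function(object, n_grid = 200, ...) {
  ec <- empirical_cdf(object$data$forces_pn)
  grid <- tibble::tibble(force_pn = seq(0, max(ec$force_pn) * 1.05,
                                        length.out = n_grid))
  grid$prob <- rupture_cdf(grid$force_pn, object$landscape, object$f_dot,
                           object$env)
  ggplot2::ggplot(ec, ggplot2::aes(x = .data$force_pn, y = .data$prob)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_vline(xintercept = object$f_star, linetype = "dotted") +
    ggplot2::labs(x = "Rupture force (pN)", y = "Cumulative probability",
                  title = sprintf("f_dot = %.3g pN/s, F* = %.1f pN",
                                  object$f_dot, object$f_star)) +
    ggplot2::theme_minimal()
}

#' Subgroup statistics of the most probable rupture force
#'
#' Randomly partitions the rupture forces of one condition into `n_groups`
#' disjoint, near-equal subgroups (selection without replacement), fits the
#' cumulative distribution in each, and reports the mean and standard
#' deviation of the per-subgroup most probable rupture forces.
#'
#' @inheritParams fit_rupture_cdf
#' @param n_groups Number of subgroups (default 3).
#' @param seed Optional integer seed for the random partition.
#' @param ... Passed to [fit_rupture_cdf()].
#'
#' @return A list of class `subgroup_stats`: `$f_star_mean`, `$f_star_sd`,
#'   `$f_dot`, `$groups` (tibble with per-group `f_star`, `k_off`,
#'   `delta_x`, `n`), `$fits`.
#' @export
subgroup_statistics <- function(data, env = flow_environment(),
                                n_groups = 3L, seed = NULL, n_floor = 20L,
                                f_dot = NULL, ...) {
  env <- as_flow_environment(env)
  if (is.numeric(data)) data <- rupture_dataset(data, f_dot)
  stopifnot(inherits(data, "rupture_dataset"), n_groups >= 2L)
  n <- length(data$forces_pn)
  if (n < n_groups * n_floor) {
    stop(sprintf("need at least n_groups * n_floor = %d forces (got %d)",
                 n_groups * n_floor, n), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  assignment <- sample(rep_len(seq_len(n_groups), n))
  fits <- lapply(seq_len(n_groups), function(g) {
    fit_rupture_cdf(rupture_dataset(data$forces_pn[assignment == g],
                                    data$f_dot, data$condition, data$channel),
                    env, n_floor = n_floor, ...)
  })
  groups <- tibble::tibble(
    group = seq_len(n_groups),
    n = as.integer(table(assignment)),
    f_star = vapply(fits, function(f) f$f_star, numeric(1)),
    k_off = vapply(fits, function(f) f$landscape$k_off, numeric(1)),
    delta_x = vapply(fits, function(f) f$landscape$delta_x, numeric(1))
  )
  structure(
    list(f_star_mean = mean(groups$f_star), f_star_sd = stats::sd(groups$f_star),
         f_dot = data$f_dot, groups = groups, fits = fits),
    class = "subgroup_stats"
  )
}

#' @export
print.subgroup_stats <- function(x, ...) {
  cat(sprintf("<subgroup_stats> f_dot = %.3g pN/s: F* = %.2f +/- %.2f pN (%d groups)\n",
              x$f_dot, x$f_star_mean, x$f_star_sd, nrow(x$groups)))
  invisible(x)
}

#' Global Evans-Ritchie fit of F* versus loading rate
#'
#' Ordinary (optionally weighted) least squares of the most probable rupture
#' force against the log loading rate. The slope `s` gives
#' `delta_x = kB T / s`; the intercept `b` gives
#' `k_off = delta_x / (n_serial kB T) * exp(-b / s)`, where `n_serial`
#' identical serially loaded bonds rupture `n_serial`-fold faster.
#' Parameter uncertainties are propagated from the regression covariance by
#' the delta method.
#'
#' @param points A data frame with columns `f_dot` and `f_star` (>= 2
#'   distinct rates); an optional `f_star_sd` column is used when
#'   `weighted = TRUE`.
#' @param env A [flow_environment()].
#' @param n_serial Number of serially connected identical bonds (default 1).
#' @param weighted If `TRUE`, weight by `1 / f_star_sd^2`.
#'
#' @return An object of class `dfs_fit`: `$landscape`, `$se` (named
#'   `k_off`, `delta_x`), `$fit` (the `lm`), `$n_serial`, `$points`.
#'   Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()].
#' @examples
#' env <- flow_environment()
#' truth <- energy_landscape(1e-4, 1.0)
#' pts <- tibble::tibble(f_dot = c(0.5, 1.5, 5),
#'                       f_star = most_probable_force(truth, 0.5, env) +
#'                         env$thermal_energy / 1.0 * log(f_dot / 0.5))
#' fit_force_vs_loading_rate(pts)
#' @export
fit_force_vs_loading_rate <- function(points, env = flow_environment(),
                                      n_serial = 1L, weighted = FALSE) {
  env <- as_flow_environment(env)
  stopifnot(is.data.frame(points),
            all(c("f_dot", "f_star") %in% names(points)))
  if (length(unique(points$f_dot)) < 2L) {
    stop("need at least two distinct loading rates", call. = FALSE)
  }
  df <- tibble::tibble(lnf = base::log(points$f_dot), f_star = points$f_star)
  w <- NULL
  if (weighted) {
    if (!"f_star_sd" %in% names(points) || any(points$f_star_sd <= 0)) {
      stop("weighted fit needs a positive `f_star_sd` column", call. = FALSE)
    }
    w <- 1 / points$f_star_sd^2
  }
  fit <- stats::lm(f_star ~ lnf, data = df, weights = w)
  s <- stats::coef(fit)[["lnf"]]
  b <- stats::coef(fit)[["(Intercept)"]]
  if (!is.finite(s) || s <= 0) {
    stop("non-positive slope of F* vs ln(loading rate): Evans-Ritchie model ",
         "violated by these points", call. = FALSE)
  }
  kbt <- env$thermal_energy
  delta_x <- kbt / s
  k_off <- delta_x / (n_serial * kbt) * exp(-b / s)
  # delta method on (b, s) -> (k_off, delta_x)
  # vcov warns on numerically perfect fits (noiseless validation inputs)
  V <- suppressWarnings(stats::vcov(fit))  # order: (Intercept), lnf
  g_dx <- c(0, -kbt / s^2)
  g_ko <- c(-k_off / s, k_off * (b / s^2 - 1 / s))
  se <- c(k_off = sqrt(drop(t(g_ko) %*% V %*% g_ko)),
          delta_x = sqrt(drop(t(g_dx) %*% V %*% g_dx)))
  structure(
    list(landscape = energy_landscape(k_off, delta_x), se = se, fit = fit,
         n_serial = n_serial, points = tibble::as_tibble(points), env = env),
    class = "dfs_fit"
  )
}

#' @export
print.dfs_fit <- function(x, ...) {
  cat(sprintf(paste0("<dfs_fit> k_off = %.3g 1/s, delta_x = %.3g nm ",
                     "(N = %d serial bonds, %d rates)\n"),
              x$landscape$k_off, x$landscape$delta_x, x$n_serial,
              length(unique(x$points$f_dot))))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dfs_fit <- function(x, ...) {
  tibble::tibble(term = c("k_off", "delta_x"),
                 estimate = c(x$landscape$k_off, x$landscape$delta_x),
                 std.error = unname(x$se[c("k_off", "delta_x")]))
}

#' @exportS3Method generics::glance
glance.dfs_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared,
                 n_rates = length(unique(x$points$f_dot)),
                 n_serial = x$n_serial)
}

#' @exportS3Method ggplot2::autoplot
autoplot.dfs_fit <- function(object, show_single_bond = FALSE, ...) {
  pts <- object$points
  grid <- tibble::tibble(
    f_dot = exp(seq(log(min(pts$f_dot)), log(max(pts$f_dot)),
                    length.out = 100))
  )
  grid$f_star <- suppressWarnings(vapply(grid$f_dot, function(fd) {
    as.numeric(most_probable_force(object$landscape, fd, object$env,
                                   n_serial = object$n_serial))
  }, numeric(1)))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$f_dot, y = .data$f_star)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Loading rate (pN/s)", y = "F* (pN)") +
    ggplot2::theme_minimal()
  if ("f_star_sd" %in% names(pts)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$f_star - .data$f_star_sd,
                   ymax = .data$f_star + .data$f_star_sd), width = 0.05)
  }
  if (show_single_bond && object$n_serial > 1) {
    single <- project_single_bond(object$landscape, object$env, grid$f_dot)
    p <- p + ggplot2::geom_line(data = single, colour = "darkgreen",
                                linetype = "dashed")
  }
  p
}

#' Project the single-bond F* versus loading rate curve
#'
#' Evaluates the most probable rupture force for a single bond (`N = 1`) on
#' a loading-rate grid, e.g. to compare a serial-bond measurement with the
#' corresponding single-interaction prediction.
#'
#' @param landscape An [energy_landscape()].
#' @param env A [flow_environment()].
#' @param rate_grid Loading rates in pN/s.
#' @return A tibble with columns `f_dot`, `f_star`, `flagged` (TRUE where
#'   the model leaves its validity region, i.e. F* <= 0).
#' @export
project_single_bond <- function(landscape, env = flow_environment(),
                                rate_grid) {
  env <- as_flow_environment(env)
  stopifnot(all(rate_grid > 0))
  f_star <- suppressWarnings(vapply(rate_grid, function(fd) {
    as.numeric(most_probable_force(landscape, fd, env, n_serial = 1L))
  }, numeric(1)))
  tibble::tibble(f_dot = rate_grid, f_star = f_star, flagged = f_star <= 0)
}

#' Full dynamic force spectroscopy fit across loading rates
#'
#' Convenience wrapper over the whole statistical pipeline: per-condition
#' subgroup statistics of the most probable rupture force, then the global
#' Evans-Ritchie regression of F* against log loading rate.
#'
#' @param datasets A list of [rupture_dataset()]s (distinct loading rates).
#' @param env A [flow_environment()].
#' @param n_groups Subgroups per condition (default 3).
#' @param seed Optional integer seed (partitioning).
#' @param n_serial Serial-bond count for the global fit.
#' @param weighted Weight the global fit by subgroup SDs.
#' @param ... Passed to [fit_rupture_cdf()].
#'
#' @return A list of class `dfs_pipeline_fit`: `$per_rate` (tibble with
#'   `f_dot`, `f_star_mean`, `f_star_sd`, `k_off`, `delta_x`), `$global`
#'   (a [fit_force_vs_loading_rate()] result), `$subgroups`.
#' @export
fit_dfs <- function(datasets, env = flow_environment(), n_groups = 3L,
                    seed = NULL, n_serial = 1L, weighted = FALSE, ...) {
  env <- as_flow_environment(env)
  stopifnot(is.list(datasets), length(datasets) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  subgroups <- lapply(datasets, function(d) {
    subgroup_statistics(d, env, n_groups = n_groups, ...)
  })
  full_fits <- lapply(datasets, function(d) fit_rupture_cdf(d, env, ...))
  per_rate <- tibble::tibble(
    f_dot = vapply(datasets, function(d) d$f_dot, numeric(1)),
    f_star_mean = vapply(subgroups, function(s) s$f_star_mean, numeric(1)),
    f_star_sd = vapply(subgroups, function(s) s$f_star_sd, numeric(1)),
    k_off = vapply(full_fits, function(f) f$landscape$k_off, numeric(1)),
    delta_x = vapply(full_fits, function(f) f$landscape$delta_x, numeric(1))
  )
  pts <- tibble::tibble(f_dot = per_rate$f_dot,
                        f_star = per_rate$f_star_mean,
                        f_star_sd = per_rate$f_star_sd)
  global <- fit_force_vs_loading_rate(pts, env, n_serial = n_serial,
                                      weighted = weighted)
  structure(list(per_rate = per_rate, global = global, subgroups = subgroups,
                 per_rate_fits = full_fits),
            class = "dfs_pipeline_fit")
}

#' @export
print.dfs_pipeline_fit <- function(x, ...) {
  print(x$per_rate)
  print(x$global)
  invisible(x)
}
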