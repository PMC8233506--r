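# Baranyi-Roberts growth model and double-strain virtual competitions.
#
# Governing law for a single strain:
#   dN/dt = r * alpha(t) * N * (1 - (N/k)^nu),  alpha(t) = q0 / (q0 + e^(-v t))
# alpha is the physiological-state adjustment producing an explicit lag phase;
# with q0 -> Inf (fully activated cells) and nu = 1 the model reduces to the
# plain logistic. The substitution w = (k/N)^nu turns the single-strain ODE
# into a linear one, giving the exact solution
#   N(t) = k * (1 + ((k/y0)^nu - 1) * exp(-nu * r * A(t)))^(-1/nu)
# with A(t) = t + (1/v) * log((q0 + e^(-v t)) / (1 + q0)).
# Trajectories therefore evaluate the closed form; the coupled two-strain
# system has no closed form and is integrated numerically.

#' Baranyi-Roberts growth parameters
#'
#' @param y0 Initial density (OD units, > 0).
#' @param r Maximum specific growth rate (per hour, > 0).
#' @param k Carrying capacity (OD units, >= y0).
#' @param nu Deceleration exponent (dimensionless, > 0); `nu = 1` gives
#'   logistic saturation.
#' @param q0 Initial physiological state (dimensionless, > 0); small values
#'   mean a long lag, large values fully activated cells.
#' @param v Adjustment rate (per hour, > 0).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(y0, r, k, nu = 1, q0, v) {
  y0 <- check_number(y0, "y0", lower = 0, allow_boundary = FALSE)
  r <- check_number(r, "r", lower = 0, allow_boundary = FALSE)
  k <- check_number(k, "k", lower = 0, allow_boundary = FALSE)
  if (k < y0) abort_arg("k", "must be >= y0")
  nu <- check_number(nu, "nu", lower = 0, allow_boundary = FALSE)
  q0 <- check_number(q0, "q0", lower = 0, allow_boundary = FALSE)
  v <- check_number(v, "v", lower = 0, allow_boundary = FALSE)
  structure(list(y0 = y0, r = r, k = k, nu = nu, q0 = q0, v = v),
            class = "growth_params")
}

#' Analytic lag time of the Baranyi-Roberts model
#'
#' `lag = log(1 + 1/q0) / v`: the time lost to the adjustment phase, i.e. the
#' horizontal offset between A(t) and t as t grows.
#'
#' @param q0 Initial physiological state (> 0).
#' @param v Adjustment rate (per hour, > 0).
#' @return Lag time in hours.
#' @export
br_lag <- function(q0, v) {
  q0 <- check_number(q0, "q0", lower = 0, allow_boundary = FALSE)
  v <- check_number(v, "v", lower = 0, allow_boundary = FALSE)
  log1p(1 / q0) / v
}

# adjusted time A(t) = integral of alpha; stable for large v*t
br_adjusted_time <- function(t, q0, v) {
  t + (log(q0 + exp(-v * t)) - log1p(q0)) / v
}

br_alpha <- function(t, q0, v) q0 / (q0 + exp(-v * t))

#' Baranyi-Roberts growth trajectory
#'
#' Evaluates the exact solution of the growth law at the requested times.
#'
#' @param params A [growth_params()] object.
#' @param times Non-negative, non-decreasing times in hours.
#' @return Numeric vector of densities (same units as `y0`).
#' @examples
#' p <- growth_params(y0 = 0.01, r = 0.8, k = 1.2, q0 = 0.05, v = 0.8)
#' br_trajectory(p, c(0, 4, 8, 24))
#' @export
br_trajectory <- function(params, times) {
  if (!inherits(params, "growth_params")) {
    abort_arg("params", "must be a growth_params object")
  }
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0)) {
    abort_arg("times", "must be finite non-negative times")
  }
  if (is.unsorted(times)) abort_arg("times", "must be non-decreasing")
  with(params, {
    capacity_gap <- expm1(nu * (log(k) - log(y0))) # (k/y0)^nu - 1 >= 0
    if (capacity_gap == 0) return(rep(k, length(times)))
    a <- br_adjusted_time(times, q0, v)
    k * exp(-log1p(capacity_gap * exp(-nu * r * a)) / nu)
  })
}

# logistic closed form, the q0 -> Inf, nu = 1 limit; used as an oracle
logistic_curve <- function(y0, r, k, times) {
  k * y0 * exp(r * times) / (k + y0 * expm1(r * times))
}

#' Fit the Baranyi-Roberts model to a growth curve
#'
#' Least-squares fit of all six parameters by Levenberg-Marquardt descent from
#' a fixed multi-start grid of data-driven initial values, so fits are
#' deterministic. Degenerate curves (flat, or not growing towards a plateau)
#' produce a fit-failure result carrying a diagnostic, never an error.
#'
#' @param curve Data frame with numeric columns `time` (hours, sorted) and
#'   `od`; at least 20 points spanning lag through saturation.
#' @return An object of class `growth_fit`: `ok`, `params` ([growth_params()]),
#'   `lag` (analytic, hours), `lag_geometric` (tangent construction, hours),
#'   `rss`, `n_points`, `diagnostic`.
#' @export
fit_growth <- function(curve) {
  if (!is.data.frame(curve) || !all(c("time", "od") %in% names(curve))) {
    abort_arg("curve", "must be a data frame with columns time, od")
  }
  curve <- curve[order(curve$time), , drop = FALSE]
  t <- as.numeric(curve$time); y <- as.numeric(curve$od)
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 20L) abort_arg("curve", "must contain at least 20 usable points")

  fail <- function(msg) {
    structure(list(ok = FALSE, params = NULL, lag = NA_real_,
                   lag_geometric = NA_real_, rss = NA_real_,
                   n_points = length(t), diagnostic = msg),
              class = "growth_fit")
  }
  y_span <- max(y) - min(y)
  if (y_span <= max(1e-8, 0.02 * max(abs(y)))) {
    return(fail("flat curve: no detectable growth"))
  }
  tail_mean <- mean(y[t >= stats::quantile(t, 0.85)])
  if (tail_mean < min(y) + 0.6 * y_span) {
    return(fail("curve does not saturate: final densities not near the maximum"))
  }
  # still accelerating at the end: late slope comparable to the peak slope
  late <- t >= stats::quantile(t, 0.85)
  slope_late <- stats::coef(stats::lm(y[late] ~ t[late]))[2]
  span <- max(3L, round(length(t) / 20))
  win <- seq_len(length(t) - span)
  slope_max <- max((y[win + span] - y[win]) / (t[win + span] - t[win]))
  if (is.finite(slope_late) && slope_late > 0.25 * slope_max) {
    return(fail("curve does not saturate: still growing at the final readings"))
  }
  if (stats::cor(t, y) < 0.3) {
    return(fail("curve is not monotone-saturating"))
  }

  # data-driven starting values
  eps <- max(1e-6, min(y[y > 0], na.rm = TRUE) * 0.5)
  y0_hat <- max(eps, mean(y[seq_len(min(3L, length(y)))]))
  k_hat <- max(y)
  logy <- log(pmax(y, eps))
  span <- max(3L, round(length(t) / 20))
  slopes <- (logy[seq_len(length(t) - span) + span] - logy[seq_len(length(t) - span)]) /
    (t[seq_len(length(t) - span) + span] - t[seq_len(length(t) - span)])
  r_hat <- max(slopes, na.rm = TRUE)
  if (!is.finite(r_hat) || r_hat <= 0) r_hat <- 1 / diff(range(t))
  rise <- which(y > y0_hat + 0.2 * (k_hat - y0_hat))
  lag_hat <- if (length(rise)) max(0.1, t[rise[1]] - log(0.2 * k_hat / y0_hat) / r_hat)
             else 0.1

  starts <- expand.grid(nu = c(0.5, 1, 2), v_mult = c(1, 2),
                        lag_mult = c(0.5, 1, 2))
  # theta holds log(y0, r, k - y0, nu, q0, v): the capacity is parameterized
  # as y0 plus a positive gap so k >= y0 throughout the descent
  residual_fun <- function(theta) {
    p <- exp(theta)
    pars <- list(y0 = p[1], r = p[2], k = p[1] + p[3], nu = p[4],
                 q0 = p[5], v = p[6])
    class(pars) <- "growth_params"
    br_trajectory(pars, t) - y
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    v0 <- r_hat * starts$v_mult[i]
    lag0 <- max(lag_hat * starts$lag_mult[i], 1e-3)
    q00 <- 1 / expm1(v0 * lag0)
    theta0 <- log(c(y0_hat, r_hat, max(k_hat - y0_hat, y0_hat * 0.01),
                    starts$nu[i], q00, v0))
    fit <- tryCatch(
      minpack.lm::nls.lm(theta0, fn = residual_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(theta = fit$par, rss = rss)
    }
  }
  if (is.null(best)) return(fail("all optimization starts failed"))

  p <- exp(best$theta)
  params <- growth_params(y0 = p[1], r = p[2], k = p[1] + p[3],
                          nu = p[4], q0 = p[5], v = p[6])
  structure(list(ok = TRUE, params = params,
                 lag = br_lag(params$q0, params$v),
                 lag_geometric = geometric_lag(params),
                 rss = best$rss, n_points = length(t), diagnostic = NULL),
            class = "growth_fit")
}

# tangent-construction lag: tangent to log N at the point of fastest log
# growth, intersected with the horizontal line log y0
geometric_lag <- function(params) {
  with(params, {
    slope_fun <- function(tt) {
      n <- br_trajectory(params, tt)
      r * br_alpha(tt, q0, v) * (1 - (n / k)^nu)
    }
    t_max <- stats::optimize(slope_fun, c(0, br_lag(q0, v) + 3 * log(k / y0) / r),
                             maximum = TRUE)$maximum
    n_star <- br_trajectory(params, t_max)
    max(0, t_max - (log(n_star) - log(y0)) / slope_fun(t_max))
  })
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!x$ok) {
    cat("growth fit FAILED:", x$diagnostic, "\n")
  } else {
    with(x$params, cat(sprintf(
      "y0 = %.4g  r = %.3f/h  k = %.3f  nu = %.3f  q0 = %.4g  v = %.3f/h\n",
      y0, r, k, nu, q0, v)))
    cat(sprintf("lag = %.3f h (geometric %.3f h), rss = %.3g on %d points\n",
                x$lag, x$lag_geometric, x$rss, x$n_points))
  }
  invisible(x)
}

#' Double-strain virtual competition over a shared nutrient pool
#'
#' Integrates the coupled Baranyi-Roberts system in which each strain grows at
#' its own rate and adjustment state but saturates against the combined
#' density scaled by its own capacity:
#' `dN_i/dt = r_i * alpha_i(t) * N_i * max(0, 1 - ((N_a + N_b)/k_i)^nu_i)`.
#' The virtual relative fitness is the ratio of realized Malthusian growth,
#' `w_virtual = log(N_a(T)/N_a(0)) / log(N_b(T)/N_b(0))`, commensurable with
#' direct serial-transfer competition fitness.
#'
#' @param params_a,params_b [growth_params()] for the two competitors.
#' @param horizon Competition duration in hours (> 0); default 24.
#' @param init_ratio Initial fraction of competitor a in the mixed culture,
#'   strictly inside (0, 1); default 0.5.
#' @param y_total Total initial density; defaults to `params_a$y0 + params_b$y0`.
#' @return A list of class `virtual_competition`: `w_virtual` (NA with
#'   `flag = "zero-growth"` when a competitor shows no net growth),
#'   `trajectories` (data frame `time`, `n_a`, `n_b`), `flag`.
#' @export
virtual_competition <- function(params_a, params_b, horizon = 24,
                                init_ratio = 0.5, y_total = NULL) {
  if (!inherits(params_a, "growth_params") || !inherits(params_b, "growth_params")) {
    abort_arg("params_a/params_b", "must be growth_params objects")
  }
  horizon <- check_number(horizon, "horizon", lower = 0, allow_boundary = FALSE)
  init_ratio <- check_number(init_ratio, "init_ratio", 0, 1, allow_boundary = FALSE)
  if (is.null(y_total)) y_total <- params_a$y0 + params_b$y0
  y_total <- check_number(y_total, "y_total", lower = 0, allow_boundary = FALSE)

  state <- c(n_a = init_ratio * y_total, n_b = (1 - init_ratio) * y_total)
  deriv <- function(t, n, parms) {
    list(c(
      params_a$r * br_alpha(t, params_a$q0, params_a$v) * n[1] *
        max(0, 1 - ((n[1] + n[2]) / params_a$k)^params_a$nu),
      params_b$r * br_alpha(t, params_b$q0, params_b$v) * n[2] *
        max(0, 1 - ((n[1] + n[2]) / params_b$k)^params_b$nu)
    ))
  }
  times <- seq(0, horizon, length.out = 201)
  sol <- deSolve::lsoda(state, times, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-12)
  traj <- data.frame(time = sol[, "time"], n_a = sol[, "n_a"], n_b = sol[, "n_b"])

  g_a <- log(traj$n_a[nrow(traj)] / traj$n_a[1])
  g_b <- log(traj$n_b[nrow(traj)] / traj$n_b[1])
  flag <- NULL
  if (abs(g_a) < 1e-6 || abs(g_b) < 1e-6) {
    w <- NA_real_
    flag <- "zero-growth"
    warning("a competitor shows no net growth over the horizon; ",
            "virtual fitness undefined", call. = FALSE)
  } else {
    w <- g_a / g_b
  }
  structure(list(w_virtual = w, trajectories = traj, flag = flag),
            class = "virtual_competition")
}

#' Concordance between direct and virtual competition fitness
#'
#' @param direct,virtual Paired numeric vectors of relative fitness values
#'   (or lists of `fitness_result` / `virtual_competition` objects), length
#'   >= 3, same length and order.
#' @return A list: `correlation` (Pearson; `NA` with a warning when either
#'   side is constant), `mean_abs_diff`, `n`.
#' @export
concordance <- function(direct, virtual) {
  pull <- function(x, field) {
    if (is.numeric(x)) return(as.numeric(x))
    vapply(x, function(el) {
      if (inherits(el, "fitness_result")) el$w_rel
      else if (inherits(el, "virtual_competition")) el$w_virtual
      else as.numeric(el)
    }, numeric(1))
  }
  d <- pull(direct); v <- pull(virtual)
  if (length(d) != length(v)) abort_arg("virtual", "must pair 1:1 with `direct`")
  if (length(d) < 3L) abort_arg("direct", "needs at least 3 paired values")
  if (stats::sd(d) < 1e-12 || stats::sd(v) < 1e-12) {
    warning("constant fitness values: correlation undefined", call. = FALSE)
    corr <- NA_real_
  } else {
    corr <- stats::cor(d, v)
  }
  list(correlation = corr, mean_abs_diff = mean(abs(d - v)), n = length(d))
}
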