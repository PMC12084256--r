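MODEL_IDS <- c(full = 0L, sqssa = 1L, slow_product = 2L, kumar_josic = 3L,
               calder_siegel = 4L, rqssa_outer = 5L, rqssa_inner = 6L)

pars_for_cpp <- function(p, m = NA_real_) {
  c(k1 = p$k1, k_neg1 = p$k_neg1, k2 = p$k2, e0 = p$e0, m = m)
}

# Reference depletion time from the closed-form sQSSA quadrature
# t(s) = (K_M log(s0/s) + s0 - s)/(k2 e0); used to size default horizons.
sqssa_time_to <- function(p, s0, s) {
  (p$K_M * log(s0 / s) + s0 - s) / (p$k2 * p$e0)
}

new_trajectory <- function(model, p, sol, s, c_, ds, dc, method, rtol,
                           atol, s_stop, complex_map = NULL) {
  dense <- sol$dense
  if (is.null(dense) || nrow(dense) == 0) dense <- NULL
  structure(list(
    model = model, params = p,
    times = as.numeric(sol$t),
    s = s, c = c_, ds = ds, dc = dc,
    dense = dense, complex_map = complex_map,
    method = method, rtol = rtol, atol = atol, s_stop = s_stop,
    n_steps = sol$n_steps, status = sol$status,
    events = list()
  ), class = "qss_trajectory")
}

#' @export
print.qss_trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory [%s]: %d nodes, t in [0, %.6g], s: %.6g -> %.6g (%s)\n",
    x$model, length(x$times), max(x$times), x$s[1], x$s[length(x$s)],
    x$method))
  invisible(x)
}

#' @export
as.data.frame.qss_trajectory <- function(x, ...) {
  data.frame(t = x$times, s = x$s, c = x$c, model = x$model)
}

#' Integrate the full mass-action system
#'
#' Adaptive integration of the planar substrate/complex dynamics with
#' error control, returning the accepted-step skeleton together with the
#' vector field at every node (which yields a C1 cubic Hermite dense
#' output used for crossing detection and resampling).
#'
#' The default horizon is 20 times the closed-form sQSSA depletion time
#' to `s_stop`, which comfortably covers the slow regime; integration
#' terminates early once `s <= s_stop` (default `1e-3 * s0`). Method
#' `"auto"` picks the explicit Dormand-Prince 5(4) pair unless the
#' product of the fast eigenvalue scale and the horizon indicates severe
#' stiffness, in which case an L-stable Rosenbrock 2(3) pair with the
#' analytic Jacobian is used.
#'
#' @param p a [rate_constants()] object.
#' @param ic initial phase state, numeric `c(s0, c0)`; must satisfy
#'   `s0 >= 0` and `0 <= c0 <= e0`.
#' @param horizon integration horizon (required when `k2 * e0 == 0`).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param s_stop early-termination substrate level.
#' @param method `"auto"`, `"dp45"` or `"ros23"`.
#' @param max_steps safety cap on accepted + rejected steps.
#' @return A `qss_trajectory` object.
#' @export
integrate_full <- function(p, ic, horizon = NULL, rtol = 1e-8,
                           atol = 1e-10, s_stop = NULL,
                           method = c("auto", "dp45", "ros23"),
                           max_steps = 5e7) {
  p <- as_rate_constants(p)
  method <- match.arg(method)
  stopifnot(length(ic) == 2, all(is.finite(ic)))
  s0 <- ic[[1]]; c0 <- ic[[2]]
  if (s0 < 0 || c0 < 0 || c0 > p$e0)
    stop("initial condition must satisfy s0 >= 0, 0 <= c0 <= e0")
  if (is.null(s_stop)) s_stop <- 1e-3 * s0
  if (is.null(horizon)) {
    if (p$k2 * p$e0 > 0 && s0 > 0) {
      horizon <- 20 * sqssa_time_to(p, s0, max(s_stop, 1e-6 * s0))
    } else stop("horizon must be supplied when k2 * e0 == 0")
  }
  if (horizon <= 0) stop("horizon must be positive")
  if (method == "auto") {
    stiffness <- p$k1 * (p$K_M + p$e0) * horizon
    method <- if (stiffness > 2e5) "ros23" else "dp45"
  }
  sol <- .ode_solve(MODEL_IDS[["full"]], pars_for_cpp(p),
                    as.numeric(ic), 0, horizon, rtol, atol, s_stop,
                    method, max_steps)
  if (sol$status != 0)
    stop(sprintf(
      "solver failure (status %d) for k1=%g k_neg1=%g k2=%g e0=%g s0=%g",
      sol$status, p$k1, p$k_neg1, p$k2, p$e0, s0))
  new_trajectory("full", p, sol, sol$y[, 1], sol$y[, 2], sol$f[, 1],
                 sol$f[, 2], method, rtol, atol, s_stop)
}

#' Integrate a reduced model
#'
#' Solves the scalar substrate equation of a reduction (or the scalar
#' complex equation for the inner reverse-QSSA piece) and reconstructs
#' the complex coordinate through the reduction's QSS curve.
#'
#' @param model a model name accepted by [reduction_model()] or a
#'   `reduction_model` object.
#' @param p a [rate_constants()] object.
#' @param s0 initial value of the integrated variable (substrate, or
#'   complex for `"rqssa_inner"`). For `"rqssa_outer"` use the substrate
#'   component of [shifted_initial_condition()] when emulating a
#'   high-enzyme launch from the s-axis.
#' @inheritParams integrate_full
#' @return A `qss_trajectory` object; for 1-D substrate reductions the
#'   `c` component is the reconstructed QSS-curve value.
#' @export
integrate_reduction <- function(model, p, s0, horizon = NULL,
                                rtol = 1e-8, atol = 1e-10, s_stop = NULL,
                                max_steps = 5e7) {
  p <- as_rate_constants(p)
  if (is.character(model)) model <- reduction_model(model, p)
  stopifnot(inherits(model, "reduction_model"))
  name <- model$name
  if (s0 < 0) stop("initial value must be nonnegative")
  if (is.null(s_stop)) s_stop <- 1e-3 * s0
  if (is.null(horizon)) {
    if (name == "rqssa_outer") {
      if (p$k2 * p$e0 <= 0) stop("horizon required when k2 * e0 == 0")
      horizon <- 1.1 * s0 / (p$k2 * p$e0)
    } else if (name == "rqssa_inner") {
      if (p$k2 <= 0) stop("horizon required when k2 == 0")
      horizon <- log(1e4) / p$k2
    } else if (p$k2 * p$e0 > 0 && s0 > 0) {
      # all substrate reductions share the sQSSA's slow timescale
      horizon <- 40 * sqssa_time_to(p, s0, max(s_stop, 1e-6 * s0))
    } else stop("horizon must be supplied when k2 * e0 == 0")
  }
  m <- if (name == "calder_siegel") origin_spectrum(p)$m else NA_real_
  sol <- .ode_solve(MODEL_IDS[[name]], pars_for_cpp(p, m), s0, 0,
                    horizon, rtol, atol, s_stop, "dp45", max_steps)
  if (sol$status != 0)
    stop(sprintf("solver failure (status %d) for reduction '%s'",
                 sol$status, name))
  sv <- sol$y[, 1]
  if (name == "rqssa_outer") sv <- pmax(sv, 0)   # clip at the hand-off
  if (name == "rqssa_inner") {
    traj <- new_trajectory(name, p, sol, rep(0, length(sv)), sv,
                           rep(0, length(sv)), sol$f[, 1],
                           "dp45", rtol, atol, s_stop)
  } else {
    cmap <- model$complex_map(sv)
    # dc/dt along the QSS curve via the chain rule where available
    dcdt <- if (name %in% c("sqssa", "kumar_josic")) {
      qss_curve("gamma_c", p)$deriv(sv) * sol$f[, 1]
    } else if (name == "slow_product") {
      qss_curve("gamma_SP", p)$deriv(sv) * sol$f[, 1]
    } else if (name == "calder_siegel") {
      qss_curve("alpha_cs", p)$deriv(sv) * sol$f[, 1]
    } else rep(0, length(sv))
    traj <- new_trajectory(name, p, sol, sv, cmap, sol$f[, 1], dcdt,
                           "dp45", rtol, atol, s_stop,
                           complex_map = model$complex_map)
  }
  traj
}

# Piecewise cubic Hermite evaluation on the accepted-step skeleton.
hermite_eval <- function(x, y, dy, xq) {
  n <- length(x)
  i <- findInterval(xq, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  h <- x[i + 1L] - x[i]
  u <- (xq - x[i]) / h
  h00 <- (1 + 2 * u) * (1 - u)^2
  h10 <- u * (1 - u)^2
  h01 <- u^2 * (3 - 2 * u)
  h11 <- u^2 * (u - 1)
  h00 * y[i] + h10 * h * dy[i] + h01 * y[i + 1L] + h11 * h * dy[i + 1L]
}

#' Dense evaluation of a trajectory
#'
#' Explicit (Dormand-Prince) trajectories carry the pair's 4th-order
#' dense-output coefficients for every accepted step, which this
#' function evaluates; for reductions the complex coordinate is
#' reconstructed through the model's QSS curve at the interpolated
#' substrate. Rosenbrock trajectories fall back to cubic Hermite
#' interpolation of the accepted-step skeleton (the stepper is 2nd
#' order, so the Hermite interpolant does not degrade accuracy).
#'
#' @param traj a `qss_trajectory`.
#' @param t_query query times inside the trajectory's time range.
#' @return A list with vectors `s` and `c` at the query times.
#' @export
trajectory_interp <- function(traj, t_query) {
  rng <- range(traj$times)
  if (any(t_query < rng[1] - 1e-12 * diff(rng)) ||
      any(t_query > rng[2] + 1e-12 * diff(rng)))
    stop("query times outside the trajectory range")
  t_query <- pmin(pmax(t_query, rng[1]), rng[2])
  if (is.null(traj$dense)) {
    return(list(s = hermite_eval(traj$times, traj$s, traj$ds, t_query),
                c = hermite_eval(traj$times, traj$c, traj$dc, t_query)))
  }
  n <- length(traj$times)
  i <- pmin(pmax(findInterval(t_query, traj$times,
                              rightmost.closed = TRUE), 1L), n - 1L)
  th <- (t_query - traj$times[i]) / (traj$times[i + 1L] - traj$times[i])
  dense_comp <- function(off) {
    r1 <- traj$dense[i, off + 1L]; r2 <- traj$dense[i, off + 2L]
    r3 <- traj$dense[i, off + 3L]; r4 <- traj$dense[i, off + 4L]
    r5 <- traj$dense[i, off + 5L]
    r1 + th * (r2 + (1 - th) * (r3 + th * (r4 + (1 - th) * r5)))
  }
  if (traj$model == "full") {
    list(s = dense_comp(0L), c = dense_comp(5L))
  } else if (traj$model == "rqssa_inner") {
    list(s = rep(0, length(t_query)), c = dense_comp(0L))
  } else {
    s <- dense_comp(0L)
    if (traj$model == "rqssa_outer") s <- pmax(s, 0)
    c_ <- if (!is.null(traj$complex_map)) traj$complex_map(s)
          else hermite_eval(traj$times, traj$c, traj$dc, t_query)
    list(s = s, c = c_)
  }
}

#' First crossing time of a phase-plane curve
#'
#' Locates the first root of \eqn{g(t) = c(t) - \gamma(s(t))} along a
#' trajectory by scanning the accepted-step skeleton for a sign change
#' and refining with bracketed root-finding on the dense interpolant.
#'
#' @param traj a `qss_trajectory` (full model, or a reduction with a
#'   reconstructed complex coordinate).
#' @param curve a [qss_curve()] object (or a curve name).
#' @param t_tol absolute time tolerance of the refinement; defaults to
#'   `1e-9` times the trajectory horizon.
#' @return The crossing time (0 when the trajectory starts on the
#'   curve), or `NA_real_` if the curve is never crossed.
#' @export
find_crossing <- function(traj, curve, t_tol = NULL) {
  if (is.character(curve)) curve <- qss_curve(curve, traj$params)
  horizon <- max(traj$times)
  if (is.null(t_tol)) t_tol <- 1e-9 * horizon
  g_nodes <- traj$c - curve$value(traj$s)
  if (g_nodes[1] == 0) return(traj$times[1])
  idx <- which(g_nodes[-1] * g_nodes[-length(g_nodes)] <= 0)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  g <- function(t) {
    st <- trajectory_interp(traj, t)
    st$c - curve$value(st$s)
  }
  stats::uniroot(g, c(traj$times[i], traj$times[i + 1L]),
                 f.lower = g_nodes[i], f.upper = g_nodes[i + 1L],
                 tol = t_tol)$root
}

#' Trajectory error metrics on the substrate component
#'
#' Resamples two trajectories on a common uniform time grid inside a
#' window and reports the maximum absolute error, maximum relative error
#' (with a floor of `1e-6 * s0` in the denominator to avoid blow-up at
#' depletion) and the root-mean-square (L2) error of `s(t)`.
#'
#' @param full,reduced `qss_trajectory` objects (any two trajectories).
#' @param window time interval `c(t1, t2)`; defaults to the overlap of
#'   the two time ranges.
#' @param n_grid number of resampling points.
#' @return A list with `max_abs`, `max_rel`, `l2`, `window`, `n_grid`.
#' @export
error_metrics <- function(full, reduced, window = NULL, n_grid = 2001) {
  t_max <- min(max(full$times), max(reduced$times))
  t_min <- max(min(full$times), min(reduced$times))
  if (is.null(window)) window <- c(t_min, t_max)
  window <- c(max(window[1], t_min), min(window[2], t_max))
  if (!(window[2] > window[1])) stop("empty comparison window")
  tq <- seq(window[1], window[2], length.out = n_grid)
  s_f <- trajectory_interp(full, tq)$s
  s_r <- trajectory_interp(reduced, tq)$s
  d <- s_r - s_f
  s0 <- full$s[1]
  denom <- pmax(abs(s_f), 1e-6 * s0)
  list(max_abs = max(abs(d)), max_rel = max(abs(d) / denom),
       l2 = sqrt(mean(d^2)), window = window, n_grid = n_grid)
}

#' Check rigorous substrate-rate bounds along a trajectory
#'
#' Verifies, pointwise along a full-model trajectory, the proved
#' envelopes on the substrate depletion rate in the slow regime:
#' \itemize{
#'   \item `"prop1"`: sQSSA rate \eqn{\le \dot s \le} Calder-Siegel
#'     rate, for \eqn{t \ge t_{cross}} (crossing of the c-nullcline);
#'   \item `"prop2"`: sQSSA rate \eqn{\le \dot s \le} Kumar-Josic rate,
#'     for \eqn{t \ge t_{cross}};
#'   \item `"eq67"`: sQSSA rate \eqn{\le} slow-product rate
#'     \eqn{\le \dot s \le} Kumar-Josic rate, for
#'     \eqn{t \ge t_{cross\_sp}} (crossing of the slow-product QSS
#'     curve) while \eqn{s \le s^*}; requires `e0 > K` and
#'     `e0 < 8*K_S`.
#' }
#' \eqn{\dot s} is evaluated exactly from the mass-action vector field
#' at each output node. A floating-point slack of `1e-8` times the local
#' envelope width is allowed.
#'
#' @param traj a full-model `qss_trajectory`.
#' @param p a [rate_constants()] object (defaults to the trajectory's).
#' @param which `"prop1"`, `"prop2"` or `"eq67"`.
#' @param slack_factor slack relative to the local envelope width.
#' @return A list with `which`, `t_start`, `n_checked`, `n_violations`,
#'   and a data frame `violations` (t, s, sdot, lower, upper).
#' @export
rate_bound_check <- function(traj, p = traj$params,
                             which = c("prop2", "prop1", "eq67"),
                             slack_factor = 1e-8) {
  which <- match.arg(which)
  p <- as_rate_constants(p)
  if (p$e0 == 0) {
    return(list(which = which, t_start = 0,
                n_checked = length(traj$times), n_violations = 0L,
                violations = data.frame()))
  }
  t_cross <- find_crossing(traj, qss_curve("gamma_c", p))
  if (is.na(t_cross)) stop("trajectory never crosses gamma_c; no window")
  if (which == "eq67") {
    if (!(p$e0 > p$K)) stop("eq67 applies only when e0 > K")
    if (!(p$e0 < 8 * p$K_S)) stop("eq67 requires e0 < 8*K_S")
    t_start <- find_crossing(traj, qss_curve("gamma_SP", p))
    if (is.na(t_start)) stop("trajectory never crosses gamma_SP")
  } else t_start <- t_cross

  sel <- traj$times >= t_start
  s <- traj$s[sel]; c_ <- traj$c[sel]; tt <- traj$times[sel]
  if (which == "eq67") {
    keep <- s <= s_star(p)
    s <- s[keep]; c_ <- c_[keep]; tt <- tt[keep]
  }
  sdot <- mass_action_rhs(s, c_, p)$ds
  lower <- sqssa_rhs(s, p)
  upper <- switch(which,
    prop1 = calder_siegel_rhs(s, p),
    prop2 = kumar_josic_rhs(s, p),
    eq67 = kumar_josic_rhs(s, p))
  slack <- slack_factor * pmax(upper - lower, .Machine$double.eps)
  bad <- sdot < lower - slack | sdot > upper + slack
  if (which == "eq67") {
    sp <- slow_product_rhs(s, p)$ds
    bad <- bad | sdot < sp - slack | lower > sp + slack
  }
  list(which = which, t_start = t_start, n_checked = length(s),
       n_violations = sum(bad),
       violations = data.frame(t = tt[bad], s = s[bad], sdot = sdot[bad],
                               lower = lower[bad], upper = upper[bad]))
}

#' Serialize a trajectory
#'
#' @param traj a `qss_trajectory`.
#' @param file output path; `.csv` writes the `(t, s, c, model)` table,
#'   `.json` writes the table together with parameters and events.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  if (grepl("\\.json$", file)) {
    payload <- list(model = traj$model,
                    params = unclass(traj$params),
                    events = traj$events,
                    t = traj$times, s = traj$s, c = traj$c)
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  }
  invisible(file)
}
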