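#' Closed-form geometric-series bound factors
#'
#' The slow-regime envelope on the substrate rate contracts the sQSSA
#' rate by the factor \eqn{1/(1+\varepsilon_{RS})} in the low-enzyme
#' regime (\eqn{\varepsilon_{RS} < 1}, where the alternating series
#' \eqn{\sum (-1)^j \varepsilon_{RS}^j} converges) and by
#' \eqn{1/(1+\varepsilon_{RS}^{-1})} in the high-enzyme regime
#' (\eqn{\varepsilon_{RS} > 1}), where the sharper factor
#' \eqn{1/(1+\mu)} with \eqn{\mu = \varepsilon_{RS}/(1+\varepsilon_{RS})^2}
#' applies on \eqn{s \in [e_0, s_0]}.
#'
#' @param p a [rate_constants()] object.
#' @param regime `"low_enzyme"` or `"high_enzyme"`.
#' @return A list with `factor` (the series closed form), `eps_RS`, and
#'   for the high-enzyme regime also `mu` and `mu_factor = 1/(1+mu)`.
#' @export
series_bound_factor <- function(p, regime = c("low_enzyme",
                                              "high_enzyme")) {
  p <- as_rate_constants(p)
  regime <- match.arg(regime)
  eps <- indicators(p)$eps_RS
  if (eps == 1) stop("eps_RS = 1: both geometric series diverge")
  if (regime == "low_enzyme") {
    if (eps > 1) stop("low_enzyme regime requires eps_RS < 1")
    list(factor = 1 / (1 + eps), eps_RS = eps)
  } else {
    if (eps < 1) stop("high_enzyme regime requires eps_RS > 1")
    mu <- eps / (1 + eps)^2
    list(factor = 1 / (1 + 1 / eps), eps_RS = eps, mu = mu,
         mu_factor = 1 / (1 + mu))
  }
}

#' Slope gaps of the QSS curves at the origin
#'
#' Near the stationary point, trajectories approach along the slow
#' eigenvector of slope `m`; the error of a QSS curve as a local
#' approximation is measured by the gap between `m` and the curve's
#' slope at the origin. The slow-product QSS curve satisfies
#' \eqn{\gamma_{SP}'(0) < m} always, and
#' \eqn{m - \gamma_{SP}'(0) < m - \gamma_c'(0)} exactly when
#' \eqn{e_0 > K} (the two gaps coincide at \eqn{e_0 = K}).
#'
#' @param p a [rate_constants()] object with `e0 > 0`.
#' @return A list with `m`, `gc_slope`, `gsp_slope`, `sqssa_gap`
#'   (`m - gc_slope`), `sp_gap` (`m - gsp_slope`), and
#'   `sp_closer` (TRUE iff `sp_gap < sqssa_gap`).
#' @export
slope_error_comparison <- function(p) {
  p <- as_rate_constants(p)
  if (p$e0 <= 0) stop("requires e0 > 0")
  m <- origin_spectrum(p)$m
  gc_slope <- qss_curve("gamma_c", p)$deriv(0)
  gsp_slope <- qss_curve("gamma_SP", p)$deriv(0)
  list(m = m, gc_slope = gc_slope, gsp_slope = gsp_slope,
       sqssa_gap = m - gc_slope, sp_gap = m - gsp_slope,
       sp_closer = (m - gsp_slope) < (m - gc_slope))
}

#' Empirical predominance ranking of reduced models
#'
#' Integrates the full mass-action system and each requested reduction,
#' then ranks the reductions by maximum relative substrate error over a
#' slow-regime window. Reductions are launched either from the same
#' initial substrate as the full model at `t = 0` (`start = "t0"`, the
#' figure-reproduction convention) or from the full model's state at the
#' c-nullcline crossing (`start = "cross"`). The window is
#' `[t_cross, end]` (`window_mode = "cross"`) or
#' `[t_cross_sp, end]` (`window_mode = "late"`, requiring the trajectory
#' to cross the slow-product QSS curve).
#'
#' @param p a [rate_constants()] object.
#' @param s0 initial substrate concentration.
#' @param models character vector of reduction names.
#' @param window_mode `"cross"` or `"late"`.
#' @param start `"t0"` or `"cross"`.
#' @param rtol,atol solver tolerances.
#' @param full optionally a precomputed full-model trajectory.
#' @return A list with `ranking` (data frame: model, max_rel, max_abs,
#'   l2, ordered by max_rel), `winner`, `t_cross`, `t_cross_sp`,
#'   `window`, and `full` (the trajectory).
#' @export
predominance_experiment <- function(p, s0,
                                    models = c("sqssa", "slow_product"),
                                    window_mode = c("cross", "late"),
                                    start = c("t0", "cross"),
                                    rtol = 1e-8, atol = 1e-10,
                                    full = NULL) {
  p <- as_rate_constants(p)
  window_mode <- match.arg(window_mode)
  start <- match.arg(start)
  if (length(models) < 1) stop("at least one model is required")
  if (is.null(full))
    full <- integrate_full(p, c(s0, 0), rtol = rtol, atol = atol)
  t_cross <- find_crossing(full, qss_curve("gamma_c", p))
  t_cross_sp <- if (window_mode == "late" || p$e0 < 8 * p$K_S) {
    tryCatch(find_crossing(full, qss_curve("gamma_SP", p)),
             error = function(e) NA_real_)
  } else NA_real_
  t_lo <- if (window_mode == "late") {
    if (is.na(t_cross_sp))
      stop("window_mode 'late' requires a gamma_SP crossing")
    t_cross_sp
  } else {
    if (is.na(t_cross)) stop("trajectory never crosses gamma_c")
    t_cross
  }
  launch_s <- if (start == "t0") s0 else trajectory_interp(full, t_cross)$s
  t_offset <- if (start == "t0") 0 else t_cross

  rows <- lapply(models, function(nm) {
    red <- integrate_reduction(nm, p, launch_s, rtol = rtol, atol = atol,
                               s_stop = full$s_stop)
    if (t_offset > 0) red$times <- red$times + t_offset
    met <- error_metrics(full, red, window = c(t_lo, Inf))
    data.frame(model = nm, max_rel = met$max_rel, max_abs = met$max_abs,
               l2 = met$l2)
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(ranking$max_rel), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking, winner = ranking$model[1],
       t_cross = t_cross, t_cross_sp = t_cross_sp,
       window = c(t_lo, min(max(full$times), Inf)), full = full)
}

#' Full validity report for a parameter set
#'
#' Aggregates the dimensionless indicators, threshold-based condition
#' verdicts, optional rigorous bound checks along a full-model
#' trajectory, and an optional empirical predominance ranking. Every
#' verdict is reported together with its raw ratio, since the sharp
#' inequalities of the theory ("much less than") are operationalized by
#' the configurable threshold `theta`.
#'
#' @param p a [rate_constants()] object.
#' @param s0 initial substrate concentration.
#' @param theta threshold in (0, 1) operationalizing "much less than".
#' @param run_bounds logical; run the Proposition-2 envelope check.
#' @param run_ranking logical; run the empirical predominance ranking.
#' @param models reductions to rank when `run_ranking` is TRUE.
#' @param rtol,atol solver tolerances for the numerical stages.
#' @return An object of class `validity_report`.
#' @export
validity_report <- function(p, s0, theta = 0.1, run_bounds = FALSE,
                            run_ranking = FALSE,
                            models = c("sqssa", "slow_product"),
                            rtol = 1e-8, atol = 1e-10) {
  p <- as_rate_constants(p)
  if (!(theta > 0 && theta < 1)) stop("theta must lie in (0, 1)")
  ind <- indicators(p)
  conditions <- list(
    reich_selkov = list(ratio = ind$eps_RS, holds = ind$eps_RS <= theta),
    predominance = list(ratio = ind$eps_K, holds = ind$eps_K <= theta,
                        strict = p$e0 < p$K),
    gamma_sp_fence = list(ratio = if (p$K_S > 0) p$e0 / (8 * p$K_S)
                                  else Inf,
                          holds = p$e0 < 8 * p$K_S),
    timescale = list(ratio = ind$node_disc, holds = ind$node_disc <= theta),
    high_enzyme = list(ratio = if (p$e0 > 0) p$K_M / p$e0 else Inf,
                       holds = p$e0 > 0 && p$K_M / p$e0 <= theta)
  )
  sstar <- if (p$k2 > 0) s_star(p) else NA_real_

  bound_results <- NULL
  ranking <- NULL
  full <- NULL
  if (run_bounds || run_ranking) {
    full <- integrate_full(p, c(s0, 0), rtol = rtol, atol = atol)
  }
  if (run_bounds) bound_results <- rate_bound_check(full, p, "prop2")
  if (run_ranking) {
    ranking <- predominance_experiment(p, s0, models, rtol = rtol,
                                       atol = atol, full = full)
  }

  verdict <- if (p$k2 == 0) {
    "slow_product"   # sQSSA rate is identically zero; flag the alternative
  } else if (conditions$predominance$holds) {
    "sqssa"
  } else if (!is.null(ranking)) {
    ranking$winner
  } else if (p$e0 < p$K) "sqssa" else "slow_product"

  out <- list(params = p, s0 = s0, theta = theta, indicators = ind,
              conditions = conditions, s_star = sstar,
              bound_results = bound_results,
              ranking = if (!is.null(ranking)) ranking$ranking else NULL,
              verdict = verdict)
  class(out) <- "validity_report"
  out
}

#' @export
print.validity_report <- function(x, ...) {
  cat("QSSA validity report\n")
  print(x$params)
  cat(sprintf("  s0 = %g, theta = %g\n", x$s0, x$theta))
  cat("indicators:\n")
  for (nm in names(x$indicators))
    cat(sprintf("  %-10s = %.6g\n", nm, x$indicators[[nm]]))
  cat("conditions (ratio vs theta):\n")
  for (nm in names(x$conditions)) {
    cn <- x$conditions[[nm]]
    cat(sprintf("  %-14s ratio = %.6g  -> %s\n", nm, cn$ratio,
                if (isTRUE(cn$holds)) "holds" else "fails"))
  }
  if (!is.na(x$s_star))
    cat(sprintf("  s* = %.6g\n", x$s_star))
  if (!is.null(x$bound_results))
    cat(sprintf("bound check (%s): %d / %d points violate\n",
                x$bound_results$which, x$bound_results$n_violations,
                x$bound_results$n_checked))
  if (!is.null(x$ranking)) {
    cat("empirical ranking (max relative substrate error):\n")
    print(x$ranking)
  }
  cat(sprintf("verdict: %s\n", x$verdict))
  invisible(x)
}

#' Serialize a validity report to JSON
#'
#' @param x a `validity_report`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_validity_report <- function(x, file) {
  payload <- list(params = unclass(x$params), s0 = x$s0, theta = x$theta,
                  indicators = x$indicators, conditions = x$conditions,
                  s_star = x$s_star, verdict = x$verdict)
  if (!is.null(x$ranking)) payload$ranking <- x$ranking
  if (!is.null(x$bound_results))
    payload$bound_check <- x$bound_results[c("which", "n_checked",
                                             "n_violations")]
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(file)
}

#' Empirical predominance map over a ratio grid
#'
#' Sweeps a log-spaced grid of the two governing ratios
#' (`e0/K_M`, `e0/K`) with `k1` and `e0` fixed, runs the empirical
#' predominance experiment (sQSSA vs slow-product QSSA) in every
#' feasible cell, and compares the empirical winner with the theoretical
#' rule "sQSSA predominates iff `e0 < K`". Cells with `e0/K < e0/K_M`
#' are infeasible (they would need `K > K_M`) and are skipped. A cell is
#' inside the rule's stated domain when `e0/K_M < 0.3` and
#' `|log(e0/K)| > log(2)`.
#'
#' @param n1,n2 grid sizes for `e0/K_M` and `e0/K`.
#' @param range1,range2 log10 ranges of the two ratios.
#' @param e0,k1,s0 fixed quantities defining each cell's rate constants.
#' @param rtol,atol solver tolerances.
#' @return A data frame, one row per cell, with the ratios, kinetic
#'   constants, feasibility/domain flags, empirical winner, the rule's
#'   prediction, and agreement.
#' @export
predominance_map <- function(n1 = 20, n2 = 20,
                             range1 = c(-3, -0.3), range2 = c(-2, 2),
                             e0 = 1, k1 = 1, s0 = 10,
                             rtol = 1e-8, atol = 1e-10) {
  r1 <- 10^seq(range1[1], range1[2], length.out = n1)  # e0/K_M
  r2 <- 10^seq(range2[1], range2[2], length.out = n2)  # e0/K
  grid <- expand.grid(eps_RS = r1, eps_K = r2)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    eps_RS <- grid$eps_RS[i]; eps_K <- grid$eps_K[i]
    K_M <- e0 / eps_RS; K <- e0 / eps_K
    feasible <- K <= K_M
    in_domain <- feasible && eps_RS < 0.3 && abs(log(eps_K)) > log(2)
    row <- data.frame(eps_RS = eps_RS, eps_K = eps_K, K_M = K_M, K = K,
                      k2 = K * k1, k_neg1 = (K_M - K) * k1,
                      feasible = feasible, in_domain = in_domain,
                      winner = NA_character_, rule = NA_character_,
                      agree = NA, err_sqssa = NA_real_,
                      err_slow_product = NA_real_)
    if (!feasible) return(row)
    p <- rate_constants(k1, (K_M - K) * k1, K * k1, e0)
    res <- tryCatch(
      predominance_experiment(p, s0, c("sqssa", "slow_product"),
                              rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(res)) return(row)
    row$winner <- res$winner
    row$rule <- if (e0 < K) "sqssa" else "slow_product"
    row$agree <- row$winner == row$rule
    row$err_sqssa <-
      res$ranking$max_rel[res$ranking$model == "sqssa"]
    row$err_slow_product <-
      res$ranking$max_rel[res$ranking$model == "slow_product"]
    row
  })
  do.call(rbind, rows)
}
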