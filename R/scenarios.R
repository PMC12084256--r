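#' Construct a named scenario
#'
#' A scenario bundles a parameter set, an initial condition on the
#' s-axis and a regime tag, and is the unit the simulation and validity
#' layers consume.
#'
#' @param label scenario label.
#' @param p a [rate_constants()] object.
#' @param s0 initial substrate concentration.
#' @param c0 initial complex concentration (0 for s-axis launches).
#' @param regime regime tag.
#' @param seed integer seed for sampled scenarios, or NULL.
#' @return An object of class `qss_scenario`.
#' @export
scenario <- function(label, p, s0, c0 = 0, regime = "fixture",
                     seed = NULL) {
  p <- as_rate_constants(p)
  structure(list(label = label, params = p, s0 = s0, c0 = c0,
                 regime = regime, seed = seed),
            class = "qss_scenario")
}

#' @export
print.qss_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' [%s]: s0 = %g, c0 = %g\n", x$label,
              x$regime, x$s0, x$c0))
  print(x$params)
  invisible(x)
}

#' Registry of figure-caption parameter fixtures
#'
#' Returns the verbatim parameter sets used in the reference numerical
#' experiments: the large-dissociation ambiguity pair (fig1), the
#' nullcline trapping-region set with six s-axis launches (fig2, shared
#' by fig3), the four slow-product/c-nullcline intersection panels
#' (fig4), the slow-product trapping-region launches (fig5), and the
#' predominance comparison pair (fig6).
#'
#' @return A named list of [scenario()] objects (17 scenarios).
#' @export
figure_fixtures <- function() {
  fx <- list()
  add <- function(label, k1, k_neg1, k2, e0, s0, regime) {
    fx[[label]] <<- scenario(label, rate_constants(k1, k_neg1, k2, e0),
                             s0 = s0, regime = regime)
  }
  add("fig1_left", 1, 100, 1, 10, 10, "large_k_neg1")
  add("fig1_right", 1, 500, 1, 10, 10, "large_k_neg1")
  for (s0 in 1:6)
    add(sprintf("fig2_s0_%d", s0), 1, 1, 1, 6, s0, "trapping")
  add("fig4_top_left", 0.1, 1, 1, 6, 10, "e0_lt_K")
  add("fig4_top_right", 0.1, 1, 0.6, 6, 10, "e0_eq_K")
  add("fig4_bottom_left", 1, 1, 1, 6, 10, "e0_gt_K")
  add("fig4_bottom_right", 1, 1, 0.4, 6, 10, "e0_gt_K")
  for (s0 in c(2, 6, 12))
    add(sprintf("fig5_s0_%d", s0), 1, 1, 1, 6, s0, "sp_trapping")
  add("fig6_left", 1, 100, 10, 6, 9, "predominant_sqssa")
  add("fig6_right", 1, 100, 4, 6, 9, "predominant_slow_product")
  fx
}

#' Look up a figure fixture by label
#'
#' @param label a fixture label, e.g. `"fig6_left"`; `"fig2"`, `"fig3"`
#'   and `"fig5"` resolve to the largest-`s0` member of their family.
#' @return A [scenario()] object.
#' @export
get_fixture <- function(label) {
  fx <- figure_fixtures()
  alias <- c(fig2 = "fig2_s0_6", fig3 = "fig2_s0_6", fig5 = "fig5_s0_12")
  if (label %in% names(alias)) label <- alias[[label]]
  if (!label %in% names(fx))
    stop(sprintf("unknown fixture '%s'; see names(figure_fixtures())",
                 label))
  fx[[label]]
}

# Regime membership predicates. The margin factor 10 operationalizes
# "much less than" at sampling time (distinct from the reporting
# threshold theta).
regime_predicates <- list(
  reich_selkov = function(p, s0) p$e0 <= p$K_M / 10,
  predominant_sqssa = function(p, s0) p$e0 <= p$K / 10,
  slow_product = function(p, s0) p$K < p$e0 && p$e0 < 8 * p$K_S,
  high_enzyme = function(p, s0) 10 * p$K_M <= p$e0 && p$e0 <= s0,
  large_k_neg1 = function(p, s0)
    p$k_neg1 >= 10 * p$k1 * p$e0 && p$k_neg1 >= 10 * p$k2
)

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample scenarios from a named parameter regime
#'
#' Draws rate constants log-uniformly on `[1e-2, 1e2]` (and `e0`, `s0`
#' likewise) and keeps draws satisfying the regime's defining
#' inequalities, by rejection. Sharp inequalities ("much less than") are
#' enforced with a margin factor of 10; ordinary inequalities strictly.
#' If the rejection cap is hit the ranges are widened tenfold and
#' sampling restarts (at most twice) before failing.
#'
#' @param regime one of `"reich_selkov"`, `"predominant_sqssa"`,
#'   `"slow_product"`, `"high_enzyme"`, `"large_k_neg1"`.
#' @param n number of scenarios.
#' @param seed integer seed; the draw is deterministic given the seed
#'   and the caller's RNG state is left untouched.
#' @param cap rejection cap per widening round.
#' @return A list of `n` [scenario()] objects, each passing its regime
#'   predicate.
#' @export
sample_regime <- function(regime, n, seed, cap = 10000) {
  if (!regime %in% names(regime_predicates))
    stop(sprintf("unknown regime '%s'", regime))
  pred <- regime_predicates[[regime]]
  stopifnot(n >= 1)
  with_preserved_seed(seed, {
    out <- vector("list", n)
    got <- 0L
    widen <- 0
    lo <- 1e-2; hi <- 1e2
    tries <- 0L
    while (got < n) {
      if (tries >= cap) {
        widen <- widen + 1
        if (widen > 2) stop("rejection sampling failed for regime ",
                            regime)
        lo <- lo / 10; hi <- hi * 10
        tries <- 0L
      }
      tries <- tries + 1L
      draw <- exp(stats::runif(5, log(lo), log(hi)))
      p <- rate_constants(draw[1], draw[2], draw[3], draw[4])
      s0 <- draw[5]
      if (regime == "high_enzyme" && s0 < p$e0) s0 <- p$e0 * (1 + draw[5])
      if (isTRUE(pred(p, s0))) {
        got <- got + 1L
        out[[got]] <- scenario(sprintf("%s_%03d", regime, got), p, s0,
                               regime = regime, seed = seed)
      }
    }
    out
  })
}

#' Synthetic noisy progress curve
#'
#' Subsamples the substrate component of a trajectory on a uniform time
#' grid and applies multiplicative log-normal noise,
#' \eqn{s_{obs} = s \exp(\sigma Z)}. The noise model is a package
#' convention for generating synthetic observation data (no noise model
#' is prescribed by the theory); it is intended only for exercising
#' downstream tooling, not for inference.
#'
#' @param traj a `qss_trajectory`.
#' @param sigma log-scale noise level, nonnegative.
#' @param seed integer seed.
#' @param n number of observation times.
#' @return A data frame with columns `t`, `s_true`, `s_obs`.
#' @export
noisy_progress_curve <- function(traj, sigma, seed, n = 100) {
  stopifnot(sigma >= 0, n >= 1)
  tq <- seq(min(traj$times), max(traj$times), length.out = n)
  s_true <- trajectory_interp(traj, tq)$s
  s_obs <- with_preserved_seed(seed,
    s_true * exp(stats::rnorm(n, 0, sigma)))
  data.frame(t = tq, s_true = s_true, s_obs = s_obs)
}
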