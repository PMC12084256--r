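#' Phase-plane QSS curves, nullclines and fences
#'
#' Constructs one of the five named curves in the (s, c) phase plane,
#' each with a closed-form value and analytic derivative:
#' \itemize{
#'   \item `gamma_c`: the c-nullcline \eqn{c = e_0 s/(K_M+s)} (the sQSS
#'     curve and upper fence of the trapping regions);
#'   \item `gamma_s`: the s-nullcline \eqn{c = e_0 s/(K_S+s)}, also the
#'     critical manifold of the slow-product scenario;
#'   \item `alpha_cs`: the Calder-Siegel lower fence
#'     \eqn{c = m e_0 s/(e_0 + m s)}, tangent to the slow eigenvector at
#'     the origin (\eqn{\alpha_{cs}'(0) = m});
#'   \item `gamma`: the refined lower fence
#'     \eqn{\gamma(s) = \frac{e_0 s}{K_S+s} -
#'       \frac{k_2 e_0 s (K_M+s)}{k_1 (K_S+s)(K_M e_0 + (K_M+s)^2)};}
#'   \item `gamma_SP`: the slow-product QSS curve
#'     \eqn{\gamma_{SP}(s) = \frac{e_0 s}{K_S+s} -
#'       \frac{k_2 e_0 s}{k_1 (K_S e_0 + (K_S+s)^2)}.}
#' }
#' Derivatives are analytic closed forms (never finite differences) so
#' fence-sign checks are free of discretization error.
#'
#' @param name one of `"gamma_c"`, `"gamma_s"`, `"alpha_cs"`, `"gamma"`,
#'   `"gamma_SP"`.
#' @param p a [rate_constants()] object.
#' @return An object of class `curve_spec`: list with `name`,
#'   `value(s)`, `deriv(s)`, `params`, and `validity` (a string
#'   describing a parameter condition attached to the curve's fence
#'   role, or NULL).
#' @export
qss_curve <- function(name, p) {
  p <- as_rate_constants(p)
  name <- match.arg(name, c("gamma_c", "gamma_s", "alpha_cs",
                            "gamma", "gamma_SP"))
  e0 <- p$e0; k1 <- p$k1; k2 <- p$k2
  K_M <- p$K_M; K_S <- p$K_S
  spec <- switch(name,
    gamma_c = list(
      value = function(s) e0 * s / (K_M + s),
      deriv = function(s) e0 * K_M / (K_M + s)^2,
      validity = NULL),
    gamma_s = list(
      value = function(s) e0 * s / (K_S + s),
      deriv = function(s) e0 * K_S / (K_S + s)^2,
      validity = NULL),
    alpha_cs = {
      if (e0 <= 0) stop("alpha_cs requires e0 > 0")
      m <- origin_spectrum(p)$m
      list(
        value = function(s) m * e0 * s / (e0 + m * s),
        deriv = function(s) m * e0^2 / (e0 + m * s)^2,
        validity = NULL)
    },
    gamma = list(
      value = function(s) {
        Q <- K_M * e0 + (K_M + s)^2
        e0 * s / (K_S + s) -
          k2 * e0 * s * (K_M + s) / (k1 * (K_S + s) * Q)
      },
      deriv = function(s) {
        Q <- K_M * e0 + (K_M + s)^2
        A <- e0 * s * (K_M + s)          # numerator of correction / (k2/k1)
        B <- (K_S + s) * Q
        dA <- e0 * (K_M + 2 * s)
        dB <- Q + (K_S + s) * 2 * (K_M + s)
        e0 * K_S / (K_S + s)^2 - (k2 / k1) * (dA * B - A * dB) / B^2
      },
      validity = NULL),
    gamma_SP = list(
      value = function(s) {
        R <- K_S * e0 + (K_S + s)^2
        e0 * s / (K_S + s) - k2 * e0 * s / (k1 * R)
      },
      deriv = function(s) {
        R <- K_S * e0 + (K_S + s)^2
        e0 * K_S / (K_S + s)^2 -
          (k2 * e0 / k1) * (R - s * 2 * (K_S + s)) / R^2
      },
      validity = "upper fence of Gamma_SP proven only for e0 < 8*K_S")
  )
  spec$name <- name
  spec$params <- p
  class(spec) <- "curve_spec"
  spec
}

#' @export
print.curve_spec <- function(x, ...) {
  cat(sprintf("phase-plane curve '%s'", x$name))
  if (!is.null(x$validity)) cat(" [", x$validity, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Intersection of the slow-product QSS curve with the c-nullcline
#'
#' The curves \eqn{\gamma_{SP}} and \eqn{\gamma_c} intersect (besides at
#' the origin) at the substrate coordinate
#' \deqn{s^* = \frac{k_{-1}}{k_2}\,(e_0 - K).}
#' \eqn{s^*} is positive iff \eqn{e_0 > K}; when \eqn{e_0 < K} the
#' intersection lies outside the first quadrant and is inconsequential.
#'
#' @param p a [rate_constants()] object with `k2 > 0`.
#' @return The (possibly negative) intersection coordinate.
#' @export
s_star <- function(p) {
  p <- as_rate_constants(p)
  if (p$k2 <= 0) stop("s_star is undefined for k2 = 0")
  (p$k_neg1 / p$k2) * (p$e0 - p$K)
}

#' Fence residual of a curve against the mass-action flow
#'
#' For a curve \eqn{c = \gamma(s)} the signed residual
#' \deqn{r(s) = \dot c(s, \gamma(s)) - \gamma'(s)\, \dot s(s, \gamma(s))}
#' measures which way the planar vector field crosses the curve: a
#' strong lower fence of an anti-funnel (in the substrate-decreasing
#' flow direction) has \eqn{r(s) < 0} everywhere, a strong upper fence
#' has \eqn{r(s) > 0}. The residual vanishes identically at \eqn{s = 0},
#' so grids must be strictly positive.
#'
#' The residual decays much faster than the terms composing it as
#' \eqn{s \to \infty} (the fences converge to the slow manifold), so its
#' floating-point sign is only meaningful down to roundoff of the
#' largest intermediate term; `detail = TRUE` additionally returns that
#' conditioning scale so callers can apply a noise floor.
#'
#' @param curve a [qss_curve()] object.
#' @param p a [rate_constants()] object.
#' @param s_grid strictly positive substrate grid.
#' @param detail logical; return a data frame with the conditioning
#'   scale instead of a bare vector.
#' @return Numeric vector of residuals, one per grid point; or, with
#'   `detail = TRUE`, a data frame with columns `s`, `residual`,
#'   `scale`.
#' @export
fence_residual <- function(curve, p, s_grid, detail = FALSE) {
  p <- as_rate_constants(p)
  if (any(s_grid <= 0)) stop("s_grid must be strictly positive")
  cc <- curve$value(s_grid)
  f <- mass_action_rhs(s_grid, cc, p)
  dv <- curve$deriv(s_grid)
  r <- f$dc - dv * f$ds
  if (!detail) return(r)
  # roundoff enters through k1*s*fl(c) with fl(c) accurate to eps*e0,
  # so the conditioning scale uses e0, not the cancelled (e0 - c)
  scale <- p$k1 * p$e0 * s_grid + (p$k_neg1 + p$k2) * abs(cc) +
    abs(dv * f$ds)
  data.frame(s = s_grid, residual = r, scale = scale)
}

#' Default logarithmic substrate grid
#'
#' Log-spaced on `(s_min, s_max]` with
#' `s_min = 1e-6 * max(K_M, e0, 1)` and
#' `s_max = 10 * max(s0, K_M, e0)`; zero excluded because every fence
#' residual vanishes there.
#'
#' @param p a [rate_constants()] object.
#' @param s0 reference initial substrate concentration.
#' @param n number of grid points.
#' @return Increasing numeric vector of length `n`.
#' @export
default_s_grid <- function(p, s0 = 1, n = 200) {
  p <- as_rate_constants(p)
  s_min <- 1e-6 * max(p$K_M, p$e0, 1)
  s_max <- 10 * max(s0, p$K_M, p$e0)
  exp(seq(log(s_min), log(s_max), length.out = n))
}

#' Anti-funnel (trapping region) between two fence curves
#'
#' Builds one of the named phase-plane regions bounded below and above
#' by fence curves:
#' \itemize{
#'   \item `Gamma`: between the c-nullcline and the s-nullcline
#'     (positively invariant; every trajectory from the s-axis enters);
#'   \item `Gamma_cs`: between the c-nullcline and the Calder-Siegel
#'     fence `alpha_cs`;
#'   \item `Gamma_0`: between the c-nullcline and `gamma` (a narrowing
#'     anti-funnel containing the unique slow manifold);
#'   \item `Gamma_SP`: between the slow-product QSS curve `gamma_SP` and
#'     `gamma`; requires `e0 < 8*K_S` for the fence property.
#' }
#'
#' @param name one of `"Gamma"`, `"Gamma_cs"`, `"Gamma_0"`, `"Gamma_SP"`.
#' @param p a [rate_constants()] object.
#' @return An object of class `anti_funnel`: list with curves `lower`
#'   and `upper` (lower/upper in the complex coordinate), `contains(s,
#'   c, tol)`, `width(s)`, logical `narrowing`, and `name`.
#' @export
anti_funnel <- function(name, p) {
  p <- as_rate_constants(p)
  name <- match.arg(name, c("Gamma", "Gamma_cs", "Gamma_0", "Gamma_SP"))
  if (name == "Gamma_SP" && !(p$e0 < 8 * p$K_S))
    stop("Gamma_SP fence property requires e0 < 8*K_S ",
         sprintf("(e0 = %g, 8*K_S = %g)", p$e0, 8 * p$K_S))
  pair <- switch(name,
    Gamma = c("gamma_c", "gamma_s"),
    Gamma_cs = c("gamma_c", "alpha_cs"),
    Gamma_0 = c("gamma_c", "gamma"),
    Gamma_SP = c("gamma_SP", "gamma"))
  lower <- qss_curve(pair[1], p)
  upper <- qss_curve(pair[2], p)
  region <- list(
    name = name,
    lower = lower,
    upper = upper,
    # Gamma is bounded by nullclines that stay apart (width -> K e0 s /
    # ... > 0 as s grows only for Gamma); the three fence-based regions
    # narrow towards the horizontal asymptote c = e0.
    narrowing = name %in% c("Gamma_cs", "Gamma_0", "Gamma_SP"),
    width = function(s) upper$value(s) - lower$value(s),
    contains = function(s, c_, tol = 0) {
      c_ >= lower$value(s) - tol & c_ <= upper$value(s) + tol
    })
  class(region) <- "anti_funnel"
  region
}

#' @export
print.anti_funnel <- function(x, ...) {
  cat(sprintf("anti-funnel %s: %s <= c <= %s%s\n", x$name,
              x$lower$name, x$upper$name,
              if (x$narrowing) " (narrowing)" else ""))
  invisible(x)
}

#' Pairwise ordering of the phase-plane curves on a grid
#'
#' Reports, for each ordered pair of the curves `gamma_c`, `gamma`,
#' `gamma_SP` (and `gamma_s`), whether the first lies strictly below the
#' second at every point of `s_grid`, and locates the
#' `gamma_SP`/`gamma_c` crossover by bracketed bisection when the
#' intersection coordinate \eqn{s^*} is positive.
#'
#' @param p a [rate_constants()] object with `k2 > 0`.
#' @param s_grid strictly positive substrate grid.
#' @return A list with `orderings` (data frame: lower, upper,
#'   holds_everywhere, fraction_of_grid), `s_star` (closed form),
#'   `crossover` (bisection root of `gamma_SP - gamma_c`, NA when none
#'   in the positive quadrant).
#' @export
curve_ordering_report <- function(p, s_grid = default_s_grid(p)) {
  p <- as_rate_constants(p)
  if (any(s_grid <= 0)) stop("s_grid must be strictly positive")
  nms <- c("gamma_c", "gamma_SP", "gamma", "gamma_s")
  vals <- sapply(nms, function(nm) qss_curve(nm, p)$value(s_grid))
  pairs <- utils::combn(nms, 2)
  orderings <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    below <- vals[, a] < vals[, b]
    data.frame(lower = a, upper = b,
               holds_everywhere = all(below),
               fraction_of_grid = mean(below))
  }))
  star <- s_star(p)
  crossover <- NA_real_
  if (star > 0) {
    # cancellation-free form of gamma_SP - gamma_c: the shared leading
    # behaviour e0*s/(K_S+s) - e0*s/(K_M+s) is collapsed analytically so
    # the bracketed bisection stays well-conditioned for large s*
    g <- function(s) {
      p$e0 * s * (p$K / ((p$K_S + s) * (p$K_M + s)) -
                  p$k2 / (p$k1 * (p$K_S * p$e0 + (p$K_S + s)^2)))
    }
    lo <- star / 2; hi <- star * 2
    if (g(lo) * g(hi) < 0) {
      crossover <- stats::uniroot(g, c(lo, hi),
                                  tol = min(1e-10, 1e-12 * star))$root
    }
  }
  list(orderings = orderings, s_star = star, crossover = crossover)
}

#' Export a curve as an (s, c) table
#'
#' @param curve a [qss_curve()] object.
#' @param s_grid substrate grid.
#' @param file optional path; when given the table is written as CSV.
#' @return A data frame with columns `s`, `c`, `curve` (invisibly when
#'   written to file).
#' @export
curve_table <- function(curve, s_grid, file = NULL) {
  tab <- data.frame(s = s_grid, c = curve$value(s_grid),
                    curve = curve$name)
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
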