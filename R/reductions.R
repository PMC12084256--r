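#' Standard QSSA substrate depletion rate
#'
#' The standard quasi-steady-state approximation (sQSSA) reduces the
#' planar mass-action system to the Michaelis-Menten rate law
#' \deqn{\dot s = -\frac{k_2 e_0 s}{K_M + s}.}
#'
#' @param s substrate concentration(s), nonnegative; vectorized.
#' @param p a [rate_constants()] object.
#' @return Numeric vector of substrate rates (nonpositive).
#' @export
sqssa_rhs <- function(s, p) {
  p <- as_rate_constants(p)
  -p$k2 * p$e0 * s / (p$K_M + s)
}

#' Slow-product QSSA reduction
#'
#' The Fenichel reduction obtained when product formation is the slow
#' process (small \eqn{k_2}):
#' \deqn{\dot s = -\frac{k_2 e_0 s (K_S+s)}{K_S e_0 + (K_S+s)^2}, \qquad
#'       \dot c = \dot s\,\frac{K_S e_0 - K (K_S+s)}{(K_S+s)^2}.}
#'
#' @inheritParams sqssa_rhs
#' @return A list with numeric vectors `ds` and `dc`.
#' @export
slow_product_rhs <- function(s, p) {
  p <- as_rate_constants(p)
  if (any(s < 0)) stop("slow_product_rhs requires s >= 0")
  ds <- -p$k2 * p$e0 * s * (p$K_S + s) / (p$K_S * p$e0 + (p$K_S + s)^2)
  dc <- ds * (p$K_S * p$e0 - p$K * (p$K_S + s)) / (p$K_S + s)^2
  list(ds = ds, dc = dc)
}

#' Kumar-Josic reduction of the substrate flow
#'
#' A refinement of the sQSSA obtained by differentiating along the
#' c-nullcline and substituting into the conservation law
#' \eqn{\dot s + \dot c + k_2 c = 0}:
#' \deqn{\dot s = -\frac{k_2 e_0 s (K_M+s)}{K_M e_0 + (K_M+s)^2}
#'   \;=\; \frac{\mathrm{sQSSA}(s)}{1+\varphi(s)}, \qquad
#'   \varphi(s) = \frac{K_M e_0}{(K_M+s)^2}.}
#' It is the upper (less negative) member of the substrate rate envelope
#' trapping the slow flow.
#'
#' @inheritParams sqssa_rhs
#' @return Numeric vector of substrate rates.
#' @export
kumar_josic_rhs <- function(s, p) {
  p <- as_rate_constants(p)
  -p$k2 * p$e0 * s * (p$K_M + s) / (p$K_M * p$e0 + (p$K_M + s)^2)
}

#' The sQSSA correction factor phi(s)
#'
#' \eqn{\varphi(s) = K_M e_0/(K_M+s)^2}; its maximum on `[0, s0]` is the
#' Reich-Sel'kov parameter \eqn{e_0/K_M}.
#'
#' @inheritParams sqssa_rhs
#' @return Numeric vector.
#' @export
phi_correction <- function(s, p) {
  p <- as_rate_constants(p)
  p$K_M * p$e0 / (p$K_M + s)^2
}

#' Calder-Siegel reduction near the stationary point
#'
#' The reduction built from the slow eigenvector slope `m` at the
#' origin:
#' \deqn{\dot s = -\frac{e_0 s}{e_0 + m s}\,(k_1 e_0 - k_{-1} m),}
#' highly accurate near the stationary point; its linearization slope at
#' \eqn{s = 0} equals the slow eigenvalue \eqn{\lambda_+}.
#'
#' @inheritParams sqssa_rhs
#' @param spectrum optionally a precomputed [origin_spectrum()] result.
#' @return Numeric vector of substrate rates.
#' @export
calder_siegel_rhs <- function(s, p, spectrum = NULL) {
  p <- as_rate_constants(p)
  if (p$e0 == 0) return(rep(0, length(s)))
  if (is.null(spectrum)) spectrum <- origin_spectrum(p)
  m <- spectrum$m
  -(p$e0 * s / (p$e0 + m * s)) * (p$k1 * p$e0 - p$k_neg1 * m)
}

#' Reverse QSSA piecewise reduction
#'
#' At high enzyme concentration the critical manifold splits into two
#' components meeting at the transcritical point \eqn{(s,c)=(0,e_0)}.
#' The Fenichel projection on the horizontal component (`piece =
#' "outer"`, valid right of the bifurcation point) gives constant-rate
#' substrate depletion \eqn{\dot s = -k_2 e_0,\ \dot c = 0}; the
#' projection on the vertical component (`piece = "inner"`) gives
#' exponential complex decay \eqn{\dot s = 0,\ \dot c = -k_2 c}.
#'
#' @param piece `"outer"` or `"inner"`.
#' @param s substrate concentration(s) (used by the outer piece only for
#'   recycling; the rates are state-independent).
#' @param c_ complex concentration(s) (used by the inner piece).
#' @param p a [rate_constants()] object.
#' @return A list with numeric vectors `ds` and `dc`.
#' @export
rqssa_rhs <- function(piece = c("outer", "inner"), s = 0, c_ = 0, p) {
  piece <- match.arg(piece)
  p <- as_rate_constants(p)
  if (piece == "outer") {
    n <- max(length(s), length(c_))
    list(ds = rep(-p$k2 * p$e0, n), dc = rep(0, n))
  } else {
    list(ds = rep(0, length(c_)), dc = -p$k2 * c_)
  }
}

#' Shifted initial condition for the outer reverse-QSSA piece
#'
#' In the high-enzyme regime a trajectory started at \eqn{(s_0, 0)} with
#' \eqn{e_0 < s_0} collapses rapidly onto \eqn{c = e_0}, consuming
#' \eqn{e_0} of substrate; the outer reduction must therefore be
#' launched from \eqn{(s_0 - e_0,\ e_0)}.
#'
#' @param p a [rate_constants()] object.
#' @param s0 initial substrate concentration; must exceed `e0`.
#' @return A list with elements `s` and `c` (the shifted phase state).
#' @export
shifted_initial_condition <- function(p, s0) {
  p <- as_rate_constants(p)
  if (s0 <= p$e0)
    stop("outside rQSSA outer regime: requires s0 > e0")
  list(s = s0 - p$e0, c = p$e0)
}

#' Reduced-model registry
#'
#' Packages a named reduction as a scalar substrate rate plus the map
#' reconstructing the complex coordinate from the associated QSS curve:
#' the c-nullcline for `"sqssa"` and `"kumar_josic"`, the slow-product
#' QSS curve for `"slow_product"`, the Calder-Siegel fence for
#' `"calder_siegel"`, and the constant \eqn{c = e_0} for `"rqssa_outer"`.
#'
#' @param name one of `"sqssa"`, `"slow_product"`, `"kumar_josic"`,
#'   `"calder_siegel"`, `"rqssa_outer"`, `"rqssa_inner"`.
#' @param p a [rate_constants()] object.
#' @return An object of class `reduction_model`: list with `name`,
#'   `rhs(s)` (scalar substrate rate; for `"rqssa_inner"` a complex
#'   rate), and `complex_map(s)` (NULL for the inner rQSSA piece).
#' @export
reduction_model <- function(name, p) {
  p <- as_rate_constants(p)
  name <- match.arg(name, c("sqssa", "slow_product", "kumar_josic",
                            "calder_siegel", "rqssa_outer", "rqssa_inner"))
  model <- switch(name,
    sqssa = list(
      rhs = function(s) sqssa_rhs(s, p),
      complex_map = function(s) qss_curve("gamma_c", p)$value(s)),
    slow_product = list(
      rhs = function(s) slow_product_rhs(s, p)$ds,
      complex_map = function(s) qss_curve("gamma_SP", p)$value(s)),
    kumar_josic = list(
      rhs = function(s) kumar_josic_rhs(s, p),
      complex_map = function(s) qss_curve("gamma_c", p)$value(s)),
    calder_siegel = {
      sp <- origin_spectrum(p)
      list(rhs = function(s) calder_siegel_rhs(s, p, sp),
           complex_map = function(s) qss_curve("alpha_cs", p)$value(s))
    },
    rqssa_outer = list(
      rhs = function(s) rep(-p$k2 * p$e0, length(s)),
      complex_map = function(s) rep(p$e0, length(s))),
    rqssa_inner = list(
      rhs = function(c_) -p$k2 * c_,
      complex_map = NULL)
  )
  model$name <- name
  model$params <- p
  class(model) <- "reduction_model"
  model
}
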