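#' Kinetic rate constants for the Michaelis-Menten mechanism
#'
#' Bundles the four kinetic parameters of the irreversible mechanism
#' \deqn{S + E \rightleftharpoons C \rightarrow E + P}
#' (association rate \eqn{k_1}, dissociation rate \eqn{k_{-1}}, catalytic
#' rate \eqn{k_2}, total enzyme \eqn{e_0}) together with the derived
#' constants: the equilibrium constant \eqn{K_S = k_{-1}/k_1}, the Van
#' Slyke-Cullen constant \eqn{K = k_2/k_1}, and the Michaelis constant
#' \eqn{K_M = (k_{-1}+k_2)/k_1 = K_S + K}.
#'
#' All quantities are in consistent arbitrary units (concentration and
#' time units are unconstrained, only their consistency matters).
#'
#' @param k1 association rate constant, must be strictly positive
#'   (units 1/(concentration * time)).
#' @param k_neg1 dissociation rate constant, nonnegative (1/time).
#' @param k2 catalytic rate constant, nonnegative (1/time).
#' @param e0 total enzyme concentration, nonnegative.
#' @return An object of class `rate_constants`: a list with elements
#'   `k1`, `k_neg1`, `k2`, `e0`, `K_M`, `K_S`, `K`.
#' @examples
#' p <- rate_constants(k1 = 1, k_neg1 = 1, k2 = 1, e0 = 6)
#' p$K_M  # 2
#' @export
rate_constants <- function(k1, k_neg1, k2, e0) {
  stopifnot(
    is.numeric(k1), length(k1) == 1L, is.finite(k1),
    is.numeric(k_neg1), length(k_neg1) == 1L, is.finite(k_neg1),
    is.numeric(k2), length(k2) == 1L, is.finite(k2),
    is.numeric(e0), length(e0) == 1L, is.finite(e0)
  )
  if (k1 <= 0) stop("k1 must be strictly positive (K_S and K divide by k1)")
  if (k_neg1 < 0) stop("k_neg1 must be nonnegative")
  if (k2 < 0) stop("k2 must be nonnegative")
  if (e0 < 0) stop("e0 must be nonnegative")
  p <- list(
    k1 = k1, k_neg1 = k_neg1, k2 = k2, e0 = e0,
    K_S = k_neg1 / k1, K = k2 / k1, K_M = (k_neg1 + k2) / k1
  )
  class(p) <- "rate_constants"
  p
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Michaelis-Menten rate constants\n")
  cat(sprintf("  k1 = %g, k_neg1 = %g, k2 = %g, e0 = %g\n",
              x$k1, x$k_neg1, x$k2, x$e0))
  cat(sprintf("  K_S = %g, K = %g, K_M = %g\n", x$K_S, x$K, x$K_M))
  invisible(x)
}

is_rate_constants <- function(p) inherits(p, "rate_constants")

as_rate_constants <- function(p) {
  if (is_rate_constants(p)) return(p)
  if (is.list(p) && all(c("k1", "k_neg1", "k2", "e0") %in% names(p)))
    return(rate_constants(p$k1, p$k_neg1, p$k2, p$e0))
  stop("cannot interpret object as rate constants")
}

#' Derived kinetic constants
#'
#' Returns the equilibrium constant \eqn{K_S = k_{-1}/k_1}, the Van
#' Slyke-Cullen constant \eqn{K = k_2/k_1} and the Michaelis constant
#' \eqn{K_M = (k_{-1}+k_2)/k_1}, which satisfy \eqn{K_M = K_S + K}.
#'
#' @param p a [rate_constants()] object.
#' @return A list with elements `K_M`, `K_S`, `K`.
#' @export
derived_constants <- function(p) {
  p <- as_rate_constants(p)
  list(K_M = p$K_M, K_S = p$K_S, K = p$K)
}

#' Mass-action vector field of the planar Michaelis-Menten system
#'
#' Evaluates the substrate/complex rates
#' \deqn{\dot s = -k_1(e_0-c)s + k_{-1}c, \qquad
#'       \dot c = k_1(e_0-c)s - (k_{-1}+k_2)c.}
#' Free enzyme is eliminated through the conservation law \eqn{e = e_0 - c}.
#'
#' @param s substrate concentration(s), nonnegative; vectorized.
#' @param c_ complex concentration(s); recycled against `s`.
#' @param p a [rate_constants()] object.
#' @return A list with numeric vectors `ds` and `dc`.
#' @export
mass_action_rhs <- function(s, c_, p) {
  p <- as_rate_constants(p)
  bind <- p$k1 * (p$e0 - c_) * s
  list(ds = -bind + p$k_neg1 * c_,
       dc = bind - (p$k_neg1 + p$k2) * c_)
}

#' Linearization of the mass-action system at the origin
#'
#' The stationary point \eqn{(s,c)=(0,0)} is a stable node with
#' eigenvalues
#' \deqn{\lambda_\pm = \frac{k_1}{2}(K_M+e_0)
#'   \left(-1 \pm \sqrt{1 - \frac{4Ke_0}{(K_M+e_0)^2}}\right),}
#' and the slow eigenvector \eqn{v^+} spans the line \eqn{c = m s}. The
#' slope `m` is evaluated in a cancellation-safe conjugate form
#' \deqn{m = \frac{2 k_1 e_0}{\sqrt{D} + k_{-1} + k_2 - k_1 e_0}, \quad
#'       D = (k_{-1}+k_2+k_1 e_0)^2 - 4 k_1 k_2 e_0,}
#' which is algebraically identical to the direct formula
#' \eqn{m = (-k_{-1}-k_2+k_1e_0+\sqrt{D})/(2k_{-1})} but avoids
#' catastrophic cancellation when \eqn{k_1 e_0 \ll k_{-1}+k_2}.
#'
#' @param p a [rate_constants()] object with `e0 > 0`.
#' @return An object of class `origin_spectrum`: list with
#'   `lambda_minus`, `lambda_plus` (both negative when `k2 > 0`), slow
#'   eigenvector slope `m`, and the discriminant ratio
#'   `disc = 1 - 4*K*e0/(K_M+e0)^2`.
#' @export
origin_spectrum <- function(p) {
  p <- as_rate_constants(p)
  if (p$e0 <= 0) stop("origin_spectrum requires e0 > 0")
  tr_scale <- p$k1 * (p$K_M + p$e0)            # -trace of the Jacobian
  disc <- 1 - 4 * p$K * p$e0 / (p$K_M + p$e0)^2
  if (disc < 0) stop("negative node discriminant: cannot occur for ",
                     "nonnegative parameters; numerical inconsistency")
  root <- sqrt(disc)
  lam_minus <- -tr_scale / 2 * (1 + root)
  # conjugate (product) form: avoids the catastrophic cancellation of
  # -1 + root when 4*K*e0 << (K_M + e0)^2
  lam_plus <- if (p$K * p$e0 == 0) 0 else
    -2 * p$k1 * p$k2 * p$e0 / (tr_scale * (1 + root))
  # sqrt(D) with D = (k_neg1+k2+k1*e0)^2 - 4*k1*k2*e0 = (tr_scale*root)^2
  sqrtD <- tr_scale * root
  a <- p$k_neg1 + p$k2 - p$k1 * p$e0
  m <- if (a >= 0) {
    # rationalized numerator: accurate when k1*e0 << k_neg1 + k2
    denom <- sqrtD + a
    if (denom > 0) 2 * p$k1 * p$e0 / denom else Inf
  } else {
    # direct form has no cancellation when k1*e0 > k_neg1 + k2
    if (p$k_neg1 > 0) (-a + sqrtD) / (2 * p$k_neg1) else Inf
  }
  out <- list(lambda_minus = lam_minus, lambda_plus = lam_plus,
              m = m, disc = disc)
  class(out) <- "origin_spectrum"
  out
}

#' @export
print.origin_spectrum <- function(x, ...) {
  cat(sprintf("origin spectrum: lambda- = %.8g, lambda+ = %.8g, m = %.8g\n",
              x$lambda_minus, x$lambda_plus, x$m))
  invisible(x)
}

#' Dimensionless validity indicators
#'
#' Computes the dimensionless ratios that govern the accuracy and
#' predominance of the QSS reductions:
#' \itemize{
#'   \item `eps_RS = e0/K_M`, the Reich-Sel'kov parameter (standard QSSA
#'     accuracy improves as it decreases);
#'   \item `eps_K = e0/K`, the predominance ratio (the standard QSSA is
#'     the predominant reduction when it is small); `Inf` when `k2 = 0`;
#'   \item `delta`, the leading-order ratio of slow to fast eigenvalues
#'     at the origin, \eqn{(e_0/K_M)\,k_2/(k_{-1}+k_2)} (the
#'     higher-order remainder in \eqn{e_0} is dropped);
#'   \item `delta_exact`, the exact eigenvalue ratio
#'     \eqn{\lambda_+/\lambda_-} for comparison with `delta`;
#'   \item `node_disc = 4*K*e0/(K_M+e0)^2`, the discriminant deficit of
#'     the node (timescale separation requires it to be well below 1);
#'   \item `mu = eps_RS/(1+eps_RS)^2`, the high-enzyme bound factor.
#' }
#'
#' @param p a [rate_constants()] object.
#' @return A list with elements `eps_RS`, `eps_K`, `delta`,
#'   `delta_exact`, `node_disc`, `mu`.
#' @export
indicators <- function(p) {
  p <- as_rate_constants(p)
  eps_RS <- if (p$K_M > 0) p$e0 / p$K_M else if (p$e0 == 0) 0 else Inf
  eps_K <- if (p$K > 0) p$e0 / p$K else if (p$e0 == 0) 0 else Inf
  delta <- if (p$k_neg1 + p$k2 > 0) eps_RS * p$k2 / (p$k_neg1 + p$k2) else 0
  delta_exact <- if (p$e0 > 0) {
    sp <- origin_spectrum(p)
    sp$lambda_plus / sp$lambda_minus
  } else 0
  node_disc <- 4 * p$K * p$e0 / (p$K_M + p$e0)^2
  mu <- eps_RS / (1 + eps_RS)^2
  list(eps_RS = eps_RS, eps_K = eps_K, delta = delta,
       delta_exact = delta_exact, node_disc = node_disc, mu = mu)
}
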