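#' Alveolar fraction of the first gas under constant inflow
#'
#' Closed-form steady-state solution for the alveolar (= end-capillary)
#' dry-gas fraction of a gas being eliminated from a single gas-exchanging
#' unit ventilated with a fixed *inspired* alveolar ventilation (constant
#' inflow). The inspired mixture contains none of the gas, the diluent is
#' treated as completely insoluble, and the dissociation curve is linear.
#'
#' @details
#' Mass balance equates the gas-phase output \eqn{\dot V_A F_A} with delivery
#' from blood \eqn{\lambda \dot Q (F_{\bar v} - F_A)}, with
#' \eqn{\dot V_A = \dot V_I / (1 - F_A)} from conservation of the insoluble
#' diluent. Eliminating \eqn{\dot V_A} gives a quadratic in \eqn{F_A} whose
#' physical root is
#' \deqn{F_A = 1 - \tfrac12\left(\alpha + \sqrt{\alpha^2 + 4\psi}\right),
#'  \quad \alpha = 1 - F_{\bar v} - \psi, \quad \psi = \dot V_I / (\lambda \dot Q).}
#' The discriminant is clamped at zero against floating-point underflow and
#' every root is verified against the original mass balance; any entry that
#' fails verification (possible only at extreme \eqn{\psi}) is re-solved by
#' bisection on the mass-balance residual.
#'
#' @param lambda Blood/gas partition coefficient, > 0.
#' @param Q Perfusion of the unit, L/min, > 0.
#' @param VI Inspired alveolar ventilation, L/min, > 0.
#' @param Fv Mixed-venous dry-gas fraction in `[0, 1)`.
#' @return Alveolar fraction `FA` in `[0, Fv]`. All arguments are recycled to
#'   a common length.
#' @seealso [expired_ventilation()], [sg_outflow()]
#' @export
#' @examples
#' alveolar_fraction_constant_inflow(0.47, Q = 5, VI = 4, Fv = 0.7) # ~0.22
alveolar_fraction_constant_inflow <- function(lambda, Q, VI, Fv) {
  n <- max(length(lambda), length(Q), length(VI), length(Fv))
  lambda <- rep_len(lambda, n); Q <- rep_len(Q, n)
  VI <- rep_len(VI, n); Fv <- rep_len(Fv, n)
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("lambda must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(Q)) || any(Q <= 0) || any(!is.finite(VI)) || any(VI <= 0)) {
    stop("Q and VI must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(Fv)) || any(Fv < 0) || any(Fv >= 1)) {
    stop("Fv must lie in [0, 1)", call. = FALSE)
  }

  psi <- VI / (lambda * Q)
  alpha <- 1 - Fv - psi
  disc <- pmax(alpha^2 + 4 * psi, 0)
  FA <- 1 - 0.5 * (alpha + sqrt(disc))
  # round-off can leave FA a hair outside [0, Fv]
  FA <- pmin(pmax(FA, 0), Fv)

  resid <- abs(VI * FA / (1 - FA) - lambda * Q * (Fv - FA))
  scale <- pmax(lambda * Q * Fv, 1)
  bad <- which(resid > 1e-10 * scale)
  for (i in bad) {
    FA[i] <- solve_fa_bisection(lambda[i], Q[i], VI[i], Fv[i])
  }
  FA
}

# Bisection on g(F) = VI F/(1-F) - lambda Q (Fv - F), increasing on [0, Fv].
solve_fa_bisection <- function(lambda, Q, VI, Fv, tol = 1e-16, maxit = 200L) {
  if (Fv == 0) return(0)
  lo <- 0; hi <- Fv
  g <- function(F) VI * F / (1 - F) - lambda * Q * (Fv - F)
  for (it in seq_len(maxit)) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  0.5 * (lo + hi)
}

#' Expired alveolar ventilation from the first-gas alveolar fraction
#'
#' With an insoluble diluent and inspired fraction zero, conservation of the
#' diluent gives `VA = VI / (1 - FA)`: expired flow exceeds inspired flow
#' while the first gas is being eliminated.
#'
#' @param VI Inspired alveolar ventilation, L/min.
#' @param FA Alveolar dry-gas fraction of the eliminated gas, in `[0, 1)`.
#' @return Expired alveolar ventilation, L/min. Vectorized.
#' @export
expired_ventilation <- function(VI, FA) {
  if (any(!is.finite(FA)) || any(FA < 0) || any(FA >= 1)) {
    stop("FA must lie in [0, 1)", call. = FALSE)
  }
  VI / (1 - FA)
}

#' Second-gas outflow from a single unit
#'
#' Gas-phase elimination rate of a trace second gas from a unit with expired
#' alveolar ventilation `VA`:
#' \deqn{\dot V_A F_A = \frac{\lambda \dot V_A F_{\bar v}}{\lambda + \dot V_A/\dot Q}.}
#' The trace gas is a passive tracer: it is present at a concentration low
#' enough that its own transfer does not alter `VA`.
#'
#' @param lambda Blood/gas partition coefficient of the second gas, > 0.
#' @param VA Expired alveolar ventilation, L/min, > 0.
#' @param Q Perfusion, L/min, > 0.
#' @param Fv Mixed-venous dry-gas fraction of the second gas, >= 0.
#' @return Elimination rate, L/min of gas-phase volume equivalent; never more
#'   than the rate `lambda * Q * Fv` at which the gas arrives in blood.
#'   Vectorized.
#' @export
#' @examples
#' sg_outflow(0.59, VA = 5.128, Q = 5, Fv = 0.01)
sg_outflow <- function(lambda, VA, Q, Fv) {
  if (any(!is.finite(lambda)) || any(lambda <= 0) ||
      any(!is.finite(VA)) || any(VA <= 0) ||
      any(!is.finite(Q)) || any(Q <= 0)) {
    stop("lambda, VA and Q must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(Fv)) || any(Fv < 0)) {
    stop("Fv must be >= 0", call. = FALSE)
  }
  lambda * VA * Fv / (lambda + VA / Q)
}

#' Second-gas outflow under constant outflow
#'
#' Under the constant-outflow ventilation pattern the *expired* alveolar
#' ventilation is held fixed, so the second-gas elimination rate is the same
#' expression as [sg_outflow()] evaluated at the fixed `VA` and, by
#' construction, is independent of any concurrent first-gas exchange: the
#' volume-expansion increment (Step 2) is identically zero in this mode.
#'
#' @inheritParams sg_outflow
#' @param VA_fixed The held expired alveolar ventilation, L/min.
#' @return Elimination rate, L/min. Vectorized.
#' @export
sg_outflow_constant_outflow <- function(lambda, VA_fixed, Q, Fv) {
  sg_outflow(lambda, VA_fixed, Q, Fv)
}
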