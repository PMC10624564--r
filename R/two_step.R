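#' Calibrate the mixed-venous nitrous oxide fraction
#'
#' Finds the mixed-venous N2O dry-gas fraction at which the whole-lung N2O
#' elimination rate (sum over compartments of `VA_i * FA_i` under constant
#' inflow) equals `target_elimination`. Whole-lung output is strictly
#' increasing in the venous fraction, so bisection on `[0, cap]` is
#' guaranteed to converge. The cap of 0.7 corresponds to the highest N2O
#' concentration usable without hypoxia.
#'
#' @param lung A [build_lung()] object.
#' @param lambda_n2o Blood/gas partition coefficient of N2O. Default 0.47.
#' @param target_elimination Whole-lung N2O elimination rate, L/min. Default 0.5.
#' @param cap Upper bound on the venous fraction. Default 0.7.
#' @param tol Convergence tolerance on the elimination rate, L/min.
#' @return The calibrated venous fraction in `[0, cap]`.
#'
#' If the target exceeds what `cap` allows, an error of condition class
#' `"sgewash_capped_target"` is signalled; its `achievable` field holds the
#' maximum elimination rate at the cap. The target is never silently clamped.
#' @export
#' @examples
#' calibrate_venous_n2o(build_lung(0)) # homogeneous lung: ~0.3239
calibrate_venous_n2o <- function(lung, lambda_n2o = 0.47,
                                 target_elimination = 0.5, cap = 0.7,
                                 tol = 1e-10) {
  stopifnot(inherits(lung, "lung_model"))
  if (target_elimination < 0) {
    stop("target_elimination must be >= 0", call. = FALSE)
  }
  if (target_elimination == 0) return(0)

  total_out <- function(Fv) {
    FA <- alveolar_fraction_constant_inflow(lambda_n2o, lung$Q, lung$VI, Fv)
    sum(lung$VI / (1 - FA) * FA)
  }
  at_cap <- total_out(cap)
  if (at_cap < target_elimination) {
    cond <- structure(
      class = c("sgewash_capped_target", "error", "condition"),
      list(
        message = sprintf(
          paste0("N2O elimination target %.6g L/min is unreachable at the ",
                 "venous-fraction cap %.3g (achievable maximum %.6g L/min)"),
          target_elimination, cap, at_cap
        ),
        call = sys.call(-1),
        achievable = at_cap, cap = cap, target = target_elimination
      )
    )
    stop(cond)
  }

  lo <- 0; hi <- cap
  repeat {
    mid <- 0.5 * (lo + hi)
    out <- total_out(mid)
    if (abs(out - target_elimination) < tol || (hi - lo) < 1e-16) break
    if (out > target_elimination) hi <- mid else lo <- mid
  }
  mid
}

# Per-compartment N2O solution under either ventilation pattern.
# Under constant inflow, FA comes from the closed-form quadratic and the
# expired flow expands to VI/(1-FA). Under constant outflow the expired flow
# is held at the inspired value and the mass balance VA FA = lambda Q (Fv-FA)
# is linear in FA.
n2o_state <- function(lung, Fv_n2o, lambda_n2o = 0.47,
                      pattern = c("constant_inflow", "constant_outflow")) {
  pattern <- match.arg(pattern)
  if (pattern == "constant_inflow") {
    FA <- alveolar_fraction_constant_inflow(lambda_n2o, lung$Q, lung$VI, Fv_n2o)
    VA <- lung$VI / (1 - FA)
  } else {
    VA <- lung$VI
    FA <- lambda_n2o * lung$Q * Fv_n2o / (lambda_n2o * lung$Q + VA)
  }
  list(FA = FA, VA = VA, efflux = VA * FA)
}

#' Step 1: second-gas elimination at constant volume
#'
#' Per-compartment elimination rate of each second gas with all exchange
#' frozen at constant gas volume: the expired ventilation equals the inspired
#' ventilation (the trace second gas itself causes negligible volume change,
#' and N2O exchange is not yet permitted). The eliminated fraction of
#' incoming gas in a compartment with ratio `r = VI/Q` is `r / (lambda + r)`.
#'
#' @param lung A [build_lung()] object.
#' @param gases Gas registry rows for the second gases (columns `name`,
#'   `lambda`). Default [default_second_gases()].
#' @param Fv_sg Mixed-venous dry-gas fraction of every second gas.
#'   Default 0.01 (a 1\% inspired mixture previously equilibrated with the
#'   body). Reported fractions are invariant to this value.
#' @return Matrix `lung$N x nrow(gases)` of Step-1 elimination rates, L/min,
#'   with gas names as column names.
#' @export
run_step1 <- function(lung, gases = default_second_gases(), Fv_sg = 0.01) {
  stopifnot(inherits(lung, "lung_model"))
  validate_gas_registry(gases)
  out <- vapply(
    gases$lambda,
    function(lam) sg_outflow(lam, VA = lung$VI, Q = lung$Q, Fv = Fv_sg),
    numeric(lung$N)
  )
  out <- matrix(out, nrow = lung$N, ncol = nrow(gases),
                dimnames = list(NULL, gases$name))
  out
}

#' Run the two-step decomposition of second-gas elimination
#'
#' Decomposes the net steady-state elimination of each trace second gas into
#' a constant-volume component (Step 1) and the extra elimination carried by
#' the gas-phase volume expansion produced by concurrent N2O washout
#' (Step 2). The decomposition is exact: Step 1 + Step 2 equals the classical
#' one-step flux computed at the expanded expired ventilation.
#'
#' @details
#' Per compartment, the N2O alveolar fraction is solved first
#' ([alveolar_fraction_constant_inflow()]), giving the expanded expired
#' ventilation `VA_i = VI_i / (1 - FA_i)` and the N2O efflux `VA_i * FA_i`.
#' Total second-gas elimination is then [sg_outflow()] at `VA_i`; Step 2 is
#' the excess over the constant-volume Step-1 flux. Under the
#' `constant_outflow` pattern the expired ventilation is held fixed and
#' Step 2 is identically zero — no second gas effect exists in that mode.
#'
#' The mixed-venous N2O fraction is either given (`Fv_n2o`) or calibrated so
#' that whole-lung N2O elimination matches `target_elimination`
#' ([calibrate_venous_n2o()]).
#'
#' @param lung A [build_lung()] object.
#' @param gases Second-gas registry rows (columns `name`, `lambda`).
#' @param Fv_sg Mixed-venous second-gas fraction. Default 0.01.
#' @param Fv_n2o Mixed-venous N2O fraction in `[0, 0.7]`, or `NULL` (default)
#'   to calibrate against `target_elimination`.
#' @param target_elimination Whole-lung N2O elimination target, L/min, used
#'   when `Fv_n2o` is `NULL`. Default 0.5.
#' @param lambda_n2o N2O blood/gas partition coefficient. Default 0.47.
#' @param cap Cap on the calibrated venous N2O fraction. Default 0.7.
#' @param pattern Ventilation pattern, `"constant_inflow"` (default) or
#'   `"constant_outflow"`.
#' @return An object of class `two_step_result`: a list with
#'   \describe{
#'     \item{lung, gases, Fv_sg, Fv_n2o, lambda_n2o, pattern}{inputs as resolved}
#'     \item{n2o}{list `FA`, `VA`, `efflux` — per-compartment N2O solution}
#'     \item{incoming, step1, step2, retained}{`N x n_gas` matrices of
#'       per-compartment fluxes, L/min; `incoming = lambda Q_i Fv_sg`,
#'       `retained = incoming - step1 - step2`}
#'     \item{summary}{data.frame per gas: flux totals and the normalized
#'       fractions `frac_step1` (of incoming), `frac_step2_of_incoming`,
#'       `frac_step2_of_step2_input` (of the Step-1 remainder), `net_frac`}
#'   }
#' @export
#' @examples
#' res <- run_two_step(build_lung(2))
#' res$summary[, c("gas", "frac_step1", "net_frac")]
run_two_step <- function(lung, gases = default_second_gases(), Fv_sg = 0.01,
                         Fv_n2o = NULL, target_elimination = 0.5,
                         lambda_n2o = 0.47, cap = 0.7,
                         pattern = c("constant_inflow", "constant_outflow")) {
  stopifnot(inherits(lung, "lung_model"))
  validate_gas_registry(gases)
  pattern <- match.arg(pattern)
  if (!is.numeric(Fv_sg) || Fv_sg < 0 || Fv_sg >= 1) {
    stop("Fv_sg must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(Fv_n2o)) {
    Fv_n2o <- calibrate_venous_n2o(lung, lambda_n2o, target_elimination, cap)
  } else if (Fv_n2o < 0 || Fv_n2o > cap) {
    stop("Fv_n2o must lie in [0, cap]", call. = FALSE)
  }

  n2o <- n2o_state(lung, Fv_n2o, lambda_n2o, pattern)
  step1 <- run_step1(lung, gases, Fv_sg)
  total <- vapply(
    gases$lambda,
    function(lam) sg_outflow(lam, VA = n2o$VA, Q = lung$Q, Fv = Fv_sg),
    numeric(lung$N)
  )
  total <- matrix(total, nrow = lung$N, ncol = nrow(gases))
  step2 <- total - step1
  incoming <- outer(lung$Q, gases$lambda) * Fv_sg
  retained <- incoming - total
  colnames(total) <- colnames(step2) <- colnames(incoming) <-
    colnames(retained) <- gases$name

  inc_t <- colSums(incoming)
  s1_t <- colSums(step1)
  s2_t <- colSums(step2)
  summary <- data.frame(
    gas = gases$name,
    lambda = gases$lambda,
    incoming_total = inc_t,
    step1_total = s1_t,
    step2_total = s2_t,
    retained_total = colSums(retained),
    frac_step1 = s1_t / inc_t,
    frac_step2_of_incoming = s2_t / inc_t,
    frac_step2_of_step2_input = s2_t / (inc_t - s1_t),
    net_frac = (s1_t + s2_t) / inc_t,
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  res <- list(
    lung = lung, gases = gases, Fv_sg = Fv_sg, Fv_n2o = Fv_n2o,
    lambda_n2o = lambda_n2o, pattern = pattern,
    n2o = n2o,
    incoming = incoming, step1 = step1, step2 = step2, retained = retained,
    summary = summary
  )
  class(res) <- "two_step_result"
  res
}

#' @export
print.two_step_result <- function(x, ...) {
  cat(sprintf(
    "Two-step second-gas elimination (%s), sigma = %.3g, N = %d\n",
    x$pattern, x$lung$sigma, x$lung$N
  ))
  cat(sprintf("  venous N2O fraction : %.6g\n", x$Fv_n2o))
  cat(sprintf("  N2O elimination     : %.6g L/min\n", sum(x$n2o$efflux)))
  cat(sprintf("  expired ventilation : %.6g L/min (inspired %.4g)\n",
              sum(x$n2o$VA), x$lung$VI_total))
  cat("\nPer-gas eliminated fractions of incoming second gas:\n")
  print(x$summary[, c("gas", "lambda", "frac_step1",
                      "frac_step2_of_incoming", "net_frac")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-compartment distribution profile of a second gas
#'
#' Converts a [run_two_step()] result into distribution curves over
#' `log10(V/Q)` for one gas: the incoming mixed-venous gas (normalized to
#' unit area), the Step-1 eliminated and retained parts, the Step-2 extra
#' elimination and final retained part (all as densities of the incoming
#' total), and the N2O efflux density in L/min per unit `log10(V/Q)`.
#'
#' @param result A `two_step_result`.
#' @param gas Name of one gas in `result$gases`.
#' @return A data.frame with one row per compartment: `x_log10`,
#'   `incoming_density`, `step1_eliminated_density`, `step1_retained_density`,
#'   `step2_extra_density`, `step2_retained_density`, `n2o_efflux_density`.
#'   Densities integrate (midpoint rule over the uniform grid) to the
#'   corresponding fraction of incoming gas; the incoming curve integrates
#'   to 1, the N2O curve to the whole-lung N2O elimination rate.
#' @export
distribution_profile <- function(result, gas) {
  stopifnot(inherits(result, "two_step_result"))
  j <- match(gas, result$gases$name)
  if (is.na(j)) stop("unknown gas: '", gas, "'", call. = FALSE)
  lung <- result$lung
  if (lung$N < 2) {
    stop("distribution profile requires a distributed lung (sigma > 0)",
         call. = FALSE)
  }
  x10 <- lung$x / log(10)
  dx <- x10[2] - x10[1]                 # uniform grid
  inc_total <- sum(result$incoming[, j])
  data.frame(
    x_log10 = x10,
    incoming_density = result$incoming[, j] / inc_total / dx,
    step1_eliminated_density = result$step1[, j] / inc_total / dx,
    step1_retained_density = (result$incoming[, j] - result$step1[, j]) /
      inc_total / dx,
    step2_extra_density = result$step2[, j] / inc_total / dx,
    step2_retained_density = result$retained[, j] / inc_total / dx,
    n2o_efflux_density = result$n2o$efflux / dx
  )
}
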