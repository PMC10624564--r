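#' Sweep the mismatch index sigma
#'
#' For each value of `sigma`, rebuilds the lung, recalibrates the venous N2O
#' fraction to the elimination target, and records the eliminated fractions
#' of every second gas: Step 1 (constant volume), Step 2 (volume expansion),
#' and the net over both steps.
#'
#' @param sigma_grid Values of the mismatch index. Default `seq(0, 2, 0.25)`.
#' @param gases Second-gas registry rows. Default [default_second_gases()].
#' @param Fv_sg Mixed-venous second-gas fraction. Default 0.01.
#' @param target_elimination Whole-lung N2O elimination target, L/min.
#' @param lambda_n2o N2O partition coefficient. Default 0.47.
#' @param pattern Ventilation pattern.
#' @param VI_total,Q_total,N,span Lung construction parameters, see
#'   [build_lung()].
#' @return A long data.frame: `sigma`, `Fv_n2o`, `gas`, `lambda`,
#'   `frac_step1`, `frac_step2_of_incoming`, `frac_step2_of_step2_input`,
#'   `net_frac`.
#' @export
sweep_sigma <- function(sigma_grid = seq(0, 2, by = 0.25),
                        gases = default_second_gases(), Fv_sg = 0.01,
                        target_elimination = 0.5, lambda_n2o = 0.47,
                        pattern = "constant_inflow",
                        VI_total = 4, Q_total = 5, N = 1001, span = 5) {
  rows <- lapply(sigma_grid, function(sg) {
    lung <- build_lung(sg, VI_total, Q_total, N, span)
    res <- run_two_step(lung, gases, Fv_sg,
                        target_elimination = target_elimination,
                        lambda_n2o = lambda_n2o, pattern = pattern)
    cbind(sigma = sg, Fv_n2o = res$Fv_n2o,
          res$summary[, c("gas", "lambda", "frac_step1",
                          "frac_step2_of_incoming",
                          "frac_step2_of_step2_input", "net_frac")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the second-gas solubility
#'
#' Eliminated fractions as a function of `log10(lambda)` of the second gas,
#' for each mismatch index in `sigma_set`. For each sigma the lung is built
#' once and the venous N2O fraction calibrated once (the N2O solution does
#' not depend on the trace gas), then the fractions are evaluated over the
#' whole solubility grid.
#'
#' @param log10_lambda_grid Grid of `log10(lambda)`. Default a 0.01-spaced
#'   grid on `[-2.5, 1.5]`.
#' @param sigma_set Mismatch indices to contrast. Default `c(0, 2)`.
#' @inheritParams sweep_sigma
#' @return A long data.frame: `sigma`, `Fv_n2o`, `log10_lambda`, `lambda`,
#'   `frac_step1`, `frac_step2_of_incoming`, `frac_step2_of_step2_input`,
#'   `net_frac`.
#' @export
sweep_solubility <- function(log10_lambda_grid = seq(-2.5, 1.5, by = 0.01),
                             sigma_set = c(0, 2), Fv_sg = 0.01,
                             target_elimination = 0.5, lambda_n2o = 0.47,
                             pattern = "constant_inflow",
                             VI_total = 4, Q_total = 5, N = 1001, span = 5) {
  if (any(log10_lambda_grid < -2.5 - 1e-9) || any(log10_lambda_grid > 1.5 + 1e-9)) {
    stop("log10_lambda_grid must lie within [-2.5, 1.5]", call. = FALSE)
  }
  rows <- lapply(sigma_set, function(sg) {
    lung <- build_lung(sg, VI_total, Q_total, N, span)
    Fv_n2o <- calibrate_venous_n2o(lung, lambda_n2o, target_elimination)
    n2o <- n2o_state(lung, Fv_n2o, lambda_n2o, pattern)
    lam <- 10^log10_lambda_grid
    frac <- vapply(lam, function(l) {
      inc <- sum(l * lung$Q * Fv_sg)
      s1 <- sum(sg_outflow(l, VA = lung$VI, Q = lung$Q, Fv = Fv_sg))
      tot <- sum(sg_outflow(l, VA = n2o$VA, Q = lung$Q, Fv = Fv_sg))
      c(s1 / inc, (tot - s1) / inc, (tot - s1) / (inc - s1), tot / inc)
    }, numeric(4))
    data.frame(
      sigma = sg, Fv_n2o = Fv_n2o,
      log10_lambda = log10_lambda_grid, lambda = lam,
      frac_step1 = frac[1, ],
      frac_step2_of_incoming = frac[2, ],
      frac_step2_of_step2_input = frac[3, ],
      net_frac = frac[4, ]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Locate the solubility of maximum mismatch sensitivity
#'
#' Finds the `log10(lambda)` at which the gap between the eliminated-fraction
#' curves at the smallest and largest sigma in a [sweep_solubility()] table
#' is widest, reported at 0.25 resolution (the argmax on the fine grid is
#' rounded to the nearest multiple of 0.25; argmax ties and exact halfway
#' roundings resolve toward the lower solubility).
#'
#' @param table A [sweep_solubility()] data.frame containing at least two
#'   sigma values.
#' @param curve Which eliminated fraction to compare: `"step1"`, `"net"`, or
#'   `"step2"` (Step 2 relative to its own input).
#' @return A list: `log10_lambda` (rounded to 0.25), `log10_lambda_fine`
#'   (the grid argmax), `gap` (the maximal gap, low-sigma minus high-sigma),
#'   `sigma_low`, `sigma_high`.
#' @export
find_max_gap <- function(table, curve = c("step1", "net", "step2")) {
  curve <- match.arg(curve)
  col <- switch(curve,
    step1 = "frac_step1",
    net = "net_frac",
    step2 = "frac_step2_of_step2_input"
  )
  if (!nrow(table)) stop("empty sweep table", call. = FALSE)
  sig <- sort(unique(table$sigma))
  if (length(sig) < 2) {
    stop("need at least two sigma values to compare", call. = FALSE)
  }
  lo <- table[table$sigma == sig[1], ]
  hi <- table[table$sigma == sig[length(sig)], ]
  lo <- lo[order(lo$log10_lambda), ]
  hi <- hi[order(hi$log10_lambda), ]
  if (!isTRUE(all.equal(lo$log10_lambda, hi$log10_lambda))) {
    stop("sigma curves must share the same solubility grid", call. = FALSE)
  }
  gap <- abs(lo[[col]] - hi[[col]])
  i <- which.max(gap)                      # first index on ties: lower lambda
  fine <- lo$log10_lambda[i]
  # round to nearest 0.25, halfway toward the lower value
  coarse <- ceiling(fine / 0.25 - 0.5) * 0.25
  list(
    log10_lambda = coarse,
    log10_lambda_fine = fine,
    gap = gap[i],
    sigma_low = sig[1],
    sigma_high = sig[length(sig)]
  )
}
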