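#' Render the standard figures from a results directory
#'
#' Reads the tables written by [cmd_run()] — no recomputation — and renders
#' three figure layouts: the per-compartment distribution profile (stacked
#' Step 1 / Step 2 panels per gas, with the N2O efflux density on a second
#' scale), the eliminated-fraction-versus-sigma line chart (one line per gas,
#' least soluble on top), and the eliminated-fraction-versus-solubility
#' envelope chart contrasting the extreme sigma values with a dashed marker
#' at the peak-gap solubility.
#'
#' @param results_dir Directory containing `profile.csv` and/or the sweep
#'   tables and `summary.json`.
#' @param out_dir Where to write the image files. Default `results_dir`.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, the paths written.
#' @export
cmd_figures <- function(results_dir, out_dir = results_dir, format = "png") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  dev_width <- 9

  save_plot <- function(p, name, height = 5) {
    path <- file.path(out_dir, paste0(name, ".", format))
    ggplot2::ggsave(path, p, width = dev_width, height = height, dpi = 150)
    path
  }

  sig_path <- file.path(results_dir, "sigma_sweep.csv")
  if (file.exists(sig_path)) {
    sweep <- utils::read.csv(sig_path)
    written <- c(written, save_plot(plot_sigma_sweep(sweep), "sigma_sweep"))
  }

  sol_path <- file.path(results_dir, "solubility_sweep.csv")
  if (file.exists(sol_path)) {
    sweep <- utils::read.csv(sol_path)
    written <- c(written, save_plot(plot_solubility_sweep(sweep),
                                    "solubility_sweep", height = 9))
  }

  prof_path <- file.path(results_dir, "profile.csv")
  if (file.exists(prof_path)) {
    profile <- utils::read.csv(prof_path, check.names = FALSE)
    written <- c(written, save_plot(plot_profile(profile), "profile", height = 6))
  }

  if (!length(written)) {
    stop("no result tables found in ", results_dir, call. = FALSE)
  }
  invisible(written)
}

#' Eliminated fraction versus mismatch index
#'
#' One line per gas for each of the Step-1, Step-2 and net eliminated
#' fractions as functions of sigma; gases are ordered by solubility so the
#' least soluble sit at the top of the Step-1 panel.
#'
#' @param sweep A [sweep_sigma()] table.
#' @return A ggplot object.
#' @export
plot_sigma_sweep <- function(sweep) {
  long <- rbind(
    data.frame(sweep[c("sigma", "gas", "lambda")], panel = "Step 1",
               frac = sweep$frac_step1),
    data.frame(sweep[c("sigma", "gas", "lambda")], panel = "Step 2",
               frac = sweep$frac_step2_of_incoming),
    data.frame(sweep[c("sigma", "gas", "lambda")], panel = "Steps 1 + 2",
               frac = sweep$net_frac)
  )
  long$panel <- factor(long$panel, c("Step 1", "Step 2", "Steps 1 + 2"))
  ord <- unique(long$gas[order(long$lambda)])
  long$gas <- factor(long$gas, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(.data$sigma, .data$frac,
                                     colour = .data$gas)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::labs(x = expression(sigma), y = "Fraction of incoming SG eliminated",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Eliminated fraction versus solubility
#'
#' Step-1, Step-2 and net eliminated fractions as functions of
#' `log10(lambda)`, with the lowest sigma in red, the highest in blue, and
#' any intermediate curves in yellow; dashed vertical lines mark the
#' solubility of maximum gap between the extremes.
#'
#' @param sweep A [sweep_solubility()] table.
#' @return A ggplot object.
#' @export
plot_solubility_sweep <- function(sweep) {
  sig <- sort(unique(sweep$sigma))
  base <- sweep[c("sigma", "log10_lambda")]
  long <- rbind(
    data.frame(base, panel = "Step 1", frac = sweep$frac_step1),
    data.frame(base, panel = "Step 2 (of Step-2 input)",
               frac = sweep$frac_step2_of_step2_input),
    data.frame(base, panel = "Net (of incoming)", frac = sweep$net_frac)
  )
  long$panel <- factor(long$panel, unique(long$panel))
  long$band <- ifelse(long$sigma == sig[1], "low",
                      ifelse(long$sigma == sig[length(sig)], "high", "mid"))
  marks <- NULL
  if (length(sig) >= 2) {
    marks <- data.frame(
      panel = factor(c("Step 1", "Net (of incoming)"), levels(long$panel)),
      at = c(find_max_gap(sweep, "step1")$log10_lambda,
             find_max_gap(sweep, "net")$log10_lambda)
    )
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$log10_lambda, .data$frac,
                                          group = .data$sigma,
                                          colour = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(low = "red", high = "blue", mid = "gold"),
      labels = c(low = sprintf("sigma = %g", sig[1]),
                 high = sprintf("sigma = %g", sig[length(sig)]),
                 mid = "intermediate"),
      name = NULL
    ) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(log[10](lambda)),
                  y = "Fraction eliminated") +
    ggplot2::theme_minimal()
  if (!is.null(marks)) {
    p <- p + ggplot2::geom_vline(data = marks,
                                 ggplot2::aes(xintercept = .data$at),
                                 linetype = "dashed", colour = "black")
  }
  p
}

#' Per-compartment distribution profile figure
#'
#' Stacked Step-1 / Step-2 panels per gas over `log10(V/Q)`: the incoming
#' second gas, its eliminated and retained parts in each step, and the N2O
#' efflux distribution (rescaled onto the fraction axis, original units
#' L/min per unit `log10(V/Q)` on the right-hand axis).
#'
#' @param profile A `profile.csv` table as written by [cmd_run()].
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  gas_tags <- sub("^incoming_", "",
                  grep("^incoming_", names(profile), value = TRUE))
  inc_tot <- vapply(gas_tags,
                    function(g) sum(profile[[paste0("incoming_", g)]]),
                    numeric(1))
  dx <- profile$x_log10[2] - profile$x_log10[1]
  rows <- lapply(gas_tags, function(g) {
    inc <- profile[[paste0("incoming_", g)]] / inc_tot[[g]] / dx
    s1 <- profile[[paste0("step1_", g)]] / inc_tot[[g]] / dx
    s2 <- profile[[paste0("step2_", g)]] / inc_tot[[g]] / dx
    ret <- profile[[paste0("retained_", g)]] / inc_tot[[g]] / dx
    rbind(
      data.frame(x = profile$x_log10, gas = g, panel = "Step 1",
                 curve = "incoming", density = inc),
      data.frame(x = profile$x_log10, gas = g, panel = "Step 1",
                 curve = "eliminated", density = s1),
      data.frame(x = profile$x_log10, gas = g, panel = "Step 2",
                 curve = "incoming", density = inc - s1),
      data.frame(x = profile$x_log10, gas = g, panel = "Step 2",
                 curve = "eliminated", density = s2),
      data.frame(x = profile$x_log10, gas = g, panel = "Step 2",
                 curve = "retained", density = ret)
    )
  })
  long <- do.call(rbind, rows)
  n2o_scale <- max(profile$n2o_efflux) /
    (dx * max(long$density[long$curve == "incoming"]))
  n2o <- data.frame(x = profile$x_log10, gas = gas_tags[1], panel = "Step 2",
                    curve = "n2o", density = profile$n2o_efflux / dx / n2o_scale)
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$density,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_area(data = n2o, fill = "yellow", alpha = 0.4,
                       colour = NA) +
    ggplot2::facet_grid(gas ~ panel) +
    ggplot2::scale_colour_manual(values = c(incoming = "grey30",
                                            eliminated = "blue",
                                            retained = "red",
                                            n2o = "yellow")) +
    ggplot2::labs(x = expression(log[10](dot(V) / dot(Q))),
                  y = "Density (fraction of incoming SG per unit x)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
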