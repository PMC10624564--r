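#' Default configuration
#'
#' The fully resolved default configuration for [cmd_run()]. Every key shown
#' here may be overridden from a YAML/JSON config file or a dotted-path
#' command-line override; the resolved values are echoed into the run
#' manifest so no default is hidden.
#'
#' @return A nested list with blocks `lung`, `gases`, `scenario`, `sweeps`,
#'   `output`.
#' @export
default_config <- function() {
  second <- default_second_gases()
  list(
    lung = list(sigma = 2, N = 1001L, span = 5, VI_total = 4, Q_total = 5),
    gases = list(
      n2o_lambda = 0.47,
      second = stats::setNames(as.list(second$lambda), second$name)
    ),
    scenario = list(
      Fv_sg = 0.01,
      n2o_mode = "target",          # "target" or "fixed"
      target_elimination = 0.5,     # L/min, used when n2o_mode == "target"
      Fv_n2o = 0.7,                 # used when n2o_mode == "fixed"
      Fv_n2o_cap = 0.7,
      ventilation_pattern = "constant_inflow",
      profile_gases = c("sulfur hexafluoride", "sevoflurane",
                        "halothane", "diethyl ether")
    ),
    sweeps = list(
      sigma = list(enabled = TRUE, from = 0, to = 2, by = 0.25),
      solubility = list(enabled = TRUE, from = -2.5, to = 1.5, by = 0.01,
                        sigma_set = c(0, 2))
    ),
    output = list(digits = 12)
  )
}

#' Load a configuration file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration and merges
#' it over [default_config()]: keys absent from the file keep their default.
#' Unknown top-level blocks or keys are rejected with the offending field
#' path.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @param overrides Optional named list of dotted-path overrides, e.g.
#'   `list("lung.sigma" = 1, "scenario.target_elimination" = 0.6)`; applied
#'   after the file.
#' @return The resolved configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    user <- switch(ext,
      yml = , yaml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop("config must be .yaml/.yml or .json, got .", ext, call. = FALSE)
    )
    if (!is.list(user)) stop("config file must contain a mapping", call. = FALSE)
    config <- merge_config(config, user, "")
  }
  for (key in names(overrides)) {
    config <- set_dotted(config, key, overrides[[key]])
  }
  validate_config(config)
  config
}

# Recursive merge of user values over defaults; unknown keys are errors so
# that typos surface with their field path.
merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown config key: ", path, call. = FALSE)
    }
    # the gas map replaces wholesale: a config listing one second gas runs
    # with exactly that gas
    if (identical(path, "gases.second")) {
      base[[key]] <- user[[key]]
      next
    }
    if (is.list(base[[key]]) && is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], path)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

set_dotted <- function(config, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  node <- config
  for (i in seq_along(parts[-length(parts)])) {
    node <- node[[parts[i]]]
    if (is.null(node)) stop("unknown config key: ", key, call. = FALSE)
  }
  config[[parts]] <- value
  config
}

validate_config <- function(config) {
  fail <- function(path, msg) {
    stop("invalid config at ", path, ": ", msg, call. = FALSE)
  }
  with(config$lung, {
    if (sigma < 0) fail("lung.sigma", "must be >= 0")
    if (N < 1 || N %% 2 == 0) fail("lung.N", "must be a positive odd integer")
    if (VI_total <= 0 || Q_total <= 0) {
      fail("lung.VI_total/Q_total", "must be > 0")
    }
  })
  if (config$gases$n2o_lambda <= 0) fail("gases.n2o_lambda", "must be > 0")
  sg <- unlist(config$gases$second)
  if (any(sg <= 0)) fail("gases.second", "all lambda must be > 0")
  sc <- config$scenario
  if (sc$Fv_sg < 0 || sc$Fv_sg >= 1) fail("scenario.Fv_sg", "must lie in [0, 1)")
  if (!sc$n2o_mode %in% c("target", "fixed")) {
    fail("scenario.n2o_mode", "must be 'target' or 'fixed'")
  }
  if (sc$n2o_mode == "fixed" &&
      (sc$Fv_n2o < 0 || sc$Fv_n2o > sc$Fv_n2o_cap)) {
    fail("scenario.Fv_n2o", "must lie in [0, Fv_n2o_cap]")
  }
  if (!sc$ventilation_pattern %in% c("constant_inflow", "constant_outflow")) {
    fail("scenario.ventilation_pattern",
         "must be 'constant_inflow' or 'constant_outflow'")
  }
  invisible(config)
}

config_gases <- function(config) {
  sg <- config$gases$second
  reg <- data.frame(
    name = names(sg),
    lambda = as.numeric(unlist(sg)),
    role = "second",
    stringsAsFactors = FALSE
  )
  reg <- reg[order(reg$lambda), , drop = FALSE]
  rownames(reg) <- NULL
  validate_gas_registry(reg)
  reg
}
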