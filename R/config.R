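# Structured run configuration: JSON files with unit-suffixed keys,
# schema-validated before any computation.

.config_error <- function(...) {
  stop(structure(class = c("zulfspin_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read and validate a run configuration
#'
#' A run configuration is a JSON object with blocks `spin_system`
#' (`label`, `isotopes`, `J_Hz`), optional `exchange` (`mechanism`,
#' `traced`, `k_d_s`, `W_a_s`, `pH`, `pKa`), `protocol` (`type` = "zulf" or
#' "highfield" plus the fields of [zulf_protocol()] /
#' [highfield_protocol()]), optional `relaxation` (`T1_C_s`, `T1_A_s`),
#' optional `processing` (`apodization_s`, `zero_fill`,
#' `min_rel_amplitude`, `exclude_hz`, `mode`) and optional `seed`. All
#' physical quantities carry their unit in the key name.
#'
#' @param path Path to a JSON configuration file.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .config_error("config file not found: ", path)
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    .config_error("malformed JSON in ", path, ": ",
                                  conditionMessage(e)))
  validate_run_config(cfg)
}

#' Validate an in-memory run configuration
#'
#' @param cfg Configuration list (see [read_run_config()]).
#' @return The configuration, classed `run_config`, invisibly usable.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$spin_system))
    .config_error("config misses the 'spin_system' block")
  ss <- cfg$spin_system
  if (is.null(ss$isotopes) || is.null(ss$J_Hz))
    .config_error("spin_system needs 'isotopes' and 'J_Hz'")
  J <- as.matrix(ss$J_Hz)
  n <- length(ss$isotopes)
  if (!all(dim(J) == c(n, n)))
    .config_error("J_Hz must be a ", n, " x ", n, " matrix")
  if (max(abs(J - t(J))) > 1e-9 * max(1, max(abs(J))))
    .config_error("J_Hz matrix must be symmetric")
  if (!all(ss$isotopes %in% isotope_table()$symbol))
    .config_error("unsupported isotope in spin_system")
  ex <- cfg$exchange
  if (!is.null(ex)) {
    if (!is.null(ex$mechanism) &&
        !ex$mechanism %in% c("generic", "single", "all"))
      .config_error("exchange mechanism must be generic, single or all")
    if (!is.null(ex$k_d_s) && ex$k_d_s < 0)
      .config_error("k_d_s must be non-negative")
    if ((is.null(ex$mechanism) || ex$mechanism == "generic") &&
        is.null(ex$traced))
      .config_error("generic exchange needs 'traced' spin indices")
  }
  pr <- cfg$protocol
  if (!is.null(pr)) {
    if (is.null(pr$type) || !pr$type %in% c("zulf", "highfield"))
      .config_error("protocol type must be 'zulf' or 'highfield'")
    if (!is.null(pr$dwell_s) && pr$dwell_s <= 0)
      .config_error("dwell_s must be positive")
    if (!is.null(pr$n_points) && pr$n_points < 2)
      .config_error("n_points must be at least 2")
  }
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Write a run configuration to JSON
#'
#' The writer round-trips with [read_run_config()].
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  class(cfg) <- "list"
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Instantiate model and protocol objects from a configuration
#'
#' @param cfg A validated `run_config` (see [read_run_config()]).
#' @return List with `model` ([exchange_model()]), `protocol`, `processing`
#'   (defaults filled in) and `seed`.
#' @export
config_to_model <- function(cfg) {
  cfg <- validate_run_config(cfg)
  ss <- cfg$spin_system
  sys <- spin_system(ss$isotopes, as.matrix(ss$J_Hz), label = ss$label)
  ex <- cfg$exchange
  rx <- cfg$relaxation
  if (is.null(ex)) {
    model <- exchange_model(sys, T1_C = rx$T1_C_s)
  } else {
    mech <- ex$mechanism %||% "generic"
    pair <- if (mech %in% c("single", "all")) {
      ammonium_pair(mechanism = mech, J_NH = as.matrix(ss$J_Hz)[1, 5])
    } else {
      exchange_pair(sys, traced = ex$traced)
    }
    model <- exchange_model(pair, k_d = ex$k_d_s %||% 0, W_a = ex$W_a_s,
                            pH = ex$pH, pKa = ex$pKa,
                            T1_C = rx$T1_C_s, T1_A = rx$T1_A_s)
  }
  pr <- cfg$protocol %||% list(type = "zulf")
  protocol <- if (pr$type == "highfield") {
    highfield_protocol(dwell_s = pr$dwell_s %||% 2e-3,
                       n_points = pr$n_points %||% 4000,
                       observe = pr$observe %||% "15N")
  } else {
    zulf_protocol(
      B_polarize_T = pr$B_polarize_T %||% 2,
      temperature_K = pr$temperature_K %||% 298,
      t_shuttle_s = pr$t_shuttle_s %||% 0.5,
      B_guide_T = pr$B_guide_T %||% 30e-6,
      B_residual_T = pr$B_residual_T %||% c(0, 0, 0),
      dwell_s = pr$dwell_s %||% 1e-3,
      n_points = pr$n_points %||% 16000,
      detection_axis = pr$detection_axis %||% "z")
  }
  proc <- cfg$processing %||% list()
  proc$zero_fill <- proc$zero_fill %||% 1L
  proc$min_rel_amplitude <- proc$min_rel_amplitude %||% 0.05
  proc$exclude_hz <- proc$exclude_hz %||%
    (if (pr$type == "highfield") 0 else 2)
  proc$mode <- proc$mode %||% "magnitude"
  list(model = model, protocol = protocol, processing = proc,
       seed = cfg$seed %||% 1L)
}

#' Serialize a fixture into a run configuration
#'
#' @param fx A fixture from [zulf_fixture()].
#' @param k_d,W_a,pH,pKa Exchange parameters to embed.
#' @return A `run_config` list.
#' @export
fixture_to_config <- function(fx, k_d = 0, W_a = NULL, pH = NULL,
                              pKa = NULL) {
  sys <- fx$system
  cfg <- list(
    label = fx$name,
    spin_system = list(label = sys$label, isotopes = sys$isotopes,
                       J_Hz = sys$J_Hz),
    protocol = c(list(type = fx$protocol$type), fx$protocol[
      setdiff(names(fx$protocol), "type")])
  )
  if (!is.null(fx$pair)) {
    cfg$exchange <- list(
      mechanism = fx$pair$mechanism,
      traced = if (!anyNA(fx$pair$traced)) fx$pair$traced,
      k_d_s = k_d, W_a_s = W_a, pH = pH, pKa = pKa)
  }
  validate_run_config(cfg)
}
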