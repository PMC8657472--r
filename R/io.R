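# Allowed run-config schema (top-level key -> allowed sub-keys; NULL = scalar)
config_schema <- list(
  segment = NULL,
  circuit = c("L", "C", "R", "kind"),
  vessel = c("r", "h", "E", "rho", "mu", "cL", "cR", "kind"),
  waveform = c("type", "mode", "path", "P0", "P0sin", "k", "t0"),
  grid = c("dt", "periods"),
  sign = NULL,
  analytics = c("reflux", "hysteresis", "transient_periods"),
  output = c("response_csv", "analytics_json", "log"),
  seed = NULL
)

config_error <- function(msg) {
  abort(msg, class = c("fractalflow_config_error", "fractalflow_domain_error"))
}

#' Read and validate a YAML run configuration
#'
#' A run configuration describes one simulation: the segment, its circuit
#' (or vessel) parameters, the driving waveform (built-in pulse or external
#' CSV), the time grid, the analytics to compute and the output paths.
#' Unknown keys are rejected so typos fail loudly, and a loaded
#' configuration survives a dump/load round trip unchanged.
#'
#' @param path YAML file path.
#' @return the validated configuration as a named list of class
#'   `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as from [yaml::read_yaml()]).
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) config_error("configuration must be a mapping.")
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    config_error(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  for (key in intersect(names(cfg), names(config_schema))) {
    allowed <- config_schema[[key]]
    if (!is.null(allowed) && is.list(cfg[[key]])) {
      bad <- setdiff(names(cfg[[key]]), allowed)
      if (length(bad)) {
        config_error(sprintf("unknown key(s) under `%s`: %s",
                             key, paste(bad, collapse = ", ")))
      }
    }
  }
  segment <- cfg$segment %||% "aorta"
  if (!segment %in% c("aorta", "arteriole")) {
    config_error("`segment` must be \"aorta\" or \"arteriole\".")
  }
  if (!is.null(cfg$circuit)) {
    if (is.null(cfg$circuit$C) || cfg$circuit$C <= 0) {
      config_error("`circuit$C` must be positive.")
    }
    tau_par <- if (segment == "aorta") cfg$circuit$L else cfg$circuit$R
    if (!is.null(tau_par) && tau_par <= 0) {
      config_error("circuit parameter defining tau must be positive.")
    }
  }
  g <- cfg$grid %||% list()
  if (!is.null(g$dt) && g$dt <= 0) config_error("`grid$dt` must be positive.")
  if (!is.null(g$periods) && g$periods < 1) {
    config_error("`grid$periods` must be >= 1.")
  }
  wf <- cfg$waveform %||% list()
  if (!is.null(wf$t0) && wf$t0 <= 0) config_error("`waveform$t0` must be positive.")
  if (!is.null(wf$type) && !wf$type %in% c("pulse", "csv")) {
    config_error("`waveform$type` must be \"pulse\" or \"csv\".")
  }
  structure(cfg, class = "run_config")
}

fmt17 <- function(x) {
  if (is.numeric(x)) signif(x, 17) else x
}

write_csv17 <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run one simulation scenario from a configuration
#'
#' Resolves the configuration (direct circuit values take precedence over
#' vessel parameters), builds the waveform, solves the flow response, and
#' writes the requested artifacts: a response CSV (`t`, `P`, `Q`,
#' `Q_deriv_part`, `Q_conv_part`, 17 significant digits so round trips are
#' exact), an analytics JSON (reflux intervals, loop area, phase lag), and
#' a log echoing the resolved parameters. The pipeline is deterministic:
#' the same configuration always produces byte-identical outputs.
#'
#' @param config a `run_config`, a raw configuration list, or a YAML path.
#' @param base_dir directory against which relative output paths are
#'   resolved (defaults to the working directory).
#' @return invisibly, a list with the resolved parameters, the
#'   [flow_response()] object, the analytics list and the written paths.
#' @export
run_scenario <- function(config, base_dir = ".") {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)

  segment <- config$segment %||% "aorta"
  if (!is.null(config$circuit)) {
    cp <- circuit_params(kind = config$circuit$kind %||% segment,
                         L = config$circuit$L %||% NA_real_,
                         C = config$circuit$C,
                         R = config$circuit$R %||% NA_real_)
  } else if (!is.null(config$vessel)) {
    v <- config$vessel
    seg <- vessel_segment(kind = v$kind %||% segment, r = v$r, h = v$h,
                          E = v$E, rho = v$rho %||% 1.05,
                          mu = v$mu %||% 0.04,
                          cL = v$cL %||% 1, cR = v$cR %||% 1)
    cp <- map_vessel_to_circuit(seg)
  } else {
    cp <- circuit_params(kind = segment,
                         L = if (segment == "aorta") 6.25 else NA_real_,
                         C = if (segment == "aorta") 1 else 0.1,
                         R = if (segment == "arteriole") 50 else NA_real_)
  }

  g <- config$grid %||% list()
  dt <- g$dt %||% 0.001
  periods <- g$periods %||% 3
  wf <- config$waveform %||% list(type = "pulse")
  waveform <- if ((wf$type %||% "pulse") == "csv") {
    read_waveform_csv(wf$path, dt = dt)
  } else {
    pp <- pulse_params(segment = segment, P0 = wf$P0, P0sin = wf$P0sin,
                       k = wf$k, t0 = wf$t0 %||% 0.8)
    sample_waveform(pp, dt = dt, n_periods = periods,
                    mode = wf$mode %||% "continuous")
  }

  resp <- tryCatch(
    flow_response(waveform, segment = segment, C = cp$C, tau = cp$tau,
                  sign = config$sign),
    error = function(e) {
      if (inherits(e, "fractalflow_domain_error")) stop(e)
      abort(paste0("numerical failure in flow solver: ",
                   conditionMessage(e)),
            class = "fractalflow_numeric_error")
    }
  )

  an <- config$analytics %||% list()
  analytics <- list(parameters = list(segment = segment, C = cp$C,
                                      tau = cp$tau, dt = dt,
                                      sign = resp$sign))
  if (an$reflux %||% TRUE) {
    analytics$reflux_intervals <- as.data.frame(detect_reflux(resp))
  }
  if ((an$hysteresis %||% TRUE) && !is.na(resp$period)) {
    loop <- hysteresis_loop(resp,
                            n_transient_periods = an$transient_periods %||%
                              min(2, periods - 1))
    analytics$loop_area <- loop$area
    analytics$phase_lag_s <- loop$phase_lag
    analytics$loop_closure_gap <- loop$closure_gap
  }

  out <- config$output %||% list()
  paths <- list()
  if (!is.null(out$response_csv)) {
    p <- file.path(base_dir, out$response_csv)
    write_csv17(resp$data, p)
    paths$response_csv <- p
  }
  if (!is.null(out$analytics_json)) {
    p <- file.path(base_dir, out$analytics_json)
    jsonlite::write_json(analytics, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths$analytics_json <- p
  }
  log_lines <- c(
    sprintf("fractalflow %s", as.character(utils::packageVersion("fractalflow"))),
    sprintf("segment=%s C=%.17g tau=%.17g sign=%s dt=%.17g periods=%g",
            segment, cp$C, cp$tau, resp$sign, dt, periods)
  )
  if (!is.null(out$log)) {
    p <- file.path(base_dir, out$log)
    writeLines(log_lines, p)
    paths$log <- p
  } else {
    message(paste(log_lines, collapse = "\n"))
  }
  invisible(list(parameters = analytics$parameters, response = resp,
                 analytics = analytics, paths = paths))
}

#' Write the bundled scenario configurations
#'
#' Emits the YAML configurations for the package's reference scenarios:
#' the dimensionless Gaussian kernel family, the kernel sweeps over
#' characteristic time and compliance for both segments (aorta `C = 1`,
#' `tau = 2.5 s`; arteriole `C = 0.1`, `tau = 5 s`), the two-harmonic
#' pulse simulations for both segments (`t0 = 0.8 s`) with their tau
#' families, and the finite-ladder truncation study. Regeneration is
#' byte-identical.
#'
#' @param out_dir writable output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
generate_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory `%s`.", out_dir),
                   class = "fractalflow_domain_error")
  }
  if (file.access(out_dir, 2) != 0) {
    abort(sprintf("directory `%s` is not writable.", out_dir),
          class = "fractalflow_domain_error")
  }
  fixtures <- list(
    kernel_family.yaml = list(
      task = "kernel_family",
      which = c("gauss_basic", "gauss_complement", "gauss_quotient",
                "gauss_qq"),
      grid = list(t_max = 3, dt = 0.01)
    ),
    kernel_sweep_tau_aorta.yaml = list(
      task = "kernel_sweep", kind = "gkf_qq", C = 1,
      tau = c(1.5, 2, 2.5, 3.5, 5),
      grid = list(t_max = 10, dt = 0.01)
    ),
    kernel_sweep_compliance_aorta.yaml = list(
      task = "kernel_sweep", kind = "gkf_qq", tau = 2.5,
      C = c(0.5, 1, 1.5, 2),
      grid = list(t_max = 10, dt = 0.01)
    ),
    kernel_sweep_tau_arteriole.yaml = list(
      task = "kernel_sweep", kind = "bkf_nef", C = 0.1,
      tau = c(1.5, 3, 5, 8),
      grid = list(t_max = 10, dt = 0.01)
    ),
    kernel_sweep_compliance_arteriole.yaml = list(
      task = "kernel_sweep", kind = "bkf_nef", tau = 5,
      C = c(0.05, 0.1, 0.2),
      grid = list(t_max = 10, dt = 0.01)
    ),
    pulse_aorta.yaml = list(
      segment = "aorta",
      circuit = list(C = 1, L = 6.25),
      waveform = list(type = "pulse", mode = "continuous", t0 = 0.8),
      grid = list(dt = 0.001, periods = 3),
      output = list(response_csv = "pulse_aorta_response.csv",
                    analytics_json = "pulse_aorta_analytics.json",
                    log = "pulse_aorta.log")
    ),
    pulse_arteriole.yaml = list(
      segment = "arteriole",
      circuit = list(C = 0.1, R = 50),
      waveform = list(type = "pulse", mode = "continuous", t0 = 0.8),
      grid = list(dt = 0.001, periods = 3),
      output = list(response_csv = "pulse_arteriole_response.csv",
                    analytics_json = "pulse_arteriole_analytics.json",
                    log = "pulse_arteriole.log")
    ),
    ladder_truncation.yaml = list(
      task = "ladder",
      t1 = list(kind = "scalar", coefficient = 1),
      t2 = list(kind = "scalar", coefficient = 1),
      levels = 4, boundary = "grounded"
    )
  )
  paths <- character(0)
  for (nm in names(fixtures)) {
    p <- file.path(out_dir, nm)
    yaml::write_yaml(fixtures[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
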