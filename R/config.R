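# YAML run configuration and the command functions behind the CLI driver
# (inst/cli/lvrsim.R). Key names mirror the constructor arguments; unknown
# keys are rejected before any computation.

config_keys <- list(
  top = c("scenario", "calibration", "treatment", "sweep"),
  scenario = c("name", "height", "n_total", "v_max", "v_min", "k", "p_tm",
               "p_tlc_apex", "p_rv_apex", "rho_frac", "n_layers"),
  calibration = c("rv_tlc", "rv_l", "tolerance"),
  treatment = c("n_removed", "p_tlc_apex_post", "p_tm_post", "height_post",
                "lobe_fraction"),
  sweep = c("parameters", "span", "points", "mode", "dominance")
)

abort_config <- function(msg, ...) {
  abort_invalid(msg, ..., class = c("lvrsim_error_config", "lvrsim_error_invalid_input"))
}

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown) > 0) {
    abort_config("unknown key(s) in {where}: {keys}.",
                 where = where, keys = paste(unknown, collapse = ", "))
  }
}

#' Read and validate a YAML run configuration
#'
#' The configuration has up to four blocks: `scenario` (a preset name,
#' `"healthy"` or `"emphysema"`, or an inline mapping whose keys mirror
#' [scenario_spec()] with flattened `v_max`/`v_min`/`k`), `calibration`
#' (anchors `rv_tlc`, `rv_l` and `tolerance`, applied to the scenario),
#' `treatment` (shared shift `n_removed`, `p_tlc_apex_post`, `p_tm_post`,
#' `height_post`, `lobe_fraction`; the upper- and lower-lobe arms are derived
#' from it), and `sweep` (`parameters`, `span`, `points`, `mode`,
#' `dominance`). Unknown keys anywhere are rejected.
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with the resolved `scenario`
#'   ([scenario_spec()]), optional `treatment` (list with `ult` and `llt`
#'   [treatment_spec()]s), optional `sweep` argument list, and `raw` (the
#'   parsed YAML, embedded in outputs for provenance).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: {path}.", path = path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) abort_config("config must be a YAML mapping.")
  check_keys(raw, config_keys$top, "config")
  if (is.null(raw$scenario)) abort_config("config must contain a `scenario` block.")

  sc <- raw$scenario
  if (is.character(sc) && length(sc) == 1) {
    scenario <- switch(sc,
      healthy = healthy_preset(),
      emphysema = emphysema_preset(calibrate = is.null(raw$calibration)),
      abort_config("unknown scenario preset \"{sc}\" (use \"healthy\" or \"emphysema\").", sc = sc)
    )
  } else if (is.list(sc)) {
    check_keys(sc, config_keys$scenario, "scenario")
    need <- c("height", "n_total", "v_max", "v_min", "k", "p_tm", "p_tlc_apex")
    missing <- setdiff(need, names(sc))
    if (length(missing) > 0) {
      abort_config("scenario block is missing: {keys}.", keys = paste(missing, collapse = ", "))
    }
    scenario <- scenario_spec(
      name = sc$name %||% "custom", height = sc$height, n_total = sc$n_total,
      params = alveolar_params(sc$v_max, sc$v_min, sc$k),
      p_tlc_apex = sc$p_tlc_apex, p_rv_apex = sc$p_rv_apex %||% NA_real_,
      p_tm = sc$p_tm, rho_frac = sc$rho_frac %||% 0.25,
      n_layers = sc$n_layers %||% 350
    )
  } else {
    abort_config("`scenario` must be a preset name or a mapping.")
  }

  if (!is.null(raw$calibration)) {
    cb <- raw$calibration
    check_keys(cb, config_keys$calibration, "calibration")
    if (is.null(cb$rv_tlc)) abort_config("calibration block needs an `rv_tlc` anchor.")
    scenario <- calibrate_scenario(scenario, rv_tlc = cb$rv_tlc,
                                   rv_l = cb$rv_l,
                                   tolerance = cb$tolerance %||% 1e-6)
  }

  treatment <- NULL
  if (!is.null(raw$treatment)) {
    tr <- raw$treatment
    check_keys(tr, config_keys$treatment, "treatment")
    need <- c("n_removed", "p_tlc_apex_post", "p_tm_post", "height_post")
    missing <- setdiff(need, names(tr))
    if (length(missing) > 0) {
      abort_config("treatment block is missing: {keys}.", keys = paste(missing, collapse = ", "))
    }
    frac <- tr$lobe_fraction %||% 0.5
    mk <- function(lobe) treatment_spec(
      region = lobe_region(scenario$height, lobe, frac),
      n_removed = tr$n_removed, p_tlc_apex_post = tr$p_tlc_apex_post,
      p_tm_post = tr$p_tm_post, height_post = tr$height_post
    )
    treatment <- list(ult = mk("upper"), llt = mk("lower"))
  }

  sweep <- NULL
  if (!is.null(raw$sweep)) {
    sw <- raw$sweep
    check_keys(sw, config_keys$sweep, "sweep")
    sweep <- list(
      parameters = sw$parameters %||% c("n", "k", "vmin_vmax", "p_tm"),
      span = sw$span %||% 0.25, points = sw$points %||% 3,
      mode = sw$mode %||% "one_at_a_time",
      dominance = isTRUE(sw$dominance)
    )
  }

  structure(list(scenario = scenario, treatment = treatment, sweep = sweep, raw = raw),
            class = "run_config")
}

provenance_extra <- function(config) {
  extra <- list(config = config$raw)
  cal <- attr(config$scenario, "calibration")
  if (!is.null(cal)) extra$calibration <- cal
  extra
}

#' Run the `simulate` command
#'
#' Simulates the configured scenario and writes `regional_profile.csv` and
#' `summary.json` (with the resolved configuration and any calibration
#' provenance embedded) into `out_dir`.
#'
#' @param config A [read_run_config()] result (or a path to a YAML file).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of written file paths, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- simulate_scenario(config$scenario)
  paths <- c(
    write_profile_csv(run$profile, file.path(out_dir, "regional_profile.csv")),
    write_summary_json(run, file.path(out_dir, "summary.json"),
                       extra = provenance_extra(config))
  )
  invisible(paths)
}

#' Run the `calibrate` command
#'
#' Writes the calibrated scenario (parameters plus calibration provenance)
#' to `scenario.json`. The configuration must contain a `calibration` block.
#'
#' @inheritParams cmd_simulate
#' @return The written file path, invisibly.
#' @export
cmd_calibrate <- function(config, out_dir) {
  config <- as_run_config(config)
  cal <- attr(config$scenario, "calibration")
  if (is.null(cal)) abort_config("`calibrate` needs a `calibration` block in the config.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scenario
  payload <- list(
    name = sc$name, height = sc$height, n_total = sc$n_total,
    v_max = sc$params$v_max, v_min = sc$params$v_min, k = sc$params$k,
    p_tm = sc$p_tm, p_tlc_apex = sc$p_tlc_apex, p_rv_apex = sc$p_rv_apex,
    rho_frac = sc$rho_frac, n_layers = sc$n_layers,
    calibration = cal, config = config$raw,
    package_version = as.character(utils::packageVersion("lvrsim"))
  )
  path <- file.path(out_dir, "scenario.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the `treat` command
#'
#' Compares the upper- and lower-lobe treatment arms on the configured
#' scenario and writes `comparison.json`.
#'
#' @inheritParams cmd_simulate
#' @return The written file path, invisibly.
#' @export
cmd_treat <- function(config, out_dir) {
  config <- as_run_config(config)
  if (is.null(config$treatment)) abort_config("`treat` needs a `treatment` block in the config.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_ult_llt(config$scenario, config$treatment$ult, config$treatment$llt)
  invisible(write_comparison_json(cmp, file.path(out_dir, "comparison.json"),
                                  extra = provenance_extra(config)))
}

#' Run the `sweep` command
#'
#' Writes the parameter-sweep table to `sweep.csv` and, when the sweep block
#' sets `dominance: true` and a `treatment` block is present, the
#' upper-lobe-dominance report to `dominance.json`.
#'
#' @inheritParams cmd_simulate
#' @return Character vector of written file paths, invisibly.
#' @export
cmd_sweep <- function(config, out_dir) {
  config <- as_run_config(config)
  if (is.null(config$sweep)) abort_config("`sweep` needs a `sweep` block in the config.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sw <- config$sweep
  spec <- sweep_spec(config$scenario, parameters = sw$parameters, span = sw$span,
                     points = sw$points, mode = sw$mode)
  res <- run_sweep(spec)
  paths <- file.path(out_dir, "sweep.csv")
  utils::write.csv(tibble::as_tibble(res), paths, row.names = FALSE,
                   fileEncoding = "UTF-8")
  if (sw$dominance) {
    if (is.null(config$treatment)) {
      abort_config("dominance scan needs a `treatment` block in the config.")
    }
    dom <- dominance_scan(config$scenario, config$treatment$ult, config$treatment$llt,
                          parameters = sw$parameters, span = sw$span, points = sw$points)
    dp <- file.path(out_dir, "dominance.json")
    jsonlite::write_json(
      list(fraction = dom$fraction, n_ok = dom$n_ok, n_error = dom$n_error,
           table = dom$table, config = config$raw,
           package_version = as.character(utils::packageVersion("lvrsim"))),
      dp, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
    paths <- c(paths, dp)
  }
  invisible(paths)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1) return(read_run_config(config))
  abort_config("`config` must be a run_config or a path to a YAML file.")
}
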