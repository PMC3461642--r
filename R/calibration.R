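#' Calibration target
#'
#' Anchors the under-specified degrees of freedom of a scenario to a stated
#' whole-lung quantity.
#'
#' @param quantity One of `"rv_tlc"` (overall RV/TLC, dimensionless) or
#'   `"rv_l"` (overall RV, liters).
#' @param value Target value.
#' @param tolerance Convergence tolerance (default `1e-6`).
#' @return An object of class `calibration_target`.
#' @export
calibration_target <- function(quantity = c("rv_tlc", "rv_l"), value,
                               tolerance = 1e-6) {
  quantity <- match.arg(quantity)
  check_number(value, "value")
  check_number(tolerance, "tolerance")
  if (tolerance <= 0) abort_invalid("`tolerance` must be > 0.")
  if (quantity == "rv_tlc" && (value <= 0 || value >= 1)) {
    abort_invalid("an RV/TLC target must lie in (0, 1).")
  }
  if (quantity == "rv_l" && value <= 0) abort_invalid("an RV target must be > 0 L.")
  structure(list(quantity = quantity, value = value, tolerance = tolerance),
            class = "calibration_target")
}

scenario_rv_tlc <- function(scenario, p_rv_apex) {
  sc <- scenario
  sc$p_rv_apex <- p_rv_apex
  simulate_scenario(sc)$summary$rv_tlc
}

#' Calibrate the deflation-limb apical pressure
#'
#' The model does not fix the apical transpulmonary pressure at residual
#' volume; it is resolved by Brent root-finding so the simulated whole-lung
#' RV/TLC hits the target anchor. Overall RV/TLC is strictly increasing in
#' the deflation pressure over the bracket (higher deflation pressure leaves
#' every open alveolus more inflated and moves closure caudally), so the root
#' is unique; this monotonicity is verified numerically at the bracket ends.
#'
#' @param scenario A [scenario_spec()] (its `p_rv_apex` is ignored).
#' @param target A [calibration_target()] on `"rv_tlc"`.
#' @param bracket Search interval for the pressure; default
#'   `c(p_tm - 2, p_tlc_apex - 0.5)` cm H2O.
#' @return The calibrated `p_rv_apex` (cm H2O) with attributes `achieved`
#'   (the re-simulated RV/TLC) and `iterations`.
#' @examples
#' sc <- emphysema_preset(calibrate = FALSE)
#' calibrate_deflation_pressure(sc, calibration_target("rv_tlc", 0.68))
#' @export
calibrate_deflation_pressure <- function(scenario, target, bracket = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(target, "calibration_target"))
  if (target$quantity != "rv_tlc") {
    abort_invalid("deflation-pressure calibration expects an \"rv_tlc\" target.")
  }
  if (is.null(bracket)) bracket <- c(scenario$p_tm - 2, scenario$p_tlc_apex - 0.5)
  f <- function(p) scenario_rv_tlc(scenario, p) - target$value
  f_lo <- f(bracket[1])
  f_hi <- f(bracket[2])
  if (f_lo > 0 || f_hi < 0) {
    rlang::abort(
      sprintf(
        "target RV/TLC %.4g is unattainable: attainable range over the bracket is [%.4g, %.4g].",
        target$value, f_lo + target$value, f_hi + target$value
      ),
      class = "lvrsim_error_unattainable"
    )
  }
  root <- stats::uniroot(f, interval = bracket, f.lower = f_lo, f.upper = f_hi,
                         tol = .Machine$double.eps^0.75)
  achieved <- root$f.root + target$value
  if (abs(root$f.root) > target$tolerance) {
    rlang::abort("deflation-pressure calibration failed to converge.",
                 class = "lvrsim_error_unattainable")
  }
  structure(root$root, achieved = achieved, iterations = root$iter)
}

#' Calibrate the absolute alveolar volume scale
#'
#' Whole-lung RV is exactly proportional to a common scale applied to
#' `(Vmax, Vmin)` at fixed `Vmin/Vmax` (every per-alveolus volume scales
#' linearly and RV/TLC is unchanged), so the scale factor solving
#' `RV = target` is closed form: `scale = target / RV(scale = 1)`.
#'
#' @param scenario A calibrated-deflation [scenario_spec()].
#' @param target A [calibration_target()] on `"rv_l"`.
#' @return The scale factor to apply to `(v_max, v_min)`, with attribute
#'   `achieved` (the re-simulated RV after scaling).
#' @export
calibrate_volume_scale <- function(scenario, target) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(target, "calibration_target"))
  if (target$quantity != "rv_l") {
    abort_invalid("volume-scale calibration expects an \"rv_l\" target.")
  }
  rv1 <- simulate_scenario(scenario)$summary$rv_l
  if (rv1 <= 0) {
    rlang::abort("degenerate scenario: RV at unit scale is zero.",
                 class = "lvrsim_error_degenerate")
  }
  s <- target$value / rv1
  sc <- scale_scenario_volumes(scenario, s)
  structure(s, achieved = simulate_scenario(sc)$summary$rv_l)
}

scale_scenario_volumes <- function(scenario, scale) {
  scenario$params <- alveolar_params(scenario$params$v_max * scale,
                                     scenario$params$v_min * scale,
                                     scenario$params$k)
  scenario
}

#' Calibrate a scenario against its two baseline anchors
#'
#' Runs [calibrate_deflation_pressure()] (anchor: overall RV/TLC) then
#' [calibrate_volume_scale()] (anchor: overall RV in liters; provably leaves
#' RV/TLC unchanged) and returns the scenario with both degrees of freedom
#' resolved. Calibration provenance (anchors, achieved values, iteration
#' count) is attached as the `calibration` attribute and is carried into
#' JSON output by the command-line driver.
#'
#' @param scenario A [scenario_spec()].
#' @param rv_tlc Baseline overall RV/TLC anchor.
#' @param rv_l Baseline overall RV anchor (liters). `NULL` skips the volume
#'   scale.
#' @param tolerance Convergence tolerance for both anchors (default `1e-6`).
#' @return The calibrated [scenario_spec()].
#' @export
calibrate_scenario <- function(scenario, rv_tlc = 0.68, rv_l = 5.8,
                               tolerance = 1e-6) {
  p <- calibrate_deflation_pressure(
    scenario, calibration_target("rv_tlc", rv_tlc, tolerance)
  )
  scenario$p_rv_apex <- as.numeric(p)
  prov <- list(
    anchor_rv_tlc = rv_tlc, achieved_rv_tlc = attr(p, "achieved"),
    p_rv_apex = as.numeric(p), iterations = attr(p, "iterations")
  )
  if (!is.null(rv_l)) {
    s <- calibrate_volume_scale(scenario, calibration_target("rv_l", rv_l, tolerance))
    scenario <- scale_scenario_volumes(scenario, as.numeric(s))
    prov$anchor_rv_l <- rv_l
    prov$achieved_rv_l <- attr(s, "achieved")
    prov$volume_scale <- as.numeric(s)
  }
  attr(scenario, "calibration") <- prov
  scenario
}
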