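#' Constitutive parameters for a class of alveoli
#'
#' Every alveolus in the model follows the exponential pressure--volume law
#' \deqn{V(P_{tp}) = V_{max} - A e^{-k P_{tp}}, \qquad A = V_{max} - V_{min},}
#' where \eqn{V_{max}} is the volume at "infinite" inflation pressure,
#' \eqn{V_{min}} the volume at zero inflation pressure, and \eqn{k} the shape
#' factor controlling the curvature of the relationship.
#'
#' @param v_max Alveolar volume at infinite inflation pressure (microliters).
#' @param v_min Alveolar volume at zero inflation pressure (microliters).
#'   Must satisfy `0 <= v_min < v_max`.
#' @param k Shape factor (per cm H2O), strictly positive.
#'
#' @return An object of class `alveolar_params`: a list with elements
#'   `v_max`, `v_min`, `k` and the derived amplitude `a = v_max - v_min`.
#' @examples
#' p <- alveolar_params(v_max = 20, v_min = 4, k = 0.2)
#' alveolar_volume(p, ptp = 5)
#' @export
alveolar_params <- function(v_max, v_min, k) {
  check_number(v_max, "v_max")
  check_number(v_min, "v_min")
  check_number(k, "k")
  if (!(v_min >= 0 && v_min < v_max)) {
    abort_invalid("`v_min` must satisfy 0 <= v_min < v_max (got v_min = {v_min}, v_max = {v_max}).",
                  v_min = v_min, v_max = v_max)
  }
  if (k <= 0) abort_invalid("`k` must be > 0 (got {k}).", k = k)
  structure(
    list(v_max = v_max, v_min = v_min, k = k, a = v_max - v_min),
    class = "alveolar_params"
  )
}

#' @export
print.alveolar_params <- function(x, ...) {
  cat(sprintf(
    "<alveolar_params> v_max = %g uL, v_min = %g uL (ratio %.3g), k = %g /cmH2O\n",
    x$v_max, x$v_min, x$v_min / x$v_max, x$k
  ))
  invisible(x)
}

#' Transpulmonary pressure profile over lung height
#'
#' Transpulmonary pressure decreases linearly with depth below the apex:
#' `Ptp(z) = p_apex - rho_frac * z`. Expressing lung tissue density as a
#' fraction of water density makes the hydrostatic term `rho * g * z` collapse
#' to `rho_frac` cm H2O per cm of depth, so no explicit gravitational constant
#' is carried.
#'
#' @param p_apex Transpulmonary pressure at the apex (cm H2O).
#' @param height Apex-to-base distance (cm), strictly positive.
#' @param rho_frac Lung tissue density as a fraction of water density
#'   (dimensionless, in `(0, 1]`, default 0.25). `rho_frac = 0` is accepted as
#'   the gravity-off degenerate case (uniform pressure at all depths).
#'
#' @return An object of class `pressure_profile`.
#' @examples
#' pr <- pressure_profile(p_apex = 14, height = 35)
#' ptp_at_depth(pr, z = c(0, 4, 35))
#' @export
pressure_profile <- function(p_apex, height, rho_frac = 0.25) {
  check_number(p_apex, "p_apex")
  check_number(height, "height")
  check_number(rho_frac, "rho_frac")
  if (height <= 0) abort_invalid("`height` must be > 0 (got {height}).", height = height)
  if (rho_frac < 0 || rho_frac > 1) {
    abort_invalid("`rho_frac` must lie in [0, 1] (got {rho_frac}).", rho_frac = rho_frac)
  }
  structure(
    list(p_apex = p_apex, height = height, rho_frac = rho_frac),
    class = "pressure_profile"
  )
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf(
    "<pressure_profile> apex %g cmH2O, gradient %g cmH2O/cm over %g cm (base %g cmH2O)\n",
    x$p_apex, x$rho_frac, x$height, x$p_apex - x$rho_frac * x$height
  ))
  invisible(x)
}

#' Airway-closure rule
#'
#' An airway closes where local transpulmonary pressure falls to the closing
#' pressure `Ptm'`; gas distal to it is trapped at the volume held at closure.
#' For homogeneous disease `Ptm'` is a single constant for the whole lung.
#'
#' @param p_tm Airway closing pressure `Ptm'` (cm H2O), non-negative.
#' @return An object of class `closure_rule`.
#' @export
closure_rule <- function(p_tm) {
  check_number(p_tm, "p_tm")
  if (p_tm < 0) abort_invalid("`p_tm` must be >= 0 (got {p_tm}).", p_tm = p_tm)
  structure(list(p_tm = p_tm), class = "closure_rule")
}

#' @export
print.closure_rule <- function(x, ...) {
  cat(sprintf("<closure_rule> Ptm' = %g cmH2O\n", x$p_tm))
  invisible(x)
}

#' Alveolar volume at a given transpulmonary pressure
#'
#' Evaluates the exponential constitutive law
#' `V = v_max - (v_max - v_min) * exp(-k * ptp)`. The function is strictly
#' increasing and concave in `ptp` and bounded above by `v_max`. Negative
#' pressures are evaluated as written (the exponential extrapolates; airway
#' closure normally intervenes first in assembled lungs).
#'
#' @param params An [alveolar_params()] object.
#' @param ptp Transpulmonary pressure(s), cm H2O. Vectorized; must be finite.
#' @return Alveolar volume(s) in microliters.
#' @export
alveolar_volume <- function(params, ptp) {
  stopifnot(inherits(params, "alveolar_params"))
  if (!is.numeric(ptp) || length(ptp) == 0 || any(!is.finite(ptp))) {
    abort_invalid("`ptp` must be finite numeric.")
  }
  params$v_max - params$a * exp(-params$k * ptp)
}

#' Transpulmonary pressure at a depth below the apex
#'
#' @param profile A [pressure_profile()].
#' @param z Depth(s) from the apex (cm), within `[0, height]`. Vectorized.
#' @return Pressure(s) in cm H2O: `p_apex - rho_frac * z`.
#' @export
ptp_at_depth <- function(profile, z) {
  stopifnot(inherits(profile, "pressure_profile"))
  if (!is.numeric(z) || length(z) == 0 || any(!is.finite(z))) {
    abort_invalid("`z` must be finite numeric.")
  }
  if (any(z < 0 | z > profile$height)) {
    rlang::abort(
      sprintf("`z` must lie in [0, %g] cm (depth from apex).", profile$height),
      class = "lvrsim_error_out_of_range"
    )
  }
  profile$p_apex - profile$rho_frac * z
}

#' Depth at which airways close
#'
#' Solves `p_apex - rho_frac * z = p_tm` for the closure depth on a given
#' pressure profile. If the closing pressure meets or exceeds the apical
#' pressure every airway is closed (`status = "all"`); if pressure at the base
#' still exceeds the closing pressure no airway closes (`status = "none"`);
#' otherwise the unique interior depth is returned.
#'
#' @param profile A [pressure_profile()] (normally the deflation limb).
#' @param rule A [closure_rule()].
#' @return An object of class `closure_point`: a list with `status`
#'   (`"interior"`, `"none"` or `"all"`), `z` (depth from apex, cm; `NA` unless
#'   interior), `z_from_base` and `height`.
#' @examples
#' closure_depth(pressure_profile(6, 35), closure_rule(1))
#' @export
closure_depth <- function(profile, rule) {
  stopifnot(inherits(profile, "pressure_profile"), inherits(rule, "closure_rule"))
  h <- profile$height
  if (rule$p_tm >= profile$p_apex) {
    out <- list(status = "all", z = NA_real_, z_from_base = NA_real_, height = h)
  } else if (rule$p_tm < profile$p_apex - profile$rho_frac * h) {
    out <- list(status = "none", z = NA_real_, z_from_base = NA_real_, height = h)
  } else {
    # rho_frac > 0 here: with rho_frac = 0 one of the branches above fires
    z <- (profile$p_apex - rule$p_tm) / profile$rho_frac
    out <- list(status = "interior", z = z, z_from_base = h - z, height = h)
  }
  structure(out, class = "closure_point")
}

#' @export
print.closure_point <- function(x, ...) {
  msg <- switch(x$status,
    interior = sprintf("closure at z = %.4g cm from apex (%.4g cm from base)", x$z, x$z_from_base),
    none = "no airway closure (open to the base)",
    all = "all airways closed"
  )
  cat("<closure_point>", msg, "\n")
  invisible(x)
}

# Effective closure depth for integration: depth below which alveoli are
# trapped. "none" -> height (nothing below), "all" -> 0 (everything below).
closure_z_effective <- function(cp) {
  switch(cp$status, interior = cp$z, none = cp$height, all = 0)
}

#' Alveolar volume on the deflation limb, with gas trapping
#'
#' Above the closure depth the airway is open and volume follows the
#' constitutive law at the local pressure. At or below the closure depth the
#' volume is pinned to the trapped-gas volume `V(p_tm)` held at the moment of
#' closure, independent of depth.
#'
#' @param params An [alveolar_params()].
#' @param profile The deflation-limb [pressure_profile()].
#' @param rule A [closure_rule()].
#' @param z Depth(s) from apex (cm), in `[0, height]`. Vectorized.
#' @return Volume(s) in microliters.
#' @export
deflation_volume <- function(params, profile, rule, z) {
  ptp <- ptp_at_depth(profile, z)
  cp <- closure_depth(profile, rule)
  closed <- switch(cp$status,
    all = rep(TRUE, length(z)),
    none = rep(FALSE, length(z)),
    interior = z >= cp$z
  )
  ifelse(closed, alveolar_volume(params, rule$p_tm), alveolar_volume(params, ptp))
}
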