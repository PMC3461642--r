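#' Scenario specification
#'
#' A scenario bundles everything needed to build a uniform layered lung and
#' evaluate it on both limbs: geometry, alveolar count, constitutive
#' parameters, boundary pressures and the airway-closure rule.
#'
#' @param name Scenario label.
#' @param height Apex-to-base distance, cm.
#' @param n_total Total alveolar count.
#' @param params An [alveolar_params()].
#' @param p_tlc_apex Apical Ptp at full inflation, cm H2O.
#' @param p_rv_apex Apical Ptp at full deflation, cm H2O. May be `NA` for an
#'   uncalibrated scenario; [simulate_scenario()] refuses to run until it is
#'   set (see [calibrate_scenario()]).
#' @param p_tm Airway closing pressure, cm H2O.
#' @param rho_frac Hydrostatic gradient (cm H2O per cm), default 0.25.
#' @param n_layers Discretization (default 350 layers).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, height, n_total, params, p_tlc_apex, p_rv_apex,
                          p_tm, rho_frac = 0.25, n_layers = 350) {
  stopifnot(inherits(params, "alveolar_params"))
  check_number(p_tlc_apex, "p_tlc_apex")
  if (!is.na(p_rv_apex)) check_number(p_rv_apex, "p_rv_apex")
  structure(
    list(
      name = name, height = height, n_total = n_total, params = params,
      p_tlc_apex = p_tlc_apex, p_rv_apex = p_rv_apex, p_tm = p_tm,
      rho_frac = rho_frac, n_layers = n_layers
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    paste0("<scenario_spec> \"%s\": n = %s, Vmax = %g uL, Vmin/Vmax = %.3g, k = %g,\n",
           "  Ptm' = %g cmH2O, height = %g cm, apical Ptp TLC = %g, RV = %s cmH2O\n"),
    x$name, format(x$n_total, big.mark = ",", scientific = FALSE),
    x$params$v_max, x$params$v_min / x$params$v_max, x$params$k,
    x$p_tm, x$height, x$p_tlc_apex,
    if (is.na(x$p_rv_apex)) "<uncalibrated>" else format(x$p_rv_apex)
  ))
  invisible(x)
}

#' @rdname scenario_spec
#' @param scenario A `scenario_spec`.
#' @export
as_lung_state <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  build_uniform_lung(scenario$height, scenario$n_total, scenario$params,
                     scenario$n_layers)
}

scenario_pressures <- function(scenario) {
  if (is.na(scenario$p_rv_apex)) {
    abort_invalid("scenario \"{name}\" has no deflation pressure; run `calibrate_scenario()` first.",
                  name = scenario$name)
  }
  lung_pressures(scenario$p_tlc_apex, scenario$p_rv_apex, scenario$rho_frac)
}

scenario_rule <- function(scenario) closure_rule(scenario$p_tm)

#' Healthy-lung preset
#'
#' Representative normal values: 300 million alveoli, `Vmax` 20 uL, `Vmin`
#' 4 uL, shape factor `k = 0.2`, closing pressure `Ptm' = 0` cm H2O, over a
#' 35 cm lung. The boundary pressures are model-supplied defaults: apical Ptp
#' at full inflation 30 cm H2O, and at full deflation `rho_frac * height`
#' (8.75 cm H2O), which places the healthy closure point exactly at the lung
#' base (`Ptm' = 0` closes where Ptp reaches 0).
#'
#' @param n_layers Discretization (default 350).
#' @return A [scenario_spec()].
#' @examples
#' healthy_preset() |> simulate_scenario()
#' @export
healthy_preset <- function(n_layers = 350) {
  height <- 35
  rho <- 0.25
  scenario_spec(
    name = "healthy", height = height, n_total = 300e6,
    params = alveolar_params(v_max = 20, v_min = 4, k = 0.2),
    p_tlc_apex = 30, p_rv_apex = rho * height, p_tm = 0,
    rho_frac = rho, n_layers = n_layers
  )
}

#' Severe homogeneous emphysema preset
#'
#' Emphysema is modeled from the healthy lung by halving the alveolar count
#' (n = 150 million), raising `Vmin/Vmax` to 0.5, raising `k` to 0.3 (loss of
#' recoil), and raising `Ptm'` to 1 cm H2O (premature airway closure). The
#' apical inflation pressure is the reduced recoil at TLC, 12.5 cm H2O.
#'
#' Two degrees of freedom are not fixed by those constants: the deflation-limb
#' apical pressure and the absolute alveolar volume scale. With
#' `calibrate = TRUE` (the default) they are resolved by
#' [calibrate_scenario()] against the baseline anchors `RV/TLC = 0.68` and
#' `RV = 5.8` L; all post-treatment outputs are then genuine predictions with
#' these parameters held fixed.
#'
#' @param calibrate Calibrate the preset against the baseline anchors
#'   (default `TRUE`).
#' @param rv_tlc,rv_l Baseline anchors used when `calibrate = TRUE`.
#' @param n_layers Discretization (default 350).
#' @return A [scenario_spec()] (calibrated unless `calibrate = FALSE`, in
#'   which case `p_rv_apex` is `NA` and `Vmax` is the nominal 40 uL).
#' @examples
#' emphysema_preset() |> simulate_scenario() |> glance()
#' @export
emphysema_preset <- function(calibrate = TRUE, rv_tlc = 0.68, rv_l = 5.8,
                             n_layers = 350) {
  sc <- scenario_spec(
    name = "emphysema", height = 35, n_total = 150e6,
    params = alveolar_params(v_max = 40, v_min = 20, k = 0.3),
    p_tlc_apex = 12.5, p_rv_apex = NA_real_, p_tm = 1,
    rho_frac = 0.25, n_layers = n_layers
  )
  if (calibrate) sc <- calibrate_scenario(sc, rv_tlc = rv_tlc, rv_l = rv_l)
  sc
}

#' Run a scenario forward
#'
#' Builds the layered lung, evaluates the regional profile on both limbs and
#' integrates the whole-lung summary.
#'
#' @param scenario A [scenario_spec()].
#' @return An object of class `lung_run`: list with `scenario`, `lung`,
#'   `profile` (a [regional_profile()] tibble) and `summary`
#'   (a [lung_summary()]). [tidy()] returns the per-layer profile and
#'   [glance()] the one-row whole-lung summary.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  lung <- as_lung_state(scenario)
  run_lung(lung, scenario_pressures(scenario), scenario_rule(scenario),
           scenario = scenario)
}

run_lung <- function(lung, pressures, rule, scenario = NULL) {
  profile <- regional_profile(lung, pressures, rule)
  structure(
    list(scenario = scenario, lung = lung, profile = profile,
         summary = lung_summary(lung, profile)),
    class = "lung_run"
  )
}

#' @export
print.lung_run <- function(x, ...) {
  if (!is.null(x$scenario)) cat(sprintf("run of scenario \"%s\"\n", x$scenario$name))
  print(x$summary)
  invisible(x)
}

#' Depth interval covered by a lobe
#'
#' The model abstracts "upper lobes" as the apical fraction of lung height
#' and "lower lobes" as the basal fraction, with the boundary at mid-height
#' by default (the lobe boundary is a geometric convention, not an anatomical
#' fissure).
#'
#' @param height Lung height, cm (or a [scenario_spec()]).
#' @param lobe `"upper"` or `"lower"`.
#' @param fraction Fraction of lung height assigned to the lobe (default 0.5).
#' @return Numeric `c(z_lo, z_hi)`, depths from the apex.
#' @export
lobe_region <- function(height, lobe = c("upper", "lower"), fraction = 0.5) {
  lobe <- match.arg(lobe)
  if (inherits(height, "scenario_spec")) height <- height$height
  check_number(height, "height")
  check_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) abort_invalid("`fraction` must be in (0, 1).")
  if (lobe == "upper") c(0, fraction * height) else c((1 - fraction) * height, height)
}

#' Volume-reduction treatment specification
#'
#' A treatment removes `n_removed` alveoli from a target depth interval,
#' shrinks the lung height, raises the recoil pressure at full inflation
#' (volume reduction re-tensions the remaining lung) and lowers the airway
#' closing pressure (restored parenchymal tethering). The rise in
#' transpulmonary pressure is applied as a uniform shift of the whole Ptp
#' field: the deflation-limb apical pressure moves by the same increment as
#' the inflation-limb pressure (`p_tlc_apex_post - p_tlc_apex_pre`) unless
#' `p_rv_shift` overrides it.
#'
#' @param region Depth interval `c(z_lo, z_hi)` targeted, cm from the apex
#'   (pre-treatment coordinates); see [lobe_region()].
#' @param n_removed Number of alveoli eliminated from the region.
#' @param p_tlc_apex_post Post-treatment apical Ptp at full inflation, cm H2O.
#' @param p_tm_post Post-treatment airway closing pressure, cm H2O.
#' @param height_post Post-treatment apex-to-base distance, cm.
#' @param p_rv_shift Optional override for the deflation-limb pressure
#'   increment (cm H2O); default `NULL` uses the inflation increment.
#' @return An object of class `treatment_spec`.
#' @examples
#' sc <- emphysema_preset()
#' ult <- treatment_spec(lobe_region(sc, "upper"), n_removed = 22e6,
#'                       p_tlc_apex_post = 14, p_tm_post = 0.5, height_post = 33)
#' @export
treatment_spec <- function(region, n_removed, p_tlc_apex_post, p_tm_post,
                           height_post, p_rv_shift = NULL) {
  if (!is.numeric(region) || length(region) != 2 || region[1] >= region[2]) {
    abort_invalid("`region` must be c(z_lo, z_hi) with z_lo < z_hi.")
  }
  check_number(n_removed, "n_removed")
  check_number(p_tlc_apex_post, "p_tlc_apex_post")
  check_number(p_tm_post, "p_tm_post")
  check_number(height_post, "height_post")
  if (n_removed < 0) abort_invalid("`n_removed` must be >= 0.")
  if (!is.null(p_rv_shift)) check_number(p_rv_shift, "p_rv_shift")
  structure(
    list(region = region, n_removed = n_removed,
         p_tlc_apex_post = p_tlc_apex_post, p_tm_post = p_tm_post,
         height_post = height_post, p_rv_shift = p_rv_shift),
    class = "treatment_spec"
  )
}

#' @export
print.treatment_spec <- function(x, ...) {
  cat(sprintf(
    "<treatment_spec> remove %s alveoli from z in [%g, %g) cm; Ptp(0) TLC -> %g, Ptm' -> %g, height -> %g cm\n",
    format(x$n_removed, big.mark = ",", scientific = FALSE),
    x$region[1], x$region[2], x$p_tlc_apex_post, x$p_tm_post, x$height_post
  ))
  invisible(x)
}

#' Apply a volume-reduction treatment to a lung
#'
#' Alveoli are removed proportionally to layer population across the layers
#' intersecting the target region (partial overlaps weighted by overlap
#' length), with largest-remainder rounding so exactly `n_removed` are
#' eliminated. The layer grid is then compressed by a uniform affine rescale
#' from the pre- to the post-treatment height; the boundary pressures shift
#' (`p_tlc_apex` to its post value, `p_rv_apex` by the same increment) and
#' the closing pressure is replaced. Constitutive parameters of the remaining
#' alveoli are unchanged.
#'
#' @param lung A [lung_state][build_uniform_lung()] (pre-treatment).
#' @param pressures The pre-treatment [lung_pressures()].
#' @param rule The pre-treatment [closure_rule()].
#' @param spec A [treatment_spec()].
#' @return A list with post-treatment `lung`, `pressures`, `rule` and the
#'   bookkeeping element `n_removed_by_layer`.
#' @export
apply_treatment <- function(lung, pressures, rule, spec) {
  stopifnot(inherits(lung, "lung_state"), inherits(pressures, "lung_pressures"),
            inherits(rule, "closure_rule"), inherits(spec, "treatment_spec"))
  if (spec$height_post > lung$height) {
    abort_invalid("`height_post` ({h}) exceeds the pre-treatment height ({h0}).",
                  h = spec$height_post, h0 = lung$height,
                  class = "lvrsim_error_invalid_treatment")
  }
  if (spec$p_tlc_apex_post < pressures$p_tlc_apex) {
    abort_invalid("volume reduction must not lower the inflation recoil pressure.",
                  class = "lvrsim_error_invalid_treatment")
  }
  if (spec$p_tm_post > rule$p_tm) {
    abort_invalid("volume reduction must not raise the airway closing pressure.",
                  class = "lvrsim_error_invalid_treatment")
  }

  ly <- lung$layers
  overlap <- pmax(0, pmin(ly$z_bottom, spec$region[2]) - pmax(ly$z_top, spec$region[1]))
  w <- ly$n_alveoli * overlap / (ly$z_bottom - ly$z_top)
  if (spec$n_removed > sum(w)) {
    abort_invalid(
      "cannot remove {nr} alveoli: only {np} present in the target region.",
      nr = spec$n_removed, np = sum(w),
      class = "lvrsim_error_invalid_treatment"
    )
  }
  removed <- if (spec$n_removed > 0) largest_remainder(spec$n_removed, w) else rep(0, nrow(ly))
  scale_z <- spec$height_post / lung$height
  ly_post <- dplyr::mutate(ly,
    z_top = .data$z_top * scale_z,
    z_bottom = .data$z_bottom * scale_z,
    z_mid = .data$z_mid * scale_z,
    n_alveoli = .data$n_alveoli - removed
  )
  shift <- spec$p_tlc_apex_post - pressures$p_tlc_apex
  rv_shift <- if (is.null(spec$p_rv_shift)) shift else spec$p_rv_shift
  list(
    lung = new_lung_state(spec$height_post, ly_post),
    pressures = lung_pressures(spec$p_tlc_apex_post,
                               pressures$p_rv_apex + rv_shift,
                               pressures$rho_frac),
    rule = closure_rule(spec$p_tm_post),
    n_removed_by_layer = removed
  )
}

#' @rdname apply_treatment
#' @param scenario A [scenario_spec()] (calibrated).
#' @return `run_treatment()` runs the post-treatment lung and returns a
#'   `lung_run`.
#' @export
run_treatment <- function(scenario, spec) {
  stopifnot(inherits(scenario, "scenario_spec"))
  post <- apply_treatment(as_lung_state(scenario), scenario_pressures(scenario),
                          scenario_rule(scenario), spec)
  run_lung(post$lung, post$pressures, post$rule)
}

#' Head-to-head comparison of upper- versus lower-lobe volume reduction
#'
#' Runs the calibrated baseline and both treatment arms (which must remove
#' the same number of alveoli and apply identical pressure and height shifts)
#' and reports whole-lung summaries with percent changes in RV/TLC.
#'
#' @param base A calibrated [scenario_spec()].
#' @param ult,llt [treatment_spec()]s for the upper- and lower-lobe arms.
#' @return An object of class `lvr_comparison`: list with `baseline`, `ult`,
#'   `llt` (each a `lung_run`) and `deltas`, a tibble of per-arm percent
#'   changes `delta_rv_tlc_percent = 100 * (post - pre) / pre`. [tidy()]
#'   returns a per-arm tibble; [glance()] a one-row overview.
#' @examples
#' sc <- emphysema_preset()
#' ult <- treatment_spec(lobe_region(sc, "upper"), 22e6, 14, 0.5, 33)
#' llt <- treatment_spec(lobe_region(sc, "lower"), 22e6, 14, 0.5, 33)
#' compare_ult_llt(sc, ult, llt)
#' @export
compare_ult_llt <- function(base, ult, llt) {
  stopifnot(inherits(base, "scenario_spec"), inherits(ult, "treatment_spec"),
            inherits(llt, "treatment_spec"))
  if (ult$n_removed != llt$n_removed) {
    abort_invalid("arms must remove the same number of alveoli ({a} vs {b}).",
                  a = ult$n_removed, b = llt$n_removed,
                  class = "lvrsim_error_invalid_comparison")
  }
  same_shift <- isTRUE(all.equal(
    c(ult$p_tlc_apex_post, ult$p_tm_post, ult$height_post),
    c(llt$p_tlc_apex_post, llt$p_tm_post, llt$height_post)
  ))
  if (!same_shift) {
    abort_invalid("arms must apply identical pressure and height shifts.",
                  class = "lvrsim_error_invalid_comparison")
  }
  baseline <- simulate_scenario(base)
  run_u <- run_treatment(base, ult)
  run_l <- run_treatment(base, llt)
  pre <- baseline$summary$rv_tlc
  deltas <- tibble::tibble(
    arm = c("ult", "llt"),
    rv_tlc_post = c(run_u$summary$rv_tlc, run_l$summary$rv_tlc),
    delta_rv_tlc_percent = 100 * (c(run_u$summary$rv_tlc, run_l$summary$rv_tlc) - pre) / pre
  )
  structure(
    list(baseline = baseline, ult = run_u, llt = run_l, deltas = deltas),
    class = "lvr_comparison"
  )
}

#' @export
print.lvr_comparison <- function(x, ...) {
  cat("<lvr_comparison>\n")
  cat(sprintf("  baseline: RV/TLC %.4f, RV %.3f L, TLC %.3f L\n",
              x$baseline$summary$rv_tlc, x$baseline$summary$rv_l, x$baseline$summary$tlc_l))
  for (arm in c("ult", "llt")) {
    s <- x[[arm]]$summary
    d <- x$deltas$delta_rv_tlc_percent[x$deltas$arm == arm]
    cat(sprintf("  %s: RV/TLC %.4f (%+.2f%%), RV %.3f L, TLC %.3f L\n",
                toupper(arm), s$rv_tlc, d, s$rv_l, s$tlc_l))
  }
  invisible(x)
}

#' Heterogeneity Index from lobar low-attenuation fractions
#'
#' The Heterogeneity Index (HI) is the ratio of the fraction of CT voxels
#' below -910 HU in the upper lobes to that in the lower lobes. Disease is
#' called homogeneous when HI lies in the inclusive band `[0.85, 1.15]`.
#'
#' @param upper_frac,lower_frac Fractions of low-attenuation voxels in the
#'   upper and lower lobes, each in `(0, 1]`.
#' @return A one-row tibble with columns `hi` and `homogeneous`.
#' @examples
#' heterogeneity_index(0.575, 0.5)
#' @export
heterogeneity_index <- function(upper_frac, lower_frac) {
  check_number(upper_frac, "upper_frac")
  check_number(lower_frac, "lower_frac")
  if (lower_frac == 0) {
    rlang::abort("`lower_frac` is zero: HI undefined.", class = "lvrsim_error_division")
  }
  for (v in c(upper_frac, lower_frac)) {
    if (v <= 0 || v > 1) abort_invalid("voxel fractions must lie in (0, 1].")
  }
  hi <- upper_frac / lower_frac
  tibble::tibble(hi = hi, homogeneous = hi >= 0.85 & hi <= 1.15)
}

#' Regional effect of treatment pressure and height shifts alone
#'
#' Evaluates the per-alveolus RV/TLC of a uniform scenario before and after
#' the treatment's pressure and height shifts (no alveoli removed), on a
#' common grid of distance from the lung base, mirroring how regional curves
#' are compared across a treatment. Three mechanism effects are visible:
#' the ratio rises toward the apex (re-tensioning distends apical alveoli),
#' falls toward the base (lower closing pressure lets basal airways stay
#' open and empty further), and the closure point moves caudally.
#'
#' @param scenario A calibrated [scenario_spec()].
#' @param spec A [treatment_spec()]; its `n_removed` is ignored here.
#' @param n_grid Number of evaluation points (default 200).
#' @return A tibble with `z_from_base_cm`, `rv_tlc_pre`, `rv_tlc_post`,
#'   `delta`, plus attributes `closure_pre` and `closure_post`.
#' @export
treatment_shift_effects <- function(scenario, spec, n_grid = 200) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(spec, "treatment_spec"))
  pres <- scenario_pressures(scenario)
  rule <- scenario_rule(scenario)
  shift <- spec$p_tlc_apex_post - pres$p_tlc_apex
  rv_shift <- if (is.null(spec$p_rv_shift)) shift else spec$p_rv_shift
  pres_post <- lung_pressures(spec$p_tlc_apex_post, pres$p_rv_apex + rv_shift,
                              pres$rho_frac)
  rule_post <- closure_rule(spec$p_tm_post)
  params <- scenario$params
  h_pre <- scenario$height
  h_post <- spec$height_post

  d <- seq(0, h_post, length.out = n_grid)  # distance from base, shared support
  ratio_at <- function(p, r, h, dist) {
    z <- h - dist
    infl <- pressure_profile(p$p_tlc_apex, h, p$rho_frac)
    defl <- pressure_profile(p$p_rv_apex, h, p$rho_frac)
    deflation_volume(params, defl, r, z) / alveolar_volume(params, ptp_at_depth(infl, z))
  }
  pre <- ratio_at(pres, rule, h_pre, d)
  post <- ratio_at(pres_post, rule_post, h_post, d)
  out <- tibble::tibble(z_from_base_cm = d, rv_tlc_pre = pre,
                        rv_tlc_post = post, delta = post - pre)
  structure(out,
    closure_pre = closure_depth(pressure_profile(pres$p_rv_apex, h_pre, pres$rho_frac), rule),
    closure_post = closure_depth(pressure_profile(pres_post$p_rv_apex, h_post, pres$rho_frac), rule_post),
    class = c("tbl_df", "tbl", "data.frame")
  )
}
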