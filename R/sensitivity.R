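#' Parameter-sweep specification
#'
#' Systematic variation of the key model parameters — alveolar count `n`,
#' shape factor `k`, the ratio `Vmin/Vmax`, and closing pressure `Ptm'` —
#' by a relative span around a base scenario. `mode = "one_at_a_time"`
#' varies each parameter alone; `mode = "joint"` evaluates the full factorial
#' grid. The deflation pressure and all other quantities are held at the
#' base scenario's values.
#'
#' @param base A [scenario_spec()] with `p_rv_apex` set.
#' @param parameters Subset of `c("n", "k", "vmin_vmax", "p_tm")`.
#' @param span Relative half-width of the variation (default 0.25 for +/-25%).
#' @param points Grid points per axis (>= 2, default 3; the base value is
#'   included when `points` is odd).
#' @param mode `"one_at_a_time"` or `"joint"`.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, parameters = c("n", "k", "vmin_vmax", "p_tm"),
                       span = 0.25, points = 3,
                       mode = c("one_at_a_time", "joint")) {
  stopifnot(inherits(base, "scenario_spec"))
  parameters <- match.arg(parameters, several.ok = TRUE)
  mode <- match.arg(mode)
  check_number(span, "span")
  check_number(points, "points")
  if (span < 0) abort_invalid("`span` must be >= 0.")
  if (points < 2) abort_invalid("`points` must be >= 2.")
  structure(list(base = base, parameters = parameters, span = span,
                 points = points, mode = mode),
            class = "sweep_spec")
}

# Multipliers (1 + delta) for one axis of the sweep
sweep_levels <- function(span, points) 1 + seq(-span, span, length.out = points)

# Apply relative multipliers to a scenario; ratio >= 1 is invalid and errors
vary_scenario <- function(base, mult) {
  sc <- base
  if (!is.null(mult$n)) sc$n_total <- round(base$n_total * mult$n)
  k <- base$params$k * (mult$k %||% 1)
  ratio <- (base$params$v_min / base$params$v_max) * (mult$vmin_vmax %||% 1)
  if (ratio >= 1) abort_invalid("varied Vmin/Vmax ratio reached {r} >= 1.", r = ratio)
  sc$params <- alveolar_params(base$params$v_max, base$params$v_max * ratio, k)
  if (!is.null(mult$p_tm)) sc$p_tm <- base$p_tm * mult$p_tm
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a parameter sweep
#'
#' Evaluates a full simulation at every grid point of a [sweep_spec()].
#' Grid points that produce an invalid scenario (for example a varied
#' `Vmin/Vmax` reaching 1) are recorded as error rows, never dropped.
#'
#' @param spec A [sweep_spec()].
#' @return A tibble of class `sweep_result`, one row per grid point, with the
#'   realized parameter values (`n`, `k`, `vmin_vmax`, `p_tm`), whole-lung
#'   `rv_tlc`, `tlc_l`, `rv_l`, the closure position `closure_z_from_base_cm`
#'   (`NA` unless interior), the regional extrema `rv_tlc_min`/`rv_tlc_max`,
#'   and an `error` column (`NA` on success).
#' @examples
#' run_sweep(sweep_spec(healthy_preset(), span = 0.25, points = 3))
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  lv <- sweep_levels(spec$span, spec$points)
  grid <- if (spec$mode == "joint") {
    tidyr::expand_grid(!!!stats::setNames(
      rep(list(lv), length(spec$parameters)), spec$parameters
    ))
  } else {
    dplyr::bind_rows(purrr::map(spec$parameters, function(p) {
      tibble::tibble(!!p := lv)
    }))
  }
  grid[is.na(grid)] <- 1  # one-at-a-time: untouched axes stay at base
  rows <- purrr::pmap(grid, function(...) {
    mult <- list(...)
    res <- tryCatch({
      sc <- vary_scenario(spec$base, mult)
      run <- simulate_scenario(sc)
      cp <- attr(run$profile, "closure")
      tibble::tibble(
        rv_tlc = run$summary$rv_tlc, tlc_l = run$summary$tlc_l,
        rv_l = run$summary$rv_l,
        closure_z_from_base_cm = if (cp$status == "interior") cp$z_from_base else NA_real_,
        rv_tlc_min = min(run$profile$rv_tlc), rv_tlc_max = max(run$profile$rv_tlc),
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(rv_tlc = NA_real_, tlc_l = NA_real_, rv_l = NA_real_,
                     closure_z_from_base_cm = NA_real_, rv_tlc_min = NA_real_,
                     rv_tlc_max = NA_real_, error = conditionMessage(e))
    })
    res
  })
  base <- spec$base
  realized <- tibble::tibble(
    n = base$n_total * (grid[["n"]] %||% rep(1, nrow(grid))),
    k = base$params$k * (grid[["k"]] %||% rep(1, nrow(grid))),
    vmin_vmax = (base$params$v_min / base$params$v_max) *
      (grid[["vmin_vmax"]] %||% rep(1, nrow(grid))),
    p_tm = base$p_tm * (grid[["p_tm"]] %||% rep(1, nrow(grid)))
  )
  out <- dplyr::bind_cols(realized, dplyr::bind_rows(rows))
  class(out) <- c("sweep_result", class(out))
  out
}

#' Sweep envelope of regional RV/TLC curves
#'
#' Computes the pointwise minimum and maximum regional RV/TLC across all
#' successful grid points of a sweep, as a function of distance from the lung
#' base — the envelope view of how parameter variation moves the regional
#' curve.
#'
#' @param spec A [sweep_spec()].
#' @return A tibble with `z_from_base_cm`, `rv_tlc_lo`, `rv_tlc_hi`,
#'   `rv_tlc_base`.
#' @export
sweep_envelope <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  lv <- sweep_levels(spec$span, spec$points)
  grid <- if (spec$mode == "joint") {
    tidyr::expand_grid(!!!stats::setNames(
      rep(list(lv), length(spec$parameters)), spec$parameters
    ))
  } else {
    dplyr::bind_rows(purrr::map(spec$parameters, ~ tibble::tibble(!!.x := lv)))
  }
  grid[is.na(grid)] <- 1
  profs <- purrr::pmap(grid, function(...) {
    tryCatch(simulate_scenario(vary_scenario(spec$base, list(...)))$profile$rv_tlc,
             error = function(e) NULL)
  })
  profs <- purrr::compact(profs)
  if (length(profs) == 0) abort_invalid("no sweep grid point produced a valid scenario.")
  m <- do.call(cbind, profs)
  base_prof <- simulate_scenario(spec$base)$profile
  tibble::tibble(
    z_from_base_cm = base_prof$z_from_base_cm,
    rv_tlc_lo = apply(m, 1, min),
    rv_tlc_hi = apply(m, 1, max),
    rv_tlc_base = base_prof$rv_tlc
  )
}

#' Scan the dominance of upper- over lower-lobe treatment
#'
#' Evaluates paired upper- and lower-lobe treatments (equal removal counts,
#' identical pressure and height shifts) over a joint parameter grid around a
#' base scenario and reports the fraction of grid points at which the
#' upper-lobe arm reduces overall RV/TLC at least as much as the lower-lobe
#' arm (ties count as dominance: the claim is "never less effective"). The
#' base scenario's calibrated deflation pressure is held fixed across the
#' grid; each grid point's arms are compared against that point's own
#' baseline.
#'
#' @param base A calibrated [scenario_spec()].
#' @param ult,llt [treatment_spec()]s (equal `n_removed`).
#' @param parameters,span,points As in [sweep_spec()]; the grid is joint.
#' @return An object of class `dominance_scan`: list with `fraction`, the
#'   paired `table` (one row per grid point with both arms' percent changes
#'   and a `dominant` flag), and the counts `n_ok`/`n_error`.
#' @export
dominance_scan <- function(base, ult, llt,
                           parameters = c("n", "k", "vmin_vmax", "p_tm"),
                           span = 0.25, points = 3) {
  stopifnot(inherits(base, "scenario_spec"))
  if (ult$n_removed != llt$n_removed) {
    abort_invalid("paired treatments must remove equal counts.",
                  class = "lvrsim_error_invalid_comparison")
  }
  spec <- sweep_spec(base, parameters, span, points, mode = "joint")
  lv <- sweep_levels(span, points)
  grid <- tidyr::expand_grid(!!!stats::setNames(
    rep(list(lv), length(parameters)), parameters
  ))
  rows <- purrr::pmap(grid, function(...) {
    mult <- list(...)
    tryCatch({
      sc <- vary_scenario(base, mult)
      cmp <- compare_ult_llt(sc, ult, llt)
      tibble::tibble(
        baseline_rv_tlc = cmp$baseline$summary$rv_tlc,
        delta_ult_percent = cmp$deltas$delta_rv_tlc_percent[cmp$deltas$arm == "ult"],
        delta_llt_percent = cmp$deltas$delta_rv_tlc_percent[cmp$deltas$arm == "llt"],
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(baseline_rv_tlc = NA_real_, delta_ult_percent = NA_real_,
                     delta_llt_percent = NA_real_, error = conditionMessage(e))
    })
  })
  realized <- tibble::tibble(
    n = base$n_total * (grid[["n"]] %||% rep(1, nrow(grid))),
    k = base$params$k * (grid[["k"]] %||% rep(1, nrow(grid))),
    vmin_vmax = (base$params$v_min / base$params$v_max) *
      (grid[["vmin_vmax"]] %||% rep(1, nrow(grid))),
    p_tm = base$p_tm * (grid[["p_tm"]] %||% rep(1, nrow(grid)))
  )
  tab <- dplyr::bind_cols(realized, dplyr::bind_rows(rows))
  tab$dominant <- tab$delta_ult_percent <= tab$delta_llt_percent + 1e-12
  ok <- !is.na(tab$dominant)
  structure(
    list(fraction = mean(tab$dominant[ok]), table = tab,
         n_ok = sum(ok), n_error = sum(!ok)),
    class = "dominance_scan"
  )
}

#' @export
print.dominance_scan <- function(x, ...) {
  cat(sprintf("<dominance_scan> ULT at least as effective as LLT at %.1f%% of %d grid points (%d errors)\n",
              100 * x$fraction, x$n_ok, x$n_error))
  invisible(x)
}
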