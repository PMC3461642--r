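#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::glance
glance.lung_summary <- function(x, ...) {
  cp <- x$closure
  tibble::tibble(
    tlc_l = x$tlc_l, rv_l = x$rv_l, rv_tlc = x$rv_tlc,
    closure_status = cp$status,
    closure_z_from_base_cm = if (cp$status == "interior") cp$z_from_base else NA_real_,
    p_tlc_apex = x$p_tlc_apex, p_rv_apex = x$p_rv_apex, n_total = x$n_total
  )
}

#' @exportS3Method generics::tidy
tidy.lung_run <- function(x, ...) tibble::as_tibble(x$profile)

#' @exportS3Method generics::glance
glance.lung_run <- function(x, ...) glance(x$summary)

#' @exportS3Method generics::tidy
tidy.lvr_comparison <- function(x, ...) {
  runs <- list(baseline = x$baseline, ult = x$ult, llt = x$llt)
  pre <- x$baseline$summary$rv_tlc
  purrr::imap(runs, function(run, arm) {
    dplyr::mutate(glance(run), arm = arm,
                  delta_rv_tlc_percent = 100 * (run$summary$rv_tlc - pre) / pre,
                  .before = 1)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(delta_rv_tlc_percent = dplyr::if_else(.data$arm == "baseline",
                                                        NA_real_,
                                                        .data$delta_rv_tlc_percent))
}

#' @exportS3Method generics::glance
glance.lvr_comparison <- function(x, ...) {
  d <- x$deltas
  tibble::tibble(
    baseline_rv_tlc = x$baseline$summary$rv_tlc,
    baseline_rv_l = x$baseline$summary$rv_l,
    ult_rv_tlc = x$ult$summary$rv_tlc,
    llt_rv_tlc = x$llt$summary$rv_tlc,
    delta_ult_percent = d$delta_rv_tlc_percent[d$arm == "ult"],
    delta_llt_percent = d$delta_rv_tlc_percent[d$arm == "llt"],
    ult_rv_l = x$ult$summary$rv_l,
    llt_rv_l = x$llt$summary$rv_l
  )
}

#' Plot a regional RV/TLC profile
#'
#' Regional RV/TLC against distance from the lung base (apex to the right),
#' with the airway-closure point marked when interior.
#'
#' @param object A [regional_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regional_profile <- function(object, ...) {
  cp <- attr(object, "closure")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$z_from_base_cm, y = .data$rv_tlc)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Distance from lung base (cm)",
                  y = "Regional RV/TLC") +
    ggplot2::ylim(0, 1)
  if (!is.null(cp) && cp$status == "interior") {
    p <- p + ggplot2::geom_vline(xintercept = cp$z_from_base, linetype = "dashed")
  }
  p
}

#' Plot an upper- versus lower-lobe comparison
#'
#' Overlays the baseline and both post-treatment regional RV/TLC curves.
#'
#' @param object An [compare_ult_llt()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lvr_comparison <- function(object, ...) {
  df <- purrr::imap(
    list(baseline = object$baseline, ult = object$ult, llt = object$llt),
    ~ dplyr::mutate(tibble::as_tibble(.x$profile), arm = .y)
  ) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_from_base_cm, y = .data$rv_tlc,
                                   colour = .data$arm)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Distance from lung base (cm)", y = "Regional RV/TLC",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}

#' Plot a sweep envelope
#'
#' @param envelope A [sweep_envelope()] tibble.
#' @return A ggplot object showing the base regional curve with the
#'   min--max band swept out by the parameter variation.
#' @export
plot_sweep_envelope <- function(envelope) {
  stopifnot(all(c("z_from_base_cm", "rv_tlc_lo", "rv_tlc_hi", "rv_tlc_base")
                %in% names(envelope)))
  ggplot2::ggplot(envelope, ggplot2::aes(x = .data$z_from_base_cm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rv_tlc_lo, ymax = .data$rv_tlc_hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rv_tlc_base), linewidth = 0.8) +
    ggplot2::labs(x = "Distance from lung base (cm)", y = "Regional RV/TLC") +
    ggplot2::ylim(0, 1)
}
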