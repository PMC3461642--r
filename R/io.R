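# Serialization of results. CSVs are RFC 4180 ('.' decimal separator, UTF-8,
# mandatory header); JSON embeds package version for provenance. Data files
# carry no timestamps so repeated runs are byte-identical.

#' Write a regional profile to CSV
#'
#' One row per layer with both axis conventions (`z_from_apex_cm`,
#' `z_from_base_cm`), counts and per-alveolus volumes in microliters.
#'
#' @param profile A [regional_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "regional_profile"))
  utils::write.csv(tibble::as_tibble(profile), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

summary_payload <- function(x) {
  g <- glance(x)
  c(as.list(g), list(package_version = as.character(utils::packageVersion("lvrsim"))))
}

#' Write a whole-lung summary to JSON
#'
#' Volumes are reported in liters (3 decimals); the package version is
#' embedded for provenance.
#'
#' @param summary A [lung_summary()] or `lung_run`.
#' @param path Output file path.
#' @param extra Optional named list merged into the payload (e.g. resolved
#'   configuration, calibration provenance).
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path, extra = NULL) {
  if (inherits(summary, "lung_run")) summary <- summary$summary
  stopifnot(inherits(summary, "lung_summary"))
  payload <- summary_payload(summary)
  payload$tlc_l <- round(payload$tlc_l, 3)
  payload$rv_l <- round(payload$rv_l, 3)
  payload <- c(payload, extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an upper- versus lower-lobe comparison to JSON
#'
#' @param comparison A [compare_ult_llt()] result.
#' @param path Output file path.
#' @param extra Optional named list merged into the payload.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(comparison, path, extra = NULL) {
  stopifnot(inherits(comparison, "lvr_comparison"))
  payload <- list(
    baseline = summary_payload(comparison$baseline$summary),
    ult = summary_payload(comparison$ult$summary),
    llt = summary_payload(comparison$llt$summary),
    delta_rv_tlc_percent = as.list(stats::setNames(
      comparison$deltas$delta_rv_tlc_percent, comparison$deltas$arm
    )),
    package_version = as.character(utils::packageVersion("lvrsim"))
  )
  payload$baseline$package_version <- NULL
  payload$ult$package_version <- NULL
  payload$llt$package_version <- NULL
  payload <- c(payload, extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
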