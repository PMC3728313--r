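#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy LP-model outputs
#'
#' One row per estimated quantity with its replicate mean, median and
#' Monte-Carlo standard error.
#'
#' @param x An `lp_outputs` object from [run_replicates()].
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `mean`, `median`, `mc_se`.
#' @method tidy lp_outputs
#' @export
tidy.lp_outputs <- function(x, ...) {
  x$summary
}

#' @describeIn tidy.lp_outputs One-row summary: headline quantities (means)
#'   plus the Monte-Carlo design.
#' @method glance lp_outputs
#' @export
glance.lp_outputs <- function(x, ...) {
  s <- x$summary
  wide <- stats::setNames(as.list(s$mean), s$quantity)
  dplyr::bind_cols(
    tibble::as_tibble(wide),
    tibble::tibble(n_families = x$n_families, n_reps = x$n_reps,
                   seed = x$seed)
  )
}

#' Tidy a calibration fit
#'
#' @param x An `lp_calibration` object from [calibrate_lp()].
#' @param ... Unused.
#' @return A tibble with one row per quantity at the calibrated model
#'   (same layout as [tidy.lp_outputs()]).
#' @method tidy lp_calibration
#' @export
tidy.lp_calibration <- function(x, ...) {
  tidy(x$outputs)
}

#' @describeIn tidy.lp_calibration One-row summary: calibrated parameters,
#'   achieved and target correlations, and headline outputs.
#' @method glance lp_calibration
#' @export
glance.lp_calibration <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(k = x$k, corr_kind = x$corr$kind, rho = x$corr$rho,
                   h2_path = x$h2_path, c2_path = x$c2_path,
                   r_mz_target = x$target$r_mz_obs,
                   r_dz_target = x$target$r_dz_obs),
    glance(x$outputs)
  )
}
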