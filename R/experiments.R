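#' Basic-LP wedge grid: variance-component bounds
#'
#' Forward sweep over basic LP models (equal pathways, independent): for each
#' combination of pathway count `k`, pathway heritability and pathway
#' common-environment fraction, simulate replicates and record the mapping
#' from the twin correlations (rMZ, rDZ) to narrow-sense heritability and
#' final-level common-environment proportion. The resulting long table shows
#' the feasible wedge: at a given (rMZ, rDZ), larger k trades narrow-sense
#' heritability for common-environment contribution.
#'
#' @param k_values Pathway counts (default `c(1, 2, 3, 5, 10)`).
#' @param h2_grid Pathway heritabilities (default `seq(0.1, 0.9, 0.1)`).
#' @param cr_grid Pathway common-environment fractions
#'   (default `seq(0, 1, 0.1)`).
#' @param n_families Families per replicate.
#' @param n_reps Replicates per grid point.
#' @param seed Integer root seed.
#' @return A tibble of class `lp_wedge`, one row per grid point with
#'   replicate-mean estimates and Monte-Carlo standard errors.
#' @export
lp_wedge_grid <- function(k_values = c(1, 2, 3, 5, 10),
                          h2_grid = seq(0.1, 0.9, by = 0.1),
                          cr_grid = seq(0, 1, by = 0.1),
                          n_families = 1e5, n_reps = 50L, seed = 1L) {
  grid <- tidyr::expand_grid(k = k_values, h2_path = h2_grid,
                             cr = cr_grid)
  res <- purrr::pmap_dfr(grid, function(k, h2_path, cr) {
    params <- lp_params(k = k, h2_path = h2_path, c2_path = cr)
    sweep_row(params, n_families, n_reps,
              seed = grid_seed(seed, k, h2_path, cr)) |>
      dplyr::mutate(k = k, h2_path = h2_path, c2_path = cr, .before = 1L)
  })
  class(res) <- c("lp_wedge", class(res))
  res
}

grid_seed <- function(seed, ...) {
  vals <- c(...)
  (as.integer(seed) %% 100000L) * 10000L +
    (sum(round(vals * 997)) %% 9999L)
}

sweep_row <- function(params, n_families, n_reps, seed) {
  out <- run_replicates(params, n_families, n_reps = n_reps, seed = seed)
  s <- out$summary
  wide <- stats::setNames(as.list(s$mean), s$quantity)
  se <- stats::setNames(as.list(s$mc_se), paste0("se_", s$quantity))
  dplyr::bind_cols(tibble::as_tibble(wide), tibble::as_tibble(se)) |>
    dplyr::mutate(n_families = n_families, n_reps = n_reps, seed = seed)
}

#' Sensitivity sweeps for phantom heritability
#'
#' Reproduction drivers for the extended-model sensitivity analyses. Panels:
#'
#' * `"mean_offset"`: two pathways, mean offset of the second pathway swept
#'   (s.d. units). Phantom heritability is maximal at zero offset and is
#'   roughly halved by a one-s.d. offset.
#' * `"var_diff"`: two pathways, variance of the second pathway swept.
#'   Phantom heritability is unaffected.
#' * `"h2_diff"`: two pathways, heritability of the second pathway swept
#'   while the first stays at `h2_path`.
#' * `"rho_sweep"`: uniform pathway correlation swept for each k, no common
#'   environment. Phantom heritability vanishes as rho approaches 1.
#' * `"rho_sweep_c10"`: as `"rho_sweep"` but with 10% of each pathway's
#'   phenotypic variance attributed to common environment, i.e.
#'   `c2_path = 0.1 / (1 - h2_path)`.
#'
#' Defaults (two pathways, `h2_path = 0.5`, no common environment,
#' independent pathways) follow the package's standard sensitivity design.
#'
#' @param panel Which sweep to run.
#' @param grid Values of the swept parameter (offset, sigma2_2, h2_2 or rho).
#' @param k_values Pathway counts for the correlation panels.
#' @param h2_path Baseline pathway heritability.
#' @param n_families,n_reps,seed Monte-Carlo design.
#' @return A tibble of class `lp_sweep`: one row per grid point (per k for
#'   the correlation panels) with replicate-mean estimates and their
#'   Monte-Carlo standard errors.
#' @export
lp_phantom_sweep <- function(panel = c("mean_offset", "var_diff", "h2_diff",
                                       "rho_sweep", "rho_sweep_c10"),
                             grid = NULL, k_values = c(2, 3, 5, 10),
                             h2_path = 0.5, n_families = 1e5, n_reps = 50L,
                             seed = 1L) {
  panel <- match.arg(panel)
  if (is.null(grid)) {
    grid <- switch(panel,
      mean_offset = seq(0, 2, by = 0.5),
      var_diff = c(1, 2, 4, 8),
      h2_diff = seq(0.1, 0.9, by = 0.2),
      rho_sweep = seq(0, 0.8, by = 0.2),
      rho_sweep_c10 = seq(0, 0.8, by = 0.2)
    )
  }
  res <- switch(panel,
    mean_offset = purrr::map_dfr(grid, function(off) {
      params <- lp_params(k = 2, mu = c(0, off), h2_path = h2_path)
      sweep_row(params, n_families, n_reps, grid_seed(seed, 1, off)) |>
        dplyr::mutate(value = off, .before = 1L)
    }),
    var_diff = purrr::map_dfr(grid, function(v2) {
      params <- lp_params(k = 2, sigma2 = c(1, v2), h2_path = h2_path)
      sweep_row(params, n_families, n_reps, grid_seed(seed, 2, v2)) |>
        dplyr::mutate(value = v2, .before = 1L)
    }),
    h2_diff = purrr::map_dfr(grid, function(h2_2) {
      params <- lp_params(k = 2, h2_path = c(h2_path, h2_2))
      sweep_row(params, n_families, n_reps, grid_seed(seed, 3, h2_2)) |>
        dplyr::mutate(value = h2_2, .before = 1L)
    }),
    rho_sweep = ,
    rho_sweep_c10 = {
      cr <- if (panel == "rho_sweep_c10") 0.1 / (1 - h2_path) else 0
      tidyr::expand_grid(k = k_values, rho = grid) |>
        purrr::pmap_dfr(function(k, rho) {
          params <- lp_params(k = k, h2_path = h2_path, c2_path = cr,
                              corr = correlation_spec("uniform", rho))
          sweep_row(params, n_families, n_reps,
                    grid_seed(seed, 4, k, rho)) |>
            dplyr::mutate(value = rho, k = k, .before = 1L)
        })
    }
  )
  res <- dplyr::mutate(res, panel = panel, .before = 1L)
  class(res) <- c("lp_sweep", class(res))
  res
}

#' Three-trait illustration table
#'
#' For each trait (a pair of observed twin correlations) and each
#' combination of pathway count and uniform pathway correlation, calibrates
#' `(h2_path, c2_path)` so the simulated twin correlations match the
#' observed ones, then reports phantom heritability, narrow-sense
#' heritability and the final-level common-environment proportion at the
#' calibrated model.
#'
#' @param traits A data frame with columns `trait`, `r_mz`, `r_dz`. Defaults
#'   to three published twin estimates: height in Danish male twins
#'   (0.89, 0.47), blood triglyceride levels in Swedish female twins
#'   (0.55, 0.28) and high-fat dairy intake in UK twins (0.23, 0.13).
#' @param k_values Pathway counts (default `c(2, 4, 10)`).
#' @param rho_values Uniform pathway correlations (default `c(0, 0.2)`).
#' @param n_families,n_reps,seed Monte-Carlo design passed to
#'   [calibration_target()] and the final output replicates.
#' @param search_reps Replicates per objective evaluation inside the
#'   calibration search (median-matched, common random numbers).
#' @return A tibble of class `lp_trait_table`: one row per
#'   (trait, k, rho) with the calibrated parameters, achieved correlations
#'   and replicate-mean `phantom`, `h2_narrow`, `c2_final`, `h2_ace`,
#'   `c2_ace` plus Monte-Carlo standard errors.
#' @export
lp_trait_table <- function(traits = trait_targets(),
                           k_values = c(2, 4, 10), rho_values = c(0, 0.2),
                           n_families = 1e5, n_reps = 50L, seed = 1L,
                           search_reps = 5L) {
  stopifnot(all(c("trait", "r_mz", "r_dz") %in% names(traits)))
  grid <- tidyr::expand_grid(trait = traits$trait, k = k_values,
                             rho = rho_values) |>
    dplyr::left_join(traits, by = "trait")
  res <- purrr::pmap_dfr(grid, function(trait, k, rho, r_mz, r_dz) {
    tgt <- calibration_target(r_mz, r_dz, n_families = n_families,
                              n_reps = search_reps,
                              seed = grid_seed(seed, k, rho))
    fit <- calibrate_lp(k = k, target = tgt,
                        corr = correlation_spec("uniform", rho),
                        output_reps = n_reps)
    s <- fit$outputs$summary
    g <- function(q) s$mean[match(q, s$quantity)]
    se <- function(q) s$mc_se[match(q, s$quantity)]
    tibble::tibble(
      trait = trait, r_mz_obs = r_mz, r_dz_obs = r_dz, k = k, rho = rho,
      h2_path = fit$h2_path, c2_path = fit$c2_path,
      r_mz = g("r_mz"), r_dz = g("r_dz"),
      h2_ace = g("h2_ace"), c2_ace = g("c2_ace"),
      phantom = g("phantom"), h2_narrow = g("h2_narrow"),
      c2_final = g("c2_final"),
      se_phantom = se("phantom"), se_h2_narrow = se("h2_narrow"),
      se_c2_final = se("c2_final")
    )
  })
  class(res) <- c("lp_trait_table", class(res))
  res
}

#' Published twin-correlation targets for the three illustration traits
#'
#' @return A tibble with columns `trait`, `r_mz`, `r_dz`.
#' @export
trait_targets <- function() {
  tibble::tibble(
    trait = c("height", "triglycerides", "high_fat_dairy"),
    r_mz = c(0.89, 0.55, 0.23),
    r_dz = c(0.47, 0.28, 0.13)
  )
}
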