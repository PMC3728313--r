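#' Disease specification for the pathway-threshold model
#'
#' Disease occurs when any standardised pathway phenotype exceeds a liability
#' threshold. The threshold is set by the per-pathway truncation proportion
#' `mu_path`: each pathway on its own would label the top `mu_path` fraction
#' of individuals affected. For k independent equal pathways the overall
#' prevalence is `mu_total = 1 - (1 - mu_path)^k`.
#'
#' Either `mu_path` or `mu_total` may be given. When `mu_total` is supplied,
#' `mu_path` is derived according to `split`: `"independent"` inverts the
#' closed form above (exact for independent pathways), `"equal_share"` uses
#' `mu_total / k` (a simple allocation that is only approximate).
#'
#' @param k Number of pathways.
#' @param mu_path Per-pathway truncation proportion in (0, 1).
#' @param mu_total Target overall prevalence in (0, 1) (alternative input).
#' @param split How to derive `mu_path` from `mu_total`.
#' @return An object of class `disease_spec` with fields `k`, `mu_path`,
#'   `threshold` (s.d. units) and `mu_total` (independent-pathway closed
#'   form).
#' @examples
#' disease_spec(k = 3, mu_path = 0.01)      # mu_total = 0.029701
#' disease_spec(k = 3, mu_total = 0.029701) # recovers mu_path = 0.01
#' @export
disease_spec <- function(k, mu_path = NULL, mu_total = NULL,
                         split = c("independent", "equal_share")) {
  k <- check_count(k, "k")
  split <- match.arg(split)
  if (is.null(mu_path) == is.null(mu_total)) {
    stop("supply exactly one of `mu_path` or `mu_total`", call. = FALSE)
  }
  if (is.null(mu_path)) {
    stopifnot(mu_total > 0, mu_total < 1)
    mu_path <- switch(split,
      independent = 1 - (1 - mu_total)^(1 / k),
      equal_share = mu_total / k
    )
  }
  structure(list(k = k, mu_path = mu_path,
                 threshold = pathway_threshold(mu_path),
                 mu_total = 1 - (1 - mu_path)^k),
            class = "disease_spec")
}

#' Liability threshold for a truncation proportion
#'
#' The standard-normal upper quantile: the threshold t such that a
#' standardised pathway phenotype exceeds t with probability `mu_path`.
#' Monotone decreasing in `mu_path`.
#'
#' @param mu_path Truncation proportion, strictly inside (0, 1).
#' @return Threshold in standard-deviation units.
#' @examples
#' pathway_threshold(0.5)   # 0
#' pathway_threshold(0.01)  # ~2.326
#' @export
pathway_threshold <- function(mu_path) {
  stopifnot(is.numeric(mu_path))
  if (any(mu_path <= 0 | mu_path >= 1)) {
    stop("`mu_path` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stats::qnorm(mu_path, lower.tail = FALSE)
}

#' Disease status, prevalence and twin concordance
#'
#' Applies the pathway-threshold disease definition to a simulated cohort:
#' an individual is affected iff any of its standardised pathway phenotypes
#' (per-pathway mean and variance divided out, so the truncation proportion
#' is scale-free) exceeds the threshold — equivalently, iff the maximum
#' standardised pathway phenotype exceeds it.
#'
#' @param cohort An `lp_cohort` from [simulate_cohort()].
#' @param spec A [disease_spec()]; its `k` must match the cohort.
#' @return A list of class `lp_disease` with `status` (tibble of binary
#'   status per role), `prevalence` (offspring sample prevalence), and a
#'   `concordance` tibble per zygosity with pairwise concordance
#'   (P(both affected)), probandwise concordance (P(co-twin affected |
#'   offspring affected)) and recurrence-risk ratio (probandwise
#'   concordance / prevalence).
#' @export
disease_status <- function(cohort, spec) {
  stopifnot(inherits(cohort, "lp_cohort"), inherits(spec, "disease_spec"))
  params <- cohort$params
  if (spec$k != params$k) stop("`spec$k` must match the cohort", call. = FALSE)
  affected <- function(role) {
    Pstd <- sweep(sweep(cohort[[role]]$P, 2L, params$mu, `-`),
                  2L, sqrt(params$sigma2), `/`)
    row_max(Pstd) > spec$threshold
  }
  st <- tibble::tibble(
    family = seq_len(cohort$n_families),
    offspring = affected("offspring"),
    mz_twin = affected("mz_twin"),
    dz_twin = affected("dz_twin")
  )
  prev <- mean(st$offspring)
  conc <- purrr::map_dfr(c(mz = "mz_twin", dz = "dz_twin"), function(role) {
    both <- mean(st$offspring & st[[role]])
    proband <- if (prev > 0) both / prev else NA_real_
    tibble::tibble(pairwise = both, probandwise = proband,
                   risk_ratio = if (prev > 0) proband / prev else NA_real_)
  }, .id = "zygosity")
  structure(list(status = st, prevalence = prev, concordance = conc,
                 spec = spec),
            class = "lp_disease")
}

#' @export
print.lp_disease <- function(x, ...) {
  cat("<lp_disease> k =", x$spec$k, "| mu_path =", signif(x$spec$mu_path, 4),
      "| threshold =", signif(x$spec$threshold, 4), "\n")
  cat("  prevalence:", signif(x$prevalence, 4),
      "(independent-pathway closed form", signif(x$spec$mu_total, 4), ")\n")
  print(x$concordance)
  invisible(x)
}

#' Disease sweep over parameter combinations
#'
#' Simulates cohorts over a grid of (k, mu_path, rho) and tabulates
#' prevalence and twin concordances, one row per combination.
#'
#' @param k_values,mu_path_values,rho_values Grid vectors.
#' @param h2_path,c2_path Pathway heritability and common-environment
#'   fraction used for every combination.
#' @param n_families Families per cohort.
#' @param seed Integer seed.
#' @return A tibble with one row per (k, mu_path, rho).
#' @export
disease_sweep <- function(k_values, mu_path_values, rho_values = 0,
                          h2_path = 0.5, c2_path = 0, n_families = 1e5,
                          seed = 1L) {
  grid <- tidyr::expand_grid(k = k_values, mu_path = mu_path_values,
                             rho = rho_values)
  purrr::pmap_dfr(grid, function(k, mu_path, rho) {
    params <- lp_params(k = k, h2_path = h2_path, c2_path = c2_path,
                        corr = correlation_spec("uniform", rho))
    coh <- simulate_cohort(params, n_families,
                           seed = replicate_seed(seed, k * 131L) + round(1000 * mu_path))
    d <- disease_status(coh, disease_spec(k = k, mu_path = mu_path))
    conc <- tidyr::pivot_wider(
      d$concordance, names_from = "zygosity",
      values_from = c("pairwise", "probandwise", "risk_ratio")
    )
    dplyr::bind_cols(
      tibble::tibble(k = k, mu_path = mu_path, rho = rho,
                     prevalence = d$prevalence,
                     prevalence_closed_form = d$spec$mu_total),
      conc
    )
  })
}
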