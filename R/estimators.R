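#' Twin correlations and phenotypic variance
#'
#' Pearson correlations of the ordered (offspring, co-twin) phenotype pairs:
#' `r_mz = cor(Y_offspring, Y_mz)`, `r_dz = cor(Y_offspring, Y_dz)`, with the
#' phenotypic variance taken from the offspring. At cohort sizes of 1e5
#' families the difference between Pearson and intraclass correlations is
#' below Monte-Carlo noise.
#'
#' @param cohort An `lp_cohort` from [simulate_cohort()].
#' @return A one-row tibble with columns `r_mz`, `r_dz`, `var_p`.
#' @export
twin_correlations <- function(cohort) {
  stopifnot(inherits(cohort, "lp_cohort"))
  y <- cohort$offspring$Y
  vp <- stats::var(y)
  if (!is.finite(vp) || vp <= 0) {
    stop("degenerate phenotype: offspring variance is not positive",
         call. = FALSE)
  }
  tibble::tibble(
    r_mz = stats::cor(y, cohort$mz_twin$Y),
    r_dz = stats::cor(y, cohort$dz_twin$Y),
    var_p = vp
  )
}

#' Falconer ACE estimates from twin correlations
#'
#' The classical twin-model estimators: `h2_ace = 2 (r_mz - r_dz)`,
#' `c2_ace = 2 r_dz - r_mz`, `e2_ace = 1 - r_mz`. The three sum to one by
#' construction. Estimates are deliberately not truncated to `[0, 1]`:
#' truncation would bias replicate means and obscure boundary behaviour.
#'
#' @param r_mz,r_dz MZ and DZ twin correlations in `[-1, 1]`. `r_mz` may also
#'   be a tibble as returned by [twin_correlations()].
#' @return A one-row tibble with `h2_ace`, `c2_ace`, `e2_ace`.
#' @examples
#' ace_estimates(0.89, 0.47)  # h2_ace = 0.84
#' @export
ace_estimates <- function(r_mz, r_dz) {
  if (is.data.frame(r_mz)) {
    r_dz <- r_mz$r_dz
    r_mz <- r_mz$r_mz
  }
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  tibble::tibble(
    h2_ace = 2 * (r_mz - r_dz),
    c2_ace = 2 * r_dz - r_mz,
    e2_ace = 1 - r_mz
  )
}

#' Narrow-sense heritability by regression on pathway additive values
#'
#' Regresses the final phenotype on the k pathway additive values (ordinary
#' least squares with intercept) and returns the proportion of phenotypic
#' variance carried by the genetic fitted values,
#' `Var(sum_j beta_j A_j) / Var(Y)`. Under the LP model this is the
#' narrow-sense heritability of the observed trait; for `k = 1` it reduces to
#' the pathway heritability. Rank-deficient additive matrices (e.g. perfectly
#' correlated pathways) fall back to the minimum-norm least-squares solution
#' with a warning.
#'
#' @param Y Numeric vector of final phenotypes.
#' @param A n x k matrix of additive pathway values for the same individuals.
#' @return Narrow-sense heritability (scalar).
#' @export
narrow_sense_h2 <- function(Y, A) {
  A <- as.matrix(A)
  n <- length(Y)
  stopifnot(nrow(A) == n, n > ncol(A) + 1L)
  X <- cbind(1, A)
  fit <- stats::lm.fit(X, Y)
  beta <- fit$coefficients[-1L]
  if (anyNA(beta)) {
    warning("additive-value matrix is rank deficient; ",
            "using minimum-norm least-squares solution")
    Ac <- scale(A, center = TRUE, scale = FALSE)
    sv <- svd(Ac)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], Y - mean(Y))) / sv$d[pos])
    beta <- drop(beta)
  }
  g <- drop(A %*% beta)
  stats::var(g) / stats::var(Y)
}

#' Common-environment proportion of the final phenotype
#'
#' The proportion of phenotypic variance common for siblings, estimated by
#' Monte Carlo under a given LP model. Three estimators are available:
#'
#' * `"mz_genetic"` (default): the MZ-twin decomposition `c2 = rMZ - H2`.
#'   The MZ correlation equals the broad-sense genetic proportion `H2` plus
#'   the common-environment proportion, so `c2` is estimated as the
#'   difference between the phenotypic covariance of MZ twins (shared genome
#'   and shared C) and the covariance of pairs sharing the genome only
#'   (independent environments), divided by the phenotypic variance. Both
#'   covariances use the same reference individual, which cancels most of
#'   the Monte-Carlo noise.
#' * `"pair"`: the covariance of pairs sharing only the family-common
#'   environmental draw C (independent additive values and unique
#'   environment), over the phenotypic variance. Because the final phenotype
#'   is a non-linear function, interactions between shared C and shared
#'   genes are excluded here, so this estimator is smaller than
#'   `"mz_genetic"` whenever `k > 1`.
#' * `"regression"`: mirrors the narrow-sense heritability estimator,
#'   regressing the final phenotype on the k common-environment values and
#'   returning the fitted-value variance over the phenotypic variance.
#'
#' For `k = 1` all three reduce to `c2_path * (1 - h2_path)` (in units of
#' the phenotypic variance).
#'
#' @param params An [lp_params()] object.
#' @param n Number of simulated pairs (>= 1e4 recommended).
#' @param seed Integer seed (ignored when `draws` is supplied).
#' @param method `"mz_genetic"` (default), `"pair"` or `"regression"`.
#' @param draws Optional [make_base_draws()] object; its independent
#'   component streams are re-used to build the pairs.
#' @return Proportion of phenotypic variance common to siblings (scalar).
#' @export
c2_final <- function(params, n = 1e5, seed = 1L,
                     method = c("mz_genetic", "pair", "regression"),
                     draws = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(params, "lp_params"))
  cov <- build_covariances(params)
  if (is.null(draws)) draws <- make_base_draws(n, params$k, seed)
  n <- draws$n
  comb <- if (params$combine == "max") row_max else row_min
  C <- sweep(draws$z_c, 2L, sqrt(cov$varC), `*`)
  sdU <- sqrt(cov$varU)
  A1 <- mvn_transform(draws$z_mother, cov$sigmaA)
  U1 <- sweep(draws$z_u_off, 2L, sdU, `*`)
  Y1 <- comb(sweep(A1 + C + U1, 2L, params$mu, `+`))
  if (method == "mz_genetic") {
    # co-twin sharing genome and C (an MZ twin) vs genome only
    U2 <- sweep(draws$z_u_mz, 2L, sdU, `*`)
    C2 <- sweep(draws$z_father, 2L, sqrt(cov$varC), `*`)
    U3 <- sweep(draws$z_u_dz, 2L, sdU, `*`)
    Y_mz <- comb(sweep(A1 + C + U2, 2L, params$mu, `+`))
    Y_gen <- comb(sweep(A1 + C2 + U3, 2L, params$mu, `+`))
    (stats::cov(Y1, Y_mz) - stats::cov(Y1, Y_gen)) / stats::var(Y1)
  } else if (method == "pair") {
    A2 <- mvn_transform(draws$z_father, cov$sigmaA)
    U2 <- sweep(draws$z_u_mz, 2L, sdU, `*`)
    Y2 <- comb(sweep(A2 + C + U2, 2L, params$mu, `+`))
    stats::cov(Y1, Y2) / ((stats::var(Y1) + stats::var(Y2)) / 2)
  } else {
    X <- cbind(1, C)
    fit <- stats::lm.fit(X, Y1)
    beta <- fit$coefficients[-1L]
    beta[is.na(beta)] <- 0
    stats::var(drop(C %*% beta)) / stats::var(Y1)
  }
}

#' Phantom heritability
#'
#' The fraction of the twin-based (ACE) heritability estimate that is not
#' true additive variance: `1 - h2_narrow / h2_ace`. Undefined for
#' `h2_ace <= 0`.
#'
#' @param h2_narrow Narrow-sense heritability of the final phenotype.
#' @param h2_ace ACE (twin-design) heritability estimate; must be > 0.
#' @return Phantom heritability (scalar, not clamped).
#' @examples
#' phantom_heritability(0.55, 0.84)  # ~0.345
#' @export
phantom_heritability <- function(h2_narrow, h2_ace) {
  if (any(h2_ace <= 0)) {
    stop("phantom heritability is undefined for h2_ace <= 0", call. = FALSE)
  }
  1 - h2_narrow / h2_ace
}

replicate_seed <- function(seed, rep) {
  (as.integer(seed) %% 1000000L) * 2000L + rep
}

estimate_once <- function(params, n_families, seed, draws = NULL,
                          c2_method = "mz_genetic") {
  coh <- simulate_cohort(params, n_families, seed = seed, draws = draws)
  tw <- twin_correlations(coh)
  ace <- ace_estimates(tw)
  h2n <- narrow_sense_h2(coh$offspring$Y, coh$offspring$A)
  c2f <- c2_final(params, n = n_families, seed = seed + 1L,
                  method = c2_method,
                  draws = if (is.null(draws)) NULL else draws)
  dplyr::bind_cols(tw, ace) |>
    dplyr::mutate(
      h2_narrow = h2n,
      c2_final = c2f,
      phantom = ifelse(.data$h2_ace > 0, 1 - h2n / .data$h2_ace, NA_real_)
    )
}

#' Replicate simulations and aggregate LP-model outputs
#'
#' Runs `n_reps` independent cohorts of `n_families` families, applies every
#' estimator per replicate, and aggregates: means, medians and Monte-Carlo
#' standard errors (standard deviation across replicates divided by
#' `sqrt(n_reps)`) per quantity. Means are the headline unbiased summaries;
#' medians are also kept because the calibration routine matches on them.
#'
#' @param params An [lp_params()] object.
#' @param n_families Families per replicate.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer root seed; replicate r uses a seed derived from
#'   `(seed, r)`.
#' @param c2_method Passed to [c2_final()].
#' @return An object of class `lp_outputs`: a list with `replicates`
#'   (tibble, one row per replicate), `summary` (tibble: quantity, mean,
#'   median, mc_se), `params`, `n_families`, `n_reps`, `seed`.
#' @examples
#' p <- lp_params(k = 2, h2_path = 0.5)
#' out <- run_replicates(p, n_families = 2000, n_reps = 3, seed = 1)
#' tidy(out)
#' @export
run_replicates <- function(params, n_families, n_reps = 50L, seed = 1L,
                           c2_method = "mz_genetic") {
  n_reps <- check_count(n_reps, "n_reps")
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    estimate_once(params, n_families, seed = replicate_seed(seed, r),
                  c2_method = c2_method) |>
      dplyr::mutate(rep = r, .before = 1L)
  })
  summary <- reps |>
    dplyr::select(-"rep") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "quantity") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      median = stats::median(.data$value),
      mc_se = stats::sd(.data$value) / sqrt(n_reps),
      .groups = "drop"
    )
  structure(list(replicates = reps, summary = summary, params = params,
                 n_families = n_families, n_reps = n_reps, seed = seed),
            class = "lp_outputs")
}

#' @export
print.lp_outputs <- function(x, ...) {
  cat("<lp_outputs>", x$n_reps, "replicates x", x$n_families, "families\n")
  print(x$summary, n = Inf)
  invisible(x)
}

lp_output_value <- function(x, quantity, stat = "mean") {
  s <- x$summary
  s[[stat]][match(quantity, s$quantity)]
}

#' Serialise LP outputs to JSON
#'
#' Writes the aggregated quantities, their Monte-Carlo standard errors, the
#' full parameter echo and the seed to a JSON file.
#'
#' @param x An `lp_outputs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp_outputs <- function(x, path) {
  stopifnot(inherits(x, "lp_outputs"))
  p <- x$params
  obj <- list(
    params = list(k = p$k, mu = p$mu, sigma2 = p$sigma2,
                  h2_path = p$h2_path, c2_path = p$c2_path,
                  corr_kind = p$corr$kind, rho = p$corr$rho,
                  combine = p$combine),
    n_families = x$n_families, n_reps = x$n_reps, seed = x$seed,
    summary = x$summary
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
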