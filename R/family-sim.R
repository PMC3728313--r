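#' @title Family simulation under the limiting-pathway model
#' @name family_sim
#' @description
#' Each simulated family comprises two parents, an offspring, its monozygotic
#' (MZ) co-twin and its dizygotic (DZ) co-twin. Parental additive values are
#' multivariate normal with the pathway additive covariance; offspring
#' additive values are the mid-parent mean plus a Mendelian sampling deviation
#' with covariance half the population additive covariance. The MZ co-twin
#' copies the offspring genome; the DZ co-twin takes an independent Mendelian
#' draw about the same mid-parent mean. Siblings share the family-common
#' environmental draw C; unique environment U is independent per sibling.
#' Parents carry the full environmental variance in a single draw (no
#' environment is shared between the parents of a child).
NULL

# Transform rows of iid standard normals Z (n x k) to MVN(0, S) draws.
# chol() needs strict positive definiteness; near-singular structures
# (e.g. rho -> 1) fall back to an eigen-decomposition square root.
mvn_transform <- function(Z, S) {
  k <- ncol(S)
  if (k == 1L) return(Z * sqrt(S[1L, 1L]))
  U <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(U)) {
    e <- eigen(S, symmetric = TRUE)
    U <- t(e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0))))
  }
  Z %*% U
}

draw_z <- function(n, k) matrix(stats::rnorm(n * k), n, k)

#' Pre-draw the standard-normal inputs of a cohort
#'
#' Draws every standard-normal matrix a cohort of `n` families needs, in a
#' fixed stream order (mothers, fathers, Mendelian offspring, Mendelian DZ,
#' shared C, unique U for the three siblings, parental E). Passing the same
#' `lp_base_draws` object to [simulate_cohort()] with different parameters
#' implements common random numbers: the calibration search re-uses one set
#' of draws across candidate parameter values, which makes its Monte-Carlo
#' objective smooth and its result deterministic given the seed.
#'
#' @param n Number of families.
#' @param k Number of pathways.
#' @param seed Integer seed.
#' @return A list of class `lp_base_draws`.
#' @export
make_base_draws <- function(n, k, seed) {
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  withr::with_seed(seed, {
    structure(list(
      n = n, k = k,
      z_mother = draw_z(n, k),
      z_father = draw_z(n, k),
      z_mend_off = draw_z(n, k),
      z_mend_dz = draw_z(n, k),
      z_c = draw_z(n, k),
      z_u_off = draw_z(n, k),
      z_u_mz = draw_z(n, k),
      z_u_dz = draw_z(n, k),
      z_e_mother = draw_z(n, k),
      z_e_father = draw_z(n, k)
    ), class = "lp_base_draws")
  })
}

#' Simulate parental additive and environmental values
#'
#' Mothers and fathers draw additive values independently from
#' `MVN(0, sigmaA)` (random mating) and a single environmental draw from
#' `MVN(0, diag(varC + varU))`: parental environment is never shared.
#'
#' @param n Number of families.
#' @param params An [lp_params()] object.
#' @param seed Integer seed (ignored when `draws` is given).
#' @param draws Optional [make_base_draws()] object for common random numbers.
#' @return A list with matrices `A_mother`, `A_father`, `E_mother`, `E_father`.
#' @export
simulate_parents <- function(n, params, seed = 1L, draws = NULL) {
  cov <- build_covariances(params)
  if (is.null(draws)) draws <- make_base_draws(n, params$k, seed)
  stopifnot(draws$n == n, draws$k == params$k)
  sdE <- sqrt(cov$varC + cov$varU)
  list(
    A_mother = mvn_transform(draws$z_mother, cov$sigmaA),
    A_father = mvn_transform(draws$z_father, cov$sigmaA),
    E_mother = sweep(draws$z_e_mother, 2L, sdE, `*`),
    E_father = sweep(draws$z_e_father, 2L, sdE, `*`)
  )
}

#' Mendelian sampling of offspring additive values
#'
#' Offspring additive pathway values are distributed about the mid-parent
#' mean with Mendelian sampling covariance `sigmaA / 2`, the infinitesimal-
#' model result for any number of pathways.
#'
#' @param A_mother,A_father n x k parental additive-value matrices.
#' @param sigmaA Population additive covariance matrix.
#' @param z Optional n x k standard-normal matrix (common random numbers);
#'   drawn internally when `NULL`.
#' @return n x k matrix of offspring additive values.
#' @export
mendelian_offspring <- function(A_mother, A_father, sigmaA, z = NULL) {
  stopifnot(identical(dim(A_mother), dim(A_father)))
  if (is.null(z)) z <- draw_z(nrow(A_mother), ncol(A_mother))
  (A_mother + A_father) / 2 + mvn_transform(z, sigmaA / 2)
}

#' Form pathway and final phenotypes
#'
#' Fills pathway phenotypes `P = mu + A + C + U` (siblings) or
#' `P = mu + A + E` (parents), and the final phenotype
#' `Y = max_j P[, j]` (or min, per `params$combine`). With `k = 1` the final
#' phenotype equals the single pathway phenotype. Phenotypes are not
#' re-standardised after combining: the estimators consume raw `Var(Y)` and
#' all reported quantities are scale-free ratios.
#'
#' @param cohort An `lp_cohort` (see [simulate_cohort()]) with component
#'   matrices present.
#' @param params An [lp_params()] object.
#' @return The cohort with `P` and `Y` filled per role.
#' @export
assemble_phenotypes <- function(cohort, params) {
  stopifnot(inherits(cohort, "lp_cohort"))
  comb <- if (params$combine == "max") row_max else row_min
  for (role in c("mother", "father")) {
    P <- sweep(cohort[[role]]$A + cohort[[role]]$E, 2L, params$mu, `+`)
    cohort[[role]]$P <- P
    cohort[[role]]$Y <- comb(P)
  }
  for (role in c("offspring", "mz_twin", "dz_twin")) {
    P <- sweep(cohort[[role]]$A + cohort[[role]]$C + cohort[[role]]$U,
               2L, params$mu, `+`)
    cohort[[role]]$P <- P
    cohort[[role]]$Y <- comb(P)
  }
  cohort
}

row_max <- function(m) do.call(pmax, as.data.frame(m))
row_min <- function(m) do.call(pmin, as.data.frame(m))

#' Simulate a cohort of twin families
#'
#' Generates `n_families` families (mother, father, offspring, MZ co-twin,
#' DZ co-twin) under an extended LP model and assembles pathway and final
#' phenotypes. Reproducible given `(params, n_families, seed)`.
#'
#' @param params An [lp_params()] object.
#' @param n_families Number of families (>= 2).
#' @param seed Integer seed (ignored when `draws` is supplied).
#' @param draws Optional [make_base_draws()] object (common random numbers).
#' @return An object of class `lp_cohort`: a list with one element per role,
#'   each holding the component matrices and the final phenotype vector `Y`,
#'   plus `n_families` and the generating `params`.
#' @examples
#' p <- lp_params(k = 2, h2_path = 0.5)
#' coh <- simulate_cohort(p, n_families = 1000, seed = 7)
#' head(coh$offspring$Y)
#' @export
simulate_cohort <- function(params, n_families, seed = 1L, draws = NULL) {
  stopifnot(inherits(params, "lp_params"))
  n <- check_count(n_families, "n_families")
  if (n < 2L) stop("`n_families` must be at least 2", call. = FALSE)
  if (is.null(draws)) draws <- make_base_draws(n, params$k, seed)
  cov <- build_covariances(params)

  par <- simulate_parents(n, params, draws = draws)
  A_off <- mendelian_offspring(par$A_mother, par$A_father, cov$sigmaA,
                               z = draws$z_mend_off)
  A_dz <- mendelian_offspring(par$A_mother, par$A_father, cov$sigmaA,
                              z = draws$z_mend_dz)
  C <- sweep(draws$z_c, 2L, sqrt(cov$varC), `*`)
  sdU <- sqrt(cov$varU)
  cohort <- structure(list(
    n_families = n,
    params = params,
    mother = list(A = par$A_mother, E = par$E_mother),
    father = list(A = par$A_father, E = par$E_father),
    offspring = list(A = A_off, C = C,
                     U = sweep(draws$z_u_off, 2L, sdU, `*`)),
    mz_twin = list(A = A_off, C = C,
                   U = sweep(draws$z_u_mz, 2L, sdU, `*`)),
    dz_twin = list(A = A_dz, C = C,
                   U = sweep(draws$z_u_dz, 2L, sdU, `*`))
  ), class = "lp_cohort")
  assemble_phenotypes(cohort, params)
}

#' @export
print.lp_cohort <- function(x, ...) {
  cat("<lp_cohort>", x$n_families, "families, k =", x$params$k,
      "pathways, combine =", x$params$combine, "\n")
  invisible(x)
}

#' Flatten a cohort to a tibble
#'
#' One row per individual: family id, role, final phenotype, and the
#' per-pathway component columns (`A1..Ak`, `C1..Ck` or `E1..Ek`, `U1..Uk`,
#' `P1..Pk`). Intended for inspection and CSV export.
#'
#' @param x An `lp_cohort`.
#' @param ... Unused.
#' @return A tibble with `5 * n_families` rows.
#' @method as_tibble lp_cohort
#' @export
as_tibble.lp_cohort <- function(x, ...) {
  roles <- c("mother", "father", "offspring", "mz_twin", "dz_twin")
  purrr::map_dfr(roles, function(role) {
    r <- x[[role]]
    out <- tibble::tibble(family = seq_len(x$n_families), role = role,
                          Y = r$Y)
    for (nm in intersect(c("A", "C", "E", "U", "P"), names(r))) {
      m <- r[[nm]]
      colnames(m) <- paste0(nm, seq_len(ncol(m)))
      out <- dplyr::bind_cols(out, tibble::as_tibble(m))
    }
    out
  }) |>
    dplyr::arrange(.data$family, .data$role)
}
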