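p2 <- lp_params(k = 2, h2_path = 0.5, corr = correlation_spec("uniform", 0.2))

test_that("cohorts are reproducible and twin structure holds by construction", {
  coh1 <- simulate_cohort(p2, 500, seed = 11)
  coh2 <- simulate_cohort(p2, 500, seed = 11)
  expect_identical(coh1, coh2)
  coh3 <- simulate_cohort(p2, 500, seed = 12)
  expect_false(identical(coh1$offspring$Y, coh3$offspring$Y))

  expect_identical(coh1$mz_twin$A, coh1$offspring$A)
  expect_false(identical(coh1$dz_twin$A, coh1$offspring$A))
  expect_identical(coh1$offspring$C, coh1$mz_twin$C)
  expect_identical(coh1$offspring$C, coh1$dz_twin$C)
  # unique environment independent across siblings
  p_c <- lp_params(k = 1, h2_path = 0.2, c2_path = 0.5)
  cohc <- simulate_cohort(p_c, 50000, seed = 3)
  expect_lt(abs(cor(cohc$offspring$U[, 1], cohc$mz_twin$U[, 1])), 0.02)
})

test_that("parental draws match the target covariance under random mating", {
  n <- 2e5
  par <- simulate_parents(n, p2, seed = 5)
  sigmaA <- build_covariances(p2)$sigmaA
  expect_equal(cov(par$A_mother), sigmaA, tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(cov(par$A_father), sigmaA, tolerance = 0.01,
               ignore_attr = TRUE)
  # random mating: no cross-covariance between mates
  expect_lt(max(abs(cov(par$A_mother, par$A_father))), 0.01)

  p_mu <- lp_params(k = 2, mu = c(3, -1), h2_path = 0.5)
  coh <- simulate_cohort(p_mu, 50000, seed = 5)
  expect_equal(colMeans(coh$mother$P), c(3, -1), tolerance = 0.02)
})

test_that("Mendelian sampling gives the infinitesimal-model covariances", {
  n <- 2e5
  coh <- simulate_cohort(p2, n, seed = 8)
  sigmaA <- build_covariances(p2)$sigmaA
  expect_equal(cov(coh$offspring$A), sigmaA, tolerance = 0.01,
               ignore_attr = TRUE)
  expect_equal(cov(coh$offspring$A, coh$mother$A), sigmaA / 2,
               tolerance = 0.01, ignore_attr = TRUE)
  expect_equal(cov(coh$offspring$A, coh$dz_twin$A), sigmaA / 2,
               tolerance = 0.01, ignore_attr = TRUE)
  expect_identical(cov(coh$offspring$A, coh$mz_twin$A),
                   cov(coh$offspring$A))
})

test_that("phenotype assembly reduces correctly and matches closed forms", {
  p1 <- lp_params(k = 1, h2_path = 0.5, c2_path = 0.2)
  coh1 <- simulate_cohort(p1, 1000, seed = 2)
  expect_equal(coh1$offspring$Y, drop(coh1$offspring$P))

  # row-wise max/min on a hand-built matrix
  expect_equal(lpathway:::row_max(rbind(c(1.2, -0.3), c(0, 2))), c(1.2, 2))
  expect_equal(lpathway:::row_min(rbind(c(1.2, -0.3), c(0, 2))), c(-0.3, 0))

  # moments of the max of two iid standard normals
  p <- lp_params(k = 2, h2_path = 0.5)
  coh <- simulate_cohort(p, 2e5, seed = 9)
  expect_equal(mean(coh$offspring$Y), 1 / sqrt(pi), tolerance = 0.01)
  expect_equal(var(coh$offspring$Y), 1 - 1 / pi, tolerance = 0.01)

  # min combine: -max(-P)
  pmin_ <- lp_params(k = 2, h2_path = 0.5, combine = "min")
  cohm <- simulate_cohort(pmin_, 2e5, seed = 9)
  expect_equal(mean(cohm$offspring$Y), -1 / sqrt(pi), tolerance = 0.01)
})

test_that("k = 1 linear cohorts satisfy the classical twin identities", {
  p <- lp_params(k = 1, h2_path = 0.5, c2_path = 0)
  coh <- simulate_cohort(p, 1e5, seed = 21)
  tw <- twin_correlations(coh)
  expect_within(tw$r_mz, 0.5, 0.01)
  expect_within(tw$r_dz, 0.25, 0.01)
})

test_that("pathway relabelling and variance scaling behave as symmetries", {
  pa <- lp_params(k = 2, mu = c(0, 1), sigma2 = c(1, 2),
                  h2_path = c(0.3, 0.7))
  pb <- lp_params(k = 2, mu = c(1, 0), sigma2 = c(2, 1),
                  h2_path = c(0.7, 0.3))
  ya <- simulate_cohort(pa, 1e5, seed = 31)$offspring$Y
  yb <- simulate_cohort(pb, 1e5, seed = 32)$offspring$Y
  expect_equal(mean(ya), mean(yb), tolerance = 0.02)
  expect_equal(var(ya), var(yb), tolerance = 0.03)

  # same base draws: scaling all sigma2 by c scales Var(Y) by c exactly and
  # leaves the twin correlations untouched
  d <- make_base_draws(20000, 2, seed = 7)
  p_scaled <- lp_params(k = 2, sigma2 = 4, h2_path = 0.5, c2_path = 0.3)
  p_unit <- lp_params(k = 2, sigma2 = 1, h2_path = 0.5, c2_path = 0.3)
  c_unit <- simulate_cohort(p_unit, 20000, draws = d)
  c_scaled <- simulate_cohort(p_scaled, 20000, draws = d)
  expect_equal(c_scaled$offspring$Y, 2 * c_unit$offspring$Y)
  expect_equal(twin_correlations(c_scaled)$r_mz,
               twin_correlations(c_unit)$r_mz)
  expect_equal(twin_correlations(c_scaled)$var_p,
               4 * twin_correlations(c_unit)$var_p)
})

test_that("cohorts flatten to a tidy per-individual table", {
  coh <- simulate_cohort(p2, 50, seed = 1)
  tb <- as_tibble(coh)
  expect_equal(nrow(tb), 5 * 50)
  expect_setequal(unique(tb$role),
                  c("mother", "father", "offspring", "mz_twin", "dz_twin"))
  expect_true(all(c("family", "Y", "A1", "A2", "P1", "P2") %in% names(tb)))
  off <- tb[tb$role == "offspring", ]
  expect_equal(off$Y, pmax(off$P1, off$P2))
})
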