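test_that("twin correlations recover linear-model expectations", {
  p <- lp_params(k = 1, h2_path = 0.8, c2_path = 0)
  coh <- simulate_cohort(p, 1e5, seed = 4)
  tw <- twin_correlations(coh)
  expect_within(tw$r_mz, 0.8, 0.01)
  expect_within(tw$r_dz, 0.4, 0.01)

  # fully heritable: MZ co-twin is an exact copy
  p1 <- lp_params(k = 2, h2_path = 1)
  coh1 <- simulate_cohort(p1, 5000, seed = 4)
  expect_equal(twin_correlations(coh1)$r_mz, 1)

  # shuffled co-twin assignment destroys both correlations
  cohs <- coh
  perm <- withr::with_seed(1, sample(coh$n_families))
  cohs$mz_twin$Y <- coh$mz_twin$Y[perm]
  cohs$dz_twin$Y <- coh$dz_twin$Y[perm]
  tws <- twin_correlations(cohs)
  expect_lt(abs(tws$r_mz), 0.02)
  expect_lt(abs(tws$r_dz), 0.02)

  cohd <- coh
  cohd$offspring$Y <- rep(1, coh$n_families)
  expect_error(twin_correlations(cohd), "degenerate")
})

test_that("Falconer estimators reproduce published values and identities", {
  expect_equal(ace_estimates(0.89, 0.47)$h2_ace, 0.84)
  expect_equal(ace_estimates(0.55, 0.28)$h2_ace, 0.54)
  expect_equal(ace_estimates(0.23, 0.13)$h2_ace, 0.20)
  for (r in c(0, 0.3, 0.9)) {
    est <- ace_estimates(r, r)
    expect_equal(est$h2_ace, 0)
    expect_equal(est$c2_ace, r)
  }
  est <- ace_estimates(0.6, 0.35)
  expect_equal(est$h2_ace + est$c2_ace + est$e2_ace, 1)
  # accepts the tibble from twin_correlations
  tw <- tibble::tibble(r_mz = 0.89, r_dz = 0.47, var_p = 1)
  expect_equal(ace_estimates(tw)$h2_ace, 0.84)
})

test_that("regression-based narrow-sense heritability is calibrated", {
  p <- lp_params(k = 1, h2_path = 0.5, c2_path = 0)
  coh <- simulate_cohort(p, 1e5, seed = 6)
  expect_within(narrow_sense_h2(coh$offspring$Y, coh$offspring$A), 0.5, 0.01)

  # two-pathway basic LP vs the Gauss-Hermite quadrature oracle
  p2 <- lp_params(k = 2, h2_path = 0.5)
  coh2 <- simulate_cohort(p2, 1e5, seed = 6)
  expect_within(narrow_sense_h2(coh2$offspring$Y, coh2$offspring$A),
                oracle_h2_basic_k2(0.5), 0.01)

  # phenotype independent of the additive values carries no heritability
  noise <- withr::with_seed(1, rnorm(1e5))
  expect_lt(narrow_sense_h2(noise, coh2$offspring$A), 0.005)

  # duplicated pathway column: rank-deficient fallback warns
  A <- coh$offspring$A
  expect_warning(
    h2dup <- narrow_sense_h2(coh$offspring$Y, cbind(A, A)),
    "rank deficient"
  )
  expect_within(h2dup, 0.5, 0.01)
})

test_that("final-level common-environment estimators are consistent", {
  # linear case: all methods equal c2_path * (1 - h2_path)
  p <- lp_params(k = 1, h2_path = 0.5, c2_path = 0.2)
  for (m in c("mz_genetic", "pair", "regression")) {
    expect_within(c2_final(p, n = 2e5, seed = 13, method = m), 0.1, 0.01)
  }
  p0 <- lp_params(k = 2, h2_path = 0.5, c2_path = 0)
  expect_equal(c2_final(p0, n = 1e5, seed = 13), 0, tolerance = 0.005)

  # k = 2 basic LP: shared-C pair covariance against the quadrature oracle
  pc <- lp_params(k = 2, h2_path = 0.5, c2_path = 0.5)
  c2p <- c2_final(pc, n = 2e5, seed = 13, method = "pair")
  expect_gte(c2p, 0)
  expect_lte(c2p, 0.25)
  expect_within(c2p, oracle_c2_pair_k2(0.5, 0.5), 0.01)

  # non-linearity: the MZ-decomposition estimate exceeds the shared-C-only
  # covariance once k > 1 (shared genes amplify the shared C contribution)
  c2m <- c2_final(pc, n = 2e5, seed = 13, method = "mz_genetic")
  expect_gt(c2m, c2p)
})

test_that("phantom heritability is the exact ACE shortfall ratio", {
  expect_equal(phantom_heritability(0.55, 0.84), 1 - 0.55 / 0.84)
  expect_equal(round(phantom_heritability(0.55, 0.84), 2), 0.35)
  expect_equal(round(phantom_heritability(0.15, 0.84), 2), 0.82)
  expect_equal(phantom_heritability(0.5, 0.5), 0)
  expect_error(phantom_heritability(0.5, 0), "undefined")
  expect_error(phantom_heritability(0.5, -0.1), "undefined")
})

test_that("replicate runs aggregate reproducibly with small MC error", {
  p <- lp_params(k = 1, h2_path = 0.5, c2_path = 0.2)
  out1 <- run_replicates(p, 20000, n_reps = 5, seed = 3)
  out2 <- run_replicates(p, 20000, n_reps = 5, seed = 3)
  expect_identical(out1$summary, out2$summary)
  expect_equal(nrow(out1$replicates), 5)

  s <- tidy(out1)
  expect_setequal(names(s), c("quantity", "mean", "median", "mc_se"))
  expect_lt(s$mc_se[s$quantity == "h2_ace"], 0.02)
  expect_equal(s$mean[s$quantity == "phantom"], 0, tolerance = 0.05)

  g <- glance(out1)
  expect_equal(g$n_reps, 5)
  expect_equal(g$h2_ace, s$mean[s$quantity == "h2_ace"])

  # epistasis appears as soon as k > 1
  p2 <- lp_params(k = 2, h2_path = 0.5)
  out_k2 <- run_replicates(p2, 20000, n_reps = 5, seed = 3)
  expect_gt(glance(out_k2)$phantom, 0.1)
})

test_that("LP outputs serialise to JSON with a full parameter echo", {
  p <- lp_params(k = 2, h2_path = 0.5, c2_path = 0.1)
  out <- run_replicates(p, 5000, n_reps = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_lp_outputs(out, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$params$k, 2)
  expect_equal(back$params$h2_path, c(0.5, 0.5))
  expect_equal(back$seed, 1)
  expect_equal(back$summary$mean[back$summary$quantity == "r_mz"],
               lpathway:::lp_output_value(out, "r_mz"))
})

test_that("ACE estimate dominates narrow-sense heritability for rho >= 0", {
  cfgs <- list(
    lp_params(k = 2, h2_path = 0.5),
    lp_params(k = 3, h2_path = 0.7, c2_path = 0.3),
    lp_params(k = 5, h2_path = 0.4,
              corr = correlation_spec("uniform", 0.2))
  )
  for (p in cfgs) {
    g <- glance(run_replicates(p, 30000, n_reps = 3, seed = 17))
    expect_gt(g$h2_ace, g$h2_narrow)
  }
})

test_that("phantom heritability is scale-free and vanishes as rho -> 1", {
  g1 <- glance(run_replicates(lp_params(k = 2, h2_path = 0.5),
                              30000, n_reps = 4, seed = 23))
  g4 <- glance(run_replicates(lp_params(k = 2, sigma2 = 4, h2_path = 0.5),
                              30000, n_reps = 4, seed = 23))
  expect_equal(g1$phantom, g4$phantom, tolerance = 1e-10)

  p99 <- lp_params(k = 3, h2_path = 0.5,
                   corr = correlation_spec("uniform", 0.99))
  g99 <- glance(run_replicates(p99, 50000, n_reps = 3, seed = 29))
  expect_lt(abs(g99$phantom), 0.03)
})
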