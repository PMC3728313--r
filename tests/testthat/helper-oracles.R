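# Quadrature oracles for the two-pathway basic LP model (mu = 0, sigma2 = 1,
# equal pathway heritability, independent pathways). Independent of the
# simulation code: expectations involving the bivariate-normal maximum are
# reduced to smooth conditional closed forms and integrated by Gauss-Hermite
# quadrature (conditioning first keeps the integrands smooth, so the rule
# converges fast).

gh_rule <- function(n = 80) {
  gh <- pracma::gaussHermite(n)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# E[f(B)] for B ~ N(0, 1)
gh_expect1 <- function(f, rule = gh_rule()) sum(rule$w * f(rule$x))

# E[f(B1, B2)] for B1, B2 iid N(0, 1)
gh_expect2 <- function(f, rule = gh_rule()) {
  W <- outer(rule$w, rule$w)
  X1 <- matrix(rule$x, length(rule$x), length(rule$x))
  sum(W * f(X1, t(X1)))
}

# moments of Y = max(X1, X2), X iid standard normal; conditional on X2 = b,
# E[max(X1, b)] = b pnorm(b) + dnorm(b) and
# E[max(X1, b)^2] = b^2 pnorm(b) + 1 - pnorm(b) + b dnorm(b)
oracle_max2_moments <- function(rule = gh_rule()) {
  m1 <- gh_expect1(function(b) b * pnorm(b) + dnorm(b), rule)
  m2 <- gh_expect1(function(b) b^2 * pnorm(b) + 1 - pnorm(b) + b * dnorm(b),
                   rule)
  list(mean = m1, var = m2 - m1^2)
}

# narrow-sense heritability of Y = max(P1, P2) for the basic LP model with
# pathway heritability h2p. The regression slope of Y on A_1 is
# Cov(Y, A1) / Var(A1) = E[max(X1, X2) X1] (since Cov(Y, A1) = h2p * c and
# Var(A1) = h2p); conditional on X2 = b, E[max(X1, b) X1] = 1 - pnorm(b).
# Then h2 = Var(c A1 + c A2) / Var(Y) = 2 c^2 h2p / Var(Y).
oracle_h2_basic_k2 <- function(h2p, rule = gh_rule()) {
  cvy <- gh_expect1(function(b) 1 - pnorm(b), rule)
  mom <- oracle_max2_moments(rule)
  2 * cvy^2 * h2p / mom$var
}

# shared-environment-only pair covariance of maxima for the basic LP model:
# conditional on the shared C = (c1, c2), the two siblings' Y are independent
# maxima of normals with means c1, c2 and common variance s2, whose
# conditional mean has a smooth closed form; its variance over C (2-D
# quadrature) is the pair covariance
oracle_c2_pair_k2 <- function(h2p, crp, rule = gh_rule()) {
  varC <- crp * (1 - h2p)
  s2 <- 1 - varC            # per-pathway variance not shared by the pair
  theta <- sqrt(2 * s2)
  m <- function(c1, c2) {
    d <- (c1 - c2) / theta
    c1 * pnorm(d) + c2 * pnorm(-d) + theta * dnorm(d)
  }
  sdC <- sqrt(varC)
  e1 <- gh_expect2(function(a, b) m(sdC * a, sdC * b), rule)
  e2 <- gh_expect2(function(a, b) m(sdC * a, sdC * b)^2, rule)
  vy <- oracle_max2_moments(rule)$var
  (e2 - e1^2) / vy
}
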