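#' Pathway genetic correlation structure
#'
#' Describes how the additive genetic values of the k latent pathways are
#' correlated. Three structures are supported:
#'
#' * `"uniform"`: every pair of pathways has correlation `rho`. The implied
#'   matrix is positive semi-definite only for `rho >= -1/(k - 1)`.
#' * `"two_block"`: pathways are split into two sets of sizes `ceiling(k/2)`
#'   and `floor(k/2)`; correlation is `+rho` within a set and `-rho` between
#'   sets. This is how block-wise negative dependence between pathways is
#'   expressed without violating positive semi-definiteness for all pairs.
#' * `"one_vs_rest"`: pathway 1 has correlation `-rho` with every other
#'   pathway, while pathways `2..k` are mutually correlated `+rho`.
#'
#' Environmental effects are always independent across pathways; the
#' correlation applies to additive genetic values only.
#'
#' @param kind One of `"uniform"`, `"two_block"`, `"one_vs_rest"`.
#' @param rho Correlation in `[-1, 1]`.
#' @return An object of class `correlation_spec`.
#' @examples
#' correlation_spec("uniform", 0.2)
#' build_correlation_matrix(4, correlation_spec("two_block", 0.2))
#' @export
correlation_spec <- function(kind = c("uniform", "two_block", "one_vs_rest"),
                             rho = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (rho < -1 || rho > 1) {
    stop("`rho` must lie in [-1, 1], got ", rho, call. = FALSE)
  }
  structure(list(kind = kind, rho = rho), class = "correlation_spec")
}

#' @export
print.correlation_spec <- function(x, ...) {
  cat("<correlation_spec> kind =", x$kind, ", rho =", x$rho, "\n")
  invisible(x)
}

#' Build a pathway correlation matrix
#'
#' Materialises the k x k additive-genetic correlation matrix implied by a
#' [correlation_spec()]. The matrix is validated to be positive semi-definite
#' (minimum eigenvalue >= -1e-10, a tolerance for eigen-decomposition noise);
#' infeasible structures raise an error naming the violated bound.
#'
#' @param k Number of pathways (integer >= 1).
#' @param spec A [correlation_spec()].
#' @return A k x k symmetric matrix with unit diagonal.
#' @export
build_correlation_matrix <- function(k, spec) {
  stopifnot(inherits(spec, "correlation_spec"))
  k <- check_count(k, "k")
  rho <- spec$rho
  if (k == 1L) {
    return(matrix(1, 1L, 1L))
  }
  R <- switch(spec$kind,
    uniform = {
      if (rho < -1 / (k - 1)) {
        stop("uniform correlation rho = ", rho,
             " is infeasible for k = ", k,
             ": positive semi-definiteness requires rho >= ",
             signif(-1 / (k - 1), 6), call. = FALSE)
      }
      m <- matrix(rho, k, k)
      diag(m) <- 1
      m
    },
    two_block = {
      sizes <- c(ceiling(k / 2), floor(k / 2))
      block <- rep.int(c(1L, 2L), sizes)
      m <- ifelse(outer(block, block, "=="), rho, -rho)
      diag(m) <- 1
      m
    },
    one_vs_rest = {
      m <- matrix(rho, k, k)
      m[1L, -1L] <- -rho
      m[-1L, 1L] <- -rho
      diag(m) <- 1
      m
    }
  )
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-10) {
    stop(spec$kind, " correlation structure with rho = ", rho,
         " is not positive semi-definite for k = ", k,
         " (minimum eigenvalue ", signif(ev, 4), ")", call. = FALSE)
  }
  R
}

#' Limiting-pathway model parameters
#'
#' The extended LP model is a six-parameter model: the number of pathways `k`,
#' per-pathway phenotype means `mu`, phenotypic variances `sigma2`, pathway
#' heritabilities `h2_path`, the fraction `c2_path` of pathway environmental
#' variance that is common to siblings of a family (a single value shared by
#' all pathways), and the genetic correlation structure between pathways.
#' The observed phenotype of an individual is the maximum (or minimum) of the
#' k pathway phenotypes.
#'
#' The basic LP model is the special case `mu = 0`, `sigma2 = 1`, equal
#' `h2_path`, and independent pathways (`uniform` correlation with `rho = 0`).
#' Scalars supplied for `mu`, `sigma2`, `h2_path` are broadcast to all k
#' pathways.
#'
#' @param k Number of pathways (integer >= 1).
#' @param mu Pathway means, length k or scalar (phenotype s.d. units).
#' @param sigma2 Pathway phenotypic variances, length k or scalar; all > 0.
#' @param h2_path Pathway heritabilities in `[0, 1]`, length k or scalar.
#' @param c2_path Fraction of pathway environmental variance common to
#'   siblings, scalar in `[0, 1]`.
#' @param corr A [correlation_spec()]; defaults to independent pathways.
#' @param combine `"max"` (default) or `"min"`: how pathway phenotypes are
#'   combined into the observed phenotype.
#' @return An object of class `lp_params`.
#' @examples
#' lp_params(k = 2, h2_path = 0.5)                      # basic LP model
#' lp_params(k = 3, mu = c(0, 1, 0), h2_path = 0.6,
#'           corr = correlation_spec("uniform", 0.2))
#' @export
lp_params <- function(k, mu = 0, sigma2 = 1, h2_path, c2_path = 0,
                      corr = correlation_spec("uniform", 0),
                      combine = c("max", "min")) {
  k <- check_count(k, "k")
  combine <- match.arg(combine)
  stopifnot(inherits(corr, "correlation_spec"))
  mu <- broadcast(mu, k, "mu")
  sigma2 <- broadcast(sigma2, k, "sigma2")
  h2_path <- broadcast(h2_path, k, "h2_path")
  if (any(sigma2 <= 0)) stop("all `sigma2` must be strictly positive", call. = FALSE)
  if (any(h2_path < 0 | h2_path > 1)) {
    stop("all `h2_path` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(c2_path), length(c2_path) == 1L)
  if (c2_path < 0 || c2_path > 1) stop("`c2_path` must lie in [0, 1]", call. = FALSE)
  # fail fast on infeasible correlation structures
  build_correlation_matrix(k, corr)
  structure(
    list(k = k, mu = mu, sigma2 = sigma2, h2_path = h2_path,
         c2_path = c2_path, corr = corr, combine = combine),
    class = "lp_params"
  )
}

#' @export
print.lp_params <- function(x, ...) {
  cat("<lp_params> k =", x$k, "| combine =", x$combine, "\n")
  cat("  mu      :", paste(signif(x$mu, 4), collapse = ", "), "\n")
  cat("  sigma2  :", paste(signif(x$sigma2, 4), collapse = ", "), "\n")
  cat("  h2_path :", paste(signif(x$h2_path, 4), collapse = ", "), "\n")
  cat("  c2_path :", x$c2_path, "\n")
  cat("  corr    :", x$corr$kind, "rho =", x$corr$rho, "\n")
  invisible(x)
}

#' Pathway-level covariance components
#'
#' Builds the covariance structure implied by an [lp_params()] object:
#' the k x k additive-genetic covariance matrix `sigmaA` with entries
#' `corr[i,j] * sqrt(h2_i sigma2_i h2_j sigma2_j)`, and the diagonal
#' common- and unique-environment variances
#' `varC = c2_path * (1 - h2) * sigma2` and `varU = (1 - c2_path) *
#' (1 - h2) * sigma2`. The three components sum to `sigma2` per pathway.
#'
#' @param params An [lp_params()] object.
#' @return A list of class `covariance_bundle` with elements `sigmaA`
#'   (k x k matrix), `varC` and `varU` (length-k vectors).
#' @export
build_covariances <- function(params) {
  stopifnot(inherits(params, "lp_params"))
  R <- build_correlation_matrix(params$k, params$corr)
  sdA <- sqrt(params$h2_path * params$sigma2)
  sigmaA <- R * tcrossprod(sdA)
  varE <- (1 - params$h2_path) * params$sigma2
  varC <- params$c2_path * varE
  varU <- varE - varC
  structure(list(sigmaA = sigmaA, varC = varC, varU = varU),
            class = "covariance_bundle")
}

#' Read LP parameters from a plain-text key-value config file
#'
#' Lines have the form `key = value`; vectors are comma-separated; `#` starts
#' a comment. Recognised keys: `k`, `mu`, `sigma2`, `h2_path`, `c2_path`,
#' `corr_kind`, `rho`, `combine`. Scalars broadcast to all k pathways.
#'
#' @param path Path to the config file.
#' @return An [lp_params()] object.
#' @export
read_lp_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  cfg <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) {
    if (is.null(cfg[[key]])) return(default)
    as.numeric(strsplit(cfg[[key]], ",", fixed = TRUE)[[1L]])
  }
  chr <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  lp_params(
    k = num("k", stop("config must set `k`", call. = FALSE)),
    mu = num("mu", 0),
    sigma2 = num("sigma2", 1),
    h2_path = num("h2_path", stop("config must set `h2_path`", call. = FALSE)),
    c2_path = num("c2_path", 0),
    corr = correlation_spec(chr("corr_kind", "uniform"), num("rho", 0)),
    combine = chr("combine", "max")
  )
}

check_count <- function(x, name) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  if (x < 1 || x != round(x)) {
    stop("`", name, "` must be a positive integer, got ", x, call. = FALSE)
  }
  as.integer(x)
}

broadcast <- function(x, k, name) {
  stopifnot(is.numeric(x))
  if (length(x) == 1L) x <- rep.int(x, k)
  if (length(x) != k) {
    stop("`", name, "` must have length 1 or k = ", k,
         ", got length ", length(x), call. = FALSE)
  }
  as.numeric(x)
}
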