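---
title: "Limiting-pathway models, twin designs and phantom heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limiting-pathway models, twin designs and phantom heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpathway)
```

## The model

A limiting-pathway (LP) model posits that an observed quantitative trait
$Y$ is the maximum (equivalently, after a sign flip, the minimum) of $k$
latent *pathway phenotypes* $P_1, \dots, P_k$ — think of a trait limited by
the scarcest component of a molecular complex, or the slowest reaction in a
set of parallel pathways. Each pathway phenotype follows an infinitesimal
additive model,
$$P_j = \mu_j + A_j + C_j + U_j,$$
with additive genetic value $A_j$, environmental effect split into a part
$C_j$ common to siblings of one family and a unique part $U_j$. Although
every pathway is purely additive, the max is not: for $k > 1$ the observed
trait carries additive-by-additive epistatic variance, and the classical
twin-design (ACE) heritability estimate overstates the true narrow-sense
heritability. The shortfall is the *phantom heritability*
$$\pi = 1 - h^2 / \hat h^2_{ACE}.$$

The extended model has six parameters: the pathway count $k$, the mean
vector $\mu$ (in phenotype s.d. units), the pathway phenotypic variances
$\sigma^2$, the pathway heritabilities $h^2_{path}$, the fraction
$c_r$ (`c2_path`) of pathway *environmental* variance that is shared by
siblings (one value for all pathways — note this is a fraction of the
environmental, not phenotypic, variance), and the genetic correlation
structure between pathways. The basic LP model is the special case of equal
means, unit variances, equal heritabilities and independent pathways.

Three correlation structures are built in (`correlation_spec()`): `uniform`
(every pair correlated $\rho$, feasible for $\rho \ge -1/(k-1)$),
`two_block` (two near-equal sets, $+\rho$ within and $-\rho$ between — the
feasible way to give *many* pathways negative dependence), and
`one_vs_rest` (pathway 1 correlated $-\rho$ with each of the mutually
$+\rho$-correlated others; this turns out to be positive semi-definite for
all $\rho \in [0, 1]$). Correlations apply to additive values only;
environmental effects are always independent across pathways. Structures
are validated by eigen-decomposition with a $-10^{-10}$ tolerance on the
minimum eigenvalue, which absorbs floating-point noise without accepting
genuinely indefinite matrices.

## The family simulator

`simulate_cohort()` generates nuclear families: two parents, an offspring,
its MZ co-twin and its DZ co-twin. Parents draw additive values from
$N(0, \Sigma_A)$ independently (random mating) with
$\Sigma_{A,ij} = \rho_{ij}\sqrt{h^2_i \sigma^2_i h^2_j \sigma^2_j}$, and a
single environmental draw carrying the full environmental variance —
nothing is shared between the parents of a child. Offspring additive values
are the mid-parent mean plus a Mendelian-sampling deviation with covariance
$\Sigma_A/2$, the standard infinitesimal-model result, applied here for any
$k$ (the defining property is that the population additive covariance is
reproduced in the offspring generation: one half from variation in parental
means, one half from Mendelian segregation). The MZ co-twin copies the
offspring's genome; the DZ co-twin takes an independent Mendelian draw
about the same mid-parent mean. The three siblings share one
common-environment draw $C$; unique environment is drawn per sibling.

Random numbers follow a fixed stream order (mothers, fathers, Mendelian
offspring, Mendelian DZ, shared C, unique U per sibling, parental E) from a
single seed per replicate, so cohorts are bit-reproducible. Final
phenotypes are *not* re-standardised after taking the max: every reported
quantity is a variance ratio and therefore scale-free (tested exactly:
scaling all $\sigma^2$ by a constant scales $\mathrm{Var}(Y)$ and changes
no correlation).

## Estimators

* **Twin correlations** are Pearson correlations of the ordered
  (offspring, co-twin) pairs. At $10^5$ families the difference from an
  intraclass correlation is far below Monte-Carlo error.
* **ACE components** use the Falconer identities
  $\hat h^2_{ACE} = 2(r_{MZ} - r_{DZ})$,
  $\hat c^2_{ACE} = 2 r_{DZ} - r_{MZ}$, $\hat e^2 = 1 - r_{MZ}$, without
  truncation to $[0, 1]$ — truncation would bias replicate means near the
  boundary.
* **Narrow-sense heritability** regresses $Y$ on the $k$ additive values
  (OLS with intercept) and reports
  $\mathrm{Var}(\sum_j \beta_j A_j)/\mathrm{Var}(Y)$. Pathway phenotypes
  under the extended model are correlated and non-exchangeable, which the
  multiple regression accommodates; for $k = 1$ it returns the pathway
  heritability. Rank-deficient designs (perfectly correlated pathways) fall
  back to the minimum-norm solution with a warning.
* **Common-variance proportion at the trait level.** The package's default
  estimator is the MZ decomposition $c^2 = r_{MZ} - H^2$, where the
  broad-sense genetic proportion $H^2$ is measured from simulated pairs
  that share the full genome but no environment; both covariances use the
  same reference individuals so most Monte-Carlo noise cancels. Two
  alternative estimators are provided (`method` in `c2_final()`): the
  covariance of pairs sharing only $C$, and a regression of $Y$ on the $C$
  values. All three coincide in the linear case
  ($c^2 = c_r (1 - h^2_{path})$), but for $k > 1$ the max couples shared
  genes with shared environment, and only the MZ decomposition reproduces
  the published three-trait table; the shared-$C$-only covariance is
  systematically smaller because it excludes that interaction.
* **Phantom heritability** is the exact ratio $1 - h^2/\hat h^2_{ACE}$,
  computed per replicate and averaged.

`run_replicates()` aggregates every estimator over independent replicate
cohorts and reports means, medians and replicate-based standard errors
(closed-form standard errors are out of scope by design).

## Calibration

The three-trait illustration requires the inverse problem: given observed
$(r_{MZ}, r_{DZ})$ — e.g. height 0.89/0.47, blood triglycerides 0.55/0.28,
high-fat dairy intake 0.23/0.13 — find $(h^2_{path}, c_r)$ so that the
*simulated* correlations match. `calibrate_lp()` exploits the monotonicity
of the map $(h^2_{path}, c_r) \to (\hat h^2_{ACE}, \hat c^2_{ACE})$
(verified numerically on a grid in the test suite): an inner bisection on
$h^2_{path}$ matches $2(r_{MZ} - r_{DZ})$, an outer bisection on $c_r$
matches $2 r_{DZ} - r_{MZ}$. Three numerical devices matter:

1. **Common random numbers.** All candidate evaluations reuse one fixed set
   of standard-normal draws per replicate, transformed by the candidate's
   covariance factor. The objective becomes a smooth deterministic function
   of the parameters, so bisection converges; matching uses the median
   across replicates, while reported outputs are means over fresh
   replicates.
2. **Residual refinement.** A fixed draw block has its own sampling offset
   (a few $10^{-3}$ on a correlation), which phantom heritability amplifies
   roughly by $2\hat h^2 / (\hat h^2_{ACE})^2$ — a factor near 10 for a
   trait with $\hat h^2_{ACE} = 0.2$. After the search, the fit is
   re-simulated with fresh seeds, and the search repeats with targets
   shifted by the measured residual; one or two passes leave only the
   fresh-replicate Monte-Carlo error.
3. **Boundary handling.** Targets with $r_{DZ} > r_{MZ}$ or outside $[0,1]$
   are rejected up front; a $c^2_{ACE}$ target above what $c_r = 1$ can
   produce raises an error reporting the attainable boundary.

Infeasibility aside, the search caps at `max_outer` $\times$ `max_inner`
evaluations (default 12 and 14); in practice convergence to the 0.002–0.005
correlation tolerance takes far fewer.

## Disease extension

For binary traits, disease occurs when *any* standardised pathway phenotype
exceeds the liability threshold $t = \Phi^{-1}(1 - \mu_{path})$.
Standardisation (per-pathway mean and variance divided out) makes the
truncation proportion scale-free. For independent equal pathways the
prevalence is $1 - (1 - \mu_{path})^k$ in closed form; `disease_spec()`
inverts this when a total prevalence is supplied (a `mu_total / k`
allocation is available as an explicit alternative, since either reading is
possible for how a stated total should be split). Pairwise and probandwise
twin concordances and recurrence-risk ratios are tabulated. Note one
asymmetry inherited from the quantitative model: genetic correlation can
make pathway *genetics* collapse to a single pathway as $\rho \to 1$, but
pathway environments remain independent, so the collapse to a
single-pathway liability model is exact only for fully heritable pathways
and is otherwise a monotone approach.

## Default study conditions and problem sizes

The reference design is 50 replicates of 100,000 families; sweep defaults
follow it. Where the sensitivity-analysis defaults are needed
(`lp_phantom_sweep()`), the package uses $k = 2$, $h^2_{path} = 0.5$,
$c_r = 0$, $\rho = 0$ unless the panel varies them, and the
10%-common-environment variant sets $c_r = 0.1/(1 - h^2_{path})$ so that
10% of each pathway's *phenotypic* variance is common. These are package
choices, stated here once, and exposed as arguments.

The test suite runs reduced designs (20,000–100,000 families, 3–16
replicates) with tolerances widened accordingly; the acceptance script
recomputes the headline calibrated cells at 100,000 families with 16–30
output replicates. A single cohort of $10^5$ families with $k = 2$ takes
about 0.15 s; a full calibration of one cell takes one to a few minutes.

## What the simulator does and does not emulate

The generator reproduces the stylised facts the model family is built on:
multivariate-normal pathway genetics with infinitesimal inheritance, random
mating, equal environments for MZ and DZ pairs, and no parental shared
environment. It does not emulate assortative mating, dominance,
non-normal pathway distributions, ascertainment, more than two
generations, or measurement error. Passing tests therefore validate the
model arithmetic and its published consequences, not the biological
adequacy of the LP assumptions for any real trait.

## Known limitations

* The ACE decomposition is estimated by the Falconer identities, not by
  maximum-likelihood structural-equation fitting; for the large simulated
  samples used here the difference is negligible, but small-sample
  behaviour differs.
* Phantom heritability for traits with small $\hat h^2_{ACE}$ is an
  ill-conditioned ratio; its Monte-Carlo error is roughly ten times that of
  the underlying correlations, which drives the replicate counts above.
* `calibrate_lp()` assumes equal pathway heritabilities and a scalar
  shared-environment fraction, as the three-trait illustration does;
  calibrating heterogeneous pathway parameters is out of scope.
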