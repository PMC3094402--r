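---
title: "Phylogenetic comparative methods for lizard life history and climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative methods for lizard life history and climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropilife)
```

## The problem

Interspecific comparisons of life-history traits — here, female body size
(snout–vent length, SVL, mm) and clutch size (eggs) across a tropical
lizard radiation — cannot treat species as independent observations:
closely related species resemble each other through shared ancestry.
`tropilife` implements the full analysis chain used in this situation when
divergence times are unknown: assign defensible *arbitrary* branch lengths
to a published topology, check them, quantify phylogenetic signal, fit a
continuum of regression models whose residual structure spans "no
phylogeny" to "full phylogeny", select among them by information criteria,
reduce collinear climate variables to a few principal components, and
reconstruct ancestral trait values.

## Branch-length schemes and their diagnostic

With a topology but no divergence times, four classical schemes provide
candidate branch lengths (`assign_branch_lengths()`):

* **constant** — every branch 1.  Not ultrametric in general.
* **grafen** — node height $(\text{descendant tips} - 1)^\rho$, rescaled to
  root height 1 (default $\rho = 1$, exposed as a parameter since the
  exponent is conventionally tunable).
* **pagel** — all segments 1, then terminal branches extended so all tips
  are contemporaneous.
* **nee** — node height proportional to $\log_2$(descendant tips),
  rescaled to root height 1.

The exact algorithmic definitions of the Pagel and Nee schemes vary
between historical implementations; the two rules above are this package's
documented conventions, and every covariance matrix records its scheme in
a provenance attribute so a swapped convention is auditable rather than
silent.

Adequacy is an empirical question: under Brownian motion on correct branch
lengths, Felsenstein's standardized contrasts are homoscedastic, so
`diagnose_branch_lengths()` tests the Pearson correlation between
$|$contrast$|$ and its standard deviation and passes a scheme when
$p \ge \alpha$ (default 0.05).  The pipeline warns rather than stops on a
failing scheme, and proceeds with the passers.

Polytomies are resolved deterministically (input-order ladder via
`ape::multi2di(random = FALSE)`) with internal branches of $10^{-8}$, which
preserves positive definiteness of the covariance while changing path
lengths negligibly.  A basal multifurcation is accepted as a rooted
polytomy: Newick cannot distinguish it from an unrooted tree, and star
phylogenies are legitimate inputs here (they are the OLS null).

## Phylogenetic signal

`blomberg_k()` computes the ratio-of-ratios statistic

$$K = \frac{MSE_0 / MSE}{E[MSE_0/MSE]},\qquad
E\!\left[\frac{MSE_0}{MSE}\right] = \frac{\mathrm{tr}(V) - n/(\mathbf{1}^\top V^{-1}\mathbf{1})}{n-1},$$

where $MSE_0$ is the error about the GLS (phylogenetically corrected) mean
under identity covariance and $MSE$ the error under the tree covariance
$V$.  $K = 1$ matches the Brownian expectation on the given tree.  One
subtlety: the *reported* `MSE_star` column of a signal table is the
star-model MSE (ordinary variance about the ordinary mean), which is
invariant to the branch-length scheme — that is why published tables print
a single star value per trait.  $MSE_0$, the ingredient of $K$, depends on
the scheme through the GLS mean and is returned separately.

The randomization test (`signal_permutation_test()`) permutes trait values
across tips.  The default test statistic is $MSE$ (smaller = more signal),
with $K$ offered as an option; the p-value uses the include-the-observed
convention $P = (1 + \#\{MSE_{perm} \le MSE_{obs}\})/(n_{perm}+1)$, so
$P \ge 1/(n_{perm}+1)$ and a seed is mandatory.  The default
$n_{perm} = 999$ resolves the 0.001–0.05 range at which such tables are
printed.  Likelihoods of the tree versus star single-mean models are ML
with the variance profiled out, natural logs.

## The regression continuum

Three residual models are fitted to the same design (`fit_ols()`,
`fit_pgls()`, `fit_regou()`):

* **OLS** — independent residuals (star phylogeny).
* **PGLS** — residual covariance $\sigma^2 V$ with $V$ from the tree;
  estimates equal a through-origin regression on independent contrasts
  (tested to $10^{-8}$).
* **RegOU** — PGLS on an Ornstein–Uhlenbeck transform $V(d)$, with
  relative depths $\tilde t = V/T$:
  $$V'(d) = T\,\frac{d^{\,2(1-\tilde t)} - d^2}{1 - d^2},$$
  evaluated analytically at the removable singularity $d = 1$ (where
  $V' = V$) and at $d = 0$ (the star limit; for an ultrametric tree
  $V'(0) = T I$).  $d$ measures residual phylogenetic signal: $d \to 0$
  means none, $d = 1$ Brownian, $d > 1$ stronger than Brownian.

**Estimating d.** $\hat d$ maximizes the REML criterion (the convention
under which published $d$ values are reported) over $[0, d_{\max}]$
(default 5) by a 0.01-resolution grid scan followed by golden-section
refinement; a monotone-decreasing criterion reports the boundary as exact
0.  Reported likelihoods are always ML so AIC is comparable across the
three models; note that at a REML-chosen $\hat d$ the ML likelihood can
sit a hair below the PGLS one, whereas `criterion = "ML"` guarantees the
nesting $lnL_{RegOU} \ge \max(lnL_{PGLS}, lnL_{OLS})$.  Near the star
boundary the transform has an extremely steep gradient for very shallow
splits (the off-diagonal term $d^{2(1-\tilde t)}$ decays slowly when
$\tilde t \to 1$), so on trees with near-zero internal branches the
small-sample REML surface is noisy near 0; exactly *at* the boundary the
RegOU fit reproduces OLS exactly, with AIC larger by exactly 2 (one extra
parameter) — the pattern published comparison tables show when
$\hat d \approx 10^{-17}$.

**Information criteria.** $AIC = -2\,lnL + 2k$ and
$AICc = AIC + 2k(k+1)/(n-k-1)$, with $k$ = regression coefficients
(intercept included) + 1 residual variance + 1 for $d$ (RegOU only).
This convention reproduces every printed AIC/AICc pair of the study's
comparison tables from their printed $lnL$ (the acceptance suite's first
criterion).  Models within 2 AIC units of the best are flagged as having
substantial support; exact AIC ties go to the model with fewer
parameters.  Per-coefficient partial-F tests use
$F = (RSS_{reduced} - RSS_{full})/(RSS_{full}/(n-p))$ on $(1, n-p)$ df
under the model's own covariance.

## Ancestral reconstruction

`squared_change_parsimony()` minimizes
$\sum_{\text{branches}} (\Delta x)^2 / w$ ($w$ = branch length if
weighted, else 1).  The stationarity conditions are linear, so the
solution is one exact linear solve, not an iterative smoothing; the
weighted root equals the GLS phylogenetic mean (verified numerically
against `blomberg_k()`'s $\hat a$), and every internal value lies within
the tip range.  For the question "how often did single-egg clutches
originate", clutch size is discretized (threshold 1 egg, a parameter) and
`count_state_origins()` computes the exact minimum number of 0/1 changes
by unit-cost dynamic programming (correct for polytomies too, validated
against exhaustive enumeration).  Continuous reconstructions on a
topology with arbitrary branch lengths are ambiguous when evolutionary
rates are high; the package reports them without error bars on purpose —
they are descriptive, not inferential.

## Climate reduction and station matching

`summarize_climate()` turns a station's daily series into the eight
standard locality variables (annual: AP, AMT, AMinT, AMaxT; gravid-month:
MT, MMinT, MMaxT, MP), with gravid months supplied per species, never
inferred.  `reduce_climate()` performs PCA on the correlation matrix (the
variables mix mm and °C), unrotated — loadings on the correlation scale,
component signs fixed so the dominant variable loads positively, scores
standardized, and components retained by the eigenvalue > 1 rule.  The
published loading table is consistent with exactly this choice; rotation
is deliberately not applied since none is reported.

`match_station()` encodes the empirical equivalence "100 m altitude ≈
100 km latitude" as an additive cost
$111.32\,|\Delta lat| + (tradeoff/100)\,|\Delta alt|$ with ties going to
the latitude-closer station; the additive form is a documented choice (the
source describes only the equivalence, not the functional form).
`calibrate_tradeoff()` re-derives the tradeoff for another region by
regressing first-component scores on latitude (km) and altitude (m):
$tradeoff = 100\,|\beta_{alt}/\beta_{lat}|$.

## The synthetic world

Because the study's museum measurements and station records are not
redistributable, `simulate_*()` generators provide data with the
*assumed* statistical structure:

* `simulate_tree()` — coalescent-style Yule: with $k$ lineages the next
  join waits $\mathrm{Exp}(k\lambda)$, so $E[\text{height}] =
  \sum_{k=2}^{n} 1/(k\lambda)$ (tested against this moment).
* `simulate_trait()` — multivariate normal with covariance
  $\sigma^2 V(d)$.
* `simulate_study()` — the study's causal chain: standardized climate
  scores, $SVL = 90 + 9.8\,CC2 + BM(400)$ and
  $clutch = 0.5 + 0.065\,SVL + BM(2.25)$ on a unit-height tree.  The two
  slopes are the magnitudes the study design targets; the intercepts and
  Brownian rates were chosen once so that simulated spans resemble the
  published ones (SVL roughly 45–150 mm, clutch roughly 1–16 eggs) and
  are not tuned thereafter.
* `simulate_climate_matrix()` — one temperature factor driving six
  temperature variables, one precipitation factor driving two, 10%
  relative noise: the two-block structure that makes "retain eigenvalue
  > 1" recover exactly two components.
* `fixture_tropidurinae()` — a deterministic 21-species stand-in with
  genus-level topology and trait values that are *synthetic* except for
  four published anchors (clutch 1–16 with *U. superciliosus* at 16, SVL
  44.7–151.0 with *E. nanuzae* and *P. plica* at the extremes).

What a green test does **not** establish: the generators draw climate
scores independently per species (no spatial autocorrelation, no
phylogenetic structure in climate), use exact Brownian/OU residuals, and
anchor only four real values — so passing tests certify the estimators
and their contracts, not the study's empirical conclusions.  The real
supplementary trait table and the published figure's exact topology would
be needed to reproduce the study's K, slopes and P-values, and the
package deliberately reports that gap instead of papering over it.

Every stochastic function requires an explicit seed, scopes its RNG use
(the caller's `.Random.seed` is restored), and identical seeds produce
byte-identical serialized output; pipeline logs carry no wall-clock
stamps for the same reason.

## Numerical choices and limitations

* Covariance solves use Cholesky factorization and fail loudly on
  non-positive-definite input; the OU transform near $d = 0$ on a
  non-ultrametric tree approaches a singular matrix and is reported as an
  error rather than silently regularized.
* The permutation count, permutation statistic (MSE vs K), Grafen
  $\rho$, OU search bound $d_{\max}$, diagnostic $\alpha$, and clutch
  discretization threshold are all exposed parameters with the defaults
  given above.
* AIC identities against printed tables are checked to 0.015 — the
  propagation of the tables' own 2-decimal rounding of $lnL$ — never
  tighter than the inputs allow.
* The package does not estimate topologies, divergence times, Pagel's
  $\lambda/\delta/\kappa$, mixed or measurement-error models.
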