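# tropilife

Phylogenetic comparative analysis of lizard life history and climate.

## What it is for

Comparative biologists asking how a life-history trait — here, clutch
size and female body size (snout–vent length, SVL) across a tropical
lizard radiation — relates to other traits and to climate cannot treat
species as independent data points: shared ancestry makes relatives
resemble each other.  When divergence times are also unavailable (only a
published topology exists), the standard workflow is:

1. assign **arbitrary branch lengths** (constant, Grafen, Pagel, Nee) and
   screen them with the independent-contrast diagnostic
   (|contrast| uncorrelated with its SD);
2. quantify **phylogenetic signal** with Blomberg's
   K = (MSE₀/MSE) / E[MSE₀/MSE] and its randomization test;
3. fit the **regression continuum** — OLS (star phylogeny), PGLS
   (Brownian residuals, `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y`), and RegOU (PGLS on an
   Ornstein–Uhlenbeck transform `V(d)` with `d` estimated by REML, `d→0`
   star, `d=1` Brownian) — and select by AIC = −2 lnL + 2k and
   AICc = AIC + 2k(k+1)/(n−k−1), with partial-F tests per coefficient;
4. reduce collinear **climate variables** by PCA on the correlation
   matrix (retain eigenvalue > 1), after matching each locality to a
   weather station under the "100 m altitude ≈ 100 km latitude" cost;
5. reconstruct **ancestral states** by squared-change parsimony
   (continuous traits, exact linear solve) and Fitch counts of minimal
   binary-state changes (e.g. origins of single-egg clutches).

`tropilife` implements all five stages as tested, seedable functions plus
a pipeline/CLI, and ships generators (`simulate_tree`, `simulate_trait`,
`simulate_study`, `simulate_climate_matrix`, `fixture_tropidurinae`) that
reproduce the statistical structure the analysis assumes, so everything
is testable without museum specimens or weather-station archives.

## Worked example

```r
library(tropilife)

fx <- fixture_tropidurinae()              # 21-species synthetic stand-in
tree <- assign_branch_lengths(fx$tree, "pagel")
svl <- trait_vector(fx$traits, "SVL")

diagnose_branch_lengths(independent_contrasts(tree, svl))
#> contrast diagnostic: r(|contrast|, sd) = -0.3753, p = 0.1030 -> PASS (alpha = 0.05, n = 20)

V <- phylo_covariance(tree)
signal_permutation_test(svl, V, n_perm = 999, seed = 1)
#> phylogenetic signal: K = 0.8101, P = 0.1280 (999 perms, stat = MSE)
#>   MSE tree = 101.3827, MSE star = 634.8276; lnL tree = -97.2278, lnL star = -97.0456

X <- as.matrix(fx$traits[, c("CC1", "CC2")]); rownames(X) <- fx$traits$species
fit_pgls(svl, X, V)
#> PGLS fit (scheme: pagel), n = 21, k = 4
#>             estimate     se        F Pr(>F)
#> (Intercept)  84.4942 4.8932 298.1691 0.0000
#> CC1           2.6867 4.6093   0.3398 0.5672
#> CC2          21.7264 4.8214  20.3062 0.0003
#> lnL = -77.3153, AIC = 162.631, AICc = 165.131
```

Reading this: on the synthetic fixture the Pagel scheme passes the
contrast diagnostic (p ≥ 0.05); SVL shows K < 1 (less resemblance among
relatives than Brownian motion predicts, not significant at P = 0.128);
and the PGLS fit finds a strong positive effect of the precipitation-like
component CC2 on body size (slope 21.7 mm per score unit,
F₁,₁₈ = 20.3, p < 0.001) but none of the temperature component CC1.
Model selection across the continuum:

```r
compare_models(list(fit_ols(svl, X), fit_pgls(svl, X, V), fit_regou(svl, X, V)))
#>   model scheme k       lnL      AIC      dAIC  best substantial
#> 1  PGLS  pagel 4 -77.31532 162.6306 0.0000000  TRUE        TRUE
#> 2 RegOU  pagel 5 -76.76257 163.5251 0.8944828 FALSE        TRUE
#> 3   OLS   none 4 -78.50457 165.0091 2.3784948 FALSE       FALSE

count_state_origins(resolve_polytomies(tree),
                    discretize_clutch(trait_vector(fx$traits, "clutch")))
#> [1] 7
```

PGLS wins on AIC; RegOU is within 2 units (substantial support); OLS is
not.  On this fixture, single-egg clutches require 7 independent state
changes under Fitch parsimony.

The full pipeline (diagnostics → signal → regressions → comparison →
reconstruction, with TSV tables and a log) runs as:

```r
res <- run_pipeline(pipeline_config(fx$tree, fx$traits, n_perm = 999,
                                    seed = 42, out_dir = "out"))
```

or from the shell via the installed CLI script:

```sh
Rscript inst/cli/tropilife run-all --tree tree.nwk --traits traits.csv --seed 42 --out out/
```

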