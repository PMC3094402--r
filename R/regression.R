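#' Regression continuum: OLS, PGLS and RegOU
#'
#' Three nested residual models for interspecific regression.  OLS assumes a
#' star phylogeny (independent residuals); PGLS assumes residuals covary in
#' proportion to shared branch length (Brownian motion on the given tree);
#' RegOU fits PGLS on an Ornstein-Uhlenbeck transform of the tree covariance
#' and estimates the transform parameter `d` from the data, so the residual
#' structure can sit anywhere between the star (`d -> 0`) and the specified
#' hierarchy (`d = 1`), or beyond it (`d > 1`).
#'
#' All likelihoods are maximum-likelihood values (residual variance profiled
#' out, natural log), so AIC values are comparable across the three models.
#' The parameter count is `k =` number of regression coefficients (intercept
#' included) `+ 1` for the residual variance `+ 1` for `d` (RegOU only).
#'
#' @param y named numeric response vector (names = species).
#' @param X predictor matrix or data frame, rows named by species (an
#'   intercept column is added internally; do not include one).
#' @param V a `"phylo_vcv"` (or a tree with branch lengths) for PGLS.
#' @return a `"phylo_fit"` object.  Fields include
#'   `coefficients`, per-coefficient partial-F statistics `F` with p-values
#'   `F_p` on `(1, n - p)` df, `lnL`, `k`, `n`, `AIC`, `AICc`, `sigma2`
#'   (ML), `se` (coefficient standard errors) and, for RegOU, `d`.
#' @examples
#' set.seed(1)
#' X <- cbind(x = rnorm(10)); rownames(X) <- paste0("s", 1:10)
#' y <- setNames(3 + 2 * X[, 1] + rnorm(10, sd = 0.1), rownames(X))
#' fit_ols(y, X)
#' @name regression
NULL

.design_matrix <- function(X, species) {
  if (is.null(X)) {
    M <- matrix(numeric(0), nrow = length(species), ncol = 0)
    rownames(M) <- species
  } else {
    M <- as.matrix(X)
    if (is.null(rownames(M))) {
      if (nrow(M) != length(species))
        stop("X has no rownames and its row count differs from the response")
      rownames(M) <- species
    }
    if (is.null(colnames(M)))
      colnames(M) <- paste0("x", seq_len(ncol(M)))
  }
  missing_sp <- setdiff(species, rownames(M))
  if (length(missing_sp))
    stop("predictor rows missing for species: ", paste(missing_sp, collapse = ", "))
  M <- M[species, , drop = FALSE]
  cbind(`(Intercept)` = 1, M)
}

# Single GLS engine behind all three models.  V = NULL -> identity (OLS).
.fit_gls <- function(y, X, V = NULL, model_kind = "OLS", scheme_label = NA_character_,
                     d = NULL, extra_k = 0L) {
  if (is.null(names(y))) stop("response vector must be named by species")
  species <- names(y)
  Xd <- .design_matrix(X, species)
  n <- length(y); p <- ncol(Xd)
  if (n <= p + 1L) stop("too few species (n = ", n, ") for ", p, " coefficients")

  if (is.null(V)) {
    wy <- y; wX <- Xd; logdet <- 0
  } else {
    V <- .as_vcv(V)
    unmatched <- setdiff(species, attr(V, "tip_order"))
    if (length(unmatched))
      stop("species absent from the covariance matrix: ",
           paste(unmatched, collapse = ", "))
    Vs <- unclass(V)[species, species, drop = FALSE]
    ops <- .vcv_ops(Vs)
    wy <- ops$white(y); wX <- ops$white(Xd)
    logdet <- ops$logdet
  }

  qr_wX <- qr(wX)
  if (qr_wX$rank < p) {
    bad <- colnames(Xd)[qr_wX$pivot[(qr_wX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_wX, wy)
  res_w <- wy - wX %*% beta
  rss <- sum(res_w^2)
  sigma2_ml <- rss / n
  lnL <- -(n / 2) * log(2 * pi * sigma2_ml) - logdet / 2 - n / 2
  # REML criterion of the same fit (used to pick d in RegOU)
  XtX <- crossprod(wX)
  sigma2_reml <- rss / (n - p)
  lnL_reml <- -((n - p) / 2) * log(2 * pi * sigma2_reml) - logdet / 2 -
    determinant(XtX, logarithm = TRUE)$modulus[1] / 2 - (n - p) / 2

  k <- p + 1L + extra_k
  ic <- information_criteria(lnL, k, n)
  # per-coefficient partial F against the same covariance
  Fs <- ps <- setNames(numeric(p), colnames(Xd))
  for (j in seq_len(p)) {
    rss_red <- if (p == 1L) sum(wy^2) else {
      b <- qr.coef(qr_red <- qr(wX[, -j, drop = FALSE]), wy)
      sum((wy - wX[, -j, drop = FALSE] %*% b)^2)
    }
    Fs[j] <- (rss_red - rss) / (rss / (n - p))
    ps[j] <- pf(Fs[j], 1, n - p, lower.tail = FALSE)
  }
  vcov_beta <- sigma2_reml * chol2inv(qr.R(qr_wX))
  dimnames(vcov_beta) <- list(colnames(Xd), colnames(Xd))

  structure(list(
    model_kind = model_kind, scheme = scheme_label,
    coefficients = setNames(as.numeric(beta), colnames(Xd)),
    F = Fs, F_p = ps, df2 = n - p,
    lnL = lnL, lnL_reml = lnL_reml, k = k, n = n,
    AIC = ic$AIC, AICc = ic$AICc,
    sigma2 = sigma2_ml, se = sqrt(diag(vcov_beta)), vcov = vcov_beta,
    d = if (is.null(d)) NA_real_ else d,
    response = unname(y), species = species,
    .wy = as.numeric(wy), .wX = wX
  ), class = "phylo_fit")
}

#' @rdname regression
#' @export
fit_ols <- function(y, X) {
  .fit_gls(y, X, V = NULL, model_kind = "OLS", scheme_label = "none")
}

#' @rdname regression
#' @export
fit_pgls <- function(y, X, V) {
  V <- .as_vcv(V)
  sch <- attr(V, "scheme")
  .fit_gls(y, X, V = V, model_kind = "PGLS",
           scheme_label = if (is.null(sch)) NA_character_ else sch$kind)
}

#' @rdname regression
#' @param tree a `"phylo"` used to build the covariance for RegOU; branch
#'   lengths are assigned with `scheme` if not already present.
#' @param scheme branch-length scheme for RegOU (a name or [branch_scheme()]).
#' @param d_max upper bound of the `d` search (default 5).
#' @param grid_step resolution of the initial grid scan over `d` (default
#'   0.01); the optimum is then refined by golden-section search.
#' @param criterion criterion maximized over `d`: `"REML"` (default, the
#'   convention for reporting `d`) or `"ML"`.  Reported `lnL`/`AIC` are
#'   always ML so models remain cross-comparable; note that at a
#'   REML-estimated `d` the ML likelihood can fall slightly below the PGLS
#'   one, whereas `criterion = "ML"` guarantees the nesting
#'   `lnL(RegOU) >= lnL(PGLS)`.
#' @param d_fixed fix `d` at this value instead of estimating it (e.g.
#'   `d_fixed = 1` reproduces the PGLS fit with one extra counted
#'   parameter).
#' @export
fit_regou <- function(y, X, tree, scheme = "constant", d_max = 5,
                      grid_step = 0.01, criterion = c("REML", "ML"),
                      d_fixed = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(tree, "phylo_vcv")) {
    V <- tree
  } else {
    if (!has_branch_lengths(tree)) tree <- assign_branch_lengths(tree, scheme)
    V <- phylo_covariance(tree)
  }
  sch <- attr(V, "scheme")
  sch_label <- if (is.null(sch)) {
    if (is.character(scheme)) scheme else scheme$kind
  } else sch$kind

  if (!is.null(d_fixed)) {
    fit <- .fit_gls(y, X, ou_transform(V, d_fixed), "RegOU", sch_label,
                    d = d_fixed, extra_k = 1L)
    fit$d_criterion <- "fixed"
    return(fit)
  }

  crit_at <- function(d) {
    f <- tryCatch(.fit_gls(y, X, ou_transform(V, d), "RegOU", sch_label,
                           d = d, extra_k = 1L),
                  error = function(e) NULL)
    if (is.null(f)) return(-Inf)
    if (criterion == "REML") f$lnL_reml else f$lnL
  }

  grid <- seq(0, d_max, by = grid_step)
  vals <- vapply(grid, crit_at, numeric(1))
  if (all(!is.finite(vals)))
    stop("RegOU criterion is non-finite over the whole d grid [0, ", d_max, "]")
  i_best <- which.max(vals)
  if (i_best == 1L) {
    # boundary: monotone decreasing criterion -> report exact d = 0
    d_hat <- 0
  } else if (i_best == length(grid)) {
    d_hat <- grid[i_best]
    warning("RegOU d estimate at the upper search bound d_max = ", d_max)
  } else {
    lo <- grid[i_best - 1L]; hi <- grid[i_best + 1L]
    opt <- optimize(crit_at, c(lo, hi), maximum = TRUE, tol = 1e-8)
    d_hat <- if (opt$objective >= vals[i_best]) opt$maximum else grid[i_best]
  }
  fit <- .fit_gls(y, X, ou_transform(V, d_hat), "RegOU", sch_label,
                  d = d_hat, extra_k = 1L)
  fit$d_criterion <- criterion
  fit
}

#' Akaike information criteria
#'
#' `AIC = -2 lnL + 2k`; the small-sample correction is
#' `AICc = AIC + 2k(k+1)/(n-k-1)`, defined only when `n > k + 1`.
#'
#' @param lnL natural-log maximum likelihood.
#' @param k number of estimated parameters (regression coefficients
#'   including the intercept, plus one for the residual variance, plus one
#'   for `d` in RegOU).
#' @param n sample size (number of species).
#' @return list with `AIC` and `AICc` (`AICc` is `NA` with a warning when
#'   `n <= k + 1`).
#' @export
information_criteria <- function(lnL, k, n) {
  aic <- -2 * lnL + 2 * k
  if (n > k + 1) {
    aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  } else {
    warning("AICc undefined: n = ", n, " <= k + 1 = ", k + 1)
    aicc <- NA_real_
  }
  list(AIC = aic, AICc = aicc)
}

#' Partial-F test for one coefficient
#'
#' Compares the fit with and without the named coefficient under the same
#' residual covariance: `F = (RSS_reduced - RSS_full) / (RSS_full / (n - p))`
#' on `(1, n - p)` degrees of freedom.
#'
#' @param fit a `"phylo_fit"`.
#' @param coefficient name (or index) of the coefficient to test.
#' @return list with `F`, `p`, `df1 = 1`, `df2 = n - p`.
#' @export
partial_f_test <- function(fit, coefficient) {
  if (!inherits(fit, "phylo_fit")) stop("expected a phylo_fit")
  nm <- names(fit$coefficients)
  j <- if (is.numeric(coefficient)) as.integer(coefficient) else match(coefficient, nm)
  if (is.na(j) || j < 1L || j > length(nm))
    stop("coefficient not present in fit: ", coefficient)
  list(F = unname(fit$F[j]), p = unname(fit$F_p[j]), df1 = 1L, df2 = fit$df2)
}

#' Compare fitted models by AIC
#'
#' Orders fits by AIC, flags the best (lowest AIC; ties broken toward fewer
#' parameters) and all models within 2 AIC units of the best as having
#' substantial support.  The AICc ordering is reported alongside.
#'
#' @param fits list of `"phylo_fit"` objects on the same response.
#' @return a `"model_comparison"` data frame, one row per fit, ordered by
#'   AIC, with columns `model`, `scheme`, `k`, `lnL`, `AIC`, `dAIC`, `AICc`,
#'   `dAICc`, `best`, `substantial`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "phylo_fit")) fits <- list(fits)
  if (!length(fits)) stop("no fits to compare")
  if (!all(vapply(fits, inherits, TRUE, "phylo_fit")))
    stop("all elements must be phylo_fit objects")
  ns <- vapply(fits, `[[`, 0, "n")
  if (length(unique(ns)) != 1L)
    stop("fits are not comparable: differing sample sizes ",
         paste(unique(ns), collapse = ", "))
  ys <- lapply(fits, function(f) sort(round(f$response, 10)))
  if (length(unique(ys)) != 1L)
    stop("fits are not comparable: responses differ")

  tab <- data.frame(
    model = vapply(fits, `[[`, "", "model_kind"),
    scheme = vapply(fits, `[[`, "", "scheme"),
    k = vapply(fits, `[[`, 0L, "k"),
    lnL = vapply(fits, `[[`, 0, "lnL"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    AICc = vapply(fits, `[[`, 0, "AICc")
  )
  ord <- order(tab$AIC, tab$k)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$dAIC <- tab$AIC - tab$AIC[1L]
  tab$dAICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab$best <- seq_len(nrow(tab)) == 1L
  tab$substantial <- tab$dAIC <= 2
  structure(tab, fits = fits[ord], class = c("model_comparison", "data.frame"))
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("%s fit (scheme: %s), n = %d, k = %d\n",
              x$model_kind, x$scheme, x$n, x$k))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    F = x$F, `Pr(>F)` = x$F_p, check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("lnL = %.4f, AIC = %.3f, AICc = %.3f", x$lnL, x$AIC, x$AICc))
  if (!is.na(x$d)) cat(sprintf(", d = %.4g", x$d))
  cat("\n")
  invisible(x)
}

#' @export
coef.phylo_fit <- function(object, ...) object$coefficients

#' @export
logLik.phylo_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.phylo_fit <- function(object, ...) object$vcov
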