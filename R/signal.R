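#' Blomberg's K statistic for phylogenetic signal
#'
#' Computes the ratio-of-ratios statistic: the observed `MSE0/MSE` (mean
#' squared error about the phylogenetically corrected mean under a star
#' versus under the tree covariance) scaled by its Brownian-motion
#' expectation.  `K = 1` matches the Brownian expectation on the given tree;
#' `K > 1` indicates more resemblance among relatives than Brownian motion
#' predicts, `K < 1` less.
#'
#' @param trait named numeric vector over the tips of `V`.
#' @param V a `"phylo_vcv"` (or tree with branch lengths).
#' @return list with `MSE0` (mean squared error about the GLS mean under
#'   identity covariance, the numerator ingredient of K), `MSE_star` (the
#'   star-model MSE, i.e. the ordinary variance about the ordinary mean --
#'   invariant to the branch-length scheme, which is how signal tables
#'   print one star value per trait), `MSE_tree` (`MSE`), `K`,
#'   `expected_ratio` and the GLS mean `a_hat`.
#' @references Blomberg, Garland & Ives (2003) *Evolution* 57:717-745.
#' @export
blomberg_k <- function(trait, V) {
  V <- .as_vcv(V)
  n <- nrow(V)
  if (n < 4L) stop("Blomberg's K needs at least 4 tips, got ", n)
  x <- .match_trait(trait, attr(V, "tip_order"))
  if (sd(x) == 0) stop("trait is constant across tips: K undefined")
  ops <- .vcv_ops(V)
  one <- rep(1, n)
  w1 <- ops$white(one)
  wx <- ops$white(x)
  s11 <- sum(w1 * w1)            # 1' V^-1 1
  a_hat <- sum(w1 * wx) / s11    # GLS mean
  mse0 <- sum((x - a_hat)^2) / (n - 1)
  wres <- wx - a_hat * w1
  mse <- sum(wres * wres) / (n - 1)
  expected <- (sum(diag(V)) - n / s11) / (n - 1)
  list(MSE0 = mse0, MSE_star = var(x), MSE_tree = mse,
       K = (mse0 / mse) / expected, expected_ratio = expected, a_hat = a_hat)
}

#' Tree versus star likelihoods of a single trait
#'
#' Maximum-likelihood fit of the mean-plus-scaled-covariance model, with the
#' variance profiled out: `lnL = -(n/2) log(2 pi s2) - log|V|/2 - n/2` where
#' `s2 = (x - a 1)' V^-1 (x - a 1) / n`.  The star model uses the identity
#' covariance (ordinary mean and variance).
#'
#' @inheritParams blomberg_k
#' @return list with `lnL_tree` and `lnL_star`.
#' @export
star_vs_tree_likelihood <- function(trait, V) {
  V <- .as_vcv(V)
  x <- .match_trait(trait, attr(V, "tip_order"))
  list(lnL_tree = .gls_mean_lnl(x, V),
       lnL_star = .gls_mean_lnl(x, NULL))
}

# lnL of x ~ N(a 1, s2 V) with a, s2 at their ML values; V = NULL -> identity
.gls_mean_lnl <- function(x, V) {
  n <- length(x)
  if (is.null(V)) {
    a <- mean(x)
    s2 <- sum((x - a)^2) / n
    logdet <- 0
  } else {
    ops <- .vcv_ops(V)
    w1 <- ops$white(rep(1, n)); wx <- ops$white(x)
    a <- sum(w1 * wx) / sum(w1 * w1)
    r <- wx - a * w1
    s2 <- sum(r * r) / n
    logdet <- ops$logdet
  }
  -(n / 2) * log(2 * pi * s2) - logdet / 2 - n / 2
}

#' Randomization test for phylogenetic signal
#'
#' Permutes trait values across the tips of the tree.  Signal makes the
#' observed tree-based mean squared error smaller than that of most
#' permutations, so the p-value is the fraction of permutations (observed
#' configuration included) whose `MSE` is at most the observed one.
#' `statistic = "K"` counts permutations with `K` at least the observed
#' instead; both orderings agree on a fixed tree up to Monte-Carlo error.
#'
#' @inheritParams blomberg_k
#' @param n_perm number of permutations (default 999, minimum 99).
#' @param seed integer seed; mandatory so reports are reproducible.
#' @param statistic permutation statistic: `"MSE"` (default) or `"K"`.
#' @return a `"signal_report"` list mirroring one row of a signal table:
#'   `MSE_tree`, `MSE_star`, `K`, `P`, `lnL_tree`, `lnL_star`, `n_perm`,
#'   `seed`, `statistic`.
#' @export
signal_permutation_test <- function(trait, V, n_perm = 999L, seed,
                                    statistic = c("MSE", "K")) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop("a seed is required for the permutation test")
  if (n_perm < 99L) stop("n_perm must be at least 99")
  V <- .as_vcv(V)
  n <- nrow(V)
  x <- .match_trait(trait, attr(V, "tip_order"))
  obs <- blomberg_k(x, V)
  lik <- star_vs_tree_likelihood(x, V)

  # permutation only reshuffles x; whiten once, stats are O(n^2) per draw
  ops <- .vcv_ops(V)
  one <- rep(1, n)
  w1 <- ops$white(one)
  s11 <- sum(w1 * w1)
  trV <- sum(diag(V))
  expected <- (trV - n / s11) / (n - 1)
  perm_stat <- function(xp) {
    wx <- ops$white(xp)
    a <- sum(w1 * wx) / s11
    r <- wx - a * w1
    mse <- sum(r * r) / (n - 1)
    if (statistic == "MSE") mse
    else (sum((xp - a)^2) / (n - 1) / mse) / expected
  }
  obs_stat <- if (statistic == "MSE") obs$MSE_tree else obs$K

  old <- .set_seed(seed)
  on.exit(.restore_seed(old), add = TRUE)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    s <- perm_stat(x[sample.int(n)])
    hit <- if (statistic == "MSE") s <= obs_stat else s >= obs_stat
    hits <- hits + hit
  }
  P <- (1 + hits) / (n_perm + 1)

  structure(list(MSE_tree = obs$MSE_tree, MSE_star = obs$MSE_star, K = obs$K,
                 P = P, lnL_tree = lik$lnL_tree, lnL_star = lik$lnL_star,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 statistic = statistic),
            class = "signal_report")
}

#' @export
print.signal_report <- function(x, ...) {
  cat(sprintf("phylogenetic signal: K = %.4f, P = %.4f (%d perms, stat = %s)\n",
              x$K, x$P, x$n_perm, x$statistic))
  cat(sprintf("  MSE tree = %.4f, MSE star = %.4f; lnL tree = %.4f, lnL star = %.4f\n",
              x$MSE_tree, x$MSE_star, x$lnL_tree, x$lnL_star))
  invisible(x)
}

#' Write signal reports as a TSV table
#'
#' One row per trait-by-branch-scheme combination with the columns
#' `trait, branches, MSEtree, MSEstar, K, P, lnL_tree, lnL_star`.
#'
#' @param reports named list of `"signal_report"` objects; names of the form
#'   `"trait|scheme"` or a `labels` data frame can be given.
#' @param path output file.
#' @param labels optional data frame with columns `trait` and `branches`,
#'   one row per report.
#' @return the table, invisibly.
#' @export
write_signal_table <- function(reports, path, labels = NULL) {
  if (inherits(reports, "signal_report")) reports <- list(reports)
  if (is.null(labels)) {
    nm <- names(reports)
    if (is.null(nm)) nm <- rep("", length(reports))
    parts <- strsplit(nm, "|", fixed = TRUE)
    labels <- data.frame(
      trait = vapply(parts, function(p) if (length(p)) p[[1L]] else NA_character_, ""),
      branches = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_, "")
    )
  }
  tab <- cbind(labels, do.call(rbind, lapply(reports, function(r)
    data.frame(MSEtree = r$MSE_tree, MSEstar = r$MSE_star, K = r$K, P = r$P,
               lnL_tree = r$lnL_tree, lnL_star = r$lnL_star))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# Seed handling: scoped so library calls don't disturb the caller's RNG state.
.set_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
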