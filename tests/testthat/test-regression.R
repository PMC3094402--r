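test_that("OLS recovers exact fits and matches the normal-equations oracle", {
  sp <- paste0("s", 1:10)
  set.seed(2)
  x <- setNames(rnorm(10), sp)
  y <- 3 + 2 * x
  f <- fit_ols(y, cbind(x = x))
  expect_equal(unname(f$coefficients), c(3, 2), tolerance = 1e-10)
  expect_lt(f$sigma2, 1e-20)

  X <- cbind(a = rnorm(10), b = rnorm(10))
  rownames(X) <- sp
  y2 <- setNames(rnorm(10), sp)
  f2 <- fit_ols(y2, X)
  Xd <- cbind(1, X)
  beta_ref <- solve(t(Xd) %*% Xd, t(Xd) %*% y2)
  expect_equal(unname(f2$coefficients), as.numeric(beta_ref), tolerance = 1e-10)
  # ML likelihood convention
  e <- y2 - Xd %*% beta_ref
  s2 <- sum(e^2) / 10
  expect_equal(f2$lnL, -5 * log(2 * pi * s2) - 5, tolerance = 1e-10)

  X3 <- cbind(a = X[, 1], b = X[, 1] * 2)
  rownames(X3) <- sp
  expect_error(fit_ols(y2, X3), "collinear")
})

test_that("PGLS equals OLS under identity covariance and the contrast oracle otherwise", {
  star <- parse_newick(paste0("(", paste0("s", 1:8, ":1", collapse = ","), ");"))
  V <- phylo_covariance(star)
  set.seed(3)
  sp <- attr(V, "tip_order")
  x <- setNames(rnorm(8), sp)
  y <- setNames(1 + x + rnorm(8), sp)
  fo <- fit_ols(y, cbind(x = x))
  fp <- fit_pgls(y, cbind(x = x), V)
  expect_equal(fp$coefficients, fo$coefficients, tolerance = 1e-10)
  expect_equal(fp$lnL, fo$lnL, tolerance = 1e-10)
  expect_equal(fp$F, fo$F, tolerance = 1e-8)

  tr <- random_tree(16, seed = 21)
  xb <- simulate_trait(tr, seed = 31)
  yb <- setNames(0.5 + 0.8 * xb + simulate_trait(tr, seed = 32), names(xb))
  fit <- fit_pgls(yb, cbind(x = xb), phylo_covariance(tr))
  cx <- independent_contrasts(tr, xb)$contrast
  cy <- independent_contrasts(tr, yb)$contrast
  expect_equal(unname(fit$coefficients["x"]), sum(cx * cy) / sum(cx^2),
               tolerance = 1e-8)

  bad <- setNames(yb, paste0("zz", seq_along(yb)))
  expect_error(fit_pgls(bad, cbind(x = xb), phylo_covariance(tr)), "zz1")
})

test_that("OU transform reproduces its formula and limits", {
  V <- phylo_covariance(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(unclass(ou_transform(V, 1)), unclass(V), tolerance = 1e-12,
               ignore_attr = TRUE)

  Vp <- ou_transform(V, 1e-12)
  off <- unclass(Vp); diag(off) <- 0
  expect_lt(max(abs(off)), 1e-6 * attr(V, "height"))

  d <- 0.5; T_h <- attr(V, "height")
  t_rel <- unclass(V) / T_h
  ref <- T_h * (d^(2 * (1 - t_rel)) - d^2) / (1 - d^2)
  expect_equal(unclass(ou_transform(V, d)), ref, tolerance = 1e-12,
               ignore_attr = TRUE)

  # continuity through d = 1
  expect_equal(unclass(ou_transform(V, 1 + 1e-7)), unclass(ou_transform(V, 1)),
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_error(ou_transform(V, -0.1), "d must be")
})

test_that("RegOU nests PGLS and OLS", {
  tr <- simulate_tree(15, seed = 8)
  x <- simulate_trait(tr, seed = 18)
  y <- setNames(2 + 0.5 * x + simulate_trait(tr, seed = 19), names(x))
  V <- phylo_covariance(tr)
  X <- cbind(x = x)

  fp <- fit_pgls(y, X, V)
  f1 <- fit_regou(y, X, V, d_fixed = 1)
  expect_equal(f1$lnL, fp$lnL, tolerance = 1e-10)
  expect_equal(f1$coefficients, fp$coefficients, tolerance = 1e-10)
  expect_equal(f1$k, fp$k + 1L)
  expect_equal(f1$AIC, fp$AIC + 2, tolerance = 1e-10)

  fml <- fit_regou(y, X, V, criterion = "ML")
  fo <- fit_ols(y, X)
  expect_gte(fml$lnL, fp$lnL - 1e-8)
  expect_gte(fml$lnL, fo$lnL - 1e-8)
})

test_that("information criteria reproduce printed-table identities", {
  # clutch model, PGLS constant branch lengths: lnL -29.29, k = 5, n = 20
  ic <- information_criteria(-29.29, 5, 20)
  expect_equal(ic$AIC, 68.58, tolerance = 1e-10)
  expect_equal(ic$AICc, 68.58 + 2 * 5 * 6 / 14, tolerance = 1e-10)
  # printed 72.86 came from the unrounded lnL; rounding noise <= 0.015
  expect_lt(abs(ic$AICc - 72.86), 0.015)

  # body-size model, OLS: lnL -81.56, k = 4, n = 20
  ic2 <- information_criteria(-81.56, 4, 20)
  expect_equal(ic2$AIC, 171.12, tolerance = 1e-10)
  expect_lt(abs(ic2$AICc - 173.79), 0.015)

  expect_equal(information_criteria(0, 0, 10)$AIC, 0)
  expect_warning(ic3 <- information_criteria(-5, 9, 10), "AICc undefined")
  expect_true(is.na(ic3$AICc))
})

test_that("partial F behaves as the algebra demands", {
  sp <- paste0("s", 1:20)
  set.seed(6)
  x <- setNames(rnorm(20), sp)
  y <- setNames(2 * x + rnorm(20, sd = 0.5), sp)
  f <- fit_ols(y, cbind(x = x))
  pf1 <- partial_f_test(f, "x")
  expect_equal(pf1$F, unname((f$coefficients["x"] / f$se["x"])^2),
               tolerance = 1e-8)
  expect_equal(pf1$df2, 18L)

  # predictor orthogonal to the response
  z <- setNames(rnorm(20), sp)
  z <- z - sum(z * y) / sum(y * y) * y
  z <- z - mean(z) + 1e-9  # orthogonalized against y and centered
  fz <- fit_ols(y, cbind(z = z))
  expect_gt(partial_f_test(fz, "z")$p, 0.5)
  expect_error(partial_f_test(fz, "nope"), "not present")
})

test_that("model comparison flags best and substantial support with ties", {
  sp <- paste0("s", 1:12)
  set.seed(10)
  x <- setNames(rnorm(12), sp)
  y <- setNames(x + rnorm(12), sp)
  tr <- simulate_tree(12, seed = 44)
  tr$tip.label <- sp  # align labels
  V <- phylo_covariance(tr)
  fits <- list(fit_ols(y, cbind(x = x)), fit_pgls(y, cbind(x = x), V),
               fit_regou(y, cbind(x = x), V))
  cmp <- compare_models(fits)
  expect_equal(sum(cmp$best), 1L)
  expect_true(cmp$substantial[1L])
  expect_true(all(diff(cmp$AIC) >= 0))
  expect_true(all(cmp$substantial == (cmp$dAIC <= 2)))

  # printed AIC pattern: {68.57, 70.24, 79.74} -> second substantial, third not
  daic <- c(68.57, 70.24, 79.74) - 68.57
  expect_equal(daic <= 2, c(TRUE, TRUE, FALSE))

  # identical AIC: fewer parameters wins the tie
  f1 <- fit_ols(y, cbind(x = x))
  f2 <- f1; f2$k <- f1$k + 1L  # same AIC forced below
  f2$AIC <- f1$AIC
  cmp2 <- compare_models(list(f2, f1))
  expect_equal(cmp2$k[1L], f1$k)
  expect_true(all(cmp2$substantial[1:2]))

  y2 <- y[1:10]
  expect_error(compare_models(list(f1, fit_ols(y2, cbind(x = x[1:10])))),
               "differing sample sizes")
})
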