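test_that("parse_newick reads minimal and topology-only trees, rejects bad input", {
  tr <- parse_newick("(A:1,B:1);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 1))

  topo <- parse_newick("((A,B),C);")
  expect_equal(length(topo$tip.label), 3L)
  expect_false(has_branch_lengths(topo))

  expect_error(parse_newick("((A,A),B);"), "duplicate tip label")
  expect_error(parse_newick("((A,B),C;"), "unclosed")
  expect_error(parse_newick("(A,B)),C;"), "unmatched")
  expect_error(parse_newick("   "), "empty")
})

test_that("newick round-trip preserves labels and lengths", {
  tr <- random_tree(12, seed = 5)
  tr2 <- parse_newick(write_phylogeny(tr))
  expect_setequal(tr2$tip.label, tr$tip.label)
  V1 <- unclass(phylo_covariance(tr))
  V2 <- unclass(phylo_covariance(tr2))[rownames(V1), colnames(V1)]
  expect_equal(V2, V1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("branch-length schemes match their defining rules", {
  topo <- parse_newick("((A,B),C);")

  const <- assign_branch_lengths(topo, "constant")
  expect_true(all(const$edge.length == 1))

  # grafen rho = 1: internal node height 0.5, root 1
  g <- assign_branch_lengths(topo, "grafen")
  depths <- tropilife:::.node_depths(g)
  expect_equal(unname(depths[match(c("A", "B", "C"), g$tip.label)]),
               c(1, 1, 1))
  expect_equal(sort(g$edge.length), c(0.5, 0.5, 0.5, 1))

  # pagel: all segments 1, C's terminal extended to 2
  p <- assign_branch_lengths(topo, "pagel")
  c_edge <- which(p$edge[, 2L] == match("C", p$tip.label))
  expect_equal(p$edge.length[c_edge], 2)
  expect_true(ape::is.ultrametric(p))

  # nee: root height 1, ultrametric, heights proportional to log2(ndesc)
  nee <- assign_branch_lengths(topo, "nee")
  expect_true(ape::is.ultrametric(nee))
  nd <- tropilife:::.node_depths(nee)
  expect_equal(max(nd), 1)
  # internal (A,B) node sits at 1 - log2(2)/log2(3) from the root
  expect_equal(unname(nd[5L]), 1 - log2(2) / log2(3), tolerance = 1e-12)

  expect_error(assign_branch_lengths(topo, "as_given"), "as_given")
})

test_that("grafen scheme agrees with the ape reference for arbitrary rho", {
  for (seed in 1:3) {
    tr <- random_tree(15, seed = seed)
    tr$edge.length <- NULL
    for (rho in c(0.5, 1, 2)) {
      mine <- assign_branch_lengths(tr, branch_scheme("grafen", rho = rho))
      ref <- ape::compute.brlen(tr, power = rho)
      expect_equal(mine$edge.length, ref$edge.length, tolerance = 1e-10)
    }
  }
})

test_that("phylo_covariance matches definitions and the path-walking oracle", {
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(unclass(phylo_covariance(star)), diag(1, 4),
               ignore_attr = TRUE)

  tr <- parse_newick("((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tr)
  expect_equal(unclass(V),
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
               ignore_attr = TRUE)
  expect_equal(attr(V, "height"), 2)

  # 21-taxon fixture under the constant scheme vs brute-force path walking
  fx <- fixture_tropidurinae()
  tr21 <- assign_branch_lengths(fx$tree, "constant")
  expect_equal(unclass(phylo_covariance(tr21)), oracle_vcv(tr21),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(phylo_covariance(fx$tree), "assign_branch_lengths")
})

test_that("covariance is permutation-consistent and scheme provenance is kept", {
  tr <- random_tree(10, seed = 11)
  V <- unclass(phylo_covariance(tr))
  perm <- sample(rownames(V))
  tr2 <- ape::rotateConstr(tr, perm)
  V2 <- unclass(phylo_covariance(tr2))
  expect_equal(V2[rownames(V), colnames(V)], V, tolerance = 1e-12,
               ignore_attr = TRUE)

  fx <- fixture_tropidurinae()
  for (s in c("grafen", "pagel", "nee")) {
    Vs <- phylo_covariance(assign_branch_lengths(fx$tree, s))
    expect_equal(attr(Vs, "scheme")$kind, s)
    # ultrametric schemes: equal diagonal
    expect_lt(diff(range(diag(Vs))), 1e-10)
  }
})

test_that("independent contrasts reproduce closed forms and ape::pic", {
  tr <- parse_newick("(A:1,B:1);")
  cs <- independent_contrasts(tr, c(A = 0, B = 2))
  expect_equal(abs(cs$contrast), 2 / sqrt(2), tolerance = 1e-10)

  tr3 <- parse_newick("((A:1,B:1):1,C:2);")
  cs3 <- independent_contrasts(tr3, c(A = 0, B = 2, C = 3))
  expect_equal(sort(abs(cs3$contrast)),
               sort(c(2 / sqrt(2), 2 / sqrt(3.5))), tolerance = 1e-5)

  # constant trait -> all contrasts zero
  cs0 <- independent_contrasts(tr3, c(A = 7, B = 7, C = 7))
  expect_true(all(cs0$contrast == 0))

  # cross-check magnitudes against ape::pic on random data
  for (seed in 1:3) {
    trn <- random_tree(14, seed = 100 + seed)
    x <- simulate_trait(trn, seed = seed)
    mine <- independent_contrasts(trn, x)
    ref <- ape::pic(x[trn$tip.label], trn)
    expect_equal(sort(abs(mine$contrast)), unname(sort(abs(ref))),
                 tolerance = 1e-8)
  }

  expect_error(independent_contrasts(tr3, c(A = 1, B = 2)), "C")
})

test_that("branch-length diagnostic passes under the null, fails under misscaling", {
  tr <- simulate_tree(20, seed = 42)
  n_rep <- 200
  pass_null <- pass_bad <- logical(n_rep)
  depths <- diag(unclass(phylo_covariance(tr)))
  for (r in seq_len(n_rep)) {
    x <- simulate_trait(tr, seed = r)
    pass_null[r] <- diagnose_branch_lengths(independent_contrasts(tr, x))$pass
    # heteroscedastic traits: per-tip noise with sd proportional to depth^2,
    # judged on constant branch lengths
    set.seed(10000 + r)
    xb <- setNames(rnorm(length(depths), sd = (3 * depths)^2), names(depths))
    trc <- assign_branch_lengths(tr, "constant")
    pass_bad[r] <- diagnose_branch_lengths(independent_contrasts(trc, xb))$pass
  }
  # null pass rate ~ 1 - alpha = 0.95; 99% binomial band for 200 reps
  expect_gt(mean(pass_null), 0.95 - 2.58 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(mean(pass_null), 1)
  # misscaled: fail rate well above alpha
  expect_gt(mean(!pass_bad), 0.25)

  cs2 <- independent_contrasts(parse_newick("((A:1,B:1):1,C:2);"),
                               c(A = 0, B = 2, C = 3))
  expect_error(diagnose_branch_lengths(cs2), "at least 3")
})

test_that("polytomies resolve deterministically with positive lengths", {
  poly <- parse_newick("(A:1,B:1,C:1,D:1);")
  r1 <- resolve_polytomies(poly)
  r2 <- resolve_polytomies(poly)
  expect_true(ape::is.binary.phylo(r1))
  expect_true(all(r1$edge.length > 0))
  expect_identical(write_phylogeny(r1), write_phylogeny(r2))
})
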