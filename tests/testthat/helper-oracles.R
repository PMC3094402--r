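# Independent oracles, deliberately naive: each re-derives a quantity from
# first principles by a different route than the package implementation.

# tip-by-tip covariance by explicit path walking from each tip to the root
oracle_vcv <- function(phy) {
  n <- length(phy$tip.label)
  parent <- integer(max(phy$edge))
  blen <- numeric(max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  blen[phy$edge[, 2L]] <- phy$edge.length
  root <- n + 1L
  path_nodes <- function(tip) {
    out <- integer(0)
    nd <- tip
    while (nd != root) {
      out <- c(out, nd)
      nd <- parent[nd]
    }
    out
  }
  paths <- lapply(seq_len(n), path_nodes)
  V <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(blen[shared])
    }
  }
  V
}

# Blomberg statistics straight from the defining matrix formulas
oracle_blomberg <- function(x, V) {
  V <- unclass(V)
  x <- x[rownames(V)]
  n <- length(x)
  Vi <- solve(V)
  one <- rep(1, n)
  a <- as.numeric((t(one) %*% Vi %*% x) / (t(one) %*% Vi %*% one))
  e <- x - a
  mse0 <- sum(e^2) / (n - 1)
  mse <- as.numeric(t(e) %*% Vi %*% e) / (n - 1)
  expected <- (sum(diag(V)) - n / as.numeric(t(one) %*% Vi %*% one)) / (n - 1)
  list(MSE0 = mse0, MSE_star = var(x), MSE_tree = mse,
       K = (mse0 / mse) / expected)
}

# exhaustive minimal binary-state changes over all internal assignments
oracle_fitch <- function(phy, states) {
  n_tip <- length(phy$tip.label)
  n_int <- phy$Nnode
  s_tip <- states[phy$tip.label]
  best <- Inf
  for (mask in 0:(2^n_int - 1L)) {
    s_int <- as.integer(intToBits(mask))[seq_len(n_int)]
    s_all <- c(s_tip, s_int)
    changes <- sum(s_all[phy$edge[, 1L]] != s_all[phy$edge[, 2L]])
    best <- min(best, changes)
  }
  best
}

# squared-change objective minimized by a generic numerical optimizer
oracle_scp <- function(phy, x, weighted = TRUE) {
  n_tip <- length(phy$tip.label)
  w <- if (weighted) phy$edge.length else rep(1, nrow(phy$edge))
  obj <- function(s_int) {
    vals <- c(x[phy$tip.label], s_int)
    sum((vals[phy$edge[, 1L]] - vals[phy$edge[, 2L]])^2 / w)
  }
  opt <- optim(rep(mean(x), phy$Nnode), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  list(states = opt$par, total = opt$value)
}

# all permutations of 1:n as a list (n small)
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# balanced tree on 2^k tips, unit branch lengths
balanced_tree <- function(k) {
  nwk <- paste0("t", 1)
  labels <- function(lo, hi) {
    if (lo == hi) return(paste0("t", lo, ":1"))
    mid <- (lo + hi) %/% 2
    paste0("(", labels(lo, mid), ",", labels(mid + 1, hi), "):1")
  }
  s <- labels(1, 2^k)
  parse_newick(paste0(sub(":1$", "", s), ";"))
}

# random binary tree + random positive branch lengths, labels s1..sn
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("s", seq_len(n))
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 2)
  tr
}
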