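#' Felsenstein's phylogenetically independent contrasts
#'
#' Standard pruning algorithm: at each internal node of a binary tree the
#' contrast is `(x1 - x2) / sqrt(v1 + v2)`, the node is assigned the
#' variance-weighted average of its daughters, and its own parent branch is
#' lengthened by `v1 * v2 / (v1 + v2)`.  Polytomies are first resolved
#' deterministically with near-zero internal branches
#' (see [resolve_polytomies()]).
#'
#' @param phy a `"phylo"` with branch lengths assigned.
#' @param trait named numeric vector, names = tip labels.
#' @return a `"contrast_set"`: data frame with columns `node`, `contrast`
#'   (standardized), `sd` (`sqrt(v1 + v2)`, the expected standard deviation
#'   of the raw contrast).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' independent_contrasts(tr, c(A = 0, B = 2, C = 3))
#' @export
independent_contrasts <- function(phy, trait) {
  validate_phylogeny(phy)
  if (!has_branch_lengths(phy))
    stop("branch lengths unassigned; call assign_branch_lengths() first")
  x <- .match_trait(trait, phy$tip.label)
  phy <- resolve_polytomies(phy)
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  val <- numeric(n_node)
  val[seq_len(n_tip)] <- x[phy$tip.label]
  # per-node corrected branch length to its parent
  blen <- numeric(n_node)
  blen[phy$edge[, 2L]] <- phy$edge.length

  po <- ape::reorder.phylo(phy, "postorder")
  kids <- split(po$edge[, 2L], po$edge[, 1L])
  internal <- unique(po$edge[, 1L])  # postorder: children before parents
  contrast <- sd_c <- numeric(length(internal))
  for (j in seq_along(internal)) {
    nd <- internal[j]
    ch <- kids[[as.character(nd)]]
    stopifnot(length(ch) == 2L)
    v1 <- blen[ch[1L]]; v2 <- blen[ch[2L]]
    s <- sqrt(v1 + v2)
    contrast[j] <- (val[ch[1L]] - val[ch[2L]]) / s
    sd_c[j] <- s
    val[nd] <- (val[ch[1L]] / v1 + val[ch[2L]] / v2) / (1 / v1 + 1 / v2)
    blen[nd] <- blen[nd] + v1 * v2 / (v1 + v2)
  }
  structure(
    data.frame(node = internal, contrast = contrast, sd = sd_c),
    node_values = val, root_value = val[n_tip + 1L],
    class = c("contrast_set", "data.frame")
  )
}

.match_trait <- function(trait, tips) {
  if (is.null(names(trait))) stop("trait vector must be named by species")
  missing_sp <- setdiff(tips, names(trait))
  if (length(missing_sp))
    stop("trait value missing for species: ", paste(missing_sp, collapse = ", "))
  x <- trait[tips]
  if (anyNA(x)) stop("NA trait value for species: ",
                     paste(tips[is.na(x)], collapse = ", "))
  x
}

#' Branch-length adequacy diagnostic
#'
#' If branch lengths are adequate for the trait, standardized contrasts are
#' homoscedastic: the absolute contrast should be uncorrelated with its
#' standard deviation.  A significant positive or negative Pearson
#' correlation indicates misscaled branch lengths, and the scheme fails the
#' diagnostic.  This is the criterion used to screen arbitrary schemes
#' before any comparative regression.
#'
#' @param cs a `"contrast_set"` from [independent_contrasts()].
#' @param alpha significance level of the screen (default 0.05); the scheme
#'   *passes* when the correlation p-value is `>= alpha`.
#' @return a `"bl_diagnostic"` list: `r`, `p`, `pass`, `alpha`, `n`.
#' @export
diagnose_branch_lengths <- function(cs, alpha = 0.05) {
  if (!inherits(cs, "contrast_set")) stop("expected a contrast_set")
  if (nrow(cs) < 3L)
    stop("diagnostic needs at least 3 contrasts, got ", nrow(cs))
  a <- abs(cs$contrast)
  if (sd(a) == 0 || sd(cs$sd) == 0)
    stop("diagnostic undefined: zero variance in |contrast| or sd")
  ct <- cor.test(a, cs$sd, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 pass = ct$p.value >= alpha, alpha = alpha, n = nrow(cs)),
            class = "bl_diagnostic")
}

#' @export
print.bl_diagnostic <- function(x, ...) {
  cat(sprintf("contrast diagnostic: r(|contrast|, sd) = %.4f, p = %.4f -> %s (alpha = %g, n = %d)\n",
              x$r, x$p, if (x$pass) "PASS" else "FAIL", x$alpha, x$n))
  invisible(x)
}
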