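#' Squared-change parsimony reconstruction of a continuous trait
#'
#' Assigns values to internal nodes minimizing the sum over branches of
#' `(change)^2 / w`, with `w` the branch length (weighted variant) or 1
#' (unweighted).  The minimum is a quadratic program whose stationarity
#' conditions are linear, so the reconstruction is solved exactly with one
#' sparse-free linear solve rather than iteratively.  The weighted root
#' value equals the GLS (phylogenetically corrected) mean of the trait.
#'
#' @param phy a `"phylo"`; branch lengths are required for the weighted
#'   variant (zero-length branches are an error there: pass
#'   [resolve_polytomies()] output or use `weighted = FALSE`).
#' @param trait named numeric vector over the tips.
#' @param weighted divide each squared change by its branch length
#'   (default `TRUE`).
#' @return an `"ancestral_states"` list: `states` (named by internal node
#'   id), `total` (the minimized objective), `method`, and `range` of the
#'   tip values (every reconstructed value lies inside it).
#' @export
squared_change_parsimony <- function(phy, trait, weighted = TRUE) {
  validate_phylogeny(phy)
  x <- .match_trait(trait, phy$tip.label)
  n_tip <- length(phy$tip.label)
  n_int <- phy$Nnode
  if (weighted) {
    if (is.null(phy$edge.length) || anyNA(phy$edge.length))
      stop("weighted reconstruction requires assigned branch lengths")
    if (any(phy$edge.length == 0))
      stop("zero-length branch in weighted mode; use an epsilon (resolve_polytomies) or weighted = FALSE")
    w <- phy$edge.length
  } else {
    w <- rep(1, nrow(phy$edge))
  }

  # unknowns: internal node values; index internal node id - n_tip
  A <- matrix(0, n_int, n_int)
  b <- numeric(n_int)
  for (e in seq_len(nrow(phy$edge))) {
    pa <- phy$edge[e, 1L] - n_tip
    ch <- phy$edge[e, 2L]
    wi <- 1 / w[e]
    A[pa, pa] <- A[pa, pa] + wi
    if (ch <= n_tip) {
      b[pa] <- b[pa] + wi * x[ch]
    } else {
      ci <- ch - n_tip
      A[pa, ci] <- A[pa, ci] - wi
      A[ci, pa] <- A[ci, pa] - wi
      A[ci, ci] <- A[ci, ci] + wi
    }
  }
  states <- solve(A, b)
  names(states) <- if (!is.null(phy$node.label) && length(phy$node.label) == n_int &&
                       all(nzchar(phy$node.label)))
    phy$node.label else paste0("node", seq_len(n_int) + n_tip)

  vals <- c(x, states)
  total <- sum((vals[phy$edge[, 1L]] - vals[phy$edge[, 2L]])^2 / w)
  structure(list(states = states, total = total,
                 method = if (weighted) "squared_change_weighted"
                          else "squared_change_unweighted",
                 range = range(x)),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(x$method, "reconstruction:", length(x$states),
      "internal nodes, total =", format(x$total, digits = 6), "\n")
  print(round(x$states, 4))
  invisible(x)
}

#' Minimum number of binary state changes (Fitch/Sankoff parsimony)
#'
#' Counts the minimal number of 0/1 state changes on the tree needed to
#' explain the tip states, by unit-cost dynamic programming over internal
#' assignments (exact for any tree, polytomies included).
#'
#' @param phy a `"phylo"` (branch lengths ignored).
#' @param binary_trait named vector of 0/1 (or logical) tip states.
#' @return integer: the minimum number of changes.
#' @export
count_state_origins <- function(phy, binary_trait) {
  validate_phylogeny(phy)
  s <- .match_trait(binary_trait, phy$tip.label)
  if (is.logical(s)) s <- as.integer(s)
  if (!all(s %in% c(0, 1)))
    stop("trait must be binary 0/1; offending species: ",
         paste(names(s)[!s %in% c(0, 1)], collapse = ", "))
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  # cost[node, state+1] = min changes in subtree given node has `state`
  cost <- matrix(0, n_node, 2L)
  cost[cbind(seq_len(n_tip), 2L - s)] <- Inf  # tips fixed at observed state
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    cost[pa, 1L] <- cost[pa, 1L] + min(cost[ch, 1L], cost[ch, 2L] + 1)
    cost[pa, 2L] <- cost[pa, 2L] + min(cost[ch, 2L], cost[ch, 1L] + 1)
  }
  as.integer(min(cost[n_tip + 1L, ]))
}

#' Discretize clutch size for step counting
#'
#' Maps a continuous clutch-size vector to the binary character
#' "single-egg clutch" (1) versus "multi-egg clutch" (0) used when asking
#' how often minimal clutches originated.
#'
#' @param clutch named numeric vector of clutch sizes.
#' @param threshold clutches `<= threshold` are coded 1 (default 1 egg).
#' @return named 0/1 integer vector.
#' @export
discretize_clutch <- function(clutch, threshold = 1) {
  setNames(as.integer(clutch <= threshold), names(clutch))
}

#' Write ancestral states
#'
#' `write_ancestral_tsv` emits a node/value table;
#' `write_annotated_newick` embeds the reconstructed values as internal node
#' labels of the Newick string.
#'
#' @param phy the tree used for the reconstruction.
#' @param anc an `"ancestral_states"` object.
#' @param path output file.
#' @return the written object, invisibly.
#' @export
write_ancestral_tsv <- function(anc, path) {
  tab <- data.frame(node = names(anc$states), value = unname(anc$states))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_ancestral_tsv
#' @export
write_annotated_newick <- function(phy, anc, path = NULL) {
  phy$node.label <- sprintf("%.6g", unname(anc$states))
  write_phylogeny(phy, path)
}
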