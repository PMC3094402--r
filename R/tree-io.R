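#' Parse a rooted Newick tree
#'
#' Reads a Newick string into an [ape::read.tree()] `"phylo"` object and
#' validates it for comparative analysis: exactly one tree, rooted, unique
#' non-empty tip labels.  Branch lengths are optional; topology-only input
#' (as when only a published cladogram is available) is accepted and the
#' missing lengths are treated as *unassigned* until a branch-length scheme
#' is applied with [assign_branch_lengths()].
#'
#' @param text a single Newick string, e.g. `"((A:1,B:1):1,C:2);"`.
#' @return an object of class `"phylo"`.  Unassigned branch lengths are
#'   represented by a missing `edge.length` component (or `NA` entries when
#'   only some lengths are given).
#' @seealso [read_phylogeny()] to read from a file path.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' has_branch_lengths(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty Newick input")
  .check_parentheses(text)
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: input could not be read as a tree")
  if (inherits(phy, "multiPhylo")) stop("expected a single tree, got ", length(phy))
  validate_phylogeny(phy)
  phy
}

#' @rdname parse_newick
#' @param path path to a Newick file (first tree line is used).
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree to Newick
#'
#' Round-trips labels and branch lengths at 10 significant digits.
#'
#' @param phy a `"phylo"` object.
#' @param path optional file path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_phylogeny <- function(phy, path = NULL) {
  txt <- ape::write.tree(phy, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# cheap structural pre-check so the error can name the offending position
.check_parentheses <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) stop("malformed Newick: ", depth, " unclosed '(' at end of input")
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants every downstream computation relies on: a single
#' root, unique non-empty tip labels, no negative branch lengths.
#'
#' @param phy a `"phylo"` object.
#' @return `phy`, invisibly.
#' @export
validate_phylogeny <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a \"phylo\" object")
  if (is.null(phy$tip.label) || length(phy$tip.label) < 2L)
    stop("tree must have at least 2 tips")
  if (anyNA(phy$tip.label) || any(!nzchar(phy$tip.label)))
    stop("empty tip label(s) present")
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  # A basal multifurcation is accepted as a rooted polytomy (a star tree is
  # legitimate input); Newick cannot distinguish it from an unrooted tree,
  # so interpretation-as-rooted is documented rather than rejected.
  # exactly one root
  n_root <- sum(tabulate(phy$edge[, 2L], nbins = max(phy$edge)) == 0L &
                  seq_len(max(phy$edge)) > length(phy$tip.label))
  if (n_root != 1L) stop("tree must have exactly one root, found ", n_root)
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0, na.rm = TRUE))
    stop("negative branch length(s) present")
  invisible(phy)
}

#' Does every branch have an assigned, positive length?
#'
#' @param phy a `"phylo"` object.
#' @return logical scalar.
#' @export
has_branch_lengths <- function(phy) {
  !is.null(phy$edge.length) && !anyNA(phy$edge.length) && all(phy$edge.length > 0)
}

# number of tips descended from each node (tips themselves count 1)
.n_desc_tips <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  nd <- integer(n_node)
  nd[seq_len(n_tip)] <- 1L
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    nd[po$edge[i, 1L]] <- nd[po$edge[i, 1L]] + nd[po$edge[i, 2L]]
  }
  nd
}

# root-to-node path lengths
.node_depths <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  depth <- numeric(n_node)
  root <- n_tip + 1L
  co <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(co$edge))) {
    depth[co$edge[i, 2L]] <- depth[co$edge[i, 1L]] + co$edge.length[i]
  }
  depth
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are expanded to a binary ladder with internal branches of
#' length `epsilon` (default 1e-8) so that downstream matrix computations
#' stay positive definite.  The expansion is deterministic: children of every
#' node are processed in their input order ([ape::multi2di()] with
#' `random = FALSE`), so repeated runs give identical trees.
#'
#' @param phy a `"phylo"` object with branch lengths assigned.
#' @param epsilon length given to the inserted internal branches.
#' @return a binary `"phylo"` object.
#' @export
resolve_polytomies <- function(phy, epsilon = 1e-8) {
  if (ape::is.binary.phylo(phy)) return(phy)
  had_lengths <- !is.null(phy$edge.length)
  res <- ape::multi2di(phy, random = FALSE)
  if (had_lengths) {
    new_zero <- is.na(res$edge.length) | res$edge.length == 0
    res$edge.length[new_zero] <- epsilon
  }
  res
}
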