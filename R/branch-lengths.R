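#' Arbitrary branch-length schemes
#'
#' When divergence times, genetic distances or any other metric proportional
#' to expected trait variance are unavailable, comparative analyses fall back
#' on topology-derived "arbitrary" branch lengths.  Four classical schemes
#' are supported, plus `"as_given"` for trees that already carry lengths:
#'
#' \describe{
#'   \item{`constant`}{every branch set to 1.  Tip depths may differ, so the
#'     result is generally *not* ultrametric.}
#'   \item{`grafen`}{node height = (number of descendant tips - 1)^`rho`,
#'     rescaled so the root height is 1; each branch is the difference
#'     between parent and child heights.  `rho = 1` by default.}
#'   \item{`pagel`}{every branch set to 1, then each terminal branch extended
#'     so that all tips are equidistant from the root (ultrametric).}
#'   \item{`nee`}{node height proportional to log2(number of descendant
#'     tips), rescaled so the root height is 1; tips at height 0.}
#' }
#'
#' Which scheme is defensible for a given data set is an empirical question
#' answered by [diagnose_branch_lengths()].
#'
#' @param kind one of `"as_given"`, `"constant"`, `"grafen"`, `"pagel"`,
#'   `"nee"`.
#' @param rho positive exponent for the Grafen scheme (ignored otherwise).
#' @return an object of class `"branch_scheme"`.
#' @examples
#' branch_scheme("grafen", rho = 0.5)
#' @export
branch_scheme <- function(kind = c("as_given", "constant", "grafen", "pagel", "nee"),
                          rho = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0)
    stop("rho must be a positive scalar")
  structure(list(kind = kind, rho = rho), class = "branch_scheme")
}

#' @export
print.branch_scheme <- function(x, ...) {
  cat("branch-length scheme:", x$kind)
  if (x$kind == "grafen") cat(" (rho =", x$rho, ")")
  cat("\n")
  invisible(x)
}

.as_scheme <- function(scheme, rho = 1) {
  if (inherits(scheme, "branch_scheme")) return(scheme)
  branch_scheme(scheme, rho = rho)
}

#' Assign branch lengths under a scheme
#'
#' @param phy a `"phylo"` object (lengths may be absent).
#' @param scheme a [branch_scheme()] object or a scheme name.
#' @param rho Grafen exponent, used when `scheme` is given as a name.
#' @return the tree with every branch length assigned and strictly positive;
#'   the scheme is recorded in `attr(phy, "scheme")`.
#' @examples
#' tr <- parse_newick("((A,B),C);")
#' assign_branch_lengths(tr, "pagel")$edge.length
#' @export
assign_branch_lengths <- function(phy, scheme = "constant", rho = 1) {
  validate_phylogeny(phy)
  scheme <- .as_scheme(scheme, rho)
  n_edge <- nrow(phy$edge)
  out <- phy
  out$edge.length <- switch(
    scheme$kind,
    as_given = {
      if (!has_branch_lengths(phy))
        stop("scheme 'as_given' requires all branch lengths assigned and > 0")
      phy$edge.length
    },
    constant = rep(1, n_edge),
    grafen = .heights_to_lengths(phy, .grafen_heights(phy, scheme$rho), "grafen"),
    pagel = .pagel_lengths(phy),
    nee = .heights_to_lengths(phy, .nee_heights(phy), "nee")
  )
  attr(out, "scheme") <- scheme
  out
}

.grafen_heights <- function(phy, rho) {
  nd <- .n_desc_tips(phy)
  h <- (nd - 1)^rho
  h / h[length(phy$tip.label) + 1L]  # root height 1
}

.nee_heights <- function(phy) {
  nd <- .n_desc_tips(phy)
  h <- log2(nd)
  h / h[length(phy$tip.label) + 1L]
}

.heights_to_lengths <- function(phy, heights, label) {
  el <- heights[phy$edge[, 1L]] - heights[phy$edge[, 2L]]
  bad <- which(el <= 0)
  if (length(bad)) {
    stop(label, " scheme yields non-positive branch length(s) above node(s) ",
         paste(phy$edge[bad, 2L], collapse = ", "),
         " (child subtends as many tips as its parent)")
  }
  el
}

.pagel_lengths <- function(phy) {
  tmp <- phy
  tmp$edge.length <- rep(1, nrow(phy$edge))
  depth <- .node_depths(tmp)
  n_tip <- length(phy$tip.label)
  tip_depth <- depth[seq_len(n_tip)]
  ext <- max(tip_depth) - tip_depth
  el <- tmp$edge.length
  is_tip_edge <- phy$edge[, 2L] <= n_tip
  el[is_tip_edge] <- el[is_tip_edge] + ext[phy$edge[is_tip_edge, 2L]]
  el
}
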