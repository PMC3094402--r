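#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian-motion expectations the covariance between two tips equals
#' the shared root-to-MRCA path length and each variance equals the tip's
#' depth.  The result carries its branch-length provenance so that analyses
#' reported downstream are auditable.
#'
#' @param phy a `"phylo"` object with all branch lengths assigned (> 0);
#'   apply [assign_branch_lengths()] first for topology-only trees.
#' @return a `"phylo_vcv"` object: the tip-by-tip matrix `V` with attributes
#'   `tip_order` (rownames order), `height` (max root-to-tip path length `T`)
#'   and `scheme` (a [branch_scheme()], when known).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' phylo_covariance(tr)
#' @export
phylo_covariance <- function(phy) {
  validate_phylogeny(phy)
  if (!has_branch_lengths(phy))
    stop("branch lengths unassigned; call assign_branch_lengths() first")
  V <- ape::vcv.phylo(phy)
  structure(V,
            tip_order = rownames(V),
            height = max(diag(V)),
            scheme = attr(phy, "scheme"),
            class = c("phylo_vcv", "matrix", "array"))
}

#' @export
print.phylo_vcv <- function(x, ...) {
  sch <- attr(x, "scheme")
  cat("phylogenetic covariance matrix:", nrow(x), "tips, height T =",
      format(attr(x, "height"), digits = 6),
      if (!is.null(sch)) paste0("(scheme: ", sch$kind, ")"), "\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more tips)\n", sep = "")
  invisible(x)
}

.as_vcv <- function(V) {
  if (inherits(V, "phylo_vcv")) return(V)
  if (inherits(V, "phylo")) return(phylo_covariance(V))
  if (is.matrix(V) && isSymmetric(unname(V)) && !is.null(rownames(V)))
    return(structure(V, tip_order = rownames(V), height = max(diag(V)),
                     class = c("phylo_vcv", "matrix", "array")))
  stop("expected a phylo_vcv, a phylo, or a named symmetric matrix")
}

#' Ornstein-Uhlenbeck transform of a phylogenetic covariance matrix
#'
#' Rescales shared history under a stabilizing-selection model governed by
#' the parameter `d`: with relative depths `t = V/T`, the transformed matrix
#' is `V' = T * (d^(2 * (1 - t)) - d^2) / (1 - d^2)`.  `d = 1` is the
#' Brownian-motion limit (`V' = V`, evaluated analytically); `d -> 0`
#' collapses shared history, approaching a star phylogeny (off-diagonals go
#' to 0; for an ultrametric tree `V'(0) = T * I`).  Values `d > 1` inflate
#' shared history relative to Brownian motion.
#'
#' @param V a `"phylo_vcv"` (or a tree, converted on the fly).
#' @param d OU transformation parameter, `d >= 0`.
#' @return the transformed `"phylo_vcv"`; `attr(, "ou_d")` records `d`.
#' @export
ou_transform <- function(V, d) {
  V <- .as_vcv(V)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("d must be a single number >= 0")
  T_h <- attr(V, "height")
  t_rel <- unclass(V) / T_h
  Vp <- if (abs(d - 1) < 1e-10) {
    # limit d -> 1: V' = T * t = V
    T_h * t_rel
  } else if (d == 0) {
    # limit d -> 0: indicator of full shared history
    T_h * (t_rel >= 1 - 1e-12)
  } else {
    T_h * (d^(2 * (1 - t_rel)) - d^2) / (1 - d^2)
  }
  dimnames(Vp) <- dimnames(V)
  structure(Vp,
            tip_order = attr(V, "tip_order"), height = max(diag(Vp)),
            scheme = attr(V, "scheme"), ou_d = d,
            class = c("phylo_vcv", "matrix", "array"))
}

# Solve V x = b via Cholesky; fails loudly on non-PD input.
.chol_vcv <- function(V) {
  ch <- tryCatch(chol(unclass(V)), error = function(e)
    stop("covariance matrix is not positive definite: ", conditionMessage(e),
         call. = FALSE))
  ch
}

# log-determinant and quadratic-form helpers reused by signal + regression
.vcv_ops <- function(V) {
  ch <- .chol_vcv(V)
  list(
    logdet = 2 * sum(log(diag(ch))),
    solve = function(b) backsolve(ch, forwardsolve(t(ch), b)),
    # "half-solve": returns L^-1 b with V = L L', so crossprod gives b' V^-1 b
    white = function(b) forwardsolve(t(ch), b)
  )
}
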