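# Phylogenetic covariance and the phylogenetic transformation.
#
# Under Brownian motion on a rooted tree, tip values have covariance
# C[i, j] = shared root-to-MRCA path length. Premultiplying the GLS
# residuals by C^(-1/2) renders species observations exchangeable; PLS,
# PGLS and rate estimation all operate on that transformed matrix U.

#' Brownian-motion covariance matrix of a tree's tips
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param species_order Optional character vector naming (a subset of) tips;
#'   rows/columns of the result follow this order. Defaults to the tree's
#'   tip order.
#' @return An N x N symmetric matrix with `C[i, j]` the root-to-MRCA path
#'   length of tips i and j and `C[i, i]` the depth of tip i; dimnames are
#'   the species names.
#' @export
phylo_covariance <- function(tree, species_order = NULL) {
  C <- ape::vcv.phylo(tree)
  if (!is.null(species_order)) {
    unknown <- setdiff(species_order, rownames(C))
    if (length(unknown))
      stop("species not in tree: ", paste(unknown, collapse = ", "))
    C <- C[species_order, species_order, drop = FALSE]
  }
  C
}

#' Inverse square root of a positive-definite covariance matrix
#'
#' Computed via the symmetric eigendecomposition (so the result is the
#' unique symmetric root, independent of species ordering), with
#' eigenvalues floored at `floor_tol` times the largest.
#'
#' @param C Symmetric positive-definite matrix.
#' @param floor_tol Relative eigenvalue floor below which the matrix is
#'   treated as singular (default 1e-12).
#' @return Symmetric matrix `M` with `M %*% C %*% M` equal to the identity.
#' @export
inv_sqrt <- function(C, floor_tol = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  lo <- floor_tol * max(e$values)
  if (any(e$values < lo)) {
    hint <- ""
    if (!is.null(rownames(C))) {
      # a vanishing eigenvalue usually means two tips share (almost) their
      # whole root-to-tip path: a zero-length cherry
      D <- outer(diag(C), diag(C), pmin) - C
      diag(D) <- Inf
      ij <- which(D == min(D), arr.ind = TRUE)[1, ]
      hint <- paste0(" (closest tip pair: ", rownames(C)[ij[1]], " / ",
                     rownames(C)[ij[2]], ")")
    }
    stop("covariance matrix is near-singular", hint)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Phylogenetic transformation of a species-by-trait matrix
#'
#' Computes the GLS estimate of the phylogenetic mean,
#' `a = (1' C^-1 1)^-1 1' C^-1 Y`, and the transformed residuals
#' `U = C^(-1/2) (Y - 1 a)`. When `C` is the identity this reduces to plain
#' column centering.
#'
#' @param Y N x p numeric matrix with rownames matching `colnames(C)` in
#'   order (species order of the pruned tree).
#' @param C Phylogenetic covariance from [phylo_covariance()].
#' @return List with `a` (1 x p phylogenetic mean), `U` (N x p transformed
#'   residuals) and `p` (trait dimensionality).
#' @export
phylo_transform <- function(Y, C) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(C)) stop("row count of Y does not match C")
  if (!is.null(rownames(Y)) && !is.null(colnames(C)) &&
      !identical(rownames(Y), colnames(C)))
    stop("rows of Y must follow the species order of C")
  Cinv1 <- solve(C, rep(1, nrow(C)))
  a <- crossprod(Cinv1, Y) / sum(Cinv1)
  U <- inv_sqrt(C) %*% sweep(Y, 2, a)
  rownames(U) <- rownames(Y)
  list(a = a, U = U, p = ncol(Y))
}
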