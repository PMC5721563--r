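# Two-block partial least squares and evolutionary integration.
#
# The integration statistic is rPLS: the absolute correlation between the
# first pair of PLS axis scores of two trait blocks (here, left and right
# valve shape). In the phylogenetic variant both blocks are first replaced
# by their phylogenetically transformed residuals, and significance comes
# from permuting species rows of the transformed second block.

first_singular_pair <- function(S) {
  sv <- svd(S, nu = 1, nv = 1)
  list(u = sv$u[, 1], v = sv$v[, 1], d = sv$d)
}

pls_r_value <- function(X1, X2) {
  # |corr| of first-axis scores; internal fast path shared with permutations
  S <- crossprod(X1, X2) / (nrow(X1) - 1)
  if (max(abs(S)) < 1e-300) return(0)
  sp <- first_singular_pair(S)
  abs(cor(X1 %*% sp$u, X2 %*% sp$v))
}

new_pls_result <- function(...) structure(list(...), class = "pls_result")

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("two-block PLS: rPLS = %.4f", x$r_pls))
  if (!is.null(x$p_value))
    cat(sprintf(", Z = %.2f, P = %.4g (%d permutations)",
                x$z_score, x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' Two-block partial least squares
#'
#' Singular-value decomposition of the cross-block covariance of two trait
#' blocks measured on the same observations. Only the first axis pair is
#' used for the integration statistic `r_pls`, the absolute Pearson
#' correlation of the first-axis scores.
#'
#' @param Y1,Y2 Numeric matrices with the same row count (n >= 3).
#' @param center Column-center the blocks first (default `TRUE`; the
#'   phylogenetic variant passes GLS-centred residuals and sets this to
#'   `FALSE`).
#' @return A `pls_result` with `r_pls`, unit `left_axis`/`right_axis`,
#'   per-observation `left_scores`/`right_scores`, the singular values, and
#'   a `degenerate` flag (`TRUE` when the cross-covariance vanishes, in
#'   which case `r_pls` is 0 and the axes are `NA`).
#' @export
two_block_pls <- function(Y1, Y2, center = TRUE) {
  Y1 <- as.matrix(Y1)
  Y2 <- as.matrix(Y2)
  if (nrow(Y1) != nrow(Y2)) stop("blocks must have the same row count")
  n <- nrow(Y1)
  if (n < 3L) stop("need at least 3 observations")
  if (center) {
    Y1 <- scale(Y1, scale = FALSE)
    Y2 <- scale(Y2, scale = FALSE)
  }
  S <- crossprod(Y1, Y2) / (n - 1)
  if (max(abs(S)) < 1e-300) {
    return(new_pls_result(r_pls = 0, left_axis = rep(NA_real_, ncol(Y1)),
                          right_axis = rep(NA_real_, ncol(Y2)),
                          left_scores = rep(NA_real_, n),
                          right_scores = rep(NA_real_, n),
                          singular_values = rep(0, min(dim(S))),
                          degenerate = TRUE, n = n))
  }
  sv <- svd(S)
  u <- sv$u[, 1]
  v <- sv$v[, 1]
  # deterministic sign convention (SVD signs are arbitrary)
  if (u[which.max(abs(u))] < 0) u <- -u
  if (v[which.max(abs(v))] < 0) v <- -v
  new_pls_result(r_pls = abs(cor(Y1 %*% u, Y2 %*% v))[1],
                 left_axis = u, right_axis = v,
                 left_scores = as.vector(Y1 %*% u),
                 right_scores = as.vector(Y2 %*% v),
                 singular_values = sv$d, degenerate = FALSE, n = n)
}

#' Phylogenetic two-block partial least squares
#'
#' Both blocks are replaced by their phylogenetically transformed residuals
#' (see [phylo_transform()]) and [two_block_pls()] is applied to those
#' without re-centering (the GLS mean has already been removed). On a star
#' phylogeny this reduces to ordinary two-block PLS of the centred data.
#'
#' @param Y1,Y2 Species-by-trait matrices with rows in the species order of
#'   `C`.
#' @param C Phylogenetic covariance from [phylo_covariance()].
#' @return A `pls_result` (see [two_block_pls()]).
#' @export
phylo_pls <- function(Y1, Y2, C) {
  U1 <- phylo_transform(Y1, C)$U
  U2 <- phylo_transform(Y2, C)$U
  two_block_pls(U1, U2, center = FALSE)
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' Permutation test for (phylogenetic) two-block PLS
#'
#' Builds the null distribution of `r_pls` by permuting rows of the
#' transformed second block relative to the first (permutation acts in the
#' transformed space, where species are exchangeable under Brownian
#' motion), recomputing `r_pls` each time. The p-value uses the +1-corrected
#' proportion of permuted values at or above the observed one, so it is
#' never 0; the effect size `z_score` standardises the Fisher-transformed
#' observed `r_pls` against the Fisher-transformed permutation distribution.
#'
#' @param Y1,Y2 Trait blocks (species-by-trait when `C` is supplied).
#' @param C Phylogenetic covariance, or `NULL` for the ordinary
#'   (non-phylogenetic, e.g. specimen-level) test on centred blocks.
#' @param n_perm Number of permutations (>= 99; 1000 in the study design).
#' @param seed Integer seed for the permutation stream (one stream per
#'   analysis; indices are regenerated, never cached).
#' @return A complete `pls_result` with `p_value`, `z_score`, `n_perm` and
#'   the stored permutation distribution `permuted_r`.
#' @export
pls_permutation <- function(Y1, Y2, C = NULL, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(C)) {
    U1 <- scale(as.matrix(Y1), scale = FALSE)
    U2 <- scale(as.matrix(Y2), scale = FALSE)
  } else {
    U1 <- phylo_transform(Y1, C)$U
    U2 <- phylo_transform(Y2, C)$U
  }
  obs <- two_block_pls(U1, U2, center = FALSE)
  n <- nrow(U1)
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    r_perm[b] <- pls_r_value(U1, U2[sample.int(n), , drop = FALSE])
  }
  obs$p_value <- (sum(r_perm >= obs$r_pls) + 1) / (n_perm + 1)
  fz <- fisher_z(r_perm)
  obs$z_score <- (fisher_z(obs$r_pls) - mean(fz)) / sd(fz)
  obs$n_perm <- n_perm
  obs$permuted_r <- r_perm
  obs
}

#' Compare integration effect sizes across analyses
#'
#' Pairwise comparison of PLS effect sizes, the standardised measure of
#' integration strength: for each pair,
#' `z_ij = |z_i - z_j| / sqrt(se_i^2 + se_j^2)` with a two-sided normal
#' p-value. Effect sizes are measured on the Fisher-transformed scale as
#' the observed statistic minus its permutation-null mean,
#' `z_i = f(r_obs) - mean(f(r_perm))`, and `se_i` is the standard error of
#' that quantity: the Fisher-scale sampling SE of a correlation,
#' `1/(N-3)`, plus the Monte Carlo error of the estimated null mean,
#' `sd(f(r_perm))^2 / n_perm`, combined in quadrature. (Using the raw
#' permutation-distribution spread as the SE is noticeably
#' anticonservative for this statistic, because the null spread of the
#' leading-axis correlation is tighter than its sampling spread under
#' integration.)
#'
#' @param results List of `pls_result` objects from [pls_permutation()]
#'   (each must carry its permutation distribution).
#' @param labels Optional analysis labels (default `names(results)` or
#'   positional).
#' @return List with matrices `z` and `p` (pairwise statistics and
#'   p-values) and the per-analysis Fisher-scale `effect_sizes`.
#' @export
compare_pls_effects <- function(results, labels = NULL) {
  if (length(results) < 2L) stop("need at least 2 results to compare")
  if (is.null(labels)) labels <- names(results)
  if (is.null(labels)) labels <- paste0("analysis", seq_along(results))
  z <- numeric(length(results))
  se <- numeric(length(results))
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (is.null(r$permuted_r))
      stop("result '", labels[i], "' lacks a stored permutation distribution")
    fz <- fisher_z(r$permuted_r)
    z[i] <- fisher_z(r$r_pls) - mean(fz)
    se[i] <- sqrt(1 / max(r$n - 3, 1) + var(fz) / r$n_perm)
  }
  m <- length(z)
  zmat <- matrix(0, m, m, dimnames = list(labels, labels))
  pmat <- matrix(1, m, m, dimnames = list(labels, labels))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      zij <- abs(z[i] - z[j]) / sqrt(se[i]^2 + se[j]^2)
      zmat[i, j] <- zij
      pmat[i, j] <- 2 * pnorm(-zij)
    }
  }
  list(z = zmat, p = pmat,
       effect_sizes = setNames(z, labels))
}
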