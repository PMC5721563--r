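# Phylogenetic generalised least squares for multidimensional responses
# with a categorical predictor (here: species-level asymmetry, or shape,
# regressed on ecomorph). The response and the design matrix are both
# premultiplied by C^(-1/2); sums of squares are traces of cross-product
# matrices, and significance comes from residual randomisation of the
# reduced (intercept-only) model (RRPP).

new_pgls_result <- function(...) structure(list(...), class = "pgls_result")

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("D-PGLS: F = %.4g (df %d, %d), SS model/resid = %.4g/%.4g",
              x$f_stat, x$df_model, x$df_resid, x$ss_model, x$ss_resid))
  if (!is.null(x$p_value) && !is.na(x$p_value))
    cat(sprintf(", P = %.4g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

pgls_matrices <- function(Y, groups, C) {
  Y <- as.matrix(Y)
  sp <- rownames(Y)
  if (is.null(sp)) stop("Y must have species rownames")
  if (!identical(sp, colnames(C)))
    stop("rows of Y must follow the species order of C")
  g <- if (!is.null(names(groups))) groups[sp] else groups
  if (anyNA(g)) stop("group missing for some species")
  g <- factor(as.character(g))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) == 0L)) stop("a group has no species in the data")
  X <- stats::model.matrix(~g)
  if (qr(X)$rank < ncol(X)) stop("collinear design (rank deficient)")
  M <- inv_sqrt(C)
  list(Yt = M %*% Y, Xt = M %*% X, X0t = M %*% matrix(1, nrow(Y), 1),
       g = g)
}

pgls_f <- function(Yt, fit_full, fit_red) {
  R_full <- Yt - fit_full$P %*% Yt
  R_red <- Yt - fit_red$P %*% Yt
  ss_resid <- sum(R_full^2)
  ss_total <- sum(R_red^2)
  ss_model <- ss_total - ss_resid
  list(ss_model = ss_model, ss_resid = ss_resid, ss_total = ss_total)
}

proj_mat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  list(P = tcrossprod(Q), rank = q$rank)
}

#' Phylogenetic generalised least squares fit (multivariate response)
#'
#' Fits the one-factor design in the phylogenetically transformed space:
#' both the response matrix and the group-indicator design are
#' premultiplied by the inverse square root of the phylogenetic covariance.
#' Sums of squares are traces of the fitted and residual cross-product
#' matrices; `F = (SS_model / df_model) / (SS_resid / df_resid)`. On a star
#' phylogeny with a 1-D trait this is the ordinary one-way ANOVA F; with
#' `C` the identity it is a non-phylogenetic multivariate Procrustes ANOVA.
#'
#' @param Y N x p response matrix with species rownames in the order of
#'   `C` (p >= 1; the study's use case is the 1-D species-mean asymmetry,
#'   but shape responses work identically).
#' @param groups Species-to-group map: character/factor vector, named by
#'   species or aligned with the rows of `Y`. At least 2 groups, each with
#'   at least 1 species.
#' @param C Phylogenetic covariance from [phylo_covariance()].
#' @return A `pgls_result` with `f_stat`, `ss_model`, `ss_resid`,
#'   `df_model`, `df_resid` (no p-value; see [dpgls_permutation()]).
#' @export
dpgls_fit <- function(Y, groups, C) {
  m <- pgls_matrices(Y, groups, C)
  fit_full <- proj_mat(m$Xt)
  fit_red <- proj_mat(m$X0t)
  ss <- pgls_f(m$Yt, fit_full, fit_red)
  df_model <- fit_full$rank - fit_red$rank
  df_resid <- nrow(m$Yt) - fit_full$rank
  f <- if (ss$ss_total <= 1e-12 * max(sum(m$Yt^2), 1e-300)) 0 else
    (ss$ss_model / df_model) / (ss$ss_resid / df_resid)
  new_pgls_result(f_stat = f, ss_model = ss$ss_model,
                  ss_resid = ss$ss_resid, ss_total = ss$ss_total,
                  df_model = df_model, df_resid = df_resid,
                  p_value = NA_real_, n_perm = 0L)
}

#' Permutation test for the D-PGLS model
#'
#' Significance by residual randomisation in the transformed space (RRPP):
#' residuals from the reduced (intercept-only) model are permuted across
#' species and added back to the reduced fit, and F is recomputed each
#' iteration. The p-value is the +1-corrected proportion of permuted F
#' values at or above the observed one.
#'
#' @inheritParams dpgls_fit
#' @param n_perm Number of permutations (>= 99; 1000 in the study design).
#' @param seed Integer seed for the permutation stream.
#' @return A complete `pgls_result` including `p_value`, `n_perm` and the
#'   permuted F distribution `permuted_f`.
#' @export
dpgls_permutation <- function(Y, groups, C, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  m <- pgls_matrices(Y, groups, C)
  fit_full <- proj_mat(m$Xt)
  fit_red <- proj_mat(m$X0t)
  df_model <- fit_full$rank - fit_red$rank
  df_resid <- nrow(m$Yt) - fit_full$rank
  fstat <- function(Yt) {
    ss <- pgls_f(Yt, fit_full, fit_red)
    if (ss$ss_total <= 1e-12 * max(sum(Yt^2), 1e-300)) 0 else
      (ss$ss_model / df_model) / (ss$ss_resid / df_resid)
  }
  f_obs <- fstat(m$Yt)
  fitted_red <- fit_red$P %*% m$Yt
  E0 <- m$Yt - fitted_red
  n <- nrow(m$Yt)
  f_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    f_perm[b] <- fstat(fitted_red + E0[sample.int(n), , drop = FALSE])
  }
  ss <- pgls_f(m$Yt, fit_full, fit_red)
  new_pgls_result(f_stat = f_obs, ss_model = ss$ss_model,
                  ss_resid = ss$ss_resid, ss_total = ss$ss_total,
                  df_model = df_model, df_resid = df_resid,
                  p_value = (sum(f_perm >= f_obs) + 1) / (n_perm + 1),
                  n_perm = n_perm, permuted_f = f_perm)
}
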