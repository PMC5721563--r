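# Independent oracles used by the geometry and PLS tests. These deliberately
# avoid the package's SVD-based code paths: rotations are searched over
# Euler angles (coarse grid + Nelder-Mead refinement) and PLS axes over unit
# projection vectors.

euler_rotation <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz2 <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

# Brute-force minimum of ||A R - B|| over proper rotations: grid at 9
# degrees then local refinement.
oracle_min_rotation_distance <- function(A, B, grid_step = pi / 20) {
  obj <- function(ang) sqrt(sum((A %*% euler_rotation(ang[1], ang[2], ang[3]) - B)^2))
  best <- c(0, 0, 0)
  best_val <- obj(best)
  for (a in seq(0, 2 * pi, by = grid_step)) {
    for (b in seq(0, pi, by = grid_step)) {
      for (c in seq(0, 2 * pi, by = grid_step)) {
        v <- obj(c(a, b, c))
        if (v < best_val) {
          best_val <- v
          best <- c(a, b, c)
        }
      }
    }
  }
  ref <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best_val, ref$value)
}

# Procrustes distance oracle: full superimposition by brute force.
oracle_procrustes_distance <- function(a, b) {
  a <- scale(a, scale = FALSE)
  b <- scale(b, scale = FALSE)
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  oracle_min_rotation_distance(b, a)
}

# Grid/refinement oracle for the first PLS axis pair: find the unit
# projection vectors maximising |cov(Y1 u, Y2 v)| (the defining property of
# the first singular pair), then report |cor| of the scores at that
# optimum. For small block dimensions (p <= 3 each).
oracle_pls_r <- function(Y1, Y2) {
  Y1 <- scale(Y1, scale = FALSE)
  Y2 <- scale(Y2, scale = FALSE)
  unit_vec <- function(ang, p) {
    if (p == 1) return(1)
    if (p == 2) return(c(cos(ang[1]), sin(ang[1])))
    c(cos(ang[1]) * cos(ang[2]), cos(ang[1]) * sin(ang[2]), sin(ang[1]))
  }
  n1 <- max(ncol(Y1) - 1, 0)
  n2 <- max(ncol(Y2) - 1, 0)
  score_cor <- function(ang) {
    u <- unit_vec(ang[seq_len(max(n1, 1))], ncol(Y1))
    v <- unit_vec(ang[max(n1, 1) + seq_len(max(n2, 1))], ncol(Y2))
    s1 <- Y1 %*% u
    s2 <- Y2 %*% v
    if (sd(s1) < 1e-14 || sd(s2) < 1e-14) return(0)
    abs(cor(s1, s2))[1]
  }
  obj <- function(ang) {
    u <- unit_vec(ang[seq_len(max(n1, 1))], ncol(Y1))
    v <- unit_vec(ang[max(n1, 1) + seq_len(max(n2, 1))], ncol(Y2))
    -abs(mean((Y1 %*% u) * (Y2 %*% v)))
  }
  k <- max(n1, 1) + max(n2, 1)
  best <- rep(0, k)
  best_val <- obj(best)
  grid <- seq(0, pi, by = pi / 18)
  pts <- as.matrix(expand.grid(rep(list(grid), k)))
  for (i in seq_len(nrow(pts))) {
    v <- obj(pts[i, ])
    if (v < best_val) {
      best_val <- v
      best <- pts[i, ]
    }
  }
  ref <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  score_cor(if (ref$value < best_val) ref$par else best)
}

# Straight-line reference for phylogenetic PLS: Cholesky-based GLS
# transform (a different matrix root than the package's symmetric one; the
# cross-block covariance, and hence rPLS, is invariant to that choice).
ref_phylo_pls_r <- function(Y1, Y2, C) {
  L <- t(chol(C))
  one <- rep(1, nrow(C))
  Ci <- chol2inv(chol(C))
  gls_mean <- function(Y) (t(one) %*% Ci %*% Y) / sum(Ci %*% one)
  t1 <- forwardsolve(L, sweep(Y1, 2, gls_mean(Y1)))
  t2 <- forwardsolve(L, sweep(Y2, 2, gls_mean(Y2)))
  S <- crossprod(t1, t2)
  sv <- svd(S, nu = 1, nv = 1)
  abs(cor(t1 %*% sv$u, t2 %*% sv$v))[1]
}

# Tip sets below each edge of a tree (for painting clade rates in tests).
edge_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) below[[tree$edge[e, 2]]])
}
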