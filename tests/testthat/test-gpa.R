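# Superimposition geometry: centering/scaling, rotations, distances,
# sliding, averaging. Oracles are rotation-grid searches (see helpers).

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

test_that("center_and_scale centres, normalises and reports size", {
  tri <- unit_triangle(offset = c(3, -2, 5))
  cs <- center_and_scale(tri)
  expect_lt(max(abs(colMeans(cs$config))), 1e-12)
  expect_equal(sqrt(sum(cs$config^2)), 1, tolerance = 1e-12)
  tri0 <- sweep(tri, 2, colMeans(tri))
  expect_equal(cs$centroid_size, sqrt(sum(tri0^2)))
  # already normalised input passes through with size 1
  cs2 <- center_and_scale(cs$config)
  expect_equal(cs2$config, cs$config, tolerance = 1e-12)
  expect_equal(cs2$centroid_size, 1, tolerance = 1e-12)
  expect_error(center_and_scale(matrix(1, 4, 3)), "degenerate")
})

test_that("optimal_rotation recovers known rotations and is proper", {
  A <- quad_config()
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% Rz
  R <- optimal_rotation(A, B)
  expect_equal(R, Rz, tolerance = 1e-10)
  expect_lt(sqrt(sum((A %*% R - B)^2)), 1e-12)
  expect_equal(optimal_rotation(A, A), diag(3), tolerance = 1e-10)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("reflections are excluded: mirrored targets match the proper-rotation oracle", {
  A <- quad_config()
  B <- mirror_configuration(A, "x")
  R <- optimal_rotation(A, B)
  expect_equal(det(R), 1, tolerance = 1e-12)
  achieved <- sqrt(sum((A %*% R - B)^2))
  oracle <- oracle_min_rotation_distance(A, B)
  expect_gt(achieved, 1e-6)  # a mirror image is not reachable
  expect_equal(achieved, oracle, tolerance = 1e-6)
})

test_that("procrustes_distance matches its definition and the grid oracle", {
  a <- quad_config()
  expect_identical(procrustes_distance(a, a, align_first = FALSE), 0)
  expect_lt(procrustes_distance(a, a, align_first = TRUE), 1e-12)
  # invariance to similarity transforms under alignment
  b <- 2.7 * a %*% euler_rotation(0.4, 1.1, -0.8) + rep(c(1, -2, 3), each = 4)
  expect_lt(procrustes_distance(a, b, align_first = TRUE), 1e-12)
  # fixed pair vs oracle
  set.seed(7)
  b2 <- a + matrix(rnorm(12, sd = 0.2), 4, 3)
  expect_equal(procrustes_distance(a, b2, align_first = TRUE),
               oracle_procrustes_distance(a, b2), tolerance = 1e-6)
  expect_error(procrustes_distance(a, unit_triangle()), "mismatch")
})

test_that("procrustes_distance is symmetric and satisfies the triangle inequality", {
  set.seed(21)
  for (i in 1:10) {
    a <- center_and_scale(matrix(rnorm(15), 5, 3))$config
    b <- center_and_scale(matrix(rnorm(15), 5, 3))$config
    c <- center_and_scale(matrix(rnorm(15), 5, 3))$config
    dab <- procrustes_distance(a, b, align_first = FALSE)
    expect_equal(dab, procrustes_distance(b, a, align_first = FALSE))
    expect_lte(dab,
               procrustes_distance(a, c, align_first = FALSE) +
                 procrustes_distance(c, b, align_first = FALSE) + 1e-12)
    # symmetry also holds with alignment
    expect_equal(procrustes_distance(a, b, align_first = TRUE),
                 procrustes_distance(b, a, align_first = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("mirror_configuration is an involution acting on one axis", {
  p <- matrix(c(1, 2, 3), 1, 3)[rep(1, 3), ]
  expect_equal(mirror_configuration(p, "x")[1, ], c(-1, 2, 3))
  a <- quad_config()
  expect_equal(mirror_configuration(mirror_configuration(a, "y"), "y"), a)
})

test_that("a planar configuration has zero distance to its mirror image", {
  # a planar shape's reflection is reachable by a proper rotation (flip
  # about an in-plane axis), so the mirror distance vanishes; a non-planar
  # shape's is not (see the reflection-exclusion test above)
  a <- cbind(quad_config()[, 1:2], 0)
  d <- procrustes_distance(a, mirror_configuration(a, "x"),
                           align_first = TRUE)
  expect_lt(d, 1e-8)
})

test_that("curve semilandmarks slide along their tangent only", {
  # two fixed anchors and one curve point between them (tangent along y)
  kind <- c("fixed", "fixed", "curve")
  topo <- semilandmark_topology(kind, prev = c(NA, NA, 1),
                                nxt = c(NA, NA, 2))
  ref <- rbind(c(1, -1, 0), c(1, 1, 0), c(1, 0, 0))
  shape <- rbind(c(1, -1, 0), c(1, 1, 0), c(1.2, 0.3, 0))
  out <- slide_semilandmarks(shape, ref, topo)
  # slides to y = 0 along the tangent; the off-tangent x-residual is kept
  expect_equal(out[3, ], c(1.2, 0, 0), tolerance = 1e-12)
  expect_identical(out[1:2, ], shape[1:2, ])  # fixed: bit-exact
  # already matching the reference: zero displacement
  out0 <- slide_semilandmarks(ref, ref, topo)
  expect_equal(out0, ref, tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("surface semilandmarks slide within the neighbour best-fit plane", {
  # neighbours spanning a tilted plane through the origin
  e1 <- c(1, 0, 0.2)
  e2 <- c(0, 1, -0.1)
  nb <- rbind(e1, -e1, e2, -e2)
  kind <- c(rep("fixed", 4), "surface")
  topo <- semilandmark_topology(kind,
                                neighbors = c(vector("list", 4), list(1:4)))
  shape <- rbind(nb, c(0.05, -0.08, 0.3))
  ref <- rbind(nb, c(0.4, 0.3, -0.2))
  out <- slide_semilandmarks(shape, ref, topo)
  disp <- out[5, ] - shape[5, ]
  # displacement lies in the plane spanned by e1, e2
  nrm <- pracma_cross(e1, e2)
  expect_lt(abs(sum(disp * nrm)) / sqrt(sum(nrm^2)), 1e-10)
  # post-slide residual equals residual minus its tangent-plane projection,
  # and matches a brute-force search over in-plane displacements
  resid <- ref[5, ] - shape[5, ]
  obj <- function(ab) {
    cand <- shape[5, ] + ab[1] * e1 / sqrt(sum(e1^2)) +
      ab[2] * e2 / sqrt(sum(e2^2))
    sum((ref[5, ] - cand)^2)
  }
  grid <- expand.grid(a = seq(-1, 1, by = 0.01), b = seq(-1, 1, by = 0.01))
  vals <- apply(grid, 1, obj)
  best <- stats::optim(as.numeric(grid[which.min(vals), ]), obj,
                       control = list(reltol = 1e-14))
  expect_equal(sum((ref[5, ] - out[5, ])^2), best$value, tolerance = 1e-6)
})

test_that("exact-registration: copies of one shape align to mutual distance 0", {
  set.seed(5)
  base <- quad_config()
  s <- toy_specimen_set(n = 3, base = base, noise = 0)
  al <- gpa_align(s, slide = FALSE)
  expect_true(al$converged)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(procrustes_distance(al$coords[, , i], al$coords[, , j],
                                  align_first = FALSE), 1e-8)
  expect_lt(max(abs(apply(al$coords, 3, colMeans))), 1e-10)
  css <- apply(al$coords, 3, function(m) sqrt(sum(m^2)))
  expect_equal(css, rep(1, 3), tolerance = 1e-10)
})

test_that("two-shape GPA matches the direct orthogonal-Procrustes solution", {
  set.seed(9)
  a <- center_and_scale(unit_triangle())$config
  b <- center_and_scale(unit_triangle() +
                          matrix(rnorm(9, sd = 0.3), 3, 3))$config
  s <- toy_specimen_set(n = 2, base = a, noise = 0)
  s$coords[, , 2] <- b
  al <- gpa_align(s, slide = FALSE)
  d12 <- procrustes_distance(al$coords[, , 1], al$coords[, , 2],
                             align_first = FALSE)
  expect_equal(d12, procrustes_distance(a, b, align_first = TRUE),
               tolerance = 1e-6)
  # consensus is the normalised average of the aligned pair
  avg <- (al$coords[, , 1] + al$coords[, , 2]) / 2
  avg <- sweep(avg, 2, colMeans(avg))
  avg <- avg / sqrt(sum(avg^2))
  expect_equal(al$mean_shape, avg, tolerance = 1e-6)
})

test_that("alignment is invariant to specimen order up to global rotation", {
  set.seed(31)
  ds <- generate_dataset(tiny_config(seed = 8))
  s <- subset_specimens(ds$left, 1:12)
  al1 <- gpa_align(s)
  perm <- sample(12)
  al2 <- gpa_align(subset_specimens(s, perm))
  d1 <- as.matrix(dist(t(apply(al1$coords, 3, c))))
  d2 <- as.matrix(dist(t(apply(al2$coords, 3, c))))[order(perm), order(perm)]
  expect_equal(d1, d2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("sliding keeps fixed landmarks bit-exact and reduces SS per pass", {
  ds <- generate_dataset(tiny_config(seed = 4))
  s <- ds$left
  al_ns <- gpa_align(s, slide = FALSE)
  al <- gpa_align(s, slide = TRUE)
  kf <- s$k_fixed
  h <- al$history
  slid <- !is.na(h$ss_before_slide)
  expect_true(any(slid))
  expect_true(all(h$ss_after_slide[slid] <= h$ss_before_slide[slid] + 1e-12))
  # consensus change shrinks to convergence
  expect_true(al$converged)
  expect_lt(h$consensus_change[nrow(h)], 1e-9)
})

test_that("average_replicates collapses (specimen, side) pairs", {
  ds <- generate_dataset(tiny_config(seed = 2))
  al <- gpa_align(ds$left, slide = FALSE)
  avg <- average_replicates(al)
  expect_equal(n_specimens(avg), n_specimens(al) / 2)  # 2 replicates
  expect_true(all(avg$labels$replicate == 1L))
  # identical replicates average to themselves
  s <- toy_specimen_set(n = 2, noise = 0)
  s$labels$specimen_id <- c("a", "a")
  s$labels$species <- c("spA", "spA")
  s$labels$replicate <- 1:2
  al2 <- gpa_align(s, slide = FALSE)
  avg2 <- average_replicates(al2)
  expect_equal(n_specimens(avg2), 1L)
  expect_equal(avg2$coords[, , 1], al2$coords[, , 1], tolerance = 1e-8)
})

test_that("species means average aligned specimens in the requested order", {
  ds <- generate_dataset(tiny_config(seed = 3))
  al <- average_replicates(gpa_align(ds$left, slide = FALSE))
  ord <- rev(unique(al$labels$species))
  ms <- species_means(al, ord)
  expect_identical(ms$species, ord)
  expect_true(all(ms$n_specimens >= 1))
  i <- which(al$labels$species == ord[1])
  m <- apply(al$coords[, , i, drop = FALSE], c(1, 2), mean)
  m <- sweep(m, 2, colMeans(m))
  expect_equal(ms$shapes[, , 1], m / sqrt(sum(m^2)), tolerance = 1e-12)
  expect_error(species_means(al, c(ord, "missing_sp")), "no specimens")
})
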