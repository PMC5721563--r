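# Synthetic-shell generator: template geometry, topology, tree simulation,
# dataset structure, reproducibility, truth recovery.

test_that("template dome follows z = convexity * (1 - r^2)", {
  tv0 <- template_valve(45, convexity = 0)
  expect_true(all(abs(unclass(tv0)[, 3]) < 1e-14))
  tv <- template_valve(45, convexity = 0.37)
  expect_equal(unname(unclass(tv)[6, 3]), 0.37)  # apex point, r = 0
  # outer ring (boundary contour) stays on the commissural plane
  topo <- valve_topology(45)
  expect_true(all(abs(unclass(tv)[topo$kind == "curve", 3]) < 1e-14))
})

test_that("template deformation is monotone in convexity", {
  d_small <- procrustes_distance(template_valve(45, convexity = 0.1),
                                 template_valve(45, convexity = 0.2))
  d_large <- procrustes_distance(template_valve(45, convexity = 0.1),
                                 template_valve(45, convexity = 0.4))
  expect_gt(d_large, d_small)
})

test_that("semilandmark counts must fit the radial grid", {
  expect_error(template_valve(8), "at least 9")
  expect_error(template_valve(12), "n_r")  # 11 = prime, no grid
  expect_silent(template_valve(197))       # the full digitising scheme
  topo <- valve_topology(197)
  expect_equal(length(topo$kind), 202)
  expect_equal(sum(topo$kind == "fixed"), 5)
})

test_that("valve topology is a consistent slide structure", {
  topo <- valve_topology(45)
  expect_equal(length(topo$kind), 50)
  expect_equal(sum(topo$kind == "curve") + sum(topo$kind == "surface"), 45)
  # every semilandmark appears in exactly one role
  for (i in which(topo$kind == "surface"))
    expect_gte(length(topo$neighbors[[i]]), 3)
  for (i in which(topo$kind == "curve")) {
    expect_false(is.na(topo$prev[i]))
    expect_false(is.na(topo$nxt[i]))
  }
  # the boundary curve is a closed cycle
  curve <- which(topo$kind == "curve")
  nxt <- topo$nxt[curve]
  expect_setequal(nxt, curve)
})

test_that("simulate_tree yields deterministic unit-depth binary trees", {
  t1 <- simulate_tree(12, seed = 5)
  t2 <- simulate_tree(12, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 12)
  expect_equal(t1$Nnode, 11)  # binary rooted: n - 1 internal nodes
  depths <- ape::node.depth.edgelength(t1)[1:12]
  expect_equal(max(depths), 1)
  expect_lt(diff(range(depths)), 1e-8)  # ultrametric
  t3 <- simulate_tree(3, seed = 1)
  expect_equal(t3$Nnode, 2)
  # pendant branches are bounded below
  pend <- t1$edge.length[t1$edge[, 2] <= 12]
  expect_gte(min(pend), 0.005)
})

test_that("generated datasets have the configured structure and labels", {
  cfg <- tiny_config(seed = 11)
  ds <- generate_dataset(cfg)
  n_expect <- 12 * 2 * 2  # species x specimens x replicates
  expect_equal(n_specimens(ds$left), n_expect)
  expect_equal(n_specimens(ds$right), n_expect)
  expect_true(all(ds$left$labels$side == "left"))
  expect_true(all(ds$right$labels$side == "right"))
  expect_setequal(unique(ds$left$labels$species), ds$tree$tip.label)
  # ecomorph constant within species and matching the truth
  eco <- tapply(ds$left$labels$ecomorph, ds$left$labels$species,
                function(e) unique(e))
  expect_true(all(lengths(eco) == 1))
  expect_identical(as.character(unlist(eco)[names(ds$truth$ecomorph)]),
                   unname(ds$truth$ecomorph))
  expect_equal(dim(ds$left$coords)[1], 5 + 21)
})

test_that("datasets are bit-reproducible from the seed", {
  ds1 <- generate_dataset(tiny_config(seed = 42))
  ds2 <- generate_dataset(tiny_config(seed = 42))
  expect_identical(ds1$left$coords, ds2$left$coords)
  expect_identical(ds1$right$coords, ds2$right$coords)
  expect_identical(ape::write.tree(ds1$tree), ape::write.tree(ds2$tree))
  d1 <- tempfile()
  d2 <- tempfile()
  write_dataset(ds1, d1)
  write_dataset(ds2, d2)
  h1 <- tools::md5sum(file.path(d1, c("landmarks.csv", "topology.csv",
                                      "tree.nwk")))
  h2 <- tools::md5sum(file.path(d2, c("landmarks.csv", "topology.csv",
                                      "tree.nwk")))
  expect_identical(unname(h1), unname(h2))
  ds3 <- generate_dataset(tiny_config(seed = 43))
  expect_false(identical(ds1$left$coords, ds3$left$coords))
})

test_that("emitted dataset files read back into the same data", {
  ds <- generate_dataset(tiny_config(seed = 13))
  d <- tempfile()
  paths <- write_dataset(ds, d)
  both <- read_landmarks_csv(paths[["landmarks"]],
                             topology = paths[["topology"]])
  expect_equal(n_specimens(both),
               n_specimens(ds$left) + n_specimens(ds$right))
  tr <- read_newick(paths[["tree"]])
  expect_setequal(tr$tip.label, ds$tree$tip.label)
})

test_that("degenerate limit: no noise, full integration, no offsets gives DA 0", {
  cfg <- tiny_config(seed = 21, n_specimens_per_species = 1,
                     integration_rho = 1, valve_rate_ratio = 1,
                     valve_rate_base = 1, da_offset = 0,
                     specimen_noise_sd = 0, replicate_noise_sd = 0)
  ds <- generate_dataset(cfg)
  # right valves are exact mirrors of left valves
  expect_equal(ds$right$coords[, 1, 1], -ds$left$coords[, 1, 1],
               tolerance = 1e-12)
  al <- joint_superimpose(ds$left, ds$right)
  da <- asymmetry_magnitude(al)
  expect_lt(max(da$specimens$da), 1e-8)
  expect_equal(max(ds$truth$da_true), 0, tolerance = 1e-8)
})

test_that("with zero noise, species means recover the latent-driven shapes", {
  cfg <- tiny_config(seed = 22, n_specimens_per_species = 2,
                     specimen_noise_sd = 0, replicate_noise_sd = 0)
  ds <- generate_dataset(cfg)
  al <- average_replicates(gpa_align(ds$left, slide = FALSE))
  ms <- species_means(al, ds$tree$tip.label)
  for (i in seq_along(ms$species)) {
    truth_shape <- do.call(
      template_valve,
      c(list(cfg$k_semi), as.list(ds$truth$theta_left[ms$species[i], ])))
    expect_lt(procrustes_distance(ms$shapes[, , i],
                                  as_coord_matrix(truth_shape)), 1e-8)
  }
})

test_that("raising one group's rate multiplier raises its estimated rate", {
  ests <- sapply(c(1, 2, 4), function(mult) {
    vals <- numeric(8)
    for (b in seq_len(8)) {
      cfg <- tiny_config(seed = 300 + b,
                         group_rate_multipliers = c(
                           cementing = 1, nestling = 1,
                           `byssal-attaching` = 1, recessing = mult,
                           `free-living` = 1, gliding = 1),
                         valve_rate_ratio = 1, valve_rate_base = 1,
                         da_offset = 0)
      ds <- generate_dataset(cfg)
      al <- average_replicates(gpa_align(ds$left, slide = FALSE))
      Y <- shape_matrix(species_means(al, ds$tree$tip.label))
      C <- phylo_covariance(ds$tree)
      U <- phylo_transform(Y, C)$U
      g <- ds$truth$ecomorph[rownames(Y)]
      ss <- rowSums(U^2)
      vals[b] <- sum(ss[g == "recessing"]) / sum(g == "recessing")
    }
    mean(vals)
  })
  expect_gt(ests[2], ests[1])
  expect_gt(ests[3], ests[2])
})
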