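# Landmark/tree IO: round trips, validation, pruning.

make_csv_set <- function(n_specimens = 2, k_semi = 21) {
  topo <- valve_topology(k_semi)
  base <- as_coord <- template_valve(k_semi)
  k <- 5 + k_semi
  coords <- array(NA_real_, c(k, 3, n_specimens))
  set.seed(99)
  for (i in seq_len(n_specimens))
    coords[, , i] <- unclass(base) + matrix(rnorm(k * 3, sd = 0.01), k, 3)
  labels <- data.frame(specimen_id = paste0("spec", seq_len(n_specimens)),
                       species = paste0("sp", seq_len(n_specimens)),
                       side = "left", replicate = 1L,
                       ecomorph = "recessing", stringsAsFactors = FALSE)
  specimen_set(coords, labels, topology = topo)
}

test_that("landmark CSV round-trips coordinates, labels and topology", {
  s <- make_csv_set()
  csv <- tempfile(fileext = ".csv")
  topo_csv <- tempfile(fileext = ".csv")
  write_landmarks_csv(s, csv, topology_path = topo_csv)
  s2 <- read_landmarks_csv(csv, topology = topo_csv)
  expect_equal(s2$coords, s$coords, tolerance = 1e-12)
  expect_identical(s2$labels$specimen_id, s$labels$specimen_id)
  expect_identical(s2$labels$ecomorph, s$labels$ecomorph)
  expect_identical(s2$k_fixed, s$k_fixed)
  expect_identical(s2$topology$kind, s$topology$kind)
  expect_identical(s2$topology$neighbors, s$topology$neighbors)
  # second round trip is exact
  csv2 <- tempfile(fileext = ".csv")
  write_landmarks_csv(s2, csv2)
  s3 <- read_landmarks_csv(csv2, topology = topo_csv)
  expect_identical(s3$coords, s2$coords)
})

test_that("landmark CSV enforces its format contract", {
  s <- make_csv_set()
  csv <- tempfile(fileext = ".csv")
  write_landmarks_csv(s, csv)
  df <- read.csv(csv)
  # missing column
  bad <- tempfile(fileext = ".csv")
  write.csv(df[, setdiff(names(df), "ecomorph")], bad, row.names = FALSE)
  expect_error(read_landmarks_csv(bad), "missing column")
  # ragged landmark counts
  write.csv(df[-1, ], bad, row.names = FALSE)
  expect_error(read_landmarks_csv(bad), "ragged|1\\.\\.k")
  # non-finite coordinate names the specimen
  df2 <- df
  df2$x[3] <- NA
  write.csv(df2, bad, row.names = FALSE)
  expect_error(read_landmarks_csv(bad), "spec1")
})

test_that("minimal 3-landmark CSV with no semilandmarks reads back", {
  df <- data.frame(specimen_id = "a", species = "spA", side = "left",
                   replicate = 1, ecomorph = "gliding",
                   landmark_index = 1:3,
                   x = c(0, 1, 0), y = c(0, 0, 1), z = c(0, 0, 0))
  csv <- tempfile(fileext = ".csv")
  write.csv(df, csv, row.names = FALSE)
  s <- read_landmarks_csv(csv)
  expect_equal(dim(s$coords), c(3, 3, 1))
  expect_identical(s$k_fixed, 3L)  # no topology: all points fixed
})

test_that("TPS files round-trip and reject the 2D dialect", {
  s <- make_csv_set()
  tps <- tempfile(fileext = ".tps")
  write_tps(s, tps)
  s2 <- read_tps(tps, metadata = s$labels, topology = s$topology)
  expect_equal(s2$coords, s$coords, tolerance = 1e-12)
  expect_identical(s2$labels, s$labels)

  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=x"), tps)
  expect_error(read_tps(tps, metadata = s$labels), "2D|LM3")

  writeLines(c("LM3=4", "0 0 0", "1 0 0", "0 1 0", "ID=x"), tps)
  md <- data.frame(specimen_id = "x", species = "spX", side = "left",
                   replicate = 1, ecomorph = "gliding")
  expect_error(read_tps(tps, metadata = md), "4 but 3|format")
})

test_that("TPS SCALE= records are applied multiplicatively", {
  tps <- tempfile(fileext = ".tps")
  writeLines(c("LM3=3", "0 0 0", "2 0 0", "0 2 0", "ID=x", "SCALE=0.5"),
             tps)
  md <- data.frame(specimen_id = "x", species = "spX", side = "left",
                   replicate = 1, ecomorph = "gliding")
  s <- read_tps(tps, metadata = md)
  expect_equal(s$coords[2, 1, 1], 1)
})

test_that("read_newick parses, validates and warns on non-ultrametric trees", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", nwk)
  tr <- read_newick(nwk)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(max(ape::node.depth.edgelength(tr)), 1)

  writeLines("((A:1,B:1):1,C:2);", nwk)
  expect_silent(tr3 <- read_newick(nwk))
  expect_equal(ape::Ntip(tr3), 3)

  writeLines("((A:1,B:2):1,C:2);", nwk)
  expect_warning(read_newick(nwk), "ultrametric")

  writeLines("((A:1,B:1):1,C);", nwk)
  expect_error(suppressWarnings(read_newick(nwk)), "branch length")
})

test_that("prune_to_common drops unshared species on both sides", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("(((spA:1,spB:1):1,spC:2):1,spD:3);", nwk)
  tr <- read_newick(nwk)
  s <- make_csv_set(3)  # species sp1..sp3; rename to overlap
  s$labels$species <- c("spA", "spB", "spC")
  s$labels$ecomorph <- "recessing"
  pr <- prune_to_common(tr, s)
  expect_setequal(pr$tree$tip.label, c("spA", "spB", "spC"))
  expect_identical(pr$species, pr$tree$tip.label)
  # extra specimen species gets dropped from the data
  s4 <- make_csv_set(4)
  s4$labels$species <- c("spA", "spB", "spC", "spZ")
  pr2 <- prune_to_common(tr, s4)
  expect_false("spZ" %in% pr2$data$labels$species)
  expect_setequal(pr2$tree$tip.label, c("spA", "spB", "spC"))
  # fewer than 3 shared species is an error
  s$labels$species <- c("spX", "spY", "spZ")
  expect_error(prune_to_common(tr, s), "insufficient overlap")
})

test_that("pruning collapses degree-2 nodes conserving root-to-tip paths", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  s <- make_csv_set(3)
  s$labels$species <- c("A", "C", "D")
  pr <- prune_to_common(tr, s)
  C <- phylo_covariance(pr$tree)
  expect_equal(unname(diag(C)[c("A", "C", "D")]), c(3, 3, 3))
  expect_equal(C["A", "C"], 1)
  # idempotent
  pr2 <- prune_to_common(pr$tree, pr$data)
  expect_equal(pr2$tree, pr$tree)
  expect_identical(pr2$data$labels, pr$data$labels)
})

test_that("specimen_set validates label invariants", {
  s <- make_csv_set(2)
  lab <- s$labels
  lab$specimen_id <- c("a", "a")
  lab$species <- c("sp1", "sp1")
  expect_error(specimen_set(s$coords, lab, topology = s$topology),
               "unique")
  lab$specimen_id <- c("a", "b")
  lab$ecomorph <- c("gliding", "recessing")
  expect_error(specimen_set(s$coords, lab, topology = s$topology),
               "constant within a species")
  lab$ecomorph <- c("gliding", "flying")[c(1, 2)]
  lab$species <- c("sp1", "sp2")
  expect_error(specimen_set(s$coords, lab, topology = s$topology),
               "unknown ecomorph")
})
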