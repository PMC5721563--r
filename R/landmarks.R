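# Landmark containers and file formats.
#
# A single valve is a k x 3 coordinate matrix ("landmark_config") whose first
# k_fixed rows are fixed anatomical landmarks and whose remaining rows are
# semilandmarks. A study sample is a "specimen_set": a k x 3 x n array plus a
# parallel label table (specimen_id, species, side, replicate, ecomorph) and a
# semilandmark topology shared by all configurations.

#' Construct a landmark configuration
#'
#' @param coords Numeric k x 3 matrix of landmark coordinates (columns x, y,
#'   z). All values must be finite and k must be at least 3.
#' @param k_fixed Number of fixed landmarks; these occupy the first `k_fixed`
#'   rows, the remaining rows are semilandmarks.
#' @return A `landmark_config`: the coordinate matrix with a `k_fixed`
#'   attribute.
#' @export
landmark_config <- function(coords, k_fixed = nrow(coords)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) < 3L) stop("a configuration needs at least 3 landmarks")
  if (!all(is.finite(coords))) stop("non-finite coordinate in configuration")
  if (k_fixed < 0L || k_fixed > nrow(coords)) stop("invalid k_fixed")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(coords, k_fixed = as.integer(k_fixed), class = "landmark_config")
}

as_coord_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "k_fixed") <- NULL
  as.matrix(m)
}

#' Construct a semilandmark topology
#'
#' Describes how each point of a configuration is allowed to move during
#' sliding: `fixed` points never move, `curve` points slide along the chord
#' between two along-curve neighbours, and `surface` points slide within the
#' best-fit plane of a neighbour set.
#'
#' @param kind Character vector of length k with values `"fixed"`, `"curve"`
#'   or `"surface"`. Fixed points must occupy the leading indices.
#' @param prev,nxt Integer vectors of length k giving the along-curve
#'   neighbours of curve points (`NA` elsewhere).
#' @param neighbors List of length k; for surface points an integer vector of
#'   at least 3 neighbour indices, `NULL` elsewhere.
#' @return A `semilandmark_topology` object.
#' @export
semilandmark_topology <- function(kind, prev = NULL, nxt = NULL,
                                  neighbors = NULL) {
  k <- length(kind)
  if (!all(kind %in% c("fixed", "curve", "surface")))
    stop("topology kind must be fixed, curve or surface")
  n_fixed <- sum(kind == "fixed")
  if (n_fixed > 0 && !all(kind[seq_len(n_fixed)] == "fixed"))
    stop("fixed landmarks must occupy the first indices")
  if (is.null(prev)) prev <- rep(NA_integer_, k)
  if (is.null(nxt)) nxt <- rep(NA_integer_, k)
  if (is.null(neighbors)) neighbors <- vector("list", k)
  for (i in seq_len(k)) {
    if (kind[i] == "curve") {
      if (is.na(prev[i]) || is.na(nxt[i]) ||
          prev[i] < 1 || prev[i] > k || nxt[i] < 1 || nxt[i] > k ||
          prev[i] == i || nxt[i] == i)
        stop("curve point ", i, " needs valid prev/next neighbours")
    } else if (kind[i] == "surface") {
      nb <- neighbors[[i]]
      if (length(nb) < 3L || any(nb < 1 | nb > k) || any(nb == i))
        stop("surface point ", i, " needs >= 3 valid neighbours")
    }
  }
  structure(list(kind = kind, prev = as.integer(prev), nxt = as.integer(nxt),
                 neighbors = neighbors),
            class = "semilandmark_topology")
}

#' @export
print.semilandmark_topology <- function(x, ...) {
  cat("semilandmark topology:", sum(x$kind == "fixed"), "fixed,",
      sum(x$kind == "curve"), "curve,", sum(x$kind == "surface"),
      "surface points\n")
  invisible(x)
}

topology_k_fixed <- function(topology) sum(topology$kind == "fixed")

#' Build a topology from a descriptor table
#'
#' The descriptor is a data frame (or CSV, see [read_topology_csv()]) with
#' columns `index`, `kind` and `neighbors`, the latter a semicolon-separated
#' index list: `prev;next` for curve points, three or more indices for
#' surface points, empty for fixed landmarks.
#'
#' @param df Data frame with columns `index`, `kind`, `neighbors`.
#' @return A [semilandmark_topology()].
#' @export
topology_from_descriptor <- function(df) {
  need <- c("index", "kind", "neighbors")
  if (!all(need %in% names(df)))
    stop("topology descriptor must have columns: ",
         paste(need, collapse = ", "))
  df <- df[order(df$index), , drop = FALSE]
  k <- nrow(df)
  if (!identical(as.integer(df$index), seq_len(k)))
    stop("topology descriptor indices must be 1..k without gaps")
  kind <- as.character(df$kind)
  prev <- rep(NA_integer_, k)
  nxt <- rep(NA_integer_, k)
  neighbors <- vector("list", k)
  for (i in seq_len(k)) {
    nb <- df$neighbors[i]
    ids <- if (is.na(nb) || !nzchar(nb)) integer(0)
           else as.integer(strsplit(as.character(nb), ";", fixed = TRUE)[[1]])
    if (kind[i] == "curve") {
      if (length(ids) != 2L) stop("curve point ", i, " needs 'prev;next'")
      prev[i] <- ids[1]
      nxt[i] <- ids[2]
    } else if (kind[i] == "surface") {
      neighbors[[i]] <- ids
    }
  }
  semilandmark_topology(kind, prev, nxt, neighbors)
}

topology_to_descriptor <- function(topology) {
  k <- length(topology$kind)
  nb <- character(k)
  for (i in seq_len(k)) {
    nb[i] <- switch(topology$kind[i],
      fixed = "",
      curve = paste(topology$prev[i], topology$nxt[i], sep = ";"),
      surface = paste(topology$neighbors[[i]], collapse = ";"))
  }
  data.frame(index = seq_len(k), kind = topology$kind, neighbors = nb,
             stringsAsFactors = FALSE)
}

#' Read / write a semilandmark topology descriptor CSV
#'
#' @param path File path.
#' @return `read_topology_csv()` returns a [semilandmark_topology()].
#' @export
read_topology_csv <- function(path) {
  topology_from_descriptor(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_topology_csv
#' @param topology A [semilandmark_topology()].
#' @export
write_topology_csv <- function(topology, path) {
  write.csv(topology_to_descriptor(topology), path, row.names = FALSE)
  invisible(path)
}

validate_labels <- function(labels) {
  need <- c("specimen_id", "species", "side", "replicate", "ecomorph")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    stop("label table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(labels$side %in% c("left", "right")))
    stop("side must be 'left' or 'right'")
  if (any(labels$replicate < 1)) stop("replicate must be a positive integer")
  bad <- setdiff(unique(labels$ecomorph), ecomorph_levels())
  if (length(bad))
    stop("unknown ecomorph value(s): ", paste(bad, collapse = ", "))
  key <- paste(labels$specimen_id, labels$side, labels$replicate)
  if (anyDuplicated(key))
    stop("(specimen_id, side, replicate) must be unique within a set")
  eco_by_sp <- tapply(labels$ecomorph, labels$species,
                      function(e) length(unique(e)))
  if (any(eco_by_sp > 1))
    stop("ecomorph must be constant within a species: ",
         paste(names(eco_by_sp)[eco_by_sp > 1], collapse = ", "))
  invisible(labels)
}

#' Construct a specimen set
#'
#' @param coords Numeric k x 3 x n array of configurations.
#' @param labels Data frame with one row per configuration and columns
#'   `specimen_id`, `species`, `side` (`"left"`/`"right"`), `replicate`
#'   (positive integer) and `ecomorph` (one of [ecomorph_levels()]).
#' @param k_fixed Number of fixed landmarks (leading rows of each
#'   configuration). Defaults to the topology's count, or all points when no
#'   topology is given.
#' @param topology Optional [semilandmark_topology()] shared by all
#'   configurations.
#' @return A `specimen_set`: list with elements `coords`, `labels`,
#'   `k_fixed`, `topology`.
#' @export
specimen_set <- function(coords, labels, k_fixed = NULL, topology = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be a k x 3 x n array")
  n <- dim(coords)[3]
  k <- dim(coords)[1]
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (nrow(labels) != n)
    stop("labels must have one row per configuration")
  validate_labels(labels)
  if (!all(is.finite(coords))) {
    bad <- which(apply(coords, 3, function(m) any(!is.finite(m))))[1]
    stop("non-finite coordinate in specimen ", labels$specimen_id[bad],
         " (", labels$side[bad], ", replicate ", labels$replicate[bad], ")")
  }
  if (!is.null(topology)) {
    if (length(topology$kind) != k)
      stop("topology length does not match landmark count")
    if (is.null(k_fixed)) k_fixed <- topology_k_fixed(topology)
    if (k_fixed != topology_k_fixed(topology))
      stop("k_fixed disagrees with topology")
  }
  if (is.null(k_fixed)) k_fixed <- k
  if (k < 3L) stop("configurations need at least 3 landmarks")
  structure(list(coords = coords, labels = labels,
                 k_fixed = as.integer(k_fixed), topology = topology),
            class = "specimen_set")
}

#' @export
print.specimen_set <- function(x, ...) {
  k <- dim(x$coords)[1]
  cat(sprintf("specimen_set: %d configurations, %d landmarks (%d fixed, %d semi), %d species\n",
              dim(x$coords)[3], k, x$k_fixed, k - x$k_fixed,
              length(unique(x$labels$species))))
  invisible(x)
}

#' Number of configurations in a set
#' @param x A `specimen_set`.
#' @return Integer count.
#' @export
n_specimens <- function(x) dim(x$coords)[3]

#' Subset a specimen set by configuration index
#'
#' @param x A `specimen_set`.
#' @param idx Integer index vector (duplicates allowed, e.g. for bootstrap
#'   resampling; specimen ids of duplicated rows are disambiguated).
#' @return A `specimen_set` with the selected configurations.
#' @export
subset_specimens <- function(x, idx) {
  labels <- x$labels[idx, , drop = FALSE]
  if (anyDuplicated(paste(labels$specimen_id, labels$side, labels$replicate))) {
    reps <- stats::ave(seq_along(idx), idx, FUN = seq_along)
    dup <- reps > 1
    labels$specimen_id[dup] <- paste0(labels$specimen_id[dup], "#", reps[dup])
  }
  rownames(labels) <- NULL
  out <- x
  out$coords <- x$coords[, , idx, drop = FALSE]
  out$labels <- labels
  out
}

# ---- landmark CSV (long format) --------------------------------------------

LANDMARK_CSV_COLS <- c("specimen_id", "species", "side", "replicate",
                       "ecomorph", "landmark_index", "x", "y", "z")

#' Read landmark data from a long-format CSV
#'
#' One row per landmark with columns `specimen_id`, `species`, `side`,
#' `replicate`, `ecomorph`, `landmark_index`, `x`, `y`, `z`. All
#' configurations must have the same landmark count; the semilandmark
#' topology comes from a companion descriptor (see [read_topology_csv()]).
#'
#' @param path Path to the CSV file.
#' @param topology A [semilandmark_topology()], a path to a descriptor CSV,
#'   or `NULL` (all points treated as fixed).
#' @return A [specimen_set()].
#' @export
read_landmarks_csv <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(LANDMARK_CSV_COLS, names(df))
  if (length(miss))
    stop("landmark CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (is.character(topology)) topology <- read_topology_csv(topology)
  key <- paste(df$specimen_id, df$side, df$replicate, sep = "\r")
  key <- factor(key, levels = unique(key))
  counts <- table(key)
  if (length(unique(counts)) != 1L)
    stop("ragged landmark counts across specimens: ",
         paste(unique(counts), collapse = " vs "))
  k <- as.integer(counts[1])
  n <- nlevels(key)
  coords <- array(NA_real_, c(k, 3, n))
  labels <- df[!duplicated(key), c("specimen_id", "species", "side",
                                   "replicate", "ecomorph")]
  rownames(labels) <- NULL
  groups <- split(seq_len(nrow(df)), key)
  for (i in seq_len(n)) {
    rows <- groups[[i]]
    sub <- df[rows, , drop = FALSE]
    ord <- order(sub$landmark_index)
    sub <- sub[ord, , drop = FALSE]
    if (!identical(as.integer(sub$landmark_index), seq_len(k)))
      stop("specimen ", sub$specimen_id[1], " (", sub$side[1],
           "): landmark_index must cover 1..k")
    coords[, , i] <- cbind(sub$x, sub$y, sub$z)
  }
  specimen_set(coords, labels, topology = topology)
}

#' Write a specimen set to the long-format landmark CSV
#'
#' @param x A [specimen_set()] (or aligned set).
#' @param path Output CSV path.
#' @param topology_path Optional path for the companion topology descriptor.
#' @param aligned If `TRUE`, an `aligned` column (value `true`) is added to
#'   mark coordinates as superimposed.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(x, path, topology_path = NULL,
                                aligned = FALSE) {
  k <- dim(x$coords)[1]
  n <- dim(x$coords)[3]
  lab <- x$labels[rep(seq_len(n), each = k), , drop = FALSE]
  df <- data.frame(lab,
                   landmark_index = rep(seq_len(k), n),
                   x = as.vector(x$coords[, 1, ]),
                   y = as.vector(x$coords[, 2, ]),
                   z = as.vector(x$coords[, 3, ]),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[, c(LANDMARK_CSV_COLS)]
  if (aligned) df$aligned <- "true"
  write.csv(df, path, row.names = FALSE)
  if (!is.null(topology_path) && !is.null(x$topology))
    write_topology_csv(x$topology, topology_path)
  invisible(path)
}

# ---- TPS -------------------------------------------------------------------

#' Read 3D landmark data from a TPS file
#'
#' Only the 3D dialect is accepted: records start with `LM3=k`, followed by k
#' whitespace-separated coordinate triples, with `ID=` naming the specimen
#' and an optional `SCALE=` factor applied multiplicatively. 2D `LM=` records
#' raise an error. Specimen metadata (species, side, replicate, ecomorph)
#' comes from a sidecar table keyed by `specimen_id`, since TPS itself cannot
#' carry it.
#'
#' @param path Path to the TPS file.
#' @param metadata Data frame (or CSV path) with columns `specimen_id`,
#'   `species`, `side`, `replicate`, `ecomorph`.
#' @param topology As in [read_landmarks_csv()].
#' @return A [specimen_set()].
#' @export
read_tps <- function(path, metadata, topology = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(metadata)) metadata <- read.csv(metadata,
                                                   stringsAsFactors = FALSE)
  if (is.character(topology)) topology <- read_topology_csv(topology)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  configs <- list()
  ids <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^LM3=", ln, ignore.case = TRUE)) {
      k <- as.integer(sub("^LM3=", "", ln, ignore.case = TRUE))
      pts <- matrix(NA_real_, k, 3)
      j <- 0L
      i <- i + 1L
      while (j < k && i <= length(lines) &&
             !grepl("^(LM3?=|ID=|SCALE=)", lines[i], ignore.case = TRUE)) {
        vals <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
        if (length(vals) != 3L)
          stop("TPS format error: expected 3 coordinates per line")
        j <- j + 1L
        pts[j, ] <- vals
        i <- i + 1L
      }
      if (j != k)
        stop("TPS format error: LM3=", k, " but ", j, " points found")
      id <- NA_character_
      scale <- 1
      while (i <= length(lines) &&
             grepl("^(ID=|SCALE=)", lines[i], ignore.case = TRUE)) {
        if (grepl("^ID=", lines[i], ignore.case = TRUE))
          id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
        else
          scale <- as.numeric(sub("^SCALE=", "", lines[i],
                                  ignore.case = TRUE))
        i <- i + 1L
      }
      if (is.na(id)) id <- paste0("specimen_", length(configs) + 1L)
      configs[[length(configs) + 1L]] <- pts * scale
      ids <- c(ids, id)
    } else if (grepl("^LM=", ln, ignore.case = TRUE)) {
      stop("unsupported TPS dialect: 2D LM= records (only LM3= is accepted)")
    } else {
      i <- i + 1L
    }
  }
  if (!length(configs)) stop("no LM3= records found in ", path)
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("ragged landmark counts across TPS records")
  coords <- array(unlist(configs), c(ks[1], 3, length(configs)))
  # TPS coordinate lines are x y z per landmark (row-wise); unlist of a k x 3
  # matrix is column-major, which matches the array layout used here.
  m <- match(ids, metadata$specimen_id)
  if (anyNA(m))
    stop("metadata missing for specimen(s): ",
         paste(ids[is.na(m)], collapse = ", "))
  labels <- metadata[m, c("specimen_id", "species", "side", "replicate",
                          "ecomorph")]
  rownames(labels) <- NULL
  specimen_set(coords, labels, topology = topology)
}

#' Write a specimen set to a 3D TPS file
#'
#' @param x A [specimen_set()].
#' @param path Output path.
#' @return `path`, invisibly. The label table is not written; pair the file
#'   with a metadata CSV for [read_tps()].
#' @export
write_tps <- function(x, path) {
  k <- dim(x$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dim(x$coords)[3])) {
    writeLines(paste0("LM3=", k), con)
    m <- x$coords[, , i]
    writeLines(paste(format(m[, 1], digits = 17, trim = TRUE, scientific = FALSE),
                     format(m[, 2], digits = 17, trim = TRUE, scientific = FALSE),
                     format(m[, 3], digits = 17, trim = TRUE, scientific = FALSE)),
               con)
    writeLines(paste0("ID=", x$labels$specimen_id[i]), con)
  }
  invisible(path)
}

# ---- trees -----------------------------------------------------------------

#' Read a rooted, time-calibrated tree from a Newick file
#'
#' @param path Path to a Newick file containing a single rooted tree with
#'   branch lengths.
#' @param ultrametric_tol Relative tolerance on tip-depth spread before a
#'   non-ultrametricity warning is issued (empirical chronograms carry
#'   rounding noise, so this is a warning, not an error).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, ultrametric_tol = 1e-6) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1]]
  }
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  check_phylogeny(tr, ultrametric_tol)
  tr
}

check_phylogeny <- function(tr, ultrametric_tol = 1e-6) {
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("tree format error: missing branch length(s)")
  if (any(tr$edge.length <= 0))
    stop("tree format error: all branch lengths must be > 0")
  if (anyDuplicated(tr$tip.label)) stop("tip names must be unique")
  depths <- tip_depths(tr)
  if (diff(range(depths)) > ultrametric_tol * max(depths))
    warning("tree is not ultrametric (tip depth range ",
            signif(diff(range(depths)), 3), " exceeds tolerance)")
  invisible(tr)
}

tip_depths <- function(tr) {
  d <- ape::node.depth.edgelength(tr)
  d[seq_len(ape::Ntip(tr))]
}

#' Prune a tree and a specimen set to their shared species
#'
#' Tips absent from the data are dropped (degree-2 nodes collapsed with
#' branch lengths summed, preserving root-to-tip path lengths), and
#' specimens of species absent from the tree are removed. The pruned tree's
#' tip order is the species order used for all downstream species-by-trait
#' matrices.
#'
#' @param tree A `phylo` tree.
#' @param data A [specimen_set()].
#' @return List with elements `tree`, `data` and `species` (the recorded
#'   species order).
#' @export
prune_to_common <- function(tree, data) {
  shared <- intersect(tree$tip.label, unique(data$labels$species))
  if (length(shared) < 3L)
    stop("insufficient overlap: only ", length(shared),
         " species shared between tree and data (need >= 3)")
  tree2 <- if (length(shared) < ape::Ntip(tree))
    ape::keep.tip(tree, shared) else tree
  keep <- data$labels$species %in% shared
  data2 <- if (all(keep)) data else subset_specimens(data, which(keep))
  list(tree = tree2, data = data2, species = tree2$tip.label)
}
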