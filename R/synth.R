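# Synthetic-shell generator.
#
# Emulates the structure of a multi-species museum sample of scallop
# valves: a clade of species in six ecomorphs whose valve shapes evolve on
# a pure-birth chronogram under Brownian motion of a small set of latent
# shape parameters (convexity, outline eccentricity, auricle proportions,
# ...), with group-specific rate multipliers on terminal branches,
# controllable left-right integration and directional-asymmetry offsets,
# per-specimen latent noise and per-replicate digitising noise. The latent
# to landmark map is smooth and fixed, so latent Brownian motion induces
# approximately Brownian landmark evolution.

LATENT_NAMES <- c("convexity", "eccentricity", "auricle_width",
                  "auricle_height", "umbo_height", "skew",
                  "apex_dx", "apex_dy", "flare", "tilt")

LATENT_BASE <- c(convexity = 0.30, eccentricity = 0.05, auricle_width = 0.45,
                 auricle_height = 0.18, umbo_height = 0.12, skew = 0,
                 apex_dx = 0, apex_dy = 0, flare = 0, tilt = 0)

default_ecomorph_counts <- function(n_species) {
  base <- c(cementing = 2, nestling = 1, `byssal-attaching` = 48,
            recessing = 11, `free-living` = 18, gliding = 6)
  if (n_species == 86L) return(base)
  # proportional allocation, at least 1 species per ecomorph
  raw <- base / sum(base) * n_species
  counts <- pmax(floor(raw), 1L)
  while (sum(counts) < n_species) {
    i <- which.max(raw - counts)
    counts[i] <- counts[i] + 1L
  }
  while (sum(counts) > n_species) {
    i <- which.max(counts)
    counts[i] <- counts[i] - 1L
  }
  counts
}

#' Configuration of the synthetic-shell generator
#'
#' Defaults emulate the study design the generator stands in for: 86
#' species in six ecomorphs (2 cementing, 1 nestling, 48 byssal-attaching,
#' 11 recessing, 18 free-living, 6 gliding), 2-14 specimens per species
#' (about 8 on average, matching a 669-shell sample), two digitising
#' replicates per valve, 5 fixed landmarks, rate multipliers elevated for
#' the gliding/recessing/nestling ecomorphs, right valves evolving faster
#' than left, and directional-asymmetry offsets largest for recessing and
#' smallest for gliding species.
#'
#' @param n_species Number of species (default 86).
#' @param ecomorph_counts Named species counts per ecomorph summing to
#'   `n_species` (default: the study proportions, rescaled if `n_species`
#'   differs from 86).
#' @param n_specimens_per_species Single count, or length-2 range sampled
#'   uniformly per species (default `c(2, 14)`).
#' @param n_replicates Digitising replicates per valve (default 2).
#' @param k_semi Number of semilandmarks per valve; must be `1 + n_r * n_s`
#'   for a radial grid (default 45; 197 mirrors the full digitising
#'   scheme).
#' @param group_rate_multipliers Named per-ecomorph multipliers of the
#'   latent Brownian rate, applied on terminal branches.
#' @param valve_rate_ratio Named per-ecomorph ratio of right- to left-valve
#'   latent rate on terminal branches (any positive value; a single unnamed
#'   number is recycled). Defaults are calibrated so the observed
#'   within-ecomorph right/left rate ratios match the study pattern
#'   (nestling by far the largest, then gliding and cementing, free-living
#'   slightly below 1).
#' @param valve_rate_base Right/left latent rate ratio on internal branches
#'   (default 1.2, the across-species excess of right-valve evolution).
#' @param da_offset Named per-ecomorph left-right convexity offset (the
#'   directional-asymmetry signal); a single number is recycled to all
#'   ecomorphs.
#' @param integration_rho Latent left-right integration in `[0, 1]`
#'   (default 0.95).
#' @param specimen_noise_sd Latent SD of individual (within-species)
#'   variation (default 0.01).
#' @param replicate_noise_sd Coordinate SD of digitising error per
#'   replicate (default 0.002).
#' @param latent_rate Base Brownian variance per unit tree depth of each
#'   latent parameter (default 0.0012).
#' @param birth_rate Pure-birth speciation rate for the simulated tree
#'   (default 1; the tree is rescaled to unit depth regardless).
#' @param seed Integer seed; the whole dataset is bit-reproducible from
#'   (config, seed).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_species = 86,
                             ecomorph_counts = NULL,
                             n_specimens_per_species = c(2, 14),
                             n_replicates = 2,
                             k_semi = 45,
                             group_rate_multipliers = c(
                               cementing = 1.0, nestling = 1.0,
                               `byssal-attaching` = 1, recessing = 5.5,
                               `free-living` = 2.4, gliding = 5.5),
                             valve_rate_ratio = c(
                               cementing = 2.2, nestling = 12.8,
                               `byssal-attaching` = 0.7, recessing = 1.8,
                               `free-living` = 0.75, gliding = 2.2),
                             valve_rate_base = 1.2,
                             da_offset = c(
                               cementing = 0.06, nestling = 0.08,
                               `byssal-attaching` = 0.02, recessing = 0.10,
                               `free-living` = 0.02, gliding = 0.01),
                             integration_rho = 0.95,
                             specimen_noise_sd = 0.01,
                             replicate_noise_sd = 0.002,
                             latent_rate = 0.0012,
                             birth_rate = 1,
                             seed = 1L) {
  if (is.null(ecomorph_counts))
    ecomorph_counts <- default_ecomorph_counts(n_species)
  if (sum(ecomorph_counts) != n_species)
    stop("ecomorph_counts must sum to n_species")
  if (!all(names(ecomorph_counts) %in% ecomorph_levels()))
    stop("unknown ecomorph in ecomorph_counts")
  recycle <- function(v) {
    if (length(v) == 1L && is.null(names(v)))
      setNames(rep(v, 6), ecomorph_levels()) else v
  }
  group_rate_multipliers <- recycle(group_rate_multipliers)
  valve_rate_ratio <- recycle(valve_rate_ratio)
  da_offset <- recycle(da_offset)
  if (valve_rate_base <= 0) stop("valve_rate_base must be positive")
  for (nm in c("group_rate_multipliers", "valve_rate_ratio", "da_offset")) {
    v <- get(nm)
    miss <- setdiff(names(ecomorph_counts), names(v))
    if (length(miss)) stop(nm, " missing ecomorph(s): ",
                           paste(miss, collapse = ", "))
  }
  if (integration_rho < 0 || integration_rho > 1)
    stop("integration_rho must be in [0, 1]")
  if (any(valve_rate_ratio <= 0))
    stop("valve_rate_ratio must be positive")
  if (specimen_noise_sd < 0 || replicate_noise_sd < 0)
    stop("noise SDs must be >= 0")
  structure(list(n_species = as.integer(n_species),
                 ecomorph_counts = ecomorph_counts,
                 n_specimens_per_species = n_specimens_per_species,
                 n_replicates = as.integer(n_replicates),
                 k_fixed = 5L, k_semi = as.integer(k_semi),
                 group_rate_multipliers = group_rate_multipliers,
                 valve_rate_ratio = valve_rate_ratio,
                 valve_rate_base = valve_rate_base,
                 da_offset = da_offset,
                 integration_rho = integration_rho,
                 specimen_noise_sd = specimen_noise_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 latent_rate = latent_rate,
                 birth_rate = birth_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Reduced paper-pattern preset
#'
#' The default [generator_config()] (which carries the study's qualitative
#' pattern: elevated rates for gliding/recessing/nestling, right valves
#' faster than left, recessing most asymmetric and gliding least) at a
#' reduced size suitable for fast simulation studies: a fixed number of
#' specimens per species and the 45-semilandmark valve template.
#'
#' @param n_specimens Specimens per species (default 3).
#' @param k_semi Semilandmarks per valve (default 45).
#' @param seed Integer seed.
#' @param ... Further overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
paper_pattern_config <- function(n_specimens = 3, k_semi = 45, seed = 1L,
                                 ...) {
  generator_config(n_specimens_per_species = n_specimens, k_semi = k_semi,
                   seed = seed, ...)
}

#' Simulate a pure-birth chronogram with species-level sampling
#'
#' Emulates the kind of time-calibrated species tree used in comparative
#' studies: a pure-birth clade larger than the sample is simulated, one
#' member of every sister pair whose terminal branches are shorter than
#' `min_pendant` (relative to depth) is dropped -- a species-level
#' chronogram does not resolve splits that recent -- and `n_tips` of the
#' remaining tips are sampled. The result is ultrametric by construction
#' and rescaled to unit root-to-tip depth; pendant edges are bounded below,
#' which keeps the Brownian covariance well conditioned when species means
#' carry measurement error.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed (uses the current RNG stream when
#'   `NULL`).
#' @param oversample Factor by which the simulated clade exceeds the
#'   sample (default 3).
#' @param min_pendant Minimum terminal branch length as a fraction of tree
#'   depth (default 0.005).
#' @return An ultrametric `phylo` tree with unit depth, tips labelled
#'   `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                          oversample = 3, min_pendant = 0.005) {
  if (n_tips < 3) stop("need at least 3 tips")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(ceiling(n_tips * oversample), birth = birth_rate,
                    death = 0)
  tr$edge.length <- tr$edge.length / max(tip_depths(tr))
  repeat {
    term <- tr$edge[, 2] <= ape::Ntip(tr)
    short <- tr$edge[term, 2][tr$edge.length[term] < min_pendant]
    if (!length(short) || ape::Ntip(tr) - length(short) < n_tips) break
    tr <- ape::drop.tip(tr, tr$tip.label[short])
    tr$edge.length <- tr$edge.length / max(tip_depths(tr))
  }
  if (ape::Ntip(tr) > n_tips)
    tr <- ape::keep.tip(tr, sample(tr$tip.label, n_tips))
  tr$edge.length <- tr$edge.length / max(tip_depths(tr))
  tr$tip.label <- sprintf("sp%03d", seq_len(ape::Ntip(tr)))
  tr
}

radial_grid_dims <- function(k_semi) {
  if (k_semi < 9) stop("k_semi must be at least 9 (radial grid)")
  m <- k_semi - 1L  # apex point + n_r rings of n_s spokes
  best <- NULL
  for (n_r in 2:floor(sqrt(m))) {
    if (m %% n_r == 0L && m %/% n_r >= 4L) best <- n_r
  }
  if (is.null(best))
    stop("k_semi must be 1 + n_r * n_s with n_r >= 2 and n_s >= 4 ",
         "(e.g. 45 or 197); got ", k_semi)
  c(n_r = best, n_s = m %/% best)
}

#' Parametric valve template
#'
#' Builds one valve configuration from latent shape parameters: five fixed
#' landmarks around the auricles and umbo on the commissural plane (z = 0)
#' and `k_semi` semilandmarks on a domed disc, `z = convexity * (1 - r^2)`
#' over a circular outline (apex point at r = 0 plus `n_r` rings of `n_s`
#' spokes; the outer ring forms the boundary-contour curve). Convexity 0
#' gives a flat (glider-like) valve; large convexity a cupped valve.
#'
#' @param k_semi Semilandmark count, `1 + n_r * n_s` (default 45).
#' @param convexity Dome height at the apex.
#' @param eccentricity Relative elongation of the outline along x.
#' @param auricle_width,auricle_height Auricle extent along the hinge and
#'   above it.
#' @param umbo_height Umbo elevation above the auricles.
#' @param skew Anterior-posterior asymmetry of the outline.
#' @param apex_dx,apex_dy Lateral displacement of the dome apex (tapering
#'   towards the outline).
#' @param flare Radial distortion of the ring spacing (inner rings pushed
#'   outward for positive values).
#' @param tilt Dorso-ventral tilt of the dome height profile.
#' @return A [landmark_config()] with `k_fixed = 5`.
#' @export
template_valve <- function(k_semi = 45,
                           convexity = LATENT_BASE[["convexity"]],
                           eccentricity = LATENT_BASE[["eccentricity"]],
                           auricle_width = LATENT_BASE[["auricle_width"]],
                           auricle_height = LATENT_BASE[["auricle_height"]],
                           umbo_height = LATENT_BASE[["umbo_height"]],
                           skew = LATENT_BASE[["skew"]],
                           apex_dx = LATENT_BASE[["apex_dx"]],
                           apex_dy = LATENT_BASE[["apex_dy"]],
                           flare = LATENT_BASE[["flare"]],
                           tilt = LATENT_BASE[["tilt"]]) {
  dims <- radial_grid_dims(k_semi)
  n_r <- dims[["n_r"]]
  n_s <- dims[["n_s"]]
  y_h <- 0.8  # dorsal hinge line
  fixed <- rbind(
    c(-auricle_width, y_h, 0),                               # ventro-posterior auricle
    c(-auricle_width, y_h + auricle_height, 0),              # dorso-posterior auricle
    c(0, y_h + auricle_height + umbo_height, 0),             # umbo
    c(auricle_width, y_h + auricle_height, 0),               # dorso-anterior auricle
    c(auricle_width, y_h, 0))                                # ventro-anterior auricle
  theta <- -pi / 2 + 2 * pi * (seq_len(n_s) - 1) / n_s
  rr <- seq_len(n_r) / n_r
  grid <- expand.grid(theta = theta, r = rr)  # ring-major: ring 1 first
  rad <- grid$r * (1 + flare * (1 - grid$r))
  y0 <- grid$r * sin(grid$theta)
  dome <- 1 - grid$r^2
  x <- rad * cos(grid$theta) * (1 + eccentricity) + skew * y0^2 +
    apex_dx * dome
  y <- rad * sin(grid$theta) + apex_dy * dome
  z <- convexity * dome + tilt * y0 * dome
  semis <- rbind(c(apex_dx, apex_dy, convexity),  # apex (r = 0)
                 cbind(x, y, z))
  landmark_config(rbind(fixed, semis), k_fixed = 5L)
}

#' Semilandmark topology of the valve template
#'
#' Matches [template_valve()]: the outer ring is a closed boundary-contour
#' curve (cyclic prev/next neighbours); the apex and inner rings are
#' surface points whose neighbour sets are the adjacent grid points.
#'
#' @param k_semi Semilandmark count as in [template_valve()].
#' @return A [semilandmark_topology()] of length `5 + k_semi`.
#' @export
valve_topology <- function(k_semi = 45) {
  dims <- radial_grid_dims(k_semi)
  n_r <- dims[["n_r"]]
  n_s <- dims[["n_s"]]
  k <- 5L + k_semi
  kind <- c(rep("fixed", 5L), rep("surface", 1L + (n_r - 1L) * n_s),
            rep("curve", n_s))
  prev <- rep(NA_integer_, k)
  nxt <- rep(NA_integer_, k)
  neighbors <- vector("list", k)
  apex <- 6L
  pt <- function(t, s) {  # ring t (1..n_r), spoke s (wrapped)
    s <- ((s - 1L) %% n_s) + 1L
    as.integer(apex + (t - 1L) * n_s + s)
  }
  neighbors[[apex]] <- vapply(seq_len(n_s), function(s) pt(1L, s),
                              integer(1))
  for (t in seq_len(n_r - 1L)) {
    for (s in seq_len(n_s)) {
      i <- pt(t, s)
      nb <- c(if (t == 1L) apex else pt(t - 1L, s), pt(t + 1L, s),
              pt(t, s - 1L), pt(t, s + 1L))
      neighbors[[i]] <- nb
    }
  }
  for (s in seq_len(n_s)) {
    i <- pt(n_r, s)
    prev[i] <- pt(n_r, s - 1L)
    nxt[i] <- pt(n_r, s + 1L)
  }
  semilandmark_topology(kind, prev, nxt, neighbors)
}

# Phylogenetically clumped ecomorph assignment: each non-ancestral
# ecomorph arises as one to three clusters of phylogenetically adjacent
# tips (ecomorphs evolved repeatedly but as clades, not scattered tips);
# byssal attachment, the widespread ancestral habit, takes the remainder.
# Cluster seeds are kept mutually distant so derived clades do not nest
# against each other (their boundaries fall in the byssal background).
assign_ecomorphs <- function(tree, counts, min_separation = 0.6) {
  tips <- tree$tip.label
  D <- stats::cophenetic(tree)
  eco <- setNames(rep(NA_character_, length(tips)), tips)
  others <- setdiff(names(counts)[counts > 0], "byssal-attaching")
  for (nm in others[order(counts[others])]) {
    n <- counts[[nm]]
    n_cl <- if (n <= 2) 1L else if (n <= 8) 2L else 3L
    sizes <- diff(round(seq(0, n, length.out = n_cl + 1)))
    for (sz in sizes) {
      if (sz == 0) next
      pool <- names(eco)[is.na(eco)]
      taken <- names(eco)[!is.na(eco)]
      if (length(taken)) {
        sep <- apply(D[pool, taken, drop = FALSE], 1, min)
        ok <- pool[sep >= min_separation]
        if (!length(ok)) ok <- pool[which.max(sep)]
      } else {
        ok <- pool
      }
      # among candidate seeds, prefer the cluster with the deepest
      # boundary split to the remaining tips (derived clades are old)
      cand <- sample(ok, min(8, length(ok)))
      best <- NULL
      best_depth <- -Inf
      for (sd_ in cand) {
        mem <- pool[order(D[sd_, pool])][seq_len(sz)]
        rest <- setdiff(tips, mem)
        depth_b <- min(D[mem, rest, drop = FALSE])
        if (depth_b > best_depth) {
          best_depth <- depth_b
          best <- mem
        }
      }
      eco[best] <- nm
    }
  }
  eco[is.na(eco)] <- "byssal-attaching"
  eco
}

template_from_theta <- function(theta, k_semi) {
  do.call(template_valve, c(list(k_semi), as.list(theta[LATENT_NAMES])))
}

# Paired Brownian fields for the two valves: one tree traversal drawing,
# for every edge, a left increment at rate base*ml and a right increment
# correlated at rho with per-edge variance base*mr. Tip-level left-right
# correlation is rho (exactly when mr/ml is constant along the path).
sim_paired_bm <- function(tree, p, base_rate, em_left, em_right, rho) {
  ntip <- ape::Ntip(tree)
  valsL <- matrix(0, ntip + tree$Nnode, p)
  valsR <- matrix(0, ntip + tree$Nnode, p)
  tr <- ape::reorder.phylo(tree, "cladewise")
  o <- match(paste(tr$edge[, 1], tr$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))
  ml <- em_left[o]
  mr <- em_right[o]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    v <- base_rate * tr$edge.length[e]
    zl <- rnorm(p, sd = sqrt(v * ml[e]))
    zr <- rho * zl * sqrt(mr[e] / ml[e]) +
      sqrt(1 - rho^2) * rnorm(p, sd = sqrt(v * mr[e]))
    valsL[child, ] <- valsL[par, ] + zl
    valsR[child, ] <- valsR[par, ] + zr
  }
  list(left = valsL[seq_len(ntip), , drop = FALSE],
       right = valsR[seq_len(ntip), , drop = FALSE])
}

# Shape-space sensitivity of each latent dimension at the base template
# (unit-size Procrustes distance per unit latent change). Latent deviations
# are rescaled by the mean-to-dim ratio of these norms so each latent
# dimension contributes equally to shape variance (isotropic latent
# variation).
latent_weights <- function(k_semi, delta = 1e-4) {
  base <- template_from_theta(LATENT_BASE, k_semi)
  J <- vapply(LATENT_NAMES, function(nm) {
    th <- LATENT_BASE
    th[[nm]] <- th[[nm]] + delta
    procrustes_distance(base, template_from_theta(th, k_semi)) / delta
  }, numeric(1))
  mean(J) / J
}

#' Generate a synthetic valve dataset
#'
#' Simulates a chronogram, assigns ecomorphs, evolves the six latent shape
#' parameters under Brownian motion with group-specific terminal-branch
#' rate multipliers, and evolves the right valve alongside as a paired
#' Brownian field whose per-edge increments are correlated with the left
#' valve's at `integration_rho` and whose rate is `valve_rate_base` times
#' the left rate on internal branches and `valve_rate_ratio[g]` times it on
#' terminal branches; the ecomorph's directional-asymmetry offset is added
#' to right-valve convexity, with per-specimen latent noise and per-replicate coordinate
#' noise, and renders landmarks through the valve template. Right valves
#' are emitted mirrored across x, as a digitising scheme reflecting them
#' onto the left-valve frame would produce.
#'
#' @param config A [generator_config()].
#' @return List with `left` and `right` [specimen_set()]s, the `tree`, the
#'   generating `truth` (latent species values, expected group rates and
#'   ratios, per-species true asymmetry magnitude and integration), and
#'   `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  N <- config$n_species
  tree <- simulate_tree(N, config$birth_rate)
  species <- tree$tip.label
  eco <- assign_ecomorphs(tree, config$ecomorph_counts)

  mult <- config$group_rate_multipliers[eco]
  ratio <- config$valve_rate_ratio[eco]
  rho <- config$integration_rho
  k_semi <- config$k_semi
  k <- 5L + k_semi
  p <- length(LATENT_NAMES)

  em_left <- terminal_edge_multipliers(tree, setNames(mult, species))
  em_right <- config$valve_rate_base *
    terminal_edge_multipliers(tree,
                              setNames(mult * ratio / config$valve_rate_base,
                                       species))
  w <- latent_weights(k_semi)
  dev <- sim_paired_bm(tree, p, config$latent_rate, em_left, em_right, rho)
  dev_left <- dev$left %*% diag(w)
  dev_right <- dev$right %*% diag(w)
  dimnames(dev_left) <- dimnames(dev_right) <- list(species, LATENT_NAMES)

  theta_left <- sweep(dev_left, 2, LATENT_BASE, "+")
  theta_right <- sweep(dev_right, 2, LATENT_BASE, "+")
  theta_right[, "convexity"] <- theta_right[, "convexity"] +
    config$da_offset[eco]

  nspec <- config$n_specimens_per_species
  n_per <- if (length(nspec) == 2L)
    sample(seq(nspec[1], nspec[2]), N, replace = TRUE)
  else rep(nspec, N)

  topo <- valve_topology(k_semi)
  n_rep <- config$n_replicates
  total <- sum(n_per) * n_rep
  make_side <- function(theta_mat, mirrored) {
    coords <- array(NA_real_, c(k, 3, total))
    labels <- vector("list", total)
    pos <- 0L
    for (i in seq_len(N)) {
      for (j in seq_len(n_per[i])) {
        th <- theta_mat[i, ] + rnorm(p, sd = config$specimen_noise_sd * w)
        names(th) <- LATENT_NAMES
        base <- as_coord_matrix(template_from_theta(th, k_semi))
        if (mirrored) base[, 1] <- -base[, 1]
        id <- sprintf("%s_ind%02d", species[i], j)
        for (r in seq_len(n_rep)) {
          pos <- pos + 1L
          coords[, , pos] <- base +
            matrix(rnorm(k * 3, sd = config$replicate_noise_sd), k, 3)
          labels[[pos]] <- data.frame(specimen_id = id,
                                      species = species[i],
                                      side = if (mirrored) "right" else "left",
                                      replicate = r,
                                      ecomorph = eco[[species[i]]],
                                      stringsAsFactors = FALSE)
        }
      }
    }
    specimen_set(coords, do.call(rbind, labels), topology = topo)
  }
  left <- make_side(theta_left, mirrored = FALSE)
  right <- make_side(theta_right, mirrored = TRUE)

  da_true <- vapply(seq_len(N), function(i) {
    procrustes_distance(template_from_theta(theta_left[i, ], k_semi),
                        template_from_theta(theta_right[i, ], k_semi),
                        align_first = TRUE)
  }, numeric(1))

  truth <- list(tree = tree, ecomorph = eco,
                theta_left = theta_left, theta_right = theta_right,
                group_rate_multipliers = config$group_rate_multipliers,
                valve_rate_ratio = config$valve_rate_ratio,
                da_offset = config$da_offset,
                da_true = setNames(da_true, species),
                integration_cor = setNames(rep(rho, N), species),
                n_specimens = setNames(n_per, species))
  list(left = left, right = right, tree = tree, truth = truth,
       config = config)
}

#' Write a generated dataset to plain-text files
#'
#' Emits the long-format landmark CSV (both sides in one file), the
#' topology descriptor CSV, the Newick tree and a JSON file of the
#' generating truth (latent values and expected rates).
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(landmarks = file.path(dir, "landmarks.csv"),
             topology = file.path(dir, "topology.csv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  both <- dataset$left
  nL <- n_specimens(dataset$left)
  nR <- n_specimens(dataset$right)
  k <- dim(both$coords)[1]
  both$coords <- array(c(dataset$left$coords, dataset$right$coords),
                       c(k, 3, nL + nR))
  both$labels <- rbind(dataset$left$labels, dataset$right$labels)
  write_landmarks_csv(both, paths[["landmarks"]])
  write_topology_csv(dataset$left$topology, paths[["topology"]])
  ape::write.tree(dataset$tree, paths[["tree"]])
  tr <- dataset$truth
  tr$tree <- ape::write.tree(tr$tree)
  jsonlite::write_json(tr, paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
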