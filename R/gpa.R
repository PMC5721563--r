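# Generalised Procrustes superimposition with sliding semilandmarks.
#
# Shapes are k x 3 matrices; sets are k x 3 x n arrays. Superimposition
# removes translation (centering), size (unit centroid size) and orientation
# (proper rotations only -- reflections are never introduced silently, since
# a silent reflection would corrupt the left/right asymmetry measurement;
# handedness is handled explicitly via mirror_configuration()).

#' Center a configuration and scale it to unit centroid size
#'
#' @param config A k x 3 coordinate matrix (or [landmark_config()]).
#' @return List with `config` (centered, unit centroid size) and
#'   `centroid_size` (the original size: the root of summed squared
#'   distances of the landmarks to their centroid).
#' @export
center_and_scale <- function(config) {
  m <- as_coord_matrix(config)
  ctr <- colMeans(m)
  m <- sweep(m, 2, ctr)
  cs <- sqrt(sum(m^2))
  if (cs < 1e-300)
    stop("degenerate configuration: all landmarks coincident")
  out <- m / cs
  attr(out, "k_fixed") <- attr(config, "k_fixed")
  list(config = out, centroid_size = cs)
}

center_scale_array <- function(A) {
  n <- dim(A)[3]
  cs <- numeric(n)
  for (i in seq_len(n)) {
    x <- A[, , i]
    x <- sweep(x, 2, colMeans(x))
    s <- sqrt(sum(x^2))
    if (s < 1e-300) stop("degenerate configuration at index ", i)
    A[, , i] <- x / s
    cs[i] <- s
  }
  list(coords = A, centroid_size = cs)
}

#' Optimal proper rotation between two centred configurations
#'
#' Returns the 3 x 3 proper rotation (determinant +1) minimising the summed
#' squared distance between `A %*% rotation` and `B`. Improper solutions are
#' corrected by flipping the singular direction with the smallest singular
#' value (for ties, the highest index), which makes rank-deficient cases
#' deterministic.
#'
#' @param A,B Centred k x 3 matrices with equal k.
#' @return A 3 x 3 rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  A <- as_coord_matrix(A)
  B <- as_coord_matrix(B)
  if (!identical(dim(A), dim(B))) stop("configurations differ in size")
  cpp_optimal_rotation(A, B)
}

#' Procrustes distance between two configurations
#'
#' The root of the summed squared distances between corresponding landmarks.
#' With `align_first = TRUE` both configurations are centred and scaled to
#' unit centroid size and `b` is rotated (proper rotation only) onto `a`
#' before the distance is taken; with `align_first = FALSE` the coordinates
#' are compared as given (the appropriate choice for shapes already in a
#' common superimposition frame).
#'
#' @param a,b k x 3 coordinate matrices with equal k.
#' @param align_first Superimpose before measuring? Default `TRUE`.
#' @return Non-negative scalar distance.
#' @export
procrustes_distance <- function(a, b, align_first = TRUE) {
  a <- as_coord_matrix(a)
  b <- as_coord_matrix(b)
  if (!identical(dim(a), dim(b))) stop("shape mismatch: landmark counts differ")
  if (align_first) {
    a <- center_and_scale(a)$config
    b <- center_and_scale(b)$config
    b <- b %*% cpp_optimal_rotation(b, a)
  }
  sqrt(sum((a - b)^2))
}

#' Mirror a configuration across a coordinate plane
#'
#' Negates the coordinate along the named axis for all landmarks, leaving
#' the landmark ordering unchanged. Used to reflect right valves onto the
#' left-valve frame before joint superimposition; applying it twice returns
#' the input.
#'
#' @param config A k x 3 matrix (or [landmark_config()]).
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return The mirrored configuration (same class/attributes as the input).
#' @export
mirror_configuration <- function(config, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  j <- match(axis, c("x", "y", "z"))
  config[, j] <- -config[, j]
  config
}

topology_slide_args <- function(topology) {
  kind <- topology$kind
  ci <- which(kind == "curve")
  si <- which(kind == "surface")
  nb <- unlist(topology$neighbors[si])
  off <- c(0L, cumsum(vapply(topology$neighbors[si], length, integer(1))))
  list(curve_idx = ci - 1L,
       curve_prev = topology$prev[ci] - 1L,
       curve_next = topology$nxt[ci] - 1L,
       surf_idx = si - 1L,
       surf_nb = as.integer(nb) - 1L,
       surf_off = as.integer(off))
}

#' Slide semilandmarks toward a reference configuration
#'
#' One sliding pass: each curve semilandmark is displaced only along its
#' tangent direction (the unit chord between its previous and next
#' along-curve neighbours) and each surface semilandmark only within its
#' local tangent plane (the two leading principal directions of its
#' neighbour set), by the orthogonal projection of its residual to the
#' reference onto that tangent subspace -- the displacement minimising the
#' squared distance to the corresponding reference point within the
#' subspace. Fixed landmarks are never moved. Tangents are taken from the
#' positions as they enter the pass.
#'
#' @param shapes A k x 3 matrix or k x 3 x n array of configurations,
#'   superimposed on `reference`.
#' @param reference The k x 3 reference (consensus) configuration.
#' @param topology A [semilandmark_topology()] for the configurations.
#' @return An object of the same shape as `shapes` with semilandmarks slid;
#'   attribute `skipped` counts points left in place due to degenerate
#'   tangents (reported with a message).
#' @export
slide_semilandmarks <- function(shapes, reference, topology) {
  was_matrix <- length(dim(shapes)) == 2L
  A <- if (was_matrix) array(shapes, c(dim(shapes), 1L)) else shapes
  args <- topology_slide_args(topology)
  res <- cpp_slide_all(A, as_coord_matrix(reference),
                       args$curve_idx, args$curve_prev, args$curve_next,
                       args$surf_idx, args$surf_nb, args$surf_off)
  if (res$skipped > 0)
    message(res$skipped,
            " semilandmark(s) had a degenerate tangent and did not slide")
  out <- if (was_matrix) res$coords[, , 1] else res$coords
  attr(out, "skipped") <- res$skipped
  out
}

normalize_shape <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

#' Generalised Procrustes alignment of a specimen set
#'
#' Iterative superimposition: all configurations are centred and scaled to
#' unit centroid size, rotated onto the current consensus, optionally slid
#' against it (one sliding pass per iteration, tangents recomputed from the
#' current positions), and the consensus is recomputed; iteration stops when
#' the Procrustes distance between successive consensus shapes falls below
#' `tol` or `max_iter` is reached. Sliding minimises Procrustes distance to
#' the consensus (tangent-subspace projection).
#'
#' Sliding runs for the first `slide_iter` iterations only. Minimising
#' Procrustes distance along tangents admits a slow tangential mode on
#' closed outlines and surface grids -- semilandmarks can migrate
#' collectively along the contour with negligible fit improvement -- which
#' would keep the consensus moving indefinitely; a small fixed number of
#' passes captures essentially all of the attainable fit gain, after which
#' plain superimposition iterations polish the consensus to tolerance.
#'
#' @param data A [specimen_set()] with at least 2 configurations.
#' @param slide Slide semilandmarks (requires a topology with semilandmark
#'   entries)? Default `TRUE`.
#' @param max_iter Maximum number of iterations (default 100).
#' @param tol Convergence tolerance on consensus displacement (default 1e-9).
#' @param slide_iter Number of leading iterations that include a sliding
#'   pass (default 5).
#' @return An `aligned_set`: the input set with aligned `coords`, plus
#'   `centroid_size` (per-specimen original sizes), `mean_shape` (consensus,
#'   unit centroid size), `iterations_run`, `converged`, and a per-iteration
#'   `history` data frame (consensus change and, when sliding, the total
#'   Procrustes sum of squares before/after the pass).
#' @export
gpa_align <- function(data, slide = TRUE, max_iter = 100, tol = 1e-9,
                      slide_iter = 5) {
  if (!inherits(data, "specimen_set")) stop("data must be a specimen_set")
  n <- n_specimens(data)
  if (n < 2L) stop("alignment needs at least 2 configurations")
  do_slide <- slide && !is.null(data$topology) &&
    any(data$topology$kind != "fixed")
  if (slide && !do_slide && is.null(data$topology)) {
    warning("no semilandmark topology attached; aligning without sliding")
  }
  cs <- center_scale_array(data$coords)
  A <- cs$coords
  # deterministic, order-independent initial reference: the first
  # configuration by label key
  key <- paste(data$labels$specimen_id, data$labels$side,
               data$labels$replicate)
  consensus <- A[, , order(key)[1]]
  args <- if (do_slide) topology_slide_args(data$topology)
  hist_delta <- numeric(0)
  hist_ss_before <- numeric(0)
  hist_ss_after <- numeric(0)
  converged <- FALSE
  skipped_total <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- cpp_rotate_all(A, consensus)
    ss_b <- ss_a <- NA_real_
    if (do_slide && it <= slide_iter) {
      cons_arr <- array(consensus, dim(A))
      ss_b <- sum((A - cons_arr)^2)
      res <- cpp_slide_all(A, consensus, args$curve_idx, args$curve_prev,
                           args$curve_next, args$surf_idx, args$surf_nb,
                           args$surf_off)
      A <- res$coords
      skipped_total <- skipped_total + res$skipped
      ss_a <- sum((A - cons_arr)^2)
      A <- center_scale_array(A)$coords
    }
    newcons <- normalize_shape(apply(A, c(1, 2), mean))
    delta <- sqrt(sum((consensus - newcons)^2))
    hist_delta <- c(hist_delta, delta)
    hist_ss_before <- c(hist_ss_before, ss_b)
    hist_ss_after <- c(hist_ss_after, ss_a)
    consensus <- newcons
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("GPA did not converge within ", max_iter,
            " iterations (last consensus change ",
            signif(hist_delta[length(hist_delta)], 3), ")")
  if (skipped_total > 0)
    message(skipped_total,
            " degenerate-tangent semilandmark slides skipped in total")
  out <- data
  out$coords <- A
  out$centroid_size <- cs$centroid_size
  out$mean_shape <- consensus
  out$iterations_run <- it
  out$converged <- converged
  out$history <- data.frame(iteration = seq_len(it), consensus_change = hist_delta,
                            ss_before_slide = hist_ss_before,
                            ss_after_slide = hist_ss_after)
  class(out) <- c("aligned_set", "specimen_set")
  out
}

#' @export
print.aligned_set <- function(x, ...) {
  NextMethod()
  cat(sprintf("  aligned: %d iterations, converged = %s\n",
              x$iterations_run, x$converged))
  invisible(x)
}

#' Average digitising replicates of each valve
#'
#' Collapses the configurations sharing a (specimen_id, side) pair to their
#' coordinate-wise mean, re-scaled to unit centroid size. Replicate labels
#' collapse to 1; recorded centroid sizes are averaged. Averaging is done on
#' the aligned shapes (after superimposition).
#'
#' @param aligned An `aligned_set` from [gpa_align()].
#' @return An `aligned_set` with one configuration per valve.
#' @export
average_replicates <- function(aligned) {
  lab <- aligned$labels
  key <- paste(lab$specimen_id, lab$side, sep = "\r")
  key <- factor(key, levels = unique(key))
  n_out <- nlevels(key)
  k <- dim(aligned$coords)[1]
  coords <- array(NA_real_, c(k, 3, n_out))
  cs <- numeric(n_out)
  first <- !duplicated(key)
  groups <- split(seq_len(nrow(lab)), key)
  for (i in seq_len(n_out)) {
    idx <- groups[[i]]
    m <- apply(aligned$coords[, , idx, drop = FALSE], c(1, 2), mean)
    coords[, , i] <- normalize_shape(m)
    cs[i] <- mean(aligned$centroid_size[idx])
  }
  labels <- lab[first, , drop = FALSE]
  labels$replicate <- 1L
  rownames(labels) <- NULL
  out <- aligned
  out$coords <- coords
  out$labels <- labels
  out$centroid_size <- cs
  out
}

#' Per-species mean shapes
#'
#' Coordinate-wise means over each species' aligned configurations,
#' re-scaled to unit centroid size and ordered by `species_order` (normally
#' the pruned tree's tip order, so rows align with the phylogenetic
#' covariance matrix).
#'
#' @param aligned An `aligned_set`.
#' @param species_order Character vector of species names; every entry must
#'   have at least one specimen. Defaults to order of first appearance.
#' @return A `mean_shapes` object: list with `species`, `shapes`
#'   (k x 3 x N array), `n_specimens` and `k_fixed`.
#' @export
species_means <- function(aligned, species_order = NULL) {
  sp <- aligned$labels$species
  if (is.null(species_order)) species_order <- unique(sp)
  missing_sp <- setdiff(species_order, sp)
  if (length(missing_sp))
    stop("no specimens for species: ", paste(missing_sp, collapse = ", "))
  k <- dim(aligned$coords)[1]
  N <- length(species_order)
  shapes <- array(NA_real_, c(k, 3, N))
  counts <- integer(N)
  for (i in seq_len(N)) {
    idx <- which(sp == species_order[i])
    counts[i] <- length(idx)
    m <- apply(aligned$coords[, , idx, drop = FALSE], c(1, 2), mean)
    shapes[, , i] <- normalize_shape(m)
  }
  structure(list(species = species_order, shapes = shapes,
                 n_specimens = counts, k_fixed = aligned$k_fixed),
            class = "mean_shapes")
}

#' @export
print.mean_shapes <- function(x, ...) {
  cat(sprintf("mean_shapes: %d species, %d landmarks\n",
              length(x$species), dim(x$shapes)[1]))
  invisible(x)
}

#' Flatten shapes to a species-by-trait matrix
#'
#' Stacks each k x 3 configuration into a row vector (all x coordinates,
#' then y, then z), giving the N x 3k trait matrix used by the comparative
#' analyses. Row names are the species (for `mean_shapes`) or specimen ids.
#'
#' @param x A `mean_shapes` object, an `aligned_set`, or a k x 3 x n array.
#' @return An n x 3k numeric matrix.
#' @export
shape_matrix <- function(x) {
  if (inherits(x, "mean_shapes")) {
    A <- x$shapes
    rn <- x$species
  } else if (inherits(x, "specimen_set")) {
    A <- x$coords
    rn <- x$labels$specimen_id
  } else {
    A <- x
    rn <- NULL
  }
  out <- t(apply(A, 3, as.vector))
  rownames(out) <- rn
  out
}
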