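# Matching asymmetry between paired valves.
#
# The magnitude of directional asymmetry (DA) of a shell is the Procrustes
# distance between its left valve and its mirrored right valve after a
# single joint superimposition of all valves of both sides. The distance is
# taken on the jointly aligned coordinates without re-rotating each pair:
# the joint GPA already placed every valve in one frame, and per-pair
# re-rotation would remove real hinge-orientation asymmetry.

#' Joint mirrored superimposition of left and right valves
#'
#' Mirrors every right-valve configuration across the given axis (the
#' anterior-posterior axis of the digitising scheme) so both sides share
#' one handedness, pools the two sets, and runs a single generalised
#' Procrustes alignment (with semilandmark sliding by default) over the
#' pooled set. Specimens present on one side only are dropped with a
#' warning (incomplete shells).
#'
#' @param left,right [specimen_set()]s sharing specimen ids and landmark
#'   scheme.
#' @param mirror_axis Axis to negate on the right valves (default `"x"`).
#' @param slide,max_iter,tol Passed to [gpa_align()].
#' @return An `aligned_set` containing both sides.
#' @export
joint_superimpose <- function(left, right, mirror_axis = "x", slide = TRUE,
                              max_iter = 100, tol = 1e-9) {
  if (dim(left$coords)[1] != dim(right$coords)[1])
    stop("left and right sets differ in landmark count")
  common <- intersect(unique(left$labels$specimen_id),
                      unique(right$labels$specimen_id))
  dropped <- setdiff(union(unique(left$labels$specimen_id),
                           unique(right$labels$specimen_id)), common)
  if (length(dropped))
    warning(length(dropped), " incomplete shell(s) dropped (one valve only): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  if (!length(common)) stop("no specimen present on both sides")
  li <- which(left$labels$specimen_id %in% common)
  ri <- which(right$labels$specimen_id %in% common)
  lcoords <- left$coords[, , li, drop = FALSE]
  rcoords <- right$coords[, , ri, drop = FALSE]
  j <- match(mirror_axis, c("x", "y", "z"))
  if (is.na(j)) stop("mirror_axis must be x, y or z")
  rcoords[, j, ] <- -rcoords[, j, ]
  k <- dim(lcoords)[1]
  coords <- array(c(lcoords, rcoords), c(k, 3, length(li) + length(ri)))
  labels <- rbind(left$labels[li, , drop = FALSE],
                  right$labels[ri, , drop = FALSE])
  rownames(labels) <- NULL
  pooled <- specimen_set(coords, labels, k_fixed = left$k_fixed,
                         topology = left$topology)
  gpa_align(pooled, slide = slide, max_iter = max_iter, tol = tol)
}

#' Per-specimen and per-species asymmetry magnitude
#'
#' For every specimen with both valves in the jointly aligned set, the DA
#' magnitude is the Procrustes distance between the left and the (already
#' mirrored) right valve on the aligned coordinates (`align_first = FALSE`).
#' Species means and variances are aggregated alongside, since the spread of
#' asymmetry within ecomorphs is itself of interest.
#'
#' @param aligned An `aligned_set` from [joint_superimpose()].
#' @param average_replicates Average digitising replicates per valve before
#'   pairing (default `TRUE`).
#' @return An `asymmetry_table`: list with `specimens` (specimen_id,
#'   species, ecomorph, da) and `species` (species, ecomorph, n, da_mean,
#'   da_var) data frames.
#' @export
asymmetry_magnitude <- function(aligned, average_replicates = TRUE) {
  if (average_replicates) aligned <- average_replicates(aligned)
  lab <- aligned$labels
  ids <- unique(lab$specimen_id)
  da <- numeric(length(ids))
  species <- character(length(ids))
  ecom <- character(length(ids))
  for (i in seq_along(ids)) {
    li <- which(lab$specimen_id == ids[i] & lab$side == "left")
    ri <- which(lab$specimen_id == ids[i] & lab$side == "right")
    if (length(li) != 1L || length(ri) != 1L)
      stop("specimen ", ids[i], " is not a complete left/right pair")
    da[i] <- sqrt(sum((aligned$coords[, , li] - aligned$coords[, , ri])^2))
    species[i] <- lab$species[li]
    ecom[i] <- lab$ecomorph[li]
  }
  specimens <- data.frame(specimen_id = ids, species = species,
                          ecomorph = ecom, da = da,
                          stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(specimens, specimens$species),
    function(d) data.frame(species = d$species[1], ecomorph = d$ecomorph[1],
                           n = nrow(d), da_mean = mean(d$da),
                           da_var = if (nrow(d) > 1) var(d$da) else 0,
                           stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(specimens = specimens, species = agg),
            class = "asymmetry_table")
}

#' @export
print.asymmetry_table <- function(x, ...) {
  cat(sprintf("asymmetry_table: %d specimens, %d species; mean DA = %.4g\n",
              nrow(x$specimens), nrow(x$species), mean(x$specimens$da)))
  invisible(x)
}

#' Per-ecomorph asymmetry summary
#'
#' @param at An `asymmetry_table`.
#' @return Data frame with one row per ecomorph: specimen count, mean and
#'   variance of specimen DA.
#' @export
asymmetry_by_ecomorph <- function(at) {
  d <- at$specimens
  out <- do.call(rbind, lapply(split(d, d$ecomorph), function(g)
    data.frame(ecomorph = g$ecomorph[1], n = nrow(g), da_mean = mean(g$da),
               da_var = if (nrow(g) > 1) var(g$da) else 0,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(match(out$ecomorph, ecomorph_levels())), , drop = FALSE]
}
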