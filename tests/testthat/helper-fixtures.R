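# Small fixtures built in code.

unit_triangle <- function(offset = c(0, 0, 0)) {
  m <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0))
  sweep(m, 2, offset, "+")
}

# A fixed asymmetric 4-point configuration (centred)
quad_config <- function() {
  m <- rbind(c(0.9, 0.1, 0.05), c(-0.4, 0.8, -0.2),
             c(-0.6, -0.5, 0.4), c(0.1, -0.4, -0.25))
  scale(m, scale = FALSE)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal specimen set: n configurations of a k-landmark template with
# optional noise; all fixed landmarks (no topology) unless one is given.
toy_specimen_set <- function(n = 4, base = quad_config(), noise = 0.05,
                             topology = NULL, species = NULL,
                             side = "left") {
  k <- nrow(base)
  coords <- array(NA_real_, c(k, 3, n))
  for (i in seq_len(n)) {
    coords[, , i] <- (base + matrix(rnorm(k * 3, sd = noise), k, 3)) %*%
      random_rotation() + rep(runif(3, -1, 1), each = k)
  }
  if (is.null(species)) species <- paste0("sp", seq_len(n))
  labels <- data.frame(specimen_id = paste0(species, "_i1"),
                       species = species, side = side, replicate = 1L,
                       ecomorph = "gliding", stringsAsFactors = FALSE)
  specimen_set(coords, labels, topology = topology)
}

# Tiny generator config for fast end-to-end tests.
tiny_config <- function(seed = 1L, n_specimens_per_species = 2, ...) {
  generator_config(n_species = 12,
                   n_specimens_per_species = n_specimens_per_species,
                   n_replicates = 2, k_semi = 21, seed = seed, ...)
}
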