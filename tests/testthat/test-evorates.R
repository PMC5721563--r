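# Multivariate Brownian-motion rates: estimator, group/trait comparisons,
# bootstrap, simulator moments.

test_that("sigma2_mult matches the hand-computed two-tip GLS case", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  C <- phylo_covariance(tr)
  Y <- matrix(c(0, 2), 2, 1, dimnames = list(c("A", "B"), NULL))
  # GLS mean 1, deviations (-1, 1): (1 + 1) / (2 * 1)
  expect_equal(sigma2_mult(Y, C), 1)
  # data at the phylogenetic mean: rate 0
  Y0 <- matrix(5, 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(sigma2_mult(Y0, C), 0)
})

test_that("sigma2 scales exactly with branch lengths and trait scale", {
  set.seed(20)
  tr <- simulate_tree(16)
  C <- phylo_covariance(tr)
  Y <- simulate_bm_tips(tr, diag(3))
  s0 <- sigma2_mult(Y, C)
  expect_equal(sigma2_mult(Y, 4 * C), s0 / 4, tolerance = 1e-10)
  expect_equal(sigma2_mult(3 * Y, C), 9 * s0, tolerance = 1e-10)
  # per_dim = FALSE multiplies by p
  expect_equal(sigma2_mult(Y, C, per_dim = FALSE), 3 * s0, tolerance = 1e-12)
})

test_that("sigma2 estimates concentrate on the truth as N grows", {
  set.seed(22)
  bias <- sapply(c(16, 64, 256), function(n) {
    tr <- simulate_tree(n)
    C <- phylo_covariance(tr)
    est <- replicate(30, sigma2_mult(simulate_bm_tips(tr, diag(2)), C))
    abs(mean(est) - 1)
  })
  expect_lt(bias[3], 0.05)
  expect_lt(bias[3], bias[1] + 0.05)
})

test_that("simulate_bm_tips has the Brownian first and second moments", {
  star <- ape::read.tree(text = "(A:2,B:2,C:2,D:2);")
  set.seed(23)
  reps <- replicate(2000, simulate_bm_tips(star, 1.5)[, 1])
  expect_equal(mean(apply(reps, 2, var) * 0 + apply(reps, 1, var)), 3,
               tolerance = 0.05 * 3)
  # correlated dimensions: tip cross-correlation matches the rate matrix
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  tips <- replicate(2000, simulate_bm_tips(star, S)[1, ])
  expect_equal(cor(t(tips))[1, 2], 0.8, tolerance = 0.05)
  # zero rate matrix: all tips zero
  expect_true(all(simulate_bm_tips(star, matrix(0, 2, 2)) == 0))
  expect_error(simulate_bm_tips(star, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("edge multipliers raise variance on the selected branches only", {
  set.seed(24)
  tr <- simulate_tree(24)
  em <- terminal_edge_multipliers(
    tr, setNames(rep(4, 12), tr$tip.label[1:12]))
  expect_equal(sum(em == 4), 12)
  expect_equal(sum(em == 1), nrow(tr$edge) - 12)
  Y <- replicate(400, simulate_bm_tips(tr, 1, edge_multipliers = em)[, 1])
  v <- apply(Y, 1, var)
  pend <- tr$edge.length[match(seq_len(24), tr$edge[, 2])]
  depth <- diag(phylo_covariance(tr))[tr$tip.label]
  expected <- depth + 3 * pend * c(rep(1, 12), rep(0, 12))
  expect_equal(unname(v), unname(expected), tolerance = 0.2)
})

test_that("trait-rate comparison: identical blocks give ratio exactly 1", {
  set.seed(25)
  tr <- simulate_tree(12)
  C <- phylo_covariance(tr)
  Y <- simulate_bm_tips(tr, diag(4))
  r <- compare_rates_traits(list(left = Y, right = Y), C, n_sim = 99,
                            seed = 1)
  expect_identical(r$ratio, 1)
  expect_equal(unname(r$sigma2[["left"]]), unname(r$sigma2[["right"]]))
})

test_that("group and trait comparisons are deterministic under a fixed seed", {
  set.seed(26)
  tr <- simulate_tree(16)
  C <- phylo_covariance(tr)
  Y <- simulate_bm_tips(tr, diag(3))
  g <- setNames(rep(c("a", "b"), 8), colnames(C))
  r1 <- compare_rates_groups(Y, g, C, n_sim = 99, seed = 5)
  r2 <- compare_rates_groups(Y, g, C, n_sim = 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$pairwise_p, r2$pairwise_p)
  expect_gt(r1$p_value, 0)
  expect_gte(r1$ratio, 1)
})

test_that("single-species groups get flagged point estimates, no test", {
  set.seed(27)
  tr <- simulate_tree(9)
  C <- phylo_covariance(tr)
  YL <- simulate_bm_tips(tr, diag(2))
  YR <- YL + simulate_bm_tips(tr, 0.3 * diag(2))
  g <- setNames(c("solo", rep(c("a", "b"), 4)), colnames(C))
  res <- rates_within_groups(YL, YR, g, C, n_sim = 99, seed = 2)
  expect_true(is.na(res$groups[["solo"]]$p_value))
  expect_true(isTRUE(res$groups[["solo"]]$unstable))
  expect_gt(res$groups[["solo"]]$ratio, 0)
  expect_false(is.na(res$groups[["a"]]$p_value))
  expect_identical(nrow(res$summary), 3L)
})

test_that("bootstrap gives zero-width intervals when every species has one specimen", {
  set.seed(28)
  ds <- generate_dataset(tiny_config(seed = 6,
                                     n_specimens_per_species = 1))
  al <- average_replicates(gpa_align(ds$left, slide = FALSE))
  C <- phylo_covariance(ds$tree)
  stat <- function(s) {
    mm <- shape_matrix(species_means(s, ds$tree$tip.label))
    c(rate = sigma2_mult(mm, C))
  }
  suppressMessages(b <- bootstrap_rate_ci(al, stat, n_boot = 100, seed = 1))
  expect_equal(b$ci$ci_low, b$ci$estimate, tolerance = 1e-12)
  expect_equal(b$ci$ci_high, b$ci$estimate, tolerance = 1e-12)
})

test_that("bootstrap intervals cover the full-data estimate", {
  set.seed(29)
  ds <- generate_dataset(tiny_config(seed = 7))
  al <- average_replicates(gpa_align(ds$left, slide = FALSE))
  C <- phylo_covariance(ds$tree)
  stat <- function(s) {
    mm <- shape_matrix(species_means(s, ds$tree$tip.label))
    c(rate = sigma2_mult(mm, C))
  }
  b <- bootstrap_rate_ci(al, stat, n_boot = 200, seed = 9)
  expect_lte(b$ci$ci_low, b$ci$estimate)
  expect_gte(b$ci$ci_high, b$ci$estimate)
  expect_gt(b$ci$ci_high, b$ci$ci_low)
  # deterministic under seed
  b2 <- bootstrap_rate_ci(al, stat, n_boot = 200, seed = 9)
  expect_identical(b$ci, b2$ci)
})
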