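test_that("interior probability honors the model's limiting behavior", {
  # agreeing Sha flanks at zero recombination rate: certainty
  expect_identical(interior_probability(1, 1, 3, 5, 0), 1)
  expect_identical(interior_probability(0, 0, 3, 5, 0), 0)
  # infinite recombination: no flanking information
  expect_equal(interior_probability(1, 1, 3, 5, 1e8), 0.5)
  expect_equal(interior_probability(0, 1, 2, 9, 1e8), 0.5)
  # disagreeing flanks at the midpoint: exactly 1/2 for any alpha
  for (a in c(0, 0.01, 0.3, 5))
    expect_equal(interior_probability(0, 1, 4, 4, a), 0.5)
  # complementarity: P(1 | ...) + P(0-coded flip) = 1
  p1 <- interior_probability(0, 1, 2, 7, 0.13)
  p0 <- interior_probability(1, 0, 2, 7, 0.13)
  expect_equal(p1 + p0, 1)
  # monotone decay toward 1/2 in alpha with agreeing flanks
  pa <- interior_probability(1, 1, 3, 5, c(0, 0.05, 0.2, 1, 10))
  expect_true(all(diff(pa) < 0) && all(pa >= 0.5))
  # continuity as the left distance shrinks: approaches the left flank
  expect_lt(abs(interior_probability(0, 1, 1e-9, 10, 0.2) - 0), 1e-6)
  expect_lt(abs(interior_probability(1, 0, 1e-9, 10, 0.2) - 1), 1e-6)
  expect_error(interior_probability(1, 1, -1, 5, 0.1), "positive")
  expect_error(interior_probability(1, 1, 1, 5, -0.1), "alpha")
})

test_that("interior probability matches the closed-form bridge on a grid", {
  set.seed(3)
  for (k in 1:50) {
    x0 <- rbinom(1, 1, 0.5); x1 <- rbinom(1, 1, 0.5)
    dl <- runif(1, 0.1, 20); dr <- runif(1, 0.1, 20)
    a <- runif(1, 0.001, 2)
    expect_equal(interior_probability(x0, x1, dl, dr, a),
                 bridge_prob(x0, x1, dl, dr, a), tolerance = 1e-12)
  }
})

test_that("edge probability follows 1/2 + delta/2 * beta^d", {
  expect_identical(edge_probability(1, 7, 1), 1)
  expect_identical(edge_probability(0, 7, 1), 0)
  expect_equal(edge_probability(0, 3, 0), 0.5)
  # direct hand evaluation at the real-data edge parameter
  expect_equal(edge_probability(1, 5, 0.9524), 0.5 + 0.5 * 0.9524^5)
  expect_equal(edge_probability(1, 5, 0.9524), 0.8918, tolerance = 1e-4)
  expect_error(edge_probability(1, 5, 1.2), "beta")
  expect_error(edge_probability(1, 0, 0.9), "positive")
})

test_that("pseudo log-likelihood equals a brute-force term sum", {
  map <- genetic_map(c("a", "b", "c"), c(1, 1, 1), c(0, 3, 8))
  g <- rbind(c(1L, 1L, 1L), c(1L, 0L, 1L))
  G <- ril_geno(g, map)
  prm <- recomb_params(alpha = 0.1, beta = 0.9)
  # two interior terms (marker b per RIL), summed by hand
  p <- bridge_prob(1, 1, 3, 5, 0.1)
  expected <- log(p) + log(1 - p)
  got <- pseudo_loglik(G, params = prm, which = "interior")
  expect_equal(got$loglik, expected, tolerance = 1e-12)
  expect_equal(got$n_terms, 2L)
  # four edge terms: a|b at d=3 and c|b at d=5, per RIL
  pe <- function(xn, d) 0.5 + 0.5 * ifelse(xn == 1, 1, -1) * 0.9^d
  exp_edge <- log(pe(1, 3)) + log(pe(1, 5)) +       # RIL 1: x=1 both ends
    log(pe(0, 3)) + log(pe(0, 5))                   # RIL 2: a=1|b=0, c=1|b=0
  got_e <- pseudo_loglik(G, params = prm, which = "edge")
  expect_equal(got_e$loglik, exp_edge, tolerance = 1e-12)
  expect_equal(got_e$n_terms, 4L)
  # terms with a missing member are skipped
  g[2, 1] <- NA
  G2 <- ril_geno(g, map)
  expect_equal(pseudo_loglik(G2, params = prm, which = "interior")$n_terms, 1L)
  # identical chain at alpha = 0: every term is ln(1) = 0
  Gid <- ril_geno(rbind(c(1L, 1L, 1L)), map)
  expect_equal(pseudo_loglik(Gid, params = recomb_params(0, 0.9),
                             which = "interior")$loglik, 0)
})

test_that("pseudo-ML estimates agree with a fine grid search", {
  map <- small_map()
  G <- sim_chain_genotypes(map, 120, alpha = 0.06, seed = 21)
  fit <- estimate_recomb_params(G)
  grid <- seq(1e-4, 0.3, by = 1e-4)
  ll <- vapply(grid, function(a)
    pseudo_loglik(G, params = recomb_params(a, 0.5),
                  which = "interior")$loglik, numeric(1))
  expect_lt(abs(fit$interior$estimate - grid[which.max(ll)]), 1e-3)
  # the maximizer dominates every grid point
  expect_true(all(fit$interior$loglik >= ll))
  # edge parameter against its own grid
  gridb <- seq(0.01, 0.999, by = 1e-4)
  llb <- vapply(gridb, function(b)
    pseudo_loglik(G, params = recomb_params(0.1, b),
                  which = "edge")$loglik, numeric(1))
  expect_lt(abs(fit$edge$estimate - gridb[which.max(llb)]), 1e-3)
})

test_that("zero observed recombination pushes alpha to the boundary", {
  map <- small_map()
  set.seed(9)
  g <- matrix(rep(rbinom(30, 1, 0.5), times = 10), 30, 10)  # constant rows
  G <- ril_geno(g, map)
  fit <- estimate_recomb_params(G)
  expect_equal(fit$interior$estimate, 0)
  expect_equal(fit$edge$estimate, 1)
  expect_equal(fit$interior$loglik, 0)
})

test_that("homogeneity LRT is near zero for duplicated chromosomes and has df C-1", {
  map <- genetic_map(paste0("m", 1:10), rep(c("A", "B"), each = 5),
                     rep(c(0, 4, 10, 13, 20), 2))
  G1 <- sim_chain_genotypes(
    genetic_map(paste0("x", 1:5), rep("A", 5), c(0, 4, 10, 13, 20)),
    80, alpha = 0.08, seed = 5)
  g <- cbind(G1$geno, G1$geno)  # identical data on both chromosomes
  G <- ril_geno(g, map)
  out <- homogeneity_lrt(G, which = "interior")
  expect_equal(out$df, 1L)
  expect_lt(out$lrt, 1e-6)
  expect_gt(out$p_chisq, 0.99)
  # relabeling chromosomes leaves the statistic unchanged
  map2 <- genetic_map(paste0("m", 1:10), rep(c("Z", "Q"), each = 5),
                      rep(c(0, 4, 10, 13, 20), 2))
  out2 <- homogeneity_lrt(ril_geno(g, map2), which = "interior")
  expect_equal(out2$lrt, out$lrt, tolerance = 1e-9)
})

test_that("bootstrap p-value under the null is not extreme", {
  map <- small_map()
  G <- sim_chain_genotypes(map, 100, alpha = 0.08, seed = 31)
  out <- homogeneity_lrt(G, which = "interior", B = 60, seed = 99)
  expect_gte(out$p_bootstrap, 0.05)
  expect_true(out$lrt >= 0)
  expect_error(homogeneity_lrt(G, which = "interior", B = 10), "seed")
})

test_that("Pearson statistic matches a hand-computed four-term fixture", {
  map <- genetic_map(c("a", "b"), c("1", "1"), c(0, 5))
  g <- rbind(c(1L, 1L), c(0L, 1L))
  G <- ril_geno(g, map)
  prm <- recomb_params(0.1, 0.9)
  pe <- function(xn) 0.5 + 0.5 * ifelse(xn == 1, 1, -1) * 0.9^5
  # terms: a|b and b|a for both RILs
  ps <- c(pe(1), pe(1), pe(1), pe(0))
  xs <- c(1, 1, 0, 1)
  expected <- sum((xs - ps)^2 / (ps * (1 - ps)))
  out <- pearson_gof(G, params = prm, which = "edge")
  expect_equal(out$statistic, expected, tolerance = 1e-12)
  expect_equal(out$df, 3L)
  # perfect-agreement chain at alpha = 0: statistic exactly 0
  Gid <- ril_geno(rbind(c(1L, 1L, 1L)),
                  genetic_map(c("a", "b", "c"), rep("1", 3), c(0, 3, 8)))
  out0 <- pearson_gof(Gid, params = recomb_params(0, 1), which = "interior")
  expect_equal(out0$statistic, 0)
})

test_that("goodness of fit is unexceptional for data simulated from the model", {
  map <- small_map()
  G <- sim_chain_genotypes(map, 150, alpha = 0.07, seed = 13)
  fit <- estimate_recomb_params(G)
  out <- pearson_gof(G, params = fit$params, which = "interior")
  expect_gt(out$p, 0.01)
})

test_that("alpha is recovered from data simulated at a known value", {
  map <- small_map()
  ests <- vapply(1:8, function(s) {
    G <- sim_chain_genotypes(map, 150, alpha = 0.05, seed = 100 + s)
    estimate_recomb_params(G)$interior$estimate
  }, numeric(1))
  expect_lt(abs(median(ests) - 0.05) / 0.05, 0.25)
})
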