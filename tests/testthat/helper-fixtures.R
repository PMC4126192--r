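# Shared fixture builders. Everything is generated in code; no data files.

# Tiny two-chromosome map for fast unit tests
small_map <- function() {
  genetic_map(paste0("m", 1:10),
              chr = rep(c("1", "2"), each = 5),
              pos = rep(c(0, 4, 10, 13, 20), 2))
}

# Simulate binary genotypes from the flanking-marker model's generating
# chain: agreement over a gap of d cM with probability (1 + exp(-alpha d))/2.
# Written independently of the package internals to serve as an oracle
# data-generator for parameter recovery.
sim_chain_genotypes <- function(map, n, alpha, seed) {
  set.seed(seed)
  g <- matrix(NA_integer_, n, nrow(map))
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    g[, idx[1]] <- rbinom(n, 1, 0.5)
    for (j in seq_along(idx)[-1]) {
      d <- map$pos[idx[j]] - map$pos[idx[j - 1]]
      agree <- rbinom(n, 1, (1 + exp(-alpha * d)) / 2)
      g[, idx[j]] <- ifelse(agree == 1, g[, idx[j - 1]], 1L - g[, idx[j - 1]])
    }
  }
  ril_geno(g, map)
}

# Independent closed-form evaluation of the interior bridge probability,
# spelled out directly for use as an oracle.
bridge_prob <- function(x0, x1, dl, dr, a) {
  d0 <- ifelse(x0 == 1, 1, -1); d1 <- ifelse(x1 == 1, 1, -1)
  (1 + d0 * exp(-a * dl)) * (1 + d1 * exp(-a * dr)) /
    (2 * (1 + d0 * d1 * exp(-a * (dl + dr))))
}

# A small design/response/weights fixture with a planted sparse signal
sparse_fixture <- function(n = 60, p = 12, seed = 1, frac_imputed = 0.1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(NULL, paste0("m", seq_len(p))))
  theta <- rep(0, p); theta[c(2, min(7, p))] <- c(0.8, -0.8)
  y <- as.numeric(X %*% theta + rnorm(n, 0, 0.5))
  W <- matrix(1, n, p)
  imp <- matrix(runif(n * p) < frac_imputed, n, p)
  W[imp] <- runif(sum(imp))
  list(X = X, y = y, W = W, theta = theta)
}
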