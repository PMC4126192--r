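# Flanking-marker probability models for binary RIL genotypes, pseudo-ML
# estimation of the recombination-rate parameters, chromosome-homogeneity
# LRT and Pearson goodness of fit.

#' Recombination model parameters
#'
#' Container for the interior-marker rate parameter `alpha` (>= 0, acting
#' like a per-cM recombination rate under an exponential decay of flanking
#' information) and the edge-marker retention parameter `beta` (in \[0, 1\]:
#' the per-cM probability-retention base raised to the distance).
#'
#' @param alpha interior rate parameter, >= 0.
#' @param beta edge retention parameter, in \[0, 1\].
#' @return An object of class `"recomb_params"`.
#' @export
recomb_params <- function(alpha, beta) {
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be finite and >= 0")
  if (!is.finite(beta) || beta < 0 || beta > 1)
    stop("beta must be in [0, 1]")
  structure(list(alpha = alpha, beta = beta), class = "recomb_params")
}

#' @export
print.recomb_params <- function(x, ...) {
  cat(sprintf("Recombination parameters: alpha = %.4g, beta = %.4g\n",
              x$alpha, x$beta))
  invisible(x)
}

# delta coding: x = 1 -> +1 (Sha), x = 0 -> -1 (Bay)
.delta <- function(x) ifelse(x == 1, 1, -1)

#' Interior-marker conditional probability
#'
#' Probability that a marker strictly inside a chromosome carries genotype 1
#' given the genotypes of its two flanking markers and the cM distances to
#' them. The model is the bridge of a symmetric two-state Markov chain in
#' which agreement over a gap of d cM has probability (1 + e^(-alpha d))/2:
#'
#'   P(x = 1 | x0, x1) =
#'     (1 + d0 e^(-a dL)) (1 + d1 e^(-a dR)) / (2 (1 + d0 d1 e^(-a (dL+dR))))
#'
#' with d0, d1 the +/-1 codings of the flanks. At alpha = 0 with agreeing
#' flanks the probability is exactly 0 or 1; as alpha grows it decays to
#' 1/2 (no flanking information); with disagreeing flanks at alpha -> 0 it
#' tends to the linear interpolation d_left / (d_left + d_right).
#'
#' @param x0,x1 left and right flanking genotypes, each 0 or 1 (vectorized).
#' @param d_left,d_right strictly positive cM distances to the flanks.
#' @param alpha rate parameter >= 0.
#' @return Probabilities in \[0, 1\].
#' @export
#' @examples
#' interior_probability(1, 1, 3, 5, alpha = 0)      # 1
#' interior_probability(0, 1, 4, 4, alpha = 0.05)   # 0.5 by symmetry
interior_probability <- function(x0, x1, d_left, d_right, alpha) {
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("alpha must be finite and >= 0")
  if (any(d_left <= 0) || any(d_right <= 0))
    stop("flanking distances must be strictly positive")
  if (any(!(x0 %in% c(0, 1))) || any(!(x1 %in% c(0, 1))))
    stop("flanking genotypes must be 0 or 1")
  d0 <- .delta(x0); d1 <- .delta(x1)
  # expm1-based factors keep precision for alpha*d near 0:
  # 1 + e^-a = 2 + expm1(-a),  1 - e^-a = -expm1(-a)
  f <- function(dlt, a) ifelse(dlt > 0, 2 + expm1(-a), -expm1(-a))
  num <- f(d0, alpha * d_left) * f(d1, alpha * d_right)
  den <- 2 * f(d0 * d1, alpha * (d_left + d_right))
  p <- num / den
  # disagreeing flanks at alpha = 0: 0/0, limit is linear interpolation
  lim <- ifelse(d0 > 0, d_right, d_left) / (d_left + d_right)
  p <- ifelse(den == 0, lim, p)
  pmin(pmax(p, 0), 1)
}

#' Edge-marker conditional probability
#'
#' Probability that a chromosome-edge marker carries genotype 1 given its
#' single immediate neighbor: 1/2 + 1/2 delta(x0) beta^d, where d is the cM
#' distance to the neighbor. The same form serves both chromosome ends
#' (`side` is informational).
#'
#' @param x0 neighbor genotype, 0 or 1 (vectorized).
#' @param d strictly positive cM distance to the neighbor.
#' @param beta retention parameter in \[0, 1\].
#' @param side `"left"` or `"right"` edge of the chromosome.
#' @return Probabilities in \[0, 1\].
#' @export
#' @examples
#' edge_probability(1, 5, 0.9524)  # ~0.8917
edge_probability <- function(x0, d, beta, side = c("right", "left")) {
  match.arg(side)
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1))
    stop("beta must be in [0, 1]")
  if (any(d <= 0)) stop("distance must be strictly positive")
  if (any(!(x0 %in% c(0, 1)))) stop("neighbor genotype must be 0 or 1")
  0.5 + 0.5 * .delta(x0) * beta^d
}

# ---- term extraction -------------------------------------------------------

# Usable interior terms: marker with both immediate map neighbors, all three
# genotypes observed. Complete-triple analysis; missing members are skipped.
interior_terms <- function(G, map) {
  stopifnot(inherits(G, "ril_geno"))
  g <- G$geno
  out <- vector("list", 0L)
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    if (length(idx) < 3L) next
    for (j in 2:(length(idx) - 1L)) {
      cl <- idx[j - 1L]; cm <- idx[j]; cr <- idx[j + 1L]
      ok <- !is.na(g[, cl]) & !is.na(g[, cm]) & !is.na(g[, cr])
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        ril = which(ok), chr = cc, marker = map$marker[cm],
        xl = g[ok, cl], x = g[ok, cm], xr = g[ok, cr],
        dl = map$pos[cm] - map$pos[cl], dr = map$pos[cr] - map$pos[cm],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(ril = integer(0), chr = character(0),
                      marker = character(0), xl = integer(0), x = integer(0),
                      xr = integer(0), dl = numeric(0), dr = numeric(0)))
  do.call(rbind, out)
}

# Usable edge terms: first and last marker of each chromosome conditioned on
# their single immediate neighbor; both members observed.
edge_terms <- function(G, map) {
  stopifnot(inherits(G, "ril_geno"))
  g <- G$geno
  out <- vector("list", 0L)
  add <- function(ce, cn, cc) {
    ok <- !is.na(g[, ce]) & !is.na(g[, cn])
    if (!any(ok)) return(NULL)
    data.frame(ril = which(ok), chr = cc, marker = map$marker[ce],
               xn = g[ok, cn], x = g[ok, ce],
               d = abs(map$pos[ce] - map$pos[cn]), stringsAsFactors = FALSE)
  }
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    if (length(idx) < 2L) next
    m <- length(idx)
    out[[length(out) + 1L]] <- add(idx[1L], idx[2L], cc)
    out[[length(out) + 1L]] <- add(idx[m], idx[m - 1L], cc)
  }
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L)
    return(data.frame(ril = integer(0), chr = character(0),
                      marker = character(0), xn = integer(0), x = integer(0),
                      d = numeric(0)))
  do.call(rbind, out)
}

.bernoulli_ll <- function(x, p) {
  # log P(x) with guard against log(0) only when genuinely impossible
  p <- pmin(pmax(p, 0), 1)
  ll <- ifelse(x == 1, log(p), log1p(-p))
  ll
}

#' Pseudo log-likelihood of the recombination model
#'
#' Sum of conditional Bernoulli log-probabilities over all usable
#' (line, marker) terms: for `which = "interior"`, markers with both
#' immediate neighbors observed; for `which = "edge"`, chromosome-end
#' markers with their single neighbor observed. Terms containing a missing
#' member are skipped.
#'
#' @param G a `"ril_geno"` object.
#' @param map its genetic map (defaults to `G$map`).
#' @param params a [recomb_params()] object.
#' @param which `"interior"` or `"edge"`.
#' @return A list with `loglik` and `n_terms`.
#' @export
pseudo_loglik <- function(G, map = G$map, params,
                          which = c("interior", "edge")) {
  which <- match.arg(which)
  if (which == "interior") {
    tt <- interior_terms(G, map)
    if (nrow(tt) == 0L) stop("no usable interior terms")
    p <- interior_probability(tt$xl, tt$xr, tt$dl, tt$dr, params$alpha)
  } else {
    tt <- edge_terms(G, map)
    if (nrow(tt) == 0L) stop("no usable edge terms")
    p <- edge_probability(tt$xn, tt$d, params$beta)
  }
  list(loglik = sum(.bernoulli_ll(tt$x, p)), n_terms = nrow(tt))
}

# Maximize a 1-D pseudo log-likelihood: coarse log-spaced bracket, then
# Brent within the bracketing interval, then boundary checks.
.maximize_1d <- function(f, lower, upper, grid) {
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- if (i == 1L) lower else grid[i - 1L]
  hi <- if (i == length(grid)) upper else grid[i + 1L]
  opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-9)
  cand_x <- c(opt$maximum, lower, upper, grid[i])
  cand_v <- c(opt$objective, f(lower), f(upper), vals[i])
  j <- which.max(cand_v)
  list(par = cand_x[j], value = cand_v[j])
}

.fit_interior <- function(tt) {
  if (nrow(tt) == 0L) stop("no usable interior terms")
  f <- function(a) sum(.bernoulli_ll(
    tt$x, interior_probability(tt$xl, tt$xr, tt$dl, tt$dr, a)))
  # log(0) = -Inf only arises at the a = 0 boundary with an observed
  # recombination between agreeing flanks; optimize() never lands there
  .maximize_1d(f, lower = 0, upper = 10,
               grid = c(0, 10^seq(-4, 1, length.out = 26)))
}

.fit_edge <- function(tt) {
  if (nrow(tt) == 0L) stop("no usable edge terms")
  f <- function(b) sum(.bernoulli_ll(tt$x, edge_probability(tt$xn, tt$d, b)))
  .maximize_1d(f, lower = 0, upper = 1,
               grid = seq(0, 1, length.out = 41))
}

#' Estimate the recombination parameters by pseudo maximum likelihood
#'
#' Maximizes the interior pseudo log-likelihood over alpha in \[0, 10\] and
#' the edge one over beta in \[0, 1\] by bracketed Brent search (absolute
#' tolerance 1e-9 on the parameter). Parental rows, if present in the file,
#' must be excluded by the caller beforehand.
#'
#' @inheritParams pseudo_loglik
#' @return A list of class `"recomb_fit"` with elements `params`
#'   (a [recomb_params()]), `interior` and `edge` (each `loglik`, `n_terms`,
#'   `estimate`).
#' @export
estimate_recomb_params <- function(G, map = G$map) {
  ti <- interior_terms(G, map)
  te <- edge_terms(G, map)
  fi <- .fit_interior(ti)
  fe <- .fit_edge(te)
  structure(list(
    params = recomb_params(fi$par, fe$par),
    interior = list(loglik = fi$value, n_terms = nrow(ti),
                    estimate = fi$par),
    edge = list(loglik = fe$value, n_terms = nrow(te), estimate = fe$par)),
    class = "recomb_fit")
}

#' @export
print.recomb_fit <- function(x, ...) {
  cat(sprintf(
    "Pseudo-ML recombination fit\n  interior: alpha = %.4g (loglik %.3f, %d terms)\n  edge:     beta  = %.4g (loglik %.3f, %d terms)\n",
    x$interior$estimate, x$interior$loglik, x$interior$n_terms,
    x$edge$estimate, x$edge$loglik, x$edge$n_terms))
  invisible(x)
}

# Simulate genotypes over given marker positions from the fitted symmetric
# Markov chain (agreement over gap d: interior (1+e^(-alpha d))/2, edge
# (1+beta^d)/2), preserving the observed missingness pattern of `g`.
.simulate_chain_like <- function(g, map, agree_fun) {
  sim <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    m <- length(idx)
    x <- matrix(0L, nrow(g), m)
    x[, 1] <- stats::rbinom(nrow(g), 1L, 0.5)
    if (m > 1L) for (j in 2:m) {
      pa <- agree_fun(map$pos[idx[j]] - map$pos[idx[j - 1L]])
      agree <- stats::rbinom(nrow(g), 1L, pa)
      x[, j] <- ifelse(agree == 1L, x[, j - 1L], 1L - x[, j - 1L])
    }
    sim[, idx] <- x
  }
  sim[is.na(g)] <- NA_integer_
  sim
}

#' Chromosome-homogeneity likelihood-ratio test
#'
#' Tests whether a single recombination parameter is adequate across
#' chromosomes against one parameter per chromosome:
#' LRT = -2 (l(shared) - l(per-chromosome)), approximated by a chi-squared
#' with (C - 1) degrees of freedom. Optionally a parametric bootstrap
#' regenerates genotypes under the fitted shared-parameter Markov chain
#' (preserving the missingness pattern) and reports the fraction of
#' replicate LRTs at or above the observed one.
#'
#' @inheritParams pseudo_loglik
#' @param which `"interior"` or `"edge"`.
#' @param B number of bootstrap replicates (0 = skip).
#' @param seed RNG seed, required when `B > 0`.
#' @return A list of class `"homogeneity_lrt"`: `lrt`, `df`, `p_chisq`,
#'   `p_bootstrap` (NA when `B = 0`), `shared`, `per_chromosome`.
#' @export
homogeneity_lrt <- function(G, map = G$map, which = c("interior", "edge"),
                            B = 0, seed = NULL) {
  which <- match.arg(which)
  terms_fun <- if (which == "interior") interior_terms else edge_terms
  fit_fun <- if (which == "interior") .fit_interior else .fit_edge
  observed_lrt <- function(g_obj) {
    tt <- terms_fun(g_obj, map)
    chrs <- unique(tt$chr)
    usable <- chrs[vapply(chrs, function(cc) sum(tt$chr == cc) > 0, logical(1))]
    if (length(usable) < length(unique(map$chr)))
      warning("chromosome(s) without usable terms dropped from the LRT")
    if (length(usable) < 2L) stop("need >= 2 chromosomes with usable terms")
    tt <- tt[tt$chr %in% usable, , drop = FALSE]
    shared <- fit_fun(tt)
    per <- lapply(usable, function(cc) fit_fun(tt[tt$chr == cc, , drop = FALSE]))
    ll_per <- sum(vapply(per, `[[`, numeric(1), "value"))
    list(lrt = max(0, -2 * (shared$value - ll_per)),
         df = length(usable) - 1L,
         shared = shared,
         per = stats::setNames(vapply(per, `[[`, numeric(1), "par"), usable))
  }
  obs <- observed_lrt(G)
  p_boot <- NA_real_
  if (B > 0) {
    if (is.null(seed)) stop("bootstrap requires an explicit seed")
    set.seed(seed)
    par0 <- obs$shared$par
    agree_fun <- if (which == "interior") {
      function(d) (1 + exp(-par0 * d)) / 2
    } else {
      function(d) (1 + par0^d) / 2
    }
    stat_b <- numeric(B)
    for (b in seq_len(B)) {
      gb <- .simulate_chain_like(G$geno, map, agree_fun)
      Gb <- ril_geno(gb, map)
      stat_b[b] <- suppressWarnings(observed_lrt(Gb)$lrt)
    }
    p_boot <- mean(stat_b >= obs$lrt)
  }
  structure(list(lrt = obs$lrt, df = obs$df,
                 p_chisq = stats::pchisq(obs$lrt, obs$df, lower.tail = FALSE),
                 p_bootstrap = p_boot,
                 shared = obs$shared$par, per_chromosome = obs$per,
                 which = which),
            class = "homogeneity_lrt")
}

#' @export
print.homogeneity_lrt <- function(x, ...) {
  cat(sprintf("Homogeneity LRT (%s): LRT = %.3f, df = %d, chi-sq p = %.3f",
              x$which, x$lrt, x$df, x$p_chisq))
  if (!is.na(x$p_bootstrap))
    cat(sprintf(", bootstrap p = %.3f", x$p_bootstrap))
  cat("\n")
  invisible(x)
}

#' Pearson goodness-of-fit test of the recombination model
#'
#' Sums (x - pi)^2 / (pi (1 - pi)) over all usable terms at the supplied
#' parameters, with pi the fitted conditional probability of genotype 1.
#' Degrees of freedom are the number of terms minus the number of fitted
#' parameters (one). Terms with pi in \{0, 1\} contribute 0 when the
#' observation matches the certain prediction and render the statistic
#' infinite (flagged lack of fit) otherwise.
#'
#' @inheritParams pseudo_loglik
#' @return A list with `statistic`, `df`, `p`.
#' @export
pearson_gof <- function(G, map = G$map, params,
                        which = c("interior", "edge")) {
  which <- match.arg(which)
  if (which == "interior") {
    tt <- interior_terms(G, map)
    if (nrow(tt) == 0L) stop("no usable interior terms")
    p <- interior_probability(tt$xl, tt$xr, tt$dl, tt$dr, params$alpha)
  } else {
    tt <- edge_terms(G, map)
    if (nrow(tt) == 0L) stop("no usable edge terms")
    p <- edge_probability(tt$xn, tt$d, params$beta)
  }
  degen <- p <= 0 | p >= 1
  contrib <- numeric(nrow(tt))
  if (any(!degen))
    contrib[!degen] <- (tt$x[!degen] - p[!degen])^2 /
      (p[!degen] * (1 - p[!degen]))
  if (any(degen))
    contrib[degen] <- ifelse(tt$x[degen] == round(p[degen]), 0, Inf)
  stat <- sum(contrib)
  df <- nrow(tt) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}
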