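# Ising-chain genotype simulation, MCAR/MAR missingness, additive-QTL
# traits, and ROC benchmarking of imputation + selection method pipelines.

#' Simulation scenario
#'
#' Bundles the knobs of the benchmarking studies. Defaults emulate the
#' motivating Bay-0 x Shahdara RIL panel: the 69-marker 5-chromosome map,
#' 165 lines, Ising coupling 0.4 on a 1-cM lattice, 10% missingness
#' (MCAR Bernoulli or MAR with a stronger coupling of 0.6 on the
#' missingness chain), 6 true QTLs with alternating effects of +/-0.5,
#' a residual-variance grid of 0.5/1/2/3, and 50 replicates.
#'
#' @param map a `"genmap"`; default [arabidopsis_like_map()].
#' @param n_rils number of lines.
#' @param eta Ising coupling of the genotype chain at 1 cM.
#' @param missing_rate marginal missingness probability in \[0, 1).
#' @param mechanism `"MCAR"`, `"MAR"` or `"none"`.
#' @param eta_mar Ising coupling of the MAR missingness chain.
#' @param qtl_layout `"evenly_spaced"` or `"clustered"`.
#' @param n_qtl number of true QTLs.
#' @param effects signed QTL effect sizes, length `n_qtl`.
#' @param sigma2 residual-variance grid.
#' @param n_reps replicates per setting.
#' @param seed base RNG seed.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(map = arabidopsis_like_map(), n_rils = 165,
                         eta = 0.4, missing_rate = 0.1,
                         mechanism = c("MCAR", "MAR", "none"),
                         eta_mar = 0.6,
                         qtl_layout = c("evenly_spaced", "clustered"),
                         n_qtl = 6, effects = rep(c(0.5, -0.5), 3),
                         sigma2 = c(0.5, 1, 2, 3), n_reps = 50,
                         seed = 1) {
  mechanism <- match.arg(mechanism)
  qtl_layout <- match.arg(qtl_layout)
  stopifnot(inherits(map, "genmap"), n_rils >= 2,
            missing_rate >= 0, missing_rate < 1,
            n_qtl <= nrow(map), length(effects) == n_qtl)
  structure(list(map = map, n_rils = n_rils, eta = eta,
                 missing_rate = missing_rate, mechanism = mechanism,
                 eta_mar = eta_mar, qtl_layout = qtl_layout, n_qtl = n_qtl,
                 effects = effects, sigma2 = sigma2, n_reps = n_reps,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# Agreement probability of neighboring Ising spins at coupling eta
.ising_agree <- function(eta) exp(eta) / (exp(eta) + exp(-eta))

#' Simulate RIL genotypes on a 1-cM lattice
#'
#' Per chromosome and line, a stationary binary Markov chain with marginal
#' 1/2 and neighbor-agreement probability `exp(eta) / (exp(eta) +
#' exp(-eta))` is simulated at 1-cM spacing over the rounded chromosome
#' length; chromosomes are independent. The observed matrix reads the
#' lattice off at the map positions rounded to the nearest lattice site.
#'
#' @param scenario a [sim_scenario()].
#' @param seed RNG seed (default `scenario$seed`).
#' @return A list: `full` (a `"ril_geno"` on the lattice map) and
#'   `observed` (a `"ril_geno"` on `scenario$map`).
#' @export
simulate_genotypes <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  map <- scenario$map
  n <- scenario$n_rils
  pa <- .ising_agree(scenario$eta)
  chrs <- unique(map$chr)
  lat_marker <- character(0); lat_chr <- character(0); lat_pos <- numeric(0)
  full_cols <- list()
  obs <- matrix(NA_integer_, n, nrow(map))
  for (cc in chrs) {
    idx <- which(map$chr == cc)
    L <- round(max(map$pos[idx]))
    m <- L + 1L  # lattice sites at 0..L cM
    x <- matrix(0L, n, m)
    x[, 1] <- stats::rbinom(n, 1L, 0.5)
    if (m > 1L) for (j in 2:m) {
      agree <- stats::rbinom(n, 1L, pa)
      x[, j] <- ifelse(agree == 1L, x[, j - 1L], 1L - x[, j - 1L])
    }
    full_cols[[cc]] <- x
    lat_marker <- c(lat_marker, paste0("c", cc, "_", 0:L))
    lat_chr <- c(lat_chr, rep(cc, m))
    lat_pos <- c(lat_pos, 0:L)
    site <- pmin(pmax(round(map$pos[idx]), 0), L) + 1L
    obs[, idx] <- x[, site]
  }
  full_map <- genetic_map(lat_marker, lat_chr, lat_pos)
  ids <- paste0("RIL", seq_len(n))
  list(full = ril_geno(do.call(cbind, full_cols), full_map, ids),
       observed = ril_geno(obs, map, ids))
}

# Solve the external field h of a two-state Ising chain (coupling eta,
# states +/-1) so that the stationary probability of state 1 equals `rate`.
# Transition: P(s' = 1 | s) = plogis(2 (h + eta * s)).
.mar_field <- function(rate, eta) {
  statp <- function(h) {
    a <- stats::plogis(2 * (h + eta))  # 1 -> 1
    b <- stats::plogis(2 * (h - eta))  # 0 -> 1
    b / (1 - a + b)
  }
  stats::uniroot(function(h) statp(h) - rate, c(-25, 25),
                 tol = 1e-12)$root
}

#' Apply a missingness mechanism
#'
#' MCAR: every entry independently missing with probability `rate`.
#' MAR: per line and chromosome, missingness indicators along the marker
#' order follow a two-state Ising chain with coupling `eta_mar` and an
#' external field calibrated (from the stationary equations) so the
#' marginal missing probability equals `rate`; missing entries then cluster
#' along the chromosome as a sequentially operating genotyping instrument
#' would produce.
#'
#' @param G a complete `"ril_geno"`.
#' @param mechanism `"MCAR"`, `"MAR"` or `"none"`.
#' @param rate marginal missingness probability in \[0, 1).
#' @param eta_mar MAR chain coupling.
#' @param seed RNG seed.
#' @return A `"ril_geno"` with `NA` entries.
#' @export
apply_missingness <- function(G, mechanism = c("MCAR", "MAR", "none"),
                              rate = 0.1, eta_mar = 0.6, seed = 1) {
  mechanism <- match.arg(mechanism)
  if (rate >= 1) stop("rate must be < 1")
  if (mechanism == "none" || rate == 0) return(G)
  set.seed(seed)
  g <- G$geno
  map <- G$map
  if (mechanism == "MCAR") {
    drop <- matrix(stats::rbinom(length(g), 1L, rate) == 1L,
                   nrow(g), ncol(g))
    g[drop] <- NA_integer_
  } else {
    h <- .mar_field(rate, eta_mar)
    a <- stats::plogis(2 * (h + eta_mar))
    b <- stats::plogis(2 * (h - eta_mar))
    for (cc in unique(map$chr)) {
      idx <- which(map$chr == cc)
      m <- length(idx)
      s <- matrix(0L, nrow(g), m)
      s[, 1] <- stats::rbinom(nrow(g), 1L, rate)
      if (m > 1L) for (j in 2:m) {
        p1 <- ifelse(s[, j - 1L] == 1L, a, b)
        s[, j] <- stats::rbinom(nrow(g), 1L, p1)
      }
      gm <- g[, idx, drop = FALSE]
      gm[s == 1L] <- NA_integer_
      g[, idx] <- gm
    }
  }
  ril_geno(g, map)
}

#' Place true QTLs on the map
#'
#' `"evenly_spaced"` picks marker indices `floor((k + 1/2) M / n_qtl) + 1`
#' over all `M` markers; `"clustered"` puts `ceiling(n_qtl/2)` QTLs in the
#' first half of chromosome 1 and the rest in the first half of
#' chromosome 2, evenly within each. Both layouts are deterministic.
#'
#' @param map a `"genmap"`.
#' @param layout `"evenly_spaced"` or `"clustered"`.
#' @param n_qtl number of QTLs.
#' @return Sorted integer marker indices.
#' @export
place_qtls <- function(map, layout = c("evenly_spaced", "clustered"),
                       n_qtl = 6) {
  layout <- match.arg(layout)
  M <- nrow(map)
  if (n_qtl > M) stop("more QTLs than markers")
  if (layout == "evenly_spaced") {
    idx <- floor((seq_len(n_qtl) - 0.5) * M / n_qtl) + 1L
  } else {
    chrs <- unique(map$chr)
    if (length(chrs) < 2L) stop("clustered layout needs >= 2 chromosomes")
    n1 <- ceiling(n_qtl / 2); n2 <- n_qtl - n1
    pick_half <- function(cc, k) {
      ci <- which(map$chr == cc)
      half <- ci[map$pos[ci] <= max(map$pos[ci]) / 2]
      if (length(half) < k)
        stop("chromosome ", cc, " first half has fewer than ", k, " markers")
      half[floor((seq_len(k) - 0.5) * length(half) / k) + 1L]
    }
    idx <- c(pick_half(chrs[1], n1), pick_half(chrs[2], n2))
  }
  sort(unique(as.integer(idx)))
}

#' Simulate an additive trait
#'
#' `y_i = sum_k effects_k x_{i, qtl_k} + e_i`, `e_i ~ N(0, sigma2)`.
#'
#' @param G a complete `"ril_geno"`.
#' @param qtl_idx marker indices of the true QTLs.
#' @param effects signed effects, one per QTL.
#' @param sigma2 residual variance.
#' @param seed RNG seed.
#' @return Numeric response of length `nrow(G$geno)`.
#' @export
simulate_trait <- function(G, qtl_idx, effects, sigma2, seed = 1) {
  stopifnot(length(qtl_idx) == length(effects))
  set.seed(seed)
  mu <- as.numeric(G$geno[, qtl_idx, drop = FALSE] %*% effects)
  mu + stats::rnorm(length(mu), 0, sqrt(sigma2))
}

#' Confusion counts and rates of a selected marker set
#'
#' @param selected logical vector (or index vector) of selected markers.
#' @param truth indices of the true QTLs.
#' @param p total marker count.
#' @return Named vector `TP, FP, TN, FN, TPR, FPR`.
#' @export
selection_confusion <- function(selected, truth, p) {
  if (!is.logical(selected)) {
    sel <- rep(FALSE, p); sel[selected] <- TRUE; selected <- sel
  }
  is_true <- rep(FALSE, p); is_true[truth] <- TRUE
  tp <- sum(selected & is_true); fp <- sum(selected & !is_true)
  fn <- sum(!selected & is_true); tn <- sum(!selected & !is_true)
  c(TP = tp, FP = fp, TN = tn, FN = fn,
    TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

# Trapezoidal area under a (FPR, TPR) point set, anchored at (0,0), (1,1)
.roc_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  x <- c(0, fpr[o], 1); y <- c(0, tpr[o], 1)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

.study_methods <- c("model1", "model2", "model3", "model4", "wlasso",
                    "lasso", "alasso_0.5", "alasso_1", "alasso_2")

# Per-method pieces: the imputer and the selector sweep. "model1"/"wlasso"
# = model imputation + weighted lasso; "model2" model imputation +
# regression scan; "model3"/"model4" nearest-marker variants; the lasso and
# adaptive-lasso baselines use the model-imputed genotypes rounded to 0/1
# with the weighting ignored.
.method_parts <- function(method) {
  if (!method %in% .study_methods) stop("unknown method: ", method)
  imputer <- if (method %in% c("model3", "model4")) "nearest" else "model"
  selector <- switch(method,
    model1 = , wlasso = "wlasso",
    model2 = , model4 = "mreg",
    model3 = "wlasso",
    lasso = "lasso",
    "alasso")
  gamma <- if (selector == "alasso")
    as.numeric(sub("alasso_", "", method)) else NA_real_
  list(imputer = imputer, selector = selector, gamma = gamma)
}

# Selection sweep: logical p x n_sweep matrix over the method's grid.
.sweep_selected <- function(parts, Xc, W, y, lambda, thresholds,
                            cd_tol = 1e-6) {
  if (parts$selector == "wlasso") {
    fit <- wlasso_path(Xc, y, W, lambda = lambda, cd_tol = cd_tol)
    fit$coef != 0
  } else if (parts$selector == "lasso") {
    lasso_path(Xc, y, lambda = lambda, tol = cd_tol)$coef != 0
  } else if (parts$selector == "alasso") {
    adaptive_lasso_path(Xc, y, gamma = parts$gamma, lambda = lambda,
                        tol = cd_tol)$coef != 0
  } else {
    multiple_regression_scan(Xc, y, thresholds = thresholds)$selected
  }
}

#' Run a benchmarking study
#'
#' For each replicate: simulate complete genotypes, generate the trait from
#' them, apply the missingness mechanism, and for every method impute the
#' genotypes, sweep its selection path (lambda grid for the lasso family,
#' significance thresholds for the regression scan), and record the
#' confusion counts against the true QTLs at every sweep point. TPR and FPR
#' are averaged pointwise over replicates on a grid shared by all
#' replicates (fixed from the first replicate for the lasso family);
#' the AUC of the averaged curve is the summary accuracy measure.
#'
#' @param scenario a [sim_scenario()]; its first `sigma2` entry is used
#'   (see [run_simulation_study()] for the full grid).
#' @param methods subset of `model1, model2, model3, model4, wlasso, lasso,
#'   alasso_0.5, alasso_1, alasso_2` (`wlasso` is an alias of `model1`).
#' @param sigma2 residual variance override (scalar).
#' @param n_reps replicate override.
#' @return A list of class `"sim_study"`: per-method `roc` (data frame with
#'   sweep index, mean TPR, mean FPR), `auc`, `confusion` (per-replicate
#'   counts at every sweep point), plus `truth` and the scenario.
#' @export
run_study <- function(scenario, methods = c("model1", "model3"),
                      sigma2 = scenario$sigma2[1],
                      n_reps = scenario$n_reps) {
  if (length(methods) == 0L) stop("empty method list")
  parts <- lapply(stats::setNames(methods, methods), .method_parts)
  map <- scenario$map
  p <- nrow(map)
  truth <- place_qtls(map, scenario$qtl_layout, scenario$n_qtl)
  thresholds <- seq(0.015, by = 0.015, length.out = 67)
  lambda <- NULL  # fixed from replicate 1, shared by all replicates
  acc <- list()
  for (r in seq_len(n_reps)) {
    seed_r <- scenario$seed + 7L * r
    sim <- simulate_genotypes(scenario, seed = seed_r)
    y <- simulate_trait(sim$observed, truth, scenario$effects,
                        sigma2, seed = seed_r + 1L)
    Gm <- apply_missingness(sim$observed, scenario$mechanism,
                            scenario$missing_rate, scenario$eta_mar,
                            seed = seed_r + 2L)
    imps <- list()
    need <- unique(vapply(parts, `[[`, character(1), "imputer"))
    if ("model" %in% need) {
      fitp <- estimate_recomb_params(Gm)
      imps$model <- impute_genotypes(Gm, params = fitp$params)
    }
    if ("nearest" %in% need)
      imps$nearest <- nearest_marker_impute(Gm)
    if (is.null(lambda)) {
      Xr <- imps[[need[1]]]$genotypes
      lambda <- lambda_grid(Xr, y)
    }
    for (m in methods) {
      imp <- imps[[parts[[m]]$imputer]]
      sel <- .sweep_selected(parts[[m]], imp$genotypes, imp$weights, y,
                             lambda, thresholds)
      conf <- t(apply(sel, 2, selection_confusion, truth = truth, p = p))
      acc[[m]][[r]] <- conf
    }
  }
  out <- lapply(stats::setNames(methods, methods), function(m) {
    tpr <- rowMeans(sapply(acc[[m]], function(z) z[, "TPR"]))
    fpr <- rowMeans(sapply(acc[[m]], function(z) z[, "FPR"]))
    roc <- data.frame(sweep = seq_along(tpr), TPR = tpr, FPR = fpr)
    list(roc = roc, auc = .roc_auc(fpr, tpr), confusion = acc[[m]])
  })
  structure(list(methods = out, truth = truth, sigma2 = sigma2,
                 n_reps = n_reps, scenario = scenario, lambda = lambda),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Simulation study: %d reps, sigma2 = %g, mechanism %s, %d true QTLs\n",
    x$n_reps, x$sigma2, x$scenario$mechanism, length(x$truth)))
  for (m in names(x$methods))
    cat(sprintf("  %-10s AUC = %.3f\n", m, x$methods[[m]]$auc))
  invisible(x)
}

#' Mean AUC per method of a study
#'
#' @param study a `"sim_study"`.
#' @return Named numeric vector of AUCs.
#' @export
study_auc <- function(study) {
  vapply(study$methods, `[[`, numeric(1), "auc")
}

#' Experiment-to-simulation variance equivalence
#'
#' Converts a per-observation experimental setting (effect size
#' `theta_exp`, residual variance `sigma2_exp`, `n_cond` replicate
#' conditions per line) to the per-line residual variance of a simulation
#' with effect size `theta_sim`:
#' `sigma2_exp (theta_sim / theta_exp)^2 / n_cond`. Used to locate a real
#' trait on the simulated ROC ladder.
#'
#' @param sigma2_exp experimental residual variance.
#' @param theta_exp experimental effect size.
#' @param theta_sim simulation effect size.
#' @param n_cond observations (conditions) per line.
#' @return Equivalent simulation residual variance.
#' @export
equivalent_sim_variance <- function(sigma2_exp, theta_exp, theta_sim,
                                    n_cond) {
  sigma2_exp * (theta_sim / theta_exp)^2 / n_cond
}
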