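# Sparse marker selection: the weighted lasso with iterative observation
# reweighting and BIC tuning, plus the comparison methods (ordinary lasso,
# adaptive lasso, multiple-regression scan) and per-marker LRT/LOD scores.

#' @useDynLib wlassoqtl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.check_xy <- function(X, y, W = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  if (!is.null(W)) {
    W <- as.matrix(W); storage.mode(W) <- "double"
    if (!all(dim(W) == dim(X))) stop("W must have the dimensions of X")
    if (any(!is.finite(W)) || any(W < 0) || any(W > 1))
      stop("W entries must lie in [0, 1]")
  }
  list(X = X, y = y, W = W)
}

#' Default penalty grid
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty at which
#' every coefficient is zero, `2 max_j |x_j' y| / pf_j`) down to
#' `lambda_max / 1000`.
#'
#' @param X design matrix.
#' @param y response.
#' @param pf per-coefficient penalty factors (default 1).
#' @param nlambda grid length.
#' @param ratio smallest/largest lambda ratio.
#' @return Descending numeric vector.
#' @export
lambda_grid <- function(X, y, pf = rep(1, ncol(X)), nlambda = 100,
                        ratio = 1e-3) {
  chk <- .check_xy(X, y)
  score <- abs(crossprod(chk$X, chk$y)) / pf
  lmax <- 2 * max(score[is.finite(score)], 0)
  if (lmax <= 0) lmax <- 1  # all-zero response: any grid gives the null path
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

#' Ordinary lasso coefficient path
#'
#' L1-penalized least squares `sum_i (y_i - x_i' theta)^2 +
#' lambda sum_j |theta_j|`, solved by warm-started cyclic coordinate
#' descent over a descending lambda grid. No intercept and no column
#' standardization: the response is expected to be a centered residual and
#' the columns are 0/1 genotypes.
#'
#' @inheritParams lambda_grid
#' @param lambda descending penalty grid; default [lambda_grid()].
#' @param pf per-coefficient penalty factors (adaptive-lasso weights);
#'   `Inf` pins a coefficient at zero.
#' @param tol coordinate-descent convergence tolerance on the max
#'   coefficient change.
#' @param max_pass maximum coordinate-descent sweeps per lambda.
#' @return A list of class `"lasso_path"`: `lambda`, `coef` (p x nlambda),
#'   `df` (nonzero counts per lambda).
#' @export
lasso_path <- function(X, y, lambda = NULL, pf = rep(1, ncol(X)),
                       tol = 1e-7, max_pass = 1000L) {
  chk <- .check_xy(X, y)
  if (is.null(lambda)) lambda <- lambda_grid(chk$X, chk$y, pf = pf)
  if (any(diff(lambda) >= 0)) stop("lambda grid must be strictly descending")
  cf <- cd_path(chk$X, chk$y, rep(1, nrow(chk$X)), pf, lambda, tol,
                as.integer(max_pass))
  rownames(cf) <- colnames(X)
  structure(list(lambda = lambda, coef = cf, df = colSums(cf != 0)),
            class = "lasso_path")
}

#' Weighted lasso coefficient path
#'
#' The weighted lasso downweights observations in proportion to how much
#' they rely on uncertain imputations at markers that currently matter.
#' For each lambda, starting from the ordinary-lasso solution (equivalent
#' to unit observation weights), it alternates
#'
#'   w_i = sum_j w_ij |theta_j| / sum_j |theta_j|
#'
#' (w_i = 1 when all coefficients are zero: no relevance information yet)
#' with the weighted L1 fit `sum_i w_i (y_i - x_i' theta)^2 +
#' lambda sum_j |theta_j|`, stopping when the squared Euclidean change of
#' the weight vector drops below `tol` or `max_iter` is reached (flagged).
#' Observations whose certainty weights are zero on every active marker
#' are thereby eliminated; fully observed rows keep weight one, so with
#' `W` all ones the path is the ordinary lasso.
#'
#' @param X design matrix of completed 0/1 genotypes (rows = responses).
#' @param y response vector (adjusted residuals).
#' @param W matrix of per-entry imputation certainty weights in \[0, 1\],
#'   same shape as `X`.
#' @param lambda descending penalty grid; default [lambda_grid()].
#' @param tol convergence threshold on the squared weight-vector change
#'   (default 1e-8).
#' @param max_iter maximum reweighting iterations per lambda.
#' @param keep_trace record the weight vector at every iteration.
#' @param cd_tol,cd_max_pass inner coordinate-descent controls.
#' @return A list of class `"wlasso_fit"`: `lambda`, `coef` (p x nlambda),
#'   `df`, `n_iter` per lambda, `converged` flags, `obs_weights`
#'   (n x nlambda, final), and optionally `obs_weights_trace` (per-lambda
#'   iteration x n matrices).
#' @export
wlasso_path <- function(X, y, W, lambda = NULL, tol = 1e-8, max_iter = 50L,
                        keep_trace = FALSE, cd_tol = 1e-7,
                        cd_max_pass = 1000L) {
  chk <- .check_xy(X, y, W)
  X <- chk$X; y <- chk$y; W <- chk$W
  n <- nrow(X); p <- ncol(X)
  if (is.null(lambda)) lambda <- lambda_grid(X, y)
  init <- lasso_path(X, y, lambda = lambda, tol = cd_tol,
                     max_pass = cd_max_pass)
  L <- length(lambda)
  cf <- init$coef
  n_iter <- integer(L)
  converged <- logical(L)
  ow <- matrix(1, n, L)
  trace <- if (keep_trace) vector("list", L) else NULL
  pf <- rep(1, p)
  for (l in seq_len(L)) {
    theta <- cf[, l]
    w_prev <- rep(1, n)   # the lasso initialization is the unit-weight fit
    tr <- if (keep_trace) list(w_prev) else NULL
    k <- 0L
    best_obj <- Inf; best_theta <- theta; best_w <- w_prev
    repeat {
      s <- abs(theta); tot <- sum(s)
      w <- if (tot == 0) rep(1, n) else
        pmin(pmax(as.numeric(W %*% s) / tot, 0), 1)  # guard FP round-off
      if (keep_trace) tr[[length(tr) + 1L]] <- w
      # the estimator is the minimizer of the self-weighted objective; the
      # alternation is not monotone in it, so keep the best visited iterate
      obj <- sum(w * (y - X %*% theta)^2) + lambda[l] * tot
      if (obj < best_obj) {
        best_obj <- obj; best_theta <- theta; best_w <- w
      }
      if (sum((w - w_prev)^2) < tol) { converged[l] <- TRUE; break }
      if (k >= max_iter) break
      k <- k + 1L
      theta <- as.numeric(cd_solve(X, y, w, pf, lambda[l], theta,
                                   cd_tol, as.integer(cd_max_pass)))
      w_prev <- w
    }
    cf[, l] <- best_theta
    n_iter[l] <- k
    ow[, l] <- best_w
    if (keep_trace) trace[[l]] <- do.call(rbind, tr)
  }
  if (!all(converged))
    warning(sum(!converged), " lambda value(s) hit max_iter without ",
            "weight convergence")
  rownames(cf) <- colnames(X)
  structure(list(lambda = lambda, coef = cf, df = colSums(cf != 0),
                 n_iter = n_iter, converged = converged, obs_weights = ow,
                 obs_weights_trace = trace),
            class = c("wlasso_fit", "lasso_path"))
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("%s: %d markers, %d lambda values (df %d..%d)\n",
              if (inherits(x, "wlasso_fit")) "Weighted lasso path"
              else "Lasso path",
              nrow(x$coef), length(x$lambda), min(x$df), max(x$df)))
  if (inherits(x, "wlasso_fit"))
    cat(sprintf("  reweighting iterations: median %g, max %d\n",
                stats::median(x$n_iter), max(x$n_iter)))
  invisible(x)
}

# Robust lambda-independent variance scale for the BIC: full-OLS residual
# variance when p < n, else a MAD-based estimate of var(y).
.bic_s2 <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  if (p < n) {
    fit <- stats::lm.fit(cbind(1, X), y)
    rdf <- n - fit$rank
    if (rdf > 0) return(sum(fit$residuals^2) / rdf)
  }
  stats::mad(y)^2
}

#' BIC selection along a penalty path
#'
#' `BIC(lambda) = RSS(lambda) / s2 + df(lambda) log(n)` with `s2` a robust
#' variance scale held fixed across lambda and `df` the nonzero-coefficient
#' count. Ties break toward the larger lambda (the sparser model).
#'
#' @param fit a `"lasso_path"` or `"wlasso_fit"`.
#' @param X,y the data the path was fitted on.
#' @param s2 variance scale; default full-OLS residual variance when
#'   `p < n`, else squared MAD of `y`.
#' @return A list: `lambda_star`, `index`, `selected` (marker indices, named
#'   when `X` has column names), `bic`, `df`, `s2`.
#' @export
bic_select <- function(fit, X, y, s2 = NULL) {
  chk <- .check_xy(X, y)
  X <- chk$X; y <- chk$y
  n <- length(y)
  if (is.null(s2)) s2 <- .bic_s2(X, y)
  rss <- colSums((y - X %*% fit$coef)^2)
  bic <- rss / s2 + fit$df * log(n)
  idx <- which.min(bic)  # grid is descending, so the first min is sparser
  sel <- which(fit$coef[, idx] != 0)
  list(lambda_star = fit$lambda[idx], index = idx, selected = sel,
       bic = bic, df = fit$df, s2 = s2)
}

#' Adaptive lasso coefficient path
#'
#' Per-coefficient penalty factors `1 / |theta_OLS_j|^gamma` from an
#' unpenalized least-squares fit; predictors with a zero OLS coefficient
#' receive an infinite penalty and stay at zero.
#'
#' @inheritParams lasso_path
#' @param gamma penalty-weight exponent, conventionally 0.5, 1 or 2.
#' @return A `"lasso_path"` with extra elements `gamma` and `pf`.
#' @export
adaptive_lasso_path <- function(X, y, gamma = 1, lambda = NULL,
                                tol = 1e-7, max_pass = 1000L) {
  chk <- .check_xy(X, y)
  X <- chk$X; y <- chk$y
  if (ncol(X) >= nrow(X))
    stop("adaptive lasso needs p < n for the OLS initial fit")
  ols <- stats::lm.fit(X, y)$coefficients
  ols[is.na(ols)] <- 0
  pf <- ifelse(ols == 0, Inf, 1 / abs(ols)^gamma)
  if (is.null(lambda)) lambda <- lambda_grid(X, y, pf = pf)
  out <- lasso_path(X, y, lambda = lambda, pf = pf, tol = tol,
                    max_pass = max_pass)
  out$gamma <- gamma
  out$pf <- pf
  out
}

#' Multiple-regression significance scan
#'
#' One full OLS fit of the response on all markers; at each significance
#' threshold the markers whose coefficient t-test p-value is at or below
#' the threshold are selected. The default grid sweeps \[0, 1\] in
#' increments of 0.015 (67 steps), the conventional sweep matching the
#' resolution of a 100-point lasso path.
#'
#' @param X design matrix with `p < n`.
#' @param y response.
#' @param thresholds significance-level sweep.
#' @return A list of class `"mreg_scan"`: `thresholds`, `p_values` (per
#'   marker), `selected` (p x n_thresholds logical matrix).
#' @export
multiple_regression_scan <- function(X, y,
                                     thresholds = seq(0.015, by = 0.015,
                                                      length.out = 67)) {
  chk <- .check_xy(X, y)
  X <- chk$X; y <- chk$y
  if (ncol(X) >= nrow(X)) stop("regression scan needs p < n")
  fit <- stats::lm(y ~ X)
  cf <- stats::coef(fit)
  if (any(is.na(cf[-1]))) stop("singular design in regression scan")
  pv <- stats::summary.lm(fit)$coefficients[-1, 4]
  sel <- outer(pv, thresholds, `<=`)
  rownames(sel) <- colnames(X)
  structure(list(thresholds = thresholds, p_values = pv, selected = sel),
            class = "mreg_scan")
}

#' Per-marker LRT / LOD scores
#'
#' For each marker in the design, the likelihood-ratio statistic comparing
#' the OLS fit on all supplied markers against the fit without that marker,
#' on a base-10 logarithmic scale (the LOD score):
#' `(n/2) log10(RSS_without / RSS_with)`. Scores below 0.01 are reported
#' as 0. `X` may be either the selected marker set or all markers.
#'
#' @param X design matrix of the marker set to score (columns = markers).
#' @param y response.
#' @return A data frame with columns `marker` and `score` (`NA` with a
#'   warning for markers made redundant by exact collinearity of the
#'   remaining design).
#' @export
marker_lrt_scores <- function(X, y) {
  chk <- .check_xy(X, y)
  X <- chk$X; y <- chk$y
  if (ncol(X) < 1L) stop("marker set is empty")
  n <- length(y)
  full <- stats::lm.fit(cbind(1, X), y)
  rss_full <- sum(full$residuals^2)
  score <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    red <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    rss_red <- sum(red$residuals^2)
    score[j] <- if (rss_full <= 0) {
      NA_real_
    } else {
      (n / 2) * log10(rss_red / rss_full)
    }
  }
  if (anyNA(score))
    warning("zero full-model RSS; scores undefined")
  score <- ifelse(!is.na(score) & score < 0.01, 0, score)
  data.frame(marker = colnames(X) %||% paste0("m", seq_len(ncol(X))),
             score = score, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
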