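# Nuisance-covariate adjustment of raw trait observations and mapping of
# residuals onto genotype rows.

#' Adjust a trait for nuisance covariates
#'
#' Fits an ordinary least-squares regression of the trait on the named
#' covariates (with intercept; categorical covariates expand to treatment
#' contrasts with lexicographically ordered levels) and returns the
#' residuals, which downstream marker selection uses as the response.
#' Rows with a missing trait value are dropped.
#'
#' @param pheno a phenotype data frame as from [read_phenotypes()], with a
#'   `ril_id` column.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (may be
#'   empty: residuals are then the centered trait).
#' @return A list of class `"adjusted_phenotype"`: `residuals`, `ril_index`
#'   (parallel line ids), `n_params` (fitted coefficient count),
#'   `sigma2_hat` (residual variance), `fit` (the `lm` object).
#' @export
adjust_phenotypes <- function(pheno, trait, covariates = character(0)) {
  if (!trait %in% names(pheno)) stop("trait column not found: ", trait)
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov))
    stop("covariates not found: ", paste(missing_cov, collapse = ", "))
  keep <- !is.na(pheno[[trait]])
  d <- pheno[keep, , drop = FALSE]
  for (v in covariates) {
    if (is.character(d[[v]]) || is.factor(d[[v]]))
      d[[v]] <- factor(as.character(d[[v]]),
                       levels = sort(unique(as.character(d[[v]]))))
  }
  fml <- if (length(covariates)) {
    stats::reformulate(covariates, response = trait)
  } else {
    stats::as.formula(paste(trait, "~ 1"))
  }
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient nuisance design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  res <- stats::residuals(fit)
  k <- length(stats::coef(fit))
  structure(list(residuals = unname(res),
                 ril_index = d$ril_id,
                 n_params = k,
                 sigma2_hat = sum(res^2) / max(1L, length(res) - k),
                 fit = fit),
            class = "adjusted_phenotype")
}

#' @export
print.adjusted_phenotype <- function(x, ...) {
  cat(sprintf(
    "Adjusted phenotype: %d residuals, %d nuisance parameters, sigma2 = %.4g\n",
    length(x$residuals), x$n_params, x$sigma2_hat))
  invisible(x)
}

#' Map residuals onto genotype rows
#'
#' Aligns adjusted residuals with the lines of a genotype matrix. In
#' `"replicate_rows"` mode every observation keeps its own residual and the
#' genotype row of its line is repeated; in `"mean_per_ril"` mode residuals
#' are averaged to one response per line.
#'
#' @param adj an `"adjusted_phenotype"`.
#' @param ril_ids line identifiers of the genotype matrix rows (e.g.
#'   `rownames(G$geno)`).
#' @param mode `"replicate_rows"` or `"mean_per_ril"`.
#' @return A list with `y` (response vector) and `row_index` (for each
#'   response, the genotype row it points at).
#' @export
aggregate_to_rils <- function(adj, ril_ids,
                              mode = c("replicate_rows", "mean_per_ril")) {
  mode <- match.arg(mode)
  ril_ids <- as.character(ril_ids)
  unknown <- setdiff(unique(adj$ril_index), ril_ids)
  if (length(unknown))
    stop("lines absent from the genotype matrix: ",
         paste(unknown, collapse = ", "))
  if (mode == "replicate_rows") {
    list(y = adj$residuals, row_index = match(adj$ril_index, ril_ids))
  } else {
    means <- tapply(adj$residuals, adj$ril_index, mean)
    present <- ril_ids[ril_ids %in% names(means)]
    list(y = as.numeric(means[present]), row_index = match(present, ril_ids))
  }
}
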