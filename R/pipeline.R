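# End-to-end orchestration: the real-data workflow (estimate -> impute ->
# adjust -> wlasso -> scores) and the simulation studies, with config
# handling and file reports.

#' Read a run configuration
#'
#' JSON (via jsonlite) or YAML (via the yaml package, when installed) with
#' fields such as `genotypes`, `map_file`, `dialect`, `phenotypes`,
#' `trait`, `covariates`, `parental_ids`, `mode`, `marker_set`, `seed`,
#' `out_dir`.
#'
#' @param path config file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

.cfg_default <- function(cfg, name, default) {
  if (is.null(cfg[[name]])) default else cfg[[name]]
}

#' Full QTL analysis pipeline
#'
#' Runs the two-step workflow on real data: estimate the recombination
#' parameters by pseudo ML (after excluding parental rows), impute missing
#' genotypes with certainty weights, adjust the trait for nuisance
#' covariates, map residuals to genotype rows, fit the weighted lasso path,
#' select the penalty by BIC, and score the selected markers with LRT/LOD
#' statistics.
#'
#' @param cfg a config list (see [read_run_config()]) or a path to one.
#'   Required fields: `genotypes`, `phenotypes`, `trait`. Optional:
#'   `dialect`, `map_file`, `covariates`, `parental_ids`, `mode`
#'   (`"replicate_rows"`, the default, or `"mean_per_ril"`), `marker_set`
#'   (`"selected_set"` or `"all_markers"` for the scores), `seed`,
#'   `out_dir` (when set, writes `scores.csv` and `report.json`).
#' @return A list of class `"qtl_report"`: `params`, `fit` (pseudo-ML
#'   report), `imputation`, `wlasso`, `bic`, `scores` (marker, chromosome,
#'   cM, score), `seed`, `config`.
#' @export
run_qtl_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  for (f in c("genotypes", "phenotypes", "trait"))
    if (is.null(cfg[[f]])) stop("config field missing: ", f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  seed <- as.integer(.cfg_default(cfg, "seed", 1L))
  G <- stage("read", read_genotypes(cfg$genotypes,
                                    dialect = .cfg_default(cfg, "dialect",
                                                           "rqtl_csv"),
                                    map_file = cfg$map_file))
  parental <- .cfg_default(cfg, "parental_ids", character(0))
  Gc <- if (length(parental)) {
    keep <- !(rownames(G$geno) %in% parental)
    ril_geno(G$geno[keep, , drop = FALSE], G$map)
  } else G
  fit <- stage("estimate", estimate_recomb_params(Gc))
  imp <- stage("impute", impute_genotypes(Gc, params = fit$params))
  pheno <- stage("read", read_phenotypes(cfg$phenotypes,
                                         id_col = cfg$id_col))
  adj <- stage("adjust", adjust_phenotypes(
    pheno, cfg$trait, covariates = .cfg_default(cfg, "covariates",
                                                character(0))))
  mode <- .cfg_default(cfg, "mode", "replicate_rows")
  agg <- stage("aggregate", aggregate_to_rils(adj, rownames(Gc$geno),
                                              mode = mode))
  X <- imp$genotypes[agg$row_index, , drop = FALSE]
  W <- imp$weights[agg$row_index, , drop = FALSE]
  wfit <- stage("wlasso", wlasso_path(X, agg$y, W))
  bic <- stage("bic", bic_select(wfit, X, agg$y))
  marker_set <- .cfg_default(cfg, "marker_set", "selected_set")
  sel_idx <- if (marker_set == "all_markers") seq_len(ncol(X)) else
    bic$selected
  scores <- if (length(sel_idx)) {
    sc <- stage("scores", marker_lrt_scores(X[, sel_idx, drop = FALSE],
                                            agg$y))
    mi <- match(sc$marker, Gc$map$marker)
    data.frame(marker = sc$marker, chr = Gc$map$chr[mi],
               pos = Gc$map$pos[mi], score = sc$score,
               stringsAsFactors = FALSE)
  } else {
    data.frame(marker = character(0), chr = character(0),
               pos = numeric(0), score = numeric(0))
  }
  report <- structure(list(params = fit$params, fit = fit, imputation = imp,
                           wlasso = wfit, bic = bic, scores = scores,
                           seed = seed, config = cfg),
                      class = "qtl_report")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      seed = seed,
      alpha = fit$interior$estimate, beta = fit$edge$estimate,
      loglik_interior = fit$interior$loglik,
      loglik_edge = fit$edge$loglik,
      lambda_star = bic$lambda_star, bic = bic$bic,
      n_selected = length(bic$selected),
      n_iter = wfit$n_iter),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.qtl_report <- function(x, ...) {
  cat("QTL analysis report\n")
  print(x$params)
  cat(sprintf("  %d markers selected at lambda = %.4g (BIC)\n",
              length(x$bic$selected), x$bic$lambda_star))
  if (nrow(x$scores)) {
    cat("  top scores:\n")
    top <- utils::head(x$scores[order(-x$scores$score), ], 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-12s chr %s %6.1f cM  %.2f\n", top$marker[i],
                  top$chr[i], top$pos[i], top$score[i]))
  }
  invisible(x)
}

#' Run a simulation study over a sigma-squared grid
#'
#' Delegates to [run_study()] for every residual variance in the
#' scenario's grid; optionally writes ROC and AUC summary CSVs.
#'
#' @param scenario a [sim_scenario()].
#' @param methods method list (see [run_study()]).
#' @param out_dir optional output directory for `roc.csv` and `auc.csv`.
#' @return A list of `"sim_study"` objects, one per `sigma2` value.
#' @export
run_simulation_study <- function(scenario, methods = c("model1", "model3"),
                                 out_dir = NULL) {
  if (length(methods) == 0L) stop("empty method list")
  studies <- lapply(scenario$sigma2, function(s2)
    run_study(scenario, methods = methods, sigma2 = s2))
  names(studies) <- paste0("sigma2_", scenario$sigma2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    roc <- do.call(rbind, lapply(seq_along(studies), function(i) {
      st <- studies[[i]]
      do.call(rbind, lapply(names(st$methods), function(m)
        cbind(sigma2 = st$sigma2, method = m, st$methods[[m]]$roc)))
    }))
    utils::write.csv(roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    auc <- do.call(rbind, lapply(studies, function(st)
      data.frame(sigma2 = st$sigma2, method = names(st$methods),
                 auc = unname(study_auc(st)), seed = st$scenario$seed)))
    utils::write.csv(auc, file.path(out_dir, "auc.csv"), row.names = FALSE)
  }
  studies
}
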