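# Genotype imputation from the fitted flanking-marker model, certainty
# weights, and the nearest-marker baseline.

.new_imputation_result <- function(prob, geno, weights, provenance, method) {
  structure(list(probabilities = prob, genotypes = geno, weights = weights,
                 provenance = provenance, method = method),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  n_imp <- sum(x$provenance != "observed")
  cat(sprintf("Imputation (%s): %d of %d entries imputed\n", x$method,
              n_imp, length(x$genotypes)))
  tab <- table(x$provenance[x$provenance != "observed"])
  if (length(tab)) {
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Model-based genotype imputation with certainty weights
#'
#' Each missing entry receives the conditional probability of genotype 1
#' given the nearest *observed* flanking markers on the same chromosome:
#' both sides observed uses the interior model, one side the edge model,
#' and a line with a fully missing chromosome falls back to P = 0.5. The
#' imputed genotype is the rounded probability (exactly 0.5 rounds down,
#' deterministically) and its certainty weight is 2 |P - 1/2|, so a
#' coin-flip probability carries weight 0. Observed entries keep their
#' genotype with probability equal to it and weight exactly 1.
#'
#' @param G a `"ril_geno"` object.
#' @param map its genetic map (defaults to `G$map`).
#' @param params a [recomb_params()] object, typically from
#'   [estimate_recomb_params()].
#' @return An `"imputation_result"`: matrices `probabilities`, `genotypes`
#'   (completed \{0,1\}), `weights` (in \[0,1\]) and `provenance` (entry
#'   flags `observed`, `model_imputed`, `edge_imputed`, `fallback`).
#' @export
impute_genotypes <- function(G, map = G$map, params) {
  g <- G$geno
  prob <- matrix(as.numeric(g), nrow(g), dimnames = dimnames(g))
  weights <- matrix(1, nrow(g), ncol(g), dimnames = dimnames(g))
  prov <- matrix("observed", nrow(g), ncol(g), dimnames = dimnames(g))
  geno <- g
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    pos <- map$pos[idx]
    sub <- g[, idx, drop = FALSE]
    for (i in seq_len(nrow(g))) {
      miss <- which(is.na(sub[i, ]))
      if (length(miss) == 0L) next
      obs <- which(!is.na(sub[i, ]))
      for (j in miss) {
        left <- obs[obs < j]
        right <- obs[obs > j]
        if (length(left) && length(right)) {
          l <- max(left); r <- min(right)
          p <- interior_probability(sub[i, l], sub[i, r],
                                    pos[j] - pos[l], pos[r] - pos[j],
                                    params$alpha)
          tag <- "model_imputed"
        } else if (length(left) || length(right)) {
          nb <- if (length(left)) max(left) else min(right)
          p <- edge_probability(sub[i, nb], abs(pos[j] - pos[nb]),
                                params$beta,
                                side = if (length(left)) "right" else "left")
          tag <- "edge_imputed"
        } else {
          p <- 0.5
          tag <- "fallback"
        }
        prob[i, idx[j]] <- p
        geno[i, idx[j]] <- if (p > 0.5) 1L else 0L
        weights[i, idx[j]] <- 2 * abs(p - 0.5)
        prov[i, idx[j]] <- tag
      }
    }
  }
  .new_imputation_result(prob, geno, weights, prov, "model")
}

#' Nearest-marker imputation baseline
#'
#' Each missing entry takes the genotype of the nearest observed marker (cM
#' distance) of the same line on the same chromosome; exact distance ties
#' break toward the lower-position neighbor. The baseline carries no
#' uncertainty, so all imputed weights are 1. A line with an entirely
#' missing chromosome is filled with 0 at weight 0 and flagged `fallback`.
#'
#' @inheritParams impute_genotypes
#' @return An `"imputation_result"` (see [impute_genotypes()]).
#' @export
nearest_marker_impute <- function(G, map = G$map) {
  g <- G$geno
  prob <- matrix(as.numeric(g), nrow(g), dimnames = dimnames(g))
  weights <- matrix(1, nrow(g), ncol(g), dimnames = dimnames(g))
  prov <- matrix("observed", nrow(g), ncol(g), dimnames = dimnames(g))
  geno <- g
  for (cc in unique(map$chr)) {
    idx <- which(map$chr == cc)
    pos <- map$pos[idx]
    sub <- g[, idx, drop = FALSE]
    for (i in seq_len(nrow(g))) {
      miss <- which(is.na(sub[i, ]))
      if (length(miss) == 0L) next
      obs <- which(!is.na(sub[i, ]))
      for (j in miss) {
        if (length(obs) == 0L) {
          geno[i, idx[j]] <- 0L
          prob[i, idx[j]] <- 0.5
          weights[i, idx[j]] <- 0
          prov[i, idx[j]] <- "fallback"
          next
        }
        dd <- abs(pos[obs] - pos[j])
        # ties: lower cM position wins; obs is sorted so which.min suffices
        nb <- obs[which.min(dd)]
        geno[i, idx[j]] <- sub[i, nb]
        prob[i, idx[j]] <- as.numeric(sub[i, nb])
        weights[i, idx[j]] <- 1
        prov[i, idx[j]] <- "model_imputed"
      }
    }
  }
  .new_imputation_result(prob, geno, weights, prov, "nearest")
}

#' Completed genotype matrix from an imputation result
#'
#' @param imp an `"imputation_result"`.
#' @param map the genetic map of the original matrix.
#' @return A `"ril_geno"` with no missing entries.
#' @export
completed_genotypes <- function(imp, map) {
  ril_geno(imp$genotypes, map)
}
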