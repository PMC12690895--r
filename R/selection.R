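#' LASSO screening of candidate variables with unpenalized covariates
#'
#' Fits an L1-penalized least-squares regression of the summarized
#' methylation values on the candidate columns plus the concomitant
#' variables. Covariates receive penalty factor 0 (always in the model,
#' never shrunk); candidates receive penalty factor 1 and are standardized
#' internally. The penalty strength is chosen by k-fold cross-validation and
#' candidates with a nonzero coefficient at the chosen lambda are returned.
#'
#' @param y Numeric response vector (summarized M values of one VML).
#' @param candidates Samples x candidates numeric matrix (cis SNP dosages
#'   and/or exposures). Constant columns are dropped with a warning.
#' @param covariates Samples x covariates numeric matrix (may have zero
#'   columns).
#' @param seed Integer seed controlling the cross-validation fold
#'   assignment.
#' @param nfolds Number of CV folds (default 10).
#' @param lambda_rule `"1se"` (default; the largest lambda whose CV error is
#'   within one standard error of the minimum — the standard parsimonious
#'   screening rule, which keeps chance-correlated candidates out of the
#'   model space) or `"min"` (lambda minimizing CV error; admits more
#'   variables).
#' @param nlambda Length of the lambda path (default 50).
#' @return Character vector of selected candidate column names, with the
#'   fitted coefficients (original scale) as attribute `coefficients`. A
#'   failed cross-validation returns an empty selection with a warning.
#' @export
lasso_select <- function(y, candidates, covariates, seed,
                         nfolds = 10L, lambda_rule = c("1se", "min"),
                         nlambda = 50L) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(dim(candidates))) candidates <- as.matrix(candidates)
  if (ncol(candidates) == 0L) return(empty_selection())
  keep <- apply(candidates, 2L, function(x) length(unique(x)) > 1L)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant candidate column(s)")
    candidates <- candidates[, keep, drop = FALSE]
  }
  if (ncol(candidates) == 0L) return(empty_selection())
  n <- length(y)
  x <- cbind(covariates, candidates)
  pf <- c(rep(0, ncol(covariates)), rep(1, ncol(candidates)))
  # glmnet needs >= 2 predictor columns; pad with a duplicated candidate
  padded <- FALSE
  if (ncol(x) < 2L) {
    x <- cbind(x, x[, 1L])
    pf <- c(pf, pf[1L])
    padded <- TRUE
  }
  cand_names <- colnames(candidates)
  fit <- with_seed(seed, {
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    tryCatch(
      glmnet::cv.glmnet(x, y, family = "gaussian", penalty.factor = pf,
                        foldid = foldid, nlambda = nlambda,
                        standardize = TRUE),
      error = function(e) e
    )
  })
  if (inherits(fit, "error")) {
    warning("cross-validated LASSO failed (", conditionMessage(fit),
            "); returning empty selection")
    return(empty_selection())
  }
  s <- if (lambda_rule == "min") "lambda.min" else "lambda.1se"
  beta <- as.matrix(stats::coef(fit, s = s))[, 1L]
  beta <- beta[setdiff(names(beta), "(Intercept)")]
  if (padded) beta <- beta[seq_len(length(beta) - 1L)]
  cand_beta <- beta[cand_names]
  sel <- cand_names[cand_beta != 0]
  structure(sel, coefficients = cand_beta[cand_beta != 0])
}

empty_selection <- function() {
  structure(character(0), coefficients = stats::setNames(numeric(0),
                                                         character(0)))
}

#' Select candidate G and E variables for one VML
#'
#' Runs the LASSO screen in three scenarios — cis SNPs only, exposures only,
#' and both together — and pools every variable selected in any scenario.
#' VMLs with no cis SNPs run the exposure-only scenario alone.
#'
#' @param y Summarized M values of the VML (named numeric vector or plain
#'   vector in sample order).
#' @param cis_snp_ids Character vector of the VML's cis SNP ids (possibly
#'   empty).
#' @param genotype Samples x SNPs dosage matrix.
#' @param exposome Samples x exposures matrix.
#' @param covariates Samples x covariates matrix.
#' @param seed Integer seed for this VML's selection (derive it per VML with
#'   a stable hash so results are order-independent).
#' @param ... Passed on to [lasso_select()] (`nfolds`, `lambda_rule`,
#'   `nlambda`).
#' @return List with character-vector elements `selected_g` and
#'   `selected_e`.
#' @export
select_variables <- function(y, cis_snp_ids, genotype, exposome, covariates,
                             seed, ...) {
  g <- genotype[, intersect(cis_snp_ids, colnames(genotype)), drop = FALSE]
  e <- exposome
  sel <- character(0)
  if (ncol(g) > 0L) {
    sel <- c(sel, lasso_select(y, g, covariates, seed = seed, ...))
  }
  sel <- c(sel, lasso_select(y, e, covariates, seed = seed + 1L, ...))
  if (ncol(g) > 0L) {
    sel <- c(sel, lasso_select(y, cbind(g, e), covariates,
                               seed = seed + 2L, ...))
  }
  sel <- unique(sel)
  list(selected_g = intersect(sel, colnames(g)),
       selected_e = intersect(sel, colnames(e)))
}
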