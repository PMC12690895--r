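#' Jointly permute genotype and exposome rows
#'
#' Applies one random permutation of the sample order to the genotype and
#' exposome matrices simultaneously, leaving methylation and covariates in
#' their original order. Because both matrices are shuffled by the same
#' permutation, every SNP-exposure correlation is preserved while any
#' association with methylation is broken.
#'
#' @param dataset An `aligned_dataset`.
#' @param seed Integer seed for the permutation.
#' @return The dataset with permuted (relabelled) genotype and exposome
#'   rows.
#' @export
permute_ge <- function(dataset, seed) {
  n <- dataset$n_samples
  perm <- with_seed(seed, sample.int(n))
  g <- dataset$genotype[perm, , drop = FALSE]
  e <- dataset$exposome[perm, , drop = FALSE]
  rownames(g) <- dataset$sample_ids
  rownames(e) <- dataset$sample_ids
  dataset$genotype <- g
  dataset$exposome <- e
  dataset
}

#' Run variable selection and model competition for a set of VMLs
#'
#' The per-VML core of the pipeline: for every VML, screens its cis SNPs
#' and the exposures with the three-scenario LASSO ([select_variables()]),
#' then fits and compares the G/E/G+E/GxE model space
#' ([select_best_model()]). VMLs where nothing is selected are assigned the
#' baseline class "B". Each VML draws its random stream from a stable hash
#' of (`seed`, `vml_id`), so results do not depend on processing order.
#'
#' @param y_mat Samples x VML summarized methylation matrix (from
#'   [summarize_vml()]).
#' @param cis Named list mapping `vml_id` to cis SNP ids (from
#'   [find_cis_snps()]).
#' @param dataset An `aligned_dataset` (its genotype, exposome and
#'   covariates are used).
#' @param seed Global integer seed.
#' @param ... Passed to [lasso_select()].
#' @return data.frame, one row per VML: `vml_id`, `model_class`, `snp_id`,
#'   `exposure_id`, `aic`, `r2`, `baseline_r2`, `delta_r2`, `partial_g`,
#'   `partial_e`, `partial_gxe`, `n_selected_g`, `n_selected_e`.
#' @export
evaluate_ge <- function(y_mat, cis, dataset, seed, ...) {
  vml_ids <- colnames(y_mat)
  rows <- vector("list", length(vml_ids))
  for (i in seq_along(vml_ids)) {
    id <- vml_ids[i]
    y <- y_mat[, i]
    sel <- select_variables(y, cis[[id]], dataset$genotype,
                            dataset$exposome, dataset$covariates,
                            seed = derive_seed(seed, id), ...)
    bm <- select_best_model(y, sel$selected_g, sel$selected_e,
                            dataset$genotype, dataset$exposome,
                            dataset$covariates)
    pr <- bm$partial_r2
    rows[[i]] <- data.frame(
      vml_id = id, model_class = bm$model_class,
      snp_id = bm$snp_id, exposure_id = bm$exposure_id,
      aic = bm$aic, r2 = bm$r2, baseline_r2 = bm$baseline_r2,
      delta_r2 = bm$delta_r2,
      partial_g = if ("g" %in% names(pr)) pr[["g"]] else NA_real_,
      partial_e = if ("e" %in% names(pr)) pr[["e"]] else NA_real_,
      partial_gxe = if ("gxe" %in% names(pr)) pr[["gxe"]] else NA_real_,
      n_selected_g = length(sel$selected_g),
      n_selected_e = length(sel$selected_e),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

stratum_of <- function(model_class) {
  ifelse(model_class %in% c("G", "E"), "marginal",
         ifelse(model_class %in% c("GE_ADD", "GXE"), "joint", NA_character_))
}

#' Build the permutation null distribution of delta R-squared
#'
#' Shuffles genotype and exposome jointly ([permute_ge()]) and re-runs
#' variable selection and model competition `n_perm` times. The R-squared
#' improvements of informative winners over the baseline are pooled across
#' permutations and VMLs, stratified into marginal (G, E) and joint (G+E,
#' GxE) winners — the two modes of the null — and the 95th percentile of
#' each stratum becomes its cutoff. Permuted runs reuse the observed run's
#' per-VML LASSO seeds so that the only difference is the shuffling.
#'
#' @param y_mat,cis,dataset,seed As in [evaluate_ge()].
#' @param n_perm Number of permutations (default 10). Few permutations give
#'   a coarse percentile when the VML set is small; consider 20 or more for
#'   fewer than a few hundred VMLs.
#' @param percentile Percentile defining the cutoffs (default 0.95).
#' @param ... Passed to [lasso_select()].
#' @return List of class `ge_null`: `delta_r2_marginal`, `delta_r2_joint`
#'   (pooled numeric vectors), `cutoff_marginal`, `cutoff_joint`,
#'   `n_permutations`, `percentile`.
#' @export
build_null <- function(y_mat, cis, dataset, seed, n_perm = 10L,
                       percentile = 0.95, ...) {
  marg <- joint <- numeric(0)
  for (p in seq_len(n_perm)) {
    permuted <- permute_ge(dataset, seed = derive_seed(seed, "permutation",
                                                       salt = p))
    res <- evaluate_ge(y_mat, cis, permuted, seed = seed, ...)
    inf <- res[res$model_class != "B", , drop = FALSE]
    if (nrow(inf) == 0L) {
      message("build_null: permutation ", p,
              " produced no informative winners")
      next
    }
    st <- stratum_of(inf$model_class)
    marg <- c(marg, inf$delta_r2[st == "marginal"])
    joint <- c(joint, inf$delta_r2[st == "joint"])
  }
  cutoff <- function(x, label) {
    if (length(x) == 0L) {
      warning("empty null stratum '", label, "'; cutoff set to 0 ",
              "(no winner in this stratum will be demoted)")
      return(0)
    }
    stats::quantile(x, probs = percentile, type = 7, names = FALSE)
  }
  structure(list(
    delta_r2_marginal = marg,
    delta_r2_joint = joint,
    cutoff_marginal = cutoff(marg, "marginal"),
    cutoff_joint = cutoff(joint, "joint"),
    n_permutations = n_perm,
    percentile = percentile
  ), class = "ge_null")
}

#' @export
print.ge_null <- function(x, ...) {
  cat("permutation null (", x$n_permutations, " permutations)\n", sep = "")
  cat("  marginal: n =", length(x$delta_r2_marginal),
      " cutoff =", signif(x$cutoff_marginal, 4), "\n")
  cat("  joint:    n =", length(x$delta_r2_joint),
      " cutoff =", signif(x$cutoff_joint, 4), "\n")
  invisible(x)
}

#' Demote winners that do not beat the permutation null
#'
#' Winners of class G or E are compared against the marginal cutoff, G+E and
#' GxE winners against the joint cutoff. A winner whose delta R-squared
#' falls below its stratum's cutoff is assigned to the baseline class "B";
#' a winner exactly at the cutoff is kept. The pre-filter class is retained
#' in `model_class_prefilter` for auditing.
#'
#' @param results data.frame from [evaluate_ge()].
#' @param null A `ge_null` from [build_null()].
#' @return The results data.frame with columns `model_class_prefilter` and
#'   `passed_null_filter` added and `model_class` updated.
#' @export
apply_null_filter <- function(results, null) {
  stopifnot(inherits(null, "ge_null"))
  st <- stratum_of(results$model_class)
  cut <- ifelse(st == "marginal", null$cutoff_marginal, null$cutoff_joint)
  keep <- is.na(st) | results$delta_r2 >= cut
  results$model_class_prefilter <- results$model_class
  results$passed_null_filter <- keep
  results$model_class[!keep] <- "B"
  results
}
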