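#' Run the full gene-environment methylome variability pipeline
#'
#' Executes every stage in order: residualize M values on the concomitant
#' variables and select highly variable probes; group HVPs into VMRs and
#' sparse VMPs and summarize each locus per sample; map cis SNPs; screen
#' candidate variables per VML with the three-scenario LASSO; fit and
#' compare the G/E/G+E/GxE model space by AIC with LMG variance
#' decomposition; and filter winners through the joint-permutation null.
#' Residual M values are used only for HVP identification — chaining
#' correlations, regional summaries and all models consume unadjusted M
#' values.
#'
#' @param dataset An `aligned_dataset` (see [align_dataset()],
#'   [load_dataset()] or [simulate_ge_dataset()]).
#' @param seed Global integer seed; every stochastic step derives its
#'   stream from it.
#' @param hvp_quantile Variance quantile for HVP selection (default 0.90).
#' @param max_gap Probe chaining distance in bp (default 1000).
#' @param min_r Minimum adjacent-probe correlation within a VMR (default
#'   0.15).
#' @param cis_window cis SNP window in bp on each side of a VML (default
#'   1e6).
#' @param n_perm Permutations for the null filter; 0 skips it (default 10).
#' @param percentile Null-distribution percentile for the cutoffs (default
#'   0.95).
#' @param ... Passed to [lasso_select()] (`nfolds`, `lambda_rule`,
#'   `nlambda`).
#' @return List of class `ge_pipeline`: `hvp` (per-probe variance table),
#'   `vml` (locus table), `y` (summarized methylation matrix), `cis`,
#'   `results` (final per-VML model table, with pre-filter classes),
#'   `null` (the `ge_null`, or NULL when `n_perm = 0`), `summary`
#'   (class proportions by VML kind), `params`.
#' @export
run_ge_pipeline <- function(dataset, seed,
                            hvp_quantile = 0.90, max_gap = 1000L,
                            min_r = 0.15, cis_window = 1e6,
                            n_perm = 10L, percentile = 0.95, ...) {
  stopifnot(inherits(dataset, "aligned_dataset"))
  residuals <- residualize_methylation(dataset$methylation,
                                       dataset$covariates)
  hvp <- find_hvps(residuals, quantile = hvp_quantile)
  hvp_ids <- hvp$probe_id[hvp$is_hvp]
  if (length(hvp_ids) == 0L) stop("no highly variable probes found")

  vml <- find_vml(hvp_ids, dataset$probe_manifest, dataset$methylation,
                  max_gap = max_gap, min_r = min_r)
  if (nrow(vml) == 0L) stop("no variably methylated loci found")
  y <- summarize_vml(dataset$methylation, vml)
  cis <- find_cis_snps(vml, dataset$snp_manifest, window = cis_window)

  results <- evaluate_ge(y, cis, dataset, seed = seed, ...)
  null <- NULL
  if (n_perm > 0L) {
    null <- build_null(y, cis, dataset, seed = seed, n_perm = n_perm,
                       percentile = percentile, ...)
    results <- apply_null_filter(results, null)
  }
  results <- merge(vml[, c("vml_id", "kind", "chrom", "start", "end",
                           "n_probes")],
                   results, by = "vml_id", sort = FALSE)

  classes <- c("B", "G", "E", "GE_ADD", "GXE")
  summary <- do.call(rbind, lapply(c("all", unique(results$kind)),
                                   function(kind) {
    sub <- if (kind == "all") results else results[results$kind == kind, ]
    prop <- prop.table(table(factor(sub$model_class, levels = classes)))
    cbind(data.frame(kind = kind, n_vml = nrow(sub)),
          as.data.frame.matrix(t(as.matrix(prop))))
  }))
  rownames(summary) <- NULL

  structure(list(hvp = hvp, vml = vml, y = y, cis = cis,
                 results = results, null = null, summary = summary,
                 params = list(seed = seed, hvp_quantile = hvp_quantile,
                               max_gap = max_gap, min_r = min_r,
                               cis_window = cis_window, n_perm = n_perm,
                               percentile = percentile)),
            class = "ge_pipeline")
}

#' @export
print.ge_pipeline <- function(x, ...) {
  cat("gene-environment methylome pipeline\n")
  cat("  HVPs:", sum(x$hvp$is_hvp), "of", nrow(x$hvp), "probes\n")
  cat("  VML: ", nrow(x$vml), "(",
      sum(x$vml$kind == "VMR"), "VMR,", sum(x$vml$kind == "sVMP"),
      "sVMP )\n")
  cat("  class proportions:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
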