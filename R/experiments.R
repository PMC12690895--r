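#' Pair overlapping VMLs between two datasets
#'
#' Two loci overlap when they share at least one genomic position
#' (1-based inclusive spans, same chromosome). By default all overlapping
#' pairs are emitted; `match = "greedy-longest"` instead resolves each locus
#' to its single longest-overlap partner (ties broken by partner order) for
#' replication-style one-to-one reports.
#'
#' @param vml_a,vml_b VML tables (must carry `vml_id`, `chrom`, `start`,
#'   `end`).
#' @param match `"all"` (default) or `"greedy-longest"`.
#' @return data.frame with columns `vml_a`, `vml_b` and `overlap_bp`.
#' @export
overlap_vml <- function(vml_a, vml_b, match = c("all", "greedy-longest")) {
  match <- match.arg(match)
  ra <- GenomicRanges::GRanges(vml_a$chrom,
                               IRanges::IRanges(vml_a$start, vml_a$end))
  rb <- GenomicRanges::GRanges(vml_b$chrom,
                               IRanges::IRanges(vml_b$start, vml_b$end))
  # disjoint chromosome sets between the two inputs are a normal condition
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ra, rb))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(vml_a$end[qi], vml_b$end[si]) -
    pmax(vml_a$start[qi], vml_b$start[si]) + 1L
  out <- data.frame(vml_a = vml_a$vml_id[qi], vml_b = vml_b$vml_id[si],
                    overlap_bp = ov, stringsAsFactors = FALSE)
  if (match == "greedy-longest" && nrow(out) > 0L) {
    out <- out[order(-out$overlap_bp, out$vml_a, out$vml_b), , drop = FALSE]
    out <- out[!duplicated(out$vml_a), , drop = FALSE]
    out <- out[!duplicated(out$vml_b), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

factor_presence <- function(model_class) {
  valid <- c("G", "E", "GE_ADD", "GXE", "B")
  if (any(!model_class %in% valid)) {
    stop("unknown model class: ",
         paste(setdiff(model_class, valid), collapse = ", "))
  }
  cbind(G = model_class %in% c("G", "GE_ADD", "GXE"),
        E = model_class %in% c("E", "GE_ADD", "GXE"),
        GxE = model_class == "GXE")
}

#' Model and factor agreement between paired VMLs
#'
#' For each pair of overlapping loci from two datasets, the winning models
#' agree overall when they are the same class, and agree on a factor (G, E
#' or GxE) when that factor is present in both or absent from both. For
#' example, an E winner and a G+E winner agree on E (present in both) and
#' on GxE (absent from both) but not on G, and do not agree overall. Pairs
#' involving a baseline (B) winner are excluded by default to improve
#' comparability.
#'
#' @param pairs data.frame from [overlap_vml()].
#' @param class_a,class_b Named character vectors mapping `vml_id` to the
#'   winning model class in each dataset.
#' @param exclude_b Drop pairs where either winner is "B" (default TRUE).
#' @return List of class `agreement_report`: `n_overlapping_vml`,
#'   `factor_agreement` (named fractions for G, E, GxE),
#'   `overall_agreement`, and the per-pair table `pairs`.
#' @export
compute_agreement <- function(pairs, class_a, class_b, exclude_b = TRUE) {
  ca <- unname(class_a[pairs$vml_a])
  cb <- unname(class_b[pairs$vml_b])
  if (anyNA(ca) || anyNA(cb)) stop("model class missing for some paired VML")
  pa <- factor_presence(ca)
  pb <- factor_presence(cb)
  keep <- if (exclude_b) ca != "B" & cb != "B" else rep(TRUE, length(ca))
  agree_fac <- pa == pb
  tab <- data.frame(
    vml_a = pairs$vml_a, vml_b = pairs$vml_b,
    class_a = ca, class_b = cb,
    agree_g = agree_fac[, "G"], agree_e = agree_fac[, "E"],
    agree_gxe = agree_fac[, "GxE"], agree_overall = ca == cb,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(
    n_overlapping_vml = nrow(tab),
    factor_agreement = c(G = mean(tab$agree_g), E = mean(tab$agree_e),
                         GxE = mean(tab$agree_gxe)),
    overall_agreement = mean(tab$agree_overall),
    pairs = tab
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement over", x$n_overlapping_vml, "overlapping VML pairs\n")
  cat("  overall:", signif(x$overall_agreement, 4), "\n")
  cat("  factors: G =", signif(x$factor_agreement[["G"]], 4),
      " E =", signif(x$factor_agreement[["E"]], 4),
      " GxE =", signif(x$factor_agreement[["GxE"]], 4), "\n")
  invisible(x)
}

#' SNP under-sampling (information imbalance) experiment
#'
#' Randomly subsamples each VML's cis SNP set to at most `k` SNPs (VMLs with
#' fewer cis SNPs keep them all, with no sampling), re-runs variable
#' selection, model competition and (optionally) the permutation null
#' filter, and tabulates winning-class counts. Repeating over `reps`
#' draws quantifies the sensitivity of the class composition to the amount
#' of genetic information supplied.
#'
#' @param y_mat,cis,dataset,seed As in [evaluate_ge()].
#' @param k_values Integer vector of SNP budgets (default
#'   `c(10, 100, 500, 1000)`).
#' @param reps Subsampling repetitions per budget (default 5).
#' @param n_perm Permutations for the null filter; 0 skips the filter.
#' @param ... Passed to [lasso_select()].
#' @return data.frame with columns `k`, `rep` and one count column per model
#'   class (`B`, `G`, `E`, `GE_ADD`, `GXE`).
#' @export
subsample_snp_experiment <- function(y_mat, cis, dataset, seed,
                                     k_values = c(10L, 100L, 500L, 1000L),
                                     reps = 5L, n_perm = 10L, ...) {
  classes <- c("B", "G", "E", "GE_ADD", "GXE")
  rows <- list()
  for (k in k_values) {
    for (r in seq_len(reps)) {
      sub_seed <- derive_seed(seed, paste0("subsample-k", k), salt = r)
      cis_k <- cis
      for (id in names(cis_k)) {
        s <- cis_k[[id]]
        if (length(s) > k) {
          pick <- with_seed(derive_seed(sub_seed, id),
                            sample.int(length(s), k))
          cis_k[[id]] <- s[sort(pick)]
        }
      }
      res <- evaluate_ge(y_mat, cis_k, dataset, seed = seed, ...)
      if (n_perm > 0L) {
        null <- build_null(y_mat, cis_k, dataset, seed = seed,
                           n_perm = n_perm, ...)
        res <- apply_null_filter(res, null)
      }
      counts <- table(factor(res$model_class, levels = classes))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(k = k, rep = r),
        as.data.frame.matrix(t(as.matrix(counts)))
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
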