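#' Configuration for the synthetic gene-environment methylation simulator
#'
#' Defines the planted architecture of a fully synthetic dataset: per-class
#' locus counts, per-term effect sizes expressed as target partial
#' R-squared (so acceptance thresholds are sample-size portable), the
#' within-region correlation, and the nuisance structure (covariate share,
#' filler probes, allele frequencies, exposure mix).
#'
#' @param n_samples Number of samples (default 500).
#' @param loci_per_class Named integer vector of planted locus counts for
#'   classes B, G, E, GE_ADD, GXE (default 20 each).
#' @param target_r2 Target partial R-squared of every planted G/E/GxE term,
#'   as a fraction of the per-probe variance (default 0.2).
#' @param rho Target within-region correlation of member probes for null
#'   (B) loci; signal loci are at least this correlated (default 0.5).
#' @param covar_r2 Variance fraction explained by the concomitant variables
#'   per probe (default 0.15).
#' @param n_covariates Number of standard-normal covariates (default 4).
#' @param n_exposures Number of exposome columns (default 15).
#' @param binary_exposure_frac Fraction of exposures that are binary with
#'   prevalence drawn from U(0.1, 0.5) (default 0.4); the rest are standard
#'   normal.
#' @param maf_range Minor allele frequency range, dosages ~ Binomial(2, maf)
#'   (default c(0.05, 0.5)).
#' @param decoy_snps_per_locus Non-causal cis SNPs planted around every
#'   locus (default 8).
#' @param cluster_size_range Probes per clustered locus (default 2 to 5).
#' @param cluster_gap_range Gap in bp between clustered probes, drawn
#'   uniformly (default 50 to 800, always chainable under a 1 kb rule).
#' @param svmp_frac Fraction of planted loci laid out as single isolated
#'   probes, exercising the sparse-VMP path (default 0.25).
#' @param filler_factor Number of low-variance filler probes per planted
#'   probe (default 9, putting planted probes just inside the top variance
#'   decile).
#' @param filler_var Total variance of filler probes (default 0.3; planted
#'   probes have unit variance).
#' @param locus_spacing Distance in bp between planted loci (default 2.5e6,
#'   keeping cis SNP sets disjoint under a 1 Mb window).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500L,
                       loci_per_class = c(B = 20L, G = 20L, E = 20L,
                                          GE_ADD = 20L, GXE = 20L),
                       target_r2 = 0.2,
                       rho = 0.5,
                       covar_r2 = 0.15,
                       n_covariates = 4L,
                       n_exposures = 15L,
                       binary_exposure_frac = 0.4,
                       maf_range = c(0.05, 0.5),
                       decoy_snps_per_locus = 8L,
                       cluster_size_range = c(2L, 5L),
                       cluster_gap_range = c(50L, 800L),
                       svmp_frac = 0.25,
                       filler_factor = 9,
                       filler_var = 0.3,
                       locus_spacing = 2.5e6) {
  stopifnot(n_samples >= 10L, target_r2 > 0, target_r2 < 1,
            rho >= 0, rho < 1, covar_r2 >= 0, covar_r2 < 1,
            maf_range[1L] > 0, maf_range[2L] <= 0.5)
  classes <- c("B", "G", "E", "GE_ADD", "GXE")
  lpc <- stats::setNames(integer(5L), classes)
  lpc[names(loci_per_class)] <- as.integer(loci_per_class)
  # feasibility: shared + covariate + unique variance must fit in 1
  max_targets <- c(B = 0, G = 1, E = 1, GE_ADD = 2, GXE = 3)
  worst <- max(max_targets[lpc > 0] * target_r2)
  if (max(worst, rho) + covar_r2 >= 0.98) {
    stop("infeasible variance budget: per-term targets, rho and covar_r2 ",
         "must leave room for probe-level noise (sum < 0.98)")
  }
  structure(list(
    n_samples = as.integer(n_samples), loci_per_class = lpc,
    target_r2 = target_r2, rho = rho, covar_r2 = covar_r2,
    n_covariates = as.integer(n_covariates),
    n_exposures = as.integer(n_exposures),
    binary_exposure_frac = binary_exposure_frac,
    maf_range = maf_range,
    decoy_snps_per_locus = as.integer(decoy_snps_per_locus),
    cluster_size_range = as.integer(cluster_size_range),
    cluster_gap_range = as.integer(cluster_gap_range),
    svmp_frac = svmp_frac, filler_factor = filler_factor,
    filler_var = filler_var, locus_spacing = locus_spacing
  ), class = "sim_config")
}

# Dosage column that is guaranteed polymorphic in the sampled cohort; the
# drawn allele frequency is attached for downstream checks.
draw_dosage <- function(n, maf_range) {
  for (i in 1:50) {
    maf <- stats::runif(1L, maf_range[1L], maf_range[2L])
    d <- stats::rbinom(n, 2L, maf)
    if (length(unique(d)) > 1L) return(structure(d, maf = maf))
  }
  stop("failed to draw a polymorphic SNP; increase n_samples or maf range")
}

#' Simulate a synthetic gene-environment methylation dataset
#'
#' Generates manifests, M values, genotype dosages, exposures and
#' covariates with a planted B/G/E/G+E/GxE architecture. Each planted locus
#' is a cluster of correlated probes (or an isolated single probe) whose M
#' values are the sum of a shared regional signal — the class-specific
#' linear predictor plus a latent factor — probe-specific covariate
#' effects, and probe-specific Gaussian noise. Effect sizes are solved from
#' the empirical variance of each term so that its expected partial
#' R-squared matches `target_r2` at the probe level; the interaction column
#' is orthogonalized against the main effects before scaling so its target
#' is not absorbed by them. Low-variance filler probes on separate
#' chromosomes put planted probes in the top variance decile.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with elements `dataset` (an `aligned_dataset`), `truth`
#'   (data.frame: `locus_id`, `true_class`, `chrom`, `start`, `end`,
#'   `n_probes`, `snp_id`, `exposure_id`, `beta_g`, `beta_e`, `beta_gxe`),
#'   `config`, and `snp_maf` (the drawn allele frequency per SNP).
#' @export
simulate_ge_dataset <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_ge_dataset_impl(config))
}

simulate_ge_dataset_impl <- function(cfg) {
  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  covariates <- matrix(stats::rnorm(n * cfg$n_covariates), nrow = n,
                       dimnames = list(sample_ids,
                                       paste0("cov", seq_len(cfg$n_covariates))))

  n_bin <- round(cfg$n_exposures * cfg$binary_exposure_frac)
  exposome <- matrix(0, nrow = n, ncol = cfg$n_exposures,
                     dimnames = list(sample_ids,
                                     paste0("EE_", seq_len(cfg$n_exposures))))
  for (j in seq_len(cfg$n_exposures)) {
    exposome[, j] <- if (j <= n_bin) {
      repeat {
        x <- stats::rbinom(n, 1L, stats::runif(1L, 0.1, 0.5))
        if (length(unique(x)) > 1L) break
      }
      x
    } else {
      stats::rnorm(n)
    }
  }

  classes <- rep(names(cfg$loci_per_class), cfg$loci_per_class)
  n_loci <- length(classes)
  classes <- sample(classes)  # interleave classes along the genome
  loci_chroms <- paste0("chr", 1:4)

  probe_rows <- list(); snp_rows <- list()
  m_cols <- list(); g_cols <- list()
  truth_rows <- list()

  for (i in seq_len(n_loci)) {
    cls <- classes[i]
    chrom <- loci_chroms[((i - 1L) %% length(loci_chroms)) + 1L]
    base <- 1e6 + ((i - 1L) %/% length(loci_chroms)) * cfg$locus_spacing
    is_svmp <- stats::runif(1L) < cfg$svmp_frac
    n_probes <- if (is_svmp) 1L else
      sample(seq(cfg$cluster_size_range[1L], cfg$cluster_size_range[2L]), 1L)
    gaps <- if (n_probes > 1L) {
      round(stats::runif(n_probes - 1L, cfg$cluster_gap_range[1L],
                         cfg$cluster_gap_range[2L]))
    } else integer(0)
    pos <- as.integer(base + cumsum(c(0L, gaps)))
    probe_ids <- sprintf("cg%05d_%02d", i, seq_len(n_probes))

    # cis SNPs: one causal (for classes with G) plus decoys
    snp_ids <- character(0)
    causal_snp <- NA_character_
    g_local <- list()
    if (cfg$decoy_snps_per_locus > 0L || cls %in% c("G", "GE_ADD", "GXE")) {
      n_decoy <- cfg$decoy_snps_per_locus
      offs <- round(stats::runif(n_decoy, -9e5, 9e5))
      snp_pos <- as.integer(base + offs)
      snp_ids <- sprintf("rs%05d_%02d", i, seq_len(n_decoy))
      for (j in seq_len(n_decoy)) {
        g_local[[snp_ids[j]]] <- draw_dosage(n, cfg$maf_range)
      }
      if (cls %in% c("G", "GE_ADD", "GXE")) {
        causal_snp <- sprintf("rs%05d_causal", i)
        snp_ids <- c(snp_ids, causal_snp)
        snp_pos <- c(snp_pos, as.integer(base + round(stats::runif(1L, -5e4,
                                                                   5e4))))
        g_local[[causal_snp]] <- draw_dosage(n, cfg$maf_range)
      }
      snp_rows[[i]] <- data.frame(snp_id = snp_ids, chrom = chrom,
                                  pos = pmax(1L, snp_pos),
                                  stringsAsFactors = FALSE)
    }

    causal_exp <- NA_character_
    if (cls %in% c("E", "GE_ADD", "GXE")) {
      causal_exp <- sample(colnames(exposome), 1L)
    }

    # class-specific shared signal with empirically calibrated effect sizes
    signal <- numeric(n)
    beta_g <- beta_e <- beta_gxe <- NA_real_
    n_terms <- 0L
    if (cls %in% c("G", "GE_ADD", "GXE")) {
      g <- g_local[[causal_snp]]
      gc <- g - mean(g)
      beta_g <- sqrt(cfg$target_r2 / stats::var(gc))
      signal <- signal + beta_g * gc
      n_terms <- n_terms + 1L
    }
    if (cls %in% c("E", "GE_ADD", "GXE")) {
      e <- exposome[, causal_exp]
      ec <- e - mean(e)
      beta_e <- sqrt(cfg$target_r2 / stats::var(ec))
      signal <- signal + beta_e * ec
      n_terms <- n_terms + 1L
    }
    if (cls == "GXE") {
      g <- g_local[[causal_snp]]
      e <- exposome[, causal_exp]
      w <- stats::lm.fit(cbind(1, g, e), g * e)$residuals
      beta_gxe <- sqrt(cfg$target_r2 / stats::var(w))
      signal <- signal + beta_gxe * w
      n_terms <- n_terms + 1L
    }
    sum_targets <- n_terms * cfg$target_r2
    shared_frac <- max(cfg$rho, sum_targets)
    v_latent <- shared_frac - sum_targets
    latent <- if (v_latent > 0) stats::rnorm(n, 0, sqrt(v_latent)) else
      numeric(n)
    u <- 1 - shared_frac - cfg$covar_r2
    shared <- signal + latent

    for (p in seq_len(n_probes)) {
      gdir <- stats::rnorm(cfg$n_covariates)
      gamma <- gdir / sqrt(sum(gdir^2)) * sqrt(cfg$covar_r2)
      m_cols[[probe_ids[p]]] <- stats::rnorm(1L, 0, 1) +
        drop(covariates %*% gamma) + shared + stats::rnorm(n, 0, sqrt(u))
    }
    probe_rows[[i]] <- data.frame(probe_id = probe_ids, chrom = chrom,
                                  pos = pos, stringsAsFactors = FALSE)
    g_cols[[i]] <- g_local
    truth_rows[[i]] <- data.frame(
      locus_id = sprintf("locus%03d", i), true_class = cls, chrom = chrom,
      start = min(pos), end = max(pos), n_probes = n_probes,
      snp_id = causal_snp, exposure_id = causal_exp,
      beta_g = beta_g, beta_e = beta_e, beta_gxe = beta_gxe,
      stringsAsFactors = FALSE
    )
  }

  # low-variance filler probes on chromosomes without planted loci
  n_planted <- sum(vapply(probe_rows, nrow, integer(1L)))
  n_filler <- round(cfg$filler_factor * n_planted)
  filler_chroms <- paste0("chr", 9:22)
  if (n_filler > 0L) {
    f_chrom <- filler_chroms[((seq_len(n_filler) - 1L) %%
                                length(filler_chroms)) + 1L]
    f_pos <- as.integer(1e5 + ((seq_len(n_filler) - 1L) %/%
                                 length(filler_chroms)) * 2000L)
    f_ids <- sprintf("cgF%06d", seq_len(n_filler))
    probe_rows[[length(probe_rows) + 1L]] <-
      data.frame(probe_id = f_ids, chrom = f_chrom, pos = f_pos,
                 stringsAsFactors = FALSE)
    sd_cov <- sqrt(cfg$covar_r2 * cfg$filler_var)
    sd_noise <- sqrt((1 - cfg$covar_r2) * cfg$filler_var)
    for (p in seq_len(n_filler)) {
      gdir <- stats::rnorm(cfg$n_covariates)
      gamma <- gdir / sqrt(sum(gdir^2)) * sd_cov
      m_cols[[f_ids[p]]] <- stats::rnorm(1L, 0, 1) +
        drop(covariates %*% gamma) + stats::rnorm(n, 0, sd_noise)
    }
  }

  probe_manifest <- do.call(rbind, probe_rows)
  snp_manifest <- do.call(rbind, snp_rows)
  methylation <- do.call(cbind, m_cols)
  dimnames(methylation) <- list(sample_ids, names(m_cols))
  g_flat <- unlist(g_cols, recursive = FALSE, use.names = TRUE)
  # unlist prefixes list names; recover SNP ids from the manifest order
  genotype <- do.call(cbind, unname(g_flat))
  dimnames(genotype) <- list(sample_ids,
                             unlist(lapply(g_cols, names), use.names = FALSE))

  dataset <- align_dataset(methylation, genotype, exposome, covariates,
                           probe_manifest, snp_manifest)
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  snp_maf <- vapply(g_flat, function(g) attr(g, "maf"), numeric(1L))
  names(snp_maf) <- colnames(genotype)
  list(dataset = dataset, truth = truth, config = cfg, snp_maf = snp_maf)
}

#' Score pipeline calls against the simulator's ground truth
#'
#' Matches every planted locus to the called VML with the largest genomic
#' overlap, builds the 5x5 confusion matrix over B/G/E/G+E/GxE, and reports
#' per-class sensitivity and precision plus causal-variable recovery (among
#' correctly classified loci, the fraction whose winning model names the
#' planted SNP and/or exposure). Planted loci with no overlapping VML count
#' as called "B" (nothing was detected there); called VMLs that overlap no
#' planted locus (filler-derived) are scored as true-class "B".
#'
#' @param results data.frame from [evaluate_ge()] / [apply_null_filter()]
#'   (columns `vml_id`, `model_class`, `snp_id`, `exposure_id`).
#' @param vml VML table from [find_vml()] carrying the coordinates of
#'   `results`' loci.
#' @param truth Ground-truth table from [simulate_ge_dataset()].
#' @return List of class `recovery_report`: `confusion` (truth x called),
#'   `sensitivity`, `precision` (named per class), `causal_recovery`,
#'   `n_undetected_truth`, `n_stray_vml`.
#' @export
evaluate_recovery <- function(results, vml, truth) {
  classes <- c("B", "G", "E", "GE_ADD", "GXE")
  res <- if (all(c("chrom", "start", "end") %in% names(results))) {
    results
  } else {
    merge(results, vml[, c("vml_id", "chrom", "start", "end")],
          by = "vml_id")
  }
  pairs <- overlap_vml(
    data.frame(vml_id = truth$locus_id, chrom = truth$chrom,
               start = truth$start, end = truth$end,
               stringsAsFactors = FALSE),
    res[, c("vml_id", "chrom", "start", "end")],
    match = "all"
  )
  # best (largest-overlap) partner per planted locus
  pairs <- pairs[order(-pairs$overlap_bp, pairs$vml_b), , drop = FALSE]
  best <- pairs[!duplicated(pairs$vml_a), , drop = FALSE]
  called <- stats::setNames(rep("B", nrow(truth)), truth$locus_id)
  called_snp <- called_exp <- stats::setNames(rep(NA_character_, nrow(truth)),
                                              truth$locus_id)
  idx <- match(best$vml_b, res$vml_id)
  called[best$vml_a] <- res$model_class[idx]
  called_snp[best$vml_a] <- res$snp_id[idx]
  called_exp[best$vml_a] <- res$exposure_id[idx]

  stray <- setdiff(res$vml_id, pairs$vml_b)
  truth_cls <- c(truth$true_class, rep("B", length(stray)))
  called_cls <- c(unname(called[truth$locus_id]),
                  res$model_class[match(stray, res$vml_id)])
  confusion <- table(truth = factor(truth_cls, levels = classes),
                     called = factor(called_cls, levels = classes))
  sens <- diag(confusion) / rowSums(confusion)
  prec <- diag(confusion) / colSums(confusion)

  correct <- truth$true_class == unname(called[truth$locus_id]) &
    truth$true_class != "B"
  ok_causal <- logical(0)
  for (i in which(correct)) {
    cls <- truth$true_class[i]
    ok <- TRUE
    if (cls %in% c("G", "GE_ADD", "GXE")) {
      ok <- ok && identical(unname(called_snp[truth$locus_id[i]]),
                            truth$snp_id[i])
    }
    if (cls %in% c("E", "GE_ADD", "GXE")) {
      ok <- ok && identical(unname(called_exp[truth$locus_id[i]]),
                            truth$exposure_id[i])
    }
    ok_causal <- c(ok_causal, ok)
  }
  structure(list(
    confusion = confusion,
    sensitivity = sens,
    precision = prec,
    causal_recovery = if (length(ok_causal)) mean(ok_causal) else NA_real_,
    n_undetected_truth = sum(!truth$locus_id %in% pairs$vml_a),
    n_stray_vml = length(stray)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery against planted truth\n")
  print(x$confusion)
  cat("sensitivity:\n")
  print(round(x$sensitivity, 3))
  cat("causal-variable recovery:", signif(x$causal_recovery, 4), "\n")
  invisible(x)
}

#' Write a simulated dataset to pipeline input files
#'
#' Writes the five input tables plus both manifests in the formats the
#' readers expect, and the ground truth as TSV.
#'
#' @param sim Result of [simulate_ge_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- sim$dataset
  paths <- c(
    methylation = file.path(dir, "methylation.tsv"),
    genotype = file.path(dir, "genotype.tsv"),
    exposome = file.path(dir, "exposome.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    probe_manifest = file.path(dir, "probe_manifest.tsv"),
    snp_manifest = file.path(dir, "snp_manifest.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  wm <- function(m, path) {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    data.table::fwrite(df, path, sep = "\t")
  }
  wm(d$methylation, paths["methylation"])
  wm(d$genotype, paths["genotype"])
  wm(d$exposome, paths["exposome"])
  wm(d$covariates, paths["covariates"])
  data.table::fwrite(d$probe_manifest, paths["probe_manifest"], sep = "\t")
  data.table::fwrite(d$snp_manifest, paths["snp_manifest"], sep = "\t")
  data.table::fwrite(sim$truth, paths["truth"], sep = "\t")
  invisible(paths)
}
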