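test_that("joint permutation preserves every SNP-exposure correlation", {
  d <- make_tiny_dataset(n = 80)
  p <- permute_ge(d, seed = 13)
  expect_equal(rownames(p$genotype), d$sample_ids)
  expect_equal(p$methylation, d$methylation)  # methylation untouched
  expect_equal(p$covariates, d$covariates)
  expect_equal(cor(p$genotype, p$exposome), cor(d$genotype, d$exposome),
               tolerance = 1e-12)
  # but the permutation really happened
  expect_false(isTRUE(all.equal(p$genotype, d$genotype)))
})

test_that("permutation destroys genotype-methylation association", {
  n <- 400
  rs <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    ids <- sprintf("s%03d", 1:n)
    g <- matrix(rbinom(n, 2, 0.3), n, 1, dimnames = list(ids, "rs1"))
    m <- matrix(0.8 * g[, 1] + rnorm(n), n, 12,
                dimnames = list(ids, sprintf("cg%02d", 1:12)))
    e <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, c("EE_1", "EE_2")))
    cv <- matrix(rnorm(n), n, 1, dimnames = list(ids, "c1"))
    pm <- manifest_of(colnames(m), "chr1",
                      seq(1e3, by = 5e3, length.out = 12))
    sm <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 2000L)
    d <- align_dataset(m, g, e, cv, pm, sm)
    p <- permute_ge(d, seed = 100 + s)
    rs[s] <- cor(p$methylation[, 1], p$genotype[, 1])
  }
  expect_lt(abs(mean(rs)), 2 / sqrt(n))
})

test_that("null cutoffs are the 95th percentile of the pooled strata", {
  null <- structure(list(
    delta_r2_marginal = seq(0, 1, length.out = 101),
    delta_r2_joint = seq(0, 2, length.out = 101),
    cutoff_marginal = quantile(seq(0, 1, length.out = 101), 0.95,
                               names = FALSE),
    cutoff_joint = quantile(seq(0, 2, length.out = 101), 0.95,
                            names = FALSE),
    n_permutations = 10L, percentile = 0.95), class = "ge_null")
  res <- data.frame(
    vml_id = c("a", "b", "c", "d", "e"),
    model_class = c("G", "E", "GE_ADD", "GXE", "B"),
    delta_r2 = c(null$cutoff_marginal, 0.80, null$cutoff_joint,
                 null$cutoff_joint - 0.01, 0),
    stringsAsFactors = FALSE
  )
  out <- apply_null_filter(res, null)
  # boundary: delta exactly at the cutoff is kept
  expect_equal(out$model_class[1], "G")       # == marginal cutoff
  expect_equal(out$model_class[2], "B")       # 0.80 < marginal cutoff
  expect_equal(out$model_class[3], "GE_ADD")  # == joint cutoff
  expect_equal(out$model_class[4], "B")       # just below joint cutoff
  expect_equal(out$model_class[5], "B")    # baseline stays baseline
  expect_equal(out$model_class_prefilter, res$model_class)
  # the filter only ever demotes to B, never relabels otherwise
  changed <- out$model_class != out$model_class_prefilter
  expect_true(all(out$model_class[changed] == "B"))
})

test_that("demotion is monotone in delta R2 within a stratum", {
  set.seed(61)
  null <- structure(list(
    delta_r2_marginal = runif(200, 0, 0.1),
    delta_r2_joint = runif(200, 0, 0.2),
    cutoff_marginal = 0.08, cutoff_joint = 0.15,
    n_permutations = 10L, percentile = 0.95), class = "ge_null")
  res <- data.frame(
    vml_id = sprintf("v%02d", 1:40),
    model_class = sample(c("G", "E", "GE_ADD", "GXE"), 40, replace = TRUE),
    delta_r2 = runif(40, 0, 0.25), stringsAsFactors = FALSE
  )
  out <- apply_null_filter(res, null)
  for (st in c("marginal", "joint")) {
    in_st <- ifelse(res$model_class %in% c("G", "E"), "marginal",
                    "joint") == st
    kept <- out$passed_null_filter[in_st]
    dr <- res$delta_r2[in_st]
    if (any(!kept) && any(kept)) {
      expect_lt(max(dr[!kept]), min(dr[kept]) + 1e-12)
    }
  }
  # all-zero improvements are all demoted
  res0 <- res; res0$delta_r2 <- 0
  out0 <- apply_null_filter(res0, null)
  expect_true(all(out0$model_class == "B"))
})

test_that("pooled null lists grow with the permutation count", {
  sim <- simulate_ge_dataset(
    sim_config(n_samples = 120, loci_per_class = c(B = 4, G = 2, E = 2),
               n_exposures = 6, decoy_snps_per_locus = 4,
               filler_factor = 4),
    seed = 71
  )
  d <- sim$dataset
  res <- residualize_methylation(d$methylation, d$covariates)
  hv <- find_hvps(res)
  vml <- suppressMessages(find_vml(hv$probe_id[hv$is_hvp], d$probe_manifest,
                                   d$methylation))
  y <- summarize_vml(d$methylation, vml)
  cis <- find_cis_snps(vml, d$snp_manifest)
  n1 <- suppressMessages(suppressWarnings(
    build_null(y, cis, d, seed = 7, n_perm = 1)))
  n3 <- suppressMessages(suppressWarnings(
    build_null(y, cis, d, seed = 7, n_perm = 3)))
  # same seed derivation per permutation index: the first permutation's
  # contributions are a prefix of the larger run's pooled lists
  pooled1 <- c(n1$delta_r2_marginal, n1$delta_r2_joint)
  pooled3 <- c(n3$delta_r2_marginal, n3$delta_r2_joint)
  expect_true(all(pooled1 %in% pooled3))
  expect_gte(length(pooled3), length(pooled1))
})

test_that("joint null winners improve R2 more than marginal ones", {
  # with mixed model classes the null delta R2 distribution is bimodal:
  # two-variable (joint) winners absorb more chance variance than
  # one-variable (marginal) winners
  sim <- simulate_ge_dataset(
    sim_config(n_samples = 150, loci_per_class = c(B = 12),
               n_exposures = 8, decoy_snps_per_locus = 10,
               filler_factor = 4),
    seed = 72
  )
  d <- sim$dataset
  res <- residualize_methylation(d$methylation, d$covariates)
  hv <- find_hvps(res)
  vml <- suppressMessages(find_vml(hv$probe_id[hv$is_hvp], d$probe_manifest,
                                   d$methylation))
  y <- summarize_vml(d$methylation, vml)
  cis <- find_cis_snps(vml, d$snp_manifest)
  null <- suppressMessages(build_null(y, cis, d, seed = 8, n_perm = 8,
                                      lambda_rule = "min"))
  expect_gt(length(null$delta_r2_marginal), 0)
  expect_gt(length(null$delta_r2_joint), 0)
  expect_gt(mean(null$delta_r2_joint), mean(null$delta_r2_marginal))
})
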