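test_that("the AIC convention matches R's Gaussian lm AIC", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", 1:k)))
    y <- rnorm(n) + x %*% rnorm(k) * 0.5
    f <- fit_ols(y, cbind(1, x))
    ref <- lm(y ~ x)
    expect_equal(f$aic, AIC(ref), tolerance = 1e-8)
    expect_equal(f$r2, summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("AIC arithmetic: equal RSS, one extra coefficient costs exactly 2", {
  set.seed(42)
  n <- 50
  y <- rnorm(n)
  x <- matrix(rnorm(n * 5), n, 5)
  f5 <- fit_ols(y, cbind(1, x[, 1:4]))
  # same fitted subspace plus a column inside it: same RSS, k + 1
  f6 <- fit_ols(y, cbind(1, x[, 1:4], x[, 1] + x[, 2]))
  expect_true(f6$singular)  # exactly collinear designs are rejected
  # instead construct equal RSS via an orthogonal column with zero fit:
  # use a column orthogonal to y and the others
  q <- qr.Q(qr(cbind(1, x[, 1:4], y)))
  extra <- qr.resid(qr(cbind(1, x[, 1:4], y)), rnorm(n))
  f6b <- fit_ols(y, cbind(1, x[, 1:4], extra))
  expect_equal(f6b$rss, f5$rss, tolerance = 1e-9)
  expect_equal(f6b$aic - f5$aic, 2, tolerance = 1e-6)
})

test_that("a perfect fit is guarded by the RSS floor", {
  set.seed(43)
  n <- 30
  x <- matrix(rnorm(n * 2), n, 2)
  y <- drop(x %*% c(1, -2)) + 3
  f <- fit_ols(y, cbind(1, x))
  expect_true(is.finite(f$aic))
  expect_equal(f$rss, 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("the AIC winner equals brute-force enumeration on random VML", {
  set.seed(44)
  n <- 120
  covars <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
  for (rep in 1:25) {
    geno <- matrix(rbinom(n * 3, 2, runif(1, 0.1, 0.5)), n, 3,
                   dimnames = list(NULL, paste0("rs", 1:3)))
    expo <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(NULL, paste0("EE_", 1:3)))
    beta <- rnorm(6, 0, 0.3)
    y <- drop(cbind(geno, expo) %*% beta) + rnorm(n)
    sel_g <- sample(colnames(geno), sample(0:3, 1))
    sel_e <- sample(colnames(expo), sample(0:3, 1))
    if (length(sel_g) == 0 && length(sel_e) == 0) sel_e <- "EE_1"
    bm <- select_best_model(y, sel_g, sel_e, geno, expo, covars)
    oracle <- brute_force_best(y, sel_g, sel_e, geno, expo, covars)
    expect_equal(bm$model_class, oracle$class)
    expect_equal(bm$aic, oracle$aic, tolerance = 1e-8)
    expect_equal(ifelse(is.na(bm$snp_id), "NA", bm$snp_id), oracle$snp)
    # model-space size follows the counting formula
    expect_equal(bm$n_models,
                 length(sel_g) + length(sel_e) +
                   2 * length(sel_g) * length(sel_e))
  }
})

test_that("interaction models carry exactly one more coefficient", {
  set.seed(45)
  n <- 60
  covars <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "c1"))
  geno <- matrix(rbinom(n, 2, 0.4), n, 1, dimnames = list(NULL, "rs1"))
  expo <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "EE_1"))
  y <- rnorm(n) + geno[, 1] * expo[, 1]
  add <- fit_ols(y, cbind(1, covars, geno, expo))
  int <- fit_ols(y, cbind(1, covars, geno, expo, geno * expo))
  expect_equal(int$k, add$k + 1)
  # nesting: the interaction wins on AIC iff it improves -2 logLik by > 2
  d_ll <- add$n * log(add$rss / int$rss)
  expect_equal(int$aic < add$aic, d_ll > 2)
})

test_that("LMG shares match the factorial oracle and sum to delta R2", {
  set.seed(46)
  n <- 100
  for (p in 1:3) {
    covars <- matrix(rnorm(n * 2), n, 2,
                     dimnames = list(NULL, c("c1", "c2")))
    terms <- setNames(lapply(seq_len(p), function(i) rnorm(n)),
                      c("g", "e", "gxe")[seq_len(p)])
    y <- rnorm(n) + Reduce(`+`, Map(`*`, terms, rnorm(p, 0, 0.6))) +
      drop(covars %*% c(0.3, -0.2))
    shares <- lmg_decompose(y, covars, terms)
    oracle <- brute_force_lmg(y, covars, terms)
    expect_equal(shares, oracle, tolerance = 1e-10)
    full <- fit_ols(y, cbind(1, covars, do.call(cbind, terms)))
    base <- fit_ols(y, cbind(1, covars))
    expect_equal(sum(shares), full$r2 - base$r2, tolerance = 1e-10)
    expect_true(all(shares > -1e-12))
  }
})

test_that("orthogonal terms get exactly their marginal R2 as LMG share", {
  n <- 64
  set.seed(47)
  # mutually orthogonal unit-norm columns (also orthogonal to the
  # intercept) via QR with the constant column first
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))
  t1 <- q[, 2]; t2 <- q[, 3]; noise <- q[, 4]
  covars <- matrix(q[, 5], n, 1, dimnames = list(NULL, "c1"))
  # y built from orthogonal pieces: shares are order-independent
  y <- sqrt(0.30) * t1 * sqrt(n) + sqrt(0.20) * t2 * sqrt(n) +
    sqrt(0.50) * noise * sqrt(n)
  y <- y - mean(y)
  shares <- lmg_decompose(y, covars, list(g = t1, e = t2))
  m1 <- fit_ols(y, cbind(1, covars, t1))
  m0 <- fit_ols(y, cbind(1, covars))
  expect_equal(unname(shares["g"]), m1$r2 - m0$r2, tolerance = 1e-8)
  # both orderings give the same increments, so shares equal the marginals
  m2 <- fit_ols(y, cbind(1, covars, t2))
  expect_equal(unname(shares["e"]), m2$r2 - m0$r2, tolerance = 1e-8)
})

test_that("a single-term winner's LMG share is exactly its delta R2", {
  set.seed(48)
  n <- 90
  covars <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
  g <- rbinom(n, 2, 0.3)
  y <- 0.7 * g + rnorm(n)
  shares <- lmg_decompose(y, covars, list(g = g))
  full <- fit_ols(y, cbind(1, covars, g))
  base <- fit_ols(y, cbind(1, covars))
  expect_equal(unname(shares["g"]), full$r2 - base$r2, tolerance = 1e-12)
})

test_that("exact AIC ties break towards parsimony then class order", {
  # two E candidates that are exact duplicates: identical AIC and k;
  # lexicographic id order decides
  set.seed(49)
  n <- 70
  covars <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "c1"))
  e <- rnorm(n)
  expo <- cbind(EE_1 = e, EE_2 = e)
  y <- 0.5 * e + rnorm(n)
  bm <- select_best_model(y, character(0), c("EE_2", "EE_1"),
                          matrix(0, n, 0), expo, covars)
  expect_equal(bm$exposure_id, "EE_1")
})

test_that("monomorphic SNPs drop their models; all-singular falls to B", {
  set.seed(50)
  n <- 40
  covars <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "c1"))
  geno <- matrix(1, n, 1, dimnames = list(NULL, "rs_mono"))
  expo <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "EE_1"))
  y <- rnorm(n)
  w <- capture_warnings(
    bm <- select_best_model(y, "rs_mono", character(0), geno, expo, covars)
  )
  expect_true(any(grepl("singular", w)))
  expect_equal(bm$model_class, "B")
  # with an exposure also selected, competition continues without the SNP
  expect_warning(
    bm2 <- select_best_model(y, "rs_mono", "EE_1", geno, expo, covars),
    "singular"
  )
  expect_equal(bm2$model_class, "E")
})

test_that("adding a constant to y leaves the winner unchanged", {
  set.seed(51)
  n <- 80
  covars <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "c1"))
  geno <- matrix(rbinom(n * 2, 2, 0.3), n, 2,
                 dimnames = list(NULL, c("rs1", "rs2")))
  expo <- matrix(rnorm(n * 2), n, 2,
                 dimnames = list(NULL, c("EE_1", "EE_2")))
  y <- 0.6 * geno[, 1] + 0.4 * expo[, 2] + rnorm(n)
  b1 <- select_best_model(y, colnames(geno), colnames(expo), geno, expo,
                          covars)
  b2 <- select_best_model(y + 100, colnames(geno), colnames(expo), geno,
                          expo, covars)
  expect_equal(b2$model_class, b1$model_class)
  expect_equal(b2$snp_id, b1$snp_id)
  expect_equal(b2$delta_r2, b1$delta_r2, tolerance = 1e-8)
})

test_that("the unscreened model-space count follows the formula", {
  expect_equal(count_total_models(2, 3), 17)
  expect_equal(count_total_models(0, 94), 94)
  expect_equal(count_total_models(c(10, 5), 94), 3023)
  expect_equal(count_total_models(integer(0), 94), 0)
})
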