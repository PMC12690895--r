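#' Ordinary least-squares fit with Gaussian AIC
#'
#' Fits `y ~ design` (the design must already contain its intercept), and
#' returns the residual sum of squares, coefficient count, R-squared and
#' AIC under the Gaussian log-likelihood convention
#' `AIC = n log(2 pi RSS / n) + n + 2 (k + 1)`, where `k` counts the
#' regression coefficients and the `+1` counts the error variance. The RSS
#' is floored at 1e-12 so that a perfect fit yields a finite AIC.
#'
#' @param y Numeric response vector.
#' @param design Numeric design matrix including the intercept column.
#' @return List with `rss`, `k`, `n`, `aic`, `r2`, `singular` (logical; when
#'   TRUE the design was rank-deficient and the other fields are NA).
#' @export
fit_ols <- function(y, design) {
  n <- length(y)
  k <- ncol(design)
  if (n <= k) stop("need more observations than coefficients (n > k)")
  qrd <- qr(design)
  if (qrd$rank < k) {
    return(list(rss = NA_real_, k = k, n = n, aic = NA_real_,
                r2 = NA_real_, singular = TRUE))
  }
  res <- qr.resid(qrd, y)
  rss <- max(sum(res^2), 1e-12)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  aic <- n * log(2 * pi * rss / n) + n + 2 * (k + 1)
  list(rss = rss, k = k, n = n, aic = aic, r2 = r2, singular = FALSE)
}

model_class_rank <- c(G = 1L, E = 2L, GE_ADD = 3L, GXE = 4L, B = 5L)

#' Fit the G/E/G+E/GxE model space for one VML and pick the AIC winner
#'
#' For every selected SNP a genotype-only model, for every selected exposure
#' an exposure-only model, and for every SNP x exposure pair an additive and
#' an interaction model (both with main effects) are fitted, each including
#' the concomitant variables. The model with the lowest AIC wins; exact ties
#' are broken towards parsimony (fewer coefficients), then by class order
#' G < E < G+E < GxE, then lexicographically by variable ids. The winner's
#' R-squared improvement over the covariates-only baseline (delta R-squared)
#' and the LMG partial R-squared of its G/E/GxE terms are attached.
#'
#' @param y Summarized M values of the VML.
#' @param selected_g,selected_e Character vectors of selected SNP and
#'   exposure ids (either may be empty; if both are, the baseline class "B"
#'   is returned).
#' @param genotype,exposome,covariates Aligned sample-by-feature matrices.
#' @return List of class `best_model`: `model_class` ("G", "E", "GE_ADD",
#'   "GXE" or "B"), `snp_id`, `exposure_id`, `aic`, `r2`, `k`, `n`,
#'   `baseline_r2`, `delta_r2`, `partial_r2` (named numeric with entries
#'   among g/e/gxe), `n_models` (size of the fitted model space).
#' @export
select_best_model <- function(y, selected_g, selected_e,
                              genotype, exposome, covariates) {
  covd <- cbind(`(Intercept)` = 1, covariates)
  base <- fit_ols(y, covd)
  if (base$singular) stop("baseline covariate design is singular")
  baseline <- list(model_class = "B", snp_id = NA_character_,
                   exposure_id = NA_character_, aic = base$aic, r2 = base$r2,
                   k = base$k, n = base$n, baseline_r2 = base$r2,
                   delta_r2 = 0, partial_r2 = stats::setNames(numeric(0),
                                                              character(0)),
                   n_models = 0L)
  class(baseline) <- "best_model"
  if (length(selected_g) == 0L && length(selected_e) == 0L) {
    return(baseline)
  }

  specs <- list()
  for (s in sort(selected_g)) {
    specs[[length(specs) + 1L]] <- list(class = "G", snp = s, exp = NA)
  }
  for (e in sort(selected_e)) {
    specs[[length(specs) + 1L]] <- list(class = "E", snp = NA, exp = e)
  }
  for (s in sort(selected_g)) {
    for (e in sort(selected_e)) {
      specs[[length(specs) + 1L]] <- list(class = "GE_ADD", snp = s, exp = e)
      specs[[length(specs) + 1L]] <- list(class = "GXE", snp = s, exp = e)
    }
  }

  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    d <- covd
    if (!is.na(sp$snp)) d <- cbind(d, snp = genotype[, sp$snp])
    if (!is.na(sp$exp)) d <- cbind(d, exp = exposome[, sp$exp])
    if (sp$class == "GXE") {
      d <- cbind(d, gxe = genotype[, sp$snp] * exposome[, sp$exp])
    }
    fits[[i]] <- fit_ols(y, d)
  }
  singular <- vapply(fits, `[[`, logical(1L), "singular")
  if (any(singular)) {
    warning(sum(singular), " model(s) dropped from the competition ",
            "(singular design, e.g. monomorphic SNP)")
  }
  ok <- which(!singular)
  if (length(ok) == 0L) {
    warning("all candidate models singular; assigning baseline")
    return(baseline)
  }
  aic <- vapply(fits[ok], `[[`, numeric(1L), "aic")
  k <- vapply(fits[ok], `[[`, numeric(1L), "k")
  cls <- vapply(specs[ok], `[[`, character(1L), "class")
  snp <- vapply(specs[ok], function(s) as.character(s$snp), character(1L))
  exp_ <- vapply(specs[ok], function(s) as.character(s$exp), character(1L))
  ord <- order(aic, k, model_class_rank[cls], snp, exp_, na.last = TRUE)
  w <- ok[ord[1L]]
  sp <- specs[[w]]
  fit <- fits[[w]]

  terms <- list()
  if (!is.na(sp$snp)) terms$g <- genotype[, sp$snp]
  if (!is.na(sp$exp)) terms$e <- exposome[, sp$exp]
  if (sp$class == "GXE") {
    terms$gxe <- genotype[, sp$snp] * exposome[, sp$exp]
  }
  partial <- lmg_decompose(y, covariates, terms)

  out <- list(model_class = sp$class,
              snp_id = if (is.na(sp$snp)) NA_character_ else sp$snp,
              exposure_id = if (is.na(sp$exp)) NA_character_ else sp$exp,
              aic = fit$aic, r2 = fit$r2, k = fit$k, n = fit$n,
              baseline_r2 = base$r2, delta_r2 = fit$r2 - base$r2,
              partial_r2 = partial, n_models = length(specs))
  class(out) <- "best_model"
  out
}

#' @export
print.best_model <- function(x, ...) {
  cat("best model:", x$model_class,
      if (!is.na(x$snp_id)) paste0("snp=", x$snp_id) else "",
      if (!is.na(x$exposure_id)) paste0("exposure=", x$exposure_id) else "",
      "\n  AIC:", signif(x$aic, 6), " R2:", signif(x$r2, 4),
      " delta R2:", signif(x$delta_r2, 4), "\n")
  invisible(x)
}

#' LMG (Lindeman-Merenda-Gold) partial R-squared decomposition
#'
#' Averages, over all orderings of the model's G/E/GxE terms, the sequential
#' R-squared increase contributed by each term, with the concomitant
#' variables always entered first. Shares are non-negative and sum exactly
#' to the model R-squared minus the covariates-only baseline R-squared. With
#' at most three terms the enumeration over orderings is exact.
#'
#' @param y Numeric response vector.
#' @param covariates Samples x covariates matrix (the always-first block).
#' @param terms Named list of numeric term columns (names among
#'   `"g"`, `"e"`, `"gxe"`).
#' @return Named numeric vector of LMG shares, one per term.
#' @export
lmg_decompose <- function(y, covariates, terms) {
  nm <- names(terms)
  p <- length(terms)
  if (p == 0L) return(stats::setNames(numeric(0), character(0)))
  covd <- cbind(`(Intercept)` = 1, covariates)
  # R-squared of covariates + each subset of terms, indexed by bitmask
  r2_of <- numeric(2^p)
  for (mask in 0:(2^p - 1L)) {
    d <- covd
    for (j in seq_len(p)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) {
        d <- cbind(d, terms[[j]])
      }
    }
    f <- fit_ols(y, d)
    if (f$singular) stop("singular design in LMG subset enumeration")
    r2_of[mask + 1L] <- f$r2
  }
  perms <- permutations_of(seq_len(p))
  shares <- stats::setNames(numeric(p), nm)
  for (perm in perms) {
    mask <- 0L
    for (j in perm) {
      new_mask <- bitwOr(mask, bitwShiftL(1L, j - 1L))
      shares[j] <- shares[j] + (r2_of[new_mask + 1L] - r2_of[mask + 1L])
      mask <- new_mask
    }
  }
  shares / length(perms)
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Total number of models in the unscreened model space
#'
#' For each VML with `G_i` cis SNPs and `E_i` candidate exposures the full
#' model space holds one model per SNP, one per exposure, and an additive
#' plus an interaction model per SNP-exposure pair:
#' `sum_i G_i + E_i + 2 G_i E_i`.
#'
#' @param cis_counts Integer vector, number of cis SNPs per VML.
#' @param n_exposures Number of candidate exposures (same for every VML).
#' @return Total model count as a (double) integer-valued scalar.
#' @export
count_total_models <- function(cis_counts, n_exposures) {
  stopifnot(all(cis_counts >= 0), n_exposures >= 0)
  g <- as.numeric(cis_counts)
  sum(g + n_exposures + 2 * g * n_exposures)
}
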