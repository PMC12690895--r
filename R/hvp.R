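#' Regress concomitant variables out of M values
#'
#' Fits, for every probe, an ordinary least-squares model of the M values on
#' an intercept plus the covariate columns, and returns the residuals. The
#' residuals are used only to rank probes by variance when selecting highly
#' variable probes; all downstream modelling consumes the unadjusted M
#' values.
#'
#' @param methylation Samples x probes numeric matrix of M values.
#' @param covariates Samples x covariates numeric matrix, same sample order.
#' @return Samples x probes matrix of residuals.
#' @export
residualize_methylation <- function(methylation, covariates) {
  stopifnot(nrow(methylation) == nrow(covariates))
  design <- cbind(`(Intercept)` = 1, covariates)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("covariate design (with intercept) is rank-deficient")
  }
  # One QR for all probes: residual = M - Q Q' M.
  res <- qr.resid(qrd, methylation)
  dimnames(res) <- dimnames(methylation)
  res
}

#' Select highly variable probes (HVPs)
#'
#' Computes the per-probe sample variance of covariate-adjusted M values and
#' keeps probes whose variance exceeds the chosen quantile of the variance
#' distribution (default: the 90th percentile, i.e. the top decile of
#' probes).
#'
#' @param residuals Samples x probes matrix of residualized M values (from
#'   [residualize_methylation()]).
#' @param quantile Variance quantile defining the cutoff (default 0.90).
#' @param inclusive If `FALSE` (default) a probe must exceed the cutoff
#'   strictly; ties at the threshold are excluded. Set `TRUE` to keep them.
#' @return data.frame with columns `probe_id`, `residual_variance`, `is_hvp`,
#'   and attribute `variance_threshold` (the interpolated quantile).
#' @export
find_hvps <- function(residuals, quantile = 0.90, inclusive = FALSE) {
  if (ncol(residuals) < 10L) stop("need at least 10 probes")
  v <- col_vars(residuals)
  thr <- stats::quantile(v, probs = quantile, type = 7, names = FALSE)
  is_hvp <- if (inclusive) v >= thr else v > thr
  out <- data.frame(
    probe_id = colnames(residuals),
    residual_variance = unname(v),
    is_hvp = unname(is_hvp),
    stringsAsFactors = FALSE
  )
  attr(out, "variance_threshold") <- thr
  out
}
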