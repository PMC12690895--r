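#' Convert methylation beta values to M values
#'
#' The M value is the log2 ratio of methylated to unmethylated intensity,
#' `log2(beta / (1 - beta))`. M values are approximately homoscedastic across
#' the methylation range and are the preferred scale for linear modelling of
#' microarray methylation data.
#'
#' @param beta Numeric vector of methylation proportions, strictly inside
#'   (0, 1).
#' @return Numeric vector of M values.
#' @seealso [m_to_beta()] for the inverse transform.
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' @export
beta_to_m <- function(beta) {
  if (!is.numeric(beta)) stop("'beta' must be numeric")
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1)) {
    stop("beta values must lie strictly inside (0, 1)")
  }
  log2(beta / (1 - beta))
}

#' Convert M values to methylation beta values
#'
#' Inverse of [beta_to_m()]: `2^m / (2^m + 1)`.
#'
#' @param m Numeric vector of M values.
#' @return Numeric vector of beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stop("'m' must be numeric")
  e <- 2^m
  e / (e + 1)
}

# Deterministic 31-bit seed derived from a global seed and a string key.
# Keeps per-locus RNG streams independent of processing order so results are
# identical under any parallel scheduling.
derive_seed <- function(seed, key, salt = 0L) {
  stopifnot(length(key) == 1L)
  h <- (as.numeric(seed) %% 2147483647) + 1
  bytes <- utf8ToInt(as.character(key))
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  h <- (h + as.numeric(salt) * 7919) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded from `seed`; global RNG
# state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Column variances with denominator n - 1, without forming residual matrices
# per column.
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) stop("at least 2 samples are required to compute variances")
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}
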