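# Independent brute-force oracles used by the model and acceptance tests.
# These deliberately use R's own lm()/AIC() machinery rather than the
# package's fitting code.

brute_force_best <- function(y, sel_g, sel_e, geno, expo, covars) {
  rows <- list()
  add <- function(class, snp, exp, fml_terms) {
    df <- data.frame(y = y, covars)
    if (!is.na(snp)) df$snp <- geno[, snp]
    if (!is.na(exp)) df$e <- expo[, exp]
    fit <- lm(stats::reformulate(fml_terms, response = "y"), data = df)
    rows[[length(rows) + 1]] <<- data.frame(
      class = class, snp = ifelse(is.na(snp), "NA", snp),
      exp = ifelse(is.na(exp), "NA", exp),
      aic = AIC(fit), k = length(coef(fit)),
      r2 = summary(fit)$r.squared, stringsAsFactors = FALSE
    )
  }
  cv_terms <- colnames(covars)
  for (s in sel_g) add("G", s, NA, c("snp", cv_terms))
  for (e in sel_e) add("E", NA, e, c("e", cv_terms))
  for (s in sel_g) for (e in sel_e) {
    add("GE_ADD", s, e, c("snp", "e", cv_terms))
    add("GXE", s, e, c("snp", "e", "snp:e", cv_terms))
  }
  tab <- do.call(rbind, rows)
  rank <- c(G = 1, E = 2, GE_ADD = 3, GXE = 4)
  tab[order(tab$aic, tab$k, rank[tab$class], tab$snp, tab$exp), ][1, ]
}

# tiny permutation enumerator (rows = orderings)
enumerate_orderings <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- enumerate_orderings(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# All-orderings LMG oracle built on lm() R-squared values only.
brute_force_lmg <- function(y, covars, terms) {
  nm <- names(terms)
  df <- data.frame(y = y, covars, as.data.frame(terms))
  r2 <- function(vars) {
    f <- stats::reformulate(c(colnames(covars), vars), response = "y")
    summary(lm(f, data = df))$r.squared
  }
  perms <- apply(enumerate_orderings(nm), 1, identity, simplify = FALSE)
  shares <- setNames(numeric(length(nm)), nm)
  for (p in perms) {
    sofar <- character(0)
    for (t in p) {
      shares[t] <- shares[t] + r2(c(sofar, t)) - r2(sofar)
      sofar <- c(sofar, t)
    }
  }
  shares / length(perms)
}
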