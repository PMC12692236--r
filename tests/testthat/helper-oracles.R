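# Brute-force LMG oracle: average sequential R2 increments over every
# ordering of the groups, enumerated explicitly. Independent of the
# package's subset-caching implementation.
lmg_bruteforce <- function(y, X, groups, covariates = NULL) {
  g <- length(groups)
  perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  base <- cbind(rep(1, nrow(X)), covariates)
  r2 <- function(cols) {
    fit <- stats::lm.fit(cbind(base, X[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  shares <- stats::setNames(numeric(g), names(groups))
  all_perms <- perms(seq_len(g))
  for (ord in all_perms) {
    cols <- character(0)
    prev <- r2(character(0))
    for (j in ord) {
      cols <- c(cols, groups[[j]])
      cur <- r2(cols)
      shares[j] <- shares[j] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(all_perms)
}
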