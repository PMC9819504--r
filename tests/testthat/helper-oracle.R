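# Closed-form normal-equations OLS, independent of fit_qsar()'s lm route.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- unname(drop(solve(t(X) %*% X, t(X) %*% y)))
  res <- y - drop(X %*% beta)
  sstot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = if (sstot == 0) 0 else 1 - sum(res^2) / sstot,
       sdep = sqrt(mean(res^2)))
}

# minimal compound table builder for tests
make_compounds <- function(log_kow, log_lc50, log_noec,
                           name = sprintf("cmpd-%02d", seq_along(log_kow)),
                           cas = NA_character_) {
  data.frame(name = name, cas = cas, log_kow = log_kow,
             log_lc50 = log_lc50, log_noec = log_noec,
             stringsAsFactors = FALSE)
}

# fixture rows expected to agree / disagree with the reported log TRO column
concordant_abbrevs <- c("TIBP", "TNBP", "TBEP", "TPHP", "DNBP", "BEHP", "BBOEP")
# diphenyl chlorophosphate has no abbreviation; matched by name in tests
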