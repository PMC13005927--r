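# Small in-code fixtures and independent oracles shared across tests.

toy_covars <- function(n, seed = 42L, prefix = "P") {
  set.seed(seed)
  covariate_table(
    patient_id = sprintf("%s%03d", prefix, seq_len(n)),
    person_time = runif(n, 0.5, 4),
    age = rnorm(n, 60, 8),
    sex = rbinom(n, 1, 0.5),
    insulin_use = rbinom(n, 1, 0.2),
    elixhauser = rpois(n, 3))
}

toy_events <- function(covars, codes, mean_events = 5, seed = 7L,
                       site_id = "A") {
  set.seed(seed)
  n_ev <- rpois(nrow(covars), mean_events)
  pid <- rep(covars$patient_id, n_ev)
  event_table(site_id, pid,
              as.Date("2018-01-01") + sample.int(900, length(pid), TRUE),
              sample(codes, length(pid), TRUE),
              rep("ICD10", length(pid)))
}

# Brute-force weighted least squares with HC0 sandwich variance.
wls_sandwich_oracle <- function(X, y, w) {
  W <- diag(w)
  bread <- solve(t(X) %*% W %*% X)
  beta <- bread %*% t(X) %*% W %*% y
  e <- drop(y - X %*% beta)
  meat <- t(X) %*% diag(w^2 * e^2) %*% X
  V <- bread %*% meat %*% bread
  list(beta = drop(beta), se = sqrt(diag(V)))
}

# Rank-statistic AUC (Mann-Whitney), independent of pROC.
auc_rank_oracle <- function(y, score) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Dense O(n^2) within-patient co-occurrence counter.
cooc_oracle <- function(events, vocab, window) {
  C <- matrix(0, length(vocab), length(vocab), dimnames = list(vocab, vocab))
  ev <- as.data.frame(events)
  ev <- ev[ev$code %in% vocab, ]
  for (p in unique(ev$patient_id)) {
    e <- ev[ev$patient_id == p, ]
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1)) for (j in (i + 1):nrow(e)) {
      if (e$code[i] != e$code[j] &&
          abs(as.integer(e$date[i]) - as.integer(e$date[j])) <= window) {
        C[e$code[i], e$code[j]] <- C[e$code[i], e$code[j]] + 1
        C[e$code[j], e$code[i]] <- C[e$code[j], e$code[i]] + 1
      }
    }
  }
  C
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
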