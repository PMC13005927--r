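#' Smoothed person-time-adjusted frequency ratio
#'
#' Descriptive cross-site usage ratio for one code:
#' \deqn{\rho = \frac{(f_A + \kappa)/PT_A}{(f_B + \kappa)/PT_B}}
#' with smoothing count \eqn{\kappa} (default 10) guarding against zero
#' counts. Swapping the sites maps \eqn{\rho \to 1/\rho}. The smoothing is
#' purely descriptive and is never applied inside the formal tests.
#'
#' @param f_a,f_b Endorsement counts at the two sites.
#' @param pt_a,pt_b Total person-time (years) at the two sites; must be > 0.
#' @param kappa Smoothing count.
#' @param code Optional code label carried into the result.
#' @return A `ratio_result` list: `code`, `f_a`, `f_b`, `pt_a`, `pt_b`,
#'   `kappa`, `ratio`.
#' @export
smoothed_frequency_ratio <- function(f_a, f_b, pt_a, pt_b, kappa = 10,
                                     code = NA_character_) {
  if (any(pt_a <= 0) || any(pt_b <= 0)) stop("person-time must be positive")
  if (any(f_a < 0) || any(f_b < 0)) stop("frequencies must be non-negative")
  rho <- ((f_a + kappa) / pt_a) / ((f_b + kappa) / pt_b)
  structure(list(code = code, f_a = f_a, f_b = f_b, pt_a = pt_a, pt_b = pt_b,
                 kappa = kappa, ratio = rho),
            class = "ratio_result")
}

#' Frequency-ratio table for two sites
#'
#' Vectorized [smoothed_frequency_ratio()] over the union of two sites'
#' code vocabularies (codes absent at one site count 0 there).
#'
#' @param freq_a,freq_b `frequency_table`s from [summarize_frequencies()].
#' @param kappa Smoothing count.
#' @return `data.table(code, f_a, f_b, ratio)`.
#' @export
frequency_ratio_table <- function(freq_a, freq_b, kappa = 10) {
  codes <- sort(union(freq_a$code, freq_b$code))
  fa <- setNames(rep(0, length(codes)), codes)
  fa[freq_a$code] <- freq_a$frequency
  fb <- setNames(rep(0, length(codes)), codes)
  fb[freq_b$code] <- freq_b$frequency
  pta <- freq_a$person_time[1L]; ptb <- freq_b$person_time[1L]
  data.table(code = codes, f_a = unname(fa), f_b = unname(fb),
             ratio = smoothed_frequency_ratio(unname(fa), unname(fb),
                                              pta, ptb, kappa)$ratio)
}

# Covariate design with intercept from a covariate table; person-time is a
# weight, not a predictor.
covariate_design <- function(covars) {
  cbind(`(Intercept)` = 1, age = covars$age, sex = covars$sex,
        insulin_use = covars$insulin_use, elixhauser = covars$elixhauser)
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  invisible(qx)
}

#' Person-time-weighted covariate-adjusted test for one code
#'
#' Operationalizes the weighted two-sample comparison of a single code's
#' per-patient endorsement rate as weighted least squares of the rate on a
#' site indicator plus baseline covariates, with person-time weights and a
#' heteroskedasticity-robust (sandwich, HC0) variance for the site
#' coefficient. Per-patient rates are heavily skewed, hence the robust
#' variance rather than the homoskedastic one.
#'
#' @param rates Per-patient code rate (endorsements / person-time), pooled
#'   over both sites.
#' @param site Binary site indicator per patient (1 = site A).
#' @param Z Covariate matrix (no intercept) or a [covariate_table()] pooled
#'   in the same patient order.
#' @param weights Person-time weights per patient.
#' @param unit Label carried into the result.
#' @return A `data.table` row: `unit`, `kind = "weighted_t"`, `statistic`
#'   (robust t for the site coefficient), `estimate`, `df`, `p`.
#' @export
code_level_test <- function(rates, site, Z, weights, unit = NA_character_) {
  if (inherits(Z, "covariate_table")) Z <- covariate_design(Z)[, -1L, drop = FALSE]
  site <- as.numeric(site)
  if (length(unique(site)) < 2L || min(table(site)) < 2L)
    stop("need at least 2 patients per site")
  X <- cbind(`(Intercept)` = 1, site = site, Z)
  check_full_rank(X)
  y <- as.numeric(rates)
  w <- as.numeric(weights)
  df <- data.frame(y = y, X[, -1L, drop = FALSE], check.names = FALSE)
  lmfit <- stats::lm(y ~ ., data = df, weights = w)
  dof <- length(y) - ncol(X)
  e <- stats::residuals(lmfit)
  degenerate <- max(abs(e)) <= 1e-10 * max(abs(y), 1)
  b <- stats::coef(lmfit)["site"]
  if (degenerate) {
    tval <- 0; p <- 1; b <- 0
  } else {
    V <- sandwich::vcovHC(lmfit, type = "HC0")
    se <- sqrt(V["site", "site"])
    tval <- if (se > 0) b / se else 0
    p <- if (se > 0) 2 * stats::pt(-abs(tval), dof) else 1
  }
  data.table(unit = unit, kind = "weighted_t", statistic = unname(tval),
             estimate = unname(b), df = dof, p = unname(p))
}

#' Fit the logistic null model of site on covariates
#'
#' Maximum-likelihood logistic regression of the site indicator on baseline
#' covariates via iteratively reweighted least squares, converged to
#' gradient norm \eqn{\le} 1e-10. This is the shared null model for the
#' burden and SKAT score tests; the federated fit ([federated_fit_null()])
#' runs the identical update from per-site cross-products.
#'
#' @param Z Covariate matrix (no intercept) or [covariate_table()]; an
#'   intercept is added internally.
#' @param site Binary outcome (site indicator).
#' @param tol Convergence tolerance on the max absolute score.
#' @param max_iter Iteration cap.
#' @return A `null_model`: `coef`, `mu` (fitted probabilities), `X` (design
#'   with intercept), `y`, `d` (= mu(1-mu)), `r` (= y - mu), `iterations`,
#'   `grad_norm`.
#' @export
fit_null_model <- function(Z, site, tol = 1e-10, max_iter = 100L) {
  if (inherits(Z, "covariate_table")) Z <- covariate_design(Z)[, -1L, drop = FALSE]
  y <- as.numeric(site)
  if (length(unique(y)) < 2L) stop("both site labels must be present")
  X <- cbind(`(Intercept)` = 1, Z)
  check_full_rank(X)
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30)
      stop("complete separation detected: diverging coefficients")
    mu <- stats::plogis(eta)
    g <- crossprod(X, y - mu)
    if (max(abs(g)) <= tol) break
    d <- mu * (1 - mu)
    H <- crossprod(X, X * d)
    beta <- beta + solve(H, g)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  g <- crossprod(X, y - mu)
  if (max(abs(g)) > tol)
    stop("IRLS did not converge to tolerance ", tol)
  structure(list(coef = setNames(drop(beta), colnames(X)), mu = mu, X = X,
                 y = y, d = mu * (1 - mu), r = y - mu, iterations = it,
                 grad_norm = max(abs(g))),
            class = "null_model")
}

# Score-test cross-products shared by burden and SKAT:
# A = G'DG - G'DZ (Z'DZ)^{-1} Z'DG with D = diag(mu(1-mu)), Z the null
# design (incl. intercept); and u = G'r with r = y - mu.
score_pieces <- function(null, G) {
  G <- as.matrix(G)
  D <- null$d
  GtDX <- crossprod(G * D, null$X)
  XtDX <- crossprod(null$X, null$X * D)
  A <- crossprod(G, G * D) - GtDX %*% solve(XtDX, t(GtDX))
  list(u = drop(crossprod(G, null$r)), A = A)
}

burden_from_pieces <- function(u, A, w, unit) {
  S <- sum(w * u)
  v <- drop(crossprod(w, A %*% w))
  if (v <= 0) {
    warning("degenerate burden (variance <= 0) for unit ", unit, "; p = 1")
    return(data.table(unit = unit, kind = "burden_score", statistic = S,
                      variance = v, df = 1, p = 1))
  }
  stat <- S^2 / v
  data.table(unit = unit, kind = "burden_score", statistic = S, variance = v,
             df = 1, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

skat_from_pieces <- function(u, A, w, unit) {
  Q <- sum((w * u)^2)
  WAW <- t(A * w) * w      # diag(w) %*% A %*% diag(w) for symmetric A
  lam <- eigen((WAW + t(WAW)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam, 0) * 1e-10]
  if (length(lam) == 0L) {
    warning("all-zero group matrix for unit ", unit, "; p = 1")
    return(data.table(unit = unit, kind = "skat_Q", statistic = Q,
                      variance = NA_real_, df = NA_real_, p = 1))
  }
  data.table(unit = unit, kind = "skat_Q", statistic = Q, variance = sum(lam^2) * 2,
             df = length(lam), p = pchisqsum(Q, lam))
}

#' Burden score test for a code group
#'
#' Score test of adding the weighted member sum \eqn{b = Gw} to the
#' logistic null model of site on covariates: \eqn{S = r'Gw}, variance
#' \eqn{v = (Gw)'D(Gw) - (Gw)'DZ(Z'DZ)^{-1}Z'D(Gw)}, and
#' \eqn{S^2/v \sim \chi^2_1} under the null. Sensitive to coding
#' differences that push all member codes in a common direction.
#'
#' @param null A `null_model` from [fit_null_model()].
#' @param G Patient x member-code matrix (counts by default; any
#'   `code_matrix` transform is accepted).
#' @param w Per-code weights (default flat 1).
#' @param unit Label for the group.
#' @return A `data.table` row with `statistic` (the score S), `variance`,
#'   `df`, `p`.
#' @export
burden_test <- function(null, G, w = NULL, unit = NA_character_) {
  G <- as.matrix(G)
  if (is.null(w)) w <- rep(1, ncol(G))
  sp <- score_pieces(null, G)
  burden_from_pieces(sp$u, sp$A, w, unit)
}

#' SKAT variance-component score test for a code group
#'
#' \eqn{Q = r'GW^2G'r} with \eqn{W = diag(w)}; under the null Q is
#' distributed as a mixture \eqn{\sum_k \lambda_k \chi^2_{1,k}} whose
#' weights are the eigenvalues of \eqn{W G'(D - DZ(Z'DZ)^{-1}Z'D) G W}.
#' Tail probabilities come from the exact mixture-series expansion in
#' [pchisqsum()], with a moment-matching fallback.
#' SKAT tolerates member effects in opposing directions and is therefore
#' the test of choice for code substitution within a group, where the
#' group-level total can balance out while member usage differs.
#'
#' @inheritParams burden_test
#' @return A `data.table` row with `statistic` (Q), `df` (number of
#'   non-null eigenvalues), `p`.
#' @export
skat_test <- function(null, G, w = NULL, unit = NA_character_) {
  G <- as.matrix(G)
  if (is.null(w)) w <- rep(1, ncol(G))
  if (all(G == 0)) {
    warning("all-zero group matrix for unit ", unit, "; p = 1")
    return(data.table(unit = unit, kind = "skat_Q", statistic = 0,
                      variance = NA_real_, df = NA_real_, p = 1))
  }
  sp <- score_pieces(null, G)
  skat_from_pieces(sp$u, sp$A, w, unit)
}

#' Bonferroni multiple-testing adjustment
#'
#' `p_adj = min(1, m * p)` with `m` the number of tests in the family
#' (codes and groups are corrected as separate families).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(pvals)`.
#' @return Adjusted p-values, order preserved.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  pmin(1, m * pvals)
}

#' Tail probability of a positively weighted chi-square mixture
#'
#' \eqn{P(\sum_k \lambda_k \chi^2_{1,k} > q)}, the reference distribution of
#' the SKAT statistic. The exact value comes from Ruben's expansion of the
#' quadratic form as a mixture of central chi-square distributions, a
#' monotone series with a computable truncation bound; if the series does
#' not converge to tolerance, or the upper tail is beyond the reach of the
#' expansion's cancellation limit (~1e-12), the Liu et al. moment-matching
#' noncentral chi-square approximation is used instead.
#'
#' @param q Observed statistic.
#' @param lambda Positive mixture weights (eigenvalues).
#' @param method `"auto"` (exact, fallback to moment matching),
#'   `"exact"`, or `"liu"`.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
pchisqsum <- function(q, lambda, method = c("auto", "exact", "liu")) {
  method <- match.arg(method)
  if (any(lambda <= 0)) stop("mixture weights must be positive")
  if (method == "liu") return(pchisqsum_liu(q, lambda))
  rb <- pchisqsum_ruben(q, lambda)
  if (method == "exact") {
    if (!rb$converged) stop("mixture-series expansion did not converge")
    return(min(max(rb$p, 0), 1))
  }
  if (!rb$converged || rb$p < 1e-12) return(min(max(pchisqsum_liu(q, lambda), 0), 1))
  min(max(rb$p, 0), 1)
}

# Ruben (1962)-style series: with beta < min(lambda), the cdf of the
# quadratic form is sum_k a_k F_chisq(q / beta; n + 2k) with all a_k > 0
# summing to 1, so the truncation error is bounded by 1 - sum(a_k).
pchisqsum_ruben <- function(q, lambda, eps = 1e-12, max_terms = 10000L) {
  n <- length(lambda)
  beta <- 0.90625 * min(lambda)
  d <- 1 - beta / lambda
  a <- numeric(max_terms + 1L)
  g <- numeric(max_terms)
  a[1L] <- exp(0.5 * sum(log(beta / lambda)))
  dk <- rep(1, n)
  sum_a <- a[1L]
  cdf <- a[1L] * stats::pchisq(q / beta, df = n)
  for (k in seq_len(max_terms)) {
    dk <- dk * d
    g[k] <- sum(dk)
    a[k + 1L] <- sum(g[seq_len(k)] * a[k:1L]) / (2 * k)
    cdf <- cdf + a[k + 1L] * stats::pchisq(q / beta, df = n + 2 * k)
    sum_a <- sum_a + a[k + 1L]
    if (1 - sum_a < eps)
      return(list(p = 1 - cdf, converged = TRUE, terms = k))
  }
  list(p = 1 - cdf, converged = FALSE, terms = max_terms)
}

# Liu, Tang & Zhang (2009) moment-matching approximation.
pchisqsum_liu <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1; delta <- 0; l <- c2^3 / c3^2
  }
  mu_x <- l + delta; sigma_x <- sqrt(2) * a
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}
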