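test_that("smoothed frequency ratio follows the +kappa person-time formula", {
  expect_equal(smoothed_frequency_ratio(90, 0, 1, 1)$ratio, 10)
  expect_equal(smoothed_frequency_ratio(0, 0, 3.2, 3.2)$ratio, 1)
  # site-swap symmetry: rho -> 1/rho
  r1 <- smoothed_frequency_ratio(70, 3, 1.7, 2.1)$ratio
  r2 <- smoothed_frequency_ratio(3, 70, 2.1, 1.7)$ratio
  expect_equal(r1, 1 / r2)
  expect_error(smoothed_frequency_ratio(1, 1, 0, 1), "positive")
})

test_that("weighted code-level test matches a brute-force WLS sandwich oracle", {
  set.seed(5)
  n <- 8
  site <- rep(c(1, 0), each = 4)
  Z <- cbind(age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5))
  w <- runif(n, 0.5, 3)
  y <- rnorm(n, 1 + 0.5 * site)
  res <- code_level_test(y, site, Z, w)
  X <- cbind(1, site, Z)
  or <- wls_sandwich_oracle(X, y, w)
  expect_equal(res$estimate, unname(or$beta[2]), tolerance = 1e-10)
  expect_equal(res$statistic, unname(or$beta[2] / or$se[2]), tolerance = 1e-10)

  # exactly equal rates across sites -> statistic 0, p = 1
  y0 <- rep(1, n)
  r0 <- code_level_test(y0, site, Z, w)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  expect_error(code_level_test(y, site, cbind(Z, dup = Z[, "age"]), w),
               "collinear")
  expect_error(code_level_test(y, rep(1, n), Z, w), "2 patients")
})

test_that("code-level p-values are uniform under a permuted-label null", {
  set.seed(31)
  n <- 80
  Z <- cbind(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  w <- runif(n, 0.5, 4)
  rate <- rpois(n, 3) / w
  ps <- replicate(200, {
    site <- sample(rep(c(1, 0), each = n / 2))
    code_level_test(rate, site, Z, w)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("logistic null model matches closed form and glm, flags separation", {
  # intercept-only: coef = log(n_A / n_B)
  y <- c(rep(1, 30), rep(0, 20))
  m0 <- fit_null_model(matrix(numeric(0), nrow = 50, ncol = 0), y)
  expect_equal(unname(m0$coef[1]), log(30 / 20), tolerance = 1e-10)

  set.seed(8)
  n <- 10
  Z <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  m <- fit_null_model(Z, y)
  g <- stats::glm(y ~ Z, family = stats::binomial,
                  control = list(epsilon = 1e-14))
  expect_lt(max(abs(m$coef - stats::coef(g))), 1e-8)
  expect_lte(m$grad_norm, 1e-10)

  sep <- cbind(x = c(-3, -2, -1, 1, 2, 3))
  expect_error(fit_null_model(sep, c(0, 0, 0, 1, 1, 1)), "separation")
})

test_that("burden and SKAT match their matrix definitions on toy data", {
  set.seed(12)
  n <- 40
  Z <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  G <- matrix(rpois(n * 3, 1.5), n, 3)
  w <- c(1, 2, 0.5)
  null <- fit_null_model(Z, y)

  # brute-force assembly from the definition
  X <- cbind(1, Z)
  D <- diag(null$d)
  r <- null$r
  A <- t(G) %*% D %*% G -
    t(G) %*% D %*% X %*% solve(t(X) %*% D %*% X) %*% t(X) %*% D %*% G
  S_or <- drop(t(r) %*% G %*% w)
  v_or <- drop(t(w) %*% A %*% w)
  bt <- burden_test(null, G, w)
  expect_equal(bt$statistic, S_or, tolerance = 1e-10)
  expect_equal(bt$variance, v_or, tolerance = 1e-10)
  expect_equal(bt$p, stats::pchisq(S_or^2 / v_or, 1, lower.tail = FALSE))

  Q_or <- sum((w * drop(crossprod(G, r)))^2)
  lam_or <- eigen(diag(w) %*% A %*% diag(w), symmetric = TRUE,
                  only.values = TRUE)$values
  st <- skat_test(null, G, w)
  expect_equal(st$statistic, Q_or, tolerance = 1e-10)
  expect_equal(st$p, pchisqsum(Q_or, lam_or[lam_or > 1e-8]), tolerance = 1e-8)

  # single-code group: burden and SKAT coincide (Q = S^2, one eigenvalue)
  g1 <- G[, 1, drop = FALSE]
  expect_equal(burden_test(null, g1)$p, skat_test(null, g1)$p, tolerance = 1e-10)

  # SKAT invariant to member order; burden invariant to patient order
  expect_equal(skat_test(null, G[, c(3, 1, 2)], w[c(3, 1, 2)])$p, st$p,
               tolerance = 1e-10)
  perm <- sample(n)
  null_p <- fit_null_model(Z[perm, ], y[perm])
  expect_equal(burden_test(null_p, G[perm, ], w)$p, bt$p, tolerance = 1e-8)

  # degenerate variance and all-zero groups warn and return p = 1
  expect_warning(b0 <- burden_test(null, matrix(0, n, 2)), "degenerate")
  expect_equal(b0$p, 1)
  expect_warning(s0 <- skat_test(null, matrix(0, n, 2)), "all-zero")
  expect_equal(s0$p, 1)
})

test_that("chi-square mixture tail matches Monte Carlo and the Liu fallback", {
  lam <- c(1, 0.5)
  q <- 4.2
  set.seed(99)
  draws <- lam[1] * stats::rchisq(1e6, 1) + lam[2] * stats::rchisq(1e6, 1)
  p_mc <- mean(draws > q)
  se_mc <- sqrt(p_mc * (1 - p_mc) / 1e6)
  p_ex <- pchisqsum(q, lam)
  expect_lt(abs(p_ex - p_mc), 3 * se_mc)

  # exact inversion and moment matching agree within 10% relative error
  # for p in [1e-6, 0.5] on random eigenvalue sets
  set.seed(17)
  for (rep in 1:20) {
    lam <- sort(runif(sample(2:8, 1), 0.2, 3), decreasing = TRUE)
    for (target in c(0.4, 0.05, 1e-3)) {
      # bracket a q giving roughly the target p
      q <- sum(lam) * stats::qchisq(1 - target, df = length(lam)) / length(lam)
      p1 <- pchisqsum(q, lam, method = "exact")
      p2 <- pchisqsum(q, lam, method = "liu")
      if (p1 >= 1e-6 && p1 <= 0.5)
        expect_lt(abs(p2 - p1) / p1, 0.10)
    }
  }
})

test_that("Bonferroni adjustment caps at 1 and preserves order", {
  expect_equal(bonferroni_adjust(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni_adjust(0.2), 0.2)
  expect_equal(bonferroni_adjust(c(1, 1, 1)), c(1, 1, 1))
  p <- c(0.001, 0.01, 0.04)
  expect_equal(order(bonferroni_adjust(p)), order(p))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "must be in")
})
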