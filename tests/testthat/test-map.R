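mk_emb <- function(V, vocab) {
  rownames(V) <- vocab
  structure(list(V = V, vocab = vocab, d = ncol(V), values = rep(1, ncol(V)),
                 mode = "PMI", shift = 1), class = "embedding_set")
}

one_group <- function(codes) group_catalog(codes, rep("g", length(codes)))

test_that("directional similarity is masked cosine with hand-checked values", {
  ea <- mk_emb(rbind(c(1, 0), c(0, 1)), c("x1", "x2"))
  eb <- mk_emb(rbind(c(1, 0), c(1, 1) / sqrt(2)), c("y1", "y2"))
  groups <- one_group(c("x1", "x2", "y1", "y2"))
  sim <- directional_similarity(ea, eb, groups)
  expect_equal(sim$sigma["x1", "y1"], 1)
  expect_equal(sim$sigma["x2", "y1"], 0)
  expect_equal(sim$sigma["x1", "y2"], sqrt(2) / 2, tolerance = 1e-12)

  # candidates outside the shared category are masked
  g2 <- group_catalog(c("x1", "y1", "x2", "y2"), c("g", "g", "h", "h"))
  sim2 <- directional_similarity(ea, eb, g2)
  expect_true(is.na(sim2$sigma["x1", "y2"]))
  expect_false(is.na(sim2$sigma["x1", "y1"]))

  # zero-norm rows are flagged
  ez <- mk_emb(rbind(c(0, 0), c(0, 1)), c("x1", "x2"))
  expect_warning(directional_similarity(ez, eb, groups), "zero-norm")
})

test_that("regression similarity equals projections for orthogonal candidates", {
  ea <- mk_emb(rbind(c(0.6, 0.8)), "x1")
  eb <- mk_emb(rbind(c(1, 0), c(0, 1)), c("y1", "y2"))
  groups <- one_group(c("x1", "y1", "y2"))
  rs <- regression_similarity(ea, eb, groups, lambda = 0)
  expect_equal(rs$sigma["x1", "y1"], 0.6, tolerance = 1e-12)
  expect_equal(rs$sigma["x1", "y2"], 0.8, tolerance = 1e-12)

  # single candidate with unit vectors reduces to the cosine
  eb1 <- mk_emb(rbind(c(1, 0)), "y1")
  rs1 <- regression_similarity(ea, eb1, one_group(c("x1", "y1")), lambda = 0)
  expect_equal(rs1$sigma["x1", "y1"], 0.6, tolerance = 1e-12)

  # correlated candidates against the regularized normal-equations oracle
  set.seed(6)
  Vb <- matrix(rnorm(12), 3, 4); Vb[2, ] <- Vb[1, ] + 0.3 * Vb[2, ]
  ebc <- mk_emb(Vb, c("y1", "y2", "y3"))
  eac <- mk_emb(matrix(rnorm(4), 1), "x1")
  gc <- one_group(c("x1", "y1", "y2", "y3"))
  lam <- 0.2
  rsc <- regression_similarity(eac, ebc, gc, lambda = lam)
  Y <- t(Vb / sqrt(rowSums(Vb^2)))
  x <- eac$V[1, ] / sqrt(sum(eac$V[1, ]^2))
  beta_or <- solve(t(Y) %*% Y + lam * diag(3)) %*% t(Y) %*% x
  expect_lt(max(abs(rsc$sigma["x1", c("y1", "y2", "y3")] - drop(beta_or))), 1e-10)

  # collinear candidates demand regularization
  Vb2 <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  expect_error(regression_similarity(eac, mk_emb(Vb2, c("y1", "y2", "y3")),
                                     gc, lambda = 0), "lambda > 0")
})

test_that("frequency refinement damps rate-discordant pairs monotonically", {
  ea <- mk_emb(rbind(c(1, 0), c(0, 1)), c("x1", "x2"))
  eb <- mk_emb(rbind(c(1, 0), c(0, 1)), c("y1", "y2"))
  groups <- one_group(c("x1", "x2", "y1", "y2"))
  sim <- directional_similarity(ea, eb, groups)
  mk_freq <- function(codes, f, pt) {
    ft <- data.table::data.table(code = codes, code_type = "ICD10",
                                 frequency = f, person_time = pt,
                                 rate = f / pt)
    class(ft) <- c("frequency_table", class(ft))
    ft
  }
  fa <- mk_freq(c("x1", "x2"), c(100, 50), 10)
  fb_eq <- mk_freq(c("y1", "y2"), c(100, 50), 10)
  # equal rates: multiplier 1; gamma = 0: identity
  r_eq <- frequency_refine(sim, fa, fb_eq, gamma = 0.7)
  expect_equal(r_eq$sigma["x1", "y1"], sim$sigma["x1", "y1"], tolerance = 1e-12)
  expect_equal(frequency_refine(sim, fa, mk_freq(c("y1", "y2"), c(7, 3), 2),
                                gamma = 0)$sigma, sim$sigma, tolerance = 1e-12)

  # rate ratio e^2 with gamma = 0.5 multiplies by e^-1 (kappa = 0 keeps
  # the ratio exact)
  fb2 <- mk_freq(c("y1", "y2"), c(100 * exp(2), 50), 10)
  r2 <- frequency_refine(sim, fa, fb2, gamma = 0.5, kappa = 0)
  expect_equal(r2$sigma["x1", "y1"], sim$sigma["x1", "y1"] * exp(-1),
               tolerance = 1e-10)

  # sign never changes; damping monotone in |log rate ratio|
  simneg <- sim; simneg$sigma <- -abs(sim$sigma)
  rneg <- frequency_refine(simneg, fa, fb2, gamma = 0.5)
  expect_true(all(sign(rneg$sigma) == sign(simneg$sigma), na.rm = TRUE))
  m1 <- frequency_refine(sim, fa, fb2, gamma = 0.5, kappa = 0)$sigma["x1", "y1"]
  fb3 <- mk_freq(c("y1", "y2"), c(100 * exp(3), 50), 10)
  m2 <- frequency_refine(sim, fa, fb3, gamma = 0.5, kappa = 0)$sigma["x1", "y1"]
  expect_lt(m2, m1)
})

test_that("top-K and threshold selection order, tie-break and truncate", {
  sigma <- rbind(x1 = c(y1 = 0.9, y2 = 0.5, y3 = 0.1))
  sim <- structure(list(sigma = sigma, kind = "DS",
                        mask = !is.na(sigma), source_vocab = "x1",
                        ref_vocab = c("y1", "y2", "y3")),
                   class = "similarity_matrix")
  top2 <- select_topk(sim, 2L)
  expect_equal(top2$selection$x1$ref, c("y1", "y2"))
  expect_equal(select_topk(sim, 5L)$selection$x1$ref, c("y1", "y2", "y3"))

  # exact tie resolved toward the higher-frequency reference code
  sigt <- rbind(x1 = c(y1 = 0.5, y2 = 0.5))
  simt <- structure(list(sigma = sigt, kind = "DS", mask = !is.na(sigt),
                         source_vocab = "x1", ref_vocab = c("y1", "y2")),
                    class = "similarity_matrix")
  pick <- select_topk(simt, 1L, ref_freq = c(y1 = 5, y2 = 500))
  expect_equal(pick$selection$x1$ref, "y2")
  # and lexicographically without frequencies
  expect_equal(select_topk(simt, 1L)$selection$x1$ref, "y1")

  thr <- select_threshold(sim, 0.4)
  expect_equal(thr$selection$x1$ref, c("y1", "y2"))
  expect_true(all(thr$selection$x1$sim > 0.4))
})

test_that("harmonizer rows are stochastic, policies apply, mass is conserved", {
  sigma <- rbind(x1 = c(y1 = 0.6, y2 = 0.2), x2 = c(y1 = NA, y2 = NA))
  sim <- structure(list(sigma = sigma, kind = "DS", mask = !is.na(sigma),
                        source_vocab = c("x1", "x2"),
                        ref_vocab = c("y1", "y2")),
                   class = "similarity_matrix")
  spec <- select_topk(sim, 2L)
  H <- build_harmonizer(spec, sim, policy = "drop")
  expect_equal(H$M["x1", ], c(y1 = 0.75, y2 = 0.25))
  expect_equal(unname(H$M["x2", ]), c(0, 0))
  expect_equal(H$unmapped, "x2")

  # top-1 gives a 0/1 row; identity-carry keeps a shared unmapped code
  H1 <- build_harmonizer(select_topk(sim, 1L), sim)
  expect_equal(unname(H1$M["x1", ]), c(1, 0))
  sigma2 <- rbind(y1 = c(y1 = NA, y2 = NA))
  sim2 <- structure(list(sigma = sigma2, kind = "DS", mask = !is.na(sigma2),
                         source_vocab = "y1", ref_vocab = c("y1", "y2")),
                    class = "similarity_matrix")
  H2 <- build_harmonizer(select_topk(sim2, 1L), sim2)
  expect_equal(unname(H2$M["y1", ]), c(1, 0))

  # all-nonpositive similarities fall back to the unmapped policy
  sigma3 <- rbind(x1 = c(y1 = -0.3, y2 = -0.1))
  sim3 <- structure(list(sigma = sigma3, kind = "DS", mask = !is.na(sigma3),
                         source_vocab = "x1", ref_vocab = c("y1", "y2")),
                    class = "similarity_matrix")
  expect_warning(H3 <- build_harmonizer(select_topk(sim3, 2L), sim3,
                                        policy = "drop"), "unmapped")
  expect_equal(sum(H3$M), 0)

  # applying the operator conserves patient-level mass for mapped rows
  X <- matrix(c(2, 0, 1, 3), 2, 2, dimnames = list(c("P1", "P2"),
                                                   c("x1", "x2")))
  attr(X, "transform") <- "count"
  Xh <- apply_harmonizer(X, H1)
  expect_equal(unname(Xh[, "y1"]), c(2, 0))  # x2 is dropped, x1 carries over
  # when every row is mapped, per-patient totals are conserved exactly
  Hfull <- build_harmonizer(select_topk(sim, 2L), sim, policy = "drop")
  Hfull$M["x2", ] <- c(0.5, 0.5)  # treat x2 as mapped for the mass check
  expect_equal(unname(rowSums(apply_harmonizer(X, Hfull))),
               unname(rowSums(X)))
  Hid <- build_harmonizer(select_topk(sim2, 1L), sim2)
  expect_error(apply_harmonizer(X, Hid), "vocabulary")
})

test_that("cross-validated threshold selection is deterministic and sane", {
  cfg <- scenario_substitution(400L, seed = 19L)
  coh <- generate_cohort(cfg)
  grp <- synth_group_catalog(cfg)
  fa <- summarize_frequencies(coh$events_a, coh$covars_a)
  fb <- summarize_frequencies(coh$events_b, coh$covars_b)
  ea <- embed_codes(pmi_matrix(count_cooccurrence(coh$events_a,
                                                  nonrare_vocab(fa), 30L)), 8L)
  eb <- embed_codes(pmi_matrix(count_cooccurrence(coh$events_b,
                                                  nonrare_vocab(fb), 30L)), 8L)
  eaa <- align_embeddings(ea, rotation_align(ea, eb))
  sim <- directional_similarity(eaa, eb, grp)
  Xa <- patient_code_matrix(coh$events_a, coh$covars_a, sim$source_vocab, "count")
  Xb <- patient_code_matrix(coh$events_b, coh$covars_b, sim$ref_vocab, "count")
  # single-threshold grid returns that threshold
  one <- select_threshold_cv(sim, Xa, Xb, grid = 0.3, seed = 4L)
  expect_equal(one$tau, 0.3)
  res1 <- select_threshold_cv(sim, Xa, Xb, grid = c(0.2, 0.6), seed = 4L)
  res2 <- select_threshold_cv(sim, Xa, Xb, grid = c(0.2, 0.6), seed = 4L)
  expect_identical(res1$tau, res2$tau)
  expect_identical(res1$spec$selection, res2$spec$selection)
  expect_error(select_threshold_cv(sim, Xa, Xb, grid = numeric(0)), "empty")
})
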