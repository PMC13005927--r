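rand_embedding <- function(vocab, d, seed) {
  set.seed(seed)
  V <- matrix(rnorm(length(vocab) * d), length(vocab), d)
  rownames(V) <- vocab
  structure(list(V = V, vocab = vocab, d = d, values = rep(1, d),
                 mode = "PMI", shift = 1), class = "embedding_set")
}

rand_orthogonal <- function(d, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d, d)))
}

test_that("anchor selection is the sorted vocabulary intersection", {
  ea <- rand_embedding(c("A", "B", "C"), 3, 1)
  eb <- rand_embedding(c("B", "C", "D"), 3, 2)
  expect_equal(select_anchors(ea, eb), c("B", "C"))
  expect_equal(select_anchors(ea, ea), c("A", "B", "C"))
  ed <- rand_embedding(c("X", "Y"), 3, 3)
  expect_error(select_anchors(ea, ed), "overlap")
})

test_that("Procrustes rotation recovers a planted orthogonal transform", {
  vocab <- sprintf("c%02d", 1:30)
  ea <- rand_embedding(vocab, 6, 10)
  ea$V <- ea$V / sqrt(rowSums(ea$V^2))  # unit rows so the planted map is exact
  T0 <- rand_orthogonal(6, 11)
  eb <- ea; eb$V <- ea$V %*% T0
  fit <- rotation_align(ea, eb)
  expect_lt(max(abs(crossprod(fit$T) - diag(6))), 1e-8)
  Xa <- ea$V; Xb <- eb$V
  expect_lt(sqrt(sum((Xa %*% fit$T - Xb)^2)), 1e-8)

  # identical embeddings: T = I
  self <- rotation_align(ea, ea)
  expect_lt(max(abs(self$T - diag(6))), 1e-8)

  # orthogonal invariance: within-site cosines unchanged by alignment
  al <- align_embeddings(ea, fit)
  Vn0 <- ea$V / sqrt(rowSums(ea$V^2)); Vn1 <- al$V / sqrt(rowSums(al$V^2))
  expect_lt(max(abs(Vn0 %*% t(Vn0) - Vn1 %*% t(Vn1))), 1e-10)

  # noisy rotation: anchor objective within 10% of an independent
  # optimizer's objective on the same instance
  set.seed(12)
  ebn <- eb; ebn$V <- eb$V + matrix(rnorm(length(eb$V), 0, 0.05), nrow(eb$V))
  fitn <- rotation_align(ea, ebn)
  Xbn <- ebn$V / sqrt(rowSums(ebn$V^2))
  obj_fun <- function(par) {
    # optimize over skew-symmetric generators: T = expm(skew)
    S <- matrix(0, 6, 6); S[upper.tri(S)] <- par
    S <- S - t(S)
    E <- diag(6); Sk <- diag(6)
    for (k in 1:30) { Sk <- Sk %*% S / k; E <- E + Sk }
    sum((Xa %*% (fitn$T %*% E) - Xbn)^2)
  }
  op <- stats::optim(rep(0, 15), obj_fun, method = "BFGS",
                     control = list(maxit = 200, reltol = 1e-12))
  expect_lte(fitn$objective, op$value * 1.10 + 1e-12)
  expect_lte(fitn$objective, sum((Xa %*% diag(6) - Xbn)^2))
})

test_that("projection alignment solves the ridge normal equations", {
  vocab <- sprintf("c%02d", 1:25)
  ea <- rand_embedding(vocab, 5, 20)
  T0 <- matrix(rnorm(25), 5, 5)
  eb <- ea
  Xa_n <- ea$V / sqrt(rowSums(ea$V^2))
  eb$V <- Xa_n %*% T0
  eb$V <- eb$V / sqrt(rowSums(eb$V^2))
  # exact recovery up to per-row scale is not expected after normalization,
  # so check the oracle equality instead on the actual solve
  fit0 <- projection_align(ea, eb, lambda = 0)
  Xb_n <- eb$V
  T_or <- solve(crossprod(Xa_n), crossprod(Xa_n, Xb_n))
  expect_lt(max(abs(fit0$T - T_or)), 1e-10)

  # exact planted-map case (orthogonal T0 keeps rows unit, so the
  # normalization is inert and recovery is exact)
  T0q <- rand_orthogonal(5, 21)
  ea2 <- ea; ea2$V <- Xa_n
  eb2 <- ea2; eb2$V <- Xa_n %*% T0q
  fit2 <- projection_align(ea2, eb2, lambda = 0)
  expect_lt(max(abs(fit2$T - T0q)), 1e-8)

  lamlarge <- projection_align(ea, eb, lambda = 1e9)
  expect_lt(max(abs(lamlarge$T)), 1e-6)
  expect_error(projection_align(ea, eb, lambda = -1), ">= 0")

  # unconstrained projection never beats rotation's residual from below
  rot <- rotation_align(ea, eb)
  expect_lte(fit0$objective, rot$objective + 1e-10)
})

test_that("within-group similarity is 1 for identical singleton groups, ~0 for noise", {
  vocab <- c("A", "B", "C")
  ea <- rand_embedding(vocab, 4, 30)
  groups <- group_catalog(vocab, c("g1", "g2", "g3"))
  expect_equal(within_group_similarity(ea, ea, groups), 1, tolerance = 1e-10)

  vocab2 <- sprintf("c%02d", 1:40)
  groups2 <- group_catalog(vocab2, rep(sprintf("g%d", 1:8), each = 5))
  ea2 <- rand_embedding(vocab2, 20, 31)
  eb2 <- rand_embedding(vocab2, 20, 32)
  val <- within_group_similarity(ea2, eb2, groups2)
  expect_lt(abs(val), 3 / sqrt(8 * 25 * 20))

  eo <- rand_embedding(c("Z9"), 4, 33)
  expect_error(within_group_similarity(ea, eo, groups), "group")
})

test_that("alignment raises within-group similarity on synthetic two-site data", {
  cfg <- scenario_substitution(800L, seed = 13L)
  coh <- generate_cohort(cfg)
  grp <- synth_group_catalog(cfg)
  fa <- summarize_frequencies(coh$events_a, coh$covars_a)
  fb <- summarize_frequencies(coh$events_b, coh$covars_b)
  ea <- embed_codes(pmi_matrix(count_cooccurrence(coh$events_a,
                                                  nonrare_vocab(fa), 30L)), 10L)
  eb <- embed_codes(pmi_matrix(count_cooccurrence(coh$events_b,
                                                  nonrare_vocab(fb), 30L)), 10L)
  before <- within_group_similarity(ea, eb, grp)
  after <- within_group_similarity(align_embeddings(ea, rotation_align(ea, eb)),
                                   eb, grp)
  expect_gt(after, before)
})
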