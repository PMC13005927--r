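# L2-penalized logistic regression by IRLS; penalty excludes the
# intercept and is fixed (unscaled) so validation AUCs are comparable
# across feature sets rather than artifacts of hyperparameter tuning.
ridge_logistic <- function(X, y, lambda = 1, tol = 1e-8, max_iter = 100L) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  pen <- c(0, rep(lambda, ncol(X) - 1L))
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    g <- crossprod(X, y - mu) - pen * beta
    if (max(abs(g)) <= tol) break
    d <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * d) + diag(pen, ncol(X))
    step <- solve(H, g)
    # dampen runaway steps on near-separable folds
    if (max(abs(step)) > 10) step <- step * (10 / max(abs(step)))
    beta <- beta + drop(step)
  }
  beta
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  rs <- restore_seed(seed)
  on.exit(rs())
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

# Save/restore the RNG state so seeded internals do not perturb the
# caller's random stream.
restore_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

apply_feature_transform <- function(X, transform) {
  switch(transform,
         log1p = log1p(as.matrix(X)),
         binary = (as.matrix(X) > 0) + 0,
         none = as.matrix(X),
         stop("unknown feature transform: ", transform))
}

#' Domain-confusion validation: site-classifier AUC
#'
#' Stacks the reference-site matrix and the harmonized source-site matrix
#' (both over the reference vocabulary), fits an L2-regularized logistic
#' regression of the site label on the code features within each
#' stratified training fold, and pools the held-out scores into a single
#' cross-validated AUC with a DeLong 95% confidence interval. Successful
#' harmonization makes the two sites statistically indistinguishable, so
#' the AUC should approach 0.5.
#'
#' @param X_ref Reference-site `code_matrix` (count scale).
#' @param X_src Source-site matrix over the same reference vocabulary
#'   (typically the output of [apply_harmonizer()]).
#' @param folds Number of stratified CV folds.
#' @param seed Integer seed (fold assignment).
#' @param transform Feature transform: `"log1p"` (default), `"binary"`,
#'   `"none"`.
#' @param lambda Fixed ridge penalty of the classifier.
#' @param feature_set Tag recorded in the report.
#' @return A `validation_report` list: `auc`, `ci` (DeLong 95%),
#'   `feature_set`, `folds`, `seed`, and the pooled out-of-fold `scores`.
#' @export
site_auc <- function(X_ref, X_src, folds = 5L, seed = 1L,
                     transform = c("log1p", "binary", "none"), lambda = 1,
                     feature_set = "harmonized") {
  transform <- match.arg(transform)
  if (!identical(colnames(X_ref), colnames(X_src)))
    stop("both matrices must share the reference vocabulary")
  X <- rbind(apply_feature_transform(X_ref, transform),
             apply_feature_transform(X_src, transform))
  y <- c(rep(0L, nrow(X_ref)), rep(1L, nrow(X_src)))
  fold <- stratified_folds(y, folds, seed)
  if (min(table(y, fold)) < 2L)
    stop("a fold has fewer than 2 patients of one site; use more data or fewer folds")
  scores <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    beta <- ridge_logistic(X[tr, , drop = FALSE], y[tr], lambda = lambda)
    scores[!tr] <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% beta)
  }
  roc <- pROC::roc(response = y, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(0L, 1L))
  ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 ci = c(lower = max(ci[1L], 0), upper = min(ci[3L], 1)),
                 feature_set = feature_set, folds = folds, seed = seed,
                 scores = scores, site = y),
            class = "validation_report")
}

#' Pre-harmonization baseline AUC on overlapping codes
#'
#' The same classifier protocol restricted to codes present in both
#' sites' vocabularies, with no harmonization applied: the reference
#' point the harmonized AUC is compared against.
#'
#' @param X_ref Reference-site `code_matrix` over its own vocabulary.
#' @param X_src Source-site `code_matrix` over its own vocabulary.
#' @inheritParams site_auc
#' @return A `validation_report` with `feature_set = "overlap_baseline"`.
#' @export
baseline_overlap_auc <- function(X_ref, X_src, folds = 5L, seed = 1L,
                                 transform = c("log1p", "binary", "none"),
                                 lambda = 1) {
  transform <- match.arg(transform)
  overlap <- intersect(colnames(X_ref), colnames(X_src))
  if (length(overlap) == 0L) stop("no overlapping codes between sites")
  site_auc(X_ref[, overlap, drop = FALSE], X_src[, overlap, drop = FALSE],
           folds = folds, seed = seed, transform = transform, lambda = lambda,
           feature_set = "overlap_baseline")
}

#' Ground-truth recovery of a mapping selection
#'
#' On synthetic data the generative ground truth gives, for each source
#' code, the set of reference codes carrying the same clinical content.
#' Recovery is the fraction of truth-covered source codes whose top-1
#' selected reference code lies in that support set.
#'
#' @param spec A `mapping_spec`.
#' @param truth A [ground_truth()].
#' @return Accuracy in `[0, 1]`.
#' @export
mapping_recovery <- function(spec, truth) {
  src <- intersect(names(spec$selection), names(truth$map))
  if (length(src) == 0L) {
    warning("mapping selection is empty or disjoint from the ground truth")
    return(0)
  }
  hits <- vapply(src, function(sc) {
    sel <- spec$selection[[sc]]
    if (nrow(sel) == 0L) return(FALSE)
    sel$ref[1L] %in% truth$map[[sc]]$ref
  }, logical(1L))
  mean(hits)
}
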