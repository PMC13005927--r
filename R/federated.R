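#' Wrap one site's patient-level data as a summary-only data holder
#'
#' A `site_view` exposes per-iteration aggregate cross-products to the
#' federated fitting routines but never row-level data: given a broadcast
#' coefficient vector it returns `X'DX` and `X'Dz` (working response), and
#' at a converged null model it returns the group-test aggregates `G'r`,
#' `G'DG`, `G'DZ`, `Z'DZ`. Every payload exchanged is recorded in an audit
#' log so the summary-only contract can be inspected.
#'
#' @param Z Covariate matrix (no intercept) or [covariate_table()].
#' @param site Binary site indicator for this holder's patients.
#' @param G Optional patient x code matrix for group tests.
#' @return A `site_view` environment.
#' @export
site_view <- function(Z, site, G = NULL) {
  if (inherits(Z, "covariate_table")) Z <- covariate_design(Z)[, -1L, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, as.matrix(Z))
  env <- new.env(parent = emptyenv())
  env$X <- X
  env$y <- as.numeric(site)
  env$G <- if (!is.null(G)) as.matrix(G) else NULL
  env$audit <- list()
  class(env) <- "site_view"
  env
}

log_payload <- function(view, what, payload) {
  dims <- if (is.matrix(payload)) dim(payload) else c(length(payload), 1L)
  view$audit <- c(view$audit, list(list(what = what, dim = dims)))
  payload
}

# One IRLS round-trip: holder receives beta, returns its X'DX and X'Dz
# contributions (z the working response) plus its score contribution.
view_irls_payload <- function(view, beta) {
  eta <- drop(view$X %*% beta)
  if (max(abs(eta)) > 30)
    stop("complete separation detected: diverging coefficients")
  mu <- stats::plogis(eta)
  d <- mu * (1 - mu)
  z <- eta + (view$y - mu) / pmax(d, 1e-12)
  list(XtDX = log_payload(view, "XtDX", crossprod(view$X, view$X * d)),
       XtDz = log_payload(view, "XtDz", crossprod(view$X, d * z)),
       score = log_payload(view, "score", crossprod(view$X, view$y - mu)))
}

#' Federated logistic null-model fit from per-site aggregates
#'
#' Runs the same iteratively reweighted least squares as
#' [fit_null_model()], but each Newton step is assembled from the sum of
#' per-holder cross-products `X'DX` and `X'Dz`; no patient-level rows cross
#' the holder boundary. The returned coefficients equal the pooled
#' individual-level fit to numerical precision, because the pooled Newton
#' update is itself a sum of exactly these per-site quantities.
#'
#' @param views List of [site_view()] holders.
#' @param tol Convergence tolerance on the max absolute pooled score.
#' @param max_iter Iteration cap.
#' @return A `null_model` (without patient-level fields `X`, `y`, `mu`;
#'   carries `coef`, `iterations`, `grad_norm` and the holder list).
#' @export
federated_fit_null <- function(views, tol = 1e-10, max_iter = 100L) {
  p <- ncol(views[[1L]]$X)
  for (v in views) stopifnot(ncol(v$X) == p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    payloads <- lapply(views, view_irls_payload, beta = beta)
    g <- Reduce(`+`, lapply(payloads, `[[`, "score"))
    if (max(abs(g)) <= tol) break
    H <- Reduce(`+`, lapply(payloads, `[[`, "XtDX"))
    b <- Reduce(`+`, lapply(payloads, `[[`, "XtDz"))
    beta <- drop(solve(H, b))
  }
  payloads <- lapply(views, view_irls_payload, beta = beta)
  g <- Reduce(`+`, lapply(payloads, `[[`, "score"))
  if (max(abs(g)) > tol) stop("federated IRLS did not converge to tolerance ", tol)
  structure(list(coef = setNames(drop(beta), colnames(views[[1L]]$X)),
                 iterations = it, grad_norm = max(abs(g)), views = views),
            class = c("federated_null_model", "null_model"))
}

#' Per-site group-test aggregates at a converged null model
#'
#' Computed by one holder at the broadcast null coefficients: residual
#' aggregate `G'r`, and the cross-products `G'DG`, `G'DZ`, `Z'DZ` with
#' `D = diag(mu(1-mu))`, `r = y - mu`, `Z` the null design including the
#' intercept. These are the complete sufficient inputs for both the burden
#' and SKAT statistics.
#'
#' @param view A [site_view()] holding a code matrix `G`.
#' @param coef Converged null-model coefficients.
#' @return A `site_aggregate` list: `Gtr`, `GtDG`, `GtDZ`, `ZtDZ`, `n`.
#' @export
site_aggregates <- function(view, coef) {
  if (is.null(view$G)) stop("holder has no code matrix")
  eta <- drop(view$X %*% coef)
  mu <- stats::plogis(eta)
  d <- mu * (1 - mu)
  r <- view$y - mu
  structure(list(
    Gtr = log_payload(view, "Gtr", drop(crossprod(view$G, r))),
    GtDG = log_payload(view, "GtDG", crossprod(view$G, view$G * d)),
    GtDZ = log_payload(view, "GtDZ", crossprod(view$G, view$X * d)),
    ZtDZ = log_payload(view, "ZtDZ", crossprod(view$X, view$X * d)),
    n = length(view$y)), class = "site_aggregate")
}

#' Federated burden and SKAT tests from summed per-site aggregates
#'
#' Assembles the same score statistics as [burden_test()] and
#' [skat_test()] purely from the elementwise sums of per-site aggregates,
#' reproducing the pooled individual-level results exactly: the pooled
#' cross-products decompose additively over sites.
#'
#' @param aggs List of [site_aggregates()] (one per holder), all over the
#'   same code vocabulary and covariates.
#' @param w Per-code weights (default flat 1).
#' @param unit Group label.
#' @return `data.table` with one `burden_score` row and one `skat_Q` row.
#' @export
federated_group_tests <- function(aggs, w = NULL, unit = NA_character_) {
  dims <- vapply(aggs, function(a) length(a$Gtr), integer(1L))
  if (length(unique(dims)) != 1L)
    stop("code-vocabulary dimension mismatch between sites")
  pz <- vapply(aggs, function(a) ncol(a$ZtDZ), integer(1L))
  if (length(unique(pz)) != 1L)
    stop("covariate dimension mismatch between sites")
  Gtr <- Reduce(`+`, lapply(aggs, `[[`, "Gtr"))
  GtDG <- Reduce(`+`, lapply(aggs, `[[`, "GtDG"))
  GtDZ <- Reduce(`+`, lapply(aggs, `[[`, "GtDZ"))
  ZtDZ <- Reduce(`+`, lapply(aggs, `[[`, "ZtDZ"))
  if (is.null(w)) w <- rep(1, length(Gtr))
  A <- GtDG - GtDZ %*% solve(ZtDZ, t(GtDZ))
  rbind(burden_from_pieces(Gtr, A, w, unit),
        skat_from_pieces(Gtr, A, w, unit),
        fill = TRUE)
}

#' Audit log of a holder's exchanged payloads
#'
#' Returns what a holder has shared: payload names and dimensions only.
#' Every payload is aggregate-shaped — at most
#' `(n_codes + n_covariates + 1)` per side — never patient-level.
#'
#' @param view A [site_view()].
#' @return `data.table(what, rows, cols)`.
#' @export
audit_log <- function(view) {
  rbindlist(lapply(view$audit, function(e)
    data.table(what = e$what, rows = e$dim[1L], cols = e$dim[2L])))
}
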