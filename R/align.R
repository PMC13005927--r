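unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  M / pmax(nrm, .Machine$double.eps)
}

cosine_rows <- function(x, y) {
  sum(x * y) / max(sqrt(sum(x^2)) * sqrt(sum(y^2)), .Machine$double.eps)
}

#' Anchor codes shared by two embedding vocabularies
#'
#' The alignment is supervised by codes present (non-rare) at both sites;
#' the anchors are the full vocabulary intersection in deterministic
#' lexicographic order, optionally restricted to the top `n_top` by a
#' supplied frequency ranking.
#'
#' @param emb_a,emb_b `embedding_set`s for the source and reference site.
#' @param n_top Optional cap: keep the `n_top` highest-frequency anchors.
#' @param freq Named frequency vector used only when `n_top` is given.
#' @return Character vector of anchor codes.
#' @export
select_anchors <- function(emb_a, emb_b, n_top = NULL, freq = NULL) {
  anchors <- sort(intersect(emb_a$vocab, emb_b$vocab))
  if (length(anchors) == 0L) stop("embedding vocabularies do not overlap")
  if (!is.null(n_top) && n_top < length(anchors)) {
    if (is.null(freq)) stop("n_top requires a frequency vector")
    anchors <- sort(anchors[order(-freq[anchors])][seq_len(n_top)])
  }
  anchors
}

#' Rotation-based (orthogonal Procrustes) embedding alignment
#'
#' Finds the orthogonal transform minimizing
#' \eqn{\|X_A T - X_B\|_F} over the anchor rows (unit-normalized before
#' fitting), via the closed-form SVD of \eqn{X_A'X_B}. The orthogonality
#' constraint keeps predictions at a common length, making the alignment
#' robust to scale differences between site-specific embeddings; it also
#' preserves all within-site cosines.
#'
#' @param emb_a,emb_b Source and reference `embedding_set`s of equal
#'   dimension.
#' @param anchors Anchor codes from [select_anchors()].
#' @return An `alignment_map`: list with `method = "rotation"`, transform
#'   `T` (orthogonal, d x d), `objective` (anchor residual Frobenius^2),
#'   `n_anchors`.
#' @export
rotation_align <- function(emb_a, emb_b, anchors = select_anchors(emb_a, emb_b)) {
  if (emb_a$d != emb_b$d)
    stop("rotation alignment requires equal embedding dimensions")
  if (length(anchors) < emb_a$d)
    warning("fewer anchors (", length(anchors), ") than dimension (",
            emb_a$d, "); rotation is still defined but weakly constrained")
  Xa <- unit_rows(emb_a$V[anchors, , drop = FALSE])
  Xb <- unit_rows(emb_b$V[anchors, , drop = FALSE])
  sv <- svd(crossprod(Xa, Xb))
  T <- sv$u %*% t(sv$v)
  obj <- sum((Xa %*% T - Xb)^2)
  structure(list(method = "rotation", T = T, objective = obj, lambda = NA_real_,
                 n_anchors = length(anchors)), class = "alignment_map")
}

#' Projection-based (ridge regression) embedding alignment
#'
#' Unconstrained linear prediction of the reference anchors from the
#' source anchors: \eqn{T = argmin \|X_A T - X_B\|_F^2 + \lambda\|T\|_F^2},
#' solved by regularized normal equations. With `lambda = 0` this is the
#' least-squares projection, which never has a larger anchor residual than
#' the rotation solution (unconstrained superset).
#'
#' @param emb_a,emb_b Source and reference `embedding_set`s.
#' @param anchors Anchor codes.
#' @param lambda Ridge penalty, `>= 0`.
#' @return An `alignment_map` with `method = "projection"`.
#' @export
projection_align <- function(emb_a, emb_b,
                             anchors = select_anchors(emb_a, emb_b),
                             lambda = 0) {
  if (lambda < 0) stop("lambda must be >= 0")
  Xa <- unit_rows(emb_a$V[anchors, , drop = FALSE])
  Xb <- unit_rows(emb_b$V[anchors, , drop = FALSE])
  XtX <- crossprod(Xa)
  if (lambda == 0 && rcond(XtX) < 1e-12)
    stop("singular anchor system with lambda = 0; use lambda > 0")
  T <- solve(XtX + diag(lambda, ncol(Xa)), crossprod(Xa, Xb))
  obj <- sum((Xa %*% T - Xb)^2)
  structure(list(method = "projection", T = T, objective = obj,
                 lambda = lambda, n_anchors = length(anchors)),
            class = "alignment_map")
}

#' Apply an alignment map to a source embedding set
#'
#' Maps the source site's vectors into the reference coordinate system;
#' the reference embedding is never transformed.
#'
#' @param emb_a Source `embedding_set`.
#' @param map An `alignment_map`.
#' @return An `embedding_set` in reference coordinates.
#' @export
align_embeddings <- function(emb_a, map) {
  V <- emb_a$V %*% map$T
  rownames(V) <- emb_a$vocab
  out <- emb_a
  out$V <- V
  out$d <- ncol(V)
  out
}

#' Average within-group cross-site directional similarity
#'
#' Diagnostic for alignment quality: over every group containing codes
#' from both sites, the mean cosine between all cross-site code pairs
#' sharing the group, averaged within group first and then across groups.
#' Near 0 for unaligned independent spaces; increases after alignment when
#' the two sites share co-occurrence geometry.
#'
#' @param emb_a Source embeddings already mapped into reference
#'   coordinates (see [align_embeddings()]).
#' @param emb_b Reference embeddings.
#' @param groups A [group_catalog()].
#' @return Scalar mean cosine.
#' @export
within_group_similarity <- function(emb_a, emb_b, groups) {
  ga <- group_of(groups, emb_a$vocab)
  gb <- group_of(groups, emb_b$vocab)
  shared <- setdiff(intersect(ga, gb), "ungrouped")
  if (length(shared) == 0L) stop("no groups shared across the two vocabularies")
  Va <- unit_rows(emb_a$V); Vb <- unit_rows(emb_b$V)
  per_group <- vapply(shared, function(g) {
    S <- Va[ga == g, , drop = FALSE] %*% t(Vb[gb == g, , drop = FALSE])
    mean(S)
  }, numeric(1L))
  mean(per_group)
}
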