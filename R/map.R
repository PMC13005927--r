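#' Candidate mask for cross-site code mapping
#'
#' Mapping candidates for a source code are the reference codes in the
#' same clinical category (group); a code with no group is a candidate
#' only for its identically named reference code, if present.
#'
#' @param source_vocab,ref_vocab Site vocabularies.
#' @param groups A [group_catalog()].
#' @return Logical matrix source x reference.
#' @export
candidate_mask <- function(source_vocab, ref_vocab, groups) {
  gs <- group_of(groups, source_vocab)
  gr <- group_of(groups, ref_vocab)
  M <- outer(gs, gr, `==`) & outer(gs != "ungrouped", rep(TRUE, length(gr)))
  ident <- outer(source_vocab, ref_vocab, `==`)
  M <- M | (ident & gs == "ungrouped")
  dimnames(M) <- list(source_vocab, ref_vocab)
  M
}

new_similarity <- function(sigma, kind, mask) {
  structure(list(sigma = sigma, kind = kind, mask = mask,
                 source_vocab = rownames(sigma), ref_vocab = colnames(sigma)),
            class = "similarity_matrix")
}

#' Directional (cosine) similarity between aligned code embeddings
#'
#' Cosine similarity between each source code's aligned vector and each
#' candidate reference code's vector; pairs outside the candidate mask are
#' `NA`. Zero-norm embedding rows yield `NA` with a warning.
#'
#' @param emb_a Source embeddings in reference coordinates.
#' @param emb_b Reference embeddings.
#' @param groups A [group_catalog()] defining candidates.
#' @return A `similarity_matrix` of kind `"DS"`.
#' @export
directional_similarity <- function(emb_a, emb_b, groups) {
  mask <- candidate_mask(emb_a$vocab, emb_b$vocab, groups)
  na <- sqrt(rowSums(emb_a$V^2)); nb <- sqrt(rowSums(emb_b$V^2))
  degen <- c(emb_a$vocab[na == 0], emb_b$vocab[nb == 0])
  if (length(degen))
    warning("zero-norm embedding row(s); similarity undefined for: ",
            paste(degen, collapse = ", "))
  S <- (emb_a$V / pmax(na, .Machine$double.eps)) %*%
    t(emb_b$V / pmax(nb, .Machine$double.eps))
  S[outer(na == 0, nb == 0, `|`)] <- NA_real_
  S[!mask] <- NA_real_
  dimnames(S) <- list(emb_a$vocab, emb_b$vocab)
  new_similarity(S, "DS", mask)
}

#' Regression (candidate-adjusted) similarity
#'
#' For each source code, ridge regression of its aligned vector on all of
#' its candidate reference vectors jointly; the similarity to a candidate
#' is its coefficient, i.e. the association adjusted for the other
#' candidates in the category (the cosine is the unadjusted analog).
#'
#' @inheritParams directional_similarity
#' @param lambda Ridge penalty `>= 0`; with `lambda = 0` collinear
#'   candidate sets raise an error advising `lambda > 0`.
#' @return A `similarity_matrix` of kind `"RS"`.
#' @export
regression_similarity <- function(emb_a, emb_b, groups, lambda = 0) {
  if (lambda < 0) stop("lambda must be >= 0")
  mask <- candidate_mask(emb_a$vocab, emb_b$vocab, groups)
  Va <- unit_rows(emb_a$V); Vb <- unit_rows(emb_b$V)
  S <- matrix(NA_real_, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  for (i in seq_len(nrow(mask))) {
    cand <- which(mask[i, ])
    if (length(cand) == 0L) next
    Y <- t(Vb[cand, , drop = FALSE])              # d x m design
    YtY <- crossprod(Y)
    if (lambda == 0 && rcond(YtY) < 1e-12)
      stop("collinear candidates for source code ", rownames(mask)[i],
           " with lambda = 0; use lambda > 0")
    S[i, cand] <- drop(solve(YtY + diag(lambda, ncol(Y)),
                             crossprod(Y, Va[i, ])))
  }
  new_similarity(S, "RS", mask)
}

#' Frequency refinement of a similarity matrix
#'
#' Downweights candidate pairs whose usage rates disagree:
#' \deqn{\sigma'_{ij} = \sigma_{ij}\exp(-\gamma\,|\log(r_{A,i}/r_{B,j})|)}
#' with smoothed rates \eqn{r = (f+\kappa)/PT}. The multiplier lies in
#' (0, 1], never changes the sign of sigma, is monotone decreasing in the
#' absolute log rate ratio, and `gamma = 0` leaves sigma unchanged.
#'
#' @param sim A `similarity_matrix`.
#' @param freq_a,freq_b `frequency_table`s for the two sites.
#' @param gamma Bandwidth `>= 0`.
#' @param kappa Smoothing count applied to the rates (default 10).
#' @return A `similarity_matrix` of kind `"refined"`.
#' @export
frequency_refine <- function(sim, freq_a, freq_b, gamma = 0.5, kappa = 10) {
  if (gamma < 0) stop("gamma must be >= 0")
  fa <- setNames(rep(0, length(sim$source_vocab)), sim$source_vocab)
  fa[intersect(freq_a$code, names(fa))] <-
    freq_a$frequency[match(intersect(freq_a$code, names(fa)), freq_a$code)]
  fb <- setNames(rep(0, length(sim$ref_vocab)), sim$ref_vocab)
  fb[intersect(freq_b$code, names(fb))] <-
    freq_b$frequency[match(intersect(freq_b$code, names(fb)), freq_b$code)]
  ra <- (fa + kappa) / freq_a$person_time[1L]
  rb <- (fb + kappa) / freq_b$person_time[1L]
  mult <- exp(-gamma * abs(log(outer(ra, rb, `/`))))
  out <- sim
  out$sigma <- sim$sigma * mult
  out$kind <- "refined"
  out
}

new_mapping_spec <- function(selection, rule, K = NA_integer_, tau = NA_real_) {
  structure(list(selection = selection, rule = rule, K = K, tau = tau),
            class = "mapping_spec")
}

# Order candidate indices by similarity desc, ties by higher reference
# frequency then lexicographic code.
order_candidates <- function(sims, refs, ref_freq) {
  f <- if (is.null(ref_freq)) rep(0, length(refs)) else {
    x <- ref_freq[refs]; x[is.na(x)] <- 0; x
  }
  order(-sims, -f, refs)
}

#' Top-K mapping selection
#'
#' For each source code, the K candidates with the highest similarity;
#' ties broken by higher reference-code frequency, then lexicographic
#' code. Source codes with fewer than K candidates keep them all.
#'
#' @param sim A `similarity_matrix`.
#' @param K Number of reference codes per source code, `>= 1`.
#' @param ref_freq Optional named frequency vector for tie-breaking.
#' @return A `mapping_spec` with per-source `data.table(ref, sim, rank)`
#'   sorted by descending similarity.
#' @export
select_topk <- function(sim, K = 1L, ref_freq = NULL) {
  if (K < 1L) stop("K must be >= 1")
  sel <- lapply(sim$source_vocab, function(sc) {
    s <- sim$sigma[sc, ]
    cand <- which(!is.na(s))
    if (length(cand) == 0L) return(data.table(ref = character(), sim = numeric(),
                                              rank = integer()))
    refs <- sim$ref_vocab[cand]
    o <- order_candidates(s[cand], refs, ref_freq)
    keep <- o[seq_len(min(K, length(o)))]
    data.table(ref = refs[keep], sim = unname(s[cand][keep]),
               rank = seq_along(keep))
  })
  names(sel) <- sim$source_vocab
  new_mapping_spec(sel, "topK", K = as.integer(K))
}

#' Threshold mapping selection
#'
#' All candidates with similarity strictly above `tau`, sorted descending.
#'
#' @param sim A `similarity_matrix`.
#' @param tau Similarity threshold.
#' @param ref_freq Optional tie-break frequencies.
#' @return A `mapping_spec`.
#' @export
select_threshold <- function(sim, tau, ref_freq = NULL) {
  sel <- lapply(sim$source_vocab, function(sc) {
    s <- sim$sigma[sc, ]
    cand <- which(!is.na(s) & s > tau)
    if (length(cand) == 0L) return(data.table(ref = character(), sim = numeric(),
                                              rank = integer()))
    refs <- sim$ref_vocab[cand]
    o <- order_candidates(s[cand], refs, ref_freq)
    data.table(ref = refs[o], sim = unname(s[cand][o]), rank = seq_along(o))
  })
  names(sel) <- sim$source_vocab
  new_mapping_spec(sel, "threshold", tau = tau)
}

#' Cross-validated threshold selection by domain confusion
#'
#' Scans a grid of thresholds (default: deciles of the masked similarity
#' values); for each, builds the harmonization operator, harmonizes the
#' source matrix, and computes the held-out site-classifier AUC. The
#' chosen threshold minimizes `|AUC - 0.5|` — i.e. the threshold whose
#' harmonized data best confuses the site classifier. Deterministic given
#' the seed; ties go to the smallest threshold.
#'
#' @param sim A `similarity_matrix`.
#' @param X_src Source-site `code_matrix` (count scale) over the source
#'   vocabulary.
#' @param X_ref Reference-site `code_matrix` over the reference vocabulary.
#' @param folds Stratified CV folds.
#' @param grid Candidate thresholds; default deciles (10%..90%) of masked
#'   similarities.
#' @param seed Integer seed controlling fold assignment.
#' @param ref_freq Optional tie-break frequencies.
#' @return List with `tau`, `spec` (the selected `mapping_spec`), and the
#'   scanned `grid` with its AUCs.
#' @export
select_threshold_cv <- function(sim, X_src, X_ref, folds = 5L, grid = NULL,
                                seed = 1L, ref_freq = NULL) {
  vals <- sim$sigma[!is.na(sim$sigma)]
  if (is.null(grid))
    grid <- unique(unname(quantile(vals, probs = seq(0.1, 0.9, by = 0.1))))
  if (length(grid) == 0L) stop("empty threshold grid")
  grid <- sort(grid)
  aucs <- vapply(grid, function(tau) {
    spec <- select_threshold(sim, tau, ref_freq)
    H <- build_harmonizer(spec, sim)
    Xh <- apply_harmonizer(X_src, H)
    site_auc(X_ref, Xh, folds = folds, seed = seed)$auc
  }, numeric(1L))
  best <- which.min(abs(aucs - 0.5))
  tau <- grid[best]
  list(tau = tau, spec = select_threshold(sim, tau, ref_freq),
       grid = data.table(tau = grid, auc = aucs))
}

#' Build the harmonization operator from a mapping selection
#'
#' A nonnegative source x reference matrix M: each mapped source code's
#' row distributes its mass over its selected reference codes with weights
#' proportional to the positive part of the similarity, normalized to sum
#' to one (mass conserving). Source codes with no usable selection follow
#' the unmapped policy: `"identity-carry"` sends the code to its
#' identically named reference code when it exists (else drops it);
#' `"drop"` zeroes the row.
#'
#' @param spec A `mapping_spec`.
#' @param sim The `similarity_matrix` the spec was selected from (supplies
#'   the vocabularies).
#' @param policy `"identity-carry"` or `"drop"`.
#' @return A `harmonization_operator`: list with matrix `M`, `policy`, and
#'   `unmapped` (source codes that fell back to the policy).
#' @export
build_harmonizer <- function(spec, sim, policy = c("identity-carry", "drop")) {
  policy <- match.arg(policy)
  src <- sim$source_vocab; ref <- sim$ref_vocab
  M <- matrix(0, length(src), length(ref), dimnames = list(src, ref))
  unmapped <- character()
  for (sc in src) {
    sel <- spec$selection[[sc]]
    w <- if (is.null(sel) || nrow(sel) == 0L) numeric() else pmax(sel$sim, 0)
    if (length(w) == 0L || sum(w) <= 0) {
      if (length(w) > 0L)
        warning("all selected similarities <= 0 for ", sc,
                "; falling back to unmapped policy")
      if (policy == "identity-carry" && sc %in% ref) M[sc, sc] <- 1
      unmapped <- c(unmapped, sc)
      next
    }
    M[sc, sel$ref] <- w / sum(w)
  }
  structure(list(M = M, policy = policy, unmapped = unmapped),
            class = "harmonization_operator")
}

#' Harmonize a source-site code matrix into the reference vocabulary
#'
#' `X_harmonized = X M`: each patient's endorsements of a mapped source
#' code are redistributed over its selected reference codes; because
#' mapped rows of M sum to one, total count mass is conserved for them.
#'
#' @param X Source `code_matrix` (columns = source vocabulary; count scale
#'   recommended).
#' @param harmonizer A `harmonization_operator`.
#' @return A `code_matrix` over the reference vocabulary.
#' @export
apply_harmonizer <- function(X, harmonizer) {
  M <- harmonizer$M
  if (!identical(colnames(X), rownames(M)))
    stop("code matrix vocabulary does not match harmonizer rows")
  out <- as.matrix(X) %*% M
  attr(out, "transform") <- attr(X, "transform")
  class(out) <- c("code_matrix", class(out))
  out
}

#' Write a mapping specification to CSV
#' @param spec A `mapping_spec`.
#' @param path Output CSV (`source_code, reference_code, similarity, rank`).
#' @return `path`, invisibly.
#' @export
write_mapping <- function(spec, path) {
  rows <- rbindlist(lapply(names(spec$selection), function(sc) {
    sel <- spec$selection[[sc]]
    if (nrow(sel) == 0L) return(NULL)
    data.table(source_code = sc, reference_code = sel$ref,
               similarity = sel$sim, rank = sel$rank)
  }))
  fwrite(rows, path)
  invisible(path)
}
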