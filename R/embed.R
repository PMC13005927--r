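#' Within-patient temporal co-occurrence counts
#'
#' Counts, for every unordered pair of distinct vocabulary codes, the
#' number of event pairs belonging to the same patient whose dates differ
#' by at most `window` days. Each qualifying *event* pair counts once (so
#' two endorsements of code A near one of code B contribute 2), preserving
#' the frequency information that matters for medical codes; the diagonal
#' is zero.
#'
#' @param events An [event_table()].
#' @param vocab Codes to count over (typically the non-rare vocabulary,
#'   site frequency >= 10; see [nonrare_vocab()]).
#' @param window Non-negative window in days.
#' @return A `cooccurrence_matrix`: list with symmetric integer matrix `C`,
#'   marginals `n` (row sums: each code's pair participation), total
#'   unordered pair count `N`, `vocab`, `window`.
#' @export
count_cooccurrence <- function(events, vocab, window = 30L) {
  if (window < 0) stop("window must be non-negative")
  vocab <- sort(unique(vocab))
  ev <- as.data.table(events)[code %in% vocab]
  m <- length(vocab)
  if (nrow(ev) == 0L) {
    C <- matrix(0, m, m, dimnames = list(vocab, vocab))
    return(structure(list(C = C, n = rowSums(C), N = 0, vocab = vocab,
                          window = window), class = "cooccurrence_matrix"))
  }
  ev[, ci := match(code, vocab)]
  ev[, day := as.integer(date)]
  setorder(ev, patient_id, day)
  ii <- jj <- vector("list", 0L)
  # per patient: sorted days; for each event, partners are the following
  # events within the window (two-pointer via findInterval)
  by_pat <- split(ev[, .(ci, day)], ev$patient_id)
  for (pe in by_pat) {
    ne <- nrow(pe)
    if (ne < 2L) next
    upto <- findInterval(pe$day + window, pe$day)
    len <- upto - seq_len(ne)
    len[len < 0L] <- 0L
    if (sum(len) == 0L) next
    i_idx <- rep.int(seq_len(ne), len)
    j_idx <- i_idx + sequence(len)
    keep <- pe$ci[i_idx] != pe$ci[j_idx]
    if (!any(keep)) next
    ii[[length(ii) + 1L]] <- pe$ci[i_idx][keep]
    jj[[length(jj) + 1L]] <- pe$ci[j_idx][keep]
  }
  C <- matrix(0, m, m, dimnames = list(vocab, vocab))
  if (length(ii)) {
    iv <- unlist(ii); jv <- unlist(jj)
    S <- sparseMatrix(i = c(iv, jv), j = c(jv, iv), x = 1, dims = c(m, m))
    C <- as.matrix(S)
    dimnames(C) <- list(vocab, vocab)
  }
  structure(list(C = C, n = rowSums(C), N = sum(C) / 2, vocab = vocab,
                 window = window), class = "cooccurrence_matrix")
}

#' Pointwise mutual information matrix from co-occurrence counts
#'
#' For observed pairs,
#' \deqn{PMI_{ij} = \log\frac{C_{ij}/N}{(n_i/N)(n_j/N)}}
#' with \eqn{n_i} code i's pair participation and N the total unordered
#' pair count; unobserved pairs are exactly 0. `mode = "SPPMI"` applies the
#' shifted-positive truncation \eqn{\max(PMI - \log s, 0)}. No rows are
#' zeroed out for high-frequency codes: frequent medical codes designate
#' common conditions and carry signal, unlike NLP stop words — the PMI mode
#' is the recommended default, SPPMI is retained for comparison.
#'
#' @param cooc A [count_cooccurrence()] result.
#' @param mode `"PMI"` or `"SPPMI"`.
#' @param shift Shift `s >= 1` (SPPMI only; `log s` is subtracted).
#' @return A `pmi_matrix`: list with symmetric matrix `P`, `vocab`, `mode`,
#'   `shift`, and `zeroed` (codes whose SPPMI row is entirely zero;
#'   empty in PMI mode).
#' @export
pmi_matrix <- function(cooc, mode = c("PMI", "SPPMI"), shift = 1) {
  mode <- match.arg(mode)
  if (shift < 1) stop("shift must be >= 1")
  if (cooc$N <= 0) stop("no co-occurring pairs (N = 0)")
  C <- cooc$C; n <- cooc$n; N <- cooc$N
  P <- matrix(0, nrow(C), ncol(C), dimnames = dimnames(C))
  obs <- C > 0
  P[obs] <- log((C[obs] / N) / ((n[row(P)[obs]] / N) * (n[col(P)[obs]] / N)))
  zeroed <- character()
  if (mode == "SPPMI") {
    P <- pmax(P - log(shift), 0)
    P[!obs] <- 0
    live <- n > 0
    zeroed <- cooc$vocab[live & rowSums(P != 0) == 0L]
  }
  structure(list(P = P, vocab = cooc$vocab, mode = mode, shift = shift,
                 zeroed = zeroed), class = "pmi_matrix")
}

#' Code embeddings by truncated spectral factorization of the PMI matrix
#'
#' Symmetric eigendecomposition of P; the embedding takes the `d`
#' largest-magnitude eigenvalues with
#' \eqn{V = U_d \, diag(\sqrt{|\sigma_d|})}. Deterministic: each column's
#' sign is fixed so its largest-magnitude entry is positive.
#'
#' @param pmi A [pmi_matrix()].
#' @param d Embedding dimension, `1 <= d <= |vocab|`; reduced with a
#'   warning if it exceeds the numerical rank.
#' @return An `embedding_set`: list with matrix `V` (codes x d, rownames =
#'   vocab), `vocab`, `d`, `values` (retained eigenvalues), and provenance
#'   (`mode`, `shift`).
#' @export
embed_codes <- function(pmi, d = 20L) {
  m <- length(pmi$vocab)
  if (d < 1 || d > m) stop("d must be in [1, |vocab|]")
  eg <- eigen((pmi$P + t(pmi$P)) / 2, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  vals <- eg$values[ord]; U <- eg$vectors[, ord, drop = FALSE]
  rank <- sum(abs(vals) > max(abs(vals)) * 1e-12)
  if (d > rank) {
    warning("requested dimension ", d, " exceeds rank ", rank, "; reduced")
    d <- rank
  }
  vals <- vals[seq_len(d)]; U <- U[, seq_len(d), drop = FALSE]
  for (k in seq_len(d)) {
    top <- which.max(abs(U[, k]))
    if (U[top, k] < 0) U[, k] <- -U[, k]
  }
  V <- U * rep(sqrt(abs(vals)), each = m)
  rownames(V) <- pmi$vocab
  structure(list(V = V, vocab = pmi$vocab, d = d, values = vals,
                 mode = pmi$mode, shift = pmi$shift),
            class = "embedding_set")
}

#' Serialize an embedding set to CSV (+ JSON provenance sidecar)
#' @param emb An [embed_codes()] result.
#' @param path CSV path; a `.json` sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  dt <- data.table(code = emb$vocab)
  V <- emb$V; colnames(V) <- sprintf("v%d", seq_len(ncol(V)))
  fwrite(cbind(dt, as.data.table(V)), path)
  jsonlite::write_json(list(d = emb$d, mode = emb$mode, shift = emb$shift),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
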