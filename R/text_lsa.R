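# Latent semantic analysis: log-entropy weighted term-document matrix,
# truncated SVD embedding, and cosine proximity.

#' Build a latent semantic model from a corpus
#'
#' Term-document counts are weighted as `log(1 + count)` times a global
#' entropy weight `1 + sum_d p log p / log(n_docs)`, then decomposed by a
#' rank-`k` truncated SVD. Each vocabulary word is represented by its
#' left-singular row scaled by the singular values; proximity between words
#' is the cosine of their vectors. Singular-vector signs are fixed by
#' forcing the largest-magnitude entry of each left-singular vector
#' positive, making the build fully deterministic.
#'
#' @param corpus character vector of documents.
#' @param k embedding rank (`"full"` for the exact decomposition).
#' @param concepts words that must be present in the vocabulary; the build
#'   fails listing any that are missing.
#' @param min_count vocabulary threshold: words occurring fewer times in
#'   the whole corpus are dropped (concept words are always kept).
#' @return list of class `sc_semantic_model`: `vocab`, `vectors`
#'   (|V| x k), `k`, `fingerprint` (corpus digest).
#' @export
build_semantic_model <- function(corpus, k = 100,
                                 concepts = default_concepts(),
                                 min_count = 2) {
  if (length(corpus) < 50)
    stop("corpus must contain at least 50 documents (got ", length(corpus),
         ")", call. = FALSE)
  doc_toks <- lapply(strsplit(tolower(corpus), "\\s+"), function(t)
    t[nzchar(t)])
  all_toks <- unlist(doc_toks)
  counts <- table(all_toks)
  vocab <- names(counts)[counts >= min_count | names(counts) %in% concepts]
  missing <- setdiff(concepts, vocab)
  if (length(missing) > 0)
    stop("concept words absent from corpus vocabulary: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n_docs <- length(corpus)
  tdm <- matrix(0L, length(vocab), n_docs,
                dimnames = list(vocab, NULL))
  for (d in seq_len(n_docs)) {
    tt <- table(factor(doc_toks[[d]], levels = vocab))
    tdm[, d] <- as.integer(tt)
  }
  gf <- rowSums(tdm)
  P <- tdm / gf
  ent <- rowSums(ifelse(P > 0, P * log(P), 0)) / log(n_docs)
  gweight <- 1 + ent
  W <- gweight * log1p(tdm)
  if (identical(k, "full")) k <- min(dim(W))
  if (k >= min(dim(W)) + 1 || k < 2)
    stop("rank k must satisfy 2 <= k <= min(|V|, #docs)", call. = FALSE)
  sv <- svd(W, nu = k, nv = 0)
  U <- sv$u
  # deterministic sign convention
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  vectors <- U %*% diag(sv$d[seq_len(k)], k)
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors, k = k,
                 fingerprint = digest_text(corpus)),
            class = "sc_semantic_model")
}

# cheap deterministic text digest (32 hex chars via two rolling hashes)
digest_text <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h1 <- 0; h2 <- 0
  for (b in bytes[seq(1, length(bytes), by = max(1, length(bytes) %/% 4096))]) {
    h1 <- (h1 * 131 + b) %% 2147483587
    h2 <- (h2 * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Cosine proximity between two words
#'
#' @param model an `sc_semantic_model`.
#' @param word_a,word_b words; both must be in the model vocabulary.
#' @return cosine similarity in \[-1, 1\].
#' @export
proximity <- function(model, word_a, word_b) {
  ia <- match(word_a, model$vocab)
  ib <- match(word_b, model$vocab)
  if (is.na(ia) || is.na(ib))
    stop("word not in model vocabulary: ",
         paste(c(word_a, word_b)[is.na(c(ia, ib))], collapse = ", "),
         call. = FALSE)
  va <- model$vectors[ia, ]
  vb <- model$vectors[ib, ]
  den <- sqrt(sum(va^2) * sum(vb^2))
  if (den == 0) return(0)
  sum(va * vb) / den
}

# Vectorized proximities of one concept against many words (by row index)
proximity_many <- function(model, concept, idx) {
  vc <- model$vectors[match(concept, model$vocab), ]
  Vm <- model$vectors[idx, , drop = FALSE]
  den <- sqrt(rowSums(Vm^2) * sum(vc^2))
  num <- as.numeric(Vm %*% vc)
  ifelse(den == 0, 0, num / den)
}

#' Extract the 21 concept-proximity semantic features
#'
#' For each concept of interest, the feature is the median cosine proximity
#' between the concept and the transcript's in-vocabulary lemmas.
#'
#' @param transcript an `sc_transcript` from [clean_and_tag()].
#' @param model an `sc_semantic_model`.
#' @param concepts concept word list (default the packaged 21).
#' @param nouns_only restrict eligible words to noun-tagged lemmas.
#' @return named numeric vector of `length(concepts)` features, names
#'   prefixed `S-`; all NA (with a warning) when no transcript lemma is in
#'   vocabulary.
#' @export
extract_semantic <- function(transcript, model,
                             concepts = default_concepts(),
                             nouns_only = FALSE) {
  lem <- transcript$lemmas
  if (nouns_only) lem <- lem[startsWith(transcript$tags, "NN")]
  idx <- match(lem, model$vocab)
  idx <- idx[!is.na(idx)]
  out <- stats::setNames(rep(NA_real_, length(concepts)),
                         paste0("S-", concepts))
  if (length(idx) == 0) {
    warning("no in-vocabulary lemmas; semantic features missing",
            call. = FALSE)
    return(out)
  }
  for (ci in seq_along(concepts))
    out[ci] <- stats::median(proximity_many(model, concepts[ci], idx))
  out
}
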