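# Distributional token embeddings trained with skip-gram negative sampling.
# Tokens sharing contexts (e.g. a misspelled variant and its canonical form)
# converge to nearby vectors, which is what entity alignment exploits.

#' Train token embeddings on a corpus
#'
#' Skip-gram with negative sampling over a symmetric context window.
#' Sampling of negatives follows the unigram distribution raised to 3/4.
#'
#' @param corpus records, a `synth_corpus`, or list of token vectors.
#' @param dim embedding dimension.
#' @param window symmetric context window in tokens.
#' @param epochs passes over the corpus.
#' @param negative negative samples per positive pair.
#' @param lr SGD learning rate (linearly decayed).
#' @param rng_seed integer seed.
#' @return object of class `token_embeddings`: `vocab` and `vectors`
#'   (|V| x dim matrix, rows named by token).
#' @export
train_token_embeddings <- function(corpus, dim = 32L, window = 2L,
                                   epochs = 5L, negative = 5L, lr = 0.05,
                                   rng_seed = 1) {
  seqs <- corpus_token_sequences(corpus)
  toks <- unlist(seqs, use.names = FALSE)
  vocab <- sort(unique(toks))
  V <- length(vocab)
  idx_seqs <- lapply(seqs, function(s) match(s, vocab))
  freq <- tabulate(unlist(idx_seqs), V)
  neg_prob <- freq^0.75 / sum(freq^0.75)
  with_seed(rng_seed, {
    W <- matrix(stats::rnorm(V * dim, 0, 0.5 / sqrt(dim)), V, dim)
    C <- matrix(0, V, dim)
    # precompute (center, context) pairs
    centers <- integer(0); contexts <- integer(0)
    for (s in idx_seqs) {
      n <- length(s)
      if (n < 2L) next
      for (off in seq_len(window)) {
        if (n <= off) next
        centers <- c(centers, s[seq_len(n - off)], s[(off + 1L):n])
        contexts <- c(contexts, s[(off + 1L):n], s[seq_len(n - off)])
      }
    }
    npair <- length(centers)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(npair)
      lr_ep <- lr * (1 - (ep - 1) / epochs)
      negs <- matrix(sample.int(V, npair * negative, replace = TRUE,
                                prob = neg_prob), npair, negative)
      for (k in seq_len(npair)) {
        i <- centers[ord[k]]; j <- contexts[ord[k]]
        w <- W[i, ]
        # positive
        sg <- 1 / (1 + exp(-sum(w * C[j, ]))) - 1
        gw <- sg * C[j, ]
        C[j, ] <- C[j, ] - lr_ep * sg * w
        # negatives
        for (m in negs[ord[k], ]) {
          if (m == j) next
          sgn <- 1 / (1 + exp(-sum(w * C[m, ])))
          gw <- gw + sgn * C[m, ]
          C[m, ] <- C[m, ] - lr_ep * sgn * w
        }
        W[i, ] <- w - lr_ep * gw
      }
    }
    rownames(W) <- vocab
    structure(list(vocab = vocab, vectors = W, dim = dim),
              class = "token_embeddings")
  })
}

#' @export
print.token_embeddings <- function(x, ...) {
  cat("<token_embeddings>", length(x$vocab), "tokens x", x$dim, "dims\n")
  invisible(x)
}

corpus_token_sequences <- function(corpus) {
  records <- if (inherits(corpus, "synth_corpus")) corpus$records else corpus
  lapply(records, function(r)
    if (is.list(r) && !is.null(r$tokens)) r$tokens else r)
}

#' Vectorize entities with token embeddings
#'
#' An entity vector is the mean of its token vectors (length-invariant
#' reduction); unknown tokens contribute a zero vector.
#'
#' @param entities character vector of entity strings.
#' @param embeddings a `token_embeddings`.
#' @return matrix, one row per entity.
#' @export
embed_entities <- function(entities, embeddings) {
  out <- t(vapply(entities, function(e) {
    toks <- entity_tokens(e)
    hit <- match(toks, embeddings$vocab)
    vs <- embeddings$vectors[hit[!is.na(hit)], , drop = FALSE]
    if (!nrow(vs)) numeric(embeddings$dim) else colMeans(vs)
  }, numeric(embeddings$dim)))
  rownames(out) <- entities
  out
}
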