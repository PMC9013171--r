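# shared fixture builders; everything is generated in code at test time

tiny_kb <- function(seed = 7, n_ent = 6, n_rel = 4, max_degree = Inf) {
  generate_kb(n_ent, n_rel, rng_seed = seed, max_degree = max_degree)
}

tiny_corpus <- function(kb = tiny_kb(), n_records = 40, noise = 0, seed = 1) {
  render_records(kb, n_records, mean_statements = 3.3, noise_rate = noise,
                 rng_seed = seed)
}

# hand-built one-sentence mining corpus from explicit tokens
sentence_corpus <- function(...) {
  sents <- list(...)
  lapply(seq_along(sents), function(i)
    list(record_id = sprintf("r%02d", i),
         tokens = c(sents[[i]], ".")))
}

# a vectorizer stub returning fixed rows for known strings
stub_vectorizer <- function(vectors) {
  function(strings) {
    out <- do.call(rbind, lapply(strings, function(s) vectors[[s]]))
    rownames(out) <- strings
    out
  }
}

# central finite-difference gradient of f at X
numeric_grad <- function(f, X, eps = 1e-5) {
  G <- X * 0
  for (i in seq_along(X)) {
    X1 <- X; X1[i] <- X[i] + eps
    X2 <- X; X2[i] <- X[i] - eps
    G[i] <- (f(X1) - f(X2)) / (2 * eps)
  }
  G
}

# brute-force CRF path enumeration helpers
all_paths <- function(T_, L) as.matrix(expand.grid(rep(list(seq_len(L)), T_)))

brute_best_path <- function(P, A, mask = NULL) {
  L <- ncol(P)
  paths <- all_paths(nrow(P), L)
  ok <- rep(TRUE, nrow(paths))
  if (!is.null(mask)) {
    for (r in seq_len(nrow(paths))) {
      y <- paths[r, ]
      if (!mask$start_legal[y[1]] || !mask$end_legal[y[length(y)]]) {
        ok[r] <- FALSE; next
      }
      if (length(y) > 1) for (t in 2:length(y))
        if (!mask$legal[y[t - 1], y[t]]) { ok[r] <- FALSE; break }
    }
  }
  sc <- apply(paths, 1, function(y) crf_sequence_score(P, A, y))
  sc[!ok] <- -Inf
  paths[which.max(sc), ]
}
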