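# Relation classification: sliding-window convolution over word vectors,
# max pooling, concatenation with a paragraph-context vector, softmax.

#' Relation CNN configuration
#'
#' Defaults follow the published selection: convolution window of 5 words
#' over 100-dimensional word vectors, 16 kernels, a 128-unit fully connected
#' layer. `kernel_geometry = "table"` is that preset; `"prose"` is the
#' alternative geometry (kernel width half the input sequence, height half
#' the word-vector dimension) kept as a documented preset since the two
#' published descriptions conflict.
#'
#' @param window convolution window h in words.
#' @param word_dim word vector dimension k.
#' @param kernels number of convolution kernels.
#' @param fc fully connected layer width.
#' @param seq_len fixed input length n; shorter inputs are padded
#'   symmetrically with the zero-vector padding token, longer ones keep
#'   their leftmost/rightmost halves.
#' @param kernel_geometry `"table"` or `"prose"`.
#' @param epochs,lr,batch_size optimizer settings.
#' @param none_threshold maximum-probability floor below which an entity
#'   pair is labeled NONE at inference.
#' @param unk_augment fraction of blank (all-unknown) inputs with
#'   prior-sampled labels mixed into each epoch; calibrates the softmax so
#'   uninformative contexts fall toward the class prior and get rejected by
#'   the NONE threshold.
#' @param activation nonlinearity of the convolution layer.
#' @export
relation_cnn_config <- function(window = 5L, word_dim = 100L, kernels = 16L,
                                fc = 128L, seq_len = 20L,
                                kernel_geometry = c("table", "prose"),
                                epochs = 12L, lr = 2e-2, batch_size = 16L,
                                none_threshold = 0.5, unk_augment = 0.1,
                                activation = c("tanh", "relu")) {
  list(window = as.integer(window), word_dim = as.integer(word_dim),
       kernels = as.integer(kernels), fc = as.integer(fc),
       seq_len = as.integer(seq_len),
       kernel_geometry = match.arg(kernel_geometry),
       epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size),
       none_threshold = none_threshold, unk_augment = unk_augment,
       activation = match.arg(activation))
}

#' Convolution + max-pooling feature extractor
#'
#' Computes `c_i = f(w . x_{i:i+h-1} + b)` for every window position and
#' max-pools each kernel's feature map to a single value. Inputs shorter
#' than the window are zero-padded rather than rejected.
#'
#' @param x_window numeric matrix, one row per word (n x k).
#' @param kernels list with `W` ((h * k) x m kernel matrix) and `b`
#'   (length-m bias).
#' @param h window length in words.
#' @param activation `"tanh"` (default) or `"relu"`.
#' @return list with `conv` (positions x kernels feature map) and `pooled`
#'   (length-m vector of maxima).
#' @export
conv_features <- function(x_window, kernels, h, activation = "tanh") {
  k <- ncol(x_window)
  if (nrow(x_window) < h)
    x_window <- rbind(x_window,
                      matrix(0, h - nrow(x_window), k))
  n <- nrow(x_window)
  npos <- n - h + 1L
  X <- t(vapply(seq_len(npos), function(i)
    as.vector(t(x_window[i:(i + h - 1L), , drop = FALSE])),
    numeric(h * k)))
  z <- sweep(X %*% kernels$W, 2, kernels$b, "+")
  conv <- if (activation == "relu") pmax(z, 0) else tanh(z)
  list(conv = conv, pooled = apply(conv, 2, max))
}

# ---- paragraph vectors -----------------------------------------------------

#' Train paragraph-context vectors
#'
#' Learns one vector per paragraph (record) by predicting the paragraph's
#' words from its vector with negative sampling against the word embedding
#' table. Word vectors are taken from pre-trained token embeddings; during
#' corpus training they receive updates too (joint mode), while
#' [infer_paragraph_vector()] freezes them.
#'
#' @param corpus records or list of token vectors.
#' @param embeddings a `token_embeddings` (word vectors; dimension sets the
#'   paragraph vector dimension).
#' @param epochs,lr training settings.
#' @param rng_seed integer seed.
#' @param joint update word vectors together with paragraph vectors.
#' @return object of class `paragraph_vectors`: `vectors` (one row per
#'   paragraph, named by record id) and the word `embeddings` used.
#' @export
train_paragraph_vectors <- function(corpus, embeddings, epochs = 5L,
                                    lr = 0.05, rng_seed = 1, joint = TRUE) {
  records <- if (inherits(corpus, "synth_corpus")) corpus$records else corpus
  ids <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (is.list(r) && !is.null(r$record_id)) r$record_id else
      sprintf("rec%05d", i)
  }, character(1))
  seqs <- corpus_token_sequences(records)
  W <- embeddings$vectors
  V <- nrow(W); dim <- ncol(W)
  with_seed(rng_seed, {
    P <- matrix(stats::rnorm(length(seqs) * dim, 0, 0.1), length(seqs), dim)
    for (ep in seq_len(epochs)) {
      for (pi in sample(seq_along(seqs))) {
        widx <- match(seqs[[pi]], embeddings$vocab)
        widx <- widx[!is.na(widx)]
        if (!length(widx)) next
        for (wi in widx) {
          pv <- P[pi, ]
          sg <- 1 / (1 + exp(-sum(pv * W[wi, ]))) - 1
          gp <- sg * W[wi, ]
          if (joint) W[wi, ] <- W[wi, ] - lr * sg * pv
          negs <- sample.int(V, min(3L, V), replace = TRUE)
          for (m in negs) {
            if (m == wi) next
            sgn <- 1 / (1 + exp(-sum(pv * W[m, ])))
            gp <- gp + sgn * W[m, ]
            if (joint) W[m, ] <- W[m, ] - lr * sgn * pv
          }
          P[pi, ] <- pv - lr * gp
        }
      }
    }
    rownames(P) <- ids
    emb2 <- embeddings
    emb2$vectors <- W
    structure(list(vectors = P, embeddings = emb2, dim = dim),
              class = "paragraph_vectors")
  })
}

#' Infer a vector for an unseen paragraph
#'
#' Gradient steps update only the new paragraph vector; the word embedding
#' table remains fixed. Deterministic given the seed; an empty paragraph
#' yields a zero vector flagged degenerate.
#'
#' @param tokens paragraph tokens.
#' @param pv a `paragraph_vectors` (supplies the frozen word vectors).
#' @param epochs,lr inference settings.
#' @param rng_seed integer seed.
#' @return numeric vector with attribute `degenerate` when empty.
#' @export
infer_paragraph_vector <- function(tokens, pv, epochs = 10L, lr = 0.05,
                                   rng_seed = 1) {
  W <- pv$embeddings$vectors
  widx <- match(tokens, pv$embeddings$vocab)
  widx <- widx[!is.na(widx)]
  if (!length(widx)) {
    v <- numeric(pv$dim)
    attr(v, "degenerate") <- TRUE
    return(v)
  }
  V <- nrow(W)
  with_seed(rng_seed, {
    vec <- stats::rnorm(pv$dim, 0, 0.1)
    for (ep in seq_len(epochs)) for (wi in widx) {
      sg <- 1 / (1 + exp(-sum(vec * W[wi, ]))) - 1
      gp <- sg * W[wi, ]
      for (m in sample.int(V, min(3L, V), replace = TRUE)) {
        if (m == wi) next
        sgn <- 1 / (1 + exp(-sum(vec * W[m, ])))
        gp <- gp + sgn * W[m, ]
      }
      vec <- vec - lr * gp
    }
    vec
  })
}

# ---- CNN model -------------------------------------------------------------

ENT_SLOT <- "<ENT>"

cnn_vocab <- function(examples) {
  c("<PAD>", "<UNK>", ENT_SLOT,
    sort(setdiff(unique(unlist(lapply(examples, `[[`, "tokens"))), ENT_SLOT)))
}

# pad or crop to fixed length; keeps leftmost and rightmost halves when long
cnn_fit_length <- function(idx, n) {
  if (length(idx) == n) return(idx)
  if (length(idx) > n) {
    half <- n %/% 2L
    return(c(idx[seq_len(half)], idx[(length(idx) - (n - half) + 1L):length(idx)]))
  }
  pad <- n - length(idx)
  left <- pad %/% 2L
  c(rep(1L, left), idx, rep(1L, pad - left))  # 1 = <PAD>
}

cnn_geometry <- function(cfg) {
  if (cfg$kernel_geometry == "table")
    list(h = cfg$window, dim_slices = list(seq_len(cfg$word_dim)))
  else {
    kh <- max(1L, cfg$word_dim %/% 2L)
    list(h = max(1L, cfg$seq_len %/% 2L),
         dim_slices = list(seq_len(kh),
                           (cfg$word_dim - kh + 1L):cfg$word_dim))
  }
}

cnn_example_logits <- function(pn, idx, pvec, cfg, geom) {
  seqemb <- ad_gather(pn$E, idx)
  npos <- cfg$seq_len - geom$h + 1L
  win_idx <- as.vector(vapply(seq_len(npos), function(i)
    i:(i + geom$h - 1L), integer(geom$h)))
  pooled <- list()
  for (sl in seq_along(geom$dim_slices)) {
    sel <- ad_slice_cols(seqemb, geom$dim_slices[[sl]])
    windows <- ad_group_rows(ad_gather(sel, win_idx), geom$h)
    z <- ad_addbias(ad_matmul(windows, pn$Wconv), pn$bconv)
    act <- if (cfg$activation == "relu") ad_relu(z) else ad_tanh(z)
    pooled[[sl]] <- ad_maxcol(act)
  }
  pool <- if (length(pooled) > 1L) {
    stacked <- do.call(ad_vcat, pooled)
    ad_maxcol(stacked)
  } else pooled[[1]]
  feat <- ad_hcat(pool, ad_const(matrix(pvec, 1)))
  fc <- ad_tanh(ad_addbias(ad_matmul(feat, pn$Wfc), pn$bfc))
  ad_addbias(ad_matmul(fc, pn$Wout), pn$bout)
}

#' Train the relation classifier
#'
#' Maximizes the log-probability of the training labels (cross-entropy)
#' with Adam. Word vectors are initialized from pre-trained token
#' embeddings and fine-tuned during training (max pooling precludes the
#' co-training used by the entity model). Each example carries a paragraph
#' id whose context vector is concatenated to the pooled features.
#'
#' @param examples list of lists with `tokens` (word/pattern sequence with
#'   `<ENT>` placeholders at the entity slots), `label` (relation type) and
#'   `paragraph_id`.
#' @param pvectors a `paragraph_vectors` object (also supplies pre-trained
#'   word vectors).
#' @param config a [relation_cnn_config()].
#' @param rng_seed integer seed.
#' @return object of class `relation_cnn`.
#' @export
train_relation_cnn <- function(examples, pvectors,
                               config = relation_cnn_config(), rng_seed = 1) {
  labels <- sort(unique(vapply(examples, `[[`, "", "label")))
  if (length(labels) < 2) stop("need at least two relation classes to train")
  vocab <- cnn_vocab(examples)
  cfg <- config
  geom <- cnn_geometry(cfg)
  k <- cfg$word_dim
  emb0 <- pvectors$embeddings
  with_seed(rng_seed, {
    E <- matrix(stats::rnorm(length(vocab) * k, 0, 0.05), length(vocab), k)
    hit <- match(vocab, emb0$vocab)
    ok <- !is.na(hit)
    if (ncol(emb0$vectors) >= k) {
      E[ok, ] <- emb0$vectors[hit[ok], seq_len(k), drop = FALSE]
    } else {
      E[ok, seq_len(ncol(emb0$vectors))] <- emb0$vectors[hit[ok], , drop = FALSE]
    }
    E[1, ] <- 0  # padding token: zero vector, frozen by convention
    nk <- cfg$kernels
    kh <- length(geom$dim_slices[[1]])
    params <- list(
      E = E,
      Wconv = matrix(stats::rnorm(geom$h * kh * nk, 0, 0.1), geom$h * kh, nk),
      bconv = matrix(0, 1, nk),
      Wfc = matrix(stats::rnorm((nk + k) * cfg$fc, 0, 0.1), nk + k, cfg$fc),
      bfc = matrix(0, 1, cfg$fc),
      Wout = matrix(stats::rnorm(cfg$fc * length(labels), 0, 0.1),
                    cfg$fc, length(labels)),
      bout = matrix(0, 1, length(labels)))
    st <- adam_state(params)
    exs <- lapply(examples, function(e) {
      idx <- match(e$tokens, vocab); idx[is.na(idx)] <- 2L
      list(idx = cnn_fit_length(idx, cfg$seq_len),
           y = match(e$label, labels),
           pid = e$paragraph_id %||% NA_character_)
    })
    pv_of <- function(pid) {
      if (!is.na(pid) && pid %in% rownames(pvectors$vectors))
        pvectors$vectors[pid, ] else numeric(k)
    }
    losses <- numeric(0)
    n_aug <- ceiling(cfg$unk_augment * length(exs))
    for (ep in seq_len(cfg$epochs)) {
      # blank-input augmentation: <ENT> unk ... <ENT> sequences trained
      # against the uniform distribution, so no-evidence inputs stay at the
      # prior and fall under the NONE threshold
      aug <- lapply(seq_len(n_aug), function(i) list(
        idx = cnn_fit_length(c(3L, rep(2L, sample.int(6L, 1)), 3L),
                             cfg$seq_len),
        y = NA_integer_,
        pid = NA_character_))
      exs_ep <- c(exs, aug)
      ord <- sample(seq_along(exs_ep))
      ep_loss <- 0
      for (bs in seq(1, length(ord), by = cfg$batch_size)) {
        bix <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
        pn <- ad_params_wrap(params)
        ls <- lapply(exs_ep[bix], function(ex) {
          logits <- cnn_example_logits(pn, ex$idx,
                                       pv_of(ex$pid)[seq_len(k)], cfg, geom)
          if (is.na(ex$y)) ad_softmax_uniform_nll(logits)
          else ad_softmax_nll(logits, ex$y)
        })
        total <- ad_scale(Reduce(ad_add, ls), 1 / length(bix))
        ad_backward(total)
        ep_loss <- ep_loss + total$value[1, 1] * length(bix)
        g <- ad_grads(pn)
        g$E[1, ] <- 0  # keep padding vector frozen
        upd <- adam_step(params, g, st, lr = cfg$lr)
        params <- upd$params; st <- upd$state
        params$E[1, ] <- 0
      }
      losses <- c(losses, ep_loss / length(ord))
    }
    structure(list(params = params, labels = labels, vocab = vocab,
                   config = cfg, geometry = geom, epoch_losses = losses,
                   pvectors = pvectors),
              class = "relation_cnn")
  })
}

#' @export
print.relation_cnn <- function(x, ...) {
  cat("<relation_cnn>", length(x$labels), "classes,", x$config$kernels,
      "kernels, window", x$geometry$h, "; final loss",
      format(utils::tail(x$epoch_losses, 1), digits = 4), "\n")
  invisible(x)
}

cnn_forward_probs <- function(model, tokens, pvec) {
  cfg <- model$config
  geom <- model$geometry
  p <- model$params
  idx <- match(tokens, model$vocab); idx[is.na(idx)] <- 2L
  idx <- cnn_fit_length(idx, cfg$seq_len)
  seqemb <- p$E[idx, , drop = FALSE]
  npos <- cfg$seq_len - geom$h + 1L
  win_idx <- as.vector(vapply(seq_len(npos), function(i)
    i:(i + geom$h - 1L), integer(geom$h)))
  pooled <- lapply(geom$dim_slices, function(sl) {
    sel <- seqemb[, sl, drop = FALSE]
    flat <- sel[win_idx, , drop = FALSE]
    windows <- matrix(0, npos, geom$h * length(sl))
    for (j in seq_len(npos))
      windows[j, ] <- as.vector(t(flat[(j - 1L) * geom$h + seq_len(geom$h), ,
                                       drop = FALSE]))
    z <- sweep(windows %*% p$Wconv, 2, p$bconv[1, ], "+")
    act <- if (cfg$activation == "relu") pmax(z, 0) else tanh(z)
    apply(act, 2, max)
  })
  pool <- if (length(pooled) > 1L) do.call(pmax, pooled) else pooled[[1]]
  feat <- c(pool, pvec[seq_len(cfg$word_dim)])
  fc <- tanh(drop(feat %*% p$Wfc) + p$bfc[1, ])
  logits <- drop(fc %*% p$Wout) + p$bout[1, ]
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Classify the relation of one input pattern
#'
#' Returns the full probability vector and the argmax label (deterministic
#' lowest-index tie-break). When `allow_none` is set, a maximum probability
#' below the configured threshold yields the rejection label `"NONE"`.
#'
#' @param tokens word sequence with `<ENT>` placeholders.
#' @param model a `relation_cnn`.
#' @param paragraph_vector numeric context vector (zero vector if absent).
#' @param allow_none apply the NONE threshold.
#' @return list with `label` and `probabilities`.
#' @export
classify_relation <- function(tokens, model, paragraph_vector = NULL,
                              allow_none = FALSE) {
  pvec <- paragraph_vector %||% numeric(model$config$word_dim)
  p <- cnn_forward_probs(model, tokens, pvec)
  names(p) <- model$labels
  lab <- model$labels[which.max(p)]
  if (allow_none && max(p) < model$config$none_threshold) lab <- "NONE"
  list(label = lab, probabilities = p)
}

#' Classify an entity pair from its context string
#'
#' Mirrors training-pattern construction at inference: enumerates the
#' substrings of the context word sequence (with the entity slots attached)
#' and aggregates predictions by the maximum class probability across
#' substrings; NONE when no substring clears the threshold.
#'
#' @param context_words word sequence between (and around) the entity pair,
#'   without placeholders.
#' @param model a `relation_cnn`.
#' @param paragraph_vector optional context vector.
#' @return list with `label`, `probabilities` (of the winning substring) and
#'   `n_substrings`.
#' @export
classify_relation_pair <- function(context_words, model,
                                   paragraph_vector = NULL) {
  k <- length(context_words)
  subs <- if (!k) list(character(0)) else
    unlist(lapply(seq_len(k), function(i)
      lapply(i:k, function(j) context_words[i:j])), recursive = FALSE)
  best <- NULL; best_p <- -1
  for (s in subs) {
    r <- classify_relation(c(ENT_SLOT, s, ENT_SLOT), model,
                           paragraph_vector, allow_none = FALSE)
    if (max(r$probabilities) > best_p) { best <- r; best_p <- max(r$probabilities) }
  }
  lab <- if (best_p < model$config$none_threshold) "NONE" else best$label
  list(label = lab, probabilities = best$probabilities,
       n_substrings = length(subs))
}

#' Build relation training examples from annotated records
#'
#' For every sentence expressing an annotated tuple, emits the sentence with
#' the subject and object mentions replaced by the `<ENT>` placeholder,
#' labeled with the tuple's relation type, carrying the record id as
#' paragraph id.
#'
#' @param records annotated records: lists with `tokens`, `spans` (or
#'   `gold_spans`) and `tuples` (or `gold_tuples`); alias surface forms are
#'   matched through the span table's `surface` column.
#' @return list of examples for [train_relation_cnn()].
#' @export
relation_examples_from_records <- function(records) {
  out <- list()
  for (r in records) {
    spans <- r$spans %||% r$gold_spans
    tups <- r$tuples %||% r$gold_tuples
    if (is.null(spans) || is.null(tups) || !nrow(spans) || !nrow(tups)) next
    surf_col <- if ("surface" %in% names(spans)) "surface" else "canonical"
    key_col <- if ("canonical" %in% names(spans)) "canonical" else surf_col
    for (sent in sentence_spans(r$tokens)) {
      lo <- sent[1] - 1L; hi <- sent[length(sent)]
      here <- spans[spans$start >= lo & spans$end <= hi, , drop = FALSE]
      if (nrow(here) < 2) next
      for (ti in seq_len(nrow(tups))) {
        si <- which(here[[key_col]] == tups$subject[ti])
        oi <- which(here[[key_col]] == tups$object[ti])
        if (!length(si) || !length(oi)) next
        si <- si[1]; oi <- oi[1]
        if (here$start[si] >= here$start[oi]) next
        toks <- r$tokens[sent]
        s0 <- here$start[si] - lo; s1 <- here$end[si] - lo
        o0 <- here$start[oi] - lo; o1 <- here$end[oi] - lo
        seqq <- c(if (s0 > 0) toks[1:s0], ENT_SLOT,
                  if (o0 > s1) toks[(s1 + 1L):o0], ENT_SLOT,
                  if (o1 < length(toks)) toks[(o1 + 1L):length(toks)])
        out[[length(out) + 1L]] <- list(
          tokens = seqq, label = tups$relation[ti],
          paragraph_id = r$record_id %||% NA_character_)
      }
    }
  }
  out
}

#' Macro-averaged F1 over relation labels
#' @param pred,gold character vectors of equal length.
#' @return macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  f1s <- vapply(sort(unique(gold)), function(cl) {
    tp <- sum(pred == cl & gold == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(pred != cl & gold == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1s)
}
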