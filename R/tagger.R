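# Character-level entity recognition: co-trained embeddings, bidirectional
# LSTM encoder with a gated context-bridge term in the cell update, and a
# linear-chain CRF output layer.

#' Tagger configuration
#'
#' Defaults follow the published hyperparameters (embedding dimension 512,
#' one LSTM layer with 200 hidden units per direction, CRF input dimension
#' 200, batch size 16; a 50-sentence batch preset is also recognised).
#' Training on the bundled synthetic corpora uses much smaller dimensions,
#' passed explicitly.
#'
#' @param embedding_dim token embedding dimension.
#' @param hidden LSTM hidden units per direction.
#' @param crf_input_dim width of the projection between the Bi-LSTM and the
#'   emission layer.
#' @param batch_size sentences per gradient step (presets: 16 or 50).
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience on validation loss.
#' @param val_fraction fraction of sentences held out for early stopping.
#' @param use_bridge whether the context-bridge cell modification is active.
#' @param clip gradient-norm clip (on by default for stability on tiny
#'   corpora).
#' @export
tagger_config <- function(embedding_dim = 512L, hidden = 200L,
                          crf_input_dim = 200L, batch_size = 16L,
                          epochs = 10L, lr = 5e-2, patience = 3L,
                          val_fraction = 0.2, use_bridge = TRUE, clip = 5) {
  stopifnot(batch_size >= 1, embedding_dim >= 2, hidden >= 2)
  list(embedding_dim = as.integer(embedding_dim), hidden = as.integer(hidden),
       crf_input_dim = as.integer(crf_input_dim),
       batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       lr = lr, patience = as.integer(patience), val_fraction = val_fraction,
       use_bridge = use_bridge, clip = clip)
}

BRIDGE_LEN <- 8L

#' Fixed-length bridge pattern slots
#'
#' A mined surface pattern is carried into the recurrent cell as the
#' concatenation of exactly eight token embeddings: longer patterns keep
#' their leftmost and rightmost four tokens, shorter ones are padded with the
#' reserved padding token.
#'
#' @param pattern a `candidate_pattern` of kind entity.
#' @return character vector of length 8.
#' @export
bridge_pattern_slots <- function(pattern) {
  toks <- c(pattern$left, pattern$right)
  n <- length(toks)
  if (n >= BRIDGE_LEN) {
    half <- BRIDGE_LEN %/% 2L
    c(toks[seq_len(half)], toks[(n - half + 1L):n])
  } else c(toks, rep("<PAD>", BRIDGE_LEN - n))
}

#' Find the bridge pattern for a token position
#'
#' Looks up validated patterns whose left context ends immediately before
#' the position and whose right context starts immediately after it. Among
#' multiple matches the longest total context wins; ties break by higher
#' pattern score, then lexicographically. Returns NULL when nothing matches
#' (the bridge is inert at that position).
#'
#' @param position 1-based token index within the sentence.
#' @param sentence character vector of tokens.
#' @param pattern_library list of scored `candidate_pattern`s; only validated
#'   entity patterns participate.
#' @return the matching pattern (with `slots` attached) or NULL.
#' @export
lookup_bridge_patterns <- function(position, sentence, pattern_library) {
  best <- NULL; best_len <- -1L; best_score <- -Inf; best_key <- ""
  for (p in pattern_library) {
    if (p$kind != "entity" || !isTRUE(p$validated)) next
    nl <- length(p$left); nr <- length(p$right)
    if (nl > 0L) {
      if (position - nl < 1L) next
      if (!all(sentence[(position - nl):(position - 1L)] == p$left)) next
    }
    if (nr > 0L) {
      if (position + nr > length(sentence)) next
      if (!all(sentence[(position + 1L):(position + nr)] == p$right)) next
    }
    tot <- nl + nr
    key <- pattern_key(p)
    better <- tot > best_len ||
      (tot == best_len && (p$score > best_score ||
                           (p$score == best_score && key < best_key)))
    if (better) {
      best <- p; best_len <- tot; best_score <- p$score; best_key <- key
    }
  }
  if (is.null(best)) return(NULL)
  best$slots <- bridge_pattern_slots(best)
  best
}

#' Context-bridge cell update
#'
#' The recurrent cell state is modified additively by a gated pattern
#' vector: `p_t = sigmoid(W_pi [H_prev, x_t] + W_pc c_prev + b_p)` and
#' `c_t = c_orig + p_t * pt`, with an elementwise gate. With a zero pattern
#' vector the update reduces to the unmodified cell.
#'
#' @param c_orig unmodified cell state (numeric vector).
#' @param pt pattern vector, already projected to the cell dimension.
#' @param H_prev,x_t previous hidden state and current input.
#' @param c_prev previous cell state.
#' @param W_pi gate weights over `[H_prev, x_t]` (H x (H + d)).
#' @param W_pc gate weights over the previous cell state (H x H).
#' @param b_p gate bias (length H).
#' @return list with `c_t` and the gate activation `p_t`.
#' @export
bridge_cell_update <- function(c_orig, pt, H_prev, x_t, c_prev,
                               W_pi, W_pc, b_p) {
  if (length(pt) != length(c_orig))
    stop("configuration error: pattern vector dimension ", length(pt),
         " does not match cell dimension ", length(c_orig))
  z <- as.vector(W_pi %*% c(H_prev, x_t)) + as.vector(W_pc %*% c_prev) + b_p
  p_t <- 1 / (1 + exp(-z))
  list(c_t = c_orig + p_t * pt, p_t = p_t)
}

# ---- CRF negative log-likelihood as a custom autograd node -----------------

crf_forward_backward <- function(P, A) {
  L <- ncol(P); T_ <- nrow(P)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  alpha <- matrix(0, T_, L); beta <- matrix(0, T_, L)
  alpha[1, ] <- A[L + 1L, ] + P[1, ]
  if (T_ > 1L) for (t in 2:T_) for (j in seq_len(L))
    alpha[t, j] <- lse(alpha[t - 1L, ] + A[seq_len(L), j]) + P[t, j]
  if (T_ > 1L) for (t in (T_ - 1L):1L) for (f in seq_len(L))
    beta[t, f] <- lse(A[f, ] + P[t + 1L, ] + beta[t + 1L, ])
  logZ <- lse(alpha[T_, ])
  gamma <- exp(alpha + beta - logZ)
  M <- matrix(0, L, L)
  if (T_ > 1L) for (t in seq_len(T_ - 1L))
    M <- M + exp(matrix(alpha[t, ], L, L) + A[seq_len(L), ] +
                 matrix(P[t + 1L, ] + beta[t + 1L, ], L, L, byrow = TRUE) -
                 logZ)
  list(logZ = logZ, gamma = gamma, M = M)
}

ad_crf_nll <- function(P_node, A_node, y) {
  P <- P_node$value; A <- A_node$value
  L <- ncol(P)
  fb <- crf_forward_backward(P, A)
  nll <- fb$logZ - crf_sequence_score(P, A, y)
  ad_node(matrix(nll, 1, 1), list(P_node, A_node), function(g) {
    gs <- g[1, 1]
    gP <- fb$gamma
    gP[cbind(seq_along(y), y)] <- gP[cbind(seq_along(y), y)] - 1
    gA <- matrix(0, L + 1L, L)
    gA[seq_len(L), ] <- fb$M
    if (length(y) > 1L) for (t in 2:length(y))
      gA[y[t - 1L], y[t]] <- gA[y[t - 1L], y[t]] - 1
    gA[L + 1L, ] <- fb$gamma[1, ]
    gA[L + 1L, y[1]] <- gA[L + 1L, y[1]] - 1
    ad_accum(P_node, gs * gP)
    ad_accum(A_node, gs * gA)
  })
}

# ---- model assembly --------------------------------------------------------

tagger_init_params <- function(V, d, H, C, L, seed) {
  with_seed(seed, {
    rn <- function(nr, nc, sc = 0.1) matrix(stats::rnorm(nr * nc, 0, sc), nr, nc)
    list(
      E = rn(V, d),
      Wf = rn(d + H, 4 * H), bf = matrix(0, 1, 4 * H),
      Wb = rn(d + H, 4 * H), bb = matrix(0, 1, 4 * H),
      Wpi_f = rn(d + H, H), Wpc_f = rn(H, H), bp_f = matrix(0, 1, H),
      Wpi_b = rn(d + H, H), Wpc_b = rn(H, H), bp_b = matrix(0, 1, H),
      Wbp = rn(BRIDGE_LEN * d, H),
      Wh = rn(2 * H, C), bh = matrix(0, 1, C),
      We = rn(C, L), be = matrix(0, 1, L),
      A = rn(L + 1, L, 0.01)
    )
  })
}

# one LSTM direction over a batch of equal-length sentences; tok_mat is
# B x T token indices, bridge_idx a list (per sentence) of per-position
# slot-index vectors or NULL. Returns a list of B x H hidden nodes per t.
lstm_run_batch <- function(p, tok_mat, bridge_idx, H, reverse = FALSE,
                           use_bridge = TRUE) {
  W <- p[[if (reverse) "Wb" else "Wf"]]
  b <- p[[if (reverse) "bb" else "bf"]]
  Wpi <- p[[if (reverse) "Wpi_b" else "Wpi_f"]]
  Wpc <- p[[if (reverse) "Wpc_b" else "Wpc_f"]]
  bp <- p[[if (reverse) "bp_b" else "bp_f"]]
  B <- nrow(tok_mat); T_ <- ncol(tok_mat)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  h <- ad_const(matrix(0, B, H))
  cc <- ad_const(matrix(0, B, H))
  hs <- vector("list", T_)
  for (t in ord) {
    x <- ad_gather(p$E, tok_mat[, t])
    inp <- ad_hcat(x, h)
    z <- ad_addbias(ad_matmul(inp, W), b)
    i_g <- ad_sigmoid(ad_slice_cols(z, seq_len(H)))
    f_g <- ad_sigmoid(ad_slice_cols(z, H + seq_len(H)))
    o_g <- ad_sigmoid(ad_slice_cols(z, 2 * H + seq_len(H)))
    g_g <- ad_tanh(ad_slice_cols(z, 3 * H + seq_len(H)))
    c_orig <- ad_add(ad_mul(f_g, cc), ad_mul(i_g, g_g))
    has_bridge <- use_bridge && any(vapply(bridge_idx, function(bi)
      !is.null(bi[[t]]), logical(1)))
    if (has_bridge) {
      slot_idx <- unlist(lapply(bridge_idx, function(bi)
        bi[[t]] %||% rep(1L, BRIDGE_LEN)))      # padding rows where inert
      mask <- matrix(as.numeric(vapply(bridge_idx, function(bi)
        !is.null(bi[[t]]), logical(1))), B, H)
      ptv <- ad_matmul(ad_group_rows(ad_gather(p$E, slot_idx), BRIDGE_LEN),
                       p$Wbp)
      gate <- ad_sigmoid(ad_addbias(
        ad_add(ad_matmul(inp, Wpi), ad_matmul(cc, Wpc)), bp))
      c_new <- ad_add(c_orig, ad_mul(ad_const(mask), ad_mul(gate, ptv)))
    } else c_new <- c_orig
    h <- ad_mul(o_g, ad_tanh(c_new))
    cc <- c_new
    hs[[t]] <- h
  }
  hs
}

# mean CRF negative log-likelihood of a batch of equal-length sentences
tagger_batch_loss <- function(p, exs, cfg) {
  H <- cfg$hidden
  tok_mat <- do.call(rbind, lapply(exs, `[[`, "tok_idx"))
  bridge_idx <- lapply(exs, `[[`, "bridge_idx")
  hf <- lstm_run_batch(p, tok_mat, bridge_idx, H, FALSE, cfg$use_bridge)
  hb <- lstm_run_batch(p, tok_mat, bridge_idx, H, TRUE, cfg$use_bridge)
  emis <- lapply(seq_len(ncol(tok_mat)), function(t)
    ad_addbias(ad_matmul(
      ad_tanh(ad_addbias(ad_matmul(ad_hcat(hf[[t]], hb[[t]]), p$Wh), p$bh)),
      p$We), p$be))                       # each B x L
  losses <- lapply(seq_along(exs), function(b) {
    P_node <- do.call(ad_vcat, lapply(emis, function(e) ad_slice(e, b)))
    ad_crf_nll(P_node, p$A, exs[[b]]$y)
  })
  ad_scale(Reduce(ad_add, losses), 1 / length(exs))
}

# plain-numeric forward pass (inference path; no tape overhead)
lstm_run_numeric <- function(p, tok_idx, bridge_idx, H, reverse,
                             use_bridge) {
  W <- p[[if (reverse) "Wb" else "Wf"]]
  b <- p[[if (reverse) "bb" else "bf"]][1, ]
  Wpi <- p[[if (reverse) "Wpi_b" else "Wpi_f"]]
  Wpc <- p[[if (reverse) "Wpc_b" else "Wpc_f"]]
  bp <- p[[if (reverse) "bp_b" else "bp_f"]][1, ]
  T_ <- length(tok_idx)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  h <- numeric(H); cc <- numeric(H)
  hs <- matrix(0, T_, H)
  sig <- function(x) 1 / (1 + exp(-x))
  for (t in ord) {
    inp <- c(p$E[tok_idx[t], ], h)
    z <- drop(inp %*% W) + b
    i_g <- sig(z[seq_len(H)]); f_g <- sig(z[H + seq_len(H)])
    o_g <- sig(z[2 * H + seq_len(H)]); g_g <- tanh(z[3 * H + seq_len(H)])
    c_new <- f_g * cc + i_g * g_g
    if (use_bridge && !is.null(bridge_idx[[t]])) {
      ptv <- drop(matrix(as.vector(t(p$E[bridge_idx[[t]], , drop = FALSE])),
                         1) %*% p$Wbp)
      gate <- sig(drop(inp %*% Wpi) + drop(cc %*% Wpc) + bp)
      c_new <- c_new + gate * ptv
    }
    h <- o_g * tanh(c_new)
    cc <- c_new
    hs[t, ] <- h
  }
  hs
}

tagger_emissions <- function(params, cfg, tok_idx, bridge_idx) {
  H <- cfg$hidden
  hf <- lstm_run_numeric(params, tok_idx, bridge_idx, H, FALSE,
                         cfg$use_bridge)
  hb <- lstm_run_numeric(params, tok_idx, bridge_idx, H, TRUE,
                         cfg$use_bridge)
  hid <- tanh(sweep(cbind(hf, hb) %*% params$Wh, 2, params$bh[1, ], "+"))
  sweep(hid %*% params$We, 2, params$be[1, ], "+")
}

tagger_vocab <- function(records) {
  toks <- unique(unlist(lapply(records, function(r)
    if (is.list(r)) r$tokens else r)))
  c("<PAD>", "<UNK>", sort(toks))
}

tok_to_idx <- function(vocab, tokens) {
  i <- match(tokens, vocab)
  i[is.na(i)] <- 2L  # <UNK>
  i
}

# index validated entity patterns by (token left of slot, token right of
# slot) so per-position lookup only inspects plausible candidates
bridge_library_index <- function(pattern_library) {
  buckets <- new.env(parent = emptyenv())
  add <- function(key, p) buckets[[key]] <- c(buckets[[key]], list(p))
  for (p in pattern_library) {
    if (p$kind != "entity" || !isTRUE(p$validated)) next
    l <- if (length(p$left)) p$left[length(p$left)] else "*"
    r <- if (length(p$right)) p$right[1] else "*"
    add(paste(l, r, sep = "\r"), p)
  }
  buckets
}

# precompute per-sentence bridge slot indices from the pattern library
sentence_bridge_idx <- function(vocab, tokens, pattern_library,
                                index = NULL) {
  if (is.null(pattern_library)) return(vector("list", length(tokens)))
  if (is.null(index)) index <- bridge_library_index(pattern_library)
  lapply(seq_along(tokens), function(t) {
    l <- if (t > 1L) tokens[t - 1L] else "\r"
    r <- if (t < length(tokens)) tokens[t + 1L] else "\r"
    cand <- c(index[[paste(l, r, sep = "\r")]],
              index[[paste(l, "*", sep = "\r")]],
              index[[paste("*", r, sep = "\r")]])
    if (is.null(cand)) return(NULL)
    p <- lookup_bridge_patterns(t, tokens, cand)
    if (is.null(p)) NULL else tok_to_idx(vocab, p$slots)
  })
}

# split annotated records into per-sentence training examples
tagger_examples <- function(records, vocab, pattern_library,
                            bridge_index = NULL) {
  if (!is.null(pattern_library) && is.null(bridge_index))
    bridge_index <- bridge_library_index(pattern_library)
  out <- list()
  for (r in records) {
    toks <- r$tokens
    spans <- r$spans %||% r$gold_spans
    for (sp in sentence_spans(toks)) {
      stoks <- toks[sp]
      off <- sp[1] - 1L  # tokens before this sentence
      ssp <- if (!is.null(spans) && nrow(spans)) {
        inside <- spans$start >= off & spans$end <= off + length(stoks)
        data.frame(start = spans$start[inside] - off,
                   end = spans$end[inside] - off,
                   type = spans$type[inside], stringsAsFactors = FALSE)
      } else data.frame(start = integer(0), end = integer(0),
                        type = character(0))
      out[[length(out) + 1L]] <- list(
        tokens = stoks,
        tok_idx = tok_to_idx(vocab, stoks),
        bridge_idx = sentence_bridge_idx(vocab, stoks, pattern_library,
                                         bridge_index),
        y = NA, labels = spans_to_labels(length(stoks), ssp))
    }
  }
  out
}

#' Train the entity tagger
#'
#' Maximizes the CRF log-likelihood (forward algorithm for the partition
#' function) by Adam over mini-batches, co-training the token embeddings
#' with the encoder. A validation split drives early stopping. With a
#' pattern library supplied, the context bridge injects gated pattern
#' vectors into the cell state wherever a validated pattern matches.
#'
#' @param records annotated records (each with `tokens` and `spans` or
#'   `gold_spans` in 0-based half-open offsets).
#' @param config a [tagger_config()].
#' @param rng_seed integer seed; the run is reproducible given the seed.
#' @param pattern_library optional scored pattern library from the
#'   bootstrapping stage.
#' @return object of class `tagger_model`.
#' @export
train_tagger <- function(records, config = tagger_config(), rng_seed = 1,
                         pattern_library = NULL) {
  scheme <- tag_scheme()
  vocab <- tagger_vocab(records)
  bridge_index <- if (!is.null(pattern_library))
    bridge_library_index(pattern_library)
  exs <- tagger_examples(records, vocab, pattern_library, bridge_index)
  n_spans <- sum(vapply(exs, function(e) sum(e$labels != "O"), numeric(1)))
  if (n_spans == 0) {
    warning("corpus contains zero entity spans; refusing to train")
    return(NULL)
  }
  for (i in seq_along(exs)) exs[[i]]$y <- unname(scheme$index[exs[[i]]$labels])
  cfg <- config
  params <- tagger_init_params(length(vocab), cfg$embedding_dim, cfg$hidden,
                               cfg$crf_input_dim, length(scheme$labels),
                               rng_seed)
  st <- adam_state(params)
  with_seed(rng_seed + 1L, {
    n <- length(exs)
    n_val <- max(1L, floor(cfg$val_fraction * n))
    val_ix <- sample.int(n, n_val)
    train_ix <- setdiff(seq_len(n), val_ix)
    lens <- vapply(exs, function(e) length(e$tok_idx), integer(1))
    # mini-batches of equal-length sentences (one matrix op per timestep)
    length_batches <- function(ix) {
      out <- list()
      perm <- sample(ix)
      for (bucket in split(perm, lens[perm])) {
        for (bs in seq(1, length(bucket), by = cfg$batch_size))
          out[[length(out) + 1L]] <-
            bucket[bs:min(bs + cfg$batch_size - 1L, length(bucket))]
      }
      out[sample.int(length(out))]
    }
    val_batches <- length_batches(val_ix)
    best <- list(params = params, val = Inf, bad = 0L)
    epoch_losses <- numeric(0)
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0
      for (bix in length_batches(train_ix)) {
        pn <- ad_params_wrap(params)
        total <- tagger_batch_loss(pn, exs[bix], cfg)
        ad_backward(total)
        ep_loss <- ep_loss + total$value[1, 1] * length(bix)
        upd <- adam_step(params, ad_grads(pn), st, lr = cfg$lr,
                         clip = cfg$clip)
        params <- upd$params; st <- upd$state
      }
      epoch_losses <- c(epoch_losses, ep_loss / length(train_ix))
      # validation NLL for early stopping
      pn <- ad_params_wrap(params)
      val_nll <- sum(vapply(val_batches, function(bix)
        tagger_batch_loss(pn, exs[bix], cfg)$value[1, 1] * length(bix),
        numeric(1))) / n_val
      if (val_nll < best$val - 1e-6) {
        best <- list(params = params, val = val_nll, bad = 0L)
      } else {
        best$bad <- best$bad + 1L
        if (best$bad >= cfg$patience) break
      }
    }
    structure(list(params = best$params, config = cfg, vocab = vocab,
                   scheme = scheme, pattern_library = pattern_library,
                   bridge_index = bridge_index,
                   epoch_losses = epoch_losses, val_nll = best$val),
              class = "tagger_model")
  })
}

#' @export
print.tagger_model <- function(x, ...) {
  cat("<tagger_model>", length(x$vocab), "vocab,",
      x$config$hidden, "hidden units,",
      length(x$epoch_losses), "epochs, val NLL",
      format(x$val_nll, digits = 4), "\n")
  invisible(x)
}

#' Extract entities from text with a trained tagger
#'
#' Decodes BIOES labels per sentence under the legality mask and converts
#' them to 0-based half-open spans over the full token sequence.
#'
#' @param tokens character vector of tokens (may span several sentences).
#' @param model a `tagger_model`.
#' @return data.frame with `start`, `end`, `type`, `surface`.
#' @export
extract_entities <- function(tokens, model) {
  scheme <- model$scheme
  mask <- list(legal = scheme$legal, start_legal = scheme$start_legal,
               end_legal = scheme$end_legal)
  out <- list()
  for (sp in sentence_spans(tokens)) {
    stoks <- tokens[sp]
    idx <- tok_to_idx(model$vocab, stoks)
    bidx <- sentence_bridge_idx(model$vocab, stoks, model$pattern_library,
                                model$bridge_index)
    P <- tagger_emissions(model$params, model$config, idx, bidx)
    path <- viterbi_decode(P, model$params$A, mask)
    spans <- labels_to_spans(scheme$labels[path])
    if (nrow(spans)) {
      spans$start <- spans$start + sp[1] - 1L
      spans$end <- spans$end + sp[1] - 1L
      spans$surface <- vapply(seq_len(nrow(spans)), function(i)
        paste(tokens[(spans$start[i] + 1L):spans$end[i]], collapse = " "),
        character(1))
      out[[length(out) + 1L]] <- spans
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      type = character(0), surface = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Span-level precision/recall/F1
#'
#' A predicted span counts as correct only on exact (start, end, type)
#' agreement.
#' @param pred,gold data.frames with `start`, `end`, `type`.
#' @return named numeric: precision, recall, f1.
#' @export
span_f1 <- function(pred, gold) {
  pk <- paste(pred$start, pred$end, pred$type)
  gk <- paste(gold$start, gold$end, gold$type)
  tp <- length(intersect(pk, gk))
  prec <- if (length(pk)) tp / length(unique(pk)) else 0
  rec <- if (length(gk)) tp / length(unique(gk)) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}
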