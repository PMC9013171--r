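# tag scheme, CRF scoring/decoding, context bridge, tagger training

test_that("the BIOES scheme has 21 labels and a sound legality table", {
  sc <- tag_scheme()
  expect_length(sc$labels, 21)
  expect_equal(anyDuplicated(sc$labels), 0)
  i <- sc$index
  expect_true(sc$legal[i[["B-DIS"]], i[["I-DIS"]]])
  expect_true(sc$legal[i[["B-DIS"]], i[["E-DIS"]]])
  expect_false(sc$legal[i[["B-DIS"]], i[["B-DIS"]]])
  expect_false(sc$legal[i[["B-DIS"]], i[["I-SYM"]]])
  expect_false(sc$legal[i[["O"]], i[["E-DIS"]]])
  expect_true(sc$legal[i[["O"]], i[["S-TRE"]]])
  expect_false(sc$start_legal[i[["I-DIS"]]])
  expect_false(sc$end_legal[i[["B-DIS"]]])
})

test_that("span encoding and decoding are exact inverses", {
  spans <- data.frame(start = c(0L, 2L, 6L), end = c(1L, 5L, 9L),
                      type = c("Disease", "Symptom", "Result"),
                      stringsAsFactors = FALSE)
  lab <- spans_to_labels(10, spans)
  expect_identical(lab[1], "S-DIS")
  expect_identical(lab[3:5], c("B-SYM", "I-SYM", "E-SYM"))
  expect_identical(lab[7:9], c("B-RES", "I-RES", "E-RES"))
  expect_identical(lab[c(2, 6, 10)], c("O", "O", "O"))
  back <- labels_to_spans(lab)
  expect_equal(back[order(back$start), ], spans, ignore_attr = TRUE)
  # random round-trip property
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    sp <- list(); at <- 0L
    while (at < n - 1) {
      len <- sample(1:3, 1)
      if (at + len > n) break
      sp[[length(sp) + 1L]] <- data.frame(
        start = at, end = at + len,
        type = sample(entity_types(), 1), stringsAsFactors = FALSE)
      at <- at + len + sample(0:2, 1)
    }
    sp <- do.call(rbind, sp)
    expect_equal(labels_to_spans(spans_to_labels(n, sp)), sp,
                 ignore_attr = TRUE)
  }
})

test_that("the CRF path score is the exact transition+emission sum", {
  expect_equal(crf_sequence_score(matrix(0, 4, 3), matrix(0, 4, 3),
                                  c(1, 2, 3, 1)), 0)
  P <- matrix(c(1, 2, 3,
                4, 5, 6,
                7, 8, 9), 3, 3, byrow = TRUE)
  A <- matrix(c(0.1, 0.2, 0.3,
                0.4, 0.5, 0.6,
                0.7, 0.8, 0.9,
                1.0, 1.1, 1.2), 4, 3, byrow = TRUE)  # last row: start
  y <- c(2L, 3L, 1L)
  # by hand: A[start,2]+P[1,2] + A[2,3]+P[2,3] + A[3,1]+P[3,1]
  expect_equal(crf_sequence_score(P, A, y),
               1.1 + 2 + 0.6 + 6 + 0.7 + 7)
  expect_error(crf_sequence_score(P, A, c(1L, 5L, 1L)), "illegal label")
})

test_that("viterbi equals exhaustive path enumeration, with and without mask", {
  set.seed(31)
  for (rep in 1:10) {
    T_ <- sample(2:6, 1); L <- sample(2:3, 1)
    P <- matrix(rnorm(T_ * L), T_, L)
    A <- matrix(rnorm((L + 1) * L), L + 1, L)
    expect_equal(viterbi_decode(P, A), unname(brute_best_path(P, A)))
  }
  # under the BIOES legality mask on a 5-label sub-scheme
  sc <- tag_scheme()
  keep <- sc$index[c("O", "B-DIS", "I-DIS", "E-DIS", "S-DIS")]
  mask <- list(legal = sc$legal[keep, keep],
               start_legal = sc$start_legal[keep],
               end_legal = sc$end_legal[keep])
  for (rep in 1:10) {
    T_ <- sample(2:6, 1)
    P <- matrix(rnorm(T_ * 5), T_, 5)
    A <- matrix(rnorm(6 * 5), 6, 5)
    got <- viterbi_decode(P, A, mask)
    expect_equal(got, unname(brute_best_path(P, A, mask)))
    # decoded sequence never contains an illegal bigram
    if (T_ > 1) for (t in 2:T_)
      expect_true(mask$legal[got[t - 1], got[t]])
  }
  # one-hot emissions on a legal path return that path
  P1 <- matrix(-10, 4, 5); path <- c(2, 3, 3, 4)  # B-I-I-E
  P1[cbind(1:4, path)] <- 10
  expect_equal(viterbi_decode(P1, matrix(0, 6, 5), mask), path)
})

test_that("the forward partition function matches brute-force summation", {
  set.seed(13)
  for (rep in 1:8) {
    T_ <- sample(2:6, 1); L <- sample(2:4, 1)
    P <- matrix(rnorm(T_ * L), T_, L)
    A <- matrix(rnorm((L + 1) * L) * 0.5, L + 1, L)
    paths <- all_paths(T_, L)
    brute <- log(sum(exp(apply(paths, 1, function(y)
      crf_sequence_score(P, A, y)))))
    expect_equal(crf_log_partition(P, A), brute, tolerance = 1e-6)
    fb <- crf_forward_backward(P, A)
    expect_equal(fb$logZ, brute, tolerance = 1e-6)
    # node marginals sum to 1 at every position
    expect_equal(unname(rowSums(fb$gamma)), rep(1, T_), tolerance = 1e-9)
  }
})

test_that("bridge patterns occupy exactly eight slots", {
  p_short <- new_entity_pattern(c("a", "b"), c("c"), "Disease")
  s <- bridge_pattern_slots(p_short)
  expect_length(s, 8)
  expect_identical(s, c("a", "b", "c", rep("<PAD>", 5)))
  p_long <- new_entity_pattern(paste0("l", 1:3), paste0("r", 1:7), "Disease")
  s2 <- bridge_pattern_slots(p_long)
  expect_length(s2, 8)
  expect_identical(s2, c("l1", "l2", "l3", "r1", "r4", "r5", "r6", "r7"))
})

test_that("bridge lookup matches exactly and breaks ties as documented", {
  mk <- function(left, right, score) {
    p <- new_entity_pattern(left, right, "Disease")
    p$score <- score; p$validated <- TRUE
    p
  }
  lib <- list(mk(c("seen", "at"), "clinic", 0.8),
              mk("at", "clinic", 0.9),
              mk("at", character(0), 0.95))
  sent <- c("seen", "at", "X", "clinic", "today")
  hit <- lookup_bridge_patterns(3, sent, lib)
  # longest total context wins over higher score
  expect_identical(hit$left, c("seen", "at"))
  expect_length(hit$slots, 8)
  # no match -> NULL (bridge inert)
  expect_null(lookup_bridge_patterns(1, sent, lib))
  # equal length: higher score wins
  lib2 <- list(mk("at", "clinic", 0.5), mk(c("at"), c("clinic"), 0.5),
               mk(character(0), c("clinic", "today"), 0.9))
  hit2 <- lookup_bridge_patterns(3, sent, lib2)
  expect_identical(unname(hit2$right), c("clinic", "today"))
  # non-validated patterns never participate
  lib3 <- list(new_entity_pattern("at", "clinic", "Disease"))
  lib3[[1]]$score <- 1; lib3[[1]]$validated <- FALSE
  expect_null(lookup_bridge_patterns(3, sent, lib3))
})

test_that("the bridge cell update follows its gating formula exactly", {
  H <- 4; d <- 3
  c_orig <- rnorm(H); pt <- rnorm(H)
  H_prev <- rnorm(H); x_t <- rnorm(d); c_prev <- rnorm(H)
  # zero pattern vector: additive identity
  r0 <- bridge_cell_update(c_orig, rep(0, H), H_prev, x_t, c_prev,
                           matrix(rnorm(H * (H + d)), H), diag(H), rnorm(H))
  expect_equal(r0$c_t, c_orig)
  # zero gate parameters: sigmoid(0) = 0.5 elementwise
  r5 <- bridge_cell_update(c_orig, pt, H_prev, x_t, c_prev,
                           matrix(0, H, H + d), matrix(0, H, H),
                           rep(0, H))
  expect_equal(r5$p_t, rep(0.5, H))
  expect_equal(r5$c_t, c_orig + 0.5 * pt)
  # random tensors against an independent formula evaluation
  set.seed(77)
  W_pi <- matrix(rnorm(H * (H + d)), H); W_pc <- matrix(rnorm(H * H), H)
  b_p <- rnorm(H)
  r <- bridge_cell_update(c_orig, pt, H_prev, x_t, c_prev, W_pi, W_pc, b_p)
  p_ref <- plogis(as.vector(W_pi %*% c(H_prev, x_t)) +
                  as.vector(W_pc %*% c_prev) + b_p)
  expect_equal(r$p_t, p_ref, tolerance = 1e-6)
  expect_equal(r$c_t, c_orig + p_ref * pt, tolerance = 1e-6)
  expect_true(all(r$p_t > 0 & r$p_t < 1))
  expect_error(bridge_cell_update(c_orig, rnorm(H + 1), H_prev, x_t, c_prev,
                                  W_pi, W_pc, b_p), "dimension")
})

test_that("an inert bridge reproduces the unmodified encoder exactly", {
  kb <- tiny_kb()
  co <- tiny_corpus(kb, n_records = 6, seed = 2)
  recs <- lapply(co$records, function(r)
    list(tokens = r$tokens, spans = r$gold_spans))
  cfg_on <- tagger_config(embedding_dim = 8, hidden = 8, crf_input_dim = 8,
                          epochs = 1, use_bridge = TRUE)
  cfg_off <- tagger_config(embedding_dim = 8, hidden = 8, crf_input_dim = 8,
                           epochs = 1, use_bridge = FALSE)
  vocab <- tagger_vocab(recs)
  params <- tagger_init_params(length(vocab), 8, 8, 8, 21, seed = 3)
  toks <- recs[[1]]$tokens
  idx <- tok_to_idx(vocab, toks)
  no_bridge <- vector("list", length(idx))  # no pattern matches anywhere
  P_on <- tagger_emissions(params, cfg_on, idx, no_bridge)
  P_off <- tagger_emissions(params, cfg_off, idx, no_bridge)
  expect_identical(P_on, P_off)
})

test_that("training reduces the loss and decodes gold spans", {
  kb <- tiny_kb(n_ent = 6, n_rel = 4)
  co <- tiny_corpus(kb, n_records = 50, seed = 6)
  recs <- lapply(co$records, function(r)
    list(tokens = r$tokens, spans = r$gold_spans))
  cfg <- tagger_config(embedding_dim = 16, hidden = 16, crf_input_dim = 16,
                       epochs = 6, lr = 0.05)
  m <- train_tagger(recs[1:40], cfg, rng_seed = 42)
  # training loss decreases over epochs (within tolerance for the tail)
  expect_lt(tail(m$epoch_losses, 1), m$epoch_losses[1])
  # held-out decoding recovers spans
  pk <- character(0); gk <- character(0)
  for (i in 41:50) {
    pred <- extract_entities(co$records[[i]]$tokens, m)
    gold <- co$records[[i]]$gold_spans
    pk <- c(pk, paste(i, pred$start, pred$end, pred$type))
    gk <- c(gk, paste(i, gold$start, gold$end, gold$type))
  }
  f1 <- span_f1(data.frame(start = pk, end = "", type = ""),
                data.frame(start = gk, end = "", type = ""))
  expect_gte(unname(f1["f1"]), 0.9)
  # gold-path local optimality: the trained score of the gold path beats
  # single-label corruptions
  sc <- m$scheme
  ex <- tagger_examples(recs[1], m$vocab, NULL)[[1]]
  P <- tagger_emissions(m$params, m$config, ex$tok_idx, ex$bridge_idx)
  y <- unname(sc$index[ex$labels])
  gold_score <- crf_sequence_score(P, m$params$A, y)
  set.seed(1)
  for (rep in 1:10) {
    y2 <- y
    t_ <- sample(length(y2), 1)
    y2[t_] <- sample(setdiff(seq_len(21), y2[t_]), 1)
    expect_gte(gold_score, crf_sequence_score(P, m$params$A, y2))
  }
})

test_that("degenerate tagging inputs behave as specified", {
  kb <- tiny_kb()
  co <- tiny_corpus(kb, n_records = 10, seed = 2)
  recs <- lapply(co$records, function(r)
    list(tokens = r$tokens, spans = r$gold_spans))
  cfg <- tagger_config(embedding_dim = 8, hidden = 8, crf_input_dim = 8,
                       epochs = 1)
  # zero entity spans: warn and refuse
  empty <- lapply(recs[1:3], function(r)
    list(tokens = r$tokens,
         spans = data.frame(start = integer(0), end = integer(0),
                            type = character(0))))
  expect_warning(m0 <- train_tagger(empty, cfg, 1), "zero entity spans")
  expect_null(m0)
})
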