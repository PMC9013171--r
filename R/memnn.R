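# Memory-network question answering: tuple-encoded memory slots, a
# generalization (utility) module over memory features, region-affinity
# attention for memory selection, and a constrained response decoder.

#' QA model configuration
#'
#' @param gamma margin of the ranking loss.
#' @param negatives negative memories / answers per positive example.
#' @param top_k memories used for answering (default 1: the memory with the
#'   highest attention score).
#' @param encoder_dim hidden width of the tuple-encoder LSTM.
#' @param epochs,lr phase-1 training settings.
#' @param gen_epochs,gen_lr generalization-module training settings.
#' @export
qa_config <- function(gamma = 0.2, negatives = 5L, top_k = 1L,
                      encoder_dim = 24L, epochs = 8L, lr = 2e-2,
                      gen_epochs = 30L, gen_lr = 5e-2) {
  stopifnot(gamma > 0, top_k >= 1)
  list(gamma = gamma, negatives = as.integer(negatives),
       top_k = as.integer(top_k), encoder_dim = as.integer(encoder_dim),
       epochs = as.integer(epochs), lr = lr,
       gen_epochs = as.integer(gen_epochs), gen_lr = gen_lr)
}

#' Intent detection rules
#'
#' Marker tokens mapped to target entity types, in document order; the first
#' matching rule wins.
#' @return data.frame with `marker`, `type`.
#' @export
intent_rules <- function() {
  data.frame(
    marker = c("whatdisease", "howtotreat", "whatsymptom", "whattest",
               "whatresult"),
    type = c("Disease", "Treatment", "Symptom", "Test", "Result"),
    stringsAsFactors = FALSE)
}

#' Detect the question intent
#'
#' Scans the question for a marker token; the first rule (in table order)
#' whose marker occurs wins. Without a match the intent is flagged unknown
#' and answering falls back to the best memory's subject type.
#'
#' @param question_tokens character vector.
#' @param rules rule table as from [intent_rules()].
#' @return list with `intent` (entity type or NA), `marker` (the matched
#'   question word or NA).
#' @export
detect_intent <- function(question_tokens, rules = intent_rules()) {
  for (i in seq_len(nrow(rules))) {
    if (rules$marker[i] %in% question_tokens)
      return(list(intent = rules$type[i], marker = rules$marker[i]))
  }
  list(intent = NA_character_, marker = NA_character_)
}

# ---- tuples and memory store -----------------------------------------------

#' Merge relation rows into knowledge tuples
#'
#' Rows sharing subject and relation merge into one tuple whose object is
#' the set of objects (sorted); tuples are globally sorted by subject,
#' relation code and object set.
#'
#' @param relations data.frame `subject`, `relation`, `object`.
#' @return list of tuples: `subject`, `relation`, `objects` (sorted),
#'   `sort_key`.
#' @export
knowledge_tuples <- function(relations) {
  if (!nrow(relations)) return(list())
  key <- paste(relations$subject, relations$relation, sep = "\r")
  groups <- split(relations$object, key)
  tup <- lapply(names(groups), function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    objs <- sort(unique(groups[[k]]))
    list(subject = parts[1], relation = parts[2], objects = objs,
         sort_key = paste(parts[1],
                          match(parts[2], relation_types()),
                          paste(objs, collapse = "|")))
  })
  tup[order(vapply(tup, `[[`, "", "sort_key"))]
}

qa_init_params <- function(emb_dim, H, seed) {
  D <- emb_dim + 5L
  with_seed(seed, {
    rn <- function(nr, nc, sc = 0.15) matrix(stats::rnorm(nr * nc, 0, sc), nr, nc)
    list(W = rn(D + H, 4 * H), b = matrix(0, 1, 4 * H),
         placeholder = rn(1, D),
         W_R = rn(2 * H, emb_dim),
         W_att = matrix(c(1, 1, 1) / 3, 1, 3))
  })
}

# plain-numeric LSTM over element rows (inference path)
qa_encode_rows <- function(rows, params, H) {
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(nrow(rows))) {
    z <- c(rows[t, ], h) %*% params$W + params$b[1, ]
    i_g <- 1 / (1 + exp(-z[seq_len(H)]))
    f_g <- 1 / (1 + exp(-z[H + seq_len(H)]))
    o_g <- 1 / (1 + exp(-z[2 * H + seq_len(H)]))
    g_g <- tanh(z[3 * H + seq_len(H)])
    cc <- f_g * cc + i_g * g_g
    h <- o_g * tanh(cc)
  }
  h
}

# autograd LSTM over element rows (training path)
qa_encode_rows_ad <- function(rows_node, nrows, pn, H) {
  h <- ad_const(matrix(0, 1, H)); cc <- ad_const(matrix(0, 1, H))
  for (t in seq_len(nrows)) {
    x <- ad_slice(rows_node, t)
    z <- ad_addbias(ad_matmul(ad_hcat(x, h), pn$W), pn$b)
    i_g <- ad_sigmoid(ad_slice_cols(z, seq_len(H)))
    f_g <- ad_sigmoid(ad_slice_cols(z, H + seq_len(H)))
    o_g <- ad_sigmoid(ad_slice_cols(z, 2 * H + seq_len(H)))
    g_g <- ad_tanh(ad_slice_cols(z, 3 * H + seq_len(H)))
    cc <- ad_add(ad_mul(f_g, cc), ad_mul(i_g, g_g))
    h <- ad_mul(o_g, ad_tanh(cc))
  }
  h
}

# element rows of a tuple: subject, relation one-hot, then sorted objects
tuple_element_rows <- function(tuple, embeddings) {
  d <- embeddings$dim
  ev <- embed_entities(c(tuple$subject, tuple$objects), embeddings)
  rel <- relation_onehot(tuple$relation)
  rbind(c(ev[1, ], numeric(5)),
        c(numeric(d), rel),
        cbind(ev[-1, , drop = FALSE], matrix(0, length(tuple$objects), 5)))
}

# element rows of a question: entities, relation one-hot (if detected),
# question-word placeholder
question_element_rows <- function(entities, relation, params, embeddings) {
  d <- embeddings$dim
  rows <- NULL
  if (length(entities))
    rows <- cbind(embed_entities(entities, embeddings),
                  matrix(0, length(entities), 5))
  if (!is.na(relation) && relation %in% relation_types())
    rows <- rbind(rows, c(numeric(d), relation_onehot(relation)))
  rbind(rows, params$placeholder[1, ])
}

#' Encode a knowledge tuple into its memory vector
#'
#' The subject vector, the relation one-hot (hasSymptom = 1, needsTest = 2,
#' then the remaining relations in schema order) and the object vectors, in
#' sorted object order, pass through the tuple-encoder LSTM; the final
#' hidden state is the memory vector. Deterministic for fixed weights;
#' object-order invariant by the pre-sorting contract.
#'
#' @param tuple a tuple from [knowledge_tuples()].
#' @param embeddings a `token_embeddings` for entity vectors.
#' @param params QA model parameters.
#' @param H encoder width.
#' @return numeric vector of length `H`.
#' @export
encode_tuple <- function(tuple, embeddings, params, H) {
  tuple$objects <- sort(tuple$objects)
  qa_encode_rows(tuple_element_rows(tuple, embeddings), params, H)
}

#' Build the sorted memory store from a knowledge graph
#'
#' @param graph a `knowledge_graph` or `medkg_kb` (its relations are used).
#' @param embeddings a `token_embeddings`.
#' @param params,H QA model parameters and encoder width.
#' @return object of class `memory_store`: `slots` (tuple, vector,
#'   usage_count), sorted entity index for binary search, and the entity
#'   type map.
#' @export
build_memory <- function(graph, embeddings, params, H) {
  relations <- if (inherits(graph, "medkg_kb")) graph$relations else
    graph$tuples
  tuples <- knowledge_tuples(relations)
  slots <- lapply(tuples, function(tp) list(
    tuple = tp,
    vector = encode_tuple(tp, embeddings, params, H),
    usage_count = 0L))
  ents <- unique(unlist(lapply(tuples, function(tp)
    c(tp$subject, tp$objects))))
  ents <- sort(ents)
  slot_of <- lapply(seq_along(ents), function(i) integer(0))
  names(slot_of) <- ents
  for (si in seq_along(tuples)) {
    for (e in c(tuples[[si]]$subject, tuples[[si]]$objects))
      slot_of[[e]] <- c(slot_of[[e]], si)
  }
  type_map <- if (inherits(graph, "medkg_kb")) {
    tm <- kb_entity_frame(graph); stats::setNames(tm$type, tm$entity)
  } else stats::setNames(graph$entities$type, graph$entities$canonical)
  structure(list(slots = slots, index_keys = ents, index_slots = slot_of,
                 type_map = type_map, embeddings = embeddings,
                 n_queries = 0L),
            class = "memory_store")
}

#' @export
print.memory_store <- function(x, ...) {
  cat("<memory_store>", length(x$slots), "slots,",
      length(x$index_keys), "indexed entities\n")
  invisible(x)
}

#' Search candidate memories by entity overlap
#'
#' Binary search over the sorted entity index returns every slot whose
#' tuple shares at least one entity (as subject or object) with the
#' question.
#'
#' @param question_entities character vector.
#' @param store a `memory_store`.
#' @return integer vector of slot indices (sorted, unique).
#' @export
memory_search <- function(question_entities, store) {
  if (!length(store$slots) || !length(question_entities)) return(integer(0))
  hits <- integer(0)
  keys <- store$index_keys
  for (e in question_entities) {
    lo <- 1L; hi <- length(keys)
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (keys[mid] < e) lo <- mid + 1L
      else if (keys[mid] > e) hi <- mid - 1L
      else { hits <- c(hits, store$index_slots[[mid]]); break }
    }
  }
  sort(unique(hits))
}

# ---- region-affinity attention ---------------------------------------------

#' Region-affinity attention between question and memory patches
#'
#' Patches (rows) are L2-normalized; `s[i, j]` is the cosine between
#' question patch i and memory patch j; each row of `alpha` is the softmax
#' of `s` over j; the attention score is `Att = W %*% [mean(alpha),
#' sum(alpha), max(alpha)]`. Zero-norm patches are excluded with a warning.
#'
#' @param u_patches question patch matrix (rows are patches).
#' @param m_patches memory patch matrix.
#' @param W 1 x 3 aggregation weights.
#' @return list with `s`, `alpha`, `features` (mean, sum, max), `att`.
#' @export
attend <- function(u_patches, m_patches, W = matrix(1 / 3, 1, 3)) {
  drop_zero <- function(M, side) {
    nrm <- sqrt(rowSums(M^2))
    if (any(nrm == 0)) {
      warning("excluding ", sum(nrm == 0), " zero-norm ", side, " patch(es)")
      M <- M[nrm > 0, , drop = FALSE]
      nrm <- nrm[nrm > 0]
    }
    M / nrm
  }
  U <- drop_zero(u_patches, "question")
  M <- drop_zero(m_patches, "memory")
  if (!nrow(U) || !nrow(M))
    return(list(s = NULL, alpha = NULL, features = c(0, 0, 0), att = 0))
  s <- U %*% t(M)
  e <- exp(s - apply(s, 1, max))
  alpha <- e / rowSums(e)
  features <- c(mean(alpha), sum(alpha), max(alpha))
  list(s = s, alpha = alpha, features = features,
       att = as.numeric(W %*% features))
}

question_patches <- function(entities, relation, params, embeddings) {
  question_element_rows(entities, relation, params, embeddings)
}

memory_patches <- function(tuple, embeddings) {
  tuple_element_rows(tuple, embeddings)
}

# ---- generalization (memory utility) ---------------------------------------

#' Table-style memory features for the generalization module
#'
#' `[input similarity, normalized used-times, entity count, relation
#' one-hot]` — the feature columns the utility network consumes.
#'
#' @param similarity cosine similarity between input and memory vectors.
#' @param usage_norm usage count normalized by total queries.
#' @param n_entities number of entities in the memory tuple.
#' @param relation the memory tuple's relation type.
#' @export
memory_features <- function(similarity, usage_norm, n_entities, relation) {
  c(similarity, usage_norm, n_entities, relation_onehot(relation))
}

utility_net_init <- function(seed = 1) {
  with_seed(seed, list(
    W1 = matrix(stats::rnorm(8 * 8, 0, 0.3), 8, 8),
    b1 = matrix(0, 1, 8),
    W2 = matrix(stats::rnorm(8, 0, 0.3), 8, 1),
    b2 = matrix(0, 1, 1)))
}

utility_value <- function(net, features) {
  h <- tanh(c(features) %*% net$W1 + net$b1[1, ])
  as.numeric(1 / (1 + exp(-(h %*% net$W2 + net$b2[1, 1]))))
}

#' Generalization decision over a memory slot
#'
#' Computes utility values for the new input (`v_n`) and the existing slot
#' (`v_i`) with the utility network, then maps them to operations by rule:
#' a question input above the similarity floor uses the memory to answer; a
#' knowledge input that duplicates a similar memory replaces it when
#' `v_n > v_i`, otherwise it is stored as new knowledge; a clean command
#' forgets slots whose usage feature is below the floor.
#'
#' @param input list with `kind` (`"question"`, `"knowledge"`, `"clean"`),
#'   `features` (the input-side feature vector) and `similarity` to the slot.
#' @param slot_features feature vector of the memory slot given the input.
#' @param utility function(features) -> value in `[0, 1]` (a trained
#'   network via [utility_value()] or a stub).
#' @param rules list with `answer_floor` (default 0.5), `dup_sim` (0.7),
#'   `usage_floor` (0.01).
#' @return list with `v_n`, `v_i`, `o_n`, `o_i`.
#' @export
generalize <- function(input, slot_features, utility,
                       rules = list(answer_floor = 0.5, dup_sim = 0.7,
                                    usage_floor = 0.01)) {
  v_i <- utility(slot_features)
  v_n <- if (is.null(input$features)) 0 else utility(input$features)
  o_n <- "no-op"; o_i <- "no-op"
  sim <- input$similarity %||% slot_features[1]
  usage <- slot_features[2]
  if (input$kind == "question") {
    if (sim >= rules$answer_floor) o_i <- "use-for-answer"
  } else if (input$kind == "knowledge") {
    if (sim >= rules$dup_sim) {
      if (v_n > v_i) { o_n <- "store-new"; o_i <- "replace-old" }
    } else o_n <- "store-new"
  } else if (input$kind == "clean") {
    if (usage < rules$usage_floor && sim < rules$answer_floor)
      o_i <- "forget"
  }
  list(v_n = v_n, v_i = v_i, o_n = o_n, o_i = o_i)
}

# ---- loss -------------------------------------------------------------------

#' Margin ranking loss of the QA model
#'
#' `sum over wrong memories of max(0, gamma - s_o(u, m_o) + s_o(u, f)) +
#' sum over wrong answers of max(0, gamma - s_R([u, m_o], a) +
#' s_R([u, m_o], a'))`, with cosine similarities. Zero exactly when every
#' negative is beaten by the margin on both terms.
#'
#' @param u question vector.
#' @param m_o supporting memory vector.
#' @param a answer vector (in entity-embedding space).
#' @param neg_memories list/matrix of incorrect memory vectors.
#' @param neg_answers list/matrix of incorrect answer vectors.
#' @param gamma margin.
#' @param W_R decoder matrix mapping `[u, m_o]` to entity-embedding space.
#' @return non-negative scalar; warns when no negatives are supplied.
#' @export
qa_margin_loss <- function(u, m_o, a, neg_memories, neg_answers, gamma,
                           W_R = NULL) {
  as_rows <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x else do.call(rbind, x)
  }
  F_ <- as_rows(neg_memories); A_ <- as_rows(neg_answers)
  if ((is.null(F_) || !nrow(F_)) && (is.null(A_) || !nrow(A_)))
    warning("no negatives supplied; loss is an empty sum")
  s_o_pos <- cosine_similarity(u, m_o)
  loss <- 0
  if (!is.null(F_)) for (i in seq_len(nrow(F_)))
    loss <- loss + max(0, gamma - s_o_pos + cosine_similarity(u, F_[i, ]))
  joint <- if (is.null(W_R)) c(u, m_o) else as.vector(c(u, m_o) %*% W_R)
  s_R_pos <- cosine_similarity(joint, a)
  if (!is.null(A_)) for (i in seq_len(nrow(A_)))
    loss <- loss + max(0, gamma - s_R_pos + cosine_similarity(joint, A_[i, ]))
  loss
}
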