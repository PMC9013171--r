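# QA system assembly: answering, two-phase training, test labeling and
# evaluation.

answer_templates <- function() {
  c(Disease = "it seems to be %s based on your description",
    Symptom = "the typical manifestation is %s",
    Treatment = "the recommended treatment is %s",
    Test = "the advised examination is %s",
    Result = "the expected finding is %s")
}

# longest-match dictionary scan of known entities in a token sequence
match_known_entities <- function(tokens, entities) {
  if (!length(entities)) return(character(0))
  ord <- entities[order(-vapply(entities, function(e)
    length(entity_tokens(e)), numeric(1)))]
  taken <- logical(length(tokens))
  found <- character(0)
  for (e in ord) {
    et <- entity_tokens(e)
    for (st in find_subseq(tokens, et)) {
      ix <- st:(st + length(et) - 1L)
      if (any(taken[ix])) next
      taken[ix] <- TRUE
      found <- c(found, e)
    }
  }
  unique(found)
}

# the relation a question expresses, given its intent and the types of the
# entities it mentions
infer_question_relation <- function(intent, given_types) {
  if (is.na(intent) || !length(given_types)) return(NA_character_)
  schema <- relation_schema()
  hit <- schema$relation[
    (schema$subject_type == intent & schema$object_type %in% given_types) |
    (schema$object_type == intent & schema$subject_type %in% given_types)]
  if (length(hit) == 1L) hit else NA_character_
}

#' Answer a question with the memory network
#'
#' Extracts known entities from the question, detects the intent, narrows
#' the memory by entity search, ranks candidates by region-affinity
#' attention, and decodes the answer entity of the intent type from the
#' best memory (constrained to its entities; falls back to the most
#' frequent intent-type entity among the top-K memories when the best
#' memory has none).
#'
#' @param question_tokens character vector.
#' @param system a trained `qa_system`.
#' @return list with `answer`, `sentence`, `intent`, `entities`, `ranking`
#'   (data.frame of candidate slots and attention scores), `slot` (winning
#'   slot index), `flagged` (fallback used).
#' @export
answer_question <- function(question_tokens, system) {
  store <- system$store
  ents <- match_known_entities(question_tokens, store$index_keys)
  it <- detect_intent(question_tokens, system$intent_rules)
  intent <- it$intent
  rel <- infer_question_relation(intent,
                                 unname(store$type_map[ents]))
  cand <- memory_search(ents, store)
  if (!length(cand)) cand <- seq_along(store$slots)
  if (!length(store$slots))
    return(list(answer = NA_character_, sentence = NA_character_,
                intent = intent, entities = ents, ranking = NULL,
                slot = NA_integer_, flagged = TRUE))
  up <- question_patches(ents, rel %||% NA_character_, system$params,
                         store$embeddings)
  att <- vapply(cand, function(si)
    attend(up, memory_patches(store$slots[[si]]$tuple, store$embeddings),
           system$params$W_att)$att, numeric(1))
  keys <- vapply(cand, function(si) store$slots[[si]]$tuple$sort_key,
                 character(1))
  ord <- order(-att, keys)
  ranking <- data.frame(slot = cand[ord], att = att[ord],
                        stringsAsFactors = FALSE)
  best <- ranking$slot[1]
  btup <- store$slots[[best]]$tuple
  if (is.na(intent)) intent <- unname(store$type_map[btup$subject])
  # candidate answer entities of the intent type in the winning memory
  mem_entities <- function(tp) {
    es <- c(tp$subject, tp$objects)
    es[!is.na(store$type_map[es]) & store$type_map[es] == intent]
  }
  cands <- setdiff(mem_entities(btup), ents)
  if (!length(cands)) cands <- mem_entities(btup)
  flagged <- FALSE
  if (!length(cands)) {
    # fallback: most frequent intent-type entity among top-K memories
    flagged <- TRUE
    topk <- ranking$slot[seq_len(min(system$config$top_k + 4L,
                                     nrow(ranking)))]
    pool <- unlist(lapply(topk, function(si)
      mem_entities(store$slots[[si]]$tuple)))
    if (length(pool)) {
      tb <- sort(table(pool), decreasing = TRUE)
      cands <- names(tb)[1]
    }
  }
  if (!length(cands))
    return(list(answer = NA_character_, sentence = NA_character_,
                intent = intent, entities = ents, ranking = ranking,
                slot = best, flagged = TRUE))
  answer <- if (length(cands) == 1L) cands else {
    # decode: score candidates against the joint question+memory vector
    H <- system$config$encoder_dim
    u_enc <- qa_encode_rows(
      question_element_rows(ents, rel %||% NA_character_, system$params,
                            store$embeddings), system$params, H)
    m_enc <- store$slots[[best]]$vector
    joint <- as.vector(c(u_enc, m_enc) %*% system$params$W_R)
    sc <- vapply(cands, function(e) {
      ev <- embed_entities(e, store$embeddings)[1, ]
      if (all(ev == 0)) -Inf else cosine_similarity(joint, ev)
    }, numeric(1))
    cands[order(-sc, cands)][1]
  }
  tmpl <- answer_templates()[[intent]] %||% "the answer is %s"
  list(answer = answer, sentence = sprintf(tmpl, answer), intent = intent,
       entities = ents, ranking = ranking, slot = best, flagged = flagged)
}

#' Train the QA model on question-answer pairs over a knowledge graph
#'
#' Phase 1 trains the tuple encoder, response decoder and attention
#' aggregation on the margin ranking loss, with negative memories and
#' answers sampled so they share no entity with the question or answer.
#' Phase 2 builds the memory store, replays the training questions, rewards
#' slots that support correct answers (usage counts), and trains the
#' generalization utility network on the resulting labels.
#'
#' @param qa_pairs list of `synth_qa`-shaped objects (`question_tokens`,
#'   `answer_entity`, `supporting_tuple`).
#' @param graph `knowledge_graph` or `medkg_kb` backing the memory.
#' @param embeddings a `token_embeddings` for entity vectors.
#' @param config a [qa_config()].
#' @param rng_seed integer seed.
#' @return object of class `qa_system`.
#' @export
train_qa <- function(qa_pairs, graph, embeddings, config = qa_config(),
                     rng_seed = 1) {
  relations <- if (inherits(graph, "medkg_kb")) graph$relations else
    graph$tuples
  if (!nrow(relations)) stop("empty knowledge graph")
  tuples <- knowledge_tuples(relations)
  kb_entities <- unique(unlist(lapply(tuples, function(tp)
    c(tp$subject, tp$objects))))
  q_entities <- unique(unlist(lapply(qa_pairs, function(p)
    c(p$supporting_tuple$subject, p$supporting_tuple$object,
      p$answer_entity))))
  if (!length(intersect(kb_entities, q_entities)))
    stop("QA pairs and knowledge graph share no entities; check inputs")
  type_map <- if (inherits(graph, "medkg_kb")) {
    tm <- kb_entity_frame(graph); stats::setNames(tm$type, tm$entity)
  } else stats::setNames(graph$entities$type, graph$entities$canonical)
  H <- config$encoder_dim
  params <- qa_init_params(embeddings$dim, H, rng_seed)
  tuple_entity_sets <- lapply(tuples, function(tp) c(tp$subject, tp$objects))
  tuple_rows <- lapply(tuples, function(tp)
    tuple_element_rows(tp, embeddings))
  slot_of_tuple <- stats::setNames(
    seq_along(tuples),
    vapply(tuples, function(tp)
      tuple_key(tp$subject, tp$relation, paste(tp$objects, collapse = "|")),
      character(1)))
  find_slot <- function(st) {
    # supporting tuple may carry a single object; match subject+relation
    for (si in seq_along(tuples)) {
      tp <- tuples[[si]]
      if (tp$subject == st$subject && tp$relation == st$relation &&
          st$object %in% tp$objects) return(si)
    }
    NA_integer_
  }
  exs <- list()
  for (p in qa_pairs) {
    si <- find_slot(p$supporting_tuple)
    if (is.na(si)) next
    q_ents <- match_known_entities(p$question_tokens, kb_entities)
    rel <- p$supporting_tuple$relation
    exs[[length(exs) + 1L]] <- list(
      q_ents = q_ents, rel = rel, pos = si, answer = p$answer_entity,
      avoid = unique(c(q_ents, p$answer_entity)))
  }
  if (!length(exs)) stop("no QA pair matches a knowledge tuple")
  gamma <- config$gamma
  with_seed(rng_seed + 1L, {
    st <- adam_state(params[c("W", "b", "placeholder", "W_R")])
    for (ep in seq_len(config$epochs)) {
      ord <- sample(seq_along(exs))
      for (bs in seq(1, length(ord), by = 8L)) {
        bix <- ord[bs:min(bs + 7L, length(ord))]
        pn <- ad_params_wrap(params[c("W", "b", "placeholder", "W_R")])
        terms <- list()
        for (ex in exs[bix]) {
          const_rows <- question_element_rows(ex$q_ents, ex$rel, params,
                                              embeddings)
          nq <- nrow(const_rows)
          rows_node <- if (nq > 1L)
            ad_vcat(ad_const(const_rows[-nq, , drop = FALSE]),
                    pn$placeholder)
          else pn$placeholder
          u <- qa_encode_rows_ad(rows_node, nq, pn, H)
          m_pos <- qa_encode_rows_ad(ad_const(tuple_rows[[ex$pos]]),
                                     nrow(tuple_rows[[ex$pos]]), pn, H)
          s_pos <- ad_cosine(u, m_pos)
          # negative memories: no entity shared with question or answer
          negs <- qa_negative_slots(tuple_entity_sets, ex$avoid, ex$pos)
          if (length(negs))
            negs <- sample(negs, min(config$negatives, length(negs)))
          for (ni in negs) {
            m_neg <- qa_encode_rows_ad(ad_const(tuple_rows[[ni]]),
                                       nrow(tuple_rows[[ni]]), pn, H)
            terms[[length(terms) + 1L]] <- ad_relu(
              ad_add(ad_sub(ad_const(matrix(gamma, 1, 1)), s_pos),
                     ad_cosine(u, m_neg)))
          }
          # response term: joint vector vs answer embedding (entities
          # absent from the corpus have zero vectors and are skipped)
          a_emb <- embed_entities(ex$answer, embeddings)[1, ]
          if (any(a_emb != 0)) {
            joint <- ad_matmul(ad_hcat(u, m_pos), pn$W_R)
            s_r_pos <- ad_cosine(joint, ad_const(matrix(a_emb, 1)))
            atype <- unname(type_map[ex$answer])
            wrong <- setdiff(names(type_map)[type_map == atype], ex$avoid)
            if (length(wrong))
              wrong <- sample(wrong, min(config$negatives, length(wrong)))
            for (w in wrong) {
              w_emb <- embed_entities(w, embeddings)[1, ]
              if (all(w_emb == 0)) next
              terms[[length(terms) + 1L]] <- ad_relu(
                ad_add(ad_sub(ad_const(matrix(gamma, 1, 1)), s_r_pos),
                       ad_cosine(joint, ad_const(matrix(w_emb, 1)))))
            }
          }
        }
        if (!length(terms)) next
        total <- ad_scale(Reduce(ad_add, terms), 1 / length(bix))
        ad_backward(total)
        upd <- adam_step(params[c("W", "b", "placeholder", "W_R")],
                         ad_grads(pn), st, lr = config$lr)
        params[names(upd$params)] <- upd$params
        st <- upd$state
      }
    }
    # attention aggregation weights: perceptron-style hinge on candidate sets
    W_att <- params$W_att
    for (ep in seq_len(3L)) for (ex in exs) {
      up <- question_patches(ex$q_ents, ex$rel, params, embeddings)
      f_pos <- attend(up, memory_patches(tuples[[ex$pos]], embeddings),
                      W_att)$features
      cand <- which(vapply(tuple_entity_sets, function(es)
        any(es %in% ex$q_ents), logical(1)))
      cand <- setdiff(cand, ex$pos)
      for (ci in cand) {
        f_neg <- attend(up, memory_patches(tuples[[ci]], embeddings),
                        W_att)$features
        if (sum(W_att * (f_pos - f_neg)) < 0.05)
          W_att <- W_att + 0.1 * matrix(f_pos - f_neg, 1)
      }
    }
    params$W_att <- W_att
    store <- build_memory(graph, embeddings, params, H)
    system <- structure(list(params = params, store = store,
                             config = config, intent_rules = intent_rules(),
                             utility_net = NULL),
                        class = "qa_system")
    # phase 2: replay questions, reward supporting slots, train utility net
    feats <- list(); labs <- integer(0)
    n_queries <- length(exs)
    for (ex in exs) {
      u_enc <- qa_encode_rows(
        question_element_rows(ex$q_ents, ex$rel, params, embeddings),
        params, H)
      res <- answer_question_internal(ex$q_ents, ex$rel, system)
      correct <- !is.na(res$slot) && res$slot == ex$pos
      if (correct)
        store$slots[[ex$pos]]$usage_count <-
          store$slots[[ex$pos]]$usage_count + 1L
      cand <- unique(c(ex$pos, utils::head(res$ranking$slot, 3)))
      for (si in cand) {
        sim <- cosine_similarity(u_enc, store$slots[[si]]$vector)
        f <- memory_features(sim,
                             store$slots[[si]]$usage_count / n_queries,
                             length(tuple_entity_sets[[si]]),
                             store$slots[[si]]$tuple$relation)
        feats[[length(feats) + 1L]] <- f
        labs <- c(labs, as.integer(si == ex$pos && correct))
      }
    }
    store$n_queries <- n_queries
    system$store <- store
    net <- utility_net_init(rng_seed)
    if (length(labs) && length(unique(labs)) > 1L) {
      Fm <- do.call(rbind, feats)
      stn <- adam_state(net)
      for (ep in seq_len(config$gen_epochs)) {
        pn <- ad_params_wrap(net)
        X <- ad_const(Fm)
        h <- ad_tanh(ad_addbias(ad_matmul(X, pn$W1), pn$b1))
        logit <- ad_addbias(ad_matmul(h, pn$W2), pn$b2)
        pr <- ad_sigmoid(logit)
        y <- ad_const(matrix(labs, ncol = 1))
        err <- ad_sub(pr, y)
        loss <- ad_mean(ad_mul(err, err))
        ad_backward(loss)
        upd <- adam_step(net, ad_grads(pn), stn, lr = config$gen_lr)
        net <- upd$params; stn <- upd$state
      }
    }
    system$utility_net <- net
    system
  })
}

#' Admissible negative memory slots
#'
#' Negative samples for the ranking loss must share no entity with the
#' question or the answer; the positive slot is excluded too.
#'
#' @param tuple_entity_sets list of entity vectors, one per memory slot.
#' @param avoid entities of the question and answer.
#' @param pos index of the supporting slot.
#' @return integer indices of admissible negative slots.
#' @export
qa_negative_slots <- function(tuple_entity_sets, avoid, pos) {
  negs <- which(vapply(tuple_entity_sets, function(es)
    !any(es %in% avoid), logical(1)))
  setdiff(negs, pos)
}

# answering from pre-extracted entities/relation (training replay path)
answer_question_internal <- function(q_ents, rel, system) {
  store <- system$store
  cand <- memory_search(q_ents, store)
  if (!length(cand)) cand <- seq_along(store$slots)
  up <- question_patches(q_ents, rel, system$params, store$embeddings)
  att <- vapply(cand, function(si)
    attend(up, memory_patches(store$slots[[si]]$tuple, store$embeddings),
           system$params$W_att)$att, numeric(1))
  keys <- vapply(cand, function(si) store$slots[[si]]$tuple$sort_key,
                 character(1))
  ord <- order(-att, keys)
  list(slot = cand[ord][1],
       ranking = data.frame(slot = cand[ord], att = att[ord]))
}

#' @export
print.qa_system <- function(x, ...) {
  cat("<qa_system>", length(x$store$slots), "memory slots, encoder dim",
      x$config$encoder_dim, "\n")
  invisible(x)
}

#' Label QA evaluation documents by rule
#'
#' The intent comes from the question's marker word; the label is the most
#' frequent intent-type entity in the body (frequency ties drop the
#' document); documents whose body expresses more than one relation type
#' are dropped.
#'
#' @param qa_docs list with `question_tokens` and `body_tokens` per doc.
#' @param entity_extractor function(tokens) -> data.frame with `type`,
#'   `surface` for each mention.
#' @param relation_detector function(tokens) -> character vector of
#'   relation types expressed in the tokens (NULL disables the
#'   one-relation filter).
#' @return data.frame with `doc`, `intent`, `label` for retained documents.
#' @export
label_qa_test_data <- function(qa_docs, entity_extractor,
                               relation_detector = NULL) {
  rows <- list()
  for (i in seq_along(qa_docs)) {
    d <- qa_docs[[i]]
    it <- detect_intent(d$question_tokens)
    if (is.na(it$intent)) next
    ments <- entity_extractor(d$body_tokens)
    if (is.null(ments) || !nrow(ments)) next
    if (!is.null(relation_detector)) {
      rels <- relation_detector(d$body_tokens)
      if (length(unique(rels)) != 1L) next
    }
    of_type <- ments$surface[ments$type == it$intent]
    if (!length(of_type)) next
    tb <- sort(table(of_type), decreasing = TRUE)
    if (length(tb) > 1L && tb[1] == tb[2]) next  # frequency tie: drop
    rows[[length(rows) + 1L]] <- data.frame(
      doc = i, intent = it$intent, label = names(tb)[1],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(doc = integer(0), intent = character(0),
                      label = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Evaluate the QA system
#'
#' P@1 is the fraction of questions whose top answer equals the label; F1
#' is the micro-averaged F1 of predicted versus gold answer entities
#' (unanswered questions count as false negatives). Standard deviations
#' come from bootstrap resamples of the test set.
#'
#' @param system a `qa_system`.
#' @param qa_docs the evaluation documents.
#' @param labels data.frame from [label_qa_test_data()].
#' @param n_boot bootstrap resamples.
#' @param rng_seed integer seed.
#' @return list with `p_at_1`, `f1`, `p_at_1_sd`, `f1_sd`, `n`,
#'   `predictions`.
#' @export
evaluate_qa <- function(system, qa_docs, labels, n_boot = 30L,
                        rng_seed = 1) {
  if (!nrow(labels)) stop("empty labeled evaluation set")
  preds <- vapply(labels$doc, function(i)
    answer_question(qa_docs[[i]]$question_tokens, system)$answer %||%
      NA_character_, character(1))
  correct <- !is.na(preds) & preds == labels$label
  answered <- !is.na(preds)
  p1 <- mean(correct)
  f1_of <- function(corr, ans) {
    tp <- sum(corr); fp <- sum(ans & !corr); fn <- sum(!corr)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }
  f1 <- f1_of(correct, answered)
  with_seed(rng_seed, {
    bs <- replicate(n_boot, {
      ix <- sample.int(length(correct), replace = TRUE)
      c(mean(correct[ix]), f1_of(correct[ix], answered[ix]))
    })
    list(p_at_1 = p1, f1 = f1,
         p_at_1_sd = stats::sd(bs[1, ]), f1_sd = stats::sd(bs[2, ]),
         n = length(correct),
         predictions = data.frame(doc = labels$doc, label = labels$label,
                                  prediction = preds,
                                  stringsAsFactors = FALSE))
  })
}
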