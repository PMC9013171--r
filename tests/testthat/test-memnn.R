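# memory network: tuples, intent, search, attention, generalization, loss

test_that("relation rows merge into sorted multi-object tuples", {
  rel <- data.frame(
    subject = c("flu", "flu", "flu", "cold"),
    relation = c("hasSymptom", "hasSymptom", "needsTest", "hasSymptom"),
    object = c("fever", "cough", "thermometer", "sneeze"),
    stringsAsFactors = FALSE)
  tp <- knowledge_tuples(rel)
  expect_length(tp, 3)
  flu_sym <- Filter(function(t)
    t$subject == "flu" && t$relation == "hasSymptom", tp)[[1]]
  expect_identical(flu_sym$objects, c("cough", "fever"))  # sorted
  keys <- vapply(tp, `[[`, "", "sort_key")
  expect_identical(keys, sort(keys))
})

test_that("tuple encoding is deterministic and object-order invariant", {
  emb <- train_token_embeddings(
    list(c("flu", "fever", "cough", "x")), dim = 8, epochs = 2)
  params <- qa_init_params(8, 6, seed = 2)
  t1 <- list(subject = "flu", relation = "hasSymptom",
             objects = c("fever", "cough"))
  t2 <- list(subject = "flu", relation = "hasSymptom",
             objects = c("cough", "fever"))  # permuted input order
  v1 <- encode_tuple(t1, emb, params, 6)
  expect_identical(v1, encode_tuple(t1, emb, params, 6))
  expect_identical(v1, encode_tuple(t2, emb, params, 6))
  # the one-hot ordering is fixed by the schema
  expect_equal(relation_onehot("hasSymptom"), c(1, 0, 0, 0, 0))
  expect_equal(relation_onehot("needsTest"), c(0, 1, 0, 0, 0))
  expect_equal(relation_onehot("hasResult"), c(0, 0, 0, 0, 1))
  expect_error(relation_onehot("isA"), "unknown relation")
})

test_that("intent detection follows the rule table in order", {
  expect_identical(detect_intent(c("whatdisease", "has", "x"))$intent,
                   "Disease")
  expect_identical(detect_intent(c("please", "howtotreat", "flu"))$intent,
                   "Treatment")
  ua <- detect_intent(c("tell", "me", "something"))
  expect_true(is.na(ua$intent))
  # first matching rule in document order wins
  both <- detect_intent(c("whatsymptom", "whatdisease"))
  expect_identical(both$intent, "Disease")
  # generator intents agree with the rules on every rendered pair
  kb <- tiny_kb(n_ent = 8, n_rel = 5)
  qa <- render_qa_pairs(kb, 60, rng_seed = 3)
  for (p in qa)
    expect_identical(detect_intent(p$question_tokens)$intent, p$intent_type)
})

test_that("memory search equals a linear scan, including object matches", {
  set.seed(9)
  kb <- generate_kb(12, 18, rng_seed = 5)
  emb <- train_token_embeddings(
    list(unique(unlist(lapply(unlist(kb$entities), entity_tokens)))),
    dim = 6, epochs = 1)
  params <- qa_init_params(6, 4, seed = 1)
  store <- build_memory(kb, emb, params, 4)
  expect_gt(length(store$slots), 20)
  all_ents <- unlist(kb$entities)
  for (rep in 1:25) {
    q <- sample(all_ents, sample(1:3, 1))
    got <- memory_search(q, store)
    linear <- which(vapply(store$slots, function(s)
      any(c(s$tuple$subject, s$tuple$objects) %in% q), logical(1)))
    expect_identical(got, linear)
  }
  # an entity appearing only as an object is still matched
  obj_only <- setdiff(kb$relations$object, kb$relations$subject)[1]
  expect_gt(length(memory_search(obj_only, store)), 0)
  # absent entity: empty candidates
  expect_length(memory_search("no such entity", store), 0)
})

test_that("region-affinity attention normalizes and ranks like its oracle", {
  # degenerate: one identical patch on each side
  v <- c(1, 2, 3)
  r <- attend(matrix(v, 1), matrix(v, 1))
  expect_equal(unname(r$s[1, 1]), 1)
  expect_equal(unname(r$alpha[1, 1]), 1)
  expect_equal(r$features, c(1, 1, 1))
  # alpha rows are probability distributions
  set.seed(2)
  for (rep in 1:10) {
    U <- matrix(rnorm(12), 3); M <- matrix(rnorm(16), 4)
    a <- attend(U, M)
    expect_equal(unname(rowSums(a$alpha)), rep(1, 3), tolerance = 1e-9)
  }
  # W = [1,0,0]: ranking equals ranking by mean attention, which matches a
  # direct mean-of-softmaxed-cosines oracle
  U <- matrix(rnorm(12), 3)
  Ms <- lapply(1:5, function(i) matrix(rnorm(8), 2))
  W <- matrix(c(1, 0, 0), 1)
  atts <- vapply(Ms, function(M) attend(U, M, W)$att, numeric(1))
  oracle <- vapply(Ms, function(M) {
    Un <- U / sqrt(rowSums(U^2)); Mn <- M / sqrt(rowSums(M^2))
    s <- Un %*% t(Mn)
    e <- exp(s - apply(s, 1, max))
    mean(e / rowSums(e))
  }, numeric(1))
  expect_equal(order(-atts), order(-oracle))
  # zero-norm patches are excluded with a warning
  expect_warning(attend(rbind(c(0, 0), c(1, 0)), matrix(c(1, 0), 1)),
                 "zero-norm")
})

test_that("generalization reproduces the three canonical behaviors", {
  # a stub utility network returning the published worked values
  stub <- function(v) function(f) v
  # question input at similarity 0.76 -> use the memory to answer
  f_mem <- memory_features(0.76, 0.017, 3, "needsTreatment")
  d1 <- generalize(list(kind = "question", similarity = 0.76,
                        features = NULL), f_mem, stub(0.83))
  expect_identical(d1$o_i, "use-for-answer")
  expect_equal(d1$v_i, 0.83)
  # duplicated knowledge with v_n > v_i -> replace the old memory
  util <- local({
    calls <- 0
    function(f) { calls <<- calls + 1; if (calls == 1) 0.83 else 0.92 }
  })
  d2 <- generalize(list(kind = "knowledge", similarity = 0.76,
                        features = memory_features(0.76, 0, 3,
                                                   "needsTreatment")),
                   f_mem, util)
  expect_identical(d2$o_i, "replace-old")
  expect_gt(d2$v_n, d2$v_i)
  # clean command on a never-used, zero-similarity slot -> forget
  f_idle <- memory_features(0, 0.00, 2, "needsTest")
  d3 <- generalize(list(kind = "clean", similarity = 0, features = NULL),
                   f_idle, stub(0.03))
  expect_identical(d3$o_i, "forget")
  # a well-used slot survives the clean command
  f_used <- memory_features(0, 0.4, 2, "needsTest")
  d4 <- generalize(list(kind = "clean", similarity = 0, features = NULL),
                   f_used, stub(0.9))
  expect_identical(d4$o_i, "no-op")
})

test_that("the margin ranking loss matches hand-evaluated hinges", {
  u <- c(1, 0, 0)
  m_o <- c(1, 0, 0)           # s_o(u, m_o) = 1
  a <- c(0, 1, 0)
  # satisfied margins: negatives at cosine -1
  f_neg <- matrix(c(-1, 0, 0), 1)
  l1 <- qa_margin_loss(u, m_o, a, f_neg, NULL, gamma = 0.2)
  expect_equal(l1, 0)
  # identical positive and negative similarities: each hinge contributes
  # exactly gamma
  same_mem <- rbind(m_o, m_o, m_o)
  same_ans <- rbind(a, a)
  l2 <- qa_margin_loss(u, m_o, a, same_mem, same_ans, gamma = 0.2)
  expect_equal(l2, 0.2 * 5)
  # monotone: raising s_o(u, m_o) cannot raise the loss
  set.seed(3)
  f <- matrix(rnorm(9), 3)
  loss_at <- function(mo) qa_margin_loss(u, mo, a, f, NULL, gamma = 0.2)
  m_far <- c(0.2, 0.8, 0); m_near <- c(0.9, 0.1, 0)
  expect_gte(loss_at(m_far), loss_at(m_near))
  expect_warning(qa_margin_loss(u, m_o, a, NULL, NULL, 0.2), "no negatives")
})

test_that("negative slots never share an entity with question or answer", {
  sets <- list(c("a", "b"), c("c", "d"), c("b", "e"), c("f", "g"))
  negs <- qa_negative_slots(sets, avoid = c("a", "e"), pos = 2)
  expect_identical(negs, 4L)
  # positive excluded even when admissible
  negs2 <- qa_negative_slots(sets, avoid = "zzz", pos = 1)
  expect_false(1L %in% negs2)
  expect_setequal(negs2, c(2L, 3L, 4L))
})

test_that("a one-tuple memory answers its forced question with the template", {
  kb <- generate_kb(1, 0, rng_seed = 1)
  kb$entities <- list(Disease = "concussion",
                      Symptom = c("dizzy", "vomiting"),
                      Treatment = character(0), Test = character(0),
                      Result = character(0))
  kb$relations <- data.frame(subject = "concussion", relation = "hasSymptom",
                             object = c("dizzy", "vomiting"),
                             stringsAsFactors = FALSE)
  kb$groundings <- numeric(0)
  emb <- train_token_embeddings(
    list(c("concussion", "dizzy", "vomiting", "x")), dim = 8, epochs = 2)
  params <- qa_init_params(8, 6, seed = 4)
  store <- build_memory(kb, emb, params, 6)
  system <- structure(list(params = params, store = store,
                           config = qa_config(encoder_dim = 6),
                           intent_rules = intent_rules(),
                           utility_net = NULL), class = "qa_system")
  res <- answer_question(c("whatdisease", "has", "symptom", "dizzy", "?"),
                         system)
  expect_identical(res$answer, "concussion")
  expect_identical(res$intent, "Disease")
  # the templated sentence contains the answer exactly once
  n_occ <- length(gregexpr("concussion", res$sentence, fixed = TRUE)[[1]])
  expect_equal(n_occ, 1)
})

test_that("test-set labeling follows the majority and one-relation rules", {
  docs <- list(
    list(question_tokens = c("whatdisease", "is", "this", "?"),
         body_tokens = c("d1", "x", "d1", "y", "d2", "d1")),
    list(question_tokens = c("whatdisease", "is", "this", "?"),
         body_tokens = c("d1", "d2")),              # frequency tie: dropped
    list(question_tokens = c("no", "marker", "here"),
         body_tokens = c("d1", "d1")),              # unknown intent: dropped
    list(question_tokens = c("whatdisease", "?"),
         body_tokens = c("d1", "d1", "d1")))        # two relations: dropped
  extractor <- function(tokens) {
    hits <- tokens[tokens %in% c("d1", "d2")]
    if (!length(hits)) return(data.frame(type = character(0),
                                         surface = character(0)))
    data.frame(type = "Disease", surface = hits, stringsAsFactors = FALSE)
  }
  detector <- function(tokens)
    if (length(tokens) == 3) c("hasSymptom", "needsTest") else "hasSymptom"
  lab <- label_qa_test_data(docs, extractor, detector)
  expect_equal(lab$doc, 1L)
  expect_identical(lab$label, "d1")
})

test_that("QA metrics match a hand-computed confusion", {
  kb <- generate_kb(1, 0, rng_seed = 1)
  kb$entities <- list(Disease = c("d1", "d2"), Symptom = c("s1", "s2"),
                      Treatment = character(0), Test = character(0),
                      Result = character(0))
  kb$relations <- data.frame(subject = c("d1", "d2"),
                             relation = "hasSymptom",
                             object = c("s1", "s2"), stringsAsFactors = FALSE)
  kb$groundings <- numeric(0)
  emb <- train_token_embeddings(list(c("d1", "d2", "s1", "s2", "x")),
                                dim = 8, epochs = 2)
  params <- qa_init_params(8, 6, seed = 4)
  store <- build_memory(kb, emb, params, 6)
  system <- structure(list(params = params, store = store,
                           config = qa_config(encoder_dim = 6),
                           intent_rules = intent_rules(),
                           utility_net = NULL), class = "qa_system")
  docs <- lapply(1:10, function(i) {
    s <- if (i <= 6) "s1" else "s2"
    d <- if (i <= 6) "d1" else "d2"
    list(question_tokens = c("whatdisease", "has", "symptom", s, "?"),
         body_tokens = rep(d, 3))
  })
  labels <- data.frame(doc = 1:10, intent = "Disease",
                       label = c(rep("d1", 6), rep("d2", 4)),
                       stringsAsFactors = FALSE)
  ev <- evaluate_qa(system, docs, labels, n_boot = 10, rng_seed = 2)
  # entity-grounded attention makes all ten correct
  expect_equal(ev$p_at_1, 1); expect_equal(ev$f1, 1)
  # force known errors: flip four labels
  labels2 <- labels; labels2$label[1:4] <- "d2"
  ev2 <- evaluate_qa(system, docs, labels2, n_boot = 10, rng_seed = 2)
  expect_equal(ev2$p_at_1, 0.6)
  expect_equal(ev2$f1, 2 * (6 / 10) * (6 / 10) / (6 / 10 + 6 / 10))
  expect_true(is.finite(ev2$p_at_1_sd) && ev2$p_at_1_sd > 0)
})
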