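# bootstrapping: pattern enumeration, Eq-style scoring, matching, the loop

test_that("entity pattern extraction enumerates the 1-3 token context grid", {
  corpus <- sentence_corpus(
    c("t1", "t2", "t3", "seedX", "r1", "r2", "r3"))
  seeds <- seed_store(list(Disease = "seedX"))
  pats <- extract_entity_patterns(corpus, seeds, "Disease")
  # 3 lefts x 3 rights + 3 left-only + 3 right-only
  expect_length(pats, 15)
  keys <- vapply(pats, pattern_key, character(1))
  expect_equal(anyDuplicated(keys), 0)
  lens <- vapply(pats, function(p)
    c(length(p$left), length(p$right)), numeric(2))
  expect_true(all(lens <= 3))
  expect_true(all(colSums(lens) >= 1))
})

test_that("a seed at the sentence start yields no left-only candidates", {
  corpus <- sentence_corpus(c("seedX", "r1", "r2"))
  pats <- extract_entity_patterns(corpus, seed_store(list(Disease = "seedX")),
                                  "Disease")
  has_left <- vapply(pats, function(p) length(p$left) > 0, logical(1))
  expect_false(any(has_left))
  expect_true(any(!has_left))
})

test_that("the admission-for pattern arises from its classic sentence", {
  # "treatment admission for diabetes and cure with cytosine"
  corpus <- sentence_corpus(
    c("treatment", "admission", "for", "diabetes", "and", "cure", "with",
      "cytosine"))
  seeds <- seed_store(list(Disease = "diabetes", Treatment = "cytosine"))
  pats <- extract_entity_patterns(corpus, seeds, "Disease")
  keys <- vapply(pats, function(p)
    paste(paste(p$left, collapse = " "), "|",
          paste(p$right, collapse = " ")), character(1))
  expect_true("admission for | and" %in% keys)
  tre <- extract_entity_patterns(corpus, seeds, "Treatment")
  tre_keys <- vapply(tre, function(p)
    paste(paste(p$left, collapse = " "), "|",
          paste(p$right, collapse = " ")), character(1))
  expect_true("cure with | " %in% tre_keys)  # right context empty at end
})

test_that("match_pattern recovers the instance between its contexts", {
  corpus <- sentence_corpus(
    c("x", "admission", "for", "pneumonia", "and", "more"),
    c("admission", "for", "influenza", "virus", "and", "rest"))
  p <- new_entity_pattern(c("admission", "for"), "and", "Disease")
  hits <- match_pattern(p, corpus)
  expect_setequal(hits$string, c("pneumonia", "influenza virus"))
  # every returned string re-wrapped with the contexts is in the corpus
  for (i in seq_len(nrow(hits))) {
    toks <- corpus[[hits$sentence[i]]]$tokens
    wrapped <- c(p$left, entity_tokens(hits$string[i]), p$right)
    expect_gt(length(find_subseq(toks, wrapped)), 0)
  }
})

test_that("candidates never cross a sentence boundary", {
  corpus <- list(list(record_id = "r1",
                      tokens = c("admission", "for", ".", "pneumonia",
                                 "and", "x", ".")))
  p <- new_entity_pattern(c("admission", "for"), "and", "Disease")
  expect_equal(nrow(match_pattern(p, corpus)), 0)
})

test_that("support, confidence and reliability match exact counting", {
  # pattern extracts {A, B, C}; seeds = {A, B}, both Disease
  corpus <- sentence_corpus(
    c("l1", "l2", "A", "r1", "r2"),
    c("l1", "l2", "B", "r1", "r2"),
    c("l1", "l2", "C", "r1", "r2"))
  seeds <- seed_store(list(Disease = c("A", "B"), Symptom = character(0)))
  p <- new_entity_pattern(c("l1", "l2"), c("r1"), "Disease")
  cfg <- bootstrap_config(w = 0.5)
  sp <- score_pattern(p, corpus, seeds, cfg)
  expect_equal(sp$support, 2 / 3)
  expect_equal(unname(sp$confidence_by_type["Disease"]), 1)
  expect_equal(unname(sp$confidence_by_type["Symptom"]), 0)
  expect_equal(sp$score, 0.5 * 2 / 3 + 0.5 * 1)

  # saturation: all extracted are seeds of one type
  seeds2 <- seed_store(list(Disease = c("A", "B", "C")))
  sp2 <- score_pattern(p, corpus, seeds2, cfg)
  expect_equal(sp2$support, 1)
  expect_equal(sp2$score, 1)
  expect_true(sp2$validated)

  # the w weight moves the score exactly linearly
  for (w in c(0, 0.25, 1)) {
    spw <- score_pattern(p, corpus, seeds, bootstrap_config(w = w))
    expect_equal(spw$score, w * 2 / 3 + (1 - w) * 1)
  }
})

test_that("validation threshold accepts at 0.7 and not below", {
  cfg <- bootstrap_config()
  # 7 of 10 extracted are seeds, all one type: score = .5*.7 + .5*1 = 0.85
  # engineer exact boundary instead via w = 1 (score = support)
  mk <- function(n_seed, n_tot) {
    sents <- lapply(seq_len(n_tot), function(i)
      c("lf", paste0("w", i), "rt"))
    corpus <- do.call(sentence_corpus, sents)
    seeds <- seed_store(list(Disease = paste0("w", seq_len(n_seed))))
    score_pattern(new_entity_pattern("lf", "rt", "Disease"),
                  corpus, seeds, bootstrap_config(w = 1))
  }
  expect_true(mk(70, 100)$validated)    # support exactly 0.70
  expect_true(mk(71, 100)$validated)
  expect_false(mk(69, 100)$validated)
  expect_error(
    score_pattern(new_entity_pattern("nope", "never", "Disease"),
                  sentence_corpus(c("a", "b")), seed_store(list(Disease = "a")),
                  cfg), "undefined support")
})

test_that("scores equal a brute-force recount on a random corpus", {
  set.seed(21)
  kb <- tiny_kb(n_ent = 6, n_rel = 4)
  co <- tiny_corpus(kb, n_records = 15, seed = 8)
  seeds <- initial_seeds(kb, co)
  cfg <- bootstrap_config()
  pats <- extract_entity_patterns(co, seeds, "Disease")
  sents <- mining_sentences(co)
  for (p in pats[seq_len(min(12, length(pats)))]) {
    ext <- unique(match_pattern(p, sents, cfg)$string)
    if (!length(ext)) next
    sp <- score_pattern(p, sents, seeds, cfg)
    seed_all <- unlist(seeds$entity_seeds)
    expect_equal(sp$support, length(intersect(ext, seed_all)) / length(ext))
    inseed <- intersect(ext, seed_all)
    for (tp in names(seeds$entity_seeds)) {
      want <- if (!length(inseed)) 0 else
        length(intersect(inseed, seeds$entity_seeds[[tp]])) / length(inseed)
      expect_equal(unname(sp$confidence_by_type[tp]), want)
    }
    expect_equal(sp$score,
                 cfg$w * sp$support + (1 - cfg$w) * max(sp$confidence_by_type))
    expect_true(sp$support >= 0 && sp$support <= 1)
  }
})

test_that("bidirectional maximum matching groups dictionary words", {
  dict <- c("leukocyte high count", "heart disease")
  toks <- c("a", "leukocyte", "high", "count", "b", "heart", "disease")
  seg <- bimm_segment(toks, dict)
  expect_identical(seg, c("a", "leukocyte high count", "b", "heart disease"))
  expect_identical(bimm_segment(c("x", "y"), dict), c("x", "y"))
})

test_that("relation context substrings follow the k(k+1)/2 law", {
  # one seed pair with a 3-word filtered context, repeated so the words
  # clear the document-frequency floor
  sents <- rep(list(c("D1", "cure", "now", "with", "T1")), 3)
  corpus <- do.call(sentence_corpus, sents)
  seeds <- seed_store(
    list(Disease = "D1", Treatment = "T1"),
    data.frame(subject = "D1", relation = "needsTreatment", object = "T1",
               stringsAsFactors = FALSE))
  cfg <- bootstrap_config(df_floor = 1)
  pats <- extract_relation_patterns(corpus, seeds, cfg)
  expect_length(pats, 3 * 4 / 2)  # substrings of (cure, now, with)
  # adjacent entities: degenerate empty pattern
  corpus2 <- sentence_corpus(c("D1", "T1"))
  pats2 <- extract_relation_patterns(corpus2, seeds, cfg)
  expect_length(pats2, 1)
  expect_true(pats2[[1]]$degenerate)
  expect_length(pats2[[1]]$context_words, 0)
})

test_that("candidate validation triages via dictionary, search and human", {
  kb <- tiny_kb()
  oracle <- ledger_oracle(kb)
  dis <- kb$entities$Disease
  cfg <- bootstrap_config(search_K = 10)
  cand <- data.frame(
    string = c(dis[1], dis[2], "junk1", "junk2"),
    type = "Disease",
    band = c("valid", "lowband", "valid", "lowband"),
    stringsAsFactors = FALSE)
  res <- validate_candidates(cand, oracle, cfg)
  expect_setequal(res$accepted$string, dis[1:2])
  expect_identical(res$accepted$via[res$accepted$string == dis[1]],
                   "dictionary")
  # junk from a lowband pattern: Score_c = 0/10 -> rejected outright
  expect_true("junk2" %in% res$rejected$string)
  expect_equal(res$rejected$score_c[res$rejected$string == "junk2"], 0)
  # junk from a valid pattern goes to the human judge, who refuses
  expect_true("junk1" %in% res$rejected$string)

  # Score_c = |H| / K arithmetic, including the saturation case
  half_oracle <- ledger_oracle(kb)
  half_oracle$search_hits <- function(string, type, K) 3L
  half_oracle$judge_entity <- function(string, type) NA
  res2 <- validate_candidates(
    data.frame(string = "maybe", type = "Disease", band = "lowband",
               stringsAsFactors = FALSE), half_oracle, cfg)
  expect_equal(res2$queued$score_c, 0.3)   # 3/10, at threshold: queued
  full_oracle <- ledger_oracle(kb)
  full_oracle$search_hits <- function(string, type, K) K
  full_oracle$judge_entity <- function(string, type) NA
  res3 <- validate_candidates(
    data.frame(string = "maybe", type = "Disease", band = "lowband",
               stringsAsFactors = FALSE), full_oracle, cfg)
  expect_equal(res3$queued$score_c, 1.0)

  # no oracle: everything queued, nothing silently accepted
  res4 <- validate_candidates(cand, NULL, cfg)
  expect_equal(nrow(res4$accepted), 0)
  expect_equal(nrow(res4$queued), nrow(cand))
})

test_that("the bootstrap loop terminates, grows monotonically and recovers", {
  kb <- tiny_kb(n_ent = 8, n_rel = 6)
  co <- tiny_corpus(kb, n_records = 40, seed = 4)
  seeds <- initial_seeds(kb, co)
  res <- run_bootstrap(co, seeds, bootstrap_config(), ledger_oracle(kb))
  tr <- res$trace
  # monotone non-decreasing seed counts, terminating fixed point
  for (col in c(entity_types(), "relations"))
    expect_true(all(diff(tr[[col]]) >= 0))
  expect_equal(tr$new_seeds[nrow(tr)], 0)
  expect_false(res$truncated)
  # precision 1: every accepted instance is a planted one
  mined <- all_entity_seeds(res$seeds)
  expect_true(all(mined %in% unlist(kb$entities)))
  got_rel <- tuple_key(res$seeds$relation_seeds$subject,
                       res$seeds$relation_seeds$relation,
                       res$seeds$relation_seeds$object)
  expect_true(all(got_rel %in% tuple_key(kb$relations$subject,
                                         kb$relations$relation,
                                         kb$relations$object)))
  # fixed point: feeding the final seeds back adds nothing
  res2 <- run_bootstrap(co, res$seeds, bootstrap_config(), ledger_oracle(kb))
  expect_equal(nrow(res2$trace), 1)
  expect_equal(res2$trace$new_seeds[1], 0)
  # annotations agree with the generator ledger on spans
  ann <- res$annotated
  gold <- co$ledger$spans
  for (i in seq_along(ann)) {
    g <- gold[gold$record_id == ann[[i]]$record_id, ]
    found <- paste(ann[[i]]$spans$start, ann[[i]]$spans$end,
                   ann[[i]]$spans$type)
    planted <- paste(g$start, g$end, g$type)
    expect_true(all(found %in% planted))
  }
})

test_that("max_iterations truncates a loop that would continue", {
  kb <- tiny_kb(n_ent = 8, n_rel = 6)
  co <- tiny_corpus(kb, n_records = 40, seed = 4)
  seeds <- initial_seeds(kb, co)
  res <- run_bootstrap(co, seeds, bootstrap_config(max_iterations = 1),
                       ledger_oracle(kb))
  expect_equal(nrow(res$trace), 1)
  expect_true(res$truncated)
})
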