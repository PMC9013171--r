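# entity alignment, consistency analysis, full fusion

# shared noisy-study fixture for the ledger-based tests below
fus_kb <- generate_kb(10, 5, rng_seed = 3, max_degree = 2)
fus_co <- render_records(fus_kb, 120, noise_rate = 0.15, rng_seed = 9)
fus_emb <- train_token_embeddings(fus_co, dim = 24, window = 5, epochs = 5,
                                  rng_seed = 4)

test_that("cosine similarity: identity, orthogonality, hand fixture", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_equal(cosine_similarity(c(1, 2), c(2, 4)), 1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("alignment triages by the 0.7 / 0.3 thresholds", {
  # engineered vectors with known cosines
  vecs <- list(
    fever     = c(1, 0, 0),
    heat      = c(0.97, sqrt(1 - 0.97^2), 0),          # cos = 0.97
    warmish   = c(0.5, sqrt(1 - 0.25), 0),             # cos = 0.50
    unrelated = c(0, 0, 1))                            # cos = 0
  ents <- data.frame(type = "Symptom",
                     surface = names(vecs),
                     count = c(10, 3, 2, 5), stringsAsFactors = FALSE)
  res <- align_entities(ents, stub_vectorizer(vecs), fusion_config())
  dec <- res$decisions
  get <- function(a, b) dec$action[(dec$a == a & dec$b == b) |
                                   (dec$a == b & dec$b == a)]
  expect_identical(get("fever", "heat"), "auto-merge")
  expect_identical(get("fever", "warmish"), "human-queue")
  expect_identical(get("fever", "unrelated"), "keep-separate")
  # canonical name: the most mentioned surface form
  cl <- res$clusters
  expect_identical(unique(cl$canonical[cl$surface %in% c("fever", "heat")]),
                   "fever")
  # boundary semantics: accepted at exactly 0.7 and 0.3
  v2 <- list(a = c(1, 0), b = c(0.7, sqrt(1 - 0.49)),
             c = c(0.3, sqrt(1 - 0.09)))
  e2 <- data.frame(type = "Disease", surface = c("a", "b", "c"),
                   count = 1, stringsAsFactors = FALSE)
  d2 <- align_entities(e2, stub_vectorizer(v2), fusion_config())$decisions
  expect_identical(d2$action[d2$a == "a" & d2$b == "b"], "auto-merge")
  expect_identical(d2$action[d2$a == "a" & d2$b == "c"], "human-queue")
})

test_that("alignment closes transitively and ignores input order", {
  vecs <- list(a = c(1, 0), b = c(0.9, sqrt(1 - 0.81)),
               c = c(0.75, sqrt(1 - 0.5625)))
  # a~b and b~c auto-merge; a~c lands in the queue band but the chain
  # still pulls all three into one cluster
  ents <- data.frame(type = "Disease", surface = c("a", "b", "c"),
                     count = c(5, 1, 1), stringsAsFactors = FALSE)
  r1 <- align_entities(ents, stub_vectorizer(vecs), fusion_config())
  expect_identical(unique(r1$clusters$canonical), "a")
  shuffled <- ents[c(3, 1, 2), ]
  r2 <- align_entities(shuffled, stub_vectorizer(vecs), fusion_config())
  expect_identical(r1$clusters, r2$clusters)
})

test_that("alias clusters on synthetic noise match the generator ledger", {
  kb <- fus_kb; co <- fus_co; emb <- fus_emb
  sp <- co$ledger$spans
  surf <- unique(sp[, c("type", "surface")])
  counts <- table(paste(sp$type, sp$surface))
  ents <- data.frame(type = surf$type, surface = surf$surface,
                     count = as.numeric(counts[paste(surf$type, surf$surface)]),
                     stringsAsFactors = FALSE)
  oracle <- ledger_oracle(kb, co$ledger$aliases)
  res <- align_entities(ents, alignment_vectorizer(emb), fusion_config(),
                        oracle)
  cl <- res$clusters
  canonical_of <- function(s) {
    hit <- match(s, co$ledger$aliases$variant)
    if (!is.na(hit)) co$ledger$aliases$canonical[hit] else s
  }
  for (i in seq_len(nrow(cl)))
    expect_identical(cl$canonical[i], canonical_of(cl$surface[i]))
})

test_that("relation confidence reproduces the worked arithmetic", {
  cfg <- fusion_config()
  tuples <- data.frame(
    subject = c("Respiratory infection", "Respiratory infection", "flu"),
    relation = c("needsTreatment", "needsTreatment", "hasSymptom"),
    object = c("Pediatrics Ibuprofen Suppositories", "antibiotic treatment",
               "fever"),
    count = c(74, 269, 50), stringsAsFactors = FALSE)
  counts <- c("Respiratory infection" = 379, flu = 50)
  res <- relation_consistency(tuples, counts, cfg)
  lg <- res$log
  expect_equal(lg$confidence[1], 74 / 379)
  expect_equal(round(lg$confidence[1], 3), 0.195)
  expect_identical(lg$decision[1], "drop")
  expect_equal(round(lg$confidence[2], 2), 0.71)
  expect_identical(lg$decision[2], "retain")
  # saturation: tuple frequency equals entity frequency
  expect_equal(lg$confidence[3], 1)
  expect_identical(lg$decision[3], "retain")
  expect_equal(nrow(res$retained), 2)
  # boundary values accepted at 0.7; queued at 0.3
  t2 <- data.frame(subject = c("s", "s"), relation = "hasSymptom",
                   object = c("x", "y"), count = c(70, 30),
                   stringsAsFactors = FALSE)
  lg2 <- relation_consistency(t2, c(s = 100), cfg)$log
  expect_identical(lg2$decision, c("retain", "human-queue"))
  expect_error(relation_consistency(t2, c(s = 0), cfg), "integrity")
})

test_that("conflicting relations keep the higher-confidence tuple", {
  tuples <- data.frame(
    subject = c("d", "d"), relation = c("hasSymptom", "hasTestResult"),
    object = c("x", "x"), count = c(90, 80), stringsAsFactors = FALSE)
  res <- relation_consistency(tuples, c(d = 100), fusion_config())
  expect_equal(nrow(res$retained), 1)
  expect_identical(res$retained$relation, "hasSymptom")
  expect_true("conflict-drop" %in% res$log$decision)
})

test_that("fusion recovers the planted KB under alias and spurious noise", {
  kb <- fus_kb; co <- fus_co; emb <- fus_emb
  oracle <- ledger_oracle(kb, co$ledger$aliases)
  # raw extractions from the ledger: alias surface forms, true counts,
  # plus ~10% spurious tuples at low counts
  sp <- co$ledger$spans
  key <- paste(sp$type, sp$surface, sep = "\t")
  tb <- table(key)
  parts <- do.call(rbind, strsplit(names(tb), "\t", fixed = TRUE))
  entities <- data.frame(type = parts[, 1], surface = parts[, 2],
                         count = as.numeric(tb), stringsAsFactors = FALSE)
  tl <- co$ledger$tuples
  tk <- tuple_key(tl$subject, tl$relation, tl$object)
  ttb <- table(tk)
  tparts <- do.call(rbind, strsplit(names(ttb), "\t", fixed = TRUE))
  tuples <- data.frame(subject = tparts[, 1], relation = tparts[, 2],
                       object = tparts[, 3], count = as.numeric(ttb),
                       stringsAsFactors = FALSE)
  set.seed(2)
  n_spur <- ceiling(0.1 * nrow(tuples))
  schema <- relation_schema()
  spur <- do.call(rbind, lapply(seq_len(n_spur), function(i) {
    srow <- schema[sample.int(5, 1), ]
    data.frame(subject = sample(kb$entities[[srow$subject_type]], 1),
               relation = srow$relation,
               object = sample(kb$entities[[srow$object_type]], 1),
               count = 1L, stringsAsFactors = FALSE)
  }))
  spur <- spur[!tuple_key(spur$subject, spur$relation, spur$object) %in% tk, ,
               drop = FALSE]
  fused <- fuse(list(entities = entities,
                     tuples = rbind(tuples, spur)),
                alignment_vectorizer(emb), fusion_config(), oracle)
  got <- tuple_key(fused$tuples$subject, fused$tuples$relation,
                   fused$tuples$object)
  want <- tuple_key(kb$relations$subject, kb$relations$relation,
                    kb$relations$object)
  expect_setequal(got, want)
  # report monotonicity: fusion only shrinks
  expect_lte(fused$report$entities_after, fused$report$entities_before)
  expect_lte(fused$report$relations_after, fused$report$relations_before)
  # canonical entities: no surviving same-type pair above the merge bar
  al <- fused$alignment_log
  merged <- al[al$action %in% c("auto-merge", "human-merge"), ]
  for (i in seq_len(nrow(merged)))
    expect_false(merged$a[i] %in% fused$entities$canonical &&
                 merged$b[i] %in% fused$entities$canonical)
})

test_that("fusion of an empty extraction set yields an empty graph", {
  g <- fuse(list(entities = NULL, tuples = NULL),
            stub_vectorizer(list()), fusion_config())
  expect_equal(nrow(g$entities), 0)
  expect_equal(nrow(g$tuples), 0)
  expect_equal(g$report$entities_before, 0)
})

test_that("fusion never invents tuples", {
  vecs <- list(a = c(1, 0), b = c(0, 1), x = c(0.5, 0.5))
  ents <- data.frame(type = c("Disease", "Symptom", "Symptom"),
                     surface = c("a", "b", "x"), count = c(10, 10, 10),
                     stringsAsFactors = FALSE)
  tup <- data.frame(subject = "a", relation = "hasSymptom", object = "b",
                    count = 10, stringsAsFactors = FALSE)
  g <- fuse(list(entities = ents, tuples = tup), stub_vectorizer(vecs),
            fusion_config())
  expect_lte(nrow(g$tuples), 1)
  got <- tuple_key(g$tuples$subject, g$tuples$relation, g$tuples$object)
  expect_true(all(got %in% tuple_key(tup$subject, tup$relation, tup$object)))
})
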