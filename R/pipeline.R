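# Pipeline orchestration, configuration and reproducibility harness.

#' Pipeline configuration
#'
#' Per-stage configuration blocks plus a global seed. Defaults carry the
#' published values where one exists (0.7/0.3 triage thresholds, entity
#' model hyperparameters, relation window 5 / dimension 100, eight-token
#' bridge patterns); the `small` preset scales the neural dimensions and
#' corpus sizes down to what a laptop-class run needs.
#'
#' @param seed global RNG seed; every stage derives its stream from it.
#' @param preset `"paper"` (published dimensions) or `"small"` (scaled-down
#'   study sizes used throughout the bundled experiments).
#' @param ... named overrides for individual blocks (`synth`, `bootstrap`,
#'   `embeddings`, `tagger`, `relation`, `fusion`, `qa`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, preset = c("small", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    synth = list(n_entities = 12L, n_relations = 5L, max_degree = 2L,
                 n_records = 150L, mean_statements = 3.3, noise_rate = 0,
                 n_qa = 250L),
    bootstrap = bootstrap_config(),
    embeddings = list(dim = 24L, window = 5L, epochs = 5L),
    tagger = if (preset == "small")
      tagger_config(embedding_dim = 16L, hidden = 16L, crf_input_dim = 16L,
                    epochs = 6L) else tagger_config(),
    relation = if (preset == "small")
      relation_cnn_config(window = 5L, word_dim = 24L, kernels = 8L,
                          fc = 32L, seq_len = 14L, epochs = 6L,
                          lr = 0.03) else relation_cnn_config(),
    fusion = fusion_config(),
    qa = if (preset == "small") qa_config(encoder_dim = 16L, epochs = 4L)
      else qa_config())
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    blk <- dots[[nm]]
    if (is.list(blk) && is.list(cfg[[nm]])) {
      unknown <- setdiff(names(blk), names(cfg[[nm]]))
      if (length(unknown))
        stop("unknown key(s) in block '", nm, "': ",
             paste(unknown, collapse = ", "))
      cfg[[nm]][names(blk)] <- blk
    } else cfg[[nm]] <- blk
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config, file = f)
  unname(tools::md5sum(f))
}

#' Run one pipeline stage with a manifest
#'
#' Executes a stage function and wraps its result with a reproducibility
#' manifest: stage name, config digest, seed, input/output file digests and
#' timestamps. Deterministic stages yield identical digests for identical
#' (config, seed, inputs).
#'
#' @param stage stage name (for the manifest).
#' @param fn function of no arguments performing the stage.
#' @param config the configuration governing the stage.
#' @param seed the seed in force.
#' @param inputs,outputs optional file paths to digest.
#' @param deterministic whether the stage is deterministic given the seed.
#' @return list with `result` and `manifest` (class `run_manifest`).
#' @export
run_stage <- function(stage, fn, config, seed, inputs = character(0),
                      outputs = character(0), deterministic = TRUE) {
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("missing input for stage '", stage, "': ",
         paste(missing_in, collapse = ", "))
  t0 <- Sys.time()
  result <- fn()
  manifest <- structure(list(
    stage = stage,
    config_digest = config_digest(config),
    seed = seed,
    deterministic = deterministic,
    input_digests = if (length(inputs)) tools::md5sum(inputs) else NULL,
    output_digests = if (length(outputs)) tools::md5sum(outputs) else NULL,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    version = as.character(utils::packageVersion("medkgqa"))),
    class = "run_manifest")
  list(result = result, manifest = manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$stage, "seed", x$seed, "config",
      substr(x$config_digest, 1, 8),
      if (x$deterministic) "(deterministic)" else "(stochastic)", "\n")
  invisible(x)
}

#' Pick initial bootstrap seeds from the corpus
#'
#' Emulates an annotator reading the text: per entity type the most
#' frequently mentioned canonical entities, and per relation the most
#' frequently expressed tuples, become the manual seed set.
#'
#' @param kb the ground-truth KB (for types).
#' @param corpus a `synth_corpus` with its ledger.
#' @param n_entity_seeds seeds per entity type.
#' @param n_relation_seeds seed tuples per relation type.
#' @return a `seed_store`.
#' @export
initial_seeds <- function(kb, corpus, n_entity_seeds = 3L,
                          n_relation_seeds = 2L) {
  sp <- corpus$ledger$spans
  ent_seeds <- lapply(stats::setNames(nm = entity_types()), function(tp) {
    tb <- sort(table(sp$canonical[sp$type == tp]), decreasing = TRUE)
    utils::head(names(tb), n_entity_seeds)
  })
  tl <- corpus$ledger$tuples
  tl$key <- tuple_key(tl$subject, tl$relation, tl$object)
  rel_seeds <- do.call(rbind, lapply(split(tl, tl$relation), function(d) {
    tb <- sort(table(d$key), decreasing = TRUE)
    picked <- utils::head(names(tb), n_relation_seeds)
    unique(d[d$key %in% picked, c("subject", "relation", "object")])
  }))
  rownames(rel_seeds) <- NULL
  seed_store(ent_seeds, rel_seeds)
}

# ---- model-driven knowledge extraction -------------------------------------

#' Extract a raw knowledge base from records with trained models
#'
#' Runs the entity tagger over every record, classifies the relation of
#' each in-sentence entity pair with the CNN (type-checked against the
#' schema, NONE-thresholded), and returns mention/tuple counts ready for
#' [fuse()].
#'
#' @param records list of records (tokens).
#' @param tagger a `tagger_model`.
#' @param cnn a `relation_cnn`.
#' @param pvectors optional `paragraph_vectors` for paragraph context.
#' @return list with `entities` (type, surface, count) and `tuples`
#'   (subject, relation, object, count).
#' @export
extract_knowledge <- function(records, tagger, cnn, pvectors = NULL) {
  schema <- relation_schema()
  ent_counts <- new.env(parent = emptyenv())
  tup_counts <- new.env(parent = emptyenv())
  bump <- function(envir, key) envir[[key]] <- (envir[[key]] %||% 0L) + 1L
  for (r in records) {
    toks <- if (is.list(r)) r$tokens else r
    rid <- if (is.list(r)) r$record_id %||% NA_character_ else NA_character_
    spans <- extract_entities(toks, tagger)
    if (!nrow(spans)) next
    for (i in seq_len(nrow(spans)))
      bump(ent_counts, paste(spans$type[i], spans$surface[i], sep = "\t"))
    pvec <- if (!is.null(pvectors) && !is.na(rid) &&
                rid %in% rownames(pvectors$vectors))
      pvectors$vectors[rid, ] else NULL
    for (sent in sentence_spans(toks)) {
      lo <- sent[1] - 1L; hi <- sent[length(sent)]
      here <- spans[spans$start >= lo & spans$end <= hi, , drop = FALSE]
      if (nrow(here) < 2) next
      here <- here[order(here$start), ]
      for (a in seq_len(nrow(here) - 1L)) for (b in (a + 1L):nrow(here)) {
        legal <- schema$relation[schema$subject_type == here$type[a] &
                                 schema$object_type == here$type[b]]
        if (!length(legal)) next
        stoks <- toks[sent]
        s0 <- here$start[a] - lo; s1 <- here$end[a] - lo
        o0 <- here$start[b] - lo; o1 <- here$end[b] - lo
        if (o0 < s1) next
        seqq <- c(if (s0 > 0) stoks[1:s0], ENT_SLOT,
                  if (o0 > s1) stoks[(s1 + 1L):o0], ENT_SLOT,
                  if (o1 < length(stoks)) stoks[(o1 + 1L):length(stoks)])
        res <- classify_relation(seqq, cnn, pvec, allow_none = TRUE)
        if (res$label == "NONE" || !(res$label %in% legal)) next
        bump(tup_counts,
             paste(here$surface[a], res$label, here$surface[b], sep = "\t"))
      }
    }
  }
  parse_env <- function(envir, cols) {
    keys <- ls(envir)
    if (!length(keys))
      return(stats::setNames(
        data.frame(matrix(character(0), 0, length(cols)), count = integer(0),
                   stringsAsFactors = FALSE), c(cols, "count")))
    parts <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    df <- data.frame(parts, count = vapply(keys, function(k) envir[[k]],
                                           integer(1)),
                     stringsAsFactors = FALSE, row.names = NULL)
    names(df) <- c(cols, "count")
    df
  }
  list(entities = parse_env(ent_counts, c("type", "surface")),
       tuples = parse_env(tup_counts, c("subject", "relation", "object")))
}

#' Run the full pipeline on synthetic data
#'
#' Generates a ground-truth KB and corpus, bootstraps annotations with the
#' ledger oracle, trains the tagger and the relation CNN on the bootstrap
#' annotations, extracts a raw KB from the corpus with the trained models,
#' fuses it, trains the memory-network QA model on synthetic QA pairs over
#' the fused graph, labels a held-out test set by rule and evaluates P@1.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list with every stage artifact and a `metrics` list
#'   (bootstrap recall/precision, tagger span F1, relation macro F1,
#'   fusion exactness, QA P@1/F1).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  seed <- config$seed
  sy <- config$synth
  say("synth kb=", sy$n_entities, "x", sy$n_relations,
      " records=", sy$n_records, " noise=", sy$noise_rate)
  kb <- generate_kb(sy$n_entities, sy$n_relations, seed,
                    max_degree = sy$max_degree)
  corpus <- render_records(kb, sy$n_records, sy$mean_statements,
                           sy$noise_rate, seed + 1L)
  oracle <- ledger_oracle(kb, corpus$ledger$aliases)
  seeds <- initial_seeds(kb, corpus, n_entity_seeds = 3L,
                         n_relation_seeds = 2L)
  say("bootstrap")
  boot <- run_bootstrap(corpus, seeds, config$bootstrap, oracle)
  planted <- unique(corpus$ledger$spans$canonical)
  canon_of <- function(x) {
    al <- corpus$ledger$aliases
    hit <- match(x, al$variant)
    ifelse(is.na(hit), x, al$canonical[hit])
  }
  mined <- unique(canon_of(all_entity_seeds(boot$seeds)))
  kb_keys <- tuple_key(kb$relations$subject, kb$relations$relation,
                       kb$relations$object)
  mined_rel <- unique(tuple_key(canon_of(boot$seeds$relation_seeds$subject),
                                boot$seeds$relation_seeds$relation,
                                canon_of(boot$seeds$relation_seeds$object)))
  say("embeddings")
  emb <- train_token_embeddings(corpus, dim = config$embeddings$dim,
                                window = config$embeddings$window,
                                epochs = config$embeddings$epochs,
                                rng_seed = seed + 2L)
  say("tagger")
  tagger <- train_tagger(boot$annotated, config$tagger, seed + 3L,
                         pattern_library = boot$patterns)
  say("paragraph vectors + relation cnn")
  pvec <- train_paragraph_vectors(corpus, emb, epochs = 2L,
                                  rng_seed = seed + 4L)
  rex <- relation_examples_from_records(boot$annotated)
  cnn <- train_relation_cnn(rex, pvec, config$relation, seed + 5L)
  say("extraction + fusion")
  extractions <- extract_knowledge(corpus$records, tagger, cnn, pvec)
  fused <- fuse(extractions, alignment_vectorizer(emb), config$fusion,
                oracle)
  say("qa")
  qa <- render_qa_pairs(kb, sy$n_qa, seed + 6L)
  n_test <- max(10L, round(0.2 * length(qa)))
  qa_test <- qa[seq_len(n_test)]
  qa_train <- qa[(n_test + 1L):length(qa)]
  qsys <- train_qa(qa_train, fused, emb, config$qa, seed + 7L)
  entity_extractor <- function(tokens) extract_entities(tokens, tagger)
  relation_detector <- function(tokens) {
    ex <- extract_knowledge(list(list(tokens = tokens)), tagger, cnn, NULL)
    unique(ex$tuples$relation)
  }
  labels <- label_qa_test_data(qa_test, entity_extractor, relation_detector)
  evalr <- if (nrow(labels))
    evaluate_qa(qsys, qa_test, labels, rng_seed = seed + 8L) else NULL
  # tagger/relation metrics on freshly rendered held-out records
  say("held-out evaluation")
  fresh <- render_records(kb, 30L, sy$mean_statements, sy$noise_rate,
                          seed + 9L)
  gold_eval <- local({
    pk <- character(0); gk <- character(0)
    for (i in seq_along(fresh$records)) {
      pred <- extract_entities(fresh$records[[i]]$tokens, tagger)
      gold <- fresh$records[[i]]$gold_spans
      pk <- c(pk, paste(i, pred$start, pred$end, pred$type))
      gk <- c(gk, paste(i, gold$start, gold$end, gold$type))
    }
    tp <- length(intersect(pk, gk))
    prec <- if (length(pk)) tp / length(pk) else 0
    rec <- if (length(gk)) tp / length(gk) else 0
    c(precision = prec, recall = rec,
      f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  })
  rel_eval <- local({
    exs <- relation_examples_from_records(fresh$records)
    if (!length(exs)) return(NA_real_)
    pred <- vapply(exs, function(e)
      classify_relation(e$tokens, cnn)$label, character(1))
    macro_f1(pred, vapply(exs, `[[`, "", "label"))
  })
  fused_keys <- tuple_key(fused$tuples$subject, fused$tuples$relation,
                          fused$tuples$object)
  metrics <- list(
    bootstrap_entity_recall = mean(planted %in% mined),
    bootstrap_entity_precision = mean(mined %in% unlist(kb$entities)),
    bootstrap_relation_recall = mean(kb_keys %in% mined_rel),
    bootstrap_relation_precision = mean(mined_rel %in% kb_keys),
    tagger_span_f1 = unname(gold_eval["f1"]),
    relation_macro_f1 = rel_eval,
    fusion_tuple_recall = mean(kb_keys %in% fused_keys),
    fusion_tuple_precision = if (length(fused_keys))
      mean(fused_keys %in% kb_keys) else NA_real_,
    qa_p_at_1 = if (!is.null(evalr)) evalr$p_at_1 else NA_real_,
    qa_f1 = if (!is.null(evalr)) evalr$f1 else NA_real_,
    qa_n = if (!is.null(evalr)) evalr$n else 0L)
  list(kb = kb, corpus = corpus, heldout = fresh, bootstrap = boot,
       embeddings = emb,
       tagger = tagger, pvectors = pvec, cnn = cnn,
       extractions = extractions, fused = fused, qa_pairs = qa,
       qa_system = qsys, labels = labels, evaluation = evalr,
       metrics = metrics, config = config)
}
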