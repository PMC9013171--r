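# candidate validation oracles and the bootstrap loop

#' Validation oracles
#'
#' An oracle bundles the two external checks the miner consults: a dictionary
#' lookup (web-encyclopedia stand-in) and a top-K retrieval returning a hit
#' count |H| for the search-validation score `Score_c = |H| / K`, plus a
#' human-judgment channel. `ledger_oracle()` answers from a ground-truth KB
#' (the synthetic generator's ledger); `static_dictionary_oracle()` answers
#' from fixed tables and leaves human judgments undecided (`NA`).
#'
#' @param kb a `medkg_kb` used as ground truth.
#' @param aliases optional (canonical, variant) data.frame from the
#'   generator's ledger; enables the alignment judgment channel and makes
#'   the entity/relation channels accept logged variant surface forms.
#' @return object of class `validation_oracle`: list of functions
#'   `lookup_entity(string, type)`, `search_hits(string, type, K)`,
#'   `judge_entity(string, type)`, `lookup_relation(subject, relation,
#'   object)`, `search_hits_relation(subject, relation, object, K)`,
#'   `judge_relation(subject, relation, object)`,
#'   `judge_alignment(a, b, type)`.
#' @export
ledger_oracle <- function(kb, aliases = NULL) {
  stopifnot(inherits(kb, "medkg_kb"))
  rel_keys <- tuple_key(kb$relations$subject, kb$relations$relation,
                        kb$relations$object)
  canonical_of <- function(string) {
    if (!is.null(aliases) && nrow(aliases)) {
      hit <- match(string, aliases$variant)
      if (!is.na(hit)) return(aliases$canonical[hit])
    }
    string
  }
  has_ent <- function(string, type) canonical_of(string) %in% kb$entities[[type]]
  has_rel <- function(s, r, o)
    tuple_key(canonical_of(s), r, canonical_of(o)) %in% rel_keys
  structure(list(
    lookup_entity = has_ent,
    search_hits = function(string, type, K) if (has_ent(string, type)) K else 0L,
    judge_entity = has_ent,
    lookup_relation = has_rel,
    search_hits_relation = function(s, r, o, K) if (has_rel(s, r, o)) K else 0L,
    judge_relation = has_rel,
    judge_alignment = function(a, b, type)
      identical(canonical_of(a), canonical_of(b))
  ), class = "validation_oracle")
}

#' @rdname ledger_oracle
#' @param entity_frame data.frame with columns `type`, `entity`.
#' @param relations data.frame with columns `subject`, `relation`, `object`.
#' @export
static_dictionary_oracle <- function(entity_frame = NULL, relations = NULL) {
  ef <- entity_frame %||% data.frame(type = character(0),
                                     entity = character(0))
  rl <- relations %||% data.frame(subject = character(0),
                                  relation = character(0),
                                  object = character(0))
  rel_keys <- tuple_key(rl$subject, rl$relation, rl$object)
  has_ent <- function(string, type)
    any(ef$entity == string & ef$type == type)
  has_rel <- function(s, r, o) tuple_key(s, r, o) %in% rel_keys
  structure(list(
    lookup_entity = has_ent,
    search_hits = function(string, type, K) if (has_ent(string, type)) K else 0L,
    judge_entity = function(string, type) NA,
    lookup_relation = has_rel,
    search_hits_relation = function(s, r, o, K) if (has_rel(s, r, o)) K else 0L,
    judge_relation = function(s, r, o) NA
  ), class = "validation_oracle")
}

#' Validate candidate entity strings
#'
#' Dictionary hits are accepted outright. Other candidates from validated
#' patterns go to the human channel. Candidates from low-band patterns are
#' scored by search validation (`Score_c = |H| / K`); those at or above the
#' low-band threshold go to the human channel, the rest are rejected. With no
#' oracle every candidate is queued, never silently accepted.
#'
#' @param candidates data.frame with columns `string`, `type`, `band`
#'   (`"valid"` or `"lowband"`).
#' @param oracle a `validation_oracle` or NULL.
#' @param config a `bootstrap_config`.
#' @return list with data.frames `accepted` (with `via` provenance),
#'   `queued`, `rejected` (with `score_c` where computed).
#' @export
validate_candidates <- function(candidates, oracle,
                                config = bootstrap_config()) {
  empty <- function() data.frame(string = character(0), type = character(0),
                                 band = character(0), score_c = numeric(0),
                                 via = character(0), stringsAsFactors = FALSE)
  if (!nrow(candidates))
    return(list(accepted = empty(), queued = empty(), rejected = empty()))
  candidates$score_c <- NA_real_
  candidates$via <- NA_character_
  if (is.null(oracle)) {
    candidates$via <- "no-oracle"
    return(list(accepted = empty(), queued = candidates, rejected = empty()))
  }
  acc <- list(); que <- list(); rej <- list()
  for (i in seq_len(nrow(candidates))) {
    row <- candidates[i, ]
    if (isTRUE(oracle$lookup_entity(row$string, row$type))) {
      row$via <- "dictionary"
      acc[[length(acc) + 1L]] <- row
      next
    }
    if (row$band == "lowband") {
      H <- oracle$search_hits(row$string, row$type, config$search_K)
      row$score_c <- H / config$search_K
      if (row$score_c < config$score_threshold_lowband) {
        row$via <- "search-reject"
        rej[[length(rej) + 1L]] <- row
        next
      }
    }
    j <- oracle$judge_entity(row$string, row$type)
    if (isTRUE(j)) {
      row$via <- "human"
      acc[[length(acc) + 1L]] <- row
    } else if (identical(j, FALSE)) {
      row$via <- "human-reject"
      rej[[length(rej) + 1L]] <- row
    } else {
      row$via <- "queued-human"
      que[[length(que) + 1L]] <- row
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else empty()
  list(accepted = bind(acc), queued = bind(que), rejected = bind(rej))
}

# same triage for relation tuples
validate_relation_candidates <- function(candidates, oracle, config) {
  empty <- function() data.frame(subject = character(0),
                                 relation = character(0),
                                 object = character(0), band = character(0),
                                 score_c = numeric(0), via = character(0),
                                 stringsAsFactors = FALSE)
  if (!nrow(candidates))
    return(list(accepted = empty(), queued = empty(), rejected = empty()))
  candidates$score_c <- NA_real_
  candidates$via <- NA_character_
  if (is.null(oracle))
    return(list(accepted = empty(), queued = transform(candidates, via = "no-oracle"),
                rejected = empty()))
  acc <- list(); que <- list(); rej <- list()
  for (i in seq_len(nrow(candidates))) {
    row <- candidates[i, ]
    if (isTRUE(oracle$lookup_relation(row$subject, row$relation, row$object))) {
      row$via <- "dictionary"; acc[[length(acc) + 1L]] <- row; next
    }
    if (row$band == "lowband") {
      H <- oracle$search_hits_relation(row$subject, row$relation, row$object,
                                       config$search_K)
      row$score_c <- H / config$search_K
      if (row$score_c < config$score_threshold_lowband) {
        row$via <- "search-reject"; rej[[length(rej) + 1L]] <- row; next
      }
    }
    j <- oracle$judge_relation(row$subject, row$relation, row$object)
    if (isTRUE(j)) { row$via <- "human"; acc[[length(acc) + 1L]] <- row }
    else if (identical(j, FALSE)) {
      row$via <- "human-reject"; rej[[length(rej) + 1L]] <- row
    } else { row$via <- "queued-human"; que[[length(que) + 1L]] <- row }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else empty()
  list(accepted = bind(acc), queued = bind(que), rejected = bind(rej))
}

#' Run the bootstrap mining loop
#'
#' Alternates pattern extraction, pattern scoring, instance extraction and
#' candidate validation until an iteration adds no new seeds (or the
#' iteration cap is reached, in which case the result is flagged truncated).
#' Seed sets are monotone non-decreasing across iterations.
#'
#' @param corpus records, a `synth_corpus`, or prepared sentence table.
#' @param seeds initial `seed_store` (at least one seed per mined type).
#' @param config a `bootstrap_config`.
#' @param oracle a `validation_oracle` (or NULL: nothing gets accepted).
#' @return list with `seeds` (final store), `patterns` (scored pattern
#'   library), `trace` (per-iteration seed counts), `annotated` (corpus with
#'   span/tuple labels for accepted instances), `truncated` flag.
#' @export
run_bootstrap <- function(corpus, seeds, config = bootstrap_config(),
                          oracle = NULL) {
  sents <- mining_sentences(corpus)
  stopifnot(inherits(seeds, "seed_store"))
  mined_types <- names(seeds$entity_seeds)[lengths(seeds$entity_seeds) > 0]
  if (!length(mined_types)) stop("need at least one entity seed")
  extraction_cache <- new.env(parent = emptyenv())
  df_cache <- new.env(parent = emptyenv())
  trace <- list()
  pattern_lib <- list()
  truncated <- FALSE
  for (iter in seq_len(config$max_iterations)) {
    n_new <- 0L
    pattern_lib <- list()
    for (tp in mined_types) {
      pats <- extract_entity_patterns(sents, seeds, tp)
      scored <- list()
      for (p in pats) {
        key <- pattern_key(p)
        extracted <- extraction_cache[[key]]
        if (is.null(extracted)) {
          extracted <- unique(match_pattern(p, sents, config)$string)
          extraction_cache[[key]] <- extracted
        }
        if (!length(extracted)) next
        scored[[length(scored) + 1L]] <-
          score_pattern(p, sents, seeds, config, extracted = extracted)
      }
      pattern_lib <- c(pattern_lib, scored)
      bands <- vapply(scored, function(p) {
        if (p$score >= config$score_threshold_valid) "valid"
        else if (p$score >= config$score_threshold_lowband) "lowband"
        else "none"
      }, character(1))
      cand_rows <- list()
      for (band in c("valid", "lowband")) {
        strings <- unique(unlist(lapply(scored[bands == band], function(p)
          extraction_cache[[pattern_key(p)]])))
        strings <- setdiff(strings, all_entity_seeds(seeds))
        if (band == "lowband" && length(cand_rows))
          strings <- setdiff(strings, cand_rows[[1]]$string)
        if (length(strings))
          cand_rows[[length(cand_rows) + 1L]] <- data.frame(
            string = strings, type = tp, band = band,
            stringsAsFactors = FALSE)
      }
      if (!length(cand_rows)) next
      res <- validate_candidates(do.call(rbind, cand_rows), oracle, config)
      if (nrow(res$accepted)) {
        for (k in seq_len(nrow(res$accepted))) {
          s <- res$accepted$string[k]
          if (!is.na(seed_type_of(seeds, s))) next  # cross-type conflict
          seeds$entity_seeds[[tp]] <- c(seeds$entity_seeds[[tp]], s)
          seeds$provenance[[s]] <-
            if (res$accepted$via[k] == "dictionary") "oracle-validated"
            else "pattern-mined"
          n_new <- n_new + 1L
        }
      }
    }
    # ---- relations --------------------------------------------------------
    if (nrow(seeds$relation_seeds)) {
      pc <- relation_pair_contexts(sents, seeds, config, df_cache)
      rpats <- extract_relation_patterns(sents, seeds, config,
                                         pair_contexts = pc)
      scored <- list()
      for (p in rpats) {
        extracted <- relation_pattern_pairs(p, pc)
        if (!length(extracted)) next
        p <- score_pattern(p, sents, seeds, config, extracted = extracted)
        attr(p, "extracted") <- extracted
        scored[[length(scored) + 1L]] <- p
      }
      pattern_lib <- c(pattern_lib, scored)
      seed_pairs <- paste(seeds$relation_seeds$subject,
                          seeds$relation_seeds$object, sep = "\t")
      cand <- list()
      for (p in scored) {
        band <- if (p$score >= config$score_threshold_valid) "valid"
          else if (p$score >= config$score_threshold_lowband) "lowband"
          else next
        for (pair in setdiff(attr(p, "extracted"), seed_pairs)) {
          se <- strsplit(pair, "\t", fixed = TRUE)[[1]]
          cand[[length(cand) + 1L]] <- data.frame(
            subject = se[1], relation = p$placeholder_type, object = se[2],
            band = band, stringsAsFactors = FALSE)
        }
      }
      if (length(cand)) {
        cand <- unique(do.call(rbind, cand))
        # a validated-pattern extraction outranks a lowband one
        cand <- cand[order(cand$band), ]
        cand <- cand[!duplicated(cand[c("subject", "relation", "object")]), ]
        res <- validate_relation_candidates(cand, oracle, config)
        if (nrow(res$accepted)) {
          add <- res$accepted[, c("subject", "relation", "object")]
          seeds$relation_seeds <- rbind(seeds$relation_seeds, add)
          for (k in seq_len(nrow(add)))
            seeds$provenance[[tuple_key(add$subject[k], add$relation[k],
                                        add$object[k])]] <-
              if (res$accepted$via[k] == "dictionary") "oracle-validated"
              else "pattern-mined"
          n_new <- n_new + nrow(add)
        }
      }
    }
    counts <- c(lapply(seeds$entity_seeds, length),
                relations = nrow(seeds$relation_seeds))
    trace[[iter]] <- data.frame(iteration = iter,
                                t(unlist(counts)), new_seeds = n_new)
    if (n_new == 0L) break
    if (iter == config$max_iterations) truncated <- TRUE
  }
  list(seeds = seeds,
       patterns = pattern_lib,
       trace = do.call(rbind, trace),
       annotated = annotate_corpus(corpus, seeds),
       truncated = truncated)
}

#' Annotate a corpus with accepted seed instances
#'
#' Marks entity spans by longest-match dictionary lookup of the seed strings
#' (left to right, non-overlapping) and relation tuples wherever a seed
#' tuple's entity pair co-occurs in a sentence.
#'
#' @param corpus records or `synth_corpus`.
#' @param seeds a `seed_store`.
#' @return list of annotated records (`record_id`, `tokens`, `spans` with
#'   0-based half-open offsets, `tuples`).
#' @export
annotate_corpus <- function(corpus, seeds) {
  records <- if (inherits(corpus, "synth_corpus")) corpus$records
    else if (inherits(corpus, "mining_sentences")) {
      rid <- vapply(corpus, `[[`, "", "record_id")
      lapply(split(seq_along(corpus), factor(rid, levels = unique(rid))),
             function(ix) list(
               record_id = corpus[[ix[1]]]$record_id,
               tokens = unlist(lapply(ix, function(i)
                 c(corpus[[i]]$tokens, SENT_BOUNDARY)))))
    } else corpus
  ents <- kb_like_entity_frame(seeds)
  ent_by_len <- if (nrow(ents))
    ents[order(-vapply(ents$entity, function(e)
      length(entity_tokens(e)), numeric(1))), ] else ents
  rel_keys <- paste(seeds$relation_seeds$subject,
                    seeds$relation_seeds$object, sep = "\t")
  lapply(records, function(r) {
    toks <- if (is.list(r)) r$tokens else r
    rid <- if (is.list(r) && !is.null(r$record_id)) r$record_id else NA
    taken <- logical(length(toks))
    spans <- list()
    if (nrow(ent_by_len)) for (k in seq_len(nrow(ent_by_len))) {
      et <- entity_tokens(ent_by_len$entity[k])
      for (st in find_subseq(toks, et)) {
        ix <- st:(st + length(et) - 1L)
        if (any(taken[ix])) next
        taken[ix] <- TRUE
        spans[[length(spans) + 1L]] <- data.frame(
          start = st - 1L, end = st + length(et) - 1L,
          type = ent_by_len$type[k], surface = ent_by_len$entity[k],
          stringsAsFactors = FALSE)
      }
    }
    spans <- if (length(spans)) {
      sp <- do.call(rbind, spans); sp[order(sp$start), ]
    } else data.frame(start = integer(0), end = integer(0),
                      type = character(0), surface = character(0))
    rownames(spans) <- NULL
    tuples <- list()
    if (nrow(seeds$relation_seeds) && nrow(spans) > 1) {
      for (sp_ix in sentence_spans(toks)) {
        here <- spans[spans$start >= sp_ix[1] - 1L &
                        spans$end <= sp_ix[length(sp_ix)], , drop = FALSE]
        if (nrow(here) < 2) next
        for (a in seq_len(nrow(here))) for (b in seq_len(nrow(here))) {
          if (a == b) next
          key <- paste(here$surface[a], here$surface[b], sep = "\t")
          hit <- which(rel_keys == key)
          if (length(hit))
            tuples[[length(tuples) + 1L]] <- data.frame(
              subject = here$surface[a],
              relation = seeds$relation_seeds$relation[hit[1]],
              object = here$surface[b], stringsAsFactors = FALSE)
        }
      }
    }
    tuples <- if (length(tuples)) unique(do.call(rbind, tuples)) else
      data.frame(subject = character(0), relation = character(0),
                 object = character(0))
    rownames(tuples) <- NULL
    list(record_id = rid, tokens = toks, spans = spans, tuples = tuples)
  })
}
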