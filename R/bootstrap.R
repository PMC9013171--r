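# Bootstrapping pattern mining: iterative seed expansion over surface patterns
# scored by support / confidence / reliability, with pluggable validation.

#' Bootstrapping configuration
#'
#' @param score_threshold_valid patterns scoring at or above this are
#'   validated (default 0.7).
#' @param score_threshold_lowband patterns in `[lowband, valid)` have their
#'   candidates rescued through search validation (Score_c = |H|/K); the same
#'   value is reused as the Score_c floor for queueing to a human judge
#'   (default 0.3).
#' @param w mixing weight between support and maximum per-type confidence in
#'   the reliability score (default 0.5).
#' @param search_K number of top search results inspected for Score_c.
#' @param max_iterations hard cap on bootstrap iterations.
#' @param max_candidate_len maximum candidate length in tokens.
#' @param same_sentence require candidate and contexts within one sentence.
#' @param cross_sentence_relations allow relation context strings to span
#'   sentence boundaries.
#' @param df_floor drop relation-context words seen in fewer than this many
#'   records (TF-IDF document-frequency floor).
#' @param stoplist words removed from relation context strings.
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(score_threshold_valid = 0.7,
                             score_threshold_lowband = 0.3,
                             w = 0.5, search_K = 10L, max_iterations = 25L,
                             max_candidate_len = 10L, same_sentence = TRUE,
                             cross_sentence_relations = FALSE,
                             df_floor = 2L,
                             stoplist = c(SENT_BOUNDARY, "?")) {
  stopifnot(0 <= score_threshold_lowband,
            score_threshold_lowband <= score_threshold_valid,
            score_threshold_valid <= 1, w >= 0, w <= 1, search_K >= 1)
  structure(list(score_threshold_valid = score_threshold_valid,
                 score_threshold_lowband = score_threshold_lowband,
                 w = w, search_K = as.integer(search_K),
                 max_iterations = as.integer(max_iterations),
                 max_candidate_len = as.integer(max_candidate_len),
                 same_sentence = same_sentence,
                 cross_sentence_relations = cross_sentence_relations,
                 df_floor = as.integer(df_floor), stoplist = stoplist),
            class = "bootstrap_config")
}

#' Seed store
#'
#' Holds entity seeds per type and relation seed tuples, with provenance
#' (`manual`, `pattern-mined`, `oracle-validated`) per instance. Seed sets
#' only grow across bootstrap iterations.
#'
#' @param entity_seeds named list: entity type -> character vector.
#' @param relation_seeds data.frame subject/relation/object (or NULL).
#' @export
seed_store <- function(entity_seeds = list(), relation_seeds = NULL) {
  entity_seeds <- lapply(entity_seeds, unique)
  if (is.null(relation_seeds))
    relation_seeds <- data.frame(subject = character(0),
                                 relation = character(0),
                                 object = character(0),
                                 stringsAsFactors = FALSE)
  prov <- c(
    stats::setNames(rep("manual", sum(lengths(entity_seeds))),
                    unlist(entity_seeds, use.names = FALSE)),
    stats::setNames(rep("manual", nrow(relation_seeds)),
                    tuple_key(relation_seeds$subject, relation_seeds$relation,
                              relation_seeds$object)))
  structure(list(entity_seeds = entity_seeds,
                 relation_seeds = relation_seeds,
                 provenance = prov),
            class = "seed_store")
}

seed_type_of <- function(store, string) {
  for (tp in names(store$entity_seeds))
    if (string %in% store$entity_seeds[[tp]]) return(tp)
  NA_character_
}

#' All entity seed strings in a store, across types
#' @param store a `seed_store`.
#' @return character vector.
#' @export
all_entity_seeds <- function(store) unlist(store$entity_seeds, use.names = FALSE)

# normalize any accepted corpus representation into a sentence table
mining_sentences <- function(corpus) {
  if (inherits(corpus, "mining_sentences")) return(corpus)
  records <- if (inherits(corpus, "synth_corpus")) corpus$records else corpus
  out <- list()
  for (r in records) {
    toks <- if (is.list(r) && !is.null(r$tokens)) r$tokens else r
    rid <- if (is.list(r) && !is.null(r$record_id)) r$record_id else
      sprintf("rec%05d", length(out) + 1L)
    for (sp in sentence_spans(toks))
      out[[length(out) + 1L]] <- list(tokens = toks[sp], record_id = rid)
  }
  structure(out, class = "mining_sentences")
}

pattern_key <- function(p) {
  if (p$kind == "entity")
    paste("E", p$placeholder_type, paste(p$left, collapse = " "), "|",
          paste(p$right, collapse = " "))
  else
    paste("R", p$placeholder_type, paste(p$context_words, collapse = " "))
}

new_entity_pattern <- function(left, right, type) {
  structure(list(kind = "entity", left = left, right = right,
                 context_words = NULL, placeholder_type = type,
                 support = NA_real_, confidence_by_type = NULL,
                 score = NA_real_, validated = FALSE),
            class = "candidate_pattern")
}

#' @export
print.candidate_pattern <- function(x, ...) {
  if (x$kind == "entity")
    cat(sprintf("<pattern> %s <%s> %s  score=%.3f%s\n",
                paste(x$left, collapse = " "), x$placeholder_type,
                paste(x$right, collapse = " "), x$score,
                if (isTRUE(x$validated)) " [valid]" else ""))
  else
    cat(sprintf("<pattern> [%s] <%s>  score=%.3f%s\n",
                paste(x$context_words, collapse = " "), x$placeholder_type,
                x$score, if (isTRUE(x$validated)) " [valid]" else ""))
  invisible(x)
}

#' Extract candidate entity patterns around seed occurrences
#'
#' For every occurrence of a seed of `entity_type`, takes 1-3 tokens to the
#' left and right (within the sentence) as left/right contexts. Every
#' combination of a left and a right context is a candidate pattern, and
#' every independent left or right context is one too. Patterns are
#' deduplicated by exact token-sequence identity.
#'
#' @param corpus records, a `synth_corpus`, or a prepared sentence table.
#' @param seeds a `seed_store`.
#' @param entity_type which entity type's seeds to use.
#' @return list of `candidate_pattern` (unscored).
#' @export
extract_entity_patterns <- function(corpus, seeds, entity_type) {
  sents <- mining_sentences(corpus)
  seed_strings <- seeds$entity_seeds[[entity_type]]
  if (is.null(seed_strings) || !length(seed_strings))
    stop("no seeds for entity type ", entity_type)
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(left, right) {
    p <- new_entity_pattern(left, right, entity_type)
    k <- pattern_key(p)
    if (is.null(seen[[k]])) { seen[[k]] <- TRUE; out[[length(out) + 1L]] <<- p }
  }
  for (s in sents) {
    toks <- s$tokens
    for (seed in seed_strings) {
      ntoks <- entity_tokens(seed)
      for (st in find_subseq(toks, ntoks)) {
        en <- st + length(ntoks) - 1L
        lefts <- lapply(seq_len(min(3L, st - 1L)), function(l)
          toks[(st - l):(st - 1L)])
        rights <- lapply(seq_len(min(3L, length(toks) - en)), function(l)
          toks[(en + 1L):(en + l)])
        for (L in lefts) for (R in rights) add(L, R)
        for (L in lefts) add(L, character(0))
        for (R in rights) add(character(0), R)
      }
    }
  }
  out
}

#' Match an entity pattern against a corpus
#'
#' Returns every string between the matched left and right contexts that
#' satisfies the constraints (maximum token length; contexts and candidate in
#' one sentence). For single-sided patterns all spans of length 1 to the
#' maximum adjacent to the context are candidates.
#'
#' @param pattern a `candidate_pattern` of kind entity.
#' @param corpus records or prepared sentence table.
#' @param config a `bootstrap_config` (supplies the constraints).
#' @return data.frame with columns `string`, `sentence`, `record_id`,
#'   `start`, `end` (0-based half-open token offsets within the sentence).
#' @export
match_pattern <- function(pattern, corpus, config = bootstrap_config()) {
  stopifnot(pattern$kind == "entity")
  if (!length(pattern$left) && !length(pattern$right))
    stop("pattern must have at least one context")
  sents <- mining_sentences(corpus)
  maxlen <- config$max_candidate_len
  rows <- list()
  for (si in seq_along(sents)) {
    toks <- sents[[si]]$tokens
    n <- length(toks)
    lends <- if (length(pattern$left))
      find_subseq(toks, pattern$left) + length(pattern$left) - 1L else NULL
    rstarts <- if (length(pattern$right))
      find_subseq(toks, pattern$right) else NULL
    spans <- list()
    if (!is.null(lends) && !is.null(rstarts)) {
      for (le in lends) for (rs in rstarts) {
        gap <- rs - le - 1L
        if (gap >= 1L && gap <= maxlen)
          spans[[length(spans) + 1L]] <- c(le + 1L, rs - 1L)
      }
    } else if (!is.null(lends)) {
      for (le in lends)
        for (l in seq_len(min(maxlen, n - le)))
          spans[[length(spans) + 1L]] <- c(le + 1L, le + l)
    } else {
      for (rs in rstarts)
        for (l in seq_len(min(maxlen, rs - 1L)))
          spans[[length(spans) + 1L]] <- c(rs - l, rs - 1L)
    }
    for (sp in spans) {
      rows[[length(rows) + 1L]] <- data.frame(
        string = paste(toks[sp[1]:sp[2]], collapse = " "),
        sentence = si, record_id = sents[[si]]$record_id,
        start = sp[1] - 1L, end = sp[2], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(string = character(0), sentence = integer(0),
                      record_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Score a candidate pattern (support, confidence, reliability)
#'
#' Support is the fraction of pattern-extracted instances that are already
#' seeds; per-type confidence is the fraction of the extracted seeds that
#' carry type `c`; the reliability score mixes support with the maximum
#' confidence: `score = w * support + (1 - w) * max_c confidence_c`. A
#' pattern scoring at or above the validation threshold is marked validated.
#' Confidence is defined as 0 when no extracted instance is a seed.
#'
#' @param pattern entity or relation `candidate_pattern`.
#' @param corpus records or prepared sentence table.
#' @param seeds a `seed_store`.
#' @param config a `bootstrap_config`.
#' @param extracted optional precomputed extraction set (internal reuse).
#' @return the pattern with `support`, `confidence_by_type`, `score`,
#'   `validated` filled in.
#' @export
score_pattern <- function(pattern, corpus, seeds,
                          config = bootstrap_config(), extracted = NULL) {
  if (pattern$kind == "entity") {
    if (is.null(extracted))
      extracted <- unique(match_pattern(pattern, corpus, config)$string)
    if (!length(extracted)) stop("undefined support: pattern extracts nothing")
    seed_all <- all_entity_seeds(seeds)
    inseed <- intersect(extracted, seed_all)
    support <- length(inseed) / length(extracted)
    conf <- vapply(names(seeds$entity_seeds), function(tp) {
      if (!length(inseed)) return(0)
      length(intersect(inseed, seeds$entity_seeds[[tp]])) / length(inseed)
    }, numeric(1))
  } else {
    if (is.null(extracted)) {
      sents <- mining_sentences(corpus)
      pc <- relation_pair_contexts(sents, seeds, config)
      extracted <- relation_pattern_pairs(pattern, pc)
    }
    if (!length(extracted)) stop("undefined support: pattern extracts nothing")
    seed_pairs <- paste(seeds$relation_seeds$subject,
                        seeds$relation_seeds$object, sep = "\t")
    inseed <- intersect(extracted, seed_pairs)
    support <- length(inseed) / length(extracted)
    conf <- vapply(relation_types(), function(rt) {
      if (!length(inseed)) return(0)
      rt_pairs <- paste(
        seeds$relation_seeds$subject[seeds$relation_seeds$relation == rt],
        seeds$relation_seeds$object[seeds$relation_seeds$relation == rt],
        sep = "\t")
      length(intersect(inseed, rt_pairs)) / length(inseed)
    }, numeric(1))
  }
  pattern$support <- support
  pattern$confidence_by_type <- conf
  pattern$score <- config$w * support + (1 - config$w) * max(conf, 0)
  pattern$validated <- pattern$score >= config$score_threshold_valid
  pattern
}

# ---- relation pattern mining ------------------------------------------------

#' Bidirectional maximum matching segmentation
#'
#' Segments a token sequence into words using a dictionary of multi-token
#' words (extracted entities); forward and backward greedy longest-match are
#' compared and the segmentation with fewer words wins (ties prefer the
#' backward pass, the common convention).
#'
#' @param tokens character vector.
#' @param dictionary character vector of space-joined multi-token words.
#' @return character vector of words (multi-token words space-joined).
#' @export
bimm_segment <- function(tokens, dictionary) {
  dict <- new.env(parent = emptyenv())
  maxlen <- 1L
  for (d in dictionary) {
    tl <- length(entity_tokens(d))
    if (tl > 1L) { dict[[d]] <- TRUE; maxlen <- max(maxlen, tl) }
  }
  n <- length(tokens)
  fwd <- character(0); i <- 1L
  while (i <= n) {
    l <- min(maxlen, n - i + 1L)
    while (l > 1L &&
           is.null(dict[[paste(tokens[i:(i + l - 1L)], collapse = " ")]]))
      l <- l - 1L
    fwd <- c(fwd, paste(tokens[i:(i + l - 1L)], collapse = " "))
    i <- i + l
  }
  bwd <- character(0); j <- n
  while (j >= 1L) {
    l <- min(maxlen, j)
    while (l > 1L &&
           is.null(dict[[paste(tokens[(j - l + 1L):j], collapse = " ")]]))
      l <- l - 1L
    bwd <- c(paste(tokens[(j - l + 1L):j], collapse = " "), bwd)
    j <- j - l
  }
  if (length(fwd) < length(bwd)) fwd else bwd
}

# document frequency of a word (possibly multi-token) over records
word_document_frequency <- function(words, sents) {
  # group sentences back into records
  recs <- split(seq_along(sents), vapply(sents, `[[`, "", "record_id"))
  vapply(words, function(w) {
    wt <- entity_tokens(w)
    sum(vapply(recs, function(ix)
      any(vapply(ix, function(i)
        length(find_subseq(sents[[i]]$tokens, wt)) > 0L, logical(1))),
      logical(1)))
  }, numeric(1))
}

filter_context_words <- function(words, sents, config, df_cache = NULL) {
  if (!length(words)) return(character(0))
  words <- words[!(words %in% config$stoplist)]
  if (!length(words)) return(character(0))
  if (!is.null(df_cache)) {
    need <- words[!vapply(words, function(w) !is.null(df_cache[[w]]), logical(1))]
    if (length(need)) {
      dfs <- word_document_frequency(unique(need), sents)
      for (w in names(dfs)) df_cache[[w]] <- dfs[[w]]
    }
    df <- vapply(words, function(w) df_cache[[w]], numeric(1))
  } else df <- word_document_frequency(words, sents)
  words[df >= config$df_floor]
}

# all typed entity-pair contexts in the corpus: for each ordered co-occurring
# pair of seed entities, the segmented + filtered context word sequence
relation_pair_contexts <- function(sents, seeds, config, df_cache = NULL) {
  ents <- kb_like_entity_frame(seeds)
  if (!nrow(ents)) return(list())
  out <- list()
  for (si in seq_along(sents)) {
    toks <- sents[[si]]$tokens
    # entity mentions in this sentence
    ment <- list()
    for (k in seq_len(nrow(ents))) {
      et <- entity_tokens(ents$entity[k])
      for (st in find_subseq(toks, et))
        ment[[length(ment) + 1L]] <- list(
          entity = ents$entity[k], type = ents$type[k],
          start = st, end = st + length(et) - 1L)
    }
    if (length(ment) < 2L) next
    for (a in ment) for (b in ment) {
      if (a$entity == b$entity) next
      if (b$start <= a$end) next               # b strictly after a
      pre <- if (a$start > 1L) toks[a$start - 1L] else character(0)
      mid <- if (b$start > a$end + 1L) toks[(a$end + 1L):(b$start - 1L)] else
        character(0)
      post <- if (b$end < length(toks)) toks[b$end + 1L] else character(0)
      dict <- ents$entity
      words <- bimm_segment(c(pre, mid, post), dict)
      words <- filter_context_words(words, sents, config, df_cache)
      out[[length(out) + 1L]] <- list(
        subject = a$entity, subject_type = a$type,
        object = b$entity, object_type = b$type,
        words = words, sentence = si)
    }
  }
  out
}

# entity frame from a seed store (type/entity columns)
kb_like_entity_frame <- function(seeds) {
  rows <- lapply(names(seeds$entity_seeds), function(tp)
    if (length(seeds$entity_seeds[[tp]]))
      data.frame(type = tp, entity = seeds$entity_seeds[[tp]],
                 stringsAsFactors = FALSE))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(type = character(0),
                                       entity = character(0)))
  do.call(rbind, rows)
}

# pairs (subject \t object keys) whose filtered context contains the pattern
relation_pattern_pairs <- function(pattern, pair_contexts) {
  schema <- relation_schema()
  srow <- schema[schema$relation == pattern$placeholder_type, ]
  keys <- character(0)
  for (pc in pair_contexts) {
    if (pc$subject_type != srow$subject_type ||
        pc$object_type != srow$object_type) next
    ok <- if (!length(pattern$context_words)) !length(pc$words) else
      length(find_subseq(pc$words, pattern$context_words)) > 0L
    if (ok) keys <- c(keys, paste(pc$subject, pc$object, sep = "\t"))
  }
  unique(keys)
}

#' Extract candidate relation patterns from seed tuples
#'
#' For every co-occurrence of a seed tuple's entity pair, forms the context
#' string (tokens between the entities plus at most one boundary token each
#' side), segments it into words with bidirectional maximum matching over a
#' dictionary that includes the extracted entities, filters the words with
#' the stop list and a document-frequency floor, and emits every substring of
#' the filtered word sequence as a candidate pattern. An empty context
#' (adjacent entities) yields a single degenerate empty pattern.
#'
#' @param corpus records or prepared sentence table.
#' @param seeds a `seed_store` carrying relation seeds (and the entity seeds
#'   used as the segmentation dictionary).
#' @param config a `bootstrap_config`.
#' @param pair_contexts optional precomputed [relation_pair_contexts] result.
#' @return list of `candidate_pattern` of kind relation (unscored).
#' @export
extract_relation_patterns <- function(corpus, seeds,
                                      config = bootstrap_config(),
                                      pair_contexts = NULL) {
  sents <- mining_sentences(corpus)
  rs <- seeds$relation_seeds
  if (!nrow(rs)) return(list())
  pc <- pair_contexts %||% relation_pair_contexts(sents, seeds, config)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (ctx in pc) {
    hit <- rs$subject == ctx$subject & rs$object == ctx$object
    if (!any(hit)) next
    rel <- rs$relation[which(hit)[1]]
    subs <- if (!length(ctx$words)) list(character(0)) else {
      k <- length(ctx$words)
      unlist(lapply(seq_len(k), function(i)
        lapply(i:k, function(j) ctx$words[i:j])), recursive = FALSE)
    }
    for (w in subs) {
      p <- structure(list(kind = "relation", left = NULL, right = NULL,
                          context_words = w, placeholder_type = rel,
                          support = NA_real_, confidence_by_type = NULL,
                          score = NA_real_, validated = FALSE,
                          degenerate = !length(w)),
                     class = "candidate_pattern")
      key <- pattern_key(p)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- p
      }
    }
  }
  out
}
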