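# synthetic clinical-style corpus generator with a ground-truth ledger
#
# Records emulate character-level clinical narratives: tokens are atomic
# pseudo-words, statements instantiate relation templates whose left/right
# contexts mirror the surface patterns the bootstrapping stage mines
# ("admission for <DIS> and ..."). Every insertion is logged, so the ledger
# is the oracle for all extraction-stage tests.

#' Statement templates of the synthetic corpus
#'
#' Each relation type has three templates; a template is a list with `left`
#' (tokens before the subject), `mid` (tokens between subject and object, the
#' relation-indicating context string) and `right` (tokens after the object).
#' @return named list: relation type -> list of templates.
#' @export
statement_templates <- function() {
  L <- list(c("admission", "for"), c("patient", "record", "of"), c("case", "of"))
  R <- list(c("noted"), c("at", "clinic"), character(0))
  mids <- list(
    hasSymptom     = list(c("and", "presenting", "complaint"),
                          c("suffering", "from"),
                          c("manifesting")),
    needsTest      = list(c("requires", "examination"),
                          c("scheduled", "for", "screening"),
                          c("evaluated", "via")),
    hasTestResult  = list(c("indicated", "by", "finding"),
                          c("suggested", "by"),
                          c("confirmed", "through", "finding")),
    needsTreatment = list(c("and", "cure", "with"),
                          c("treated", "using"),
                          c("prescribed")),
    hasResult      = list(c("returned", "reading"),
                          c("yielded"),
                          c("measured", "as"))
  )
  out <- lapply(names(mids), function(rel) {
    lapply(seq_len(3), function(k)
      list(left = L[[k]], mid = mids[[rel]][[k]], right = R[[k]]))
  })
  names(out) <- names(mids)
  out
}

# misspelled variant of a surface form: one token gets a fixed typo suffix
noise_variant <- function(tokens, pos) {
  tokens[pos] <- paste0(tokens[pos], "x")
  tokens
}

render_statement <- function(tuple, template, noise_rate) {
  subj <- entity_tokens(tuple$subject)
  obj <- entity_tokens(tuple$object)
  mentions <- list(
    list(canonical = tuple$subject, toks = subj,
         type = tuple$subject_type),
    list(canonical = tuple$object, toks = obj,
         type = tuple$object_type))
  aliases <- list()
  for (k in 1:2) {
    if (noise_rate > 0 && stats::runif(1) < noise_rate) {
      pos <- sample.int(length(mentions[[k]]$toks), 1)
      vt <- noise_variant(mentions[[k]]$toks, pos)
      aliases[[length(aliases) + 1L]] <-
        data.frame(canonical = mentions[[k]]$canonical,
                   variant = paste(vt, collapse = " "),
                   stringsAsFactors = FALSE)
      mentions[[k]]$toks <- vt
    }
  }
  toks <- c(template$left, mentions[[1]]$toks, template$mid,
            mentions[[2]]$toks, template$right, SENT_BOUNDARY)
  s_start <- length(template$left)                      # 0-based
  s_end <- s_start + length(mentions[[1]]$toks)
  o_start <- s_end + length(template$mid)
  o_end <- o_start + length(mentions[[2]]$toks)
  spans <- data.frame(
    start = c(s_start, o_start), end = c(s_end, o_end),
    type = c(tuple$subject_type, tuple$object_type),
    canonical = c(tuple$subject, tuple$object),
    surface = c(paste(mentions[[1]]$toks, collapse = " "),
                paste(mentions[[2]]$toks, collapse = " ")),
    stringsAsFactors = FALSE)
  list(tokens = toks, spans = spans, aliases = aliases)
}

#' Render clinical-style records from a knowledge base
#'
#' Each record is a sequence of relational statements (shifted-Poisson count
#' with the requested mean); statements instantiate templates with KB tuples.
#' Stratified sampling guarantees every KB tuple is expressed at least once
#' when `n_records * mean_statements` allows. With `noise_rate > 0` a fraction
#' of entity mentions is corrupted by a one-token substitution; the resulting
#' (canonical, variant) alias pairs are logged for entity-alignment testing.
#'
#' @param kb a `medkg_kb` with at least one relation.
#' @param n_records number of records to generate.
#' @param mean_statements mean statements per record (default 3.3, matching
#'   typical clinical records).
#' @param noise_rate per-mention corruption probability in `[0, 1]`.
#' @param rng_seed integer seed.
#' @return object of class `synth_corpus`: `$records` (list of `synth_record`,
#'   each with `record_id`, `department`, `tokens`, `gold_spans` (0-based
#'   half-open token spans), `gold_tuples`, `statement_count`) and `$ledger`
#'   (`$spans`, `$tuples`, `$aliases` data frames plus the source `$kb`).
#' @export
render_records <- function(kb, n_records, mean_statements = 3.3,
                           noise_rate = 0, rng_seed = 1) {
  if (!inherits(kb, "medkg_kb") || is.null(kb$relations) ||
      nrow(kb$relations) == 0)
    stop("kb must be a non-empty medkg_kb with at least one relation")
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]")
  stopifnot(n_records >= 1, mean_statements >= 1)
  templates <- statement_templates()
  schema <- relation_schema()
  departments <- c("InternalMed", "Surgery", "Pediatrics", "Laboratory",
                   "Radiology")
  with_seed(rng_seed, {
    counts <- 1L + stats::rpois(n_records, mean_statements - 1)
    total <- sum(counts)
    ntup <- nrow(kb$relations)
    # stratified: every tuple at least once (round-robin), remainder uniform
    tuple_idx <- c(rep(seq_len(ntup), length.out = min(ntup, total)),
                   if (total > ntup) sample.int(ntup, total - ntup, replace = TRUE))
    tuple_idx <- sample(tuple_idx)  # shuffle positions
    at <- 0L
    span_log <- list(); tuple_log <- list(); alias_log <- list()
    records <- vector("list", n_records)
    for (ri in seq_len(n_records)) {
      rid <- sprintf("rec%05d", ri)
      toks <- character(0)
      spans <- list(); tups <- list()
      for (si in seq_len(counts[ri])) {
        at <- at + 1L
        row <- kb$relations[tuple_idx[at], ]
        srow <- schema[schema$relation == row$relation, ]
        tup <- list(subject = row$subject, relation = row$relation,
                    object = row$object,
                    subject_type = srow$subject_type,
                    object_type = srow$object_type)
        st <- render_statement(tup, templates[[row$relation]][[
          sample.int(3, 1)]], noise_rate)
        st$spans$start <- st$spans$start + length(toks)
        st$spans$end <- st$spans$end + length(toks)
        toks <- c(toks, st$tokens)
        spans[[si]] <- st$spans
        tups[[si]] <- data.frame(subject = row$subject,
                                 relation = row$relation,
                                 object = row$object, stringsAsFactors = FALSE)
        for (al in st$aliases) alias_log[[length(alias_log) + 1L]] <- al
      }
      gold_spans <- do.call(rbind, spans)
      gold_tuples <- unique(do.call(rbind, tups))
      rownames(gold_spans) <- rownames(gold_tuples) <- NULL
      records[[ri]] <- structure(
        list(record_id = rid,
             department = sample(departments, 1),
             tokens = toks,
             gold_spans = gold_spans,
             gold_tuples = gold_tuples,
             statement_count = counts[ri]),
        class = "synth_record")
      span_log[[ri]] <- cbind(record_id = rid, gold_spans,
                              stringsAsFactors = FALSE)
      tuple_log[[ri]] <- cbind(record_id = rid,
                               do.call(rbind, tups), stringsAsFactors = FALSE)
    }
    aliases <- if (length(alias_log)) unique(do.call(rbind, alias_log)) else
      data.frame(canonical = character(0), variant = character(0),
                 stringsAsFactors = FALSE)
    rownames(aliases) <- NULL
    structure(list(
      records = records,
      ledger = list(spans = do.call(rbind, span_log),
                    tuples = do.call(rbind, tuple_log),
                    aliases = aliases, kb = kb)),
      class = "synth_corpus")
  })
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("<synth_corpus>", length(x$records), "records,",
      nrow(x$ledger$spans), "gold spans,",
      nrow(x$ledger$aliases), "alias pairs\n")
  invisible(x)
}

# question form table: one ask-subject and one ask-object form per relation
qa_question_forms <- function() {
  data.frame(
    relation = rep(relation_types(), each = 2),
    ask = rep(c("subject", "object"), times = 5),
    marker = c("whatdisease", "whatsymptom",
               "whatdisease", "whattest",
               "whatdisease", "whatresult",
               "whatdisease", "howtotreat",
               "whattest", "whatresult"),
    stringsAsFactors = FALSE)
}

qa_question_tokens <- function(relation, ask, marker, given_tokens) {
  lead <- switch(relation,
    hasSymptom     = if (ask == "subject") c("has", "symptom") else c("of"),
    needsTest      = if (ask == "subject") c("needs", "screening") else c("for"),
    hasTestResult  = if (ask == "subject") c("shows", "finding") else c("indicates"),
    needsTreatment = if (ask == "subject") c("cured", "by") else character(0),
    hasResult      = if (ask == "subject") c("yields") else c("from"))
  c(marker, lead, given_tokens, "?")
}

#' Render question-answer pairs from a knowledge base
#'
#' Each pair asks for one side of a KB tuple. The question contains an intent
#' marker token (mapped to the answer's entity type by `intent_rules()`) and
#' the tuple's other entity. The answer document (`body_tokens`) expresses a
#' single relation type and mentions the answer entity three times against
#' at most one mention of any distractor of the same type, so the
#' most-frequent-entity test-labeling rule recovers the answer.
#'
#' @param kb a `medkg_kb` with at least one relation.
#' @param n_pairs number of QA pairs.
#' @param rng_seed integer seed.
#' @param form_weights optional numeric vector of length `nrow(qa_question_forms())`
#'   giving the mixture over question forms (default uniform over forms whose
#'   relation has tuples).
#' @return list of `synth_qa` objects with fields `question_tokens`,
#'   `answer_entity`, `intent_type`, `supporting_tuple`, `body_tokens`.
#' @export
render_qa_pairs <- function(kb, n_pairs, rng_seed = 1, form_weights = NULL) {
  if (!inherits(kb, "medkg_kb") || nrow(kb$relations) == 0)
    stop("kb has no relations; cannot render QA pairs")
  forms <- qa_question_forms()
  schema <- relation_schema()
  templates <- statement_templates()
  have <- forms$relation %in% kb$relations$relation
  w <- form_weights %||% rep(1, nrow(forms))
  stopifnot(length(w) == nrow(forms))
  w[!have] <- 0
  if (sum(w) == 0) stop("no question form has supporting tuples")
  # single-fact filter: only ask questions whose answer is uniquely
  # determined by the KB (one subject per object for ask-subject forms, one
  # object per subject for ask-object forms)
  eligible <- lapply(seq_len(nrow(forms)), function(fi) {
    f <- forms[fi, ]
    cand <- kb$relations[kb$relations$relation == f$relation, , drop = FALSE]
    if (!nrow(cand)) return(cand)
    if (f$ask == "subject") {
      tb <- table(cand$object)
      cand[cand$object %in% names(tb)[tb == 1L], , drop = FALSE]
    } else {
      tb <- table(cand$subject)
      cand[cand$subject %in% names(tb)[tb == 1L], , drop = FALSE]
    }
  })
  w[vapply(eligible, nrow, integer(1)) == 0L] <- 0
  if (sum(w) == 0) stop("no question form has uniquely answerable tuples")
  with_seed(rng_seed, {
    lapply(seq_len(n_pairs), function(i) {
      fi <- sample.int(nrow(forms), 1, prob = w)
      f <- forms[fi, ]
      cand <- eligible[[fi]]
      row <- cand[sample.int(nrow(cand), 1), ]
      srow <- schema[schema$relation == f$relation, ]
      if (f$ask == "subject") {
        answer <- row$subject; given <- row$object
        intent <- srow$subject_type
      } else {
        answer <- row$object; given <- row$subject
        intent <- srow$object_type
      }
      question <- qa_question_tokens(f$relation, f$ask, f$marker,
                                     entity_tokens(given))
      # body: supporting tuple through all three templates (answer x3),
      # plus at most one distractor statement of the same relation type
      tup <- list(subject = row$subject, relation = row$relation,
                  object = row$object,
                  subject_type = srow$subject_type,
                  object_type = srow$object_type)
      body <- unlist(lapply(sample(1:3), function(k)
        render_statement(tup, templates[[f$relation]][[k]], 0)$tokens))
      others <- cand[cand$subject != row$subject | cand$object != row$object, ,
                     drop = FALSE]
      if (nrow(others)) {
        drow <- others[sample.int(nrow(others), 1), ]
        dans <- if (f$ask == "subject") drow$subject else drow$object
        if (dans != answer) {
          dtup <- list(subject = drow$subject, relation = drow$relation,
                       object = drow$object,
                       subject_type = srow$subject_type,
                       object_type = srow$object_type)
          body <- c(body, render_statement(
            dtup, templates[[f$relation]][[sample.int(3, 1)]], 0)$tokens)
        }
      }
      structure(list(
        question_tokens = question,
        answer_entity = answer,
        intent_type = intent,
        supporting_tuple = list(subject = row$subject,
                                relation = row$relation,
                                object = row$object),
        body_tokens = body),
        class = "synth_qa")
    })
  })
}
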