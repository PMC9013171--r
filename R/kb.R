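# ground-truth knowledge base: five entity classes, five typed relations

#' Generate a ground-truth knowledge base
#'
#' Draws a random knowledge base over the five-class medical ontology
#' (Disease, Symptom, Treatment, Test, Result) with typed relations
#' (`relation_schema()`). Entity surface forms are 1-3 synthetic tokens; every
#' `hasTestResult` object is guaranteed to also appear as the object of a
#' `hasResult` tuple so that qualitative results stay grounded, and each
#' Result entity carries a numeric measurement standard (its DataGrounding).
#'
#' @param n_entities_per_type number of entities drawn for each of the five
#'   entity types (>= 1).
#' @param n_relations_per_type number of tuples drawn for each relation type;
#'   must not exceed the subject x object pair space.
#' @param rng_seed integer seed; the KB is deterministic given the seed.
#' @param max_degree cap on the number of tuples any single entity
#'   participates in (default unlimited). Clinical knowledge graphs are
#'   sparse; a low cap keeps per-tuple supportability high.
#' @return an object of class `medkg_kb`: list with `entities` (named list of
#'   character vectors by type), `relations` (data.frame subject, relation,
#'   object) and `groundings` (named numeric, Result entity -> measurement
#'   standard).
#' @export
generate_kb <- function(n_entities_per_type, n_relations_per_type, rng_seed,
                        max_degree = Inf) {
  stopifnot(n_entities_per_type >= 1, n_relations_per_type >= 0)
  with_seed(rng_seed, {
    types <- entity_types()
    prefixes <- c(Disease = "mor", Symptom = "alg", Treatment = "rem",
                  Test = "ass", Result = "sig")
    syll <- c("ba", "do", "fe", "gi", "ka", "lo", "mu", "ne", "pa", "qo",
              "ri", "sa", "tu", "ve", "wi", "xa", "yo", "zu", "cho", "pla")
    mods <- c("acuta", "chronica", "gravis", "levis", "minor", "major",
              "alba", "rubra", "vera", "tarda")
    entities <- lapply(types, function(tp) {
      heads <- character(0)
      while (length(heads) < n_entities_per_type) {
        h <- paste0(prefixes[[tp]],
                    paste(sample(syll, 3, replace = TRUE), collapse = ""))
        if (!h %in% heads) heads <- c(heads, h)
      }
      vapply(seq_len(n_entities_per_type), function(i) {
        len <- sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
        toks <- heads[i]
        if (len > 1) toks <- c(toks, sample(mods, len - 1))
        paste(toks, collapse = " ")
      }, character(1))
    })
    names(entities) <- types

    schema <- relation_schema()
    rel_rows <- list()
    degree <- new.env(parent = emptyenv())
    deg <- function(e) degree[[e]] %||% 0L
    for (r in seq_len(nrow(schema))) {
      subs <- entities[[schema$subject_type[r]]]
      objs <- entities[[schema$object_type[r]]]
      space <- length(subs) * length(objs)
      if (n_relations_per_type > space)
        stop("capacity error: requested ", n_relations_per_type, " ",
             schema$relation[r], " tuples but only ", space, " pairs exist")
      if (n_relations_per_type == 0) next
      pick <- sample.int(space)   # shuffled pair space
      chosen <- integer(0)
      for (p in pick) {
        if (length(chosen) == n_relations_per_type) break
        s <- subs[((p - 1L) %% length(subs)) + 1L]
        o <- objs[((p - 1L) %/% length(subs)) + 1L]
        if (deg(s) >= max_degree || deg(o) >= max_degree) next
        degree[[s]] <- deg(s) + 1L
        degree[[o]] <- deg(o) + 1L
        chosen <- c(chosen, p)
      }
      if (length(chosen) < n_relations_per_type)
        stop("capacity error: degree cap ", max_degree, " leaves only ",
             length(chosen), " feasible ", schema$relation[r], " tuples")
      si <- ((chosen - 1L) %% length(subs)) + 1L
      oi <- ((chosen - 1L) %/% length(subs)) + 1L
      rel_rows[[schema$relation[r]]] <- data.frame(
        subject = subs[si], relation = schema$relation[r], object = objs[oi],
        stringsAsFactors = FALSE)
    }
    relations <- if (length(rel_rows)) do.call(rbind, rel_rows) else
      data.frame(subject = character(0), relation = character(0),
                 object = character(0), stringsAsFactors = FALSE)
    rownames(relations) <- NULL

    # ground every hasTestResult object through some hasResult tuple
    htr_obj <- unique(relations$object[relations$relation == "hasTestResult"])
    hr_obj <- relations$object[relations$relation == "hasResult"]
    missing <- setdiff(htr_obj, hr_obj)
    if (length(missing)) {
      # ground through the least-loaded Test so the degree cap stays honest
      subj <- vapply(missing, function(m) {
        loads <- vapply(entities$Test, deg, integer(1))
        pick <- entities$Test[which.min(loads)]
        degree[[pick]] <- deg(pick) + 1L
        degree[[m]] <- deg(m) + 1L
        pick
      }, character(1))
      extra <- data.frame(subject = unname(subj), relation = "hasResult",
                          object = missing, stringsAsFactors = FALSE)
      relations <- rbind(relations, extra)
    }
    relations <- unique(relations)
    rownames(relations) <- NULL

    groundings <- stats::setNames(round(stats::runif(n_entities_per_type, 1, 100), 1),
                                  entities$Result)
    structure(list(entities = entities, relations = relations,
                   groundings = groundings),
              class = "medkg_kb")
  })
}

#' @export
print.medkg_kb <- function(x, ...) {
  cat("<medkg_kb>", sum(lengths(x$entities)), "entities,",
      nrow(x$relations), "relations\n")
  for (tp in names(x$entities))
    cat("  ", tp, ": ", length(x$entities[[tp]]), "\n", sep = "")
  print(table(x$relations$relation))
  invisible(x)
}

# all entity strings with their types as a two-column frame
kb_entity_frame <- function(kb) {
  do.call(rbind, lapply(names(kb$entities), function(tp)
    if (length(kb$entities[[tp]]))
      data.frame(type = tp, entity = kb$entities[[tp]],
                 stringsAsFactors = FALSE)))
}

# type of an entity string within a KB (NA if absent)
kb_entity_type <- function(kb, entity) {
  for (tp in names(kb$entities))
    if (entity %in% kb$entities[[tp]]) return(tp)
  NA_character_
}
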