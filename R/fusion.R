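# Knowledge fusion: embedding-based entity alignment with two-threshold
# triage, and supportability-based consistency analysis for relations.

#' Cosine similarity
#' @param v1,v2 numeric vectors of equal length; must be non-zero.
#' @return scalar in `[-1, 1]`; symmetric.
#' @export
cosine_similarity <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for zero vector")
  sum(v1 * v2) / (n1 * n2)
}

#' Fusion thresholds
#'
#' Pairs (or relations) at or above `merge` are handled automatically; those
#' in `[queue, merge)` are routed to a human/oracle judgment; the rest are
#' kept separate (or dropped).
#' @param merge auto-accept threshold (default 0.7).
#' @param queue lower band edge for human judgment (default 0.3).
#' @export
fusion_config <- function(merge = 0.7, queue = 0.3) {
  stopifnot(0 <= queue, queue <= merge, merge <= 1)
  list(merge = merge, queue = queue)
}

# character n-grams with word boundary markers (token itself included)
entity_char_ngrams <- function(s, lo = 3L, hi = 4L) {
  words <- paste0("<", entity_tokens(s), ">")
  out <- character(0)
  for (w in words) {
    n <- nchar(w)
    for (k in lo:hi) if (n >= k)
      out <- c(out, substring(w, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
    out <- c(out, w)
  }
  out
}

#' Entity vectorizer for alignment
#'
#' Builds the similarity space entity alignment works in: the concatenation
#' of (a) the distributional entity vector (mean of co-trained token
#' embeddings) and (b) a character n-gram count vector of the surface form,
#' each L2-normalized and weighted. The surface component carries the
#' compositional signal that makes a misspelled variant land next to its
#' canonical form; the distributional component ties together forms used in
#' the same contexts.
#'
#' @param embeddings a `token_embeddings` (distributional component).
#' @param dist_weight weight of the distributional component in `[0, 1]`
#'   (default 0.3; the surface component gets the rest).
#' @return function: character vector of entity strings -> matrix (one row
#'   per entity) suitable for cosine comparison.
#' @export
alignment_vectorizer <- function(embeddings, dist_weight = 0.3) {
  force(embeddings); force(dist_weight)
  function(strings) {
    grams <- lapply(strings, entity_char_ngrams)
    space <- sort(unique(unlist(grams)))
    G <- t(vapply(grams, function(g) {
      v <- numeric(length(space))
      tb <- table(g)
      v[match(names(tb), space)] <- as.numeric(tb)
      v
    }, numeric(length(space))))
    E <- embed_entities(strings, embeddings)
    nrm <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)
    out <- cbind(sqrt(dist_weight) * nrm(E), sqrt(1 - dist_weight) * nrm(G))
    rownames(out) <- strings
    out
  }
}

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
uf_union <- function(uf, i, j) {
  ri <- uf_find(uf, i); rj <- uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

#' Align extracted entities into alias clusters
#'
#' Same-type entity pairs are compared by cosine similarity in the
#' vectorizer's space. Pairs at or above the merge threshold auto-merge;
#' pairs in the queue band go to the oracle's alignment judgment; everything
#' else stays separate. Auto-merges (and accepted judgments) close
#' transitively into alias clusters; each cluster's canonical name is the
#' surface form with the highest mention count (ties break lexicographically).
#' Cluster formation is order-independent.
#'
#' @param entities data.frame with columns `type`, `surface`, `count`
#'   (mention counts).
#' @param vectorizer function from [alignment_vectorizer()] (or compatible).
#' @param config a [fusion_config()].
#' @param oracle optional oracle with a `judge_alignment(a, b, type)` call.
#' @return list with `clusters` (data.frame `type`, `canonical`, `surface`,
#'   `count`) and `decisions` (data.frame `a`, `b`, `type`, `similarity`,
#'   `action`).
#' @export
align_entities <- function(entities, vectorizer, config = fusion_config(),
                           oracle = NULL) {
  stopifnot(all(c("type", "surface", "count") %in% names(entities)))
  entities <- entities[order(entities$type, entities$surface), ]
  rownames(entities) <- NULL
  n <- nrow(entities)
  uf <- uf_new(n)
  decisions <- list()
  if (n > 1) {
    V <- vectorizer(entities$surface)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (entities$type[i] != entities$type[j]) next
      sim <- cosine_similarity(V[i, ], V[j, ])
      action <- if (sim >= config$merge) "auto-merge"
        else if (sim >= config$queue) "human-queue"
        else "keep-separate"
      if (action == "human-queue" && !is.null(oracle) &&
          !is.null(oracle$judge_alignment)) {
        verdict <- oracle$judge_alignment(entities$surface[i],
                                          entities$surface[j],
                                          entities$type[i])
        if (isTRUE(verdict)) action <- "human-merge"
        else if (identical(verdict, FALSE)) action <- "human-separate"
      }
      if (action %in% c("auto-merge", "human-merge"))
        uf <- uf_union(uf, i, j)
      decisions[[length(decisions) + 1L]] <- data.frame(
        a = entities$surface[i], b = entities$surface[j],
        type = entities$type[i], similarity = sim, action = action,
        stringsAsFactors = FALSE)
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(uf, i), integer(1))
  canonical <- vapply(seq_len(n), function(i) {
    members <- which(root == root[i])
    m <- entities[members, ]
    m <- m[order(-m$count, m$surface), ]
    m$surface[1]
  }, character(1))
  clusters <- data.frame(type = entities$type, canonical = canonical,
                         surface = entities$surface, count = entities$count,
                         stringsAsFactors = FALSE)
  list(clusters = clusters,
       decisions = if (length(decisions)) do.call(rbind, decisions) else
         data.frame(a = character(0), b = character(0), type = character(0),
                    similarity = numeric(0), action = character(0)))
}

#' Supportability-based consistency analysis of relation tuples
#'
#' The confidence of a tuple is its extraction frequency divided by the
#' mention frequency of its subject entity. Tuples at or above the retain
#' threshold are kept; those in the queue band go to the oracle; the rest
#' are dropped. Tuples sharing subject and object but differing in relation
#' type conflict: the higher-confidence one is kept, ties go to the oracle.
#'
#' @param tuples data.frame `subject`, `relation`, `object`, `count`.
#' @param entity_counts named numeric: mention count per entity.
#' @param config a [fusion_config()].
#' @param oracle optional oracle with `judge_relation`.
#' @return list with `retained` (tuple data.frame) and `log` (per-tuple
#'   confidence and decision).
#' @export
relation_consistency <- function(tuples, entity_counts,
                                 config = fusion_config(), oracle = NULL) {
  if (!nrow(tuples))
    return(list(retained = tuples,
                log = cbind(tuples, confidence = numeric(0),
                            decision = character(0))))
  ec <- entity_counts[tuples$subject]
  if (any(is.na(ec) | ec == 0))
    stop("data-integrity error: tuple subject with zero mention count: ",
         tuples$subject[which(is.na(ec) | ec == 0)[1]])
  conf <- tuples$count / as.numeric(ec)
  decision <- ifelse(conf >= config$merge, "retain",
                     ifelse(conf >= config$queue, "human-queue", "drop"))
  for (i in which(decision == "human-queue")) {
    if (!is.null(oracle) && !is.null(oracle$judge_relation)) {
      verdict <- oracle$judge_relation(tuples$subject[i], tuples$relation[i],
                                       tuples$object[i])
      if (isTRUE(verdict)) decision[i] <- "human-retain"
      else if (identical(verdict, FALSE)) decision[i] <- "human-drop"
    }
  }
  keep <- decision %in% c("retain", "human-retain")
  # conflicting relations on the same subject-object pair
  pair <- paste(tuples$subject, tuples$object, sep = "\t")
  for (pk in unique(pair[keep])) {
    ix <- which(pair == pk & keep)
    if (length(ix) > 1 && length(unique(tuples$relation[ix])) > 1) {
      best <- ix[order(-conf[ix], tuples$relation[ix])][1]
      ties <- ix[conf[ix] == conf[best] & ix != best]
      for (t_ in setdiff(ix, best)) {
        if (t_ %in% ties && !is.null(oracle) &&
            !is.null(oracle$judge_relation)) {
          v <- oracle$judge_relation(tuples$subject[t_], tuples$relation[t_],
                                     tuples$object[t_])
          if (isTRUE(v)) next
        }
        keep[t_] <- FALSE
        decision[t_] <- "conflict-drop"
      }
    }
  }
  log <- cbind(tuples, confidence = conf, decision = decision,
               stringsAsFactors = FALSE)
  retained <- tuples[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, log = log)
}

#' Fuse raw extractions into a knowledge graph
#'
#' Runs entity alignment first (so alias mention counts pool), rewrites
#' tuples onto canonical names, aggregates tuple counts, then applies
#' consistency analysis. Emits a before/after size report.
#'
#' @param extractions list with `entities` (data.frame `type`, `surface`,
#'   `count`) and `tuples` (data.frame `subject`, `relation`, `object`,
#'   `count`).
#' @param vectorizer entity vectorizer for alignment.
#' @param config a [fusion_config()].
#' @param oracle optional validation oracle (alignment + relation channels).
#' @param groundings optional named numeric DataGrounding values.
#' @return object of class `knowledge_graph`: `entities` (canonical, type,
#'   aliases, count), `tuples` (with counts), `report`, `alignment_log`,
#'   `consistency_log`.
#' @export
fuse <- function(extractions, vectorizer, config = fusion_config(),
                 oracle = NULL, groundings = NULL) {
  ents <- extractions$entities
  tups <- extractions$tuples
  if (is.null(ents) || !nrow(ents)) {
    return(structure(list(
      entities = data.frame(canonical = character(0), type = character(0),
                            count = numeric(0)),
      tuples = data.frame(subject = character(0), relation = character(0),
                          object = character(0), count = numeric(0)),
      report = list(entities_before = 0L, entities_after = 0L,
                    relations_before = 0L, relations_after = 0L),
      alignment_log = NULL, consistency_log = NULL, groundings = groundings),
      class = "knowledge_graph"))
  }
  al <- align_entities(ents, vectorizer, config, oracle)
  cl <- al$clusters
  canon_of <- stats::setNames(cl$canonical, cl$surface)
  canon <- stats::aggregate(count ~ type + canonical, data = cl, FUN = sum)
  aliases <- lapply(canon$canonical, function(cn)
    sort(cl$surface[cl$canonical == cn]))
  tup_out <- data.frame(subject = character(0), relation = character(0),
                        object = character(0), count = numeric(0))
  clog <- NULL
  if (!is.null(tups) && nrow(tups)) {
    tups$subject <- unname(ifelse(is.na(canon_of[tups$subject]),
                                  tups$subject, canon_of[tups$subject]))
    tups$object <- unname(ifelse(is.na(canon_of[tups$object]),
                                 tups$object, canon_of[tups$object]))
    tups <- stats::aggregate(count ~ subject + relation + object, data = tups,
                             FUN = sum)
    entity_counts <- stats::setNames(canon$count, canon$canonical)
    cons <- relation_consistency(tups, entity_counts, config, oracle)
    tup_out <- cons$retained
    clog <- cons$log
  }
  report <- list(entities_before = nrow(ents),
                 entities_after = nrow(canon),
                 relations_before = if (is.null(extractions$tuples)) 0L else
                   nrow(extractions$tuples),
                 relations_after = nrow(tup_out))
  structure(list(
    entities = data.frame(canonical = canon$canonical, type = canon$type,
                          count = canon$count, stringsAsFactors = FALSE,
                          aliases = I(aliases)),
    tuples = tup_out[order(tup_out$subject, tup_out$relation,
                           tup_out$object), , drop = FALSE],
    report = report, alignment_log = al$decisions, consistency_log = clog,
    groundings = groundings),
    class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  r <- x$report
  cat("<knowledge_graph>", nrow(x$entities), "entities,", nrow(x$tuples),
      "tuples\n  entities:", r$entities_before, "->", r$entities_after,
      "; relations:", r$relations_before, "->", r$relations_after, "\n")
  invisible(x)
}
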