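# shared constants and small helpers

#' Entity and relation schema
#'
#' The ontology has five entity classes and five relation types linking them.
#' `relation_schema()` returns one row per relation with its subject and
#' object entity types; the row order fixes the one-hot encoding used
#' throughout the package (hasSymptom first, needsTest second, then the
#' remaining relations in schema order).
#'
#' @return `entity_types()`: character vector of the five entity types.
#'   `relation_schema()`: data.frame with columns `relation`, `subject_type`,
#'   `object_type`.
#' @export
entity_types <- function() c("Disease", "Symptom", "Treatment", "Test", "Result")

#' @rdname entity_types
#' @export
relation_schema <- function() {
  data.frame(
    relation     = c("hasSymptom", "needsTest", "hasTestResult",
                     "needsTreatment", "hasResult"),
    subject_type = c("Disease", "Disease", "Disease", "Disease", "Test"),
    object_type  = c("Symptom", "Test", "Result", "Treatment", "Result"),
    stringsAsFactors = FALSE
  )
}

relation_types <- function() relation_schema()$relation

relation_onehot <- function(relation) {
  rels <- relation_types()
  i <- match(relation, rels)
  if (anyNA(i)) stop("unknown relation type: ", relation[is.na(i)][1])
  v <- numeric(length(rels))
  v[i] <- 1
  v
}

# sentence boundary marker used by the synthetic corpus and the miners
SENT_BOUNDARY <- "."

# run code under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# split token vector into sentences at the boundary marker; returns list of
# integer index vectors into the original token vector
sentence_spans <- function(tokens) {
  b <- which(tokens == SENT_BOUNDARY)
  starts <- c(1L, b + 1L)
  ends <- c(b - 1L, length(tokens))
  keep <- starts <= ends
  mapply(function(s, e) s:e, starts[keep], ends[keep], SIMPLIFY = FALSE)
}

# locate occurrences of a multi-token needle in a token vector
find_subseq <- function(tokens, needle) {
  n <- length(needle)
  if (n == 0L || length(tokens) < n) return(integer(0))
  hits <- which(tokens == needle[1])
  hits <- hits[hits + n - 1L <= length(tokens)]
  if (n > 1L) {
    ok <- vapply(hits, function(s)
      all(tokens[s:(s + n - 1L)] == needle), logical(1))
    hits <- hits[ok]
  }
  hits
}

entity_tokens <- function(entity_string) strsplit(entity_string, " ", fixed = TRUE)[[1]]

tuple_key <- function(subject, relation, object) {
  paste(subject, relation, object, sep = "\t")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
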