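# format readers/writers: JSON-lines corpus dialect, seed TSVs, KB exports

#' Write and read the JSON-lines corpus dialect
#'
#' One JSON object per line with fields `record_id`, `department`, `tokens`
#' and, when present, `gold_spans`, `gold_tuples`, `statement_count`. The
#' round trip is lossless including annotations; UTF-8 tokens are preserved.
#'
#' @param corpus a `synth_corpus` or plain list of `synth_record` objects.
#' @param path file path.
#' @return `read_corpus`: list of `synth_record` objects.
#' @export
write_corpus <- function(corpus, path) {
  records <- if (inherits(corpus, "synth_corpus")) corpus$records else corpus
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(
      record_id = r$record_id,
      department = r$department,
      tokens = r$tokens,
      gold_spans = r$gold_spans,
      gold_tuples = r$gold_tuples,
      statement_count = r$statement_count
    ), auto_unbox = TRUE, null = "null", dataframe = "rows")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
                    error = function(e)
                      stop("malformed corpus line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(obj$record_id) || is.null(obj$tokens))
      stop("malformed corpus line ", i, ": missing record_id/tokens",
           call. = FALSE)
    gs <- obj$gold_spans
    if (!is.null(gs) && length(gs)) gs <- as.data.frame(gs) else gs <- NULL
    gt <- obj$gold_tuples
    if (!is.null(gt) && length(gt)) gt <- as.data.frame(gt) else gt <- NULL
    structure(list(record_id = obj$record_id,
                   department = obj$department,
                   tokens = as.character(obj$tokens),
                   gold_spans = gs, gold_tuples = gt,
                   statement_count = obj$statement_count),
              class = "synth_record")
  })
}

#' Read and write seed lists
#'
#' Entity seeds: two-column TSV `type<TAB>string`. Relation seeds:
#' three-column TSV `subject<TAB>relation<TAB>object`.
#' @param path file path.
#' @param entity_seeds named list type -> character vector.
#' @param relation_seeds data.frame with subject, relation, object.
#' @export
write_entity_seeds <- function(entity_seeds, path) {
  df <- do.call(rbind, lapply(names(entity_seeds), function(tp)
    if (length(entity_seeds[[tp]]))
      data.frame(type = tp, string = entity_seeds[[tp]],
                 stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_entity_seeds
#' @export
read_entity_seeds <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "",
                          col.names = c("type", "string"),
                          stringsAsFactors = FALSE)
  split(df$string, factor(df$type, levels = unique(df$type)))
}

#' @rdname write_entity_seeds
#' @export
write_relation_seeds <- function(relation_seeds, path) {
  utils::write.table(relation_seeds[, c("subject", "relation", "object")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_entity_seeds
#' @export
read_relation_seeds <- function(path) {
  utils::read.table(path, sep = "\t", quote = "",
                    col.names = c("subject", "relation", "object"),
                    stringsAsFactors = FALSE)
}

kb_triples <- function(graph) {
  if (inherits(graph, "medkg_kb")) {
    tr <- graph$relations
    tr$aliases <- ""; tr$count <- NA_integer_
  } else if (inherits(graph, "knowledge_graph")) {
    tr <- graph$tuples[, c("subject", "relation", "object")]
    al <- vapply(tr$subject, function(s) {
      a <- graph$entities$aliases[[match(s, graph$entities$canonical)]]
      paste(setdiff(a, s), collapse = "|")
    }, character(1))
    tr$aliases <- al
    tr$count <- graph$tuples$count
  } else stop("unsupported graph object")
  tr <- tr[order(tr$subject, tr$relation, tr$object), , drop = FALSE]
  rownames(tr) <- NULL
  tr
}

#' Export a knowledge graph
#'
#' `tsv`: triples sorted by (subject, relation, object) with alias and count
#' columns. `turtle`: OWL-style Turtle declaring the five entity classes, the
#' five object properties and the DataGrounding data property, then all
#' instances. `json`: the full object.
#'
#' @param graph a `medkg_kb` or fused `knowledge_graph`.
#' @param path output file.
#' @param format one of `"tsv"`, `"turtle"`, `"json"`.
#' @export
export_kb <- function(graph, path, format = c("tsv", "turtle", "json")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown format '", format[1],
         "'; supported formats: tsv, turtle, json", call. = FALSE))
  if (format == "tsv") {
    utils::write.table(kb_triples(graph), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else if (format == "json") {
    jsonlite::write_json(unclass(graph), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    writeLines(kb_turtle(graph), path, useBytes = TRUE)
  }
  invisible(path)
}

ttl_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

kb_turtle <- function(graph) {
  ents <- if (inherits(graph, "medkg_kb")) kb_entity_frame(graph) else
    data.frame(type = graph$entities$type, entity = graph$entities$canonical,
               stringsAsFactors = FALSE)
  tr <- kb_triples(graph)
  groundings <- if (inherits(graph, "medkg_kb")) graph$groundings else
    graph$groundings %||% numeric(0)
  head <- c(
    "@prefix ex: <http://example.org/medkg#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "",
    vapply(entity_types(), function(tp)
      paste0("ex:", tp, " rdf:type owl:Class ."), character(1)),
    "",
    unlist(lapply(seq_len(nrow(relation_schema())), function(i) {
      s <- relation_schema()[i, ]
      c(paste0("ex:", s$relation, " rdf:type owl:ObjectProperty ;"),
        paste0("    rdfs:domain ex:", s$subject_type, " ;"),
        paste0("    rdfs:range ex:", s$object_type, " ."))
    })),
    "",
    "ex:DataGrounding rdf:type owl:DatatypeProperty ;",
    "    rdfs:domain ex:Result ;",
    "    rdfs:range xsd:decimal .",
    "")
  inst <- vapply(seq_len(nrow(ents)), function(i)
    paste0("ex:", ttl_id(ents$entity[i]), " rdf:type ex:", ents$type[i],
           " ; rdfs:label \"", ents$entity[i], "\" ."), character(1))
  rels <- if (nrow(tr)) vapply(seq_len(nrow(tr)), function(i)
    paste0("ex:", ttl_id(tr$subject[i]), " ex:", tr$relation[i],
           " ex:", ttl_id(tr$object[i]), " ."), character(1)) else character(0)
  grnd <- if (length(groundings)) vapply(seq_along(groundings), function(i)
    paste0("ex:", ttl_id(names(groundings)[i]), " ex:DataGrounding \"",
           groundings[[i]], "\"^^xsd:decimal ."), character(1)) else character(0)
  c(head, inst, "", rels, "", grnd)
}

#' Re-import a TSV knowledge-graph export
#' @param path TSV written by [export_kb()].
#' @return data.frame of triples with alias and count columns.
#' @export
import_kb_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "character", "integer"))
  df$aliases[is.na(df$aliases)] <- ""
  df
}
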