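# BIOES x entity-type tag scheme and linear-chain CRF scoring/decoding

type_codes <- function() c(Disease = "DIS", Symptom = "SYM", Treatment = "TRE",
                           Test = "TST", Result = "RES")

#' BIOES tag scheme over the five entity types
#'
#' 21 labels: `O` plus `{B,I,E,S} x {DIS,SYM,TRE,TST,RES}`. The transition
#' legality table (e.g. `I-DIS` may only follow `B-DIS` or `I-DIS`) is
#' derived from the scheme and used in decoding.
#'
#' @return list with `labels`, `index` (label -> integer), `legal`
#'   (L x L logical transition matrix), `start_legal`, `end_legal`.
#' @export
tag_scheme <- function() {
  codes <- unname(type_codes())
  labels <- c("O", as.vector(outer(c("B", "I", "E", "S"), codes,
                                   function(p, c) paste0(p, "-", c))))
  L <- length(labels)
  pre <- sub("-.*", "", labels)
  typ <- ifelse(labels == "O", "", sub(".*-", "", labels))
  legal <- matrix(FALSE, L, L, dimnames = list(labels, labels))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    from_open <- pre[i] %in% c("B", "I")        # inside an entity
    if (from_open) {
      legal[i, j] <- pre[j] %in% c("I", "E") && typ[j] == typ[i]
    } else {
      legal[i, j] <- pre[j] %in% c("O", "B", "S")
    }
  }
  start_legal <- pre %in% c("O", "B", "S")
  end_legal <- pre %in% c("O", "E", "S")
  list(labels = labels, index = stats::setNames(seq_len(L), labels),
       legal = legal, start_legal = start_legal, end_legal = end_legal)
}

#' Encode gold spans as BIOES labels / decode labels back to spans
#'
#' Spans are 0-based half-open over token indices. Encoding and decoding are
#' exact inverses for non-overlapping spans.
#'
#' @param n_tokens sentence length.
#' @param spans data.frame with `start`, `end`, `type` columns.
#' @param labels character vector of BIOES labels.
#' @return `spans_to_labels`: character vector of labels;
#'   `labels_to_spans`: data.frame `start`, `end`, `type`.
#' @export
spans_to_labels <- function(n_tokens, spans) {
  codes <- type_codes()
  lab <- rep("O", n_tokens)
  if (!is.null(spans) && nrow(spans)) for (i in seq_len(nrow(spans))) {
    s <- spans$start[i] + 1L; e <- spans$end[i]   # 1-based inclusive
    code <- codes[[spans$type[i]]]
    if (e == s) lab[s] <- paste0("S-", code)
    else {
      lab[s] <- paste0("B-", code)
      lab[e] <- paste0("E-", code)
      if (e > s + 1L) lab[(s + 1L):(e - 1L)] <- paste0("I-", code)
    }
  }
  lab
}

#' @rdname spans_to_labels
#' @export
labels_to_spans <- function(labels) {
  codes <- type_codes()
  rev_codes <- stats::setNames(names(codes), codes)
  out <- list()
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    l <- labels[i]
    if (l == "O") { i <- i + 1L; next }
    pre <- sub("-.*", "", l); code <- sub(".*-", "", l)
    if (pre == "S") {
      out[[length(out) + 1L]] <- data.frame(start = i - 1L, end = i,
                                            type = rev_codes[[code]])
      i <- i + 1L
    } else if (pre == "B") {
      j <- i + 1L
      while (j <= n && labels[j] == paste0("I-", code)) j <- j + 1L
      if (j <= n && labels[j] == paste0("E-", code)) {
        out[[length(out) + 1L]] <- data.frame(start = i - 1L, end = j,
                                              type = rev_codes[[code]])
        i <- j + 1L
      } else i <- i + 1L  # malformed open span: skip
    } else i <- i + 1L
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      type = character(0),
                                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df$type <- as.character(df$type)
  df
}

#' Linear-chain CRF path score
#'
#' `score(x, y) = A[start, y_1] + P[1, y_1] + sum_t (A[y_{t-1}, y_t] + P[t, y_t])`:
#' the sum of transition and emission scores along a label path, including
#' the start transition (row `L + 1` of `A`).
#'
#' @param P emission score matrix, T x L.
#' @param A transition score matrix, (L + 1) x L; row `L + 1` holds start
#'   transitions.
#' @param y integer label path of length T.
#' @return scalar path score.
#' @export
crf_sequence_score <- function(P, A, y) {
  L <- ncol(P)
  stopifnot(length(y) == nrow(P), nrow(A) == L + 1L)
  if (any(y < 1L | y > L)) stop("illegal label index in path")
  s <- A[L + 1L, y[1]] + P[1, y[1]]
  if (length(y) > 1L) for (t in 2:length(y))
    s <- s + A[y[t - 1L], y[t]] + P[t, y[t]]
  s
}

# log partition function by the forward algorithm (unconstrained)
crf_log_partition <- function(P, A) {
  L <- ncol(P); T_ <- nrow(P)
  alpha <- A[L + 1L, ] + P[1, ]
  if (T_ > 1L) for (t in 2:T_) {
    m <- max(alpha)
    alpha <- m + log(colSums(exp(alpha - m + A[seq_len(L), , drop = FALSE]))) +
      P[t, ]
  }
  m <- max(alpha)
  m + log(sum(exp(alpha - m)))
}

#' Viterbi decoding under BIOES legality
#'
#' Finds the label path maximizing the CRF path score subject to the legality
#' mask (transition table plus start/end legality). Ties break
#' deterministically toward the lowest label index.
#'
#' @param P emission matrix T x L.
#' @param A transition matrix (L + 1) x L with start row.
#' @param mask optional list with `legal` (L x L logical), `start_legal`,
#'   `end_legal`; defaults to no constraint.
#' @return integer label path of length T.
#' @export
viterbi_decode <- function(P, A, mask = NULL) {
  L <- ncol(P); T_ <- nrow(P)
  NEG <- -1e30
  legal <- mask$legal %||% matrix(TRUE, L, L)
  start_legal <- mask$start_legal %||% rep(TRUE, L)
  end_legal <- mask$end_legal %||% rep(TRUE, L)
  delta <- A[L + 1L, ] + P[1, ]
  delta[!start_legal] <- NEG
  back <- matrix(0L, T_, L)
  if (T_ > 1L) for (t in 2:T_) {
    scores <- delta + A[seq_len(L), , drop = FALSE]   # from x to
    scores[!legal] <- NEG
    best_from <- apply(scores, 2, which.max)          # first max: lowest index
    delta <- scores[cbind(best_from, seq_len(L))] + P[t, ]
    back[t, ] <- best_from
  }
  delta[!end_legal] <- NEG
  path <- integer(T_)
  path[T_] <- which.max(delta)
  if (T_ > 1L) for (t in T_:2) path[t - 1L] <- back[t, path[t]]
  path
}
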