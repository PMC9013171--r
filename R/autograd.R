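# Minimal tape-based reverse-mode automatic differentiation over R matrices.
# Vectors are column matrices; scalars are 1x1 matrices. Every op returns a
# node environment holding the value, the parent nodes and a closure that
# distributes the incoming gradient. Gradients are verified against central
# finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  force(value)   # nested calls must register their nodes first,
  force(parents) # so the creation index is a topological order
  n <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  n$idx <- .ad$counter
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  class(n) <- "ad_node"
  n
}

ad_const <- function(x) ad_node(as.matrix(x))

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

#' @noRd
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  # collect reachable nodes iteratively (graphs can be deep)
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$idx)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$idx, integer(1)), decreasing = TRUE)
  loss$grad <- matrix(1, 1, 1)
  for (i in ord) {
    n <- nodes[[i]]
    if (!is.null(n$backfn) && !is.null(n$grad)) n$backfn(n$grad)
  }
  invisible(loss)
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) {
    ad_accum(a, g); ad_accum(b, g)
  })
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g) {
    ad_accum(a, g); ad_accum(b, -g)
  })
}

ad_mul <- function(a, b) {
  ad_node(a$value * b$value, list(a, b), function(g) {
    ad_accum(a, g * b$value); ad_accum(b, g * a$value)
  })
}

ad_scale <- function(a, k) {
  ad_node(a$value * k, list(a), function(g) ad_accum(a, g * k))
}

ad_matmul <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    ad_accum(a, g %*% t(b$value)); ad_accum(b, t(a$value) %*% g)
  })
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_node(v, list(a), function(g) ad_accum(a, g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(v, list(a), function(g) ad_accum(a, g * v * (1 - v)))
}

ad_relu <- function(a) {
  v <- pmax(a$value, 0)
  ad_node(v, list(a), function(g) ad_accum(a, g * (a$value > 0)))
}

ad_vcat <- function(...) {
  ps <- list(...)
  rows <- vapply(ps, function(p) nrow(p$value), integer(1))
  ad_node(do.call(rbind, lapply(ps, function(p) p$value)), ps, function(g) {
    at <- 0L
    for (k in seq_along(ps)) {
      ad_accum(ps[[k]], g[at + seq_len(rows[k]), , drop = FALSE])
      at <- at + rows[k]
    }
  })
}

ad_hcat <- function(...) {
  ps <- list(...)
  cols <- vapply(ps, function(p) ncol(p$value), integer(1))
  ad_node(do.call(cbind, lapply(ps, function(p) p$value)), ps, function(g) {
    at <- 0L
    for (k in seq_along(ps)) {
      ad_accum(ps[[k]], g[, at + seq_len(cols[k]), drop = FALSE])
      at <- at + cols[k]
    }
  })
}

ad_slice_cols <- function(a, cols) {
  ad_node(a$value[, cols, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    ga[, cols] <- g
    ad_accum(a, ga)
  })
}

# regroup consecutive row blocks: (g*m x k) -> (m x g*k), row j the
# concatenation of rows (j-1)*g+1 .. j*g
ad_group_rows <- function(a, g) {
  v <- a$value
  m <- nrow(v) %/% g; k <- ncol(v)
  stopifnot(nrow(v) == m * g)
  out <- matrix(0, m, g * k)
  for (j in seq_len(m))
    out[j, ] <- as.vector(t(v[(j - 1L) * g + seq_len(g), , drop = FALSE]))
  ad_node(out, list(a), function(gr) {
    ga <- matrix(0, nrow(v), k)
    for (j in seq_len(m))
      ga[(j - 1L) * g + seq_len(g), ] <- matrix(gr[j, ], g, k, byrow = TRUE)
    ad_accum(a, ga)
  })
}

# flatten a matrix into a single row (row-major over rows)
ad_flatten_row <- function(a) {
  nr <- nrow(a$value); nc <- ncol(a$value)
  ad_node(matrix(as.vector(t(a$value)), 1), list(a), function(g) {
    ad_accum(a, matrix(g[1, ], nr, nc, byrow = TRUE))
  })
}

ad_slice <- function(a, rows) {
  ad_node(a$value[rows, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    ga[rows, ] <- g
    ad_accum(a, ga)
  })
}

# rows of an embedding table; gradients accumulate per index
ad_gather <- function(E, idx) {
  ad_node(E$value[idx, , drop = FALSE], list(E), function(g) {
    gE <- matrix(0, nrow(E$value), ncol(E$value))
    for (k in seq_along(idx)) gE[idx[k], ] <- gE[idx[k], ] + g[k, ]
    ad_accum(E, gE)
  })
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$value), 1, 1), list(a), function(g) {
    ad_accum(a, matrix(g[1, 1], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$value))

# column-wise max over rows: X (n x m) -> (1 x m), used for max pooling
ad_maxcol <- function(a) {
  am <- apply(a$value, 2, which.max)
  v <- matrix(a$value[cbind(am, seq_len(ncol(a$value)))], 1)
  ad_node(v, list(a), function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    ga[cbind(am, seq_len(ncol(ga)))] <- g[1, ]
    ad_accum(a, ga)
  })
}

# row-vector bias broadcast: X (n x m) + b (1 x m)
ad_addbias <- function(X, b) {
  ad_node(sweep(X$value, 2, b$value[1, ], "+"), list(X, b), function(g) {
    ad_accum(X, g); ad_accum(b, matrix(colSums(g), 1))
  })
}

# mean negative log-likelihood of a softmax over rows of logits
ad_softmax_nll <- function(logits, targets) {
  L <- logits$value
  m <- apply(L, 1, max)
  lse <- m + log(rowSums(exp(L - m)))
  picked <- L[cbind(seq_len(nrow(L)), targets)]
  nll <- mean(lse - picked)
  ad_node(matrix(nll, 1, 1), list(logits), function(g) {
    P <- exp(L - lse)  # row softmax
    P[cbind(seq_len(nrow(L)), targets)] <-
      P[cbind(seq_len(nrow(L)), targets)] - 1
    ad_accum(logits, g[1, 1] * P / nrow(L))
  })
}

# cross-entropy of row softmaxes against the uniform distribution
ad_softmax_uniform_nll <- function(logits) {
  L <- logits$value
  m <- apply(L, 1, max)
  lse <- m + log(rowSums(exp(L - m)))
  nll <- mean(lse - rowMeans(L))
  ad_node(matrix(nll, 1, 1), list(logits), function(g) {
    P <- exp(L - lse)
    ad_accum(logits, g[1, 1] * (P - 1 / ncol(L)) / nrow(L))
  })
}

# cosine similarity of two vectors (any orientation) as a scalar node
ad_cosine <- function(u, v) {
  uu <- as.vector(u$value); vv <- as.vector(v$value)
  nu <- sqrt(sum(uu^2)); nv <- sqrt(sum(vv^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  c0 <- sum(uu * vv) / (nu * nv)
  ad_node(matrix(c0, 1, 1), list(u, v), function(g) {
    gs <- g[1, 1]
    gu <- gs * (vv / (nu * nv) - c0 * uu / nu^2)
    gv <- gs * (uu / (nu * nv) - c0 * vv / nv^2)
    dim(gu) <- dim(u$value); dim(gv) <- dim(v$value)
    ad_accum(u, gu)
    ad_accum(v, gv)
  })
}

# ---- parameter store & optimizer -------------------------------------------

ad_params_wrap <- function(params) lapply(params, ad_const)

ad_grads <- function(nodes) {
  lapply(nodes, function(n) {
    if (is.null(n$grad)) matrix(0, nrow(n$value), ncol(n$value)) else n$grad
  })
}

adam_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr = 1e-2, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    nrm <- sqrt(sum(g^2))
    if (is.finite(nrm) && nrm > clip) g <- g * (clip / nrm)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
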