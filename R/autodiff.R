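# Minimal tape-based reverse-mode automatic differentiation over numeric
# matrices.  Every value is a matrix; scalars are 1x1.  Parameters are
# persistent leaf nodes whose gradients accumulate across forward/backward
# passes until ad_zero_grads(); intermediate nodes live on a tape that is
# reset before each forward pass.  Gradient correctness is checked against
# central finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

ad_reset_tape <- function() {
  .ad$id <- 0L
  invisible(NULL)
}

.ad_new <- function(val, parents = NULL, backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  requires <- FALSE
  if (!is.null(parents)) {
    for (p in parents) if (p$requires) { requires <- TRUE; break }
  }
  e$requires <- requires
  if (requires) {
    e$parents <- parents
    e$backward <- backward
    e$id <- .ad$id <- .ad$id + 1L
    e$seen <- FALSE
  }
  e
}

# constant leaf (no gradient ever flows into it)
ad_const <- function(val) {
  if (!is.matrix(val)) val <- as.matrix(val)
  e <- new.env(parent = emptyenv())
  e$val <- val; e$grad <- NULL; e$requires <- FALSE
  e
}

# trainable leaf; persists across tapes, gradient accumulates
ad_param <- function(val) {
  if (!is.matrix(val)) val <- as.matrix(val)
  e <- new.env(parent = emptyenv())
  e$val <- val; e$grad <- NULL; e$requires <- TRUE; e$is_param <- TRUE
  e
}

.acc <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# run backward from a scalar loss node: collect the reachable interior nodes
# by iterative depth-first search, then replay them in reverse creation
# order (a valid reverse-topological order, since parents predate children)
ad_backward <- function(loss) {
  stopifnot(loss$requires)
  nodes <- vector("list", 256L); k <- 0L
  stack <- vector("list", 256L); sp <- 1L
  stack[[1L]] <- loss
  loss$seen <- TRUE
  while (sp > 0L) {
    nd <- stack[[sp]]; sp <- sp - 1L
    k <- k + 1L
    if (k > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[k]] <- nd
    for (p in nd$parents) {
      if (p$requires && !is.null(p$backward) && !p$seen) {
        p$seen <- TRUE
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[sp]] <- p
      }
    }
  }
  nodes <- nodes[seq_len(k)]
  ids <- vapply(nodes, function(e) e$id, integer(1))
  loss$grad <- matrix(1, 1L, 1L)
  for (nd in nodes[order(ids, decreasing = TRUE)]) nd$backward(nd)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# operations

ad_matmul <- function(a, b) {
  .ad_new(a$val %*% b$val, list(a, b), function(nd) {
    g <- nd$grad
    .acc(nd$parents[[1]], g %*% t(nd$parents[[2]]$val))
    .acc(nd$parents[[2]], t(nd$parents[[1]]$val) %*% g)
  })
}

ad_add <- function(a, b) {
  .ad_new(a$val + b$val, list(a, b), function(nd) {
    .acc(nd$parents[[1]], nd$grad)
    .acc(nd$parents[[2]], nd$grad)
  })
}

ad_sub <- function(a, b) {
  .ad_new(a$val - b$val, list(a, b), function(nd) {
    .acc(nd$parents[[1]], nd$grad)
    .acc(nd$parents[[2]], -nd$grad)
  })
}

# add a 1 x n bias row to every row of a (B x n)
ad_add_bias <- function(a, b) {
  v <- a$val
  .ad_new(v + rep(b$val, each = nrow(v)), list(a, b), function(nd) {
    g <- nd$grad
    .acc(nd$parents[[1]], g)
    .acc(nd$parents[[2]], matrix(colSums(g), 1L))
  })
}

ad_mul <- function(a, b) {
  .ad_new(a$val * b$val, list(a, b), function(nd) {
    g <- nd$grad
    .acc(nd$parents[[1]], g * nd$parents[[2]]$val)
    .acc(nd$parents[[2]], g * nd$parents[[1]]$val)
  })
}

# multiply row i of a (M x d) by w[i] (w is M x 1)
ad_cmul <- function(a, w) {
  wv <- as.vector(w$val)
  .ad_new(a$val * wv, list(a, w), function(nd) {
    g <- nd$grad
    av <- nd$parents[[1]]$val
    .acc(nd$parents[[1]], g * as.vector(nd$parents[[2]]$val))
    .acc(nd$parents[[2]], matrix(rowSums(g * av), ncol = 1L))
  })
}

# elementwise product with a fixed numeric matrix (dropout masks, seq masks)
ad_mulc <- function(a, m) {
  .ad_new(a$val * m, list(a), local({
    mm <- m
    function(nd) .acc(nd$parents[[1]], nd$grad * mm)
  }))
}

# add a fixed numeric matrix
ad_addc <- function(a, m) {
  .ad_new(a$val + m, list(a), function(nd) .acc(nd$parents[[1]], nd$grad))
}

ad_scale <- function(a, k) {
  .ad_new(a$val * k, list(a), local({
    kk <- k
    function(nd) .acc(nd$parents[[1]], nd$grad * kk)
  }))
}

ad_tanh <- function(a) {
  .ad_new(tanh(a$val), list(a), function(nd) {
    .acc(nd$parents[[1]], nd$grad * (1 - nd$val^2))
  })
}

ad_sigmoid <- function(a) {
  .ad_new(1 / (1 + exp(-a$val)), list(a), function(nd) {
    .acc(nd$parents[[1]], nd$grad * nd$val * (1 - nd$val))
  })
}

ad_relu <- function(a) {
  .ad_new(pmax(a$val, 0), list(a), function(nd) {
    .acc(nd$parents[[1]], nd$grad * (nd$parents[[1]]$val > 0))
  })
}

# numerically stable row-wise softmax
ad_softmax_rows <- function(a) {
  v <- a$val
  m <- v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]
  e <- exp(v - m)
  s <- e / rowSums(e)
  .ad_new(s, list(a), function(nd) {
    g <- nd$grad
    sv <- nd$val
    rs <- rowSums(g * sv)
    .acc(nd$parents[[1]], sv * (g - rs))
  })
}

ad_sum <- function(a) {
  .ad_new(matrix(sum(a$val), 1L, 1L), list(a), function(nd) {
    p <- nd$parents[[1]]
    .acc(p, matrix(nd$grad[1L], nrow(p$val), ncol(p$val)))
  })
}

ad_t <- function(a) {
  .ad_new(t(a$val), list(a), function(nd) .acc(nd$parents[[1]], t(nd$grad)))
}

# select rows idx of an embedding-style parameter (with repetition)
ad_rows <- function(a, idx) {
  .ad_new(a$val[idx, , drop = FALSE], list(a), local({
    ii <- idx
    function(nd) {
      p <- nd$parents[[1]]
      rs <- rowsum(nd$grad, ii)
      g <- matrix(0, nrow(p$val), ncol(p$val))
      g[as.integer(rownames(rs)), ] <- rs
      .acc(p, g)
    }
  }))
}

# max over rows for each column (max-over-time pooling): T x F -> 1 x F
ad_maxcol <- function(a) {
  v <- a$val
  am <- max.col(t(v), ties.method = "first")
  .ad_new(matrix(v[cbind(am, seq_len(ncol(v)))], 1L), list(a), local({
    idx <- am
    function(nd) {
      p <- nd$parents[[1]]
      g <- matrix(0, nrow(p$val), ncol(p$val))
      g[cbind(idx, seq_len(ncol(g)))] <- nd$grad[1L, ]
      .acc(p, g)
    }
  }))
}

# stack a list of 1 x d rows into an n x d matrix
ad_vcat <- function(rows) {
  vals <- lapply(rows, function(r) r$val)
  .ad_new(do.call(rbind, vals), rows, local({
    nr <- vapply(vals, nrow, integer(1))
    function(nd) {
      g <- nd$grad
      at <- 0L
      for (j in seq_along(nd$parents)) {
        .acc(nd$parents[[j]], g[at + seq_len(nr[j]), , drop = FALSE])
        at <- at + nr[j]
      }
    }
  }))
}

ad_hcat <- function(a, b) {
  na <- ncol(a$val)
  .ad_new(cbind(a$val, b$val), list(a, b), local({
    ka <- na
    function(nd) {
      g <- nd$grad
      .acc(nd$parents[[1]], g[, seq_len(ka), drop = FALSE])
      .acc(nd$parents[[2]], g[, -seq_len(ka), drop = FALSE])
    }
  }))
}

# sort every row into descending order (used to make the rumination
# relevance profile invariant to post storage order)
ad_sort_rows_desc <- function(a) {
  v <- a$val
  ords <- t(apply(v, 1L, order, decreasing = TRUE))
  if (ncol(v) == 1L) ords <- matrix(ords, nrow(v))
  val <- v
  for (i in seq_len(nrow(v))) val[i, ] <- v[i, ords[i, ]]
  .ad_new(val, list(a), local({
    oo <- ords
    function(nd) {
      g <- nd$grad
      gp <- g
      for (i in seq_len(nrow(g))) gp[i, oo[i, ]] <- g[i, ]
      .acc(nd$parents[[1]], gp)
    }
  }))
}

# right-pad with zero columns (or truncate) to exactly k columns
ad_pad_cols <- function(a, k) {
  v <- a$val
  nc <- ncol(v)
  if (nc == k) return(a)
  val <- if (nc > k) v[, seq_len(k), drop = FALSE] else
    cbind(v, matrix(0, nrow(v), k - nc))
  .ad_new(val, list(a), local({
    n0 <- nc; kk <- k
    function(nd) {
      g <- nd$grad
      gp <- if (n0 > kk) cbind(g, matrix(0, nrow(g), n0 - kk)) else
        g[, seq_len(n0), drop = FALSE]
      .acc(nd$parents[[1]], gp)
    }
  }))
}

# select columns idx of a node
ad_cols <- function(a, idx) {
  .ad_new(a$val[, idx, drop = FALSE], list(a), local({
    ii <- idx
    function(nd) {
      p <- nd$parents[[1]]
      g <- matrix(0, nrow(p$val), ncol(p$val))
      g[, ii] <- g[, ii] + nd$grad
      .acc(p, g)
    }
  }))
}

# normalize every row to unit Euclidean norm
ad_unit_rows <- function(a) {
  v <- a$val
  r <- sqrt(rowSums(v^2))
  r[r == 0] <- 1
  y <- v / r
  .ad_new(y, list(a), local({
    rr <- r
    function(nd) {
      g <- nd$grad
      yv <- nd$val
      .acc(nd$parents[[1]], (g - yv * rowSums(g * yv)) / rr)
    }
  }))
}

# binary cross-entropy from a scalar logit (numerically stable)
ad_bce_with_logit <- function(z, y) {
  zv <- z$val[1L]
  loss <- max(zv, 0) - zv * y + log1p(exp(-abs(zv)))
  .ad_new(matrix(loss, 1L, 1L), list(z), local({
    yy <- y
    function(nd) {
      zz <- nd$parents[[1]]$val[1L]
      p <- 1 / (1 + exp(-zz))
      .acc(nd$parents[[1]], nd$grad * matrix(p - yy, 1L, 1L))
    }
  }))
}

# inverted dropout with a freshly drawn mask (training only)
ad_dropout <- function(a, rate) {
  if (rate <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$val), 1L, 1 - rate), nrow(a$val)) / (1 - rate)
  ad_mulc(a, mask)
}
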