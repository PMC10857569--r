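# Minimal reverse-mode automatic differentiation on a tape of matrix
# operations. This is deliberately small: just the operations the
# architecture-searched message-passing model needs (dense/sparse matrix
# products, elementwise nonlinearities, concatenation, neighbourhood max,
# convex mixtures weighted by Gumbel-softmax samples, and a binary
# cross-entropy loss). Gradients are validated against central finite
# differences in the test suite.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t
}

ad_node <- function(tape, value, parents = list(), bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

ad_const <- function(tape, x) ad_node(tape, x)

ad_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the tape.
ad_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || is.null(n$bw)) next
    n$bw(n)
  }
  invisible(NULL)
}

zeros_like <- function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

# ---- operations ------------------------------------------------------------

# a %*% b; either operand may be a constant R matrix (incl. sparse Matrix)
ad_mm <- function(tape, a, b) {
  av <- if (is.environment(a)) a$value else a
  bv <- if (is.environment(b)) b$value else b
  parents <- Filter(is.environment, list(a, b))
  ad_node(tape, as.matrix(av %*% bv), parents, bw = function(n) {
    g <- n$grad
    if (is.environment(a)) ad_accum(a, as.matrix(g %*% Matrix::t(bv)))
    if (is.environment(b)) ad_accum(b, as.matrix(Matrix::t(av) %*% g))
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), bw = function(n) {
    ad_accum(a, n$grad); ad_accum(b, n$grad)
  })
}

# add a 1 x k row vector (bias) to every row
ad_add_bias <- function(tape, a, bias) {
  ad_node(tape, sweep(a$value, 2, bias$value, "+"), list(a, bias),
          bw = function(n) {
            ad_accum(a, n$grad); ad_accum(bias, colSums(n$grad))
          })
}

ad_relu <- function(tape, a) {
  ad_node(tape, pmax(a$value, 0), list(a), bw = function(n) {
    ad_accum(a, n$grad * (a$value > 0))
  })
}

# PReLU with a scalar learnable negative slope
ad_prelu <- function(tape, a, slope) {
  s <- as.numeric(slope$value)
  neg <- a$value < 0
  ad_node(tape, ifelse(neg, s * a$value, a$value), list(a, slope),
          bw = function(n) {
            ad_accum(a, n$grad * ifelse(neg, s, 1))
            ad_accum(slope, sum(n$grad * a$value * neg))
          })
}

ad_concat_cols <- function(tape, a, b) {
  ka <- ncol(a$value)
  ad_node(tape, cbind(a$value, b$value), list(a, b), bw = function(n) {
    ad_accum(a, n$grad[, seq_len(ka), drop = FALSE])
    ad_accum(b, n$grad[, -seq_len(ka), drop = FALSE])
  })
}

ad_concat_rows <- function(tape, nodes) {
  sizes <- vapply(nodes, function(x) nrow(x$value), integer(1))
  ends <- cumsum(sizes)
  ad_node(tape, do.call(rbind, lapply(nodes, function(x) x$value)), nodes,
          bw = function(n) {
            for (i in seq_along(nodes)) {
              rows <- (ends[i] - sizes[i] + 1L):ends[i]
              ad_accum(nodes[[i]], n$grad[rows, , drop = FALSE])
            }
          })
}

# elementwise max of two same-shape matrices; ties differentiate to `a`
ad_emax <- function(tape, a, b) {
  mask <- a$value >= b$value
  ad_node(tape, pmax(a$value, b$value), list(a, b), bw = function(n) {
    ad_accum(a, n$grad * mask)
    ad_accum(b, n$grad * !mask)
  })
}

# row selection with repetition; gradient scatter-adds into source rows
ad_rows <- function(tape, a, idx) {
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), bw = function(n) {
    g <- rowsum(n$grad, group = idx)
    full <- zeros_like(a$value)
    full[as.integer(rownames(g)), ] <- g
    ad_accum(a, full)
  })
}

# per-node columnwise max over each node's neighbour rows of `h`
# (empty neighbourhood -> zero vector); nlist is a list of integer vectors
ad_neigh_max <- function(tape, h, nlist) {
  hv <- h$value
  n <- length(nlist)
  d <- ncol(hv)
  out <- matrix(0, n, d)
  arg <- matrix(0L, n, d)
  for (v in seq_len(n)) {
    nb <- nlist[[v]]
    if (!length(nb)) next
    sub <- hv[nb, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    arg[v, ] <- nb[w]
    out[v, ] <- sub[cbind(w, seq_len(d))]
  }
  ad_node(tape, out, list(h), bw = function(nd) {
    g <- zeros_like(hv)
    for (v in seq_len(n)) {
      if (arg[v, 1] == 0L) next
      ix <- cbind(arg[v, ], seq_len(d))
      g[ix] <- g[ix] + nd$grad[v, ]
    }
    ad_accum(h, g)
  })
}

# convex mixture sum_i eps[i] * M_i with eps a vector-valued node
ad_mix <- function(tape, mats, eps) {
  e <- as.numeric(eps$value)
  stopifnot(length(mats) == length(e))
  val <- Reduce(`+`, Map(function(m, w) w * m$value, mats, e))
  ad_node(tape, val, c(mats, list(eps)), bw = function(n) {
    ge <- numeric(length(mats))
    for (i in seq_along(mats)) {
      ad_accum(mats[[i]], e[i] * n$grad)
      ge[i] <- sum(n$grad * mats[[i]]$value)
    }
    ad_accum(eps, ge)
  })
}

# pick one element of a vector node as a scalar node
ad_elem <- function(tape, v, i) {
  ad_node(tape, as.numeric(v$value)[i], list(v), bw = function(n) {
    g <- zeros_like(as.numeric(v$value))
    g[i] <- n$grad
    ad_accum(v, g)
  })
}

ad_smul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), bw = function(n) {
    ad_accum(a, n$grad * b$value)
    ad_accum(b, n$grad * a$value)
  })
}

# scale a matrix node by a scalar node
ad_scale_by <- function(tape, m, s) {
  ad_node(tape, as.numeric(s$value) * m$value, list(m, s), bw = function(n) {
    ad_accum(m, as.numeric(s$value) * n$grad)
    ad_accum(s, sum(n$grad * m$value))
  })
}

# scale each column j of a matrix node by s[j] (vector-valued node)
ad_colscale <- function(tape, m, s) {
  sv <- as.numeric(s$value)
  ad_node(tape, sweep(m$value, 2, sv, "*"), list(m, s), bw = function(n) {
    ad_accum(m, sweep(n$grad, 2, sv, "*"))
    ad_accum(s, colSums(n$grad * m$value))
  })
}

# row-wise dot product of two same-shape matrices -> n x 1 column
ad_rowdot <- function(tape, a, b) {
  ad_node(tape, matrix(rowSums(a$value * b$value), ncol = 1), list(a, b),
          bw = function(n) {
            g <- as.numeric(n$grad)
            ad_accum(a, b$value * g)
            ad_accum(b, a$value * g)
          })
}

# Gumbel-softmax relaxation: eps = softmax((alpha + g) / tau) where alpha
# are log-weights and g = -log(-log U) are fixed Gumbel draws
ad_gumbel_softmax <- function(tape, alpha, gumbel, tau) {
  z <- (as.numeric(alpha$value) + gumbel) / tau
  z <- z - max(z)
  e <- exp(z)
  p <- e / sum(e)
  ad_node(tape, p, list(alpha), bw = function(n) {
    g <- n$grad
    ad_accum(alpha, (p * g - p * sum(p * g)) / tau)
  })
}

# mean binary cross-entropy with logits (stable softplus form)
ad_bce_logits <- function(tape, logits, y) {
  z <- as.numeric(logits$value)
  val <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  ad_node(tape, val, list(logits), bw = function(n) {
    g <- (plogis(z) - y) / length(z) * n$grad
    ad_accum(logits, matrix(g, ncol = 1))
  })
}

# ---- parameters and optimiser ---------------------------------------------

# Parameter store: named list of numeric arrays living outside any tape;
# each forward pass wraps them into fresh nodes via ad_wrap_params().
ad_wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_node(tape, p))
}

adam_state <- function(params) {
  list(m = lapply(params, zeros_like), v = lapply(params, zeros_like),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    # decoupled weight decay (AdamW)
    params[[k]] <- params[[k]] * (1 - lr * weight_decay) -
      lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
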