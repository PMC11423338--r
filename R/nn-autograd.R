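# Minimal reverse-mode automatic differentiation over matrix operations.
#
# Nodes are environments holding $value (a matrix), $grad, and a $backward
# closure that routes the incoming gradient to the parents. Operations that
# create differentiable nodes append them to a global tape; backward() walks
# the tape in reverse creation order, which is a valid topological order.
# Parameters are off-tape leaf nodes whose gradients accumulate across the
# walk. This is deliberately small: just what GRU/conv/batchnorm VAEs need,
# validated against numerical differentiation in the test suite.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$n <- 0L

agResetTape <- function() {
  .ag$tape <- vector("list", 2048L)
  .ag$n <- 0L
  invisible(NULL)
}

.ag_record <- function(nd) {
  .ag$n <- .ag$n + 1L
  if (.ag$n > length(.ag$tape)) length(.ag$tape) <- 2L * length(.ag$tape)
  .ag$tape[[.ag$n]] <- nd
  nd
}

agNode <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$leaf <- is.null(backward)
  nd$backward <- backward
  if (!is.null(backward)) .ag_record(nd)
  nd
}

# parameters get a freshly allocated value matrix: the optimizer updates
# them in place, so they must never share memory with another R object
agParam <- function(value) {
  value <- as.matrix(value)
  agNode(matrix(as.numeric(value), nrow(value), ncol(value)))
}

agConst <- function(x) {
  if (is.environment(x)) return(x)
  nd <- agNode(as.matrix(x))
  nd$const <- TRUE
  nd
}

.acc <- function(nd, g) {
  if (isTRUE(nd$const)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# accumulate into a row/column block of the parent's gradient without
# materializing a full-size sparse update (hot path for per-timestep slices)
.acc_rows <- function(nd, rows, g) {
  if (isTRUE(nd$const)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- matrix(0, nrow(nd$value), ncol(nd$value))
  nd$grad[rows, ] <- nd$grad[rows, , drop = FALSE] + g
  invisible(NULL)
}

.acc_cols <- function(nd, cols, g) {
  if (isTRUE(nd$const)) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- matrix(0, nrow(nd$value), ncol(nd$value))
  nd$grad[, cols] <- nd$grad[, cols, drop = FALSE] + g
  invisible(NULL)
}

agBackward <- function(loss) {
  loss$grad <- matrix(1, nrow(loss$value), ncol(loss$value))
  for (i in rev(seq_len(.ag$n))) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# global gradient-norm clipping (standard training stabilizer)
clipGradNorm <- function(params, maxNorm = 10) {
  tot <- 0
  for (p in params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
  tot <- sqrt(tot)
  if (is.finite(tot) && tot > maxNorm) {
    s <- maxNorm / tot
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * s
  }
  invisible(tot)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- operations ------------------------------------------------------------

agMatmul <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agNode(a$value %*% b$value, function(g) {
    .acc(a, g %*% t(b$value))
    .acc(b, t(a$value) %*% g)
  })
}

agAdd <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agNode(a$value + b$value, function(g) { .acc(a, g); .acc(b, g) })
}

agSub <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agNode(a$value - b$value, function(g) { .acc(a, g); .acc(b, -g) })
}

agMul <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agNode(a$value * b$value, function(g) {
    .acc(a, g * b$value)
    .acc(b, g * a$value)
  })
}

agScale <- function(a, s) {
  a <- agConst(a)
  agNode(a$value * s, function(g) .acc(a, g * s))
}

agAddBias <- function(x, b) {
  # b is a 1 x n parameter broadcast over rows of x
  x <- agConst(x); b <- agConst(b)
  agNode(sweep(x$value, 2L, as.numeric(b$value), "+"), function(g) {
    .acc(x, g)
    .acc(b, matrix(colSums(g), 1L))
  })
}

agSigmoid <- function(x) {
  x <- agConst(x)
  v <- 1 / (1 + exp(-x$value))
  agNode(v, function(g) .acc(x, g * v * (1 - v)))
}

agTanh <- function(x) {
  x <- agConst(x)
  v <- tanh(x$value)
  agNode(v, function(g) .acc(x, g * (1 - v * v)))
}

agRelu <- function(x) {
  x <- agConst(x)
  v <- pmax(x$value, 0)
  agNode(v, function(g) .acc(x, g * (x$value > 0)))
}

.SELU_ALPHA <- 1.6732632423543772848170429916717
.SELU_LAMBDA <- 1.0507000009873554804934193349852946

agSelu <- function(x) {
  x <- agConst(x)
  pos <- x$value > 0
  v <- ifelse(pos, .SELU_LAMBDA * x$value,
              .SELU_LAMBDA * .SELU_ALPHA * (exp(x$value) - 1))
  dim(v) <- dim(x$value)
  agNode(v, function(g) {
    d <- ifelse(pos, .SELU_LAMBDA,
                .SELU_LAMBDA * .SELU_ALPHA * exp(x$value))
    dim(d) <- dim(x$value)
    .acc(x, g * d)
  })
}

agExp <- function(x) {
  x <- agConst(x)
  v <- exp(x$value)
  agNode(v, function(g) .acc(x, g * v))
}

agSquare <- function(x) {
  x <- agConst(x)
  agNode(x$value^2, function(g) .acc(x, 2 * g * x$value))
}

agAbs <- function(x) {
  x <- agConst(x)
  agNode(abs(x$value), function(g) .acc(x, g * sign(x$value)))
}

agOneMinus <- function(x) {
  x <- agConst(x)
  agNode(1 - x$value, function(g) .acc(x, -g))
}

agSumAll <- function(x) {
  x <- agConst(x)
  agNode(matrix(sum(x$value), 1L, 1L), function(g) {
    .acc(x, matrix(g[1L], nrow(x$value), ncol(x$value)))
  })
}

agColMeans <- function(x) {
  x <- agConst(x)
  n <- nrow(x$value)
  agNode(matrix(colMeans(x$value), 1L), function(g) {
    .acc(x, matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

agSweepSub <- function(x, rv) {
  # x minus a 1 x n row vector, broadcast over rows
  x <- agConst(x); rv <- agConst(rv)
  agNode(sweep(x$value, 2L, as.numeric(rv$value), "-"), function(g) {
    .acc(x, g)
    .acc(rv, matrix(-colSums(g), 1L))
  })
}

agSweepDivVec <- function(x, dv) {
  # x divided columnwise by a positive 1 x n row vector
  x <- agConst(x); dv <- agConst(dv)
  d <- as.numeric(dv$value)
  v <- sweep(x$value, 2L, d, "/")
  agNode(v, function(g) {
    .acc(x, sweep(g, 2L, d, "/"))
    .acc(dv, matrix(-colSums(g * v) / d, 1L))
  })
}

agPowConst <- function(x, p) {
  x <- agConst(x)
  agNode(x$value^p, function(g) .acc(x, g * p * x$value^(p - 1)))
}

agAddScalar <- function(x, s) {
  x <- agConst(x)
  agNode(x$value + s, function(g) .acc(x, g))
}

agCols <- function(x, idx) {
  x <- agConst(x)
  agNode(x$value[, idx, drop = FALSE], function(g) .acc_cols(x, idx, g))
}

agRowsRange <- function(x, from, to) {
  x <- agConst(x)
  agNode(x$value[from:to, , drop = FALSE],
         function(g) .acc_rows(x, from:to, g))
}

agLerpConst <- function(m, a, b) {
  # m * a + (1 - m) * b with a constant mask m (no gradient w.r.t. m)
  a <- agConst(a); b <- agConst(b)
  agNode(m * a$value + (1 - m) * b$value, function(g) {
    .acc(a, g * m)
    .acc(b, g * (1 - m))
  })
}

agColcat <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  na <- ncol(a$value)
  agNode(cbind(a$value, b$value), function(g) {
    .acc(a, g[, seq_len(na), drop = FALSE])
    .acc(b, g[, -seq_len(na), drop = FALSE])
  })
}

agRowbind <- function(nodes) {
  nodes <- lapply(nodes, agConst)
  sizes <- vapply(nodes, function(nd) nrow(nd$value), 0L)
  ends <- cumsum(sizes)
  vals <- lapply(nodes, function(nd) nd$value)
  agNode(do.call(rbind, vals), function(g) {
    for (i in seq_along(nodes)) {
      .acc(nodes[[i]],
           g[(ends[i] - sizes[i] + 1L):ends[i], , drop = FALSE])
    }
  })
}

agEmbed <- function(W, idx) {
  # W: vocab x d parameter; idx: integer vector of rows (with repeats)
  W <- agConst(W)
  agNode(W$value[idx, , drop = FALSE], function(g) {
    gg <- rowsum(g, idx)
    rows <- as.integer(rownames(gg))
    full <- matrix(0, nrow(W$value), ncol(W$value))
    full[rows, ] <- gg
    .acc(W, full)
  })
}

agTileRows <- function(z, times) {
  # vertically tile a B x d matrix `times` times (time-major layout)
  z <- agConst(z)
  B <- nrow(z$value)
  idx <- rep(seq_len(B), times = times)
  agNode(z$value[idx, , drop = FALSE], function(g) {
    .acc(z, rowsum(g, idx))
  })
}

agDropout <- function(x, rate, train = TRUE) {
  x <- agConst(x)
  if (!train || rate <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= rate) /
    (1 - rate)
  agNode(x$value * mask, function(g) .acc(x, g * mask))
}

agSoftmaxCE <- function(logits, target, weight, norm) {
  # fused masked softmax + cross-entropy: sum_i weight_i * (-log p[target_i])
  # divided by norm. Rows with weight 0 are ignored entirely.
  logits <- agConst(logits)
  L <- logits$value
  mx <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  ex <- exp(L - mx)
  p <- ex / rowSums(ex)
  n <- nrow(L)
  tgt_p <- p[cbind(seq_len(n), target)]
  loss <- sum(weight * (-log(pmax(tgt_p, 1e-12)))) / norm
  nd <- agNode(matrix(loss, 1L, 1L), function(g) {
    gl <- p
    gl[cbind(seq_len(n), target)] <- gl[cbind(seq_len(n), target)] - 1
    .acc(logits, gl * (weight / norm) * g[1L])
  })
  nd$probs <- p
  nd
}

agConv1d <- function(x, Wk, b, L, Cin, Cout, kernel) {
  # x: B x (L*Cin) position-major node; Wk: (kernel*Cin) x Cout parameter.
  # "Valid" convolution: output positions 1..L-kernel+1, returned as a
  # (B*Lout) x Cout node in time-major layout.
  x <- agConst(x)
  Lout <- L - kernel + 1L
  if (Lout < 1L) stop("kernel longer than input")
  B <- nrow(x$value)
  acc <- NULL
  for (j in seq_len(kernel)) {
    cols <- ((j - 1L) * Cin + 1L):((j - 1L + Lout) * Cin)
    xj <- agCols(x, cols)                      # B x (Lout*Cin)
    xj <- agReshapeToTimeMajor(xj, B, Lout, Cin)  # (B*Lout) x Cin
    wj <- agRowsRange(Wk, (j - 1L) * Cin + 1L, j * Cin)
    term <- agMatmul(xj, wj)
    acc <- if (is.null(acc)) term else agAdd(acc, term)
  }
  agAddBias(acc, b)
}

agReshapeToTimeMajor <- function(x, B, L, C) {
  # B x (L*C) position-major  ->  (B*L) x C with row (l-1)*B + b
  x <- agConst(x)
  src_row <- rep(seq_len(B), times = L)
  src_l <- rep(seq_len(L), each = B)
  # element (r, c) of output = x[src_row[r], (src_l[r]-1)*C + c]
  out <- matrix(0, B * L, C)
  for (c in seq_len(C)) out[, c] <- x$value[cbind(src_row, (src_l - 1L) * C + c)]
  agNode(out, function(g) {
    gg <- matrix(0, B, L * C)
    for (c in seq_len(C)) gg[cbind(src_row, (src_l - 1L) * C + c)] <-
      gg[cbind(src_row, (src_l - 1L) * C + c)] + g[, c]
    .acc(x, gg)
  })
}

agReshapeToPositionMajor <- function(x, B, L, C) {
  # inverse of agReshapeToTimeMajor
  x <- agConst(x)
  src_row <- rep(seq_len(B), times = L)
  src_l <- rep(seq_len(L), each = B)
  out <- matrix(0, B, L * C)
  for (c in seq_len(C)) out[cbind(src_row, (src_l - 1L) * C + c)] <- x$value[, c]
  agNode(out, function(g) {
    gg <- matrix(0, B * L, C)
    for (c in seq_len(C)) gg[, c] <- g[cbind(src_row, (src_l - 1L) * C + c)]
    .acc(x, gg)
  })
}

# ---- optimizer -------------------------------------------------------------

adamInit <- function(params) {
  st <- list(t = 0L, m = lapply(params, function(p) p$value * 0),
             v = lapply(params, function(p) p$value * 0))
  st
}

adamStep <- function(params, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (!is.matrix(g)) g <- as.matrix(g)
    .adam_update_cpp(p$value, g, state$m[[i]], state$v[[i]], lr, beta1,
                     beta2, eps, state$t)
  }
  state
}
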