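# User-facing layer math and training schedules, plus the GRU cell shared by
# the tape (training) and plain-matrix (inference) code paths.

#' SELU activation
#'
#' Scaled exponential linear unit,
#' \eqn{\lambda x} for \eqn{x > 0} and
#' \eqn{\lambda\alpha(e^x - 1)} for \eqn{x \le 0}, with the original
#' constants \eqn{\alpha = 1.6732632423543772848170429916717} and
#' \eqn{\lambda = 1.0507000009873554804934193349852946}.
#'
#' @param x numeric vector/matrix.
#' @return same shape as `x`.
#' @examples
#' seluActivation(c(-1, 0, 1))
#' @export
seluActivation <- function(x) {
  out <- ifelse(x > 0, .SELU_LAMBDA * x,
                .SELU_LAMBDA * .SELU_ALPHA * (exp(x) - 1))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' @describeIn seluActivation the SELU constants as a named vector.
#' @export
seluConstants <- function() c(alpha = .SELU_ALPHA, lambda = .SELU_LAMBDA)

#' One-dimensional "valid" convolution
#'
#' The transformed feature at position i is the dot product of the kernel
#' with the input window starting at i; only positions where the kernel fits
#' entirely are produced, so the output length is
#' `length(input) - length(kernel) + 1`.
#'
#' @param input numeric vector.
#' @param kernel numeric kernel, no longer than the input.
#' @return numeric vector of transformed features.
#' @examples
#' conv1dForward(c(1, 2, 3), c(1, 0, -1))  # -2
#' @export
conv1dForward <- function(input, kernel) {
  L <- length(input); k <- length(kernel)
  if (k > L) stop("kernel longer than input")
  vapply(seq_len(L - k + 1L),
         function(i) sum(input[i:(i + k - 1L)] * kernel), 0)
}

#' Batch standardization
#'
#' Training-mode batch normalization without learned scale/shift: each
#' feature (column) is centered to mean 0 and scaled to variance 1 within
#' the batch, with an `epsilon = 1e-5` regularizer inside the square root.
#' Population (1/n) variance is used, as in batch normalization.
#'
#' @param batch numeric matrix, rows = batch items, columns = features.
#' @param epsilon variance regularizer (default 1e-5).
#' @return standardized matrix of the same shape.
#' @export
batchnormForward <- function(batch, epsilon = 1e-5) {
  batch <- as.matrix(batch)
  if (nrow(batch) < 2L)
    stop("degenerate batch: batch normalization needs >= 2 items in training mode")
  mu <- colMeans(batch)
  xc <- sweep(batch, 2L, mu, "-")
  v <- colMeans(xc^2)
  sweep(xc, 2L, sqrt(v + epsilon), "/")
}

#' Gaussian KL divergence to the standard normal
#'
#' \eqn{KL(N(\mu, diag(\sigma^2)) \| N(0, I)) =
#' \frac12 \sum_d (\mu_d^2 + \sigma_d^2 - 1 - \ln \sigma_d^2)}, averaged over
#' the batch (rows).
#'
#' @param mu matrix of means, batch x D (a vector is a batch of one).
#' @param sigma matrix of standard deviations, same shape, all positive.
#' @return mean KL divergence in nats.
#' @examples
#' klLoss(0, 1)       # 0
#' klLoss(1, 1)       # 0.5
#' @export
klLoss <- function(mu, sigma) {
  mu <- rbind(mu); sigma <- rbind(sigma)
  stopifnot(all(dim(mu) == dim(sigma)), all(sigma > 0))
  mean(rowSums(mu^2 + sigma^2 - 1 - log(sigma^2)) / 2)
}

#' Reconstruction cross-entropy of token sequences
#'
#' Mean over the batch of the summed per-token negative log probability of
#' the correct token under the decoder's per-step distributions (teacher
#' forcing). Probabilities for steps beyond a sequence's end are ignored.
#'
#' @param trueSeqs list of integer token vectors (targets, end token
#'   included, start token excluded).
#' @param probsList list of matrices, one per sequence, steps x vocabulary;
#'   row t is the decoder's distribution for step t.
#' @return loss in nats (>= 0).
#' @examples
#' reconstructionLoss(list(c(2L)), list(matrix(c(0.5, 0.5), 1)))  # log(2)
#' @export
reconstructionLoss <- function(trueSeqs, probsList) {
  stopifnot(length(trueSeqs) == length(probsList))
  per <- mapply(function(y, p) {
    p <- rbind(p)
    if (nrow(p) < length(y)) stop("probability rows shorter than sequence")
    -sum(log(pmax(p[cbind(seq_along(y), y)], 1e-300)))
  }, trueSeqs, probsList)
  mean(per)
}

#' L1 reconstruction loss for IEVs
#'
#' Sum of absolute deviations over the vector dimensions, averaged over the
#' batch; symmetric in its arguments.
#'
#' @param true,reconstructed numeric matrices (batch x dims) or vectors of
#'   equal length.
#' @return loss in kcal/mol.
#' @examples
#' ievL1Loss(c(1, 2), c(0, 0))  # 3
#' @export
ievL1Loss <- function(true, reconstructed) {
  true <- rbind(true); reconstructed <- rbind(reconstructed)
  if (!all(dim(true) == dim(reconstructed)))
    stop("shape mismatch between true and reconstructed IEVs")
  mean(rowSums(abs(true - reconstructed)))
}

#' Training schedules
#'
#' `klAlphaSchedule`: the KL weight at (0-indexed) epoch e is
#' `init + e * rate` (default: starts at 0, annealed by 5e-3 per epoch, no
#' cap). `lrStepSchedule`: step decay `init * decay^floor(step / every)`,
#' used with per-batch steps (IEV-VAE: 1e-3, x0.9 every 2000 batches) or
#' per-epoch steps (end-to-end: 1e-4, x0.8 every 20 epochs).
#'
#' @param epoch,step 0-indexed epoch / step counter (vectorized).
#' @param init initial value.
#' @param rate linear increment per epoch.
#' @param decay multiplicative factor.
#' @param every steps between decays.
#' @return numeric schedule value(s).
#' @examples
#' klAlphaSchedule(10)                     # 0.05
#' lrStepSchedule(4000, 1e-3, 0.9, 2000)   # 8.1e-4
#' @export
klAlphaSchedule <- function(epoch, rate = 5e-3, init = 0) init + epoch * rate

#' @rdname klAlphaSchedule
#' @export
lrStepSchedule <- function(step, init, decay, every)
  init * decay^(step %/% every)

# ---- GRU cell --------------------------------------------------------------

.gru_init <- function(inDim, hidden, rng) {
  k <- 1 / sqrt(hidden)
  u <- function(nr, nc) matrix(rng(nr * nc, k), nr, nc)
  list(Wx = u(inDim, 3L * hidden), bx = u(1L, 3L * hidden),
       Whrz = u(hidden, 2L * hidden), Whn = u(hidden, hidden),
       bhn = u(1L, hidden))
}

# one GRU step on the tape; x_rz: B x 2H node, x_n: B x H node
.gru_step_tape <- function(x_rz, x_n, h, p, H) {
  rz <- agSigmoid(agAdd(x_rz, agMatmul(h, p$Whrz)))
  r <- agCols(rz, seq_len(H))
  z <- agCols(rz, H + seq_len(H))
  hn <- agAddBias(agMatmul(h, p$Whn), p$bhn)
  n <- agTanh(agAdd(x_n, agMul(r, hn)))
  agAdd(agMul(agOneMinus(z), n), agMul(z, h))
}

# Whole GRU layer as one fused tape node: the time-stepped recurrence and
# its backpropagation-through-time run in compiled code (src/nn_kernels.cpp)
# so the autodiff overhead is independent of sequence length. Gradients are
# checked against numerical differentiation in the tests. `XW` is the
# (B*T) x 3H input-projection node (time-major), `h0` the initial hidden
# node, `mask` an optional B x T 0/1 matrix holding the previous hidden
# state where 0.
agGruLayer <- function(XW, h0, p, B, T, H, mask = NULL) {
  XW <- agConst(XW); h0 <- agConst(h0)
  m <- if (is.null(mask)) matrix(0, 0L, 0L) else mask
  fw <- .gru_forward_cpp(XW$value, h0$value, p$Whrz$value, p$Whn$value,
                         as.numeric(p$bhn$value), m)
  agNode(fw$out, function(G) {
    bw <- .gru_backward_cpp(G, fw$out, h0$value, fw$rzs, fw$hns, fw$ns,
                            p$Whrz$value, p$Whn$value, m)
    .acc(XW, bw$dX)
    .acc(h0, bw$dh0)
    .acc(p$Whrz, bw$dWrz); .acc(p$Whn, bw$dWn)
    .acc(p$bhn, matrix(as.numeric(bw$dbn), 1L))
  })
}

# plain-matrix GRU step (inference); xw: B x 3H precomputed input projection
.gru_step_eval <- function(xw, h, p, H) {
  pre_rz <- xw[, seq_len(2L * H), drop = FALSE] + h %*% p$Whrz$value
  rz <- 1 / (1 + exp(-pre_rz))
  r <- rz[, seq_len(H), drop = FALSE]
  z <- rz[, H + seq_len(H), drop = FALSE]
  hn <- sweep(h %*% p$Whn$value, 2L, as.numeric(p$bhn$value), "+")
  n <- tanh(xw[, 2L * H + seq_len(H), drop = FALSE] + r * hn)
  (1 - z) * n + z * h
}

.gru_input_proj_eval <- function(x, p) {
  sweep(x %*% p$Wx$value, 2L, as.numeric(p$bx$value), "+")
}

agMulRowvec <- function(x, rv) {
  x <- agConst(x); rv <- agConst(rv)
  d <- as.numeric(rv$value)
  agNode(sweep(x$value, 2L, d, "*"), function(g) {
    .acc(x, sweep(g, 2L, d, "*"))
    .acc(rv, matrix(colSums(g * x$value), 1L))
  })
}

# batchnorm on the tape with running-stat tracking (train) or running stats
# (eval). `state` is an environment with $mean, $var.
.batchnorm_tape <- function(x, gamma, beta, state, train, momentum = 0.1,
                            eps = 1e-5) {
  if (train) {
    if (nrow(x$value) < 2L) stop("degenerate batch in batch normalization")
    mu <- agColMeans(x)
    xc <- agSweepSub(x, mu)
    v <- agColMeans(agSquare(xc))
    state$mean <- (1 - momentum) * state$mean + momentum * as.numeric(mu$value)
    nb <- nrow(x$value)
    state$var <- (1 - momentum) * state$var +
      momentum * as.numeric(v$value) * nb / max(nb - 1L, 1L)
    sd <- agPowConst(agAddScalar(v, eps), 0.5)
    xhat <- agSweepDivVec(xc, sd)
  } else {
    xhat <- agConst(sweep(sweep(x$value, 2L, state$mean, "-"), 2L,
                          sqrt(state$var + eps), "/"))
  }
  agAddBias(agMulRowvec(xhat, gamma), beta)
}

.batchnorm_eval <- function(x, gamma, beta, state, eps = 1e-5) {
  xhat <- sweep(sweep(x, 2L, state$mean, "-"), 2L, sqrt(state$var + eps), "/")
  sweep(sweep(xhat, 2L, as.numeric(gamma$value), "*"), 2L,
        as.numeric(beta$value), "+")
}
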