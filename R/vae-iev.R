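# IEV variational autoencoder: conv1d + fully-connected encoder to a
# 56-dimensional latent, fully-connected decoder; L1 reconstruction + KL
# objective with a step-decayed learning rate.

#' IEV-VAE hyperparameters
#'
#' Defaults follow the original setup where printed (latent 56, batch 128,
#' 100 epochs, Adam with learning rate 1e-3 multiplied by 0.9 every 2000
#' batches) and modest conventional values for the unprinted layer sizes:
#' two conv blocks (32 then 64 channels, kernel 5) with batch normalization
#' and ReLU/SELU activations, dropout 0.1, and a 256-wide fully connected
#' stage; the decoder is a mirrored fully-connected stack with SELU.
#'
#' @param latentDim latent dimension (56).
#' @param convChannels channel counts of the two conv blocks.
#' @param kernel conv kernel length.
#' @param fcHidden width of the fully connected stage.
#' @param dropout dropout rate.
#' @param batchSize,epochs Adam training settings.
#' @param lrInit,lrDecay,lrEvery step-decay learning-rate schedule
#'   `lrInit * lrDecay^floor(batches / lrEvery)`.
#' @return named list of settings.
#' @export
ievVaeConfig <- function(latentDim = 56L, convChannels = c(32L, 64L),
                         kernel = 5L, fcHidden = 256L, dropout = 0.1,
                         batchSize = 128L, epochs = 100L, lrInit = 1e-3,
                         lrDecay = 0.9, lrEvery = 2000L) {
  stopifnot(latentDim > 0, length(convChannels) == 2L, kernel >= 1L,
            lrDecay > 0, lrDecay < 1, lrEvery > 0)
  list(latentDim = as.integer(latentDim),
       convChannels = as.integer(convChannels), kernel = as.integer(kernel),
       fcHidden = as.integer(fcHidden), dropout = dropout,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       lrInit = lrInit, lrDecay = lrDecay, lrEvery = as.integer(lrEvery))
}

.iev_vae_init <- function(inputDim, config, seed) {
  set.seed(as.integer(seed))
  rng <- function(n, k) stats::runif(n, -k, k)
  u <- function(nr, nc, k) agParam(matrix(rng(nr * nc, k), nr, nc))
  k <- config$kernel; C1 <- config$convChannels[1]; C2 <- config$convChannels[2]
  L1 <- inputDim - k + 1L; L2 <- L1 - k + 1L
  if (L2 < 1L) stop("IEV too short for the configured conv stack")
  Fh <- config$fcHidden; D <- config$latentDim
  flatDim <- L2 * C2
  p <- list(
    conv1.W = u(k * 1L, C1, 1 / sqrt(k)), conv1.b = u(1L, C1, 0.01),
    bn1.gamma = agParam(matrix(1, 1L, C1)), bn1.beta = agParam(matrix(0, 1L, C1)),
    conv2.W = u(k * C1, C2, 1 / sqrt(k * C1)), conv2.b = u(1L, C2, 0.01),
    bn2.gamma = agParam(matrix(1, 1L, C2)), bn2.beta = agParam(matrix(0, 1L, C2)),
    fc1.W = u(flatDim, Fh, 1 / sqrt(flatDim)), fc1.b = u(1L, Fh, 0.01),
    mu.W = u(Fh, D, 1 / sqrt(Fh)), mu.b = u(1L, D, 0.01),
    lv.W = u(Fh, D, 1 / sqrt(Fh)), lv.b = u(1L, D, 0.01),
    dfc1.W = u(D, Fh, 1 / sqrt(D)), dfc1.b = u(1L, Fh, 0.01),
    dfc2.W = u(Fh, Fh, 1 / sqrt(Fh)), dfc2.b = u(1L, Fh, 0.01),
    dout.W = u(Fh, inputDim, 1 / sqrt(Fh)), dout.b = u(1L, inputDim, 0.01))
  bnstate <- list(
    bn1 = local({ e <- new.env(); e$mean <- rep(0, C1); e$var <- rep(1, C1); e }),
    bn2 = local({ e <- new.env(); e$mean <- rep(0, C2); e$var <- rep(1, C2); e }))
  list(params = p, bn = bnstate, dims = list(L1 = L1, L2 = L2, C1 = C1,
                                             C2 = C2, flatDim = flatDim))
}

.iev_encode_tape <- function(st, x, config, train = TRUE) {
  p <- st$params; d <- st$dims
  B <- nrow(x$value); k <- config$kernel
  L <- ncol(x$value)
  h <- agConv1d(x, p$conv1.W, p$conv1.b, L, 1L, d$C1, k)     # (B*L1) x C1
  h <- .batchnorm_tape(h, p$bn1.gamma, p$bn1.beta, st$bn$bn1, train)
  h <- agRelu(h)
  h <- agReshapeToPositionMajor(h, B, d$L1, d$C1)
  h <- agConv1d(h, p$conv2.W, p$conv2.b, d$L1, d$C1, d$C2, k) # (B*L2) x C2
  h <- .batchnorm_tape(h, p$bn2.gamma, p$bn2.beta, st$bn$bn2, train)
  h <- agSelu(h)
  h <- agReshapeToPositionMajor(h, B, d$L2, d$C2)             # B x flatDim
  h <- agDropout(h, config$dropout, train)
  h <- agSelu(agAddBias(agMatmul(h, p$fc1.W), p$fc1.b))
  list(mu = agAddBias(agMatmul(h, p$mu.W), p$mu.b),
       lv = agAddBias(agMatmul(h, p$lv.W), p$lv.b))
}

.iev_decode_tape <- function(st, z, config, train = TRUE) {
  p <- st$params
  h <- agSelu(agAddBias(agMatmul(z, p$dfc1.W), p$dfc1.b))
  h <- agDropout(h, config$dropout, train)
  h <- agSelu(agAddBias(agMatmul(h, p$dfc2.W), p$dfc2.b))
  agAddBias(agMatmul(h, p$dout.W), p$dout.b)
}

#' Pretrain an IEV variational autoencoder
#'
#' Objective: the unweighted sum of the L1 reconstruction loss
#' (sum over dimensions, mean over batch) and the Gaussian KL divergence.
#' Adam learning rate decays as `lrInit * lrDecay^floor(b / lrEvery)` with b
#' the number of batches processed so far.
#'
#' @param ievs numeric matrix of training IEVs (rows) or list of
#'   [IEV-class] objects with identical labels.
#' @param config from [ievVaeConfig].
#' @param seed integer RNG seed.
#' @param labels optional IEV column labels (taken from IEV objects when
#'   given a list).
#' @return a trained [IevVae-class].
#' @export
pretrainIevVae <- function(ievs, config = ievVaeConfig(), seed = 1L,
                           labels = NULL) {
  if (is.list(ievs) && length(ievs) && methods::is(ievs[[1]], "IEV")) {
    labels <- ievs[[1]]@labels
    ievs <- do.call(rbind, lapply(ievs, function(v) v@values))
  }
  ievs <- as.matrix(ievs)
  if (nrow(ievs) == 0L) stop("empty IEV dataset")
  if (is.null(labels)) labels <- colnames(ievs)
  if (is.null(labels)) labels <- character()
  bs <- config$batchSize
  if (nrow(ievs) < 2L * bs) {
    bs <- max(2L, nrow(ievs) %/% 2L)
    warning("dataset smaller than two batches; batch size shrunk to ", bs)
  }
  st <- .iev_vae_init(ncol(ievs), config, seed)
  flat <- st$params
  opt <- adamInit(flat)
  n <- nrow(ievs); D <- config$latentDim
  nbatches <- 0L
  log <- vector("list", config$epochs)
  for (e in seq_len(config$epochs) - 1L) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    batches <- batches[lengths(batches) >= 2L]   # batchnorm needs >= 2
    er <- ek <- 0; nseen <- 0L; lr <- config$lrInit
    for (bi in batches) {
      lr <- lrStepSchedule(nbatches, config$lrInit, config$lrDecay,
                           config$lrEvery)
      agResetTape()
      x <- agConst(ievs[bi, , drop = FALSE])
      g <- .iev_encode_tape(st, x, config, train = TRUE)
      B <- length(bi)
      epsC <- agConst(matrix(stats::rnorm(B * D), B, D))
      z <- agAdd(g$mu, agMul(agExp(agScale(g$lv, 0.5)), epsC))
      xhat <- .iev_decode_tape(st, z, config, train = TRUE)
      l1 <- agScale(agSumAll(agAbs(agSub(x, xhat))), 1 / B)
      klterm <- agScale(agSumAll(
        agSub(agAdd(agSquare(g$mu), agExp(g$lv)), agAddScalar(g$lv, 1))),
        0.5 / B)
      total <- agAdd(l1, klterm)
      agZeroGrad(flat)
      agBackward(total)
      clipGradNorm(flat)
      opt <- adamStep(flat, opt, lr)
      nbatches <- nbatches + 1L
      er <- er + l1$value[1L] * B; ek <- ek + klterm$value[1L] * B
      nseen <- nseen + B
    }
    er <- er / nseen; ek <- ek / nseen
    log[[e + 1L]] <- data.frame(epoch = e, lIev = er, lKl = ek, lr = lr,
                                total = er + ek)
  }
  agResetTape()
  params <- c(st$params,
              list(bn1.mean = st$bn$bn1$mean, bn1.var = st$bn$bn1$var,
                   bn2.mean = st$bn$bn2$mean, bn2.var = st$bn$bn2$var),
              list(.dims = st$dims))
  new("IevVae", params = params, config = config,
      inputDim = ncol(ievs), labels = as.character(labels),
      trainLog = do.call(rbind, log))
}

.iev_model_state <- function(model) {
  p <- model@params
  bn <- list(
    bn1 = local({ e <- new.env(); e$mean <- p$bn1.mean; e$var <- p$bn1.var; e }),
    bn2 = local({ e <- new.env(); e$mean <- p$bn2.mean; e$var <- p$bn2.var; e }))
  list(params = p[!(names(p) %in% c("bn1.mean", "bn1.var", "bn2.mean",
                                    "bn2.var", ".dims"))],
       bn = bn, dims = p$.dims)
}

#' Encode IEVs into the 56-dimensional latent Gaussian
#'
#' Deterministic evaluation-mode encoding (batch normalization uses running
#' statistics, dropout off).
#'
#' @param model an [IevVae-class].
#' @param ievs numeric matrix (rows = IEVs), a single numeric vector, or an
#'   [IEV-class].
#' @return list with matrices `mu` and `sigma`.
#' @export
encodeIev <- function(model, ievs) {
  if (methods::is(ievs, "IEV")) ievs <- matrix(ievs@values, 1L)
  if (is.null(dim(ievs))) ievs <- matrix(ievs, 1L)
  if (ncol(ievs) != model@inputDim) stop("IEV dimension mismatch")
  st <- .iev_model_state(model)
  agResetTape()
  g <- .iev_encode_tape(st, agConst(ievs), model@config, train = FALSE)
  agResetTape()
  list(mu = g$mu$value, sigma = exp(0.5 * g$lv$value))
}

#' Decode latent vectors back into IEVs
#'
#' @param model an [IevVae-class].
#' @param z matrix of latent vectors (rows) or a single vector.
#' @return numeric matrix of reconstructed IEVs.
#' @export
decodeIev <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, 1L)
  if (ncol(z) != model@config$latentDim) stop("latent dimension mismatch")
  st <- .iev_model_state(model)
  agResetTape()
  out <- .iev_decode_tape(st, agConst(z), model@config, train = FALSE)
  agResetTape()
  out$value
}
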