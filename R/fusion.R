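# Fusion of the two latent spaces: a three-layer fully connected network
# (the "Z-DNN") maps the concatenated SMILES latent (128) and IEV latent
# (56) back into the SMILES latent space (128), so its output feeds the
# SMILES decoder directly. End-to-end training freezes the SMILES encoder
# and the whole IEV-VAE and fine-tunes only the decoder and the fusion
# network, with the SMILES reconstruction cross-entropy as the sole loss.

#' Fusion-model hyperparameters
#'
#' @param hidden widths of the two hidden fully connected layers
#'   (input 128 + 56 = 184, output 128, ReLU between layers).
#' @param batchSize,epochs Adam training settings.
#' @param lrInit,lrDecay,lrEvery per-epoch step decay
#'   `lrInit * lrDecay^floor(epoch / lrEvery)`.
#' @param useMean feed the frozen encoders' posterior means to the fusion
#'   network instead of reparameterized samples (default FALSE: samples,
#'   mirroring generation-time stochasticity).
#' @return named list of settings.
#' @export
fusionConfig <- function(hidden = c(256L, 192L), batchSize = 128L,
                         epochs = 100L, lrInit = 1e-4, lrDecay = 0.8,
                         lrEvery = 20L, useMean = FALSE) {
  stopifnot(length(hidden) == 2L, lrDecay > 0, lrDecay < 1)
  list(hidden = as.integer(hidden), batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), lrInit = lrInit, lrDecay = lrDecay,
       lrEvery = as.integer(lrEvery), useMean = isTRUE(useMean))
}

.zdnn_init <- function(dIn, dOut, config, seed) {
  set.seed(as.integer(seed))
  u <- function(nr, nc) agParam(matrix(stats::runif(nr * nc, -1, 1) /
                                         sqrt(nr), nr, nc))
  h <- config$hidden
  list(W1 = u(dIn, h[1]), b1 = agParam(matrix(0, 1L, h[1])),
       W2 = u(h[1], h[2]), b2 = agParam(matrix(0, 1L, h[2])),
       W3 = u(h[2], dOut), b3 = agParam(matrix(0, 1L, dOut)))
}

.zdnn_tape <- function(zp, x) {
  h <- agRelu(agAddBias(agMatmul(x, zp$W1), zp$b1))
  h <- agRelu(agAddBias(agMatmul(h, zp$W2), zp$b2))
  agAddBias(agMatmul(h, zp$W3), zp$b3)
}

.zdnn_eval <- function(zp, x) {
  h <- pmax(sweep(x %*% zp$W1$value, 2L, as.numeric(zp$b1$value), "+"), 0)
  h <- pmax(sweep(h %*% zp$W2$value, 2L, as.numeric(zp$b2$value), "+"), 0)
  sweep(h %*% zp$W3$value, 2L, as.numeric(zp$b3$value), "+")
}

#' Fusion-network forward pass
#'
#' Maps a SMILES latent (128) and an IEV latent (56) to a 128-dimensional
#' vector in the SMILES latent space; deterministic given the weights.
#'
#' @param model a [FusionModel-class].
#' @param zSmiles matrix (rows) or vector of SMILES latents.
#' @param zIev matrix (rows) or vector of IEV latents.
#' @return matrix of 128-dimensional outputs.
#' @export
zdnnForward <- function(model, zSmiles, zIev) {
  if (is.null(dim(zSmiles))) zSmiles <- matrix(zSmiles, 1L)
  if (is.null(dim(zIev))) zIev <- matrix(zIev, 1L)
  if (ncol(zSmiles) != model@smilesVae@config$latentDim ||
      ncol(zIev) != model@ievVae@config$latentDim ||
      nrow(zSmiles) != nrow(zIev))
    stop("latent dimension mismatch")
  .zdnn_eval(model@zdnn, cbind(zSmiles, zIev))
}

#' Digest of a parameter set
#'
#' MD5 digest of the raw bytes of all parameter matrices of one component,
#' in a fixed order; used to verify the frozen-weight contract of end-to-end
#' training.
#'
#' @param model a [SmilesVae-class], [IevVae-class] or [FusionModel-class].
#' @param component which parameters to digest: "smilesEncoder",
#'   "smilesDecoder", "ievVae", "zdnn" or "all".
#' @return a 32-character MD5 string.
#' @export
paramDigest <- function(model,
                        component = c("all", "smilesEncoder",
                                      "smilesDecoder", "ievVae", "zdnn")) {
  component <- match.arg(component)
  collect <- function(p) unlist(lapply(.flatten_params(p),
                                       function(x) as.numeric(x$value)))
  vals <- switch(component,
    all = if (methods::is(model, "FusionModel"))
            c(collect(model@smilesVae@params),
              collect(.iev_model_state(model@ievVae)$params),
              model@ievVae@params$bn1.mean, model@ievVae@params$bn1.var,
              model@ievVae@params$bn2.mean, model@ievVae@params$bn2.var,
              collect(model@zdnn))
          else if (methods::is(model, "IevVae"))
            c(collect(.iev_model_state(model)$params),
              model@params$bn1.mean, model@params$bn1.var,
              model@params$bn2.mean, model@params$bn2.var)
          else collect(model@params),
    smilesEncoder = {
      sv <- if (methods::is(model, "FusionModel")) model@smilesVae else model
      collect(sv@params[.smiles_encoder_param_names()])
    },
    smilesDecoder = {
      sv <- if (methods::is(model, "FusionModel")) model@smilesVae else model
      collect(sv@params[.smiles_decoder_param_names()])
    },
    ievVae = {
      iv <- if (methods::is(model, "FusionModel")) model@ievVae else model
      c(collect(.iev_model_state(iv)$params),
        iv@params$bn1.mean, iv@params$bn1.var,
        iv@params$bn2.mean, iv@params$bn2.var)
    },
    zdnn = collect(model@zdnn))
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(vals, f)
  unname(tools::md5sum(f))
}

#' Train the conditional generator end to end
#'
#' Couples a pretrained SMILES-VAE and IEV-VAE through the fusion network.
#' Per batch: the frozen SMILES encoder and frozen IEV encoder produce
#' latent Gaussians for each (SMILES, IEV) pair; a reparameterized sample
#' (or the mean, see [fusionConfig]) from each is concatenated and mapped by
#' the fusion network into the SMILES latent space; the decoder is
#' teacher-forced on the true SMILES. The loss is the reconstruction
#' cross-entropy only (no KL term); only decoder and fusion-network weights
#' receive gradient updates.
#'
#' @param dataset a [PairedIevDataset-class], or a list with `smiles`
#'   (character) and `iev` (matrix).
#' @param smilesVae pretrained [SmilesVae-class].
#' @param ievVae pretrained [IevVae-class].
#' @param config from [fusionConfig].
#' @param seed integer RNG seed.
#' @return a [FusionModel-class] with per-epoch training log.
#' @export
trainEndToEnd <- function(dataset, smilesVae, ievVae,
                          config = fusionConfig(), seed = 1L) {
  smiles <- if (methods::is(dataset, "PairedIevDataset")) dataset@smiles
            else dataset$smiles
  iev <- if (methods::is(dataset, "PairedIevDataset")) dataset@iev
         else as.matrix(dataset$iev)
  stopifnot(length(smiles) == nrow(iev))
  if (ncol(iev) != ievVae@inputDim)
    stop("IEV dimension does not match the pretrained IEV-VAE")
  seqs <- lapply(smiles, tokenizeSmiles, vocab = smilesVae@vocab)
  if (any(vapply(seqs, is.null, TRUE)))
    stop("dataset contains SMILES outside the pretrained vocabulary")

  # deep-copy the decoder parameters so the pretrained model is not mutated
  sv <- smilesVae
  newp <- sv@params
  for (nm in .smiles_decoder_param_names()) {
    if (is.list(newp[[nm]])) newp[[nm]] <- lapply(newp[[nm]],
                                                  function(q) agParam(q$value))
    else newp[[nm]] <- agParam(newp[[nm]]$value)
  }
  sv@params <- newp
  zdnn <- .zdnn_init(sv@config$latentDim + ievVae@config$latentDim,
                     sv@config$latentDim, config, seed)
  trainable <- c(.flatten_params(sv@params[.smiles_decoder_param_names()]),
                 .flatten_params(zdnn))
  opt <- adamInit(trainable)
  n <- length(seqs)
  Ds <- sv@config$latentDim; Di <- ievVae@config$latentDim
  bs <- min(config$batchSize, n)
  log <- vector("list", config$epochs)
  gz_iev <- encodeIev(ievVae, iev)   # frozen; precompute once
  for (e in seq_len(config$epochs) - 1L) {
    lr <- lrStepSchedule(e, config$lrInit, config$lrDecay, config$lrEvery)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    er <- 0
    for (bi in batches) {
      B <- length(bi)
      gs <- encodeSmiles(sv, seqs[bi])   # frozen encoder, eval mode
      zs <- if (config$useMean) gs$mu
            else gs$mu + gs$sigma * matrix(stats::rnorm(B * Ds), B)
      zi <- if (config$useMean) gz_iev$mu[bi, , drop = FALSE]
            else gz_iev$mu[bi, , drop = FALSE] +
                 gz_iev$sigma[bi, , drop = FALSE] *
                 matrix(stats::rnorm(B * Di), B)
      agResetTape()
      zout <- .zdnn_tape(zdnn, agConst(cbind(zs, zi)))
      tf <- .pad_teacher(seqs[bi])
      recon <- .decode_tape(sv@params, zout, tf, sv@config, train = TRUE)
      agZeroGrad(trainable)
      agBackward(recon)
      clipGradNorm(trainable)
      opt <- adamStep(trainable, opt, lr)
      er <- er + recon$value[1L] * B
    }
    log[[e + 1L]] <- data.frame(epoch = e, lSmiles = er / n, lr = lr)
  }
  agResetTape()
  new("FusionModel", smilesVae = sv, ievVae = ievVae, zdnn = zdnn,
      config = config, trainLog = do.call(rbind, log))
}

#' Generate molecules conditioned on a target IEV
#'
#' For each of the `n` samples: (i) the target IEV is encoded by the frozen
#' IEV-VAE encoder and its latent is sampled anew, (ii) a fresh
#' 128-dimensional standard-normal vector is drawn, (iii) both are
#' concatenated and mapped by the fusion network, (iv) the result is decoded
#' into a SMILES string (multinomial token sampling by default). Invalid
#' SMILES are kept and flagged, so validity statistics refer to all `n`
#' samples.
#'
#' @param model a trained [FusionModel-class].
#' @param targetIev an [IEV-class] (or numeric vector) matching the model's
#'   IEV input dimension.
#' @param n number of molecules to generate.
#' @param seed integer RNG seed; the full sample list is reproducible.
#' @param mode token selection mode, "multinomial" (default) or "greedy".
#' @return a [GenerationResult-class].
#' @export
generateMolecules <- function(model, targetIev, n = 100L, seed = 1L,
                              mode = c("multinomial", "greedy")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  tgt <- if (methods::is(targetIev, "IEV")) targetIev
         else new("IEV", values = as.numeric(targetIev),
                  labels = if (length(model@ievVae@labels))
                             model@ievVae@labels
                           else paste0("r", seq_along(targetIev)))
  if (length(tgt@values) != model@ievVae@inputDim)
    stop("target IEV length does not match the trained IEV-VAE")
  set.seed(as.integer(seed))
  if (n == 0L)
    return(new("GenerationResult", targetIev = tgt, smiles = character(),
               valid = logical(), nRequested = 0L, seed = as.integer(seed)))
  g <- encodeIev(model@ievVae, tgt@values)
  Di <- model@ievVae@config$latentDim
  Ds <- model@smilesVae@config$latentDim
  # latents resampled for every draw
  zi <- matrix(rep(g$mu, each = n), n) +
        matrix(rep(g$sigma, each = n), n) * matrix(stats::rnorm(n * Di), n)
  zs <- matrix(stats::rnorm(n * Ds), n)
  zout <- .zdnn_eval(model@zdnn, cbind(zs, zi))
  dec <- decodeLatent(model@smilesVae, zout, mode = mode)
  smi <- vapply(dec, `[[`, "", "smiles")
  new("GenerationResult", targetIev = tgt, smiles = smi,
      valid = isValidSmiles(smi), nRequested = n, seed = as.integer(seed))
}

#' @describeIn generateMolecules generated SMILES of a result.
#' @param x a [GenerationResult-class].
#' @export
generatedSmiles <- function(x) x@smiles

#' @describeIn generateMolecules validity flags of a result.
#' @export
generatedValid <- function(x) x@valid
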