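# SMILES variational autoencoder: bidirectional GRU encoder to a
# 128-dimensional diagonal Gaussian, 3-layer GRU decoder with dropout,
# trained with cross-entropy reconstruction + KL-annealed divergence.

#' SMILES-VAE hyperparameters
#'
#' Defaults follow the original setup where printed (latent 128, batch 512,
#' 100 epochs, Adam at a fixed 3e-4, KL weight annealed linearly from 0 by
#' 5e-3 per epoch, 3 decoder GRU layers) and common VAE-benchmark values
#' where not (hidden widths, embedding size, dropout).
#'
#' @param latentDim latent dimension D (128).
#' @param embDim token embedding size.
#' @param encHidden width of each encoder GRU direction.
#' @param decHidden width of each decoder GRU layer.
#' @param decLayers number of decoder GRU layers (3).
#' @param dropout decoder inter-layer dropout rate.
#' @param batchSize,epochs,lr Adam training settings.
#' @param klAnnealRate,klInit KL weight schedule alpha(e) = klInit +
#'   e * klAnnealRate, e 0-indexed, uncapped.
#' @param maxLength maximum token count for generation/tokenization.
#' @return named list of settings.
#' @export
smilesVaeConfig <- function(latentDim = 128L, embDim = 30L, encHidden = 256L,
                            decHidden = 512L, decLayers = 3L, dropout = 0.2,
                            batchSize = 512L, epochs = 100L, lr = 3e-4,
                            klAnnealRate = 5e-3, klInit = 0,
                            maxLength = 120L) {
  stopifnot(latentDim > 0, encHidden > 0, decHidden > 0, decLayers == 3L,
            dropout >= 0, dropout < 1, batchSize > 0, epochs >= 0, lr > 0)
  list(latentDim = as.integer(latentDim), embDim = as.integer(embDim),
       encHidden = as.integer(encHidden), decHidden = as.integer(decHidden),
       decLayers = as.integer(decLayers), dropout = dropout,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       lr = lr, klAnnealRate = klAnnealRate, klInit = klInit,
       maxLength = as.integer(maxLength))
}

.smiles_vae_init <- function(vocab, config, seed) {
  set.seed(as.integer(seed))
  rng <- function(n, k) stats::runif(n, -k, k)
  V <- vocabSize(vocab)
  E <- config$embDim; He <- config$encHidden; Hd <- config$decHidden
  D <- config$latentDim
  u <- function(nr, nc, k) agParam(matrix(rng(nr * nc, k), nr, nc))
  p <- list(
    embE = u(V, E, 0.1), embD = u(V, E, 0.1),
    mu.W = u(2L * He, D, 1 / sqrt(2 * He)), mu.b = u(1L, D, 0.01),
    lv.W = u(2L * He, D, 1 / sqrt(2 * He)), lv.b = u(1L, D, 0.01),
    z2h.W = u(D, Hd, 1 / sqrt(D)), z2h.b = u(1L, Hd, 0.01),
    out.W = u(Hd, V, 1 / sqrt(Hd)), out.b = u(1L, V, 0.01))
  for (nm in c("encF", "encB"))
    p[[nm]] <- lapply(.gru_init(E, He, rng), agParam)
  p$dec1 <- lapply(.gru_init(E + D, Hd, rng), agParam)
  p$dec2 <- lapply(.gru_init(Hd, Hd, rng), agParam)
  p$dec3 <- lapply(.gru_init(Hd, Hd, rng), agParam)
  p
}

.flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]]) && !is.environment(p[[nm]]))
      for (sub in names(p[[nm]])) out[[paste0(nm, ".", sub)]] <- p[[nm]][[sub]]
    else out[[nm]] <- p[[nm]]
  }
  out
}

.smiles_encoder_param_names <- function()
  c("embE", "encF", "encB", "mu.W", "mu.b", "lv.W", "lv.b")

.smiles_decoder_param_names <- function()
  c("embD", "z2h.W", "z2h.b", "dec1", "dec2", "dec3", "out.W", "out.b")

# pad a list of full token sequences ([start ... end]) for teacher forcing
.pad_teacher <- function(seqs) {
  lens <- lengths(seqs)                 # full lengths incl start and end
  Td <- max(lens) - 1L                  # decoder steps
  B <- length(seqs)
  inp <- matrix(1L, B, Td); tgt <- matrix(1L, B, Td); w <- matrix(0, B, Td)
  for (i in seq_len(B)) {
    li <- lens[i] - 1L
    inp[i, seq_len(li)] <- seqs[[i]][seq_len(li)]
    tgt[i, seq_len(li)] <- seqs[[i]][1L + seq_len(li)]
    w[i, seq_len(li)] <- 1
  }
  list(inp = inp, tgt = tgt, w = w, Td = Td, B = B)
}

.pad_encoder <- function(seqs) {
  lens <- lengths(seqs)
  Te <- max(lens); B <- length(seqs)
  m <- matrix(1L, B, Te); mask <- matrix(0, B, Te)
  for (i in seq_len(B)) {
    m[i, seq_len(lens[i])] <- seqs[[i]]
    mask[i, seq_len(lens[i])] <- 1
  }
  list(tok = m, mask = mask, Te = Te, B = B)
}

# encoder on the tape: returns mu and logvar nodes (B x D)
.encode_tape <- function(p, enc, He) {
  B <- enc$B; Te <- enc$Te
  run_dir <- function(gp, times) {
    idx <- as.integer(enc$tok[, times])       # column-major: time-major flat
    X <- agEmbed(p$embE, idx)
    XW <- agAddBias(agMatmul(X, gp$Wx), gp$bx)
    out <- agGruLayer(XW, agConst(matrix(0, B, He)), gp, B, Te, He,
                      mask = enc$mask[, times, drop = FALSE])
    agRowsRange(out, (Te - 1L) * B + 1L, Te * B)   # final hidden state
  }
  hf <- run_dir(p$encF, seq_len(Te))
  hb <- run_dir(p$encB, rev(seq_len(Te)))
  hcat <- agColcat(hf, hb)
  mu <- agAddBias(agMatmul(hcat, p$mu.W), p$mu.b)
  lv <- agAddBias(agMatmul(hcat, p$lv.W), p$lv.b)
  list(mu = mu, lv = lv)
}

# decoder on the tape: teacher-forced cross-entropy given latent node z
.decode_tape <- function(p, z, tf, config, train = TRUE) {
  B <- tf$B; Td <- tf$Td; Hd <- config$decHidden
  idx <- as.integer(tf$inp)                   # time-major flat
  Xd <- agEmbed(p$embD, idx)
  X <- agColcat(Xd, agTileRows(z, Td))
  h0 <- agTanh(agAddBias(agMatmul(z, p$z2h.W), p$z2h.b))
  layer_in <- X
  for (l in seq_len(config$decLayers)) {
    gp <- p[[paste0("dec", l)]]
    XW <- agAddBias(agMatmul(layer_in, gp$Wx), gp$bx)
    layer_in <- agGruLayer(XW, h0, gp, B, Td, Hd)
    if (l < config$decLayers)
      layer_in <- agDropout(layer_in, config$dropout, train)
  }
  logits <- agAddBias(agMatmul(layer_in, p$out.W), p$out.b)
  agSoftmaxCE(logits, as.integer(tf$tgt), as.numeric(tf$w), norm = B)
}

#' Pretrain a SMILES variational autoencoder
#'
#' Trains on a SMILES corpus with the Adam optimizer at a fixed learning
#' rate; the loss is the teacher-forced token cross-entropy plus
#' `alpha(epoch)` times the Gaussian KL divergence, with alpha annealed
#' linearly per epoch (see [klAlphaSchedule]). One row per epoch is logged
#' with the exact decomposition `total = lSmiles + alpha * lKl`.
#'
#' @param corpus character vector of training SMILES.
#' @param config from [smilesVaeConfig].
#' @param seed integer RNG seed (initialization, shuffling, sampling,
#'   dropout).
#' @param vocab optional [Vocabulary-class]; built from the corpus when NULL.
#' @return a trained [SmilesVae-class].
#' @export
pretrainSmilesVae <- function(corpus, config = smilesVaeConfig(), seed = 1L,
                              vocab = NULL) {
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  if (is.null(vocab)) vocab <- buildVocabulary(corpus, config$maxLength)
  seqs <- lapply(corpus, tokenizeSmiles, vocab = vocab)
  keep <- !vapply(seqs, is.null, TRUE)
  if (!all(keep)) {
    warning(sum(!keep), " corpus entr(y/ies) not tokenizable; skipped")
    seqs <- seqs[keep]
  }
  if (length(seqs) == 0L) stop("no tokenizable corpus entry")
  p <- .smiles_vae_init(vocab, config, seed)
  flat <- .flatten_params(p)
  opt <- adamInit(flat)
  n <- length(seqs); D <- config$latentDim
  log <- vector("list", config$epochs)
  lens <- lengths(seqs)
  for (e in seq_len(config$epochs) - 1L) {
    alpha <- klAlphaSchedule(e, config$klAnnealRate, config$klInit)
    # length-bucketed batching: shuffle, sort by length with random
    # tie-breaks, cut into batches, shuffle batch order — similar-length
    # sequences batch together, so little compute is spent on padding
    ord <- sample.int(n)
    ord <- ord[order(lens[ord])]
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    batches <- batches[sample.int(length(batches))]
    er <- ek <- 0
    for (bi in batches) {
      agResetTape()
      enc <- .pad_encoder(seqs[bi])
      tf <- .pad_teacher(seqs[bi])
      g <- .encode_tape(p, enc, config$encHidden)
      epsC <- agConst(matrix(stats::rnorm(enc$B * D), enc$B, D))
      z <- agAdd(g$mu, agMul(agExp(agScale(g$lv, 0.5)), epsC))
      recon <- .decode_tape(p, z, tf, config, train = TRUE)
      klterm <- agScale(agSumAll(
        agSub(agAdd(agSquare(g$mu), agExp(g$lv)), agAddScalar(g$lv, 1))),
        0.5 / enc$B)
      total <- agAdd(recon, agScale(klterm, alpha))
      agZeroGrad(flat)
      agBackward(total)
      clipGradNorm(flat)
      opt <- adamStep(flat, opt, config$lr)
      er <- er + recon$value[1L] * length(bi)
      ek <- ek + klterm$value[1L] * length(bi)
    }
    er <- er / n; ek <- ek / n
    log[[e + 1L]] <- data.frame(epoch = e, lSmiles = er, lKl = ek,
                                alpha = alpha, lr = config$lr,
                                total = er + alpha * ek)
  }
  agResetTape()
  new("SmilesVae", vocab = vocab, params = p, config = config,
      trainLog = do.call(rbind, log))
}

#' Encode SMILES into the latent Gaussian
#'
#' Deterministic (evaluation-mode) encoding: returns the posterior mean and
#' standard deviation of each molecule's 128-dimensional latent Gaussian.
#'
#' @param model a [SmilesVae-class].
#' @param smiles character vector of SMILES (must tokenize under the model's
#'   vocabulary), or a list of integer token sequences.
#' @return list with matrices `mu` and `sigma` (batch x latentDim).
#' @export
encodeSmiles <- function(model, smiles) {
  seqs <- if (is.list(smiles)) smiles
          else lapply(smiles, tokenizeSmiles, vocab = model@vocab)
  if (any(vapply(seqs, is.null, TRUE)))
    stop("input contains SMILES outside the model vocabulary or too long")
  p <- model@params; cfg <- model@config; He <- cfg$encHidden
  enc <- .pad_encoder(seqs)
  B <- enc$B
  run_dir <- function(gp, times) {
    h <- matrix(0, B, He)
    for (t in times) {
      x <- p$embE$value[enc$tok[, t], , drop = FALSE]
      xw <- .gru_input_proj_eval(x, gp)
      hnew <- .gru_step_eval(xw, h, gp, He)
      mk <- enc$mask[, t]
      h <- hnew * mk + h * (1 - mk)
    }
    h
  }
  hcat <- cbind(run_dir(p$encF, seq_len(enc$Te)),
                run_dir(p$encB, rev(seq_len(enc$Te))))
  mu <- sweep(hcat %*% p$mu.W$value, 2L, as.numeric(p$mu.b$value), "+")
  lv <- sweep(hcat %*% p$lv.W$value, 2L, as.numeric(p$lv.b$value), "+")
  list(mu = mu, sigma = exp(0.5 * lv))
}

#' Reparameterized sample from a latent Gaussian
#'
#' `z = mu + sigma * eps` with `eps ~ N(0, I)`, reproducible from the seed.
#'
#' @param gaussian list with matrices `mu` and `sigma` (as returned by
#'   [encodeSmiles] / [encodeIev]).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return matrix of samples, same shape as `mu`.
#' @export
sampleLatent <- function(gaussian, seed = NULL) {
  mu <- rbind(gaussian$mu); sigma <- rbind(gaussian$sigma)
  stopifnot(all(dim(mu) == dim(sigma)), all(sigma >= 0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu + sigma * matrix(stats::rnorm(length(mu)), nrow(mu))
}

# batched plain-matrix decoder step shared by generation paths;
# state: list(h1, h2, h3); returns new state and token distributions
.decoder_step_eval <- function(p, cfg, tok, z, state) {
  Hd <- cfg$decHidden
  x <- cbind(p$embD$value[tok, , drop = FALSE], z)
  hs <- state
  layer_in <- x
  for (l in seq_len(cfg$decLayers)) {
    gp <- p[[paste0("dec", l)]]
    xw <- .gru_input_proj_eval(layer_in, gp)
    hs[[l]] <- .gru_step_eval(xw, hs[[l]], gp, Hd)
    layer_in <- hs[[l]]
  }
  logits <- sweep(layer_in %*% p$out.W$value, 2L, as.numeric(p$out.b$value),
                  "+")
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  list(state = hs, probs = ex / rowSums(ex))
}

#' Decode latent vectors into SMILES token sequences
#'
#' Runs the 3-layer GRU decoder from latent vectors, stepping until the end
#' token or `maxLength`. Greedy mode picks the argmax token (deterministic
#' given z); multinomial mode samples each token from the softmax
#' distribution (reproducible from the seed). Each step's full token
#' distribution is returned; rows sum to 1.
#'
#' @param model a [SmilesVae-class].
#' @param z matrix of latent vectors (rows) or a single vector.
#' @param mode "multinomial" (default) or "greedy".
#' @param seed integer seed for multinomial sampling.
#' @param maxLength cap on generated tokens (default: model config).
#' @return list per row of `z`: list(tokens, smiles, probs, truncated).
#' @export
decodeLatent <- function(model, z, mode = c("multinomial", "greedy"),
                         seed = NULL, maxLength = NULL) {
  mode <- match.arg(mode)
  if (is.null(dim(z))) z <- matrix(z, 1L)
  if (ncol(z) != model@config$latentDim) stop("latent dimension mismatch")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- model@params; cfg <- model@config
  maxLength <- if (is.null(maxLength)) cfg$maxLength else as.integer(maxLength)
  B <- nrow(z)
  h0 <- tanh(sweep(z %*% p$z2h.W$value, 2L, as.numeric(p$z2h.b$value), "+"))
  state <- rep(list(h0), cfg$decLayers)
  tok <- rep(2L, B)                      # start token
  alive <- rep(TRUE, B)
  toks <- rep(list(integer()), B)
  probs <- vector("list", B)
  step <- 0L
  V <- vocabSize(model@vocab)
  while (any(alive) && step < maxLength) {
    step <- step + 1L
    st <- .decoder_step_eval(p, cfg, tok, z, state)
    state <- st$state
    nxt <- integer(B)
    for (i in seq_len(B)) {
      if (!alive[i]) { nxt[i] <- 1L; next }
      pr <- st$probs[i, ]
      nxt[i] <- if (mode == "greedy") which.max(pr)
                else sample.int(V, 1L, prob = pr)
      probs[[i]] <- rbind(probs[[i]], pr)
      toks[[i]] <- c(toks[[i]], nxt[i])
      if (nxt[i] == 3L) alive[i] <- FALSE
    }
    tok <- nxt
  }
  lapply(seq_len(B), function(i) {
    tk <- toks[[i]]
    trunc <- length(tk) == 0L || tk[length(tk)] != 3L
    list(tokens = tk, smiles = detokenizeSmiles(tk, model@vocab),
         probs = probs[[i]], truncated = trunc)
  })
}

# evaluation-mode teacher-forced per-step distributions (dropout off);
# used to tie the training code path to reconstructionLoss()
.teacher_forced_probs <- function(model, seqs) {
  p <- model@params; cfg <- model@config
  tf <- .pad_teacher(seqs)
  enc <- .pad_encoder(seqs)
  g <- encodeSmiles(model, seqs)
  z <- g$mu
  h0 <- tanh(sweep(z %*% p$z2h.W$value, 2L, as.numeric(p$z2h.b$value), "+"))
  state <- rep(list(h0), cfg$decLayers)
  out <- vector("list", tf$B)
  for (t in seq_len(tf$Td)) {
    st <- .decoder_step_eval(p, cfg, tf$inp[, t], z, state)
    state <- st$state
    for (i in seq_len(tf$B)) if (tf$w[i, t] > 0)
      out[[i]] <- rbind(out[[i]], st$probs[i, ])
  }
  list(probs = out,
       targets = lapply(seq_len(tf$B), function(i)
         tf$tgt[i, tf$w[i, ] > 0]))
}

#' Greedy reconstruction accuracy
#'
#' Fraction of molecules whose greedy decoding of the posterior mean
#' reproduces the input SMILES string exactly.
#'
#' @param model a [SmilesVae-class].
#' @param smiles character vector of SMILES.
#' @return fraction in `[0, 1]`.
#' @export
greedyReconstructionAccuracy <- function(model, smiles) {
  g <- encodeSmiles(model, smiles)
  dec <- decodeLatent(model, g$mu, mode = "greedy")
  mean(vapply(dec, `[[`, "", "smiles") == smiles)
}
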