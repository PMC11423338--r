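test_that("fusion network maps latents into the SMILES latent space and
           responds to its conditioning input", {
  parts <- fxFusionParts()
  fm <- trainEndToEnd(parts$ds, parts$sv, parts$iv,
                      fusionConfig(hidden = c(16L, 12L), batchSize = 15L,
                                   epochs = 1L), seed = 10L)
  D <- parts$sv@config$latentDim
  set.seed(30)
  zs <- matrix(stats::rnorm(D), 1L)
  zi1 <- matrix(stats::rnorm(6), 1L)
  zi2 <- matrix(stats::rnorm(6), 1L)
  o1 <- zdnnForward(fm, zs, zi1)
  expect_identical(dim(o1), c(1L, D))
  expect_true(all(is.finite(o1)))
  # deterministic given weights and inputs
  expect_identical(o1, zdnnForward(fm, zs, zi1))
  # sensitivity probe: same SMILES latent, different IEV latent
  expect_false(isTRUE(all.equal(o1, zdnnForward(fm, zs, zi2))))
  expect_error(zdnnForward(fm, zs, matrix(1, 1L, 3L)), "mismatch")
})

test_that("end-to-end training freezes the encoders and follows its
           learning-rate schedule", {
  parts <- fxFusionParts()
  encBefore <- paramDigest(parts$sv, "smilesEncoder")
  decBefore <- paramDigest(parts$sv, "smilesDecoder")
  ievBefore <- paramDigest(parts$iv, "ievVae")
  fm <- trainEndToEnd(parts$ds, parts$sv, parts$iv,
                      fusionConfig(hidden = c(16L, 12L), batchSize = 15L,
                                   epochs = 5L, lrInit = 1e-4,
                                   lrDecay = 0.8, lrEvery = 2L), seed = 11L)
  # frozen components are bit-identical, both in the source objects and in
  # the fused model
  expect_identical(paramDigest(parts$sv, "smilesEncoder"), encBefore)
  expect_identical(paramDigest(parts$iv, "ievVae"), ievBefore)
  expect_identical(paramDigest(fm, "smilesEncoder"), encBefore)
  expect_identical(paramDigest(fm, "ievVae"), ievBefore)
  # the decoder was fine-tuned (and the pretrained copy left untouched)
  expect_false(identical(paramDigest(fm, "smilesDecoder"), decBefore))
  expect_identical(paramDigest(parts$sv, "smilesDecoder"), decBefore)
  # per-epoch step decay of the learning rate
  expect_equal(fm@trainLog$lr, 1e-4 * 0.8^((0:4) %/% 2L))
  # the objective is reconstruction cross-entropy only
  expect_identical(colnames(fm@trainLog), c("epoch", "lSmiles", "lr"))
  expect_true(all(fm@trainLog$lSmiles >= 0))
})

test_that("end-to-end objective equals the public reconstruction loss on the
           same batch", {
  parts <- fxFusionParts()
  sv <- parts$sv; iv <- parts$iv
  ns <- asNamespace("ievgen")
  seqs <- lapply(pairedSmiles(parts$ds)[1:6], tokenizeSmiles,
                 vocab = sv@vocab)
  cfgF <- fusionConfig(hidden = c(16L, 12L), useMean = TRUE)
  zdnn <- ns$.zdnn_init(sv@config$latentDim + iv@config$latentDim,
                        sv@config$latentDim, cfgF, seed = 12L)
  gs <- encodeSmiles(sv, seqs)
  gi <- encodeIev(iv, pairedIev(parts$ds)[1:6, ])
  ns$agResetTape()
  zout <- ns$.zdnn_tape(zdnn, ns$agConst(cbind(gs$mu, gi$mu)))
  tf <- ns$.pad_teacher(seqs)
  recon <- ns$.decode_tape(sv@params, zout, tf, sv@config, train = FALSE)
  ns$agResetTape()
  # recompute through the evaluation path + reconstructionLoss
  zeval <- ns$.zdnn_eval(zdnn, cbind(gs$mu, gi$mu))
  p <- sv@params; cfg <- sv@config
  h0 <- tanh(sweep(zeval %*% p$z2h.W$value, 2L,
                   as.numeric(p$z2h.b$value), "+"))
  state <- rep(list(h0), cfg$decLayers)
  probs <- vector("list", 6L)
  for (t in seq_len(tf$Td)) {
    st <- ns$.decoder_step_eval(p, cfg, tf$inp[, t], zeval, state)
    state <- st$state
    for (i in 1:6) if (tf$w[i, t] > 0)
      probs[[i]] <- rbind(probs[[i]], st$probs[i, ])
  }
  targets <- lapply(1:6, function(i) tf$tgt[i, tf$w[i, ] > 0])
  expect_equal(recon$value[1], reconstructionLoss(targets, probs),
               tolerance = 1e-9)
})

test_that("conditional generation honors n, the seed and the validity flag", {
  parts <- fxFusionParts()
  fm <- trainEndToEnd(parts$ds, parts$sv, parts$iv,
                      fusionConfig(hidden = c(16L, 12L), batchSize = 15L,
                                   epochs = 1L), seed = 13L)
  tgt <- iev(pairedIev(parts$ds)[1, ],
             residueIds = pocketResidues(parts$ds@pocket))
  g <- generateMolecules(fm, tgt, n = 25L, seed = 14L)
  expect_identical(length(generatedSmiles(g)), 25L)
  expect_identical(generatedValid(g), isValidSmiles(generatedSmiles(g)))
  g2 <- generateMolecules(fm, tgt, n = 25L, seed = 14L)
  expect_identical(generatedSmiles(g), generatedSmiles(g2))
  g3 <- generateMolecules(fm, tgt, n = 25L, seed = 15L)
  expect_false(identical(generatedSmiles(g), generatedSmiles(g3)))
  g0 <- generateMolecules(fm, tgt, n = 0L, seed = 14L)
  expect_identical(length(generatedSmiles(g0)), 0L)
})
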