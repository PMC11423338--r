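test_that("SELU matches its closed form and printed constants", {
  k <- seluConstants()
  expect_equal(seluActivation(0), 0)
  expect_equal(seluActivation(1), unname(k["lambda"]), tolerance = 1e-15)
  expect_equal(seluActivation(-1),
               unname(k["lambda"] * k["alpha"] * (exp(-1) - 1)),
               tolerance = 1e-15)
  # independent recomputation on random inputs
  set.seed(5)
  x <- stats::rnorm(1000, sd = 2)
  ref <- ifelse(x > 0, 1.0507000009873554 * x,
                1.0507000009873554 * 1.6732632423543772 * (exp(x) - 1))
  expect_equal(seluActivation(x), ref, tolerance = 1e-6)
})

test_that("valid 1-d convolution computes windowed dot products", {
  expect_equal(conv1dForward(c(5, -2, 7), 1), c(5, -2, 7))  # identity kernel
  expect_equal(conv1dForward(c(1, 2, 3), c(1, 0, -1)), -2)
  expect_error(conv1dForward(c(1, 2), c(1, 1, 1)), "longer")
  # linearity
  set.seed(6)
  a <- stats::rnorm(10); b <- stats::rnorm(10); k <- stats::rnorm(3)
  expect_equal(conv1dForward(a + b, k),
               conv1dForward(a, k) + conv1dForward(b, k), tolerance = 1e-12)
})

test_that("batch standardization centers and scales each feature", {
  out <- batchnormForward(matrix(c(0, 2), 2, 1))
  expect_equal(as.numeric(out), c(-1, 1), tolerance = 1e-2)
  # constant features shrink to ~0 under the epsilon regularizer
  expect_equal(as.numeric(batchnormForward(matrix(3, 4, 2))), rep(0, 8))
  set.seed(7)
  x <- matrix(stats::rnorm(200, mean = 5, sd = 3), 50)
  out <- batchnormForward(x)
  expect_lt(max(abs(colMeans(out))), 1e-6)
  # variance is 1 up to the epsilon regularization
  expect_equal(apply(out, 2, function(c) mean(c^2)), rep(1, 4),
               tolerance = 1e-4)
  # independent closed-form recomputation
  ref <- sweep(sweep(x, 2, colMeans(x), "-"), 2,
               sqrt(colMeans(sweep(x, 2, colMeans(x))^2) + 1e-5), "/")
  expect_equal(out, ref, tolerance = 1e-6)
  expect_error(batchnormForward(matrix(1, 1, 3)), "degenerate")
})

test_that("Gaussian KL loss matches closed form and Monte-Carlo estimate", {
  expect_equal(klLoss(0, 1), 0)
  expect_equal(klLoss(1, 1), 0.5)
  # batch averaging over rows
  expect_equal(klLoss(rbind(c(0, 0), c(1, 1)), matrix(1, 2, 2)), 0.5)
  # non-negativity on random Gaussians
  set.seed(8)
  for (i in 1:20) {
    mu <- stats::rnorm(4); s <- stats::runif(4, 0.3, 2)
    expect_gte(klLoss(mu, s), 0)
  }
  # Monte-Carlo estimate: KL = E_q[log q - log p] over 1e5 draws
  set.seed(9)
  mu <- c(0.5, -1); s <- c(0.7, 1.4)
  z <- cbind(stats::rnorm(1e5, mu[1], s[1]), stats::rnorm(1e5, mu[2], s[2]))
  logq <- stats::dnorm(z[, 1], mu[1], s[1], log = TRUE) +
    stats::dnorm(z[, 2], mu[2], s[2], log = TRUE)
  logp <- stats::dnorm(z[, 1], log = TRUE) + stats::dnorm(z[, 2], log = TRUE)
  mc <- mean(logq - logp)
  expect_equal(klLoss(mu, s), mc, tolerance = 0.02)
})

test_that("reconstruction loss is the summed token cross-entropy", {
  # probability 1 on every correct token -> 0
  expect_equal(reconstructionLoss(list(c(1L, 2L)),
                                  list(rbind(c(1, 0), c(0, 1)))), 0)
  # single token with p = 0.5 -> ln 2
  expect_equal(reconstructionLoss(list(1L), list(matrix(c(0.5, 0.5), 1))),
               log(2), tolerance = 1e-12)
  # non-negative for arbitrary distributions
  set.seed(10)
  p <- matrix(stats::runif(12), 3); p <- p / rowSums(p)
  expect_gte(reconstructionLoss(list(c(1L, 4L, 2L)), list(p)), 0)
})

test_that("IEV L1 loss sums dimensions and averages the batch", {
  expect_equal(ievL1Loss(c(1, 2), c(1, 2)), 0)
  expect_equal(ievL1Loss(c(1, 2), c(0, 0)), 3)
  a <- matrix(stats::rnorm(6), 2); b <- matrix(stats::rnorm(6), 2)
  expect_equal(ievL1Loss(a, b), ievL1Loss(b, a))
  expect_equal(ievL1Loss(a, b), mean(rowSums(abs(a - b))))
  expect_error(ievL1Loss(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("training schedules reproduce the printed values exactly", {
  expect_identical(klAlphaSchedule(0), 0)
  expect_identical(klAlphaSchedule(10), 0.05)
  expect_equal(klAlphaSchedule(0:99), 5e-3 * (0:99))
  expect_identical(lrStepSchedule(0, 1e-3, 0.9, 2000), 1e-3)
  expect_equal(lrStepSchedule(4000, 1e-3, 0.9, 2000), 8.1e-4)
  expect_equal(lrStepSchedule(40, 1e-4, 0.8, 20), 6.4e-5)
  expect_equal(lrStepSchedule(1999, 1e-3, 0.9, 2000), 1e-3)
})

test_that("autodiff gradients agree with numerical differentiation", {
  ns <- asNamespace("ievgen")
  v <- buildVocabulary(c("CCO", "CCN", "c1ccccc1"))
  cfg <- smilesVaeConfig(latentDim = 5L, embDim = 4L, encHidden = 6L,
                         decHidden = 7L, batchSize = 3L, epochs = 0L,
                         dropout = 0)
  p <- ns$.smiles_vae_init(v, cfg, seed = 2L)
  flat <- ns$.flatten_params(p)
  seqs <- lapply(c("CCO", "CCN", "c1ccccc1"), tokenizeSmiles, vocab = v)
  lossfun <- function() {
    ns$agResetTape()
    set.seed(99)
    enc <- ns$.pad_encoder(seqs); tf <- ns$.pad_teacher(seqs)
    g <- ns$.encode_tape(p, enc, cfg$encHidden)
    epsC <- ns$agConst(matrix(stats::rnorm(enc$B * cfg$latentDim), enc$B))
    z <- ns$agAdd(g$mu, ns$agMul(ns$agExp(ns$agScale(g$lv, 0.5)), epsC))
    recon <- ns$.decode_tape(p, z, tf, cfg, train = FALSE)
    kl <- ns$agScale(ns$agSumAll(ns$agSub(
      ns$agAdd(ns$agSquare(g$mu), ns$agExp(g$lv)),
      ns$agAddScalar(g$lv, 1))), 0.5 / enc$B)
    ns$agAdd(recon, ns$agScale(kl, 0.3))
  }
  total <- lossfun()
  ns$agZeroGrad(flat)
  ns$agBackward(total)
  set.seed(20)
  h <- 1e-6
  for (nm in c("embE", "encF.Whrz", "encB.Wx", "mu.W", "z2h.W",
               "dec1.Wx", "dec2.Whn", "dec3.bhn", "out.W", "embD")) {
    pp <- flat[[nm]]
    i <- sample(length(pp$value), 1L)
    ana <- if (is.null(pp$grad)) 0 else pp$grad[i]
    orig <- pp$value[i]
    pp$value[i] <- orig + h; lp <- lossfun()$value[1]
    pp$value[i] <- orig - h; lm <- lossfun()$value[1]
    pp$value[i] <- orig
    num <- (lp - lm) / (2 * h)
    expect_equal(ana, num, tolerance = 1e-3,
                 label = paste("analytic grad of", nm))
  }
})

test_that("optimization reduces the reconstruction loss on a fixed batch", {
  # alpha forced to 0, one fixed batch: the loss trend must be decreasing
  corpus <- fxCorpus(10L)
  cfg <- smilesVaeConfig(embDim = 12L, encHidden = 16L, decHidden = 24L,
                         batchSize = 10L, epochs = 50L, dropout = 0,
                         klAnnealRate = 0, klInit = 0, maxLength = 60L)
  m <- pretrainSmilesVae(corpus, cfg, seed = 6L)
  l <- m@trainLog$lSmiles
  expect_lt(l[50], l[1])
  # each successive 10-step average is no larger than the previous
  avg <- colMeans(matrix(l, 10))
  expect_true(all(diff(avg) <= 0))
  # log decomposition holds exactly at every step
  expect_identical(m@trainLog$total,
                   m@trainLog$lSmiles + m@trainLog$alpha * m@trainLog$lKl)
})
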