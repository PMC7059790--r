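test_that("configuration validates its hyperparameters", {
  expect_error(corenet_config(Dt = 0), "Dt")
  expect_error(corenet_config(Pd = 1), "Pd")
  cfg <- corenet_config()
  expect_equal(c(cfg$Dt, cfg$Nr, cfg$Nc), c(10L, 3L, 512L))
  expect_equal(cfg$Pd, 0.3)
})

test_that("feature enhancement duplicates the input block Dt times", {
  X <- matrix(rnorm(4 * 57), 4, 57)
  E <- corenet:::enhance(X, 10L)
  expect_equal(ncol(E), 570)
  expect_equal(E[, 1:57], X, ignore_attr = TRUE)
  expect_equal(E[, 57 + 1:57], X, ignore_attr = TRUE)
  expect_identical(corenet:::enhance(X, 1L), X)
})

test_that("the residual stack carries an identity skip path", {
  # zeroing every residual branch must make the stack depth irrelevant
  zero_branches <- function(net, Nr) {
    for (r in seq_len(Nr)) {
      nm <- sprintf("res%d.fc2", r)
      net$P[[paste0(nm, ".W")]][] <- 0
      net$P[[paste0(nm, ".b")]][] <- 0
    }
    net
  }
  cfg3 <- corenet_config(Dt = 2, Nr = 3, Nc = 12, Pd = 0,
                         pred_widths = c(8, 6, 4), seed = 1)
  cfg1 <- corenet_config(Dt = 2, Nr = 1, Nc = 12, Pd = 0,
                         pred_widths = c(8, 6, 4), seed = 1)
  set.seed(2)
  net3 <- corenet:::net_init(cfg3, input_dim = 9)
  set.seed(2)
  net1 <- corenet:::net_init(cfg1, input_dim = 9)
  shared <- intersect(names(net1$P), names(net3$P))
  shared <- shared[!grepl("^res", shared)]
  for (nm in shared) net1$P[[nm]] <- net3$P[[nm]]
  net3 <- zero_branches(net3, 3L)
  net1 <- zero_branches(net1, 1L)
  X <- matrix(rnorm(5 * 9), 5, 9)
  expect_equal(corenet:::net_forward(net3, X, cfg3)$p,
               corenet:::net_forward(net1, X, cfg1)$p, tolerance = 1e-12)
  # and the parameter list names reflect exactly Nr residual units
  expect_length(grep("^res\\d+\\.bn\\.gamma$", names(net3$P)), 3)
})

test_that("an untrained network with a zeroed head predicts exactly 0.5", {
  cfg <- corenet_config(Dt = 2, Nr = 2, Nc = 10, Pd = 0.3,
                        pred_widths = c(8, 6, 4))
  set.seed(6)
  net <- corenet:::net_init(cfg, input_dim = 8)
  net$P[["pred.fc5.W"]][] <- 0
  net$P[["pred.fc5.b"]][] <- 0
  X <- matrix(rnorm(7 * 8), 7, 8)
  expect_equal(corenet:::net_forward(net, X, cfg)$p, rep(0.5, 7))
})

test_that("binary cross-entropy at random initialization is close to log 2", {
  cfg <- corenet_config(Dt = 3, Nr = 2, Nc = 32, Pd = 0.3,
                        pred_widths = c(16, 12, 8))
  set.seed(41)
  net <- corenet:::net_init(cfg, input_dim = 20)
  X <- matrix(rnorm(200 * 20), 200, 20)
  y <- rep(c(0, 1), 100)
  p <- corenet:::net_forward(net, X, cfg)$p
  expect_equal(corenet:::bce_loss(p, y), log(2), tolerance = 0.1)
})

test_that("analytic gradients match central finite differences", {
  cfg <- corenet_config(Dt = 2, Nr = 2, Nc = 8, Pd = 0,
                        pred_widths = c(6, 5, 4), seed = 3)
  set.seed(3)
  net <- corenet:::net_init(cfg, input_dim = 7)
  X <- matrix(rnorm(8 * 7), 8, 7)
  y <- rep(c(0, 1), 4)
  fw <- corenet:::net_forward(net, X, cfg, training = TRUE)
  G <- corenet:::net_backward(net, fw, X, y, cfg)
  loss_at <- function(P) {
    n2 <- net
    n2$P <- P
    corenet:::bce_loss(corenet:::net_forward(n2, X, cfg, training = TRUE)$p,
                       y)
  }
  eps <- 1e-6
  set.seed(8)
  for (nm in names(G)) {
    for (i in sample(length(net$P[[nm]]), min(2, length(net$P[[nm]])))) {
      Pp <- net$P; Pp[[nm]][i] <- Pp[[nm]][i] + eps
      Pm <- net$P; Pm[[nm]][i] <- Pm[[nm]][i] - eps
      num <- (loss_at(Pp) - loss_at(Pm)) / (2 * eps)
      expect_equal(G[[nm]][i], num, tolerance = 1e-3,
                   info = paste(nm, i))
    }
  }
})

test_that("training overfits 32 separable rows and loss decreases almost monotonically", {
  set.seed(5)
  n <- 32
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rep(c(0, 1), each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + 3
  cfg <- corenet_config(Dt = 2, Nr = 1, Nc = 16, Pd = 0,
                        pred_widths = c(8, 6, 4), batch_size = 32,
                        max_epochs = 200, patience = 200,
                        validation_fraction = 0, seed = 9)
  tr <- corenet:::net_train(X, y, cfg)
  expect_lt(min(tr$history$train_loss), 0.01)
  d <- diff(tr$history$train_loss[seq_len(tr$best_epoch)])
  expect_gte(mean(d < 0), 0.9)
})

test_that("training with a fixed seed is exactly reproducible", {
  set.seed(5)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y <- rep(c(0, 1), 30)
  cfg <- corenet_config(Dt = 2, Nr = 1, Nc = 12, Pd = 0.2,
                        pred_widths = c(8, 6, 4), batch_size = 16,
                        max_epochs = 5, seed = 17)
  t1 <- corenet:::net_train(X, y, cfg)
  t2 <- corenet:::net_train(X, y, cfg)
  expect_identical(t1$net$P, t2$net$P)
  expect_identical(t1$history, t2$history)
})

test_that("degenerate labels abort training", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(corenet:::net_train(X, rep(1, 20), corenet_config()),
               "single class")
})
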