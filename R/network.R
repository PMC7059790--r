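# Residual fully-connected network, written directly in base R matrix code.
#
# Architecture (all widths per corenet_config):
#   enhancement : repeat the 57 inputs Dt times -> 57*Dt
#   compression : BN -> FC(Nc) -> ReLU -> drop -> FC(Nc) -> ReLU -> drop
#   residual    : Nr units, each BN -> FC -> ReLU -> drop -> FC, added to the
#                 unit input (identity skip), ReLU after the addition
#   integration : two units; each concatenates its input with the compression
#                 output, then BN -> FC(Nc) -> ReLU -> drop
#   prediction  : BN -> FC(Nc) -> ReLU -> drop -> FC(256) -> ... -> FC(64)
#                 -> FC(1) -> sigmoid (five FC layers in total)
# Batch normalization opens every unit, matching the design where all units
# first renormalize their incoming activations.

#' Network and training hyperparameters
#'
#' @param Dt Duplication count of the feature-enhancement module.
#' @param Nr Number of residual units.
#' @param Nc Width of the fully connected layers in the feature-learning
#'   module.
#' @param Pd Dropout probability.
#' @param pred_widths Widths of the three inner prediction layers.
#' @param learning_rate Base adaptive step size.
#' @param final_lr Asymptotic bound of the clipped adaptive step.
#' @param batch_size Minibatch size.
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); ignored when \code{validation_fraction} is 0, in which
#'   case the training loss is monitored.
#' @param validation_fraction Fraction of training rows held out for early
#'   stopping (stratified).
#' @param optimizer \code{"adabound"} (bound-clipped adaptive steps) or
#'   plain \code{"adam"}.
#' @param seed Integer seed controlling initialization, batching and dropout.
#' @return An object of class \code{corenet_config}.
#' @export
corenet_config <- function(Dt = 10L, Nr = 3L, Nc = 512L, Pd = 0.3,
                           pred_widths = c(256L, 128L, 64L),
                           learning_rate = 1e-3, final_lr = 0.1,
                           batch_size = 256L, max_epochs = 60L,
                           patience = 10L, validation_fraction = 0.1,
                           optimizer = c("adabound", "adam"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  cfg <- list(Dt = as.integer(Dt), Nr = as.integer(Nr), Nc = as.integer(Nc),
              Pd = Pd, pred_widths = as.integer(pred_widths),
              learning_rate = learning_rate, final_lr = final_lr,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              validation_fraction = validation_fraction,
              optimizer = optimizer, seed = as.integer(seed))
  if (cfg$Dt < 1L || cfg$Nr < 1L || cfg$Nc < 1L) {
    stop("Dt, Nr and Nc must all be >= 1")
  }
  if (cfg$Pd < 0 || cfg$Pd >= 1) stop("Pd must be in [0, 1)")
  if (length(cfg$pred_widths) != 3L) {
    stop("pred_widths must give the three inner prediction-layer widths")
  }
  class(cfg) <- "corenet_config"
  cfg
}

#' @export
print.corenet_config <- function(x, ...) {
  cat("corenet network configuration\n")
  cat(sprintf("  Dt = %d, Nr = %d, Nc = %d, Pd = %.2f\n",
              x$Dt, x$Nr, x$Nc, x$Pd))
  cat(sprintf("  optimizer = %s (lr %.2g, final bound %.2g), batch %d,",
              x$optimizer, x$learning_rate, x$final_lr, x$batch_size),
      sprintf("max %d epochs, patience %d\n", x$max_epochs, x$patience))
  invisible(x)
}

# feature enhancement: repeat columns Dt times
enhance <- function(x, Dt) {
  if (Dt == 1L) return(x)
  x[, rep(seq_len(ncol(x)), Dt), drop = FALSE]
}

# ---- layer primitives -------------------------------------------------------

he_init <- function(n_in, n_out, scale = sqrt(2)) {
  matrix(stats::rnorm(n_in * n_out, sd = scale / sqrt(n_in)), n_in, n_out)
}

dense_f <- function(x, W, b) sweep(x %*% W, 2L, b, "+")

dense_b <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_f <- function(x, gamma, beta, rmean, rvar, training) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu, "-")
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2L, invstd, "*")
    rmean <- BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * mu
    rvar <- BN_MOMENTUM * rvar + (1 - BN_MOMENTUM) * v
  } else {
    invstd <- 1 / sqrt(rvar + BN_EPS)
    xhat <- sweep(sweep(x, 2L, rmean, "-"), 2L, invstd, "*")
  }
  list(y = sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+"),
       xhat = xhat, invstd = invstd, rmean = rmean, rvar = rvar,
       training = training)
}

bn_b <- function(dy, cache, gamma) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  if (cache$training) {
    n <- nrow(dy)
    dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                  cache$xhat *
                  matrix(colMeans(dxhat * cache$xhat), n, ncol(dy),
                         byrow = TRUE),
                2L, cache$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

drop_f <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
  list(y = x * mask, mask = mask)
}

drop_b <- function(dy, mask) if (is.null(mask)) dy else dy * mask

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- parameter container ----------------------------------------------------

# initialize all weights; params ("P") are optimized, batchnorm running
# statistics ("S") are tracked alongside
net_init <- function(config, input_dim = 57L) {
  Nc <- config$Nc
  d_in <- input_dim * config$Dt
  pw <- config$pred_widths
  P <- list()
  S <- list()
  add_bn <- function(name, d) {
    P[[paste0(name, ".gamma")]] <<- rep(1, d)
    P[[paste0(name, ".beta")]] <<- rep(0, d)
    S[[paste0(name, ".mean")]] <<- rep(0, d)
    S[[paste0(name, ".var")]] <<- rep(1, d)
  }
  add_fc <- function(name, a, b, scale = sqrt(2)) {
    P[[paste0(name, ".W")]] <<- he_init(a, b, scale)
    P[[paste0(name, ".b")]] <<- rep(0, b)
  }
  add_bn("comp.bn", d_in)
  add_fc("comp.fc1", d_in, Nc)
  add_fc("comp.fc2", Nc, Nc)
  for (r in seq_len(config$Nr)) {
    add_bn(sprintf("res%d.bn", r), Nc)
    add_fc(sprintf("res%d.fc1", r), Nc, Nc)
    add_fc(sprintf("res%d.fc2", r), Nc, Nc)
  }
  add_bn("int1.bn", 2L * Nc)
  add_fc("int1.fc", 2L * Nc, Nc)
  add_bn("int2.bn", 2L * Nc)
  add_fc("int2.fc", 2L * Nc, Nc)
  add_bn("pred.bn", Nc)
  add_fc("pred.fc1", Nc, Nc)
  add_fc("pred.fc2", Nc, pw[1L])
  add_fc("pred.fc3", pw[1L], pw[2L])
  add_fc("pred.fc4", pw[2L], pw[3L])
  # small head initialization so the untrained network starts near p = 0.5
  add_fc("pred.fc5", pw[3L], 1L, scale = 0.01)
  list(P = P, S = S, input_dim = input_dim)
}

# one unit of: BN -> FC -> ReLU -> dropout, used by integration units;
# returns output plus caches
unit_bfrd <- function(x, P, S, name, fcname, Pd, training) {
  bn <- bn_f(x, P[[paste0(name, ".gamma")]], P[[paste0(name, ".beta")]],
             S[[paste0(name, ".mean")]], S[[paste0(name, ".var")]], training)
  z <- dense_f(bn$y, P[[paste0(fcname, ".W")]], P[[paste0(fcname, ".b")]])
  a <- pmax(z, 0)
  dr <- drop_f(a, Pd, training)
  list(y = dr$y, bn = bn, bn_in = x, z = z, a = a, mask = dr$mask)
}

# full forward pass; returns probability of the positive (coding) class and
# every intermediate needed for backprop, plus updated running statistics
net_forward <- function(net, x, config, training = FALSE) {
  P <- net$P
  S <- net$S
  Pd <- config$Pd
  cache <- list()

  xE <- enhance(x, config$Dt)
  # compression unit
  cbn <- bn_f(xE, P[["comp.bn.gamma"]], P[["comp.bn.beta"]],
              S[["comp.bn.mean"]], S[["comp.bn.var"]], training)
  S[["comp.bn.mean"]] <- cbn$rmean; S[["comp.bn.var"]] <- cbn$rvar
  cz1 <- dense_f(cbn$y, P[["comp.fc1.W"]], P[["comp.fc1.b"]])
  ca1 <- pmax(cz1, 0)
  cd1 <- drop_f(ca1, Pd, training)
  cz2 <- dense_f(cd1$y, P[["comp.fc2.W"]], P[["comp.fc2.b"]])
  ca2 <- pmax(cz2, 0)
  cd2 <- drop_f(ca2, Pd, training)
  C <- cd2$y
  cache$comp <- list(xE = xE, bn = cbn, z1 = cz1, a1 = ca1, m1 = cd1$mask,
                     d1 = cd1$y, z2 = cz2, a2 = ca2, m2 = cd2$mask)

  # residual stack
  h <- C
  cache$res <- vector("list", config$Nr)
  for (r in seq_len(config$Nr)) {
    nm <- sprintf("res%d", r)
    rbn <- bn_f(h, P[[paste0(nm, ".bn.gamma")]], P[[paste0(nm, ".bn.beta")]],
                S[[paste0(nm, ".bn.mean")]], S[[paste0(nm, ".bn.var")]],
                training)
    S[[paste0(nm, ".bn.mean")]] <- rbn$rmean
    S[[paste0(nm, ".bn.var")]] <- rbn$rvar
    rz1 <- dense_f(rbn$y, P[[paste0(nm, ".fc1.W")]], P[[paste0(nm, ".fc1.b")]])
    ra1 <- pmax(rz1, 0)
    rd1 <- drop_f(ra1, Pd, training)
    rz2 <- dense_f(rd1$y, P[[paste0(nm, ".fc2.W")]], P[[paste0(nm, ".fc2.b")]])
    pre <- h + rz2
    h_out <- pmax(pre, 0)
    cache$res[[r]] <- list(h_in = h, bn = rbn, z1 = rz1, a1 = ra1,
                           m1 = rd1$mask, d1 = rd1$y, z2 = rz2, pre = pre)
    h <- h_out
  }

  # integration units (fuse with the compression output)
  i1 <- unit_bfrd(cbind(h, C), P, S, "int1.bn", "int1.fc", Pd, training)
  S[["int1.bn.mean"]] <- i1$bn$rmean; S[["int1.bn.var"]] <- i1$bn$rvar
  i2 <- unit_bfrd(cbind(i1$y, C), P, S, "int2.bn", "int2.fc", Pd, training)
  S[["int2.bn.mean"]] <- i2$bn$rmean; S[["int2.bn.var"]] <- i2$bn$rvar
  cache$int1 <- i1
  cache$int2 <- i2

  # prediction module
  pbn <- bn_f(i2$y, P[["pred.bn.gamma"]], P[["pred.bn.beta"]],
              S[["pred.bn.mean"]], S[["pred.bn.var"]], training)
  S[["pred.bn.mean"]] <- pbn$rmean; S[["pred.bn.var"]] <- pbn$rvar
  act <- pbn$y
  pc <- list(bn = pbn)
  for (l in 1:4) {
    nm <- sprintf("pred.fc%d", l)
    z <- dense_f(act, P[[paste0(nm, ".W")]], P[[paste0(nm, ".b")]])
    a <- pmax(z, 0)
    dr <- drop_f(a, Pd, training)
    pc[[nm]] <- list(x = act, z = z, a = a, mask = dr$mask)
    act <- dr$y
  }
  logit <- dense_f(act, P[["pred.fc5.W"]], P[["pred.fc5.b"]])
  pc$fc5_in <- act
  cache$pred <- pc
  list(p = as.numeric(sigmoid(logit)), cache = cache, S = S)
}

clip01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

bce_loss <- function(p, y) {
  p <- clip01(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# full backward pass; fw is the result of net_forward(training = TRUE)
net_backward <- function(net, fw, x, y, config) {
  P <- net$P
  cache <- fw$cache
  G <- list()
  n <- length(y)
  p <- clip01(fw$p)
  dlogit <- matrix((p - y) / n, ncol = 1L)

  bwd_dense <- function(nm, dy, xin) {
    d <- dense_b(dy, xin, P[[paste0(nm, ".W")]])
    G[[paste0(nm, ".W")]] <<- d$dW
    G[[paste0(nm, ".b")]] <<- d$db
    d$dx
  }
  bwd_bn <- function(nm, dy, bncache) {
    d <- bn_b(dy, bncache, P[[paste0(nm, ".gamma")]])
    G[[paste0(nm, ".gamma")]] <<- d$dgamma
    G[[paste0(nm, ".beta")]] <<- d$dbeta
    d$dx
  }

  # prediction module
  pc <- cache$pred
  dact <- bwd_dense("pred.fc5", dlogit, pc$fc5_in)
  for (l in 4:1) {
    nm <- sprintf("pred.fc%d", l)
    lc <- pc[[nm]]
    dact <- drop_b(dact, lc$mask)
    dz <- dact * (lc$z > 0)
    dact <- bwd_dense(nm, dz, lc$x)
  }
  dI2 <- bwd_bn("pred.bn", dact, pc$bn)

  # integration unit 2
  i2 <- cache$int2
  d <- drop_b(dI2, i2$mask) * (i2$z > 0)
  dcat2 <- bwd_bn("int2.bn", bwd_dense("int2.fc", d, i2$bn$y), i2$bn)
  Nc <- config$Nc
  dI1 <- dcat2[, seq_len(Nc), drop = FALSE]
  dC <- dcat2[, Nc + seq_len(Nc), drop = FALSE]

  # integration unit 1
  i1 <- cache$int1
  d <- drop_b(dI1, i1$mask) * (i1$z > 0)
  dcat1 <- bwd_bn("int1.bn", bwd_dense("int1.fc", d, i1$bn$y), i1$bn)
  dh <- dcat1[, seq_len(Nc), drop = FALSE]
  dC <- dC + dcat1[, Nc + seq_len(Nc), drop = FALSE]

  # residual stack (reverse)
  for (r in rev(seq_len(config$Nr))) {
    nm <- sprintf("res%d", r)
    rc <- cache$res[[r]]
    dpre <- dh * (rc$pre > 0)
    dz2 <- dpre
    dd1 <- bwd_dense(paste0(nm, ".fc2"), dz2, rc$d1)
    da1 <- drop_b(dd1, rc$m1)
    dz1 <- da1 * (rc$z1 > 0)
    dbn <- bwd_dense(paste0(nm, ".fc1"), dz1, rc$bn$y)
    dh_in <- bwd_bn(paste0(nm, ".bn"), dbn, rc$bn)
    dh <- dpre + dh_in      # skip path + branch path
  }
  dC <- dC + dh

  # compression unit
  cc <- cache$comp
  da2 <- drop_b(dC, cc$m2) * (cc$z2 > 0)
  dd1 <- bwd_dense("comp.fc2", da2, cc$d1)
  da1 <- drop_b(dd1, cc$m1) * (cc$z1 > 0)
  dbn <- bwd_dense("comp.fc1", da1, cc$bn$y)
  invisible(bwd_bn("comp.bn", dbn, cc$bn))
  G
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(P) {
  list(m = lapply(P, function(p) p * 0), v = lapply(P, function(p) p * 0),
       t = 0L)
}

ADAM_B1 <- 0.9
ADAM_B2 <- 0.999
ADAM_EPS <- 1e-8
ADABOUND_GAMMA <- 1e-3

opt_step <- function(P, G, st, config) {
  st$t <- st$t + 1L
  t <- st$t
  lr <- config$learning_rate
  bc <- sqrt(1 - ADAM_B2^t) / (1 - ADAM_B1^t)
  if (config$optimizer == "adabound") {
    lb <- config$final_lr * (1 - 1 / (ADABOUND_GAMMA * t + 1))
    ub <- config$final_lr * (1 + 1 / (ADABOUND_GAMMA * t))
  }
  for (nm in names(G)) {
    g <- G[[nm]]
    st$m[[nm]] <- ADAM_B1 * st$m[[nm]] + (1 - ADAM_B1) * g
    st$v[[nm]] <- ADAM_B2 * st$v[[nm]] + (1 - ADAM_B2) * g^2
    if (config$optimizer == "adabound") {
      eta <- pmin(pmax(lr * bc / (sqrt(st$v[[nm]]) + ADAM_EPS), lb), ub)
      P[[nm]] <- P[[nm]] - eta * st$m[[nm]]
    } else {
      P[[nm]] <- P[[nm]] - lr * bc * st$m[[nm]] /
        (sqrt(st$v[[nm]]) + ADAM_EPS * sqrt(1 - ADAM_B2^t))
    }
  }
  list(P = P, st = st)
}

# ---- training loop ----------------------------------------------------------

# X: scaled feature matrix; y: 0/1 labels (1 = coding)
net_train <- function(X, y, config) {
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class")
  }
  set.seed(config$seed)
  net <- net_init(config, input_dim = ncol(X))

  n <- nrow(X)
  val_idx <- integer(0)
  if (config$validation_fraction > 0) {
    for (cls in c(0, 1)) {
      ic <- which(y == cls)
      n_val <- max(1L, round(config$validation_fraction * length(ic)))
      val_idx <- c(val_idx, sample(ic, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]
  monitor_val <- length(val_idx) > 0L

  st <- opt_init(net$P)
  best <- list(loss = Inf, P = net$P, S = net$S, epoch = 0L)
  waited <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(ytr))
    nb <- ceiling(length(ord) / config$batch_size)
    starts <- (seq_len(nb) - 1L) * config$batch_size + 1L
    epoch_loss <- 0
    epoch_correct <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L,
                                length(ord))]
      if (length(idx) < 2L) next   # batchnorm needs >= 2 rows
      xb <- Xtr[idx, , drop = FALSE]
      yb <- ytr[idx]
      fw <- net_forward(net, xb, config, training = TRUE)
      net$S <- fw$S
      loss <- bce_loss(fw$p, yb)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; inspect feature scaling and learning rate")
      }
      G <- net_backward(net, fw, xb, yb, config)
      up <- opt_step(net$P, G, st, config)
      net$P <- up$P
      st <- up$st
      epoch_loss <- epoch_loss + loss * length(idx)
      epoch_correct <- epoch_correct + sum((fw$p >= 0.5) == (yb == 1))
    }
    train_loss <- epoch_loss / length(ytr)
    train_acc <- epoch_correct / length(ytr)
    if (monitor_val) {
      pv <- net_forward(net, Xva, config, training = FALSE)$p
      val_loss <- bce_loss(pv, yva)
      val_acc <- mean((pv >= 0.5) == (yva == 1))
    } else {
      val_loss <- NA_real_
      val_acc <- NA_real_
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                train_acc = train_acc, val_loss = val_loss,
                                val_acc = val_acc)
    watch <- if (monitor_val) val_loss else train_loss
    if (watch < best$loss - 1e-6) {
      best <- list(loss = watch, P = net$P, S = net$S, epoch = epoch)
      waited <- 0L
    } else {
      waited <- waited + 1L
      if (waited >= config$patience) break
    }
  }
  net$P <- best$P
  net$S <- best$S
  list(net = net, history = do.call(rbind, hist), best_epoch = best$epoch)
}

# eval-mode probability of the coding class
net_predict <- function(net, X, config) {
  net_forward(net, X, config, training = FALSE)$p
}
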