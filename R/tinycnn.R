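# A small convolutional network implemented directly on BLAS-backed matrix
# algebra (im2col + GEMM).  Architecture family: repeated [3x3 same conv ->
# ReLU -> 2x2 max-pool (floor)] blocks, then dropout and two fully connected
# layers ending in a 2-way softmax, trained by Adam on the cross-entropy
#   L_CE = -sum_i Y_i * log(P_i).
# Inputs are (S, S, 3, N) arrays scaled to [0,1] and centered internally.

# ---- im2col ---------------------------------------------------------------

# index matrix mapping each output pixel of a 3x3 same-padded conv to the 9*C
# positions it reads in the zero-padded (H+2, W+2, C) array of one sample
im2col_index <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  col <- 0L
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    col <- col + 1L
    idx[, col] <- (c - 1L) * Hp * Wp + (j + dj - 1L) * Hp + (i + di)
  }
  idx
}

# batch im2col: x is (H, W, C, N); returns (N*H*W) x (9C) matrix whose rows are
# sample-major blocks of column-major output pixels, plus the padded array
batch_im2col <- function(x, idx) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- array(0, dim = c(H + 2L, W + 2L, C, N))
  xp[2L:(H + 1L), 2L:(W + 1L), , ] <- x
  per <- (H + 2L) * (W + 2L) * C
  big <- idx[rep(seq_len(H * W), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * per, each = H * W)
  matrix(xp[big], nrow = N * H * W)
}

# ---- architecture ---------------------------------------------------------

#' Tiny-CNN architecture description
#'
#' @param input_size patch side length S.
#' @param filters integer vector, one entry per conv block; blocks are dropped
#'   from the end if pooling would shrink the map below 2 px.
#' @param fc_units width of the hidden fully connected layer.
#' @param dropout dropout probability applied before each FC layer.
#' @param n_classes output classes (2 for the cascade nodes).
#' @return list describing layer shapes, with total parameter count
#'   \code{n_params}.
#' @export
tinycnn_architecture <- function(input_size, filters = c(16L, 32L, 64L),
                                 fc_units = 64L, dropout = 0.25, n_classes = 2L) {
  S <- as.integer(input_size)
  shapes <- list(); Cin <- 3L; sz <- S
  for (f in filters) {
    if (sz %/% 2L < 2L) break
    shapes[[length(shapes) + 1L]] <- list(type = "conv", Cin = Cin, Cout = as.integer(f),
                                          H = sz, W = sz)
    sz <- sz %/% 2L   # floor semantics of 2x2 max pooling
    Cin <- as.integer(f)
  }
  flat <- sz * sz * Cin
  n_params <- sum(vapply(shapes, function(s) 9L * s$Cin * s$Cout + s$Cout, 0L)) +
    flat * fc_units + fc_units + fc_units * n_classes + n_classes
  list(input_size = S, conv = shapes, flat = flat,
       fc_units = as.integer(fc_units), dropout = dropout,
       n_classes = as.integer(n_classes), n_params = n_params)
}

# He-initialized parameters for an architecture
tinycnn_init <- function(arch, seed = 1L) {
  with_seed(seed, {
    layers <- lapply(arch$conv, function(s) {
      fan_in <- 9L * s$Cin
      list(type = "conv",
           W = matrix(rnorm(fan_in * s$Cout, sd = sqrt(2 / fan_in)), fan_in, s$Cout),
           b = numeric(s$Cout),
           idx = im2col_index(s$H, s$W, s$Cin), h = s$H, w = s$W,
           Cin = s$Cin, Cout = s$Cout)
    })
    fc1 <- list(type = "fc",
                W = matrix(rnorm(arch$flat * arch$fc_units, sd = sqrt(2 / arch$flat)),
                           arch$flat, arch$fc_units),
                b = numeric(arch$fc_units))
    fc2 <- list(type = "fc",
                W = matrix(rnorm(arch$fc_units * arch$n_classes,
                                 sd = sqrt(2 / arch$fc_units)),
                           arch$fc_units, arch$n_classes),
                b = numeric(arch$n_classes))
    list(arch = arch, conv = layers, fc1 = fc1, fc2 = fc2)
  })
}

# 2x2 max pool with floor semantics; returns pooled array and argmax slot
maxpool2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  i1 <- seq.int(1L, 2L * Ho, 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, 2L * Wo, 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; dd <- x[i2, j2, , , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  # first slot achieving the max wins (deterministic tie-break)
  slot <- array(1L, dim(out))
  slot[a < out & b == out] <- 2L
  slot[a < out & b < out & cc == out] <- 3L
  slot[a < out & b < out & cc < out & dd == out] <- 4L
  list(out = out, slot = slot, H = H, W = W)
}

maxpool2_backward <- function(dout, pool) {
  d <- dim(dout); Ho <- d[1]; Wo <- d[2]; C <- d[3]; N <- d[4]
  dx <- array(0, dim = c(pool$H, pool$W, C, N))
  i1 <- seq.int(1L, 2L * Ho, 2L); j1 <- seq.int(1L, 2L * Wo, 2L)
  for (s in 1:4) {
    sel <- pool$slot == s
    if (!any(sel)) next
    di <- i1 + (s - 1L) %% 2L
    dj <- j1 + (s - 1L) %/% 2L
    sub <- array(0, dim = d)
    sub[sel] <- dout[sel]
    dx[di, dj, , ] <- dx[di, dj, , , drop = FALSE] + sub
  }
  dx
}

# forward pass; returns class probabilities and (optionally) caches for backprop
tinycnn_forward <- function(model, x, train = FALSE) {
  N <- dim(x)[4]
  a <- x - 0.5      # inputs are in [0,1]; center (normalization handled upstream)
  caches <- list()
  for (li in seq_along(model$conv)) {
    ly <- model$conv[[li]]
    colm <- batch_im2col(a, ly$idx)
    z <- colm %*% ly$W
    z <- z + rep(ly$b, each = nrow(z))
    relu <- z > 0
    z[!relu] <- 0
    HW <- ly$h * ly$w
    act <- aperm(array(z, dim = c(HW, N, ly$Cout)), c(1L, 3L, 2L))
    dim(act) <- c(ly$h, ly$w, ly$Cout, N)
    pool <- maxpool2(act)
    if (train) caches[[li]] <- list(colm = colm, relu = relu, pool = pool, in_dim = dim(a))
    a <- pool$out
  }
  flat <- matrix(a, nrow = prod(dim(a)[1:3]), ncol = N)  # D x N
  X1 <- t(flat)
  p <- model$arch$dropout
  m1 <- NULL
  if (train && p > 0) {
    m1 <- matrix(runif(length(X1)) >= p, nrow(X1), ncol(X1)) / (1 - p)
    X1 <- X1 * m1
  }
  h <- X1 %*% model$fc1$W
  h <- sweep(h, 2L, model$fc1$b, "+")
  relu1 <- h > 0
  h[!relu1] <- 0
  H1 <- h
  m2 <- NULL
  if (train && p > 0) {
    m2 <- matrix(runif(length(H1)) >= p, nrow(H1), ncol(H1)) / (1 - p)
    H1 <- H1 * m2
  }
  logits <- sweep(H1 %*% model$fc2$W, 2L, model$fc2$b, "+")
  lmax <- apply(logits, 1L, max)
  e <- exp(logits - lmax)
  probs <- e / rowSums(e)
  if (!train) return(list(probs = probs))
  list(probs = probs, caches = caches, X1 = X1, H1 = H1, relu1 = relu1,
       m1 = m1, m2 = m2, N = N)
}

#' Cross-entropy loss
#'
#' \code{-sum_i Y_i log(P_i)} averaged over samples; Y is the one-hot
#' indicator, P the predicted class probabilities.  A perfect one-hot
#' prediction scores 0 and a uniform 2-class prediction scores log(2).
#'
#' @param probs N x M matrix of predicted probabilities (rows sum to 1).
#' @param y integer class labels (1-based, length N).
#' @return mean cross-entropy.
#' @export
cross_entropy <- function(probs, y) {
  stopifnot(nrow(probs) == length(y))
  p <- probs[cbind(seq_along(y), y)]
  mean(-log(pmax(p, 1e-12)))
}

# one gradient step worth of backprop; returns list of grads matching params
tinycnn_backward <- function(model, fwd, y) {
  N <- fwd$N
  Y <- matrix(0, N, model$arch$n_classes)
  Y[cbind(seq_len(N), y)] <- 1
  dlogits <- (fwd$probs - Y) / N
  g <- list()
  g$fc2W <- t(fwd$H1) %*% dlogits
  g$fc2b <- colSums(dlogits)
  dH1 <- dlogits %*% t(model$fc2$W)
  if (!is.null(fwd$m2)) dH1 <- dH1 * fwd$m2
  dH1[!fwd$relu1] <- 0
  g$fc1W <- t(fwd$X1) %*% dH1
  g$fc1b <- colSums(dH1)
  dX1 <- dH1 %*% t(model$fc1$W)
  if (!is.null(fwd$m1)) dX1 <- dX1 * fwd$m1
  da <- t(dX1)  # D x N
  g$conv <- vector("list", length(model$conv))
  for (li in rev(seq_along(model$conv))) {
    ly <- model$conv[[li]]
    ca <- fwd$caches[[li]]
    dim(da) <- dim(ca$pool$out)
    dact <- maxpool2_backward(da, ca$pool)
    HW <- ly$h * ly$w
    # reshape (H, W, Cout, N) -> (N*HW) x Cout with rows sample-major
    dz <- array(dact, dim = c(HW, ly$Cout, dim(dact)[4]))
    dz <- aperm(dz, c(1L, 3L, 2L))
    dz <- matrix(dz, nrow = HW * dim(dact)[4], ncol = ly$Cout)
    dz[!ca$relu] <- 0
    g$conv[[li]] <- list(W = t(ca$colm) %*% dz, b = colSums(dz))
    if (li > 1L) {
      dcol <- dz %*% t(ly$W)  # (N*HW) x 9Cin
      prev <- ca$in_dim
      Hp <- prev[1] + 2L; Wp <- prev[2] + 2L; C <- prev[3]; Nn <- prev[4]
      per <- Hp * Wp * C
      big <- ly$idx[rep(seq_len(HW), Nn), , drop = FALSE] +
        rep((seq_len(Nn) - 1L) * per, each = HW)
      acc <- rowsum(as.vector(dcol), group = as.vector(big))
      dxp <- numeric(per * Nn)
      dxp[as.integer(rownames(acc))] <- acc
      dim(dxp) <- c(Hp, Wp, C, Nn)
      da <- dxp[2L:(prev[1] + 1L), 2L:(prev[2] + 1L), , , drop = FALSE]
    }
  }
  g
}

# Adam update; state carries first/second moments per tensor
adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(w, gw, key) {
    if (is.null(state[[key]])) state[[key]] <<- list(m = 0 * w, v = 0 * w)
    st <- state[[key]]
    st$m <- beta1 * st$m + (1 - beta1) * gw
    st$v <- beta2 * st$v + (1 - beta2) * gw * gw
    state[[key]] <<- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    w - lr * mhat / (sqrt(vhat) + eps)
  }
  for (li in seq_along(model$conv)) {
    model$conv[[li]]$W <- upd(model$conv[[li]]$W, grads$conv[[li]]$W, paste0("cW", li))
    model$conv[[li]]$b <- upd(model$conv[[li]]$b, grads$conv[[li]]$b, paste0("cb", li))
  }
  model$fc1$W <- upd(model$fc1$W, grads$fc1W, "f1W")
  model$fc1$b <- upd(model$fc1$b, grads$fc1b, "f1b")
  model$fc2$W <- upd(model$fc2$W, grads$fc2W, "f2W")
  model$fc2$b <- upd(model$fc2$b, grads$fc2b, "f2b")
  list(model = model, state = state)
}

#' Train a tiny CNN on labeled patches
#'
#' Adam on mini-batches of the cross-entropy loss, with early stopping on
#' validation loss (the paper trains each network "to the minimum" of the
#' loss; patience is how that is operationalized here).
#'
#' @param x (S, S, 3, N) array of patches, values 0..255.
#' @param y integer class labels in 1..n_classes.
#' @param arch from \code{\link{tinycnn_architecture}}.
#' @param xval,yval validation split (same formats).
#' @param lr learning rate; \code{batch} mini-batch size; \code{epochs} cap;
#'   \code{patience} epochs without validation-loss improvement before stopping.
#' @param seed RNG seed for init, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return list with the fitted \code{model}, \code{history} (per-epoch data
#'   frame of train/validation loss and accuracy) and \code{val_accuracy}.
#' @export
tinycnn_train <- function(x, y, arch, xval, yval, lr = 1e-3, batch = 32L,
                          epochs = 30L, patience = 6L, seed = 1L, verbose = FALSE) {
  model <- tinycnn_init(arch, seed = derive_seed(seed, "init"))
  # per-channel standardization fitted on the training set; stored with the
  # model so prediction applies the identical transform
  mu <- vapply(1:3, function(ch) mean(x[, , ch, ]), 0)
  sg <- vapply(1:3, function(ch) max(sd(x[, , ch, ]), 1e-6), 0)
  model$norm <- list(mu = mu, sd = sg)
  normalize <- function(a) {
    for (ch in 1:3) a[, , ch, ] <- ((a[, , ch, ] - mu[ch]) / sg[ch]) / 2 + 0.5
    a
  }
  x <- normalize(x); xval <- normalize(xval)
  N <- dim(x)[4]
  state <- list()
  best <- list(loss = Inf, model = model, epoch = 0L)
  hist <- data.frame()
  t_global <- 0L
  with_seed(derive_seed(seed, "sgd"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      tr_loss <- 0; nb <- 0L
      for (start in seq.int(1L, N, by = batch)) {
        ids <- ord[start:min(start + batch - 1L, N)]
        xb <- x[, , , ids, drop = FALSE]
        fwd <- tinycnn_forward(model, xb, train = TRUE)
        tr_loss <- tr_loss + cross_entropy(fwd$probs, y[ids])
        nb <- nb + 1L
        grads <- tinycnn_backward(model, fwd, y[ids])
        t_global <- t_global + 1L
        res <- adam_step(model, grads, state, lr, t_global)
        model <- res$model; state <- res$state
      }
      pv <- tinycnn_forward(model, xval)$probs
      vloss <- cross_entropy(pv, yval)
      vacc <- mean(max.col(pv, ties.method = "first") == yval)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss / nb,
                                     val_loss = vloss, val_accuracy = vacc))
      if (verbose) message(sprintf("epoch %d: train %.4f val %.4f acc %.3f",
                                   ep, tr_loss / nb, vloss, vacc))
      if (vloss < best$loss - 1e-6) best <- list(loss = vloss, model = model, epoch = ep)
      if (ep - best$epoch >= patience) break
    }
  })
  pv <- tinycnn_forward(best$model, xval)$probs
  list(model = best$model, history = hist,
       val_accuracy = mean(max.col(pv, ties.method = "first") == yval),
       val_loss = best$loss)
}

#' Predict class probabilities for a batch of patches
#'
#' @param model fitted model from \code{\link{tinycnn_train}} (or
#'   \code{tinycnn_init}).
#' @param x (S, S, 3, N) array, values 0..255.
#' @param chunk maximum samples per forward pass (memory guard).
#' @return N x n_classes probability matrix.
#' @export
tinycnn_predict <- function(model, x, chunk = 512L) {
  N <- dim(x)[4]
  if (!is.null(model$norm)) {
    for (ch in 1:3) {
      x[, , ch, ] <- ((x[, , ch, ] - model$norm$mu[ch]) / model$norm$sd[ch]) / 2 + 0.5
    }
  } else {
    x <- x / 255
  }
  out <- matrix(0, N, model$arch$n_classes)
  for (start in seq.int(1L, N, by = chunk)) {
    ids <- start:min(start + chunk - 1L, N)
    out[ids, ] <- tinycnn_forward(model, x[, , , ids, drop = FALSE])$probs
  }
  out
}
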