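# Minimal neural-network primitives used by the three classifiers.
# Every layer implements forward(layer, x, training) -> list(out, cache)
# and backward(layer, cache, dout) -> list(dx, grads), with grads named
# like the layer's parameter fields. Shapes keep the batch as the first
# array dimension throughout, so reshapes are plain `dim<-` calls.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

## ---- time-distributed 1-D convolution over the Mel axis --------------
# x: (n, T, P, C); kernel W: (k, C, K); out: (n, T, P - k + 1, K), ReLU.

nn_td_conv1d <- function(c_in, k_out, kernel = 3L) {
  list(type = "td_conv1d",
       W = glorot(kernel * c_in, k_out, c(kernel, c_in, k_out)),
       b = numeric(k_out), kernel = kernel)
}

fwd_td_conv1d <- function(layer, x, training) {
  d <- dim(x)  # n, T, P, C
  r <- d[1] * d[2]
  p_out <- d[3] - layer$kernel + 1L
  k_out <- length(layer$b)
  x3 <- x; dim(x3) <- c(r, d[3], d[4])
  out <- matrix(rep(layer$b, each = r * p_out), r * p_out, k_out)
  for (dk in seq_len(layer$kernel)) {
    xs <- x3[, dk:(dk + p_out - 1L), , drop = FALSE]
    dim(xs) <- c(r * p_out, d[4])
    wdk <- layer$W[dk, , ]
    if (is.null(dim(wdk))) wdk <- matrix(wdk, d[4], k_out)
    out <- out + xs %*% wdk
  }
  mask <- out > 0
  out[!mask] <- 0
  dim(out) <- c(d[1], d[2], p_out, k_out)
  list(out = out, cache = list(x3 = x3, mask = mask, d = d, p_out = p_out))
}

bwd_td_conv1d <- function(layer, cache, dout) {
  d <- cache$d
  r <- d[1] * d[2]
  p_out <- cache$p_out
  k_out <- length(layer$b)
  dm <- dout; dim(dm) <- c(r * p_out, k_out)
  dm <- dm * cache$mask
  dW <- array(0, dim(layer$W))
  dx3 <- array(0, c(r, d[3], d[4]))
  for (dk in seq_len(layer$kernel)) {
    xs <- cache$x3[, dk:(dk + p_out - 1L), , drop = FALSE]
    dim(xs) <- c(r * p_out, d[4])
    dW[dk, , ] <- crossprod(xs, dm)
    wdk <- layer$W[dk, , ]
    if (is.null(dim(wdk))) wdk <- matrix(wdk, d[4], k_out)
    dxs <- dm %*% t(wdk)
    dim(dxs) <- c(r, p_out, d[4])
    dx3[, dk:(dk + p_out - 1L), ] <-
      dx3[, dk:(dk + p_out - 1L), , drop = FALSE] + dxs
  }
  dim(dx3) <- d
  list(dx = dx3, grads = list(W = dW, b = colSums(dm)))
}

## ---- max pooling over the Mel axis (time-distributed) ----------------
# x: (n, T, P, C) with even P -> (n, T, P/2, C)

nn_pool_freq <- function() list(type = "pool_freq")

fwd_pool_freq <- function(layer, x, training) {
  d <- dim(x)
  p2 <- d[3] %/% 2L  # odd tail position is dropped
  a <- x[, , seq(1L, 2L * p2, 2L), , drop = FALSE]
  b <- x[, , seq(2L, 2L * p2, 2L), , drop = FALSE]
  first <- a >= b
  list(out = pmax(a, b), cache = list(first = first, d = d, p2 = p2))
}

bwd_pool_freq <- function(layer, cache, dout) {
  d <- cache$d
  dx <- array(0, d)
  dx[, , seq(1L, 2L * cache$p2, 2L), ] <- dout * cache$first
  dx[, , seq(2L, 2L * cache$p2, 2L), ] <- dout * !cache$first
  list(dx = dx, grads = NULL)
}

## ---- 2-D convolution --------------------------------------------------
# x: (n, H, W, C); kernel W: (kh, kw, C, K); valid convolution, ReLU.

nn_conv2d <- function(c_in, k_out, kernel = c(3L, 3L)) {
  list(type = "conv2d",
       W = glorot(prod(kernel) * c_in, k_out, c(kernel, c_in, k_out)),
       b = numeric(k_out), kernel = as.integer(kernel))
}

fwd_conv2d <- function(layer, x, training) {
  d <- dim(x)  # n, H, W, C
  kh <- layer$kernel[1]; kw <- layer$kernel[2]
  h_out <- d[2] - kh + 1L; w_out <- d[3] - kw + 1L
  k_out <- length(layer$b)
  r <- d[1] * h_out * w_out
  out <- matrix(rep(layer$b, each = r), r, k_out)
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      xs <- x[, i:(i + h_out - 1L), j:(j + w_out - 1L), , drop = FALSE]
      dim(xs) <- c(r, d[4])
      wij <- layer$W[i, j, , ]
      if (is.null(dim(wij))) wij <- matrix(wij, d[4], k_out)
      out <- out + xs %*% wij
    }
  }
  mask <- out > 0
  out[!mask] <- 0
  dim(out) <- c(d[1], h_out, w_out, k_out)
  list(out = out,
       cache = list(x = x, mask = mask, d = d, h_out = h_out, w_out = w_out))
}

bwd_conv2d <- function(layer, cache, dout) {
  d <- cache$d
  kh <- layer$kernel[1]; kw <- layer$kernel[2]
  h_out <- cache$h_out; w_out <- cache$w_out
  k_out <- length(layer$b)
  r <- d[1] * h_out * w_out
  dm <- dout; dim(dm) <- c(r, k_out)
  dm <- dm * cache$mask
  dW <- array(0, dim(layer$W))
  dx <- array(0, d)
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      xs <- cache$x[, i:(i + h_out - 1L), j:(j + w_out - 1L), , drop = FALSE]
      dim(xs) <- c(r, d[4])
      dW[i, j, , ] <- crossprod(xs, dm)
      wij <- layer$W[i, j, , ]
      if (is.null(dim(wij))) wij <- matrix(wij, d[4], k_out)
      dxs <- dm %*% t(wij)
      dim(dxs) <- c(d[1], h_out, w_out, d[4])
      dx[, i:(i + h_out - 1L), j:(j + w_out - 1L), ] <-
        dx[, i:(i + h_out - 1L), j:(j + w_out - 1L), , drop = FALSE] + dxs
    }
  }
  list(dx = dx, grads = list(W = dW, b = colSums(dm)))
}

## ---- 2x2 max pooling ---------------------------------------------------

nn_pool2d <- function() list(type = "pool2d")

fwd_pool2d <- function(layer, x, training) {
  d <- dim(x)
  pool_h <- d[2] %/% 2L; pool_w <- d[3] %/% 2L  # odd tails dropped
  oi <- seq(1L, 2L * pool_h, 2L); ei <- seq(2L, 2L * pool_h, 2L)
  oj <- seq(1L, 2L * pool_w, 2L); ej <- seq(2L, 2L * pool_w, 2L)
  c1 <- x[, oi, oj, , drop = FALSE]; c2 <- x[, ei, oj, , drop = FALSE]
  c3 <- x[, oi, ej, , drop = FALSE]; c4 <- x[, ei, ej, , drop = FALSE]
  out <- pmax(c1, c2, c3, c4)
  w1 <- c1 == out
  w2 <- (c2 == out) & !w1
  w3 <- (c3 == out) & !w1 & !w2
  w4 <- !(w1 | w2 | w3)
  list(out = out, cache = list(w1 = w1, w2 = w2, w3 = w3, w4 = w4, d = d,
                               pool_h = pool_h, pool_w = pool_w))
}

bwd_pool2d <- function(layer, cache, dout) {
  d <- cache$d
  oi <- seq(1L, 2L * cache$pool_h, 2L); ei <- seq(2L, 2L * cache$pool_h, 2L)
  oj <- seq(1L, 2L * cache$pool_w, 2L); ej <- seq(2L, 2L * cache$pool_w, 2L)
  dx <- array(0, d)
  dx[, oi, oj, ] <- dout * cache$w1
  dx[, ei, oj, ] <- dout * cache$w2
  dx[, oi, ej, ] <- dout * cache$w3
  dx[, ei, ej, ] <- dout * cache$w4
  list(dx = dx, grads = NULL)
}

## ---- flatten, dense, dropout ------------------------------------------

nn_flatten <- function() list(type = "flatten")

fwd_flatten <- function(layer, x, training) {
  d <- dim(x)
  out <- x; dim(out) <- c(d[1], prod(d[-1]))
  list(out = out, cache = list(d = d))
}

bwd_flatten <- function(layer, cache, dout) {
  dim(dout) <- cache$d
  list(dx = dout, grads = NULL)
}

nn_dense <- function(n_in, n_out, activation = "relu") {
  list(type = "dense", W = glorot(n_in, n_out, c(n_in, n_out)),
       b = numeric(n_out), activation = activation)
}

fwd_dense <- function(layer, x, training) {
  z <- sweep(x %*% layer$W, 2L, layer$b, `+`)
  if (layer$activation == "relu") {
    mask <- z > 0
    z[!mask] <- 0
  } else {
    mask <- NULL
  }
  list(out = z, cache = list(x = x, mask = mask))
}

bwd_dense <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  list(dx = dout %*% t(layer$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

nn_dropout <- function(p) list(type = "dropout", p = p)

fwd_dropout <- function(layer, x, training) {
  if (!training || layer$p <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- array(stats::runif(length(x)) >= layer$p, dim(x)) / (1 - layer$p)
  list(out = x * mask, cache = list(mask = mask))
}

bwd_dropout <- function(layer, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  list(dx = dout, grads = NULL)
}

## ---- LSTM unit: time-distributed dense skip path + bidirectional LSTM --
# x: (n, T, In) -> (n, T, td_units + 2 * hidden)

nn_lstm_unit <- function(n_in, td_units, hidden) {
  list(type = "lstm_unit",
       td_W = glorot(n_in, td_units, c(n_in, td_units)),
       td_b = numeric(td_units),
       fw_W = glorot(n_in + hidden, 4 * hidden, c(n_in + hidden, 4 * hidden)),
       fw_b = lstm_bias(hidden),
       bw_W = glorot(n_in + hidden, 4 * hidden, c(n_in + hidden, 4 * hidden)),
       bw_b = lstm_bias(hidden),
       td_units = td_units, hidden = hidden)
}

# forget-gate bias initialized to 1 for stable early training
lstm_bias <- function(hidden) {
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1
  b
}

lstm_dir_forward <- function(x, W, b, hidden) {
  d <- dim(x)  # n, T, In
  n <- d[1]; tt <- d[2]
  H <- hidden
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  go <- (3 * H + 1):(4 * H)
  I <- array(0, c(n, tt, H)); Fg <- I; G <- I; O <- I
  C <- I; HC <- I; Hprev <- I; Cprev <- I
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  out <- array(0, c(n, tt, H))
  for (t in seq_len(tt)) {
    xt <- x[, t, ]
    if (is.null(dim(xt))) xt <- matrix(xt, n)
    z <- sweep(cbind(xt, h) %*% W, 2L, b, `+`)
    it <- sigmoid(z[, gi, drop = FALSE])
    ft <- sigmoid(z[, gf, drop = FALSE])
    gt <- tanh(z[, gg, drop = FALSE])
    ot <- sigmoid(z[, go, drop = FALSE])
    Cprev[, t, ] <- cc
    Hprev[, t, ] <- h
    cc <- ft * cc + it * gt
    hc <- tanh(cc)
    h <- ot * hc
    I[, t, ] <- it; Fg[, t, ] <- ft; G[, t, ] <- gt; O[, t, ] <- ot
    C[, t, ] <- cc; HC[, t, ] <- hc
    out[, t, ] <- h
  }
  list(out = out, cache = list(x = x, I = I, F = Fg, G = G, O = O, C = C,
                               HC = HC, Hprev = Hprev, Cprev = Cprev))
}

lstm_dir_backward <- function(cache, W, dout, hidden) {
  x <- cache$x
  d <- dim(x)
  n <- d[1]; tt <- d[2]; n_in <- d[3]
  H <- hidden
  dW <- array(0, dim(W)); db <- numeric(4 * H)
  dx <- array(0, d)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(tt))) {
    it <- cache$I[, t, , drop = FALSE]; dim(it) <- c(n, H)
    ft <- cache$F[, t, , drop = FALSE]; dim(ft) <- c(n, H)
    gt <- cache$G[, t, , drop = FALSE]; dim(gt) <- c(n, H)
    ot <- cache$O[, t, , drop = FALSE]; dim(ot) <- c(n, H)
    hc <- cache$HC[, t, , drop = FALSE]; dim(hc) <- c(n, H)
    cprev <- cache$Cprev[, t, , drop = FALSE]; dim(cprev) <- c(n, H)
    hprev <- cache$Hprev[, t, , drop = FALSE]; dim(hprev) <- c(n, H)
    dh <- dout[, t, , drop = FALSE]; dim(dh) <- c(n, H)
    dh <- dh + dh_next
    do_ <- dh * hc
    dc <- dc_next + dh * ot * (1 - hc^2)
    di <- dc * gt
    dg <- dc * it
    df <- dc * cprev
    dc_next <- dc * ft
    dz <- cbind(di * it * (1 - it), df * ft * (1 - ft),
                dg * (1 - gt^2), do_ * ot * (1 - ot))
    xt <- x[, t, ]
    if (is.null(dim(xt))) xt <- matrix(xt, n)
    dW <- dW + crossprod(cbind(xt, hprev), dz)
    db <- db + colSums(dz)
    din <- dz %*% t(W)
    dx[, t, ] <- din[, seq_len(n_in), drop = FALSE]
    dh_next <- din[, n_in + seq_len(H), drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

rev_time <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]

fwd_lstm_unit <- function(layer, x, training) {
  d <- dim(x)
  # skip path: shared dense over each frame, ReLU
  x2 <- x; dim(x2) <- c(d[1] * d[2], d[3])
  td_z <- sweep(x2 %*% layer$td_W, 2L, layer$td_b, `+`)
  td_mask <- td_z > 0
  td_z[!td_mask] <- 0
  td_out <- td_z; dim(td_out) <- c(d[1], d[2], layer$td_units)
  fw <- lstm_dir_forward(x, layer$fw_W, layer$fw_b, layer$hidden)
  bw <- lstm_dir_forward(rev_time(x), layer$bw_W, layer$bw_b, layer$hidden)
  out <- array(0, c(d[1], d[2], layer$td_units + 2L * layer$hidden))
  out[, , seq_len(layer$td_units)] <- td_out
  out[, , layer$td_units + seq_len(layer$hidden)] <- fw$out
  out[, , layer$td_units + layer$hidden + seq_len(layer$hidden)] <-
    rev_time(bw$out)
  list(out = out, cache = list(d = d, td_mask = td_mask, x2 = x2,
                               fw = fw$cache, bw = bw$cache))
}

bwd_lstm_unit <- function(layer, cache, dout) {
  d <- cache$d
  u <- layer$td_units; H <- layer$hidden
  d_td <- dout[, , seq_len(u), drop = FALSE]
  d_fw <- dout[, , u + seq_len(H), drop = FALSE]
  d_bw <- rev_time(dout[, , u + H + seq_len(H), drop = FALSE])
  dim(d_td) <- c(d[1] * d[2], u)
  d_td <- d_td * cache$td_mask
  dx <- d_td %*% t(layer$td_W)
  dim(dx) <- d
  g_td_W <- crossprod(cache$x2, d_td)
  g_td_b <- colSums(d_td)
  fw <- lstm_dir_backward(cache$fw, layer$fw_W, d_fw, H)
  bw <- lstm_dir_backward(cache$bw, layer$bw_W, d_bw, H)
  dx <- dx + fw$dx + rev_time(bw$dx)
  list(dx = dx,
       grads = list(td_W = g_td_W, td_b = g_td_b,
                    fw_W = fw$dW, fw_b = fw$db,
                    bw_W = bw$dW, bw_b = bw$db))
}

## ---- dispatch ----------------------------------------------------------

FWD <- list(td_conv1d = fwd_td_conv1d, pool_freq = fwd_pool_freq,
            conv2d = fwd_conv2d, pool2d = fwd_pool2d,
            flatten = fwd_flatten, dense = fwd_dense,
            dropout = fwd_dropout, lstm_unit = fwd_lstm_unit)

BWD <- list(td_conv1d = bwd_td_conv1d, pool_freq = bwd_pool_freq,
            conv2d = bwd_conv2d, pool2d = bwd_pool2d,
            flatten = bwd_flatten, dense = bwd_dense,
            dropout = bwd_dropout, lstm_unit = bwd_lstm_unit)

layer_param_names <- function(layer) {
  intersect(c("W", "b", "td_W", "td_b", "fw_W", "fw_b", "bw_W", "bw_b"),
            names(layer))
}

network_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    res <- FWD[[layers[[i]]$type]](layers[[i]], x, training)
    x <- res$out
    caches[[i]] <- res$cache
  }
  list(out = x, caches = caches)
}

network_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    res <- BWD[[layers[[i]]$type]](layers[[i]], caches[[i]], dout)
    dout <- res$dx
    grads[i] <- list(res$grads)
  }
  grads
}
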