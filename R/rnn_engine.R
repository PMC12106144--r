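# Recurrent-network engine for next-day dedication prediction.
#
# Sequences are represented as a list of S matrices (batch x features), one
# per time step. All layers expose init/forward/backward; gradients are exact
# analytic backpropagation (verified against numerical differentiation in the
# test suite). Inputs are internally scaled from percent to [0, 1]; outputs
# stay on the percent scale through a ReLU dense head, so predictions are
# always non-negative.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

## ---- LSTM ----------------------------------------------------------------

.lstm_init <- function(d_in, units) {
  b <- rep(0, 4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias starts open
  list(Wx = .glorot(d_in, 4 * units), Wh = .glorot(units, 4 * units), b = b)
}

# Forward over a sequence; reverse = TRUE processes right-to-left (the output
# list is returned in original time order). return_seq = FALSE keeps only the
# final hidden state (the state after the whole sequence has been read).
.lstm_forward <- function(p, xs, units, reverse = FALSE, return_seq = TRUE) {
  S <- length(xs); B <- nrow(xs[[1]])
  ord <- if (reverse) rev(seq_len(S)) else seq_len(S)
  h <- matrix(0, B, units); cc <- matrix(0, B, units)
  cache <- vector("list", S); hs <- vector("list", S)
  for (k in seq_len(S)) {
    s <- ord[k]
    z <- xs[[s]] %*% p$Wx + h %*% p$Wh + matrix(p$b, B, 4 * units, byrow = TRUE)
    i <- .sigmoid(z[, 1:units, drop = FALSE])
    f <- .sigmoid(z[, (units + 1):(2 * units), drop = FALSE])
    g <- tanh(z[, (2 * units + 1):(3 * units), drop = FALSE])
    o <- .sigmoid(z[, (3 * units + 1):(4 * units), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[k]] <- list(x = xs[[s]], h_prev = h, c_prev = cc,
                       i = i, f = f, g = g, o = o, tc = tc)
    cc <- c_new
    h <- o * tc
    hs[[s]] <- h
  }
  list(out = if (return_seq) hs else h, cache = cache, ord = ord,
       last = h)
}

# Backprop through time. d_out: list per step (time order) if the forward
# returned a sequence, else a single matrix for the final state.
.lstm_backward <- function(p, fwd, d_out, units, return_seq = TRUE) {
  cache <- fwd$cache; ord <- fwd$ord
  S <- length(cache); B <- nrow(cache[[1]]$x)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dxs <- vector("list", S)
  dh_next <- matrix(0, B, units); dc_next <- matrix(0, B, units)
  for (k in rev(seq_len(S))) {
    s <- ord[k]
    cs <- cache[[k]]
    dh <- dh_next
    if (return_seq) dh <- dh + d_out[[s]]
    else if (k == S) dh <- dh + d_out
    dc <- dc_next + dh * cs$o * (1 - cs$tc^2)
    d_i <- dc * cs$g * cs$i * (1 - cs$i)
    d_f <- dc * cs$c_prev * cs$f * (1 - cs$f)
    d_g <- dc * cs$i * (1 - cs$g^2)
    d_o <- dh * cs$tc * cs$o * (1 - cs$o)
    dz <- cbind(d_i, d_f, d_g, d_o)
    dWx <- dWx + crossprod(cs$x, dz)
    dWh <- dWh + crossprod(cs$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[s]] <- dz %*% t(p$Wx)
    dh_next <- dz %*% t(p$Wh)
    dc_next <- dc * cs$f
  }
  list(dxs = dxs, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## ---- 1-D convolution over time (valid padding, ReLU) ----------------------

.conv_init <- function(d_in, filters, kernel) {
  list(K = lapply(seq_len(kernel), function(j) .glorot(d_in, filters)),
       b = rep(0, filters))
}

.conv_forward <- function(p, xs) {
  S <- length(xs); k <- length(p$K); B <- nrow(xs[[1]])
  S_out <- S - k + 1
  if (S_out < 1) stop("conv kernel longer than the input sequence")
  pre <- vector("list", S_out)
  for (s in seq_len(S_out)) {
    z <- matrix(p$b, B, length(p$b), byrow = TRUE)
    for (j in seq_len(k)) z <- z + xs[[s + j - 1]] %*% p$K[[j]]
    pre[[s]] <- z
  }
  list(out = lapply(pre, function(z) pmax(z, 0)), cache = list(xs = xs, pre = pre))
}

.conv_backward <- function(p, fwd, d_out) {
  xs <- fwd$xs; pre <- fwd$pre
  S <- length(xs); k <- length(p$K); S_out <- length(pre)
  dK <- lapply(p$K, function(m) m * 0); db <- p$b * 0
  dxs <- lapply(xs, function(m) m * 0)
  for (s in seq_len(S_out)) {
    dz <- d_out[[s]] * (pre[[s]] > 0)
    db <- db + colSums(dz)
    for (j in seq_len(k)) {
      dK[[j]] <- dK[[j]] + crossprod(xs[[s + j - 1]], dz)
      dxs[[s + j - 1]] <- dxs[[s + j - 1]] + dz %*% t(p$K[[j]])
    }
  }
  list(dxs = dxs, grads = list(K = dK, b = db))
}

## ---- Additive attention over time steps ------------------------------------
# Scores e_s = tanh(h_s W + b) v, alphas = softmax over steps; the sequence is
# reweighted step-wise (out_s = alpha_s * h_s) and fed to the next recurrent
# layer. Alphas are non-negative and sum to 1 over the window by construction.

.attn_init <- function(d_in, attn_units) {
  list(W = .glorot(d_in, attn_units), b = rep(0, attn_units),
       v = .glorot(attn_units, 1))
}

.attn_forward <- function(p, xs) {
  S <- length(xs); B <- nrow(xs[[1]])
  u <- vector("list", S)
  e <- matrix(0, B, S)
  for (s in seq_len(S)) {
    u[[s]] <- tanh(xs[[s]] %*% p$W + matrix(p$b, B, length(p$b), byrow = TRUE))
    e[, s] <- u[[s]] %*% p$v
  }
  e <- e - apply(e, 1, max)
  alpha <- exp(e); alpha <- alpha / rowSums(alpha)
  out <- lapply(seq_len(S), function(s) xs[[s]] * alpha[, s])
  list(out = out, cache = list(xs = xs, u = u, alpha = alpha))
}

.attn_backward <- function(p, fwd, d_out) {
  xs <- fwd$xs; u <- fwd$u; alpha <- fwd$alpha
  S <- length(xs); B <- nrow(xs[[1]])
  dW <- p$W * 0; db <- p$b * 0; dv <- p$v * 0
  dxs <- vector("list", S)
  dalpha <- matrix(0, B, S)
  for (s in seq_len(S)) {
    dalpha[, s] <- rowSums(d_out[[s]] * xs[[s]])
    dxs[[s]] <- d_out[[s]] * alpha[, s]
  }
  de <- alpha * (dalpha - rowSums(alpha * dalpha))  # softmax jacobian
  for (s in seq_len(S)) {
    dv <- dv + crossprod(u[[s]], de[, s, drop = FALSE])
    du <- (de[, s, drop = FALSE] %*% t(p$v)) * (1 - u[[s]]^2)
    dW <- dW + crossprod(xs[[s]], du)
    db <- db + colSums(du)
    dxs[[s]] <- dxs[[s]] + du %*% t(p$W)
  }
  list(dxs = dxs, grads = list(W = dW, b = db, v = dv))
}

## ---- Dense -----------------------------------------------------------------

.dense_init <- function(d_in, d_out) {
  list(W = .glorot(d_in, d_out), b = rep(0, d_out))
}

.dense_forward <- function(p, x, relu = FALSE) {
  z <- x %*% p$W + matrix(p$b, nrow(x), length(p$b), byrow = TRUE)
  list(out = if (relu) pmax(z, 0) else z, cache = list(x = x, z = z))
}

.dense_backward <- function(p, fwd, d_out, relu = FALSE) {
  dz <- if (relu) d_out * (fwd$z > 0) else d_out
  list(dx = dz %*% t(p$W),
       grads = list(W = crossprod(fwd$x, dz), b = colSums(dz)))
}

## ---- Dropout (inverted, training only) -------------------------------------

.dropout_mask <- function(dim_, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(prod(dim_), 1, 1 - rate), dim_[1], dim_[2]) / (1 - rate)
}
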