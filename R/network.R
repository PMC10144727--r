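# From-scratch neural value networks: a feed-forward MLP (40 -> 50 -> 50 -> 6,
# ReLU) and a recurrent variant with a 27-unit LSTM plus dropout inserted
# before the output layer. Plain matrix arithmetic; gradients are verified
# against numerical differentiation in the test suite.

glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

#' Network architecture descriptor
#'
#' @param variant `"feedforward"` (input 40, two ReLU hidden layers of 50,
#'   output 6) or `"recurrent"` (the same trunk with a 27-unit LSTM layer
#'   followed by dropout inserted before the output layer).
#' @param input,hidden,outputs Layer sizes; defaults match the value
#'   network used throughout (40, c(50, 50), 6).
#' @param lstm_units,dropout Recurrent-variant parameters (defaults 27
#'   units, dropout probability 0.2).
#' @return An object of class `network_arch`.
#' @export
network_arch <- function(variant = c("feedforward", "recurrent"),
                         input = FEATURE_DIM, hidden = c(50L, 50L),
                         outputs = N_ACTIONS, lstm_units = 27L,
                         dropout = 0.2) {
  variant <- match.arg(variant)
  if (length(hidden) != 2L) stop("exactly two hidden layers are supported")
  structure(list(variant = variant, input = as.integer(input),
                 hidden = as.integer(hidden), outputs = as.integer(outputs),
                 lstm_units = as.integer(lstm_units), dropout = dropout),
            class = "network_arch")
}

# seeded parameter initialisation: Glorot-uniform weights, zero biases
# (LSTM forget-gate bias 1, a standard stabilising choice)
init_theta <- function(arch) {
  h1 <- arch$hidden[1]; h2 <- arch$hidden[2]
  theta <- list(W1 = glorot(arch$input, h1), b1 = numeric(h1),
                W2 = glorot(h1, h2), b2 = numeric(h2))
  if (arch$variant == "feedforward") {
    theta$W3 <- glorot(h2, arch$outputs)
    theta$b3 <- numeric(arch$outputs)
  } else {
    H <- arch$lstm_units
    theta$Wx <- glorot(h2, 4L * H)
    theta$Wh <- glorot(H, 4L * H)
    bl <- numeric(4L * H)
    bl[(H + 1L):(2L * H)] <- 1      # forget gate
    theta$bl <- bl
    theta$W3 <- glorot(H, arch$outputs)
    theta$b3 <- numeric(arch$outputs)
  }
  theta
}

addb <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

## ---- feed-forward --------------------------------------------------------

mlp_forward <- function(theta, X) {
  A1 <- pmax(addb(X %*% theta$W1, theta$b1), 0)
  A2 <- pmax(addb(A1 %*% theta$W2, theta$b2), 0)
  Q <- addb(A2 %*% theta$W3, theta$b3)
  list(Q = Q, X = X, A1 = A1, A2 = A2)
}

mlp_backward <- function(theta, cache, dQ) {
  dA2 <- dQ %*% t(theta$W3)
  dZ2 <- dA2 * (cache$A2 > 0)
  dA1 <- dZ2 %*% t(theta$W2)
  dZ1 <- dA1 * (cache$A1 > 0)
  list(W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
       W2 = crossprod(cache$A1, dZ2), b2 = colSums(dZ2),
       W3 = crossprod(cache$A2, dQ), b3 = colSums(dQ))
}

## ---- recurrent (LSTM) ----------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward over a whole ordered sequence X (N x input); drop_mask is a
# per-sequence (variational) dropout mask on the LSTM output, or NULL for
# evaluation (identity).
lstm_forward_seq <- function(theta, X, arch, drop_mask = NULL) {
  H <- arch$lstm_units
  A1 <- pmax(addb(X %*% theta$W1, theta$b1), 0)
  A2 <- pmax(addb(A1 %*% theta$W2, theta$b2), 0)
  N <- nrow(X)
  hs <- matrix(0, N + 1L, H); cs <- matrix(0, N + 1L, H)
  gates <- array(0, c(N, 4L, H))     # i, f, g, o (post-nonlinearity)
  tanhc <- matrix(0, N, H)
  for (t in seq_len(N)) {
    z <- A2[t, ] %*% theta$Wx + hs[t, ] %*% theta$Wh + theta$bl
    i <- sigmoid(z[1L:H]); f <- sigmoid(z[(H + 1L):(2L * H)])
    g <- tanh(z[(2L * H + 1L):(3L * H)]); o <- sigmoid(z[(3L * H + 1L):(4L * H)])
    cs[t + 1L, ] <- f * cs[t, ] + i * g
    tanhc[t, ] <- tanh(cs[t + 1L, ])
    hs[t + 1L, ] <- o * tanhc[t, ]
    gates[t, 1L, ] <- i; gates[t, 2L, ] <- f; gates[t, 3L, ] <- g; gates[t, 4L, ] <- o
  }
  Hd <- hs[-1L, , drop = FALSE]
  if (!is.null(drop_mask)) Hd <- Hd * matrix(drop_mask, N, H, byrow = TRUE)
  Q <- addb(Hd %*% theta$W3, theta$b3)
  list(Q = Q, X = X, A1 = A1, A2 = A2, hs = hs, cs = cs, gates = gates,
       tanhc = tanhc, Hd = Hd, drop_mask = drop_mask)
}

lstm_backward_seq <- function(theta, cache, dQ, arch) {
  H <- arch$lstm_units
  N <- nrow(dQ)
  g <- list(W1 = theta$W1 * 0, b1 = theta$b1 * 0, W2 = theta$W2 * 0,
            b2 = theta$b2 * 0, Wx = theta$Wx * 0, Wh = theta$Wh * 0,
            bl = theta$bl * 0, W3 = crossprod(cache$Hd, dQ), b3 = colSums(dQ))
  dHd <- dQ %*% t(theta$W3)
  if (!is.null(cache$drop_mask))
    dHd <- dHd * matrix(cache$drop_mask, N, H, byrow = TRUE)
  dA2 <- matrix(0, N, ncol(cache$A2))
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(N))) {
    dh <- dHd[t, ] + dh_next
    i <- cache$gates[t, 1L, ]; f <- cache$gates[t, 2L, ]
    gg <- cache$gates[t, 3L, ]; o <- cache$gates[t, 4L, ]
    dc <- dh * o * (1 - cache$tanhc[t, ]^2) + dc_next
    di <- dc * gg * i * (1 - i)
    df <- dc * cache$cs[t, ] * f * (1 - f)
    dg <- dc * i * (1 - gg^2)
    do <- dh * cache$tanhc[t, ] * o * (1 - o)
    dz <- c(di, df, dg, do)
    g$Wx <- g$Wx + outer(cache$A2[t, ], dz)
    g$Wh <- g$Wh + outer(cache$hs[t, ], dz)
    g$bl <- g$bl + dz
    dA2[t, ] <- dz %*% t(theta$Wx)
    dh_next <- as.numeric(dz %*% t(theta$Wh))
    dc_next <- dc * f
  }
  dZ2 <- dA2 * (cache$A2 > 0)
  dA1 <- dZ2 %*% t(theta$W2)
  dZ1 <- dA1 * (cache$A1 > 0)
  g$W1 <- crossprod(cache$X, dZ1); g$b1 <- colSums(dZ1)
  g$W2 <- crossprod(cache$A1, dZ2); g$b2 <- colSums(dZ2)
  g
}

# one-step stateful forward for greedy/epsilon-greedy rollout of the
# recurrent variant (no dropout at decision time)
lstm_cell <- function(theta, x, arch, state = NULL) {
  H <- arch$lstm_units
  if (is.null(state)) state <- list(h = numeric(H), c = numeric(H))
  a1 <- pmax(as.numeric(x %*% theta$W1) + theta$b1, 0)
  a2 <- pmax(as.numeric(a1 %*% theta$W2) + theta$b2, 0)
  z <- as.numeric(a2 %*% theta$Wx) + as.numeric(state$h %*% theta$Wh) + theta$bl
  i <- sigmoid(z[1L:H]); f <- sigmoid(z[(H + 1L):(2L * H)])
  gg <- tanh(z[(2L * H + 1L):(3L * H)]); o <- sigmoid(z[(3L * H + 1L):(4L * H)])
  c_new <- f * state$c + i * gg
  h_new <- o * tanh(c_new)
  list(q = as.numeric(h_new %*% theta$W3) + theta$b3,
       state = list(h = h_new, c = c_new))
}

## ---- Adam ----------------------------------------------------------------

init_adam <- function(theta)
  list(m = lapply(theta, function(p) p * 0),
       v = lapply(theta, function(p) p * 0),
       t = 0L)

# one Adam step; L2 (weight decay added to the gradient) applies to weight
# matrices only, not biases
adam_update <- function(theta, grads, opt, alpha, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, l2 = 0) {
  opt$t <- opt$t + 1L
  for (nm in names(theta)) {
    g <- grads[[nm]]
    if (l2 > 0 && startsWith(nm, "W")) g <- g + l2 * theta[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    theta[[nm]] <- theta[[nm]] - alpha * mhat / (sqrt(vhat) + eps)
  }
  list(theta = theta, opt = opt)
}
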