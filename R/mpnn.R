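# Message-passing neural network internals: parameter initialization,
# forward pass, analytic backpropagation, and the Adam optimizer.
#
# Architecture: node states are atom feature vectors zero-padded to
# hidden_dim; for T rounds each node receives sum_j A(e_ij) h_j where the
# edge network A() maps bond features to a hidden_dim x hidden_dim matrix,
# and updates through a gated recurrent unit. A set2set readout (GRU
# controller with dot-product attention, M processing steps) produces a
# permutation-invariant graph vector [q; r], which a single hidden layer
# with rectified-linear activation maps to the scaled retention time.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

.mpnn_init <- function(hidden_dim, atom_len, bond_len) {
  d <- hidden_dim
  list(
    Wb = .glorot(d * d, bond_len) / d,  # edge network kept small at init
    bb = numeric(d * d),
    Wz = .glorot(d, d), Wr = .glorot(d, d), Wn = .glorot(d, d),
    Uz = .glorot(d, d), Ur = .glorot(d, d), Un = .glorot(d, d),
    bz = numeric(d), br = numeric(d), bn = numeric(d),
    Sz = .glorot(d, d), Sr = .glorot(d, d), Sn = .glorot(d, d),
    Tz = .glorot(d, d), Tr = .glorot(d, d), Tn = .glorot(d, d),
    cz = numeric(d), cr = numeric(d), cn = numeric(d),
    W1 = .glorot(d, 2 * d), b1 = numeric(d),
    w2 = numeric(d), b2 = 0
  )
}

.zero_like <- function(p) lapply(p, function(x) x * 0)

# GRU applied columnwise: input Mx (d x n), state H (d x n)
.gru_forward <- function(W, U, b, Mx, H) {
  Z <- .sigmoid(W$z %*% Mx + U$z %*% H + b$z)
  R <- .sigmoid(W$r %*% Mx + U$r %*% H + b$r)
  RH <- R * H
  Nt <- tanh(W$n %*% Mx + U$n %*% RH + b$n)
  Hn <- (1 - Z) * Nt + Z * H
  list(H = Hn, Z = Z, R = R, N = Nt, RH = RH, Mx = Mx, Hin = H)
}

# returns dMx, dHin and adds parameter grads into g (an environment)
.gru_backward <- function(W, U, cache, dH, g, names) {
  Z <- cache$Z; R <- cache$R; Nt <- cache$N
  H <- cache$Hin; Mx <- cache$Mx; RH <- cache$RH
  dZ <- dH * (H - Nt)
  dN <- dH * (1 - Z)
  dHin <- dH * Z
  dNpre <- dN * (1 - Nt^2)
  dRH <- crossprod(U$n, dNpre)
  dR <- dRH * H
  dHin <- dHin + dRH * R
  dZpre <- dZ * Z * (1 - Z)
  dRpre <- dR * R * (1 - R)
  g[[names$Wz]] <- g[[names$Wz]] + tcrossprod(dZpre, Mx)
  g[[names$Wr]] <- g[[names$Wr]] + tcrossprod(dRpre, Mx)
  g[[names$Wn]] <- g[[names$Wn]] + tcrossprod(dNpre, Mx)
  g[[names$Uz]] <- g[[names$Uz]] + tcrossprod(dZpre, H)
  g[[names$Ur]] <- g[[names$Ur]] + tcrossprod(dRpre, H)
  g[[names$Un]] <- g[[names$Un]] + tcrossprod(dNpre, RH)
  g[[names$bz]] <- g[[names$bz]] + rowSums(dZpre)
  g[[names$br]] <- g[[names$br]] + rowSums(dRpre)
  g[[names$bn]] <- g[[names$bn]] + rowSums(dNpre)
  dHin <- dHin + crossprod(U$z, dZpre) + crossprod(U$r, dRpre)
  dMx <- crossprod(W$z, dZpre) + crossprod(W$r, dRpre) + crossprod(W$n, dNpre)
  list(dMx = dMx, dHin = dHin)
}

# forward pass on one graph; returns scaled prediction and (optionally) the
# cache needed for backprop
.mpnn_forward <- function(par, graph, config, keep_cache = FALSE) {
  d <- config$hidden_dim
  n <- graph$n_atoms
  if (n < 1) stop("empty graph: no atoms")
  Tsteps <- config$message_steps
  Msteps <- config$set2set_steps

  H <- matrix(0, d, n)
  H[seq_len(ncol(graph$atom_features)), ] <- t(graph$atom_features)

  n_e <- nrow(graph$bonds)
  A <- vector("list", n_e)
  if (n_e > 0) {
    Araw <- par$Wb %*% t(graph$bond_features) + par$bb  # (d*d) x n_e
    for (e in seq_len(n_e)) A[[e]] <- matrix(Araw[, e], d, d)
  }
  Wm <- list(z = par$Wz, r = par$Wr, n = par$Wn)
  Um <- list(z = par$Uz, r = par$Ur, n = par$Un)
  bm <- list(z = par$bz, r = par$br, n = par$bn)

  msg_caches <- vector("list", Tsteps)
  Hs <- vector("list", Tsteps + 1L); Hs[[1L]] <- H
  bi <- graph$bonds[, 1L]; bj <- graph$bonds[, 2L]
  for (t in seq_len(Tsteps)) {
    Mx <- matrix(0, d, n)
    for (e in seq_len(n_e)) {
      Mx[, bi[e]] <- Mx[, bi[e]] + A[[e]] %*% H[, bj[e]]
      Mx[, bj[e]] <- Mx[, bj[e]] + A[[e]] %*% H[, bi[e]]
    }
    cc <- .gru_forward(Wm, Um, bm, Mx, H)
    H <- cc$H
    msg_caches[[t]] <- cc
    Hs[[t + 1L]] <- H
  }

  # set2set readout
  Ws <- list(z = par$Sz, r = par$Sr, n = par$Sn)
  Us <- list(z = par$Tz, r = par$Tr, n = par$Tn)
  bs <- list(z = par$cz, r = par$cr, n = par$cn)
  q <- numeric(d); r <- numeric(d)
  s2s <- vector("list", Msteps)
  for (m in seq_len(Msteps)) {
    cc <- .gru_forward(Ws, Us, bs, matrix(r, d, 1), matrix(q, d, 1))
    q <- drop(cc$H)
    ee <- drop(crossprod(H, q))
    ee <- ee - max(ee)
    a <- exp(ee); a <- a / sum(a)
    r <- drop(H %*% a)
    s2s[[m]] <- list(gru = cc, a = a, q = q)
  }
  qstar <- c(q, r)

  u <- drop(par$W1 %*% qstar + par$b1)
  v <- pmax(u, 0)
  ys <- sum(par$w2 * v) + par$b2

  if (!keep_cache) return(list(ys = ys))
  list(ys = ys, cache = list(H = H, Hs = Hs, msg = msg_caches, A = A,
                             s2s = s2s, qstar = qstar, u = u, v = v, n = n))
}

# backprop of dL/dys through one graph; accumulates into grad environment g
.mpnn_backward <- function(par, graph, config, cache, dys, g) {
  d <- config$hidden_dim
  n <- cache$n
  n_e <- nrow(graph$bonds)
  bi <- graph$bonds[, 1L]; bj <- graph$bonds[, 2L]

  # head
  dv <- par$w2 * dys
  du <- dv * (cache$u > 0)
  g$W1 <- g$W1 + tcrossprod(du, cache$qstar)
  g$b1 <- g$b1 + du
  g$w2 <- g$w2 + cache$v * dys
  g$b2 <- g$b2 + dys
  dqstar <- drop(crossprod(par$W1, du))
  dq <- dqstar[seq_len(d)]
  dr <- dqstar[d + seq_len(d)]

  # set2set, reversed
  Ws <- list(z = par$Sz, r = par$Sr, n = par$Sn)
  Us <- list(z = par$Tz, r = par$Tr, n = par$Tn)
  s2s_names <- list(Wz = "Sz", Wr = "Sr", Wn = "Sn",
                    Uz = "Tz", Ur = "Tr", Un = "Tn",
                    bz = "cz", br = "cr", bn = "cn")
  H <- cache$H
  dH <- matrix(0, d, n)
  for (m in rev(seq_len(config$set2set_steps))) {
    st <- cache$s2s[[m]]
    a <- st$a; q <- st$q
    # r = H a
    da <- drop(crossprod(H, dr))
    dH <- dH + tcrossprod(dr, a)
    # softmax
    de <- a * (da - sum(a * da))
    # e = t(H) q
    dq <- dq + drop(H %*% de)
    dH <- dH + tcrossprod(q, de)
    bk <- .gru_backward(Ws, Us, st$gru, matrix(dq, d, 1), g, s2s_names)
    dr <- drop(bk$dMx)
    dq <- drop(bk$dHin)
  }

  # message-passing, reversed
  Wm <- list(z = par$Wz, r = par$Wr, n = par$Wn)
  Um <- list(z = par$Uz, r = par$Ur, n = par$Un)
  msg_names <- list(Wz = "Wz", Wr = "Wr", Wn = "Wn",
                    Uz = "Uz", Ur = "Ur", Un = "Un",
                    bz = "bz", br = "br", bn = "bn")
  dA <- if (n_e > 0) vector("list", n_e) else list()
  for (e in seq_len(n_e)) dA[[e]] <- matrix(0, d, d)
  for (t in rev(seq_len(config$message_steps))) {
    bk <- .gru_backward(Wm, Um, cache$msg[[t]], dH, g, msg_names)
    dMx <- bk$dMx
    dH <- bk$dHin
    Hprev <- cache$Hs[[t]]
    for (e in seq_len(n_e)) {
      Ae <- cache$A[[e]]
      dH[, bj[e]] <- dH[, bj[e]] + crossprod(Ae, dMx[, bi[e]])
      dH[, bi[e]] <- dH[, bi[e]] + crossprod(Ae, dMx[, bj[e]])
      dA[[e]] <- dA[[e]] + tcrossprod(dMx[, bi[e]], Hprev[, bj[e]]) +
                           tcrossprod(dMx[, bj[e]], Hprev[, bi[e]])
    }
  }
  if (n_e > 0) {
    dAraw <- vapply(dA, as.numeric, numeric(d * d))  # (d*d) x n_e
    if (n_e == 1L) dAraw <- matrix(dAraw, ncol = 1L)
    g$Wb <- g$Wb + dAraw %*% graph$bond_features
    g$bb <- g$bb + rowSums(dAraw)
  }
  invisible(NULL)
}

.adam_update <- function(par, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    gr <- g[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  par
}
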