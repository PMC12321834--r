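# Analytic backward pass for the CMPNN. Mirrors cmpnn_forward step by step
# in reverse; verified against central-difference numerical gradients in the
# test suite.

zero_like <- function(params) {
  lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
         else numeric(length(p)))
}

# Gradient of mean binary cross-entropy w.r.t. every parameter.
# fw: result of cmpnn_forward(..., keep_cache = TRUE); y: 0/1 labels.
cmpnn_backward <- function(params, batch, config, fw, y) {
  ca <- fw$cache
  n <- length(y)
  g <- zero_like(params)
  h <- config$hidden_size
  three <- config$booster_concat == "three_way"
  has_bias <- !is.null(params$ba)

  dlogit <- matrix((fw$yhat - y) / n, ncol = 1)
  g$W2 <- crossprod(ca$H1d, dlogit)
  g$b2 <- sum(dlogit)
  dH1d <- dlogit %*% t(params$W2)
  dH1 <- if (!is.null(ca$dropout_mask)) {
    dH1d * ca$dropout_mask / (1 - config$dropout)
  } else dH1d
  dA1 <- dH1 * (ca$A1 > 0)
  g$W1 <- crossprod(fw$hmol, dA1)
  g$b1 <- colSums(dA1)
  dhmol <- dA1 %*% t(params$W1)

  # --- GRU backward through time -----------------------------------------
  M <- batch$n_mols
  dHv <- matrix(0, batch$n_atoms, h)
  dh_carry <- matrix(0, M, h)
  for (t in rev(seq_along(ca$gru))) {
    st <- ca$gru[[t]]
    act <- st$act
    dh <- dhmol[act, , drop = FALSE] + dh_carry[act, , drop = FALSE]
    z <- st$z; r <- st$r; n_ <- st$n; hp <- st$hp; x <- st$x
    dz <- dh * (hp - n_)
    dn <- dh * (1 - z)
    dhp <- dh * z
    dan <- dn * (1 - n_^2)
    daz <- dz * z * (1 - z)
    drh <- dan %*% t(params$Uh)       # grad w.r.t. (r * hp)
    dr <- drh * hp
    dhp <- dhp + drh * r
    dar <- dr * r * (1 - r)
    g$Wh <- g$Wh + crossprod(x, dan)
    g$Uh <- g$Uh + crossprod(r * hp, dan)
    g$bh <- g$bh + colSums(dan)
    g$Wz <- g$Wz + crossprod(x, daz)
    g$Uz <- g$Uz + crossprod(hp, daz)
    g$bz <- g$bz + colSums(daz)
    g$Wr <- g$Wr + crossprod(x, dar)
    g$Ur <- g$Ur + crossprod(hp, dar)
    g$br <- g$br + colSums(dar)
    dx <- dan %*% t(params$Wh) + daz %*% t(params$Wz) + dar %*% t(params$Wr)
    dhp <- dhp + daz %*% t(params$Uz) + dar %*% t(params$Ur)
    dHv[st$idx, ] <- dx
    dh_carry[act, ] <- dhp
  }

  # --- message-passing backward -------------------------------------------
  V <- batch$n_atoms
  E <- batch$n_edges
  dHe <- matrix(0, E, h)
  K <- config$depth
  for (t in rev(seq_len(K))) {
    st <- ca$steps[[t]]
    if (!is.null(st$zee_pos)) {
      dZee <- dHe * st$zee_pos
      g$W_e <- g$W_e + crossprod(st$D, dZee)
      if (has_bias) g$be <- g$be + colSums(dZee)
      dD <- dZee %*% t(params$W_e)
      dHv <- dHv + scatter_add(dD[, seq_len(h), drop = FALSE],
                               batch$edge_dst, V)
      dHe <- dHe + dD[, h + seq_len(h), drop = FALSE]
    }
    dZn <- dHv * st$zn_pos
    g$W_n <- g$W_n + crossprod(st$C, dZn)
    if (has_bias) g$bn <- g$bn + colSums(dZn)
    dC <- dZn %*% t(params$W_n)
    dHv <- dC[, seq_len(h), drop = FALSE]
    dMp <- dC[, h + seq_len(h), drop = FALSE]
    dB <- dMp * st$M
    if (three) dB <- dB + dC[, 2 * h + seq_len(h), drop = FALSE]
    dM <- dMp * st$B
    if (E > 0) {
      dHe <- dHe + dM[batch$edge_dst, , drop = FALSE]
      valid <- st$A > 0
      if (any(valid)) {
        cells <- cbind(st$A[valid], col(st$A)[valid])
        dHe[cells] <- dHe[cells] + dB[valid]
      }
    }
  }
  dZa <- dHv * (ca$Za > 0)
  g$W_a <- crossprod(ca$Xa, dZa)
  if (has_bias) g$ba <- colSums(dZa)
  if (E > 0) {
    dZe0 <- dHe * (ca$Ze0 > 0)
    g$W_b <- crossprod(ca$Ein, dZe0)
    if (has_bias) g$bb <- colSums(dZe0)
  }
  g
}

bce_loss <- function(yhat, y) {
  eps <- 1e-12
  -mean(y * log(yhat + eps) + (1 - y) * log(1 - yhat + eps))
}
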