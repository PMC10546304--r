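# Minimal dense/convolutional layer kit with hand-written backward passes.
# Everything is plain double arrays; a forward pass returns the output plus
# the caches needed for the exact gradient. im2col index matrices are memoized
# per geometry so repeated forward passes only gather and multiply.

.layerCache <- new.env(parent = emptyenv())

#' @noRd
.im2colIndex <- function(H, W, Cin, k, stride, pad) {
  key <- paste(H, W, Cin, k, stride, pad, sep = "_")
  hit <- .layerCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  H2 <- (Hp - k) %/% stride + 1L
  W2 <- (Wp - k) %/% stride + 1L
  ois <- rep(seq_len(H2) - 1L, times = W2) * stride
  ojs <- rep(seq_len(W2) - 1L, each = H2) * stride
  off <- expand.grid(di = seq_len(k) - 1L, dj = seq_len(k) - 1L,
                     ci = seq_len(Cin) - 1L)
  nO <- H2 * W2; nK <- k * k * Cin
  idx <- matrix(0L, nO, nK)
  for (cc in seq_len(nK)) {
    idx[, cc] <- (ois + off$di[cc]) + Hp * (ojs + off$dj[cc]) +
      Hp * Wp * off$ci[cc] + 1L
  }
  out <- list(idx = idx, H2 = H2, W2 = W2, Hp = Hp, Wp = Wp)
  .layerCache[[key]] <- out
  out
}

#' @noRd
.convForward <- function(x, Wmat, b, k, stride, pad) {
  d <- dim(x)
  ii <- .im2colIndex(d[1], d[2], d[3], k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(ii$Hp, ii$Wp, d[3]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  } else xp <- x
  cols <- xp[as.vector(ii$idx)]
  dim(cols) <- dim(ii$idx)
  out <- cols %*% Wmat
  out <- sweep(out, 2L, b, "+")
  dim(out) <- c(ii$H2, ii$W2, length(b))
  list(out = out, cache = list(cols = cols, ii = ii, dIn = d))
}

#' @noRd
.convBackward <- function(dOut, cache, Wmat, k, stride, pad) {
  ii <- cache$ii; d <- cache$dIn
  Cout <- ncol(Wmat)
  dM <- matrix(dOut, ii$H2 * ii$W2, Cout)
  dW <- crossprod(cache$cols, dM)
  db <- colSums(dM)
  dcols <- dM %*% t(Wmat)
  dxp <- numeric(ii$Hp * ii$Wp * d[3])
  for (cc in seq_len(ncol(ii$idx))) {
    # within one column all target indices are distinct, so plain
    # accumulation indexing is exact
    tgt <- ii$idx[, cc]
    dxp[tgt] <- dxp[tgt] + dcols[, cc]
  }
  dim(dxp) <- c(ii$Hp, ii$Wp, d[3])
  dx <- if (pad > 0L) {
    dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
  } else dxp
  dim(dx) <- d
  list(dW = dW, db = db, dx = dx)
}

#' @noRd
.maxpoolForward <- function(x, f, stride) {
  d <- dim(x)
  H2 <- (d[1] - f) %/% stride + 1L
  W2 <- (d[2] - f) %/% stride + 1L
  C <- d[3]
  out <- array(-Inf, c(H2, W2, C))
  arg <- array(0L, c(H2, W2, C))
  chOff <- rep((seq_len(C) - 1L) * d[1] * d[2], each = H2 * W2)
  for (di in seq_len(f) - 1L) {
    xi <- stride * (seq_len(H2) - 1L) + di + 1L
    for (dj in seq_len(f) - 1L) {
      xj <- stride * (seq_len(W2) - 1L) + dj + 1L
      sub <- x[xi, xj, , drop = FALSE]
      plin <- rep((xi - 1L), times = W2) +
        d[1] * rep((xj - 1L), each = H2)
      full <- rep(plin + 1L, times = C) + chOff
      upd <- sub > out
      out[upd] <- sub[upd]
      arg[upd] <- full[upd]
    }
  }
  list(out = out, cache = list(arg = arg, dIn = d))
}

#' @noRd
.maxpoolBackward <- function(dOut, cache) {
  dx <- numeric(prod(cache$dIn))
  s <- rowsum(as.vector(dOut), group = as.vector(cache$arg))
  tgt <- as.integer(rownames(s))
  dx[tgt] <- dx[tgt] + s[, 1]
  dim(dx) <- cache$dIn
  dx
}

#' @noRd
.gapForward <- function(x) {
  d <- dim(x)
  list(out = colMeans(matrix(x, d[1] * d[2], d[3])), cache = d)
}

#' @noRd
.gapBackward <- function(dOut, d) {
  array(rep(dOut / (d[1] * d[2]), each = d[1] * d[2]), d)
}

# Bilinear resize of a square slice (used by the AlexNet-style backbone to
# reach its native input size); linear, so the backward pass is the
# transposed interpolation.
#' @noRd
.resizeMatrix <- function(nIn, nOut) {
  key <- paste("rs", nIn, nOut, sep = "_")
  hit <- .layerCache[[key]]
  if (!is.null(hit)) return(hit)
  t <- (seq_len(nOut) - 1) * (nIn - 1) / max(nOut - 1, 1L) + 1
  i0 <- pmin(floor(t), nIn - 1L)
  w <- t - i0
  M <- matrix(0, nOut, nIn)
  M[cbind(seq_len(nOut), i0)] <- 1 - w
  M[cbind(seq_len(nOut), i0 + 1L)] <- M[cbind(seq_len(nOut), i0 + 1L)] + w
  .layerCache[[key]] <- M
  M
}

# Forward pass through a backbone layer list. Layer types: conv, relu,
# maxpool, gap, resize (with optional channel replication).
#' @noRd
.nnForward <- function(layers, weights, x) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    if (L$type == "conv") {
      r <- .convForward(x, weights[[li]]$W, weights[[li]]$b, L$k, L$stride,
                        L$pad)
      x <- r$out; caches[[li]] <- r$cache
    } else if (L$type == "relu") {
      caches[[li]] <- x > 0
      x <- x * caches[[li]]
    } else if (L$type == "maxpool") {
      r <- .maxpoolForward(x, L$f, L$stride)
      x <- r$out; caches[[li]] <- r$cache
    } else if (L$type == "gap") {
      r <- .gapForward(x)
      x <- r$out; caches[[li]] <- r$cache
    } else if (L$type == "resize") {
      d <- dim(x)
      M <- .resizeMatrix(d[1], L$size)
      y <- array(0, c(L$size, L$size, d[3]))
      for (ch in seq_len(d[3])) y[, , ch] <- M %*% x[, , ch] %*% t(M)
      caches[[li]] <- d
      if (isTRUE(L$replicate) && d[3] == 1L) {
        y <- array(rep(y, 3L), c(L$size, L$size, 3L))
      }
      x <- y
    } else stop("unknown layer type: ", L$type)
  }
  list(out = x, caches = caches)
}

#' @noRd
.nnBackward <- function(layers, weights, caches, dOut) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    L <- layers[[li]]
    if (L$type == "conv") {
      r <- .convBackward(dOut, caches[[li]], weights[[li]]$W, L$k, L$stride,
                         L$pad)
      grads[[li]] <- list(W = r$dW, b = r$db)
      dOut <- r$dx
    } else if (L$type == "relu") {
      dOut <- dOut * caches[[li]]
    } else if (L$type == "maxpool") {
      dOut <- .maxpoolBackward(dOut, caches[[li]])
    } else if (L$type == "gap") {
      dOut <- .gapBackward(dOut, caches[[li]])
    } else if (L$type == "resize") {
      d <- caches[[li]]
      if (isTRUE(L$replicate) && d[3] == 1L) {
        dOut <- array(dOut[, , 1] + dOut[, , 2] + dOut[, , 3],
                      c(dim(dOut)[1], dim(dOut)[2], 1L))
      }
      M <- .resizeMatrix(d[1], L$size)
      dx <- array(0, d)
      for (ch in seq_len(d[3])) dx[, , ch] <- t(M) %*% dOut[, , ch] %*% M
      dOut <- dx
    }
  }
  list(grads = grads, dx = dOut)
}

# Two-layer fully-connected classifier head with softmax output.
#' @noRd
.headInit <- function(nIn, hidden, seedOffset = 0L) {
  list(W1 = matrix(stats::rnorm(nIn * hidden, 0, sqrt(2 / nIn)), nIn, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * 2L, 0, sqrt(1 / hidden)), hidden, 2L),
       b2 = numeric(2L))
}

#' @noRd
.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' @noRd
.headForward <- function(head, x) {
  h <- drop(x %*% head$W1) + head$b1
  hr <- pmax(h, 0)
  z <- drop(hr %*% head$W2) + head$b2
  p <- .softmax(z)
  list(p = p, cache = list(x = x, hr = hr, mask = h > 0))
}

# dz is the gradient at the logits (for softmax + CE: p - y).
#' @noRd
.headBackward <- function(head, cache, dz) {
  dW2 <- outer(cache$hr, dz)
  db2 <- dz
  dh <- drop(head$W2 %*% dz) * cache$mask
  dW1 <- outer(cache$x, dh)
  db1 <- dh
  dx <- drop(head$W1 %*% dh)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dx = dx)
}
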