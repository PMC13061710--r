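# Convolution primitives on (H, W, B, C) arrays, implemented as
# shift-and-accumulate over kernel offsets so every inner product is a single
# BLAS matmul of the flattened (position, channel) matrix.

pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# full convolution: x (H,W,B,Cin), W (kh,kw,Cin,Cout), b (Cout) or NULL
ag_conv2d <- function(x, W, b = NULL, stride = 1L, pad = NULL) {
  x <- as_node(x); W <- as_node(W)
  bn <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; Wv <- W$value
  dx <- dim(xv); dw <- dim(Wv)
  kh <- dw[1]; kw <- dw[2]; Cin <- dw[3]; Cout <- dw[4]
  stopifnot(dx[4] == Cin)
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  if (kh == 1L && kw == 1L && stride == 1L && pad == 0L) {
    return(ag_pointwise(x, W, bn, xv, Wv, dx, Cin, Cout))
  }
  xp <- pad_spatial(xv, pad)
  Hp <- dx[1] + 2 * pad; Wp <- dx[2] + 2 * pad
  oH <- (Hp - kh) %/% stride + 1L
  oW <- (Wp - kw) %/% stride + 1L
  B <- dx[3]
  nflat <- oH * oW * B
  out <- matrix(0, nflat, Cout)
  for (ki in seq_len(kh)) {
    rows <- seq.int(ki, by = stride, length.out = oH)
    for (kj in seq_len(kw)) {
      cols <- seq.int(kj, by = stride, length.out = oW)
      xs <- xp[rows, cols, , , drop = FALSE]
      dim(xs) <- c(nflat, Cin)
      out <- out + xs %*% matrix(Wv[ki, kj, , ], Cin, Cout)
    }
  }
  if (!is.null(bn)) out <- sweep(out, 2, as.numeric(bn$value), "+")
  dim(out) <- c(oH, oW, B, Cout)
  parents <- if (is.null(bn)) list(x, W) else list(x, W, bn)
  ag_op(out, parents, function(g) {
    gm <- g
    dim(gm) <- c(nflat, Cout)
    dW <- array(0, dw)
    dxp <- array(0, c(Hp, Wp, B, Cin))
    for (ki in seq_len(kh)) {
      rows <- seq.int(ki, by = stride, length.out = oH)
      for (kj in seq_len(kw)) {
        cols <- seq.int(kj, by = stride, length.out = oW)
        xs <- xp[rows, cols, , , drop = FALSE]
        dim(xs) <- c(nflat, Cin)
        dW[ki, kj, , ] <- crossprod(xs, gm)
        gxs <- gm %*% t(matrix(Wv[ki, kj, , ], Cin, Cout))
        dim(gxs) <- c(oH, oW, B, Cin)
        dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + gxs
      }
    }
    dxv <- dxp[pad + seq_len(dx[1]), pad + seq_len(dx[2]), , , drop = FALSE]
    dim(dxv) <- dx
    if (is.null(bn)) list(dxv, dW) else list(dxv, dW, colSums(gm))
  })
}

# 1x1 convolution: a single matmul over the flattened positions
ag_pointwise <- function(x, W, bn, xv, Wv, dx, Cin, Cout) {
  nflat <- dx[1] * dx[2] * dx[3]
  xm <- xv
  dim(xm) <- c(nflat, Cin)
  Wm <- matrix(Wv, Cin, Cout)
  out <- xm %*% Wm
  if (!is.null(bn)) out <- sweep(out, 2, as.numeric(bn$value), "+")
  dim(out) <- c(dx[1], dx[2], dx[3], Cout)
  parents <- if (is.null(bn)) list(x, W) else list(x, W, bn)
  ag_op(out, parents, function(g) {
    dim(g) <- c(nflat, Cout)
    dxv <- g %*% t(Wm)
    dim(dxv) <- dx
    dW <- crossprod(xm, g)
    dim(dW) <- c(1L, 1L, Cin, Cout)
    if (is.null(bn)) list(dxv, dW) else list(dxv, dW, colSums(g))
  })
}

# depthwise convolution: one k x k filter per channel, stride 1, same
# padding (C++ kernel)
ag_depthwise_conv <- function(x, K, b = NULL) {
  x <- as_node(x); K <- as_node(K)
  bn <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; Kv <- K$value
  dx <- dim(xv); dk <- dim(Kv)
  kh <- dk[1]; kw <- dk[2]; C <- dk[3]
  stopifnot(dx[4] == C, kh %% 2L == 1L, kw %% 2L == 1L)
  bias <- if (is.null(bn)) numeric(C) else as.numeric(bn$value)
  out <- dw_conv_fwd_cpp(xv, as.integer(dx), Kv, as.integer(dk), bias)
  dim(out) <- dx
  parents <- if (is.null(bn)) list(x, K) else list(x, K, bn)
  ag_op(out, parents, function(g) {
    bw <- dw_conv_bwd_cpp(g, xv, as.integer(dx), Kv, as.integer(dk))
    dxv <- bw$dx; dim(dxv) <- dx
    dKv <- bw$dk; dim(dKv) <- dk
    if (is.null(bn)) list(dxv, dKv) else list(dxv, dKv, bw$db)
  })
}

# transposed convolution, kernel 2, stride 2 (exact x2 upsampling):
# out[2i-1+di, 2j-1+dj, , ] = x[i, j, , ] %*% W[di, dj, , ]
ag_conv2d_transpose2 <- function(x, W, b = NULL) {
  x <- as_node(x); W <- as_node(W)
  bn <- if (is.null(b)) NULL else as_node(b)
  xv <- x$value; Wv <- W$value
  dx <- dim(xv); dw <- dim(Wv)
  stopifnot(dw[1] == 2L, dw[2] == 2L, dx[4] == dw[3])
  h <- dx[1]; w <- dx[2]; B <- dx[3]; Cin <- dw[3]; Cout <- dw[4]
  xf <- xv
  dim(xf) <- c(h * w * B, Cin)
  out <- array(0, c(2 * h, 2 * w, B, Cout))
  for (di in 1:2) for (dj in 1:2) {
    o <- xf %*% matrix(Wv[di, dj, , ], Cin, Cout)
    dim(o) <- c(h, w, B, Cout)
    out[seq.int(di, 2 * h, 2), seq.int(dj, 2 * w, 2), , ] <- o
  }
  if (!is.null(bn)) out <- out + rep(as.numeric(bn$value), each = 4 * h * w * B)
  parents <- if (is.null(bn)) list(x, W) else list(x, W, bn)
  ag_op(out, parents, function(g) {
    dW <- array(0, dw)
    dxf <- matrix(0, h * w * B, Cin)
    for (di in 1:2) for (dj in 1:2) {
      gs <- g[seq.int(di, 2 * h, 2), seq.int(dj, 2 * w, 2), , , drop = FALSE]
      dim(gs) <- c(h * w * B, Cout)
      dW[di, dj, , ] <- crossprod(xf, gs)
      dxf <- dxf + gs %*% t(matrix(Wv[di, dj, , ], Cin, Cout))
    }
    dim(dxf) <- dx
    if (is.null(bn)) {
      list(dxf, dW)
    } else {
      gm <- g; dim(gm) <- c(4 * h * w * B, Cout)
      list(dxf, dW, colSums(gm))
    }
  })
}
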