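# Row-major (row-wise concatenation) flattening between (H, W, B, C) feature
# maps and (L, B, C) token sequences, plus the differentiable state-space
# scan wrapping the C++ recurrence kernel.

# token t (1-based) sits at position (row = (t-1) %/% W + 1, col = (t-1) %% W + 1)
ag_flatten_rows <- function(x) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv)
  v <- aperm(xv, c(2, 1, 3, 4))
  dim(v) <- c(d[1] * d[2], d[3], d[4])
  ag_op(v, list(x), function(g) {
    dim(g) <- c(d[2], d[1], d[3], d[4])
    list(aperm(g, c(2, 1, 3, 4)))
  })
}

ag_unflatten <- function(x, H, W) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv)
  stopifnot(d[1] == H * W)
  v <- xv
  dim(v) <- c(W, H, d[2], d[3])
  v <- aperm(v, c(2, 1, 3, 4))
  ag_op(v, list(x), function(g) {
    g <- aperm(g, c(2, 1, 3, 4))
    dim(g) <- d
    list(g)
  })
}

ag_reverse_seq <- function(x) {
  x <- as_node(x)
  xv <- x$value
  L <- dim(xv)[1]
  idx <- seq.int(L, 1L)
  ag_op(xv[idx, , , drop = FALSE], list(x),
        function(g) list(g[idx, , , drop = FALSE]))
}

# x: (L, B, C); a, b, c: (C, N) nodes (a already mapped into (0,1)); d: (C)
ag_ssm_scan <- function(x, a, b, c, d) {
  x <- as_node(x); a <- as_node(a); b <- as_node(b)
  c <- as_node(c); d <- as_node(d)
  xv <- x$value
  dims <- dim(xv)
  av <- a$value; bv <- b$value; cv <- c$value
  dv <- as.numeric(d$value)
  if (!all(is.finite(av)) || !all(is.finite(bv)) ||
      !all(is.finite(cv)) || !all(is.finite(dv))) {
    stop("non-finite state-space parameters")
  }
  y <- ssm_scan_fwd_cpp(xv, as.integer(dims), av, bv, cv, dv)
  dim(y) <- dims
  ag_op(y, list(x, a, b, c, d), function(g) {
    bw <- ssm_scan_bwd_cpp(g, xv, as.integer(dims), av, bv, cv, dv)
    dx <- bw$dx
    dim(dx) <- dims
    list(dx, bw$da, bw$db, bw$dc, bw$dd)
  })
}
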