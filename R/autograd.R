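# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Conventions used throughout the network code:
#   feature map : 4-D array (H, W, B, C)   -- batch third, channels last, so
#                 `dim(x) <- c(H*W*B, C)` yields the (position, channel) matrix
#   token seq   : 3-D array (L, B, C), L = H*W in row-major (row-wise) order
#   vector      : matrix (B, C)
#   spatial map : 3-D array (H, W, B)
#   scalar      : length-1 numeric
#
# A node is an environment holding $value, $grad, $parents and $vjp (a
# function mapping the incoming gradient to a list of parent gradients).
# Ops append nodes to the active tape; with no active tape (inference) the
# same ops run value-only and keep no caches.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

ag_tape_begin <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 512L)
  tape$n <- 0L
  .ag$tape <- tape
  invisible(tape)
}

ag_tape_end <- function() {
  .ag$tape <- NULL
  invisible(NULL)
}

ag_recording <- function() !is.null(.ag$tape)

ag_leaf <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- NULL
  nd$vjp <- NULL
  class(nd) <- "ag_node"
  nd
}

is_ag_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_ag_node(x)) x$value else x

as_node <- function(x) if (is_ag_node(x)) x else ag_leaf(x)

# Create an op node; `vjp` receives the upstream gradient and returns a list
# of gradients aligned with `parents` (NULL entries allowed).
ag_op <- function(value, parents, vjp) {
  nd <- ag_leaf(value)
  tape <- .ag$tape
  if (!is.null(tape)) {
    nd$parents <- parents
    nd$vjp <- vjp
    n <- tape$n + 1L
    if (n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

# Reverse sweep over the active tape starting from a scalar loss node.
ag_backward <- function(loss) {
  stopifnot(is_ag_node(loss), length(loss$value) == 1L)
  tape <- .ag$tape
  if (is.null(tape)) stop("ag_backward() requires an active tape")
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (j in seq_along(gs)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    # free caches as we go
    nd$vjp <- NULL
    nd$grad <- NULL
    tape$nodes[i] <- list(NULL)
  }
  invisible(NULL)
}

same_shape <- function(g, x) {
  if (!is.null(dim(x))) dim(g) <- dim(x)
  g
}

## ---- elementwise / scalar ops -------------------------------------------

ag_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_op(a$value + b$value, list(a, b),
        function(g) list(g, same_shape(g, b$value)))
}

ag_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ag_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g) list(g * bv, same_shape(g * av, bv)))
}

ag_scale <- function(x, k) {
  x <- as_node(x)
  ag_op(k * x$value, list(x), function(g) list(k * g))
}

ag_shift <- function(x, k) {
  x <- as_node(x)
  ag_op(x$value + k, list(x), function(g) list(g))
}

ag_one_minus <- function(x) ag_shift(ag_scale(x, -1), 1)

# multiply a tensor by a scalar parameter node
ag_mul_scalar <- function(x, s) {
  x <- as_node(x); s <- as_node(s)
  xv <- x$value; sv <- as.numeric(s$value)
  ag_op(sv * xv, list(x, s),
        function(g) list(sv * g, sum(g * xv)))
}

ag_exp <- function(x) {
  x <- as_node(x)
  v <- exp(x$value)
  ag_op(v, list(x), function(g) list(g * v))
}

ag_sigmoid <- function(x) {
  x <- as_node(x)
  v <- 1 / (1 + exp(-x$value))
  ag_op(v, list(x), function(g) list(g * v * (1 - v)))
}

ag_softplus <- function(x) {
  x <- as_node(x)
  xv <- x$value
  # numerically stable log(1 + exp(x))
  v <- pmax(xv, 0) + log1p(exp(-abs(xv)))
  ag_op(v, list(x), function(g) list(g / (1 + exp(-xv))))
}

ag_gelu <- function(x) {
  # sigmoid approximation x * sigmoid(1.702 x): within ~1e-2 of the exact
  # Gaussian form and much cheaper on large arrays
  x <- as_node(x)
  xv <- x$value
  sg <- 1 / (1 + exp(-1.702 * xv))
  ag_op(xv * sg, list(x),
        function(g) list(g * (sg + 1.702 * xv * sg * (1 - sg))))
}

ag_sum <- function(x) {
  x <- as_node(x)
  xv <- x$value
  ag_op(sum(xv), list(x), function(g) list(same_shape(array(g, dim = c(length(xv))), xv)))
}

## ---- shape ops -----------------------------------------------------------

ag_reshape <- function(x, dims) {
  x <- as_node(x)
  v <- x$value
  old <- dim(v)
  dim(v) <- dims
  ag_op(v, list(x), function(g) { dim(g) <- old; list(g) })
}

# concatenate along the last dimension (channels for maps and vectors)
ag_concat_last <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  k <- length(da)
  stopifnot(length(db) == k, all(da[-k] == db[-k]))
  lead <- prod(da[-k])
  m <- cbind(matrix(av, lead, da[k]), matrix(bv, lead, db[k]))
  dim(m) <- c(da[-k], da[k] + db[k])
  ag_op(m, list(a, b), function(g) {
    dim(g) <- c(lead, da[k] + db[k])
    ga <- g[, seq_len(da[k]), drop = FALSE]
    gb <- g[, da[k] + seq_len(db[k]), drop = FALSE]
    dim(ga) <- da; dim(gb) <- db
    list(ga, gb)
  })
}

## ---- broadcast multiplies -----------------------------------------------

# x: (H, W, B, C) map; a: (B, C) per-channel weights
ag_mul_channel <- function(x, a) {
  x <- as_node(x); a <- as_node(a)
  xv <- x$value; av <- a$value
  d <- dim(xv); hw <- d[1] * d[2]
  ab <- av[rep(seq_len(d[3] * d[4]), each = hw)]
  dim(ab) <- d
  ag_op(xv * ab, list(x, a), function(g) {
    gx <- g * ab
    gm <- g * xv
    dim(gm) <- c(hw, d[3] * d[4])
    ga <- matrix(colSums(gm), d[3], d[4])
    list(gx, ga)
  })
}

# x: (H, W, B, C) map; m: (H, W, B) spatial weights broadcast over channels
ag_mul_spatial <- function(x, m) {
  x <- as_node(x); m <- as_node(m)
  xv <- x$value; mv <- m$value
  d <- dim(xv)
  mb <- rep(as.vector(mv), times = d[4])
  dim(mb) <- d
  ag_op(xv * mb, list(x, m), function(g) {
    gx <- g * mb
    gm0 <- g * xv
    dim(gm0) <- c(d[1] * d[2] * d[3], d[4])
    gm <- rowSums(gm0)
    dim(gm) <- d[1:3]
    list(gx, gm)
  })
}

## ---- pooling / dense -----------------------------------------------------

# global average pool (H, W, B, C) -> (B, C)
ag_gap <- function(x) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv); hw <- d[1] * d[2]
  m <- xv
  dim(m) <- c(hw, d[3] * d[4])
  out <- matrix(colMeans(m), d[3], d[4])
  ag_op(out, list(x), function(g) {
    gx <- g[rep(seq_len(d[3] * d[4]), each = hw)] / hw
    dim(gx) <- d
    list(gx)
  })
}

# dense affine map: x (B, Cin), W (Cin, Cout), b (Cout)
ag_dense <- function(x, W, b = NULL) {
  x <- as_node(x); W <- as_node(W)
  xv <- x$value; Wv <- W$value
  out <- xv %*% Wv
  if (is.null(b)) {
    ag_op(out, list(x, W),
          function(g) list(g %*% t(Wv), crossprod(xv, g)))
  } else {
    b <- as_node(b)
    out <- sweep(out, 2, b$value, "+")
    ag_op(out, list(x, W, b),
          function(g) list(g %*% t(Wv), crossprod(xv, g), colSums(g)))
  }
}

## ---- normalization / dropout --------------------------------------------

# layer normalization across channels at every (h, w, b) position
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  xv <- x$value
  d <- dim(xv); C <- d[4]; n <- prod(d[1:3])
  m <- xv
  dim(m) <- c(n, C)
  mu <- rowMeans(m)
  xc <- m - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- as.numeric(gamma$value); bv <- as.numeric(beta$value)
  out <- sweep(xhat, 2, gv, "*")
  out <- sweep(out, 2, bv, "+")
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function(g) {
    dim(g) <- c(n, C)
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    gh <- sweep(g, 2, gv, "*")
    # d/dx of xhat with per-row mean/var
    t1 <- gh
    t2 <- rowMeans(gh)
    t3 <- rowMeans(gh * xhat)
    gx <- istd * (t1 - t2 - xhat * t3)
    dim(gx) <- d
    list(gx, dgamma, dbeta)
  })
}

ag_dropout <- function(x, p, training = FALSE) {
  if (!training || p <= 0) return(as_node(x))
  x <- as_node(x)
  xv <- x$value
  keep <- (stats::runif(length(xv)) >= p) / (1 - p)
  dim(keep) <- dim(xv)
  ag_op(xv * keep, list(x), function(g) list(g * keep))
}

## ---- losses --------------------------------------------------------------

# softmax + cross-entropy against (possibly smoothed) target rows, with
# per-sample weights; returns scalar node, softmax probs in attr "probs"
ag_softmax_ce <- function(logits, targets, sample_weights = NULL) {
  logits <- as_node(logits)
  lv <- logits$value
  B <- nrow(lv)
  if (is.null(sample_weights)) sample_weights <- rep(1, B)
  mx <- apply(lv, 1, max)
  e <- exp(lv - mx)
  p <- e / rowSums(e)
  ce <- -rowSums(targets * log(pmax(p, 1e-12)))
  loss <- sum(sample_weights * ce) / B
  nd <- ag_op(loss, list(logits), function(g) {
    list(g * (p - targets) * (sample_weights / B))
  })
  attr(nd, "probs") <- p
  nd
}

# mean over batch of (1 - Pearson correlation) between two (H, W, B) maps;
# zero-variance samples contribute the neutral value 1 with zero gradient
ag_pearson_loss <- function(u, e, var_tol = 1e-12) {
  u <- as_node(u); e <- as_node(e)
  uv <- u$value; ev <- e$value
  d <- dim(uv)
  n <- d[1] * d[2]; B <- d[3]
  um <- matrix(uv, n, B); em <- matrix(ev, n, B)
  uc <- sweep(um, 2, colMeans(um))
  ec <- sweep(em, 2, colMeans(em))
  su2 <- colSums(uc^2); se2 <- colSums(ec^2)
  ok <- su2 > var_tol & se2 > var_tol
  rho <- rep(0, B)
  rho[ok] <- colSums(uc[, ok, drop = FALSE] * ec[, ok, drop = FALSE]) /
    sqrt(su2[ok] * se2[ok])
  loss <- mean(1 - rho)
  nd <- ag_op(loss, list(u, e), function(g) {
    gu <- matrix(0, n, B); ge <- matrix(0, n, B)
    if (any(ok)) {
      for (bb in which(ok)) {
        su <- sqrt(su2[bb]); se <- sqrt(se2[bb])
        # d rho / d u = e_c/(su*se) - rho * u_c/su^2
        gu[, bb] <- -(ec[, bb] / (su * se) - rho[bb] * uc[, bb] / su2[bb])
        ge[, bb] <- -(uc[, bb] / (su * se) - rho[bb] * ec[, bb] / se2[bb])
        # centering: projecting out the mean
        gu[, bb] <- gu[, bb] - mean(gu[, bb])
        ge[, bb] <- ge[, bb] - mean(ge[, bb])
      }
    }
    gu <- gu * (g / B); ge <- ge * (g / B)
    dim(gu) <- d; dim(ge) <- d
    list(gu, ge)
  })
  attr(nd, "rho") <- rho
  attr(nd, "degenerate") <- !ok
  nd
}

# |p - y| for p in [0,1] and scalar labels y in {0,1}: E = y + (1-2y) p
ag_error_map <- function(p, y) {
  p <- as_node(p)
  pv <- p$value
  d <- dim(pv); hw <- d[1] * d[2]
  slope <- rep(1 - 2 * y, each = hw)
  inter <- rep(y, each = hw)
  dim(slope) <- d; dim(inter) <- d
  ag_op(inter + slope * pv, list(p), function(g) list(g * slope))
}

## ---- entropy of normalized squared channel intensities -------------------

# x: (H, W, B, C) -> U: (H, W, B), p_c = (x_c^2 + eps) / (sum x^2 + C*eps)
ag_entropy_map <- function(x, eps = 1e-8) {
  x <- as_node(x)
  xv <- x$value
  d <- dim(xv); C <- d[4]; n <- prod(d[1:3])
  m <- xv
  dim(m) <- c(n, C)
  q <- m * m + eps
  s <- rowSums(q)
  p <- q / s
  lp <- log(p)
  U <- -rowSums(p * lp)
  dim(U) <- d[1:3]
  ag_op(U, list(x), function(g) {
    dUdp <- -(lp + 1)
    inner <- dUdp - rowSums(p * dUdp)
    gx <- (2 * m / s) * inner * as.vector(g)
    dim(gx) <- d
    list(gx)
  })
}

## ---- bilinear resize of spatial maps ------------------------------------

# 1-D linear interpolation matrix (n_out x n_in), endpoints aligned
lin_interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) { M[, 1] <- 1; return(M) }
  if (n_out == 1L) { M[1, ] <- 1 / n_in; return(M) }  # average for collapse
  src <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(src), n_in - 2)
  w <- src - i0
  for (k in seq_len(n_out)) {
    M[k, i0[k] + 1] <- M[k, i0[k] + 1] + (1 - w[k])
    M[k, i0[k] + 2] <- M[k, i0[k] + 2] + w[k]
  }
  M
}

# u: (h, w, B) -> (H2, W2, B), separable bilinear (exact linear map)
ag_bilinear_resize <- function(u, H2, W2) {
  u <- as_node(u)
  uv <- u$value
  d <- dim(uv)
  if (d[1] == H2 && d[2] == W2) return(u)
  Rh <- lin_interp_matrix(d[1], H2)
  Rw <- lin_interp_matrix(d[2], W2)
  fwd <- function(v, h, w, B) {
    m <- v; dim(m) <- c(h, w * B)
    m <- Rh %*% m                      # (H2, w*B)
    dim(m) <- c(H2, w, B)
    m <- aperm(m, c(2, 1, 3))          # (w, H2, B)
    dim(m) <- c(w, H2 * B)
    m <- Rw %*% m                      # (W2, H2*B)
    dim(m) <- c(W2, H2, B)
    aperm(m, c(2, 1, 3))
  }
  bwd <- function(g) {
    m <- aperm(g, c(2, 1, 3))          # (W2, H2, B)
    dim(m) <- c(W2, H2 * d[3])
    m <- crossprod(Rw, m)              # (w, H2*B)
    dim(m) <- c(d[2], H2, d[3])
    m <- aperm(m, c(2, 1, 3))          # (H2, w, B)
    dim(m) <- c(H2, d[2] * d[3])
    m <- crossprod(Rh, m)              # (h, w*B)
    dim(m) <- c(d[1], d[2], d[3])
    m
  }
  ag_op(fwd(uv, d[1], d[2], d[3]), list(u), function(g) list(bwd(g)))
}
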