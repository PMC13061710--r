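# Independent brute-force oracles used across the suite. These are written
# as plain loops, deliberately sharing no code with the package internals.

# dense 2-D convolution, same padding, stride 1; W is (k, k, Cin, Cout);
# returns the output and the number of multiplications performed
dense_conv_ref <- function(x, W, b = NULL) {
  d <- dim(x); dw <- dim(W)
  k <- dw[1]; p <- (k - 1) %/% 2
  Cout <- dw[4]
  out <- array(0, c(d[1], d[2], Cout))
  mults <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (co in seq_len(Cout)) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1L - p; jj <- j + kj - 1L - p
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2]) {
        for (ci in seq_len(d[3])) {
          acc <- acc + x[ii, jj, ci] * W[ki, kj, ci, co]
          mults <- mults + 1L
        }
      }
    }
    out[i, j, co] <- acc
  }
  attr(out, "mults") <- mults
  out
}

# compose depthwise + pointwise factors into the equivalent dense kernel
compose_dsc_kernel <- function(dwK, pwW) {
  dk <- dim(dwK); Cin <- dk[3]; Cout <- ncol(pwW)
  W <- array(0, c(dk[1], dk[2], Cin, Cout))
  for (ci in seq_len(Cin)) for (co in seq_len(Cout)) {
    W[, , ci, co] <- dwK[, , ci] * pwW[ci, co]
  }
  W
}

# state-space recurrence as a per-step loop with an explicit step counter
ssm_loop_ref <- function(X, params) {
  L <- nrow(X); C <- ncol(X); N <- ncol(params$a)
  Y <- matrix(0, L, C)
  steps <- 0L
  for (ch in seq_len(C)) {
    s <- rep(0, N)
    for (t in seq_len(L)) {
      s <- params$a[ch, ] * s + params$b[ch, ] * X[t, ch]
      Y[t, ch] <- sum(params$c[ch, ] * s) + params$d[ch] * X[t, ch]
      steps <- steps + 1L
    }
  }
  attr(Y, "steps") <- steps / C
  Y
}

# per-position entropy by direct evaluation
entropy_ref <- function(f, eps = 1e-8) {
  d <- dim(f)
  U <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    q <- f[i, j, ]^2 + eps
    p <- q / sum(q)
    U[i, j] <- -sum(p * log(p))
  }
  U
}

# Mann-Whitney U based AUC
auc_ref <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  u <- 0
  for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(pos) * length(neg))
}

# small random feature map
rand_map <- function(h, w, c, sd = 1) array(rnorm(h * w * c, sd = sd), c(h, w, c))

# numeric finite-difference gradient of f at x[k]
fd_grad <- function(f, x, k, eps = 1e-5) {
  x1 <- x; x1[k] <- x1[k] + eps
  x2 <- x; x2[k] <- x2[k] - eps
  (f(x1) - f(x2)) / (2 * eps)
}
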