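# User-facing layer operations on single feature maps.
#
# These are thin wrappers over the differentiable batched kernels (run in
# value-only mode), so the documented API and the training path share one
# implementation. Feature maps are plain (H, W, C) arrays.

#' Depthwise separable convolution
#'
#' Applies one `k x k` spatial filter per input channel (plus bias), then a
#' pointwise (1x1) channel-mixing convolution (plus bias), with same padding:
#' `F_local = PointwiseConv(DepthwiseConv(F_in, k) + b_dw) + b_pw`.
#'
#' @param f_in numeric array `(H, W, C_in)`.
#' @param dw_kernels numeric array `(k, k, C_in)`, `k` odd.
#' @param pw_weights numeric matrix `(C_in, C_out)`.
#' @param b_dw,b_pw biases of length `C_in` / `C_out` (default zero).
#' @return numeric array `(H, W, C_out)`.
#' @export
depthwise_separable_conv <- function(f_in, dw_kernels, pw_weights,
                                     b_dw = NULL, b_pw = NULL) {
  d <- dim(f_in); dk <- dim(dw_kernels)
  if (length(dk) != 3L || dk[3] != d[3])
    stop("depthwise kernels must be (k, k, C_in)")
  if (dk[1] %% 2L != 1L) stop("kernel size must be odd")
  pw_weights <- as.matrix(pw_weights)
  if (nrow(pw_weights) != d[3])
    stop("pointwise weights must have C_in rows")
  if (is.null(b_dw)) b_dw <- numeric(d[3])
  if (is.null(b_pw)) b_pw <- numeric(ncol(pw_weights))
  x <- as_batched(f_in)
  h <- ag_depthwise_conv(x, dw_kernels, b_dw)
  pw <- array(pw_weights, c(1L, 1L, d[3], ncol(pw_weights)))
  out <- ag_conv2d(h, pw, b_pw, stride = 1L, pad = 0L)
  unbatch(ag_value(out))
}

#' Flatten a feature map to a token sequence (row-wise)
#'
#' Tokens are the per-pixel channel vectors in row-major order: token `t`
#' (1-based) corresponds to position `(floor((t-1)/W)+1, (t-1) %% W + 1)`.
#'
#' @param f numeric array `(H, W, C)`.
#' @return an `(L, C)` matrix with attribute `origin_shape = c(H, W)`.
#' @export
flatten_rows <- function(f) {
  d <- dim(f)
  stopifnot(length(d) == 3L)
  v <- ag_value(ag_flatten_rows(as_batched(f)))
  dim(v) <- c(d[1] * d[2], d[3])
  attr(v, "origin_shape") <- c(d[1], d[2])
  v
}

#' Restore a token sequence to a feature map
#'
#' @param tokens `(L, C)` matrix; `origin_shape` taken from its attribute
#'   unless given explicitly.
#' @param origin_shape integer `c(H, W)` with `H * W == L`.
#' @return numeric array `(H, W, C)`.
#' @export
unflatten <- function(tokens, origin_shape = attr(tokens, "origin_shape")) {
  if (is.null(origin_shape)) stop("origin_shape required")
  H <- origin_shape[1]; W <- origin_shape[2]
  if (nrow(tokens) != H * W) stop("L must equal H * W")
  C <- ncol(tokens)
  v <- array(as.numeric(tokens), c(H * W, 1L, C))
  unbatch(ag_value(ag_unflatten(v, H, W)))
}

#' Create a bank of per-channel diagonal state-space parameters
#'
#' One independent linear recurrence of state size `state_dim` per channel.
#' Transition entries are drawn strictly inside (0, 1) for stability.
#'
#' @param channels number of channels `C`.
#' @param state_dim state size `N`.
#' @param seed integer seed for the random draw.
#' @return list with `(C, N)` matrices `a`, `b`, `c` and length-`C` vector `d`.
#' @export
ssm_params <- function(channels, state_dim, seed = 1L) {
  with_seed(seed, {
    list(
      a = matrix(stats::runif(channels * state_dim, 0.5, 0.95),
                 channels, state_dim),
      b = matrix(stats::rnorm(channels * state_dim, sd = 1 / sqrt(state_dim)),
                 channels, state_dim),
      c = matrix(stats::rnorm(channels * state_dim, sd = 1 / sqrt(state_dim)),
                 channels, state_dim),
      d = rep(1, channels)
    )
  })
}

#' Linear state-space scan over a token sequence
#'
#' Runs the per-channel recurrence `s_t = a s_(t-1) + b x_t`,
#' `y_t = c . s_t + d x_t` with `s_0 = 0` over all `L` tokens (exactly `L`
#' recurrence steps). The backward direction reverses the sequence, scans,
#' and reverses the output.
#'
#' @param tokens `(L, C)` matrix.
#' @param params list as returned by [ssm_params()].
#' @param direction `"forward"` or `"backward"`.
#' @return `(L, C)` matrix of outputs.
#' @export
ssm_scan <- function(tokens, params, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  tokens <- as.matrix(tokens)
  L <- nrow(tokens); C <- ncol(tokens)
  stopifnot(nrow(params$a) == C)
  if (any(params$a <= 0 | params$a >= 1))
    stop("transition entries must lie strictly inside (0, 1)")
  x <- array(tokens, c(L, 1L, C))
  if (direction == "backward") x <- x[seq.int(L, 1L), , , drop = FALSE]
  y <- ag_value(ag_ssm_scan(x, params$a, params$b, params$c, params$d))
  if (direction == "backward") y <- y[seq.int(L, 1L), , , drop = FALSE]
  matrix(y, L, C)
}

#' Bidirectional global feature extraction
#'
#' Flattens the map row-wise, scans forward and backward, concatenates the
#' two outputs along channels, applies a bias-free linear projection back to
#' `C` channels and restores the spatial layout.
#'
#' @param f numeric array `(H, W, C)`.
#' @param params_fwd,params_bwd state-space parameter banks ([ssm_params()]).
#' @param projection `(2C, C)` projection matrix.
#' @return numeric array `(H, W, C)`.
#' @export
bidirectional_global_extract <- function(f, params_fwd, params_bwd,
                                         projection) {
  d <- dim(f)
  projection <- as.matrix(projection)
  if (nrow(projection) != 2 * d[3] || ncol(projection) != d[3])
    stop("projection must map 2C -> C")
  tok <- flatten_rows(f)
  yf <- ssm_scan(tok, params_fwd, "forward")
  yb <- ssm_scan(tok, params_bwd, "backward")
  y <- cbind(yf, yb) %*% projection
  attr(y, "origin_shape") <- c(d[1], d[2])
  unflatten(y)
}

#' Channel attention weights for local/global fusion
#'
#' `alpha = sigmoid(GAP(F_local (+) F_global) W_att + b_att)` where `(+)` is
#' channel concatenation and GAP is the spatial mean per channel.
#'
#' @param f_local,f_global `(H, W, C)` arrays of identical shape.
#' @param w_att `(2C, C)` matrix; `b_att` length-`C` bias.
#' @return numeric vector of length `C`, entries in (0, 1).
#' @export
channel_attention <- function(f_local, f_global, w_att, b_att) {
  if (!identical(dim(f_local), dim(f_global)))
    stop("local and global maps must have the same shape")
  C <- dim(f_local)[3]
  w_att <- as.matrix(w_att)
  stopifnot(nrow(w_att) == 2 * C, ncol(w_att) == C)
  pooled <- c(apply(f_local, 3, mean), apply(f_global, 3, mean))
  as.numeric(1 / (1 + exp(-(pooled %*% w_att + b_att))))
}

#' Convex fusion of local and global features
#'
#' `F_fusion = alpha * F_local + (1 - alpha) * F_global`, with `alpha` either
#' a per-channel vector (broadcast over space) or an `(H, W)` map (broadcast
#' over channels).
#'
#' @param f_local,f_global `(H, W, C)` arrays.
#' @param alpha weights in `[0, 1]`.
#' @return numeric array `(H, W, C)`.
#' @export
fuse_features <- function(f_local, f_global, alpha) {
  if (!identical(dim(f_local), dim(f_global)))
    stop("local and global maps must have the same shape")
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  d <- dim(f_local)
  if (is.matrix(alpha)) {
    stopifnot(all(dim(alpha) == d[1:2]))
    ab <- array(rep(as.vector(alpha), d[3]), d)
  } else {
    stopifnot(length(alpha) == d[3])
    ab <- array(rep(alpha, each = d[1] * d[2]), d)
  }
  ab * f_local + (1 - ab) * f_global
}
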