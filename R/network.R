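# Full encoder-decoder assembly.
#
# Layout (default config, 224x224x3 input):
#   stem conv (3x3, stride 2, 3 -> 64)                 -> 112x112x64
#   encoder block 1 (64) | down (stride 2, 64 -> 128)  -> 56x56x128
#   encoder block 2      | down (128 -> 256)           -> 28x28x256
#   encoder block 3      | down (256 -> 512)           -> 14x14x512
#   encoder block 4 (bottleneck)                       -> 14x14x512
#   uncertainty map U = entropy(bottleneck)            -> 14x14
#   decoder block 4 (bottleneck refinement, 512)       -> 14x14x512
#   up (512 -> 256) [+ skip 3, 1x1 reduce] | block 3   -> 28x28x256
#   up (256 -> 128) [+ skip 2]             | block 2   -> 56x56x128
#   up (128 ->  64) [+ skip 1]             | block 1   -> 112x112x64
#   stem-mirror up (64 -> 64)                          -> 224x224x64
#   head: GAP -> dropout -> affine -> softmax; aux: 1x1 conv -> sigmoid.
#
# The printed bottleneck contract (14 x 14 x 512 from a 224 input) forces a
# total spatial reduction of 16, hence the stride-2 stem in addition to the
# three stride-2 downsamplings between the four encoder blocks; the decoder
# mirrors it with four blocks around three transposed-convolution
# upsamplings plus a final stem-mirror upsampling back to input resolution,
# so the classification head pools a full-resolution base-channel map.
#
# Each block fuses a depthwise-separable local branch with a bidirectional
# state-space global branch that consumes the local branch's output.
# Encoder blocks weight the fusion with channel attention; decoder blocks
# use the uncertainty-adjusted spatial weight alpha'(i,j) =
# alpha0 * exp(-lambda * U(i,j)) (broadcast over channels), with alpha0
# learnable per block through a sigmoid. Blocks are pre-norm with a
# residual connection.

#' Model configuration
#'
#' @param tile_size input side length; must be divisible by
#'   `2^n_levels` (stem + downsamplings).
#' @param base_channels channels after the stem (doubled at each of the
#'   three downsamplings; 64 gives the 64-128-256-512 schedule).
#' @param n_levels number of encoder blocks (fixed architecture depth 4).
#' @param state_dim state size of each per-channel recurrence.
#' @param num_classes output classes.
#' @param dropout dropout rate on the pooled vector before the classifier.
#' @param kernel depthwise kernel size (odd).
#' @param ud_lambda sensitivity of the uncertainty weight adjustment.
#' @param ud_eps entropy guard.
#' @return list of class `model_config`.
#' @export
model_config <- function(tile_size = 224L, base_channels = 64L,
                         n_levels = 4L, state_dim = 16L, num_classes = 2L,
                         dropout = 0.1, kernel = 3L, ud_lambda = 1.0,
                         ud_eps = 1e-8) {
  if (tile_size %% (2^n_levels) != 0)
    stop("tile_size must be divisible by 2^n_levels")
  if (n_levels != 4L)
    stop("this architecture is defined for 4 encoder levels")
  structure(list(tile_size = as.integer(tile_size),
                 base_channels = as.integer(base_channels),
                 n_levels = as.integer(n_levels),
                 state_dim = as.integer(state_dim),
                 num_classes = as.integer(num_classes),
                 dropout = dropout, kernel = as.integer(kernel),
                 ud_lambda = ud_lambda, ud_eps = ud_eps),
            class = "model_config")
}

#' Tiny desk-scale configuration used by tests and examples
#' @param tile_size,base_channels,state_dim see [model_config()].
#' @export
tiny_config <- function(tile_size = 64L, base_channels = 8L,
                        state_dim = 8L) {
  model_config(tile_size = tile_size, base_channels = base_channels,
               state_dim = state_dim)
}

inv_softplus <- function(y) log(expm1(y))

init_block <- function(P, name, C, N, k, local, attention, alpha0) {
  rn <- function(d, sd) array(stats::rnorm(prod(d), 0, sd), d)
  P[[paste0(name, ".ln.gamma")]] <- rep(1, C)
  P[[paste0(name, ".ln.beta")]] <- rep(0, C)
  if (local) {
    P[[paste0(name, ".dw.K")]] <- rn(c(k, k, C), sqrt(2 / (k * k)))
    P[[paste0(name, ".dw.b")]] <- rep(0, C)
    P[[paste0(name, ".pw.W")]] <- rn(c(1, 1, C, C), sqrt(2 / C))
    P[[paste0(name, ".pw.b")]] <- rep(0, C)
  }
  for (dir in c("f", "b")) {
    a0 <- matrix(stats::runif(C * N, 0.5, 0.95), C, N)
    P[[paste0(name, ".ssm.ahat_", dir)]] <- inv_softplus(-log(a0))
    P[[paste0(name, ".ssm.b_", dir)]] <- rn(c(C, N), 1 / sqrt(N))
    P[[paste0(name, ".ssm.c_", dir)]] <- rn(c(C, N), 1 / sqrt(N))
    P[[paste0(name, ".ssm.d_", dir)]] <- rep(1, C)
  }
  P[[paste0(name, ".proj.W")]] <- rn(c(2 * C, C), 1 / sqrt(2 * C))
  if (attention) {
    P[[paste0(name, ".att.W")]] <- rn(c(2 * C, C), 1 / sqrt(2 * C))
    P[[paste0(name, ".att.b")]] <- rep(0, C)
  }
  if (alpha0) {
    P[[paste0(name, ".alpha0_raw")]] <- 0   # sigmoid(0) = 0.5
  }
  P
}

#' Build a model
#'
#' @param config a [model_config()].
#' @param seed seed for weight initialization.
#' @param variant ablation variant 1..5 (see [make_variant()]).
#' @param decoder_mode override for the decoder fusion weighting: `"ud"`
#'   (uncertainty-adjusted), `"channel"` (channel attention, the `--no-ud`
#'   setting) or `"fixed"` (constant 0.5).
#' @return object of class `histomamba_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L, variant = 1L,
                        decoder_mode = NULL) {
  stopifnot(inherits(config, "model_config"))
  variant <- as.integer(variant)
  if (!variant %in% 1:5) stop("unknown variant: ", variant)
  arch <- list(
    local_branch = !(variant %in% c(3L, 5L)),
    skips = variant != 4L,
    decoder_mode = if (variant %in% c(2L, 5L)) "fixed" else "ud",
    use_ual = !(variant %in% c(2L, 5L)),
    variant = variant
  )
  if (!is.null(decoder_mode)) {
    arch$decoder_mode <- match.arg(decoder_mode, c("ud", "channel", "fixed"))
    if (arch$decoder_mode != "ud") arch$use_ual <- arch$decoder_mode == "channel"
  }
  cfg <- config
  ch <- cfg$base_channels * 2^(0:(cfg$n_levels - 1))
  N <- cfg$state_dim; k <- cfg$kernel
  P <- with_seed(seed, {
    P <- list()
    rn <- function(d, sd) array(stats::rnorm(prod(d), 0, sd), d)
    P[["stem.W"]] <- rn(c(k, k, 3, ch[1]), sqrt(2 / (k * k * 3)))
    P[["stem.b"]] <- rep(0, ch[1])
    for (l in 1:4) {
      P <- init_block(P, paste0("enc", l), ch[l], N, k,
                      local = arch$local_branch, attention = TRUE,
                      alpha0 = FALSE)
      if (l < 4) {
        P[[paste0("down", l, ".W")]] <- rn(c(k, k, ch[l], ch[l + 1]),
                                           sqrt(2 / (k * k * ch[l])))
        P[[paste0("down", l, ".b")]] <- rep(0, ch[l + 1])
      }
    }
    P <- init_block(P, "dec4", ch[4], N, k,
                    local = arch$local_branch,
                    attention = arch$decoder_mode == "channel",
                    alpha0 = arch$decoder_mode == "ud")
    for (l in 3:1) {
      P[[paste0("up", l, ".W")]] <- rn(c(2, 2, ch[l + 1], ch[l]),
                                       sqrt(2 / (4 * ch[l + 1])))
      P[[paste0("up", l, ".b")]] <- rep(0, ch[l])
      if (arch$skips) {
        P[[paste0("skipred", l, ".W")]] <- rn(c(1, 1, 2 * ch[l], ch[l]),
                                              sqrt(2 / (2 * ch[l])))
        P[[paste0("skipred", l, ".b")]] <- rep(0, ch[l])
      }
      P <- init_block(P, paste0("dec", l), ch[l], N, k,
                      local = arch$local_branch,
                      attention = arch$decoder_mode == "channel",
                      alpha0 = arch$decoder_mode == "ud")
    }
    P[["up0.W"]] <- rn(c(2, 2, ch[1], ch[1]), sqrt(2 / (4 * ch[1])))
    P[["up0.b"]] <- rep(0, ch[1])
    P[["head.W"]] <- rn(c(ch[1], cfg$num_classes), 1 / sqrt(ch[1]))
    P[["head.b"]] <- rep(0, cfg$num_classes)
    P[["aux.W"]] <- rn(c(1, 1, ch[1], 1), 1 / sqrt(ch[1]))
    P[["aux.b"]] <- 0
    P
  })
  structure(list(config = cfg, arch = arch, params = P, channels = ch,
                 seed = seed),
            class = "histomamba_model")
}

#' Build an ablation variant
#'
#' 1 = full model; 2 = no uncertainty adjustment (fixed decoder fusion
#' weight 0.5, no calibration loss); 3 = state-space-only blocks (local
#' branch removed); 4 = no skip connections; 5 = 2 and 3 combined.
#'
#' @param config a [model_config()].
#' @param variant integer 1..5.
#' @param seed weight-initialization seed.
#' @export
make_variant <- function(config, variant, seed = 1L) {
  build_model(config, seed = seed, variant = variant)
}

#' Number of learnable parameters
#' @param model a `histomamba_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

## ---- forward graph -------------------------------------------------------

block_forward <- function(P, name, x, cfg, arch, alpha_map = NULL,
                          fixed_alpha = NULL) {
  g <- function(suffix) P[[paste0(name, ".", suffix)]]
  h <- ag_layernorm(x, g("ln.gamma"), g("ln.beta"))
  local <- if (arch$local_branch) {
    ag_gelu(ag_conv2d(ag_depthwise_conv(h, g("dw.K"), g("dw.b")),
                      g("pw.W"), g("pw.b"), stride = 1L, pad = 0L))
  } else {
    h
  }
  d <- dim(ag_value(local))
  tok <- ag_flatten_rows(local)
  mk_a <- function(dir) ag_exp(ag_scale(ag_softplus(g(paste0("ssm.ahat_", dir))), -1))
  yf <- ag_ssm_scan(tok, mk_a("f"), g("ssm.b_f"), g("ssm.c_f"), g("ssm.d_f"))
  xr <- ag_reverse_seq(tok)
  yb <- ag_reverse_seq(ag_ssm_scan(xr, mk_a("b"), g("ssm.b_b"),
                                   g("ssm.c_b"), g("ssm.d_b")))
  y2 <- ag_concat_last(yf, yb)                       # (L, B, 2C)
  L <- d[1] * d[2]
  ym <- ag_reshape(y2, c(L * d[3], 2 * d[4]))
  yp <- ag_dense(ym, g("proj.W"))
  global <- ag_unflatten(ag_reshape(yp, c(L, d[3], d[4])), d[1], d[2])
  if (!is.null(fixed_alpha)) {
    fused <- ag_add(ag_scale(local, fixed_alpha),
                    ag_scale(global, 1 - fixed_alpha))
  } else if (!is.null(alpha_map)) {
    fused <- ag_add(ag_mul_spatial(local, alpha_map),
                    ag_mul_spatial(global, ag_one_minus(alpha_map)))
  } else {
    pooled <- ag_concat_last(ag_gap(local), ag_gap(global))   # (B, 2C)
    alpha <- ag_sigmoid(ag_dense(pooled, g("att.W"), g("att.b")))
    fused <- ag_add(ag_mul_channel(local, alpha),
                    ag_mul_channel(global, ag_one_minus(alpha)))
  }
  ag_add(x, fused)
}

decoder_alpha <- function(P, name, U, h, w, cfg, arch) {
  switch(arch$decoder_mode,
    ud = {
      a0 <- ag_sigmoid(as_node(P[[paste0(name, ".alpha0_raw")]]))
      ul <- ag_bilinear_resize(U, h, w)
      list(alpha_map = ag_mul_scalar(ag_exp(ag_scale(ul, -cfg$ud_lambda)), a0),
           fixed_alpha = NULL)
    },
    channel = list(alpha_map = NULL, fixed_alpha = NULL),
    fixed = list(alpha_map = NULL, fixed_alpha = 0.5)
  )
}

# builds the full graph; x is an (H, W, B, 3) array or node
model_graph <- function(model, x, training = FALSE) {
  cfg <- model$config; arch <- model$arch
  P <- lapply(model$params, ag_leaf)
  xs <- ag_gelu(ag_conv2d(x, P[["stem.W"]], P[["stem.b"]],
                          stride = 2L, pad = (cfg$kernel - 1L) %/% 2L))
  enc <- vector("list", 4L)
  h <- xs
  for (l in 1:4) {
    h <- block_forward(P, paste0("enc", l), h, cfg, arch)
    enc[[l]] <- h
    if (l < 4) {
      h <- ag_gelu(ag_conv2d(h, P[[paste0("down", l, ".W")]],
                             P[[paste0("down", l, ".b")]],
                             stride = 2L, pad = (cfg$kernel - 1L) %/% 2L))
    }
  }
  U <- ag_entropy_map(enc[[4]], eps = cfg$ud_eps)     # (H/16, W/16, B)
  dd <- dim(ag_value(h))
  aw <- decoder_alpha(P, "dec4", U, dd[1], dd[2], cfg, arch)
  d <- block_forward(P, "dec4", h, cfg, arch,
                     alpha_map = aw$alpha_map, fixed_alpha = aw$fixed_alpha)
  for (l in 3:1) {
    d <- ag_conv2d_transpose2(d, P[[paste0("up", l, ".W")]],
                              P[[paste0("up", l, ".b")]])
    if (arch$skips) {
      d <- ag_conv2d(ag_concat_last(d, enc[[l]]),
                     P[[paste0("skipred", l, ".W")]],
                     P[[paste0("skipred", l, ".b")]],
                     stride = 1L, pad = 0L)
    }
    dd <- dim(ag_value(d))
    aw <- decoder_alpha(P, paste0("dec", l), U, dd[1], dd[2], cfg, arch)
    d <- block_forward(P, paste0("dec", l), d, cfg, arch,
                       alpha_map = aw$alpha_map, fixed_alpha = aw$fixed_alpha)
  }
  d <- ag_gelu(ag_conv2d_transpose2(d, P[["up0.W"]], P[["up0.b"]]))
  pooled <- ag_gap(d)                                  # (B, C1)
  pooled <- ag_dropout(pooled, cfg$dropout, training = training)
  logits <- ag_dense(pooled, P[["head.W"]], P[["head.b"]])
  pmap4 <- ag_sigmoid(ag_conv2d(d, P[["aux.W"]], P[["aux.b"]],
                                stride = 1L, pad = 0L))
  ddp <- dim(ag_value(pmap4))
  pmap <- ag_reshape(pmap4, ddp[1:3])                  # (H, W, B)
  list(P = P, logits = logits, U = U, pmap = pmap, bottleneck = enc[[4]],
       pooled = pooled)
}

tiles_to_array <- function(tiles) {
  if (inherits(tiles, "rgb_tile")) tiles <- list(tiles)
  if (is.list(tiles)) {
    d <- dim(tiles[[1]]$pixels)
    x <- array(0, c(d[1], d[2], length(tiles), 3L))
    for (i in seq_along(tiles)) x[, , i, ] <- tiles[[i]]$pixels
    x
  } else {
    d <- dim(tiles)
    if (length(d) == 3L) as_batched(tiles)[, , 1L, , drop = FALSE] else tiles
  }
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' Run the model on tiles (inference)
#'
#' @param model a `histomamba_model`.
#' @param tiles an [rgb_tile()], a list of them, or an `(H, W, B, 3)` array
#'   with `H = W = config$tile_size`.
#' @return list: `class_probabilities` (B x num_classes, rows sum to 1),
#'   `predicted` (0/1), `uncertainty_map` (bottleneck resolution, `(h, w,
#'   B)`), `local_prob_map` (`(H, W, B)` in `[0, 1]`).
#' @export
model_forward <- function(model, tiles) {
  x <- tiles_to_array(tiles)
  d <- dim(x)
  if (d[1] != model$config$tile_size || d[2] != model$config$tile_size)
    stop("input spatial size must equal config$tile_size")
  gr <- model_graph(model, x, training = FALSE)
  probs <- softmax_rows(ag_value(gr$logits))
  list(class_probabilities = probs,
       predicted = as.integer(probs[, 2] > probs[, 1]),
       uncertainty_map = ag_value(gr$U),
       local_prob_map = ag_value(gr$pmap))
}
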