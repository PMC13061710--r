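# small shared helpers

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a child seed from a base seed and an index, kept within 32-bit range
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483587) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# bilinear resize of an (H, W) matrix or (H, W, C) array (endpoint-aligned)
bilinear_resize <- function(x, out_h, out_w) {
  d <- dim(x)
  was_matrix <- length(d) == 2L
  if (was_matrix) dim(x) <- c(d[1], d[2], 1L)
  d <- dim(x)
  Rh <- lin_interp_matrix(d[1], out_h)
  Rw <- lin_interp_matrix(d[2], out_w)
  m <- x
  dim(m) <- c(d[1], d[2] * d[3])
  m <- Rh %*% m
  dim(m) <- c(out_h, d[2], d[3])
  m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(d[2], out_h * d[3])
  m <- Rw %*% m
  dim(m) <- c(out_w, out_h, d[3])
  out <- aperm(m, c(2, 1, 3))
  if (was_matrix) dim(out) <- c(out_h, out_w)
  out
}

# promote a single (H, W, C) map to the internal batched (H, W, 1, C) layout
as_batched <- function(f) {
  d <- dim(f)
  stopifnot(length(d) == 3L)
  array(f, c(d[1], d[2], 1L, d[3]))
}

unbatch <- function(f) {
  d <- dim(f)
  array(f, c(d[1], d[2], d[4]))
}
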