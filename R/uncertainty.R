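# Entropy-based uncertainty estimation and dynamic fusion-weight adjustment.
#
# The uncertainty of an intermediate feature map is the per-position Shannon
# entropy (natural log) of the normalized squared channel intensities:
#   p_c(i,j) = (F(i,j,c)^2 + eps) / (sum_c' F(i,j,c')^2 + C*eps)
#   U(i,j)   = -sum_c p_c log p_c            (0 <= U <= log C)
# The small eps guards the all-zero vector, which then yields the uniform
# distribution and hence maximal uncertainty: zero activations carry no
# evidence. The decoder fusion weight is lowered where uncertainty is high:
#   alpha'(i,j) = alpha0 * exp(-lambda * U(i,j)).

#' Per-position entropy of a feature map
#'
#' @param f_enc numeric array `(H, W, C)` with finite entries.
#' @param eps nonnegative guard added to each squared intensity.
#' @return `(H, W)` matrix, entries in `[0, log(C)]`.
#' @export
feature_entropy <- function(f_enc, eps = 1e-8) {
  d <- dim(f_enc)
  stopifnot(length(d) == 3L)
  if (!all(is.finite(f_enc))) stop("feature map must be finite")
  u <- ag_value(ag_entropy_map(as_batched(f_enc), eps = eps))
  matrix(u, d[1], d[2])
}

#' Resize an uncertainty map to a target resolution
#'
#' Bilinear (endpoint-aligned) interpolation; output values stay inside the
#' range of the input.
#'
#' @param u `(H, W)` matrix.
#' @param target integer `c(H2, W2)`.
#' @return `(H2, W2)` matrix.
#' @export
resize_uncertainty <- function(u, target) {
  stopifnot(length(target) == 2L, all(target >= 1))
  bilinear_resize(as.matrix(u), target[1], target[2])
}

#' Parameters of the dynamic weight adjustment
#'
#' @param alpha0 base attention weight in (0, 1); initialized at 0.5 and
#'   learnable inside the network.
#' @param lambda positive sensitivity of the weight to uncertainty.
#' @export
ud_params <- function(alpha0 = 0.5, lambda = 1.0) {
  if (!(alpha0 > 0 && alpha0 < 1)) stop("alpha0 must lie in (0, 1)")
  if (lambda <= 0) stop("lambda must be positive")
  list(alpha0 = alpha0, lambda = lambda)
}

#' Uncertainty-adjusted fusion weight map
#'
#' `alpha'(i,j) = alpha0 * exp(-lambda * U(i,j))`: equal to `alpha0` where
#' uncertainty is zero, strictly decreasing in uncertainty.
#'
#' @param u nonnegative uncertainty map (matrix).
#' @param params list from [ud_params()].
#' @return matrix of weights in `(0, alpha0]`.
#' @export
adjust_weight <- function(u, params = ud_params()) {
  if (is.null(params$lambda) || params$lambda <= 0)
    stop("lambda must be positive")
  if (any(u < 0)) stop("uncertainty must be nonnegative")
  params$alpha0 * exp(-params$lambda * u)
}
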