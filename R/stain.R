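# Macenko stain separation and standardization for H&E tiles.
#
# Pixels and stains interact through the Beer-Lambert law: optical density
# OD = -log10(I / I0) is linear in stain concentration, OD = M %*% conc,
# where M is the 3x2 matrix of unit stain color vectors (hematoxylin,
# eosin). The stain matrix of a tile is estimated from the principal plane
# of its above-threshold OD pixels, taking the extreme-angle directions at a
# small percentile; normalization re-renders the tile's concentrations
# through a reference stain profile.

degenerate_stain_error <- function(msg) {
  stop(errorCondition(msg,
                      class = c("histomamba_degenerate_stain", "error")))
}

#' Construct an RGB tile
#'
#' @param pixels numeric array `(H, W, 3)` with values in `[0, 1]`.
#' @param label 0 (normal) or 1 (abnormal), or NA.
#' @param patient_id,tile_id identifier strings.
#' @return object of class `rgb_tile`.
#' @export
rgb_tile <- function(pixels, label = NA_integer_, patient_id = NA_character_,
                     tile_id = NA_character_) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L, d[3] == 3L)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixels must lie in [0, 1]")
  structure(list(pixels = pixels, label = label,
                 patient_id = patient_id, tile_id = tile_id),
            class = "rgb_tile")
}

tile_pixels <- function(x) if (inherits(x, "rgb_tile")) x$pixels else x

#' RGB to optical density
#'
#' `OD = -log10((I + eps) / I0)`, clipped at zero so background pixels at
#' the illumination intensity map to exactly 0. Monotone decreasing in pixel
#' intensity.
#'
#' @param tile an `rgb_tile` or `(H, W, 3)` array.
#' @param background_intensity illumination level `I0` (> 0); 1 for pixels
#'   scaled to `[0, 1]`, 255 for 8-bit integer data.
#' @param eps guard added to the intensity before the log.
#' @return `(H, W, 3)` array of nonnegative optical densities.
#' @export
rgb_to_od <- function(tile, background_intensity = 1,
                      eps = background_intensity * 1e-6) {
  if (background_intensity <= 0)
    stop("background_intensity must be positive")
  px <- tile_pixels(tile)
  pmax(-log10((px + eps) / background_intensity), 0)
}

#' Optical density back to RGB
#'
#' @param od `(H, W, 3)` array of optical densities.
#' @inheritParams rgb_to_od
#' @return `(H, W, 3)` array of intensities in `[0, background_intensity]`.
#' @export
od_to_rgb <- function(od, background_intensity = 1) {
  clamp(background_intensity * 10^(-od), 0, background_intensity)
}

order_stain_columns <- function(M) {
  # convention: hematoxylin (column 1) has the larger blue-channel OD
  if (M[3, 1] >= M[3, 2]) M else M[, 2:1]
}

#' Estimate the stain matrix of a tile (Macenko)
#'
#' Keeps OD pixels whose Euclidean norm exceeds `od_threshold`, finds the
#' two principal directions of the (uncentered) OD cloud, and returns the
#' unit vectors at the extreme angles (`angle_percentile` and
#' `100 - angle_percentile`) of the projections in that plane.
#'
#' @param od `(H, W, 3)` optical-density array (or `(n, 3)` pixel matrix).
#' @param od_threshold transparency threshold on OD magnitude.
#' @param angle_percentile percentile in (0, 50) for the extreme angles.
#' @return 3x2 matrix with unit columns (hematoxylin, eosin).
#' @export
estimate_stain_matrix <- function(od, od_threshold = 0.15,
                                  angle_percentile = 1.0) {
  if (!(angle_percentile > 0 && angle_percentile < 50))
    stop("angle_percentile must lie in (0, 50)")
  X <- od
  if (length(dim(X)) == 3L) {
    d <- dim(X)
    X <- matrix(X, d[1] * d[2], 3L)
  }
  keep <- sqrt(rowSums(X^2)) > od_threshold
  if (sum(keep) < 2L)
    degenerate_stain_error("fewer than 2 pixels above the OD threshold")
  X <- X[keep, , drop = FALSE]
  eg <- eigen(crossprod(X), symmetric = TRUE)
  if (eg$values[2] <= eg$values[1] * 1e-9)
    degenerate_stain_error("rank-deficient OD cloud (single stain direction)")
  V <- eg$vectors[, 1:2, drop = FALSE]
  # orient the plane so projections land in a consistent half-space
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]
  if (sum(V[, 2]) < 0) V[, 2] <- -V[, 2]
  pr <- X %*% V
  phi <- atan2(pr[, 2], pr[, 1])
  qs <- stats::quantile(phi, c(angle_percentile, 100 - angle_percentile) / 100,
                        names = FALSE)
  mk <- function(a) {
    v <- V %*% c(cos(a), sin(a))
    if (sum(v) < 0) v <- -v
    v / sqrt(sum(v^2))
  }
  M <- cbind(mk(qs[1]), mk(qs[2]))
  order_stain_columns(M)
}

#' Reference stain profile
#'
#' A stain profile is a target stain matrix together with reference
#' high-percentile concentrations per stain, the fixed point of
#' [normalize_stains()].
#'
#' @param stain_matrix 3x2 matrix with unit, linearly independent columns.
#' @param concentration_scale two positive reference concentrations.
#' @return object of class `stain_profile`.
#' @export
stain_profile <- function(stain_matrix, concentration_scale = c(1.5, 1.0)) {
  stain_matrix <- as.matrix(stain_matrix)
  stopifnot(all(dim(stain_matrix) == c(3L, 2L)))
  nrm <- sqrt(colSums(stain_matrix^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("stain columns must be unit norm")
  if (any(concentration_scale <= 0))
    stop("concentration_scale must be positive")
  structure(list(stain_matrix = order_stain_columns(stain_matrix),
                 concentration_scale = as.numeric(concentration_scale)),
            class = "stain_profile")
}

#' Default H&E reference profile
#'
#' The widely used reference stain vectors (hematoxylin then eosin), unit
#' normalized.
#' @return a [stain_profile()].
#' @export
default_stain_profile <- function() {
  M <- cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  stain_profile(M, c(1.5, 1.0))
}

#' Stain concentrations by least squares
#'
#' Solves `OD = M %*% conc` per pixel in the least-squares sense and clips
#' negative concentrations at zero.
#'
#' @param od `(H, W, 3)` array or `(n, 3)` matrix.
#' @param stain_matrix 3x2 stain matrix.
#' @return `(n, 2)` matrix of nonnegative concentrations.
#' @export
stain_concentrations <- function(od, stain_matrix) {
  X <- od
  if (length(dim(X)) == 3L) X <- matrix(X, prod(dim(X)[1:2]), 3L)
  conc <- X %*% stain_matrix %*% solve(crossprod(stain_matrix))
  pmax(conc, 0)
}

#' Macenko stain normalization of a tile
#'
#' Estimates the tile's own stain matrix, extracts per-pixel concentrations,
#' rescales them so their 99th percentile matches the target profile's
#' reference concentrations (with floor `regularization`), and re-renders
#' through the target stain matrix. Tiles that do not admit stain estimation
#' (e.g. pure background) pass through unchanged with a warning.
#'
#' @param tile `rgb_tile` (or `(H, W, 3)` array) with pixels in `[0, 1]`.
#' @param target a [stain_profile()].
#' @param od_threshold transparency threshold on OD magnitude.
#' @param angle_percentile extreme-angle percentile.
#' @param regularization floor on the per-stain concentration scale.
#' @param conc_percentile percentile defining the concentration scale.
#' @param background_intensity illumination level for the OD transform.
#' @return object of the same type as `tile`, same pixel range.
#' @export
normalize_stains <- function(tile, target = default_stain_profile(),
                             od_threshold = 0.15, angle_percentile = 1.0,
                             regularization = 0.01, conc_percentile = 99,
                             background_intensity = 1) {
  px <- tile_pixels(tile)
  d <- dim(px)
  od <- rgb_to_od(px, background_intensity)
  M <- tryCatch(
    estimate_stain_matrix(od, od_threshold, angle_percentile),
    histomamba_degenerate_stain = function(e) NULL
  )
  if (is.null(M)) {
    warning("tile does not admit stain estimation; passing through unchanged")
    return(tile)
  }
  conc <- stain_concentrations(od, M)
  sc <- apply(conc, 2, stats::quantile, probs = conc_percentile / 100,
              names = FALSE)
  sc <- pmax(sc, regularization)
  conc <- sweep(conc, 2, target$concentration_scale / sc, "*")
  od2 <- conc %*% t(target$stain_matrix)
  out <- od_to_rgb(array(od2, d), background_intensity)
  if (inherits(tile, "rgb_tile")) {
    tile$pixels <- out
    tile
  } else {
    out
  }
}

#' Per-column angular error between two stain matrices (degrees)
#'
#' Columns are matched by the blue-channel ordering convention; sign is
#' ignored.
#' @param m1,m2 3x2 stain matrices.
#' @return numeric length-2 vector of angles in degrees.
#' @export
stain_angle_error <- function(m1, m2) {
  m1 <- order_stain_columns(as.matrix(m1))
  m2 <- order_stain_columns(as.matrix(m2))
  vapply(1:2, function(j) {
    a <- m1[, j] / sqrt(sum(m1[, j]^2))
    b <- m2[, j] / sqrt(sum(m2[, j]^2))
    acos(clamp(abs(sum(a * b)), 0, 1)) * 180 / pi
  }, numeric(1))
}

#' Read / write a stain profile as JSON
#'
#' @param profile a [stain_profile()].
#' @param path file path.
#' @name stain_profile_io
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(
    list(stain_matrix = unclass(profile$stain_matrix),
         concentration_scale = profile$concentration_scale),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' @rdname stain_profile_io
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_profile(matrix(unlist(x$stain_matrix), 3, 2),
                as.numeric(x$concentration_scale))
}

#' Read / write image tiles
#'
#' PNG is the native format; JPEG/TIFF are read when the corresponding
#' package is installed. Pixels are returned in `[0, 1]`.
#'
#' @param path file path (`.png`, `.jpg`/`.jpeg`).
#' @name tile_io
#' @export
read_tile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("package 'jpeg' required to read JPEG tiles")
      jpeg::readJPEG(path)
    },
    stop("unsupported tile format: ", ext)
  )
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px
}

#' @rdname tile_io
#' @param pixels `(H, W, 3)` array in `[0, 1]` (or an `rgb_tile`).
#' @export
write_tile <- function(pixels, path) {
  px <- clamp(tile_pixels(pixels), 0, 1)
  png::writePNG(px, path)
  invisible(path)
}
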