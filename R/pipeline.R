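# Patient-independent splitting, minority oversampling, training-time
# augmentation, and manifest I/O.

#' Patient-independent train/val/test split
#'
#' Whole patients are assigned to exactly one subset by a greedy randomized
#' rule: patients are visited in a seeded random order and each goes to the
#' subset with the largest remaining tile deficit relative to its target
#' fraction. No patient ever appears in two subsets.
#'
#' @param manifest data.frame with columns `patient_id` and `tile_id` (one
#'   row per tile).
#' @param fractions length-3 numeric (train, val, test) summing to 1.
#' @param seed integer seed controlling the patient order.
#' @return data.frame of class `split_manifest` (patient_id, subset) with
#'   attributes `fractions` and `seed`.
#' @export
patient_independent_split <- function(manifest,
                                      fractions = c(0.70, 0.15, 0.15),
                                      seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  pats <- unique(manifest$patient_id)
  subsets <- c("train", "val", "test")
  if (length(pats) < length(subsets))
    stop("need at least as many patients as subsets")
  counts <- table(factor(manifest$patient_id, levels = pats))
  total <- sum(counts)
  target <- fractions * total
  assigned <- c(train = 0, val = 0, test = 0)
  ord <- with_seed(seed, sample(seq_along(pats)))
  out <- character(length(pats))
  for (i in ord) {
    deficit <- target - assigned
    s <- which.max(deficit)
    out[i] <- subsets[s]
    assigned[s] <- assigned[s] + counts[[i]]
  }
  structure(data.frame(patient_id = pats, subset = out,
                       stringsAsFactors = FALSE),
            class = c("split_manifest", "data.frame"),
            fractions = fractions, seed = seed)
}

#' Attach subset assignments to a tile manifest
#'
#' @param manifest tile-level data.frame with `patient_id`.
#' @param split a [patient_independent_split()] result.
#' @return the manifest with a `subset` column.
#' @export
apply_split <- function(manifest, split) {
  idx <- match(manifest$patient_id, split$patient_id)
  if (anyNA(idx)) stop("manifest contains patients absent from the split")
  manifest$subset <- split$subset[idx]
  manifest
}

#' Equalize class counts by oversampling the minority class
#'
#' Duplicates minority-class rows by seeded sampling with replacement until
#' both classes have the majority count; majority rows are untouched.
#'
#' @param x data.frame with a `label` column (0/1), or a list of
#'   [rgb_tile()] objects.
#' @param seed integer seed.
#' @return object of the same type as `x`, classes balanced.
#' @export
oversample_minority <- function(x, seed = 1L) {
  labels <- if (is.data.frame(x)) x$label
            else vapply(x, function(t) t$label, numeric(1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  if (n0 == n1) return(x)
  minority <- if (n0 < n1) 0 else 1
  min_idx <- which(labels == minority)
  extra <- with_seed(seed, min_idx[sample.int(length(min_idx),
                                              abs(n0 - n1), replace = TRUE)])
  if (is.data.frame(x)) {
    rbind(x, x[extra, , drop = FALSE])
  } else {
    c(x, x[extra])
  }
}

#' Augmentation parameters
#'
#' @param crop logical; random crop to a scale in `crop_scale` then resize
#'   back.
#' @param crop_scale range of the crop scale.
#' @param flip_h,flip_v flip probabilities.
#' @param rotate one of `"none"`, `"right-angle"` (multiples of 90 degrees,
#'   no interpolation) or `"arbitrary"` (bilinear, white fill).
#' @param noise_sd sd of additive Gaussian pixel noise (0 disables).
#' @export
augment_params <- function(crop = TRUE, crop_scale = c(0.8, 1.0),
                           flip_h = 0.5, flip_v = 0.5,
                           rotate = c("right-angle", "arbitrary", "none"),
                           noise_sd = 0.01) {
  list(crop = crop, crop_scale = crop_scale, flip_h = flip_h,
       flip_v = flip_v, rotate = match.arg(rotate), noise_sd = noise_sd)
}

rotate_bilinear <- function(px, angle, fill = 1) {
  d <- dim(px)
  H <- d[1]; W <- d[2]
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  th <- angle * pi / 180
  ii <- matrix(seq_len(H) - ci, H, W)
  jj <- matrix(seq_len(W) - cj, H, W, byrow = TRUE)
  si <- cos(th) * ii - sin(th) * jj + ci
  sj <- sin(th) * ii + cos(th) * jj + cj
  i0 <- floor(si); j0 <- floor(sj)
  wi <- si - i0; wj <- sj - j0
  out <- array(fill, d)
  gv <- function(i, j, ch) {
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    v <- matrix(fill, H, W)
    v[ok] <- px[cbind(i[ok], j[ok], ch)]
    v
  }
  for (ch in seq_len(d[3])) {
    out[, , ch] <-
      gv(i0, j0, ch) * (1 - wi) * (1 - wj) +
      gv(i0 + 1, j0, ch) * wi * (1 - wj) +
      gv(i0, j0 + 1, ch) * (1 - wi) * wj +
      gv(i0 + 1, j0 + 1, ch) * wi * wj
  }
  out
}

#' Randomly augment a tile
#'
#' Applies, in order: random crop-and-resize, horizontal/vertical flips,
#' rotation, additive Gaussian noise, then clipping to `[0, 1]`. Label and
#' patient identity are unchanged. With all transforms disabled the tile is
#' returned exactly.
#'
#' @param tile an [rgb_tile()] (or `(H, W, 3)` array).
#' @param params an [augment_params()] list.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @return object of the same type as `tile`.
#' @export
augment_tile <- function(tile, params = augment_params(), seed = NULL) {
  run <- function() {
    px <- tile_pixels(tile)
    d <- dim(px)
    if (isTRUE(params$crop)) {
      s <- stats::runif(1, params$crop_scale[1], params$crop_scale[2])
      h2 <- max(2L, round(s * d[1])); w2 <- max(2L, round(s * d[2]))
      i0 <- sample.int(d[1] - h2 + 1L, 1L)
      j0 <- sample.int(d[2] - w2 + 1L, 1L)
      px <- bilinear_resize(px[i0:(i0 + h2 - 1L), j0:(j0 + w2 - 1L), ,
                               drop = FALSE], d[1], d[2])
    }
    if (params$flip_h > 0 && stats::runif(1) < params$flip_h)
      px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    if (params$flip_v > 0 && stats::runif(1) < params$flip_v)
      px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    if (params$rotate == "right-angle") {
      k <- sample(0:3, 1L)
      for (r in seq_len(k)) {
        px <- aperm(px, c(2, 1, 3))[rev(seq_len(dim(px)[2])), , ,
                                    drop = FALSE]
      }
    } else if (params$rotate == "arbitrary") {
      px <- rotate_bilinear(px, stats::runif(1, 0, 360))
    }
    if (params$noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, params$noise_sd)
    }
    px <- clamp(px, 0, 1)
    if (inherits(tile, "rgb_tile")) {
      tile$pixels <- px
      tile
    } else {
      px
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Read / write tile manifests and split tables
#'
#' Plain CSV round trip for `manifest.csv` (tile_id, patient_id, label,
#' path) and `splits.csv` (patient_id, subset).
#'
#' @param manifest,split data.frames.
#' @param path CSV path.
#' @name manifest_io
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname manifest_io
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(tile_id = "character",
                                 patient_id = "character"))
}

#' @rdname manifest_io
#' @export
write_split <- function(split, path) {
  utils::write.csv(as.data.frame(split), path, row.names = FALSE)
  invisible(path)
}

#' @rdname manifest_io
#' @export
read_split <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character"))
}
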