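# Synthetic H&E tile simulator with patient structure.
#
# Tiles are rendered through the Beer-Lambert law: two nonnegative
# concentration maps (hematoxylin-like nuclear material, eosin-like stroma)
# are combined through a patient-specific stain matrix,
# I = 10^(-M %*% conc), so the stain-estimation module can be validated
# against the generating matrix. Class morphology follows the tissue types
# the model is meant to separate:
#   normal (label 0)  : gland rings of regularly sized, regularly spaced
#                       nuclei around an empty lumen, low nucleus-size
#                       variance;
#   abnormal (label 1): crowded, irregular clusters of pleomorphic nuclei
#                       (high size variance, random eccentricity and
#                       orientation), no glandular organisation.
# Every patient carries one perturbed stain matrix (a small random 3-D
# rotation of the reference vectors) shared by all of its tiles, emulating
# per-site staining and scanner variation.

random_rotation3 <- function(angle_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Perturb a stain matrix by a small random rotation
#'
#' @param base 3x2 stain matrix (defaults to the reference H&E vectors).
#' @param sd_deg standard deviation of the rotation angle in degrees.
#' @return 3x2 unit-column stain matrix.
#' @export
jitter_stain_matrix <- function(base = default_stain_profile()$stain_matrix,
                                sd_deg = 3) {
  R <- random_rotation3(stats::rnorm(1, 0, sd_deg))
  M <- R %*% base
  M <- pmax(M, 1e-4)              # stay in the nonnegative OD octant
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  order_stain_columns(M)
}

# draw a soft ellipse into `canvas` (matrix), returning the updated matrix
draw_nucleus <- function(canvas, cx, cy, rx, ry, theta, amp) {
  S <- nrow(canvas)
  r <- max(rx, ry)
  i0 <- max(1L, floor(cx - r - 1)); i1 <- min(S, ceiling(cx + r + 1))
  j0 <- max(1L, floor(cy - r - 1)); j1 <- min(S, ceiling(cy + r + 1))
  if (i0 > i1 || j0 > j1) return(canvas)
  ii <- i0:i1; jj <- j0:j1
  dx <- outer(ii - cx, rep(1, length(jj)))
  dy <- outer(rep(1, length(ii)), jj - cy)
  u <- (dx * cos(theta) + dy * sin(theta)) / rx
  v <- (-dx * sin(theta) + dy * cos(theta)) / ry
  m <- pmax(1 - (u^2 + v^2), 0)
  canvas[ii, jj] <- canvas[ii, jj] + amp * sqrt(m)
  canvas
}

smooth_field <- function(S, coarse, lo, hi) {
  g <- matrix(stats::runif(coarse * coarse, lo, hi), coarse, coarse)
  bilinear_resize(g, S, S)
}

#' Generate one synthetic H&E tile
#'
#' @param label 0 = normal (gland rings), 1 = abnormal (pleomorphic
#'   clusters).
#' @param patient_stain 3x2 stain matrix of the synthetic patient.
#' @param seed integer seed; the same `(label, seed, stain)` triple yields a
#'   bit-identical tile.
#' @param tile_size side length in pixels (square tiles).
#' @param patient_id,tile_id identifiers stored on the tile.
#' @return an [rgb_tile()].
#' @export
generate_tile <- function(label, patient_stain = default_stain_profile()$stain_matrix,
                          seed = 1L, tile_size = 64L,
                          patient_id = NA_character_,
                          tile_id = NA_character_) {
  stopifnot(label %in% c(0L, 1L))
  S <- as.integer(tile_size)
  sc <- S / 64                      # morphology scale factor
  with_seed(seed, {
    # eosin-like stroma: smooth field with light texture
    cE <- smooth_field(S, max(4L, S %/% 16L), 0.15, 0.45) +
      matrix(stats::rnorm(S * S, 0, 0.02), S, S)
    cH <- matrix(stats::runif(S * S, 0, 0.03), S, S)

    if (label == 0L) {
      n_gl <- max(1L, round(2.5 * sc^2 + stats::runif(1, -0.5, 0.5)))
      for (g in seq_len(n_gl)) {
        r <- stats::runif(1, 0.14, 0.2) * S
        cx <- stats::runif(1, r + 2, S - r - 2)
        cy <- stats::runif(1, r + 2, S - r - 2)
        rn <- 2.1 * sc                      # regular nucleus radius
        k <- max(8L, round(2 * pi * r / (2.4 * rn)))
        ang <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)] +
          stats::runif(1, 0, 2 * pi)
        for (a in ang) {
          rr <- rn * stats::rnorm(1, 1, 0.06)  # low size variance
          cH <- draw_nucleus(cH, cx + r * cos(a), cy + r * sin(a),
                             rr, rr * stats::rnorm(1, 1, 0.04),
                             stats::runif(1, 0, pi),
                             stats::runif(1, 0.75, 0.95))
        }
        # empty lumen inside the ring
        lum <- pmax(1 - ((outer(seq_len(S) - cx, rep(1, S))^2 +
                          outer(rep(1, S), seq_len(S) - cy)^2) /
                           (0.75 * r)^2), 0)
        cE <- cE * (1 - 0.85 * lum)
      }
    } else {
      n_cl <- max(2L, round(3 * sc^2 + stats::runif(1, -0.5, 0.5)))
      for (g in seq_len(n_cl)) {
        cx <- stats::runif(1, 0.15 * S, 0.85 * S)
        cy <- stats::runif(1, 0.15 * S, 0.85 * S)
        spread <- stats::runif(1, 0.1, 0.16) * S
        k <- round(stats::runif(1, 9, 16))
        for (j in seq_len(k)) {
          # pleomorphic: radii span ~4x, arbitrary eccentricity/orientation
          rr <- stats::runif(1, 1.1, 4.6) * sc
          ecc <- stats::runif(1, 0.45, 1)
          cH <- draw_nucleus(cH, cx + stats::rnorm(1, 0, spread),
                             cy + stats::rnorm(1, 0, spread),
                             rr, rr * ecc, stats::runif(1, 0, pi),
                             stats::runif(1, 0.85, 1.25))
        }
      }
      # denser, slightly disordered stroma
      cE <- cE + smooth_field(S, max(4L, S %/% 8L), 0, 0.2)
    }

    # nuclei displace cytoplasm/stroma, so dense chromatin is close to pure
    # hematoxylin (needed for extreme-angle stain estimation to see both
    # stain rays)
    cE <- cE * (1 - 0.85 * clamp(cH, 0, 1))
    conc <- cbind(pmax(as.vector(cH), 0), pmax(as.vector(cE), 0))
    od <- conc %*% t(patient_stain)
    px <- clamp(10^(-od), 0, 1)
    rgb_tile(array(px, c(S, S, 3L)), label = as.integer(label),
             patient_id = patient_id, tile_id = tile_id)
  })
}

#' Specification of a synthetic cohort
#'
#' @param n_patients number of synthetic patients (>= 2).
#' @param tiles_per_patient tiles per patient (>= 1).
#' @param normal_fraction fraction of normal tiles; the default reproduces
#'   the 148120 : 97076 normal-to-abnormal composition of the public gastric
#'   histopathology benchmark the model targets.
#' @param tile_size tile side length in pixels.
#' @param stain_jitter sd (degrees) of the per-patient stain rotation.
#' @param seed cohort seed.
#' @param mixed_classes if TRUE, labels are drawn per tile instead of per
#'   patient.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, tiles_per_patient,
                        normal_fraction = 148120 / 245196,
                        tile_size = 64L, stain_jitter = 3, seed = 1L,
                        mixed_classes = FALSE) {
  stopifnot(n_patients >= 2L, tiles_per_patient >= 1L,
            normal_fraction > 0, normal_fraction < 1)
  structure(list(n_patients = as.integer(n_patients),
                 tiles_per_patient = as.integer(tiles_per_patient),
                 normal_fraction = normal_fraction,
                 tile_size = as.integer(tile_size),
                 stain_jitter = stain_jitter,
                 seed = as.integer(seed),
                 mixed_classes = isTRUE(mixed_classes)),
            class = "cohort_spec")
}

#' Generate a labeled cohort of synthetic tiles
#'
#' Each patient receives one jittered stain matrix shared by all of its
#' tiles and (by default) a single class; the number of normal patients is
#' chosen so the realized class fraction tracks `normal_fraction`.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory: tiles are written as PNG and the
#'   manifest as `manifest.csv` (columns tile_id, patient_id, label, path).
#' @return list with `tiles` (list of [rgb_tile()]) and `manifest`
#'   (data.frame: tile_id, patient_id, label, path).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_patients
  n_normal <- min(max(round(np * spec$normal_fraction), 1L), np - 1L)
  pat_labels <- c(rep(0L, n_normal), rep(1L, np - n_normal))
  pat_ids <- sprintf("P%03d", seq_len(np))
  stains <- lapply(seq_len(np), function(i) {
    with_seed(derive_seed(spec$seed, i),
              jitter_stain_matrix(sd_deg = spec$stain_jitter))
  })
  tiles <- vector("list", np * spec$tiles_per_patient)
  rows <- vector("list", length(tiles))
  k <- 0L
  for (i in seq_len(np)) {
    for (j in seq_len(spec$tiles_per_patient)) {
      k <- k + 1L
      lab <- if (spec$mixed_classes) {
        with_seed(derive_seed(spec$seed, 100000L + k),
                  as.integer(stats::runif(1) > spec$normal_fraction))
      } else {
        pat_labels[i]
      }
      tid <- sprintf("%s_T%03d", pat_ids[i], j)
      tiles[[k]] <- generate_tile(lab, stains[[i]],
                                  seed = derive_seed(spec$seed, 1000L * i + j),
                                  tile_size = spec$tile_size,
                                  patient_id = pat_ids[i], tile_id = tid)
      rows[[k]] <- data.frame(tile_id = tid, patient_id = pat_ids[i],
                              label = lab, path = NA_character_,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(out_dir, paste0(manifest$tile_id, ".png"))
    for (k in seq_along(tiles)) write_tile(tiles[[k]], manifest$path[k])
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(tiles = tiles, manifest = manifest)
}

#' Simple morphology statistics of a tile
#'
#' Projects the tile's optical density onto the hematoxylin reference vector,
#' thresholds the resulting nuclear channel and labels connected components
#' (4-connectivity). Used as an architecture-free check that the two classes
#' carry signal (blob counts, nucleus-area variance, mean intensity).
#'
#' @param tile [rgb_tile()] or `(H, W, 3)` array.
#' @param threshold threshold on the hematoxylin OD projection.
#' @return list: `n_blobs`, `areas`, `area_var`, `mean_intensity`.
#' @export
tile_morphology_stats <- function(tile, threshold = 0.35) {
  px <- tile_pixels(tile)
  d <- dim(px)
  od <- rgb_to_od(px)
  h_ref <- default_stain_profile()$stain_matrix[, 1]
  hmap <- matrix(matrix(od, d[1] * d[2], 3) %*% h_ref, d[1], d[2])
  mask <- hmap > threshold
  lab <- label_components(mask)
  areas <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
  areas <- areas[areas >= 3]        # discard speckle
  list(n_blobs = length(areas), areas = areas,
       area_var = if (length(areas) > 1) stats::var(areas) else 0,
       mean_intensity = mean(px))
}

# connected-component labeling of a logical matrix, 4-connectivity
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  stack <- integer(H * W)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      i <- (p - 1L) %% H + 1L
      j <- (p - 1L) %/% H + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < H) p + 1L,
                  if (j > 1L) p - H, if (j < W) p + H)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  lab
}
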