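test_that("rgb_to_od matches the Beer-Lambert transform", {
  # three pixels at I0, I0/10, I0/100 (all channels equal)
  px <- array(rep(c(1, 0.1, 0.01), 3), c(3, 1, 3))
  od <- rgb_to_od(px, background_intensity = 1)
  expect_equal(od[1, 1, ], rep(0, 3), tolerance = 1e-5)
  expect_equal(od[2, 1, ], rep(1, 3), tolerance = 1e-4)
  expect_equal(od[3, 1, ], rep(2, 3), tolerance = 1e-3)
  # monotone decreasing in intensity
  set.seed(1)
  a <- array(runif(48, 0.1, 0.9), c(4, 4, 3))
  expect_true(all(rgb_to_od(a + 0.05) <= rgb_to_od(a)))
  expect_error(rgb_to_od(a, background_intensity = 0), "positive")
})

test_that("od <-> rgb round trip is identity within 1/255", {
  set.seed(2)
  px <- array(runif(3 * 16 * 16, 0.02, 1), c(16, 16, 3))
  back <- od_to_rgb(rgb_to_od(px))
  expect_lt(max(abs(back - px)), 1 / 255)
})

test_that("stain matrix is recovered from rendered tiles within 5 degrees", {
  errs <- vapply(1:20, function(s) {
    M <- with_seed(s, jitter_stain_matrix(sd_deg = 4))
    tile <- generate_tile(s %% 2, M, seed = 300 + s, tile_size = 64)
    Mhat <- estimate_stain_matrix(rgb_to_od(tile$pixels))
    max(stain_angle_error(M, Mhat))
  }, numeric(1))
  expect_lt(max(errs), 5)
})

test_that("degenerate tiles raise a degenerate-stain error", {
  white <- array(1, c(8, 8, 3))
  expect_error(estimate_stain_matrix(rgb_to_od(white)),
               class = "histomamba_degenerate_stain")
  # single stain direction: all OD pixels on one ray
  ray <- matrix(rep(c(0.6, 0.7, 0.38), each = 50) * runif(50, 0.5, 2),
                50, 3)
  expect_error(estimate_stain_matrix(ray),
               class = "histomamba_degenerate_stain")
})

test_that("an OD cloud on two rays yields columns parallel to the rays", {
  v1 <- c(0.65, 0.70, 0.29); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(0.07, 0.99, 0.11); v2 <- v2 / sqrt(sum(v2^2))
  set.seed(3)
  X <- rbind(outer(runif(200, 0.2, 2), v1), outer(runif(200, 0.2, 2), v2))
  M <- estimate_stain_matrix(X, od_threshold = 0.1, angle_percentile = 0.5)
  expect_lt(max(stain_angle_error(M, cbind(v1, v2))), 0.5)
})

test_that("normalization is idempotent and aligns perturbed renders", {
  M1 <- with_seed(41, jitter_stain_matrix(sd_deg = 4))
  M2 <- with_seed(42, jitter_stain_matrix(sd_deg = 4))
  t1 <- generate_tile(1, M1, seed = 9, tile_size = 64)
  t2 <- generate_tile(1, M2, seed = 9, tile_size = 64)  # same morphology
  n1 <- normalize_stains(t1)
  n2 <- normalize_stains(t2)
  expect_lt(mean(abs(n1$pixels - n2$pixels)), 0.05)
  # idempotence
  n11 <- normalize_stains(n1)
  expect_lt(mean(abs(n11$pixels - n1$pixels)), 1e-2)
})

test_that("tiles without tissue pass through with a warning", {
  gray <- rgb_tile(array(0.5, c(16, 16, 3)))
  expect_warning(out <- normalize_stains(gray), "pass")
  expect_identical(out$pixels, gray$pixels)
})

test_that("stain profiles validate and round-trip through JSON", {
  expect_error(stain_profile(matrix(1, 3, 2)), "unit")
  expect_error(stain_profile(default_stain_profile()$stain_matrix,
                             c(-1, 1)), "positive")
  prof <- default_stain_profile()
  expect_equal(colSums(prof$stain_matrix^2), c(1, 1), tolerance = 1e-9)
  # hematoxylin column carries the larger blue-channel OD
  expect_gt(prof$stain_matrix[3, 1], prof$stain_matrix[3, 2])
  path <- tempfile(fileext = ".json")
  write_stain_profile(prof, path)
  prof2 <- read_stain_profile(path)
  expect_equal(prof2$stain_matrix, prof$stain_matrix, tolerance = 1e-12)
  expect_equal(prof2$concentration_scale, prof$concentration_scale)
})

test_that("tiles round-trip through PNG", {
  t1 <- generate_tile(0, seed = 5, tile_size = 16)
  path <- tempfile(fileext = ".png")
  write_tile(t1, path)
  back <- read_tile(path)
  expect_equal(dim(back), c(16, 16, 3))
  expect_lt(max(abs(back - t1$pixels)), 1 / 255)
})
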