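small_cfg <- function(ts = 32) tiny_config(tile_size = ts, base_channels = 4,
                                           state_dim = 4)

test_that("configuration invariants are enforced", {
  expect_error(model_config(tile_size = 100), "divisible")
  cfg <- model_config()
  expect_equal(cfg$base_channels * 2^(cfg$n_levels - 1), 512)
  expect_error(build_model(small_cfg(), variant = 6), "variant")
})

test_that("forward output honors the shape and probability contracts", {
  for (ts in c(32, 64)) {
    m <- build_model(small_cfg(ts), seed = 1)
    x <- array(runif(ts * ts * 2 * 3), c(ts, ts, 2, 3))
    out <- model_forward(m, x)
    expect_equal(dim(out$class_probabilities), c(2L, 2L))
    expect_equal(rowSums(out$class_probabilities), c(1, 1), tolerance = 1e-6)
    expect_true(all(out$class_probabilities >= 0))
    expect_equal(dim(out$uncertainty_map), c(ts / 16, ts / 16, 2))
    expect_equal(dim(out$local_prob_map), c(ts, ts, 2))
    expect_true(all(out$local_prob_map >= 0 & out$local_prob_map <= 1))
    expect_true(all(out$uncertainty_map >= 0 &
                    out$uncertainty_map <= log(4 * 8) + 1e-6))
  }
  m <- build_model(small_cfg(32), seed = 1)
  expect_error(model_forward(m, array(0.5, c(16, 16, 1, 3))), "tile_size")
})

test_that("eval-mode forward is deterministic", {
  m <- build_model(small_cfg(32), seed = 2)
  x <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  o1 <- model_forward(m, x)
  o2 <- model_forward(m, x)
  expect_identical(o1$class_probabilities, o2$class_probabilities)
  expect_identical(o1$local_prob_map, o2$local_prob_map)
})

test_that("ablation variants flip the right switches", {
  cfg <- small_cfg(32)
  m1 <- make_variant(cfg, 1)
  m2 <- make_variant(cfg, 2)
  m3 <- make_variant(cfg, 3)
  m4 <- make_variant(cfg, 4)
  m5 <- make_variant(cfg, 5)
  expect_identical(m1$arch,
                   build_model(cfg, seed = m1$seed, variant = 1)$arch)
  expect_equal(m2$arch$decoder_mode, "fixed")
  expect_false(m2$arch$use_ual)
  expect_false(m3$arch$local_branch)
  expect_true(m3$arch$decoder_mode == "ud")
  expect_false(m4$arch$skips)
  expect_false(any(grepl("skipred", names(m4$params))))
  expect_false(m5$arch$local_branch)
  expect_equal(m5$arch$decoder_mode, "fixed")
  # variant 2: no uncertainty-weight parameters anywhere
  expect_false(any(grepl("alpha0", names(m2$params))))
  # parameter-count ordering: removing branches removes parameters
  expect_gte(n_parameters(m1), n_parameters(m3))
  expect_gte(n_parameters(m1), n_parameters(m5))
  # without skips the decoder still emits full-resolution outputs
  x <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  out4 <- model_forward(m4, x)
  expect_equal(dim(out4$local_prob_map), c(32, 32, 1))
})

test_that("the no-ud override restores channel attention in the decoder", {
  m <- build_model(small_cfg(32), seed = 1, decoder_mode = "channel")
  expect_true(any(grepl("dec1\\.att", names(m$params))))
  expect_false(any(grepl("alpha0", names(m$params))))
  x <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  expect_equal(rowSums(model_forward(m, x)$class_probabilities), 1,
               tolerance = 1e-6)
})

test_that("a supplied spatial fusion weight acts locally", {
  # changing alpha' at one position only changes that position's output
  set.seed(8)
  m <- build_model(small_cfg(32), seed = 3)
  hm <- asNamespace("histomamba")
  P <- lapply(m$params, hm$ag_leaf)
  x <- array(rnorm(8 * 8 * 1 * 4), c(8, 8, 1, 4))
  a1 <- array(0.5, c(8, 8, 1))
  a2 <- a1; a2[3, 5, 1] <- 0.9
  o1 <- hm$ag_value(block_forward(P, "dec1", hm$ag_leaf(x), m$config,
                                  m$arch, alpha_map = hm$ag_leaf(a1)))
  o2 <- hm$ag_value(block_forward(P, "dec1", hm$ag_leaf(x), m$config,
                                  m$arch, alpha_map = hm$ag_leaf(a2)))
  d <- abs(o1 - o2)
  changed <- which(apply(d, c(1, 2), max) > 0)
  expect_equal(changed, which(matrix(seq_len(64), 8, 8) == (4 * 8 + 3)))
})

test_that("every parameter receives gradient and dropout is train-only", {
  # 32px keeps the bottleneck at 2x2 so no path is structurally degenerate
  cfg <- small_cfg(32)
  m <- build_model(cfg, seed = 4)
  x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  tc <- train_config(epochs = 5, warmup_epochs = 1, batch_size = 2)
  tc$.class_weights <- c(1, 1)
  set.seed(11)
  ag_tape_begin()
  st <- training_graph(m, x, c(0, 1), tc)
  ag_backward(st$loss)
  grads <- lapply(st$graph$P, function(nd) nd$grad)
  ag_tape_end()
  expect_true(all(!vapply(grads, is.null, logical(1))))
  expect_true(all(vapply(grads, function(g) any(g != 0), logical(1))))
  # dropout: active only in training mode
  hm <- asNamespace("histomamba")
  v <- matrix(1, 10, 100)
  set.seed(3)
  dr <- hm$ag_value(hm$ag_dropout(v, 0.5, training = TRUE))
  expect_gt(sum(dr == 0), 300)                 # about half dropped
  expect_equal(unique(dr[dr != 0]), 2)         # inverted scaling 1/(1-p)
  expect_identical(hm$ag_value(hm$ag_dropout(v, 0.5, training = FALSE)), v)
  e1 <- as.numeric(ag_value(model_graph(m, x, FALSE)$logits))
  e2 <- as.numeric(ag_value(model_graph(m, x, FALSE)$logits))
  expect_identical(e1, e2)
})

test_that("checkpoints round-trip through disk", {
  m <- build_model(small_cfg(16), seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3))
  expect_identical(model_forward(m, x)$class_probabilities,
                   model_forward(m2, x)$class_probabilities)
})
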