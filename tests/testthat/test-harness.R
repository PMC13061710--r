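test_that("learning-rate schedule follows warm-up then cosine", {
  tc <- train_config()
  expect_equal(lr_schedule(tc$warmup_epochs, tc), 1e-4)
  expect_equal(lr_schedule(tc$epochs, tc), 1e-6, tolerance = 1e-12)
  # midpoint of the cosine phase
  mid <- tc$warmup_epochs + (tc$epochs - tc$warmup_epochs) / 2
  expect_equal(lr_schedule(mid, tc), (1e-4 + 1e-6) / 2, tolerance = 1e-10)
  # warm-up is a linear ramp
  expect_equal(lr_schedule(1, tc), 1e-4 / 5)
  expect_error(train_config(lr = 1e-7), "lr")
  expect_error(train_config(warmup_epochs = 10, epochs = 5), "warmup")
})

tiny_cohort <- function(n_pat = 6, tpp = 4, ts = 16, seed = 31) {
  co <- generate_cohort(cohort_spec(n_pat, tpp, tile_size = ts, seed = seed))
  sp <- patient_independent_split(co$manifest, seed = seed)
  list(tiles = co$tiles, manifest = apply_split(co$manifest, sp))
}

micro_cfg <- function(ts = 16) tiny_config(tile_size = ts, base_channels = 4,
                                           state_dim = 2)

test_that("training is reproducible and early stopping obeys patience", {
  d <- tiny_cohort()
  tc <- train_config(epochs = 2, warmup_epochs = 1, batch_size = 8,
                     patience = 5, lr = 1e-3, seed = 9)
  m <- build_model(micro_cfg(), seed = 7)
  r1 <- train_model(m, d$tiles, d$manifest, tc)
  r2 <- train_model(m, d$tiles, d$manifest, tc)
  expect_equal(r1$history$train_loss[1], r2$history$train_loss[1])
  expect_identical(r1$model$params, r2$model$params)
  # patience 1 with a frozen model (lr ~ 0): stops after 2 epochs
  tc0 <- train_config(epochs = 10, warmup_epochs = 1, batch_size = 8,
                      patience = 1, lr = 1e-12, min_lr = 1e-13, seed = 9)
  r0 <- train_model(m, d$tiles, d$manifest, tc0)
  expect_equal(nrow(r0$history), 2)
})

test_that("a tiny model can overfit eight tiles (capacity sanity)", {
  co <- generate_cohort(cohort_spec(4, 2, tile_size = 32, seed = 13))
  man <- co$manifest
  man$subset <- "train"
  m <- build_model(micro_cfg(32), seed = 17)
  # ~200 optimization steps on the memorized batch
  tc <- train_config(epochs = 200, warmup_epochs = 5, patience = 200,
                     batch_size = 8, lr = 3e-3, min_lr = 1e-4, seed = 13)
  rec <- train_model(m, co$tiles, man, tc, augment = NULL)
  ev <- evaluate_model(rec$model, co$tiles, man, subset = "train")
  expect_equal(ev$accuracy, 1.0)
})

test_that("evaluation is deterministic and honors subsets", {
  d <- tiny_cohort()
  m <- build_model(micro_cfg(), seed = 19)
  e1 <- evaluate_model(m, d$tiles, d$manifest, subset = "test")
  e2 <- evaluate_model(m, d$tiles, d$manifest, subset = "test")
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1[c("accuracy", "f1", "auc")],
                   e2[c("accuracy", "f1", "auc")])
  expect_equal(length(e1$scores), sum(d$manifest$subset == "test"))
  path <- tempfile(fileext = ".json")
  evaluate_model(m, d$tiles, d$manifest, subset = "test",
                 metrics_path = path)
  js <- jsonlite::read_json(path)
  expect_named(js, c("accuracy", "precision", "recall", "f1", "auc",
                     "mean_rho"))
  expect_error(evaluate_model(m, d$tiles, d$manifest, subset = "bogus"),
               "no tiles")
})

test_that("ablation plumbing emits one row per variant/seed", {
  d <- tiny_cohort()
  tc <- train_config(epochs = 1, warmup_epochs = 0, batch_size = 8,
                     patience = 2, lr = 1e-3, seed = 3)
  tab <- run_ablation(micro_cfg(), d$tiles, d$manifest, tc,
                      variants = c(1, 5), seeds = 1)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$variant, c(1, 5))
  expect_true(all(c("accuracy", "f1", "auc", "mean_rho") %in% names(tab)))
})

test_that("divergent loss aborts with a diagnostic", {
  d <- tiny_cohort()
  m <- build_model(micro_cfg(), seed = 7)
  m$params$head.W[] <- 1e308            # force an overflow
  tc <- train_config(epochs = 2, warmup_epochs = 1, batch_size = 8, seed = 1)
  expect_error(train_model(m, d$tiles, d$manifest, tc), "non-finite")
})
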