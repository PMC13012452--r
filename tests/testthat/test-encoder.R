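small_cfg <- function(seed = 1L) {
  encoder_config(conv_channels = c(4L, 6L), kernels = c(5L, 3L),
                 lstm_hidden = 4L, seed = seed)
}

test_that("embeddings obey the shape law L = ceil(T / r)", {
  cfg3 <- encoder_config(conv_channels = c(4L, 4L, 4L),
                         kernels = c(7L, 5L, 3L), lstm_hidden = 4L,
                         seed = 2L)
  model <- new_encoder(cfg3)
  expect_equal(cfg3$r, 8L)
  for (Tn in c(1000L, 17L, 64L, 101L)) {
    E <- encode_curves(list(spiro_curve(rnorm(Tn), 0.01)), model)[[1]]
    expect_equal(nrow(E), as.integer(ceiling(Tn / 8)))
    expect_equal(ncol(E), cfg3$d_feat)
    expect_true(all(is.finite(E)))
  }
  expect_error(encode_curves(list(spiro_curve(rnorm(4), 0.01)), model),
               class = "spirokit_input_error")
})

test_that("padding leaks no information into embeddings", {
  model <- new_encoder(small_cfg())
  set.seed(31)
  cu <- spiro_curve(rnorm(40), 0.01)
  long <- spiro_curve(rnorm(160), 0.01)
  alone <- encode_curves(list(cu), model)[[1]]
  padded <- encode_curves(list(cu, long), model)[[1]]
  expect_lt(max(abs(alone - padded)), 1e-5)
  # probabilities likewise
  p1 <- classify_curves(list(cu), model)
  p2 <- classify_curves(list(cu, long), model)[1]
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("evaluation mode is exactly deterministic", {
  model <- new_encoder(small_cfg())
  cu <- synthesize_curve(spiro_curve_params(4, 7, 0.2, 2, dt = 0.01))
  a <- encode_curves(list(cu), model)[[1]]
  b <- encode_curves(list(cu), model)[[1]]
  expect_identical(a, b)
})

test_that("a zero-weight head outputs probability one half", {
  model <- new_encoder(small_cfg())
  model$params$head$w[] <- 0
  model$params$head$b <- 0
  cu <- spiro_curve(rnorm(50), 0.01)
  expect_equal(classify_curves(list(cu), model), 0.5)
  # and probabilities always live strictly inside (0, 1)
  model2 <- new_encoder(small_cfg(seed = 7L))
  p <- classify_curves(lapply(1:8, function(i)
    spiro_curve(rnorm(30 + i), 0.01)), model2)
  expect_true(all(p > 0 & p < 1))
})

test_that("training reduces loss, overfits a tiny set, and is seeded", {
  bm <- separable_benchmark(16, seed = 5)
  cfg <- encoder_config(conv_channels = c(6L, 8L), kernels = c(5L, 3L),
                        lstm_hidden = 8L, seed = 9L)
  m <- train_encoder(bm$curves, bm$labels, config = cfg, epochs = 25L,
                     batch_size = 16L, lr = 1e-2)
  # loss decreases over the early epochs
  expect_lt(m$history$train_loss[5], m$history$train_loss[1])
  # single-batch capacity check: near-perfect training accuracy
  p <- classify_curves(bm$curves, m)
  expect_gte(mean((p > 0.5) == bm$labels), 0.99)
  # fixed seed reproduces the first-epoch loss exactly
  m2 <- train_encoder(bm$curves, bm$labels, config = cfg, epochs = 1L,
                      batch_size = 16L, lr = 1e-2)
  expect_identical(m2$history$train_loss[1], m$history$train_loss[1])
  expect_error(train_encoder(list(), integer(0), config = cfg),
               class = "spirokit_input_error")
})

test_that("early stopping halts on a stagnant validation loss", {
  bm <- separable_benchmark(24, seed = 6)
  cfg <- encoder_config(conv_channels = 4L, kernels = 3L,
                        lstm_hidden = 3L, seed = 2L)
  m <- train_encoder(bm$curves[1:16], bm$labels[1:16],
                     bm$curves[17:24], bm$labels[17:24],
                     config = cfg, epochs = 40L, batch_size = 16L,
                     lr = 0, patience = 3L)
  # zero learning rate: no improvement, so patience cuts training short
  expect_lte(nrow(m$history), 4L)
})

test_that("saliency maps are normalised to the input grid", {
  model <- new_encoder(small_cfg(seed = 4L))
  cu <- synthesize_curve(spiro_curve_params(4.2, 7, 0.2, 2.5, dt = 0.01))
  sal <- encoder_saliency(cu, model)
  expect_length(sal$weight, length(cu$flow))
  expect_true(all(sal$weight >= 0 & sal$weight <= 1))
  expect_equal(max(sal$weight), 1)
  # all-zero weights give degenerate activations -> uniform map + warning
  zero <- new_encoder(small_cfg())
  zero$params <- rapply(zero$params, function(x) x * 0, how = "replace")
  expect_warning(us <- encoder_saliency(cu, zero), "uniform")
  expect_true(all(us$weight == 1))
  # CSV export
  path <- withr::local_tempfile(fileext = ".csv")
  write_saliency_csv(sal, path)
  df <- read.csv(path)
  expect_named(df, c("time_s", "flow_lps", "weight"))
  expect_equal(nrow(df), length(cu$flow))
})

test_that("checkpoints round-trip through a single JSON file", {
  bm <- separable_benchmark(8, seed = 3)
  cfg <- small_cfg(seed = 13L)
  model <- train_encoder(bm$curves, bm$labels, config = cfg, epochs = 1L)
  path <- withr::local_tempfile(fileext = ".json")
  save_encoder(model, path)
  back <- load_encoder(path)
  p1 <- classify_curves(bm$curves, model)
  p2 <- classify_curves(bm$curves, back)
  expect_equal(p1, p2, tolerance = 1e-12)
})
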