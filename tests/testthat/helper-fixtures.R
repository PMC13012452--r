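# Fixtures built in code: curves from explicit flow functions, trivial LMS
# tables, minimal cohort records, and a cached trained benchmark model
# shared by the slower tests.

# Sample a curve from a flow function of time on [0, t_max].
curve_from_fn <- function(fn, dt, t_max, blow_id = 1L) {
  tt <- seq(0, t_max, by = dt)
  spiro_curve(fn(tt), dt, blow_id = blow_id)
}

# LMS table with constant M (no height/age dependence), constant S, L.
constant_lms_table <- function(M = 4, S = 0.1, L = 1,
                               indices = c("FVC", "FEV1", "FEV1_FVC",
                                           "PEF", "FEF25_75", "FEF75")) {
  coef <- expand.grid(sex = c("male", "female"), index = indices,
                      stringsAsFactors = FALSE)
  coef$a0 <- log(M); coef$a1 <- 0; coef$a2 <- 0
  coef$b0 <- log(S); coef$b1 <- 0; coef$L <- L
  spl <- do.call(rbind, lapply(seq_len(nrow(coef)), function(i) {
    data.frame(sex = coef$sex[i], index = coef$index[i],
               age = c(0, 120), m_spline = 0, s_spline = 0)
  }))
  lms_table(coef, spl)
}

demo_row <- function(age = 55, sex = "male", height = 176,
                     smoking = "former") {
  data.frame(age = age, sex = sex, height = height, smoking = smoking,
             stringsAsFactors = FALSE)
}

# Minimal record carrying a prefabricated pft_result (no curves needed).
fake_pft <- function(values, z_ratio = NA_real_) {
  idx <- data.frame(
    name = c("FVC", "FEV1", "FEV1_FVC", "PEF", "FEF25_75", "FEF75"),
    measured = NA_real_, predicted = NA_real_, lln = NA_real_,
    z_score = NA_real_, pct_predicted = NA_real_,
    stringsAsFactors = FALSE)
  for (nm in names(values)) {
    idx$measured[idx$name == nm] <- values[[nm]]
  }
  idx$z_score[idx$name == "FEV1_FVC"] <- z_ratio
  structure(list(indices = idx, t25 = 0.5, t75 = 1.5),
            class = "pft_result")
}

fake_record <- function(id, label = 0L, FVC = 4, FEV1 = 3, PEF = 8,
                        z_ratio = NA_real_, codes = character(0)) {
  list(subject_id = id, curves = list(), demographics = demo_row(),
       diagnosis_codes = codes, label = as.integer(label),
       pft = fake_pft(list(FVC = FVC, FEV1 = FEV1, PEF = PEF),
                      z_ratio = z_ratio))
}

# One trained model on the separable morphology benchmark, cached so the
# classifier-recovery and saliency tests share a single training run.
.benchmark_cache <- new.env(parent = emptyenv())

trained_benchmark <- function() {
  if (!is.null(.benchmark_cache$model)) {
    return(list(model = .benchmark_cache$model, bm = .benchmark_cache$bm,
                holdout = .benchmark_cache$holdout))
  }
  bm <- separable_benchmark(400, seed = 11)
  holdout <- seq(301, 400)
  cfg <- encoder_config(conv_channels = c(8L, 16L, 16L),
                        kernels = c(7L, 5L, 3L), lstm_hidden = 16L,
                        seed = 3L)
  model <- train_encoder(bm$curves[1:300], bm$labels[1:300],
                         bm$curves[holdout], bm$labels[holdout],
                         config = cfg, epochs = 4L, batch_size = 32L,
                         lr = 3e-3)
  .benchmark_cache$model <- model
  .benchmark_cache$bm <- bm
  .benchmark_cache$holdout <- holdout
  list(model = model, bm = bm, holdout = holdout)
}
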