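#' CNN-BiLSTM encoder configuration
#'
#' Three 1-D convolution blocks (conv, ReLU, stride-2 max pooling) capture
#' local flow patterns and downsample time by `r = 2^n_blocks`; a
#' bidirectional LSTM then models temporal context, producing a feature
#' matrix of width `D_feat = 2 * lstm_hidden` per reduced timestep.
#'
#' @param conv_channels integer vector of channels per conv block.
#' @param kernels odd kernel sizes, same length as `conv_channels`.
#' @param lstm_hidden LSTM hidden width per direction.
#' @param dropout dropout rate on the feature embedding during training.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `encoder_config`; `r` is the total temporal
#'   downsampling ratio and `d_feat` the output feature width.
#' @export
encoder_config <- function(conv_channels = c(32L, 64L, 64L),
                           kernels = c(7L, 5L, 3L),
                           lstm_hidden = 64L, dropout = 0, seed = 1L) {
  stopifnot(length(conv_channels) == length(kernels),
            all(kernels %% 2 == 1), lstm_hidden >= 1,
            dropout >= 0, dropout < 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 kernels = as.integer(kernels),
                 lstm_hidden = as.integer(lstm_hidden),
                 dropout = dropout, seed = as.integer(seed),
                 r = 2L^length(conv_channels),
                 d_feat = 2L * as.integer(lstm_hidden)),
            class = "encoder_config")
}

# Seeded parameter initialisation: He for conv, uniform +-1/sqrt(H) for
# LSTM with forget bias 1, small-normal head.
encoder_init <- function(config) {
  with_seed(config$seed, {
    cin <- 2L  # normalised flow + constant dt channel
    conv <- list()
    for (i in seq_along(config$conv_channels)) {
      K <- config$kernels[i]; cout <- config$conv_channels[i]
      conv[[i]] <- list(
        W = array(stats::rnorm(K * cin * cout, sd = sqrt(2 / (K * cin))),
                  c(K, cin, cout)),
        b = numeric(cout))
      cin <- cout
    }
    H <- config$lstm_hidden
    lstm_dir <- function(cin) {
      s <- 1 / sqrt(H)
      b <- numeric(4L * H)
      b[H + seq_len(H)] <- 1  # forget-gate bias
      list(Wx = matrix(stats::runif(cin * 4L * H, -s, s), cin, 4L * H),
           Wh = matrix(stats::runif(H * 4L * H, -s, s), H, 4L * H),
           b = b)
    }
    list(conv = conv,
         bilstm = list(fwd = lstm_dir(cin), bwd = lstm_dir(cin)),
         head = list(w = matrix(stats::rnorm(config$d_feat, sd = 0.01),
                                config$d_feat, 1),
                     b = 0,
                     u = matrix(stats::rnorm(config$d_feat, sd = 0.1),
                                config$d_feat, 1)))
  })
}

# Pad a list of curves into a (B, L, 2) array: channel 1 is flow scaled by
# its own peak, channel 2 the constant dt. Returns the valid lengths too.
prep_curve_batch <- function(curves, pad_to = NULL) {
  lengths <- vapply(curves, function(cu) length(cu$flow), integer(1))
  L <- if (is.null(pad_to)) max(lengths) else pad_to
  stopifnot(L >= max(lengths))
  B <- length(curves)
  x <- array(0, c(B, L, 2L))
  for (bi in seq_len(B)) {
    f <- curves[[bi]]$flow
    pk <- max(abs(f))
    if (pk == 0) pk <- 1
    x[bi, seq_along(f), 1L] <- f / pk
    x[bi, seq_along(f), 2L] <- curves[[bi]]$dt
  }
  list(x = x, lengths = lengths)
}

# Zero activations beyond each sequence's valid length so deeper layers
# see the same (zero) context regardless of how far the batch is padded.
zero_pad_tail <- function(x, lengths) {
  L <- dim(x)[2]
  for (bi in seq_along(lengths)) {
    if (lengths[bi] < L) x[bi, (lengths[bi] + 1L):L, ] <- 0
  }
  x
}

# Forward pass to the feature matrix, keeping caches for backprop.
encoder_forward <- function(x, lengths, params, config) {
  caches <- list()
  h <- x
  lred <- lengths
  for (i in seq_along(params$conv)) {
    cv <- nn_conv1d_forward(h, params$conv[[i]]$W, params$conv[[i]]$b)
    rl <- nn_relu_forward(cv$out)
    mp <- nn_maxpool2_forward(rl$out)
    lred <- ceiling(lred / 2)
    caches[[i]] <- list(conv = cv, relu = rl, pool = mp, lred = lred)
    h <- zero_pad_tail(mp$out, lred)
  }
  bl <- nn_bilstm_forward(h, params$bilstm, as.integer(lred))
  list(E = bl$out, red_lengths = as.integer(lred),
       caches = caches, bilstm_cache = bl, conv_out = h)
}

encoder_backward <- function(dE, fw, params, config) {
  gb <- nn_bilstm_backward(dE, fw$bilstm_cache, fw$conv_out, params$bilstm)
  dh <- gb$dx
  gconv <- vector("list", length(params$conv))
  for (i in rev(seq_along(params$conv))) {
    cs <- fw$caches[[i]]
    # the forward pass zeroed activations beyond each valid length, so
    # no gradient flows into those positions
    dh <- zero_pad_tail(dh, cs$lred)
    dh <- nn_maxpool2_backward(dh, cs$pool)
    dh <- nn_relu_backward(dh, cs$relu)
    cb <- nn_conv1d_backward(dh, cs$conv, params$conv[[i]]$W)
    gconv[[i]] <- list(W = cb$dW, b = cb$db)
    dh <- cb$dx
  }
  list(conv = gconv, bilstm = list(fwd = gb$fwd, bwd = gb$bwd), dx = dh)
}

#' Encode a batch of curves into feature embeddings
#'
#' Maps each curve of length `T_i` to an embedding of shape
#' `ceiling(T_i / r) x D_feat`; padding timesteps are excluded from the
#' returned matrices. Deterministic in evaluation mode.
#'
#' @param curves list of [spiro_curve()] objects.
#' @param model a `spiro_encoder` model (from [train_encoder()] or
#'   [new_encoder()]).
#' @return list of per-curve embedding matrices.
#' @export
encode_curves <- function(curves, model) {
  config <- model$config
  lens <- vapply(curves, function(cu) length(cu$flow), integer(1))
  if (any(lens < config$r)) {
    abort_spk(sprintf("curve shorter than downsampling ratio r = %d",
                      config$r), "spirokit_input_error")
  }
  pb <- prep_curve_batch(curves)
  fw <- encoder_forward(pb$x, pb$lengths, model$params, config)
  lapply(seq_along(curves), function(bi) {
    l <- fw$red_lengths[bi]
    matrix(fw$E[bi, seq_len(l), ], l, config$d_feat)
  })
}

#' Untrained encoder model
#'
#' @param config an [encoder_config()].
#' @return a `spiro_encoder` model with seeded initial weights.
#' @export
new_encoder <- function(config = encoder_config()) {
  structure(list(config = config, params = encoder_init(config),
                 history = NULL),
            class = "spiro_encoder")
}

#' @export
print.spiro_encoder <- function(x, ...) {
  cat(sprintf(
    "<spiro_encoder> conv %s, r = %d, D_feat = %d%s\n",
    paste(x$config$conv_channels, collapse = "/"), x$config$r,
    x$config$d_feat,
    if (is.null(x$history)) " (untrained)" else
      sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

# Masked temporal attention pooling + logistic head, with caches.
# Attention scores s_t = E_t . u / sqrt(D) are softmaxed over the valid
# timesteps; the pooled vector sum(alpha_t E_t) feeds a logistic unit.
# The attention weights double as the model's saliency readout.
classifier_forward <- function(E, red_lengths, head) {
  d <- dim(E); B <- d[1]; Df <- d[3]
  pool <- matrix(0, B, Df)
  alpha <- vector("list", B)
  for (bi in seq_len(B)) {
    l <- red_lengths[bi]
    Eb <- matrix(E[bi, seq_len(l), ], l, Df)
    s <- drop(Eb %*% head$u) / sqrt(Df)
    a <- exp(s - max(s))
    a <- a / sum(a)
    alpha[[bi]] <- a
    pool[bi, ] <- drop(crossprod(Eb, a))
  }
  logit <- drop(pool %*% head$w) + head$b
  list(p = nn_sigmoid(logit), pool = pool, logit = logit, alpha = alpha,
       E = E)
}

classifier_backward <- function(dlogit, cf, red_lengths, head, dimE) {
  B <- dimE[1]; Df <- dimE[3]
  dpool <- outer(dlogit, drop(head$w))
  dE <- array(0, dimE)
  du <- matrix(0, Df, 1)
  for (bi in seq_len(B)) {
    l <- red_lengths[bi]
    # rebuild E_b from the cache-free path: pool grad needs E itself, so
    # the caller passes E through cf$E
    Eb <- matrix(cf$E[bi, seq_len(l), ], l, Df)
    a <- cf$alpha[[bi]]
    dp <- dpool[bi, ]
    ct <- drop(Eb %*% dp)            # per-timestep pool contribution grad
    gs <- a * (ct - sum(a * ct))     # softmax backward
    dE[bi, seq_len(l), ] <- a %o% dp +
      (gs %o% drop(head$u)) / sqrt(Df)
    du <- du + crossprod(Eb, gs) / sqrt(Df)
  }
  list(dE = dE,
       head = list(w = matrix(crossprod(cf$pool, dlogit), ncol = 1),
                   b = sum(dlogit), u = du))
}

#' COPD probability for a batch of curves
#'
#' Masked temporal attention pooling over the feature embedding followed
#' by a logistic head; padding timesteps receive zero attention.
#'
#' @param curves list of [spiro_curve()] objects.
#' @param model a `spiro_encoder`.
#' @return numeric vector of probabilities in (0, 1).
#' @export
classify_curves <- function(curves, model) {
  pb <- prep_curve_batch(curves)
  if (any(pb$lengths < model$config$r)) {
    abort_spk("curve shorter than downsampling ratio",
              "spirokit_input_error")
  }
  fw <- encoder_forward(pb$x, pb$lengths, model$params, model$config)
  classifier_forward(fw$E, fw$red_lengths, model$params$head)$p
}

# One forward/backward pass on a batch; returns loss and gradients.
# Dropout (inverted scaling) is applied to the feature embedding in
# training only.
encoder_loss_grads <- function(curves, y, params, config) {
  pb <- prep_curve_batch(curves)
  fw <- encoder_forward(pb$x, pb$lengths, params, config)
  E <- fw$E
  mask <- NULL
  if (config$dropout > 0) {
    mask <- array(stats::rbinom(length(E), 1L, 1 - config$dropout) /
                    (1 - config$dropout), dim(E))
    E <- E * mask
  }
  cf <- classifier_forward(E, fw$red_lengths, params$head)
  eps <- 1e-12
  loss <- -mean(y * log(cf$p + eps) + (1 - y) * log(1 - cf$p + eps))
  B <- length(y)
  dlogit <- (cf$p - y) / B
  cb <- classifier_backward(dlogit, cf, fw$red_lengths, params$head,
                            dim(fw$E))
  if (!is.null(mask)) cb$dE <- cb$dE * mask
  eb <- encoder_backward(cb$dE, fw, params, config)
  list(loss = loss,
       grads = list(conv = eb$conv, bilstm = eb$bilstm, head = cb$head),
       p = cf$p)
}

#' Train the CNN-BiLSTM COPD classifier
#'
#' Minimises binary cross-entropy with Adam over minibatches, evaluates
#' validation loss each epoch, and early-stops when validation loss has not
#' improved for `patience` epochs, restoring the best weights. Shuffling
#' and initialisation are seeded through the config, so a fixed seed yields
#' an identical loss trajectory.
#'
#' @param curves,labels training curves (list) and 0/1 labels.
#' @param val_curves,val_labels validation data (may be `NULL` to skip
#'   early stopping).
#' @param config an [encoder_config()].
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs).
#' @param verbose print per-epoch losses.
#' @return a `spiro_encoder` with `history` (data.frame epoch, train_loss,
#'   val_loss).
#' @export
train_encoder <- function(curves, labels, val_curves = NULL,
                          val_labels = NULL, config = encoder_config(),
                          epochs = 20L, batch_size = 32L, lr = 1e-3,
                          patience = 5L, verbose = FALSE) {
  if (length(curves) == 0) abort_spk("empty training set",
                                     "spirokit_input_error")
  stopifnot(length(curves) == length(labels))
  params <- encoder_init(config)
  state <- adam_init(params)
  n <- length(curves)
  best <- list(loss = Inf, params = params, since = 0L)
  hist <- list()
  val_loss_of <- function(ps) {
    if (is.null(val_curves)) return(NA_real_)
    pb <- prep_curve_batch(val_curves)
    fw <- encoder_forward(pb$x, pb$lengths, ps, config)
    p <- classifier_forward(fw$E, fw$red_lengths, ps$head)$p
    -mean(val_labels * log(p + 1e-12) +
            (1 - val_labels) * log(1 - p + 1e-12))
  }
  with_seed(config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, n)]
        lg <- encoder_loss_grads(curves[sel], labels[sel], params, config)
        st <- adam_step(params, lg$grads, state, lr = lr)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      vl <- val_loss_of(params)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                               val_loss = vl)
      if (verbose) message(sprintf("epoch %d train %.4f val %.4f",
                                   ep, ep_loss / nb, vl))
      if (!is.na(vl)) {
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, params = params, since = 0L)
        } else {
          best$since <- best$since + 1L
          if (best$since >= patience) break
        }
      } else {
        best$params <- params
      }
    }
  })
  structure(list(config = config, params = best$params,
                 history = do.call(rbind, hist)),
            class = "spiro_encoder")
}

#' Saliency map from final-layer activations
#'
#' Maps the encoder's final-layer activations onto the input grid as an
#' attention-style weight per timestep, linearly upsampled from the
#' reduced temporal resolution and min-max normalised to [0, 1].
#'
#' Three readouts are available. The default, `"attention"`, uses the
#' classifier's own temporal attention weights over the final-layer
#' activations — the weights the model learned in order to pool diagnostic
#' evidence, which on trained models concentrate on the descending limb
#' for diseased and normal curves alike. `"class_evidence"` is the
#' magnitude of each timestep's contribution to the COPD logit (a
#' CAM-style non-gradient map); `"activation_norm"` the plain L2 norm of
#' the activations, which tracks signal magnitude rather than diagnostic
#' evidence. All-equal readouts yield a uniform map of ones with a
#' warning.
#'
#' @param curve a [spiro_curve()].
#' @param model a `spiro_encoder`.
#' @param method `"attention"` (default), `"class_evidence"`, or
#'   `"activation_norm"`.
#' @return object of class `spiro_saliency`: list with `weight` (length of
#'   the curve, in [0, 1], max 1), `time_s`, `flow_lps`.
#' @export
encoder_saliency <- function(curve, model,
                             method = c("attention", "class_evidence",
                                        "activation_norm")) {
  method <- match.arg(method)
  pb <- prep_curve_batch(list(curve))
  if (pb$lengths[1] < model$config$r) {
    abort_spk("curve shorter than downsampling ratio",
              "spirokit_input_error")
  }
  fw <- encoder_forward(pb$x, pb$lengths, model$params, model$config)
  l <- fw$red_lengths[1]
  E <- matrix(fw$E[1, seq_len(l), ], l, model$config$d_feat)
  norms <- switch(method,
    attention = classifier_forward(fw$E, fw$red_lengths,
                                   model$params$head)$alpha[[1]],
    class_evidence = abs(drop(E %*% model$params$head$w)),
    activation_norm = sqrt(rowSums(E^2)))
  Tn <- length(curve$flow)
  w <- if (length(norms) == 1L) rep(norms, Tn) else {
    stats::approx(seq(1, Tn, length.out = length(norms)), norms,
                  xout = seq_len(Tn))$y
  }
  rng <- range(w)
  if (diff(rng) < 1e-12) {
    warning("degenerate (all-equal) activations; uniform saliency map")
    w <- rep(1, Tn)
  } else {
    w <- (w - rng[1]) / diff(rng)
  }
  structure(list(weight = w,
                 time_s = (seq_len(Tn) - 1L) * curve$dt,
                 flow_lps = curve$flow),
            class = "spiro_saliency")
}

#' Export a saliency map as CSV (`time_s,flow_lps,weight`)
#'
#' @param sal a `spiro_saliency`.
#' @param path output CSV path.
#' @param plot_path optional PNG path for a flow-vs-time rendering with
#'   saliency colouring.
#' @return `path`, invisibly.
#' @export
write_saliency_csv <- function(sal, path, plot_path = NULL) {
  utils::write.csv(data.frame(time_s = sal$time_s, flow_lps = sal$flow_lps,
                              weight = sal$weight),
                   path, row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 800, height = 400)
    on.exit(grDevices::dev.off())
    cols <- grDevices::rgb(sal$weight, 0.2, 1 - sal$weight)
    plot(sal$time_s, sal$flow_lps, col = cols, pch = 16, cex = 0.4,
         xlab = "time (s)", ylab = "flow (L/s)",
         main = "expiratory flow, saliency-coloured")
  }
  invisible(path)
}

# --- checkpoint (single JSON file: config + weights + seed) -----------------

flatten_arrays <- function(x) {
  if (is.list(x)) return(lapply(x, flatten_arrays))
  list(dim = if (is.null(dim(x))) length(x) else dim(x), data = as.numeric(x))
}

unflatten_arrays <- function(x) {
  if (!is.null(x$dim) && !is.null(x$data)) {
    d <- as.integer(unlist(x$dim))
    v <- as.numeric(unlist(x$data))
    if (length(d) == 1L) return(v)
    return(array(v, d))
  }
  lapply(x, unflatten_arrays)
}

#' Save / load an encoder checkpoint
#'
#' Checkpoints are a single JSON file holding the config (including its
#' seed) and all weights.
#'
#' @param model a `spiro_encoder`.
#' @param path checkpoint path (`.json`).
#' @return `save_encoder` returns `path` invisibly; `load_encoder` a
#'   `spiro_encoder`.
#' @export
save_encoder <- function(model, path) {
  obj <- list(config = unclass(model$config),
              params = flatten_arrays(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  cfg <- do.call(encoder_config, obj$config[c("conv_channels", "kernels",
                                              "lstm_hidden", "dropout",
                                              "seed")])
  params <- unflatten_arrays(obj$params)
  # restore matrix shapes for head
  params$head$w <- matrix(params$head$w, ncol = 1)
  params$head$u <- matrix(params$head$u, ncol = 1)
  structure(list(config = cfg, params = params, history = NULL),
            class = "spiro_encoder")
}
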