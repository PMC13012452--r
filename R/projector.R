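#' Cross-modal projector parameters
#'
#' A two-layer perceptron that maps encoder features (width `d_feat`) into
#' a language-model embedding space (width `d_llm`):
#' `P = Dropout(ReLU(E W1 + b1)) W2 + b2`, applied row-wise to the feature
#' matrix. Dropout is active only in training mode.
#'
#' @param d_feat input feature width.
#' @param d_llm target embedding width (default 256; the width itself does
#'   not affect correctness and is configurable).
#' @param dropout_rate dropout probability in training mode.
#' @param seed integer initialisation seed.
#' @return an object of class `spiro_projector` with fields `W1, b1, W2,
#'   b2, dropout_rate, d_feat, d_llm`.
#' @export
projector_params <- function(d_feat, d_llm = 256L, dropout_rate = 0.1,
                             seed = 1L) {
  stopifnot(d_feat >= 1, d_llm >= 1, dropout_rate >= 0, dropout_rate < 1)
  with_seed(seed, {
    s1 <- sqrt(2 / d_feat); s2 <- sqrt(2 / d_llm)
    structure(list(
      W1 = matrix(stats::rnorm(d_feat * d_llm, sd = s1), d_feat, d_llm),
      b1 = numeric(d_llm),
      W2 = matrix(stats::rnorm(d_llm * d_llm, sd = s2), d_llm, d_llm),
      b2 = numeric(d_llm),
      dropout_rate = dropout_rate,
      d_feat = as.integer(d_feat), d_llm = as.integer(d_llm)),
      class = "spiro_projector")
  })
}

#' @export
print.spiro_projector <- function(x, ...) {
  cat(sprintf("<spiro_projector> %d -> %d (dropout %.2f)\n",
              x$d_feat, x$d_llm, x$dropout_rate))
  invisible(x)
}

#' Project a feature embedding into the language-model space
#'
#' @param E feature matrix (`L x d_feat`).
#' @param params a [projector_params()].
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @param seed seed for the training-mode dropout mask.
#' @return projected matrix (`L x d_llm`).
#' @export
project_embedding <- function(E, params, mode = c("eval", "train"),
                              seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "spiro_projector"))
  E <- as.matrix(E)
  if (ncol(E) != params$d_feat) {
    abort_spk(sprintf("embedding width %d != projector d_feat %d",
                      ncol(E), params$d_feat), "spirokit_shape_error")
  }
  H <- pmax(sweep(E %*% params$W1, 2, params$b1, `+`), 0)
  if (mode == "train" && params$dropout_rate > 0) {
    keep <- 1 - params$dropout_rate
    mask <- with_seed(seed, matrix(stats::rbinom(length(H), 1L, keep),
                                   nrow(H), ncol(H)))
    H <- H * mask / keep
  }
  sweep(H %*% params$W2, 2, params$b2, `+`)
}

#' Pre-train the projector against target embeddings
#'
#' With the encoder frozen upstream, minimises the mean squared alignment
#' loss between projected features and target embedding sequences (as
#' produced by any pluggable text-embedding function) using Adam. This is
#' the desk-scale analogue of aligning signal features with the embeddings
#' of curve-morphology descriptions.
#'
#' @param E_list list of feature matrices (`L_i x d_feat`).
#' @param target_list list of target matrices (`L_i x d_llm`).
#' @param params a [projector_params()].
#' @param epochs full passes over the pairs.
#' @param lr Adam learning rate.
#' @param use_dropout apply training-mode dropout during pre-training.
#' @param seed seed controlling dropout masks.
#' @return list with `params` (trained) and `history` (per-epoch MSE).
#' @export
pretrain_projector <- function(E_list, target_list, params, epochs = 100L,
                               lr = 1e-2, use_dropout = FALSE, seed = 1L) {
  stopifnot(length(E_list) == length(target_list), length(E_list) >= 1)
  for (i in seq_along(E_list)) {
    if (ncol(as.matrix(E_list[[i]])) != params$d_feat ||
        ncol(as.matrix(target_list[[i]])) != params$d_llm ||
        nrow(as.matrix(E_list[[i]])) != nrow(as.matrix(target_list[[i]]))) {
      abort_spk("inconsistent widths between features and targets",
                "spirokit_shape_error")
    }
  }
  theta <- params[c("W1", "b1", "W2", "b2")]
  state <- adam_init(theta)
  hist <- numeric(epochs)
  keep <- 1 - params$dropout_rate
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      g <- list(W1 = theta$W1 * 0, b1 = theta$b1 * 0,
                W2 = theta$W2 * 0, b2 = theta$b2 * 0)
      total <- 0; n_el <- 0
      for (i in seq_along(E_list)) {
        E <- as.matrix(E_list[[i]]); Tg <- as.matrix(target_list[[i]])
        H1 <- sweep(E %*% theta$W1, 2, theta$b1, `+`)
        A <- pmax(H1, 0)
        if (use_dropout && params$dropout_rate > 0) {
          mask <- matrix(stats::rbinom(length(A), 1L, keep),
                         nrow(A), ncol(A)) / keep
          A <- A * mask
        }
        P <- sweep(A %*% theta$W2, 2, theta$b2, `+`)
        R <- P - Tg
        total <- total + sum(R^2); n_el <- n_el + length(R)
        dP <- 2 * R
        g$W2 <- g$W2 + crossprod(A, dP)
        g$b2 <- g$b2 + colSums(dP)
        dA <- dP %*% t(theta$W2)
        if (use_dropout && params$dropout_rate > 0) dA <- dA * mask
        dH1 <- dA * (H1 > 0)
        g$W1 <- g$W1 + crossprod(E, dH1)
        g$b1 <- g$b1 + colSums(dH1)
      }
      g <- lapply(g, function(x) x / n_el)
      hist[ep] <- total / n_el
      st <- adam_step(theta, g, state, lr = lr)
      theta <- st$params; state <- st$state
    }
  })
  params$W1 <- theta$W1; params$b1 <- theta$b1
  params$W2 <- theta$W2; params$b2 <- theta$b2
  list(params = params, history = hist)
}
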