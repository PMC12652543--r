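#' Configuration for the autoencoder dimension-reduction stage
#'
#' A single-hidden-layer autoencoder with tied, unit-norm encoder columns
#' (weight normalization), free per-unit decoder scales and a linear output
#' layer, trained by proximal gradient descent to reconstruct the clean
#' input from a corrupted copy. Corruption is random dropout
#' (`noise_kind = "mask"`: each entry independently zeroed with probability
#' `input_dropout_rate`) or additive Gaussian noise. The L1 weight penalty is
#' applied as a proximal soft-threshold on the encoder columns, which makes
#' the training dynamics behave like thresholded power iteration and lets
#' the encoder perform sparse feature selection — the property that allows
#' it to recover weak correlated signal blocks buried in high-dimensional
#' noise (see the methods vignette). The L2 penalty acts on the decoder
#' scales; `activation_l1` adds an L1 sparsity penalty on latent
#' activations (the sparse-autoencoder variant).
#'
#' @param noise_kind "mask" (random dropout) or "gaussian".
#' @param input_dropout_rate corruption probability for mask noise (0 trains
#'   an uncorrupted autoencoder).
#' @param hidden_dropout_rate dropout on latent activations during training;
#'   default 0 — under weight normalization the regularization it would
#'   provide is already supplied by the unit-norm constraint and L1, and
#'   nonzero rates degrade the sparse recovery (vignette).
#' @param gaussian_sigma2 noise variance when `noise_kind = "gaussian"`.
#' @param l1_penalty sparse-coding penalty on encoder weights, expressed as
#'   a relative proximal soft-threshold: at every step each encoder column
#'   is soft-thresholded at `learning_rate * l1_penalty * mad(|gradient|)`
#'   of that column. Scaling the threshold to the gradient's noise floor
#'   keeps the selection behavior stable across noise levels; 0 disables
#'   sparsity.
#' @param l2_penalty ridge penalty on the decoder scales.
#' @param activation_l1 L1 penalty on latent activations, 0 off.
#' @param activation "identity" (default) or "relu" for the encoder.
#' @param hidden_size_grid candidate latent widths for
#'   [grid_search_hidden()]; the first entry is the default width for a
#'   direct [train_dae()] call.
#' @param epochs number of full passes of proximal gradient descent.
#' @param learning_rate step size.
#' @param batch_size minibatch size; `NULL` (default) trains full-batch.
#' @param validation_fraction held-out fraction for the validation loss
#'   trace and width selection.
#' @param standardize center/scale each feature before training (replayed at
#'   encode time).
#' @param seed integer seed for the split, initialization, corruption and
#'   dropout draws.
#' @return object of class `dae_config`.
#' @export
dae_config <- function(noise_kind = c("mask", "gaussian"),
                       input_dropout_rate = 0.1, hidden_dropout_rate = 0,
                       gaussian_sigma2 = 1,
                       l1_penalty = 3, l2_penalty = 0.1,
                       activation_l1 = 0,
                       activation = c("identity", "relu"),
                       hidden_size_grid = 16L,
                       epochs = 400L, learning_rate = 0.05,
                       batch_size = NULL, validation_fraction = 0.1,
                       standardize = TRUE, seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  activation <- match.arg(activation)
  if (input_dropout_rate < 0 || input_dropout_rate >= 1) {
    stop("input_dropout_rate must be in [0, 1)")
  }
  if (hidden_dropout_rate < 0 || hidden_dropout_rate >= 1) {
    stop("hidden_dropout_rate must be in [0, 1)")
  }
  if (input_dropout_rate > 0.5 || hidden_dropout_rate > 0.5) {
    warning("dropout rates above 0.5 are outside the supported sensitivity range [0, 0.5]")
  }
  if (l1_penalty < 0 || l2_penalty < 0 || activation_l1 < 0) {
    stop("penalties must be nonnegative")
  }
  if (length(hidden_size_grid) < 1) stop("hidden_size_grid must be nonempty")
  structure(list(
    noise_kind = noise_kind,
    input_dropout_rate = input_dropout_rate,
    hidden_dropout_rate = hidden_dropout_rate,
    gaussian_sigma2 = gaussian_sigma2,
    l1_penalty = l1_penalty, l2_penalty = l2_penalty,
    activation_l1 = activation_l1, activation = activation,
    hidden_size_grid = as.integer(hidden_size_grid),
    epochs = as.integer(epochs), learning_rate = learning_rate,
    batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
    validation_fraction = validation_fraction,
    standardize = standardize, seed = as.integer(seed)),
    class = "dae_config")
}

#' Corrupt an input matrix for denoising-autoencoder training
#'
#' @param x numeric matrix (samples x features).
#' @param config a [dae_config()]; `noise_kind` selects masking (independent
#'   zeroing with probability `input_dropout_rate`) or additive Gaussian
#'   noise with variance `gaussian_sigma2`.
#' @param seed RNG seed; `NULL` uses the current RNG stream.
#' @return matrix of the same shape.
#' @export
apply_noise <- function(x, config, seed = NULL) {
  stop_if_not_matrix(x)
  with_local_seed(seed, {
    if (config$noise_kind == "mask") {
      if (config$input_dropout_rate == 0) return(x)
      # column-major recycling: equivalent to an elementwise mask matrix
      x * (stats::runif(length(x)) >= config$input_dropout_rate)
    } else {
      x + matrix(stats::rnorm(length(x), sd = sqrt(config$gaussian_sigma2)),
                 nrow(x), ncol(x))
    }
  })
}

unit_cols <- function(W) sweep(W, 2, pmax(sqrt(colSums(W * W)), 1e-12), "/")

# column-wise MAD of |A| (1.4826 consistency constant), lean inner loop
col_mads_abs <- function(A) {
  h <- ncol(A)
  out <- numeric(h)
  for (j in seq_len(h)) {
    v <- abs(A[, j])
    m <- stats::median.default(v)
    out[j] <- 1.4826 * stats::median.default(abs(v - m))
  }
  out
}

#' Train a (denoising) autoencoder on one omic
#'
#' Minimizes the mean (per-sample) squared reconstruction error between the
#' clean input and the decoded output of the corrupted input, under an L1
#' proximal penalty on the tied encoder weights, a ridge penalty on the
#' decoder scales and, optionally, an L1 penalty on latent activations.
#' Encoder columns are renormalized to unit length after every step; a
#' column shrunk to zero by the soft-threshold is reseeded from the
#' initialization distribution so capacity is never lost. Fully
#' deterministic given `config$seed`.
#'
#' @param x numeric matrix, samples x features, at least 2 samples.
#' @param config a [dae_config()].
#' @param hidden_size latent width; defaults to the first entry of
#'   `config$hidden_size_grid`.
#' @return object of class `dae_model` with the trained weights (`W`,
#'   `bias`, decoder scales `alpha`, output bias), the feature scaling, and
#'   `loss` — a data frame of per-epoch training and validation
#'   reconstruction MSE (per matrix entry, on the standardized scale when
#'   `standardize` is on).
#' @export
train_dae <- function(x, config, hidden_size = config$hidden_size_grid[1]) {
  stop_if_not_matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 samples")
  h <- as.integer(hidden_size)
  if (h >= p) {
    stop(sprintf("latent width %d must be smaller than the input width %d",
                 h, p))
  }

  center <- rep(0, p); scale_ <- rep(1, p)
  if (config$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ < 1e-8] <- 1
  }
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  relu_on <- config$activation == "relu"
  # the per-sample objective scales with the input's mean square, so the
  # step size must shrink accordingly for unstandardized inputs
  lr <- config$learning_rate / max(1, mean(xs * xs))
  dh <- config$hidden_dropout_rate

  with_local_seed(config$seed, {
    # validation_fraction = 0 trains on every sample (no held-out trace);
    # the split is only needed when widths compete in grid_search_hidden()
    n_val <- floor(config$validation_fraction * n)
    if (n_val >= n) n_val <- n - 1L
    if (n_val > 0) {
      val_idx <- sample.int(n, n_val)
      tr <- xs[-val_idx, , drop = FALSE]
      va <- xs[val_idx, , drop = FALSE]
    } else {
      tr <- xs
      va <- NULL
    }
    ntr <- nrow(tr)
    bs <- if (is.null(config$batch_size)) ntr else min(config$batch_size, ntr)

    W <- unit_cols(matrix(stats::rnorm(p * h, sd = sqrt(1 / p)), p, h))
    if (config$l1_penalty == 0) {
      # without a sparsity constraint the optimal encoder subspace is the
      # principal subspace: warm-start there (classic PCA pretraining)
      xc <- sweep(tr, 2, colMeans(tr), "-")
      nv <- min(h, nrow(tr), p)
      W[, seq_len(nv)] <- svd(xc, nu = 0, nv = nv)$v
    }
    bias <- rep(0, h)
    alpha <- rep(1, h)
    out_bias <- rep(0, p)
    trace_train <- numeric(config$epochs)
    trace_val <- numeric(config$epochs)
    # bold-driver safeguard: strongly structured inputs can destabilize the
    # fixed step; on a non-finite or sharply increased epoch loss the last
    # epoch's parameters are restored and the step is halved
    step_mult <- 1
    best_loss <- Inf
    snapshot <- list(W = W, bias = bias, alpha = alpha, out_bias = out_bias)

    for (ep in seq_len(config$epochs)) {
      lr_t <- lr * step_mult
      blown <- FALSE
      ord <- if (bs < ntr) sample.int(ntr) else seq_len(ntr)
      ep_loss <- 0; ep_n <- 0
      for (start in seq(1L, ntr, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, ntr)]
        clean <- tr[idx, , drop = FALSE]
        nb <- length(idx)
        # inline corruption (validated input; same draws as apply_noise)
        noisy <- if (config$noise_kind == "mask") {
          if (config$input_dropout_rate > 0) {
            clean * (stats::runif(length(clean)) >= config$input_dropout_rate)
          } else clean
        } else {
          clean + stats::rnorm(length(clean),
                               sd = sqrt(config$gaussian_sigma2))
        }
        Z0 <- noisy %*% W
        Z0 <- Z0 + rep(bias, each = nb)
        Z <- if (relu_on) pmax(Z0, 0) else Z0
        if (dh > 0) {
          Mh <- (matrix(stats::runif(nb * h), nb, h) >= dh) / (1 - dh)
          Zd <- Z * Mh
        } else Zd <- Z
        recon <- tcrossprod(Zd * rep(alpha, each = nb), W)
        recon <- recon + rep(out_bias, each = nb)
        E <- recon - clean
        loss <- sum(E * E) / length(E)
        if (!is.finite(loss)) { blown <- TRUE; break }
        ep_loss <- ep_loss + loss * nb; ep_n <- ep_n + nb

        Dl <- E * (2 / nb)
        DlW <- Dl %*% W
        g_alpha <- colSums(Zd * DlW) + config$l2_penalty * alpha
        g_dec <- crossprod(Dl, Zd) * rep(alpha, each = p)
        Dz <- DlW * rep(alpha, each = nb)
        if (dh > 0) Dz <- Dz * Mh
        if (config$activation_l1 > 0) {
          Dz <- Dz + config$activation_l1 * sign(Z) / nb
        }
        if (relu_on) Dz <- Dz * (Z0 > 0)
        g_enc <- crossprod(noisy, Dz)

        g_W <- g_dec + g_enc
        W <- W - lr_t * g_W
        if (config$l1_penalty > 0) {
          # proximal step; threshold level tracks the gradient's noise floor
          thr <- lr_t * config$l1_penalty * col_mads_abs(g_W)
          W <- sign(W) * pmax(abs(W) - rep(thr, each = p), 0)
        }
        nrm <- sqrt(colSums(W * W))
        dead <- nrm < 1e-8
        if (any(dead)) {
          W[, dead] <- matrix(stats::rnorm(p * sum(dead), sd = sqrt(1 / p)),
                              p, sum(dead))
          alpha[dead] <- 1
          bias[dead] <- 0
        }
        W <- unit_cols(W)
        alpha <- alpha - lr_t * g_alpha
        bias <- bias - lr_t * colSums(Dz)
        out_bias <- out_bias - lr_t * colSums(Dl)
      }
      ep_train <- if (ep_n > 0) ep_loss / ep_n else NaN
      # only genuine blow-ups trigger the revert: two-timescale dynamics
      # oscillate benignly within an order of magnitude of the best loss
      if (blown || !is.finite(ep_train) || ep_train > 100 * best_loss) {
        # restore the last stable state and retry more cautiously
        W <- snapshot$W; bias <- snapshot$bias
        alpha <- snapshot$alpha; out_bias <- snapshot$out_bias
        step_mult <- step_mult / 2
        if (step_mult < 1e-4) {
          stop(sprintf(
            "training unstable at width %d: non-finite loss persists at minimal step (epoch %d)",
            h, ep))
        }
        trace_train[ep] <- if (ep > 1) trace_train[ep - 1L] else NA_real_
        trace_val[ep] <- if (ep > 1) trace_val[ep - 1L] else NA_real_
        next
      }
      trace_train[ep] <- ep_train
      if (ep_train < best_loss) {
        best_loss <- ep_train
        snapshot <- list(W = W, bias = bias, alpha = alpha,
                         out_bias = out_bias)
      }
      step_mult <- min(1, step_mult * 1.05)
      if (!is.null(va)) {
        Zv0 <- sweep(va %*% W, 2, bias, "+")
        Zv <- if (relu_on) pmax(Zv0, 0) else Zv0
        rv <- sweep(Zv %*% (alpha * t(W)), 2, out_bias, "+")
        trace_val[ep] <- mean((va - rv)^2)
        if (!is.finite(trace_val[ep])) {
          stop(sprintf("non-finite validation loss at epoch %d (width %d)", ep, h))
        }
      } else {
        trace_val[ep] <- NA_real_
      }
    }

    structure(list(
      W = W, bias = bias, alpha = alpha, out_bias = out_bias,
      hidden_size = h, config = config,
      center = center, scale = scale_, p = p,
      feature_names = colnames(x),
      loss = data.frame(epoch = seq_len(config$epochs),
                        train = trace_train, validation = trace_val)),
      class = "dae_model")
  })
}

#' @export
print.dae_model <- function(x, ...) {
  cat(sprintf(
    "dae_model: %d -> %d (%s), final train/val MSE %.4g/%.4g, nnz %.1f%%\n",
    x$p, x$hidden_size, x$config$activation,
    x$loss$train[nrow(x$loss)], x$loss$validation[nrow(x$loss)],
    100 * mean(abs(x$W) > 1e-10)))
  invisible(x)
}

#' Encode samples into the learned latent space
#'
#' Applies the stored feature scaling and the encoder to the clean input,
#' with corruption and dropout disabled: deterministic, and duplicate input
#' rows map to identical latent rows.
#'
#' @param x matrix with the same features the model was trained on.
#' @param model a `dae_model` from [train_dae()].
#' @return samples x latent-width matrix (class `latent_matrix`) with the
#'   sample identifiers of `x` as row names.
#' @export
encode <- function(x, model) {
  stop_if_not_matrix(x)
  if (ncol(x) != model$p) {
    stop(sprintf("feature mismatch: model trained on %d features, got %d",
                 model$p, ncol(x)))
  }
  xs <- sweep(sweep(x, 2, model$center, "-"), 2, model$scale, "/")
  z <- sweep(xs %*% model$W, 2, model$bias, "+")
  if (model$config$activation == "relu") z <- pmax(z, 0)
  rownames(z) <- rownames(x)
  class(z) <- c("latent_matrix", class(z))
  z
}

#' Select the latent width by grid search
#'
#' Trains one model per candidate width under identical seeds and training
#' schedules and returns the width with the smallest final held-out
#' reconstruction MSE; ties (within 1e-9) go to the smaller width.
#'
#' @param x samples x features matrix.
#' @param config a [dae_config()] whose `hidden_size_grid` lists the
#'   candidates.
#' @return list with `hidden_size` (chosen), `losses` (named final
#'   validation MSE per width) and `model` (the winning `dae_model`).
#' @export
grid_search_hidden <- function(x, config) {
  grid <- sort(unique(config$hidden_size_grid))
  if (length(grid) == 0) stop("hidden_size_grid is empty")
  if (config$validation_fraction <= 0) {
    stop("grid search needs validation_fraction > 0 to compare widths")
  }
  losses <- rep(NA_real_, length(grid))
  names(losses) <- grid
  best <- NULL; best_loss <- Inf; best_width <- NA_integer_
  for (i in seq_along(grid)) {
    w <- grid[i]
    model <- tryCatch(train_dae(x, config, hidden_size = w),
                      error = function(e) {
                        stop(sprintf("training failed at width %d: %s",
                                     w, conditionMessage(e)), call. = FALSE)
                      })
    losses[i] <- model$loss$validation[nrow(model$loss)]
    if (losses[i] < best_loss - 1e-9) {
      best_loss <- losses[i]; best <- model; best_width <- w
    }
  }
  list(hidden_size = best_width, losses = losses, model = best)
}
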