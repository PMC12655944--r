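#' Outcome class levels
#'
#' Fixed class order used everywhere: `favorable` (survival) first,
#' `unfavorable` (death) second. Prediction ties break toward the first
#' class; metrics treat `unfavorable` as the positive class by default.
#'
#' @return Character vector of length 2.
#' @export
outcome_levels <- function() c("favorable", "unfavorable")

#' Specify a CNN-LSTM architecture
#'
#' Describes one fusion network: up to five 1-D convolution blocks
#' (convolution over time, activation, max pooling), up to three stacked
#' LSTM layers, and up to two dense layers before the 2-way softmax output.
#'
#' @param conv_layers List of blocks, each `list(filters, kernel_size,
#'   pool_size, activation)`; kernels must be odd ("same" padding).
#' @param lstm_layers List of `list(units)`; the last layer's width is the
#'   latent dimension fused with the auxiliary features.
#' @param dense_layers List of `list(units, dropout)` with dropout in [0, 1).
#' @param training List: `learning_rate`, `batch_size`, `epochs`,
#'   `optimizer` (`adam`, `rmsprop` or `sgd`).
#' @return An `architecture_spec`.
#' @export
#' @examples
#' architecture_spec(
#'   conv_layers = list(list(filters = 8, kernel_size = 5, pool_size = 4,
#'                           activation = "relu")),
#'   lstm_layers = list(list(units = 16)),
#'   dense_layers = list(list(units = 16, dropout = 0.2)),
#'   training = list(learning_rate = 1e-3, batch_size = 16, epochs = 5,
#'                   optimizer = "adam"))
architecture_spec <- function(conv_layers, lstm_layers, dense_layers, training) {
  assert_that(length(conv_layers) >= 1 && length(conv_layers) <= 5,
              "between 1 and 5 convolution layers are supported",
              class = "comafusion_architecture_error")
  assert_that(length(lstm_layers) >= 1 && length(lstm_layers) <= 3,
              "between 1 and 3 LSTM layers are supported",
              class = "comafusion_architecture_error")
  assert_that(length(dense_layers) >= 0 && length(dense_layers) <= 2,
              "at most 2 dense layers are supported",
              class = "comafusion_architecture_error")
  for (cl in conv_layers) {
    assert_that(cl$filters >= 1 && cl$kernel_size >= 1 && cl$pool_size >= 1,
                "convolution layer counts must be positive",
                class = "comafusion_architecture_error")
    assert_that(cl$kernel_size %% 2 == 1, "kernel sizes must be odd",
                class = "comafusion_architecture_error")
  }
  for (ll in lstm_layers) {
    assert_that(ll$units >= 1, "LSTM units must be positive",
                class = "comafusion_architecture_error")
  }
  for (dl in dense_layers) {
    assert_that(dl$units >= 1 && dl$dropout >= 0 && dl$dropout < 1,
                "dense layers need positive units and dropout in [0, 1)",
                class = "comafusion_architecture_error")
  }
  assert_that(training$learning_rate > 0 && training$batch_size >= 1 &&
                training$epochs >= 0,
              "training parameters must be positive",
              class = "comafusion_architecture_error")
  structure(list(conv_layers = conv_layers, lstm_layers = lstm_layers,
                 dense_layers = dense_layers, training = training),
            class = "architecture_spec")
}

#' Reference fusion architecture
#'
#' The packaged reference configuration: a 128-unit LSTM latent state (the
#' documented latent width of the study's best model) with two convolution
#' blocks, one dense layer and Adam training defaults drawn from the genome
#' schema's domains.
#'
#' @return An [architecture_spec()].
#' @export
reference_architecture <- function() {
  architecture_spec(
    conv_layers = list(
      list(filters = 32, kernel_size = 7, pool_size = 4, activation = "relu"),
      list(filters = 32, kernel_size = 5, pool_size = 4, activation = "relu")),
    lstm_layers = list(list(units = 128)),
    dense_layers = list(list(units = 64, dropout = 0.2)),
    training = list(learning_rate = 1e-3, batch_size = 16, epochs = 15,
                    optimizer = "adam"))
}

#' Stack EEG segments into a fixed-shape tensor
#'
#' Converts the `signal` list-column (channels x samples matrices) into a
#' batch-by-time-by-channels array. Segments longer than `n_samples` are
#' truncated, shorter ones zero-padded, so cohorts recorded at different
#' sampling rates share one tensor shape. Optionally z-scores each channel
#' of each segment over time (standard deviation 0 clamps to 1).
#'
#' @param segments Segment tibble with a `signal` list-column.
#' @param n_samples Target sample count; default the maximum in the batch.
#' @param scale Per-segment, per-channel z-scoring (default `TRUE`).
#' @return Numeric array `n_segments x n_samples x n_channels`.
#' @export
eeg_tensor <- function(segments, n_samples = NULL, scale = TRUE) {
  sigs <- segments$signal
  assert_that(length(sigs) > 0, "no segments to stack")
  n_samples <- n_samples %||% max(vapply(sigs, ncol, integer(1)))
  n_ch <- nrow(sigs[[1]])
  X <- array(0, c(length(sigs), n_samples, n_ch))
  for (i in seq_along(sigs)) {
    s <- sigs[[i]]
    keep <- min(ncol(s), n_samples)
    X[i, seq_len(keep), ] <- t(s[, seq_len(keep), drop = FALSE])
  }
  if (scale) {
    for (i in seq_along(sigs)) {
      m <- matrix(X[i, , ], nrow = n_samples)
      mu <- colMeans(m)
      sdv <- sqrt(colMeans(sweep(m, 2, mu)^2))
      sdv[sdv == 0] <- 1
      X[i, , ] <- sweep(sweep(m, 2, mu), 2, sdv, "/")
    }
  }
  X
}

# temporal length after the pooling chain; error if it collapses
pooled_length <- function(T, conv_layers) {
  for (cl in conv_layers) {
    T <- T %/% cl$pool_size
    if (T < 1) {
      abort("pooling chain collapses the temporal axis below 1 step",
            class = "comafusion_architecture_error")
    }
  }
  T
}

#' Build a hierarchical-fusion CNN-LSTM model
#'
#' Realizes the fusion classifier: stacked 1-D convolutions with max
#' pooling extract a reduced temporal feature map from the raw EEG, stacked
#' LSTMs summarize it into the final hidden state (the latent
#' representation), that latent vector is concatenated with the auxiliary
#' (patient + time-domain) feature vector, and a dense stack ends in a
#' 2-way softmax. With `n_aux_features = 0` the model is the EEG-only
#' CNN-LSTM baseline. The dense stack's input width is, by construction,
#' `D_LSTM + n_aux_features`; it is asserted after building and exposed in
#' `$contract`.
#'
#' @param spec An [architecture_spec()].
#' @param input_shape `c(T, C)`: samples per segment and channel count.
#' @param n_aux_features Number of auxiliary features fused after the LSTM.
#' @param seed Optional seed for weight initialization (otherwise the
#'   current random stream is consumed).
#' @param scale_eeg Z-score each segment's channels before the CNN.
#' @return A `fusion_model` handle.
#' @export
build_fusion_model <- function(spec, input_shape, n_aux_features = 0,
                               seed = NULL, scale_eeg = TRUE) {
  assert_that(inherits(spec, "architecture_spec"), "spec must be an architecture_spec")
  T <- input_shape[1]; C <- input_shape[2]
  Tp <- pooled_length(T, spec$conv_layers)
  init <- function() {
    conv <- list(); d_in <- C
    for (cl in spec$conv_layers) {
      conv[[length(conv) + 1]] <- list(
        W = glorot(cl$kernel_size * d_in, cl$filters),
        b = rep(0, cl$filters),
        K = cl$kernel_size, pool = cl$pool_size, act = cl$activation)
      d_in <- cl$filters
    }
    lstm <- list()
    for (ll in spec$lstm_layers) {
      lstm[[length(lstm) + 1]] <- c(lstm_init(d_in, ll$units), list(H = ll$units))
      d_in <- ll$units
    }
    d_lstm <- d_in
    dense <- list(); d_in <- d_lstm + n_aux_features
    for (dl in spec$dense_layers) {
      dense[[length(dense) + 1]] <- list(W = glorot(d_in, dl$units),
                                         b = rep(0, dl$units),
                                         dropout = dl$dropout)
      d_in <- dl$units
    }
    out <- list(W = glorot(d_in, 2), b = rep(0, 2))
    list(conv = conv, lstm = lstm, dense = dense, out = out, d_lstm = d_lstm)
  }
  net <- if (is.null(seed)) init() else with_local_seed(seed, init())
  d_lstm <- net$d_lstm
  fusion_dim <- d_lstm + n_aux_features
  dense_in <- if (length(net$dense) > 0) nrow(net$dense[[1]]$W) else nrow(net$out$W)
  assert_that(dense_in == fusion_dim,
              "internal error: dense input width != D_LSTM + n_aux_features")
  model <- structure(list(
    net = net, spec = spec, input_shape = input_shape,
    n_aux = n_aux_features, scale_eeg = scale_eeg, trained = FALSE,
    history = NULL,
    contract = list(T = T, C = C, T_prime = Tp,
                    D_CNN = tail(spec$conv_layers, 1)[[1]]$filters,
                    D_LSTM = d_lstm, n_aux = n_aux_features,
                    fusion_dim = fusion_dim)),
    class = c("fusion_model", "comafusion_model"))
  model
}

# full forward pass; returns probabilities and (optionally) caches
fusion_forward <- function(model, eeg, aux, train = FALSE) {
  net <- model$net
  B <- dim(eeg)[1]
  X <- eeg
  conv_caches <- list()
  for (i in seq_along(net$conv)) {
    ly <- net$conv[[i]]
    cv <- conv1d_forward(X, ly$W, ly$b, ly$K)
    a <- act_fun(ly$act)(cv$z)
    mp <- maxpool_forward(a, ly$pool)
    conv_caches[[i]] <- list(conv = cv, pooled = mp, X_in = X)
    X <- mp$out
  }
  lstm_caches <- list()
  lstm_inputs <- list()
  for (i in seq_along(net$lstm)) {
    lstm_inputs[[i]] <- X
    lf <- lstm_forward(X, net$lstm[[i]])
    lstm_caches[[i]] <- lf
    X <- lf$Hseq
  }
  Tp <- dim(X)[2]
  h <- matrix(X[, Tp, ], nrow = B)
  z <- if (model$n_aux > 0) cbind(h, aux) else h
  dense_caches <- list()
  for (i in seq_along(net$dense)) {
    ly <- net$dense[[i]]
    zpre <- sweep(z %*% ly$W, 2, ly$b, "+")
    a <- act_fun("relu")(zpre)
    mask <- NULL
    if (train && ly$dropout > 0) {
      mask <- matrix(runif(length(a)) >= ly$dropout, nrow(a), ncol(a)) /
        (1 - ly$dropout)
      a <- a * mask
    }
    dense_caches[[i]] <- list(z_in = z, zpre = zpre, mask = mask)
    z <- a
  }
  logits <- sweep(z %*% net$out$W, 2, net$out$b, "+")
  list(logits = logits, p = softmax_rows(logits), z_out_in = z,
       conv = conv_caches, lstm = lstm_caches, lstm_inputs = lstm_inputs,
       dense = dense_caches, Tp = Tp, B = B)
}

# backward pass from dlogits; returns flat named list of gradients
fusion_backward <- function(model, fw, dlogits) {
  net <- model$net
  grads <- list()
  grads[["out.W"]] <- crossprod(fw$z_out_in, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dz <- tcrossprod(dlogits, net$out$W)
  for (i in rev(seq_along(net$dense))) {
    ca <- fw$dense[[i]]
    ly <- net$dense[[i]]
    if (!is.null(ca$mask)) dz <- dz * ca$mask
    dzpre <- dz * act_grad("relu")(ca$zpre)
    grads[[paste0("dense", i, ".W")]] <- crossprod(ca$z_in, dzpre)
    grads[[paste0("dense", i, ".b")]] <- colSums(dzpre)
    dz <- tcrossprod(dzpre, ly$W)
  }
  d_lstm <- model$contract$D_LSTM
  dh <- dz[, seq_len(d_lstm), drop = FALSE]  # aux gradient discarded
  dH <- array(0, c(fw$B, fw$Tp, d_lstm))
  dH[, fw$Tp, ] <- dh
  for (i in rev(seq_along(net$lstm))) {
    lb <- lstm_backward(fw$lstm_inputs[[i]], net$lstm[[i]], fw$lstm[[i]], dH)
    grads[[paste0("lstm", i, ".W")]] <- lb$dW
    grads[[paste0("lstm", i, ".U")]] <- lb$dU
    grads[[paste0("lstm", i, ".b")]] <- lb$db
    dH <- lb$dX
  }
  dX <- dH
  for (i in rev(seq_along(net$conv))) {
    ca <- fw$conv[[i]]
    ly <- net$conv[[i]]
    da <- maxpool_backward(ca$pooled, dX)
    dzc <- da * act_grad(ly$act)(ca$conv$z)
    cb <- conv1d_backward(ca$conv, ly$W, ly$K, dzc)
    grads[[paste0("conv", i, ".W")]] <- cb$dW
    grads[[paste0("conv", i, ".b")]] <- cb$db
    dX <- cb$dX
  }
  grads
}

fusion_get_params <- function(net) {
  out <- list()
  for (i in seq_along(net$conv)) {
    out[[paste0("conv", i, ".W")]] <- net$conv[[i]]$W
    out[[paste0("conv", i, ".b")]] <- net$conv[[i]]$b
  }
  for (i in seq_along(net$lstm)) {
    out[[paste0("lstm", i, ".W")]] <- net$lstm[[i]]$W
    out[[paste0("lstm", i, ".U")]] <- net$lstm[[i]]$U
    out[[paste0("lstm", i, ".b")]] <- net$lstm[[i]]$b
  }
  for (i in seq_along(net$dense)) {
    out[[paste0("dense", i, ".W")]] <- net$dense[[i]]$W
    out[[paste0("dense", i, ".b")]] <- net$dense[[i]]$b
  }
  out[["out.W"]] <- net$out$W
  out[["out.b"]] <- net$out$b
  out
}

fusion_set_params <- function(net, params) {
  for (i in seq_along(net$conv)) {
    net$conv[[i]]$W <- params[[paste0("conv", i, ".W")]]
    net$conv[[i]]$b <- params[[paste0("conv", i, ".b")]]
  }
  for (i in seq_along(net$lstm)) {
    net$lstm[[i]]$W <- params[[paste0("lstm", i, ".W")]]
    net$lstm[[i]]$U <- params[[paste0("lstm", i, ".U")]]
    net$lstm[[i]]$b <- params[[paste0("lstm", i, ".b")]]
  }
  for (i in seq_along(net$dense)) {
    net$dense[[i]]$W <- params[[paste0("dense", i, ".W")]]
    net$dense[[i]]$b <- params[[paste0("dense", i, ".b")]]
  }
  net$out$W <- params[["out.W"]]
  net$out$b <- params[["out.b"]]
  net
}

encode_outcome <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  assert_that(all(y %in% outcome_levels()),
              "labels must be 'favorable' or 'unfavorable'")
  match(y, outcome_levels())
}

#' Train a model
#'
#' Mini-batch gradient training of a [build_fusion_model()] or
#' [build_mlp_baseline()] handle. Deterministic given `seed` (weights are
#' kept from the build; shuffling and dropout are seeded here). A non-finite
#' loss aborts with a `comafusion_training_error`.
#'
#' @param model A model handle.
#' @param eeg EEG tensor `B x T x C` (fusion models; ignored for MLPs).
#' @param aux Auxiliary feature matrix `B x n_aux` (or `NULL`).
#' @param y Labels (`favorable`/`unfavorable`).
#' @param x Input feature matrix (MLP models).
#' @param epochs,batch_size,learning_rate,optimizer Override the spec's
#'   training parameters.
#' @param seed Seed for shuffling and dropout.
#' @param ... Unused.
#' @return The trained model; `$history` holds a per-epoch tibble with
#'   `loss` and `accuracy`.
#' @export
train_model <- function(model, ...) UseMethod("train_model")

#' @rdname train_model
#' @export
train_model.fusion_model <- function(model, eeg, aux = NULL, y,
                                     epochs = NULL, batch_size = NULL,
                                     learning_rate = NULL, optimizer = NULL,
                                     seed = 1L, ...) {
  tr <- model$spec$training
  epochs <- epochs %||% tr$epochs
  batch_size <- batch_size %||% tr$batch_size
  learning_rate <- learning_rate %||% tr$learning_rate
  optimizer <- optimizer %||% tr$optimizer
  yi <- encode_outcome(y)
  B <- dim(eeg)[1]
  assert_that(length(yi) == B, "labels must match the batch dimension")
  if (model$n_aux > 0) {
    aux <- as.matrix(aux)
    assert_that(nrow(aux) == B && ncol(aux) == model$n_aux,
                "aux matrix must be B x n_aux")
  }
  if (model$scale_eeg) eeg <- rescale_tensor(eeg)
  params <- fusion_get_params(model$net)
  state <- opt_init(params)
  hist <- vector("list", epochs)
  step <- 0L
  with_local_seed(seed, {
    for (ep in seq_len(max(epochs, 0))) {
      ord <- sample.int(B)
      losses <- c(); accs <- c()
      for (start in seq(1, B, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, B)]
        model$net <- fusion_set_params(model$net, params)
        fw <- fusion_forward(model,
                             eeg[idx, , , drop = FALSE],
                             if (model$n_aux > 0) aux[idx, , drop = FALSE] else NULL,
                             train = TRUE)
        hd <- softmax_ce(fw$logits, yi[idx])
        if (!is.finite(hd$loss)) {
          abort("non-finite training loss", class = "comafusion_training_error")
        }
        losses <- c(losses, hd$loss)
        accs <- c(accs, mean(max.col(hd$p, ties.method = "first") == yi[idx]))
        grads <- fusion_backward(model, fw, hd$dlogits)
        step <- step + 1L
        up <- opt_step(params, grads, state, optimizer, learning_rate, step)
        params <- up$params
        state <- up$state
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                   accuracy = mean(accs))
    }
  })
  model$net <- fusion_set_params(model$net, params)
  model$trained <- TRUE
  model$history <- if (epochs > 0) dplyr::bind_rows(hist) else
    tibble::tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
  model
}

rescale_tensor <- function(eeg) {
  for (i in seq_len(dim(eeg)[1])) {
    m <- matrix(eeg[i, , ], nrow = dim(eeg)[2])
    mu <- colMeans(m)
    sdv <- sqrt(colMeans(sweep(m, 2, mu)^2))
    sdv[sdv == 0] <- 1
    eeg[i, , ] <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  }
  eeg
}

#' Per-segment class probabilities and labels
#'
#' Scores segments with a trained model. Probability ties break toward the
#' first class (`favorable`). Output is invariant to how the batch is
#' partitioned.
#'
#' @param model Trained model handle.
#' @param eeg EEG tensor (fusion models).
#' @param aux Auxiliary matrix (fusion models with `n_aux > 0`).
#' @param x Feature matrix (MLP models).
#' @param ... Unused.
#' @return Tibble: `prob_favorable`, `prob_unfavorable`, `pred` (factor).
#' @export
predict_segments <- function(model, ...) UseMethod("predict_segments")

#' @rdname predict_segments
#' @export
predict_segments.fusion_model <- function(model, eeg, aux = NULL, ...) {
  if (model$scale_eeg) eeg <- rescale_tensor(eeg)
  fw <- fusion_forward(model, eeg,
                       if (model$n_aux > 0) as.matrix(aux) else NULL,
                       train = FALSE)
  p <- fw$p
  pred <- ifelse(p[, 1] >= p[, 2], outcome_levels()[1], outcome_levels()[2])
  tibble::tibble(prob_favorable = p[, 1], prob_unfavorable = p[, 2],
                 pred = factor(pred, levels = outcome_levels()))
}

#' Build the MLP baseline
#'
#' A single-hidden-layer perceptron over auxiliary features only: hidden
#' width equal to the number of inputs (ReLU), one sigmoid output unit,
#' binary cross-entropy loss, trained for 30 epochs with Adam at learning
#' rate 1e-4 by default. The sigmoid output is the probability of the
#' `unfavorable` class.
#'
#' @param n_inputs Number of input features (also the hidden width).
#' @param seed Optional seed for weight initialization.
#' @return An `mlp_model` handle.
#' @export
build_mlp_baseline <- function(n_inputs, seed = NULL) {
  assert_that(n_inputs >= 1, "n_inputs must be positive")
  init <- function() {
    list(hidden = list(W = glorot(n_inputs, n_inputs), b = rep(0, n_inputs)),
         out = list(W = glorot(n_inputs, 1), b = 0))
  }
  net <- if (is.null(seed)) init() else with_local_seed(seed, init())
  structure(list(net = net, n_inputs = n_inputs, trained = FALSE,
                 history = NULL,
                 training = list(learning_rate = 1e-4, batch_size = 32,
                                 epochs = 30, optimizer = "adam")),
            class = c("mlp_model", "comafusion_model"))
}

mlp_forward <- function(net, x) {
  zpre <- sweep(x %*% net$hidden$W, 2, net$hidden$b, "+")
  a <- pmax(zpre, 0)
  z <- a %*% net$out$W + net$out$b
  list(z = z, a = a, zpre = zpre)
}

#' @rdname train_model
#' @export
train_model.mlp_model <- function(model, x, y, epochs = NULL,
                                  batch_size = NULL, learning_rate = NULL,
                                  optimizer = NULL, seed = 1L, ...) {
  tr <- model$training
  epochs <- epochs %||% tr$epochs
  batch_size <- batch_size %||% tr$batch_size
  learning_rate <- learning_rate %||% tr$learning_rate
  optimizer <- optimizer %||% tr$optimizer
  x <- as.matrix(x)
  yb <- encode_outcome(y) - 1  # unfavorable = 1
  B <- nrow(x)
  params <- list(hidden.W = model$net$hidden$W, hidden.b = model$net$hidden$b,
                 out.W = model$net$out$W, out.b = model$net$out$b)
  state <- opt_init(params)
  hist <- vector("list", epochs)
  step <- 0L
  with_local_seed(seed, {
    for (ep in seq_len(max(epochs, 0))) {
      ord <- sample.int(B)
      losses <- c(); accs <- c()
      for (start in seq(1, B, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, B)]
        net <- list(hidden = list(W = params$hidden.W, b = params$hidden.b),
                    out = list(W = params$out.W, b = params$out.b))
        fw <- mlp_forward(net, x[idx, , drop = FALSE])
        hd <- sigmoid_bce(fw$z, yb[idx])
        if (!is.finite(hd$loss)) {
          abort("non-finite training loss", class = "comafusion_training_error")
        }
        losses <- c(losses, hd$loss)
        accs <- c(accs, mean((hd$p > 0.5) == (yb[idx] == 1)))
        dz <- hd$dz
        grads <- list(out.W = crossprod(fw$a, dz), out.b = sum(dz))
        da <- tcrossprod(dz, params$out.W) * (fw$zpre > 0)
        grads$hidden.W <- crossprod(x[idx, , drop = FALSE], da)
        grads$hidden.b <- colSums(da)
        step <- step + 1L
        up <- opt_step(params, grads, state, optimizer, learning_rate, step)
        params <- up$params
        state <- up$state
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                   accuracy = mean(accs))
    }
  })
  model$net <- list(hidden = list(W = params$hidden.W, b = params$hidden.b),
                    out = list(W = params$out.W, b = params$out.b))
  model$trained <- TRUE
  model$history <- if (epochs > 0) dplyr::bind_rows(hist) else
    tibble::tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
  model
}

#' @rdname predict_segments
#' @export
predict_segments.mlp_model <- function(model, x, ...) {
  fw <- mlp_forward(model$net, as.matrix(x))
  p_unf <- as.numeric(sigm(fw$z))
  pred <- ifelse(p_unf > 0.5, outcome_levels()[2], outcome_levels()[1])
  tibble::tibble(prob_favorable = 1 - p_unf, prob_unfavorable = p_unf,
                 pred = factor(pred, levels = outcome_levels()))
}

#' @export
print.fusion_model <- function(x, ...) {
  ct <- x$contract
  cat(sprintf(
    "<fusion_model> T=%d C=%d -> T'=%d x D_CNN=%d -> D_LSTM=%d (+%d aux) -> fusion_dim=%d%s\n",
    ct$T, ct$C, ct$T_prime, ct$D_CNN, ct$D_LSTM, ct$n_aux, ct$fusion_dim,
    if (x$trained) " [trained]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.comafusion_model <- function(x, ...) {
  x$history %||%
    tibble::tibble(epoch = integer(), loss = numeric(), accuracy = numeric())
}

#' @exportS3Method generics::glance
glance.fusion_model <- function(x, ...) {
  n_par <- sum(vapply(fusion_get_params(x$net), length, integer(1)))
  tibble::tibble(n_parameters = n_par,
                 d_lstm = x$contract$D_LSTM,
                 n_aux = x$contract$n_aux,
                 fusion_dim = x$contract$fusion_dim,
                 trained = x$trained,
                 final_loss = if (x$trained && nrow(x$history) > 0)
                   tail(x$history$loss, 1) else NA_real_)
}
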