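#' Configuration of the 1D-convolutional regression head
#'
#' The aggregated length-`F` slide vector is treated as a one-channel
#' sequence and passed through three 1D convolutional blocks (rectified
#' linear activations): C1 with 256 kernels of size 5, C2 and C3 with 512
#' kernels of size 1 (no padding, stride 1).  Under the default
#' `pool_then_dense` ordering the sequence is then global-average pooled
#' and a dense linear layer maps to `output_dim` gene values.  The
#' alternative `conv_out_then_pool` ordering applies the linear output map
#' per position (a 1x1 convolution to `output_dim` channels) and pools
#' afterwards; both orderings are provided because descriptions of this
#' architecture differ on the point, and they coincide in expressive power
#' for this head.
#'
#' @param conv_channels integer vector of channel counts per conv block.
#' @param kernel_sizes integer vector of kernel sizes, same length.
#' @param output_dim number of output genes (default 138).
#' @param ordering_variant `"pool_then_dense"` (default) or
#'   `"conv_out_then_pool"`.
#' @return Object of class `head_config`.
#' @export
head_config <- function(conv_channels = c(256, 512, 512),
                        kernel_sizes = c(5, 1, 1),
                        output_dim = 138,
                        ordering_variant = c("pool_then_dense",
                                             "conv_out_then_pool")) {
  ordering_variant <- match.arg(ordering_variant)
  conv_channels <- as.integer(conv_channels)
  kernel_sizes <- as.integer(kernel_sizes)
  if (length(conv_channels) != length(kernel_sizes))
    stop("conv_channels and kernel_sizes must have the same length")
  stopifnot(all(conv_channels >= 1), all(kernel_sizes >= 1),
            output_dim >= 1)
  structure(list(conv_channels = conv_channels,
                 kernel_sizes = kernel_sizes,
                 output_dim = as.integer(output_dim),
                 ordering_variant = ordering_variant),
            class = "head_config")
}

#' Training configuration for the regression head
#'
#' Defaults follow the recipe the model was designed with: Adam, mean
#' squared error, learning rate 0.001, minibatches of 12, early stopping
#' with patience 4 on a held-out validation split (10% of patients), at
#' most 150 epochs, with the best-loss weights restored at the end.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (>= 1).
#' @param early_stop_patience epochs without improvement before stopping.
#' @param max_epochs epoch cap.
#' @param validation_fraction fraction of patients held out to monitor
#'   early stopping, in `[0, 1)`; 0 monitors the training loss instead.
#' @param seed integer seed for weight initialisation and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 12,
                         early_stop_patience = 4, max_epochs = 150,
                         validation_fraction = 0.1, seed = 1) {
  stopifnot(learning_rate > 0, batch_size >= 1, early_stop_patience >= 1,
            max_epochs >= 1, validation_fraction >= 0,
            validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build (initialise) a regression head
#'
#' Validates the architecture against the input dimension and initialises
#' weights: He-scaled Gaussians for the rectified conv layers, Glorot
#' uniform for the linear output layer, zero biases.
#'
#' @param config a [head_config()].
#' @param input_dim feature dimension `F` (must be at least the first
#'   kernel size).
#' @param seed integer seed for the initialisation.
#' @return Object of class `head_model` with fields `config`, `input_dim`,
#'   `weights` and `seq_lengths` (sequence length after each conv block).
#' @export
build_head <- function(config, input_dim, seed = 1) {
  stopifnot(inherits(config, "head_config"))
  input_dim <- as.integer(input_dim)
  lens <- integer(length(config$kernel_sizes))
  len <- input_dim
  for (l in seq_along(config$kernel_sizes)) {
    if (len < config$kernel_sizes[l])
      stop(sprintf(
        "input/sequence length %d is smaller than kernel size %d at conv block %d",
        len, config$kernel_sizes[l], l))
    len <- len - config$kernel_sizes[l] + 1L
    lens[l] <- len
  }
  with_seed(seed, {
    weights <- list(conv = list(), dense = NULL)
    c_in <- 1L
    for (l in seq_along(config$conv_channels)) {
      k <- config$kernel_sizes[l]; c_out <- config$conv_channels[l]
      fan_in <- k * c_in
      weights$conv[[l]] <- list(
        W = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                   fan_in, c_out),
        b = numeric(c_out))
      c_in <- c_out
    }
    lim <- sqrt(6 / (c_in + config$output_dim))
    weights$dense <- list(
      W = matrix(runif(c_in * config$output_dim, -lim, lim),
                 c_in, config$output_dim),
      b = numeric(config$output_dim))
    structure(list(config = config, input_dim = input_dim,
                   weights = weights, seq_lengths = lens),
              class = "head_model")
  })
}

#' Number of trainable parameters of a head
#' @param model a `head_model` or `trained_head`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  w <- model$weights
  sum(vapply(w$conv, function(l) length(l$W) + length(l$b), numeric(1))) +
    length(w$dense$W) + length(w$dense$b)
}

# ---- forward / backward -----------------------------------------------

# Sliding-window expansion for a valid 1D convolution over batched rows.
# h: (B*L) x C matrix, blocks of L consecutive rows per sample.
# Returns (B*Lout) x (k*C); column block j holds the channels at tap j.
im2col <- function(h, B, L, k) {
  if (k == 1L) return(h)
  Lout <- L - k + 1L
  C <- ncol(h)
  out <- matrix(0, B * Lout, k * C)
  base <- rep((0:(B - 1)) * L, each = Lout) + seq_len(Lout)
  for (j in seq_len(k))
    out[, ((j - 1) * C + 1):(j * C)] <- h[base + (j - 1), , drop = FALSE]
  out
}

col2im <- function(dcol, B, L, k, C) {
  if (k == 1L) return(dcol)
  Lout <- L - k + 1L
  dh <- matrix(0, B * L, C)
  base <- rep((0:(B - 1)) * L, each = Lout) + seq_len(Lout)
  for (j in seq_len(k)) {
    rows <- base + (j - 1)
    dh[rows, ] <- dh[rows, ] + dcol[, ((j - 1) * C + 1):(j * C),
                                    drop = FALSE]
  }
  dh
}

head_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$config; w <- model$weights
  B <- nrow(X)
  h <- matrix(t(X), ncol = 1)           # (B*F) x 1, one channel
  L <- model$input_dim
  cache <- if (keep_cache) list(xcols = list(), acts = list(),
                                lens = integer(0)) else NULL
  c_in <- 1L
  for (l in seq_along(w$conv)) {
    k <- cfg$kernel_sizes[l]
    xcol <- im2col(h, B, L, k)
    z <- sweep(xcol %*% w$conv[[l]]$W, 2, w$conv[[l]]$b, "+")
    a <- pmax(z, 0)
    if (keep_cache) {
      cache$xcols[[l]] <- xcol
      cache$acts[[l]] <- a
      cache$lens[l] <- L
    }
    h <- a
    L <- L - k + 1L
    c_in <- cfg$conv_channels[l]
  }
  group <- rep(seq_len(B), each = L)
  if (cfg$ordering_variant == "pool_then_dense") {
    g <- rowsum(h, group, reorder = FALSE) / L
    out <- sweep(g %*% w$dense$W, 2, w$dense$b, "+")
    if (keep_cache) cache$pooled <- g
  } else {
    p <- sweep(h %*% w$dense$W, 2, w$dense$b, "+")
    out <- rowsum(p, group, reorder = FALSE) / L
  }
  if (keep_cache) { cache$L_last <- L; cache$B <- B }
  if (keep_cache) list(out = out, cache = cache) else out
}

head_backward <- function(model, cache, dout) {
  cfg <- model$config; w <- model$weights
  B <- cache$B; L <- cache$L_last
  nconv <- length(w$conv)
  grads <- list(conv = vector("list", nconv), dense = NULL)
  h_last <- cache$acts[[nconv]]
  if (cfg$ordering_variant == "pool_then_dense") {
    g <- cache$pooled
    grads$dense <- list(W = crossprod(g, dout), b = colSums(dout))
    dg <- dout %*% t(w$dense$W)
    dh <- dg[rep(seq_len(B), each = L), , drop = FALSE] / L
  } else {
    dp <- dout[rep(seq_len(B), each = L), , drop = FALSE] / L
    grads$dense <- list(W = crossprod(h_last, dp), b = colSums(dp))
    dh <- dp %*% t(w$dense$W)
  }
  for (l in rev(seq_len(nconv))) {
    a <- cache$acts[[l]]
    dz <- dh * (a > 0)
    grads$conv[[l]] <- list(W = crossprod(cache$xcols[[l]], dz),
                            b = colSums(dz))
    if (l > 1) {
      dcol <- dz %*% t(w$conv[[l]]$W)
      dh <- col2im(dcol, B, cache$lens[l], cfg$kernel_sizes[l],
                   cfg$conv_channels[l - 1])
    }
  }
  grads
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(weights) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- list(w = w, m = m, v = v)
      for (nm in seq_along(w)) {
        r <- walk(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$w[[nm]] <- r$w; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else upd(w, g, m, v)
  }
  r <- walk(weights, grads, state$m, state$v)
  list(weights = r$w, state = list(m = r$m, v = r$v, t = state$t))
}

# ---- early stopping ---------------------------------------------------

# Epoch at which training halts for a monitored loss series: after
# `patience` consecutive epochs without strict improvement over the best
# loss so far.  Returns list(stop_epoch, best_epoch).
early_stop_epoch <- function(losses, patience) {
  best <- Inf; best_epoch <- 0L; since <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best) {
      best <- losses[e]; best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience)
        return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(losses), best_epoch = best_epoch)
}

mse <- function(pred, truth) mean((pred - truth)^2)

# ---- training ---------------------------------------------------------

align_features_targets <- function(features, targets) {
  if (inherits(features, "synthetic_cohort"))
    features <- aggregate_cohort(features)
  if (is.list(features) && !is.matrix(features))
    features <- aggregate_cohort(features)
  stopifnot(is.matrix(features))
  if (!inherits(targets, "expr_matrix"))
    stop("targets must be an expr_matrix")
  if (expr_scale(targets) != "log2p1")
    stop("targets must be on the log2(1+x) scale; call log_transform() first")
  fids <- rownames(features); tids <- rownames(targets)
  if (is.null(fids) || is.null(tids))
    stop("features and targets must carry patient ids as row names")
  missing_t <- setdiff(fids, tids); missing_f <- setdiff(tids, fids)
  if (length(missing_t) || length(missing_f))
    stop("patient ids do not align; missing from targets: [",
         paste(missing_t, collapse = ", "), "]; missing from features: [",
         paste(missing_f, collapse = ", "), "]")
  list(X = features[fids, , drop = FALSE],
       Y = unclass(targets)[fids, , drop = FALSE])
}

#' Train the regression head on aggregated features
#'
#' Minibatch Adam on the mean-squared-error loss.  A patient-level
#' validation split (fraction `validation_fraction`) is carved out and its
#' loss monitored for early stopping; with `validation_fraction = 0` the
#' training loss is monitored instead.  The weights achieving the lowest
#' monitored loss are restored at the end.  The output-layer bias is
#' initialised at the per-gene mean of the training targets so gene
#' baseline levels do not have to be learned by gradient steps.
#'
#' @param features patients x F matrix with patient-id row names, a list
#'   of [aggregate_features()] results, or a `synthetic_cohort`.
#' @param targets an [expr_matrix()] on the `log2p1` scale, aligned by
#'   patient id.
#' @param train_cfg a [train_config()].
#' @param config a [head_config()]; its `output_dim` is set from the
#'   targets.
#' @return Object of class `trained_head`: fields `config`, `train_cfg`,
#'   `weights` (best), `history` (per-epoch data frame with `epoch`,
#'   `train_loss`, `val_loss`, `monitored`, `samples_seen`), `best_epoch`,
#'   `input_dim`, `gene_symbols`, `samples_per_epoch`.
#' @export
train_head <- function(features, targets, train_cfg = train_config(),
                       config = head_config()) {
  al <- align_features_targets(features, targets)
  train_head_core(al$X, al$Y, train_cfg, config,
                  row_patient = rownames(al$X))
}

# Shared trainer: rows of X are training records (one per patient for the
# aggregation strategy, one per patch for the patch-based reference);
# row_patient groups rows by patient so the validation split never splits
# a patient across sides.
train_head_core <- function(X, Y, train_cfg, config, row_patient) {
  stopifnot(inherits(train_cfg, "train_config"),
            inherits(config, "head_config"))
  config$output_dim <- ncol(Y)
  n <- nrow(X)
  with_seed(train_cfg$seed, {
    patients <- unique(row_patient)
    n_val_pat <- floor(train_cfg$validation_fraction * length(patients))
    val_pat <- if (n_val_pat > 0) sample(patients, n_val_pat) else character(0)
    val_idx <- which(row_patient %in% val_pat)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Xval <- X[val_idx, , drop = FALSE]; Yval <- Y[val_idx, , drop = FALSE]
    batch <- train_cfg$batch_size
    if (nrow(Xtr) < batch) {
      warning(sprintf(
        "fewer training records (%d) than the batch size (%d); falling back to full-batch steps",
        nrow(Xtr), batch))
      batch <- nrow(Xtr)
    }
    model <- build_head(config, ncol(X),
                        seed = sample.int(.Machine$integer.max, 1))
    model$weights$dense$b <- colMeans(Ytr)
    opt <- adam_init(model$weights)
    hist_train <- numeric(0); hist_val <- numeric(0)
    best <- Inf; best_epoch <- 0L; best_weights <- model$weights
    since <- 0L; epoch <- 0L
    while (epoch < train_cfg$max_epochs) {
      epoch <- epoch + 1L
      ord <- sample(nrow(Xtr))
      for (s in seq(1, nrow(Xtr), by = batch)) {
        idx <- ord[s:min(s + batch - 1, nrow(Xtr))]
        fw <- head_forward(model, Xtr[idx, , drop = FALSE],
                           keep_cache = TRUE)
        dout <- 2 * (fw$out - Ytr[idx, , drop = FALSE]) / length(fw$out)
        grads <- head_backward(model, fw$cache, dout)
        st <- adam_step(model$weights, grads, opt, train_cfg$learning_rate)
        model$weights <- st$weights; opt <- st$state
      }
      tr_loss <- mse(head_forward(model, Xtr), Ytr)
      val_loss <- if (length(val_idx))
        mse(head_forward(model, Xval), Yval) else NA_real_
      monitored <- if (length(val_idx)) val_loss else tr_loss
      hist_train <- c(hist_train, tr_loss); hist_val <- c(hist_val, val_loss)
      if (monitored < best) {
        best <- monitored; best_epoch <- epoch
        best_weights <- model$weights; since <- 0L
      } else {
        since <- since + 1L
        if (since >= train_cfg$early_stop_patience) break
      }
    }
    model$weights <- best_weights
    history <- data.frame(
      epoch = seq_len(epoch), train_loss = hist_train, val_loss = hist_val,
      monitored = if (length(val_idx)) hist_val else hist_train,
      samples_seen = nrow(Xtr))
    structure(list(config = config, train_cfg = train_cfg,
                   weights = best_weights, history = history,
                   best_epoch = best_epoch,
                   best_loss = best,
                   input_dim = ncol(X),
                   seq_lengths = model$seq_lengths,
                   gene_symbols = colnames(Y),
                   samples_per_epoch = nrow(Xtr),
                   validation_patients = val_pat),
              class = "trained_head")
  })
}

#' @export
print.trained_head <- function(x, ...) {
  cat(sprintf(
    "<trained_head> F = %d -> %d genes; %d epoch(s), best epoch %d (monitored loss %.4g), %d record(s)/epoch\n",
    x$input_dim, x$config$output_dim, nrow(x$history), x$best_epoch,
    x$best_loss, x$samples_per_epoch))
  invisible(x)
}

#' Predict gene expression from aggregated features
#'
#' @param object a `trained_head`.
#' @param newdata patients x F matrix, single length-F vector, an
#'   [aggregate_features()] result, or a list of them.
#' @param ... unused.
#' @return Patients x genes matrix of predictions (log2p1 scale).
#' @export
predict.trained_head <- function(object, newdata, ...) {
  if (inherits(newdata, "aggregated_feature"))
    newdata <- aggregate_cohort(list(newdata))
  if (is.list(newdata) && !is.matrix(newdata))
    newdata <- aggregate_cohort(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$input_dim)
    stop(sprintf("feature length %d does not match the trained input dimension %d",
                 ncol(newdata), object$input_dim))
  out <- head_forward(object, newdata)
  rownames(out) <- rownames(newdata)
  colnames(out) <- object$gene_symbols
  out
}
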