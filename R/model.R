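#' Model configuration
#'
#' Describes a motif kernel network: a single kernel layer (Nystroem
#' projection with `n_anchors` learnable motif-position anchors) whose
#' flattened output feeds a linear hidden layer of `hidden_units` nodes and
#' a linear output layer with one node per class. Only linear layers follow
#' the kernel layer, which is what keeps the model directly interpretable.
#'
#' @param pam A [pam_params()] object (pass `beta = "auto"` there with the
#'   training length `L` to use the \eqn{L^2/10} rule).
#' @param n_anchors Number of anchor points in the kernel layer.
#' @param hidden_units Hidden layer width (default 200).
#' @param n_classes Number of output nodes (default 2).
#' @param epochs Training epochs (default 50).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size; `NULL` means full batch for datasets
#'   of at most 2048 sequences and batches of 128 above that.
#' @param seed RNG seed used for anchor sampling/initialisation and weight
#'   initialisation.
#' @param n_sampled_pairs Pairs sampled for anchor initialisation; `NULL`
#'   means `max(100 * n_anchors, 3000)` capped at the number of windows.
#' @param train_positions Should anchor positions be updated by the
#'   optimiser (anchor motifs always are)?
#' @param epsilon Eigenvalue floor for the Gram inverse square root.
#' @param optimizer `"adam"` (default) or `"sgd"` (plain gradient descent
#'   with momentum 0.9). SGD concentrates weight on strongly informative
#'   features, which sharpens the positive-weight interpretation readout;
#'   Adam converges faster on poorly scaled problems.
#' @param loss `"bce"` (elementwise binary cross-entropy with logits against
#'   one-hot targets, the default) or `"softmax"` (multinomial
#'   cross-entropy).
#' @param weight_decay Optional l2 penalty on the fully-connected weights
#'   (default 0).
#' @return A `pam_config` object.
#' @export
pam_config <- function(pam, n_anchors = 50L, hidden_units = 200L,
                       n_classes = 2L, epochs = 50L, learning_rate = 1e-3,
                       batch_size = NULL, seed = 1L, n_sampled_pairs = NULL,
                       train_positions = TRUE, epsilon = 1e-6,
                       optimizer = c("adam", "sgd"),
                       loss = c("bce", "softmax"), weight_decay = 0) {
  stopifnot(inherits(pam, "pam_params"), n_anchors >= 1, hidden_units >= 1,
            n_classes >= 2, epochs >= 1, learning_rate > 0, weight_decay >= 0)
  structure(list(pam = pam, n_anchors = as.integer(n_anchors),
                 hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes), epochs = as.integer(epochs),
                 learning_rate = learning_rate, batch_size = batch_size,
                 seed = as.integer(seed), n_sampled_pairs = n_sampled_pairs,
                 train_positions = isTRUE(train_positions), epsilon = epsilon,
                 optimizer = match.arg(optimizer),
                 loss = match.arg(loss), weight_decay = weight_decay),
            class = "pam_config")
}

# stack the one-hot windows of all sequences: (N * L_out) x (|A| k) matrix,
# sequence-major, window-position-minor
stack_windows <- function(data, k) {
  lens <- vapply(data, `[[`, integer(1), "length")
  if (length(unique(lens)) != 1L) {
    stop("fixed-length model: all sequences must have equal length (got ",
         paste(sort(unique(lens)), collapse = ", "), ")")
  }
  L <- lens[1]
  if (L < k) stop("sequences shorter than the motif length")
  W <- do.call(rbind, lapply(data, sequence_windows, k = k))
  list(W = W, L = L, L_out = L - k + 1L, N = length(data))
}

# kernel-layer responses for stacked windows; returns the pre-projection K0
# (rows follow the stacking) and the N x (L_out * n) flattened feature matrix
kernel_features <- function(stacked, anchors, state, params) {
  P <- map_position(seq_len(stacked$L_out), stacked$L)
  if (stacked$L_out == 1L) P <- matrix(P, nrow = 1)
  Prep <- P[rep(seq_len(stacked$L_out), stacked$N), , drop = FALSE]
  cpos <- params$beta / (2 * params$sigma^2)
  K0 <- exp(params$alpha * (stacked$W %*% t(anchors$motifs) - params$k) +
            cpos * (Prep %*% t(anchors$positions) - 1))
  Ffull <- K0 %*% state$K_ZZ_inv_sqrt
  X <- matrix(as.vector(t(Ffull)), nrow = stacked$N, byrow = TRUE)
  list(K0 = K0, X = X, Prep = Prep)
}

init_linear <- function(n_out, n_in) {
  b <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_out * n_in, -b, b), n_out, n_in),
       b = stats::runif(n_out, -b, b))
}

#' Build an untrained model
#'
#' Samples motif-position pairs from the training sequences, initialises the
#' anchors by constrained k-means ([init_anchors()]), computes the initial
#' Nystroem state and initialises the fully-connected weights with the
#' standard symmetric uniform scheme. All randomness derives from
#' `config$seed`.
#'
#' @param config A [pam_config()].
#' @param train_data List of `encoded_seq`, all of one length.
#' @return A `pam_model` (untrained).
#' @export
build_model <- function(config, train_data) {
  k <- config$pam$k
  stacked <- stack_windows(train_data, k)
  n_windows <- stacked$N * stacked$L_out
  m <- config$n_sampled_pairs
  if (is.null(m)) m <- min(max(100L * config$n_anchors, 3000L), n_windows)
  set.seed(config$seed)
  pairs <- sample_pairs(train_data, m, k)
  d <- nrow(train_data[[1]]$matrix)
  anchors <- init_anchors(pairs, config$n_anchors, d, k)
  state <- gram_inverse_sqrt(anchors, config$pam, config$epsilon)
  n_feat <- stacked$L_out * config$n_anchors
  fc1 <- init_linear(config$hidden_units, n_feat)
  fc2 <- init_linear(config$n_classes, config$hidden_units)
  structure(list(config = config, anchors = anchors, nystrom = state,
                 W1 = fc1$W, b1 = fc1$b, W2 = fc2$W, b2 = fc2$b,
                 L = stacked$L, L_out = stacked$L_out,
                 alphabet_size = d, kind = train_data[[1]]$kind,
                 training_log = numeric(0)),
            class = "pam_model")
}

#' @export
print.pam_model <- function(x, ...) {
  cat(sprintf(paste0("<pam_model> kernel layer: %d anchors (k=%d) on length-%d",
                     " sequences -> %d features; head: %d -> %d\n"),
              x$anchors$n, x$config$pam$k, x$L, x$L_out * x$anchors$n,
              x$config$hidden_units, x$config$n_classes),
      if (length(x$training_log)) sprintf("  trained %d epochs, final loss %.6g\n",
                                          length(x$training_log),
                                          utils::tail(x$training_log, 1)) else "")
  invisible(x)
}

# numerically stable log(1 + exp(o))
softplus <- function(o) pmax(o, 0) + log1p(exp(-abs(o)))

bce_loss_grad <- function(O, Y) {
  n <- length(O)
  loss <- mean(softplus(O) - Y * O)
  grad <- (stats::plogis(O) - Y) / n
  list(loss = loss, grad = grad)
}

softmax_loss_grad <- function(O, Y) {
  m <- apply(O, 1, max)
  E <- exp(O - m)
  P <- E / rowSums(E)
  loss <- -mean(rowSums(Y * (O - m - log(rowSums(E)))))
  grad <- (P - Y) / nrow(O)
  list(loss = loss, grad = grad)
}

adam_new <- function(shape) {
  list(m = array(0, dim = shape), v = array(0, dim = shape), t = 0L)
}

adam_step <- function(st, g, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^st$t)
  vh <- st$v / (1 - b2^st$t)
  st$delta <- lr * mh / (sqrt(vh) + eps)
  st
}

# classical momentum; reuses the Adam state slots (m = velocity)
sgd_step <- function(st, g, lr, momentum = 0.9) {
  st$m <- momentum * st$m + g
  st$delta <- lr * st$m
  st
}

opt_step <- function(optimizer, st, g, lr) {
  if (optimizer == "adam") adam_step(st, g, lr) else sgd_step(st, g, lr)
}

#' Train a model end-to-end
#'
#' Minimises the configured loss (default: elementwise binary cross-entropy
#' with logits against one-hot targets over the output nodes) with Adam.
#' Anchor motifs (and positions, if `train_positions`) are trained jointly
#' with the fully-connected weights; after every optimiser step the anchors
#' are projected back onto their constraint sets and \eqn{K_{ZZ}^{-1/2}} is
#' recomputed from the moved anchors. The gradient treats
#' \eqn{K_{ZZ}^{-1/2}} as a constant within a step (stop-gradient).
#'
#' @param model A `pam_model` from [build_model()].
#' @param data Training sequences (same length as at build time).
#' @param labels Integer labels in `0 .. n_classes-1`; taken from the
#'   sequences when `NULL`.
#' @param verbose Print per-epoch loss to stderr?
#' @return The trained `pam_model` with `training_log` filled in.
#' @export
train_model <- function(model, data, labels = NULL, verbose = FALSE) {
  config <- model$config
  params <- config$pam
  if (is.null(labels)) labels <- sequence_labels(data)
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0 | labels >= config$n_classes)) {
    stop("labels must be integers in 0 .. n_classes-1")
  }
  stacked <- stack_windows(data, params$k)
  if (stacked$L != model$L) stop("sequence length differs from build time")
  N <- stacked$N
  Y <- matrix(0, N, config$n_classes)
  Y[cbind(seq_len(N), labels + 1L)] <- 1
  batch <- config$batch_size
  if (is.null(batch)) batch <- if (N <= 2048L) N else 128L
  loss_fun <- if (config$loss == "bce") bce_loss_grad else softmax_loss_grad
  cpos <- params$beta / (2 * params$sigma^2)
  lr <- config$learning_rate

  opt <- list(W1 = adam_new(dim(model$W1)), b1 = adam_new(length(model$b1)),
              W2 = adam_new(dim(model$W2)), b2 = adam_new(length(model$b2)),
              Am = adam_new(dim(model$anchors$motifs)),
              Ap = adam_new(dim(model$anchors$positions)))
  set.seed(config$seed + 1L)
  log <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- if (batch < N) sample.int(N) else seq_len(N)
    starts <- seq(1L, N, by = batch)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, N)]
      rows <- as.vector(t(outer(idx - 1L, seq_len(stacked$L_out), function(a, b)
        a * stacked$L_out + b)))
      sub <- list(W = stacked$W[rows, , drop = FALSE], L = stacked$L,
                  L_out = stacked$L_out, N = length(idx))
      state <- gram_inverse_sqrt(model$anchors, params, config$epsilon)
      kf <- kernel_features(sub, model$anchors, state, params)
      H <- kf$X %*% t(model$W1) + rep(model$b1, each = length(idx))
      O <- H %*% t(model$W2) + rep(model$b2, each = length(idx))
      lg <- loss_fun(O, Y[idx, , drop = FALSE])
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d; try a smaller learning rate",
                     epoch))
      }
      epoch_loss <- epoch_loss + lg$loss * length(idx)
      dO <- lg$grad
      gW2 <- t(dO) %*% H + config$weight_decay * model$W2
      gb2 <- colSums(dO)
      dH <- dO %*% model$W2
      gW1 <- t(dH) %*% kf$X + config$weight_decay * model$W1
      gb1 <- colSums(dH)
      dX <- dH %*% model$W1
      dF <- matrix(as.vector(t(dX)), ncol = model$anchors$n, byrow = TRUE)
      G <- (dF %*% state$K_ZZ_inv_sqrt) * kf$K0
      gAm <- params$alpha * t(G) %*% sub$W
      optim <- config$optimizer
      opt$W1 <- opt_step(optim, opt$W1, gW1, lr)
      model$W1 <- model$W1 - opt$W1$delta
      opt$b1 <- opt_step(optim, opt$b1, gb1, lr)
      model$b1 <- as.numeric(model$b1 - opt$b1$delta)
      opt$W2 <- opt_step(optim, opt$W2, gW2, lr)
      model$W2 <- model$W2 - opt$W2$delta
      opt$b2 <- opt_step(optim, opt$b2, gb2, lr)
      model$b2 <- as.numeric(model$b2 - opt$b2$delta)
      opt$Am <- opt_step(optim, opt$Am, gAm, lr)
      model$anchors$motifs <- model$anchors$motifs - opt$Am$delta
      if (config$train_positions) {
        gAp <- cpos * t(G) %*% kf$Prep
        opt$Ap <- opt_step(optim, opt$Ap, gAp, lr)
        model$anchors$positions <- model$anchors$positions - opt$Ap$delta
      }
      model$anchors <- constraint_project(model$anchors)
    }
    log[epoch] <- epoch_loss / N
    if (verbose) message(sprintf("epoch %d/%d loss %.6f", epoch,
                                 config$epochs, log[epoch]))
  }
  model$nystrom <- gram_inverse_sqrt(model$anchors, params, config$epsilon)
  model$training_log <- log
  model
}

#' Class scores and predicted labels
#'
#' Runs the kernel layer and linear head on new sequences. Scores are the
#' raw output logits; the predicted label is their argmax. Predictions are
#' deterministic and independent of batch composition.
#'
#' @param object A trained `pam_model`.
#' @param data List of `encoded_seq` of the training length.
#' @param ... Unused.
#' @return A list with `scores` (N x n_classes logit matrix) and `labels`
#'   (integer vector in `0 .. n_classes-1`).
#' @export
predict.pam_model <- function(object, data, ...) {
  params <- object$config$pam
  stacked <- stack_windows(data, params$k)
  if (stacked$L != object$L) {
    stop(sprintf("sequence length %d does not match training length %d",
                 stacked$L, object$L))
  }
  kf <- kernel_features(stacked, object$anchors, object$nystrom, params)
  H <- kf$X %*% t(object$W1) + rep(object$b1, each = stacked$N)
  O <- H %*% t(object$W2) + rep(object$b2, each = stacked$N)
  if (!all(is.finite(O))) stop("non-finite logits")
  list(scores = O, labels = max.col(O, ties.method = "first") - 1L)
}
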