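# The LONN network engine: reference architecture with a frozen logic block,
# a dense ReLU baseline, mini-batch ADAM training with gradients flowing
# through (but never updating) frozen layers, and JSON serialization.

#' LONN architecture specification
#'
#' The reference logic-operator network: a trainable ELU input layer, a
#' frozen "M-node" hypothesis-grouping layer, a frozen AND-gate layer, a
#' parameter-free OR stage (all logic layers activated by the squashing
#' function with slope `beta_int`), and a trainable sigmoid head. With the
#' defaults the network holds exactly 116 trainable and 59 frozen
#' parameters.
#'
#' @param input_dim number of input covariates (default 10, V1-V10).
#' @param first_layer_width width of the trainable ELU layer.
#' @param m_layer_width number of frozen M (hypothesis) nodes.
#' @param and_layer_width number of frozen AND gates.
#' @param or_stage_width number of parameter-free OR combinations; must not
#'   exceed `and_layer_width`.
#' @param output_dim number of outputs (default 2: normalized therapy time
#'   and treatment-key probability).
#' @param beta_int squashing slope of all logic layers (nonzero).
#' @param seed integer seed for all weight initialization.
#' @return object of class `lonn_spec`.
#' @export
lonn_spec <- function(input_dim = 10L, first_layer_width = 10L,
                      m_layer_width = 4L, and_layer_width = 3L,
                      or_stage_width = 2L, output_dim = 2L,
                      beta_int = 1.5, seed = 1L) {
  .check_beta(beta_int)
  dims <- c(input_dim, first_layer_width, m_layer_width, and_layer_width,
            or_stage_width, output_dim)
  if (any(dims < 1) || any(dims != round(dims)))
    stop("all layer widths must be positive integers", call. = FALSE)
  if (or_stage_width > and_layer_width)
    stop("or_stage_width must not exceed and_layer_width", call. = FALSE)
  structure(
    list(input_dim = as.integer(input_dim),
         first_layer_width = as.integer(first_layer_width),
         m_layer_width = as.integer(m_layer_width),
         and_layer_width = as.integer(and_layer_width),
         or_stage_width = as.integer(or_stage_width),
         output_dim = as.integer(output_dim),
         beta_int = beta_int, seed = as.integer(seed)),
    class = "lonn_spec"
  )
}

.glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# He-uniform: the standard fan-in scaling for ReLU layers
.he <- function(n_out, n_in) {
  lim <- sqrt(6 / n_in)
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

# Fixed 0/1 disjunction wiring: or_w overlapping windows over and_w inputs.
.or_stage_weights <- function(and_w, or_w) {
  win <- and_w - or_w + 1L
  W <- matrix(0, or_w, and_w)
  for (j in seq_len(or_w)) W[j, j:(j + win - 1L)] <- 1
  W
}

.default_input_names <- function(d) {
  if (d == length(.COHORT_INPUTS)) .COHORT_INPUTS else paste0("V", seq_len(d))
}

#' Build the reference LONN
#'
#' Layer stack: `Dense(input -> first, ELU, trainable)` ->
#' `Dense(-> m, squashing, frozen)` with each M node a seeded random convex
#' combination (weights drawn uniform on \[0,1\] and normalized to sum 1,
#' bias 0) -> `Dense(-> and, squashing, frozen)` whose units are AND gates
#' over the full M fan-in ([gate_parameters()]) -> a parameter-free OR stage
#' of fixed unit-weight disjunctions over overlapping windows of AND outputs
#' -> `Dense(-> output, sigmoid, trainable)`. All randomness flows from
#' `spec$seed`.
#'
#' @param spec a [lonn_spec()].
#' @return object of class `lonn_model`.
#' @export
build_lonn <- function(spec = lonn_spec()) {
  if (!inherits(spec, "lonn_spec")) stop("'spec' must be a lonn_spec")
  set.seed(spec$seed)
  # bias 1 starts the frozen conjunction block in its responsive region
  # (pre-activation near 0) instead of the saturated tail, where the
  # squashing derivative would throttle the gradient reaching this layer
  first <- dense_layer(.glorot(spec$first_layer_width, spec$input_dim),
                       rep(1, spec$first_layer_width),
                       "elu", trainable = TRUE, name = "input_elu")
  Wm <- matrix(stats::runif(spec$m_layer_width * spec$first_layer_width),
               spec$m_layer_width, spec$first_layer_width)
  Wm <- Wm / rowSums(Wm)
  m_layer <- dense_layer(Wm, rep(0, spec$m_layer_width), "squashing",
                         beta = spec$beta_int, trainable = FALSE,
                         name = "m_hypotheses")
  and_par <- gate_parameters("AND", spec$m_layer_width)
  and_layer <- dense_layer(
    matrix(and_par$weights, spec$and_layer_width, spec$m_layer_width,
           byrow = TRUE),
    rep(and_par$bias, spec$and_layer_width), "squashing",
    beta = spec$beta_int, trainable = FALSE, name = "and_gates")
  or_layer <- dense_layer(
    .or_stage_weights(spec$and_layer_width, spec$or_stage_width),
    rep(0, spec$or_stage_width), "squashing", beta = spec$beta_int,
    trainable = FALSE, counted = FALSE, name = "or_stage")
  head <- dense_layer(.glorot(spec$output_dim, spec$or_stage_width),
                      rep(0, spec$output_dim), "sigmoid",
                      trainable = TRUE, name = "sigmoid_head")
  structure(
    list(kind = "lonn",
         layers = list(first, m_layer, and_layer, or_layer, head),
         spec = spec,
         input_names = .default_input_names(spec$input_dim)),
    class = "lonn_model"
  )
}

#' Build the dense ReLU baseline
#'
#' The all-trainable control network: hidden ReLU widths (10, 10, 4, 3, 2)
#' followed by a 2-unit sigmoid head; 293 trainable parameters with the
#' default dimensions.
#'
#' @param input_dim,output_dim network dimensions.
#' @param seed integer seed for Glorot initialization.
#' @return object of class `lonn_model` (kind `"dense"`).
#' @export
build_dense_baseline <- function(input_dim = 10L, output_dim = 2L, seed = 1L) {
  if (input_dim < 1 || output_dim < 1) stop("dims must be positive")
  set.seed(seed)
  widths <- c(input_dim, 10L, 10L, 4L, 3L, 2L)
  layers <- vector("list", length(widths))
  # He init with a small positive bias keeps the narrow (4, 3, 2) ReLU
  # layers alive; zero-bias Glorot collapses them to dead units
  for (l in seq_len(length(widths) - 1L)) {
    layers[[l]] <- dense_layer(.he(widths[l + 1L], widths[l]),
                               rep(0.1, widths[l + 1L]), "relu",
                               name = paste0("relu_", l))
  }
  layers[[length(widths)]] <- dense_layer(
    .glorot(output_dim, widths[length(widths)]), rep(0, output_dim),
    "sigmoid", name = "sigmoid_head")
  structure(
    list(kind = "dense", layers = layers,
         spec = list(input_dim = as.integer(input_dim),
                     output_dim = as.integer(output_dim),
                     seed = as.integer(seed)),
         input_names = .default_input_names(input_dim)),
    class = "lonn_model"
  )
}

.forward_pass <- function(model, X) {
  L <- length(model$layers)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    layer <- model$layers[[l]]
    Z[[l]] <- A[[l]] %*% t(layer$W) +
      matrix(layer$b, nrow(X), length(layer$b), byrow = TRUE)
    A[[l + 1L]] <- .act_forward(Z[[l]], layer$activation, layer$beta)
  }
  list(A = A, Z = Z, output = A[[L + 1L]])
}

#' Predict with a network
#'
#' @param object a `lonn_model`.
#' @param X numeric matrix (`n x input_dim`) or a single input vector.
#' @param ... unused.
#' @return `n x output_dim` matrix; the sigmoid head keeps values in (0, 1).
#' @export
predict.lonn_model <- function(object, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ncol(object$layers[[1L]]$W))
    stop(sprintf("model expects %d input columns, got %d",
                 ncol(object$layers[[1L]]$W), ncol(X)), call. = FALSE)
  .forward_pass(object, X)$output
}

#' End-to-end gradients of the MSE loss
#'
#' Backpropagates the mean-squared-error loss `mean((Y - Yhat)^2)` through
#' the whole stack. Gradients are computed for every layer — the chain rule
#' uses the frozen layers' fixed weights — but the optimizer only ever
#' applies the trainable ones.
#'
#' @param model a `lonn_model`.
#' @param X,Y input and target matrices with equal row counts.
#' @return list with `loss` and `grads` (per layer: `dW`, `db`).
#' @export
network_gradients <- function(model, X, Y) {
  fp <- .forward_pass(model, X)
  out <- fp$output
  loss <- mean((out - Y)^2)
  dA <- 2 * (out - Y) / length(out)
  L <- length(model$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    layer <- model$layers[[l]]
    dZ <- dA * .act_grad(fp$Z[[l]], layer$activation, layer$beta)
    dW <- t(dZ) %*% fp$A[[l]]
    dimnames(dW) <- NULL
    grads[[l]] <- list(dW = dW, db = unname(colSums(dZ)))
    dA <- dZ %*% layer$W
  }
  list(loss = loss, grads = grads)
}

#' Training configuration
#'
#' Defaults reproduce the selected optimizer hyperparameters: mini-batch
#' size 50, learning rate 0.02, 100 epochs, with standard ADAM moment
#' constants. The loss is always the mean squared error; the per-epoch data
#' order is reshuffled from `shuffle_seed`.
#'
#' @param learning_rate ADAM step size.
#' @param batch_size mini-batch size; the last incomplete batch is used.
#' @param epochs number of passes over the data.
#' @param adam_beta1,adam_beta2,adam_epsilon ADAM moment decay rates and
#'   numerical floor.
#' @param shuffle_seed integer seed for the per-epoch shuffles.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.02, batch_size = 50L,
                         epochs = 100L, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_epsilon = 1e-8,
                         shuffle_seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1)
    stop("invalid training configuration", call. = FALSE)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), adam_beta1 = adam_beta1,
         adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon,
         shuffle_seed = as.integer(shuffle_seed)),
    class = "train_config"
  )
}

#' Train a network by mini-batch ADAM on the MSE loss
#'
#' Frozen layers are never updated (their parameters stay bit-identical),
#' though gradients flow through them to reach the trainable input layer.
#'
#' @param model a `lonn_model` from [build_lonn()] or
#'   [build_dense_baseline()].
#' @param X normalized input matrix (values in \[0, 1\]).
#' @param Y normalized outcome matrix (same row count as `X`).
#' @param config a [train_config()].
#' @return object of class `lonn_training`: `$model` (the trained network)
#'   and `$history` (per-epoch `loss` and `training_error_pct`, the MAE on
#'   normalized outputs times 100).
#' @export
train_network <- function(model, X, Y, config = train_config()) {
  if (!inherits(model, "lonn_model")) stop("'model' must be a lonn_model")
  if (!is.matrix(X) || !is.matrix(Y)) stop("X and Y must be matrices")
  if (nrow(X) == 0L) stop("empty training data", call. = FALSE)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts")
  n <- nrow(X)
  L <- length(model$layers)
  adam <- lapply(model$layers, function(layer) {
    if (!layer$trainable) return(NULL)
    list(mW = layer$W * 0, vW = layer$W * 0,
         mb = layer$b * 0, vb = layer$b * 0)
  })
  step <- 0L
  hist_loss <- hist_mae <- numeric(config$epochs)
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  eps <- config$adam_epsilon; lr <- config$learning_rate
  for (epoch in seq_len(config$epochs)) {
    set.seed(config$shuffle_seed + epoch - 1L)
    idx <- sample.int(n)
    for (s in seq(1L, n, by = config$batch_size)) {
      b <- idx[s:min(s + config$batch_size - 1L, n)]
      g <- network_gradients(model, X[b, , drop = FALSE],
                             Y[b, , drop = FALSE])
      step <- step + 1L
      c1 <- 1 - b1^step
      c2 <- 1 - b2^step
      for (l in seq_len(L)) {
        if (!model$layers[[l]]$trainable) next
        st <- adam[[l]]
        st$mW <- b1 * st$mW + (1 - b1) * g$grads[[l]]$dW
        st$vW <- b2 * st$vW + (1 - b2) * g$grads[[l]]$dW^2
        st$mb <- b1 * st$mb + (1 - b1) * g$grads[[l]]$db
        st$vb <- b2 * st$vb + (1 - b2) * g$grads[[l]]$db^2
        model$layers[[l]]$W <- model$layers[[l]]$W -
          lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
        model$layers[[l]]$b <- model$layers[[l]]$b -
          lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
        adam[[l]] <- st
      }
    }
    out <- .forward_pass(model, X)$output
    hist_loss[epoch] <- mean((out - Y)^2)
    hist_mae[epoch] <- mean(abs(out - Y)) * 100
    if (!is.finite(hist_loss[epoch]))
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
           call. = FALSE)
  }
  structure(
    list(model = model,
         history = data.frame(epoch = seq_len(config$epochs),
                              loss = hist_loss,
                              training_error_pct = hist_mae),
         config = config),
    class = "lonn_training"
  )
}

#' Count network parameters
#'
#' Weights plus biases per layer, partitioned by the trainable flag.
#' Parameter-free stages (the LONN's fixed OR wiring) contribute zero. The
#' default LONN reports (116, 59); the dense baseline (293, 0).
#'
#' @param model a `lonn_model`.
#' @return named integer vector `c(trainable = , non_trainable = )`.
#' @export
count_parameters <- function(model) {
  if (!inherits(model, "lonn_model")) stop("'model' must be a lonn_model")
  tr <- ntr <- 0L
  for (layer in model$layers) {
    if (!layer$counted) next
    k <- length(layer$W) + length(layer$b)
    if (layer$trainable) tr <- tr + k else ntr <- ntr + k
  }
  c(trainable = tr, non_trainable = ntr)
}

.MODEL_FORMAT <- "lonnrec-model/1"

#' Save / load a network as JSON
#'
#' The round trip preserves all weights, flags and beta values bit-exactly;
#' predictions after [load_model()] are identical to those before
#' [save_model()].
#'
#' @param model a `lonn_model`.
#' @param path file path of the JSON document.
#' @return `save_model` returns `path` invisibly; `load_model` the restored
#'   `lonn_model`.
#' @export
.model_doc <- function(model) {
  list(
    format_version = .MODEL_FORMAT,
    kind = model$kind,
    input_names = model$input_names,
    spec = unclass(model$spec),
    layers = lapply(model$layers, function(layer) {
      list(name = layer$name, activation = layer$activation,
           beta = layer$beta, trainable = layer$trainable,
           counted = layer$counted, W_dim = dim(layer$W),
           W_data = as.numeric(layer$W), b = layer$b)
    })
  )
}

save_model <- function(model, path) {
  if (!inherits(model, "lonn_model")) stop("'model' must be a lonn_model")
  jsonlite::write_json(.model_doc(model), path, digits = I(17),
                       auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stop("model deserialization failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  .model_from_doc(doc)
}

.model_from_doc <- function(doc) {
  if (is.null(doc$format_version) || doc$format_version != .MODEL_FORMAT)
    stop(sprintf("unsupported model format version '%s' (expected '%s')",
                 doc$format_version %||% "<missing>", .MODEL_FORMAT),
         call. = FALSE)
  for (f in c("kind", "layers", "spec"))
    if (is.null(doc[[f]])) stop("malformed model file: missing field '",
                                f, "'", call. = FALSE)
  layers <- lapply(doc$layers, function(ld) {
    for (f in c("W_dim", "W_data", "b", "activation", "trainable", "counted"))
      if (is.null(ld[[f]])) stop("malformed model file: missing layer field '",
                                 f, "'", call. = FALSE)
    dense_layer(matrix(as.numeric(ld$W_data), ld$W_dim[1L], ld$W_dim[2L]),
                as.numeric(ld$b), ld$activation,
                beta = if (is.null(ld$beta) || is.na(ld$beta)) NA_real_
                       else as.numeric(ld$beta),
                trainable = ld$trainable, counted = ld$counted,
                name = ld$name %||% "dense")
  })
  spec <- doc$spec
  if (identical(doc$kind, "lonn")) class(spec) <- "lonn_spec"
  structure(
    list(kind = doc$kind, layers = layers, spec = spec,
         input_names = unlist(doc$input_names)),
    class = "lonn_model"
  )
}

#' @export
print.lonn_model <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf("<lonn_model kind=%s, %d layers, %d trainable / %d frozen parameters>\n",
              x$kind, length(x$layers), cp[["trainable"]],
              cp[["non_trainable"]]))
  for (layer in x$layers)
    cat(sprintf("  %-14s %3d -> %3d  %-9s %s\n", layer$name, ncol(layer$W),
                nrow(layer$W), layer$activation,
                if (layer$trainable) "trainable" else "frozen"))
  invisible(x)
}
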