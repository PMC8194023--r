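# Dense layers and their activations. Every layer of a network is a dense
# perceptron layer h = sigma(W x + b); the OR stage of a LONN is simply a
# dense layer whose fixed 0/1 weights are excluded from parameter counts.

.ACTIVATIONS <- c("linear", "relu", "elu", "sigmoid", "squashing")

#' Construct a dense layer
#'
#' A fully connected layer computing `sigma(W x + b)` per unit. `trainable`
#' marks whether the optimizer may touch the parameters; `counted` whether
#' they appear in parameter counts (the LONN's fixed OR stage holds
#' structural, uncounted weights).
#'
#' @param W weight matrix, `out x in`.
#' @param b bias vector, length `out`.
#' @param activation one of `"linear"`, `"relu"`, `"elu"`, `"sigmoid"`,
#'   `"squashing"`.
#' @param beta squashing slope, required when `activation = "squashing"`.
#' @param trainable logical; frozen layers keep their parameters bit-identical
#'   through any training run.
#' @param counted logical; whether the parameters enter [count_parameters()].
#' @param name layer label used in printing and serialization.
#' @return object of class `dense_layer`.
#' @export
dense_layer <- function(W, b, activation = "linear", beta = NA_real_,
                        trainable = TRUE, counted = TRUE, name = "dense") {
  W <- as.matrix(W)
  b <- as.numeric(b)
  activation <- match.arg(activation, .ACTIVATIONS)
  if (length(b) != nrow(W))
    stop("bias length must equal nrow(W)", call. = FALSE)
  if (activation == "squashing") .check_beta(beta)
  structure(
    list(W = W, b = b, activation = activation, beta = beta,
         trainable = isTRUE(trainable), counted = isTRUE(counted),
         name = name),
    class = "dense_layer"
  )
}

.act_forward <- function(z, activation, beta = NA_real_) {
  switch(activation,
    linear    = z,
    relu      = pmax(z, 0),
    elu       = ifelse(z > 0, z, expm1(z)),  # alpha = 1
    sigmoid   = stats::plogis(z),
    squashing = {
      out <- (.softplus(beta * z) - .softplus(beta * (z - 1))) / beta
      if (is.matrix(z)) dim(out) <- dim(z)
      out
    },
    stop("unknown activation: ", activation)
  )
}

.act_grad <- function(z, activation, beta = NA_real_) {
  switch(activation,
    linear    = array(1, dim = dim(z) %||% length(z)),
    relu      = (z > 0) + 0,
    elu       = ifelse(z > 0, 1, exp(z)),
    sigmoid   = { s <- stats::plogis(z); s * (1 - s) },
    squashing = stats::plogis(beta * z) - stats::plogis(beta * (z - 1)),
    stop("unknown activation: ", activation)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward pass through one dense layer
#'
#' @param layer a [dense_layer()].
#' @param inputs numeric vector (one sample) or matrix (`n x fan_in`).
#' @return activated outputs; a vector for vector input, a matrix otherwise.
#' @export
dense_forward <- function(layer, inputs) {
  if (!inherits(layer, "dense_layer"))
    stop("'layer' must be a dense_layer", call. = FALSE)
  vec <- !is.matrix(inputs)
  X <- if (vec) matrix(inputs, nrow = 1L) else inputs
  if (ncol(X) != ncol(layer$W))
    stop(sprintf("layer expects %d inputs, got %d", ncol(layer$W), ncol(X)),
         call. = FALSE)
  Z <- X %*% t(layer$W) +
    matrix(layer$b, nrow(X), length(layer$b), byrow = TRUE)
  A <- .act_forward(Z, layer$activation, layer$beta)
  if (vec) as.numeric(A) else A
}
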