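# Continuous-valued (nilpotent) logic primitives: the squashing activation
# family S_beta, the cutting function it approximates, and logic gates
# realized as fixed-weight perceptrons.

# overflow-safe log(1 + exp(z))
.softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

.check_beta <- function(beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta == 0)
    stop("'beta' must be a single finite nonzero number", call. = FALSE)
  invisible(beta)
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite numeric input", name), call. = FALSE)
  invisible(x)
}

#' Squashing activation function
#'
#' The parametric sigmoid-like family
#' \deqn{S_\beta(x) = \frac{1}{\beta}\,
#'   \ln\!\frac{1 + e^{\beta x}}{1 + e^{\beta (x-1)}},}
#' evaluated in the overflow-safe softplus-difference form
#' \eqn{(\mathrm{softplus}(\beta x) - \mathrm{softplus}(\beta(x-1)))/\beta}.
#' For every nonzero \eqn{\beta} the function maps the reals strictly into
#' (0, 1), passes through (0.5, 0.5), is increasing for \eqn{\beta > 0} and
#' decreasing for \eqn{\beta < 0}, and converges to the cutting function
#' [cutting()] as \eqn{\beta \to +\infty}. It is the differentiable
#' approximation of the Lukasiewicz-style truncation used by all frozen
#' logic layers of a LONN.
#'
#' @param x numeric vector of finite inputs.
#' @param beta single nonzero slope parameter; the sign acts as a negation.
#' @return numeric vector in (0, 1), same length as `x`.
#' @seealso [squashing_gradient()], [cutting()], [gate_apply()]
#' @examples
#' squashing(0.5, 1.5)   # 0.5 for every beta
#' squashing(0, 100)     # ~0: large beta approaches the cutting function
#' @export
squashing <- function(x, beta) {
  .check_beta(beta)
  .check_finite(x, "x")
  (.softplus(beta * x) - .softplus(beta * (x - 1))) / beta
}

#' Exact derivative of the squashing function
#'
#' \eqn{dS_\beta/dx = \mathrm{logistic}(\beta x) - \mathrm{logistic}(\beta (x-1))},
#' strictly positive for \eqn{\beta > 0} and strictly negative for
#' \eqn{\beta < 0}; this closed form is what makes the logic layers usable
#' with gradient-based optimization.
#'
#' @inheritParams squashing
#' @return numeric vector, same length as `x`.
#' @export
squashing_gradient <- function(x, beta) {
  .check_beta(beta)
  .check_finite(x, "x")
  stats::plogis(beta * x) - stats::plogis(beta * (x - 1))
}

#' Cutting function
#'
#' The nilpotent-logic truncation `min(1, max(0, x))`: the exact,
#' non-differentiable limit of [squashing()] as \eqn{\beta \to +\infty}.
#'
#' @param x numeric vector of finite inputs.
#' @return numeric vector clamped to \[0, 1\].
#' @export
cutting <- function(x) {
  .check_finite(x, "x")
  pmin(1, pmax(0, x))
}

.GATE_KINDS <- c("AND", "OR", "NOT", "NOR")

#' Fixed perceptron weights of a nilpotent logic gate
#'
#' Returns the frozen weight vector and bias realizing a logical operator
#' as a perceptron unit `S_beta(w . x + b)`. For two inputs these are the
#' published gate encodings (AND: w = (1,1), b = -1; OR: w = (1,1), b = 0;
#' NOT: w = -1, b = 1; NOR i.e. "not(x) and not(y)": w = (-1,-1), b = 1).
#' The generalization to other arities follows the nilpotent operator
#' family: conjunction is `cutting(sum(x) - (k - 1))`, disjunction
#' `cutting(sum(x))`.
#'
#' @param kind one of `"AND"`, `"OR"`, `"NOT"`, `"NOR"` (case-insensitive).
#' @param fan_in positive integer number of inputs; `NOT` requires 1.
#' @return list with elements `weights` (length `fan_in`) and `bias`.
#' @export
gate_parameters <- function(kind, fan_in) {
  kind <- toupper(as.character(kind)[1L])
  if (!kind %in% .GATE_KINDS)
    stop(sprintf("unsupported gate kind '%s'", kind), call. = FALSE)
  if (!is.numeric(fan_in) || length(fan_in) != 1L || fan_in < 1 ||
      fan_in != round(fan_in))
    stop("'fan_in' must be a positive integer", call. = FALSE)
  fan_in <- as.integer(fan_in)
  if (kind == "NOT" && fan_in != 1L)
    stop("NOT gate is unary: fan_in must be 1", call. = FALSE)
  switch(kind,
    AND = list(weights = rep(1, fan_in), bias = -(fan_in - 1)),
    OR  = list(weights = rep(1, fan_in), bias = 0),
    NOT = list(weights = -1, bias = 1),
    NOR = list(weights = rep(-1, fan_in), bias = 1)
  )
}

#' Construct an immutable logic-gate specification
#'
#' @inheritParams gate_parameters
#' @return object of class `gate_spec` with fields `kind`, `fan_in`,
#'   `weights`, `bias`.
#' @export
logic_gate <- function(kind, fan_in) {
  par <- gate_parameters(kind, fan_in)
  structure(
    list(kind = toupper(kind), fan_in = as.integer(fan_in),
         weights = par$weights, bias = par$bias),
    class = "gate_spec"
  )
}

#' Evaluate a logic gate on fuzzy inputs
#'
#' Computes `squashing(weights . inputs + bias, beta)`. At large `beta`
#' (e.g. 50) crisp Boolean inputs reproduce the gate's truth table after
#' rounding.
#'
#' @param gate a [logic_gate()] object.
#' @param inputs numeric vector of length `gate$fan_in`, values in \[0, 1\].
#' @param beta nonzero slope of the squashing activation.
#' @return a single value in (0, 1).
#' @export
gate_apply <- function(gate, inputs, beta) {
  if (!inherits(gate, "gate_spec"))
    stop("'gate' must be a gate_spec (see logic_gate())", call. = FALSE)
  .check_finite(inputs, "inputs")
  if (length(inputs) != gate$fan_in)
    stop(sprintf("gate expects %d inputs, got %d", gate$fan_in,
                 length(inputs)), call. = FALSE)
  squashing(sum(gate$weights * inputs) + gate$bias, beta)
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("<%s gate, fan-in %d> weights: %s  bias: %g\n",
              x$kind, x$fan_in, paste(x$weights, collapse = ", "), x$bias))
  invisible(x)
}
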