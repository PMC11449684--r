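#' Names of the supported activation functions
#'
#' Nine scalar nonlinearities: ReLU, Leaky ReLU, Clipped ReLU, ELU, GELU,
#' hyperbolic tangent, softsign, swish, and the rectified softsign
#' (softsign composed with ReLU: `x / (1 + x)` for `x >= 0`, zero below).
#'
#' @return Character vector of activation names accepted by
#'   [activation_spec()].
#' @export
list_activations <- function() {
  c("relu", "leaky_relu", "clipped_relu", "elu", "gelu",
    "tanh", "softsign", "swish", "rectified_softsign")
}

#' Describe an activation function and its hyperparameters
#'
#' Builds an `activation_spec` object naming one of the nine supported
#' scalar nonlinearities together with the hyperparameters it uses.
#' Hyperparameters not used by the named function are stored but ignored.
#'
#' @param name One of [list_activations()].
#' @param slope Negative-side slope for `leaky_relu` (default 0.01, the
#'   common toolbox convention).
#' @param ceiling Positive clipping threshold for `clipped_relu`
#'   (default 10, a common toolbox default).
#' @param alpha Positive saturation parameter for `elu` (default 1).
#' @param gelu_constant The factor multiplying `x` inside `erf()` for
#'   `gelu`.  Defaults to `1/sqrt(2)` (the exact Gaussian CDF form); set it
#'   to `0.707` to reproduce a truncated-constant variant literally.
#' @return An object of class `activation_spec`.
#' @examples
#' spec <- activation_spec("rectified_softsign")
#' activate(spec, c(-3, 0, 1, 3))
#' @export
activation_spec <- function(name, slope = 0.01, ceiling = 10, alpha = 1,
                            gelu_constant = 1 / sqrt(2)) {
  name <- as.character(name)[1]
  if (!name %in% list_activations()) {
    stop("unknown activation '", name, "'; expected one of: ",
         paste(list_activations(), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(slope), length(slope) == 1, is.finite(slope))
  if (!is.numeric(ceiling) || length(ceiling) != 1 || !(ceiling > 0))
    stop("'ceiling' must be a positive number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || !(alpha > 0))
    stop("'alpha' must be a positive number", call. = FALSE)
  structure(
    list(name = name, slope = slope, ceiling = ceiling, alpha = alpha,
         gelu_constant = gelu_constant),
    class = "activation_spec")
}

#' @export
print.activation_spec <- function(x, ...) {
  extra <- switch(x$name,
    leaky_relu = sprintf(" (slope = %g)", x$slope),
    clipped_relu = sprintf(" (ceiling = %g)", x$ceiling),
    elu = sprintf(" (alpha = %g)", x$alpha),
    gelu = sprintf(" (erf factor = %.6g)", x$gelu_constant),
    "")
  cat("<activation_spec> ", x$name, extra, "\n", sep = "")
  invisible(x)
}

act_code_ <- function(name) match(name, list_activations())

# unchecked kernels used by the network's hot path
act_fwd_ <- function(spec, x) {
  out <- act_fwd_cpp(act_code_(spec$name), x, spec$slope, spec$ceiling,
                     spec$alpha, spec$gelu_constant)
  attributes(out) <- attributes(x)
  out
}

act_bwd_ <- function(spec, x) {
  out <- act_bwd_cpp(act_code_(spec$name), x, spec$slope, spec$ceiling,
                     spec$alpha, spec$gelu_constant)
  attributes(out) <- attributes(x)
  out
}

#' Apply an activation function elementwise
#'
#' Evaluates the named scalar nonlinearity at every element of `x`,
#' preserving the shape of `x` (scalar, vector, matrix or array).
#'
#' @param spec An [activation_spec()].
#' @param x Numeric scalar, vector, matrix or array of finite values.
#' @return Numeric object of the same shape as `x`.
#' @export
activate <- function(spec, x) {
  stopifnot(inherits(spec, "activation_spec"))
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite", call. = FALSE)
  act_fwd_(spec, x)
}

#' Derivative of an activation function
#'
#' Closed-form elementwise derivative of the named nonlinearity.  At the
#' kinks of the piecewise functions the right-hand limit is used: the
#' derivative at `x = 0` is 1 for `relu`, `clipped_relu` and
#' `rectified_softsign`, and the derivative of `clipped_relu` at
#' `x = ceiling` is 0.
#'
#' @inheritParams activate
#' @return Numeric object of the same shape as `x`.
#' @export
activate_grad <- function(spec, x) {
  stopifnot(inherits(spec, "activation_spec"))
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite", call. = FALSE)
  act_bwd_(spec, x)
}
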