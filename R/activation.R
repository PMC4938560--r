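#' Activation function bundle
#'
#' An activation is a smooth squashing nonlinearity together with its first
#' two derivatives, packaged so that network code and learning rules can be
#' written for any such function. The network model requires the range to be
#' the open interval (0, 1): the variance of a single output unit is then
#' bounded above by 0.25 (the Bernoulli(1/2) bound), which fixes the scale of
#' the phase diagram over output variances.
#'
#' @param g vectorized map from the reals to (0, 1), strictly increasing
#' @param g_prime first derivative of `g`
#' @param g_double_prime second derivative of `g`
#' @param name label used in printing
#' @return an object of class `synmax_activation`
#' @seealso [logistic_activation()]
#' @export
activation <- function(g, g_prime, g_double_prime, name = "custom") {
  stopifnot(is.function(g), is.function(g_prime), is.function(g_double_prime))
  structure(list(g = g, g_prime = g_prime, g_double_prime = g_double_prime,
                 name = name),
            class = "synmax_activation")
}

#' Logistic activation
#'
#' The standard logistic squashing function g(u) = 1 / (1 + exp(-u)) with
#' exact derivatives g' = g(1 - g) and g'' = g(1 - g)(1 - 2g). This is the
#' default nonlinearity of all models in the package; its output variance
#' bound of 0.25 is what the two-unit phase diagram is parameterized against.
#'
#' @return a `synmax_activation` object
#' @examples
#' act <- logistic_activation()
#' act$g(0)        # 0.5
#' act$g_prime(0)  # 0.25
#' @export
logistic_activation <- function() {
  g <- function(u) 1 / (1 + exp(-u))
  # saturation-stable derivative forms: g(u)(1 - g(u)) cancels to exactly 0
  # in double precision once |u| > ~37, while exp(-|u|)/(1+exp(-|u|))^2
  # stays accurate down to the underflow limit
  g_prime <- function(u) { e <- exp(-abs(u)); e / (1 + e)^2 }
  activation(
    g = g,
    g_prime = g_prime,
    g_double_prime = function(u) -g_prime(u) * tanh(u / 2),
    name = "logistic"
  )
}

#' @export
print.synmax_activation <- function(x, ...) {
  cat("<synmax_activation> ", x$name, "\n", sep = "")
  invisible(x)
}
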