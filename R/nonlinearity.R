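#' Single-neuron firing-rate nonlinearities
#'
#' Constructs a nonlinearity object mapping membrane potential (mV) to
#' momentary firing rate. Three kinds are supported:
#'
#' * `"powerlaw"`: the supralinear threshold power law
#'   `r(V) = k * max(V - V0, 0)^n` (rates in 1/s), the defining
#'   nonlinearity of the stabilized supralinear network (SSN);
#' * `"rect_tanh"`: the rectified saturating form
#'   `r(V) = gmax * tanh(k * max(V, 0))` used by the multi-attractor ring;
#' * `"tanh"`: the unrectified `r(V) = tanh(V)` of the classic chaotic
#'   rate network (output in `[-1, 1]`, may be negative).
#'
#' @param kind one of `"powerlaw"`, `"rect_tanh"`, `"tanh"`.
#' @param k gain. Units: mV^-n s^-1 for `powerlaw`, mV^-1 for `rect_tanh`.
#' @param n exponent of the power law (dimensionless).
#' @param V0 rectification threshold potential (mV, `powerlaw` only).
#' @param gmax maximal firing rate (1/s, `rect_tanh` only).
#' @return an object of class `ssn_nonlinearity`.
#' @examples
#' f <- nonlinearity("powerlaw", k = 0.3, n = 2, V0 = -70)
#' eval_nonlinearity(f, c(-75, -70, -60)) # 0, 0, 30 Hz
#' @export
nonlinearity <- function(kind = c("powerlaw", "rect_tanh", "tanh"),
                         k = 0.3, n = 2, V0 = -70, gmax = 100) {
  kind <- match.arg(kind)
  nl <- list(kind = kind, k = k, n = n, V0 = V0, gmax = gmax)
  if (kind == "powerlaw" && (k <= 0 || n <= 0))
    stop("powerlaw nonlinearity needs k > 0 and n > 0")
  if (kind == "rect_tanh" && (k <= 0 || gmax <= 0))
    stop("rect_tanh nonlinearity needs k > 0 and gmax > 0")
  class(nl) <- "ssn_nonlinearity"
  nl
}

#' Evaluate a firing-rate nonlinearity
#'
#' Applies the nonlinearity elementwise to a vector or matrix of membrane
#' potentials.
#'
#' @param nl an [nonlinearity()] object.
#' @param V membrane potentials (mV); vector or matrix.
#' @return rates, same shape as `V` (1/s for `powerlaw` and `rect_tanh`).
#' @export
eval_nonlinearity <- function(nl, V) {
  switch(nl$kind,
    powerlaw  = nl$k * pmax(V - nl$V0, 0)^nl$n,
    rect_tanh = nl$gmax * tanh(nl$k * pmax(V, 0)),
    tanh      = tanh(V),
    stop("unknown nonlinearity kind: ", nl$kind)
  )
}

#' Analytic derivative of a firing-rate nonlinearity
#'
#' Slope `f'(V)` used to form effective (linearized) connection weights.
#' For the power law with `n = 2` this is `2k * max(V - V0, 0)`.
#'
#' @inheritParams eval_nonlinearity
#' @return derivative of rate with respect to voltage, same shape as `V`.
#' @export
nl_derivative <- function(nl, V) {
  switch(nl$kind,
    powerlaw  = nl$k * nl$n * pmax(V - nl$V0, 0)^(nl$n - 1),
    rect_tanh = {
      u <- pmax(V, 0)
      ifelse(V > 0, nl$gmax * nl$k / cosh(nl$k * u)^2, 0)
    },
    tanh      = 1 / cosh(V)^2,
    stop("unknown nonlinearity kind: ", nl$kind)
  )
}

#' @export
print.ssn_nonlinearity <- function(x, ...) {
  desc <- switch(x$kind,
    powerlaw  = sprintf("r(V) = %g * max(V - (%g), 0)^%g  [1/s]", x$k, x$V0, x$n),
    rect_tanh = sprintf("r(V) = %g * tanh(%g * max(V, 0))  [1/s]", x$gmax, x$k),
    tanh      = "r(V) = tanh(V)")
  cat("<ssn_nonlinearity>", desc, "\n")
  invisible(x)
}
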