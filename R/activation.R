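#' Activation functions for pathway output production
#'
#' The production rate of each pathway output is a monotone function of the
#' shared intermediate. Three kinds are supported:
#'
#' * `linear_activation()` — identity, `f(u) = u`; the weakly-activated
#'   regime, in which only a small fraction of each component is ever active
#'   and kinetics are effectively linear.
#' * `hill_activation(exponent, threshold)` — a Hill function
#'   `f(u) = u^n / (u^n + eps^n)`. `exponent = 1` gives the hyperbolic
#'   (Michaelian) response of standard enzyme kinetics; `exponent > 1` gives
#'   an ultrasensitive, switch-like response. `f` is 0 at `u = 0`, exactly
#'   0.5 at `u = threshold`, and saturates at 1.
#' * `custom_activation(fun)` — an arbitrary user-supplied monotone
#'   non-decreasing function; useful for probing results that hold for any
#'   monotone activation (e.g. the impossibility of mutual fidelity).
#'
#' @param exponent Hill exponent (`n` or `m`), a real number >= 1.
#' @param threshold half-maximal concentration (`eps_X` or `eps_Y`), > 0.
#' @param fun a vectorized monotone non-decreasing function of a
#'   non-negative concentration. Monotonicity is the caller's contract; it
#'   is not verified pointwise.
#' @param label optional label used when printing a custom activation.
#'
#' @return An object of class `sigspec_activation`.
#' @examples
#' f <- hill_activation(exponent = 3, threshold = 1)
#' evaluate_activation(f, 1)   # 0.5 at the threshold
#' @export
hill_activation <- function(exponent = 1, threshold = 1) {
  stopifnot(is.numeric(exponent), length(exponent) == 1L, is.finite(exponent),
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  if (exponent < 1)
    stop("Hill `exponent` must be >= 1", call. = FALSE)
  if (threshold <= 0)
    stop("Hill `threshold` must be > 0", call. = FALSE)
  structure(list(kind = "hill", exponent = as.numeric(exponent),
                 threshold = as.numeric(threshold)),
            class = "sigspec_activation")
}

#' @rdname hill_activation
#' @export
linear_activation <- function() {
  structure(list(kind = "linear", exponent = NULL, threshold = NULL),
            class = "sigspec_activation")
}

#' @rdname hill_activation
#' @export
custom_activation <- function(fun, label = "custom") {
  stopifnot(is.function(fun))
  structure(list(kind = "custom", fun = fun, label = label),
            class = "sigspec_activation")
}

#' Evaluate an activation function
#'
#' @param f an activation function created by [hill_activation()],
#'   [linear_activation()] or [custom_activation()].
#' @param u concentration(s) of the upstream component, >= 0.
#'
#' @return For the Hill kind, a dimensionless value in `[0, 1]`; for the
#'   linear kind, `u` itself; for a custom kind, `fun(u)`.
#' @export
evaluate_activation <- function(f, u) {
  if (!inherits(f, "sigspec_activation"))
    stop("`f` must be a sigspec_activation object", call. = FALSE)
  if (!is.numeric(u) || any(!is.finite(u)) || any(u < 0))
    stop("activation input `u` must be finite and non-negative", call. = FALSE)
  switch(f$kind,
    linear = u,
    hill = {
      # work with (u/eps)^n so large u cannot overflow before the ratio
      r <- (u / f$threshold)^f$exponent
      ifelse(is.infinite(r), 1, r / (1 + r))
    },
    custom = f$fun(u),
    stop("unknown activation kind", call. = FALSE)
  )
}

#' @export
print.sigspec_activation <- function(x, ...) {
  if (x$kind == "hill") {
    cat(sprintf("Hill activation: f(u) = u^%g / (u^%g + %g^%g)\n",
                x$exponent, x$exponent, x$threshold, x$exponent))
  } else if (x$kind == "linear") {
    cat("Linear activation: f(u) = u\n")
  } else {
    cat(sprintf("Custom monotone activation (%s)\n", x$label))
  }
  invisible(x)
}
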