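#' Parameterize a two-pathway signaling network
#'
#' Builds the full parameter set for one network instance: two pathways (X
#' and Y) that share the intermediate component `x1`, with inputs `x0` and
#' `y0`, outputs `x2` and `y2`, and optionally one insulating mechanism.
#'
#' Mechanisms:
#' * `"basic"` — no insulating mechanism; `x1` feeds both outputs.
#' * `"cpi"` — cross-pathway inhibition: the X output `x2` inhibits
#'   production of the Y output `y2` with IC50 `eps_g`.
#' * `"cs"` — combinatorial signaling: `x2` is a coincidence detector that
#'   also requires an independent input; when only the Y input is present
#'   its production is scaled by the leak fraction `k_leak`.
#' * `"sc"` — scaffolding/compartmentalization: the shared component exists
#'   in two exchanging pools, scaffold-anchored `x1N` (feeding `x2`) and
#'   cytosolic `x1C` (feeding `y2`), exchanging at rates `D_out`
#'   (N -> C) and `D_in` (C -> N).
#'
#' Rate equations (state `(x1, x2, y2)`, or `(x1N, x1C, x2, y2)` for `"sc"`):
#' \deqn{\dot x_1 = a_1 x_0 + b_1 y_0 - d_1 x_1}
#' \deqn{\dot x_2 = a_2 R f^X(x_1) - d_{2x} x_2}
#' \deqn{\dot y_2 = b_2 f^Y(x_1) / (1 + x_2/\epsilon_g) - d_{2y} y_2}
#' where the combinatorial factor `R` is 1 except under Y input for `"cs"`
#' (then `k_leak`), and the inhibition factor applies only for `"cpi"`.
#' For `"sc"`:
#' \deqn{\dot x_{1N} = a_1 x_0 - D_{out} x_{1N} + D_{in} x_{1C} - d_{1x} x_{1N}}
#' \deqn{\dot x_{1C} = b_1 y_0 - D_{in} x_{1C} + D_{out} x_{1N} - d_{1y} x_{1C}}
#' with `x2` produced from `x1N` and `y2` from `x1C` (production prefactors
#' `a2`, `b2` default to 1).
#'
#' The derived connection strengths are `alpha = a2/d2x` and `beta = b2/d2y`.
#'
#' @param mechanism one of `"basic"`, `"cpi"`, `"cs"`, `"sc"`.
#' @param a1,b1 activation rate coefficients of the shared component by the
#'   X and Y inputs (concentration/time per unit input), > 0.
#' @param a2,b2 production rate coefficients of the outputs, > 0.
#' @param d1 decay rate of the shared component (1/time); shorthand setting
#'   both `d1x` and `d1y`.
#' @param d1x,d1y pool-specific decay rates (only `"sc"` distinguishes
#'   them; the single-pool mechanisms require `d1x == d1y`).
#' @param d2x,d2y decay rates of the outputs (1/time), > 0.
#' @param fX,fY activation functions (see [hill_activation()]).
#' @param x0,y0 input levels, >= 0.
#' @param eps_g CPI IC50: amount of `x2` giving 50% inhibition of `y2`
#'   production (required iff `mechanism == "cpi"`).
#' @param k_leak CS leak fraction in `[0, 1]` (required iff `"cs"`).
#' @param D_in,D_out SC pool-exchange rate constants, >= 0 (required iff
#'   `"sc"`).
#'
#' @return An object of class `sigspec_network`.
#' @examples
#' p <- network_parameters("basic", a1 = 1, b1 = 1, a2 = 2, d2x = 1)
#' connection_strengths(p)
#' @export
network_parameters <- function(mechanism = c("basic", "cpi", "cs", "sc"),
                               a1, b1, a2 = 1, b2 = 1,
                               d1 = 1, d1x = d1, d1y = d1,
                               d2x = 1, d2y = 1,
                               fX = linear_activation(),
                               fY = linear_activation(),
                               x0 = 1, y0 = 1,
                               eps_g = NULL, k_leak = NULL,
                               D_in = NULL, D_out = NULL) {
  mechanism <- match.arg(mechanism)
  chk_pos <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a finite positive scalar", nm), call. = FALSE)
    as.numeric(v)
  }
  chk_nonneg <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("`%s` must be a finite non-negative scalar", nm), call. = FALSE)
    as.numeric(v)
  }
  a1 <- chk_pos(a1, "a1"); b1 <- chk_pos(b1, "b1")
  a2 <- chk_pos(a2, "a2"); b2 <- chk_pos(b2, "b2")
  d1x <- chk_pos(d1x, "d1x"); d1y <- chk_pos(d1y, "d1y")
  d2x <- chk_pos(d2x, "d2x"); d2y <- chk_pos(d2y, "d2y")
  x0 <- chk_nonneg(x0, "x0"); y0 <- chk_nonneg(y0, "y0")
  if (!inherits(fX, "sigspec_activation") || !inherits(fY, "sigspec_activation"))
    stop("`fX` and `fY` must be sigspec_activation objects", call. = FALSE)
  if (mechanism != "sc" && d1x != d1y)
    stop(sprintf("mechanism '%s' uses a single shared-component decay rate: d1x must equal d1y",
                 mechanism), call. = FALSE)

  # mechanism-specific fields are required iff the mechanism matches
  reject_if_set <- function(v, nm) {
    if (!is.null(v))
      stop(sprintf("`%s` is not a parameter of the '%s' mechanism", nm, mechanism),
           call. = FALSE)
  }
  if (mechanism == "cpi") {
    if (is.null(eps_g)) stop("mechanism 'cpi' requires `eps_g`", call. = FALSE)
    eps_g <- chk_pos(eps_g, "eps_g")
    reject_if_set(k_leak, "k_leak"); reject_if_set(D_in, "D_in"); reject_if_set(D_out, "D_out")
  } else if (mechanism == "cs") {
    if (is.null(k_leak)) stop("mechanism 'cs' requires `k_leak`", call. = FALSE)
    k_leak <- chk_nonneg(k_leak, "k_leak")
    if (k_leak > 1) stop("`k_leak` must lie in [0, 1]", call. = FALSE)
    reject_if_set(eps_g, "eps_g"); reject_if_set(D_in, "D_in"); reject_if_set(D_out, "D_out")
  } else if (mechanism == "sc") {
    if (is.null(D_in) || is.null(D_out))
      stop("mechanism 'sc' requires `D_in` and `D_out`", call. = FALSE)
    D_in <- chk_nonneg(D_in, "D_in"); D_out <- chk_nonneg(D_out, "D_out")
    reject_if_set(eps_g, "eps_g"); reject_if_set(k_leak, "k_leak")
  } else {
    reject_if_set(eps_g, "eps_g"); reject_if_set(k_leak, "k_leak")
    reject_if_set(D_in, "D_in"); reject_if_set(D_out, "D_out")
  }

  structure(list(mechanism = mechanism,
                 a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 d1x = d1x, d1y = d1y, d2x = d2x, d2y = d2y,
                 fX = fX, fY = fY, x0 = x0, y0 = y0,
                 eps_g = eps_g, k_leak = k_leak,
                 D_in = D_in, D_out = D_out),
            class = "sigspec_network")
}

#' Derived connection strengths
#'
#' `alpha = a2/d2x` measures the connection strength from the shared
#' component to the X output; `beta = b2/d2y` to the Y output.
#'
#' @param params a [network_parameters()] object.
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @export
connection_strengths <- function(params) {
  stopifnot(inherits(params, "sigspec_network"))
  c(alpha = params$a2 / params$d2x, beta = params$b2 / params$d2y)
}

# Resolve an exclusive input condition into actual input levels.
# X_on: (x0 > 0, y0 = 0); Y_on: (x0 = 0, y0 > 0).
with_condition <- function(params, condition = c("X_on", "Y_on")) {
  condition <- match.arg(condition)
  if (condition == "X_on") {
    if (params$x0 <= 0) stop("X_on requires x0 > 0", call. = FALSE)
    params$y0 <- 0
  } else {
    if (params$y0 <= 0) stop("Y_on requires y0 > 0", call. = FALSE)
    params$x0 <- 0
  }
  params
}

#' Right-hand side of the network ODE system
#'
#' Time derivatives of the active species. State ordering is
#' `(x1, x2, y2)` for the single-pool mechanisms and `(x1N, x1C, x2, y2)`
#' for scaffolding/compartmentalization. The combinatorial factor for
#' `"cs"` is resolved from the input levels stored in `params` (inputs are
#' exclusive): `k_leak` when the Y input is present, 1 otherwise.
#'
#' @param params a [network_parameters()] object.
#' @param state numeric state vector, all entries >= 0.
#' @return Numeric vector of time derivatives, same length as `state`.
#' @export
network_rhs <- function(params, state) {
  stopifnot(inherits(params, "sigspec_network"))
  dim_needed <- if (params$mechanism == "sc") 4L else 3L
  if (!is.numeric(state) || length(state) != dim_needed)
    stop(sprintf("mechanism '%s' needs a state vector of length %d",
                 params$mechanism, dim_needed), call. = FALSE)
  if (any(state < 0))
    stop("state entries must be non-negative", call. = FALSE)
  p <- params
  if (p$mechanism == "sc") {
    x1N <- state[1]; x1C <- state[2]; x2 <- state[3]; y2 <- state[4]
    c(p$a1 * p$x0 - p$D_out * x1N + p$D_in * x1C - p$d1x * x1N,
      p$b1 * p$y0 - p$D_in * x1C + p$D_out * x1N - p$d1y * x1C,
      p$a2 * evaluate_activation(p$fX, x1N) - p$d2x * x2,
      p$b2 * evaluate_activation(p$fY, x1C) - p$d2y * y2)
  } else {
    x1 <- state[1]; x2 <- state[2]; y2 <- state[3]
    R <- if (p$mechanism == "cs" && p$y0 > 0) p$k_leak else 1
    inhib <- if (p$mechanism == "cpi") 1 / (1 + x2 / p$eps_g) else 1
    c(p$a1 * p$x0 + p$b1 * p$y0 - p$d1x * x1,
      p$a2 * R * evaluate_activation(p$fX, x1) - p$d2x * x2,
      p$b2 * evaluate_activation(p$fY, x1) * inhib - p$d2y * y2)
  }
}

#' @export
print.sigspec_network <- function(x, ...) {
  cat(sprintf("Two-pathway signaling network (mechanism: %s)\n", x$mechanism))
  cat(sprintf("  a1 = %g, b1 = %g, a2 = %g, b2 = %g\n", x$a1, x$b1, x$a2, x$b2))
  cat(sprintf("  d1x = %g, d1y = %g, d2x = %g, d2y = %g\n",
              x$d1x, x$d1y, x$d2x, x$d2y))
  cat(sprintf("  inputs: x0 = %g, y0 = %g\n", x$x0, x$y0))
  cs <- connection_strengths(x)
  cat(sprintf("  alpha = %g, beta = %g\n", cs[["alpha"]], cs[["beta"]]))
  if (x$mechanism == "cpi") cat(sprintf("  eps_g = %g\n", x$eps_g))
  if (x$mechanism == "cs") cat(sprintf("  k_leak = %g\n", x$k_leak))
  if (x$mechanism == "sc") cat(sprintf("  D_in = %g, D_out = %g\n", x$D_in, x$D_out))
  cat("  fX: "); print(x$fX)
  cat("  fY: "); print(x$fY)
  invisible(x)
}
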