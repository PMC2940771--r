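# Quartet and indicators as a function of the two Hill exponents, holding
# every other parameter fixed. Requires Hill activation on both branches.
indicators_at_exponents <- function(params, n, m) {
  params$fX <- hill_activation(n, params$fX$threshold)
  params$fY <- hill_activation(m, params$fY$threshold)
  specificity_indicators(output_quartet(params))
}

fd_sign <- function(value_fn, at, h, zero_tol) {
  d1 <- (value_fn(at + h) - value_fn(at - h)) / (2 * h)
  d2 <- (value_fn(at + h / 2) - value_fn(at - h / 2)) / h
  if (!is.finite(d1) || !is.finite(d2)) return("zero")
  if (abs(d2) <= zero_tol || sign(d1) != sign(d2)) return("zero")
  if (d2 > 0) "positive" else "negative"
}

#' Signs of indicator derivatives with respect to the Hill exponents
#'
#' Which pathway benefits from becoming more switch-like? For each
#' indicator (`S_X`, `S_Y`, `F_X`, `F_Y`) this computes the sign of its
#' partial derivative with respect to the Hill exponents `n` (X branch)
#' and `m` (Y branch), treating exponents as continuous, by central finite
#' differences on the closed-form steady-state indicators with step
#' halving to confirm sign stability. Derivatives below numerical
#' resolution are reported as `"zero"` (e.g. when the shared component
#' sits exactly at an activation threshold, where the Hill value is 0.5
#' for every exponent).
#'
#' For the single-pool mechanisms the signs obey threshold conditions on
#' the shared component's two steady states: e.g. `S_X` increases with `n`
#' iff `x1|Xin > eps_X`, and increases with `m` iff `x1|Xin < eps_Y`. For
#' scaffolding/compartmentalization the same conditions apply pool-wise
#' (`x1N` against `eps_X`, `x1C` against `eps_Y`), which is what lets both
#' exponents be beneficial simultaneously.
#'
#' @param params a [network_parameters()] object with Hill activation on
#'   both branches and positive stored input levels `x0`, `y0`.
#' @param step base finite-difference step; default
#'   `max(1e-4, 1e-4 * n)` per exponent.
#' @return An object of class `sigspec_derivative_signs`: the eight signs
#'   (`d_sx_dn`, ..., `d_fy_dm`), the steady-state pools used, and
#'   `conditions_satisfiable` — whether thresholds exist that would make
#'   increasing both exponents beneficial for every indicator (see
#'   [mutual_benefit_feasible()]).
#' @export
derivative_signs <- function(params, step = NULL) {
  stopifnot(inherits(params, "sigspec_network"))
  if (params$fX$kind != "hill" || params$fY$kind != "hill")
    stop("derivative analysis requires Hill activation on both branches",
         call. = FALSE)
  if (params$x0 <= 0 || params$y0 <= 0)
    stop("derivative analysis needs positive stored input levels", call. = FALSE)
  n0 <- params$fX$exponent
  m0 <- params$fY$exponent
  h_n <- if (is.null(step)) max(1e-4, 1e-4 * n0) else step
  h_m <- if (is.null(step)) max(1e-4, 1e-4 * m0) else step
  # exponents must stay >= 1 for the difference stencil
  if (n0 - h_n < 1 || m0 - h_m < 1)
    stop("exponents must exceed 1 by at least the finite-difference step",
         call. = FALSE)

  inds <- c("s_x", "s_y", "f_x", "f_y")
  base <- indicators_at_exponents(params, n0, m0)
  signs <- list()
  for (ind in inds) {
    zt <- 1e-7 * (1 + abs(base[[ind]]))
    signs[[paste0("d_", sub("_", "", ind), "_dn")]] <-
      fd_sign(function(n) indicators_at_exponents(params, n, m0)[[ind]],
              n0, h_n, zt)
    signs[[paste0("d_", sub("_", "", ind), "_dm")]] <-
      fd_sign(function(m) indicators_at_exponents(params, n0, m)[[ind]],
              m0, h_m, zt)
  }

  pools <- steady_state_pools(params)
  feas <- mutual_benefit_feasible(params$mechanism, pools,
                                  eps_x = params$fX$threshold,
                                  eps_y = params$fY$threshold)
  structure(c(signs,
              list(mechanism = params$mechanism, pools = pools,
                   conditions_satisfiable = feas$feasible)),
            class = "sigspec_derivative_signs")
}

#' Shared-component steady states under both inputs
#'
#' @param params a [network_parameters()] object with positive stored
#'   input levels.
#' @return Named vector: `c(x1_X, x1_Y)` for single-pool mechanisms;
#'   `c(x1N_X, x1N_Y, x1C_X, x1C_Y)` for scaffolding/compartmentalization.
#' @export
steady_state_pools <- function(params) {
  on_x <- steady_state_analytic(params, "X_on")
  on_y <- steady_state_analytic(params, "Y_on")
  if (params$mechanism == "sc")
    c(x1N_X = on_x$x1N, x1N_Y = on_y$x1N, x1C_X = on_x$x1C, x1C_Y = on_y$x1C)
  else
    c(x1_X = on_x$x1, x1_Y = on_y$x1)
}

#' Can increasing both Hill exponents benefit every indicator?
#'
#' For the single-pool mechanisms (basic, cpi, cs) the threshold
#' conditions under which both `n` and `m` raise all four indicators
#' require `x1|Xin < eps_Y < x1|Yin < eps_X < x1|Xin` — a cyclic chain
#' that no thresholds can satisfy, since it forces the shared component's
#' two steady states each to be below the other. These mechanisms can
#' therefore use ultrasensitivity in only one pathway at a time. For
#' scaffolding/compartmentalization the pools decouple the chain into two
#' genuine intervals,
#' `x1N|Yin < eps_X < x1N|Xin` and `x1C|Xin < eps_Y < x1C|Yin`,
#' which are satisfiable whenever each pool is larger under its own
#' pathway's input.
#'
#' @param mechanism one of `"basic"`, `"cpi"`, `"cs"`, `"sc"`.
#' @param pools shared-component steady states under both inputs, as
#'   returned by [steady_state_pools()].
#' @param eps_x,eps_y activation thresholds to test (for `"sc"` the
#'   feasibility also reports, as witness, the open intervals any
#'   satisfying thresholds must lie in).
#' @return A list with `feasible` (logical), and either `witness` (the
#'   satisfying threshold intervals) or `violation` (why none exist).
#' @export
mutual_benefit_feasible <- function(mechanism, pools, eps_x, eps_y) {
  mechanism <- match.arg(mechanism, c("basic", "cpi", "cs", "sc"))
  if (mechanism != "sc") {
    return(list(feasible = FALSE,
                violation = paste("single-pool mechanisms need",
                                  "x1|Xin < eps_Y < x1|Yin < eps_X < x1|Xin,",
                                  "a cyclic chain no thresholds satisfy")))
  }
  need <- c("x1N_X", "x1N_Y", "x1C_X", "x1C_Y")
  if (!all(need %in% names(pools)))
    stop("sc feasibility needs pools named x1N_X, x1N_Y, x1C_X, x1C_Y",
         call. = FALSE)
  ok_n <- pools[["x1N_Y"]] < eps_x && eps_x < pools[["x1N_X"]]
  ok_c <- pools[["x1C_X"]] < eps_y && eps_y < pools[["x1C_Y"]]
  if (ok_n && ok_c) {
    list(feasible = TRUE,
         witness = list(eps_x_interval = c(pools[["x1N_Y"]], pools[["x1N_X"]]),
                        eps_y_interval = c(pools[["x1C_X"]], pools[["x1C_Y"]]),
                        eps_x = eps_x, eps_y = eps_y))
  } else {
    list(feasible = FALSE,
         violation = sprintf(
           "need x1N|Yin < eps_X < x1N|Xin (%s) and x1C|Xin < eps_Y < x1C|Yin (%s)",
           if (ok_n) "holds" else "fails", if (ok_c) "holds" else "fails"))
  }
}

#' @export
print.sigspec_derivative_signs <- function(x, ...) {
  cat(sprintf("Indicator derivative signs (mechanism: %s)\n", x$mechanism))
  cat(sprintf("  wrt n: dS_X %s, dS_Y %s, dF_X %s, dF_Y %s\n",
              x$d_sx_dn, x$d_sy_dn, x$d_fx_dn, x$d_fy_dn))
  cat(sprintf("  wrt m: dS_X %s, dS_Y %s, dF_X %s, dF_Y %s\n",
              x$d_sx_dm, x$d_sy_dm, x$d_fx_dm, x$d_fy_dm))
  cat(sprintf("  joint benefit from raising both exponents feasible: %s\n",
              x$conditions_satisfiable))
  invisible(x)
}
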