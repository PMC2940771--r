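#' Input fold-change between two fractional outputs of a Hill function
#'
#' For a Hill function with exponent `n`, the ratio of inputs producing
#' fractional outputs `hi` and `lo` of maximum is
#' \deqn{\left[\frac{hi\,(1-lo)}{lo\,(1-hi)}\right]^{1/n}}
#' For `lo = 0.1`, `hi = 0.9` this is `81^(1/n)`: a hyperbolic response
#' (`n = 1`) needs an 81-fold input change to go from 10% to 90% of
#' maximal output, while ultrasensitive responses with `n = 2` and
#' `n = 4` need only 9-fold and 3-fold changes.
#'
#' @param n Hill exponent, >= 1.
#' @param lo,hi fractional outputs, `0 < lo < hi < 1`.
#' @return The input fold-change (dimensionless, > 1).
#' @examples
#' hill_fold_change(1)  # 81
#' hill_fold_change(2)  # 9
#' @export
hill_fold_change <- function(n, lo = 0.1, hi = 0.9) {
  stopifnot(is.numeric(n), all(n >= 1), is.numeric(lo), is.numeric(hi))
  if (any(lo <= 0) || any(hi >= 1) || any(lo >= hi))
    stop("fractions must satisfy 0 < lo < hi < 1", call. = FALSE)
  ((hi * (1 - lo)) / (lo * (1 - hi)))^(1 / n)
}

#' Upper bound on MFMS at fixed cross-regulatory strength
#'
#' Maximum attainable MFMS for each insulating mechanism and activation
#' kind, as a function of the cross-regulatory term (CRT):
#'
#' | mechanism | linear           | ultrasensitive                    |
#' |-----------|------------------|-----------------------------------|
#' | cpi       | 1                | 1 + CRT                           |
#' | cs        | sqrt(CRT)        | CRT                               |
#' | sc        | 1 + CRT          | exact symmetric value, Eq. below  |
#'
#' The linear-CS value is the optimum of
#' `min(alpha/beta, (beta/alpha) CRT, (x1X/x1Y) CRT, x1Y/x1X)` over the
#' free ratios, which is the geometric mean `sqrt(CRT)` (attained at
#' `alpha/beta = sqrt(CRT)` and `x1Y/x1X = 1/sqrt(CRT)`); the package
#' verifies this against a brute-force optimizer rather than trusting any
#' printed form. For ultrasensitive scaffolding/compartmentalization the
#' symmetric network's MFMS is exact, not merely a bound — see
#' [sc_symmetric_mfms()]; `n` and `a` are then required.
#'
#' @param mechanism `"cpi"`, `"cs"` or `"sc"`.
#' @param activation `"linear"` or `"ultrasensitive"`.
#' @param crt cross-regulatory term, >= 0.
#' @param n Hill exponent (sc/ultrasensitive symmetric case only).
#' @param a symmetric input-strength parameter (sc/ultrasensitive only).
#' @return The bound (dimensionless).
#' @export
mfms_bound <- function(mechanism = c("cpi", "cs", "sc"),
                       activation = c("linear", "ultrasensitive"),
                       crt, n = NULL, a = NULL) {
  mechanism <- match.arg(mechanism)
  activation <- match.arg(activation)
  stopifnot(is.numeric(crt), all(crt >= 0))
  if (mechanism == "cpi") {
    if (activation == "linear") rep(1, length(crt)) else 1 + crt
  } else if (mechanism == "cs") {
    if (activation == "linear") sqrt(crt) else crt
  } else {
    if (activation == "linear") 1 + crt
    else {
      if (is.null(n) || is.null(a))
        stop("the ultrasensitive sc bound needs `n` and `a` (symmetric case)",
             call. = FALSE)
      sc_symmetric_mfms(a = a, crt = crt, n = n)
    }
  }
}

#' Exact MFMS of the symmetric scaffolding/compartmentalization network
#'
#' Under the symmetric reduction (`a1 = b1 = a`, `alpha = beta`, `n = m`,
#' `eps_X = eps_Y = 1`, `d1 = 1`, `D = 1/CRT`, unit inputs) all four
#' indicators coincide and MFMS equals
#' \deqn{\mathrm{MFMS} = \frac{a^n (1+CRT)^n + (1+CRT)^n (2+CRT)^n}
#'                            {a^n (1+CRT)^n + (2+CRT)^n}
#'       \sim (1+CRT)^n}
#' This is an equality for the symmetric network, not just a bound, and it
#' grows super-linearly in CRT whenever `n > 1` — the route by which
#' ultrasensitivity in both pathways compounds with compartmentalization.
#'
#' @param a symmetric input strength (`a1 x0 = b1 y0 = a`), > 0.
#' @param crt cross-regulatory term `d1/D`, >= 0.
#' @param n Hill exponent shared by both pathways, >= 1.
#' @return MFMS of the symmetric network (dimensionless).
#' @seealso [sc_symmetric_network()] for the corresponding full
#'   parameterization.
#' @export
sc_symmetric_mfms <- function(a, crt, n) {
  stopifnot(is.numeric(a), all(a > 0), is.numeric(crt), all(crt >= 0),
            is.numeric(n), all(n >= 1))
  A <- a^n
  u <- (1 + crt)^n
  v <- (2 + crt)^n
  (A * u + u * v) / (A * u + v)
}

#' @rdname sc_symmetric_mfms
#' @details `sc_symmetric_network()` builds the pinned network realizing
#'   the symmetric reduction: `d1x = d1y = 1`, `D_in = D_out = 1/crt`,
#'   `a1 = b1 = a` with unit inputs, `a2 = b2 = d2x = d2y = 1` (so
#'   `alpha = beta = 1`) and Hill thresholds fixed at 1. Its steady-state
#'   pools are `x1N|Xin = a (1+CRT)/(2+CRT)` and
#'   `x1C|Xin = a/(2+CRT)`, from which the quartet reproduces the exact
#'   MFMS formula.
#' @export
sc_symmetric_network <- function(a, crt, n) {
  stopifnot(length(a) == 1L, length(crt) == 1L, length(n) == 1L, crt > 0)
  network_parameters("sc", a1 = a, b1 = a, a2 = 1, b2 = 1,
                     d1 = 1, d2x = 1, d2y = 1,
                     fX = hill_activation(n, 1), fY = hill_activation(n, 1),
                     x0 = 1, y0 = 1,
                     D_in = 1 / crt, D_out = 1 / crt)
}

#' MFMS bound curves for export
#'
#' Tabulates [mfms_bound()] over a CRT grid for plotting or CSV export
#' (one row per CRT x mechanism x activation).
#'
#' @param crt numeric vector of CRT values.
#' @param mechanisms subset of `c("cpi", "cs", "sc")`.
#' @param activations subset of `c("linear", "ultrasensitive")`.
#' @param n,a symmetric-case parameters used for sc/ultrasensitive rows.
#' @return A data frame with columns `crt`, `mechanism`, `activation`,
#'   `n`, `bound`.
#' @export
bound_curve <- function(crt, mechanisms = c("cpi", "cs", "sc"),
                        activations = c("linear", "ultrasensitive"),
                        n = 2, a = 2) {
  grid <- expand.grid(crt = crt, mechanism = mechanisms,
                      activation = activations,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n <- ifelse(grid$activation == "ultrasensitive", n, 1)
  grid$bound <- mapply(function(m, act, c0) mfms_bound(m, act, c0, n = n, a = a),
                       grid$mechanism, grid$activation, grid$crt)
  grid
}
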