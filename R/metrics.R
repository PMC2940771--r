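#' Output quartet container
#'
#' The four steady-state outputs of a two-pathway network: `X|X` (X output
#' given X input), `X|Y`, `Y|X` and `Y|Y`. Accepts a numeric vector of
#' length 4 in the order `(x_given_x, x_given_y, y_given_x, y_given_y)`,
#' or a named vector/list with those names.
#'
#' @param x numeric vector or list of the four outputs, all finite and
#'   >= 0.
#' @return An object of class `sigspec_quartet`.
#' @examples
#' q <- as_output_quartet(c(4, 1, 2, 8))
#' specificity_indicators(q)
#' @export
as_output_quartet <- function(x) {
  if (inherits(x, "sigspec_quartet")) return(x)
  x <- unlist(x)
  nms <- c("x_given_x", "x_given_y", "y_given_x", "y_given_y")
  if (length(x) != 4L || !is.numeric(x))
    stop("an output quartet has exactly four numeric entries", call. = FALSE)
  if (!is.null(names(x)) && all(nms %in% names(x))) x <- x[nms]
  if (any(!is.finite(x)) || any(x < 0))
    stop("quartet entries must be finite and non-negative", call. = FALSE)
  structure(as.list(stats::setNames(as.numeric(x), nms)),
            class = "sigspec_quartet")
}

#' @export
print.sigspec_quartet <- function(x, ...) {
  cat("Steady-state output quartet:\n")
  cat(sprintf("  X|X = %g   X|Y = %g\n", x$x_given_x, x$x_given_y))
  cat(sprintf("  Y|X = %g   Y|Y = %g\n", x$y_given_x, x$y_given_y))
  invisible(x)
}

# extended-real ratio: positive/0 -> +Inf (zero crosstalk means infinite
# specificity); 0/0 -> degenerate network, not a numeric artifact
indicator_ratio <- function(num, den, what) {
  if (den > 0) return(num / den)
  if (num > 0) return(Inf)
  stop(sprintf("indicator %s is 0/0: degenerate network (both outputs vanish)", what),
       call. = FALSE)
}

#' Specificity and fidelity indicators
#'
#' Output specificity measures how much a pathway's input activates its own
#' output rather than the other pathway's output; input fidelity measures
#' how much a pathway's output responds to its own input rather than the
#' other input:
#' \deqn{S_X = \frac{X|X}{Y|X}, \quad S_Y = \frac{Y|Y}{X|Y}, \quad
#'       F_X = \frac{X|X}{X|Y}, \quad F_Y = \frac{Y|Y}{Y|X}}
#' The composites are minima over both pathways:
#' `MS = min(S_X, S_Y)`, `MF = min(F_X, F_Y)`, `MFMS = min(MS, MF)`.
#' `MFMS > 1` means the network communicates faithfully through both
#' pathways at once.
#'
#' A positive numerator over a zero denominator yields `+Inf` (a pathway
#' with no crosstalk has infinite specificity); `0/0` raises an error.
#' Minima over values including `+Inf` follow extended-real ordering.
#'
#' @param q an output quartet (see [as_output_quartet()]).
#' @param normalized if `TRUE`, compute the indicators of the
#'   diagonal-normalized quartet instead (equivalent to
#'   [normalized_indicators()]).
#' @return An object of class `sigspec_indicators` with fields `s_x`,
#'   `s_y`, `f_x`, `f_y`, `ms`, `mf`, `mfms`, `normalized`.
#' @export
specificity_indicators <- function(q, normalized = FALSE) {
  q <- as_output_quartet(q)
  if (isTRUE(normalized)) return(normalized_indicators(q))
  s_x <- indicator_ratio(q$x_given_x, q$y_given_x, "S_X")
  s_y <- indicator_ratio(q$y_given_y, q$x_given_y, "S_Y")
  f_x <- indicator_ratio(q$x_given_x, q$x_given_y, "F_X")
  f_y <- indicator_ratio(q$y_given_y, q$y_given_x, "F_Y")
  ms <- min(s_x, s_y); mf <- min(f_x, f_y)
  structure(list(s_x = s_x, s_y = s_y, f_x = f_x, f_y = f_y,
                 ms = ms, mf = mf, mfms = min(ms, mf),
                 normalized = FALSE),
            class = "sigspec_indicators")
}

#' Indicators of the diagonal-normalized quartet
#'
#' Outputs are often measured in incomparable units (different reporter
#' genes, kinases, ...). Normalizing each output by its own cognate
#' steady-state level (`X|X` for the X column, `Y|Y` for the Y column)
#' makes every entry a unit-less fraction of its pathway's authentic
#' response. Under this normalization specificity and fidelity coincide
#' across pathways: the identities `S_X = F_Y = (Y|Y)/(Y|X)` and
#' `S_Y = F_X = (X|X)/(X|Y)` hold exactly, and MS, MF and MFMS are all
#' equal. Normalization is an explicit opt-in; which characteristic level
#' to normalize by is system-specific.
#'
#' @param q an output quartet with strictly positive diagonal entries
#'   `X|X` and `Y|Y`.
#' @return A `sigspec_indicators` object with `normalized = TRUE`.
#' @export
normalized_indicators <- function(q) {
  q <- as_output_quartet(q)
  if (q$x_given_x <= 0 || q$y_given_y <= 0)
    stop("normalization requires positive cognate outputs X|X and Y|Y",
         call. = FALSE)
  q_hat <- as_output_quartet(c(x_given_x = 1,
                               x_given_y = q$x_given_y / q$x_given_x,
                               y_given_x = q$y_given_x / q$y_given_y,
                               y_given_y = 1))
  out <- specificity_indicators(q_hat)
  out$normalized <- TRUE
  out
}

#' @export
print.sigspec_indicators <- function(x, ...) {
  cat(sprintf("Specificity/fidelity indicators%s:\n",
              if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  S_X = %g   S_Y = %g\n", x$s_x, x$s_y))
  cat(sprintf("  F_X = %g   F_Y = %g\n", x$f_x, x$f_y))
  cat(sprintf("  MS = %g   MF = %g   MFMS = %g\n", x$ms, x$mf, x$mfms))
  invisible(x)
}

#' Cross-regulatory term (CRT)
#'
#' A single dimensionless number quantifying the strength of an insulating
#' mechanism, allowing mechanisms to be compared at matched degrees of
#' cross-regulation:
#' * cross-pathway inhibition: `CRT = alpha / eps_g`
#' * combinatorial signaling: `CRT = 1 / k_leak` (`+Inf` when
#'   `k_leak = 0`, i.e. the leak is fully closed)
#' * scaffolding/compartmentalization: `CRT = d1 / D`, requiring
#'   `D_in = D_out = D` and `d1x = d1y = d1` (`+Inf` when `D = 0`: the
#'   pools are decoupled and crosstalk vanishes)
#'
#' @param params a [network_parameters()] object with an insulating
#'   mechanism (`"basic"` has no CRT and raises an error).
#' @return A non-negative number, possibly `+Inf`.
#' @export
cross_regulatory_term <- function(params) {
  stopifnot(inherits(params, "sigspec_network"))
  switch(params$mechanism,
    basic = stop("the basic architecture has no cross-regulatory term",
                 call. = FALSE),
    cpi = unname(connection_strengths(params)["alpha"]) / params$eps_g,
    cs = if (params$k_leak == 0) Inf else 1 / params$k_leak,
    sc = {
      if (params$D_in != params$D_out)
        stop("CRT for 'sc' requires D_in == D_out", call. = FALSE)
      if (params$d1x != params$d1y)
        stop("CRT for 'sc' requires d1x == d1y", call. = FALSE)
      if (params$D_in == 0) Inf else params$d1x / params$D_in
    })
}
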