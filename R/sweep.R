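#' Default parameter ranges for Monte-Carlo sweeps
#'
#' Per-mechanism ranges for the dimensionless ratios sampled during
#' sweeps: `a1/d1`, `b1/d1`, `a2/d2x`, `b2/d2y` and the Y-branch
#' activation threshold `eps_Y`. The X input is favored for CPI
#' (`a1/d1` in `[1, 5]`, `b1/d1` in `[0.1, 1]`), the Y input for CS, and
#' both are strong for SC; the output ratios span `[0.1, 5]` and `eps_Y`
#' spans three decades, `[0.01, 10]`, for every mechanism. `eps_X` is
#' fixed at 1 (the sweep's concentration unit).
#'
#' @param mechanism `"cpi"`, `"cs"` or `"sc"`.
#' @return Named list of `c(low, high)` ranges.
#' @export
default_sweep_ranges <- function(mechanism = c("cpi", "cs", "sc")) {
  mechanism <- match.arg(mechanism)
  first <- switch(mechanism,
    cpi = list(a1_d1 = c(1, 5), b1_d1 = c(0.1, 1)),
    cs = list(a1_d1 = c(0.1, 1), b1_d1 = c(1, 5)),
    sc = list(a1_d1 = c(1, 5), b1_d1 = c(1, 5)))
  c(first, list(a2_d2x = c(0.1, 5), b2_d2y = c(0.1, 5), eps_Y = c(0.01, 10)))
}

#' Configure a Monte-Carlo parameter sweep
#'
#' A sweep samples `trials` random parameter sets per point of an
#' exponent grid, computes the steady-state quartet and indicators for
#' each, and summarizes MFMS by a percentile curve over the grid. The same
#' per-trial random draws are reused across the whole exponent grid
#' (common random numbers), so percentile curves vary smoothly with the
#' exponents.
#'
#' Conventions: decay rates and inputs are fixed at 1, so the sampled
#' ratios are the parameters themselves; `eps_X = 1`; `eps_Y` is sampled
#' log-uniformly (its default range spans three decades) and the rate
#' ratios uniformly on a linear scale; the mechanism's cross-regulation
#' parameter is pinned to `crt` (default 10: held constant and
#' sufficiently high while the exponents vary), or sampled log-uniformly
#' over CRT in `[0.01, 100]` (`[1, 100]` for CS, whose leak fraction
#' cannot exceed 1) when `crt = "free"`.
#'
#' @param mechanism `"cpi"`, `"cs"` or `"sc"`.
#' @param n_grid,m_grid Hill exponents to grid over (all pairs are run).
#' @param trials number of random parameter draws per grid point.
#' @param seed integer seed; identical `(config, seed)` give identical
#'   results.
#' @param percentile summary percentile in `(0, 1)` (default 0.9).
#' @param crt pinned cross-regulatory term (> 0), or `"free"`.
#' @param ranges per-parameter ranges, see [default_sweep_ranges()].
#' @param activation `"hill"` (default) or `"linear"`; the linear variant
#'   ignores exponents and thresholds.
#' @param ratio_law,eps_law sampling law for the rate ratios and for
#'   `eps_Y`: `"uniform"` or `"log-uniform"`.
#' @return A `sigspec_sweep_config` object.
#' @export
sweep_config <- function(mechanism = c("cpi", "cs", "sc"),
                         n_grid = 1, m_grid = 1,
                         trials = 1000, seed = 1L, percentile = 0.9,
                         crt = 10, ranges = default_sweep_ranges(mechanism),
                         activation = c("hill", "linear"),
                         ratio_law = c("uniform", "log-uniform"),
                         eps_law = c("log-uniform", "uniform")) {
  mechanism <- match.arg(mechanism)
  activation <- match.arg(activation)
  ratio_law <- match.arg(ratio_law)
  eps_law <- match.arg(eps_law)
  stopifnot(is.numeric(n_grid), all(n_grid >= 1),
            is.numeric(m_grid), all(m_grid >= 1),
            is.numeric(trials), trials >= 1,
            is.numeric(percentile), percentile > 0, percentile < 1)
  if (!identical(crt, "free")) {
    stopifnot(is.numeric(crt), length(crt) == 1L, crt > 0)
    if (mechanism == "cs" && crt < 1)
      stop("CS needs CRT >= 1 (k_leak = 1/CRT must lie in [0, 1])", call. = FALSE)
  }
  need <- c("a1_d1", "b1_d1", "a2_d2x", "b2_d2y", "eps_Y")
  if (!all(need %in% names(ranges)))
    stop("`ranges` must name a1_d1, b1_d1, a2_d2x, b2_d2y, eps_Y", call. = FALSE)
  structure(list(mechanism = mechanism, n_grid = n_grid, m_grid = m_grid,
                 trials = as.integer(trials), seed = as.integer(seed),
                 percentile = percentile, crt = crt, ranges = ranges,
                 activation = activation, ratio_law = ratio_law,
                 eps_law = eps_law),
            class = "sigspec_sweep_config")
}

# deterministic per-draw sampling of the dimensionless ratios; isolates
# the global RNG state
sample_ratios <- function(config, draw_index) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  seed_i <- as.integer((as.numeric(config$seed) %% 65011 * 33013 +
                          as.numeric(draw_index) * 7919) %% 2147483629)
  set.seed(seed_i)
  draw <- function(range, law) {
    if (law == "uniform") stats::runif(1, range[1], range[2])
    else exp(stats::runif(1, log(range[1]), log(range[2])))
  }
  r <- config$ranges
  crt <- if (identical(config$crt, "free")) {
    lo <- if (config$mechanism == "cs") 1 else 0.01
    exp(stats::runif(1, log(lo), log(100)))
  } else config$crt
  list(a1_d1 = draw(r$a1_d1, config$ratio_law),
       b1_d1 = draw(r$b1_d1, config$ratio_law),
       a2_d2x = draw(r$a2_d2x, config$ratio_law),
       b2_d2y = draw(r$b2_d2y, config$ratio_law),
       eps_Y = draw(r$eps_Y, config$eps_law),
       crt = crt)
}

build_sweep_network <- function(config, ratios, n, m) {
  act_x <- if (config$activation == "linear") linear_activation()
           else hill_activation(n, 1)
  act_y <- if (config$activation == "linear") linear_activation()
           else hill_activation(m, ratios$eps_Y)
  alpha <- ratios$a2_d2x
  extra <- switch(config$mechanism,
    cpi = list(eps_g = alpha / ratios$crt),
    cs = list(k_leak = 1 / ratios$crt),
    sc = list(D_in = 1 / ratios$crt, D_out = 1 / ratios$crt))
  do.call(network_parameters,
          c(list(mechanism = config$mechanism,
                 a1 = ratios$a1_d1, b1 = ratios$b1_d1,
                 a2 = ratios$a2_d2x, b2 = ratios$b2_d2y,
                 d1 = 1, d2x = 1, d2y = 1,
                 fX = act_x, fY = act_y, x0 = 1, y0 = 1),
            extra))
}

#' Sample one network from a sweep configuration
#'
#' Deterministic in `(config$seed, draw_index)`: the same pair always
#' yields the same network.
#'
#' @param config a [sweep_config()] object.
#' @param draw_index trial index (1-based).
#' @param n,m Hill exponents to install (default: first grid entries).
#' @return A [network_parameters()] object.
#' @export
sample_parameters <- function(config, draw_index,
                              n = config$n_grid[1], m = config$m_grid[1]) {
  stopifnot(inherits(config, "sigspec_sweep_config"))
  build_sweep_network(config, sample_ratios(config, draw_index), n, m)
}

#' Nearest-rank percentile with infinite values ranked above finite ones
#'
#' @param v numeric vector (may include `Inf`; `NA`s are removed).
#' @param p percentile in `(0, 1)`.
#' @return The nearest-rank percentile value.
#' @export
rank_percentile <- function(v, p) {
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  sort(v)[ceiling(p * length(v))]  # Inf sorts above every finite value
}

#' Run a Monte-Carlo parameter sweep
#'
#' For every exponent pair in the grid and every trial, computes the
#' steady-state quartet, the specificity/fidelity indicators and MFMS.
#' Trials whose indicators are undefined (0/0 ratios, degenerate networks)
#' are dropped and counted, not fatal.
#'
#' @param config a [sweep_config()] object.
#' @return A `sigspec_sweep` object: `records` (one row per trial x grid
#'   point with the sampled ratios and all indicators), `percentile_curve`
#'   (per grid point, the configured MFMS percentile), `dropped` (count of
#'   degenerate trials) and `config`.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "sigspec_sweep_config"))
  grid <- expand.grid(n = config$n_grid, m = config$m_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n_rec <- nrow(grid) * config$trials
  rec <- data.frame(draw = integer(n_rec), n = numeric(n_rec),
                    m = numeric(n_rec), a1_d1 = numeric(n_rec),
                    b1_d1 = numeric(n_rec), a2_d2x = numeric(n_rec),
                    b2_d2y = numeric(n_rec), eps_Y = numeric(n_rec),
                    crt = numeric(n_rec), s_x = numeric(n_rec),
                    s_y = numeric(n_rec), f_x = numeric(n_rec),
                    f_y = numeric(n_rec), ms = numeric(n_rec),
                    mf = numeric(n_rec), mfms = numeric(n_rec))
  dropped <- 0L
  row <- 0L
  for (draw in seq_len(config$trials)) {
    ratios <- sample_ratios(config, draw)
    for (g in seq_len(nrow(grid))) {
      row <- row + 1L
      params <- build_sweep_network(config, ratios, grid$n[g], grid$m[g])
      ind <- tryCatch(specificity_indicators(output_quartet(params)),
                      error = function(e) NULL)
      rec[row, c("draw", "n", "m")] <- c(draw, grid$n[g], grid$m[g])
      rec[row, c("a1_d1", "b1_d1", "a2_d2x", "b2_d2y", "eps_Y", "crt")] <-
        unlist(ratios)
      if (is.null(ind)) {
        dropped <- dropped + 1L
        rec[row, c("s_x", "s_y", "f_x", "f_y", "ms", "mf", "mfms")] <- NA_real_
      } else {
        rec[row, c("s_x", "s_y", "f_x", "f_y", "ms", "mf", "mfms")] <-
          c(ind$s_x, ind$s_y, ind$f_x, ind$f_y, ind$ms, ind$mf, ind$mfms)
      }
    }
  }
  curve <- grid
  curve$percentile_mfms <- vapply(seq_len(nrow(grid)), function(g) {
    sel <- rec$n == grid$n[g] & rec$m == grid$m[g]
    rank_percentile(rec$mfms[sel], config$percentile)
  }, numeric(1))
  structure(list(records = rec, percentile_curve = curve,
                 dropped = dropped, config = config),
            class = "sigspec_sweep")
}

#' @export
print.sigspec_sweep <- function(x, ...) {
  cat(sprintf("Monte-Carlo sweep: %s, %d trials x %d grid points (%d dropped)\n",
              x$config$mechanism, x$config$trials,
              nrow(x$percentile_curve), x$dropped))
  cat(sprintf("MFMS percentile curve (p = %g):\n", x$config$percentile))
  print(x$percentile_curve, row.names = FALSE)
  invisible(x)
}

#' Maximize MFMS at fixed cross-regulatory strength
#'
#' Multi-start random search plus Nelder-Mead refinement over the free
#' network parameters, used to verify numerically that the closed-form
#' MFMS bounds are sharp. The mechanism's cross-regulation parameter is
#' pinned to `crt`, or searched over several decades of CRT when
#' `crt = NULL`.
#'
#' Free parameters (searched on a log scale over `[0.01, 100]`, exponents
#' uniformly over `[1, 10]`): the shared-component steady states under
#' each input (via `a1 x0` and `b1 y0`), the connection strengths `alpha`
#' and `beta`, and for ultrasensitive activation the thresholds `eps_X`,
#' `eps_Y` and exponents `n`, `m`. The ultrasensitive
#' scaffolding/compartmentalization search is restricted to the symmetric
#' family (free `a` and `n = m`), where MFMS has an exact closed form to
#' compare against.
#'
#' @param mechanism `"cpi"`, `"cs"` or `"sc"`.
#' @param activation `"linear"` or `"ultrasensitive"`.
#' @param crt pinned CRT (> 0; >= 1 for CS), or `NULL` to search over CRT.
#' @param budget number of random starts before refinement.
#' @param seed integer seed for the random phase.
#' @param refine number of top starts polished by Nelder-Mead.
#' @param maxit Nelder-Mead iteration cap per refinement.
#' @return A list: `mfms` (best value found), `params` (the realizing
#'   network), `theta` (internal coordinates), `bound` (the corresponding
#'   [mfms_bound()], `NA` when `crt = NULL`) and `below_bound`.
#' @export
maximize_mfms <- function(mechanism = c("cpi", "cs", "sc"),
                          activation = c("linear", "ultrasensitive"),
                          crt = NULL, budget = 2000, seed = 1L,
                          refine = 5L, maxit = 300L) {
  mechanism <- match.arg(mechanism)
  activation <- match.arg(activation)
  free_crt <- is.null(crt)
  if (!free_crt) {
    stopifnot(is.numeric(crt), length(crt) == 1L, crt > 0)
    if (mechanism == "cs" && crt < 1)
      stop("CS needs CRT >= 1", call. = FALSE)
  }

  lo_lcrt <- if (mechanism == "cs") 0 else -2
  # coordinate layout: magnitudes as log10 in [-2, 2], exponents in [1, 10]
  if (mechanism == "sc" && activation == "ultrasensitive") {
    box_lo <- c(-2, 1); box_hi <- c(2, 10)
  } else if (activation == "linear") {
    box_lo <- rep(-2, 4); box_hi <- rep(2, 4)
  } else {
    box_lo <- c(rep(-2, 6), 1, 1); box_hi <- c(rep(2, 6), 10, 10)
  }
  if (free_crt) { box_lo <- c(box_lo, lo_lcrt); box_hi <- c(box_hi, 2) }

  build <- function(theta) {
    theta <- pmin(pmax(theta, box_lo), box_hi)
    crt_use <- if (free_crt) 10^theta[length(theta)] else crt
    if (mechanism == "sc" && activation == "ultrasensitive")
      return(sc_symmetric_network(a = 10^theta[1], crt = crt_use, n = theta[2]))
    p1 <- 10^theta[1]; p2 <- 10^theta[2]
    alpha <- 10^theta[3]; beta <- 10^theta[4]
    if (activation == "linear") {
      fX <- linear_activation(); fY <- linear_activation()
    } else {
      fX <- hill_activation(theta[7], 10^theta[5])
      fY <- hill_activation(theta[8], 10^theta[6])
    }
    extra <- switch(mechanism,
      cpi = list(eps_g = alpha / crt_use),
      cs = list(k_leak = 1 / crt_use),
      sc = list(D_in = 1 / crt_use, D_out = 1 / crt_use))
    do.call(network_parameters,
            c(list(mechanism = mechanism, a1 = p1, b1 = p2,
                   a2 = alpha, b2 = beta, d1 = 1, d2x = 1, d2y = 1,
                   fX = fX, fY = fY, x0 = 1, y0 = 1),
              extra))
  }
  evaluate <- function(theta) {
    tryCatch(specificity_indicators(output_quartet(build(theta)))$mfms,
             error = function(e) NA_real_)
  }

  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  k <- length(box_lo)
  starts <- matrix(stats::runif(budget * k, rep(box_lo, each = budget),
                                rep(box_hi, each = budget)),
                   nrow = budget, ncol = k)
  vals <- apply(starts, 1, evaluate)
  ord <- order(vals, decreasing = TRUE, na.last = TRUE)
  best_theta <- starts[ord[1], ]
  best_val <- vals[ord[1]]

  obj <- function(theta) {
    v <- evaluate(theta)
    if (is.na(v) || v <= 0) return(1e10)
    -log(min(v, 1e15))
  }
  for (i in seq_len(min(refine, budget))) {
    th0 <- starts[ord[i], ]
    fit <- tryCatch(stats::optim(th0, obj, method = "Nelder-Mead",
                                 control = list(maxit = maxit)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      v <- evaluate(fit$par)
      if (!is.na(v) && (is.na(best_val) || v > best_val)) {
        best_val <- v
        best_theta <- pmin(pmax(fit$par, box_lo), box_hi)
      }
    }
  }

  bound <- if (free_crt) NA_real_
  else if (mechanism == "sc" && activation == "ultrasensitive")
    sc_symmetric_mfms(a = 10^best_theta[1], crt = crt, n = best_theta[2])
  else mfms_bound(mechanism, activation, crt)
  list(mfms = best_val, params = build(best_theta), theta = best_theta,
       bound = bound,
       below_bound = if (is.na(bound)) NA else best_val <= bound * (1 + 1e-9))
}
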