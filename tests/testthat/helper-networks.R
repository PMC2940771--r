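# Randomized fixture builders. Tests seed the RNG before calling these.

random_hill <- function(exp_range = c(1, 6), eps_range = c(0.2, 2)) {
  hill_activation(exponent = runif(1, exp_range[1], exp_range[2]),
                  threshold = runif(1, eps_range[1], eps_range[2]))
}

# strictly increasing piecewise-linear activation with positive values,
# constant beyond the last knot (still monotone non-decreasing)
random_monotone_activation <- function() {
  xs <- c(0, sort(runif(5, 0.1, 8)))
  ys <- cumsum(runif(6, 0.05, 1))
  custom_activation(function(u) {
    stats::approx(xs, ys, xout = pmin(u, max(xs)), rule = 2)$y
  }, label = "piecewise-linear")
}

random_network <- function(mechanism = c("basic", "cpi", "cs", "sc"),
                           fX = random_hill(), fY = random_hill()) {
  mechanism <- match.arg(mechanism)
  base <- list(mechanism = mechanism,
               a1 = runif(1, 0.2, 5), b1 = runif(1, 0.2, 5),
               a2 = runif(1, 0.2, 5), b2 = runif(1, 0.2, 5),
               d1 = runif(1, 0.2, 2),
               d2x = runif(1, 0.2, 2), d2y = runif(1, 0.2, 2),
               fX = fX, fY = fY, x0 = 1, y0 = 1)
  extra <- switch(mechanism,
    basic = list(),
    cpi = list(eps_g = runif(1, 0.05, 5)),
    cs = list(k_leak = runif(1, 0.05, 1)),
    sc = list(D_in = runif(1, 0.05, 5), D_out = runif(1, 0.05, 5)))
  if (mechanism == "sc") {
    base$d1 <- NULL
    base$d1x <- runif(1, 0.2, 2)
    base$d1y <- runif(1, 0.2, 2)
  }
  do.call(network_parameters, c(base, extra))
}

random_quartet <- function() {
  as_output_quartet(exp(runif(4, -3, 3)))
}

# worst-case relative disagreement between two steady states
steady_state_rel_err <- function(a, b) {
  va <- unlist(a[setdiff(names(a), c("mechanism", "condition"))])
  vb <- unlist(b[names(va)])
  max(abs(va - vb) / (abs(va) + 1e-12))
}
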