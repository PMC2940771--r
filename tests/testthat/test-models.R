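test_that("rhs fixed points and trivial cases behave", {
  empty <- network_parameters("basic", a1 = 1, b1 = 1, x0 = 0, y0 = 0)
  expect_equal(network_rhs(empty, c(0, 0, 0)), c(0, 0, 0))

  p <- network_parameters("basic", a1 = 1, b1 = 1, d1 = 1, x0 = 1, y0 = 0)
  expect_equal(network_rhs(p, c(1, 0.3, 0.7))[1], 0)  # x1 at its fixed point

  expect_error(network_rhs(p, c(1, 2)), "length 3")
  expect_error(network_rhs(p, c(-1, 0, 0)), "non-negative")
})

test_that("CPI inhibition halves y2 production when x2 equals the IC50", {
  base <- network_parameters("basic", a1 = 1, b1 = 1, a2 = 1, b2 = 2,
                             x0 = 1, y0 = 0)
  cpi <- network_parameters("cpi", a1 = 1, b1 = 1, a2 = 1, b2 = 2,
                            x0 = 1, y0 = 0, eps_g = 0.4)
  st <- c(1.3, 0.4, 0)  # x2 at eps_g, y2 empty so dy2 is pure production
  expect_equal(network_rhs(cpi, st)[3], network_rhs(base, st)[3] / 2)
  expect_equal(network_rhs(cpi, st)[1:2], network_rhs(base, st)[1:2])
})

test_that("analytic steady state matches the worked linear example", {
  p <- network_parameters("basic", a1 = 1, b1 = 1, a2 = 2, b2 = 1,
                          d1 = 1, d2x = 1, d2y = 1)
  ss <- steady_state_analytic(p, "X_on")
  expect_equal(c(ss$x1, ss$x2, ss$y2), c(1, 2, 1))
  # numerical integration from the empty state is the independent oracle
  sn <- steady_state_numeric(p, "X_on")
  expect_equal(steady_state_rel_err(ss, sn), 0, tolerance = 1e-8)
})

test_that("scaffold pool ratio under own input is 1 + d1/D", {
  p <- network_parameters("sc", a1 = 1, b1 = 1, d1 = 1,
                          D_in = 1, D_out = 1, x0 = 1, y0 = 1)
  ss <- steady_state_analytic(p, "X_on")
  expect_equal(ss$x1N / ss$x1C, 2)
  p2 <- network_parameters("sc", a1 = 3, b1 = 2, d1 = 1,
                           D_in = 0.25, D_out = 0.25, x0 = 1, y0 = 1)
  ss2 <- steady_state_analytic(p2, "X_on")
  expect_equal(ss2$x1N / ss2$x1C, 1 + 1 / 0.25)
})

test_that("mechanism limits recover the basic architecture or decouple", {
  set.seed(31)
  base <- random_network("basic")
  # CPI with a huge IC50 is indistinguishable from basic
  cpi <- do.call(network_parameters,
                 c(list(mechanism = "cpi", eps_g = 1e12),
                   base[c("a1", "b1", "a2", "b2", "d2x", "d2y", "fX", "fY",
                          "x0", "y0")],
                   list(d1 = base$d1x)))
  expect_equal(unlist(steady_state_analytic(cpi, "X_on")[c("x1", "x2", "y2")]),
               unlist(steady_state_analytic(base, "X_on")[c("x1", "x2", "y2")]),
               tolerance = 1e-10)
  # fully closed combinatorial leak removes X output under Y input
  cs0 <- network_parameters("cs", a1 = 1, b1 = 2, k_leak = 0)
  expect_equal(steady_state_analytic(cs0, "Y_on")$x2, 0)
  # zero exchange decouples the scaffold pools entirely
  sc0 <- network_parameters("sc", a1 = 1, b1 = 1, D_in = 0, D_out = 0)
  expect_equal(steady_state_analytic(sc0, "X_on")$x1C, 0)
  expect_equal(steady_state_numeric(sc0, "X_on")$x1C, 0, tolerance = 1e-10)
})

test_that("analytic and numeric steady states agree on randomized networks", {
  set.seed(41)
  for (mech in c("basic", "cpi", "cs", "sc")) {
    for (i in 1:10) {
      p <- random_network(mech)
      cond <- sample(c("X_on", "Y_on"), 1)
      err <- steady_state_rel_err(steady_state_analytic(p, cond),
                                  steady_state_numeric(p, cond))
      expect_lt(err, 1e-6)
    }
  }
})

test_that("analytic steady states are exact zeros of the rhs", {
  set.seed(51)
  for (mech in c("basic", "cpi", "cs", "sc")) {
    for (i in 1:5) {
      p <- random_network(mech)
      cond <- sample(c("X_on", "Y_on"), 1)
      ss <- steady_state_analytic(p, cond)
      pc <- sigspec:::with_condition(p, cond)
      resid <- network_rhs(pc, sigspec:::as_state_vector(ss))
      expect_lt(max(abs(resid)), 1e-12)
      expect_true(all(sigspec:::as_state_vector(ss) >= 0))
      expect_true(all(is.finite(sigspec:::as_state_vector(ss))))
    }
  }
})

test_that("basic-architecture steady state is monotone in the input level", {
  set.seed(61)
  for (i in 1:8) {
    p <- random_network("basic")
    lvls <- sort(runif(5, 0.1, 6))
    out <- sapply(lvls, function(x0) {
      p$x0 <- x0
      unlist(steady_state_analytic(p, "X_on")[c("x1", "x2", "y2")])
    })
    expect_true(all(diff(out["x1", ]) >= 0))
    expect_true(all(diff(out["x2", ]) >= -1e-14))
    expect_true(all(diff(out["y2", ]) >= -1e-14))
  }
})

test_that("CPI only suppresses Y outputs; CS only scales X|Y by k_leak", {
  set.seed(71)
  for (i in 1:8) {
    base <- random_network("basic")
    shared <- c(base[c("a1", "b1", "a2", "b2", "d2x", "d2y", "fX", "fY",
                       "x0", "y0")], list(d1 = base$d1x))
    qb <- output_quartet(base)

    cpi <- do.call(network_parameters,
                   c(list(mechanism = "cpi", eps_g = runif(1, 0.05, 5)), shared))
    qc <- output_quartet(cpi)
    expect_equal(qc$x_given_x, qb$x_given_x)
    expect_equal(qc$x_given_y, qb$x_given_y)
    expect_lt(qc$y_given_x, qb$y_given_x)
    expect_lt(qc$y_given_y, qb$y_given_y)

    k <- runif(1, 0.05, 0.95)
    cs <- do.call(network_parameters,
                  c(list(mechanism = "cs", k_leak = k), shared))
    qs <- output_quartet(cs)
    expect_equal(qs$x_given_y, k * qb$x_given_y, tolerance = 1e-12)
    expect_equal(qs$x_given_x, qb$x_given_x)
    expect_equal(qs$y_given_x, qb$y_given_x)
    expect_equal(qs$y_given_y, qb$y_given_y)
  }
})

test_that("quartet symmetries of the linear basic architecture", {
  p <- network_parameters("basic", a1 = 1.4, b1 = 0.6, a2 = 2, b2 = 2,
                          d2x = 1.25, d2y = 1.25)
  q <- output_quartet(p)
  expect_equal(q$x_given_x, q$y_given_x)  # alpha == beta
  expect_equal(q$x_given_y, q$y_given_y)
  p2 <- network_parameters("basic", a1 = 0.9, b1 = 0.9, a2 = 3, b2 = 1)
  q2 <- output_quartet(p2)
  expect_equal(q2$x_given_x, q2$x_given_y)  # a1 = b1, x0 = y0
})

test_that("numeric solver reports non-convergence instead of truncating", {
  p <- network_parameters("basic", a1 = 1, b1 = 1)
  expect_error(steady_state_numeric(p, "X_on", t_max = 1e-4), "steady state")
})

test_that("config files round-trip through read/write", {
  set.seed(81)
  for (mech in c("basic", "cpi", "cs", "sc")) {
    p <- random_network(mech)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_network_config(p, path)
    p2 <- read_network_config(path)
    expect_equal(p2, p, tolerance = 1e-12)
  }
  expect_error(read_network_config(withr::local_tempfile()), "not found")
})

test_that("mechanism-specific fields are required iff the mechanism matches", {
  expect_error(network_parameters("cpi", a1 = 1, b1 = 1), "eps_g")
  expect_error(network_parameters("cs", a1 = 1, b1 = 1), "k_leak")
  expect_error(network_parameters("sc", a1 = 1, b1 = 1), "D_in")
  expect_error(network_parameters("basic", a1 = 1, b1 = 1, eps_g = 1), "eps_g")
  expect_error(network_parameters("cs", a1 = 1, b1 = 1, k_leak = 1.4), "0, 1")
  expect_error(network_parameters("cpi", a1 = 1, b1 = 1, eps_g = 1,
                                  d1x = 1, d1y = 2), "d1x")
})
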