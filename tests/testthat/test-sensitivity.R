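# expected sign of dS/d(exponent) from the threshold conditions on the
# shared-component steady states (single-pool mechanisms)
threshold_sign <- function(pool, eps) if (pool > eps) "positive" else "negative"

test_that("specificity derivative signs match the threshold conditions", {
  set.seed(151)
  for (mech in c("basic", "cpi", "cs")) {
    tested <- 0
    while (tested < 8) {
      p <- random_network(mech, fX = random_hill(c(1.5, 6)),
                          fY = random_hill(c(1.5, 6)))
      pools <- steady_state_pools(p)
      eps <- c(p$fX$threshold, p$fY$threshold)
      # stay away from the threshold boundary (sign degenerates) and from
      # deep Hill saturation (derivative falls below numerical resolution)
      ratios <- abs(log(c(pools / eps[1], pools / eps[2])))
      if (min(ratios) < 0.05 || max(ratios) > log(5)) next
      tested <- tested + 1
      ds <- derivative_signs(p)
      expect_equal(ds$d_sx_dn, threshold_sign(pools[["x1_X"]], eps[1]))
      expect_equal(ds$d_sy_dn, threshold_sign(eps[1], pools[["x1_Y"]]))
      expect_equal(ds$d_sx_dm, threshold_sign(eps[2], pools[["x1_X"]]))
      expect_equal(ds$d_sy_dm, threshold_sign(pools[["x1_Y"]], eps[2]))
      expect_false(ds$conditions_satisfiable)
    }
  }
})

test_that("scaffold pools give pool-wise threshold conditions", {
  # symmetric network, a = 2, CRT = 1: anchored pool is 4/3 under its own
  # input and 2/3 under the other input
  net <- sc_symmetric_network(2, 1, 2)
  pools <- steady_state_pools(net)
  expect_equal(unname(pools), c(4 / 3, 2 / 3, 2 / 3, 4 / 3), tolerance = 1e-12)
  ds <- derivative_signs(net)
  expect_equal(ds$d_sx_dn, "positive")  # x1N|Xin = 4/3 > eps_X = 1
  expect_equal(ds$d_sy_dn, "positive")  # x1N|Yin = 2/3 < eps_X = 1
  expect_equal(ds$d_sx_dm, "positive")  # x1C|Xin = 2/3 < eps_Y = 1
  expect_equal(ds$d_sy_dm, "positive")  # x1C|Yin = 4/3 > eps_Y = 1
  expect_true(ds$conditions_satisfiable)

  set.seed(161)
  for (i in 1:8) {
    p <- random_network("sc", fX = random_hill(c(1.5, 6)),
                        fY = random_hill(c(1.5, 6)))
    pools <- steady_state_pools(p)
    eps <- c(p$fX$threshold, p$fY$threshold)
    ratios <- abs(log(c(pools[c("x1N_X", "x1N_Y")] / eps[1],
                        pools[c("x1C_X", "x1C_Y")] / eps[2])))
    if (min(ratios) < 0.05 || max(ratios) > log(5)) next
    ds <- derivative_signs(p)
    expect_equal(ds$d_sx_dn, threshold_sign(pools[["x1N_X"]], eps[1]))
    expect_equal(ds$d_sy_dn, threshold_sign(eps[1], pools[["x1N_Y"]]))
    expect_equal(ds$d_sx_dm, threshold_sign(eps[2], pools[["x1C_X"]]))
    expect_equal(ds$d_sy_dm, threshold_sign(pools[["x1C_Y"]], eps[2]))
  }
})

test_that("a pool exactly at threshold gives a zero derivative", {
  # x1|Xin = a1 x0 / d1 = 1 = eps_X: the Hill value is 0.5 for every n
  p <- network_parameters("basic", a1 = 1, b1 = 0.4,
                          fX = hill_activation(2, 1),
                          fY = hill_activation(2, 0.1))
  ds <- derivative_signs(p)
  expect_equal(ds$d_sx_dn, "zero")
})

test_that("CPI can exploit n only; CS can exploit m only", {
  # CPI operating regime eps_Y < x1|Yin < eps_X < x1|Xin
  cpi <- network_parameters("cpi", a1 = 3, b1 = 0.5, eps_g = 0.5,
                            fX = hill_activation(3, 1),
                            fY = hill_activation(3, 0.1))
  ds <- derivative_signs(cpi)
  expect_true(all(c(ds$d_sx_dn, ds$d_sy_dn, ds$d_fx_dn, ds$d_fy_dn) ==
                    "positive"))
  expect_equal(ds$d_sx_dm, "negative")
  expect_equal(ds$d_sy_dm, "positive")

  # CS operating regime eps_X < x1|Xin < eps_Y < x1|Yin
  cs <- network_parameters("cs", a1 = 0.5, b1 = 3, k_leak = 0.1,
                           fX = hill_activation(3, 0.1),
                           fY = hill_activation(3, 1))
  ds <- derivative_signs(cs)
  expect_true(all(c(ds$d_sx_dm, ds$d_sy_dm, ds$d_fy_dm) == "positive"))
  expect_equal(ds$d_fx_dm, "zero")  # F_X has no m dependence under CS
  expect_equal(ds$d_sy_dn, "negative")
})

test_that("with satisfiable pool conditions SC MFMS rises in both exponents", {
  net <- sc_symmetric_network(2, 3, 2)
  expect_true(derivative_signs(net)$conditions_satisfiable)
  mfms_at <- function(n, m) {
    net$fX <- hill_activation(n, 1)
    net$fY <- hill_activation(m, 1)
    specificity_indicators(output_quartet(net))$mfms
  }
  for (e in list(c(1, 1), c(2, 2), c(4, 4), c(2, 5))) {
    base <- mfms_at(e[1], e[2])
    expect_gte(mfms_at(e[1] + 1, e[2]), base)
    expect_gte(mfms_at(e[1], e[2] + 1), base)
  }
})

test_that("joint exponent benefit is infeasible except for scaffolding", {
  expect_false(mutual_benefit_feasible("basic", c(x1_X = 2, x1_Y = 0.5),
                                       1, 1)$feasible)
  expect_false(mutual_benefit_feasible("cpi", c(x1_X = 0.5, x1_Y = 2),
                                       1, 1)$feasible)
  res <- mutual_benefit_feasible("sc",
                                 c(x1N_X = 4 / 3, x1N_Y = 2 / 3,
                                   x1C_X = 2 / 3, x1C_Y = 4 / 3),
                                 eps_x = 1, eps_y = 1)
  expect_true(res$feasible)
  expect_equal(res$witness$eps_x_interval, c(2 / 3, 4 / 3))

  # infinitely fast exchange equalizes the pools: the intervals are empty
  equalized <- c(x1N_X = 1, x1N_Y = 1, x1C_X = 1, x1C_Y = 1)
  expect_false(mutual_benefit_feasible("sc", equalized, 1, 1)$feasible)
})

test_that("derivative analysis rejects unsuitable inputs", {
  lin <- network_parameters("basic", a1 = 1, b1 = 1)
  expect_error(derivative_signs(lin), "Hill")
  p <- network_parameters("basic", a1 = 1, b1 = 1,
                          fX = hill_activation(1, 1), fY = hill_activation(2, 1))
  expect_error(derivative_signs(p), "exceed 1")
})
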