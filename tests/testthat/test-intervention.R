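test_that("cost forms hit their endpoints and the printed midpoint", {
  for (form in c("exponential", "linear", "quadratic")) {
    expect_equal(intervention_cost(1, 1, form), 0)
    expect_equal(intervention_cost(0, 0, form), 1)
  }
  expect_equal(intervention_cost(0.5, 0.5),
               (exp(-1) - exp(-2)) / (1 - exp(-2)))
  # strictly decreasing in each entry
  g <- seq(0, 1, by = 0.1)
  for (form in c("exponential", "linear", "quadratic")) {
    expect_true(all(diff(intervention_cost(g, 0.4, form)) < 0))
    expect_true(all(diff(intervention_cost(0.4, g, form)) < 0))
  }
  expect_error(intervention_cost(1.2, 0), "\\[0, 1\\]")
})

test_that("a non-spreading threshold makes the whole square controllable", {
  m <- tl_model_poisson(20, 0.5)
  # theta = 1: m.omega > k can never hold, nothing ever spreads
  b <- controllable_boundary(m, theta = 1, rho0 = 0.17, grid_step = 0.25)
  expect_true(all(b$omega_inter == 1))
  res <- optimal_intervention(m, theta = 1, rho0 = 0.17, grid_step = 0.25)
  expect_equal(unname(res$omega_o), c(1, 1))
  expect_equal(res$cost, 0)
})

test_that("a zero threshold collapses the controllable region", {
  m <- tl_model_poisson(20, 0.5)
  b <- controllable_boundary(m, theta = 0, rho0 = 0.17, grid_step = 0.25,
                             tol = 1e-3)
  # only the fully suppressed corner survives: at omega_intra = 0 the
  # boundary bisects down to ~0, and any positive omega_intra percolates
  expect_lte(b$omega_inter[b$omega_intra == 0], 0.01)
  expect_true(all(is.na(b$omega_inter[b$omega_intra >= 0.25])))
})

test_that("the boundary is monotone and the optimum sits on it, contained", {
  m <- tl_model_poisson(20, 0.2)
  b <- controllable_boundary(m, theta = 0.1, rho0 = 0.17, grid_step = 0.05)
  ok <- !is.na(b$omega_inter)
  expect_monotone_increasing(rev(b$omega_inter[ok]), tol = 1e-4)
  res <- optimal_intervention(m, theta = 0.1, rho0 = 0.17, grid_step = 0.05)
  # re-verify containment at 10x tighter fixed-point tolerance
  expect_true(tl_contained(m, res$omega_o, theta = 0.1, rho0 = 0.17,
                           tol = 1e-11))
  expect_gte(res$cost, 0)
  expect_lte(res$cost, 1)
})

test_that("community strength steers the optimal regulation split", {
  # strong communities: intra reinforcement drives spreading, so the
  # optimum regulates intra harder (lower omega_intra); weak communities
  # shift the burden to the inter channel
  res_modular <- optimal_intervention(tl_model_poisson(20, 0.2),
                                      theta = 0.1, rho0 = 0.17,
                                      grid_step = 0.05)
  expect_lt(res_modular$omega_o["omega_intra"],
            res_modular$omega_o["omega_inter"])

  res_mixed <- optimal_intervention(tl_model_poisson(20, 0.8),
                                    theta = 0.1, rho0 = 0.17,
                                    grid_step = 0.05)
  expect_lt(res_mixed$omega_o["omega_inter"],
            res_mixed$omega_o["omega_intra"])
})

test_that("alternative cost forms keep moderate mixing the hardest to control", {
  for (form in c("linear", "quadratic")) {
    costs <- vapply(c(0.2, 0.5, 0.8), function(mu)
      optimal_intervention(tl_model_poisson(20, mu), theta = 0.1,
                           rho0 = 0.17, form = form,
                           grid_step = 0.05)$cost, numeric(1))
    expect_gt(costs[2], costs[1])
    expect_gt(costs[2], costs[3])
  }
})
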