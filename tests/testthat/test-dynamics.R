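test_that("threshold rules follow strict-inequality gating", {
  expect_identical(threshold_rule(c(0, 0), c(1, 1), 0.25, 4), 0L)
  expect_identical(threshold_rule(c(2, 0), c(1, 1), 0.25, 4), 1L) # 2 > 1
  expect_identical(threshold_rule(c(1, 0), c(1, 1), 0.25, 4), 0L) # tie: 1 > 1 fails
  expect_identical(threshold_rule(c(0, 0), c(1, 1), 0, 0), 0L)    # k = 0 never adopts

  expect_identical(constant_threshold_rule(c(2, 1), c(1, 1), 2), 1L)
  expect_identical(constant_threshold_rule(c(2, 1), c(1, 1), 3), 0L) # tie fails
  expect_identical(constant_threshold_rule(c(4, 0), c(0, 1), 0), 0L) # suppressed
})

test_that("equal regulation reduces to a total-count threshold rule", {
  cases <- expand.grid(m1 = 0:4, m2 = 0:4, w = c(0.3, 0.7, 1),
                       theta = c(0.1, 0.25, 0.5), k = c(4, 8))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_identical(
      threshold_rule(c(cs$m1, cs$m2), c(cs$w, cs$w), cs$theta, cs$k),
      threshold_rule(c(cs$m1 + cs$m2, 0), c(cs$w, cs$w), cs$theta, cs$k))
  }
})

test_that("hand-worked six-node cascades reproduce exactly", {
  net <- toy_two_triangles()
  cfg <- contagion_config(theta = 0.4, rho0 = 0)
  # theta = 0.4: node 2 adopts at step 1 (1 > 0.8), node 3 at step 2
  # (2 > 1.2), node 4 never (1 > 1.2 fails): cascade stays in module A
  tr <- run_cascade(net, c(1, 1), cfg, init = c(1, 0, 0, 0, 0, 0))
  expect_identical(tr$state, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(tr$rho_inf, 0.5)
  expect_identical(tr$steps, 2L)
  expect_equal(tr$rho, c(1, 2, 3) / 6)

  # theta = 0.3: the bridge transmits (1 > 0.9) and module B follows
  cfg2 <- contagion_config(theta = 0.3, rho0 = 0)
  tr2 <- run_cascade(net, c(1, 1), cfg2, init = c(1, 0, 0, 0, 0, 0))
  expect_identical(tr2$state, rep(1L, 6))
  expect_equal(tr2$rho_inf, 1)
})

test_that("seeding places the exact count inside the seed module", {
  set.seed(1)
  net <- build_modular_network(c(500, 500), poisson_dist(5), poisson_dist(2))
  x <- seed_initial(net, 0.1, 1)
  expect_identical(sum(x), 100L)
  expect_true(all(net$labels[x == 1L] == 1L))

  set.seed(4); a <- seed_initial(net, 0.07, 2)
  set.seed(4); b <- seed_initial(net, 0.07, 2)
  expect_identical(a, b)
  expect_error(seed_initial(net, 0.9, 1), "exceeds")
})

test_that("complete suppression freezes the cascade at its seeds", {
  set.seed(8)
  net <- build_modular_network(c(400, 400), poisson_dist(7.5), poisson_dist(7.5))
  set.seed(9)
  tr <- run_cascade(net, c(0, 0), contagion_config(theta = 0.25, rho0 = 0.1))
  expect_equal(tr$rho_inf, 0.1)
  expect_identical(tr$steps, 0L)
})

test_that("trajectories are monotone and rho_inf is bounded", {
  set.seed(12)
  net <- build_modular_network(c(400, 400), poisson_dist(7.5), poisson_dist(7.5))
  for (om in list(c(0.4, 0.4), c(0.7, 0.7), c(1, 1))) {
    set.seed(13)
    tr <- run_cascade(net, om, contagion_config(theta = 0.25, rho0 = 0.1))
    expect_monotone_increasing(tr$rho)
    expect_gte(tr$rho_inf, 0.1)
    expect_lte(tr$rho_inf, 1)
    expect_true(tr$converged)
  }
})

test_that("rho_inf is non-decreasing in the regulation entries", {
  set.seed(21)
  net <- build_modular_network(c(1000, 1000), poisson_dist(7.5), poisson_dist(7.5))
  set.seed(22)
  init <- seed_initial(net, 0.1, 1)
  cfg <- contagion_config(theta = 0.25, rho0 = 0.1)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  # sweep the diagonal and each entry separately on the same network + seeds
  diag_r <- vapply(grid, function(w)
    run_cascade(net, c(w, w), cfg, init = init)$rho_inf, numeric(1))
  expect_monotone_increasing(diag_r)
  intra_r <- vapply(grid, function(w)
    run_cascade(net, c(w, 1), cfg, init = init)$rho_inf, numeric(1))
  expect_monotone_increasing(intra_r)
  inter_r <- vapply(grid, function(w)
    run_cascade(net, c(1, w), cfg, init = init)$rho_inf, numeric(1))
  expect_monotone_increasing(inter_r)
})

test_that("constant-rule cascades run and respect suppression", {
  set.seed(30)
  net <- build_modular_network(c(300, 300), poisson_dist(6), poisson_dist(2))
  cfg <- contagion_config(rule = "constant", C = 1, rho0 = 0.1)
  set.seed(31)
  tr <- run_cascade(net, c(1, 1), cfg)
  expect_gt(tr$rho_inf, 0.9) # C = 1: two adopted neighbors anywhere suffice
  set.seed(31)
  tr0 <- run_cascade(net, c(0, 0), cfg)
  expect_equal(tr0$rho_inf, 0.1)
})

test_that("ensemble statistics are reproducible and exact under suppression", {
  cfg <- contagion_config(theta = 0.25, rho0 = 0.1)
  ens <- suppressMessages(
    ensemble_rho_inf(c(200, 200), poisson_dist(6), poisson_dist(2),
                     c(0, 0), cfg, n_realizations = 3, seed = 5))
  expect_equal(ens$mean, 0.1)
  expect_equal(ens$sd, 0)
  ens2 <- suppressMessages(
    ensemble_rho_inf(c(200, 200), poisson_dist(6), poisson_dist(2),
                     c(0, 0), cfg, n_realizations = 3, seed = 5))
  expect_identical(ens$rho_inf, ens2$rho_inf)
})
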