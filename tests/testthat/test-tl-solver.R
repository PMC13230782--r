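test_that("complete suppression pins the fixed point at the seed level", {
  m <- study_model(0.5)
  fp <- tl_fixed_point(m, c(0, 0), theta = 0.25, rho0 = 0.1)
  expect_equal(fp$y_inf, c(0.2, 0))
  expect_equal(fp$rho_inf, c(0.2, 0))
  expect_equal(fp$rho_inf_global, 0.1)
  # single update already returns rho0 for any y
  expect_equal(tl_update_two(c(0.7, 0.4), m, c(0, 0), theta = 0.25,
                             rho0 = c(0.2, 0)),
               c(0.2, 0))
})

test_that("the all-adopted corner matches its closed form", {
  m <- study_model(0.5)
  y <- tl_update_two(c(1, 1), m, c(1, 1), theta = 0.25, rho0 = c(0.2, 0))
  # with every neighbor adopted, a degree-k node sees m = k - 1 in the
  # cavity and adopts iff k - 1 > 0.25 k, i.e. k >= 2; only total degree 1
  # fails, and it carries link weight 1/z
  p1 <- m$dists[[1]][[1]]; p2 <- m$dists[[1]][[2]]
  p_tot1 <- p1$pmf[p1$support == 1] * p2$pmf[p2$support == 0] +
    p1$pmf[p1$support == 0] * p2$pmf[p2$support == 1]
  z <- p1$mean + p2$mean
  expect_equal(y[1], 0.2 + 0.8 * (1 - p_tot1 / z), tolerance = 1e-12)
})

test_that("the update is monotone in y and iterates are non-decreasing", {
  m <- study_model(0.5)
  lo <- tl_update_two(c(0.2, 0.2), m, c(0.8, 0.8), theta = 0.25, rho0 = c(0.2, 0))
  hi <- tl_update_two(c(0.3, 0.3), m, c(0.8, 0.8), theta = 0.25, rho0 = c(0.2, 0))
  expect_true(all(hi >= lo))

  y <- c(0.2, 0)
  path <- y
  for (l in 1:40) {
    y <- tl_update_two(y, m, c(1, 1), theta = 0.25, rho0 = c(0.2, 0))
    path <- rbind(path, y)
  }
  expect_monotone_increasing(path[, 1])
  expect_monotone_increasing(path[, 2])
  expect_true(all(path <= 1))
})

test_that("compiled two-community path equals the literal reference sums", {
  m <- small_tl_model()
  set.seed(42)
  for (i in 1:6) {
    y <- runif(2)
    om <- regulation_matrix(runif(1), runif(1))
    th <- runif(1, 0.05, 0.6)
    for (cav in c("full", "decremented")) {
      fast <- tl_update_two(y, m, om, theta = th, rho0 = c(0.2, 0),
                            cavity_threshold = cav)
      ref <- tl_update_general(y, m, om, theta = th, rho0 = c(0.2, 0),
                               cavity_threshold = cav)
      expect_equal(fast, as.numeric(ref), tolerance = 1e-12)
    }
    # constant rule too
    fastc <- tl_update_two(y, m, om, rho0 = c(0.2, 0), rule = "constant", C = 1.5)
    refc <- tl_update_general(y, m, om, rho0 = c(0.2, 0), rule = "constant", C = 1.5)
    expect_equal(fastc, as.numeric(refc), tolerance = 1e-12)
  }
  # full fixed points agree between engines as well
  fp_two <- tl_fixed_point(m, c(0.9, 0.7), theta = 0.2, rho0 = 0.1, engine = "two")
  fp_gen <- tl_fixed_point(m, c(0.9, 0.7), theta = 0.2, rho0 = 0.1, engine = "general")
  expect_equal(fp_two$y_inf, fp_gen$y_inf, tolerance = 1e-9)
  expect_equal(fp_two$rho_inf, fp_gen$rho_inf, tolerance = 1e-9)
})

test_that("three-community models respect symmetry and suppression", {
  d_in <- poisson_dist(2.5, 1e-8)
  d_out <- poisson_dist(1, 1e-8)
  m3 <- tl_model(d_in, d_out, n = 3)
  rho0 <- seed_fractions(0.1, 3)
  expect_equal(rho0, c(0.3, 0, 0))

  y0 <- tl_update_general(rho0, m3, regulation_matrix(0, 0, 3),
                          theta = 0.25, rho0 = rho0)
  expect_equal(as.numeric(y0), rho0)

  y1 <- tl_update_general(rho0, m3, regulation_matrix(1, 1, 3),
                          theta = 0.2, rho0 = rho0)
  expect_equal(y1[2], y1[3], tolerance = 1e-12) # unseeded modules identical
  fp3 <- tl_fixed_point(m3, regulation_matrix(1, 1, 3), theta = 0.2, rho0 = 0.1)
  expect_equal(fp3$rho_inf[2], fp3$rho_inf[3], tolerance = 1e-10)
})

test_that("constant and proportional rules match when they gate identically", {
  # regular degrees 6 + 4: every node has k = 10, so theta = 0.25 demands
  # m > 2.5 and C = 2.25 demands m > 2.25 -- the same integer gate (m >= 3)
  m <- tl_model(regular_dist(6), regular_dist(4))
  fp_prop <- tl_fixed_point(m, c(0.9, 0.9), theta = 0.25, rho0 = 0.1)
  fp_const <- tl_fixed_point(m, c(0.9, 0.9), rho0 = 0.1,
                             rule = "constant", C = 2.25)
  expect_equal(fp_prop$y_inf, fp_const$y_inf, tolerance = 1e-12)
  expect_equal(fp_prop$rho_inf_global, fp_const$rho_inf_global, tolerance = 1e-12)
})

test_that("fixed-point densities are monotone in omega, rho0 and theta", {
  m <- study_model(0.5)
  r_omega <- vapply(c(0.3, 0.55, 0.8, 1), function(w)
    tl_fixed_point(m, c(w, w), theta = 0.25, rho0 = 0.1)$rho_inf_global,
    numeric(1))
  expect_monotone_increasing(r_omega)

  r_rho0 <- vapply(c(0.05, 0.1, 0.2, 0.3), function(r)
    tl_fixed_point(m, c(0.6, 0.6), theta = 0.25, rho0 = r)$rho_inf_global,
    numeric(1))
  expect_monotone_increasing(r_rho0)

  r_theta <- vapply(c(0.1, 0.2, 0.3, 0.45), function(th)
    tl_fixed_point(m, c(1, 1), theta = th, rho0 = 0.1)$rho_inf_global,
    numeric(1))
  expect_monotone_increasing(rev(r_theta)) # non-increasing in theta
})

test_that("containment indicator agrees with the full solve", {
  m <- study_model(0.5)
  for (om in list(c(0.3, 0.3), c(0.5, 1), c(1, 1), c(0.9, 0.2))) {
    full <- tl_fixed_point(m, om, theta = 0.25, rho0 = 0.1)
    expect_identical(tl_contained(m, om, theta = 0.25, rho0 = 0.1),
                     full$rho_inf_global <= 0.1 + 0.1)
  }
})
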