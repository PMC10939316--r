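test_that("generated forces respect the bias, scale and geometry contract", {
  # fully biased, purely radial
  p <- model_params(rho = 1, alpha = 1, theta_max = 0,
                    step_force_jitter = 0)
  set.seed(1)
  f <- sample_generated_force(p, 10)
  expect_equal(unname(f[, "fx"]), rep(0, 10))
  expect_equal(unname(f[, "fy"]), rep(1, 10))

  # sign and scale forced the other way
  p2 <- model_params(rho = 0, alpha = 2, theta_max = 0,
                     step_force_jitter = 0)
  set.seed(1)
  f2 <- sample_generated_force(p2, 10)
  expect_equal(unname(f2[, "fy"]), rep(-2, 10))

  # magnitude law |F| = alpha * u, u ~ U(1 - j, 1 + j)
  p3 <- model_params(rho = 0.5, alpha = 3, theta_max = 60,
                     step_force_jitter = 0.2)
  set.seed(2)
  f3 <- sample_generated_force(p3, 5000)
  mag <- sqrt(rowSums(f3^2))
  expect_true(all(mag >= 3 * 0.8 - 1e-12 & mag <= 3 * 1.2 + 1e-12))
  expect_equal(mean(mag), 3, tolerance = 0.01)
})

test_that("empirical pial-ward fraction converges to rho (binomial 3 sigma)", {
  n <- 1e5
  for (rho in c(0.5, 0.51, 0.65, 1.0)) {
    p <- model_params(rho = rho, alpha = 1)
    frac <- pial_ward_fraction(p, n = n, seed = 123)
    tol <- 3 * sqrt(rho * (1 - rho) / n)
    expect_true(abs(frac - rho) <= max(tol, 1e-12),
                label = sprintf("rho = %g realised %g", rho, frac))
  }
})

test_that("step_cell stalls below threshold and stores the spring force", {
  p <- model_params(rho = 1, alpha = 0.5, theta_max = 0,
                    step_force_jitter = 0, k_spring = 0.8)
  fld <- resistance_field(100, magnitudes = 1)   # R * v_ref = 1 > 0.5
  st <- cell_state(c(10, 50))
  st2 <- step_cell(st, p, fld)
  expect_equal(st2$position, st$position)
  expect_equal(st2$spring_force, c(0, 0.8 * 0.5))
})

test_that("stalled-step count matches the scalar accumulation oracle", {
  fld <- resistance_field(100, magnitudes = 1)
  for (f in c(0.13, 0.26, 0.34, 0.49, 0.71)) {
    p <- model_params(rho = 1, alpha = f, theta_max = 0,
                      step_force_jitter = 0, k_spring = 1)
    expected <- naive_first_move_step(f, threshold = 1)
    st <- cell_state(c(0, 10))
    moved_at <- NA
    for (s in 1:50) {
      st <- step_cell(st, p, fld)
      if (st$position[2] != 10) { moved_at <- s; break }
    }
    expect_equal(moved_at, expected, label = sprintf("f = %g", f))
    # spec closed form: first move at ceiling(threshold / f) when
    # threshold / f is not integer
    expect_equal(expected, ceiling(1 / f))
    # spring resets after the move
    expect_equal(st$spring_force, c(0, 0))
  }
})

test_that("strong pial-ward forcing gives monotone ascent until reflection", {
  p <- model_params(rho = 1, alpha = 10, theta_max = 0,
                    step_force_jitter = 0)
  fld <- resistance_field(1e5, magnitudes = 0.05)
  st <- cell_state(c(0, 0))
  ys <- numeric(20)
  for (s in 1:20) { st <- step_cell(st, p, fld); ys[s] <- st$position[2] }
  expect_true(all(diff(c(0, ys)) > 0))
})

test_that("effective parameters interpolate linearly between anchors", {
  pc <- control_params()
  pk <- ko_params()
  expect_equal(effective_parameters(1, pc, pk)$rho, pc$rho)
  expect_equal(effective_parameters(1, pc, pk)$alpha, pc$alpha)
  expect_equal(effective_parameters(0, pc, pk)$rho, pk$rho)
  expect_equal(effective_parameters(0, pc, pk)$alpha, pk$alpha)
  mid <- effective_parameters(0.5, model_params(0.65, 1),
                              model_params(0.51, 1))
  expect_equal(mid$rho, 0.58)
  expect_error(effective_parameters(1.2, pc, pk), "beta")
})

test_that("simulation is deterministic, bounded and strictly time-ordered", {
  sp <- population_spec(20, 5, control_params(), ko_params(),
                        control_field())
  s1 <- simulate_population(sp, 50, seed = 11)
  s2 <- simulate_population(sp, 50, seed = 11)
  expect_identical(s1$trajectories, s2$trajectories)
  tr <- s1$trajectories
  expect_true(all(tr$y_um >= 0 & tr$y_um <= 300))
  expect_equal(sort(unique(tr$t_min)), (0:50) * 15)
  expect_equal(sum(tr$cell_class == "mutant"), 5 * 51)
  expect_error(simulate_population(sp, 0, seed = 1), "n_steps")
})

test_that("increasing alpha never decreases mean net radial displacement", {
  fld <- ko_field(height = 1e4)   # uniform, tall enough to avoid reflection
  net_y <- vapply(c(1.2, 1.6, 2.0, 2.6), function(a) {
    p <- model_params(0.65, a, k_spring = 0.65, step_force_jitter = 0.05)
    sp <- population_spec(60, 0, p, p, fld)
    sim <- simulate_population(sp, 120, seed = 99)
    tr <- sim$trajectories
    y0 <- tr$y_um[tr$t_min == 0]
    y1 <- tr$y_um[tr$t_min == max(tr$t_min)]
    mean(y1 - y0)
  }, 0)
  expect_true(all(diff(net_y) >= 0))
})

test_that("mixed-model coupling limits reproduce the pure populations", {
  # n_mutant -> 0: mutant parameters equal control parameters
  sp <- population_spec(999, 1, control_params(), ko_params(),
                        control_field())
  pe <- effective_parameters(999 / 1000, control_params(), ko_params())
  expect_equal(pe$rho, control_params()$rho, tolerance = 1e-3)
  expect_equal(pe$alpha, control_params()$alpha, tolerance = 1e-2)
  # n_control = 0: exactly the knockout parameters
  pe0 <- effective_parameters(0, control_params(), ko_params())
  expect_identical(pe0$rho, ko_params()$rho)
  expect_identical(pe0$alpha, ko_params()$alpha)
})
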