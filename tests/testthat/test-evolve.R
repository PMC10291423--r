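test_that("the selection gradient points toward the equilibrium share", {
  pp <- unit_params()
  expect_identical(selection_gradient(pp, 0.5), 0)
  expect_equal(selection_gradient(pp, 0.25), 0.25)
  expect_equal(selection_gradient(pp, 0.75), -0.25)
  cgrid <- seq(0.005, 0.995, length.out = 99)
  g <- selection_gradient(pp, cgrid)
  expect_true(all(g[cgrid < 0.5] > 0))
  expect_true(all(g[cgrid > 0.5] < 0))
  # gradient scales with 1 / (wbar p)
  expect_equal(selection_gradient(skew_params(2, 1), 0.25),
               selection_gradient(pp, 0.25) / 2)
})

test_that("adaptive dynamics converge monotonically to the equilibrium share", {
  pp <- unit_params()
  fixed <- adaptive_dynamics(pp, c0 = 0.5, steps = 100)
  expect_true(all(fixed$c == 0.5))

  up <- adaptive_dynamics(pp, c0 = 0.1, step = 0.1, steps = 2000)
  expect_equal(nrow(up), 2001)
  expect_lt(abs(tail(up$c, 1) - 0.5), 1e-4)
  expect_true(all(diff(up$c) >= 0))
  # closed-form flow: 1/2 + (c0 - 1/2) exp(-t / (wbar p))
  expect_equal(up$c, 0.5 - 0.4 * exp(-up$time), tolerance = 5e-3)

  down <- adaptive_dynamics(pp, c0 = 0.9, step = 0.1, steps = 2000)
  expect_lt(abs(tail(down$c, 1) - 0.5), 1e-4)
  expect_true(all(diff(down$c) <= 0))

  expect_error(adaptive_dynamics(pp, 0.5, step = 0), "step")
})

test_that("the simulation configuration is validated and seeds are mandatory", {
  expect_error(sim_config(population_size = 100, generations = 10), "seed")
  expect_error(sim_config(population_size = 1, seed = 1), "population_size")
  expect_s3_class(sim_config(seed = 1), "skew_sim_config")
  expect_error(simulate_evolution(unit_params(), list(seed = 1)), "sim_config")
})

test_that("the Wright-Fisher run is reproducible and respects trait bounds", {
  pp <- unit_params()
  cfg <- sim_config(population_size = 120, generations = 60, seed = 99)
  t1 <- simulate_evolution(pp, cfg)
  t2 <- simulate_evolution(pp, cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 61) # includes generation 0
  expect_true(all(t1$mean_c >= 0 & t1$mean_c <= 1))
  expect_true(all(t1$gini >= 0 & t1$gini <= 1))
  expect_true(all(is.na(t1$mean_a)))

  t3 <- simulate_evolution(pp, sim_config(population_size = 120,
                                          generations = 60, seed = 100))
  expect_false(identical(t1$mean_c, t3$mean_c))
})

test_that("without mutation a monomorphic population stays put", {
  cfg <- sim_config(population_size = 50, generations = 30,
                    mutation_rate = 0, mutation_sd = 1e-9,
                    initial_c_mean = 0.5, initial_c_sd = 0, seed = 4)
  traj <- simulate_evolution(unit_params(), cfg)
  expect_true(all(traj$mean_c == 0.5))
  expect_true(all(traj$sd_c == 0))
})

test_that("selection drives the paternity share toward the analytic attractor", {
  # long horizon so the mutation-selection dynamics reach their stationary band
  pp <- unit_params()
  finals <- vapply(1:5, function(s) {
    traj <- simulate_evolution(pp, sim_config(population_size = 200,
                                              generations = 1200, seed = s))
    glance(traj)$longrun_mean_c
  }, numeric(1))
  expect_true(all(abs(finals - 0.5) < 0.05))
})

test_that("the coevolving feeding reaction norm recovers its best-response slope", {
  pp <- unit_params()
  traj <- simulate_evolution(pp, sim_config(population_size = 300,
                                            generations = 300,
                                            coevolve_beta = TRUE, seed = 2))
  expect_false(any(is.na(traj$mean_a)))
  expect_lt(abs(tail(traj$mean_a, 1) - 0.5), 0.1)
  expect_equal(glance(traj)$a_target, 0.5)
})

test_that("trajectories round-trip through the delimited export", {
  traj <- simulate_evolution(unit_params(),
                             sim_config(population_size = 60,
                                        generations = 20, seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("generation", "mean_c", "sd_c", "mean_a",
                 "mean_alpha_fitness", "mean_beta_fitness", "gini"))
  expect_equal(back$mean_c, traj$mean_c, tolerance = 1e-12)
})
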