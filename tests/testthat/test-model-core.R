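test_that("parameter validation enforces the model's domain", {
  expect_s3_class(skew_params(1, 1), "skew_params")
  expect_true(skew_params(1, 1)$interior)
  expect_false(skew_params(0.3, 1)$interior)
  expect_error(skew_params(0, 1), "wbar")
  expect_error(skew_params(1, 0), "p")
  expect_error(skew_params(1, 2), "probability")
  expect_error(skew_params(1, 1, z = -0.1), "z")
  expect_error(skew_params(1, 1, Z = -1), "Z")
  expect_error(mortality_hazard(skew_params(1, 1), 1.5), "\\[0, 1\\]")
  expect_error(beta_period_fitness(skew_params(1, 1), c = -0.1, f = 0.5), "\\[0, 1\\]")
})

test_that("fitness primitives match their closed forms", {
  pp <- unit_params()
  expect_identical(mortality_hazard(pp, 0), 0)
  expect_equal(mortality_hazard(pp, 0.25), 0.0625)
  expect_equal(mortality_hazard(skew_params(1, 0.5), 1), 0.5)

  expect_equal(beta_period_fitness(pp, c = 0.5, f = 0.25), 0.0625)
  expect_identical(beta_period_fitness(pp, c = 0.7, f = 0), 0)
  expect_equal(beta_period_fitness(pp, c = 1, f = 0.5), 0.25)

  expect_equal(beta_lifetime_fitness(pp, c = 0.5, f = 0.25), 1.0625)
  expect_equal(beta_lifetime_fitness(skew_params(2, 0.5), c = 0, f = 0), 2)
  expect_equal(beta_lifetime_fitness(pp, c = 1, f = 1), 1)
})

test_that("best responses maximize fitness and clamp at the feasible maximum", {
  pp <- unit_params()
  expect_equal(as.numeric(beta_best_response(pp, 0.5)), 0.25)
  expect_identical(as.numeric(beta_best_response(pp, 0)), 0)
  br <- beta_best_response(skew_params(0.5, 1), 1)
  expect_equal(as.numeric(br), 1)
  expect_false(attr(br, "clamped")) # optimum exactly at the boundary
  br2 <- beta_best_response(skew_params(0.25, 1), 1)
  expect_equal(as.numeric(br2), 1)
  expect_true(attr(br2, "clamped"))

  expect_equal(alpha_beta_brood_fitness(pp, 0.5), 0.125)
  expect_identical(alpha_beta_brood_fitness(pp, 1), 0)
  expect_equal(alpha_beta_brood_fitness(pp, 0.6), 0.12)

  own <- alpha_own_brood_optimum(pp)
  expect_equal(c(own$F_star, own$W_alpha), c(0.5, 0.25))
  own2 <- alpha_own_brood_optimum(skew_params(2, 0.25))
  expect_equal(c(own2$F_star, own2$W_alpha), c(1, 0.5))
  own3 <- alpha_own_brood_optimum(skew_params(4, 0.25))
  expect_equal(c(own3$F_star, own3$W_alpha), c(0.5, 0.25))
})

test_that("best response beats every grid alternative and satisfies the FOC", {
  set.seed(42)
  fgrid <- seq(0, 1, length.out = 1000)
  for (i in 1:200) {
    pp <- skew_params(wbar = runif(1, 0.2, 4), p = runif(1, 0.05, 1))
    cc <- runif(1)
    fstar <- as.numeric(beta_best_response(pp, cc))
    expect_gte(
      beta_period_fitness(pp, cc, fstar),
      max(beta_period_fitness(pp, cc, fgrid)) - 1e-9
    )
    if (!attr(beta_best_response(pp, cc), "clamped")) {
      # interior first-order condition: c - 2 * wbar * p * f = 0
      expect_lt(abs(cc - 2 * pp$wbar * pp$p * fstar), 1e-9)
    }
  }
})

test_that("lifetime fitness is period fitness plus the future stock", {
  set.seed(7)
  for (i in 1:50) {
    pp <- skew_params(runif(1, 0.2, 4), runif(1, 0.05, 1))
    cc <- runif(1); ff <- runif(1)
    expect_equal(
      beta_lifetime_fitness(pp, cc, ff),
      beta_period_fitness(pp, cc, ff) + pp$wbar
    )
  }
})

test_that("the unconstrained equilibrium reproduces the closed forms", {
  eq <- unconstrained_equilibrium(unit_params())
  expect_equal(eq$c_star, 0.5)
  expect_equal(eq$f_star, 0.25)
  expect_equal(eq$F_star, 0.5)
  expect_equal(eq$fitness$w, 1 / 16)
  expect_equal(eq$fitness$W_beta, 1 / 8)
  expect_equal(eq$fitness$W_alpha, 1 / 4)
  expect_equal(eq$fitness$W_total, 3 / 8)
  expect_equal(eq$fitness$W_beta / eq$fitness$w, 2)
  expect_equal(eq$regime, "incentive_binding")
  expect_false(eq$boundary_clamped)

  row <- tidy(eq)
  expect_equal(row$W_total, row$W_beta + row$W_alpha)
  expect_equal(row$joint, row$w + row$W_total)

  g <- glance(eq)
  expect_equal(g$joint_max, 0.5)
  expect_equal(g$efficiency_gap, 0.5 - 0.4375)
})

test_that("everything depends on wbar and p only through their product", {
  eqs <- purrr::map(scale_triplet(), unconstrained_equilibrium)
  ref <- tidy(eqs[[1]])[c("c_star", "f_star", "F_star", "w", "W_beta",
                          "W_alpha", "W_total", "joint", "gini")]
  for (eq in eqs[-1]) {
    expect_equal(tidy(eq)[names(ref)], ref)
  }
  for (pp in scale_triplet()) {
    expect_equal(joint_total_fitness(pp, c(0, 0.5, 1)), c(0.25, 0.4375, 0.5))
  }
})

test_that("a boundary-clamped parameter set is solved numerically and flagged", {
  pp <- skew_params(0.2, 0.5) # wbar * p = 0.1 < 1/2
  eq <- unconstrained_equilibrium(pp)
  expect_true(eq$boundary_clamped)
  # dominant's payoff peaks at the clamp kink c = 2 * wbar * p
  expect_equal(eq$c_star, 0.2, tolerance = 1e-6)
  expect_equal(eq$f_star, 1)
  cgrid <- seq(0, 1, length.out = 2001)
  expect_gte(alpha_beta_brood_fitness(pp, eq$c_star),
             max(alpha_beta_brood_fitness(pp, cgrid)) - 1e-8)
})

test_that("joint total fitness is non-decreasing in the paternity share", {
  set.seed(11)
  cgrid <- seq(0, 1, length.out = 101)
  pars <- c(random_interior_params(5),
            list(skew_params(0.3, 1), skew_params(0.2, 0.4)))
  for (pp in pars) {
    expect_true(all(diff(joint_total_fitness(pp, cgrid)) >= -1e-12))
  }
  expect_equal(joint_total_fitness(unit_params(), 0.5), 0.4375)
})
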