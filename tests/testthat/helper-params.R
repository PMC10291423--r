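# Canonical interior parameter set (wbar * p = 1): all of the model's
# closed forms take their simplest values here.
unit_params <- function(z = 0, Z = 0) skew_params(wbar = 1, p = 1, z = z, Z = Z)

# Parameter sets sharing wbar * p = 1 for scale-property checks.
scale_triplet <- function() {
  list(skew_params(1, 1), skew_params(2, 0.5), skew_params(4, 0.25))
}

# Random interior parameter sets (closed forms valid, p <= 1).
random_interior_params <- function(n) {
  wp <- runif(n, 0.5, 4)
  wbar <- wp + runif(n, 0, 4)
  purrr::map2(wbar, wp / wbar, skew_params)
}

equilibrium_profile <- function(params) {
  eq <- unconstrained_equilibrium(params)
  list(c = eq$c_star, f = eq$f_star, F = eq$F_star)
}
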