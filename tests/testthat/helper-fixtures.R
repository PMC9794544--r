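# Shared fixtures, built in code at test time.

# Sinusoidal grating whose stripes run ALONG `angle_deg` from the x-axis
# (x = columns, y = rows): the phase varies perpendicular to the stripes.
make_grating <- function(n = 128, angle_deg = 30, period = 10,
                         mean = 127.5, amp = 127) {
  a <- angle_deg * pi / 180
  outer(seq_len(n), seq_len(n), function(r, cl)
    mean + amp * sin(2 * pi / period * (-cl * sin(a) + r * cos(a))))
}

# Small, fast stack configuration for structural tests where recovery
# accuracy is not at stake.
small_stack <- function(...) {
  args <- list(width = 160L, height = 160L, n_planes = 3L, n_fibers = 60L,
               fiber_length_range = c(25, 45), noise_sigma = 0)
  do.call(stack_config, utils::modifyList(args, list(...)))
}

# Hand-built orientation field with a single orientation everywhere.
uniform_field <- function(angle, n = 32) {
  structure(list(orientation = matrix(angle, n, n),
                 energy = matrix(1, n, n),
                 coherency = matrix(1, n, n), window_sigma = 2),
            class = "orientation_field")
}

# Temporal laws + params under which all three coefficients equal 1:
# constant spread, constant density matching rho0 with C1 = 1, and a
# maturation clock far past saturation.
identity_model <- function() {
  list(laws = temporal_laws(c(0.5, 0), c(30, 0)),
       params = model_params(K1 = 23.87, C1 = 1, t_prime = 7, K2 = 1000,
                             rho0 = 30))
}
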