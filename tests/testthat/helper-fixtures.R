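# Shared fixtures, built once per test run and memoized.
# Everything is generated in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# small 2D phantom mesh (~465 nodes) for FD oracles and quick solves
small_mesh <- function() memo("small_mesh", {
  build_phantom(head_phantom_spec(), 2 * pi * 0.09 / 40)
})

small_fm <- function() memo("small_fm", forward_model(small_mesh()))

# tiny 8-electrode disk (~200 nodes) for dense-oracle equivalence tests
tiny_spec <- function() head_phantom_spec(n_electrodes = 8L,
                                          hemorrhage_diameters = c(0.02, 0.03))
tiny_mesh <- function() memo("tiny_mesh", build_phantom(tiny_spec(), "coarse"))
tiny_fm <- function() memo("tiny_fm", forward_model(tiny_mesh()))

# reconstruction setup of the scaled-down study: fine simulation mesh,
# medium potential mesh, coarse conductivity mesh
study_setup <- function() memo("study_setup", {
  spec <- head_phantom_spec()
  sim <- build_phantom(spec, "fine")
  pot <- build_phantom(spec, "medium")
  cond <- build_phantom(spec, "coarse")
  fm_sim <- forward_model(sim)
  fm <- forward_model(pot, conductivity_mesh = cond)
  ref <- make_reference(cond)
  V0 <- forward_solve(fm_sim, assign_conductivity(sim, state = "healthy"))$V
  list(spec = spec, sim = sim, fm_sim = fm_sim, fm = fm, ref = ref,
       noise_std = 6.7e-4 * max(abs(V0)))
})

study_frame <- function(state, seed, label = "t") {
  s <- study_setup()
  key <- paste0("frame_", paste(state, collapse = ""), "_", seed)
  memo(key, simulate_frame(s$fm_sim, assign_conductivity(s$sim, state = state),
                           noise_std = s$noise_std, seed = seed, label = label))
}

# scaled-down replication grids (shared by the acceptance criteria)
acceptance_grid4 <- function() memo("acceptance_grid4", {
  suppressWarnings(run_experiment(
    states = c(0, 0.010, 0.020, 0.030), locations = "cortical",
    algorithms = c("tv", "ld", "mo"), seed = 1))
})

acceptance_grid6 <- function() memo("acceptance_grid6", {
  suppressWarnings(run_experiment(
    states = c(0, seq(0.010, 0.030, 0.005)), locations = "cortical",
    algorithms = "mo", seed = 1, store_fields = TRUE))
})

expect_rel <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)) /
                        max(abs(expected), 1e-300), tol)
}
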