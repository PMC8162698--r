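# Shared fixtures. Expensive scenario builds/solves are memoized so that
# several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

calibrated_globals <- function(...) {
  g <- global_params(...)
  g$alpha <- calibrate_alpha(g, default_gene("MLH1"))
  g
}

lynch_sm <- function() cached("lynch_sm", build_system_matrix(preset("lynch-mlh1")))
lynch_traj <- function() cached("lynch_traj", solve_trajectory(lynch_sm()))

# Lynch with all fitness terms zeroed (mass-conserving generator)
lynch_b0_sm <- function() cached("lynch_b0_sm", {
  cfg <- preset("lynch-mlh1")
  cfg$genes <- lapply(cfg$genes, function(gn) { gn$b_altered <- 0; gn })
  build_system_matrix(cfg)
})

# Lynch with every dependency component switched off (independent mutations)
lynch_indep_sm <- function() cached("lynch_indep_sm", {
  cfg <- preset("lynch-mlh1")
  cfg$active <- character(0)
  build_system_matrix(cfg)
})
lynch_indep_traj <- function() cached("lynch_indep_traj",
                                      solve_trajectory(lynch_indep_sm()))

fap_traj <- function() cached("fap_traj",
                              solve_trajectory(build_system_matrix(preset("fap"))))

# 2-gene model small enough for dense inspection but with all five component
# types representable (MMR + APC analogues are needed for B/D; this one is
# for generic solver checks only).
toy_two_state <- function(r = 0.3, N = 100) {
  M <- matrix(c(-r, r, 0, 0), 2, 2, byrow = TRUE)
  list(M = M, x0 = c(N, 0), r = r, N = N)
}
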