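# Shared fixtures: cohort runs are deterministic given the seed, so the
# expensive developmental experiments are computed once per test session and
# reused across test files.

.msidev_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.msidev_cache[[key]])) .msidev_cache[[key]] <- force(expr)
  .msidev_cache[[key]]
}

td_development <- function(seed = 1L) {
  cached(paste0("dev_td_", seed),
         train_network(network_params("td_child"),
                       training_schedule(seed = seed)))
}

cohort_trajectory <- function(name, seed = 1L) {
  cached(paste0("traj_", name, "_", seed), run_cohort(name, seed = seed))
}

traj_cells_of <- function(traj, age) {
  x <- traj$median_rt_ms[traj$age_group == age]
  names(x) <- traj$condition[traj$age_group == age]
  x[trial_conditions]
}

battery_rts <- function(params, ...) {
  b <- rt_battery(params, ...)
  stats::setNames(b$rt_ms, b$condition)
}

# minimal trace object for readout tests with analytic output time courses
synthetic_trace <- function(t, z_m, dt = t[2] - t[1], z_max = 1) {
  n <- length(t)
  df <- data.frame(t_ms = t, z_a = 0, z_v = 0, z_m = z_m,
                   z_Ia = 0, z_Iv = 0, q_a = 0, q_v = 0)
  structure(df, class = c("msidev_trace", "data.frame"),
            dt = dt, z_max = z_max)
}
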