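test_that("activation is a bounded monotone logistic with the exact closed form", {
  p <- network_params(act_slope = 0.3, act_center = 20, z_max = 1)
  expect_equal(activation(20, p), 0.5)            # midpoint
  expect_equal(activation(30, p), 1 / (1 + exp(-3)))  # closed-form oracle
  expect_lt(activation(-1e3, p), 1e-10)
  u <- seq(-50, 80, by = 0.5)
  z <- activation(u, p)
  expect_true(all(diff(z) >= 0))
  expect_true(all(z > 0 & z < 1))
  p2 <- network_params(z_max = 1)
  expect_equal(activation(p2$act_center, p2), 0.5 * p2$z_max)
})

test_that("a single Euler step honours the identity and fixed-point contracts", {
  p <- network_params("td_child")
  s <- rest_state(p)
  expect_identical(step_state(s, params = p, dt = 0), s)

  # all weights zero: u = 0 is the leak equilibrium and stays fixed
  p0 <- network_params(w_ma = 0, w_mv = 0, w_av = 0, w_va = 0, w_Ia = 0,
                       w_Iv = 0, l_av = 0, l_va = 0, l_a = 0, l_v = 0)
  s0 <- network_state()
  s1 <- step_state(s0, params = p0, dt = 1)
  expect_equal(s1$u, s0$u, tolerance = 1e-12)

  bad <- s
  bad$u[1] <- NaN
  expect_error(step_state(bad, params = p), "non-finite")
})

test_that("an isolated unit relaxes along the closed-form exponential", {
  # weights all zero: du/dt = (i0*ext - u)/tau, so u(t) = i0*(1 - exp(-t/tau))
  p <- network_params(w_ma = 0, w_mv = 0, w_av = 0, w_va = 0, w_Ia = 0,
                      w_Iv = 0, l_av = 0, l_va = 0, l_a = 0, l_v = 0,
                      i0_a = 10)
  dt <- 0.05
  s <- network_state()
  for (i in seq_len(round(60 / dt)))
    s <- step_state(s, ext = c(a = 1, v = 0), params = p, dt = dt)
  expect_equal(s$u[["a"]], 10 * (1 - exp(-60 / p$tau_fast)), tolerance = 1e-3)
  # convergence to u* = i0
  for (i in seq_len(round(600 / dt)))
    s <- step_state(s, ext = c(a = 1, v = 0), params = p, dt = dt)
  expect_equal(s$u[["a"]], 10, tolerance = 1e-6)
})

test_that("the compiled integrator matches the reference R step exactly", {
  p <- network_params("td_child", w_av = -7, w_va = -12, l_a = 3, l_v = 5)
  ev <- stim_events("AV", 20)
  jit <- list(a = 7.3e-7, v = -7.3e-7)
  tr <- simulate_events(ev, p, duration = 120, dt = 1, jitter = jit)
  s <- rest_state(p)
  for (i in seq_len(120)) {
    if (i == 21) { s$u[["Ia"]] <- s$u[["Ia"]] + jit$a; s$u[["Iv"]] <- s$u[["Iv"]] + jit$v }
    ext <- if (i >= 21 && i <= 80) c(a = 1, v = 1) else c(a = 0, v = 0)
    s <- step_state(s, ext = ext, params = p, dt = 1)
  }
  z <- activation(s$u, p)
  last <- nrow(tr)
  expect_equal(unname(tr$z_a[last]), unname(z[["a"]]), tolerance = 1e-12)
  expect_equal(unname(tr$z_m[last]), unname(z[["m"]]), tolerance = 1e-12)
  expect_equal(unname(tr$q_v[last]), unname(s$q[["v"]]), tolerance = 1e-12)
})

test_that("rest stays below the detection threshold and events drive the traces", {
  for (preset in c("td_child", "asd_child", "adult")) {
    p <- network_params(preset)
    tr <- simulate_events(stim_events("A", 1)[0, ], p, duration = 3000)
    expect_lt(max(tr$z_a, tr$z_v, tr$z_m, tr$z_Ia, tr$z_Iv), 0.10 * p$z_max)
  }
})

test_that("cross-modal competition suppresses and facilitation enhances input activity", {
  peak_za <- function(p, mod) {
    tr <- simulate_events(stim_events(mod, 500), p, duration = 1500)
    max(tr$z_a[tr$t_ms >= 500 & tr$t_ms <= 800])
  }
  child <- network_params("td_child")
  expect_lt(peak_za(child, "AV"), peak_za(child, "A"))   # mutual suppression
  adult <- network_params("adult")
  expect_gt(peak_za(adult, "AV"), peak_za(adult, "A"))   # mutual excitation
})

test_that("firing rates and slow traces stay within [0, z_max] for random drives", {
  set.seed(101)
  for (i in 1:8) {
    p <- network_params("td_child",
                        w_ma = runif(1, 0, 12), w_mv = runif(1, 0, 12),
                        w_av = runif(1, -25, 6), w_va = runif(1, -25, 6),
                        l_a = runif(1, 0, 12), l_v = runif(1, 0, 12),
                        i0_a = runif(1, 5, 25), i0_v = runif(1, 5, 25))
    ev <- stim_events(sample(c("A", "V", "AV"), 3, replace = TRUE),
                      onset = c(200, 1500, 3100))
    tr <- simulate_events(ev, p, duration = 4000, jitter_seed = i)
    z <- as.matrix(tr[, c("z_a", "z_v", "z_m", "z_Ia", "z_Iv", "q_a", "q_v")])
    expect_true(all(z >= 0 & z <= p$z_max))
  }
})

test_that("identical inputs give bit-identical traces", {
  p <- network_params("td_child")
  ev <- stim_events(c("V", "AV"), c(300, 2300))
  tr1 <- simulate_events(ev, p, duration = 4000, jitter_seed = 9L)
  tr2 <- simulate_events(ev, p, duration = 4000, jitter_seed = 9L)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
})

test_that("feedback inhibition persists across the task's ISI range", {
  p <- network_params("td_child")
  tr <- simulate_events(stim_events("V", 500), p, duration = 4000)
  q1 <- tr$q_v[tr$t_ms == 1500]   # onset + 1000
  q3 <- tr$q_v[tr$t_ms == 3500]   # onset + 3000
  rest_q <- tr$q_v[tr$t_ms == 400]
  expect_gt(q1, q3)
  expect_gt(q3, 0)
  expect_gt(q1, rest_q)           # the pulse actually charged the trace
})

test_that("the winner-takes-all circuit selects exactly one interneuron", {
  for (preset in c("td_child", "adult")) {
    p <- network_params(preset)
    tr <- simulate_events(stim_events("AV", 500), p, duration = 2000,
                          jitter_seed = 3L)
    sel <- tr$t_ms >= 500 & tr$t_ms <= 900
    tops <- sort(c(max(tr$z_Ia[sel]), max(tr$z_Iv[sel])))
    expect_gt(tops[2], 0.5 * p$z_max)
    expect_lt(tops[1], 0.5 * p$z_max)
  }
})

test_that("auditory/visual relabelling mirrors the dynamics exactly", {
  p <- network_params("td_child", w_ma = 6, w_mv = 9, w_av = -9, w_va = -15,
                      l_a = 2, l_v = 4, i0_a = 14, i0_v = 17)
  jit <- list(a = c(6e-7, -8e-7), v = c(-6e-7, 8e-7))
  mir <- list(a = jit$v, v = jit$a)
  ev <- stim_events(c("A", "AV"), c(300, 2300))
  ev_m <- stim_events(c("V", "AV"), c(300, 2300))
  tr <- simulate_events(ev, p, duration = 4000, jitter = jit)
  tr_m <- simulate_events(ev_m, swap_modalities(p), duration = 4000,
                          jitter = mir)
  expect_identical(tr$z_a, tr_m$z_v)
  expect_identical(tr$z_v, tr_m$z_a)
  expect_identical(tr$z_m, tr_m$z_m)
  expect_identical(tr$z_Ia, tr_m$z_Iv)
  expect_identical(tr$q_a, tr_m$q_v)
})

test_that("malformed protocols and parameters are rejected", {
  p <- network_params("td_child")
  expect_error(simulate_events(stim_events(c("A", "A"), c(100, 130)), p, 1000),
               "overlapping")
  expect_error(simulate_events(stim_events("A", 900), p, 920), "within")
  expect_error(simulate_events(stim_events("A", 100), p, 1000.5), "divide")
  expect_error(network_params(tau_fast = 2000), "tau_slow")
  expect_error(network_params(l_a = -1), "l_a")
  expect_error(network_params(nonsense = 1), "unknown")
  expect_error(stim_events("A", 100, duration = 0), "pulse_duration")
})
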