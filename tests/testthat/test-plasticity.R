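test_that("the Hebbian and anti-Hebbian update rules match hand arithmetic", {
  expect_equal(hebb_ltp(0.1, 0.8, 0.5, 0.01, lower = 0, upper = 1), 0.104)
  expect_equal(hebb_ltp(0.1, 0, 0.5, 0.01), 0.1)              # silent pre
  expect_equal(hebb_ltp(1, 0.9, 0.9, 0.5, upper = 1), 1)      # saturated
  expect_equal(hebb_ltp(-5, 0.5, 0.5, 1, lower = -8, upper = 2), -4.75)
  expect_equal(anti_hebb(0.2, 0.9, 0, 0.01, l_max = 1), 0.209)
  expect_equal(anti_hebb(0.2, 0, 0.3, 0.01, l_max = 1), 0.2)  # silent pre
  expect_equal(anti_hebb(0.2, 0.9, 1, 0.01, l_max = 1), 0.2)  # no suppression
  expect_equal(anti_hebb(0.99, 1, 0, 0.5, l_max = 1), 1)      # clipped
  expect_error(hebb_ltp(0, 1, 1, -0.1), "gamma")
  expect_error(anti_hebb(-1, 1, 0, 0.1, 1), "l")
})

test_that("reduced-plasticity rates are 80 percent of typical in every class", {
  td <- learning_rates("td")
  asd <- learning_rates("asd")
  expect_equal(asd$gamma_ff / td$gamma_ff, 0.8)
  expect_equal(asd$gamma_cm / td$gamma_cm, 0.8)
  expect_equal(asd$gamma_fb / td$gamma_fb, 0.8)
  expect_identical(asd$w_max_ff, td$w_max_ff)
  expect_identical(asd$l_max_fb, td$l_max_fb)
})

test_that("zero learning rates freeze the network", {
  rates0 <- learning_rates("td", gamma_ff = 0, gamma_cm = 0, gamma_fb = 0)
  sched <- training_schedule(n_epochs = 60, rates = rates0,
                             checkpoints = c(0, 30, 60), seed = 2)
  dev <- train_network(network_params("td_child"), sched)
  p0 <- network_params("td_child")
  for (cp in dev$checkpoints)
    expect_equal(unclass(cp), unclass(p0))
})

test_that("an all-audiovisual stream is replayed exactly by the reference oracle", {
  # 10 AV exposures, small cross-modal rate: the per-exposure updates are
  # recomputed with the pure-R integrator and the standalone update rule
  rates <- learning_rates("td", gamma_ff = 0, gamma_cm = 0.5, gamma_fb = 0)
  sched <- training_schedule(n_epochs = 10, mix = mix_spec(1, 0, 0),
                             rates = rates, checkpoints = c(0, 10), seed = 4,
                             dt = 1)
  dev <- train_network(network_params("td_child"), sched)
  expect_true(all(diff(c(-18, dev$weight_log$w_av)) > 0))  # strict growth

  # independent replay
  set.seed(4)
  stream <- make_training_stream(mix_schedule(0L, mix_spec(1, 0, 0)), 10)
  jmag <- runif(10, 5e-7, 1e-6)
  jsgn <- ifelse(runif(10) < 0.5, -1, 1)
  p <- network_params("td_child")
  s <- rest_state(p)
  for (i in seq_len(500)) s <- step_state(s, params = p, dt = 1)
  w_path <- numeric(10)
  for (e in 1:10) {
    n <- round(stream$isi_ms[e])
    zs <- matrix(NA_real_, n + 1, 2)
    s$u[["Ia"]] <- s$u[["Ia"]] + jmag[e] * jsgn[e]
    s$u[["Iv"]] <- s$u[["Iv"]] - jmag[e] * jsgn[e]
    zs[1, ] <- activation(s$u[c("a", "v")], p)
    for (i in seq_len(n)) {
      ext <- if (i <= 60) c(a = 1, v = 1) else c(a = 0, v = 0)
      s <- step_state(s, ext = ext, params = p, dt = 1)
      zs[i + 1, ] <- activation(s$u[c("a", "v")], p)
    }
    win <- zs[1:501, , drop = FALSE]
    exc <- colMeans(pmax(win - 0.1, 0))
    p$w_av <- hebb_ltp(p$w_av, exc[2], exc[1], 0.5, -20, 1.5)
    p$w_va <- hebb_ltp(p$w_va, exc[1], exc[2], 0.5, -20, 1.5)
    w_path[e] <- p$w_av
  }
  expect_equal(dev$weight_log$w_av, w_path, tolerance = 1e-10)
})

test_that("typical development strengthens all trained synapses monotonically", {
  dev <- td_development()
  w <- summary(dev)$weights
  for (nm in c("w_ma", "w_mv", "l_a", "l_v", "w_av", "w_va"))
    expect_true(all(diff(w[[nm]]) >= -1e-12), info = nm)
  # cross-modal weights change sign exactly once over the whole log
  signs <- sign(dev$weight_log$w_av)
  signs <- signs[signs != 0]
  expect_equal(sum(diff(signs) != 0), 1)
  # the flip falls between the adolescent and adult checkpoints
  fe <- sign_flip_epoch(dev)
  expect_gt(fe, 1000)
  expect_lte(fe, 1500)
  # untrained weights and constants never move
  final <- dev$checkpoints[["3000"]]
  p0 <- network_params("td_child")
  for (nm in c("w_Ia", "w_Iv", "l_av", "l_va", "tau_fast", "tau_slow",
               "act_slope", "act_center", "z_max", "i0_a", "i0_v"))
    expect_identical(final[[nm]], p0[[nm]], info = nm)
})

test_that("reduced plasticity delays the cross-modal sign flip", {
  td <- td_development()
  asd <- cached("dev_asd_plast_1", train_network(
    network_params("asd_child"),
    training_schedule(rates = learning_rates("asd"), seed = 1)))
  for (cp in c("500", "1000", "1500")) {
    expect_lt(asd$checkpoints[[cp]]$w_av, td$checkpoints[[cp]]$w_av)
  }
  expect_gt(sign_flip_epoch(asd), sign_flip_epoch(td))
})

test_that("training is deterministic per seed and stable under reordering", {
  sched <- function(s) training_schedule(n_epochs = 400,
                                         checkpoints = c(0, 200, 400), seed = s)
  d1 <- train_network(network_params("td_child"), sched(21))
  d2 <- train_network(network_params("td_child"), sched(21))
  expect_identical(d1$weight_log, d2$weight_log)
  # different exposure order: checkpoint weights within 10% of the class scale
  d3 <- train_network(network_params("td_child"), sched(22))
  r <- learning_rates("td")
  scale <- c(w_ma = r$w_max_ff, w_mv = r$w_max_ff,
             w_av = r$w_cm_cap + r$w_cm_floor,
             w_va = r$w_cm_cap + r$w_cm_floor,
             l_a = r$l_max_fb, l_v = r$l_max_fb)
  for (nm in names(scale)) {
    delta <- abs(d1$checkpoints[["400"]][[nm]] - d3$checkpoints[["400"]][[nm]])
    expect_lt(delta / scale[[nm]], 0.10, label = nm)
  }
})
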