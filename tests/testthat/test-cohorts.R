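test_that("cohort mix schedules encode the experimental protocols", {
  td <- build_mix_schedule("TD")
  expect_length(td$mixes, 1)
  expect_equal(unlist(td$mixes[[1]]), c(p_av = 0.30, p_a = 0.20, p_v = 0.50))
  expect_equal(build_mix_schedule("ASD_plasticity")$mixes[[1]]$p_av, 0.30)

  ae <- build_mix_schedule("ASD_exposure")
  expect_equal(ae$start_epoch, seq(0L, 2500L, by = 500L))
  expect_equal(vapply(ae$mixes, `[[`, numeric(1), "p_av"),
               seq(0.20, 0.70, by = 0.10))
  expect_equal(ae$mixes[[1]]$p_a, 0.40)
  expect_equal(ae$mixes[[1]]$p_v, 0.40)
  # non-AV remainder split equally in every phase
  for (m in ae$mixes) expect_equal(m$p_a, m$p_v)

  ae_cap <- build_mix_schedule("ASD_exposure", cap_at_td = TRUE)
  expect_lte(max(vapply(ae_cap$mixes, `[[`, numeric(1), "p_av")), 0.30)

  for (nm in c("ASD_plasticity_intervention_early",
               "ASD_exposure_intervention_early")) {
    sc <- build_mix_schedule(nm)
    expect_equal(unlist(sc$mixes[[1]]), c(p_av = 0.60, p_a = 0.10, p_v = 0.30))
  }
  late <- build_mix_schedule("ASD_exposure_intervention_late")
  expect_equal(late$start_epoch, c(0L, 500L))
  expect_equal(late$mixes[[1]]$p_av, 0.20)   # pre-intervention phase
  expect_equal(late$mixes[[2]]$p_av, 0.60)   # from the second age group on
  expect_error(build_mix_schedule("unknown_cohort"), "cohort")
})

test_that("cohort specs wire presets and intervention onsets correctly", {
  expect_equal(cohort_spec("TD")$params_preset, "td_child")
  for (nm in grep("^ASD", cohort_names, value = TRUE))
    expect_equal(cohort_spec(nm)$params_preset, "asd_child")
  expect_equal(cohort_spec("ASD_plasticity")$rates_preset, "asd")
  expect_equal(cohort_spec("ASD_exposure")$rates_preset, "td")
  expect_equal(cohort_spec("ASD_plasticity_intervention_early")$intervention_start, 0L)
  expect_equal(cohort_spec("ASD_exposure_intervention_late")$intervention_start, 500L)
})

test_that("trajectory distance is a symmetric RMS over matched cells", {
  a <- make_fixture_reference("TD-like", seed = 1)
  expect_equal(trajectory_distance(a, a), 0)
  b <- a
  b$median_rt_ms <- b$median_rt_ms + 10
  expect_equal(trajectory_distance(a, b), 10)
  expect_equal(trajectory_distance(a, b), trajectory_distance(b, a))
  bad <- a[a$condition != "AV-switch", ]
  class(bad) <- class(a)
  expect_error(trajectory_distance(a, bad), "cells")
})

test_that("one-way ANOVA reproduces the hand-computed oracle", {
  # groups {1,2,3} vs {4,5,6}: SSB = 13.5 on 1 df, MSW = 1 on 4 df
  res <- anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(anova_oneway(list(1:3, 1:3))$F, 0)
  expect_warning(res0 <- anova_oneway(list(c(2, 2), c(2, 2))), "undefined")
  expect_true(is.na(res0$F))
  expect_error(anova_oneway(list(1:3)), "two groups")
  expect_error(anova_oneway(list(1:3, 5)), "two values")
})

test_that("the ANOVA holds its nominal type-I error under the null", {
  set.seed(42)
  hits <- mean(replicate(1000, {
    anova_oneway(list(rnorm(6), rnorm(6)))$p < 0.05
  }))
  expect_gt(hits, 0.025)
  expect_lt(hits, 0.075)
})

test_that("model-versus-reference comparison reports F, distance and deltas", {
  a <- cohort_trajectory("TD")
  cmp <- compare_to_reference(a, a)
  expect_equal(cmp$anova$F, 0)
  expect_equal(cmp$distance, 0)
  b <- a
  b$median_rt_ms <- b$median_rt_ms + 25
  cmp2 <- compare_to_reference(a, b)
  expect_equal(cmp2$distance, 25)
  expect_gt(cmp2$anova$F, 0)
  expect_equal(cmp2$deltas$delta_ms, rep(-25, 24))
  # smoke contract against the synthetic reference table
  cmp3 <- compare_to_reference(a, make_fixture_reference("TD-like"))
  expect_true(is.finite(cmp3$anova$F))
  expect_true(is.finite(cmp3$anova$p))
  expect_equal(cmp3$anova$df_within, 46)
})

test_that("a frozen network yields identical rows at every age group", {
  rates0 <- learning_rates("td", gamma_ff = 0, gamma_cm = 0, gamma_fb = 0)
  traj <- run_cohort("TD", seed = 3, rates = rates0)
  base <- traj_cells_of(traj, "6-9")
  for (ag in age_groups[-1])
    expect_equal(traj_cells_of(traj, ag), base, tolerance = 1e-12)
})

test_that("trajectory tables are validated cell by cell", {
  a <- as.data.frame(make_fixture_reference("TD-like", seed = 1))
  expect_s3_class(rt_trajectory(a), "rt_trajectory")
  expect_error(rt_trajectory(a[a$condition != "AV-switch", ]), "AV-switch")
  bad <- a
  bad$condition[1] <- "AV-weird"
  expect_error(rt_trajectory(bad), "unknown condition")
  bad <- a
  bad$median_rt_ms[3] <- -10
  expect_error(rt_trajectory(bad), "positive")
  expect_error(rt_trajectory(a[, -4]), "missing column")
})

test_that("typical development passes the qualitative-ordering battery", {
  checks <- check_trajectory(cohort_trajectory("TD"))
  expect_true(attr(checks, "ok"))
})
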