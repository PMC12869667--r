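#' Six-condition repeat/switch test battery
#'
#' Runs the full trial battery (A/V/AV, repeat and switch, ISI 2000 ms) with
#' plasticity frozen and returns the reaction time to the second stimulus of
#' each pair.  The audiovisual switch condition is simulated in both
#' variants (V then AV, and A then AV) and averaged.
#'
#' @param params A [network_params()] object.
#' @param isi Inter-stimulus interval (ms, battery default 2000).
#' @param dt Euler step (ms).
#' @param jitter_seed Seed for the winner-takes-all onset jitters.
#' @param ... Passed to [run_condition()].
#' @return Data.frame with columns \code{condition}, \code{rt_ms}
#'   (\code{NA} on timeout) and \code{timeout}.
#' @export
rt_battery <- function(params, isi = 2000, dt = 1, jitter_seed = 1L, ...) {
  one <- function(cond, from = "V") {
    run_condition(params, make_condition_pair(cond, isi = isi,
                                              av_switch_from = from),
                  dt = dt, jitter_seed = jitter_seed, ...)
  }
  rts <- vapply(setdiff(trial_conditions, "AV-switch"),
                function(cc) one(cc)$rt_second, numeric(1))
  av_sw <- c(one("AV-switch", "V")$rt_second, one("AV-switch", "A")$rt_second)
  rts <- c(rts, "AV-switch" = if (anyNA(av_sw)) NA_real_ else mean(av_sw))
  rts <- rts[trial_conditions]
  data.frame(condition = trial_conditions, rt_ms = unname(rts),
             timeout = is.na(unname(rts)), row.names = NULL)
}

#' Cohort names of the developmental experiments
#' @export
cohort_names <- c("TD", "ASD_plasticity", "ASD_exposure",
                  "ASD_plasticity_intervention_early",
                  "ASD_plasticity_intervention_late",
                  "ASD_exposure_intervention_early",
                  "ASD_exposure_intervention_late")

#' Specify a developmental cohort
#'
#' Encodes the experimental arms: typical development (TD); the two
#' autism-spectrum hypotheses (reduced plasticity: learning rates at 80
#' percent; reduced exposure: audiovisual share starting at 20 percent and
#' rising by 10 percentage points every 500 epochs); and the multisensory
#' intervention (60 percent AV) applied from the start ("early") or from
#' epoch 500 ("late") under either hypothesis.  All ASD arms start from the
#' ASD child parameter preset (more inhibitory cross-modal synapses).
#'
#' @param name One of [cohort_names].
#' @return Object of class \code{msidev_cohort} with fields \code{name},
#'   \code{params_preset}, \code{rates_preset},
#'   \code{intervention_start} (\code{NA}, 0 or 500).
#' @export
cohort_spec <- function(name) {
  if (length(name) != 1 || !name %in% cohort_names)
    stop("unknown cohort: ", paste(name, collapse = ", "))
  asd <- grepl("^ASD", name)
  structure(list(
    name = name,
    params_preset = if (asd) "asd_child" else "td_child",
    rates_preset = if (grepl("plasticity", name)) "asd" else "td",
    intervention_start = if (grepl("intervention_early", name)) 0L
                         else if (grepl("intervention_late", name)) 500L
                         else NA_integer_),
    class = "msidev_cohort")
}

#' Stimulus-mix phase schedule for a cohort
#'
#' TD and the reduced-plasticity arm use the constant typical mix (30
#' percent AV, 20 percent A, 50 percent V).  The reduced-exposure arm
#' starts at 20 percent AV / 40 / 40 and gains 10 percentage points of AV
#' per 500 epochs (the remainder split equally between A and V);
#' \code{cap_at_td} optionally stops the increments at the typical 30
#' percent.  Intervention arms switch to 60 percent AV / 10 A / 30 V at
#' their start epoch and keep it to the end.
#'
#' @param spec A [cohort_spec()] (or cohort name).
#' @param n_epochs Training length (default 3000).
#' @param cap_at_td Cap the reduced-exposure increments at the typical AV
#'   share instead of increasing literally throughout.
#' @return A [mix_schedule()].
#' @export
#' @examples
#' build_mix_schedule("ASD_exposure")$mixes[[1]]$p_av  # 0.20
build_mix_schedule <- function(spec, n_epochs = 3000, cap_at_td = FALSE) {
  if (is.character(spec)) spec <- cohort_spec(spec)
  if (!inherits(spec, "msidev_cohort")) stop("unknown cohort")
  td_mix <- mix_spec(0.30, 0.20, 0.50)
  intervention_mix <- mix_spec(0.60, 0.10, 0.30)
  exposure_phase <- function(k) {
    p_av <- 0.20 + 0.10 * k
    if (cap_at_td) p_av <- min(p_av, 0.30)
    p_av <- min(p_av, 1)
    mix_spec(p_av, (1 - p_av) / 2, (1 - p_av) / 2)
  }
  starts <- seq(0L, n_epochs - 1L, by = 500L)
  base <- switch(sub("_intervention.*", "", spec$name),
    TD = mix_schedule(0L, td_mix),
    ASD_plasticity = mix_schedule(0L, td_mix),
    ASD_exposure = mix_schedule(starts,
                                lapply(seq_along(starts) - 1L, exposure_phase)))
  if (is.na(spec$intervention_start)) return(base)
  s0 <- spec$intervention_start
  keep <- base$start_epoch < s0
  mix_schedule(c(base$start_epoch[keep], s0),
               c(base$mixes[keep], list(intervention_mix)))
}

#' Run one developmental cohort experiment
#'
#' Trains the cohort's network through its exposure schedule, freezes
#' plasticity at every checkpoint, runs the six-condition test battery and
#' assembles the reaction-time trajectory: rows 6-9, 10-12 and 13-17 years
#' come from checkpoints 0, 500 and 1000; the adult row is the mean over
#' checkpoints 1500, 2000, 2500 and 3000.
#'
#' @param spec A [cohort_spec()] or cohort name.
#' @param seed Integer seed for the exposure stream.
#' @param dt Euler step (ms).
#' @param n_epochs Training length (default 3000).
#' @param cap_at_td Passed to [build_mix_schedule()].
#' @param rates Optional [learning_rates()] override (default: the cohort's
#'   preset).
#' @param keep_development Attach the [train_network()] object as attribute
#'   \code{"development"}.
#' @return An \code{rt_trajectory}: data.frame with columns \code{cohort},
#'   \code{age_group}, \code{condition}, \code{median_rt_ms},
#'   \code{timeout}.
#' @export
run_cohort <- function(spec, seed = 1L, dt = 1, n_epochs = 3000,
                       cap_at_td = FALSE, rates = NULL,
                       keep_development = FALSE) {
  if (is.character(spec)) spec <- cohort_spec(spec)
  if (!inherits(spec, "msidev_cohort")) stop("unknown cohort")
  if (is.null(rates)) rates <- learning_rates(spec$rates_preset)
  sched <- training_schedule(n_epochs = n_epochs,
                             mix = build_mix_schedule(spec, n_epochs,
                                                      cap_at_td),
                             rates = rates,
                             checkpoints = seq(0, n_epochs, by = 500),
                             seed = seed, dt = dt)
  dev <- train_network(network_params(spec$params_preset), sched)
  bat <- predict(dev, dt = dt)
  traj <- battery_to_trajectory(bat, cohort = spec$name)
  if (keep_development) attr(traj, "development") <- dev
  traj
}

# collapse a checkpoint battery into the 4 age-group x 6 condition table
battery_to_trajectory <- function(bat, cohort) {
  bat$age_group <- epoch_age_group(bat$epoch)
  bat <- bat[!is.na(bat$age_group), , drop = FALSE]
  agg <- stats::aggregate(rt_ms ~ age_group + condition, data = bat,
                          FUN = mean, na.action = stats::na.pass)
  tmo <- stats::aggregate(timeout ~ age_group + condition, data = bat,
                          FUN = any)
  out <- merge(agg, tmo, by = c("age_group", "condition"))
  names(out)[names(out) == "rt_ms"] <- "median_rt_ms"
  rt_trajectory(cbind(cohort = cohort, out))
}

#' Construct / validate an RT trajectory table
#'
#' @param df Data.frame with columns \code{cohort}, \code{age_group},
#'   \code{condition}, \code{median_rt_ms} and optionally \code{timeout}.
#' @return The validated \code{rt_trajectory} (rows ordered by age group and
#'   condition; all 24 cells present).
#' @export
rt_trajectory <- function(df) {
  need <- c("cohort", "age_group", "condition", "median_rt_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"timeout" %in% names(df)) df$timeout <- is.na(df$median_rt_ms)
  bad <- setdiff(unique(df$condition), trial_conditions)
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$age_group), age_groups)
  if (length(bad)) stop("unknown age group(s): ", paste(bad, collapse = ", "))
  want <- expand.grid(age_group = age_groups, condition = trial_conditions,
                      stringsAsFactors = FALSE)
  key <- paste(df$age_group, df$condition)
  missing_cells <- setdiff(paste(want$age_group, want$condition), key)
  if (length(missing_cells))
    stop("missing trajectory cell(s): ", paste(missing_cells, collapse = "; "))
  if (anyDuplicated(key)) stop("duplicated trajectory cells")
  if (any(!df$timeout & (!is.finite(df$median_rt_ms) | df$median_rt_ms <= 0)))
    stop("median_rt_ms must be positive for non-timeout cells")
  df <- df[order(match(df$age_group, age_groups),
                 match(df$condition, trial_conditions)),
           c("cohort", "age_group", "condition", "median_rt_ms", "timeout")]
  rownames(df) <- NULL
  class(df) <- c("rt_trajectory", "data.frame")
  df
}

traj_cells <- function(traj) {
  x <- traj$median_rt_ms
  names(x) <- paste(traj$age_group, traj$condition)
  x
}

#' Root-mean-square distance between two RT trajectories
#'
#' @param a,b \code{rt_trajectory} objects over the same 24 cells.
#' @return RMS difference in ms.
#' @export
trajectory_distance <- function(a, b) {
  ca <- traj_cells(a); cb <- traj_cells(b)
  if (!setequal(names(ca), names(cb)))
    stop("trajectories cover different cells")
  cb <- cb[names(ca)]
  sqrt(mean((ca - cb)^2))
}

#' Classical one-way fixed-effects ANOVA
#'
#' Thin wrapper over \code{stats::oneway.test(var.equal = TRUE)} with the F
#' statistic and degrees of freedom exposed directly, used for the
#' model-versus-data source comparisons.
#'
#' @param groups List of at least two numeric vectors, each with at least
#'   two values.
#' @return List with \code{F}, \code{p}, \code{df_between},
#'   \code{df_within}.  If both the between- and within-group variances are
#'   zero the F ratio is undefined and \code{NA} is returned with a
#'   warning.
#' @export
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(4, 5, 6)))$F  # 13.5
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(y) == 0) {
    warning("undefined F: zero between- and within-group variance",
            call. = FALSE)
    return(list(F = NA_real_, p = NA_real_,
                df_between = length(groups) - 1L,
                df_within = length(y) - length(groups)))
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value),
       df_between = unname(ft$parameter[1]),
       df_within = unname(ft$parameter[2]))
}

#' Compare a simulated trajectory with a reference trajectory
#'
#' Performs the one-way data-source ANOVA over the two 24-cell sets,
#' computes the RMS trajectory distance and tabulates per-cell differences.
#'
#' @param model,reference \code{rt_trajectory} objects over the same cells.
#' @return Object of class \code{msidev_comparison}: list with
#'   \code{anova} (see [anova_oneway()]), \code{distance} (ms) and
#'   \code{deltas} (data.frame of per-cell model minus reference, ms).
#' @export
compare_to_reference <- function(model, reference) {
  cm <- traj_cells(model); cr <- traj_cells(reference)
  if (!setequal(names(cm), names(cr)))
    stop("trajectories cover different cells")
  cr <- cr[names(cm)]
  an <- anova_oneway(list(unname(cm), unname(cr)))
  deltas <- data.frame(age_group = model$age_group,
                       condition = model$condition,
                       delta_ms = unname(cm - cr))
  structure(list(anova = an, distance = trajectory_distance(model, reference),
                 deltas = deltas),
            class = "msidev_comparison")
}

#' @export
print.msidev_comparison <- function(x, ...) {
  cat(sprintf("Data-source ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  cat(sprintf("RMS trajectory distance: %.4g ms\n", x$distance))
  cat("Largest per-cell differences (ms):\n")
  d <- x$deltas[order(-abs(x$deltas$delta_ms)), ]
  print(utils::head(d, 5), row.names = FALSE)
  invisible(x)
}

#' Qualitative-ordering checks on an RT trajectory
#'
#' Applies the developmental orderings expected of a typically-developing
#' trajectory: reaction times non-increasing with age in every condition;
#' unisensory switch cost positive and non-decreasing with age; audiovisual
#' switch cost negligible at every age; no multisensory facilitation in the
#' youngest group but positive facilitation in the adult group.
#'
#' @param traj An \code{rt_trajectory}.
#' @param tol Negligibility tolerance in ms (default 5).
#' @return Named logical vector of check results, with attribute
#'   \code{"ok"} (all passed).
#' @export
check_trajectory <- function(traj, tol = 5) {
  cells <- traj_cells(traj)
  rt <- function(age, cond) unname(cells[paste(age, cond)])
  ages <- age_groups
  noninc <- all(vapply(trial_conditions, function(cc) {
    x <- vapply(ages, rt, numeric(1), cond = cc)
    all(diff(x) <= 1e-9)
  }, logical(1)))
  ucost <- vapply(ages, function(a) {
    mean(c(rt(a, "A-switch") - rt(a, "A-repeat"),
           rt(a, "V-switch") - rt(a, "V-repeat")))
  }, numeric(1))
  avcost <- vapply(ages, function(a) rt(a, "AV-switch") - rt(a, "AV-repeat"),
                   numeric(1))
  gain <- vapply(ages, function(a) {
    multisensory_gain(rt(a, "AV-repeat"), rt(a, "A-repeat"),
                      rt(a, "V-repeat"))
  }, numeric(1))
  checks <- c(
    rt_nonincreasing_with_age = noninc,
    unisensory_cost_positive = all(ucost > 0),
    unisensory_cost_nondecreasing = all(diff(ucost) >= -1e-9),
    av_cost_negligible = all(abs(avcost) <= tol),
    child_gain_negligible = gain[1] <= tol,
    adult_gain_positive = gain[length(gain)] > 0)
  attr(checks, "ok") <- all(checks)
  checks
}
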