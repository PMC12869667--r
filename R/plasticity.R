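#' Learning rates and saturation bounds for developmental training
#'
#' One rate per synapse class: \code{gamma_ff} for the feedforward
#' projections (\code{w_ma}, \code{w_mv}), \code{gamma_cm} for the signed
#' cross-modal projections (\code{w_av}, \code{w_va}) and \code{gamma_fb}
#' for the feedback inhibition magnitudes (\code{l_a}, \code{l_v}).  Each
#' class carries a saturation bound; the cross-modal weights live in the
#' symmetric range \code{[-w_cm_cap, +w_cm_cap]} so repeated audiovisual
#' co-activation can drive them across zero from inhibitory to excitatory.
#' The \code{"asd"} preset reduces every learning rate to 80 percent of the
#' \code{"td"} value (the reduced-plasticity hypothesis) and keeps the
#' bounds.
#'
#' @param preset \code{"td"} or \code{"asd"}.
#' @param ... Named overrides (\code{gamma_ff}, \code{gamma_cm},
#'   \code{gamma_fb}, \code{w_max_ff}, \code{w_cm_cap}, \code{w_cm_floor},
#'   \code{l_max_fb}).
#' @return Object of class \code{msidev_rates}.
#' @export
#' @examples
#' learning_rates("asd")$gamma_cm / learning_rates("td")$gamma_cm  # 0.8
learning_rates <- function(preset = c("td", "asd"), ...) {
  preset <- match.arg(preset)
  r <- list(gamma_ff = 2, gamma_cm = 54, gamma_fb = 0.008,
            w_max_ff = 8, w_cm_cap = 1.5, w_cm_floor = 20, l_max_fb = 12)
  if (preset == "asd") {
    r$gamma_ff <- 0.8 * r$gamma_ff
    r$gamma_cm <- 0.8 * r$gamma_cm
    r$gamma_fb <- 0.8 * r$gamma_fb
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(r))
  if (length(bad)) stop("unknown learning-rate field(s): ", paste(bad, collapse = ", "))
  r[names(dots)] <- dots
  if (any(unlist(r[c("gamma_ff", "gamma_cm", "gamma_fb")]) < 0))
    stop("learning rates must be >= 0")
  if (any(unlist(r[c("w_max_ff", "w_cm_cap", "w_cm_floor", "l_max_fb")]) <= 0))
    stop("saturation bounds must be > 0")
  structure(r, class = "msidev_rates")
}

#' Hebbian long-term potentiation update
#'
#' \code{w' = clip(w + gamma * pre * post, lower, upper)}: correlated pre-
#' and postsynaptic activity strengthens the connection, clipped to the
#' class bounds.  Applied to the feedforward weights (bounds
#' \code{[0, w_max_ff]}) and to the signed cross-modal weights (bounds
#' \code{[-w_cm_floor, +w_cm_cap]}, so the value may cross zero).
#'
#' @param w Current weight.
#' @param pre,post Pre- and postsynaptic activity statistics in
#'   \code{[0, z_max]}.
#' @param gamma Learning rate (>= 0).
#' @param lower,upper Saturation bounds.
#' @return Updated weight.
#' @export
#' @examples
#' hebb_ltp(0.1, 0.8, 0.5, 0.01, lower = 0, upper = 1)  # 0.104
hebb_ltp <- function(w, pre, post, gamma, lower = 0, upper = Inf) {
  if (gamma < 0) stop("gamma must be >= 0")
  min(max(w + gamma * pre * post, lower), upper)
}

#' Anti-Hebbian update for inhibitory feedback synapses
#'
#' \code{l' = clip(l + gamma * pre * (z_max - post), 0, l_max)}: the
#' inhibitory connection strengthens when the presynaptic interneuron is
#' active while the postsynaptic input unit is suppressed.  Applied to
#' \code{l_a}, \code{l_v}.
#'
#' @param l Current inhibition magnitude (>= 0).
#' @param pre Presynaptic (interneuron) activity statistic.
#' @param post Postsynaptic (inhibited input unit) activity statistic.
#' @param gamma Learning rate (>= 0).
#' @param l_max Upper saturation bound.
#' @param z_max Maximum firing rate.
#' @return Updated magnitude.
#' @export
#' @examples
#' anti_hebb(0.2, 0.9, 0, 0.01, l_max = 1)  # 0.209
anti_hebb <- function(l, pre, post, gamma, l_max, z_max = 1) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (l < 0) stop("l must be >= 0")
  min(max(l + gamma * pre * (z_max - post), 0), l_max)
}

#' Developmental training schedule
#'
#' Bundles everything one training run needs: number of exposures, the
#' stimulus-mix phase schedule, learning rates, checkpoint epochs and the
#' epoch-to-age-group mapping (500 exposures correspond to about three years
#' of age; the adult row is the mean over the checkpoints from 1500 to
#' 3000).
#'
#' @param n_epochs Total exposures (default 3000 = full development).
#' @param mix A [mix_schedule()] or single [mix_spec()] (default the
#'   typically-developing mix: 30 percent AV, 20 percent A, 50 percent V).
#' @param rates A [learning_rates()] object.
#' @param checkpoints Epochs at which parameter snapshots are taken
#'   (default 0, 500, ..., 3000; must lie in \code{[0, n_epochs]}).
#' @param seed Integer seed for the exposure stream and winner-takes-all
#'   jitters.
#' @param dt Euler step (ms).
#' @param stat_window Window (ms after each exposure onset) over which the
#'   pre/post firing-rate statistics driving the updates are averaged.
#' @param learn_threshold Activation threshold for plasticity, as a fraction
#'   of \code{z_max} (default 0.10, tied to the detection threshold): the
#'   Hebbian pre/post statistics are the mean rates in excess of this
#'   threshold, rectified per step, so learning is gated on genuine
#'   stimulus-driven co-activation rather than baseline firing.
#' @param stim_duration Pulse duration (ms).
#' @param isi_lo,isi_hi Training ISI range (ms).
#' @return Object of class \code{msidev_schedule}.
#' @export
training_schedule <- function(n_epochs = 3000,
                              mix = mix_spec(0.30, 0.20, 0.50),
                              rates = learning_rates("td"),
                              checkpoints = seq(0, 3000, by = 500),
                              seed = 1L, dt = 1, stat_window = 500,
                              learn_threshold = 0.10, stim_duration = 60,
                              isi_lo = 1000, isi_hi = 3000) {
  if (inherits(mix, "msidev_mix")) mix <- mix_schedule(0L, mix)
  if (!inherits(mix, "msidev_mix_schedule")) stop("mix must be a mix_schedule()")
  if (!inherits(rates, "msidev_rates")) stop("rates must come from learning_rates()")
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 0 | checkpoints > n_epochs))
    stop("checkpoints must lie in [0, n_epochs]")
  if (!(learn_threshold >= 0 && learn_threshold < 1))
    stop("learn_threshold must lie in [0, 1)")
  structure(list(n_epochs = as.integer(n_epochs), mix = mix, rates = rates,
                 checkpoints = checkpoints, seed = as.integer(seed), dt = dt,
                 stat_window = stat_window, learn_threshold = learn_threshold,
                 stim_duration = stim_duration,
                 isi_lo = isi_lo, isi_hi = isi_hi),
            class = "msidev_schedule")
}

#' Age groups of the developmental comparison
#' @export
age_groups <- c("6-9", "10-12", "13-17", "adult")

#' Map a checkpoint epoch to its age group
#'
#' Epoch 0 corresponds to 6-9 years, 500 to 10-12, 1000 to 13-17; every
#' checkpoint from 1500 to 3000 contributes to the adult group (which is
#' averaged over them).
#'
#' @param epoch Checkpoint epoch(s).
#' @return Character vector of age-group labels (\code{NA} for epochs that
#'   belong to no group).
#' @export
epoch_age_group <- function(epoch) {
  out <- rep(NA_character_, length(epoch))
  out[epoch == 0] <- "6-9"
  out[epoch == 500] <- "10-12"
  out[epoch == 1000] <- "13-17"
  out[epoch >= 1500 & epoch <= 3000] <- "adult"
  out
}

trained_weights <- c("w_ma", "w_mv", "w_av", "w_va", "l_a", "l_v")

# One Hebbian/anti-Hebbian update per exposure.  `exc` holds the mean
# suprathreshold rates (rate above the detection threshold, rectified per
# step) that gate the Hebbian products; `raw` holds plain mean rates, used
# for the anti-Hebbian postsynaptic suppression term.
apply_updates <- function(p, exc, raw, rates) {
  p$w_ma <- hebb_ltp(p$w_ma, exc[["z_a"]], exc[["z_m"]], rates$gamma_ff,
                     0, rates$w_max_ff)
  p$w_mv <- hebb_ltp(p$w_mv, exc[["z_v"]], exc[["z_m"]], rates$gamma_ff,
                     0, rates$w_max_ff)
  p$w_av <- hebb_ltp(p$w_av, exc[["z_v"]], exc[["z_a"]], rates$gamma_cm,
                     -rates$w_cm_floor, rates$w_cm_cap)
  p$w_va <- hebb_ltp(p$w_va, exc[["z_a"]], exc[["z_v"]], rates$gamma_cm,
                     -rates$w_cm_floor, rates$w_cm_cap)
  p$l_a <- anti_hebb(p$l_a, exc[["z_Ia"]], raw[["z_v"]], rates$gamma_fb,
                     rates$l_max_fb, p$z_max)
  p$l_v <- anti_hebb(p$l_v, exc[["z_Iv"]], raw[["z_a"]], rates$gamma_fb,
                     rates$l_max_fb, p$z_max)
  p
}

#' Train the network through developmental exposure
#'
#' Simulates the whole exposure stream as one continuous session (slow
#' feedback traces carry across exposures).  After each exposure the mean
#' firing rates over the first \code{stat_window} ms are used as the
#' pre/post statistics of one Hebbian update of the feedforward and
#' cross-modal weights and one anti-Hebbian update of the feedback
#' inhibition magnitudes.  The untrained weights (\code{w_Ia}, \code{w_Iv},
#' \code{l_av}, \code{l_va}) and all biophysical constants are never
#' modified.  Deep-copied parameter snapshots are taken at every checkpoint
#' epoch.
#'
#' @param params0 Initial [network_params()] (checkpoint 0 equals this).
#' @param schedule A [training_schedule()].
#' @param seed Optional override of the schedule's seed.
#' @return Object of class \code{msidev_development} with components
#'   \code{checkpoints} (named list epoch -> \code{msidev_params}),
#'   \code{weight_log} (per-epoch trained-weight values after the update),
#'   \code{stream}, \code{schedule}, \code{params0} and \code{seed}.
#'   Supports \code{print}, \code{summary}, \code{coef}, \code{plot} and
#'   \code{predict} (RT trajectory) methods.
#' @seealso [run_cohort()] for the full cohort experiments.
#' @export
train_network <- function(params0, schedule, seed = NULL) {
  validate_params(params0)
  if (!inherits(schedule, "msidev_schedule")) stop("schedule must come from training_schedule()")
  seed <- if (is.null(seed)) schedule$seed else as.integer(seed)
  n <- schedule$n_epochs
  stream <- make_training_stream(schedule$mix, n, seed = seed,
                                 isi_lo = schedule$isi_lo,
                                 isi_hi = schedule$isi_hi)
  jit_mag <- stats::runif(n, 5e-7, 1e-6)   # continues the seeded RNG stream
  jit_sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
  dt <- schedule$dt
  rates <- schedule$rates
  ws <- as.integer(round(schedule$stat_window / dt))
  thr <- schedule$learn_threshold * params0$z_max
  pulse <- as.integer(round(schedule$stim_duration / dt))

  p <- params0
  state <- rest_state(p)
  # settle before the first exposure
  settle_steps <- as.integer(round(500 / dt))
  res <- cpp_simulate(unname(state$u), unname(state$q),
                      numeric(settle_steps), numeric(settle_steps),
                      par_vec(p), dt, integer(0), numeric(0), numeric(0),
                      FALSE)

  snapshots <- vector("list", length(schedule$checkpoints))
  names(snapshots) <- as.character(schedule$checkpoints)
  if ("0" %in% names(snapshots)) snapshots[["0"]] <- p
  wlog <- matrix(NA_real_, nrow = n, ncol = length(trained_weights),
                 dimnames = list(NULL, trained_weights))

  u <- res$u; q <- res$q
  for (e in seq_len(n)) {
    n_steps <- as.integer(round(stream$isi_ms[e] / dt))
    ext <- numeric(n_steps)
    ext[seq_len(min(pulse, n_steps))] <- 1
    mod <- stream$modality[e]
    ext_a <- if (mod %in% c("A", "AV")) ext else numeric(n_steps)
    ext_v <- if (mod %in% c("V", "AV")) ext else numeric(n_steps)
    res <- cpp_simulate(u, q, ext_a, ext_v, par_vec(p), dt,
                        0L, jit_mag[e] * jit_sgn[e],
                        -jit_mag[e] * jit_sgn[e], TRUE)
    u <- res$u; q <- res$q
    win <- res$trace[seq_len(min(ws, n_steps) + 1L), 1:5, drop = FALSE]
    raw <- colMeans(win)
    exc <- colMeans(pmax(win - thr, 0))
    names(raw) <- names(exc) <- c("z_a", "z_v", "z_m", "z_Ia", "z_Iv")
    p <- apply_updates(p, exc, raw, rates)
    if (!all(is.finite(unlist(p[trained_weights]))))
      stop("non-finite weight at training epoch ", e)
    wlog[e, ] <- unlist(p[trained_weights])
    key <- as.character(e)
    if (key %in% names(snapshots)) snapshots[[key]] <- p
  }

  structure(list(checkpoints = snapshots,
                 weight_log = cbind(data.frame(epoch = seq_len(n)),
                                    as.data.frame(wlog)),
                 stream = stream, schedule = schedule,
                 params0 = params0, seed = seed),
            class = "msidev_development")
}

#' Epoch at which a trained cross-modal weight first becomes excitatory
#'
#' @param dev An \code{msidev_development} from [train_network()].
#' @param weight \code{"w_av"} or \code{"w_va"}.
#' @return The 1-based epoch of the first positive value, or \code{NA} if
#'   the weight never crosses zero.
#' @export
sign_flip_epoch <- function(dev, weight = c("w_av", "w_va")) {
  weight <- match.arg(weight)
  idx <- which(dev$weight_log[[weight]] > 0)
  if (!length(idx)) return(NA_integer_)
  dev$weight_log$epoch[idx[1]]
}

#' @export
print.msidev_development <- function(x, ...) {
  cat("Developmental training run:", x$schedule$n_epochs, "exposures, seed",
      x$seed, "\n")
  cat("Checkpoints:", paste(names(x$checkpoints), collapse = ", "), "\n")
  fe <- sign_flip_epoch(x)
  if (is.na(fe)) cat("Cross-modal synapses did not become excitatory\n")
  else cat("Cross-modal synapses became excitatory at epoch", fe, "\n")
  invisible(x)
}

#' @export
summary.msidev_development <- function(object, ...) {
  cps <- names(object$checkpoints)
  tab <- t(vapply(object$checkpoints,
                  function(p) unlist(p[trained_weights]),
                  numeric(length(trained_weights))))
  out <- data.frame(epoch = as.integer(cps),
                    age_group = epoch_age_group(as.integer(cps)), tab,
                    row.names = NULL)
  structure(list(weights = out,
                 flip_epoch = sign_flip_epoch(object),
                 n_epochs = object$schedule$n_epochs),
            class = "summary.msidev_development")
}

#' @export
print.summary.msidev_development <- function(x, ...) {
  cat("Trained synaptic weights at checkpoints (", x$n_epochs,
      " exposures):\n", sep = "")
  print(x$weights, digits = 4)
  if (!is.na(x$flip_epoch))
    cat("Cross-modal sign flip (w_av > 0) at epoch", x$flip_epoch, "\n")
  invisible(x)
}

#' @export
coef.msidev_development <- function(object, epoch = NULL, ...) {
  key <- if (is.null(epoch)) names(object$checkpoints)[length(object$checkpoints)]
         else as.character(epoch)
  p <- object$checkpoints[[key]]
  if (is.null(p)) stop("no checkpoint at epoch ", key)
  unlist(p[trained_weights])
}

#' @export
plot.msidev_development <- function(x, ...) {
  wl <- x$weight_log
  graphics::matplot(wl$epoch, wl[, trained_weights], type = "l", lty = 1,
                    xlab = "training epoch (exposures)",
                    ylab = "synaptic efficacy",
                    main = "Trained weight trajectories", ...)
  graphics::abline(h = 0, col = "grey", lty = 3)
  graphics::legend("topleft", legend = trained_weights, col = 1:6, lty = 1,
                   cex = 0.8, bty = "n")
  invisible(x)
}

#' Predict reaction times from a training run
#'
#' Freezes plasticity at each requested checkpoint and runs the
#' six-condition repeat/switch test battery.
#'
#' @param object An \code{msidev_development}.
#' @param epochs Checkpoint epochs (default: all snapshots).
#' @param ... Passed to [rt_battery()].
#' @return Data.frame with columns \code{epoch}, \code{condition},
#'   \code{rt_ms}, \code{timeout}.
#' @export
predict.msidev_development <- function(object, epochs = NULL, ...) {
  keys <- if (is.null(epochs)) names(object$checkpoints)
          else as.character(epochs)
  out <- lapply(keys, function(k) {
    p <- object$checkpoints[[k]]
    if (is.null(p)) stop("no checkpoint at epoch ", k)
    cbind(epoch = as.integer(k), rt_battery(p, ...))
  })
  do.call(rbind, out)
}
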