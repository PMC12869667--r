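#' Logistic activation function
#'
#' Converts a unit's membrane input into a firing rate through a logistic
#' sigmoid bounded in \code{(0, z_max)}, with midpoint \code{act_center} and
#' steepness \code{act_slope}.
#'
#' @param u Membrane input (numeric, vectorized).
#' @param params A [network_params()] object supplying \code{act_slope},
#'   \code{act_center} and \code{z_max}.
#' @return Firing rate(s) in \code{(0, z_max)}.
#' @export
#' @examples
#' p <- network_params(act_slope = 0.3, act_center = 20)
#' activation(20, p)  # midpoint: 0.5 * z_max
activation <- function(u, params) {
  validate_params(params)
  params$z_max / (1 + exp(-params$act_slope * (u - params$act_center)))
}

#' Construct a network state
#'
#' @param u Named numeric of membrane inputs for units
#'   \code{a, v, m, Ia, Iv}.
#' @param q Named numeric of slow feedback-inhibition traces \code{a, v}.
#' @param t Current simulation time (ms).
#' @return An object of class \code{msidev_state} with fields \code{u},
#'   \code{q}, \code{t} and derived firing rates \code{z} (filled by
#'   [step_state()] / [rest_state()]).
#' @export
network_state <- function(u = c(a = 0, v = 0, m = 0, Ia = 0, Iv = 0),
                          q = c(a = 0, v = 0), t = 0) {
  u <- u[c("a", "v", "m", "Ia", "Iv")]
  q <- q[c("a", "v")]
  if (anyNA(u) || anyNA(q)) stop("state requires units a, v, m, Ia, Iv and traces a, v")
  structure(list(u = u, q = q, t = t), class = "msidev_state")
}

state_rates <- function(state, params) {
  activation(state$u, params)
}

net_inputs <- function(z, q, ext, params) {
  c(a  = params$i0_a * ext[["a"]] + params$w_av * z[["v"]] - params$l_v * q[["v"]],
    v  = params$i0_v * ext[["v"]] + params$w_va * z[["a"]] - params$l_a * q[["a"]],
    m  = params$w_ma * z[["a"]] + params$w_mv * z[["v"]],
    Ia = params$w_Ia * z[["a"]] - params$l_va * z[["Iv"]],
    Iv = params$w_Iv * z[["v"]] - params$l_av * z[["Ia"]])
}

#' One explicit-Euler step of the network dynamics
#'
#' Reference (pure-R) update used for testing and didactics; the bulk
#' simulation entry point [simulate_events()] runs the identical scheme in
#' compiled code.  All five units relax toward their net input with time
#' constant \code{tau_fast}; the two slow traces low-pass filter the
#' interneuron rates with \code{tau_slow}.
#'
#' @param state An \code{msidev_state}.
#' @param ext Named numeric \code{c(a=, v=)} of external input amplitudes
#'   (multiplied by the stimulus efficacies \code{i0_a}, \code{i0_v}).
#' @param params A [network_params()] object.
#' @param dt Step size in ms; \code{dt = 0} returns the state unchanged.
#' @return The updated \code{msidev_state}.
#' @export
step_state <- function(state, ext = c(a = 0, v = 0), params, dt = 1) {
  validate_params(params)
  if (!is.finite(dt) || dt < 0) stop("dt must be a nonnegative finite number")
  if (!all(is.finite(state$u)) || !all(is.finite(state$q)))
    stop("non-finite state")
  if (dt == 0) return(state)
  z <- state_rates(state, params)
  net <- net_inputs(z, state$q, ext, params)
  u <- state$u + dt / params$tau_fast * (net - state$u)
  q <- state$q + dt / params$tau_slow * (z[c("Ia", "Iv")] - state$q)
  names(q) <- c("a", "v")
  network_state(u = u, q = q, t = state$t + dt)
}

#' Zero-input resting state
#'
#' Finds the fixed point of the dynamics under zero external input by damped
#' fixed-point iteration on the membrane inputs (the slow traces settle to
#' the interneuron rates).  Used to initialize every simulation; a settling
#' period still precedes each trial's first stimulus.
#'
#' @param params A [network_params()] object.
#' @param tol Convergence tolerance on the membrane inputs.
#' @return An \code{msidev_state} at the resting fixed point.
#' @export
rest_state <- function(params, tol = 1e-12) {
  validate_params(params)
  u <- c(a = 0, v = 0, m = 0, Ia = 0, Iv = 0)
  q <- c(a = 0, v = 0)
  ext <- c(a = 0, v = 0)
  for (i in seq_len(10000)) {
    z <- params$z_max / (1 + exp(-params$act_slope * (u - params$act_center)))
    qn <- 0.5 * q + 0.5 * z[c("Ia", "Iv")]
    names(qn) <- c("a", "v")
    un <- 0.5 * u + 0.5 * net_inputs(z, qn, ext, params)
    if (max(abs(un - u), abs(qn - q)) < tol) { u <- un; q <- qn; break }
    u <- un; q <- qn
  }
  network_state(u = u, q = q, t = 0)
}

#' Build a stimulus event list
#'
#' @param modality Character vector of \code{"A"}, \code{"V"} or \code{"AV"}.
#' @param onset Numeric vector of onsets (ms).
#' @param duration Pulse duration(s) in ms (default 60, the protocol value).
#' @param efficacy Per-event input amplitude scale (default 1 on each active
#'   channel; audiovisual events drive both channels with equal efficacy).
#' @return A data.frame of class \code{msidev_events}.
#' @export
stim_events <- function(modality, onset, duration = 60, efficacy = 1) {
  modality <- match.arg(as.character(modality), c("A", "V", "AV"),
                        several.ok = TRUE)
  n <- length(onset)
  ev <- data.frame(modality = rep_len(modality, n),
                   onset = as.numeric(onset),
                   duration = rep_len(as.numeric(duration), n),
                   efficacy = rep_len(as.numeric(efficacy), n))
  if (any(ev$duration <= 0)) stop("pulse_duration must be > 0")
  if (any(ev$onset < 0)) stop("onsets must be >= 0")
  class(ev) <- c("msidev_events", "data.frame")
  ev[order(ev$onset), , drop = FALSE]
}

# amplitude vector for one channel across the step grid; errors on overlap
channel_drive <- function(events, channel, n_steps, dt) {
  amp <- numeric(n_steps)
  hit <- events$modality %in% c(channel, "AV")
  sub <- events[hit, , drop = FALSE]
  if (nrow(sub) > 1) {
    o <- order(sub$onset)
    s <- sub[o, ]
    if (any(s$onset[-1] < (s$onset + s$duration)[-nrow(s)]))
      stop("overlapping stimulus events on channel ", channel)
  }
  for (i in seq_len(nrow(sub))) {
    from <- floor(sub$onset[i] / dt) + 1
    to <- min(n_steps, ceiling((sub$onset[i] + sub$duration[i]) / dt))
    if (from <= n_steps) amp[from:min(to, n_steps)] <- sub$efficacy[i]
  }
  amp
}

# seeded, infinitesimal interneuron jitter at each stimulus onset, used to
# break the winner-takes-all symmetry for audiovisual inputs; leaves the
# global RNG untouched
onset_jitters <- function(n, jitter_seed, amplitude = 1e-6) {
  if (n == 0) return(list(a = numeric(0), v = numeric(0)))
  runif_local <- function(k, min, max) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old))
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(jitter_seed)
    list(mag = runif(k, 0.5 * amplitude, amplitude),
         sgn = sign(runif(k) - 0.5))
  }
  d <- runif_local(n)
  sgn <- ifelse(d$sgn == 0, 1, d$sgn)
  list(a = d$mag * sgn, v = -d$mag * sgn)
}

#' Simulate the network response to a stimulus protocol
#'
#' Integrates the full network over \code{[0, duration]} with explicit Euler
#' steps of size \code{dt} (compiled core).  External input on a channel is
#' the event's efficacy during \code{[onset, onset + duration)} and 0
#' elsewhere.  At each stimulus onset an infinitesimal seeded jitter
#' (\code{<= 1e-6}, equal magnitude and opposite sign on the two
#' interneurons) breaks the winner-takes-all symmetry for audiovisual
#' stimuli; the simulation is deterministic given \code{jitter_seed}.
#'
#' @param events An [stim_events()] data.frame (all within the duration).
#' @param params A [network_params()] object.
#' @param duration Total simulated time (ms); must be a multiple of \code{dt}.
#' @param dt Euler step (ms), default 1.
#' @param init Initial \code{msidev_state}; defaults to [rest_state()].
#' @param jitter_seed Integer seed for the onset jitters.
#' @param jitter Optional list with numeric vectors \code{a} and \code{v}
#'   (one entry per event) overriding the seeded jitters; used e.g. to mirror
#'   the symmetry breaking when simulating a modality-swapped protocol.
#' @return An object of class \code{msidev_trace}: a data.frame with columns
#'   \code{t_ms, z_a, z_v, z_m, z_Ia, z_Iv, q_a, q_v} on the uniform time
#'   grid, with the event list, \code{dt} and final state as attributes.
#' @export
#' @examples
#' p <- network_params("td_child")
#' tr <- simulate_events(stim_events("A", 500), p, duration = 1500)
#' max(tr$z_m)
simulate_events <- function(events, params, duration, dt = 1,
                            init = rest_state(params), jitter_seed = 1L,
                            jitter = NULL) {
  validate_params(params)
  if (!inherits(events, "msidev_events")) stop("events must come from stim_events()")
  if (dt <= 0) stop("dt must be > 0")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) stop("dt must divide duration")
  n_steps <- as.integer(round(n_steps))
  if (nrow(events) && any(events$onset + events$duration > duration + 1e-9))
    stop("events must lie within [0, duration]")
  ext_a <- channel_drive(events, "A", n_steps, dt)
  ext_v <- channel_drive(events, "V", n_steps, dt)
  jit <- if (is.null(jitter)) onset_jitters(nrow(events), jitter_seed)
         else jitter
  if (length(jit$a) != nrow(events) || length(jit$v) != nrow(events))
    stop("jitter must supply one value per event and channel")
  jstep <- as.integer(floor(events$onset / dt))
  o <- order(jstep)
  res <- cpp_simulate(unname(init$u), unname(init$q), ext_a, ext_v,
                      par_vec(params), dt,
                      jstep[o], jit$a[o], jit$v[o], TRUE)
  tr <- as.data.frame(res$trace)
  names(tr) <- c("z_a", "z_v", "z_m", "z_Ia", "z_Iv", "q_a", "q_v")
  tr <- cbind(t_ms = seq(0, duration, by = dt), tr)
  final <- network_state(
    u = stats::setNames(res$u, c("a", "v", "m", "Ia", "Iv")),
    q = stats::setNames(res$q, c("a", "v")),
    t = init$t + duration)
  structure(tr, class = c("msidev_trace", "data.frame"),
            dt = dt, events = events, final_state = final,
            z_max = params$z_max)
}

#' Write a simulation trace to CSV
#'
#' Columns: \code{t_ms, z_a, z_v, z_m, z_Ia, z_Iv, q_a, q_v}.
#'
#' @param trace An \code{msidev_trace}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "msidev_trace")) stop("not an msidev_trace")
  utils::write.csv(as.data.frame(trace)[, c("t_ms", "z_a", "z_v", "z_m",
                                            "z_Ia", "z_Iv", "q_a", "q_v")],
                   path, row.names = FALSE)
  invisible(path)
}
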