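#' Threshold-crossing reaction time from a simulation trace
#'
#' The simulated reaction time is the interval between stimulus onset and
#' the first instant at which the output unit's activity reaches the
#' detection threshold \code{phi * z_max} (default 10 percent of the maximum
#' activity).  The crossing time is linearly interpolated between grid
#' samples so RTs are not quantized by the integration step.  If no crossing
#' occurs within \code{window} ms of the onset the trial is a timeout and
#' \code{NA} is returned.
#'
#' @param trace An \code{msidev_trace} from [simulate_events()].
#' @param stimulus_onset Onset time (ms); must lie inside the trace.
#' @param phi Threshold as a fraction of \code{z_max} (default 0.10).
#' @param window Response window after onset (ms, default 1000).
#' @return RT in ms, or \code{NA_real_} on timeout.
#' @export
#' @examples
#' p <- network_params("td_child")
#' tr <- simulate_events(stim_events("AV", 500), p, duration = 2000)
#' detect_rt(tr, 500)
detect_rt <- function(trace, stimulus_onset, phi = 0.10, window = 1000) {
  if (!inherits(trace, "msidev_trace")) stop("not an msidev_trace")
  if (!(phi > 0 && phi < 1)) stop("phi must lie in (0, 1)")
  t <- trace$t_ms
  if (stimulus_onset < t[1] || stimulus_onset > t[length(t)])
    stop("stimulus_onset lies outside the trace")
  zmax <- attr(trace, "z_max")
  if (is.null(zmax)) zmax <- 1
  thr <- phi * zmax
  z <- trace$z_m
  sel <- which(t >= stimulus_onset & t <= stimulus_onset + window & z >= thr)
  if (!length(sel)) return(NA_real_)
  i <- sel[1]
  if (i == 1 || z[i - 1] >= thr) return(t[i] - stimulus_onset)
  tc <- t[i - 1] + (t[i] - t[i - 1]) * (thr - z[i - 1]) / (z[i] - z[i - 1])
  tc <- max(tc, stimulus_onset)
  tc - stimulus_onset
}

# winner of the interneuron competition around a stimulus onset
trace_winner <- function(trace, onset, span = 300) {
  sel <- trace$t_ms >= onset & trace$t_ms <= onset + span
  if (!any(sel)) return(NA_character_)
  if (max(trace$z_Ia[sel]) >= max(trace$z_Iv[sel])) "A" else "V"
}

#' Simulate one repeat/switch trial and read out both reaction times
#'
#' Runs a settling period, the first stimulus, the inter-stimulus interval
#' and the second stimulus as one continuous simulation (so the slow
#' feedback-inhibition traces built by the first stimulus act on the
#' second), and applies [detect_rt()] at both onsets.
#'
#' @param params A [network_params()] object.
#' @param pair A [make_condition_pair()] trial pair.
#' @param dt Euler step (ms).
#' @param settle Settling time before the first stimulus (ms, default 500).
#' @param phi,window Threshold fraction and response window for
#'   [detect_rt()].
#' @param stim_duration Pulse duration (ms, default 60).
#' @param jitter_seed Seed for the winner-takes-all onset jitters.
#' @return List with \code{rt_first}, \code{rt_second} (ms, \code{NA} on
#'   timeout), \code{timeout_first}, \code{timeout_second}, the interneuron
#'   \code{winner_first}/\code{winner_second}, the condition label and the
#'   trace.
#' @export
run_condition <- function(params, pair, dt = 1, settle = 500, phi = 0.10,
                          window = 1000, stim_duration = 60,
                          jitter_seed = 1L) {
  if (!inherits(pair, "msidev_pair")) stop("pair must come from make_condition_pair()")
  onsets <- c(settle, settle + pair$isi)
  duration <- settle + pair$isi + window + 200
  ev <- stim_events(c(pair$first_modality, pair$second_modality),
                    onset = onsets, duration = stim_duration)
  tr <- simulate_events(ev, params, duration = duration, dt = dt,
                        jitter_seed = jitter_seed)
  rt1 <- detect_rt(tr, onsets[1], phi = phi, window = window)
  rt2 <- detect_rt(tr, onsets[2], phi = phi, window = window)
  list(rt_first = rt1, rt_second = rt2,
       timeout_first = is.na(rt1), timeout_second = is.na(rt2),
       winner_first = trace_winner(tr, onsets[1]),
       winner_second = trace_winner(tr, onsets[2]),
       condition = pair$condition, trace = tr)
}

rt_undefined <- function(what) {
  warning("undefined ", what, ": timeout input", call. = FALSE)
  NA_real_
}

#' Modality switch cost
#'
#' Difference between the switch-trial and repeat-trial reaction times;
#' positive values mean switching is slower.
#'
#' @param rt_switch,rt_repeat RTs in ms.
#' @return \code{rt_switch - rt_repeat} (ms); \code{NA} with a warning if an
#'   input is a timeout.
#' @export
switch_cost <- function(rt_switch, rt_repeat) {
  if (is.na(rt_switch) || is.na(rt_repeat)) return(rt_undefined("switch cost"))
  rt_switch - rt_repeat
}

#' Multisensory gain
#'
#' RT advantage of the audiovisual stimulus over the best unisensory
#' stimulus; positive values mean facilitation, negative values competition.
#'
#' @param rt_av,rt_a,rt_v RTs in ms.
#' @return \code{min(rt_a, rt_v) - rt_av} (ms); \code{NA} with a warning if
#'   an input is a timeout.
#' @export
multisensory_gain <- function(rt_av, rt_a, rt_v) {
  if (is.na(rt_av) || is.na(rt_a) || is.na(rt_v))
    return(rt_undefined("multisensory gain"))
  min(rt_a, rt_v) - rt_av
}
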