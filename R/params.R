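#' Network parameters for the audiovisual interaction model
#'
#' Builds the full synaptic and biophysical parameter set of the five-unit
#' firing-rate network: auditory and visual input units (A, V), a multisensory
#' output unit (M) and two modality-specific inhibitory interneurons (Ia, Iv)
#' whose output is low-pass filtered into slow feedback-inhibition traces.
#'
#' Three named presets are shipped.  \code{"td_child"} is the immature
#' configuration (cross-modal synapses inhibitory, weak feedforward and
#' feedback efficacies) used as the starting point of typically-developing
#' training; \code{"asd_child"} differs only in strictly more inhibitory
#' cross-modal synapses; \code{"adult"} is the mature configuration with
#' excitatory cross-modal synapses and strengthened feedforward and feedback
#' efficacies.  All preset values are calibrated for this realization of the
#' model so that the immature network shows no multisensory facilitation and
#' only a small unisensory switch cost, while the mature network shows clear
#' facilitation; see the package vignette for the calibration rationale.
#'
#' @param preset Name of a shipped preset (\code{"td_child"},
#'   \code{"asd_child"}, \code{"adult"}), or \code{NULL} to start from
#'   \code{"td_child"} values.
#' @param ... Named overrides for individual fields (e.g. \code{w_av = -10}).
#'
#' @return An object of class \code{msidev_params}: a named list with fields
#'   \describe{
#'     \item{w_ma, w_mv}{feedforward efficacy from A/V to M (>= 0).}
#'     \item{w_av, w_va}{signed cross-modal efficacy (\code{w_av}: V to A,
#'       \code{w_va}: A to V); negative = competition, positive =
#'       facilitation.}
#'     \item{w_Ia, w_Iv}{efficacy from input unit to its same-modality
#'       interneuron (>= 0).}
#'     \item{l_av, l_va}{mutual winner-takes-all inhibition between
#'       interneurons (>= 0); \code{l_av} inhibits Iv from Ia, \code{l_va}
#'       inhibits Ia from Iv.}
#'     \item{l_a, l_v}{slow feedback inhibition magnitude from the Ia / Iv
#'       trace onto the opposite-modality input unit (>= 0).}
#'     \item{tau_fast, tau_slow}{time constants (ms) of unit dynamics and of
#'       the slow inhibition traces; \code{tau_slow > tau_fast}.}
#'     \item{act_slope, act_center}{logistic activation parameters.}
#'     \item{z_max}{maximum firing rate (normalized, 1).}
#'     \item{i0_a, i0_v}{external stimulus efficacies.}
#'   }
#' @export
#' @examples
#' p <- network_params("td_child")
#' p$w_av   # inhibitory in the immature network
network_params <- function(preset = NULL, ...) {
  base <- .msidev_presets[["td_child"]]
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(.msidev_presets))
    base <- .msidev_presets[[preset]]
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad))
      stop("unknown network parameter(s): ", paste(bad, collapse = ", "))
    base[names(dots)] <- dots
  }
  p <- structure(base, class = "msidev_params")
  validate_params(p)
  p
}

# Calibrated presets.  The immature ("child") configurations carry inhibitory
# cross-modal synapses (more so in the ASD preset) and weak feedforward /
# feedback efficacies; the adult preset sits at the saturation bounds the
# training loop converges to.
.msidev_presets <- list(
  td_child = list(
    w_ma = 7.7, w_mv = 7.7, w_av = -18, w_va = -18,
    w_Ia = 150, w_Iv = 150, l_av = 260, l_va = 260, l_a = 1, l_v = 1,
    tau_fast = 15, tau_slow = 1200, act_slope = 0.3, act_center = 11.5,
    z_max = 1, i0_a = 15, i0_v = 15),
  asd_child = list(
    w_ma = 7.7, w_mv = 7.7, w_av = -21, w_va = -21,
    w_Ia = 150, w_Iv = 150, l_av = 260, l_va = 260, l_a = 1, l_v = 1,
    tau_fast = 15, tau_slow = 1200, act_slope = 0.3, act_center = 11.5,
    z_max = 1, i0_a = 15, i0_v = 15),
  adult = list(
    w_ma = 8, w_mv = 8, w_av = 1.5, w_va = 1.5,
    w_Ia = 150, w_Iv = 150, l_av = 260, l_va = 260, l_a = 2.5, l_v = 2.5,
    tau_fast = 15, tau_slow = 1200, act_slope = 0.3, act_center = 11.5,
    z_max = 1, i0_a = 15, i0_v = 15))

#' Validate a network parameter set
#'
#' Checks sign and positivity constraints: nonnegative feedforward,
#' interneuron-drive, winner-takes-all and feedback efficacies; positive time
#' constants with \code{tau_slow > tau_fast}; positive \code{z_max} and
#' \code{act_slope}; all values finite.  Cross-modal efficacies may take
#' either sign.
#'
#' @param p An object from [network_params()].
#' @return \code{p}, invisibly, or an error describing the violation.
#' @export
validate_params <- function(p) {
  if (!inherits(p, "msidev_params")) stop("not an msidev_params object")
  need <- names(.msidev_presets$td_child)
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  vals <- unlist(p[need])
  if (!all(is.finite(vals))) stop("non-finite network parameter")
  nonneg <- c("w_ma", "w_mv", "w_Ia", "w_Iv", "l_av", "l_va", "l_a", "l_v")
  for (nm in nonneg)
    if (p[[nm]] < 0) stop(nm, " must be >= 0")
  if (p$tau_fast <= 0 || p$tau_slow <= 0) stop("time constants must be > 0")
  if (p$tau_slow <= p$tau_fast) stop("tau_slow must exceed tau_fast")
  if (p$z_max <= 0) stop("z_max must be > 0")
  if (p$act_slope <= 0) stop("act_slope must be > 0")
  invisible(p)
}

# fixed positional layout shared with the compiled integrator
par_vec <- function(p) {
  as.numeric(c(p$w_ma, p$w_mv, p$w_av, p$w_va, p$w_Ia, p$w_Iv,
               p$l_av, p$l_va, p$l_a, p$l_v,
               p$tau_fast, p$tau_slow, p$act_slope, p$act_center, p$z_max,
               p$i0_a, p$i0_v))
}

#' @export
print.msidev_params <- function(x, ...) {
  regime <- if (x$w_av > 0 && x$w_va > 0) "facilitative (excitatory cross-modal)"
  else if (x$w_av < 0 && x$w_va < 0) "competitive (inhibitory cross-modal)"
  else "mixed cross-modal"
  cat("Audiovisual network parameters —", regime, "\n")
  cat(sprintf("  feedforward   w_ma = %.3g, w_mv = %.3g\n", x$w_ma, x$w_mv))
  cat(sprintf("  cross-modal   w_av = %.3g, w_va = %.3g\n", x$w_av, x$w_va))
  cat(sprintf("  interneurons  w_Ia = %.3g, w_Iv = %.3g, WTA l_av = %.3g, l_va = %.3g\n",
              x$w_Ia, x$w_Iv, x$l_av, x$l_va))
  cat(sprintf("  feedback inh  l_a = %.3g, l_v = %.3g (tau_slow = %.0f ms)\n",
              x$l_a, x$l_v, x$tau_slow))
  cat(sprintf("  units         tau_fast = %.0f ms, activation slope %.3g / center %.3g, z_max = %.3g\n",
              x$tau_fast, x$act_slope, x$act_center, x$z_max))
  cat(sprintf("  stimuli       i0_a = %.3g, i0_v = %.3g\n", x$i0_a, x$i0_v))
  invisible(x)
}

#' Swap the auditory and visual sides of a parameter set
#'
#' Exchanges every A-labelled parameter with its V-labelled counterpart.
#' Useful for symmetry checks: simulating a mirrored stimulus protocol under
#' swapped parameters must reproduce the original traces with the unit roles
#' exchanged.
#'
#' @param p An object from [network_params()].
#' @return The mirrored \code{msidev_params} object.
#' @export
swap_modalities <- function(p) {
  validate_params(p)
  q <- p
  swp <- function(a, b) { tmp <- q[[a]]; q[[a]] <<- q[[b]]; q[[b]] <<- tmp }
  swp("w_ma", "w_mv"); swp("w_av", "w_va"); swp("w_Ia", "w_Iv")
  swp("l_av", "l_va"); swp("l_a", "l_v"); swp("i0_a", "i0_v")
  q
}
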