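#' Conditions of the repeat/switch trial battery
#'
#' The six two-stimulus conditions: for each modality (A, V, AV) a repeat
#' trial (same modality twice) and a switch trial (the second stimulus
#' changes modality: A-switch is V then A, V-switch is A then V, AV-switch is
#' a unisensory stimulus followed by AV).
#' @export
trial_conditions <- c("A-repeat", "A-switch", "V-repeat", "V-switch",
                      "AV-repeat", "AV-switch")

#' Sample an inter-stimulus interval
#'
#' Uniform draw on \code{[lo, hi]} ms, matching the task's 1-3 s range with
#' mean 2 s.  Draws come from the session RNG, so seed with
#' \code{set.seed()} for reproducibility.
#'
#' @param n Number of draws.
#' @param lo,hi Interval bounds in ms (defaults 1000 and 3000).
#' @return Numeric vector of ISIs (ms).
#' @export
sample_isi <- function(n = 1, lo = 1000, hi = 3000) {
  if (!(lo > 0) || lo > hi) stop("require 0 < lo <= hi")
  stats::runif(n, lo, hi)
}

#' Build a two-stimulus trial pair for a named condition
#'
#' @param condition One of [trial_conditions].
#' @param isi Inter-stimulus interval in ms (test-battery default 2000).
#' @param av_switch_from For \code{"AV-switch"}, the modality of the first
#'   (unisensory) stimulus; the battery default is \code{"V"} and both
#'   variants can be averaged by the caller.
#' @return An object of class \code{msidev_pair}: list with
#'   \code{first_modality}, \code{second_modality}, \code{isi},
#'   \code{condition}.
#' @export
#' @examples
#' make_condition_pair("A-switch")   # V then A
make_condition_pair <- function(condition, isi = 2000, av_switch_from = "V") {
  condition <- match.arg(condition, trial_conditions)
  if (!is.numeric(isi) || isi <= 0) stop("isi must be positive")
  av_switch_from <- match.arg(av_switch_from, c("V", "A"))
  pair <- switch(condition,
    "A-repeat"  = c("A", "A"),
    "A-switch"  = c("V", "A"),
    "V-repeat"  = c("V", "V"),
    "V-switch"  = c("A", "V"),
    "AV-repeat" = c("AV", "AV"),
    "AV-switch" = c(av_switch_from, "AV"))
  structure(list(first_modality = pair[1], second_modality = pair[2],
                 isi = isi, condition = condition),
            class = "msidev_pair")
}

#' Stimulus-mix specification
#'
#' Probabilities of audiovisual, auditory-only and visual-only exposures in a
#' training phase; must sum to one.
#'
#' @param p_av,p_a,p_v Exposure probabilities.
#' @return An object of class \code{msidev_mix}.
#' @export
#' @examples
#' mix_spec(0.30, 0.20, 0.50)  # typical development
mix_spec <- function(p_av, p_a, p_v) {
  p <- c(p_av = p_av, p_a = p_a, p_v = p_v)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("mix probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop("mix probabilities must sum to 1 (got ", sum(p), ")")
  structure(as.list(p), class = "msidev_mix")
}

#' Phase schedule of stimulus mixes
#'
#' @param start_epoch Integer vector of phase start epochs; must begin at 0
#'   and be strictly increasing.
#' @param mixes List of [mix_spec()] objects, one per phase.
#' @return Object of class \code{msidev_mix_schedule}.
#' @export
mix_schedule <- function(start_epoch, mixes) {
  if (inherits(mixes, "msidev_mix")) mixes <- list(mixes)
  if (length(start_epoch) == 0 || length(start_epoch) != length(mixes))
    stop("one start epoch per mix phase required")
  if (start_epoch[1] != 0) stop("schedule must start at epoch 0")
  if (is.unsorted(start_epoch, strictly = TRUE))
    stop("phase start epochs must be strictly increasing")
  ok <- vapply(mixes, inherits, logical(1), "msidev_mix")
  if (!all(ok)) stop("mixes must be mix_spec() objects")
  structure(list(start_epoch = as.integer(start_epoch), mixes = mixes),
            class = "msidev_mix_schedule")
}

phase_mix <- function(schedule, epoch) {
  idx <- findInterval(epoch, schedule$start_epoch)
  schedule$mixes[[max(1L, idx)]]
}

#' Generate a seeded training exposure stream
#'
#' Draws one stimulus modality per epoch from the mix of the phase covering
#' that epoch, with an ISI to the next exposure sampled by [sample_isi()].
#' Exposures form one continuous session so that the slow feedback traces
#' carry across them.
#'
#' @param schedule A [mix_schedule()] (or a single [mix_spec()] used for all
#'   epochs).
#' @param n_epochs Number of exposures (one epoch = one exposure).
#' @param seed Optional integer seed applied via \code{set.seed()}.
#' @param isi_lo,isi_hi ISI range in ms (default 1000-3000).
#' @param stratified If \code{TRUE} (default) each phase contains the exact
#'   mix proportions (largest-remainder apportionment) in randomized order,
#'   so cohort comparisons are not confounded by sampling noise in the
#'   stream composition; \code{FALSE} draws each exposure independently
#'   from the mix probabilities.
#' @return Data.frame with columns \code{epoch} (1-based), \code{modality}
#'   and \code{isi_ms} (interval to the next exposure onset).
#' @export
make_training_stream <- function(schedule, n_epochs, seed = NULL,
                                 isi_lo = 1000, isi_hi = 3000,
                                 stratified = TRUE) {
  if (inherits(schedule, "msidev_mix")) schedule <- mix_schedule(0L, schedule)
  if (!inherits(schedule, "msidev_mix_schedule"))
    stop("schedule must be a mix_schedule()")
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mods <- character(n_epochs)
  for (ph in seq_along(schedule$start_epoch)) {
    from <- schedule$start_epoch[ph] + 1L
    to <- if (ph < length(schedule$start_epoch))
      schedule$start_epoch[ph + 1L] else n_epochs
    if (from > n_epochs) break
    to <- min(to, n_epochs)
    m <- schedule$mixes[[ph]]
    k <- to - from + 1L
    if (stratified) {
      p <- c(AV = m$p_av, A = m$p_a, V = m$p_v)
      n_exact <- floor(p * k)
      rem <- k - sum(n_exact)
      if (rem > 0) {
        frac <- p * k - n_exact
        top <- order(frac, decreasing = TRUE)[seq_len(rem)]
        n_exact[top] <- n_exact[top] + 1L
      }
      mods[from:to] <- sample(rep(names(n_exact), n_exact))
    } else {
      mods[from:to] <- sample(c("AV", "A", "V"), k, replace = TRUE,
                              prob = c(m$p_av, m$p_a, m$p_v))
    }
  }
  data.frame(epoch = seq_len(n_epochs), modality = mods,
             isi_ms = sample_isi(n_epochs, isi_lo, isi_hi))
}

#' Write a training stream to CSV
#' @param stream Data.frame from [make_training_stream()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_stream <- function(stream, path) {
  utils::write.csv(stream[, c("epoch", "modality", "isi_ms")], path,
                   row.names = FALSE)
  invisible(path)
}
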