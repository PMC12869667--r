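#' Read an empirical reference RT table
#'
#' Reads a CSV with schema \code{cohort, age_group, condition,
#' median_rt_ms} (one row per cell; a logical \code{timeout} column is
#' optional) and validates that all 24 cells of one cohort are present.
#'
#' @param path CSV file path.
#' @return An \code{rt_trajectory}.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rt_trajectory(df)
}

#' Write an RT trajectory to CSV
#'
#' @param traj An \code{rt_trajectory}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "rt_trajectory")) stop("not an rt_trajectory")
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic reference RT table
#'
#' Produces a plausible 24-cell median-RT table on the empirical scale
#' (hundreds of ms) obeying the developmental orderings: RT decreasing with
#' age; unisensory switch cost positive and growing; negligible audiovisual
#' switch cost; no multisensory gain in the youngest group and positive
#' gain in adults.  The \code{"ASD-like"} style is slower than
#' \code{"TD-like"} at the two middle age groups and converges at the adult
#' row.  This is a synthetic stand-in for unpublished empirical tables,
#' intended for tests and worked examples; it is not measured data.
#'
#' @param style \code{"TD-like"} or \code{"ASD-like"}.
#' @param seed Integer seed for the small reproducible cell noise.
#' @return An \code{rt_trajectory} with cohort name equal to \code{style}.
#' @export
#' @examples
#' ref <- make_fixture_reference("TD-like", seed = 1)
#' attr(check_trajectory(ref), "ok")
make_fixture_reference <- function(style = c("TD-like", "ASD-like"),
                                   seed = 1L) {
  style <- match.arg(style)
  set.seed(seed)
  # base unisensory repeat RTs by age group (ms)
  base_a <- c(520, 470, 420, 350)
  base_v <- base_a + 15
  ucost <- c(15, 30, 45, 60)          # unisensory switch cost, grows with age
  gain <- c(0, 8, 20, 45)             # multisensory gain emerges with age
  avcost <- c(1, 1.5, 2, 2.5)         # audiovisual switch cost stays negligible
  delay <- if (style == "ASD-like") c(25, 60, 55, 0) else c(0, 0, 0, 0)
  noise <- function() stats::runif(4, 0, 2)
  rt_a <- base_a + delay + noise()
  rt_v <- base_v + delay + noise()
  rt_av <- pmin(rt_a, rt_v) - gain
  rows <- data.frame(
    cohort = style,
    age_group = rep(age_groups, times = 6),
    condition = rep(trial_conditions, each = 4),
    median_rt_ms = c(rt_a, rt_a + ucost, rt_v, rt_v + ucost,
                     rt_av, rt_av + avcost))
  rt_trajectory(rows)
}
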