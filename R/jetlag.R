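#' Kinetic rate presets for the three jet-lag scenarios
#'
#' Per-entity activation/inhibition constants (per hour) of the continuous
#' transitions. The normal preset is the baseline calibration of the
#' undisrupted clock; the mild and chronic presets lower the activation
#' rates and raise the inhibition rates of the light-sensitive clock
#' proteins (BMAL1, PER-CRY, REV-ERBs) with increasing severity, while
#' CLOCK-BMAL1, Myc and p53 keep unit rates throughout.
#'
#' @param name one of \code{"normal"}, \code{"mild"}, \code{"chronic"}.
#' @return data.frame with columns \code{entity}, \code{activation},
#'   \code{inhibition}.
#' @examples
#' rate_preset("chronic")
#' @export
rate_preset <- function(name = c("normal", "mild", "chronic")) {
  name <- match.arg(name)
  ents <- c("Bmal", "CB", "PC", "Rev", "Myc", "p53")
  act <- switch(name,
    normal = c(1, 1, 0.97, 0.97, 1, 1),
    mild = c(0.50, 1, 0.40, 0.40, 1, 1),
    chronic = c(0.15, 1, 0.20, 0.20, 1, 1))
  inh <- switch(name,
    normal = c(1, 1, 1, 1, 1, 1),
    mild = c(1.3, 1, 1.3, 1, 1, 1),
    chronic = c(2, 1, 2, 1, 1, 1))
  data.frame(entity = ents, activation = act, inhibition = inh,
             stringsAsFactors = FALSE)
}

place_col <- function(traj, entity) {
  col <- paste0("P_", entity)
  if (!col %in% names(traj))
    stop("trajectory has no place for entity: ", entity)
  traj[[col]]
}

## indices of strict local maxima of y
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
}

#' Oscillation period of an entity's trajectory
#'
#' Mean spacing of successive local maxima of the entity's place marking
#' after the transient. Returns \code{NA} (no oscillation) when fewer than
#' two maxima are detected.
#'
#' @param traj a \code{tcpn_trajectory}.
#' @param entity entity name.
#' @param transient initial stretch (hours) excluded from the analysis.
#' @return period in hours, or \code{NA_real_}.
#' @export
compute_period <- function(traj, entity, transient = 24) {
  y <- place_col(traj, entity)
  keep <- traj$time >= transient
  tt <- traj$time[keep]
  pk <- local_maxima(y[keep])
  if (length(pk) < 2L) return(NA_real_)
  mean(diff(tt[pk]))
}

#' Peak clock time of an oscillating entity
#'
#' Circular mean of the per-cycle times of maximal expression, reported
#' modulo the gate period (hours after midnight).
#'
#' @inheritParams compute_period
#' @param period clock period in hours used for the modulo.
#' @return clock time in [0, period), or \code{NA_real_} when no
#'   oscillation is detected.
#' @export
peak_time <- function(traj, entity, transient = 24, period = 24) {
  y <- place_col(traj, entity)
  keep <- traj$time >= transient
  tt <- traj$time[keep]
  pk <- local_maxima(y[keep])
  if (length(pk) < 1L) return(NA_real_)
  ang <- 2 * pi * (tt[pk] %% period) / period
  mu <- atan2(mean(sin(ang)), mean(cos(ang)))
  (mu * period / (2 * pi)) %% period
}

#' Persistence index of an expression trace
#'
#' Ratio of the minimum to the maximum marking over a set of time windows:
#' 1 for a perfectly flat (persistent) signal, 0 for one that collapses to
#' zero inside a window. Operationalizes "persistently high expression".
#'
#' @inheritParams compute_period
#' @param windows list of length-2 numeric vectors \code{c(from, to)} in
#'   hours.
#' @return ratio in [0, 1].
#' @export
persistence_index <- function(traj, entity,
                              windows = list(c(10, 20), c(30, 40),
                                             c(50, 60), c(80, 90))) {
  y <- place_col(traj, entity)
  sel <- rep(FALSE, length(y))
  for (w in windows) {
    stopifnot(length(w) == 2L)
    inw <- traj$time >= w[1] & traj$time <= w[2]
    if (!any(inw))
      stop("empty window [", w[1], ", ", w[2], "] for this trajectory")
    sel <- sel | inw
  }
  hi <- max(y[sel])
  if (hi == 0) return(0)
  min(y[sel]) / hi
}

clock_entities <- function() c("Bmal", "CB", "PC", "Rev")

#' Run one jet-lag scenario end to end
#'
#' Pipeline: designated logical model -> timed continuous Petri net ->
#' preset rates -> default gate schedule -> simulation -> oscillation
#' metrics. The first \code{transient} hours (one full period from the
#' all-zero initial marking) are excluded from all metrics.
#'
#' @param preset preset name (\code{"normal"}, \code{"mild"},
#'   \code{"chronic"}) or a rate data.frame such as
#'   \code{\link{severity_rates}} returns.
#' @param horizon simulation horizon in hours (>= 3 periods).
#' @param step output sampling step in hours.
#' @param transient hours discarded before computing metrics.
#' @param gates gate schedule (default \code{\link{default_gate_schedule}}).
#' @return object of class \code{scenario_result}: the trajectory plus a
#'   per-entity metrics table (period, peak clock time, peak/trough values,
#'   amplitude) and the Myc/p53 anti-phase score (Pearson correlation of
#'   the two markings after the transient; negative = opposite behavior).
#' @examples
#' \donttest{
#' res <- run_scenario("normal", horizon = 120)
#' res$metrics
#' }
#' @export
run_scenario <- function(preset = "normal", horizon = 120, step = 0.05,
                         transient = 24, gates = default_gate_schedule()) {
  if (is.character(preset)) {
    name <- match.arg(preset, c("normal", "mild", "chronic"))
    rates <- rate_preset(name)
  } else {
    name <- "custom"
    rates <- as.data.frame(preset, stringsAsFactors = FALSE)
  }
  if (horizon < 3 * 24)
    stop("horizon must cover at least three periods (72 h)")
  circ <- circadian_fixture()
  pn <- logical_to_petrinet(circ$network, circ$selected)
  pn <- attach_rates(pn, rates)
  pn <- attach_gates(pn, gates)
  traj <- simulate_tcpn(pn, t_end = horizon, step = step)
  ents <- entity_names(circ$network)
  keep <- traj$time >= transient
  metrics <- do.call(rbind, lapply(ents, function(e) {
    y <- place_col(traj, e)[keep]
    tt <- traj$time[keep]
    pk <- local_maxima(y)
    data.frame(entity = e,
               period = compute_period(traj, e, transient),
               peak_clock_time = peak_time(traj, e, transient),
               peak_value = if (length(pk)) mean(y[pk]) else max(y),
               trough_value = min(y),
               amplitude = max(y) - min(y),
               stringsAsFactors = FALSE)
  }))
  antiphase <- stats::cor(place_col(traj, "Myc")[keep],
                          place_col(traj, "p53")[keep])
  structure(list(scenario = name, horizon = horizon, step = step,
                 transient = transient, trajectory = traj,
                 metrics = metrics, myc_p53_antiphase = antiphase),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario:", x$scenario, "(", x$horizon, "h, step", x$step, "h )\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  cat(sprintf("Myc/p53 anti-phase score (Pearson r): %.3f (%s)\n",
              x$myc_p53_antiphase,
              if (is.na(x$myc_p53_antiphase)) "undefined"
              else if (x$myc_p53_antiphase < 0) "opposite" else "aligned"))
  invisible(x)
}

window_maxima <- function(traj, entity, windows) {
  y <- place_col(traj, entity)
  vapply(windows, function(w)
    max(y[traj$time >= w[1] & traj$time <= w[2]]), numeric(1))
}

#' Compare the three jet-lag scenarios
#'
#' Tabulates the oscillation metrics of matched scenario runs and derives
#' ordering verdicts from the stored values: the per-cycle p53 maxima
#' (highest p53 marking within each full post-transient 24 h cycle) should
#' decrease strictly with severity, the Myc persistence index over the
#' comparison time frames should increase strictly, and the clock-protein
#' amplitudes should shrink.
#'
#' @param normal,mild,chronic \code{scenario_result} objects produced by
#'   \code{\link{run_scenario}} with identical horizon, step and gates.
#' @param windows comparison time frames (hours) for the Myc persistence
#'   index.
#' @param period cycle length (hours) used to slice the post-transient
#'   horizon for the per-cycle p53 maxima.
#' @return object of class \code{comparison_report} with the metric tables
#'   and logical verdicts.
#' @export
compare_scenarios <- function(normal, mild, chronic,
                              windows = list(c(10, 20), c(30, 40),
                                             c(50, 60), c(80, 90)),
                              period = 24) {
  runs <- list(normal = normal, mild = mild, chronic = chronic)
  stopifnot(all(vapply(runs, inherits, logical(1), "scenario_result")))
  if (length(unique(vapply(runs, `[[`, numeric(1), "horizon"))) != 1L ||
      length(unique(vapply(runs, `[[`, numeric(1), "step"))) != 1L)
    stop("scenarios must be run with identical horizon and step")
  cycle_starts <- seq(normal$transient, normal$horizon - period, by = period)
  cycles <- lapply(cycle_starts, function(s) c(s, s + period))
  p53_max <- vapply(runs, function(r)
    window_maxima(r$trajectory, "p53", cycles), numeric(length(cycles)))
  myc_persistence <- vapply(runs, function(r)
    persistence_index(r$trajectory, "Myc", windows), numeric(1))
  amp <- vapply(runs, function(r) {
    m <- r$metrics
    stats::setNames(m$amplitude, m$entity)[clock_entities()]
  }, numeric(length(clock_entities())))
  strictly_dec <- function(v) all(diff(v) < 0)
  strictly_inc <- function(v) all(diff(v) > 0)
  verdicts <- list(
    p53_suppression = all(apply(p53_max, 1L, strictly_dec)),
    myc_persistence = strictly_inc(myc_persistence),
    clock_amplitude_damping = all(apply(amp, 1L, strictly_dec)))
  structure(list(windows = windows, cycles = cycles,
                 p53_cycle_maxima = p53_max,
                 myc_persistence = myc_persistence,
                 clock_amplitudes = amp, verdicts = verdicts),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Jet-lag scenario comparison (normal / mild / chronic)\n")
  cat("p53 per-cycle maxima:\n")
  print(round(x$p53_cycle_maxima, 6))
  cat("Myc persistence index:\n")
  print(round(x$myc_persistence, 4))
  cat("Clock-protein amplitudes:\n")
  print(round(x$clock_amplitudes, 4))
  cat("Verdicts:\n")
  for (v in names(x$verdicts))
    cat(sprintf("  %-24s %s\n", v, x$verdicts[[v]]))
  invisible(x)
}
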