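#' Convert a boolean logical model to a timed continuous Petri net
#'
#' Every entity E of a boolean network becomes a complementary pair of
#' continuous places \code{P_E} (level) and \code{P_E_n} (its complement,
#' so the pair always sums to 1) plus two continuous transitions:
#' \code{t_E_p} moves marking from \code{P_E_n} to \code{P_E} (activation)
#' and \code{t_E_n} moves it back (inhibition). The K-parameters of the
#' logical model supply the enabling conditions: \code{t_E_p} is enabled in
#' markings whose thresholded levels (marking >= 0.5 counts as level 1)
#' give E the target level 1, and \code{t_E_n} when the target is 0.
#' Kinetic rates and a periodic gate schedule are attached afterwards with
#' \code{\link{attach_rates}} and \code{\link{attach_gates}}.
#'
#' @param net boolean \code{regulatory_network} (every \code{max_level} 1).
#' @param params complete \code{parameter_table} for \code{net}.
#' @return object of class \code{tcpn}: places, transitions, the embedded
#'   logical model, the all-zero initial marking, and empty rate/gate slots.
#' @examples
#' circ <- circadian_fixture()
#' pn <- logical_to_petrinet(circ$network, circ$selected)
#' nrow(pn$places)       # 12
#' @export
logical_to_petrinet <- function(net, params) {
  if (any(net$entities$max_level != 1L))
    stop("only boolean networks (max_level 1) can be converted")
  params <- parameter_table(net, params)   # validates completeness
  ents <- entity_names(net)
  places <- data.frame(
    name = as.vector(rbind(paste0("P_", ents), paste0("P_", ents, "_n"))),
    entity = rep(ents, each = 2L),
    complement = rep(c(FALSE, TRUE), length(ents)),
    m0 = rep(c(0, 1), length(ents)),
    stringsAsFactors = FALSE)
  transitions <- data.frame(
    name = as.vector(rbind(paste0("t_", ents, "_p"),
                           paste0("t_", ents, "_n"))),
    entity = rep(ents, each = 2L),
    kind = rep(c("p", "n"), length(ents)),
    rate = NA_real_,
    stringsAsFactors = FALSE)
  structure(list(network = net, params = params, places = places,
                 transitions = transitions, rates = NULL, gates = NULL),
            class = "tcpn")
}

#' @export
print.tcpn <- function(x, ...) {
  cat("Timed continuous Petri net:", nrow(x$places), "places,",
      nrow(x$transitions), "continuous transitions\n")
  if (is.null(x$rates)) cat("  rates: not attached\n")
  else cat("  rates: attached\n")
  if (is.null(x$gates)) cat("  gates: none\n")
  else cat("  gates:", paste(x$gates$schedule$entity, collapse = ", "),
           "( period", x$gates$period, "h )\n")
  invisible(x)
}

#' Attach mass-action rate constants
#'
#' Sets, per entity, the activation constant of \code{t_E_p} and the
#' inhibition constant of \code{t_E_n}. The instantaneous speed of an
#' enabled transition is its constant times the marking of its source
#' place (mass action in the source place), so trajectories are smooth
#' saturating exponentials rather than piecewise-linear ramps.
#'
#' @param tcpn a \code{tcpn}.
#' @param rates data.frame with columns \code{entity}, \code{activation},
#'   \code{inhibition} (per hour), covering every entity; see
#'   \code{\link{rate_preset}}.
#' @return the net with rates attached.
#' @export
attach_rates <- function(tcpn, rates) {
  stopifnot(inherits(tcpn, "tcpn"))
  rates <- as.data.frame(rates, stringsAsFactors = FALSE)
  stopifnot(all(c("entity", "activation", "inhibition") %in% names(rates)))
  ents <- entity_names(tcpn$network)
  missing <- setdiff(ents, rates$entity)
  if (length(missing))
    stop("no rates for entities: ", paste(missing, collapse = ", "))
  if (any(rates$activation < 0) || any(rates$inhibition < 0))
    stop("rate constants must be non-negative")
  rates <- rates[match(ents, rates$entity), , drop = FALSE]
  rownames(rates) <- NULL
  tcpn$rates <- rates
  i <- match(tcpn$transitions$entity, rates$entity)
  tcpn$transitions$rate <- ifelse(tcpn$transitions$kind == "p",
                                  rates$activation[i], rates$inhibition[i])
  tcpn
}

#' Periodic gate schedule for the clock entities
#'
#' The oscillatory timing of the core clock proteins is enforced by a
#' subnet of deterministic (delayed) transitions that toggle a gate per
#' entity: while the gate is on only the activation transition may fire,
#' while it is off only the inhibition transition. The default schedule is
#' calibrated so that, with the normal rates, expression maxima fall at the
#' experimentally reported clock times: BMAL1 peaks near 06:00 (gate on
#' 18:00, off 06:00), REV-ERBs near 08:00 (on 0:00, off 8:00) and PER-CRY
#' near 18:00 (on 6:00, off 18:00). CLOCK-BMAL1 stays ungated and follows
#' its K-logic, i.e. the thresholded BMAL1 marking.
#'
#' @param period gate period in hours.
#' @return data.frame with columns \code{entity}, \code{on}, \code{off}
#'   (clock hours) and attribute-free \code{period} column semantics handled
#'   by \code{\link{attach_gates}}.
#' @export
default_gate_schedule <- function(period = 24) {
  data.frame(entity = c("Bmal", "Rev", "PC"),
             on = c(18, 0, 6), off = c(6, 8, 18),
             stringsAsFactors = FALSE)
}

#' Attach a gate schedule
#'
#' @param tcpn a \code{tcpn}.
#' @param schedule data.frame with columns \code{entity}, \code{on},
#'   \code{off} (hours within one period); only clock entities (Bmal, CB,
#'   PC, Rev) may be gated — Myc and p53 evolve solely through their
#'   regulator-driven enabling. An empty or \code{NULL} schedule leaves the
#'   net purely regulator-driven.
#' @param period period of the schedule in hours (default 24).
#' @return the net with the gate subnet attached.
#' @export
attach_gates <- function(tcpn, schedule, period = 24) {
  stopifnot(inherits(tcpn, "tcpn"))
  if (is.null(schedule) || nrow(as.data.frame(schedule)) == 0L) {
    tcpn$gates <- NULL
    return(tcpn)
  }
  schedule <- as.data.frame(schedule, stringsAsFactors = FALSE)
  stopifnot(all(c("entity", "on", "off") %in% names(schedule)))
  if (period <= 0) stop("gate period must be positive")
  forbidden <- intersect(schedule$entity, c("Myc", "p53"))
  if (length(forbidden))
    stop("Myc and p53 must not be gated (they are regulator-driven): ",
         paste(forbidden, collapse = ", "))
  unknown <- setdiff(schedule$entity, entity_names(tcpn$network))
  if (length(unknown))
    stop("gate schedule names unknown entities: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(schedule$entity))
    stop("at most one gate per entity")
  schedule$on <- schedule$on %% period
  schedule$off <- schedule$off %% period
  if (any(schedule$on == schedule$off))
    stop("gate on_time must differ from off_time")
  tcpn$gates <- list(period = period, schedule = schedule)
  tcpn
}

## gate state at clock time h for a wrapping [on, off) window
gate_on_at <- function(h, on, off, period) {
  h <- h %% period
  if (on < off) h >= on & h < off else h >= on | h < off
}

#' Simulate the timed continuous Petri net
#'
#' Integrates the piecewise-smooth marking dynamics. Between events each
#' entity obeys the linear law
#' \code{dm/dt = act * (1 - m) * [p enabled] - inh * m * [n enabled]},
#' whose solution is an exact exponential, so the simulator propagates
#' segment-by-segment in closed form and restarts at every event: delayed
#' gate firings and crossings of the 0.5 enabling threshold by any place.
#' Complementary places hold \code{1 - m} at all times by construction.
#'
#' @param tcpn a \code{tcpn} with rates attached (gates optional).
#' @param t_end simulation horizon in hours.
#' @param step output sampling step in hours (the integration itself is
#'   exact between events; \code{step} only controls the reported grid).
#' @param force_enabled optional character vector of transition names whose
#'   enabling is forced on regardless of gates and K-logic — a diagnostic
#'   mode for studying the unconstrained mass-action core (with both
#'   transitions of an entity forced, its marking relaxes to
#'   \code{act / (act + inh)}).
#' @return object of class \code{tcpn_trajectory}: a data.frame with a
#'   \code{time} column and one column per place.
#' @examples
#' net1 <- regulatory_network("G", NULL)
#' p1 <- parameter_table(net1, c("G{}" = 1L))
#' pn <- attach_rates(logical_to_petrinet(net1, p1),
#'                    data.frame(entity = "G", activation = 1, inhibition = 1))
#' tr <- simulate_tcpn(pn, t_end = 5)
#' max(abs(tr$P_G - (1 - exp(-tr$time))))  # ~ 0
#' @export
simulate_tcpn <- function(tcpn, t_end, step = 0.05, force_enabled = NULL) {
  stopifnot(inherits(tcpn, "tcpn"))
  if (is.null(tcpn$rates))
    stop("attach rates before simulating (see attach_rates)")
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive")
  if (!is.numeric(step) || step <= 0) stop("step must be positive")

  net <- tcpn$network
  ents <- entity_names(net)
  k <- length(ents)
  act <- tcpn$rates$activation
  inh <- tcpn$rates$inhibition
  gated <- rep(FALSE, k)
  on_h <- off_h <- rep(NA_real_, k)
  period <- 24
  if (!is.null(tcpn$gates)) {
    period <- tcpn$gates$period
    sch <- tcpn$gates$schedule
    i <- match(sch$entity, ents)
    gated[i] <- TRUE
    on_h[i] <- sch$on
    off_h[i] <- sch$off
  }
  forced_p <- ents %in% sub("^t_(.*)_p$", "\\1",
                            grep("^t_.*_p$", force_enabled, value = TRUE))
  forced_n <- ents %in% sub("^t_(.*)_n$", "\\1",
                            grep("^t_.*_n$", force_enabled, value = TRUE))

  ## sorted delayed-transition firing times over the horizon
  gate_times <- numeric()
  if (any(gated)) {
    ks <- 0:ceiling(t_end / period)
    for (i in which(gated))
      gate_times <- c(gate_times, outer(ks * period, c(on_h[i], off_h[i]), "+"))
    gate_times <- sort(unique(gate_times[gate_times > 0 & gate_times <= t_end]))
  }

  ## precompute, per entity, its regulator indices and the K target for
  ## every combination of regulator levels, so enabling tests are O(1)
  reg_idx <- lapply(ents, function(e) match(regulators(net, e), ents))
  tgt_tab <- lapply(seq_len(k), function(i) {
    nr <- length(reg_idx[[i]])
    combos <- if (nr == 0L) matrix(integer(), 1L, 0L) else
      as.matrix(expand.grid(rep(list(0:1), nr), KEEP.OUT.ATTRS = FALSE))
    apply(combos, 1L, function(lv) {
      st <- stats::setNames(rep(0L, k), ents)
      st[reg_idx[[i]]] <- as.integer(lv)
      target_level(net, tcpn$params, ents[i], st)
    })
  })
  target_of <- function(i, lv) {
    ri <- reg_idx[[i]]
    if (length(ri) == 0L) return(tgt_tab[[i]][1L])
    tgt_tab[[i]][1L + sum(lv[ri] * 2^(seq_along(ri) - 1L))]
  }
  enabling <- function(lv, t) {
    en_p <- en_n <- logical(k)
    for (i in seq_len(k)) {
      if (forced_p[i] || forced_n[i]) {
        en_p[i] <- forced_p[i]; en_n[i] <- forced_n[i]
      } else if (gated[i]) {
        on <- gate_on_at(t, on_h[i], off_h[i], period)
        en_p[i] <- on; en_n[i] <- !on
      } else {
        tgt <- target_of(i, lv)
        en_p[i] <- tgt == 1L; en_n[i] <- tgt == 0L
      }
    }
    list(p = en_p, n = en_n)
  }
  levels_of <- function(m) as.integer(m >= 0.5)

  out_t <- seq(0, t_end, by = step)
  if (out_t[length(out_t)] < t_end) out_t <- c(out_t, t_end)
  out_m <- matrix(NA_real_, length(out_t), k)
  m <- rep(0, k)                     # all entities at level 0 initially
  t <- 0
  out_i <- 1L
  gi <- 1L                           # next gate event index
  n_events <- 0L
  ## Filippov regularization state: negative feedback between ungated
  ## entities can drive their markings into the 0.5 switching surface with
  ## switching times accumulating (a Zeno spiral). When a long run of
  ## near-instantaneous crossing events is detected, the markings caught on
  ## the surface are held at exactly 0.5 (the sliding solution) until a gate
  ## firing or another place's crossing changes the enabling context.
  frozen <- rep(FALSE, k)
  fast_run <- 0L
  ## a set of places held on the switching surface may leave it only when a
  ## consistent escape mode exists: an assignment of levels to the held
  ## places under which every held place's field pushes its marking to the
  ## side of 0.5 that the assignment claims
  try_release <- function(m, t) {
    idx <- which(frozen)
    base <- levels_of(m)
    nf <- length(idx)
    for (code in 0:(2^nf - 1L)) {
      sigma <- as.integer(bitwAnd(code %/% 2^(seq_len(nf) - 1L), 1L))
      lv <- base
      lv[idx] <- sigma
      en <- enabling(lv, t)
      A <- act * en$p
      B <- act * en$p + inh * en$n
      Cx <- ifelse(B > 0, A / B, 0)
      ok <- (sigma == 1L & Cx[idx] > 0.5) | (sigma == 0L & Cx[idx] < 0.5)
      if (all(ok)) {
        m[idx] <- 0.5 + 1e-9 * (2 * sigma - 1)
        frozen[idx] <<- FALSE
        return(m)
      }
    }
    m
  }
  while (t < t_end) {
    en <- enabling(levels_of(m), t)
    A <- act * en$p
    B <- act * en$p + inh * en$n
    A[frozen] <- 0
    B[frozen] <- 0
    C <- ifelse(B > 0, A / B, 0)
    seg_m <- function(dt) ifelse(B > 0, C + (m - C) * exp(-B * dt), m)
    ## next 0.5-crossing among all entity places, in closed form
    r <- (0.5 - C) / (m - C)
    t_cross <- ifelse(B > 0 & is.finite(r) & r > 0 & r < 1, -log(r) / B, Inf)
    t_cross[t_cross < 1e-12] <- Inf
    next_gate <- if (gi <= length(gate_times)) gate_times[gi] else Inf
    t_next <- min(t + min(t_cross), next_gate, t_end)
    if (!is.finite(t_next) || t_next <= t) {
      ## no progress: report as an integration failure with a time stamp
      stop("integration failure at t = ", format(t),
           " h: no forward progress (possible sliding mode)")
    }
    while (out_i <= length(out_t) && out_t[out_i] <= t_next + 1e-12) {
      out_m[out_i, ] <- seg_m(out_t[out_i] - t)
      out_i <- out_i + 1L
    }
    dt <- t_next - t
    m <- seg_m(dt)
    crossed <- is.finite(min(t_cross)) && t + min(t_cross) <= t_next + 1e-12
    if (crossed) {
      ## nudge places that just reached the 0.5 threshold slightly past it
      ## in their direction of motion, so the flip survives rounding
      j <- which(t_cross <= min(t_cross) + 1e-12)
      m[j] <- 0.5 + 1e-9 * sign(C[j] - 0.5)
    }
    if (any(!is.finite(m)))
      stop("integration failure at t = ", format(t_next),
           " h: non-finite marking")
    gate_fired <- t_next >= next_gate - 1e-12
    t <- t_next
    if (gate_fired) gi <- gi + 1L
    ## Zeno detection: a long run of near-instantaneous crossings means the
    ## switched dynamics are spiralling into the 0.5 surface; hold the
    ## places caught there at exactly 0.5 (the sliding solution)
    if (crossed && dt < 1e-4) {
      fast_run <- fast_run + 1L
      if (fast_run >= 50L) {
        hold <- abs(m - 0.5) <= 1e-3 & !gated & !frozen
        m[hold] <- 0.5
        frozen[hold] <- TRUE
        fast_run <- 0L
      }
    } else {
      fast_run <- 0L
    }
    if (any(frozen)) m <- try_release(m, t)
    n_events <- n_events + 1L
    if (n_events > 2e5)
      stop("integration failure at t = ", format(t),
           " h: event cap exceeded (chattering enabling condition)")
  }
  traj <- data.frame(time = out_t)
  for (i in seq_len(k)) {
    traj[[paste0("P_", ents[i])]] <- out_m[, i]
    traj[[paste0("P_", ents[i], "_n")]] <- 1 - out_m[, i]
  }
  structure(traj, class = c("tcpn_trajectory", "data.frame"),
            step = step, t_end = t_end)
}
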