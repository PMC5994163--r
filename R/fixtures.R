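#' The two-entity worked example
#'
#' The classic didactic kinetic-logic instance: X activates Y, Y inhibits X
#' (both thresholds 1), with parameters K_X{}=0, K_X{Y}=1, K_Y{}=0,
#' K_Y{X}=1. Its asynchronous state graph is the closed cycle
#' (0,0) -> (1,0) -> (1,1) -> (0,1) -> (0,0).
#'
#' @return list with components \code{network} and \code{params}.
#' @export
toy_fixture <- function() {
  net <- regulatory_network(
    c("X", "Y"),
    data.frame(source = c("X", "Y"), target = c("Y", "X"),
               sign = c("+", "-"), threshold = 1L,
               stringsAsFactors = FALSE))
  params <- parameter_table(net, c("X{}" = 0L, "X{Y}" = 1L,
                                   "Y{}" = 0L, "Y{X}" = 1L))
  list(network = net, params = params)
}

#' The circadian clock / MYC / p53 regulatory network
#'
#' The six-entity boolean network coupling the core clock (BMAL1, the
#' CLOCK-BMAL1 complex \code{CB}, the PER-CRY complex \code{PC}, REV-ERBs
#' \code{Rev}) to the cell-cycle regulators \code{Myc} and \code{p53}:
#' six activations (Bmal->CB, CB->PC, CB->Rev, Bmal->p53, Myc->p53,
#' Myc->Myc) and four inhibitions (PC->CB, Rev->Bmal, CB->Myc, p53->Myc),
#' all thresholds 1. Ships with the permitted K-level space used for model
#' selection and the biologically designated table.
#'
#' @return list with components \code{network}, \code{space} (a
#'   \code{parameter_space}) and \code{selected} (a \code{parameter_table}).
#' @examples
#' circ <- circadian_fixture()
#' circ$network
#' @export
circadian_fixture <- function() {
  ents <- c("Bmal", "CB", "PC", "Rev", "Myc", "p53")
  inter <- data.frame(
    source = c("Bmal", "CB", "CB", "Bmal", "Myc", "Myc",
               "PC", "Rev", "CB", "p53"),
    target = c("CB", "PC", "Rev", "p53", "p53", "Myc",
               "CB", "Bmal", "Myc", "Myc"),
    sign = c(rep("+", 6L), rep("-", 4L)),
    threshold = 1L, stringsAsFactors = FALSE)
  net <- regulatory_network(ents, inter)
  allowed <- list(
    "Bmal{}" = 0L, "Bmal{Rev}" = 1L,
    "CB{}" = 0L, "CB{Bmal}" = 0:1, "CB{PC}" = 0L, "CB{Bmal,PC}" = 1L,
    "PC{}" = 0L, "PC{CB}" = 1L,
    "Rev{}" = 0L, "Rev{CB}" = 1L,
    "p53{}" = 0L, "p53{Bmal}" = 1L, "p53{Myc}" = 1L, "p53{Bmal,Myc}" = 1L,
    "Myc{}" = 0L, "Myc{p53}" = 0L, "Myc{CB}" = 0L, "Myc{Myc}" = 0:1,
    "Myc{CB,p53}" = 0:1, "Myc{Myc,p53}" = 0L, "Myc{CB,Myc}" = 0L,
    "Myc{CB,Myc,p53}" = 1L)
  selected <- c(
    "Bmal{}" = 0L, "Bmal{Rev}" = 1L,
    "CB{}" = 0L, "CB{Bmal}" = 1L, "CB{PC}" = 0L, "CB{Bmal,PC}" = 1L,
    "PC{}" = 0L, "PC{CB}" = 1L,
    "Rev{}" = 0L, "Rev{CB}" = 1L,
    "p53{}" = 0L, "p53{Bmal}" = 1L, "p53{Myc}" = 1L, "p53{Bmal,Myc}" = 1L,
    "Myc{}" = 0L, "Myc{p53}" = 0L, "Myc{CB}" = 0L, "Myc{Myc}" = 0L,
    "Myc{CB,p53}" = 1L, "Myc{Myc,p53}" = 0L, "Myc{CB,Myc}" = 0L,
    "Myc{CB,Myc,p53}" = 1L)
  list(network = net,
       space = parameter_space(net, allowed),
       selected = parameter_table(net, selected))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Random boolean regulatory network with a complete parameter table
#'
#' Draws a weakly connected signed digraph on \code{n} boolean entities
#' (named E1..En, all thresholds 1, at most one edge per ordered pair) and a
#' complete K-parameter table, optionally restricted to resource-monotone
#' (Snoussi) tables. Deterministic for a fixed seed.
#'
#' @param n number of entities (>= 1).
#' @param edge_prob probability of each ordered non-self pair carrying an
#'   interaction (self-loops drawn at half this probability).
#' @param activation_prob probability an interaction is an activation.
#' @param seed integer seed.
#' @param snoussi logical; force K(S) <= K(S') whenever S is a subset of S'.
#' @return list with components \code{network} and \code{params}.
#' @export
random_brn <- function(n, edge_prob = 0.4, activation_prob = 0.5,
                       seed = 1L, snoussi = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  stopifnot(edge_prob >= 0, edge_prob <= 1,
            activation_prob >= 0, activation_prob <= 1)
  with_seed(seed, {
    ents <- paste0("E", seq_len(n))
    pairs <- expand.grid(source = ents, target = ents,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    p <- ifelse(pairs$source == pairs$target, edge_prob / 2, edge_prob)
    keep <- stats::runif(nrow(pairs)) < p
    inter <- pairs[keep, , drop = FALSE]
    ## stitch components together so the digraph is weakly connected
    if (n > 1L) {
      repeat {
        und <- unique(rbind(as.matrix(inter[, c("source", "target")]),
                            as.matrix(inter[, c("target", "source")])))
        comp <- stats::setNames(seq_len(n), ents)
        changed <- TRUE
        while (changed && nrow(und) > 0L) {
          changed <- FALSE
          for (i in seq_len(nrow(und))) {
            a <- und[i, 1L]; b <- und[i, 2L]
            if (comp[a] != comp[b]) {
              comp[comp == comp[b]] <- comp[a]
              changed <- TRUE
            }
          }
        }
        if (length(unique(comp)) == 1L) break
        ## connect two components with a random edge
        cs <- unique(comp)
        from <- sample(ents[comp == cs[1L]], 1L)
        to <- sample(ents[comp == cs[2L]], 1L)
        inter <- unique(rbind(inter,
                              data.frame(source = from, target = to,
                                         stringsAsFactors = FALSE)))
      }
    }
    inter$sign <- ifelse(stats::runif(nrow(inter)) < activation_prob,
                         "+", "-")
    inter$threshold <- rep(1L, nrow(inter))
    net <- regulatory_network(ents, inter)
    vals <- integer()
    for (e in ents) {
      regs <- regulators(net, e)
      subs <- list(character())
      for (r in regs)
        subs <- c(subs, lapply(subs, function(s) c(s, r)))
      sizes <- vapply(subs, length, integer(1))
      subs <- subs[order(sizes)]   # smaller subsets first for monotone draws
      kv <- stats::setNames(integer(length(subs)),
                            vapply(subs, function(s) param_key(e, s),
                                   character(1)))
      for (i in seq_along(subs)) {
        lo <- 0L
        if (snoussi && length(subs[[i]])) {
          drop1 <- lapply(seq_along(subs[[i]]),
                          function(j) subs[[i]][-j])
          lo <- max(vapply(drop1,
                           function(s) kv[[param_key(e, s)]], integer(1)))
        }
        kv[[param_key(e, subs[[i]])]] <- sample(lo:1L, 1L)
      }
      vals <- c(vals, kv)
    }
    list(network = net, params = parameter_table(net, vals))
  })
}

#' Random CTL formula
#'
#' Samples a formula over the given entities from a bounded-depth grammar:
#' at each node an atom is drawn with probability \code{atom_prob} (always
#' at depth 0), otherwise a connective or path-state quantifier chosen
#' uniformly. Used to exercise the model checker against the brute-force
#' oracle.
#'
#' @param entities character vector of entity names.
#' @param max_levels integer vector of maximal levels (recycled).
#' @param depth maximal nesting depth.
#' @param atom_prob probability of emitting an atom at an inner node.
#' @return a \code{ctl_formula}. Draws from the R random stream (seed it
#'   with \code{set.seed} for reproducibility).
#' @export
random_ctl_formula <- function(entities, max_levels = 1L, depth = 4L,
                               atom_prob = 0.4) {
  max_levels <- rep_len(as.integer(max_levels), length(entities))
  gen <- function(d) {
    if (d <= 0L || stats::runif(1) < atom_prob) {
      i <- sample.int(length(entities), 1L)
      return(ctl_atom(entities[i],
                      sample(c("=", "!=", "<=", ">="), 1L),
                      sample(0:max_levels[i], 1L)))
    }
    op <- sample(c("not", "and", "or", "implies",
                   "EX", "AX", "EF", "AF", "EG", "AG", "EU", "AU"), 1L)
    switch(op,
      not = ctl_not(gen(d - 1L)),
      and = ctl_and(gen(d - 1L), gen(d - 1L)),
      or = ctl_or(gen(d - 1L), gen(d - 1L)),
      implies = ctl_implies(gen(d - 1L), gen(d - 1L)),
      EU = ctl_EU(gen(d - 1L), gen(d - 1L)),
      AU = ctl_AU(gen(d - 1L), gen(d - 1L)),
      ctl_node(op, sub = gen(d - 1L)))
  }
  gen(as.integer(depth))
}

#' Brute-force CTL evaluation (independent oracle)
#'
#' Evaluates CTL on a state graph by explicit reachability algebra on the
#' boolean adjacency matrix: \code{EX} by one matrix product, \code{EF} and
#' \code{E[. U .]} through the reflexive-transitive closure of (restricted)
#' relations, \code{EG} by reaching a cycle inside the restricted relation,
#' and the universal quantifiers through their classical dualities. This
#' route shares no code with the fixed-point labelling of
#' \code{\link{ctl_check}} and serves as its test oracle.
#'
#' @inheritParams ctl_check
#' @return logical vector over the states.
#' @export
brute_force_ctl <- function(graph, formula) {
  n <- nrow(graph$states)
  if (n > 4096L)
    stop("brute-force evaluation refused for graphs with more than 4096 states")
  M <- matrix(FALSE, n, n)
  M[graph$edges] <- TRUE
  closure <- function(A) {           # reflexive-transitive closure
    R <- A | diag(TRUE, n)
    repeat {
      R2 <- R | ((R %*% R) > 0)
      if (identical(R2, R)) return(R)
      R <- R2
    }
  }
  restrict <- function(set) M & outer(set, set)
  ev <- function(f) {
    EX <- function(s) as.vector(M %*% s) > 0
    EF <- function(s) as.vector(closure(M) %*% s) > 0
    EG <- function(s) {
      Ms <- restrict(s)
      Cs <- closure(Ms)
      on_cycle <- diag((Ms %*% Cs) > 0)          # a cycle within s
      s & (as.vector(Cs %*% on_cycle) > 0)
    }
    EU <- function(a, b) {
      Ca <- closure(restrict(a))
      b | (a & (as.vector(Ca %*% (as.vector(M %*% b) > 0)) > 0))
    }
    switch(f$kind,
      true = rep(TRUE, n),
      false = rep(FALSE, n),
      atom = check_atom(graph, f),
      not = !ev(f$sub),
      and = ev(f$lhs) & ev(f$rhs),
      or = ev(f$lhs) | ev(f$rhs),
      implies = !ev(f$lhs) | ev(f$rhs),
      EX = EX(ev(f$sub)),
      AX = !EX(!ev(f$sub)),
      EF = EF(ev(f$sub)),
      AG = !EF(!ev(f$sub)),
      EG = EG(ev(f$sub)),
      AF = !EG(!ev(f$sub)),
      EU = EU(ev(f$lhs), ev(f$rhs)),
      AU = {
        a <- ev(f$lhs); b <- ev(f$rhs)
        !(EU(!b, !a & !b) | EG(!b))
      },
      stop("unknown CTL node kind: ", f$kind))
  }
  ev(formula)
}

#' Interpolated jet-lag severity rates
#'
#' Linear interpolation, entity by entity, between the normal (\code{alpha
#' = 0}) and chronic (\code{alpha = 1}) kinetic rate presets. The shipped
#' mild preset is its own calibration, not the midpoint of this sweep.
#'
#' @param alpha interpolation weight in [0, 1].
#' @return a rate data.frame as produced by \code{\link{rate_preset}}.
#' @examples
#' severity_rates(0.5)
#' @export
severity_rates <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  lo <- rate_preset("normal")
  hi <- rate_preset("chronic")
  stopifnot(identical(lo$entity, hi$entity))
  data.frame(entity = lo$entity,
             activation = (1 - alpha) * lo$activation + alpha * hi$activation,
             inhibition = (1 - alpha) * lo$inhibition + alpha * hi$inhibition,
             stringsAsFactors = FALSE)
}
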