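#' Biological regulatory networks in the kinetic-logic formalism
#'
#' A regulatory network is a signed, threshold-labelled directed graph over
#' named entities. Each entity has a maximal discrete expression level
#' (\code{max_level = 1} for a boolean entity); each interaction carries a
#' sign (\code{"+"} activation, \code{"-"} inhibition) and an integer
#' threshold at which it becomes effective.
#'
#' @param entities either a character vector of entity names (all boolean) or
#'   a data.frame with columns \code{name} and \code{max_level}.
#' @param interactions a data.frame with columns \code{source}, \code{target},
#'   \code{sign} (\code{"+"} or \code{"-"}) and \code{threshold}.
#' @return an object of class \code{regulatory_network} with components
#'   \code{entities} and \code{interactions}.
#' @examples
#' net <- regulatory_network(
#'   c("X", "Y"),
#'   data.frame(source = c("X", "Y"), target = c("Y", "X"),
#'              sign = c("+", "-"), threshold = 1L))
#' regulators(net, "X")
#' @export
regulatory_network <- function(entities, interactions) {
  if (is.character(entities)) {
    entities <- data.frame(name = entities, max_level = 1L,
                           stringsAsFactors = FALSE)
  }
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "max_level") %in% names(entities)))
  entities$name <- as.character(entities$name)
  entities$max_level <- as.integer(entities$max_level)
  if (anyDuplicated(entities$name))
    stop("entity names must be unique")
  if (any(entities$max_level < 1L))
    stop("max_level must be >= 1 for every entity")

  if (is.null(interactions) || nrow(as.data.frame(interactions)) == 0L) {
    interactions <- data.frame(source = character(), target = character(),
                               sign = character(), threshold = integer(),
                               stringsAsFactors = FALSE)
  }
  interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "sign", "threshold") %in%
                  names(interactions)))
  interactions$source <- as.character(interactions$source)
  interactions$target <- as.character(interactions$target)
  interactions$sign <- as.character(interactions$sign)
  interactions$threshold <- as.integer(interactions$threshold)

  bad <- setdiff(unique(c(interactions$source, interactions$target)),
                 entities$name)
  if (length(bad))
    stop("interaction endpoints not declared as entities: ",
         paste(bad, collapse = ", "))
  if (!all(interactions$sign %in% c("+", "-")))
    stop("interaction sign must be '+' or '-'")
  if (anyDuplicated(interactions[, c("source", "target")]))
    stop("at most one interaction per ordered (source, target) pair")
  src_max <- entities$max_level[match(interactions$source, entities$name)]
  if (any(interactions$threshold < 1L | interactions$threshold > src_max))
    stop("thresholds must lie in [1, max_level(source)]")

  structure(list(entities = entities, interactions = interactions),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", nrow(x$entities), "entities,",
      nrow(x$interactions), "interactions\n")
  cat("  entities:", paste(x$entities$name, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$interactions))) {
    r <- x$interactions[i, ]
    cat(sprintf("  %s -%s%d-> %s\n", r$source, r$sign, r$threshold, r$target))
  }
  invisible(x)
}

entity_names <- function(net) net$entities$name

max_level <- function(net, entity) {
  i <- match(entity, net$entities$name)
  if (is.na(i)) stop("unknown entity: ", entity)
  net$entities$max_level[i]
}

#' Regulators of an entity
#'
#' @param net a \code{regulatory_network}.
#' @param entity entity name.
#' @return sorted character vector of the names of entities acting on
#'   \code{entity} (sources of interactions targeting it).
#' @export
regulators <- function(net, entity) {
  if (!entity %in% net$entities$name)
    stop("unknown entity: ", entity)
  sort(net$interactions$source[net$interactions$target == entity])
}

#' Resources of an entity in a state
#'
#' The resources of an entity are the regulators currently "helping" it:
#' an activator is a resource when its level reaches the interaction
#' threshold, an inhibitor is a resource when its level stays below the
#' threshold (the absence of an inhibitor is treated as a resource).
#'
#' @param net a \code{regulatory_network}.
#' @param entity entity name.
#' @param state named integer vector giving the level of every entity.
#' @return sorted character vector of resource regulator names.
#' @export
resources <- function(net, entity, state) {
  if (!entity %in% net$entities$name)
    stop("unknown entity: ", entity)
  ia <- net$interactions[net$interactions$target == entity, , drop = FALSE]
  if (nrow(ia) == 0L) return(character())
  lev <- state[ia$source]
  if (anyNA(lev))
    stop("state is missing levels for: ",
         paste(ia$source[is.na(lev)], collapse = ", "))
  res <- ifelse(ia$sign == "+", lev >= ia$threshold, lev < ia$threshold)
  sort(ia$source[res])
}

## canonical key for a (entity, resource set) parameter entry
param_key <- function(entity, members) {
  paste0(entity, "{", paste(sort(members), collapse = ","), "}")
}

## all subsets of a regulator set, canonical keys, lexicographic order
entity_param_keys <- function(net, entity) {
  regs <- regulators(net, entity)
  subs <- list(character())
  for (r in regs)
    subs <- c(subs, lapply(subs, function(s) c(s, r)))
  sort(vapply(subs, function(s) param_key(entity, s), character(1)))
}

all_param_keys <- function(net) {
  unlist(lapply(sort(entity_names(net)), entity_param_keys, net = net),
         use.names = FALSE)
}

#' Logical parameter table
#'
#' The K-parameters of a kinetic-logic model: for every entity and every
#' subset of its regulators, the discrete level the entity evolves toward
#' when exactly that subset is its current resource set. Entries are keyed
#' as \code{"entity{r1,r2,...}"} with resource names sorted.
#'
#' @param net a \code{regulatory_network}.
#' @param values named list or vector of integer levels, one entry per
#'   (entity, resource subset) key.
#' @return an object of class \code{parameter_table} (a named integer vector
#'   with the network's canonical key order).
#' @examples
#' toy <- toy_fixture()
#' toy$params[["X{Y}"]]
#' @export
parameter_table <- function(net, values) {
  values <- unlist(values)
  keys <- all_param_keys(net)
  missing <- setdiff(keys, names(values))
  if (length(missing))
    stop("parameter table is missing entries: ",
         paste(missing, collapse = "; "))
  extra <- setdiff(names(values), keys)
  if (length(extra))
    stop("parameter table has unknown entries: ",
         paste(extra, collapse = "; "))
  k <- as.integer(values[keys])
  ent <- sub("\\{.*$", "", keys)
  ml <- net$entities$max_level[match(ent, net$entities$name)]
  if (any(k < 0L | k > ml))
    stop("parameter values must lie in [0, max_level(entity)]")
  structure(stats::setNames(k, keys), class = "parameter_table")
}

#' @export
print.parameter_table <- function(x, ...) {
  cat("K-parameter table (", length(x), " entries)\n", sep = "")
  for (i in seq_along(x))
    cat(sprintf("  K_%s = %d\n", names(x)[i], x[[i]]))
  invisible(x)
}

#' Target level of an entity
#'
#' Looks up the K-parameter of the entity under its current resource set:
#' the discrete level toward which the entity evolves from \code{state}.
#'
#' @inheritParams resources
#' @param params a \code{parameter_table} complete for \code{net}.
#' @return integer target level.
#' @export
target_level <- function(net, params, entity, state) {
  key <- param_key(entity, resources(net, entity, state))
  if (!key %in% names(params))
    stop("no parameter entry for K_", key)
  params[[key]]
}

#' Asynchronous successors of a state
#'
#' Under asynchronous unit-step dynamics every entity whose target level
#' differs from its current level yields one successor in which that entity
#' alone moves one level toward its target. A state where every entity sits
#' at its target has no successor (a deadlock; \code{\link{build_state_graph}}
#' adds a self-loop there).
#'
#' @inheritParams target_level
#' @return list of named integer state vectors (possibly empty).
#' @export
successors <- function(net, params, state) {
  out <- list()
  for (e in entity_names(net)) {
    tgt <- target_level(net, params, e, state)
    cur <- state[[e]]
    if (tgt != cur) {
      s2 <- state
      s2[[e]] <- cur + as.integer(sign(tgt - cur))
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

## enumerate all states as an integer matrix, first entity most significant
state_space <- function(net) {
  ents <- entity_names(net)
  lv <- lapply(rev(ents), function(e) 0:max_level(net, e))
  g <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g[, rev(seq_along(ents)), drop = FALSE])
  colnames(m) <- ents
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

state_label <- function(states) {
  apply(states, 1L, function(r)
    paste(paste0(colnames(states), "=", r), collapse = ","))
}

#' Build the asynchronous state graph
#'
#' Enumerates every discrete state of the network and connects each state to
#' its asynchronous unit-step successors under the given parameter table.
#' Deadlock states (no enabled change) receive a self-loop so that the
#' transition relation is total, as standard CTL semantics requires.
#'
#' @inheritParams target_level
#' @return an object of class \code{state_graph}: a list with \code{states}
#'   (integer matrix, one row per state), \code{edges} (two-column integer
#'   matrix of row indices), \code{adj} (successor index list),
#'   \code{deadlock} (logical), and the network's \code{entities}.
#' @examples
#' toy <- toy_fixture()
#' g <- build_state_graph(toy$network, toy$params)
#' nrow(g$states)  # 4
#' @export
build_state_graph <- function(net, params) {
  states <- state_space(net)
  n <- nrow(states)
  ents <- colnames(states)
  radix <- vapply(ents, function(e) max_level(net, e) + 1L, integer(1))
  ## index of a state row under the mixed-radix enumeration of state_space()
  idx_of <- function(s) {
    i <- 0L
    for (j in seq_along(ents)) i <- i * radix[j] + as.integer(s[[ents[j]]])
    i + 1L
  }
  adj <- vector("list", n)
  deadlock <- logical(n)
  for (i in seq_len(n)) {
    st <- stats::setNames(as.integer(states[i, ]), ents)
    succ <- successors(net, params, st)
    if (length(succ) == 0L) {
      deadlock[i] <- TRUE
      adj[[i]] <- i
    } else {
      adj[[i]] <- sort(vapply(succ, idx_of, integer(1)))
    }
  }
  edges <- cbind(from = rep.int(seq_len(n), lengths(adj)),
                 to = unlist(adj, use.names = FALSE))
  structure(list(entities = net$entities, states = states, edges = edges,
                 adj = adj, deadlock = deadlock),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat("State graph:", nrow(x$states), "states,", nrow(x$edges),
      "transitions (", sum(x$deadlock), "deadlock self-loops )\n")
  invisible(x)
}
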