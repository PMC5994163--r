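#' Parameter space for model selection
#'
#' A parameter space maps every (entity, resource subset) key of a network
#' to the set of K-levels a candidate model may assign there. Enumerating
#' the Cartesian product of these sets and keeping the tables whose state
#' graph satisfies the observed temporal-logic properties is the
#' model-checking route to parameter inference.
#'
#' @param net a \code{regulatory_network}.
#' @param allowed named list mapping parameter keys (see
#'   \code{\link{parameter_table}}) to integer vectors of permitted levels.
#' @return object of class \code{parameter_space}.
#' @export
parameter_space <- function(net, allowed) {
  keys <- all_param_keys(net)
  missing <- setdiff(keys, names(allowed))
  if (length(missing))
    stop("parameter space is missing entries: ",
         paste(missing, collapse = "; "))
  extra <- setdiff(names(allowed), keys)
  if (length(extra))
    stop("parameter space has unknown entries: ",
         paste(extra, collapse = "; "))
  allowed <- lapply(allowed[keys], function(v) sort(unique(as.integer(v))))
  if (any(lengths(allowed) == 0L))
    stop("every parameter entry needs at least one permitted level")
  ent <- sub("\\{.*$", "", keys)
  ml <- net$entities$max_level[match(ent, net$entities$name)]
  for (i in seq_along(allowed))
    if (any(allowed[[i]] < 0L | allowed[[i]] > ml[i]))
      stop("permitted levels out of range for ", keys[i])
  structure(list(network = net, allowed = allowed),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  n <- prod(lengths(x$allowed))
  cat("Parameter space:", length(x$allowed), "entries,", n,
      "candidate tables\n")
  invisible(x)
}

## K non-decreasing as resources are added (checked on one-element extensions,
## which implies the full subset order by transitivity)
snoussi_ok <- function(net, values) {
  for (e in entity_names(net)) {
    regs <- regulators(net, e)
    subs <- list(character())
    for (r in regs)
      subs <- c(subs, lapply(subs, function(s) c(s, r)))
    for (s in subs) {
      for (r in setdiff(regs, s)) {
        if (values[[param_key(e, s)]] > values[[param_key(e, c(s, r))]])
          return(FALSE)
      }
    }
  }
  TRUE
}

#' Enumerate candidate parameter tables
#'
#' Generates the Cartesian product of the permitted level sets in a fixed
#' lexicographic order (keys sorted by entity name then canonical resource
#' set; the first key is the most significant digit). With
#' \code{snoussi = TRUE}, tables violating resource monotonicity (K may not
#' decrease when a resource is added) are dropped.
#'
#' @param space a \code{parameter_space}.
#' @param snoussi logical; apply the monotonicity restriction.
#' @return list of \code{parameter_table} objects.
#' @examples
#' circ <- circadian_fixture()
#' length(enumerate_tables(circ$space))  # 8
#' @export
enumerate_tables <- function(space, snoussi = FALSE) {
  allowed <- space$allowed
  keys <- names(allowed)
  counts <- lengths(allowed)
  n <- prod(counts)
  out <- vector("list", n)
  kept <- 0L
  idx <- rep(1L, length(keys))
  for (i in seq_len(n)) {
    vals <- mapply(function(v, j) v[[j]], allowed, idx)
    names(vals) <- keys
    if (!snoussi || snoussi_ok(space$network, as.list(vals))) {
      kept <- kept + 1L
      out[[kept]] <- parameter_table(space$network, vals)
    }
    ## advance mixed-radix counter, last key varies fastest
    j <- length(keys)
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= counts[j]) break
      idx[j] <- 1L
      j <- j - 1L
    }
  }
  out[seq_len(kept)]
}

#' Select parameter tables by model checking
#'
#' Builds the asynchronous state graph of every candidate table enumerated
#' from the space and keeps those whose graph satisfies the formula in every
#' state (see \code{\link{ctl_satisfies}}).
#'
#' @param space a \code{parameter_space}.
#' @param formula a \code{ctl_formula} (e.g. \code{psi_library()$psi_all}).
#' @param snoussi logical; restrict enumeration to monotone tables.
#' @return object of class \code{selection_result} with components
#'   \code{candidates} (count enumerated), \code{satisfying} (list of
#'   passing \code{parameter_table}s) and \code{selected} (\code{NULL} until
#'   a table is designated, e.g. on biological grounds).
#' @examples
#' circ <- circadian_fixture()
#' sel <- select_models(circ$space, psi_library()$psi_all)
#' sel$candidates; length(sel$satisfying)
#' @export
select_models <- function(space, formula, snoussi = FALSE) {
  tables <- enumerate_tables(space, snoussi = snoussi)
  keep <- logical(length(tables))
  for (i in seq_along(tables)) {
    g <- build_state_graph(space$network, tables[[i]])
    keep[i] <- ctl_satisfies(g, formula)
  }
  structure(list(candidates = length(tables),
                 satisfying = tables[keep],
                 selected = NULL),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Model selection:", x$candidates, "candidate tables,",
      length(x$satisfying), "satisfying the property\n")
  if (length(x$satisfying) > 1L) {
    ## report the entries on which the satisfying tables disagree
    m <- do.call(rbind, lapply(x$satisfying, unclass))
    vary <- colnames(m)[apply(m, 2L, function(col) length(unique(col)) > 1L)]
    if (length(vary))
      cat("  tables differ in:", paste(vary, collapse = ", "), "\n")
  }
  if (!is.null(x$selected)) cat("  one table designated as selected\n")
  invisible(x)
}
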