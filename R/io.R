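#' Write a model document to JSON
#'
#' The model dialect is a single versioned JSON document holding the
#' network, optionally a parameter space and/or a concrete parameter
#' table, rate presets and a gate schedule — everything needed to rebuild
#' the full pipeline.
#'
#' @param model list with components \code{network} (required) and
#'   optionally \code{space}, \code{params}, \code{rate_presets} (named
#'   list of rate data.frames), \code{gates} (gate schedule data.frame).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model$network, "regulatory_network"))
  doc <- list(
    format = "clocknet-model",
    version = 1L,
    entities = model$network$entities,
    interactions = model$network$interactions)
  if (!is.null(model$space))
    doc$parameter_space <- model$space$allowed
  if (!is.null(model$params))
    doc$parameters <- as.list(unclass(model$params))
  if (!is.null(model$rate_presets))
    doc$rate_presets <- model$rate_presets
  if (!is.null(model$gates))
    doc$gate_schedule <- model$gates
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a model document
#'
#' Parses the JSON model dialect and validates it: unknown entity
#' references, out-of-range thresholds and parameter levels, and
#' incomplete tables are all collected and reported together.
#'
#' @param path path to a model JSON file.
#' @return list with components \code{network}, \code{space} (or NULL),
#'   \code{params} (or NULL), \code{rate_presets}, \code{gates}.
#' @examples
#' path <- system.file("extdata", "circadian_model.json",
#'                     package = "clocknet")
#' mod <- read_model(path)
#' nrow(mod$network$interactions)  # 10
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("model file is not valid JSON: ",
                         conditionMessage(e)))
  if (!identical(doc$format, "clocknet-model"))
    stop("not a clocknet model document (format field missing or wrong)")
  errs <- character()
  net <- tryCatch(regulatory_network(doc$entities, doc$interactions),
                  error = function(e) {
                    errs <<- c(errs, conditionMessage(e))
                    NULL
                  })
  space <- params <- NULL
  if (!is.null(net) && !is.null(doc$parameter_space)) {
    space <- tryCatch(parameter_space(net, doc$parameter_space),
                      error = function(e) {
                        errs <<- c(errs, conditionMessage(e))
                        NULL
                      })
  }
  if (!is.null(net) && !is.null(doc$parameters)) {
    params <- tryCatch(parameter_table(net, doc$parameters),
                       error = function(e) {
                         errs <<- c(errs, conditionMessage(e))
                         NULL
                       })
  }
  gates <- doc$gate_schedule
  if (!is.null(net) && !is.null(gates)) {
    bad <- setdiff(gates$entity, entity_names(net))
    if (length(bad))
      errs <- c(errs, paste("gate schedule names unknown entities:",
                            paste(bad, collapse = ", ")))
  }
  if (length(errs))
    stop("model validation failed:\n  - ", paste(errs, collapse = "\n  - "))
  list(network = net, space = space, params = params,
       rate_presets = doc$rate_presets, gates = gates)
}

state_graph_igraph <- function(graph) {
  lab <- state_label(graph$states)
  g <- igraph::graph_from_edgelist(
    cbind(lab[graph$edges[, 1L]], lab[graph$edges[, 2L]]), directed = TRUE)
  ## keep isolated states too (cannot occur with a total relation, but be safe)
  miss <- setdiff(lab, igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  igraph::V(g)$label <- igraph::V(g)$name
  g
}

#' Export a state graph
#'
#' @param graph a \code{state_graph}.
#' @param path output file.
#' @param format \code{"dot"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
export_state_graph <- function(graph, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  g <- state_graph_igraph(graph)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Export a timed continuous Petri net as PNML
#'
#' Writes standard PNML (place/transition/arc) with the initial marking;
#' rate constants and the delayed gate subnet are annotated in
#' \code{toolspecific} text so the structural net remains schema-valid.
#'
#' @param tcpn a \code{tcpn}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
export_pnml <- function(tcpn, path) {
  stopifnot(inherits(tcpn, "tcpn"))
  doc <- xml2::xml_new_root(
    "pnml", xmlns = "http://www.pnml.org/version-2009/grammar/pnml")
  net <- xml2::xml_add_child(
    doc, "net", id = "clocknet",
    type = "http://www.pnml.org/version-2009/grammar/ptnet")
  page <- xml2::xml_add_child(net, "page", id = "page0")
  add_name <- function(node, text) {
    nm <- xml2::xml_add_child(node, "name")
    xml2::xml_add_child(nm, "text", text)
  }
  for (i in seq_len(nrow(tcpn$places))) {
    p <- xml2::xml_add_child(page, "place", id = tcpn$places$name[i])
    add_name(p, tcpn$places$name[i])
    mk <- xml2::xml_add_child(p, "initialMarking")
    xml2::xml_add_child(mk, "text", format(tcpn$places$m0[i]))
  }
  for (i in seq_len(nrow(tcpn$transitions))) {
    tr <- tcpn$transitions[i, ]
    tn <- xml2::xml_add_child(page, "transition", id = tr$name)
    add_name(tn, tr$name)
    if (!is.na(tr$rate)) {
      ts <- xml2::xml_add_child(tn, "toolspecific", tool = "clocknet",
                                version = "1")
      xml2::xml_add_child(ts, "text",
                          paste0("continuous rate=", format(tr$rate)))
    }
    src <- if (tr$kind == "p") paste0("P_", tr$entity, "_n")
           else paste0("P_", tr$entity)
    dst <- if (tr$kind == "p") paste0("P_", tr$entity)
           else paste0("P_", tr$entity, "_n")
    xml2::xml_add_child(page, "arc", id = paste0("a_", tr$name, "_in"),
                        source = src, target = tr$name)
    xml2::xml_add_child(page, "arc", id = paste0("a_", tr$name, "_out"),
                        source = tr$name, target = dst)
  }
  if (!is.null(tcpn$gates)) {
    sch <- tcpn$gates$schedule
    for (i in seq_len(nrow(sch))) {
      e <- sch$entity[i]
      gp <- xml2::xml_add_child(page, "place", id = paste0("G_", e))
      add_name(gp, paste0("G_", e))
      mk <- xml2::xml_add_child(gp, "initialMarking")
      on0 <- gate_on_at(0, sch$on[i], sch$off[i], tcpn$gates$period)
      xml2::xml_add_child(mk, "text", if (on0) "1" else "0")
      for (ev in c("on", "off")) {
        dt <- xml2::xml_add_child(page, "transition",
                                  id = paste0("d_", e, "_", ev))
        add_name(dt, paste0("d_", e, "_", ev))
        ts <- xml2::xml_add_child(dt, "toolspecific", tool = "clocknet",
                                  version = "1")
        xml2::xml_add_child(
          ts, "text",
          paste0("delayed fire_at=", sch[[ev]][i], " period=",
                 tcpn$gates$period))
        if (ev == "on")
          xml2::xml_add_child(page, "arc",
                              id = paste0("a_d_", e, "_on"),
                              source = paste0("d_", e, "_on"),
                              target = paste0("G_", e))
        else
          xml2::xml_add_child(page, "arc",
                              id = paste0("a_d_", e, "_off"),
                              source = paste0("G_", e),
                              target = paste0("d_", e, "_off"))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a simulated trajectory as CSV
#'
#' @param traj a \code{tcpn_trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
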