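# shared helpers for building tiny networks and state vectors in tests

st <- function(...) {
  v <- c(...)
  stats::setNames(as.integer(v), names(v))
}

toy_graph <- function() {
  toy <- toy_fixture()
  build_state_graph(toy$network, toy$params)
}

# index of a state (named levels) among a state graph's rows
state_row <- function(graph, state) {
  hit <- apply(graph$states, 1L, function(r)
    all(r[names(state)] == state))
  which(hit)
}

one_entity_net <- function(k0 = 1L) {
  net <- regulatory_network("G", NULL)
  list(network = net,
       params = parameter_table(net, stats::setNames(as.integer(k0), "G{}")))
}
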