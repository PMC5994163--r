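test_that("resources follow the present-activator / absent-inhibitor rule", {
  toy <- toy_fixture()
  # Y inhibits X: at Y=0 the absent inhibitor is X's resource
  expect_identical(resources(toy$network, "X", st(X = 0, Y = 0)), "Y")
  expect_identical(resources(toy$network, "X", st(X = 0, Y = 1)), character())
  # X activates Y: absent activator is no resource
  expect_identical(resources(toy$network, "Y", st(X = 0, Y = 0)), character())
  expect_identical(resources(toy$network, "Y", st(X = 1, Y = 0)), "X")

  circ <- circadian_fixture()
  s <- st(Bmal = 0, CB = 0, PC = 0, Rev = 0, Myc = 1, p53 = 0)
  # Myc's own activation present, both inhibitors (CB, p53) absent
  expect_identical(resources(circ$network, "Myc", s),
                   c("CB", "Myc", "p53"))
  expect_error(resources(circ$network, "Wee1", s), "unknown entity")
})

test_that("target levels are the K-parameters of the current resources", {
  toy <- toy_fixture()
  expect_identical(target_level(toy$network, toy$params, "X",
                                st(X = 0, Y = 0)), 1L)
  expect_identical(target_level(toy$network, toy$params, "Y",
                                st(X = 0, Y = 0)), 0L)
  circ <- circadian_fixture()
  s <- st(Bmal = 1, CB = 0, PC = 0, Rev = 0, Myc = 0, p53 = 0)
  expect_identical(
    target_level(circ$network, circ$selected, "p53", s), 1L)
})

test_that("asynchronous successors move one entity one unit toward target", {
  toy <- toy_fixture()
  succ <- successors(toy$network, toy$params, st(X = 0, Y = 0))
  expect_length(succ, 1L)
  expect_identical(succ[[1L]], st(X = 1, Y = 0))
  succ2 <- successors(toy$network, toy$params, st(X = 1, Y = 0))
  expect_identical(succ2[[1L]], st(X = 1, Y = 1))
  # repeated calls on equal inputs give equal outputs (purity)
  expect_identical(successors(toy$network, toy$params, st(X = 1, Y = 1)),
                   successors(toy$network, toy$params, st(X = 1, Y = 1)))
})

test_that("the toy state graph is exactly the printed 4-cycle", {
  g <- toy_graph()
  expect_identical(nrow(g$states), 4L)
  cyc <- list(st(X = 0, Y = 0), st(X = 1, Y = 0),
              st(X = 1, Y = 1), st(X = 0, Y = 1))
  idx <- vapply(cyc, function(s) state_row(g, s), integer(1))
  want <- cbind(from = idx, to = idx[c(2, 3, 4, 1)])
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]),
                  paste(want[, 1], want[, 2]))
  expect_false(any(g$deadlock))
})

test_that("state graphs have the full state count and unit-step edges", {
  circ <- circadian_fixture()
  g <- build_state_graph(circ$network, circ$selected)
  expect_identical(nrow(g$states), 64L)
  nonloop <- g$edges[g$edges[, 1] != g$edges[, 2], , drop = FALSE]
  d <- abs(g$states[nonloop[, 1], ] - g$states[nonloop[, 2], ])
  expect_true(all(rowSums(d) == 1L))

  # random instances keep the invariant too
  for (seed in 1:5) {
    rb <- random_brn(3, seed = seed)
    gg <- build_state_graph(rb$network, rb$params)
    expect_identical(nrow(gg$states), 8L)
    nl <- gg$edges[gg$edges[, 1] != gg$edges[, 2], , drop = FALSE]
    if (nrow(nl))
      expect_true(all(rowSums(abs(gg$states[nl[, 1], , drop = FALSE] -
                                    gg$states[nl[, 2], , drop = FALSE])) == 1L))
    # deadlocks carry self-loops so the relation is total
    expect_true(all(lengths(gg$adj) >= 1L))
  }
})

test_that("a self-degrading single entity yields (1)->(0) with a self-loop", {
  one <- one_entity_net(0L)
  g <- build_state_graph(one$network, one$params)
  expect_identical(nrow(g$states), 2L)
  i0 <- state_row(g, st(G = 0)); i1 <- state_row(g, st(G = 1))
  expect_setequal(paste(g$edges[, 1], g$edges[, 2]),
                  paste(c(i1, i0), c(i0, i0)))
  expect_true(g$deadlock[i0])
})

test_that("constructors validate their invariants", {
  expect_error(regulatory_network(c("A", "A"), NULL), "unique")
  expect_error(
    regulatory_network("A", data.frame(source = "A", target = "B",
                                       sign = "+", threshold = 1)),
    "not declared")
  expect_error(
    regulatory_network(c("A", "B"),
                       data.frame(source = "A", target = "B",
                                  sign = "+", threshold = 2)),
    "threshold")
  toy <- toy_fixture()
  expect_error(parameter_table(toy$network, c("X{}" = 0L)), "missing")
  expect_error(parameter_table(toy$network,
                               c("X{}" = 0L, "X{Y}" = 2L,
                                 "Y{}" = 0L, "Y{X}" = 1L)),
               "lie in")
})
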