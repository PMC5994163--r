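test_that("atom labeling and reachability on the toy cycle", {
  g <- toy_graph()
  origin <- ctl_and(ctl_atom("X", "=", 0), ctl_atom("Y", "=", 0))
  lab <- ctl_check(g, origin)
  expect_identical(sum(lab), 1L)
  expect_true(lab[state_row(g, st(X = 0, Y = 0))])
  # every state of the cycle reaches the origin, and keeps doing so
  expect_true(all(ctl_check(g, ctl_EF(origin))))
  expect_true(all(ctl_check(g, ctl_AG(ctl_EF(origin)))))
  expect_true(ctl_satisfies(g, ctl_EF(origin)))
  expect_false(ctl_satisfies(g, ctl_atom("X", "=", 0)))
  expect_error(ctl_check(g, ctl_atom("Z", "=", 0)), "unknown entity")
  expect_error(ctl_check(g, ctl_atom("X", "=", 5)), "out of range")
})

test_that("the checker agrees with the brute-force oracle on random inputs", {
  set.seed(42)
  n_pairs <- 0L
  while (n_pairs < 200L) {
    n <- sample(2:4, 1L)
    rb <- random_brn(n, seed = sample.int(10000L, 1L))
    g <- build_state_graph(rb$network, rb$params)
    for (j in 1:4) {
      f <- random_ctl_formula(entity_names(rb$network), depth = 4L)
      expect_identical(ctl_check(g, f), brute_force_ctl(g, f),
                       info = paste("formula:", ctl_text(f)))
      n_pairs <- n_pairs + 1L
    }
  }
})

test_that("CTL dualities hold extensionally on random inputs", {
  set.seed(7)
  for (i in 1:25) {
    rb <- random_brn(sample(2:4, 1L), seed = 1000L + i)
    g <- build_state_graph(rb$network, rb$params)
    f <- random_ctl_formula(entity_names(rb$network), depth = 3L)
    expect_identical(ctl_check(g, ctl_AG(f)),
                     !ctl_check(g, ctl_EF(ctl_not(f))))
    expect_identical(ctl_check(g, ctl_AF(f)),
                     !ctl_check(g, ctl_EG(ctl_not(f))))
    expect_identical(ctl_check(g, ctl_AX(f)),
                     !ctl_check(g, ctl_EX(ctl_not(f))))
    # EF is monotone: it contains the base set
    base <- ctl_check(g, f)
    expect_true(all(ctl_check(g, ctl_EF(f)) | !base))
  }
})

test_that("the formula parser round-trips constructed formulas", {
  set.seed(11)
  for (i in 1:50) {
    f <- random_ctl_formula(c("X", "Y"), depth = 4L)
    g <- parse_ctl(ctl_text(f))
    expect_identical(ctl_text(g), ctl_text(f))
  }
  f <- parse_ctl("X=0 & Y=0 -> E[X=0 U Y=1] | !AG(X<=1)")
  expect_s3_class(f, "ctl_formula")
  # implication is right-associative
  h <- parse_ctl("X=0 -> Y=0 -> X=1")
  expect_identical(h$rhs$kind, "implies")
  expect_error(parse_ctl("EF("), "syntax")
  expect_error(parse_ctl("X=="), "syntax")
})

test_that("the psi library encodes the published observations", {
  psi <- psi_library()
  expect_named(psi, c("psi1", "psi2", "psi3", "psi4", "psi5", "psi_all"))
  # psi1's initial state leaves Bmal unconstrained, as printed
  expect_false(grepl("Bmal", ctl_text(psi$psi1)))
  expect_match(ctl_text(psi$psi4), "EF\\(EG\\(Myc=1\\)\\)")
  # atoms refer to the circadian entities, so the toy graph must refuse
  expect_error(ctl_check(toy_graph(), psi$psi5), "unknown entity")
  # the designated table's state graph satisfies all five in all states
  circ <- circadian_fixture()
  g <- build_state_graph(circ$network, circ$selected)
  expect_true(ctl_satisfies(g, psi$psi_all))
})

test_that("universal persistence claims are unsatisfiable across the space", {
  # asynchronous dynamics always keep a path on which the poised
  # antagonist (p53 on Myc, Myc's own shutdown on p53) fires, so the
  # AG variants of the persistence properties hold in no state, for any
  # admissible table; this is why the library uses the EG reading
  circ <- circadian_fixture()
  psiU <- psi_library(universal = TRUE)
  for (tb in enumerate_tables(circ$space)) {
    g <- build_state_graph(circ$network, tb)
    expect_identical(sum(ctl_check(g, psiU$psi4)), 0L)
    expect_identical(sum(ctl_check(g, psiU$psi5)), 0L)
  }
})
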