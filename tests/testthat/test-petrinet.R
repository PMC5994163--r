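rates_unit <- function(net) {
  data.frame(entity = clocknet:::entity_names(net),
             activation = 1, inhibition = 1)
}

test_that("conversion builds complementary places and p/n transitions", {
  circ <- circadian_fixture()
  pn <- logical_to_petrinet(circ$network, circ$selected)
  expect_identical(nrow(pn$places), 12L)
  expect_identical(nrow(pn$transitions), 12L)
  # complementary pairs start at (0, 1): level 0 everywhere
  expect_true(all(pn$places$m0[!pn$places$complement] == 0))
  expect_true(all(pn$places$m0[pn$places$complement] == 1))

  toy <- toy_fixture()
  pn2 <- logical_to_petrinet(toy$network, toy$params)
  expect_identical(nrow(pn2$places), 4L)
  expect_identical(nrow(pn2$transitions), 4L)

  multi <- regulatory_network(data.frame(name = "A", max_level = 2), NULL)
  pmulti <- parameter_table(multi, c("A{}" = 0L))
  expect_error(logical_to_petrinet(multi, pmulti), "boolean")
})

test_that("rate and gate attachment validate their inputs", {
  toy <- toy_fixture()
  pn <- logical_to_petrinet(toy$network, toy$params)
  expect_error(attach_rates(pn, data.frame(entity = "X", activation = 1,
                                           inhibition = 1)),
               "no rates")
  expect_error(simulate_tcpn(pn, 10), "attach rates")
  circ <- circadian_fixture()
  pnc <- logical_to_petrinet(circ$network, circ$selected)
  pnc <- attach_rates(pnc, rate_preset("normal"))
  expect_error(attach_gates(pnc, data.frame(entity = "Myc", on = 0, off = 12)),
               "must not be gated")
  expect_error(attach_gates(pnc, data.frame(entity = "Bmal", on = 6, off = 6)),
               "differ")
})

test_that("an always-activated entity follows the closed form 1 - exp(-t)", {
  one <- one_entity_net(1L)
  pn <- attach_rates(logical_to_petrinet(one$network, one$params),
                     rates_unit(one$network))
  tr <- simulate_tcpn(pn, t_end = 8, step = 0.01)
  expect_lt(max(abs(tr$P_G - (1 - exp(-tr$time)))), 1e-4)
})

test_that("with both transitions enabled the marking relaxes to act/(act+inh)", {
  one <- one_entity_net(1L)
  pn <- attach_rates(logical_to_petrinet(one$network, one$params),
                     data.frame(entity = "G", activation = 0.6,
                                inhibition = 0.4))
  tr <- simulate_tcpn(pn, t_end = 30, step = 0.05,
                      force_enabled = c("t_G_p", "t_G_n"))
  expected <- 0.6 / (0.6 + 0.4) * (1 - exp(-(0.6 + 0.4) * tr$time))
  expect_lt(max(abs(tr$P_G - expected)), 1e-8)
})

test_that("all-zero rates freeze the marking", {
  one <- one_entity_net(1L)
  pn <- attach_rates(logical_to_petrinet(one$network, one$params),
                     data.frame(entity = "G", activation = 0, inhibition = 0))
  tr <- simulate_tcpn(pn, t_end = 10)
  expect_true(all(tr$P_G == 0))
  expect_true(all(tr$P_G_n == 1))
})

test_that("complementary pairs conserve marking and stay non-negative", {
  circ <- circadian_fixture()
  pn <- logical_to_petrinet(circ$network, circ$selected)
  pn <- attach_rates(pn, rate_preset("normal"))
  pn <- attach_gates(pn, default_gate_schedule())
  tr <- simulate_tcpn(pn, t_end = 120, step = 0.1)
  for (e in c("Bmal", "CB", "PC", "Rev", "Myc", "p53")) {
    s <- tr[[paste0("P_", e)]] + tr[[paste0("P_", e, "_n")]]
    expect_lt(max(abs(s - 1)), 1e-6)
    expect_gte(min(tr[[paste0("P_", e)]]), -1e-9)
    expect_gte(min(tr[[paste0("P_", e, "_n")]]), -1e-9)
  }
})

test_that("gating makes BMAL1 rise on [on, off) and decay on [off, on)", {
  circ <- circadian_fixture()
  pn <- logical_to_petrinet(circ$network, circ$selected)
  pn <- attach_rates(pn, rate_preset("normal"))
  pn <- attach_gates(pn, default_gate_schedule())
  tr <- simulate_tcpn(pn, t_end = 48, step = 0.05)
  rising <- tr$time > 24.1 & tr$time < 29.9    # clock 0-6, gate on
  falling <- tr$time > 30.1 & tr$time < 41.9   # clock 6-18, gate off
  expect_true(all(diff(tr$P_Bmal[rising]) > 0))
  expect_true(all(diff(tr$P_Bmal[falling]) < 0))
})

test_that("trajectories are deterministic and step-halving converges", {
  circ <- circadian_fixture()
  pn <- logical_to_petrinet(circ$network, circ$selected)
  pn <- attach_rates(pn, rate_preset("chronic"))
  pn <- attach_gates(pn, default_gate_schedule())
  a <- simulate_tcpn(pn, t_end = 60, step = 0.1)
  b <- simulate_tcpn(pn, t_end = 60, step = 0.1)
  expect_identical(a, b)
  h <- simulate_tcpn(pn, t_end = 60, step = 0.05)
  common <- match(round(a$time, 8), round(h$time, 8))
  expect_lt(max(abs(as.matrix(h[common, -1]) - as.matrix(a[, -1]))), 1e-4)
})
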