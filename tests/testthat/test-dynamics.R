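ffl_spec <- function() {
  dynamics_spec(alpha = 0.2, gamma = c(X = 0.12, Y = 0.7),
                k = c(X = 0.5, Y = 0.1))
}

test_that("single-step updates follow the gate-combined threshold rule", {
  ffl <- make_circuit("FFL")
  spec <- ffl_spec()
  state <- c(X = 1, Y = 0.7, Z = 0)
  nxt <- step_state(ffl, spec, state, drive = c(X = 1))
  # Y: one activator above threshold -> production gamma_x
  expect_equal(unname(nxt["Y"]), 0.8 * 0.7 + 0.12)
  # Z: AND gate, both regulators above threshold -> gamma_x * gamma_y
  expect_equal(unname(nxt["Z"]), 0.12 * 0.7)

  # repressor autoregulation with y above threshold shuts production off
  ar <- make_circuit("AR")
  arspec <- dynamics_spec(alpha = 0.2, gamma = c(Y = 0.5), k = c(Y = 0.3))
  nxt <- step_state(ar, arspec, c(Y = 0.6))
  expect_equal(unname(nxt["Y"]), 0.8 * 0.6)       # Delta y = -alpha y
  nxt <- step_state(ar, arspec, c(Y = 0.1))       # below threshold: produces
  expect_equal(unname(nxt["Y"]), 0.8 * 0.1 + 0.5)

  # absorbing zero state without drive
  nxt <- step_state(ffl, spec, c(X = 0, Y = 0, Z = 0))
  expect_equal(unname(nxt), c(0, 0, 0))

  # OR gate takes the maximum production factor
  or_spec <- dynamics_spec(alpha = 0.2, gamma = c(X = 0.12, Y = 0.7),
                           k = c(X = 0.5, Y = 0.1), gate = "OR")
  nxt <- step_state(ffl, or_spec, state, drive = c(X = 1))
  expect_equal(unname(nxt["Z"]), 0.7)
})

test_that("dynamics refuse unknown-sign regulation and missing parameters", {
  net <- regnet(data.frame(source = "X", target = "Y", sign = "unknown"))
  spec <- dynamics_spec(alpha = 0.2, gamma = c(X = 1), k = c(X = 1))
  expect_error(step_state(net, spec, c(X = 1, Y = 0)), "unknown-sign")

  net2 <- regnet(data.frame(source = "X", target = "Y", sign = "activator"))
  spec2 <- dynamics_spec(alpha = 0.2, gamma = c(W = 1), k = c(W = 1))
  expect_error(step_state(net2, spec2, c(X = 1, Y = 0)), "missing gamma/k")
})

test_that("FFL saturates at the non-synchronized fixed points", {
  tr <- simulate_network(make_circuit("FFL"), ffl_spec(),
                         initial = c(Y = 0.7, Z = 0),
                         drive = list(X = drive_constant(1)), T = 500)
  yT <- tr$levels[501, "Y"]
  zT <- tr$levels[501, "Z"]
  expect_equal(unname(yT), 0.12 / 0.2, tolerance = 1e-9)   # gamma_x / alpha
  expect_equal(unname(zT), 0.12 * 0.7 / 0.2, tolerance = 1e-9)
  # persistent gap: no synchronization
  expect_equal(sync_error(tr, "Y", "Z", burn_in = 400), 0.18,
               tolerance = 1e-6)
})

test_that("feed-forward fibers synchronize from distinct initial conditions", {
  # SAT-FFF: synchronization into a fixed point
  spec <- dynamics_spec(alpha = 0.06, gamma = c(X = 0.775, Y = 0.775),
                        k = c(X = 0.5, Y = 0.1))
  tr <- simulate_network(make_circuit("SAT_FFF"), spec,
                         initial = c(Y = 0.85, Z = 0),
                         drive = list(X = drive_constant(1)), T = 600)
  expect_lt(sync_error(tr, "Y", "Z", burn_in = 400), 1e-9)

  # UNSAT-FFF: synchronization into a limit cycle
  spec2 <- dynamics_spec(alpha = 0.205, gamma = c(X = 0.454, Y = 0.454),
                         k = c(X = 0.5, Y = 1.0))
  tr2 <- simulate_network(make_circuit("UNSAT_FFF"), spec2,
                          initial = c(Y = 0.9, Z = 0.2),
                          drive = list(X = drive_constant(1)), T = 3000)
  expect_lt(sync_error(tr2, "Y", "Z", burn_in = 2000), 1e-9)
  osc <- detect_oscillation(tr2, "Y", burn_in = 2000)
  expect_true(osc$oscillating)
  expect_gt(osc$amplitude, 0)

  # trivial identity
  expect_equal(sync_error(tr2, "Y", "Y", burn_in = 0), 0)
  expect_error(sync_error(tr2, "Y", "nope"), "unknown gene")
})

test_that("square-wave drive gates expression on and off", {
  spec <- ffl_spec()
  tr <- simulate_network(make_circuit("FFL"), spec,
                         initial = c(Y = 0.7, Z = 0),
                         drive = list(X = drive_square(high = 1, low = 0,
                                                       period = 200)), T = 400)
  # near the end of the first high half-wave y approaches gamma_x / alpha
  expect_equal(unname(tr$levels[100, "Y"]), 0.6, tolerance = 1e-6)
  # during the low half-wave production stops and y decays toward zero
  expect_lt(tr$levels[200, "Y"], 1e-5)
})

test_that("undriven unregulated genes decay geometrically (or hold)", {
  net <- regnet(genes = c("A"))
  spec <- dynamics_spec(alpha = 0.25, gamma = c(A = 1), k = c(A = 1))
  tr <- simulate_network(net, spec, initial = c(A = 1), T = 3)
  expect_equal(unname(tr$levels[, "A"]), 0.75^(0:3))

  hold <- dynamics_spec(alpha = 0.25, gamma = c(A = 1), k = c(A = 1),
                        undriven = "hold")
  tr2 <- simulate_network(net, hold, initial = c(A = 1), T = 3)
  expect_equal(unname(tr2$levels[, "A"]), rep(1, 4))
})

test_that("oscillation detector classifies constant, convergent and periodic tails", {
  expect_false(detect_oscillation(rep(1, 100), burn_in = 10)$oscillating)
  conv <- 0.5 + 0.4 * 0.8^(0:200)   # monotone convergence
  expect_false(detect_oscillation(conv, burn_in = 20)$oscillating)
  per <- rep(c(0.2, 0.9, 0.5), 50)
  d <- detect_oscillation(per, burn_in = 12)
  expect_true(d$oscillating)
  expect_equal(d$period, 3)
  expect_equal(d$amplitude, 0.7)
  expect_error(detect_oscillation(c(1, 2), burn_in = 5), "too short")
})

test_that("trajectories expose a tidy (time, gene, level) view", {
  tr <- simulate_network(make_circuit("FFL"), ffl_spec(),
                         initial = c(Y = 0.7), T = 5)
  df <- as.data.frame(tr)
  expect_equal(names(df), c("time", "gene", "level"))
  expect_equal(nrow(df), 6 * 3)
  expect_equal(df$level[df$gene == "Y" & df$time == 0], 0.7)
})
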