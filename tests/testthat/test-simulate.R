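test_that("signal programs honor their shape contracts", {
  pulse <- signal_program("gaussian_pulse", s_min = 10, s_max = 80,
                          center = 100, tau = 20)
  expect_equal(pulse$value(100), 80)
  expect_equal(pulse$value(1e9), 10)
  expect_equal(pulse$value(100 + 20), 10 + 70 * exp(-0.5), tolerance = 1e-12)
  wie <- signal_program("wiener", s_start = 30, sigma = 1.5, dt = 0.01,
                        seed = 4, t_max = 100)
  expect_true(all(wie$value(seq(0, 100, by = 0.5)) >= 0))
  wie2 <- signal_program("wiener", s_start = 30, sigma = 1.5, dt = 0.01,
                         seed = 4, t_max = 100)
  expect_identical(wie$path, wie2$path)
})

test_that("trajectories respect equilibria of the flow", {
  mod <- reference_circuit("A1_mushroom")
  ss <- steady_states(mod, S = 10)
  stable <- ss[ss$stable, ]
  w0 <- as.numeric(stable[1, 1:2])
  sig <- signal_program("constant", s_max = 10)
  tr <- simulate_circuit(mod, sig, t_span = c(0, 100), initial_state = w0)
  expect_lt(max(abs(tr$states[nrow(tr$states), ] - w0)), 1e-6 * (1 + max(w0)))
  # random start relaxes onto some root of the flow
  set.seed(12)
  tr2 <- simulate_circuit(mod, sig, t_span = c(0, 400),
                          initial_state = runif(2, 0, 300))
  final <- tr2$states[nrow(tr2$states), ]
  d <- apply(as.matrix(ss[, 1:2]), 1, function(w)
    sqrt(sum((w - final)^2)) / (1 + sqrt(sum(w^2))))
  expect_lt(min(d), 1e-4)
})

test_that("final states classify by branch identity", {
  mod <- reference_circuit("A1_mushroom")
  dg <- trace_diagram(mod, default_s_grid())
  ss <- steady_states(mod, S = 24)  # inside the neck: ON state only
  on_state <- as.numeric(ss[ss$stable, 1:2][1, ])
  sig <- signal_program("constant", s_max = 24)
  tr_on <- simulate_circuit(mod, sig, t_span = c(0, 50),
                            initial_state = on_state)
  expect_equal(classify_final_state(tr_on, dg, mod), "ON")
  # outer locus at low signal is OFF
  sig10 <- signal_program("constant", s_max = 10)
  ss10 <- steady_states(mod, S = 10)
  off_state <- ss10[ss10$stable, 1:2]
  off_state <- as.numeric(off_state[which.min(off_state$u), ])
  tr_off <- simulate_circuit(mod, sig10, t_span = c(0, 50),
                             initial_state = off_state)
  expect_equal(classify_final_state(tr_off, dg, mod), "OFF")
})

test_that("pulse activation requires intermediate peaks and enough duration", {
  mod <- reference_circuit("A1_mushroom")
  dg <- trace_diagram(mod, default_s_grid())
  am <- activation_map(mod, tau_grid = c(0.5, 8, 30),
                       smax_grid = c(12, 24, 45, 400), diagram = dg,
                       s_min = 10, t_span = c(0, 250))
  # a sufficiently long pulse of intermediate intensity activates
  expect_true(am["30", "24"] || am["30", "45"])
  # very low and very high peaks never activate
  expect_false(any(am[, "12"]))
  expect_false(any(am[, "400"]))
  # very brief pulses are filtered out by the saddle-node ghost
  expect_false(any(am["0.5", ]))
  # activation is monotone in pulse duration at fixed intermediate peak
  for (j in colnames(am)) {
    col <- am[, j]
    expect_true(all(diff(as.integer(col)) >= 0))
  }
})

test_that("quasi-static up and down sweeps show hysteresis", {
  mod <- reference_circuit("A1_mushroom")
  ss5 <- steady_states(mod, S = 5)
  start_lo <- as.numeric(ss5[ss5$stable & ss5$u < 10, 1:2][1, ])
  # slow ramp up into the neck, then back down
  ramp <- function(s_from, s_to, w0) {
    sig <- structure(list(kind = "constant", value = function(t)
      s_from + (s_to - s_from) * pmin(pmax(t / 400, 0), 1)),
      class = "signal_program")
    simulate_circuit(mod, sig, t_span = c(0, 500), initial_state = w0)
  }
  up <- ramp(5, 24, start_lo)
  w_up <- up$states[nrow(up$states), ]
  down <- ramp(24, 5, w_up)
  w_down <- down$states[nrow(down$states), ]
  # after the excursion the state sits on a different branch than it started
  expect_gt(abs(w_down[1] - start_lo[1]) / (1 + start_lo[1]), 0.5)
})

test_that("isola memory is irreversible under noisy signals", {
  mod <- reference_circuit("A1_isola")
  dg <- trace_diagram(mod, default_s_grid())
  for (seed in c(21, 22)) {
    sig <- signal_program("wiener", s_start = 30, sigma = 2.5, dt = 0.01,
                          seed = seed, t_max = 400)
    demo <- isola_memory_demo(mod, sig,
                              reset_rule = list(param = c("p1", "p3"),
                                                value = 20),
                              diagram = dg, t_span = c(0, 400))
    expect_true(demo$on_isola[1])
    # a strong noisy signal crosses a fold and the state leaves the branch
    expect_gte(nrow(demo$events), 1L)
    expect_false(demo$on_isola[length(demo$on_isola)])
    # irreversibility: even when the signal returns inside the isola
    # range, a state that has left the closed branch never rejoins it
    inside <- demo$trajectory$signal > demo$fold_S[1] &
      demo$trajectory$signal < demo$fold_S[2]
    expect_true(all(diff(demo$on_isola[inside]) <= 0))
    expect_equal(classify_final_state(demo$trajectory, dg, mod), "OFF")
  }
  # paths that never exit the isola range produce no events
  sigq <- signal_program("wiener", s_start = 30, sigma = 0.05, dt = 0.01,
                         seed = 3, t_max = 150)
  demo_q <- isola_memory_demo(mod, sigq, diagram = dg, t_span = c(0, 150))
  expect_equal(nrow(demo_q$events), 0L)
  expect_true(all(demo_q$on_isola))
})
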