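test_that("signal input follows the Hill form and its contracts", {
  expect_equal(signal_input(10, R = 143, K = 10), 71.5)
  expect_equal(signal_input(5, R = 7, K = 5, n = 2), 3.5)
  expect_equal(signal_input(0, R = 100, K = 10), 0)
  S <- seq(0, 50, length.out = 200)
  q <- signal_input(S, R = 143, K = 10)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= 143))
  expect_error(signal_input(-1, 1, 1), "nonnegative")
  expect_error(signal_input(1, -1, 1), "positive")
  expect_error(signal_input(1, 1, 0), "positive")
})

test_that("generalized RHS reproduces the displayed three-gene system", {
  topo <- printed_3gene_topology()
  ps <- random_parameter_set(3, seed = 11)
  mod <- circuit_model(topo, ps)
  f_gen <- circuit_rhs(mod)
  f_ref <- printed_3gene_rhs(ps)
  set.seed(2)
  for (i in 1:25) {
    w <- exp(runif(3, log(1e-3), log(500)))
    S <- exp(runif(1, log(1e-2), log(1e3)))
    expect_equal(f_gen(w, S), f_ref(w, S), tolerance = 1e-12)
  }
})

test_that("uncoupled genes reduce to the closed-form leak expression", {
  topo <- topology(matrix(0L, 2, 2), signal_mask = c(FALSE, FALSE))
  ps <- parameter_set(p = c(100, 50), l = c(3, 7), k = 0.1,
                      R = c(100, 100), K = c(10, 10), d = c(1, 2))
  f <- circuit_rhs(circuit_model(topo, ps))
  w <- c(5, 5)
  expect_equal(f(w, 10),
               ps$p * ps$l / (1 + ps$l) - ps$d * w, tolerance = 1e-12)
  ss <- steady_states(circuit_model(topo, ps), S = 3)
  expect_equal(nrow(ss), 1L)
  expect_true(ss$stable)
  expect_equal(as.numeric(ss[1, 1:2]),
               ps$p * ps$l / (ps$d * (1 + ps$l)), tolerance = 1e-8)
})

test_that("cross-repressed signal-activated pair has positive rates at the origin", {
  topo <- topology(rbind(c(0L, -1L), c(-1L, 0L)))
  ps <- random_parameter_set(2, seed = 5)
  f <- circuit_rhs(circuit_model(topo, ps))
  S <- 20
  q <- signal_input(S, ps$R, ps$K)
  expected <- ps$p * (ps$l + q) / (1 + ps$l + q)
  expect_equal(f(c(0, 0), S), expected, tolerance = 1e-12)
  expect_true(all(f(c(0, 0), S) > 0))
})

test_that("steady states of the mushroom circuit match dense-seed counts", {
  mod <- reference_circuit("A1_mushroom")
  # inside the first bistable range: 3 equilibria, 2 stable
  ss <- steady_states(mod, S = 10)
  expect_equal(nrow(ss), 3L)
  expect_equal(sum(ss$stable), 2L)
  # far above the mushroom: single stable equilibrium
  ss_hi <- steady_states(mod, S = 3000)
  expect_equal(nrow(ss_hi), 1L)
  expect_true(all(ss_hi$stable))
  # every root passes an independent residual check at tighter tolerance
  f <- circuit_rhs(mod)
  for (i in seq_len(nrow(ss)))
    expect_lt(max(abs(f(as.numeric(ss[i, 1:2]), 10))), 1e-6)
})

test_that("trajectories stay nonnegative and bounded from nonnegative starts", {
  for (seed in 1:4) {
    topo <- random_topology(2, seed)
    ps <- random_parameter_set(2, seed + 100)
    mod <- circuit_model(topo, ps)
    sig <- signal_program("constant", s_max = 15)
    set.seed(seed)
    init <- runif(2, 0, ps$p / ps$d)
    tr <- simulate_circuit(mod, sig, t_span = c(0, 30),
                           initial_state = init, n_out = 100)
    expect_true(all(tr$states >= -1e-8))
    bound <- rep(ps$p / ps$d + 1e-6, each = nrow(tr$states))
    expect_true(all(t(tr$states) <= ps$p / ps$d + pmax(init, 0) + 1e-6))
  }
})

test_that("model assumptions are applied before evaluation", {
  topo <- topology(rbind(c(0L, -1L), c(-1L, 0L)))
  ps <- random_parameter_set(2, seed = 9)
  mod <- circuit_model(topo, ps, assumptions = list(d = c(1, 2)))
  expect_equal(mod$params$d, c(1, 2))
  expect_error(circuit_model(topo, ps, assumptions = list(zz = 1)),
               "unknown assumption")
})
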