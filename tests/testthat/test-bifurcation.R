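test_that("extended Jacobian matches finite differences and analytics", {
  # 1-state toy with known derivatives
  toy <- function(w, S) S - w^2
  expect_equal(extended_jacobian(toy, 0, 0), matrix(c(0, 1), 1),
               tolerance = 1e-8)
  expect_equal(extended_jacobian(toy, 2, 1), matrix(c(-4, 1), 1),
               tolerance = 1e-6)
  # analytic circuit Jacobian vs central differences of the RHS
  for (seed in c(3, 7)) {
    for (n in 2:3) {
      mod <- circuit_model(random_topology(n, seed),
                           random_parameter_set(n, seed + 50))
      f <- circuit_rhs(mod)
      set.seed(seed)
      w <- exp(runif(n, log(0.5), log(200)))
      S <- exp(runif(1, log(1), log(500)))
      Q <- extended_jacobian(mod, w, S)
      expect_identical(dim(Q), c(n, n + 1L))
      Qfd <- extended_jacobian(f, w, S)
      expect_equal(Q, Qfd, tolerance = 1e-5)
    }
  }
})

test_that("tangent vector is the unit null vector with fixed sign", {
  expect_equal(tangent_vector(matrix(c(0, 1), 1)), c(1, 0))
  expect_equal(tangent_vector(matrix(c(1, 0), 1)), c(0, 1))
  set.seed(4)
  for (i in 1:20) {
    Q <- matrix(rnorm(12), 3, 4)
    beta <- tangent_vector(Q)
    expect_equal(sqrt(sum(beta^2)), 1, tolerance = 1e-12)
    expect_lt(max(abs(Q %*% beta)), 1e-8 * norm(Q, "F"))
    expect_gt(beta[which.max(abs(beta))], 0)
  }
  # rank-deficient extended Jacobian triggers the degeneracy error
  Qdeg <- rbind(c(1, 2, 3), c(2, 4, 6))
  expect_error(tangent_vector(Qdeg), class = "bifdesign_degenerate_point")
})

test_that("fold objective is zero at a fold and 4/5 at the toy regular point", {
  toy <- function(w, S) S - w^2
  expect_equal(saddle_node_objective(toy, 0, 0), 0, tolerance = 1e-10)
  # at (1, 1): Q = [-2, 1], beta = (1, 2)/sqrt(5), J = 4/5
  expect_equal(saddle_node_objective(toy, 1, 1), 0.8, tolerance = 1e-8)
  # far from the equilibrium manifold the residual gate trips
  expect_error(saddle_node_objective(toy, 5, 0), "equilibrium")
})

test_that("detected saddle nodes satisfy the fold conditions sharply", {
  mod <- reference_circuit("A1_mushroom")
  dg <- trace_diagram(mod, default_s_grid())
  expect_equal(nrow(dg$saddle_nodes), 4L)
  f <- circuit_rhs(mod)
  for (i in seq_len(nrow(dg$saddle_nodes))) {
    w <- as.numeric(dg$saddle_nodes[i, c("u", "v")])
    S <- dg$saddle_nodes$S[i]
    expect_lt(max(abs(f(w, S))) / max(mod$params$p), 1e-10)
    expect_lt(dg$saddle_nodes$J[i], 1e-8)
    ev <- eigen(extended_jacobian(mod, w, S)[, 1:2])$values
    expect_lt(min(abs(Re(ev))), 1e-4)
  }
})
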