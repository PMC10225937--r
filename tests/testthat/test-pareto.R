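test_that("pareto front handles the elementary cases", {
  out <- pareto_front(rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 1)))
  expect_equal(unname(out$points), rbind(c(1, 1)))
  # strict trade-off: all points on the front
  pts <- rbind(c(4, 1), c(5, 2), c(6, 3))
  out2 <- pareto_front(pts, orientation = c("min", "max"))
  expect_equal(nrow(out2$points), 3L)
  expect_equal(out2$points[, 1], c(4, 5, 6))
  expect_length(pareto_front(matrix(numeric(0), 0, 2))$payloads, 0L)
  expect_error(pareto_front(pts, orientation = "min"), "each objective")
})

test_that("pareto front agrees with the brute-force domination oracle", {
  oracle <- function(P, sgn) {
    Q <- sweep(P, 2, sgn, `*`)
    keep <- vapply(seq_len(nrow(Q)), function(i)
      !any(vapply(seq_len(nrow(Q)), function(j)
        j != i && all(Q[j, ] <= Q[i, ]) && any(Q[j, ] < Q[i, ]), TRUE)),
      TRUE)
    sort(which(keep))
  }
  set.seed(42)
  for (case in 1:100) {
    d <- sample(2:3, 1)
    npt <- sample(5:40, 1)
    P <- matrix(round(rnorm(npt * d), sample(0:2, 1)), npt, d)
    orient <- sample(c("min", "max"), d, replace = TRUE)
    sgn <- ifelse(orient == "max", -1, 1)
    got <- sort(pareto_front(P, orientation = orient)$index)
    expect_identical(got, oracle(P, sgn))
  }
})

test_that("epsilon sweep recovers the simplex edge on the two-objective toy", {
  # feasible set: x on the unit simplex (x1 + x2 = 1, x >= 0); minimizing
  # x1 under x2 <= eps gives x1 = 1 - eps
  problem <- list(lower = c(0, 0), upper = c(1, 1),
                  objectives = list(function(x) x[1], function(x) x[2]),
                  eq = function(x) sum(x) - 1)
  eps <- c(0.2, 0.4, 0.6, 0.8)
  sw <- epsilon_constraint_sweep(problem, objective_index = 1,
                                 epsilon_grid = eps, n_starts = 25,
                                 seed = 2)
  vals <- vapply(sw$levels, function(l) l$objectives[1], 0)
  expect_equal(vals, 1 - eps, tolerance = 1e-3)
  # the union is the sampled edge of the front
  expect_equal(nrow(sw$front$points), length(eps))
  # single-objective problems are rejected
  expect_error(epsilon_constraint_sweep(list(objectives = list(identity)),
                                        1, eps), "2 objectives")
})

test_that("burden-constrained design solutions do not exceed multistart burdens", {
  ref_x <- reference_x()
  y <- rbind(c(-1L, -1L), c(-1L, 0L))
  prob <- design_problem(n_genes = 2, y_lower = y, y_upper = y,
                         x_lower = ref_x / 10, x_upper = ref_x * 10,
                         objectives = c("psi", "protein_burden"))
  pool <- suppressWarnings(multistart_search(prob, n_runs = 40, seed = 6))
  expect_gte(length(pool$solutions), 1L)
  burdens <- vapply(pool$solutions, function(s) sum(s$params$p), 0)
  sw <- suppressWarnings(
    epsilon_constraint_sweep(prob, objective_index = 2,
                             epsilon_grid = 1e-6, n_starts = 40, seed = 6))
  expect_true(sw$levels[[1]]$feasible)
  expect_lte(sw$levels[[1]]$objectives[2], max(burdens))
})
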