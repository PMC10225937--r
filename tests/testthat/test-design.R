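test_that("fold placement objective matches its contracts", {
  # toy normal form: one fold at the origin
  toy <- function(w, S) S - w^2
  expect_equal(mushroom_objective(toy, list(list(S = 0, omega = 0)),
                                  n_folds = 1L), 0, tolerance = 1e-10)
  # all four folds of the traced reference mushroom give Psi <= 4e-8
  mod <- reference_circuit("A1_mushroom")
  dg <- trace_diagram(mod, default_s_grid())
  psi <- mushroom_objective(mod, dg$saddle_nodes, n_folds = 4L)
  expect_lt(psi, 4e-8)
  # wrong fold count is a precondition error
  expect_error(mushroom_objective(mod, dg$saddle_nodes[1:3, ],
                                  n_folds = 4L), "expected 4")
})

test_that("design problems validate their inputs", {
  expect_error(target_box(c(5, 1), cbind(0, 10)), "increasing")
  expect_error(target_box(c(1, 5), cbind(10, 0)), "increasing")
  p <- design_problem(n_genes = 2)
  expect_equal(p$n_folds, 4L)
  expect_length(p$boxes, 2L)
  expect_error(design_problem(n_genes = 2, n_folds = 4, boxes =
                                bifdesign:::default_target_boxes(2)[1]),
               "per fold")
  expect_error(design_problem(n_genes = 2, y_lower = matrix(2L, 2, 2),
                              y_upper = matrix(2L, 2, 2)), "edge bounds")
  expect_error(design_problem(n_genes = 2, curvature_signs = c(1, -1)),
               "two-fold")
})

test_that("identical start seeds give identical solve records", {
  ref_x <- reference_x()
  y <- rbind(c(-1L, -1L), c(-1L, 0L))
  prob <- design_problem(n_genes = 2, y_lower = y, y_upper = y,
                         x_lower = ref_x / 10, x_upper = ref_x * 10)
  a <- suppressWarnings(solve_single(prob, 12345))
  b <- suppressWarnings(solve_single(prob, 12345))
  expect_identical(class(a), class(b))
  if (inherits(a, "design_solution")) {
    expect_identical(a$x, b$x)
    expect_identical(a$folds, b$folds)
  } else {
    expect_identical(a$reason, b$reason)
  }
})

test_that("forbidding regulation forbids folds", {
  # k pinned (numerically) to zero: uncoupled models cannot fold
  ref_x <- reference_x()
  lo <- ref_x / 10; hi <- ref_x * 10
  lo["k"] <- 1e-12; hi["k"] <- 1.0000001e-12
  prob <- design_problem(n_genes = 2, x_lower = lo, x_upper = hi)
  res <- suppressWarnings(multistart_search(prob, n_runs = 25, seed = 3))
  expect_length(res$solutions, 0L)
})

test_that("multistart rejects empty run budgets and aggregates by topology", {
  prob <- design_problem(n_genes = 2)
  expect_error(multistart_search(prob, n_runs = 0), "n_runs")
  ref_x <- reference_x()
  y <- rbind(c(-1L, -1L), c(-1L, 0L))
  probT <- design_problem(n_genes = 2, y_lower = y, y_upper = y,
                          x_lower = ref_x / 10, x_upper = ref_x * 10)
  res <- suppressWarnings(multistart_search(probT, n_runs = 30, seed = 2))
  if (length(res$solutions)) {
    expect_true(all(res$frequency$topology == paste(as_topology_vector(
      topology(y, c(TRUE, TRUE))), collapse = ",")))
    expect_equal(sum(res$frequency$hits), length(res$solutions))
    # every verified solution re-classifies as a mushroom with folds in box
    for (s in res$solutions) {
      expect_true(s$verified_label %in% c("mushroom", "inverted_mushroom"))
      expect_lt(s$psi, 1e-6)
      expect_equal(nrow(s$folds), 4L)
    }
    # solution sets carry the design vectors
    sets <- solution_sets(res)
    expect_equal(nrow(sets[[1]]$param_rows), length(res$solutions))
  }
})

test_that("search recovers a mushroom near the reference values", {
  ref_x <- reference_x()
  y <- rbind(c(-1L, -1L), c(-1L, 0L))
  prob <- design_problem(n_genes = 2, y_lower = y, y_upper = y,
                         x_lower = ref_x / 10, x_upper = ref_x * 10)
  res <- suppressWarnings(multistart_search(prob, n_runs = 60, seed = 1,
                                            stop_after = 1))
  expect_gte(length(res$solutions), 1L)
  s <- res$solutions[[1]]
  expect_true(s$verified_label %in% c("mushroom", "inverted_mushroom"))
  # independently re-verify: residuals, J, classification, fold-in-box
  f <- circuit_rhs(circuit_model(s$topology, s$params))
  for (i in seq_len(nrow(s$folds))) {
    w <- as.numeric(s$folds[i, c("u", "v")])
    expect_lt(max(abs(f(w, s$folds$S[i]))) / max(s$params$p), 1e-9)
    expect_lt(s$folds$J[i], 1e-8)
  }
  dg <- trace_diagram(circuit_model(s$topology, s$params), default_s_grid())
  expect_true(dg$label %in% c("mushroom", "inverted_mushroom"))
})

test_that("isola design requires two folds and flipped curvature selects the switch", {
  expect_error(isola_design(design_problem(n_genes = 2, n_folds = 4)),
               "n_folds = 2")
  # a two-fold problem built around the isola reference values verifies
  ref_x <- reference_x()
  ref_x["p1"] <- 200
  y <- rbind(c(-1L, -1L), c(-1L, 0L))
  boxes <- list(target_box(c(2, 2000), cbind(c(0.01, 0.01), c(300, 800))))
  prob <- design_problem(n_genes = 2, y_lower = y, y_upper = y,
                         x_lower = ref_x / 4, x_upper = ref_x * 4,
                         boxes = rep(boxes, 1), n_folds = 2,
                         curvature_signs = c(1, -1))
  res <- suppressWarnings(isola_design(prob, n_runs = 40, seed = 5))
  if (length(res$solutions)) {
    for (s in res$solutions) expect_equal(s$verified_label, "isola")
  }
  # flipped signs target the open hysteresis switch instead
  prob2 <- prob
  prob2$curvature_signs <- c(-1, 1)
  res2 <- suppressWarnings(isola_design(prob2, n_runs = 25, seed = 5))
  if (length(res2$solutions)) {
    for (s in res2$solutions)
      expect_equal(s$verified_label, "bistable_switch")
  }
})

test_that("single-input screens find no two-gene mushrooms", {
  prob <- design_problem(n_genes = 2, signal_mask = c(TRUE, FALSE))
  res <- suppressWarnings(multistart_search(prob, n_runs = 120, seed = 17))
  expect_length(res$solutions, 0L)
})
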