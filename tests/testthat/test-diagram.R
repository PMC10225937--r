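test_that("uncoupled circuits trace to a monotone monostable diagram", {
  topo <- topology(matrix(0L, 2, 2), signal_mask = c(FALSE, FALSE))
  ps <- parameter_set(p = c(100, 50), l = c(3, 7), k = 0.1,
                      R = c(100, 100), K = c(10, 10), d = c(1, 2))
  dg <- trace_diagram(circuit_model(topo, ps), default_s_grid(60))
  expect_equal(dg$label, "monostable")
  expect_equal(nrow(dg$saddle_nodes), 0L)
  expect_equal(max(dg$counts$n_total), 1L)
})

test_that("reference mushroom traces to 4 folds, 3 stable loci, 2 bistable ranges", {
  dg <- trace_diagram(reference_circuit("A1_mushroom"), default_s_grid())
  expect_equal(dg$label, "mushroom")
  expect_equal(nrow(dg$saddle_nodes), 4L)
  expect_equal(nrow(dg$bistable_ranges), 2L)
  # two disjoint bistable signal windows
  br <- dg$bistable_ranges[order(dg$bistable_ranges[, 1]), ]
  expect_lt(br[1, 2], br[2, 1])
  # three stable loci: outer-left, head, outer-right
  stable_branches <- dg$branches[dg$branches$stable %in% TRUE, ]
  expect_gte(nrow(stable_branches), 3L)
})

test_that("raising the leakiness pinches the mushroom into a verified isola", {
  dg <- trace_diagram(reference_circuit("A1_isola"), default_s_grid())
  expect_equal(dg$label, "isola")
  expect_equal(nrow(dg$saddle_nodes), 2L)
  cc <- bifdesign:::closed_two_fold_component(dg)
  expect_false(is.null(cc))
  expect_true(isola_curvature_check(dg))
})

test_that("traced equilibrium counts agree with an independent dense root sweep", {
  mod <- reference_circuit("A1_mushroom")
  dg <- trace_diagram(mod, default_s_grid())
  set.seed(31)
  s_check <- exp(runif(20, log(0.25), log(1900)))
  for (S in s_check) {
    ss <- steady_states(mod, S, n_seed_axis = 10L)
    # count from the diagram: branches whose S-extent covers this signal
    g <- dg$counts$S[which.min(abs(log(dg$counts$S) - log(S)))]
    # compare to the sweep count at the nearest traced grid point
    ss_g <- steady_states(mod, g, n_seed_axis = 10L)
    expect_equal(dg$counts$n_total[dg$counts$S == g], nrow(ss_g))
    expect_true(nrow(ss) %in% c(1L, 3L))
  }
})

test_that("stable and unstable segments alternate across each fold", {
  dg <- trace_diagram(reference_circuit("A1_mushroom"), default_s_grid())
  br <- dg$branches
  for (f in dg$saddle_nodes$fold) {
    incident <- br[(!is.na(br$start) & br$start == f) |
                     (!is.na(br$end) & br$end == f), ]
    expect_equal(nrow(incident), 2L)
    expect_setequal(incident$stable, c(TRUE, FALSE))
  }
})

test_that("isola curvature geometry: circle passes, open S-curve fails", {
  circle <- circle_isola_diagram()
  expect_true(isola_curvature_check(circle))
  expect_equal(circle$label, "isola")
  scurve <- s_curve_diagram()
  expect_false(isola_curvature_check(scurve))
  expect_equal(scurve$label, "bistable_switch")
  # fewer than 2 folds: not applicable
  mono <- trace_diagram(circuit_model(topology(matrix(0L, 2, 2),
                                               c(FALSE, FALSE)),
                                      parameter_set(c(10, 10), c(1, 1),
                                                    0.1, c(10, 10),
                                                    c(10, 10), c(1, 1))),
                        default_s_grid(60))
  expect_error(isola_curvature_check(mono), "not applicable")
})

test_that("lowering the v degradation pinches the mushroom before it collapses", {
  mod <- reference_circuit("A1_mushroom")
  labels <- vapply(c(1.38, 0.9, 0.45), function(dv)
    trace_diagram(set_param(mod, "dv", dv), default_s_grid())$label, "")
  expect_identical(labels, c("mushroom", "isola", "monostable"))
})

test_that("a fully symmetric two-gene circuit yields an exchange-symmetric diagram", {
  topo <- topology(rbind(c(0L, -1L), c(-1L, 0L)))
  ps <- parameter_set(p = 300, l = 20, k = 0.05, R = 200, K = 30, d = 1,
                      n_genes = 2L)
  dg <- trace_diagram(circuit_model(topo, ps), default_s_grid(60))
  for (g in sort(unique(dg$points$S))) {
    pts <- dg$points[dg$points$S == g, c("u", "v")]
    swapped <- data.frame(u = pts$v, v = pts$u)
    for (i in seq_len(nrow(pts))) {
      d_min <- min(sqrt((swapped$u - pts$u[i])^2 +
                          (swapped$v - pts$v[i])^2) /
                     (1 + sqrt(pts$u[i]^2 + pts$v[i]^2)))
      expect_lt(d_min, 1e-6)
    }
  }
})

test_that("phase map around the sweepable parameterization shows all four regimes", {
  mod <- reference_circuit("A3_base")
  pm <- phase_map(mod,
                  axis1 = list(name = "dv", grid = c(1.5, 2.5, 4.5, 5.5, 10)),
                  axis2 = list(name = "k", grid = c(0.1, 0.15)),
                  s_grid = default_s_grid())
  expect_true(all(c("mushroom", "isola", "bistable_switch", "monostable")
                  %in% pm))
  # degenerate 1x1 grid at the mushroom fixture values
  pm1 <- phase_map(reference_circuit("A1_mushroom"),
                   axis1 = list(name = "dv", grid = 1.38),
                   axis2 = list(name = "k", grid = 9.04e-2),
                   s_grid = default_s_grid())
  expect_identical(as.vector(pm1), "mushroom")
  # the uncoupled limit k -> 0 is monostable
  pm0 <- phase_map(reference_circuit("A1_mushroom"),
                   axis1 = list(name = "dv", grid = 1.38),
                   axis2 = list(name = "k", grid = 1e-12),
                   s_grid = default_s_grid(60))
  expect_identical(as.vector(pm0), "monostable")
})

test_that("classification window truncation yields incomplete mushroom labels", {
  mod <- reference_circuit("A1_mushroom")
  # window starting inside the first bistable range truncates the head left
  sg <- exp(seq(log(8), log(2000), length.out = 70))
  dg <- trace_diagram(mod, sg)
  expect_equal(dg$label, "incomplete_mushroom_left")
  # window ending inside the second bistable range truncates it right
  sg2 <- exp(seq(log(0.2), log(50), length.out = 70))
  dg2 <- trace_diagram(mod, sg2)
  expect_equal(dg2$label, "incomplete_mushroom_right")
})
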