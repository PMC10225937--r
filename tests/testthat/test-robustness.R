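make_set <- function(rows, topo_seed = 1) {
  solution_set(random_topology(2, topo_seed), rows)
}

gauss_rows <- function(n, d, seed, mean = 0, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * d, mean, sd), n, d)
  colnames(m) <- paste0("x", seq_len(d))
  m
}

test_that("standardization centers and scales against the pooled sample", {
  a <- make_set(gauss_rows(60, 4, 1, mean = 5, sd = 2), 1)
  b <- make_set(gauss_rows(40, 4, 2, mean = -1, sd = 0.5), 2)
  std <- standardize_sets(list(a, b))
  pooled <- rbind(std$sets[[1]]$param_rows, std$sets[[2]]$param_rows)
  expect_equal(unname(colMeans(pooled)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 4), tolerance = 1e-12)
  # identical sets transform identically
  std2 <- standardize_sets(list(a, a))
  expect_equal(std2$sets[[1]]$param_rows, std2$sets[[2]]$param_rows)
  # round trip restores the originals
  back <- unstandardize_set(std$sets[[1]], std)
  expect_equal(back$param_rows, a$param_rows, tolerance = 1e-12)
  # zero-variance columns scale to 1 with a warning
  const <- make_set(cbind(x1 = rep(2, 10), x2 = rnorm(10)), 3)
  expect_warning(sc <- standardize_sets(list(const)), "zero pooled variance")
  expect_equal(unname(sc$scale["x1"]), 1)
})

test_that("log-det score follows the determinant scaling identity exactly", {
  rows <- gauss_rows(200, 5, 4)
  base <- robustness_logdet(rows)
  for (c_fac in c(2, 3.7)) {
    expect_equal(robustness_logdet(rows * c_fac),
                 base + 2 * 5 * log(c_fac), tolerance = 1e-9)
  }
  # known diagonal covariance: score approaches sum(2 log sigma_j)
  sds <- c(0.5, 1, 2, 4)
  big <- sweep(gauss_rows(10000, 4, 5), 2, sds, `*`)
  expect_equal(robustness_logdet(big), sum(2 * log(sds)), tolerance = 0.1)
  # degenerate inputs raise the dedicated error
  expect_error(robustness_logdet(rows[1:3, ]), "at least")
  dup <- rows[rep(1, 10), ]
  expect_error(robustness_logdet(dup),
               class = "bifdesign_singular_covariance")
})

test_that("IQR score: constants, uniform columns, and permutation invariance", {
  expect_equal(robustness_iqr(matrix(5, 10, 3)), 0)
  set.seed(6)
  u <- matrix(runif(10000 * 4), ncol = 4)
  expect_equal(robustness_iqr(u), 0.5 * 4, tolerance = 0.02)
  rows <- gauss_rows(50, 4, 7)
  expect_equal(robustness_iqr(rows[, c(3, 1, 4, 2)]),
               robustness_iqr(rows))
  expect_equal(robustness_iqr(rows[sample(50), ]), robustness_iqr(rows))
  expect_error(robustness_iqr(rows[1:3, ]), "at least 4")
})

test_that("scaling standardized rows up increases both scores strictly", {
  rows <- gauss_rows(80, 4, 8)
  for (c_fac in c(1.5, 3)) {
    expect_gt(robustness_logdet(rows * c_fac), robustness_logdet(rows))
    expect_gt(robustness_iqr(rows * c_fac), robustness_iqr(rows))
  }
})

test_that("bootstrap reports are seeded, ordered and consistent", {
  rows <- gauss_rows(1000, 3, 9)
  r1 <- bootstrap_scores(rows, n_boot = 200, seed = 11)
  r2 <- bootstrap_scores(rows, n_boot = 200, seed = 11)
  expect_identical(r1$logdet_boot, r2$logdet_boot)
  expect_identical(r1$iqr_boot, r2$iqr_boot)
  expect_lte(r1$logdet_boot["q25"], r1$logdet_boot["median"])
  expect_lte(r1$logdet_boot["median"], r1$logdet_boot["q75"])
  expect_lte(r1$iqr_boot["q25"], r1$iqr_boot["median"])
  # tight cloud at n = 1000: bootstrap median within 5% of the point score
  expect_lt(abs(r1$iqr_boot["median"] - r1$iqr_score),
            0.05 * abs(r1$iqr_score))
  expect_lt(abs(r1$logdet_boot["median"] - r1$logdet_score),
            0.05 * abs(r1$logdet_score) + 0.05)
  expect_error(bootstrap_scores(rows, n_boot = 10), "n_boot")
})

test_that("robustness-versus-complexity fronts follow the spread structure", {
  topo2 <- topology(rbind(c(0L, -1L), c(-1L, 0L)))          # 2 connections
  topo3 <- topology(rbind(c(-1L, -1L), c(-1L, 0L)))         # 3 connections
  topo4 <- topology(rbind(c(-1L, -1L), c(-1L, -1L)))        # 4 connections
  # spread shrinks as connections grow: only the smallest topology remains
  sets <- list(solution_set(topo2, gauss_rows(80, 4, 1, sd = 4)),
               solution_set(topo3, gauss_rows(80, 4, 2, sd = 1)),
               solution_set(topo4, gauss_rows(80, 4, 3, sd = 0.2)))
  rv <- robustness_vs_complexity(sets)
  expect_equal(nrow(rv$front$points), 1L)
  expect_equal(rv$front$points[1, 1], 2)
  # strict trade-off: spread grows with connections, all on the front
  sets2 <- list(solution_set(topo2, gauss_rows(80, 4, 1, sd = 0.2)),
                solution_set(topo3, gauss_rows(80, 4, 2, sd = 1)),
                solution_set(topo4, gauss_rows(80, 4, 3, sd = 4)))
  rv2 <- robustness_vs_complexity(sets2)
  expect_equal(nrow(rv2$front$points), 3L)
})
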