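# shared fixtures for the test suite: built in code, no stored data

# the printed three-gene example system, written out by hand exactly as
# displayed (cross-repression u<->v plus v<->w, signal on u and v)
printed_3gene_rhs <- function(params) {
  with(params, function(w, S) {
    u <- w[1]; v <- w[2]; wg <- w[3]
    q1 <- R[1] * S^2 / (K[1]^2 + S^2)
    q2 <- R[2] * S^2 / (K[2]^2 + S^2)
    c(p[1] * (l[1] + q1) / (1 + l[1] + q1 + k * v^2) - d[1] * u,
      p[2] * (l[2] + q2) / (1 + l[2] + q2 + k * u^2 + k * wg^2) - d[2] * v,
      p[3] * l[3] / (1 + l[3] + k * v^2) - d[3] * wg)
  })
}

printed_3gene_topology <- function() {
  # y_vu = y_uv = y_wv = y_vw = -1, all others 0; signal on U and V
  e <- matrix(0L, 3, 3)
  e[2, 1] <- e[1, 2] <- e[3, 2] <- e[2, 3] <- -1L
  topology(e, signal_mask = c(TRUE, TRUE, FALSE))
}

random_parameter_set <- function(n_genes, seed) {
  set.seed(seed)
  parameter_set(p = exp(runif(n_genes, log(20), log(1000))),
                l = exp(runif(n_genes, log(1), log(200))),
                k = exp(runif(1, log(1e-3), log(0.5))),
                R = exp(runif(n_genes, log(50), log(500))),
                K = exp(runif(n_genes, log(2), log(300))),
                d = exp(runif(n_genes, log(0.2), log(5))))
}

random_topology <- function(n_genes, seed) {
  set.seed(seed)
  topology(matrix(sample(c(-1L, 0L, 1L), n_genes^2, replace = TRUE),
                  n_genes, n_genes),
           signal_mask = seq_len(n_genes) <= 2L)
}

default_s_grid <- function(n = 80) exp(seq(log(0.2), log(2000),
                                           length.out = n))

# reference design vector of the bundled mushroom circuit
reference_x <- function() c(p0 = 361, p1 = 30, p2 = 411, k = 9.04e-2,
                            R1 = 143, R2 = 300, dv = 1.38, K1 = 10,
                            K2 = 137)

# assemble a synthetic diagram from an analytic closed curve (circle in
# (S, u) space) plus an open stable branch below it; everything is sampled
# on a shared S grid so per-signal equilibrium counts are well defined
circle_isola_diagram <- function(S0 = 50, u0 = 40, r = 20, n = 80) {
  grid <- seq(1, 100, length.out = n)
  inside <- grid > S0 - r & grid < S0 + r
  half <- sqrt(pmax(r^2 - (grid[inside] - S0)^2, 0))
  pts <- rbind(
    data.frame(S = grid, branch = 1L, stable = TRUE, u = 2 + 0.01 * grid),
    data.frame(S = grid[inside], branch = 2L, stable = TRUE,
               u = u0 + half),
    data.frame(S = grid[inside], branch = 3L, stable = FALSE,
               u = u0 - half))
  sn <- data.frame(fold = 1:2, S = c(S0 - r, S0 + r), u = c(u0, u0),
                   J = c(0, 0))
  ends <- data.frame(branch = 1:3, start = c(NA, 1L, 1L),
                     end = c(NA, 2L, 2L))
  bifurcation_diagram(pts, sn, s_range = c(1, 100), branch_ends = ends)
}

# classic open S-curve (hysteresis switch) between folds S1 < S2
s_curve_diagram <- function(S1 = 30, S2 = 70, n = 80) {
  grid <- seq(1, 100, length.out = n)
  lowS <- grid[grid <= S2]
  upS <- grid[grid >= S1]
  midS <- grid[grid >= S1 & grid <= S2]
  pts <- rbind(
    data.frame(S = lowS, branch = 1L, stable = TRUE, u = 5 + 0.05 * lowS),
    data.frame(S = upS, branch = 2L, stable = TRUE, u = 60 + 0.05 * upS),
    data.frame(S = midS, branch = 3L, stable = FALSE,
               u = 10 + 50 * (S2 - midS) / (S2 - S1)))
  sn <- data.frame(fold = 1:2, S = c(S1, S2), u = c(62, 9), J = c(0, 0))
  ends <- data.frame(branch = 1:3, start = c(NA, 1L, 1L),
                     end = c(2L, NA, 2L))
  bifurcation_diagram(pts, sn, s_range = c(1, 100), branch_ends = ends)
}
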