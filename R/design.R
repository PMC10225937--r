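#' Rectangular target region for a saddle-node point
#'
#' Designs prescribe where saddle nodes must sit in the bifurcation
#' diagram through rectangular boxes: an interval for the signal
#' coordinate and per-gene bounds for the state coordinates.
#'
#' @param s_interval numeric `c(lower, upper)` for the signal.
#' @param omega_box numeric matrix `n_genes x 2` (columns lower, upper).
#' @return Object of class `"target_box"`.
#' @export
target_box <- function(s_interval, omega_box) {
  s_interval <- as.numeric(s_interval)
  omega_box <- matrix(as.numeric(omega_box), ncol = 2)
  if (length(s_interval) != 2 || diff(s_interval) <= 0)
    stop("'s_interval' must be an increasing pair")
  if (any(omega_box[, 2] - omega_box[, 1] <= 0))
    stop("'omega_box' rows must be increasing intervals")
  if (any(c(s_interval, omega_box) < 0))
    stop("target boxes must be nonnegative")
  structure(list(s_interval = s_interval, omega_box = omega_box),
            class = "target_box")
}

in_box <- function(box, S, omega) {
  S >= box$s_interval[1] && S <= box$s_interval[2] &&
    all(omega >= box$omega_box[, 1]) && all(omega <= box$omega_box[, 2])
}

# default target boxes: two paired regions (low-signal fold pair,
# high-signal fold pair) wide enough to admit typical designs, with a
# stricter expression range on gene U than on the remaining genes to break
# the U/V symmetry of the superstructure
default_target_boxes <- function(n_genes, n_boxes = 2L) {
  w_hi <- c(300, rep(800, n_genes - 1))
  wb <- cbind(rep(0.01, n_genes), w_hi)
  if (n_boxes == 2L)
    list(target_box(c(0.5, 60), wb), target_box(c(5, 1500), wb))
  else
    rep(list(target_box(c(0.5, 1500), wb)), n_boxes)
}

#' Specify a circuit design problem
#'
#' Bundles everything the automated search needs: the superstructure (edge
#' sign bounds and signal mask), bounds for the real-valued design vector,
#' target boxes for the prescribed saddle nodes, the number of folds and
#' the diagram class to verify against, optional curvature-sign conditions
#' for isola targets, parameter-tying rules, and the signal window used
#' for verification.
#'
#' @param n_genes 2 or 3.
#' @param signal_mask logical vector; default genes 1 and 2 induced.
#' @param y_lower,y_upper integer matrices of edge-sign bounds; defaults
#'   `-1`/`+1` everywhere (the full superstructure). Setting both to the
#'   same matrix fixes the topology.
#' @param x_lower,x_upper named design-vector bounds; default
#'   [default_parameter_bounds()].
#' @param boxes list of [target_box()]; either one box per fold or one box
#'   per fold pair (the default two paired regions).
#' @param n_folds number of prescribed saddle nodes (4 for a mushroom, 2
#'   for an isola or switch).
#' @param target_label diagram class a verified solution must have.
#' @param curvature_signs optional `c(sign at S1, sign at S2)` for
#'   two-fold targets (`c(1, -1)` selects an isola).
#' @param tying parameter-tying overrides, see [params_from_x()].
#' @param s_range signal window for verification tracing.
#' @param s_points number of (log-spaced) verification grid points.
#' @param n_runs default multistart size.
#' @param seed default master seed.
#' @return Object of class `"design_problem"`.
#' @export
design_problem <- function(n_genes = 2L, signal_mask = NULL,
                           y_lower = NULL, y_upper = NULL,
                           x_lower = NULL, x_upper = NULL,
                           boxes = NULL, n_folds = 4L,
                           target_label = if (n_folds == 4L) "mushroom"
                           else "isola",
                           curvature_signs = NULL,
                           objectives = "psi",
                           tying = list(), s_range = c(0.1, 5000),
                           s_points = if (n_genes >= 3) 70L else 90L,
                           n_runs = 100L, seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.null(signal_mask)) signal_mask <- seq_len(n_genes) <= 2L
  if (is.null(y_lower)) y_lower <- matrix(-1L, n_genes, n_genes)
  if (is.null(y_upper)) y_upper <- matrix(1L, n_genes, n_genes)
  storage.mode(y_lower) <- storage.mode(y_upper) <- "integer"
  if (any(y_lower > y_upper)) stop("y_lower must not exceed y_upper")
  if (any(abs(c(y_lower, y_upper)) > 1L))
    stop("edge bounds must lie in {-1, 0, 1}")
  bounds <- default_parameter_bounds(n_genes)
  if (is.null(x_lower)) x_lower <- bounds$lower
  if (is.null(x_upper)) x_upper <- bounds$upper
  nm <- x_names(n_genes)
  if (!all(nm %in% names(x_lower)) || !all(nm %in% names(x_upper)))
    stop("x bounds must be named after the design vector: ",
         paste(nm, collapse = ", "))
  x_lower <- x_lower[nm]; x_upper <- x_upper[nm]
  if (any(x_lower <= 0) || any(x_lower >= x_upper))
    stop("x bounds must be positive with lower < upper")
  n_folds <- as.integer(n_folds)
  if (is.null(boxes)) boxes <- default_target_boxes(n_genes)
  if (!length(boxes) %in% c(n_folds, n_folds / 2L))
    stop("'boxes' must contain one box per fold or per fold pair")
  ok_box <- vapply(boxes, inherits, TRUE, what = "target_box")
  if (!all(ok_box)) stop("'boxes' must be target_box objects")
  if (!is.null(curvature_signs)) {
    if (n_folds != 2L)
      stop("curvature conditions apply to two-fold (isola-type) targets")
    if (length(curvature_signs) != 2)
      stop("'curvature_signs' must have length 2")
  }
  structure(list(n_genes = n_genes, signal_mask = as.logical(signal_mask),
                 y_lower = y_lower, y_upper = y_upper,
                 x_lower = x_lower, x_upper = x_upper,
                 boxes = boxes, n_folds = n_folds,
                 target_label = target_label,
                 curvature_signs = curvature_signs,
                 objectives = objectives,
                 tying = tying, s_range = as.numeric(s_range),
                 s_points = as.integer(s_points),
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "design_problem")
}

# which box does fold k (in S-sorted order) belong to
fold_box <- function(problem, k) {
  if (length(problem$boxes) == problem$n_folds) problem$boxes[[k]]
  else problem$boxes[[ceiling(k / 2)]]
}

#' Saddle-node placement objective
#'
#' The design objective `Psi = sum_k J_k`, where `J_k` is the
#' [saddle_node_objective()] evaluated at the k-th prescribed fold
#' coordinate `(omega_k, S_k)`. `Psi` vanishes exactly when every
#' prescribed coordinate is a saddle-node point of the model; equilibrium
#' feasibility is handled by the solver's constraints, not inside `Psi`.
#' Degenerate points (rank-deficient extended Jacobian) contribute a large
#' finite penalty (`1e6`) with a warning.
#'
#' @param model a [circuit_model()] or function `f(omega, S)`.
#' @param folds list of `list(S = , omega = )` (or a data frame with
#'   columns `S` and the state coordinates).
#' @param n_folds expected number of folds (defaults to 4).
#' @param residual_gate forwarded to [saddle_node_objective()].
#' @return Nonnegative scalar.
#' @export
mushroom_objective <- function(model, folds, n_folds = 4L,
                               residual_gate = 1e-3) {
  if (is.data.frame(folds)) {
    cols <- setdiff(names(folds), c("fold", "S", "J"))
    folds <- lapply(seq_len(nrow(folds)), function(i)
      list(S = folds$S[i], omega = as.numeric(folds[i, cols])))
  }
  if (length(folds) != n_folds)
    stop("expected ", n_folds, " fold coordinates, got ", length(folds))
  total <- 0
  for (f in folds) {
    J <- tryCatch(saddle_node_objective(model, f$omega, f$S,
                                        residual_gate = residual_gate),
                  bifdesign_degenerate_point = function(e) {
                    warning("degenerate point in objective; penalized")
                    1e6
                  })
    total <- total + J
  }
  total
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-run seed derived from the master seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 7919) %% 2147483629)
}

# equilibrium-count profile of a candidate design over a probe signal grid
count_profile <- function(topo, params, s_probe, lattice_axis) {
  m <- circuit_model(topo, params)
  cm <- compile_model(m)
  W0 <- seed_lattice(m, lattice_axis)
  # loose, capped Newton: the probe only needs the window structure
  sw <- cpp_sweep(cm, s_probe, W0, 1e-9, 30L, 1e-4)
  vapply(sw, function(r) nrow(r$states), 0L)
}

# merit of a count profile: rewards interior multistable signal windows
# (up to the number of prescribed fold pairs) and monostable window edges
profile_score <- function(cnt, n_windows_wanted) {
  multi <- cnt >= 3
  r <- rle(multi)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  w_any <- sum(r$values)
  w_int <- sum(r$values & starts > 1 & ends < length(cnt))
  300 * min(w_int, n_windows_wanted) +
    60 * ((cnt[1] == 1) + (cnt[length(cnt)] == 1)) +
    10 * w_any + sum(multi)
}

# score reached when the wanted interior windows exist with monostable edges
profile_target <- function(n_windows_wanted) 300 * n_windows_wanted + 120

#' Single local design solve from a seeded random start
#'
#' One unit of the multistart strategy, a diversification/intensification
#' hybrid followed by a constrained least-squares fold placement:
#'
#' 1. *Sample*: a topology uniform within the superstructure's edge
#'    bounds; design vectors log-uniform within their bounds until one
#'    shows multiple equilibria somewhere on a probe signal grid (up to
#'    `n_div` draws).
#' 2. *Morph*: seeded stochastic hill climbing in log-parameter space on
#'    a diagram-shape merit (number of interior bistable signal windows,
#'    monostable window edges), until the count profile matches the
#'    target class (up to `n_hill` steps).
#' 3. *Place folds*: bounded Levenberg-Marquardt (minpack.lm) on the
#'    stacked residual (equilibrium residuals and tangent last components
#'    at the prescribed folds) over the design vector and fold
#'    coordinates, with fold coordinates confined to their target boxes;
#'    initialized at the morphed candidate's own window borders.
#'
#' A candidate is accepted only if the fold conditions are met
#' (`Psi <= 1e-6` after polishing) and the traced, classified diagram
#' confirms the target label with every saddle node inside its box. The
#' whole run is deterministic given `start_seed`.
#'
#' @param problem a [design_problem()].
#' @param start_seed integer seed for this start.
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @param n_div diversification draws.
#' @param n_hill hill-climbing steps.
#' @param hill_sigma log-space step size of the hill climber.
#' @return A `"design_solution"` (success) or `"design_failure"` list with
#'   diagnostics; never an exception for solver non-convergence.
#' @export
solve_single <- function(problem, start_seed, maxiter = 150L, n_div = 60L,
                         n_hill = 400L, hill_sigma = 0.6) {
  stopifnot(inherits(problem, "design_problem"))
  n <- problem$n_genes
  nf <- problem$n_folds
  nm <- names(problem$x_lower)
  lattice_axis <- if (n >= 3L) 3L else 5L
  s_probe <- exp(seq(log(problem$s_range[1] * 1.5),
                     log(problem$s_range[2] / 1.5), length.out = 21L))
  n_windows <- nf %/% 2L
  with_seed(start_seed, {
    y <- matrix(mapply(function(lo, hi) sample(seq.int(lo, hi), 1L),
                       problem$y_lower, problem$y_upper), n, n)
    topo <- topology(y, problem$signal_mask)
    fail <- function(reason, psi = NA_real_)
      structure(list(success = FALSE, reason = reason, topology = topo,
                     psi = psi, start_seed = start_seed),
                class = "design_failure")
    lx <- log(problem$x_lower); ux <- log(problem$x_upper)
    # diversification: find a multistable candidate
    zx <- NULL; cnt <- NULL
    for (t in seq_len(n_div)) {
      zc <- stats::runif(length(lx), lx, ux)
      x <- stats::setNames(exp(zc), nm)
      cc <- count_profile(topo, params_from_x(x, n, problem$tying),
                          s_probe, lattice_axis)
      if (any(cc >= 3)) { zx <- zc; cnt <- cc; break }
    }
    if (is.null(zx)) return(fail("no multistable candidate found"))
    sc <- profile_score(cnt, n_windows)
    target <- profile_target(n_windows)
    # intensification: stochastic hill climbing on the diagram shape
    # (random coordinate subsets, restart from the incumbent when stuck)
    n_sub <- min(if (n >= 3L) 4L else 3L, length(zx))
    best_z <- zx; best_sc <- sc
    stuck <- 0L; t_best <- 0L
    for (t in seq_len(n_hill)) {
      if (sc >= target) break
      if (t - t_best > 220L) break # no progress; abandon this start
      idx <- sample.int(length(zx), n_sub)
      zp <- zx
      zp[idx] <- pmin(pmax(zp[idx] + stats::rnorm(n_sub, 0, hill_sigma),
                           lx[idx]), ux[idx])
      x <- stats::setNames(exp(zp), nm)
      cc <- count_profile(topo, params_from_x(x, n, problem$tying),
                          s_probe, lattice_axis)
      s2 <- profile_score(cc, n_windows)
      if (s2 >= sc) {
        stuck <- if (s2 > sc) 0L else stuck + 1L
        zx <- zp; sc <- s2; cnt <- cc
        if (sc > best_sc) { best_z <- zx; best_sc <- sc; t_best <- t }
      } else stuck <- stuck + 1L
      if (stuck > 60L) {
        zx <- pmin(pmax(best_z + stats::rnorm(length(zx), 0, 0.5), lx), ux)
        x <- stats::setNames(exp(zx), nm)
        cnt <- count_profile(topo, params_from_x(x, n, problem$tying),
                             s_probe, lattice_axis)
        sc <- profile_score(cnt, n_windows)
        stuck <- 0L
      }
    }
    if (sc < target) return(fail("target diagram shape not reached"))
    x0 <- stats::setNames(exp(zx), nm)
    model0 <- circuit_model(topo, params_from_x(x0, n, problem$tying))
    # fold starting guesses from the candidate's own window borders
    lo_f <- hi_f <- matrix(0, nf, n + 1L)
    for (k in seq_len(nf)) {
      b <- fold_box(problem, k)
      lo_f[k, ] <- log(c(pmax(b$omega_box[, 1], 1e-6), b$s_interval[1]))
      hi_f[k, ] <- log(c(b$omega_box[, 2], b$s_interval[2]))
    }
    trans <- which(diff(cnt >= 3) != 0)
    fold_S_est <- sqrt(s_probe[trans] * s_probe[trans + 1])
    z0f <- matrix(0, nf, n + 1L)
    for (k in seq_len(nf)) {
      Sk <- if (k <= length(fold_S_est)) fold_S_est[k] else
        exp(stats::runif(1, lo_f[k, n + 1L], hi_f[k, n + 1L]))
      Sk <- min(max(Sk, exp(lo_f[k, n + 1L]) * 1.001),
                exp(hi_f[k, n + 1L]) * 0.999)
      eq <- steady_states(model0, Sk, n_seed_axis = lattice_axis)
      wk <- if (nrow(eq) >= 2) {
        co <- as.matrix(eq[, seq_len(n), drop = FALSE])
        dm <- as.matrix(stats::dist(log(co + 1e-9)))
        diag(dm) <- Inf
        ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        exp((log(co[ij[1], ] + 1e-9) + log(co[ij[2], ] + 1e-9)) / 2)
      } else if (nrow(eq) == 1) {
        as.numeric(eq[1, seq_len(n)])
      } else exp(stats::runif(n, lo_f[k, seq_len(n)], hi_f[k, seq_len(n)]))
      wk <- pmin(pmax(wk, exp(lo_f[k, seq_len(n)]) * 1.001),
                 exp(hi_f[k, seq_len(n)]) * 0.999)
      z0f[k, ] <- log(c(wk, Sk))
    }
    z0 <- c(zx, as.numeric(z0f))
    lower <- c(lx, as.numeric(lo_f))
    upper <- c(ux, as.numeric(hi_f))
    nx <- length(lx)
    # weak Tikhonov rows keep the least-squares system overdetermined (the
    # fold system has fewer equations than unknowns) and select the
    # solution nearest the sampled start; mu is small enough not to
    # perturb the fold conditions beyond the acceptance gates
    mu <- 1e-4
    resfun <- function(z) {
      x <- exp(z[seq_len(nx)])
      names(x) <- names(problem$x_lower)
      fz <- matrix(exp(z[-seq_len(nx)]), nf, n + 1L)
      params <- tryCatch(params_from_x(x, n, problem$tying),
                         error = function(e) NULL)
      if (is.null(params))
        return(c(rep(1e3, nf * n + nf), mu * (z - z0)))
      cm <- compile_model(circuit_model(topo, params))
      r <- cpp_fold_system(cm, fz[, seq_len(n), drop = FALSE], fz[, n + 1L])
      r[!is.finite(r)] <- 1e3
      c(r, mu * (z - z0))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = z0, fn = resfun, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info == 0) return(fail("solver error"))
    r <- resfun(fit$par)
    if (any(!is.finite(r))) return(fail("non-finite residuals"))
    res_eq <- max(abs(r[seq_len(nf * n)]))
    psi_hat <- sum(r[nf * n + seq_len(nf)]^2)
    if (res_eq > 1e-5 || psi_hat > 1e-3)
      return(fail("fold conditions not met", psi_hat))
    x <- exp(fit$par[seq_len(nx)])
    names(x) <- names(problem$x_lower)
    fz <- matrix(exp(fit$par[-seq_len(nx)]), nf, n + 1L)
    fail <- function(reason, psi = NA_real_)
      structure(list(success = FALSE, reason = reason, topology = topo,
                     x = x, fold_guess = fz, psi = psi,
                     start_seed = start_seed),
                class = "design_failure")
    params <- params_from_x(x, n, problem$tying)
    accepted <- accepted_labels(problem$target_label)
    model <- circuit_model(topo, params)
    s_grid <- exp(seq(log(problem$s_range[1]), log(problem$s_range[2]),
                      length.out = problem$s_points))
    dg <- tryCatch(trace_diagram(model, s_grid,
                                 n_seed_axis = if (n >= 3L) 6L else 8L),
                   error = function(e) NULL)
    if (is.null(dg)) return(fail("tracing failed", psi_hat))
    if (!dg$label %in% accepted)
      return(fail(paste0("verified as ", dg$label), psi_hat))
    sn <- dg$saddle_nodes[order(dg$saddle_nodes$S), , drop = FALSE]
    if (nrow(sn) != nf) return(fail("fold count mismatch", psi_hat))
    gene_cols <- gene_labels(n)
    for (k in seq_len(nf)) {
      if (!in_box(fold_box(problem, k), sn$S[k],
                  as.numeric(sn[k, gene_cols])))
        return(fail("fold outside its target box", psi_hat))
    }
    if (!is.null(problem$curvature_signs)) {
      cc <- closed_two_fold_component(dg)
      want_isola <- all(problem$curvature_signs == c(1, -1))
      if (want_isola && (is.null(cc) || !isola_curvature_check(dg)))
        return(fail("curvature conditions not met", psi_hat))
      if (!want_isola && !is.null(cc))
        return(fail("curvature conditions not met", psi_hat))
    }
    psi <- sum(sn$J)
    if (psi > 1e-6) return(fail("polished objective above tolerance", psi))
    structure(list(success = TRUE, topology = topo, params = params,
                   x = x, folds = sn, psi = psi, verified_label = dg$label,
                   diagram = dg, start_seed = start_seed),
              class = "design_solution")
  })
}

#' @export
print.design_solution <- function(x, ...) {
  cat(sprintf("design_solution: %s, Psi = %.3g, y = (%s)\n",
              x$verified_label, x$psi,
              paste(as_topology_vector(x$topology), collapse = " ")))
  invisible(x)
}

#' Multistart topology and parameter search
#'
#' Runs [solve_single()] from `n_runs` seeded random starts, aggregates
#' the verified solutions and groups them by topology (raw edge-sign
#' vector; symmetric structures are deliberately kept distinct). The
#' per-topology frequency ranking orders the result. Fully replayable:
#' run `i` uses a seed derived deterministically from `(seed, i)`.
#'
#' @param problem a [design_problem()].
#' @param n_runs number of starts (default `problem$n_runs`).
#' @param seed master seed (default `problem$seed`).
#' @param progress print a line every 100 runs?
#' @param stop_after stop early once this many verified solutions have
#'   been collected (default `Inf`: run all starts).
#' @return Object of class `"design_result"`: list with `solutions` (list
#'   of `design_solution`), `frequency` (data frame: topology key,
#'   connection count, hits), `n_runs`, `seed`.
#' @export
multistart_search <- function(problem, n_runs = problem$n_runs,
                              seed = problem$seed, progress = FALSE,
                              stop_after = Inf) {
  stopifnot(inherits(problem, "design_problem"))
  if (n_runs < 1) stop("'n_runs' must be >= 1")
  sols <- list()
  n_done <- 0L
  for (i in seq_len(n_runs)) {
    s <- solve_single(problem, derive_seed(seed, i))
    n_done <- i
    if (inherits(s, "design_solution")) {
      s$run <- i
      sols[[length(sols) + 1L]] <- s
      if (length(sols) >= stop_after) break
    }
    if (progress && i %% 100L == 0L)
      message(sprintf("run %d/%d: %d verified solutions", i, n_runs,
                      length(sols)))
  }
  design_result(sols, n_done, seed)
}

design_result <- function(sols, n_runs, seed) {
  keys <- vapply(sols, function(s)
    paste(as_topology_vector(s$topology), collapse = ","), "")
  freq <- if (length(keys)) {
    tb <- sort(table(keys), decreasing = TRUE)
    data.frame(topology = names(tb),
               n_connections = vapply(names(tb), function(k)
                 sum(as.integer(strsplit(k, ",")[[1]]) != 0L), 0L),
               hits = as.integer(tb), row.names = NULL)
  } else data.frame(topology = character(0), n_connections = integer(0),
                    hits = integer(0))
  structure(list(solutions = sols, frequency = freq, n_runs = n_runs,
                 seed = seed),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("design_result: %d/%d runs verified, %d distinct topologies\n",
              length(x$solutions), x$n_runs, nrow(x$frequency)))
  if (nrow(x$frequency)) print(utils::head(x$frequency, 10))
  invisible(x)
}

#' Group verified solutions into per-topology solution sets
#'
#' @param result a `"design_result"` from [multistart_search()].
#' @return Named list of `"solution_set"` objects, each holding the
#'   topology and the matrix of successful design vectors (solutions in
#'   rows, parameters in columns), ordered by frequency.
#' @export
solution_sets <- function(result) {
  stopifnot(inherits(result, "design_result"))
  keys <- vapply(result$solutions, function(s)
    paste(as_topology_vector(s$topology), collapse = ","), "")
  out <- list()
  for (key in result$frequency$topology) {
    members <- result$solutions[keys == key]
    rows <- do.call(rbind, lapply(members, function(s) s$x))
    out[[key]] <- solution_set(members[[1]]$topology, rows)
  }
  out
}

#' Build a solution set from a topology and design-vector rows
#'
#' @param topology a [topology()].
#' @param param_rows numeric matrix, one verified design vector per row,
#'   with named columns.
#' @return Object of class `"solution_set"`.
#' @export
solution_set <- function(topology, param_rows) {
  param_rows <- as.matrix(param_rows)
  structure(list(topology = topology, param_rows = param_rows,
                 parameter_names = colnames(param_rows)),
            class = "solution_set")
}

#' Automated isola design
#'
#' Variant of [multistart_search()] targeting a two-fold isola: the
#' problem must prescribe exactly 2 saddle nodes, and acceptance
#' additionally requires the closed-branch curvature conditions (positive
#' at the lower fold, negative at the upper) and a verified `isola`
#' label. Flipping the curvature signs targets the open bistable switch
#' instead.
#'
#' @param problem a [design_problem()] with `n_folds = 2` and
#'   `curvature_signs` set (defaulted to `c(1, -1)` when absent).
#' @param n_runs,seed,progress as in [multistart_search()].
#' @return A `"design_result"`.
#' @export
isola_design <- function(problem, n_runs = problem$n_runs,
                         seed = problem$seed, progress = FALSE) {
  stopifnot(inherits(problem, "design_problem"))
  if (problem$n_folds != 2L)
    stop("isola design requires n_folds = 2")
  if (is.null(problem$curvature_signs))
    problem$curvature_signs <- c(1, -1)
  problem$target_label <- if (all(problem$curvature_signs == c(1, -1)))
    "isola" else "bistable_switch"
  multistart_search(problem, n_runs, seed, progress)
}

# a "mushroom" target accepts both orientations (the search allows ON
# states at lower expression than OFF, i.e. inverted mushrooms)
accepted_labels <- function(target) {
  if (target == "mushroom") c("mushroom", "inverted_mushroom") else target
}
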