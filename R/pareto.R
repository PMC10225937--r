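#' Pareto front of a set of points
#'
#' Returns the non-dominated subset of a collection of objective vectors.
#' A point dominates another when it is at least as good in every
#' objective and strictly better in at least one, with "good" defined per
#' axis by `orientation`. The front is returned ordered by the first
#' objective.
#'
#' @param points numeric matrix (one point per row) or list of numeric
#'   vectors of equal length.
#' @param payloads optional list of payloads, one per point; defaults to
#'   the row indices.
#' @param orientation character vector of `"min"`/`"max"` per objective
#'   (default all `"min"`).
#' @return List with `payloads` (non-dominated, ordered by first
#'   objective), `points` (their objective vectors) and `index` (their
#'   positions in the input).
#' @examples
#' pareto_front(rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 1)))$points
#' @export
pareto_front <- function(points, payloads = NULL,
                         orientation = NULL) {
  if (is.list(points) && !is.data.frame(points) && !is.matrix(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) == 0)
    return(list(payloads = list(), points = points, index = integer(0)))
  d <- ncol(points)
  if (is.null(orientation)) orientation <- rep("min", d)
  if (length(orientation) != d)
    stop("'orientation' must declare min/max for each objective")
  if (is.null(payloads)) payloads <- as.list(seq_len(nrow(points)))
  if (length(payloads) != nrow(points))
    stop("one payload per point required")
  sgn <- ifelse(orientation == "max", -1, 1)
  P <- sweep(points, 2, sgn, `*`) # now everything is minimized
  ord <- do.call(order, as.data.frame(P))
  keep <- integer(0)
  for (i in ord) {
    dominated <- FALSE
    for (j in keep) {
      if (all(P[j, ] <= P[i, ]) && any(P[j, ] < P[i, ])) {
        dominated <- TRUE
        break
      }
    }
    if (!dominated) keep <- c(keep, i)
  }
  # remove points dominated by later entrants (possible for > 2 objectives)
  final <- keep[vapply(keep, function(i)
    !any(vapply(keep, function(j)
      j != i && all(P[j, ] <= P[i, ]) && any(P[j, ] < P[i, ]), TRUE)),
    TRUE)]
  final <- final[order(points[final, 1])]
  list(payloads = payloads[final], points = points[final, , drop = FALSE],
       index = final)
}

# built-in design objectives for multi-criteria sweeps
design_objective <- function(name) {
  switch(name,
         psi = function(sol) sol$psi,
         protein_burden = function(sol) sum(sol$params$p),
         n_connections = function(sol) n_connections(sol$topology),
         leakiness = function(sol) sum(sol$params$l),
         stop("unknown objective '", name, "'"))
}

#' Epsilon-constraint sweep for multi-objective design
#'
#' Scalarizes a multi-objective problem: one objective is minimized while
#' every other objective is bounded above by a sweep level `epsilon`, and
#' the saddle-node placement condition `Psi = 0` is kept as a hard
#' constraint (through verified solutions). The union of the per-level
#' optima, filtered for dominance, approximates the Pareto set.
#'
#' Two problem forms are supported: a [design_problem()] whose
#' `objectives` are named design criteria (`"protein_burden"`,
#' `"n_connections"`, `"leakiness"`), solved by seeded multistart with
#' verification; or a plain continuous problem given as a list with
#' fields `lower`, `upper` (box bounds), `objectives` (list of functions
#' of `x`) and optional `eq` (equality constraint function, enforced to
#' `|eq(x)| <= 1e-6`), solved by penalized multistart `optim`.
#'
#' @param problem a [design_problem()] carrying an `objectives` character
#'   vector of length >= 2, or a plain-list continuous problem.
#' @param objective_index which objective to minimize.
#' @param epsilon_grid vector of bound levels applied to the remaining
#'   objectives.
#' @param n_starts starts per epsilon level.
#' @param seed master seed.
#' @return List with `levels` (one entry per epsilon: the level, the best
#'   solution or `NULL`, its objective vector, and a `feasible` flag) and
#'   `front` (non-dominated union across levels, see [pareto_front()]).
#' @export
epsilon_constraint_sweep <- function(problem, objective_index, epsilon_grid,
                                     n_starts = 50L, seed = 1L) {
  objs <- problem$objectives
  if (is.null(objs) || length(objs) < 2)
    stop("epsilon-constraint sweep needs at least 2 objectives")
  if (inherits(problem, "design_problem"))
    sweep_design(problem, objs, objective_index, epsilon_grid, n_starts,
                 seed)
  else
    sweep_continuous(problem, objs, objective_index, epsilon_grid,
                     n_starts, seed)
}

sweep_design <- function(problem, objs, objective_index, epsilon_grid,
                         n_starts, seed) {
  fns <- lapply(objs, design_objective)
  levels <- list()
  pts <- list(); pls <- list()
  for (le in seq_along(epsilon_grid)) {
    eps <- epsilon_grid[le]
    best <- NULL; best_val <- Inf
    for (i in seq_len(n_starts)) {
      s <- solve_single(problem, derive_seed(seed + le * 1000L, i))
      if (!inherits(s, "design_solution")) next
      vals <- vapply(fns, function(f) f(s), 0)
      if (any(vals[-objective_index] > eps)) next
      if (vals[objective_index] < best_val) {
        best <- s; best_val <- vals[objective_index]
        best$objective_values <- vals
      }
    }
    feasible <- !is.null(best)
    levels[[le]] <- list(epsilon = eps, solution = best,
                         objectives = if (feasible) best$objective_values,
                         feasible = feasible)
    if (feasible) {
      pts[[length(pts) + 1L]] <- best$objective_values
      pls[[length(pls) + 1L]] <- best
    }
  }
  front <- if (length(pts)) pareto_front(do.call(rbind, pts), pls)
  else list(payloads = list(), points = NULL, index = integer(0))
  list(levels = levels, front = front)
}

sweep_continuous <- function(problem, objs, objective_index, epsilon_grid,
                             n_starts, seed) {
  lower <- problem$lower; upper <- problem$upper
  eq <- problem$eq
  levels <- list()
  pts <- list(); pls <- list()
  for (le in seq_along(epsilon_grid)) {
    eps <- epsilon_grid[le]
    pen <- function(x) {
      v <- objs[[objective_index]](x)
      for (j in seq_along(objs))
        if (j != objective_index)
          v <- v + 1e4 * max(0, objs[[j]](x) - eps)^2
      if (!is.null(eq)) v <- v + 1e6 * sum(eq(x)^2)
      v
    }
    best <- NULL; best_val <- Inf
    with_seed(derive_seed(seed, le), {
      for (i in seq_len(n_starts)) {
        x0 <- stats::runif(length(lower), lower, upper)
        fit <- tryCatch(stats::optim(x0, pen, method = "L-BFGS-B",
                                     lower = lower, upper = upper),
                        error = function(e) NULL)
        if (is.null(fit)) next
        x <- fit$par
        if (!is.null(eq) && max(abs(eq(x))) > 1e-6) next
        if (any(vapply(seq_along(objs), function(j)
          j != objective_index && objs[[j]](x) > eps + 1e-8, TRUE))) next
        v <- objs[[objective_index]](x)
        if (v < best_val) { best <- x; best_val <- v }
      }
    })
    feasible <- !is.null(best)
    vals <- if (feasible) vapply(objs, function(f) f(best), 0)
    levels[[le]] <- list(epsilon = eps, solution = best, objectives = vals,
                         feasible = feasible)
    if (feasible) {
      pts[[length(pts) + 1L]] <- vals
      pls[[length(pls) + 1L]] <- best
    }
  }
  front <- if (length(pts)) pareto_front(do.call(rbind, pts), pls)
  else list(payloads = list(), points = NULL, index = integer(0))
  list(levels = levels, front = front)
}
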