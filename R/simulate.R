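#' Time-varying signal program
#'
#' Defines the inducer signal S(t) driving a simulation:
#'
#' * `constant` -- `S(t) = s_max`;
#' * `gaussian_pulse` -- `S(t) = s_min + (s_max - s_min) *
#'   exp(-((t - center)/tau)^2 / 2)`, a transient pulse peaking at
#'   `s_max`;
#' * `wiener` -- a Wiener (Brownian) path starting at `s_start` with
#'   diffusion `sigma`, precomputed at fixed steps `dt` from `seed` and
#'   held piecewise constant between steps, clamped at 0.
#'
#' @param kind signal type.
#' @param s_min,s_max baseline and peak concentrations.
#' @param center,tau pulse center time and width.
#' @param s_start,sigma,dt,seed,t_max Wiener start level, diffusion
#'   coefficient, step, seed, and horizon of the precomputed path.
#' @return Object of class `"signal_program"` with a `value(t)` function.
#' @export
signal_program <- function(kind = c("constant", "gaussian_pulse", "wiener"),
                           s_min = 0, s_max = 10, center = 100, tau = 20,
                           s_start = NULL, sigma = 1.5, dt = 0.01,
                           seed = 1L, t_max = 500) {
  kind <- match.arg(kind)
  if (s_min < 0 || s_max < 0) stop("signal levels must be nonnegative")
  path <- NULL
  if (kind == "wiener") {
    if (is.null(s_start)) s_start <- (s_min + s_max) / 2
    n_steps <- ceiling(t_max / dt) + 1L
    incr <- with_seed(seed, stats::rnorm(n_steps - 1L, 0, sigma * sqrt(dt)))
    path <- cumsum(c(s_start, incr))
    path <- pmax(path, 0)
  }
  value <- switch(kind,
    constant = function(t) rep_len(s_max, length(t)),
    gaussian_pulse = function(t)
      s_min + (s_max - s_min) * exp(-0.5 * ((t - center) / tau)^2),
    wiener = function(t) {
      idx <- pmin(pmax(floor(t / dt) + 1L, 1L), length(path))
      path[idx]
    })
  structure(list(kind = kind, s_min = s_min, s_max = s_max,
                 center = center, tau = tau, s_start = s_start,
                 sigma = sigma, dt = dt, seed = seed, t_max = t_max,
                 path = path, value = value),
            class = "signal_program")
}

#' Simulate circuit dynamics under a signal program
#'
#' Integrates `d omega/dt = f(omega, S(t))` with a stiff-capable adaptive
#' integrator (`deSolve::ode`, method `lsoda`).
#'
#' @param model a [circuit_model()].
#' @param signal a [signal_program()].
#' @param t_span `c(t0, t1)`.
#' @param initial_state nonnegative state vector (default: the stable
#'   equilibrium reached from the origin at `S(t0)`).
#' @param n_out number of stored time points.
#' @param atol,rtol integrator tolerances.
#' @return Object of class `"trajectory"`: `times`, `states` (matrix),
#'   `signal` (S at the stored times), `events` (empty data frame; filled
#'   by analysis helpers).
#' @export
simulate_circuit <- function(model, signal, t_span = c(0, 200),
                             initial_state = NULL, n_out = 400L,
                             atol = 1e-8, rtol = 1e-8) {
  stopifnot(inherits(model, "circuit_model"),
            inherits(signal, "signal_program"))
  cm <- compile_model(model)
  if (is.null(initial_state)) {
    ss <- steady_states(model, signal$value(t_span[1]), n_seed_axis = 5L)
    ss <- ss[ss$stable, , drop = FALSE]
    initial_state <- if (nrow(ss)) as.numeric(ss[which.min(rowSums(
      ss[, seq_len(cm$n), drop = FALSE])), seq_len(cm$n)]) else
        rep(0, cm$n)
  }
  if (any(initial_state < 0)) stop("initial state must be nonnegative")
  times <- seq(t_span[1], t_span[2], length.out = n_out)
  deriv <- function(t, y, parms)
    list(as.numeric(cpp_rhs(cm, matrix(pmax(y, 0), 1L), signal$value(t))))
  sol <- deSolve::ode(y = initial_state, times = times, func = deriv,
                      parms = NULL, method = "lsoda", atol = atol,
                      rtol = rtol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed at t = ", max(sol[, 1]))
  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  colnames(states) <- gene_labels(cm$n)
  structure(list(times = sol[, 1], states = states,
                 signal = signal$value(sol[, 1]),
                 events = data.frame(time = numeric(0),
                                     type = character(0))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d points, t in [%g, %g], final state (%s)\n",
              length(x$times), min(x$times), max(x$times),
              paste(signif(x$states[nrow(x$states), ], 4), collapse = ", ")))
  invisible(x)
}

#' Assign the end of a trajectory to an ON or OFF branch
#'
#' Matches the final state against the stable equilibria of the model at
#' the final signal value and labels it by branch identity in the
#' reference diagram: the intermediate branch (mushroom head, or the
#' closed isola branch) is ON, the outer locus is OFF. Assignment is by
#' branch membership, not by expression threshold.
#'
#' @param trajectory a [simulate_circuit()] result.
#' @param diagram the model's [bifurcation_diagram()].
#' @param model the [circuit_model()] (used to re-resolve equilibria at
#'   the final signal).
#' @param rel_tol maximum relative distance to the matched branch state.
#' @return `"ON"`, `"OFF"` or `"other"`.
#' @export
classify_final_state <- function(trajectory, diagram, model,
                                 rel_tol = 0.05) {
  stopifnot(inherits(trajectory, "trajectory"),
            inherits(diagram, "bifurcation_diagram"))
  s_end <- trajectory$signal[length(trajectory$signal)]
  if (s_end < diagram$s_range[1] || s_end > diagram$s_range[2])
    stop("final signal value lies outside the diagram window")
  w_end <- trajectory$states[nrow(trajectory$states), ]
  on_ids <- on_branch_ids(diagram)
  pts <- diagram$points[diagram$points$stable, , drop = FALSE]
  if (!nrow(pts)) return("other")
  # nearest stable diagram point in (log S, state) proximity: restrict to
  # points at the two grid signals bracketing s_end
  s_near <- sort(unique(pts$S))
  s_pick <- s_near[order(abs(log(s_near) - log(max(s_end, 1e-12))))]
  s_pick <- s_pick[seq_len(min(2L, length(s_pick)))]
  cand <- pts[pts$S %in% s_pick, , drop = FALSE]
  d <- apply(cand[, diagram$gene_cols, drop = FALSE], 1, function(w)
    rel_state_dist(as.numeric(w), w_end))
  if (min(d) > rel_tol) return("other")
  hit <- cand$branch[which.min(d)]
  if (hit %in% on_ids) "ON" else "OFF"
}

# stable branches bounded by folds on both sides (mushroom head or the
# stable side of a closed isola branch)
on_branch_ids <- function(diagram) {
  br <- diagram$branches
  br$branch[br$stable %in% TRUE & !is.na(br$start) & !is.na(br$end)]
}

# stable equilibrium at signal S belonging to an OFF (outer-locus) branch
off_branch_state <- function(model, diagram, S) {
  ss <- steady_states(model, S)
  ss <- ss[ss$stable, , drop = FALSE]
  if (!nrow(ss)) stop("no stable state at S = ", S)
  on_ids <- on_branch_ids(diagram)
  pts <- diagram$points[diagram$points$stable, , drop = FALSE]
  s_near <- sort(unique(pts$S))
  s_pick <- s_near[order(abs(log(s_near) - log(max(S, 1e-12))))]
  cand <- pts[pts$S %in% s_pick[seq_len(min(2L, length(s_pick)))], ,
              drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(ss))) {
    w <- as.numeric(ss[i, diagram$gene_cols])
    d <- apply(cand[, diagram$gene_cols, drop = FALSE], 1, function(p)
      rel_state_dist(as.numeric(p), w))
    if (!cand$branch[which.min(d)] %in% on_ids) return(w)
    if (is.null(best)) best <- w
  }
  best
}

#' Pulse-response activation map
#'
#' Applies a Gaussian signal pulse for every combination of duration
#' `tau` and peak intensity `s_max`, and records whether the circuit ends
#' on the ON branch. The map exposes the mushroom's biosensor/timer
#' behavior: activation requires an intermediate peak intensity (inside
#' the neck) sustained long enough to escape the saddle-node ghost.
#'
#' @param model a [circuit_model()] classified as a mushroom.
#' @param tau_grid,smax_grid grids of pulse widths and peak intensities.
#' @param diagram reference diagram (traced on demand when `NULL`).
#' @param s_min pulse baseline.
#' @param center pulse center time.
#' @param t_span simulation window.
#' @param s_grid signal grid used when tracing the reference diagram.
#' @return Logical matrix (`tau` on rows, `s_max` on columns); cells
#'   where simulation fails are `NA`.
#' @export
activation_map <- function(model, tau_grid, smax_grid, diagram = NULL,
                           s_min = 10, center = 100, t_span = c(0, 250),
                           s_grid = NULL) {
  if (is.null(diagram)) {
    if (is.null(s_grid))
      s_grid <- exp(seq(log(0.2), log(2000), length.out = 80))
    diagram <- trace_diagram(model, s_grid)
  }
  if (!diagram$label %in% c("mushroom", "inverted_mushroom"))
    stop("activation maps require a mushroom-classified model")
  # rest the circuit on the OFF branch at the pulse baseline
  init <- off_branch_state(model, diagram, s_min)
  out <- matrix(NA, length(tau_grid), length(smax_grid),
                dimnames = list(signif(tau_grid, 6), signif(smax_grid, 6)))
  for (i in seq_along(tau_grid)) for (j in seq_along(smax_grid)) {
    sig <- signal_program("gaussian_pulse", s_min = s_min,
                          s_max = smax_grid[j], center = center,
                          tau = tau_grid[i])
    res <- tryCatch({
      tr <- simulate_circuit(model, sig, t_span = t_span,
                             initial_state = init)
      classify_final_state(tr, diagram, model) == "ON"
    }, error = function(e) NA)
    out[i, j] <- res
  }
  out
}

#' Irreversible isola memory demonstration
#'
#' Places the system on the closed isola branch (using a parameter
#' override that temporarily re-opens the mushroom, then restoring the
#' isola parameters), drives it with a noisy Wiener signal, and records
#' the first time the signal crosses either fold of the isola. After a
#' crossing the state leaves the closed branch and, because re-entry
#' requires passing through a fold that no longer exists, it never
#' returns: the events table plus the per-time branch distance make this
#' irreversibility checkable.
#'
#' @param model a [circuit_model()] whose diagram is an isola.
#' @param signal a Wiener [signal_program()].
#' @param reset_rule list `list(param = , value = )`: the override
#'   producing the open-mushroom model whose ON state initializes the
#'   run; `param` may name several parameters (default `p1` and `p3`,
#'   the tied leakiness pair).
#' @param diagram optional pre-traced diagram of `model`.
#' @param t_span simulation window.
#' @param s_grid tracing grid when `diagram` is `NULL`.
#' @return List with `trajectory`, `events` (data frame: time, type),
#'   `on_isola` (logical vector: is the state near the closed branch at
#'   each stored time), `fold_S` (the isola fold signals).
#' @export
isola_memory_demo <- function(model, signal,
                              reset_rule = list(param = c("p1", "p3"),
                                                value = 20),
                              diagram = NULL, t_span = c(0, 400),
                              s_grid = NULL) {
  stopifnot(inherits(signal, "signal_program"))
  if (signal$kind != "wiener") stop("the memory demo uses a wiener signal")
  if (is.null(diagram)) {
    if (is.null(s_grid))
      s_grid <- exp(seq(log(0.2), log(2000), length.out = 80))
    diagram <- trace_diagram(model, s_grid)
  }
  if (diagram$label != "isola")
    stop("model must be classified as an isola")
  cc <- closed_two_fold_component(diagram)
  fold_S <- sort(cc$fold_S)
  # initial state: ON state of the re-opened mushroom at the start signal
  open_model <- model
  for (pn in reset_rule$param)
    open_model <- set_param(open_model, pn, reset_rule$value)
  s0 <- signal$value(t_span[1])
  ss <- steady_states(open_model, s0)
  ss <- ss[ss$stable, , drop = FALSE]
  if (!nrow(ss)) stop("no stable state of the reset model at S(t0)")
  # pick the reset state nearest the closed branch
  iso_pts <- diagram$points[diagram$points$branch %in% cc$members &
                              diagram$points$stable, , drop = FALSE]
  dist_iso <- function(w) min(apply(iso_pts[, diagram$gene_cols,
                                            drop = FALSE], 1,
                                    function(p) rel_state_dist(
                                      as.numeric(p), w)))
  d0 <- apply(ss[, diagram$gene_cols, drop = FALSE], 1, function(w)
    dist_iso(as.numeric(w)))
  reset_state <- as.numeric(ss[which.min(d0), diagram$gene_cols])
  # restoring the isola parameters lets the reset state relax onto the
  # closed branch (it lies in the branch's basin when the reset regime is
  # chosen sensibly)
  ss_iso <- steady_states(model, s0, seeds = rbind(reset_state))
  ss_iso <- ss_iso[ss_iso$stable, , drop = FALSE]
  if (!nrow(ss_iso)) stop("no stable state of the isola model at S(t0)")
  d1 <- apply(ss_iso[, diagram$gene_cols, drop = FALSE], 1, function(w)
    sqrt(sum((as.numeric(w) - reset_state)^2)))
  init <- as.numeric(ss_iso[which.min(d1), diagram$gene_cols])
  tr <- simulate_circuit(model, signal, t_span = t_span,
                         initial_state = init)
  # signal fold crossings
  above <- tr$signal > fold_S[2]
  below <- tr$signal < fold_S[1]
  first_cross <- which(above | below)[1]
  events <- if (is.na(first_cross))
    data.frame(time = numeric(0), type = character(0))
  else
    data.frame(time = tr$times[first_cross],
               type = if (above[first_cross]) "exit_high" else "exit_low")
  on_isola <- vapply(seq_along(tr$times), function(i)
    dist_iso(tr$states[i, ]) < 0.1, TRUE)
  tr$events <- events
  list(trajectory = tr, events = events, on_isola = on_isola,
       fold_S = fold_S)
}
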