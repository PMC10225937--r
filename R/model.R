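#' Hill-type signal input
#'
#' Concentration of activating transcription factor recruited by an inducer
#' signal: `q(S) = R * S^n / (K^n + S^n)`. Monotone nondecreasing in `S`
#' and bounded by the total transcription-factor concentration `R`.
#'
#' @param S signal concentration(s), `>= 0`.
#' @param R total transcription-factor concentration, `> 0`.
#' @param K dissociation constant, `> 0`.
#' @param n Hill cooperativity (default 2).
#' @return Numeric vector of active transcription-factor concentrations.
#' @examples
#' signal_input(10, R = 143, K = 10) # half saturation: 71.5
#' @export
signal_input <- function(S, R, K, n = 2L) {
  if (any(S < 0)) stop("'S' must be nonnegative")
  if (any(R <= 0) || any(K <= 0)) stop("'R' and 'K' must be positive")
  if (n < 1) stop("'n' must be >= 1")
  R * S^n / (K^n + S^n)
}

#' Parametrized circuit model
#'
#' Binds a [topology()] to a [parameter_set()], giving the ODE system
#' `d omega / dt = f(omega, S)` with thermodynamic regulatory kinetics: for
#' gene i,
#' `f_i = p_i * N_i / D_i - d_i * omega_i`, where the promoter occupancy
#' numerator `N_i` collects the leakiness, the signal input `q_i(S)` (for
#' signal-receiving genes) and `k * omega_j^m` for every activator j, and
#' the denominator `D_i = 1 + N_i + sum of k * omega_j^m` over repressors j
#' (`m` is the regulator binding exponent, 2 for dimers). Self-edges follow
#' the same rule.
#'
#' @param topology a [topology()].
#' @param params a [parameter_set()] with matching gene count.
#' @param assumptions optional named list of parameter-tying overrides
#'   applied before any evaluation; supported entries are direct slot
#'   overrides such as `list(d = c(1, 2))` or `list(l = 30)`.
#' @return An object of class `"circuit_model"`.
#' @export
circuit_model <- function(topology, params, assumptions = NULL) {
  stopifnot(inherits(topology, "topology"), inherits(params, "parameter_set"))
  if (topology$n_genes != params$n_genes)
    stop("topology and parameter set disagree on the number of genes")
  if (!is.null(assumptions)) {
    for (nm in names(assumptions)) {
      if (!nm %in% c("p", "l", "k", "R", "K", "d"))
        stop("unknown assumption '", nm, "'")
      params[[nm]] <- rep_len(as.numeric(assumptions[[nm]]), params$n_genes)
      if (nm == "k") params$k <- as.numeric(assumptions[[nm]])[1]
    }
    validate_parameter_set(params)
  }
  structure(list(topology = topology, params = params),
            class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat("circuit_model\n")
  print(x$topology)
  print(x$params)
  invisible(x)
}

# plain-list view consumed by the compiled core
compile_model <- function(model) {
  stopifnot(inherits(model, "circuit_model"))
  tp <- model$topology
  ps <- model$params
  list(n = tp$n_genes,
       p = ps$p, l = ps$l, k = ps$k, R = ps$R, K = ps$K, d = ps$d,
       mask = as.integer(tp$signal_mask),
       act = matrix(as.integer(tp$edges == 1L), tp$n_genes),
       rep = matrix(as.integer(tp$edges == -1L), tp$n_genes),
       hn = ps$hill_n, me = ps$dimer_exponent)
}

#' Right-hand side of the circuit ODE system
#'
#' Returns a function `(omega, S) -> rate vector` evaluating
#' `d omega / dt` for the model; `omega` may also be a matrix with one
#' state per row, in which case a matrix of rates is returned.
#'
#' @param model a [circuit_model()].
#' @return Function of `(omega, S)`.
#' @examples
#' mod <- reference_circuit("A1_mushroom")
#' f <- circuit_rhs(mod)
#' f(c(1, 1), S = 10)
#' @export
circuit_rhs <- function(model) {
  cm <- compile_model(model)
  n <- cm$n
  function(omega, S) {
    if (is.matrix(omega)) {
      cpp_rhs(cm, omega, S)
    } else {
      if (length(omega) != n) stop("state must have length ", n)
      drop(cpp_rhs(cm, matrix(omega, 1L), S))
    }
  }
}

# default lattice of Newton seeds: per-coordinate grid over [0, p_i/d_i]
seed_lattice <- function(model, n_axis = 8L) {
  ps <- model$params
  hi <- ps$p / ps$d
  grids <- lapply(seq_len(ps$n_genes),
                  function(i) seq(0, hi[i], length.out = n_axis))
  as.matrix(do.call(expand.grid, grids))
}

#' Steady states of a circuit at a fixed signal
#'
#' Finds the nonnegative equilibria of the model at signal `S` by damped
#' Newton iteration from a dense seed lattice (a per-coordinate grid over
#' `[0, p_i/d_i]`) plus any user seeds, deduplicating converged roots at
#' relative distance `1e-4`. Stability comes from the eigenvalues of the
#' state Jacobian (stable iff all real parts are negative).
#'
#' @param model a [circuit_model()].
#' @param S signal concentration.
#' @param seeds optional matrix of extra starting states (one per row).
#' @param tol residual tolerance: every returned state satisfies
#'   `max(abs(f)) / max(1, p) <= tol` componentwise.
#' @param n_seed_axis lattice resolution per state coordinate (default 8).
#' @return Data frame with one row per equilibrium: the state coordinates
#'   and a logical `stable` column. Zero rows when no seed converges.
#' @export
steady_states <- function(model, S, seeds = NULL, tol = 1e-10,
                          n_seed_axis = 8L) {
  stopifnot(tol > 0)
  cm <- compile_model(model)
  W0 <- seed_lattice(model, n_seed_axis)
  if (!is.null(seeds)) {
    seeds <- as.matrix(seeds)
    if (ncol(seeds) != cm$n) stop("seeds must have one column per gene")
    W0 <- rbind(W0, seeds)
  }
  res <- cpp_steady_states(cm, S, W0, tol, 80L, 1e-4)
  states <- res$states
  stable <- res$stable
  if (anyNA(stable) && nrow(states) > 0) {
    for (i in which(is.na(stable))) {
      ev <- eigen(cpp_state_jac(cm, states[i, ], S), only.values = TRUE)$values
      stable[i] <- all(Re(ev) < 0)
    }
  }
  out <- as.data.frame(states)
  names(out) <- gene_labels(cm$n)
  out$stable <- stable
  out
}
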