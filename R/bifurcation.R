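#' Extended Jacobian of the circuit dynamics
#'
#' The N x (N+1) matrix `Q = [D_omega f, D_S f]`: the state Jacobian
#' augmented with the derivative of the dynamics with respect to the
#' bifurcation parameter S. For a [circuit_model()] the derivatives are
#' analytic; an arbitrary function `f(omega, S)` may be supplied instead,
#' in which case central finite differences are used.
#'
#' @param model a [circuit_model()], or a function `f(omega, S)` returning
#'   the rate vector.
#' @param omega state vector (nonnegative).
#' @param S signal concentration (nonnegative).
#' @param h relative finite-difference step for the function interface.
#' @return Numeric matrix of dimension `N x (N + 1)`.
#' @export
extended_jacobian <- function(model, omega, S, h = 1e-6) {
  if (inherits(model, "circuit_model")) {
    Q <- cpp_ext_jac(compile_model(model), as.numeric(omega), S)
  } else if (is.function(model)) {
    f0 <- model(omega, S)
    n <- length(f0)
    if (length(omega) != n) stop("state dimension mismatch")
    Q <- matrix(0, n, n + 1L)
    for (j in seq_len(n)) {
      hj <- h * (1 + abs(omega[j]))
      up <- dn <- omega
      up[j] <- omega[j] + hj
      dn[j] <- omega[j] - hj
      Q[, j] <- (model(up, S) - model(dn, S)) / (2 * hj)
    }
    hs <- h * (1 + abs(S))
    Q[, n + 1L] <- (model(omega, S + hs) - model(omega, S - hs)) / (2 * hs)
  } else stop("'model' must be a circuit_model or a function")
  if (any(!is.finite(Q)))
    stop("non-finite dynamics at the requested point")
  Q
}

#' Tangent vector of an equilibrium branch
#'
#' The unit null vector `beta` of the extended Jacobian; along a branch of
#' equilibria, `beta` is tangent to the branch in `(omega, S)` space, and a
#' saddle-node (fold) point is characterized by a vanishing last component
#' `beta[N + 1]`. Computed by singular value decomposition; the sign is
#' fixed so that the largest-magnitude entry is positive.
#'
#' @param Q extended Jacobian matrix (`N x (N + 1)`).
#' @param gate degeneracy gate: the second-smallest singular value must
#'   exceed `gate` times the smallest (default `1e3`), otherwise the null
#'   space is not one-dimensional and an error of class
#'   `"bifdesign_degenerate_point"` is thrown.
#' @return Unit numeric vector of length `N + 1` with `||Q beta|| <=
#'   1e-8 * ||Q||`.
#' @export
tangent_vector <- function(Q, gate = 1e3) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  if (ncol(Q) != n + 1L) stop("'Q' must be N x (N+1)")
  sv <- svd(Q, nu = 0, nv = n + 1L)
  # an N x (N+1) matrix always has a null direction; the null space is
  # one-dimensional iff the smallest of the N singular values is far from
  # zero relative to machine precision (gate times eps times the largest)
  if (n >= 2) {
    s <- sv$d
    if (s[n] <= gate * .Machine$double.eps * max(s[1], .Machine$double.xmin))
      stop(degenerate_point_error())
  }
  beta <- sv$v[, n + 1L]
  beta <- beta / sqrt(sum(beta^2))
  i <- which.max(abs(beta))
  if (beta[i] < 0) beta <- -beta
  beta
}

degenerate_point_error <- function() {
  structure(class = c("bifdesign_degenerate_point", "error", "condition"),
            list(message = paste("extended Jacobian is rank deficient",
                                 "(null space dimension > 1)"),
                 call = NULL))
}

#' Saddle-node objective at a point
#'
#' The squared last component of the unit branch tangent,
#' `J = beta[N + 1]^2`. Along an equilibrium branch `J = 0` exactly at a
#' fold with respect to the signal, so minimizing `J` locates saddle-node
#' bifurcations.
#'
#' @param model a [circuit_model()] or function `f(omega, S)`.
#' @param omega state vector, near an equilibrium.
#' @param S signal concentration.
#' @param residual_gate loose equilibrium gate (default `1e-3`): the scaled
#'   residual `max(abs(f)/max(1, p))` must not exceed it.
#' @return Nonnegative scalar.
#' @examples
#' fold_toy <- function(w, S) S - w^2
#' saddle_node_objective(fold_toy, 0, 0)  # 0 at the fold
#' saddle_node_objective(fold_toy, 1, 1)  # 0.8 at a regular point
#' @export
saddle_node_objective <- function(model, omega, S, residual_gate = 1e-3) {
  if (inherits(model, "circuit_model")) {
    f <- circuit_rhs(model)(omega, S)
    scale <- pmax(1, model$params$p)
  } else {
    f <- model(omega, S)
    scale <- pmax(1, abs(omega) * 0 + 1)
  }
  if (max(abs(f) / scale) > residual_gate)
    stop("point is not close enough to an equilibrium (residual gate ",
         residual_gate, ")")
  beta <- tangent_vector(extended_jacobian(model, omega, S))
  unname(beta[length(beta)]^2)
}

#' Polish a saddle-node point
#'
#' Newton iteration on the fold system `f(omega, S) = 0`,
#' `det(D_omega f) = 0` in the unknowns `(omega, S)`, starting from an
#' approximate fold location (typically a bisection estimate from
#' [trace_diagram()]).
#'
#' @param model a [circuit_model()].
#' @param omega,S approximate fold coordinates.
#' @param tol convergence tolerance on the scaled residuals.
#' @param maxit maximum Newton iterations.
#' @return List with elements `omega`, `S`, `beta`, `J`, `converged`.
#' @export
refine_fold <- function(model, omega, S, tol = 1e-11, maxit = 60L) {
  cm <- compile_model(model)
  res <- cpp_fold_polish(cm, as.numeric(omega), S, tol, maxit)
  out <- list(omega = res$omega, S = res$S, converged = res$converged,
              beta = NULL, J = NA_real_)
  if (res$converged) {
    beta <- tryCatch(tangent_vector(extended_jacobian(model, res$omega,
                                                      res$S)),
                     bifdesign_degenerate_point = function(e) NULL)
    if (!is.null(beta)) {
      out$beta <- beta
      out$J <- unname(beta[length(beta)]^2)
    }
  }
  out
}
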