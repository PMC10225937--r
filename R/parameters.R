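#' Kinetic parameter set of a circuit model
#'
#' Holds the real-valued design parameters of the thermodynamic circuit
#' model: per-gene promoter strengths `p` (concentration/time), promoter
#' leakiness `l` (dimensionless), a single interaction strength `k`
#' (1/concentration^2) shared by every active regulatory edge, per-gene
#' transcription-factor totals `R` and dissociation constants `K` for the
#' signal input, per-gene degradation rates `d` (1/time), the signal Hill
#' cooperativity `hill_n` and the regulator binding exponent
#' `dimer_exponent` (repressors and activators bind as dimers by default).
#'
#' @param p,l,R,K,d numeric vectors recycled to the number of genes.
#' @param k single positive interaction strength.
#' @param hill_n,dimer_exponent positive integer exponents (defaults 2).
#' @param n_genes number of genes; inferred from the longest vector when
#'   missing.
#' @return An object of class `"parameter_set"`.
#' @export
parameter_set <- function(p, l, k, R, K, d, hill_n = 2L, dimer_exponent = 2L,
                          n_genes = NULL) {
  if (is.null(n_genes))
    n_genes <- max(length(p), length(l), length(R), length(K), length(d))
  rec <- function(x) rep_len(as.numeric(x), n_genes)
  ps <- structure(list(
    n_genes = as.integer(n_genes),
    p = rec(p), l = rec(l), k = as.numeric(k),
    R = rec(R), K = rec(K), d = rec(d),
    hill_n = as.integer(hill_n),
    dimer_exponent = as.integer(dimer_exponent)
  ), class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

validate_parameter_set <- function(ps) {
  with(ps, {
    if (any(!is.finite(c(p, l, k, R, K, d))))
      stop("parameters must be finite")
    if (any(p <= 0) || any(R <= 0) || any(K <= 0) || any(d <= 0) || k < 0)
      stop("p, R, K, d must be strictly positive and k nonnegative")
    if (any(l < 0)) stop("leakiness must be >= 0")
    if (hill_n < 1L || dimer_exponent < 1L)
      stop("hill_n and dimer_exponent must be >= 1")
  })
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("parameter_set (%d genes): k = %g, hill_n = %d, dimer = %d\n",
              x$n_genes, x$k, x$hill_n, x$dimer_exponent))
  m <- rbind(p = x$p, l = x$l, R = x$R, K = x$K, d = x$d)
  colnames(m) <- gene_labels(x$n_genes)
  print(m)
  invisible(x)
}

# canonical design-vector layout: the search optimizes a flat named vector x.
# 2 genes: p0 p1 p2 k R1 R2 dv K1 K2       (p3 = p1 and du = 1 tied)
# 3 genes: p0 p1 p2 p4 p5 k R1 R2 dv dw K1 K2
x_names <- function(n_genes) {
  if (n_genes == 2L)
    c("p0", "p1", "p2", "k", "R1", "R2", "dv", "K1", "K2")
  else if (n_genes == 3L)
    c("p0", "p1", "p2", "p4", "p5", "k", "R1", "R2", "dv", "dw", "K1", "K2")
  else stop("design vectors are defined for 2 or 3 genes")
}

#' Build a parameter set from a flat design vector
#'
#' Maps the named design vector used by the optimizer onto a
#' [parameter_set()], applying the dimensionality-reduction assumptions
#' `p3 = p1` (leakiness of gene V tied to gene U) and `du = 1` (time is
#' measured in units of gene U's protein lifetime) unless overridden in
#' `tying`.
#'
#' @param x named numeric vector with names from the canonical layout
#'   (`p0, p1, p2, k, R1, R2, dv, K1, K2` for two genes, plus
#'   `p4, p5, dw` for three).
#' @param n_genes 2 or 3.
#' @param tying named list of overrides; supported entries `p3`, `du`
#'   (numeric values) to replace the default tying rules.
#' @return A [parameter_set()].
#' @export
params_from_x <- function(x, n_genes, tying = list()) {
  nm <- x_names(n_genes)
  if (!all(nm %in% names(x)))
    stop("missing design-vector entries: ",
         paste(setdiff(nm, names(x)), collapse = ", "))
  x <- x[nm]
  p3 <- if (!is.null(tying$p3)) tying$p3 else unname(x["p1"])
  du <- if (!is.null(tying$du)) tying$du else 1
  if (n_genes == 2L) {
    parameter_set(p = c(x["p0"], x["p2"]), l = c(x["p1"], p3), k = x["k"],
                  R = c(x["R1"], x["R2"]), K = c(x["K1"], x["K2"]),
                  d = c(du, x["dv"]), n_genes = 2L)
  } else {
    parameter_set(p = c(x["p0"], x["p2"], x["p4"]),
                  l = c(x["p1"], p3, x["p5"]), k = x["k"],
                  R = c(x["R1"], x["R2"], x["R2"]),
                  K = c(x["K1"], x["K2"], x["K2"]),
                  d = c(du, x["dv"], x["dw"]), n_genes = 3L)
  }
}

#' Default design-vector bounds for the topology search
#'
#' Wide log-scale bounds covering every parameter value of the bundled
#' reference circuits: promoter strengths in \[10, 2000\], leakiness in
#' \[1, 500\], interaction strength in \[1e-3, 1\], transcription-factor
#' totals in \[50, 500\], dissociation constants in \[1, 300\] and
#' degradation rates in \[0.1, 10\].
#'
#' @param n_genes 2 or 3.
#' @return List with named numeric vectors `lower` and `upper`.
#' @export
default_parameter_bounds <- function(n_genes) {
  nm <- x_names(n_genes)
  lo <- c(p0 = 10, p1 = 1, p2 = 10, p4 = 10, p5 = 1, k = 1e-3,
          R1 = 50, R2 = 50, dv = 0.1, dw = 0.1, K1 = 1, K2 = 1)
  hi <- c(p0 = 2000, p1 = 500, p2 = 2000, p4 = 2000, p5 = 500, k = 1,
          R1 = 500, R2 = 500, dv = 10, dw = 10, K1 = 300, K2 = 300)
  list(lower = lo[nm], upper = hi[nm])
}

#' Bundled reference circuits
#'
#' Curated two-gene circuits used throughout the package as regression
#' fixtures: cross-repression between U and V with an additional
#' self-repression on U, both genes induced by the signal. The parameter
#' sets place the circuit in characteristic regimes:
#'
#' * `"A1_mushroom"` -- a mushroom diagram with four saddle nodes and two
#'   separate bistable signal ranges.
#' * `"A1_isola"` -- the same circuit with leakiness `p1 = 200`, which
#'   pinches the mushroom neck into a closed isola branch with two folds.
#' * `"A1_reset"` -- leakiness `p1 = 20`, which re-opens the mushroom; used
#'   to place the state onto the isola branch before memory experiments.
#' * `"A3_base"` -- a second parameterization whose diagram morphs between
#'   mushroom, isola, bistable switch and monostable regimes as the
#'   degradation rate `dv` and interaction strength `k` vary (`dv` and `k`
#'   are set to a mushroom-forming pair by default and are meant to be
#'   swept, e.g. with [phase_map()]).
#'
#' @param name one of `"A1_mushroom"`, `"A1_isola"`, `"A1_reset"`,
#'   `"A3_base"`.
#' @return A [circuit_model()] with attribute `"expected_label"`.
#' @examples
#' mod <- reference_circuit("A1_mushroom")
#' @export
reference_circuit <- function(name = c("A1_mushroom", "A1_isola", "A1_reset",
                                       "A3_base")) {
  name <- match.arg(name)
  topo <- topology(rbind(c(-1L, -1L), c(-1L, 0L)),
                   signal_mask = c(TRUE, TRUE))
  if (name %in% c("A1_mushroom", "A1_isola", "A1_reset")) {
    p1 <- switch(name, A1_mushroom = 30, A1_isola = 200, A1_reset = 20)
    ps <- parameter_set(p = c(361, 411), l = c(p1, p1), k = 9.04e-2,
                        R = c(143, 300), K = c(10, 137), d = c(1, 1.38))
    label <- if (name == "A1_isola") "isola" else "mushroom"
  } else {
    # mushroom-forming (dv, k) pair for the sweepable parameterization
    ps <- parameter_set(p = c(230, 1000), l = c(50, 50), k = 0.15,
                        R = c(264, 275), K = c(10, 133), d = c(1, 4.5))
    label <- "mushroom"
  }
  mod <- circuit_model(topo, ps)
  attr(mod, "expected_label") <- label
  mod
}
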