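#' Standardize solution sets against the pooled parameter distribution
#'
#' Centers and scales every design-vector column by the mean and standard
#' deviation of the aggregated rows of all sets, so that robustness
#' scores of different topologies are measured on a common scale. The
#' scaler is returned for reuse and inversion.
#'
#' @param all_sets list of [solution_set()] objects sharing the same
#'   parameter columns.
#' @return List with `sets` (transformed solution sets), `center` and
#'   `scale` (named vectors). Columns with zero pooled variance get scale
#'   1 with a warning.
#' @export
standardize_sets <- function(all_sets) {
  stopifnot(length(all_sets) >= 1)
  nm <- all_sets[[1]]$parameter_names
  for (s in all_sets)
    if (!identical(s$parameter_names, nm))
      stop("all sets must share the same parameter columns")
  pooled <- do.call(rbind, lapply(all_sets, function(s) s$param_rows))
  if (nrow(pooled) < 2) stop("at least 2 pooled rows are required")
  center <- colMeans(pooled)
  scale <- apply(pooled, 2, stats::sd)
  if (any(scale == 0)) {
    warning("zero pooled variance in column(s): ",
            paste(nm[scale == 0], collapse = ", "), "; scale set to 1")
    scale[scale == 0] <- 1
  }
  sets <- lapply(all_sets, function(s) {
    s$param_rows <- sweep(sweep(s$param_rows, 2, center), 2, scale, `/`)
    s
  })
  list(sets = sets, center = center, scale = scale)
}

#' Invert the standardization of a solution set
#' @param set a transformed [solution_set()].
#' @param scaler the `center`/`scale` list from [standardize_sets()].
#' @return The solution set on the original scale.
#' @export
unstandardize_set <- function(set, scaler) {
  set$param_rows <- sweep(sweep(set$param_rows, 2, scaler$scale, `*`), 2,
                          -scaler$center)
  set
}

#' Log-determinant robustness score
#'
#' Natural logarithm of the determinant of the sample covariance of the
#' (standardized) successful design vectors: a measure of the hypervolume
#' of parameter space occupied by working designs. Larger is more robust.
#'
#' @param set a [solution_set()] (standardized rows) or a plain numeric
#'   matrix of rows.
#' @return Scalar score.
#' @export
robustness_logdet <- function(set) {
  rows <- if (inherits(set, "solution_set")) set$param_rows else
    as.matrix(set)
  d <- ncol(rows)
  if (nrow(rows) < d + 1)
    stop("need at least ", d + 1, " solutions for a ", d,
         "-parameter covariance")
  cv <- stats::cov(rows)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || min(ev) < max(ev) * 1e-12)
    stop(structure(class = c("bifdesign_singular_covariance", "error",
                             "condition"),
                   list(message = "singular covariance: log-determinant undefined",
                        call = NULL)))
  sum(log(ev))
}

#' Interquartile-range robustness score
#'
#' Sum over parameters of the interquartile range (Q3 - Q1, linear
#' interpolation quantiles) of the successful design vectors: a spread
#' measure that is defined even when the covariance is singular.
#'
#' @param set a [solution_set()] or numeric matrix of rows.
#' @return Scalar score.
#' @export
robustness_iqr <- function(set) {
  rows <- if (inherits(set, "solution_set")) set$param_rows else
    as.matrix(set)
  if (nrow(rows) < 4) stop("need at least 4 solutions")
  sum(apply(rows, 2, function(col)
    diff(stats::quantile(col, c(0.25, 0.75), names = FALSE, type = 7))))
}

#' Bootstrap uncertainty of the robustness scores
#'
#' Resamples the solution rows with replacement `n_boot` times,
#' recomputes both robustness scores per replicate, and reports the
#' median and quartiles. Replicates with singular covariance contribute
#' only to the IQR score (their count is reported).
#'
#' @param set a [solution_set()] or numeric matrix.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed RNG seed; the report is deterministic given the seed.
#' @return Object of class `"robustness_report"`.
#' @export
bootstrap_scores <- function(set, n_boot = 1000L, seed = 1L) {
  rows <- if (inherits(set, "solution_set")) set$param_rows else
    as.matrix(set)
  if (n_boot < 100) stop("'n_boot' must be >= 100")
  point_logdet <- tryCatch(robustness_logdet(rows),
                           bifdesign_singular_covariance = function(e)
                             NA_real_)
  point_iqr <- robustness_iqr(rows)
  ld <- iq <- numeric(n_boot)
  n_singular <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(rows), replace = TRUE)
      rb <- rows[idx, , drop = FALSE]
      ld[b] <- tryCatch(robustness_logdet(rb),
                        bifdesign_singular_covariance = function(e) {
                          n_singular <<- n_singular + 1L
                          NA_real_
                        },
                        error = function(e) NA_real_)
      iq[b] <- robustness_iqr(rb)
    }
  })
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
                                    na.rm = TRUE, type = 7)
  structure(list(logdet_score = point_logdet, iqr_score = point_iqr,
                 logdet_boot = stats::setNames(qs(ld), c("q25", "median",
                                                         "q75")),
                 iqr_boot = stats::setNames(qs(iq), c("q25", "median",
                                                      "q75")),
                 n_solutions = nrow(rows), n_boot = n_boot,
                 n_singular = n_singular, seed = seed,
                 quantile_type = "linear interpolation (type 7)",
                 log_base = "natural"),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report (n = %d, %d bootstrap replicates)\n",
              x$n_solutions, x$n_boot))
  cat(sprintf("  log-det: %.4g  [boot median %.4g, quartiles %.4g / %.4g]\n",
              x$logdet_score, x$logdet_boot["median"],
              x$logdet_boot["q25"], x$logdet_boot["q75"]))
  cat(sprintf("  IQR sum: %.4g  [boot median %.4g, quartiles %.4g / %.4g]\n",
              x$iqr_score, x$iqr_boot["median"], x$iqr_boot["q25"],
              x$iqr_boot["q75"]))
  if (x$n_singular > 0)
    cat(sprintf("  %d replicates had singular covariance (IQR only)\n",
                x$n_singular))
  invisible(x)
}

#' Robustness versus wiring complexity
#'
#' Standardizes the given per-topology solution sets against their pooled
#' distribution, scores each topology, and computes the Pareto front of
#' robustness (maximized) against the number of connections (minimized).
#'
#' @param sets list of [solution_set()] objects (>= 2 topologies).
#' @param score which robustness score drives the front (`"logdet"` or
#'   `"iqr"`).
#' @return List with `table` (data frame: topology key, connections, both
#'   scores) and `front` (see [pareto_front()]; payloads are rows of the
#'   table).
#' @export
robustness_vs_complexity <- function(sets, score = c("logdet", "iqr")) {
  score <- match.arg(score)
  if (length(sets) < 2) stop("need at least 2 topologies")
  std <- standardize_sets(sets)
  rows <- lapply(seq_along(std$sets), function(i) {
    s <- std$sets[[i]]
    ld <- tryCatch(robustness_logdet(s),
                   bifdesign_singular_covariance = function(e) NA_real_,
                   error = function(e) NA_real_)
    iq <- tryCatch(robustness_iqr(s), error = function(e) NA_real_)
    data.frame(topology = paste(as_topology_vector(s$topology),
                                collapse = ","),
               n_connections = n_connections(s$topology),
               logdet = ld, iqr = iq)
  })
  tab <- do.call(rbind, rows)
  sc <- tab[[score]]
  ok <- !is.na(sc)
  front <- pareto_front(cbind(tab$n_connections[ok], sc[ok]),
                        payloads = split(tab[ok, ], seq_len(sum(ok))),
                        orientation = c("min", "max"))
  list(table = tab, front = front)
}
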