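#' Signed circuit topology
#'
#' A topology encodes the wiring of a gene circuit as a signed integer
#' adjacency matrix `edges` where `edges[i, j]` is the regulatory effect of
#' gene `j` on gene `i`: `+1` activation, `-1` repression, `0` no edge.
#' `signal_mask` marks the genes that receive the activating input signal S
#' (in the default two- and three-gene superstructures the first two genes,
#' U and V, are induced and gene W is not).
#'
#' @param edges integer matrix with entries in `{-1, 0, 1}`.
#' @param signal_mask logical vector, one entry per gene; defaults to the
#'   superstructure convention (genes 1 and 2 signal-activated).
#' @return An object of class `"topology"`.
#' @examples
#' # the classic cross-repression pair, both genes induced by the signal
#' topology(rbind(c(0, -1), c(-1, 0)))
#' @export
topology <- function(edges, signal_mask = NULL) {
  edges <- as.matrix(edges)
  if (nrow(edges) != ncol(edges))
    stop("'edges' must be a square matrix")
  n <- nrow(edges)
  if (n < 1) stop("at least one gene is required")
  if (!all(edges %in% c(-1L, 0L, 1L)))
    stop("every edge entry must be -1, 0 or +1")
  storage.mode(edges) <- "integer"
  if (is.null(signal_mask)) signal_mask <- seq_len(n) <= 2L
  signal_mask <- as.logical(signal_mask)
  if (length(signal_mask) != n)
    stop("'signal_mask' must have one entry per gene")
  gene_names <- gene_labels(n)
  dimnames(edges) <- list(gene_names, gene_names)
  structure(list(n_genes = n, edges = edges, signal_mask = signal_mask),
            class = "topology")
}

gene_labels <- function(n) {
  base <- c("u", "v", "w")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("g", 4:n))[seq_len(n)]
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d genes, %d connections%s\n", x$n_genes,
              n_connections(x),
              if (is_connected_topology(x)) "" else " (not connected)"))
  print(x$edges)
  cat("signal ->", paste(gene_labels(x$n_genes)[x$signal_mask],
                         collapse = ", "), "\n")
  invisible(x)
}

#' Number of nonzero edges of a topology
#' @param topo a [topology()].
#' @return Integer count of active connections.
#' @export
n_connections <- function(topo) {
  stopifnot(inherits(topo, "topology"))
  sum(topo$edges != 0L)
}

#' Is a topology connected?
#'
#' A topology counts as connected when at least one off-diagonal edge is
#' nonzero, i.e. some gene regulates another gene.
#' @param topo a [topology()].
#' @return `TRUE` or `FALSE`.
#' @export
is_connected_topology <- function(topo) {
  stopifnot(inherits(topo, "topology"))
  e <- topo$edges
  diag(e) <- 0L
  any(e != 0L)
}

#' Flatten a topology into its integer encoding
#'
#' The encoding lists the edge signs gene-by-gene in the order
#' `y_uu, y_vu, y_wu, y_uv, y_vv, ...` (the regulated gene index varying
#' fastest), matching the 9-vector used for the three-gene superstructure.
#'
#' @param topo a [topology()].
#' @return Integer vector of length `n_genes^2`.
#' @export
as_topology_vector <- function(topo) {
  stopifnot(inherits(topo, "topology"))
  as.integer(topo$edges)
}

#' Rebuild a topology from its integer encoding
#' @param y integer vector of length `n_genes^2` (see [as_topology_vector()]).
#' @param n_genes number of genes.
#' @param signal_mask optional logical vector, see [topology()].
#' @return A [topology()].
#' @export
topology_from_vector <- function(y, n_genes, signal_mask = NULL) {
  if (length(y) != n_genes^2)
    stop("'y' must have length n_genes^2")
  topology(matrix(as.integer(y), n_genes, n_genes), signal_mask)
}

#' Enumerate all signed topologies of a small superstructure
#'
#' Generates every assignment of `{-1, 0, +1}` to the `n_genes^2` possible
#' edges, optionally excluding self-edges and topologies with no cross-gene
#' connection. For the two-gene superstructure with self-edges this yields
#' the 72 connected structures (3^4 assignments minus the 9 with no
#' cross-edge).
#'
#' @param n_genes 2 or 3 (exhaustive enumeration only).
#' @param allow_self include self-edges `y[i, i]`?
#' @param require_connected drop topologies whose off-diagonal edges are all
#'   zero?
#' @param signal_mask optional logical vector passed to [topology()].
#' @return List of [topology()] objects.
#' @export
enumerate_topologies <- function(n_genes, allow_self = TRUE,
                                 require_connected = TRUE,
                                 signal_mask = NULL) {
  if (!n_genes %in% c(1L, 2L, 3L))
    stop("exhaustive enumeration supports n_genes in {1, 2, 3}")
  free <- matrix(TRUE, n_genes, n_genes)
  if (!allow_self) diag(free) <- FALSE
  idx <- which(free)
  grid <- do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), length(idx)))
  out <- vector("list", nrow(grid))
  keep <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    e <- matrix(0L, n_genes, n_genes)
    e[idx] <- as.integer(unlist(grid[r, ], use.names = FALSE))
    topo <- topology(e, signal_mask)
    keep[r] <- !require_connected || is_connected_topology(topo)
    out[[r]] <- topo
  }
  out[keep]
}
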