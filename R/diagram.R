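#' Construct a bifurcation diagram object
#'
#' Low-level constructor normally called by [trace_diagram()]; exposed so
#' that diagrams can also be assembled from externally computed branch
#' data (e.g. analytic test curves).
#'
#' @param points data frame with columns `S`, `branch` (integer id),
#'   `stable` (logical) and one column per state coordinate.
#' @param saddle_nodes data frame with columns `fold`, `S`, one column per
#'   state coordinate, and `J`; may have zero rows.
#' @param s_range numeric length-2 signal window.
#' @param branch_ends optional data frame with columns `branch`, `start`,
#'   `end` where `start`/`end` give the fold id terminating the branch at
#'   its low/high-S end, or `NA` when the branch reaches the window edge.
#'   Reconstructed heuristically from proximity when omitted.
#' @param label optional class label; computed by [classify_diagram()]
#'   when omitted.
#' @return An object of class `"bifurcation_diagram"`.
#' @export
bifurcation_diagram <- function(points, saddle_nodes, s_range,
                                branch_ends = NULL, label = NULL) {
  gene_cols <- setdiff(names(points), c("S", "branch", "stable"))
  stopifnot(length(gene_cols) >= 1, all(c("S", "branch", "stable") %in%
                                          names(points)))
  points <- points[order(points$branch, points$S), , drop = FALSE]
  branches <- summarize_branches(points, saddle_nodes, s_range, gene_cols,
                                 branch_ends)
  comp <- branch_components(branches)
  counts <- count_table(points)
  dg <- structure(list(points = points, branches = branches,
                       saddle_nodes = saddle_nodes,
                       components = comp,
                       counts = counts,
                       bistable_ranges = bistable_ranges_from(counts,
                                                              saddle_nodes),
                       s_range = as.numeric(s_range),
                       gene_cols = gene_cols,
                       label = "other"),
                  class = "bifurcation_diagram")
  dg$label <- if (is.null(label)) classify_diagram(dg) else label
  dg
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat(sprintf("bifurcation diagram: %s | %d branches, %d saddle nodes, S in [%g, %g]\n",
              x$label, nrow(x$branches), nrow(x$saddle_nodes),
              x$s_range[1], x$s_range[2]))
  if (nrow(x$saddle_nodes))
    print(x$saddle_nodes, digits = 4)
  if (nrow(x$bistable_ranges))
    cat("bistable S ranges:",
        paste(apply(x$bistable_ranges, 1, function(r)
          sprintf("[%.3g, %.3g]", r[1], r[2])), collapse = ", "), "\n")
  invisible(x)
}

rel_state_dist <- function(a, b) {
  sqrt(sum((a - b)^2)) / (1 + sqrt(max(sum(a^2), sum(b^2))))
}

count_table <- function(points) {
  s_vals <- sort(unique(points$S))
  n_tot <- n_stab <- integer(length(s_vals))
  for (i in seq_along(s_vals)) {
    rows <- points$S == s_vals[i]
    n_tot[i] <- sum(rows)
    n_stab[i] <- sum(points$stable[rows])
  }
  data.frame(S = s_vals, n_total = n_tot, n_stable = n_stab)
}

summarize_branches <- function(points, saddle_nodes, s_range, gene_cols,
                               branch_ends) {
  ids <- sort(unique(points$branch))
  out <- data.frame(branch = ids, stable = NA, S_min = NA_real_,
                    S_max = NA_real_, start = NA_integer_,
                    end = NA_integer_, mean_level = NA_real_)
  span <- diff(range(s_range))
  edge_tol <- 0.02 * span
  for (r in seq_along(ids)) {
    pb <- points[points$branch == ids[r], , drop = FALSE]
    out$stable[r] <- pb$stable[1]
    out$S_min[r] <- min(pb$S)
    out$S_max[r] <- max(pb$S)
    out$mean_level[r] <- mean(pb[[gene_cols[1]]])
  }
  if (!is.null(branch_ends)) {
    m <- match(out$branch, branch_ends$branch)
    out$start <- branch_ends$start[m]
    out$end <- branch_ends$end[m]
  } else if (nrow(saddle_nodes)) {
    # attach a branch end to a fold when the branch endpoint is close to it
    for (r in seq_along(ids)) {
      pb <- points[points$branch == ids[r], , drop = FALSE]
      lo <- as.numeric(pb[which.min(pb$S), gene_cols])
      hi <- as.numeric(pb[which.max(pb$S), gene_cols])
      for (f in seq_len(nrow(saddle_nodes))) {
        fs <- saddle_nodes$S[f]
        fw <- as.numeric(saddle_nodes[f, gene_cols])
        if (abs(out$S_min[r] - fs) < 0.25 * span &&
            out$S_min[r] >= fs - 1e-9 * (1 + abs(fs)) &&
            rel_state_dist(lo, fw) < 0.15 &&
            abs(out$S_min[r] - fs) <= abs(out$S_min[r] - s_range[1]))
          out$start[r] <- saddle_nodes$fold[f]
        if (abs(out$S_max[r] - fs) < 0.25 * span &&
            out$S_max[r] <= fs + 1e-9 * (1 + abs(fs)) &&
            rel_state_dist(hi, fw) < 0.15 &&
            abs(out$S_max[r] - fs) <= abs(s_range[2] - out$S_max[r]))
          out$end[r] <- saddle_nodes$fold[f]
      }
    }
  }
  out
}

# connected components of the branch/fold incidence graph, plus closedness
branch_components <- function(branches) {
  nb <- nrow(branches)
  folds <- stats::na.omit(unique(c(branches$start, branches$end)))
  comp <- seq_len(nb)
  repeat {
    changed <- FALSE
    for (f in folds) {
      inc <- which(branches$start %in% f | branches$end %in% f)
      if (length(inc) > 1) {
        tgt <- min(comp[inc])
        if (any(comp[inc] != tgt)) { comp[inc] <- tgt; changed <- TRUE }
      }
    }
    # propagate transitive merges
    for (i in seq_len(nb)) {
      if (comp[comp[i]] != comp[i]) { comp[i] <- comp[comp[i]]; changed <- TRUE }
    }
    if (!changed) break
  }
  comp_ids <- unique(comp)
  closed <- logical(length(comp_ids))
  for (ci in seq_along(comp_ids)) {
    members <- which(comp == comp_ids[ci])
    # closed iff every member branch terminates at folds on both sides
    closed[ci] <- all(!is.na(branches$start[members])) &&
      all(!is.na(branches$end[members]))
  }
  list(membership = comp, ids = comp_ids, closed = closed)
}

bistable_ranges_from <- function(counts, saddle_nodes) {
  bi <- counts$n_stable >= 2
  if (!any(bi)) return(matrix(numeric(0), 0, 2))
  r <- rle(bi)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  out <- NULL
  fold_s <- saddle_nodes$S
  for (i in which(r$values)) {
    lo <- counts$S[starts[i]]
    hi <- counts$S[ends[i]]
    # snap interval ends to the nearest fold just outside the grid interval
    if (length(fold_s)) {
      cand <- fold_s[fold_s <= lo & (starts[i] == 1 |
                                       fold_s >= counts$S[max(1, starts[i] - 1)])]
      if (length(cand)) lo <- max(cand)
      cand <- fold_s[fold_s >= hi & (ends[i] == nrow(counts) |
                                       fold_s <= counts$S[min(nrow(counts), ends[i] + 1)])]
      if (length(cand)) hi <- min(cand)
    }
    out <- rbind(out, c(lo, hi))
  }
  out
}

#' Trace the bifurcation diagram of a circuit over a signal grid
#'
#' At every grid signal value all equilibria are located by dense-seeded
#' Newton iteration (see [steady_states()]); equilibria at adjacent grid
#' points are linked into branches by stability-aware nearest-neighbor
#' continuation. Every change in the equilibrium count is bracketed by
#' bisection and the underlying saddle-node point polished by Newton
#' iteration on the fold system, so disconnected closed branches (isolas)
#' are found as reliably as connected ones.
#'
#' @param model a [circuit_model()].
#' @param s_grid increasing vector of signal values (>= 50 points
#'   recommended; a log-spaced grid suits signal ranges spanning decades).
#' @param n_seed_axis seed-lattice resolution per state coordinate.
#' @param ftol equilibrium residual tolerance.
#' @param link_tol relative distance below which equilibria at adjacent
#'   grid points are linked into the same branch.
#' @return A [bifurcation_diagram()] with the classification label filled
#'   in.
#' @examples
#' \donttest{
#' mod <- reference_circuit("A1_mushroom")
#' dg <- trace_diagram(mod, s_grid = exp(seq(log(0.2), log(2000), length.out = 80)))
#' dg$label # "mushroom"
#' }
#' @export
trace_diagram <- function(model, s_grid, n_seed_axis = 8L, ftol = 1e-10,
                          link_tol = 0.4) {
  stopifnot(length(s_grid) >= 2, all(diff(s_grid) > 0))
  cm <- compile_model(model)
  n <- cm$n
  W0 <- seed_lattice(model, n_seed_axis)
  sweep_res <- cpp_sweep(cm, s_grid, W0, ftol, 80L, 1e-4)
  rootsets <- lapply(seq_along(s_grid), function(g) {
    r <- sweep_res[[g]]
    st <- r$stable
    if (anyNA(st) && nrow(r$states) > 0)
      for (i in which(is.na(st))) {
        ev <- eigen(cpp_state_jac(cm, r$states[i, ], s_grid[g]),
                    only.values = TRUE)
        st[i] <- all(Re(ev$values) < 0)
      }
    list(states = r$states, stable = st)
  })
  if (all(vapply(rootsets, function(r) nrow(r$states) == 0L, TRUE)))
    stop("no equilibria found anywhere on the signal grid")

  link <- link_branches(rootsets, s_grid, link_tol)
  folds <- locate_folds(model, cm, link, rootsets, s_grid, W0, ftol)

  gene_cols <- gene_labels(n)
  pts <- link$points
  names(pts) <- c("S", "branch", "stable", gene_cols)
  sn <- folds$table
  dg <- bifurcation_diagram(pts, sn, range(s_grid),
                            branch_ends = folds$branch_ends)
  attr(dg, "beta") <- folds$beta
  dg
}

# stability-aware nearest-neighbor linking of per-S root sets
link_branches <- function(rootsets, s_grid, link_tol) {
  n <- ncol(rootsets[[1]]$states)
  next_id <- 0L
  active <- list() # id -> list(state, stable)
  pts <- list()
  deaths <- births <- list()
  for (g in seq_along(s_grid)) {
    st <- rootsets[[g]]$states
    fl <- rootsets[[g]]$stable
    r <- nrow(st)
    assign_id <- integer(r)
    if (length(active) && r > 0) {
      cand <- NULL
      act_ids <- names(active)
      for (ai in seq_along(active)) for (ri in seq_len(r)) {
        if (!identical(active[[ai]]$stable, fl[ri])) next
        d <- rel_state_dist(active[[ai]]$state, st[ri, ])
        if (d < link_tol) cand <- rbind(cand, c(ai, ri, d))
      }
      if (!is.null(cand)) {
        cand <- cand[order(cand[, 3]), , drop = FALSE]
        used_a <- logical(length(active)); used_r <- logical(r)
        for (j in seq_len(nrow(cand))) {
          ai <- cand[j, 1]; ri <- cand[j, 2]
          if (used_a[ai] || used_r[ri]) next
          used_a[ai] <- TRUE; used_r[ri] <- TRUE
          assign_id[ri] <- as.integer(act_ids[ai])
        }
      }
    }
    dead <- if (length(active))
      as.integer(names(active)[!as.integer(names(active)) %in% assign_id])
    else integer(0)
    if (length(dead) && g > 1)
      deaths[[length(deaths) + 1L]] <- list(interval = c(g - 1L, g),
                                            branches = dead)
    new_active <- list()
    for (ri in seq_len(r)) {
      if (assign_id[ri] == 0L) {
        next_id <- next_id + 1L
        assign_id[ri] <- next_id
        if (g > 1)
          births[[length(births) + 1L]] <- list(interval = c(g - 1L, g),
                                                branch = next_id)
      }
      new_active[[as.character(assign_id[ri])]] <-
        list(state = st[ri, ], stable = fl[ri])
      pts[[length(pts) + 1L]] <- c(s_grid[g], assign_id[ri], fl[ri], st[ri, ])
    }
    active <- new_active
  }
  points <- as.data.frame(do.call(rbind, pts))
  points[[3]] <- as.logical(points[[3]])
  list(points = points, deaths = deaths, births = births)
}

# bracket each count-change event by bisection, then polish the fold
locate_folds <- function(model, cm, link, rootsets, s_grid, W0, ftol) {
  n <- cm$n
  pts <- link$points
  gene_idx <- 3L + seq_len(n)
  get_state <- function(branch, g) {
    rows <- pts[[2]] == branch & pts[[1]] == s_grid[g]
    if (!any(rows)) return(NULL)
    as.numeric(pts[rows, gene_idx][1, ])
  }
  # group simultaneous deaths (or births) into merging pairs by proximity
  pair_events <- function(evts, side) {
    out <- list()
    for (e in evts) {
      g_in <- if (side == "death") e$interval[1] else e$interval[2]
      if (side == "death") {
        brs <- e$branches
        states <- lapply(brs, get_state, g = g_in)
      } else {
        brs <- e$branch
        states <- lapply(brs, get_state, g = g_in)
      }
      for (i in seq_along(brs))
        out[[length(out) + 1L]] <- list(branch = brs[i],
                                        state = states[[i]],
                                        interval = e$interval, side = side)
    }
    out
  }
  evts <- c(pair_events(link$deaths, "death"), pair_events(link$births, "birth"))
  if (!length(evts))
    return(list(table = empty_fold_table(n), beta = NULL, branch_ends = NULL))

  folds <- list()
  beta_rows <- list()
  ends <- list() # per event: branch + which side attaches to which fold
  for (e in evts) {
    if (is.null(e$state)) next
    ga <- e$interval[1]; gb <- e$interval[2]
    lo <- s_grid[ga]; hi <- s_grid[gb]
    w_seed <- e$state
    # bisection on survival of the nearby root pair/point
    for (it in 1:12) {
      mid <- sqrt(lo * hi)
      if (!is.finite(mid) || mid <= 0) mid <- (lo + hi) / 2
      res <- cpp_steady_states(cm, mid, rbind(W0, w_seed), ftol, 80L, 1e-4)
      d <- if (nrow(res$states)) apply(res$states, 1, rel_state_dist,
                                       b = w_seed) else numeric(0)
      survives <- sum(d < 0.25) >= 2 # stable/unstable pair still distinct
      if ((e$side == "death") == survives) {
        if (e$side == "death") lo <- mid else hi <- mid
        if (survives) {
          near <- res$states[order(d)[1:2], , drop = FALSE]
          w_seed <- colMeans(near)
        }
      } else {
        if (e$side == "death") hi <- mid else lo <- mid
      }
    }
    pol <- refine_fold(model, w_seed, sqrt(lo * hi))
    if (!pol$converged || !is.finite(pol$J)) next
    folds[[length(folds) + 1L]] <- c(pol$S, pol$omega, pol$J)
    beta_rows[[length(beta_rows) + 1L]] <- pol$beta
    ends[[length(ends) + 1L]] <- list(branch = e$branch, side = e$side,
                                      idx = length(folds))
  }
  if (!length(folds))
    return(list(table = empty_fold_table(n), beta = NULL, branch_ends = NULL))
  tab <- as.data.frame(do.call(rbind, folds))
  names(tab) <- c("S", gene_labels(n), "J")
  beta <- do.call(rbind, beta_rows)
  # deduplicate folds (several branches can terminate at the same fold)
  keep <- !logical(nrow(tab))
  remap <- seq_len(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(tab))) {
      if (j <= i || !keep[j]) next
      same_s <- abs(tab$S[i] - tab$S[j]) <
        1e-3 * (1 + abs(tab$S[i]))
      same_w <- rel_state_dist(as.numeric(tab[i, 1 + seq_len(n)]),
                               as.numeric(tab[j, 1 + seq_len(n)])) < 1e-3
      if (same_s && same_w) { keep[j] <- FALSE; remap[j] <- i }
    }
  }
  new_id <- cumsum(keep)
  remap <- new_id[remap]
  tab <- tab[keep, , drop = FALSE]
  beta <- beta[keep, , drop = FALSE]
  tab <- cbind(fold = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  # branch -> fold attachment table
  all_branches <- sort(unique(pts[[2]]))
  be <- data.frame(branch = all_branches, start = NA_integer_,
                   end = NA_integer_)
  for (e in ends) {
    fid <- remap[e$idx]
    row <- which(be$branch == e$branch)
    if (e$side == "death") be$end[row] <- fid else be$start[row] <- fid
  }
  list(table = tab, beta = beta, branch_ends = be)
}

empty_fold_table <- function(n) {
  tab <- as.data.frame(matrix(numeric(0), 0, n + 3))
  names(tab) <- c("fold", "S", gene_labels(n), "J")
  tab
}

#' Curvature test for an isola
#'
#' An isola is a closed equilibrium branch bounded by two saddle nodes at
#' signals `S1 < S2`; along the closed curve the inverse branch function
#' `S(u)` has positive curvature at `S1` and negative curvature at `S2`
#' (the curve opens towards the interior of `[S1, S2]` at both ends). For
#' an open S-shaped hysteresis curve the folds do not bound a closed
#' branch and the test fails.
#'
#' @param diagram a [bifurcation_diagram()].
#' @param gene index of the state coordinate used as `u` (default 1).
#' @return `TRUE` iff the diagram has a candidate closed two-fold branch
#'   with the isola curvature signs.
#' @export
isola_curvature_check <- function(diagram, gene = 1L) {
  stopifnot(inherits(diagram, "bifurcation_diagram"))
  if (nrow(diagram$saddle_nodes) < 2)
    stop("not applicable: fewer than 2 saddle nodes")
  cc <- closed_two_fold_component(diagram)
  if (is.null(cc)) return(FALSE)
  s1 <- min(cc$fold_S); s2 <- max(cc$fold_S)
  c1 <- branch_curvature(diagram, cc$members, s1, gene)
  c2 <- branch_curvature(diagram, cc$members, s2, gene)
  isTRUE(c1 > 0) && isTRUE(c2 < 0)
}

# find a closed component whose folds number exactly 2
closed_two_fold_component <- function(diagram) {
  comp <- diagram$components
  br <- diagram$branches
  for (ci in seq_along(comp$ids)) {
    if (!comp$closed[ci]) next
    members <- br$branch[comp$membership == comp$ids[ci]]
    fids <- unique(stats::na.omit(c(br$start[br$branch %in% members],
                                    br$end[br$branch %in% members])))
    if (length(fids) == 2) {
      fs <- diagram$saddle_nodes$S[match(fids, diagram$saddle_nodes$fold)]
      return(list(members = members, folds = fids, fold_S = fs))
    }
  }
  NULL
}

# second-order FD curvature of S as a function of u near a fold, using the
# 5 component points nearest the fold (plus the fold itself)
branch_curvature <- function(diagram, members, fold_S, gene) {
  g_col <- diagram$gene_cols[gene]
  pb <- diagram$points[diagram$points$branch %in% members, , drop = FALSE]
  if (!nrow(pb)) return(NA_real_)
  ord <- order(abs(pb$S - fold_S))
  pb <- pb[ord[seq_len(min(5L, nrow(pb)))], , drop = FALSE]
  fr <- diagram$saddle_nodes[which.min(abs(diagram$saddle_nodes$S - fold_S)), ]
  u <- c(pb[[g_col]], fr[[g_col]])
  s <- c(pb$S, fr$S)
  if (length(unique(u)) < 3) return(NA_real_)
  fit <- stats::lm(s ~ u + I(u^2))
  2 * unname(stats::coef(fit)[3])
}

#' Classify a bifurcation diagram
#'
#' Applies the structural taxonomy of signal-driven equilibrium diagrams:
#'
#' * `mushroom` -- four folds bounding two disjoint bistable signal ranges,
#'   with an intermediate branch reachable only through the folds
#'   (`inverted_mushroom` when the intermediate branch sits at lower
#'   expression of the reporting gene than the outer locus);
#' * `isola` -- a closed two-fold branch (passing
#'   [isola_curvature_check()]) coexisting with a fold-free open branch;
#' * `bistable_switch` -- two folds bounding a single bistable range on
#'   open branches;
#' * `incomplete_mushroom_left` / `incomplete_mushroom_right` -- two or
#'   three folds with the mushroom head truncated by the signal window;
#' * `monostable` -- no folds and a unique equilibrium everywhere;
#' * `other` -- anything else (including ambiguous traces).
#'
#' @param diagram a [bifurcation_diagram()].
#' @param reporting_gene state coordinate used for the
#'   mushroom-vs-inverted orientation (default 1).
#' @return Character label.
#' @export
classify_diagram <- function(diagram, reporting_gene = 1L) {
  stopifnot(inherits(diagram, "bifurcation_diagram"))
  nf <- nrow(diagram$saddle_nodes)
  counts <- diagram$counts
  nb_ranges <- nrow(diagram$bistable_ranges)
  left_multi <- counts$n_total[1] > 1
  right_multi <- counts$n_total[nrow(counts)] > 1
  if (nf == 0) {
    if (max(counts$n_total) == 1) return("monostable")
    return("other")
  }
  if (nf == 4 && nb_ranges == 2 && !left_multi && !right_multi) {
    orient <- mushroom_orientation(diagram, reporting_gene)
    return(if (isTRUE(orient < 0)) "inverted_mushroom" else "mushroom")
  }
  if (nf %in% c(2L, 3L) && (left_multi || right_multi)) {
    return(if (left_multi && !right_multi) "incomplete_mushroom_left"
           else if (right_multi && !left_multi) "incomplete_mushroom_right"
           else "other")
  }
  if (nf == 2 && nb_ranges == 1) {
    cc <- closed_two_fold_component(diagram)
    if (!is.null(cc)) {
      open_free <- open_foldfree_branch(diagram, cc$members)
      if (open_free && isola_curvature_check(diagram, reporting_gene))
        return("isola")
      return("other")
    }
    return("bistable_switch")
  }
  "other"
}

# sign of (mean intermediate-branch level - mean outer-locus level)
mushroom_orientation <- function(diagram, gene) {
  g_col <- diagram$gene_cols[gene]
  br <- diagram$branches
  stable_br <- br[br$stable %in% TRUE, , drop = FALSE]
  if (nrow(stable_br) < 2) return(NA_real_)
  # the intermediate (head) branch is the stable branch bounded by folds on
  # both sides; outer branches touch the window boundary
  inner <- stable_br[!is.na(stable_br$start) & !is.na(stable_br$end), ,
                     drop = FALSE]
  outer <- stable_br[is.na(stable_br$start) | is.na(stable_br$end), ,
                     drop = FALSE]
  if (!nrow(inner) || !nrow(outer)) {
    # fall back: branch spanning the middle gap between bistable ranges
    mid <- mean(range(diagram$bistable_ranges))
    pm <- diagram$points[abs(diagram$points$S - mid) ==
                           min(abs(diagram$points$S - mid)), , drop = FALSE]
    pm <- pm[pm$stable, , drop = FALSE]
    if (!nrow(pm)) return(NA_real_)
    inner_level <- mean(pm[[g_col]])
    outer_level <- mean(stable_br$mean_level)
    return(sign(inner_level - outer_level))
  }
  sign(mean(inner$mean_level) - mean(outer$mean_level))
}

# is there an open branch without folds outside the given members?
open_foldfree_branch <- function(diagram, exclude) {
  br <- diagram$branches
  others <- br[!br$branch %in% exclude, , drop = FALSE]
  if (!nrow(others)) return(FALSE)
  any(is.na(others$start) & is.na(others$end))
}

#' Map diagram classes over a parameter plane
#'
#' Classifies the bifurcation diagram of the model at every point of a
#' two-parameter grid (for instance degradation rate `dv` versus
#' interaction strength `k`), producing the phase portrait of diagram
#' types around a working point.
#'
#' @param model template [circuit_model()].
#' @param axis1,axis2 lists `list(name = <parameter name>, grid = <numeric
#'   vector>)`; parameter names follow the design-vector convention
#'   (`p0, p1, p2, p4, p5, k, R1..R3, K1..K3, du, dv, dw`).
#' @param s_grid signal grid passed to [trace_diagram()].
#' @param ... further arguments to [trace_diagram()].
#' @return Character matrix of labels with `axis1` on rows; cells where
#'   tracing fails are labelled `"error"`.
#' @export
phase_map <- function(model, axis1, axis2, s_grid, ...) {
  stopifnot(is.list(axis1), is.list(axis2),
            all(c("name", "grid") %in% names(axis1)),
            all(c("name", "grid") %in% names(axis2)))
  out <- matrix(NA_character_, length(axis1$grid), length(axis2$grid),
                dimnames = list(signif(axis1$grid, 6),
                                signif(axis2$grid, 6)))
  for (i in seq_along(axis1$grid)) for (j in seq_along(axis2$grid)) {
    mod_ij <- set_param(set_param(model, axis1$name, axis1$grid[i]),
                        axis2$name, axis2$grid[j])
    out[i, j] <- tryCatch(trace_diagram(mod_ij, s_grid, ...)$label,
                          error = function(e) "error")
  }
  out
}

#' Override a single named parameter of a circuit model
#'
#' @param model a [circuit_model()].
#' @param name parameter name in the design-vector convention: `p0, p2,
#'   p4` (promoter strengths), `p1, p3, p5` (leakiness), `k`, `R1..R3`,
#'   `K1..K3`, `du, dv, dw` (or `d1, d2, d3`).
#' @param value numeric replacement.
#' @return Modified [circuit_model()].
#' @export
set_param <- function(model, name, value) {
  stopifnot(inherits(model, "circuit_model"), is.numeric(value))
  ps <- model$params
  slot_map <- list(p0 = c("p", 1), p2 = c("p", 2), p4 = c("p", 3),
                   p1 = c("l", 1), p3 = c("l", 2), p5 = c("l", 3),
                   R1 = c("R", 1), R2 = c("R", 2), R3 = c("R", 3),
                   K1 = c("K", 1), K2 = c("K", 2), K3 = c("K", 3),
                   du = c("d", 1), dv = c("d", 2), dw = c("d", 3),
                   d1 = c("d", 1), d2 = c("d", 2), d3 = c("d", 3))
  if (name == "k") {
    ps$k <- as.numeric(value)
  } else if (name %in% names(slot_map)) {
    slot <- slot_map[[name]][1]
    idx <- as.integer(slot_map[[name]][2])
    if (idx > ps$n_genes) stop("parameter '", name,
                               "' does not exist for this model")
    ps[[slot]][idx] <- as.numeric(value)
  } else stop("unknown parameter '", name, "'")
  validate_parameter_set(ps)
  model$params <- ps
  model
}
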