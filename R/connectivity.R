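# Friction surface, multi-source least-cost accumulation over the 16-cell
# knight's neighborhood, and rescaled, binned connectivity.

#' Friction surface
#'
#' Per-cell resistance to movement, the fuzzy complement of favorability:
#' `friction = 1 - F`.  Patch interiors (F > 0.8) are the only cells with
#' friction below 0.2.
#'
#' @param f a fitted `favorability_model` or favorability matrix.
#' @return matrix of frictions in \[0, 1\], `NA` outside the study area.
#' @export
friction_surface <- function(f) {
  fm <- as_favorability_matrix(f)
  1 - fm
}

source_mask_from <- function(sources, dim_ref) {
  m <- if (inherits(sources, "patch_set")) sources$labels > 0L
  else if (is.logical(sources) && is.matrix(sources)) sources
  else stop("`sources` must be a patch_set or a logical matrix")
  if (!identical(dim(m), dim_ref))
    stop("sources and friction are not on the same grid")
  m & !is.na(m)
}

#' Accumulate least cost from favorable patches
#'
#' Multi-source Dijkstra over the grid graph: every source (patch) cell
#' starts at cost 0, and moving from cell i to neighbor j costs
#' `d(i, j) * (friction_i + friction_j) / 2`, with step length `d` = 1 for
#' cardinal moves, sqrt(2) for diagonal and sqrt(5) for knight moves
#' (lengths in cell sides).  The default move set is the 16-cell knight's
#' neighborhood.  NODATA cells are impassable; valid cells isolated by
#' NODATA get infinite cost and are counted in `n_unreachable`.
#'
#' @param friction friction matrix from [friction_surface()] (`NA` =
#'   NODATA).
#' @param sources a `patch_set` or logical source mask; at least one
#'   source cell.
#' @param neighborhood `"knight16"` (default), `"queen8"` or `"rook4"`.
#' @return a `cost_surface`: `cost` matrix (0 on sources, `Inf` on
#'   unreachable valid cells, `NA` on NODATA), `source_mask`, `min_cost`
#'   and `max_cost` over reachable matrix (non-source) cells,
#'   `n_unreachable`, `neighborhood`.
#' @export
#' @examples
#' fr <- matrix(0.5, 1, 3)
#' src <- matrix(c(TRUE, FALSE, FALSE), 1, 3)
#' accumulate_cost(fr, src)$cost  # 0, 0.5, 1.0
accumulate_cost <- function(friction, sources,
                            neighborhood = c("knight16", "queen8",
                                             "rook4")) {
  neighborhood <- match.arg(neighborhood)
  stopifnot(is.matrix(friction))
  src <- source_mask_from(sources, dim(friction))
  if (!any(src)) stop("no source cells")
  nr <- nrow(friction); nc <- ncol(friction); n <- nr * nc
  fr <- as.vector(friction)
  valid <- !is.na(fr)
  moves <- neighbor_moves(neighborhood)
  dist <- rep(Inf, n)
  dist[src] <- 0
  done <- !valid
  row_of <- rep(seq_len(nr), nc)
  col_of <- rep(seq_len(nc), each = nr)
  repeat {
    dwork <- dist
    dwork[done] <- Inf
    u <- which.min(dwork)
    if (!is.finite(dwork[u])) break
    done[u] <- TRUE
    vr <- row_of[u] + moves[, 1L]
    vc <- col_of[u] + moves[, 2L]
    ok <- vr >= 1L & vr <= nr & vc >= 1L & vc <= nc
    if (!any(ok)) next
    v <- (vc[ok] - 1L) * nr + vr[ok]
    d <- moves[ok, 3L]
    keep <- valid[v] & !done[v]
    v <- v[keep]; d <- d[keep]
    if (!length(v)) next
    nd <- dist[u] + d * (fr[u] + fr[v]) / 2
    upd <- nd < dist[v]
    dist[v[upd]] <- nd[upd]
  }
  cost <- matrix(dist, nr, nc)
  cost[!valid] <- NA_real_
  matrix_cells <- valid & !src
  reach <- matrix_cells & is.finite(dist)
  structure(list(cost = cost, source_mask = src,
                 min_cost = if (any(reach)) min(dist[reach]) else NA_real_,
                 max_cost = if (any(reach)) max(dist[reach]) else NA_real_,
                 n_unreachable = sum(matrix_cells & !is.finite(dist)),
                 neighborhood = neighborhood),
            class = "cost_surface")
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf("cost_surface (%s): %d source cells; matrix cost range [%.4g, %.4g]; %d unreachable\n",
              x$neighborhood, sum(x$source_mask), x$min_cost, x$max_cost,
              x$n_unreachable))
  invisible(x)
}

#' Convert accumulated cost to rescaled connectivity
#'
#' Over matrix (non-source) cells the raw connectivity is
#' `1 - (cost - min_cost) / (max_cost - min_cost)`, using the minimum and
#' maximum over the reachable matrix cells of the same map, then rescaled
#' to \[0, 0.9\]: 0.9 at the patch border (minimum cost), 0 at maximum
#' cost.  Patch cells are set to exactly 1 — full connectivity is the
#' defining property of the patch interior.  Unreachable cells get 0.
#' With a flat cost field (`max == min`) every matrix cell gets 0.9 and
#' the map is flagged degenerate.
#'
#' @param cost a `cost_surface` from [accumulate_cost()].
#' @return a `connectivity_map`: `connectivity` matrix, `source_mask`,
#'   `degenerate` flag, `n_unreachable`, and `binned = NULL` (see
#'   [bin_connectivity()]).
#' @export
connectivity_from_cost <- function(cost) {
  stopifnot(inherits(cost, "cost_surface"))
  cm <- cost$cost
  src <- cost$source_mask
  valid <- !is.na(cm)
  matrix_cells <- valid & !src
  reach <- matrix_cells & is.finite(cm)
  if (!any(reach)) stop("no reachable matrix cell: connectivity undefined")
  conn <- matrix(NA_real_, nrow(cm), ncol(cm))
  degenerate <- cost$max_cost <= cost$min_cost
  if (degenerate) {
    conn[reach] <- 0.9
  } else {
    raw <- 1 - (cm[reach] - cost$min_cost) / (cost$max_cost - cost$min_cost)
    conn[reach] <- 0.9 * raw
  }
  conn[matrix_cells & !is.finite(cm)] <- 0
  conn[src] <- 1
  structure(list(connectivity = conn, source_mask = src,
                 degenerate = degenerate,
                 n_unreachable = cost$n_unreachable, binned = NULL),
            class = "connectivity_map")
}

#' Bin connectivity into the 18-level display scale
#'
#' Matrix cells are graded into eighteen levels of width 0.05 spanning
#' connectivity 0 to 0.9: `level = floor(connectivity / 0.05)`, clamped to
#' 17 at connectivity 0.9, so every map shares a homogeneous standard.
#' Patch cells are excluded from binning (rendered as their own class,
#' `NA` in `binned`).
#'
#' @param conn a `connectivity_map`.
#' @return the map with integer `binned` filled (levels 0..17 on matrix
#'   cells).
#' @export
bin_connectivity <- function(conn) {
  stopifnot(inherits(conn, "connectivity_map"))
  cm <- conn$connectivity
  lev <- matrix(NA_integer_, nrow(cm), ncol(cm))
  matrix_cells <- !is.na(cm) & !conn$source_mask
  lev[matrix_cells] <- pmin(as.integer(floor(cm[matrix_cells] / 0.05)), 17L)
  conn$binned <- lev
  conn
}

#' @export
print.connectivity_map <- function(x, ...) {
  mc <- !is.na(x$connectivity) & !x$source_mask
  cat(sprintf("connectivity_map: %d patch cells (=1), %d matrix cells in [%.3f, %.3f]%s\n",
              sum(x$source_mask), sum(mc),
              min(x$connectivity[mc]), max(x$connectivity[mc]),
              if (x$degenerate) " [degenerate rescale]" else ""))
  if (!is.null(x$binned))
    cat("  binned into 18 levels of width 0.05\n")
  invisible(x)
}

#' Pairwise least-cost distances between patches
#'
#' For each patch, accumulates cost from that patch alone and reads the
#' minimum over every other patch's cells — the border-to-border least
#' accumulated cost.
#'
#' @param friction friction matrix.
#' @param patches a `patch_set` with at least two patches.
#' @inheritParams accumulate_cost
#' @return symmetric numeric matrix (0 diagonal) of inter-patch costs.
#' @export
patch_cost_matrix <- function(friction, patches,
                              neighborhood = "knight16") {
  stopifnot(inherits(patches, "patch_set"))
  k <- patches$n_patches
  if (k < 2) stop("need at least two patches")
  out <- matrix(0, k, k)
  for (i in seq_len(k)) {
    cs <- accumulate_cost(friction, patches$labels == i, neighborhood)
    for (j in seq_len(k)) {
      if (j == i) next
      out[i, j] <- min(cs$cost[patches$labels == j])
    }
  }
  (out + t(out)) / 2
}
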