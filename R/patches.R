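# Favorable-patch detection, occupancy labelling, and metapopulation
# classification.

#' Connected components of a logical grid mask
#'
#' Flood-fill labelling under queen (8-neighbor) or rook (4-neighbor)
#' adjacency.  Labels are assigned in first-encounter (column-major) order,
#' so they are contiguous from 1 and deterministic.
#'
#' @param mask logical matrix (`NA` treated as `FALSE`).
#' @param adjacency `"queen"` or `"rook"`.
#' @return list: integer `labels` matrix (0 outside the mask), component
#'   count `n`, and `sizes`.
#' @export
label_components <- function(mask, adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  stopifnot(is.matrix(mask))
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  moves <- neighbor_moves(if (adjacency == "queen") "queen8" else "rook4")
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  queue <- integer(nr * nc)
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    queue[1L] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      ur <- ((u - 1L) %% nr) + 1L
      uc <- ((u - 1L) %/% nr) + 1L
      for (k in seq_len(nrow(moves))) {
        vr <- ur + moves[k, 1L]; vc <- uc + moves[k, 2L]
        if (vr < 1L || vr > nr || vc < 1L || vc > nc) next
        v <- (vc - 1L) * nr + vr
        if (mask[v] && labels[v] == 0L) {
          labels[v] <- lab
          tail <- tail + 1L
          queue[tail] <- v
        }
      }
    }
  }
  list(labels = labels, n = lab,
       sizes = if (lab > 0) as.vector(tabulate(labels[labels > 0L], lab))
       else integer(0))
}

as_favorability_matrix <- function(f) {
  if (inherits(f, "favorability_model")) {
    if (is.null(f$grid) || is.null(f$favorability))
      stop("model has no favorability surface; fit it with favorability_fit()")
    land <- structure(list(n_rows = f$grid$n_rows, n_cols = f$grid$n_cols,
                           valid = f$grid$valid), class = "grid_landscape")
    surface_matrix(land, f$favorability)
  } else if (is.matrix(f)) f
  else stop("`f` must be a favorability_model or a matrix")
}

#' Detect favorable patches
#'
#' Thresholds the favorability surface at `threshold` (default 0.8, the
#' conventional high-favorability cut) and labels maximal sets of
#' contiguous cells as patches.  Contiguity is queen (8-neighbor) by
#' default — diagonal neighbors are also treated as passable in the
#' connectivity stage — with rook available.
#'
#' @param f a fitted `favorability_model` or a favorability matrix (`NA`
#'   outside the study area).
#' @param threshold favorability cut defining "favorable".
#' @param adjacency `"queen"` or `"rook"`.
#' @return a `patch_set`: integer `labels` matrix (0 = matrix cells, `NA`
#'   pattern follows the input), `n_patches`, `sizes`, `threshold`,
#'   `adjacency`, and `occupied` (`NULL` until [label_occupancy()]).
#' @export
detect_patches <- function(f, threshold = 0.8,
                           adjacency = c("queen", "rook")) {
  adjacency <- match.arg(adjacency)
  fm <- as_favorability_matrix(f)
  comp <- label_components(!is.na(fm) & fm >= threshold, adjacency)
  structure(list(labels = comp$labels, n_patches = comp$n,
                 sizes = comp$sizes, threshold = threshold,
                 adjacency = adjacency, occupied = NULL),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d favorable patch(es) at F >= %g (%s adjacency), %d cells total\n",
              x$n_patches, x$threshold, x$adjacency, sum(x$sizes)))
  if (!is.null(x$occupied))
    cat(sprintf("  occupied: %d, empty: %d\n", sum(x$occupied),
                sum(!x$occupied)))
  invisible(x)
}

#' Label patches as occupied or empty
#'
#' A patch is occupied as a whole if at least one of its cells has a
#' recorded presence.  Empty favorable patches are kept: they are the
#' recolonizable habitat a metapopulation analysis must retain.
#'
#' @param patches a `patch_set` from [detect_patches()].
#' @param occurrence the [species_occurrence] on the same grid.
#' @return the `patch_set` with logical `occupied` filled (length
#'   `n_patches`).
#' @export
label_occupancy <- function(patches, occurrence) {
  stopifnot(inherits(patches, "patch_set"),
            inherits(occurrence, "species_occurrence"))
  if (max(occurrence$cell_id) > length(patches$labels))
    stop("occurrence and patches are not on the same grid")
  pres_cells <- occurrence$cell_id[occurrence$presence == 1L]
  hit <- patches$labels[pres_cells]
  patches$occupied <- seq_len(patches$n_patches) %in% hit[hit > 0L]
  patches
}

#' Classify a species' distribution structure
#'
#' Applies the metapopulation rule: the distribution is a metapopulation
#' when the favorable area is patchy (>= 2 patches) AND the proportion of
#' recorded presences lying in high-favorability cells exceeds 0.5
#' (strictly).  One patch is a non-fragmented distribution; no favorable
#' cell at all is its own category; fragmented distributions failing the
#' proportion rule are fragmented but not metapopulations (typically
#' generalists whose presences spread over the matrix).
#'
#' @param patches a `patch_set` (occupancy labels are filled in if absent).
#' @param f the favorability surface (model or matrix) the patches came
#'   from.
#' @param occurrence the [species_occurrence] on the same grid.
#' @param proportion_threshold strict lower bound on the proportion of
#'   presences in favorable cells (default 0.5; exactly 0.5 does not
#'   qualify).
#' @return a `structure_classification`: `category` (one of
#'   `"no_favorable_area"`, `"non_fragmented"`, `"metapopulation"`,
#'   `"fragmented_non_metapopulation"`), `n_patches`,
#'   `n_occupied_patches`, `n_empty_patches`, and
#'   `presence_in_favorable_proportion` (`NA` with zero presences; the
#'   metapopulation condition then cannot be established).
#' @export
classify_structure <- function(patches, f, occurrence,
                               proportion_threshold = 0.5) {
  stopifnot(inherits(patches, "patch_set"),
            inherits(occurrence, "species_occurrence"))
  if (is.null(patches$occupied))
    patches <- label_occupancy(patches, occurrence)
  fm <- as_favorability_matrix(f)
  pres_cells <- occurrence$cell_id[occurrence$presence == 1L]
  prop <- if (length(pres_cells) == 0) NA_real_
  else mean(fm[pres_cells] >= patches$threshold)
  category <-
    if (patches$n_patches == 0L) "no_favorable_area"
    else if (patches$n_patches == 1L) "non_fragmented"
    else if (!is.na(prop) && prop > proportion_threshold) "metapopulation"
    else "fragmented_non_metapopulation"
  structure(list(category = category,
                 n_patches = patches$n_patches,
                 n_occupied_patches = sum(patches$occupied),
                 n_empty_patches = sum(!patches$occupied),
                 presence_in_favorable_proportion = prop),
            class = "structure_classification")
}

#' @export
print.structure_classification <- function(x, ...) {
  cat(sprintf("distribution structure: %s\n", x$category))
  cat(sprintf("  %d patch(es): %d occupied, %d empty; presences in favorable cells: %s\n",
              x$n_patches, x$n_occupied_patches, x$n_empty_patches,
              ifelse(is.na(x$presence_in_favorable_proportion), "NA",
                     sprintf("%.3f", x$presence_in_favorable_proportion))))
  invisible(x)
}
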