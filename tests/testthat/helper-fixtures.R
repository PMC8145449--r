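# Fixture builders and independent oracles shared across the suite.

# landscape built directly from matrices (no RNG), all cells valid unless
# a mask is given
toy_landscape <- function(..., valid = NULL, cell_size = 10) {
  preds <- list(...)
  if (length(preds) == 1 && is.list(preds[[1]]) && !is.matrix(preds[[1]]))
    preds <- preds[[1]]
  dims <- dim(preds[[1]])
  if (is.null(valid)) valid <- matrix(TRUE, dims[1], dims[2])
  preds <- lapply(preds, function(m) { m[!valid] <- NA_real_; m })
  structure(list(n_rows = dims[1], n_cols = dims[2], cell_size = cell_size,
                 valid = valid, predictors = preds),
            class = "grid_landscape")
}

# an empty-predictor landscape, for occurrence-only fixtures
bare_landscape <- function(n_rows, n_cols, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, n_rows, n_cols)
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = 10,
                 valid = valid, predictors = list()),
            class = "grid_landscape")
}

# Independent least-cost oracle: explicit weighted graph + igraph.
# The move set is written out literally here, on purpose, so the oracle
# shares no code with the package's Dijkstra.
oracle_moves <- function(neighborhood) {
  all_moves <- rbind(
    expand.grid(dr = -1:1, dc = -1:1),
    data.frame(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
               dc = c(-1, 1, -2, 2, -2, 2, -1, 1)))
  all_moves <- all_moves[!(all_moves$dr == 0 & all_moves$dc == 0), ]
  all_moves$d <- sqrt(all_moves$dr^2 + all_moves$dc^2)
  switch(neighborhood,
         rook4 = all_moves[all_moves$d == 1, ],
         queen8 = all_moves[all_moves$d <= sqrt(2), ],
         knight16 = all_moves)
}

oracle_cost <- function(friction, src, neighborhood = "knight16") {
  nr <- nrow(friction); nc <- ncol(friction)
  n <- nr * nc
  moves <- oracle_moves(neighborhood)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(friction[r, c])) next
    u <- (c - 1) * nr + r
    for (k in seq_len(nrow(moves))) {
      r2 <- r + moves$dr[k]; c2 <- c + moves$dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(friction[r2, c2])) next
      v <- (c2 - 1) * nr + r2
      from <- c(from, u); to <- c(to, v)
      w <- c(w, moves$d[k] * (friction[r, c] + friction[r2, c2]) / 2)
    }
  }
  super <- n + 1L
  src_idx <- which(src & !is.na(friction))
  g <- igraph::make_empty_graph(n = super, directed = TRUE)
  g <- igraph::add_edges(g, c(rbind(from, to),
                              rbind(rep(super, length(src_idx)), src_idx)))
  igraph::E(g)$weight <- c(w, rep(0, length(src_idx)))
  d <- igraph::distances(g, v = super, mode = "out")[1, seq_len(n)]
  out <- matrix(d, nr, nc)
  out[is.na(friction)] <- NA_real_
  out
}

# independent component count: igraph on an explicitly built adjacency
oracle_components <- function(mask, adjacency = "queen") {
  nr <- nrow(mask); nc <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  cells <- which(mask)
  if (!length(cells)) return(0L)
  moves <- oracle_moves(if (adjacency == "queen") "queen8" else "rook4")
  from <- integer(0); to <- integer(0)
  for (u in cells) {
    r <- ((u - 1) %% nr) + 1; c <- ((u - 1) %/% nr) + 1
    for (k in seq_len(nrow(moves))) {
      r2 <- r + moves$dr[k]; c2 <- c + moves$dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- (c2 - 1) * nr + r2
      if (mask[v]) { from <- c(from, u); to <- c(to, v) }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(cells)))
  as.integer(igraph::components(g)$no)
}
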