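#' Grid move tables
#'
#' Relative moves and step lengths for the neighborhoods used in patch
#' labelling and cost accumulation.  `"knight16"` is the 16-cell knight's
#' neighborhood: the 8 queen moves plus the 8 chess-knight moves, with
#' Euclidean step lengths 1, sqrt(2) and sqrt(5) cell sides.
#'
#' @param neighborhood one of `"knight16"`, `"queen8"`, `"rook4"`.
#' @return a numeric matrix with columns `dr`, `dc`, `d` (row offset,
#'   column offset, step length in cell sides).
#' @export
#' @examples
#' nrow(neighbor_moves("knight16"))  # 16
neighbor_moves <- function(neighborhood = c("knight16", "queen8", "rook4")) {
  neighborhood <- match.arg(neighborhood)
  rook <- cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L), d = 1)
  diag <- cbind(dr = c(-1L, -1L, 1L, 1L), dc = c(-1L, 1L, -1L, 1L),
                d = sqrt(2))
  knight <- cbind(dr = c(-2L, -2L, -1L, -1L, 1L, 1L, 2L, 2L),
                  dc = c(-1L, 1L, -2L, 2L, -2L, 2L, -1L, 1L),
                  d = sqrt(5))
  switch(neighborhood,
         rook4 = rook,
         queen8 = rbind(rook, diag),
         knight16 = rbind(rook, diag, knight))
}

# place a valid-cell vector back onto the full grid (NA outside the mask)
#' Expand a valid-cell vector to a full grid matrix
#'
#' Values are stored per valid cell in the column-major order of
#' `which(landscape$valid)`; this puts them back at their grid position,
#' with `NA` on cells outside the study area.
#'
#' @param landscape a [grid_landscape] object.
#' @param values numeric vector, one value per valid cell.
#' @return an `n_rows` by `n_cols` matrix.
#' @export
surface_matrix <- function(landscape, values) {
  stopifnot(inherits(landscape, "grid_landscape"))
  if (length(values) != sum(landscape$valid))
    stop("`values` must have one entry per valid cell")
  m <- matrix(NA_real_, landscape$n_rows, landscape$n_cols)
  m[landscape$valid] <- values
  m
}

# run `expr` with a private RNG stream; restores the caller's .Random.seed
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

# polynomial rolling hash of a deparsed object, for provenance stamps
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
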