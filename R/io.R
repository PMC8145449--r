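# File exchange: ESRI ASCII grids, CSV tables, JSON sidecars.

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster format readable by QGIS/GRASS: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by the rows, top row first.  `NA` cells are
#' written as the NODATA value.  Integer matrices are written exactly;
#' doubles with 10 significant digits.
#'
#' @param m numeric or integer matrix (row 1 = top of the map).
#' @param path output file.
#' @param cell_size cell side length.
#' @param xll,yll lower-left corner coordinates.
#' @param nodata NODATA sentinel.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cell_size = 10, xll = 0, yll = 0,
                             nodata = -9999) {
  stopifnot(is.matrix(m))
  int <- is.integer(m) || (is.numeric(m) &&
                             all(m == round(m), na.rm = TRUE))
  fmt <- if (int) "%d" else "%.10g"
  vals <- m
  vals[is.na(vals)] <- nodata
  header <- c(sprintf("ncols %d", ncol(m)),
              sprintf("nrows %d", nrow(m)),
              sprintf("xllcorner %.10g", xll),
              sprintf("yllcorner %.10g", yll),
              sprintf("cellsize %.10g", cell_size),
              sprintf("NODATA_value %s", sprintf(fmt, nodata)))
  body <- apply(vals, 1, function(r)
    paste(sprintf(fmt, if (int) as.integer(r) else r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any ESRI ASCII
#'   raster).
#' @return list: `matrix` (NODATA as `NA`), `cell_size`, `xll`, `yll`,
#'   `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nc <- header$ncols; nr <- header$nrows
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("malformed ASCII grid: ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- header$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA
  list(matrix = m, cell_size = header$cellsize,
       xll = header$xllcorner, yll = header$yllcorner, nodata = nodata)
}

#' Write a landscape as a raster stack + sidecar
#'
#' One `.asc` file per predictor layer, a `mask.asc` (1 valid / NODATA),
#' and a JSON sidecar with the grid geometry and layer names.  A
#' long-format CSV (`cell_id`, `row`, `col`, `predictor`, `value`) is
#' written alongside for table-based workflows.
#'
#' @param landscape a `grid_landscape`.
#' @param dir output directory (created if needed).
#' @param name stem used for the sidecar and CSV.
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir, name = "landscape") {
  stopifnot(inherits(landscape, "grid_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask <- matrix(NA_integer_, landscape$n_rows, landscape$n_cols)
  mask[landscape$valid] <- 1L
  write_ascii_grid(mask, file.path(dir, "mask.asc"),
                   cell_size = landscape$cell_size)
  for (nm in names(landscape$predictors))
    write_ascii_grid(landscape$predictors[[nm]],
                     file.path(dir, paste0(nm, ".asc")),
                     cell_size = landscape$cell_size)
  df <- as.data.frame(landscape)
  long <- do.call(rbind, lapply(names(landscape$predictors), function(nm)
    data.frame(cell_id = df$cell_id, row = df$row, col = df$col,
               predictor = nm, value = df[[nm]])))
  utils::write.csv(long, file.path(dir, paste0(name, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_rows = landscape$n_rows, n_cols = landscape$n_cols,
         cell_size = landscape$cell_size,
         predictors = names(landscape$predictors)),
    file.path(dir, paste0(name, ".json")), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a species occurrence table
#'
#' Long CSV: `species_id`, `cell_id`, `presence`.  If the occurrence
#' carries generative truth (from [generate_species()]), the true
#' intercept and coefficients go to a JSON sidecar next to it.
#'
#' @param occurrence a `species_occurrence`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrence <- function(occurrence, path) {
  stopifnot(inherits(occurrence, "species_occurrence"))
  utils::write.csv(
    data.frame(species_id = occurrence$species_id,
               cell_id = occurrence$cell_id,
               presence = occurrence$presence),
    path, row.names = FALSE)
  if (!is.null(occurrence$truth))
    jsonlite::write_json(
      list(species_id = occurrence$species_id,
           intercept = occurrence$truth$intercept,
           coefficients = as.list(occurrence$truth$coefficients)),
      sub("\\.csv$", "_truth.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a model registry
#'
#' JSON array, one record per fitted model: species, selected variables,
#' intercept and coefficients with z and p, AIC, class counts — the
#' machine-readable analogue of a "logit equations" appendix.
#'
#' @param models list of `favorability_model` objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_registry <- function(models, path) {
  recs <- lapply(models, function(m) {
    stopifnot(inherits(m, "favorability_model"))
    list(species_id = m$species_id, variables = m$variables,
         intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         z = as.list(m$coefficient_z), p = as.list(m$coefficient_p),
         aic = m$aic, n1 = m$n1, n0 = m$n0,
         engine = m$engine, separation = m$separation)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
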