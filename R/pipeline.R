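# End-to-end orchestration: fit -> evaluate -> patches -> classify ->
# connectivity, per species and over a panel.

#' Pipeline configuration
#'
#' All stage thresholds in one place, defaulting to the standard values of
#' the favorability workflow: patches at F >= 0.8, classification at
#' F = 0.5 (the prevalence anchor), FDR q = 0.05, trim alpha = 0.05,
#' metapopulation proportion strictly > 0.5.
#'
#' @param favorability_patch favorability cut defining favorable patches.
#' @param classification_threshold favorability cut for the confusion
#'   metrics.
#' @param fdr_q FDR level of the univariate screening.
#' @param trim_alpha Wald level of the trimming stage.
#' @param metapop_proportion strict lower bound on the proportion of
#'   presences in favorable cells.
#' @param adjacency patch contiguity: `"queen"` or `"rook"`.
#' @param neighborhood cost-accumulation move set: `"knight16"`,
#'   `"queen8"` or `"rook4"`.
#' @param hl_bins Hosmer-Lemeshow bin count.
#' @param seed optional integer recorded for provenance (the pipeline
#'   itself is deterministic; the seed matters when the inputs are
#'   generated).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(favorability_patch = 0.8,
                            classification_threshold = 0.5,
                            fdr_q = 0.05, trim_alpha = 0.05,
                            metapop_proportion = 0.5,
                            adjacency = c("queen", "rook"),
                            neighborhood = c("knight16", "queen8",
                                             "rook4"),
                            hl_bins = 10L, seed = NULL) {
  thr <- c(favorability_patch, classification_threshold, fdr_q,
           trim_alpha, metapop_proportion)
  if (any(thr <= 0 | thr >= 1))
    stop("all thresholds must lie strictly inside (0, 1)")
  structure(list(favorability_patch = favorability_patch,
                 classification_threshold = classification_threshold,
                 fdr_q = fdr_q, trim_alpha = trim_alpha,
                 metapop_proportion = metapop_proportion,
                 adjacency = match.arg(adjacency),
                 neighborhood = match.arg(neighborhood),
                 hl_bins = as.integer(hl_bins), seed = seed),
            class = "pipeline_config")
}

log_stage <- function(verbose, species_id, stage, t0, ...) {
  if (!verbose) return(invisible())
  extra <- list(...)
  rec <- c(list(species = species_id, stage = stage,
                elapsed_s = round(as.numeric(Sys.time()) - t0, 3)), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n")
}

#' Run the full pipeline for one species
#'
#' Screen, select and trim the logistic model, transform to favorability,
#' evaluate, detect and label favorable patches, classify the distribution
#' structure, and — when patches exist — build the friction surface,
#' accumulate least cost over the configured neighborhood, rescale to
#' connectivity and bin it.  Fully deterministic for given inputs.
#'
#' @param occurrence a [species_occurrence] with both classes (a
#'   single-class species raises a `favmeta_degenerate_species` error;
#'   [run_panel()] turns that into a logged skip).
#' @param landscape the matching [grid_landscape].
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, write all artifacts there (favorability,
#'   probability, patch-label, connectivity and binned-connectivity ASCII
#'   grids plus a JSON report).
#' @param verbose emit one JSON log line per stage.
#' @return a `species_report`: `model` summary, `metrics`,
#'   `classification`, `connectivity` summary (min/max cost, unreachable
#'   count, bin occupancy), `flags`, and the `config_hash`.
#' @export
run_species <- function(occurrence, landscape, config = pipeline_config(),
                        out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (occurrence$n1 == 0 || occurrence$n0 == 0)
    stop(structure(class = c("favmeta_degenerate_species", "error",
                             "condition"),
                   list(message = paste0("species '",
                                         occurrence$species_id,
                                         "' has a single class; skipped"),
                        call = sys.call())))
  t0 <- as.numeric(Sys.time())
  model <- favorability_fit(occurrence, landscape, q = config$fdr_q,
                            trim_alpha = config$trim_alpha)
  log_stage(verbose, occurrence$species_id, "fit", t0,
            variables = length(model$variables),
            separation = model$separation)
  metrics <- evaluate_model(model,
                            threshold = config$classification_threshold,
                            n_bins = config$hl_bins)
  log_stage(verbose, occurrence$species_id, "evaluate", t0,
            auc = round(metrics$auc, 4))
  fm <- as_favorability_matrix(model)
  patches <- detect_patches(fm, threshold = config$favorability_patch,
                            adjacency = config$adjacency)
  patches <- label_occupancy(patches, occurrence)
  classification <- classify_structure(
    patches, fm, occurrence,
    proportion_threshold = config$metapop_proportion)
  log_stage(verbose, occurrence$species_id, "structure", t0,
            n_patches = patches$n_patches,
            category = classification$category)

  conn_summary <- NULL
  conn <- NULL
  if (patches$n_patches > 0 && any(patches$labels == 0L & !is.na(fm))) {
    fr <- friction_surface(fm)
    cs <- accumulate_cost(fr, patches, neighborhood = config$neighborhood)
    conn <- bin_connectivity(connectivity_from_cost(cs))
    lev <- conn$binned[!is.na(conn$binned)]
    bin_frac <- as.vector(tabulate(lev + 1L, 18L)) / length(lev)
    conn_summary <- list(min_cost = cs$min_cost, max_cost = cs$max_cost,
                         n_unreachable = cs$n_unreachable,
                         degenerate_rescale = conn$degenerate,
                         bin_fraction = bin_frac)
    if (cs$n_unreachable > 0)
      warning("species '", occurrence$species_id, "': ",
              cs$n_unreachable, " matrix cell(s) unreachable from any patch")
    log_stage(verbose, occurrence$species_id, "connectivity", t0,
              degenerate = conn$degenerate)
  }

  report <- structure(list(
    species_id = occurrence$species_id,
    model = list(variables = model$variables,
                 intercept = model$intercept,
                 coefficients = model$coefficients,
                 aic = model$aic, n1 = model$n1, n0 = model$n0,
                 engine = model$engine),
    metrics = metrics,
    classification = classification,
    connectivity = conn_summary,
    flags = list(separation = model$separation,
                 degenerate_rescale = isTRUE(conn_summary$degenerate_rescale),
                 unreachable_cells = isTRUE(conn_summary$n_unreachable > 0)),
    config_hash = config_hash(unclass(config))),
    class = "species_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sid <- occurrence$species_id
    land <- structure(list(n_rows = landscape$n_rows,
                           n_cols = landscape$n_cols,
                           valid = landscape$valid), class = "grid_landscape")
    cs_len <- landscape$cell_size
    write_ascii_grid(surface_matrix(land, model$favorability),
                     file.path(out_dir, paste0(sid, "_F.asc")), cs_len)
    write_ascii_grid(surface_matrix(land, model$fitted_probability),
                     file.path(out_dir, paste0(sid, "_P.asc")), cs_len)
    write_ascii_grid(patches$labels,
                     file.path(out_dir, paste0(sid, "_patches.asc")), cs_len)
    if (!is.null(conn)) {
      write_ascii_grid(conn$connectivity,
                       file.path(out_dir, paste0(sid, "_connectivity.asc")),
                       cs_len)
      write_ascii_grid(conn$binned,
                       file.path(out_dir, paste0(sid, "_connectivity_bins.asc")),
                       cs_len)
    }
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, paste0(sid, "_report.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$metrics <- unclass(r$metrics)
  r$classification <- unclass(r$classification)
  r$model$coefficients <- as.list(r$model$coefficients)
  r
}

#' @export
print.species_report <- function(x, ...) {
  cat(sprintf("species report '%s'\n", x$species_id))
  cat(sprintf("  model: %s (AIC %.2f)\n",
              if (length(x$model$variables))
                paste(x$model$variables, collapse = " + ")
              else "intercept only", x$model$aic))
  cat(sprintf("  AUC %.3f (%s); category %s (%d patches, %d occupied)\n",
              x$metrics$auc, x$metrics$auc_class,
              x$classification$category, x$classification$n_patches,
              x$classification$n_occupied_patches))
  flg <- names(Filter(isTRUE, x$flags))
  if (length(flg)) cat("  flags:", paste(flg, collapse = ", "), "\n")
  invisible(x)
}

#' Run the pipeline over a panel of species
#'
#' Applies [run_species()] to every occurrence, skipping (with a logged
#' reason) species with a single class, and tabulates the per-species
#' outcomes: structure categories, AUC quality classes, calibration
#' verdicts.
#'
#' @param occurrences list of [species_occurrence] objects on the same
#'   landscape.
#' @param landscape the shared [grid_landscape].
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, per-species artifacts plus `summary.csv`
#'   and `model_registry.json` are written there.
#' @param verbose per-stage JSON log lines.
#' @return a `panel_summary`: data.frame `summary` (one row per processed
#'   species), `reports` (list), `skipped` (data.frame of species_id and
#'   reason), and count tables `category_counts`, `auc_class_counts`,
#'   `n_well_calibrated`.
#' @export
run_panel <- function(occurrences, landscape, config = pipeline_config(),
                      out_dir = NULL, verbose = FALSE) {
  reports <- list()
  skipped <- data.frame(species_id = character(0), reason = character(0))
  for (occ in occurrences) {
    rep_i <- tryCatch(
      run_species(occ, landscape, config, out_dir = out_dir,
                  verbose = verbose),
      favmeta_degenerate_species = function(e) {
        if (verbose)
          cat(jsonlite::toJSON(list(species = occ$species_id,
                                    stage = "skip",
                                    reason = conditionMessage(e)),
                               auto_unbox = TRUE), "\n")
        skipped <<- rbind(skipped,
                          data.frame(species_id = occ$species_id,
                                     reason = conditionMessage(e)))
        NULL
      })
    if (!is.null(rep_i)) reports[[rep_i$species_id]] <- rep_i
  }
  summary_df <- do.call(rbind, lapply(reports, function(r)
    data.frame(species_id = r$species_id,
               category = r$classification$category,
               n_patches = r$classification$n_patches,
               n_occupied = r$classification$n_occupied_patches,
               n_empty = r$classification$n_empty_patches,
               proportion = r$classification$presence_in_favorable_proportion,
               auc = r$metrics$auc, auc_class = r$metrics$auc_class,
               well_calibrated = r$metrics$well_calibrated,
               kappa = r$metrics$kappa, ccr = r$metrics$ccr,
               separation = r$flags$separation,
               row.names = NULL)))
  if (is.null(summary_df))
    summary_df <- data.frame(species_id = character(0))
  out <- structure(list(
    summary = summary_df, reports = reports, skipped = skipped,
    category_counts = if (nrow(summary_df))
      table(factor(summary_df$category,
                   levels = c("no_favorable_area", "non_fragmented",
                              "metapopulation",
                              "fragmented_non_metapopulation")))
    else table(character(0)),
    auc_class_counts = if (nrow(summary_df))
      table(factor(summary_df$auc_class,
                   levels = c("outstanding", "excellent", "acceptable",
                              "poor")))
    else table(character(0)),
    n_well_calibrated = sum(summary_df$well_calibrated)),
    class = "panel_summary")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("panel: %d species processed, %d skipped\n",
              nrow(x$summary), nrow(x$skipped)))
  cat("  structure categories:\n")
  print(x$category_counts)
  cat("  AUC classes:\n")
  print(x$auc_class_counts)
  cat(sprintf("  well-calibrated: %d\n", x$n_well_calibrated))
  invisible(x)
}
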