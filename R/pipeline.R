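# Pipeline drivers tying the modules together: diet, home range, and RSF
# runs from file inputs to file outputs, with reproducible headers.

.pkg_version <- function() {
  as.character(utils::packageVersion("wildcanid"))
}

# Write a data frame as CSV with a reproducibility header.
write_output_csv <- function(df, path, seed, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wildcanid %s seed=%s config=%s", .pkg_version(),
                     format(seed), config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' Either a YAML/JSON file path or a plain list. Recognized fields are
#' documented in the run functions.
#'
#' @param config list or path to a YAML (or JSON) file.
#' @return a named list.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  config
}

#' Run the diet pipeline
#'
#' Reads scats and correction factors, writes the seasonal composition
#' table, niche breadth per season, and (when an availability table is
#' given) ungulate electivity.
#'
#' Config fields: `scats` (CSV path), `cf` (CSV path), `out_dir`,
#' optional `availability` (CSV: species, density_per_km2,
#' adult_female_mass_kg), `trace_threshold` (default 2), `seed` (default 1).
#'
#' @param config list or YAML path (see [load_config()]).
#' @return invisibly, a list of written file paths.
#' @export
run_diet <- function(config) {
  config <- load_config(config)
  seed <- config$seed %||% 1L
  scats <- read_scats_csv(config$scats)
  cf <- read_cf_csv(config$cf)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  comp <- composition_table(scats, cf,
                            trace_threshold = config$trace_threshold %||% 2)
  paths <- list(composition = file.path(config$out_dir, "composition.csv"))
  write_output_csv(comp, paths$composition, seed, config)
  items <- comp[comp$level == "item", , drop = FALSE]
  breadth <- do.call(rbind, lapply(split(items, items$season), function(s) {
    data.frame(season = s$season[1],
               levins_B = levins_B(as_proportions(s$biomass_percent)),
               n_scats = s$n_scats[1], stringsAsFactors = FALSE)
  }))
  paths$niche_breadth <- file.path(config$out_dir, "niche_breadth.csv")
  write_output_csv(breadth, paths$niche_breadth, seed, config)
  if (!is.null(config$availability)) {
    av <- utils::read.csv(config$availability, comment.char = "#",
                          stringsAsFactors = FALSE)
    avail <- available_biomass(
      stats::setNames(av$density_per_km2, av$species),
      stats::setNames(av$adult_female_mass_kg, av$species))
    sel <- ungulate_selection(comp, avail)
    paths$electivity <- file.path(config$out_dir, "electivity.csv")
    write_output_csv(sel, paths$electivity, seed, config)
  }
  invisible(paths)
}

#' Run the home-range pipeline
#'
#' Per animal: bandwidth selection (0.8 h_ref vs ad hoc rule), 95/50% KDE
#' isopleths and 95/50% MCPs, a summary CSV, isopleth GeoJSON, and
#' optionally monthly ranges. Animals with fewer than 5 locations are
#' skipped with a warning.
#'
#' Config fields: `relocations` (CSV path), `out_dir`, optional `monthly`
#' (logical), `grid_n` (default 128), `factor` (default 0.8), `seed`.
#'
#' @param config list or YAML path.
#' @return invisibly, a list with the summary data frame and file paths.
#' @export
run_homerange <- function(config) {
  config <- load_config(config)
  seed <- config$seed %||% 1L
  grid_n <- config$grid_n %||% 128L
  factor <- config$factor %||% 0.8
  relocs <- read_relocations_csv(config$relocations)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); geo <- list()
  for (id in unique(relocs$animal_id)) {
    sub <- relocs[relocs$animal_id == id, , drop = FALSE]
    if (nrow(sub) < 5) {
      warning("skipping animal ", id, ": fewer than 5 locations", call. = FALSE)
      next
    }
    xy <- sub[, c("x", "y")]
    bw <- select_bandwidth(xy, factor = factor, grid_n = grid_n)
    ud <- kde_ud(xy, bw$h_used, grid_n = grid_n)
    iso95 <- isopleth(ud, 0.95); iso50 <- isopleth(ud, 0.50)
    rows[[id]] <- data.frame(
      animal_id = id, n_locations = nrow(sub), h_used = bw$h_used,
      kde95_km2 = iso95$area_km2, kde50_km2 = iso50$area_km2,
      mcp95_km2 = mcp(xy, 0.95)$area_km2, mcp50_km2 = mcp(xy, 0.50)$area_km2,
      stringsAsFactors = FALSE)
    geo[[id]] <- list(iso95 = isopleth_polygons(iso95),
                      iso50 = isopleth_polygons(iso50))
  }
  if (length(rows) == 0) stop("no animal with enough locations", call. = FALSE)
  summary_df <- do.call(rbind, rows)
  row.names(summary_df) <- NULL
  paths <- list(summary = file.path(config$out_dir, "homerange_summary.csv"))
  write_output_csv(summary_df, paths$summary, seed, config)
  feat <- list()
  for (id in names(geo)) {
    for (lv in names(geo[[id]])) {
      for (ring in geo[[id]][[lv]]) {
        feat[[length(feat) + 1L]] <- list(
          type = "Feature",
          properties = list(animal_id = id, isopleth = lv),
          geometry = list(type = "Polygon",
                          coordinates = list(unname(
                            apply(ring, 1, as.list, simplify = FALSE)))))
      }
    }
  }
  paths$polygons <- file.path(config$out_dir, "homerange_polygons.geojson")
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection", features = feat),
                              auto_unbox = TRUE, digits = NA), paths$polygons)
  if (isTRUE(config$monthly)) {
    mr <- monthly_ranges(relocs, factor = factor, grid_n = grid_n)
    paths$monthly <- file.path(config$out_dir, "monthly_ranges.csv")
    write_output_csv(mr, paths$monthly, seed, config)
  }
  invisible(c(list(summary_df = summary_df), paths))
}

#' Run the resource-selection pipeline
#'
#' Builds the used-available design (1:ratio within each animal's 100%
#' MCP), preprocesses covariates, fits the weighted logistic RSF, and runs
#' individual-blocked cross-validation.
#'
#' Config fields: `relocations` (CSV), `landscape` (GeoJSON), `out_dir`,
#' optional `types`, `ratio` (10), `weight` (1000), `collin_threshold`
#' (0.7), `drop_priority`, `method` ("mixed"; "fixed" for the
#' fixed-effects-only model), `cv` (logical, default TRUE), `seed`.
#'
#' @param config list or YAML path.
#' @return invisibly, a list with the model, CV result, and file paths.
#' @export
run_rsf <- function(config) {
  config <- load_config(config)
  seed <- config$seed %||% 1L
  relocs <- read_relocations_csv(config$relocations)
  landscape <- read_landscape_geojson(config$landscape)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  types <- config$types %||% setdiff(feature_types(landscape), "ddf")
  design <- rsf_design(relocs, landscape, types = types,
                       ratio = config$ratio %||% 10,
                       weight_available = config$weight %||% 1000,
                       seed = seed)
  design <- preprocess(design,
                       collin_threshold = config$collin_threshold %||% 0.7,
                       drop_priority = config$drop_priority)
  if (length(attr(design, "covariates")) < 1) {
    stop("collinearity screen left no covariates", call. = FALSE)
  }
  paths <- list(design = file.path(config$out_dir, "design.csv"))
  write_output_csv(as.data.frame(design), paths$design, seed, config)
  model <- fit_rsf(design, method = config$method %||% "mixed")
  paths$coefficients <- file.path(config$out_dir, "coefficients.csv")
  write_output_csv(model$coefficients, paths$coefficients, seed, config)
  cv <- NULL
  if (config$cv %||% TRUE) {
    cv <- blocked_kfold_cv(design)
    cv_df <- rbind(cv$folds,
                   data.frame(animal_id = "pooled", rho = cv$pooled_rho,
                              p = cv$pooled_p, stringsAsFactors = FALSE))
    paths$cv_report <- file.path(config$out_dir, "cv.csv")
    write_output_csv(cv_df, paths$cv_report, seed, config)
  }
  invisible(c(list(model = model, cv = cv), paths))
}
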