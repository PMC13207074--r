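# End-to-end pipeline: scenes -> seasonal composites -> indicators ->
# per-year RSEI -> trend and change-point maps -> report tables.

#' Default pipeline configuration
#'
#' @return Named list of defaults; see [run_pipeline()] for the meaning of
#'   each key.
#' @export
default_config <- function() {
  list(
    mode = "synthetic",            # "synthetic" or "scenes"
    preset = "mmr_like",
    scene_dir = NULL,              # for mode "scenes"
    n_rows = 30L, n_cols = 30L, cell_size_deg = 0.005,
    origin_lon = -36.1, origin_lat = -9.3,
    first_year = 2001L, last_year = 2025L,
    scenes_per_season = 4L,
    composite_statistic = "median",
    season_start_month_day = "09-01", season_end_month_day = "03-31",
    qa_bit_spec = "single",        # "single" (synthetic) or "mod09a1"
    reflectance_scale = NULL,
    cloud_fraction = 0.15, noise_sd = 0.02,
    min_years = 10L,
    z_crit = c(1.645, 1.96, 2.574),
    changepoint_alpha = 0.10,
    write_scenes = FALSE,
    out_dir = "rsei_out",
    seed = 1L,
    log_level = "info")
}

.log <- function(cfg, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a pipeline configuration
#'
#' @param config A named list of overrides, or the path of a YAML file
#'   whose keys match [default_config()].
#' @return The merged, validated configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(default_config(), config)
  if (!cfg$mode %in% c("synthetic", "scenes"))
    stop("mode must be 'synthetic' or 'scenes'")
  if (cfg$mode == "scenes" && is.null(cfg$scene_dir))
    stop("mode 'scenes' requires scene_dir")
  if (cfg$last_year < cfg$first_year) stop("empty year range")
  if (!cfg$composite_statistic %in% c("median", "mean"))
    stop("composite_statistic must be 'median' or 'mean'")
  if (!cfg$qa_bit_spec %in% c("single", "mod09a1"))
    stop("qa_bit_spec must be 'single' or 'mod09a1'")
  cfg
}

# gather the dated observations for one index year from a rendered series
.year_slice <- function(series, y) {
  idx <- which(series$index_year == y)
  if (length(idx) == 0L) stop("no scenes available for index year ", y)
  list(reflectance = series$reflectance[idx], thermal = series$thermal[idx],
       qa = series$qa[idx], qa_thermal = series$qa_thermal[idx])
}

# read a scene directory written by write_scene()/run_pipeline(); expects
# files <date>_reflectance.tif, <date>_thermal.tif, <date>_qa.tif
.read_scene_dir <- function(cfg) {
  rf <- sort(list.files(cfg$scene_dir, "_reflectance\\.tif$",
                        full.names = TRUE))
  if (length(rf) == 0L) stop("no *_reflectance.tif in ", cfg$scene_dir)
  dates <- as.Date(vapply(rf, .date_from_filename, ""))
  pair <- function(d, kind) file.path(cfg$scene_dir,
                                      sprintf("%s_%s.tif", format(d), kind))
  refl <- lapply(rf, read_scene, kind = "reflectance",
                 reflectance_scale = cfg$reflectance_scale)
  therm <- lapply(dates, function(d) read_scene(pair(d, "thermal"), "thermal"))
  qa <- lapply(dates, function(d) {
    r <- read_geotiff(pair(d, "qa"))
    w <- r$values[, , 1L]
    matrix(as.integer(ifelse(is.na(w), NA, w)), nrow(w), ncol(w))
  })
  qa_t <- lapply(seq_along(dates), function(i) {
    if (grids_equal(therm[[i]]$grid, refl[[i]]$grid)) qa[[i]]
    else {
      w <- resample_nearest(qa[[i]], refl[[i]]$grid, therm[[i]]$grid)
      matrix(as.integer(w), nrow(w), ncol(w))
    }
  })
  # index year of a date: months >= Sep belong to the following label
  iy <- as.integer(format(dates, "%Y")) +
    as.integer(as.integer(format(dates, "%m")) >= 9L)
  list(dates = dates, index_year = iy, reflectance = refl, thermal = therm,
       qa = qa, qa_thermal = qa_t, thermal_grid = therm[[1L]]$grid)
}

#' Run the full RSEI pipeline
#'
#' Orchestrates scene generation or loading, quality masking, resampling
#' of thermal scenes to the common analysis grid, Sep-Mar compositing,
#' indicator and per-year RSEI computation, and (for multi-year runs)
#' per-pixel Theil-Sen/Mann-Kendall trend and Pettitt change-point maps.
#' All products are written under `out_dir` and listed in a JSON manifest;
#' the run is deterministic given the seed.
#'
#' @param config See [load_config()]; a list of overrides or a YAML path.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  years <- seq.int(cfg$first_year, cfg$last_year)
  bit_spec <- switch(cfg$qa_bit_spec, single = qa_bits_single(),
                     mod09a1 = qa_bits_mod09a1())

  if (cfg$mode == "synthetic") {
    scn <- make_scenario(preset = cfg$preset, n_rows = cfg$n_rows,
                         n_cols = cfg$n_cols,
                         cell_size_deg = cfg$cell_size_deg,
                         origin_lon = cfg$origin_lon,
                         origin_lat = cfg$origin_lat, years = years,
                         noise_sd = cfg$noise_sd,
                         cloud_fraction = cfg$cloud_fraction,
                         seed = cfg$seed)
    series <- render_series(scn, cfg$scenes_per_season)
    .log(cfg, "info", "rendered ", length(series$dates),
         " synthetic scene dates (preset ", cfg$preset, ")")
    if (cfg$write_scenes) {
      sdir <- file.path(out, "scenes")
      dir.create(sdir, showWarnings = FALSE)
      for (i in seq_along(series$dates)) {
        d <- format(series$dates[i])
        write_scene(series$reflectance[[i]],
                    file.path(sdir, paste0(d, "_reflectance.tif")))
        write_scene(series$thermal[[i]],
                    file.path(sdir, paste0(d, "_thermal.tif")))
        write_geotiff(series$qa[[i]], scn$grid,
                      file.path(sdir, paste0(d, "_qa.tif")), "uint8",
                      nodata = 255,
                      description = list(acq_date = d, kind = "qa_words"))
      }
    }
  } else {
    series <- .read_scene_dir(cfg)
    .log(cfg, "info", "read ", length(series$dates), " scene dates from ",
         cfg$scene_dir)
  }
  grid <- series$reflectance[[1L]]$grid

  cube <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, length(years)))
  stats_rows <- list(); pca_rows <- list(); area_rows <- list()
  year_files <- list()
  for (k in seq_along(years)) {
    y <- years[k]
    sl <- .year_slice(series, y)
    refl <- lapply(seq_along(sl$reflectance), function(i)
      apply_quality_mask(sl$reflectance[[i]], sl$qa[[i]], bit_spec))
    therm <- lapply(seq_along(sl$thermal), function(i) {
      s <- apply_quality_mask(sl$thermal[[i]], sl$qa_thermal[[i]], bit_spec)
      if (grids_equal(s$grid, grid)) s else resample_scene(s, grid)
    })
    comp <- seasonal_composite(refl, therm, y,
                               statistic = cfg$composite_statistic,
                               season_start = cfg$season_start_month_day,
                               season_end = cfg$season_end_month_day)
    stack <- indicator_stack(comp)
    layer <- compute_rsei(stack)
    cube[, , k] <- layer$rsein

    fy <- list()
    for (nm in c("dryness", "greenness", "heat", "wetness")) {
      fy[[nm]] <- file.path(out, sprintf("%d_%s.tif", y, nm))
      write_geotiff(stack[[nm]], grid, fy[[nm]], "float32")
    }
    fy$rsein <- file.path(out, sprintf("%d_rsein.tif", y))
    write_geotiff(layer$rsein, grid, fy$rsein, "float32")
    fy$class <- file.path(out, sprintf("%d_class.tif", y))
    cls <- layer$class_raster
    write_geotiff(ifelse(is.na(cls), 255L, cls), grid, fy$class, "uint8",
                  nodata = 255)
    year_files[[as.character(y)]] <- fy

    stats_rows[[k]] <- annual_stats(layer$rsein, y)
    pca_rows[[k]] <- data.frame(
      year = y, t(stats::setNames(layer$pca$loadings,
                                  paste0("load_", names(layer$pca$loadings)))),
      t(stats::setNames(layer$pca$explained_fraction, paste0("ev", 1:4))),
      flipped = layer$pca$flipped)
    tab <- tabulate(cls[!is.na(cls)], 5L)
    area_rows[[k]] <- data.frame(
      year = y, class = rsei_class_labels, cells = tab,
      percent = if (sum(tab)) 100 * tab / sum(tab) else rep(0, 5L))
    .log(cfg, "debug", "year ", y, " done (",
         sum(layer$valid_mask), " valid cells)")
  }

  tables <- list(
    annual_stats = file.path(out, "annual_stats.csv"),
    pca = file.path(out, "pca_explained_variance.csv"),
    class_areas = file.path(out, "class_areas.csv"))
  utils::write.csv(do.call(rbind, stats_rows), tables$annual_stats,
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, pca_rows), tables$pca, row.names = FALSE)
  utils::write.csv(do.call(rbind, area_rows), tables$class_areas,
                   row.names = FALSE)

  trend_files <- NULL; cp_files <- NULL
  if (length(years) < 2L) {
    warning("single-year run: trend and change-point stages skipped")
    .log(cfg, "warn", "single-year run: trend/change-point stages skipped")
  } else {
    min_years <- min(cfg$min_years, length(years))
    trend <- trend_map(cube, years, min_years = min_years,
                       z_crit = cfg$z_crit)
    trend_files <- list(beta = file.path(out, "trend_beta.tif"),
                        s = file.path(out, "trend_s.tif"),
                        z = file.path(out, "trend_z.tif"),
                        sig = file.path(out, "trend_sig.tif"),
                        areas = file.path(out, "trend_class_areas.csv"))
    write_geotiff(trend$beta, grid, trend_files$beta, "float32")
    write_geotiff(trend$s, grid, trend_files$s, "float32")
    write_geotiff(trend$z, grid, trend_files$z, "float32")
    write_geotiff(ifelse(is.na(trend$sig_code), 255L, trend$sig_code + 3L),
                  grid, trend_files$sig, "uint8", nodata = 255)
    utils::write.csv(trend_class_areas(trend), trend_files$areas,
                     row.names = FALSE)

    cp <- changepoint_map(cube, years, min_years = min_years,
                          alpha = cfg$changepoint_alpha)
    cp_files <- list(k = file.path(out, "pettitt_k.tif"),
                     p = file.path(out, "pettitt_p.tif"),
                     tau = file.path(out, "pettitt_tau.tif"),
                     histogram = file.path(out, "change_year_histogram.csv"))
    write_geotiff(cp$k_stat, grid, cp_files$k, "float32")
    write_geotiff(cp$p_approx, grid, cp_files$p, "float32")
    write_geotiff(ifelse(is.na(cp$tau_year_sig), -1L, cp$tau_year_sig),
                  grid, cp_files$tau, "int32", nodata = -1)
    utils::write.csv(changepoint_histogram(cp), cp_files$histogram,
                     row.names = FALSE)
  }

  manifest <- list(
    package = "rseimap",
    config = cfg[setdiff(names(cfg), "z_crit")],
    z_crit = cfg$z_crit,
    years = years,
    grid = grid[c("n_rows", "n_cols", "cell_size_deg", "origin_lon",
                  "origin_lat", "crs_id")],
    products = list(per_year = year_files, tables = tables,
                    trend = trend_files, changepoint = cp_files))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  manifest$path <- file.path(out, "manifest.json")
  .log(cfg, "info", "pipeline complete; manifest at ", manifest$path)
  invisible(manifest)
}

#' Summarize a pipeline run into a plain-text report
#'
#' Reads the manifest's tables and emits the headline quantities: minimum
#' and maximum annual mean RSEI with their years, PC1 explained-variance
#' range, average ecological class shares, trend-class areas and the modal
#' significant change year.  A pure function of the manifest: regenerating
#' the report yields identical bytes.
#'
#' @param manifest A manifest list from [run_pipeline()] or the path of a
#'   `manifest.json`.
#' @param path Output text file; default `report.txt` beside the manifest
#'   tables.
#' @return The report lines (character vector), invisibly; also written to
#'   `path`.
#' @export
summarize_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    mdir <- dirname(manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  } else mdir <- dirname(manifest$products$tables$annual_stats)
  tb <- manifest$products$tables
  if (is.null(tb)) stop("manifest has no tables")
  if (is.null(path)) path <- file.path(mdir, "report.txt")
  st <- utils::read.csv(tb$annual_stats)
  pca <- utils::read.csv(tb$pca)
  areas <- utils::read.csv(tb$class_areas)

  fmt <- function(x) formatC(x, format = "f", digits = 3)
  lines <- c(
    "RSEI run summary",
    "================",
    sprintf("Years analyzed: %d-%d (%d annual composites)",
            min(st$year), max(st$year), nrow(st)),
    sprintf("Annual mean RSEI: min %s in %d, max %s in %d",
            fmt(min(st$mean)), st$year[which.min(st$mean)],
            fmt(max(st$mean)), st$year[which.max(st$mean)]),
    sprintf("PC1 explained variance: %s%% to %s%%",
            fmt(100 * min(pca$ev1)), fmt(100 * max(pca$ev1))),
    "Average class shares (% of valid cells):")
  cls_mean <- vapply(rsei_class_labels, function(cl)
    mean(areas$percent[areas$class == cl]), 0)
  lines <- c(lines, sprintf("  %-9s %s%%", rsei_class_labels,
                            fmt(cls_mean)))
  if (!is.null(manifest$products$trend)) {
    tr <- utils::read.csv(manifest$products$trend$areas)
    lines <- c(lines, "Trend classes (% of analyzable cells):",
               sprintf("  %-6s %s%%", tr$class, fmt(tr$percent)))
  }
  if (!is.null(manifest$products$changepoint)) {
    h <- utils::read.csv(manifest$products$changepoint$histogram)
    if (sum(h$cells) > 0) {
      modal <- h$year[which.max(h$cells)]
      lines <- c(lines, sprintf(
        "Significant change points: %d cells, modal change year %d",
        sum(h$cells), modal))
    } else {
      lines <- c(lines, "Significant change points: none")
    }
  }
  writeLines(lines, path)
  invisible(lines)
}
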