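# Plain-text raster I/O (ESRI ASCII grid) and the orchestrating pipeline.
#
# Coordinate convention: matrices are row-major with origin at the top-left
# corner; matrix row 1 is the northernmost raster row.

#' Write a raster to an ESRI ASCII grid file
#'
#' Integer-valued rasters round-trip bit-exactly; doubles are written at full
#' precision. NA cells are written as the nodata value.
#'
#' @param raster numeric/integer/logical matrix.
#' @param path output file path (.asc).
#' @param cell_size cell side length (written as `cellsize`).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata nodata sentinel.
#' @return invisibly `path`.
#' @export
write_raster <- function(raster, path, cell_size = 1, xll = 0, yll = 0,
                         nodata = -9999) {
  stopifnot(is.matrix(raster))
  m <- raster
  if (is.logical(m)) m <- m + 0L
  storage <- if (is.integer(m) || all(is.na(m) | m == round(m))) "integer" else "double"
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cell_size), sprintf("NODATA_value %.10g", nodata)
  )
  fmt <- if (storage == "integer") "%d" else "%.17g"
  body <- apply(m, 1, function(r) {
    paste(sprintf(fmt, if (storage == "integer") as.integer(r) else r),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path file path.
#' @return numeric (or integer) matrix with attributes `cell_size`, `xll`,
#'   `yll`; nodata cells become NA.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  vals <- scan(text = paste(lines[(i + 1L):length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    abort(sprintf("'%s': expected %d values, found %d", path, nr * nc, length(vals)))
  }
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (all(is.na(m) | m == round(m))) storage.mode(m) <- "integer"
  attr(m, "cell_size") <- hdr$cellsize %||% 1
  attr(m, "xll") <- hdr$xllcorner %||% 0
  attr(m, "yll") <- hdr$yllcorner %||% 0
  m
}

#' Run the full ECA pipeline on a synthetic scenario
#'
#' Chains the framework stages: generate (or accept) a scenario, compute
#' per-unit structure metrics and LESSI per period, the criticality surface
#' and ECA mask per period, evolution patches and types per consecutive
#' period pair, the driver table and random-forest attribution, and a
#' machine-readable report.
#'
#' @param config an [scenario_config()] object, or an existing
#'   `eca_scenario`.
#' @param n_bins,smooth_window threshold-extraction parameters.
#' @param buffer_radius LEI buffer radius, km.
#' @param n_trees random-forest size.
#' @param connectivity patch connectivity for structure metrics.
#' @return object of class `eca_report`: nested list with sections `meta`,
#'   `periods` (per-period threshold, ECA count and share), `changes`
#'   (per-pair counts, proportions, percent change, type summaries, LEI
#'   distribution), `drivers` (per-response accuracy, importance, grades),
#'   plus the intermediate objects in `objects`.
#' @export
run_pipeline <- function(config, n_bins = 100, smooth_window = 5,
                         buffer_radius = 1, n_trees = 500, connectivity = 8) {
  scen <- if (inherits(config, "eca_scenario")) config else generate_timeseries(config)
  cfg <- scen$config
  cs <- cfg$cell_size

  metrics <- compute_metrics(scen$landcover, scen$zones, connectivity, cs)
  lt <- lessi(metrics)
  lsurf <- lessi_surface(lt, scen$zones)

  crit <- lapply(cfg$periods, function(p) {
    criticality_surface(scen$services[[p]], lsurf, n_bins, smooth_window, p)
  })
  names(crit) <- cfg$periods

  pairs <- if (length(cfg$periods) > 1) {
    paste(cfg$periods[-length(cfg$periods)], cfg$periods[-1], sep = "-")
  } else character(0)
  evolutions <- list()
  for (i in seq_along(pairs)) {
    evolutions[[pairs[i]]] <- classify_evolution(
      crit[[i]]$mask, crit[[i + 1]]$mask, buffer_radius, cs
    )
  }

  period_section <- lapply(cfg$periods, function(p) {
    list(period = p, threshold = crit[[p]]$threshold$threshold,
         n_eca = attr(crit[[p]]$mask, "n_eca"),
         share_pct = 100 * attr(crit[[p]]$mask, "share"))
  })
  names(period_section) <- cfg$periods

  change_section <- lapply(pairs, function(pr) {
    s <- summarize_evolution(evolutions[[pr]])
    i <- match(pr, pairs)
    list(
      pair = pr,
      modes = as.data.frame(s$modes), types = as.data.frame(s$types),
      eca_percent_change = percent_change(
        attr(crit[[i]]$mask, "n_eca") + 0, attr(crit[[i + 1]]$mask, "n_eca")),
      lei_summary = as.data.frame(
        as_tibble(evolutions[[pr]]) |>
          dplyr::group_by(.data$mode) |>
          dplyr::summarise(min = min(.data$lei), median = stats::median(.data$lei),
                           max = max(.data$lei), .groups = "drop"))
    )
  })
  names(change_section) <- pairs

  driver_section <- list()
  forests <- list()
  if (length(evolutions)) {
    tbl <- assemble_driver_table(scen$drivers, scen$landcover, scen$zones,
                                 evolutions, cs)
    for (resp in c("mode", "expansion_type", "degradation_type")) {
      sec <- tryCatch({
        f <- fit_forest(tbl, resp, n_trees = n_trees, seed = cfg$seed)
        imp <- gini_importance(f)
        gr <- geometric_interval_grades(stats::setNames(imp$p_pct, imp$variable))
        forests[[resp]] <- f
        list(response = resp, accuracy_pct = f$accuracy, n_rows = f$n,
             importance = as.data.frame(dplyr::mutate(imp, grade = as.character(gr$grade))))
      }, error = function(e) list(response = resp, skipped = conditionMessage(e)))
      driver_section[[resp]] <- sec
    }
  } else {
    tbl <- NULL
  }

  structure(list(
    meta = list(
      seed = cfg$seed, shape = cfg$shape, cell_size = cs,
      n_zones = cfg$n_zones, periods = cfg$periods,
      n_bins = n_bins, smooth_window = smooth_window,
      buffer_radius = buffer_radius, n_trees = n_trees,
      connectivity = connectivity,
      coordinates = "row-major, origin top-left, cell (row, col), 1-based"
    ),
    periods = period_section,
    changes = change_section,
    drivers = driver_section,
    objects = list(scenario = scen, metrics = metrics, lessi = lt,
                   criticality = crit, evolutions = evolutions,
                   driver_table = tbl, forests = forests)
  ), class = "eca_report")
}

#' @export
print.eca_report <- function(x, ...) {
  cat(sprintf("<eca_report> seed %d, %d periods, %d period pairs\n",
              x$meta$seed, length(x$periods), length(x$changes)))
  for (p in x$periods) {
    cat(sprintf("  %s: T = %.4f, ECA %d cells (%.1f%%)\n",
                p$period, p$threshold, p$n_eca, p$share_pct))
  }
  for (ch in x$changes) {
    m <- ch$modes
    cat(sprintf("  %s: %s\n", ch$pair,
                paste(sprintf("%s %d (%.2f%%)", m$mode, m$n_cells, m$prop_count),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write the pipeline report as JSON
#'
#' Serialises every section except the raw raster objects. Reruns with the
#' same config and seed produce byte-identical files.
#'
#' @param report an `eca_report` object.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_report <- function(report, path) {
  out <- report[c("meta", "periods", "changes", "drivers")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
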