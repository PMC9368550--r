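# Driver-table assembly, random-forest attribution of ECA evolution, percent
# Gini-importance contributions P(r) and geometric-interval grading.

driver_predictors <- paste0("x", 1:12)

#' Assemble the unit-level driver table
#'
#' One row per analysis unit and period pair. Predictors follow the standard
#' twelve-variable layout: x1 mean DEM (m), x2 mean slope (deg), x3 mean
#' temperature (deg C), x4 total precipitation (mm), x5-x7 forest/grassland/
#' cropland area shares, x8 mean GDP, x9 population density, x10 mean
#' nightlight, x11/x12 mean Euclidean distance (km) from impervious and
#' cropland cells, computed here by distance transform. Each row is labelled
#' with the unit's dominant evolution mode and its dominant specific type per
#' mode; ties break toward degradation, then lexicographically. Units with no
#' changed cells get NA responses (they are dropped when fitting).
#'
#' @param drivers named list of driver rasters from [generate_drivers()] (or
#'   equivalent: dem, slope, temperature, precipitation, gdp, population,
#'   nightlight).
#' @param landcover categorical land-cover raster.
#' @param zones integer unit raster.
#' @param evolutions named list of `eca_evolution` objects, one per period
#'   pair (names are the pair labels).
#' @param cell_size cell side length in km.
#' @return tibble: unit, pair, x1..x12, mode, expansion_type,
#'   degradation_type.
#' @export
assemble_driver_table <- function(drivers, landcover, zones, evolutions,
                                  cell_size = 1) {
  check_same_grid(landcover, zones, c("landcover", "zones"))
  for (nm in names(drivers)) {
    check_same_grid(landcover, drivers[[nm]], c("landcover", nm))
  }
  imp <- landcover == eca_classes[["impervious"]]
  crop <- landcover == eca_classes[["cropland"]]
  d_imp <- distance_to(imp, cell_size)
  d_crop <- distance_to(crop, cell_size)
  units <- sort(unique(zones[!is.na(zones)]))
  pred <- purrr::map_dfr(units, function(u) {
    in_u <- !is.na(zones) & zones == u
    n <- sum(in_u)
    tibble(
      unit = u,
      x1 = mean(drivers$dem[in_u]), x2 = mean(drivers$slope[in_u]),
      x3 = mean(drivers$temperature[in_u]),
      x4 = sum(drivers$precipitation[in_u]),
      x5 = sum(landcover[in_u] == eca_classes[["forest"]]) / n,
      x6 = sum(landcover[in_u] == eca_classes[["grassland"]]) / n,
      x7 = sum(landcover[in_u] == eca_classes[["cropland"]]) / n,
      x8 = mean(drivers$gdp[in_u]),
      x9 = sum(drivers$population[in_u]) / (n * cell_size^2),
      x10 = mean(drivers$nightlight[in_u]),
      x11 = mean(d_imp[in_u]), x12 = mean(d_crop[in_u])
    )
  })
  rows <- purrr::map_dfr(names(evolutions), function(pair) {
    ev <- evolutions[[pair]]
    labs <- attr(ev, "labels")
    tab <- as_tibble(ev)
    resp <- purrr::map_dfr(units, function(u) {
      in_u <- !is.na(zones) & zones == u
      counts <- c(expansion = 0, degradation = 0)
      type_counts <- list(expansion = integer(0), degradation = integer(0))
      for (mode in names(labs)) {
        ids <- labs[[mode]][in_u]
        ids <- ids[ids > 0L]
        counts[mode] <- length(ids)
        if (length(ids)) {
          types <- tab$type[tab$mode == mode][match(ids, tab$patch[tab$mode == mode])]
          type_counts[[mode]] <- sort(table(types), decreasing = TRUE)
        }
      }
      dominant_type <- function(tc) {
        if (!length(tc)) return(NA_character_)
        best <- tc[tc == max(tc)]
        sort(names(best))[1]
      }
      tibble(
        unit = u, pair = pair,
        mode = if (sum(counts) == 0) NA_character_ else
          if (counts["degradation"] >= counts["expansion"]) "degradation" else "expansion",
        expansion_type = dominant_type(type_counts$expansion),
        degradation_type = dominant_type(type_counts$degradation)
      )
    })
    dplyr::left_join(resp, pred, by = "unit")
  })
  dplyr::relocate(rows, "unit", "pair", dplyr::all_of(driver_predictors))
}

#' Fit a random-forest classifier of ECA evolution
#'
#' Ensemble of CART trees grown on bootstrap samples with the Gini impurity
#' `Gini(t) = 1 - sum_q p(q|t)^2` as split criterion; accuracy is the
#' out-of-bag percent correct. Reproducible for a fixed seed.
#'
#' @param table tibble from [assemble_driver_table()] (or any data frame with
#'   the predictor columns and the response).
#' @param response name of the response column: `"mode"`, `"expansion_type"`
#'   or `"degradation_type"`.
#' @param n_trees number of trees.
#' @param seed integer RNG seed.
#' @param predictors character vector of predictor column names.
#' @return object of class `eca_forest`: list with `fit` (randomForest),
#'   `accuracy` (OOB percent correct), `response`, `n`, `n_trees`, `seed`.
#' @export
fit_forest <- function(table, response = "mode", n_trees = 500, seed = 1,
                       predictors = driver_predictors) {
  stopifnot(response %in% names(table), all(predictors %in% names(table)))
  dat <- table[stats::complete.cases(table[c(predictors, response)]), ]
  y <- factor(dat[[response]])
  if (nlevels(y) < 2) abort(sprintf("response '%s' has a single class", response))
  if (nrow(dat) < 20) abort("need at least 20 complete rows to fit")
  x <- as.data.frame(dat[predictors])
  fit <- withr::with_seed(substream_seed(seed, paste0("forest_", response)), {
    randomForest::randomForest(x, y, ntree = n_trees,
                               mtry = max(1L, floor(sqrt(length(predictors)))),
                               importance = FALSE)
  })
  acc <- 100 * mean(fit$predicted == y, na.rm = TRUE)
  structure(list(fit = fit, accuracy = acc, response = response,
                 n = nrow(dat), n_trees = n_trees, seed = seed),
            class = "eca_forest")
}

#' @export
print.eca_forest <- function(x, ...) {
  cat(sprintf("<eca_forest> response '%s': %d rows, %d trees, OOB accuracy %.2f%%\n",
              x$response, x$n, x$n_trees, x$accuracy))
  invisible(x)
}

#' Percent Gini-importance contributions
#'
#' The total Gini impurity decrease attributable to each predictor across all
#' tree nodes, normalised so contributions sum to 100:
#' `P(r) = sum_trees sum_nodes dGini_r / sum_r' (same) x 100`.
#'
#' @param forest an `eca_forest` object (or a fitted randomForest).
#' @return tibble: variable, p_pct (descending), summing to 100.
#' @export
gini_importance <- function(forest) {
  fit <- if (inherits(forest, "eca_forest")) forest$fit else forest
  imp <- fit$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  if (total <= 0) abort("model has no Gini decrease; was it fitted?")
  tibble(variable = names(imp), p_pct = unname(100 * imp / total)) |>
    dplyr::arrange(dplyr::desc(.data$p_pct))
}

#' Six-grade break preset on the percent-importance scale
#'
#' Upper break points of grades I..VI as used in the original ECA grading
#' scheme this package reimplements.
#' @export
grade_breaks_preset <- c(0, 0.5037, 1.5381, 3.7400, 8.4272, 18.4052, 39.6460)

#' Geometric-interval grading of importances
#'
#' Assigns each percent contribution a grade I..`n_classes` (low to high).
#' With `breaks = NULL` the break points are computed so the class widths
#' form a geometric progression spanning `[min, max]`, with the common ratio
#' chosen (over a grid including its inverse) to balance the class counts.
#' Fixed user-supplied breaks (e.g. [grade_breaks_preset]) are honoured for
#' replication; values above the top break clamp to the top grade.
#'
#' @param importances numeric vector of non-negative percent contributions.
#' @param n_classes number of grades (>= 2).
#' @param breaks optional numeric vector of `n_classes + 1` ascending break
#'   points.
#' @return tibble: variable index or names, p_pct, grade (ordered factor
#'   I..n); attribute `breaks` carries the break points used.
#' @export
geometric_interval_grades <- function(importances, n_classes = 6, breaks = NULL) {
  stopifnot(n_classes >= 2)
  x <- as.numeric(importances)
  if (any(x < 0)) abort("importances must be non-negative")
  nm <- names(importances) %||% as.character(seq_along(x))
  if (is.null(breaks)) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warn("all importances equal; single grade")
      breaks <- c(lo, rep(hi, n_classes))
    } else {
      ratios <- sort(unique(c(seq(1.1, 6, by = 0.1), 1 / seq(1.1, 6, by = 0.1), 1)))
      best <- NULL; best_obj <- Inf
      for (g in ratios) {
        widths <- if (g == 1) rep(1, n_classes) else g^(seq_len(n_classes) - 1)
        b <- lo + (hi - lo) * cumsum(c(0, widths)) / sum(widths)
        cnt <- tabulate(pmin(pmax(findInterval(x, b, left.open = TRUE), 1L),
                             n_classes), n_classes)
        obj <- stats::var(cnt) + 1e-9 * abs(log(g))
        if (obj < best_obj) { best_obj <- obj; best <- b }
      }
      breaks <- best
    }
  } else {
    if (length(breaks) != n_classes + 1 || is.unsorted(breaks)) {
      abort(sprintf("breaks must be %d ascending values", n_classes + 1))
    }
  }
  grade_idx <- pmin(pmax(findInterval(x, breaks, left.open = TRUE), 1L), n_classes)
  lev <- as.character(utils::as.roman(seq_len(n_classes)))
  out <- tibble(
    variable = nm, p_pct = x,
    grade = factor(lev[grade_idx], levels = lev, ordered = TRUE)
  )
  attr(out, "breaks") <- breaks
  out
}
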