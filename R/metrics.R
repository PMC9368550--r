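# Class-level landscape structure metrics and the landscape ecological
# structure security index (LESSI).
#
# Conventions (FRAGSTATS-style, on a square grid):
#   patch        maximal connected same-class cell set (8-connectivity default)
#   area a       n_cells * cell_size^2                                   [km^2]
#   perimeter p  exposed cell edges * cell_size; edges on the unit or raster
#                border count toward p (a unit-filling square has AWMSI = 1)
#   PD           patches per km^2 of unit area
#   ED           interior between-class edge length per km^2; border edges do
#                NOT count toward ED, and the unit/landscape total is the sum
#                over classes (shared edges counted once per adjoining class)
#   AWMSI        sum_j (0.25 p_j / sqrt(a_j)) * (a_j / sum a)
#   F            sum_j (2 ln(0.25 p_j) / ln a_j) * (a_j / sum a); a patch of a
#                single 1-km^2 cell contributes the minimum dimension 1
#   D            1 - sum_j (a_j / A)^2  with A the unit area

# per-cell counts of exposed edges (4-neighbourhood), split into all exposed
# edges (for p) and interior cross-class edges (for ED)
edge_counts <- function(cls) {
  nr <- nrow(cls); nc <- ncol(cls)
  pad <- matrix(NA, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- cls
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  exposed <- matrix(0L, nr, nc)
  interior <- matrix(0L, nr, nc)
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- pad[2:(nr + 1L) + off[1], 2:(nc + 1L) + off[2], drop = FALSE]
    diff <- is.na(nb) | nb != ctr
    exposed <- exposed + (diff & !is.na(ctr))
    interior <- interior + (!is.na(nb) & !is.na(ctr) & nb != ctr)
  }
  list(exposed = exposed, interior = interior)
}

# patch table for one (possibly NA-clipped) categorical raster
patch_table <- function(lc, connectivity = 8, cell_size = 1) {
  ec <- edge_counts(lc)
  classes <- sort(unique(lc[!is.na(lc)]))
  out <- vector("list", length(classes))
  labels <- matrix(0L, nrow(lc), ncol(lc))
  next_id <- 0L
  for (i in seq_along(classes)) {
    k <- classes[i]
    lab <- label_components(!is.na(lc) & lc == k, connectivity)
    n <- max(lab)
    if (n == 0L) next
    cells <- which(lab > 0L)
    a <- tabulate(lab[cells], n) * cell_size^2
    p <- as.vector(tapply(ec$exposed[cells], lab[cells], sum)) * cell_size
    e <- as.vector(tapply(ec$interior[cells], lab[cells], sum)) * cell_size
    labels[cells] <- lab[cells] + next_id
    out[[i]] <- tibble(
      patch = next_id + seq_len(n), class = k,
      n_cells = as.integer(a / cell_size^2), area = a, perimeter = p,
      interior_edge = e
    )
    next_id <- next_id + n
  }
  list(patches = dplyr::bind_rows(out), labels = labels)
}

#' Delineate land-cover patches
#'
#' Maximal connected same-class cell sets; every non-NA cell belongs to
#' exactly one patch.
#'
#' @param landcover categorical integer raster (NA = nodata).
#' @param connectivity 4 or 8 (FRAGSTATS convention; default 8).
#' @param cell_size cell side length in km.
#' @return list with `patches` (tibble: patch, class, n_cells, area km^2,
#'   perimeter km of exposed edges, interior_edge km of between-class edges)
#'   and `labels` (integer raster of patch ids).
#' @export
delineate_patches <- function(landcover, connectivity = 8, cell_size = 1) {
  stopifnot(is.matrix(landcover))
  if (!any(!is.na(landcover))) abort("empty raster: no non-missing cells")
  patch_table(landcover, connectivity, cell_size)
}

# area-weighted shape aggregates for a set of patches sharing a weight base
shape_aggregates <- function(a, p, total_a) {
  w <- a / total_a
  msi <- 0.25 * p / sqrt(a)
  fd <- ifelse(abs(log(a)) < 1e-12, 1, 2 * log(0.25 * p) / log(a))
  list(awmsi = sum(msi * w), frac_dim = sum(fd * w))
}

#' Per-unit class-level landscape metrics
#'
#' Computes PD, ED, AWMSI, fractal dimension and division for every analysis
#' unit, per class and for the whole unit mosaic (`class = "landscape"`).
#' Patches are clipped to the unit boundary before measurement, so units are
#' independent of one another.
#'
#' @inheritParams delineate_patches
#' @param zones integer raster of unit ids covering the grid.
#' @return tibble with columns unit, class ("landscape" or a class code as
#'   character), n_patches, n_cells, area, pd, ed, awmsi, frac_dim, division,
#'   missing. A unit with no valid cell yields one row flagged
#'   `missing = TRUE`.
#' @export
compute_metrics <- function(landcover, zones, connectivity = 8, cell_size = 1) {
  check_same_grid(landcover, zones, c("landcover", "zones"))
  units <- sort(unique(zones[!is.na(zones)]))
  rows <- vector("list", length(units))
  for (i in seq_along(units)) {
    u <- units[i]
    lc_u <- landcover
    lc_u[is.na(zones) | zones != u] <- NA
    rows[[i]] <- unit_metric_rows(lc_u, u, connectivity, cell_size)
  }
  dplyr::bind_rows(rows)
}

unit_metric_rows <- function(lc_u, unit, connectivity, cell_size) {
  n_valid <- sum(!is.na(lc_u))
  if (n_valid == 0L) {
    return(tibble(unit = unit, class = "landscape", n_patches = NA_integer_,
                  n_cells = NA_integer_, area = NA_real_, pd = NA_real_,
                  ed = NA_real_, awmsi = NA_real_, frac_dim = NA_real_,
                  division = NA_real_, missing = TRUE))
  }
  A <- n_valid * cell_size^2
  pt <- patch_table(lc_u, connectivity, cell_size)$patches
  per_class <- pt |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_patches = dplyr::n(), n_cells = sum(.data$n_cells),
      pd = dplyr::n() / A, ed = sum(.data$interior_edge) / A,
      awmsi = shape_aggregates(.data$area, .data$perimeter, sum(.data$area))$awmsi,
      frac_dim = shape_aggregates(.data$area, .data$perimeter, sum(.data$area))$frac_dim,
      division = 1 - sum((.data$area / A)^2),
      area = sum(.data$area),
      .groups = "drop"
    ) |>
    dplyr::mutate(unit = unit, class = as.character(.data$class), missing = FALSE)
  agg <- shape_aggregates(pt$area, pt$perimeter, A)
  landscape <- tibble(
    unit = unit, class = "landscape", n_patches = nrow(pt),
    n_cells = n_valid, area = A,
    pd = nrow(pt) / A, ed = sum(per_class$ed),
    awmsi = agg$awmsi, frac_dim = agg$frac_dim,
    division = 1 - sum((pt$area / A)^2), missing = FALSE
  )
  dplyr::bind_rows(landscape, per_class[names(landscape)])
}

#' Landscape fragmentation composite V
#'
#' Weighted sum of rescaled shape-complexity components:
#' `V = 0.5 AWMSI' + 0.3 F' + 0.2 D'`. Inputs are expected on the unit
#' interval (see [lessi()], which rescales across units before calling this).
#'
#' @param awmsi,frac_dim,division numeric vectors rescaled to `[0, 1]`.
#' @param weights numeric(3) summing to 1.
#' @return numeric vector V in `[0, 1]`.
#' @export
fragmentation_v <- function(awmsi, frac_dim, division,
                            weights = c(0.5, 0.3, 0.2)) {
  if (!isTRUE(all.equal(sum(weights), 1))) abort("weights must sum to 1")
  weights[1] * awmsi + weights[2] * frac_dim + weights[3] * division
}

#' Landscape ecological structure security index per unit
#'
#' `LESSI = 1 - [(PD + ED) * 2.5 V]` computed on rescaled components. PD, ED,
#' AWMSI, F and D are min-max rescaled across units within the period; the
#' bracket `(PD' + ED') * 2.5 V` is then normalised so the index lies in
#' `[0, 1]`: either by its cross-unit maximum (default) or by its theoretical
#' maximum 5.
#'
#' @param metrics tibble from [compute_metrics()] (the `landscape` rows are
#'   used).
#' @param weights weights of AWMSI, F, D in the fragmentation composite.
#' @param rescale `"cross_unit_max"` or `"theoretical"`.
#' @return tibble: unit, v, bracket, lessi (in `[0, 1]`).
#' @export
lessi <- function(metrics, weights = c(0.5, 0.3, 0.2),
                  rescale = c("cross_unit_max", "theoretical")) {
  rescale <- match.arg(rescale)
  m <- metrics |>
    dplyr::filter(.data$class == "landscape", !.data$missing)
  if (nrow(m) == 0L) abort("no valid units in metrics")
  v <- fragmentation_v(minmax_units(m$awmsi), minmax_units(m$frac_dim),
                       minmax_units(m$division), weights)
  bracket <- (minmax_units(m$pd) + minmax_units(m$ed)) * 2.5 * v
  denom <- if (rescale == "cross_unit_max") max(bracket) else 5
  scaled <- if (denom > 0) bracket / denom else bracket * 0
  tibble(unit = m$unit, v = v, bracket = bracket,
         lessi = pmin(1, pmax(0, 1 - scaled)))
}

#' Broadcast per-unit LESSI to a raster
#'
#' @param lessi_tbl tibble from [lessi()].
#' @param zones integer unit raster.
#' @return numeric raster of LESSI values (NA where the unit is absent).
#' @export
lessi_surface <- function(lessi_tbl, zones) {
  vals <- lessi_tbl$lessi[match(zones, lessi_tbl$unit)]
  matrix(vals, nrow(zones), ncol(zones))
}

#' Moving-window LESSI
#'
#' Alternative to the per-unit index: the structure metrics are measured in a
#' square window centred on each cell and the rescaling runs across cells.
#' Quadratic in window size per cell; intended for small rasters.
#'
#' @inheritParams delineate_patches
#' @param window odd window side length in cells.
#' @param weights weights of AWMSI, F, D.
#' @return numeric raster of LESSI values.
#' @export
lessi_window <- function(landcover, window = 11, weights = c(0.5, 0.3, 0.2),
                         connectivity = 8, cell_size = 1) {
  stopifnot(window %% 2 == 1, window >= 3)
  nr <- nrow(landcover); nc <- ncol(landcover)
  h <- (window - 1L) / 2L
  comp <- matrix(NA_real_, nr * nc, 5)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      sub <- landcover[max(1L, r - h):min(nr, r + h),
                       max(1L, c - h):min(nc, c + h), drop = FALSE]
      row <- unit_metric_rows(sub, 1L, connectivity, cell_size)[1, ]
      comp[(c - 1L) * nr + r, ] <- c(row$pd, row$ed, row$awmsi,
                                     row$frac_dim, row$division)
    }
  }
  v <- fragmentation_v(minmax_units(comp[, 3]), minmax_units(comp[, 4]),
                       minmax_units(comp[, 5]), weights)
  bracket <- (minmax_units(comp[, 1]) + minmax_units(comp[, 2])) * 2.5 * v
  denom <- max(bracket, na.rm = TRUE)
  scaled <- if (isTRUE(denom > 0)) bracket / denom else bracket * 0
  matrix(pmin(1, pmax(0, 1 - scaled)), nr, nc)
}
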