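# Two-date ECA change detection, buffer-overlap patch building, the landscape
# expansion index LEI = 100 * A0 / (AE - AP), and the six evolution types.
#
# Buffer geometry on the raster: a cell belongs to a buffer iff its centre
# lies within buffer_radius of the centre of some patch cell. With 1-km cells
# and the 1-km default radius this is the 4-neighbour cross of each cell.

#' Difference two ECA masks
#'
#' @param eca_t1,eca_t2 co-registered logical masks (earlier, later date).
#' @return list of three disjoint logical rasters: `expansion`
#'   (non-ECA -> ECA), `degradation` (ECA -> non-ECA), `retained`.
#' @export
diff_masks <- function(eca_t1, eca_t2) {
  check_same_grid(eca_t1, eca_t2, c("eca_t1", "eca_t2"))
  a <- unclass(eca_t1) & TRUE
  b <- unclass(eca_t2) & TRUE
  list(expansion = !a & b, degradation = a & !b, retained = a & b)
}

#' Group changed cells into patches by buffer overlap
#'
#' Changed cells whose buffers overlap belong to the same patch; implemented
#' as connected components (4-connectivity) of the buffer-dilated mask,
#' restricted back to the changed cells.
#'
#' @param change_mask logical raster of changed cells.
#' @param buffer_radius buffer radius in km (> 0; default 1).
#' @param cell_size cell side length in km.
#' @return integer raster: patch id on changed cells, 0 elsewhere, ids
#'   numbered from 1 in column-major order of first occurrence.
#' @export
build_patches <- function(change_mask, buffer_radius = 1, cell_size = 1) {
  stopifnot(buffer_radius > 0)
  if (!any(change_mask)) return(matrix(0L, nrow(change_mask), ncol(change_mask)))
  dil <- dilate_mask(change_mask, buffer_radius, cell_size)
  lab <- label_components(dil, connectivity = 4)
  lab[!change_mask] <- 0L
  ids <- unique(lab[lab > 0L])
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Landscape expansion index of one change patch
#'
#' The buffer zone is the patch dilated by `buffer_radius` (patch included):
#' `A_E` its area, `A_P` the patch area, `A_0` the reference-ECA area inside
#' the buffer zone, and `LEI = 100 A_0 / (A_E - A_P)`, defined as 0 when
#' `A_E = A_P`.
#'
#' @param patch_mask logical raster of the patch cells (non-empty).
#' @param reference_mask logical raster of reference ECA, disjoint from the
#'   patch.
#' @param buffer_radius buffer radius in km.
#' @param cell_size cell side length in km.
#' @return list: `lei` in `[0, 100]`, `a0`, `ae`, `ap` (km^2).
#' @export
lei <- function(patch_mask, reference_mask, buffer_radius = 1, cell_size = 1) {
  check_same_grid(patch_mask, reference_mask, c("patch", "reference"))
  if (!any(patch_mask)) abort("empty patch")
  if (any(patch_mask & reference_mask)) {
    abort("reference mask must be disjoint from the patch cells")
  }
  zone <- dilate_mask(patch_mask, buffer_radius, cell_size)
  ap <- sum(patch_mask) * cell_size^2
  ae <- sum(zone) * cell_size^2
  a0 <- sum(reference_mask & zone) * cell_size^2
  val <- if (ae > ap) 100 * a0 / (ae - ap) else 0
  list(lei = val, a0 = a0, ae = ae, ap = ap)
}

#' Classify the specific evolution type from mode and LEI
#'
#' Expansion: LEI = 0 isolation, 0 < LEI <= 50 spread, 50 < LEI <= 100
#' infilling. Degradation mirrors these as departed, atrophy, disintegration.
#'
#' @param mode `"expansion"` or `"degradation"` (vectorised).
#' @param lei numeric LEI in `[0, 100]` (vectorised).
#' @return character vector of types.
#' @export
classify_type <- function(mode, lei) {
  if (any(lei < 0 | lei > 100)) abort("LEI outside [0, 100]")
  mode <- as.character(mode)
  if (!all(mode %in% c("expansion", "degradation"))) {
    abort("mode must be 'expansion' or 'degradation'")
  }
  band <- findInterval(lei, c(0, 1e-12, 50 + 1e-12)) # 1: =0, 2: (0,50], 3: (50,100]
  tbl <- rbind(expansion = c("isolation", "spread", "infilling"),
               degradation = c("departed", "atrophy", "disintegration"))
  tbl[cbind(match(mode, rownames(tbl)), band)]
}

#' Detect and classify ECA evolution between two dates
#'
#' Differs the masks, builds mode-pure change patches by buffer overlap,
#' computes each patch's LEI and assigns the six specific types. For
#' expansion patches the LEI reference is the earlier-date ECA ("original
#' ECA"); for degradation patches it is the retained ECA by default
#' (`degradation_reference = "retained"`), switchable to the earlier-date
#' mask minus the patch cells (`"previous"`).
#'
#' @inheritParams diff_masks
#' @param buffer_radius buffer radius in km.
#' @param cell_size cell side length in km.
#' @param degradation_reference `"retained"` or `"previous"`.
#' @return object of class `eca_evolution`: tibble with one row per patch
#'   (patch, mode, type, lei, a0, ae, ap, n_cells, area) and attributes
#'   `labels` (list of expansion/degradation label rasters), `diff` (the
#'   [diff_masks()] output) and `cell_size`.
#' @export
classify_evolution <- function(eca_t1, eca_t2, buffer_radius = 1, cell_size = 1,
                               degradation_reference = c("retained", "previous")) {
  degradation_reference <- match.arg(degradation_reference)
  d <- diff_masks(eca_t1, eca_t2)
  labs <- list(expansion = build_patches(d$expansion, buffer_radius, cell_size),
               degradation = build_patches(d$degradation, buffer_radius, cell_size))
  rows <- list()
  for (mode in c("expansion", "degradation")) {
    lab <- labs[[mode]]
    n <- max(lab)
    if (n == 0L) next
    ref <- if (mode == "expansion") {
      unclass(eca_t1) & TRUE
    } else if (degradation_reference == "retained") {
      d$retained
    } else {
      (unclass(eca_t1) & TRUE) & !d$degradation
    }
    for (k in seq_len(n)) {
      pm <- lab == k
      l <- lei(pm, ref & !pm, buffer_radius, cell_size)
      rows[[length(rows) + 1L]] <- tibble(
        patch = k, mode = mode, type = classify_type(mode, l$lei),
        lei = l$lei, a0 = l$a0, ae = l$ae, ap = l$ap,
        n_cells = sum(pm), area = sum(pm) * cell_size^2
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(patch = integer(), mode = character(), type = character(),
           lei = numeric(), a0 = numeric(), ae = numeric(), ap = numeric(),
           n_cells = integer(), area = numeric())
  structure(out, labels = labs, diff = d, cell_size = cell_size,
            class = c("eca_evolution", class(out)))
}

#' Summarise evolution modes and types
#'
#' Grid counts, patch areas and proportions per mode and per specific type.
#' Mode proportions are each mode's grid count over all changed grids; type
#' proportions are within-mode, by count and by area.
#'
#' @param patches an `eca_evolution` object (or its tibble).
#' @return list of two tibbles: `modes` (mode, n_cells, n_patches, area,
#'   prop_count) and `types` (mode, type, n_cells, n_patches, area,
#'   prop_count, prop_area).
#' @export
summarize_evolution <- function(patches) {
  p <- as_tibble(patches)
  total <- sum(p$n_cells)
  modes <- p |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(n_cells = sum(.data$n_cells), n_patches = dplyr::n(),
                     area = sum(.data$area), .groups = "drop") |>
    dplyr::mutate(prop_count = if (total > 0) 100 * .data$n_cells / total else NA_real_)
  types <- p |>
    dplyr::group_by(.data$mode, .data$type) |>
    dplyr::summarise(n_cells = sum(.data$n_cells), n_patches = dplyr::n(),
                     area = sum(.data$area), .groups = "drop_last") |>
    dplyr::mutate(prop_count = 100 * .data$n_cells / sum(.data$n_cells),
                  prop_area = 100 * .data$area / sum(.data$area)) |>
    dplyr::ungroup()
  list(modes = modes, types = types)
}

#' Percent change between two counts
#'
#' `100 (a - b) / a`, rounded to two decimals: positive for a decrease from
#' `a` to `b`, negative for an increase.
#'
#' @param count_a reference (earlier) count, > 0.
#' @param count_b later count.
#' @return numeric scalar, 2 decimal places.
#' @export
percent_change <- function(count_a, count_b) {
  if (!is.finite(count_a) || count_a <= 0) abort("count_a must be > 0")
  round(100 * (count_a - count_b) / count_a, 2)
}
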