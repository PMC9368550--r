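#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Rasters are plain numeric/integer/logical matrices: row-major, origin at the
# top-left corner, a cell addressed by (row, col), 1-based. `cell_size` is the
# side length of a square cell in km.

#' Check that two rasters share a grid
#'
#' @param a,b matrices.
#' @param names character(2) used in the error message.
#' @return invisibly `TRUE`; aborts on mismatch.
#' @keywords internal
check_same_grid <- function(a, b, names = c("a", "b")) {
  if (!all(dim(a) == dim(b))) {
    abort(sprintf(
      "grid mismatch: '%s' is %dx%d but '%s' is %dx%d",
      names[1], nrow(a), ncol(a), names[2], nrow(b), ncol(b)
    ))
  }
  invisible(TRUE)
}

#' Euclidean distance to the nearest TRUE cell
#'
#' Distance from every cell centre to the nearest centre of a `TRUE` cell,
#' in km. Cells of the source set get 0.
#'
#' @param mask logical matrix.
#' @param cell_size cell side length in km.
#' @return numeric matrix; all `Inf` (with a warning) when `mask` has no
#'   `TRUE` cell.
#' @export
distance_to <- function(mask, cell_size = 1) {
  stopifnot(is.matrix(mask))
  m <- mask & !is.na(mask)
  if (!any(m)) {
    warn("distance_to(): empty source set, returning Inf everywhere")
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  x <- matrix(1, nrow(mask), ncol(mask))
  x[m] <- 0
  as.matrix(EBImage::distmap(x)) * cell_size
}

#' Dilate a mask by a metric radius
#'
#' A cell belongs to the dilated set iff its centre lies within
#' `radius` of the centre of some source cell (source cells included).
#'
#' @inheritParams distance_to
#' @param radius buffer radius in km.
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, radius, cell_size = 1) {
  stopifnot(radius > 0)
  if (!any(mask, na.rm = TRUE)) return(mask & FALSE)
  distance_to(mask, cell_size) <= radius + 1e-9
}

#' Label connected components of a logical mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 (rook) or 8 (queen) adjacency.
#' @return integer matrix; 0 outside the mask, components numbered from 1 in
#'   order of their first cell in column-major order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask & !is.na(mask)
  cells <- which(m)                      # ascending linear (column-major) index
  lab <- matrix(0L, nr, nc)
  if (length(cells) == 0L) return(lab)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  e_from <- integer(0); e_to <- integer(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rows <- seq_len(nr); cols <- seq_len(nc)
    rows <- rows[rows + dr >= 1 & rows + dr <= nr]
    cols <- cols[cols + dc >= 1 & cols + dc <= nc]
    if (!length(rows) || !length(cols)) next
    a <- m[rows, cols, drop = FALSE] & m[rows + dr, cols + dc, drop = FALSE]
    if (!any(a)) next
    idx <- which(a)
    r0 <- ((idx - 1L) %% length(rows)) + 1L
    c0 <- ((idx - 1L) %/% length(rows)) + 1L
    from <- (cols[c0] - 1L) * nr + rows[r0]
    to <- (cols[c0] + dc - 1L) * nr + rows[r0] + dr
    e_from <- c(e_from, from); e_to <- c(e_to, to)
  }
  v <- match(cells, cells)               # 1..n
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (length(e_from)) {
    g <- igraph::add_edges(g, rbind(match(e_from, cells), match(e_to, cells)))
  }
  memb <- igraph::components(g)$membership
  memb <- match(memb, unique(memb))      # renumber by first occurrence
  lab[cells] <- memb
  lab
}

#' Smooth Gaussian random field
#'
#' White noise convolved with a Gaussian kernel, standardised to the requested
#' standard deviation. Draws from the current RNG stream.
#'
#' @param nr,nc raster dimensions.
#' @param corr_len correlation length in cells (Gaussian sigma).
#' @param sd target standard deviation of the field.
#' @return numeric matrix with mean 0 and sd `sd`.
#' @export
gauss_field <- function(nr, nc, corr_len = 3, sd = 1) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len > 0) z <- as.matrix(EBImage::gblur(z, sigma = corr_len))
  z <- z - mean(z)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s * sd
  z
}

norm01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[2] == r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

# min-max rescale a vector across units; all-equal collapses to 0
minmax_units <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] == r[1]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Slope from a digital elevation model
#'
#' Central-difference gradient magnitude converted to degrees. One-sided
#' differences are used on the raster border.
#'
#' @param dem elevation raster, metres.
#' @param cell_size cell side length in km.
#' @return slope raster in degrees; 0 everywhere for a flat DEM.
#' @export
slope_from_dem <- function(dem, cell_size = 1) {
  nr <- nrow(dem); nc <- ncol(dem)
  run <- cell_size * 1000                # metres
  up <- dem[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- dem[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  span_r <- matrix(ifelse(seq_len(nr) %in% c(1L, nr), run, 2 * run), nr, nc)
  dzdr <- (dn - up) / span_r
  lf <- dem[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- dem[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  span_c <- matrix(ifelse(seq_len(nc) %in% c(1L, nc), run, 2 * run), nr, nc, byrow = TRUE)
  dzdc <- (rt - lf) / span_c
  atan(sqrt(dzdr^2 + dzdc^2)) * 180 / pi
}

# deterministic per-operation RNG substream seed (< 2^31)
substream_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op))) %% 99991L
  as.integer((abs(seed) %% 20000L) * 100003L + h)
}
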