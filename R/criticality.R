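# MESLI, ECI, histogram-peak threshold extraction and the ECA mask.

#' Multiple ecosystem services landscape index
#'
#' Sum of the min-max normalised service layers,
#' `MESLI = sum_i (x_i - min x_i) / (max x_i - min x_i)`, with the minimum and
#' maximum taken over the period's valid study-area cells. Range `[0, n]` for
#' n services.
#'
#' @param services named list of co-registered numeric service rasters.
#' @return numeric raster; NA wherever any service layer is NA.
#' @export
mesli <- function(services) {
  stopifnot(is.list(services), length(services) >= 1)
  nm <- names(services) %||% paste0("service", seq_along(services))
  out <- 0
  for (i in seq_along(services)) {
    x <- services[[i]]
    if (i > 1L) check_same_grid(services[[1]], x, c(nm[1], nm[i]))
    r <- range(x, na.rm = TRUE)
    if (!is.finite(r[1]) || r[2] == r[1]) {
      abort(sprintf("service layer '%s' is constant (max = min); cannot normalise", nm[i]))
    }
    out <- out + (x - r[1]) / (r[2] - r[1])
  }
  out
}

#' Ecological critical index
#'
#' Cell-wise product `ECI = MESLI x LESSI`. NA propagates.
#'
#' @param mesli_raster raster from [mesli()].
#' @param lessi_raster raster from [lessi_surface()] (or [lessi_window()]).
#' @return numeric raster.
#' @export
eci <- function(mesli_raster, lessi_raster) {
  check_same_grid(mesli_raster, lessi_raster, c("mesli", "lessi"))
  mesli_raster * lessi_raster
}

#' Extract the ECA threshold from the ECI frequency distribution
#'
#' Histogram over the value range with `n_bins` equal-width bins, smoothed by
#' a centred moving average of `smooth_window` bins. Peaks are strict local
#' maxima of the smoothed curve over interior bins (plateaus collapse to their
#' centre bin) whose height reaches at least `min_peak_frac` of the global
#' smoothed maximum -- the floor discards the spurious micro-peaks that
#' isolated straggler counts in the sparse right tail would otherwise create.
#' The threshold T is the centre of the highest-value ("last") peak bin. If no
#' qualifying interior local maximum exists, the global maximum bin is used
#' with a warning.
#'
#' @param eci_values numeric vector (or raster) of ECI values; needs at least
#'   1000 finite values.
#' @param n_bins number of histogram bins (>= 10).
#' @param smooth_window moving-average width in bins (odd).
#' @param min_peak_frac minimum peak height as a fraction of the smoothed
#'   curve's maximum.
#' @return object of class `eca_threshold`: list with `threshold`, `curve`
#'   (tibble: bin, mid, count, smoothed, peak) and `peaks` (bin indices).
#' @export
extract_threshold <- function(eci_values, n_bins = 100, smooth_window = 5,
                              min_peak_frac = 0.08) {
  x <- as.vector(eci_values)
  x <- x[is.finite(x)]
  if (length(x) < 1000) abort("need at least 1000 finite ECI values")
  if (n_bins < 10) abort("n_bins must be >= 10")
  brk <- seq(min(x), max(x), length.out = n_bins + 1L)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  counts <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE), n_bins),
                     nbins = n_bins)
  h <- (smooth_window - 1L) %/% 2L
  sm <- vapply(seq_len(n_bins), function(i) {
    mean(counts[max(1L, i - h):min(n_bins, i + h)])
  }, numeric(1))
  # strict local maxima with plateau collapse, interior runs only
  runs <- rle(sm)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- integer(0)
  floor_h <- min_peak_frac * max(sm)
  for (k in seq_along(runs$values)) {
    if (starts[k] == 1L || ends[k] == n_bins) next
    if (runs$values[k] < floor_h) next
    if (sm[starts[k] - 1L] < runs$values[k] && sm[ends[k] + 1L] < runs$values[k]) {
      peaks <- c(peaks, (starts[k] + ends[k]) %/% 2L)
    }
  }
  if (!length(peaks)) {
    warn("no interior local maximum in smoothed histogram; using global maximum bin")
    peaks <- which.max(sm)
  }
  t_bin <- max(peaks)
  structure(list(
    threshold = mid[t_bin],
    curve = tibble(bin = seq_len(n_bins), mid = mid, count = counts,
                   smoothed = sm, peak = seq_len(n_bins) %in% peaks),
    peaks = peaks,
    bin_width = diff(brk[1:2])
  ), class = "eca_threshold")
}

#' @export
print.eca_threshold <- function(x, ...) {
  cat(sprintf("<eca_threshold> T = %.4f (%d peak%s, bin width %.4f)\n",
              x$threshold, length(x$peaks),
              if (length(x$peaks) == 1) "" else "s", x$bin_width))
  invisible(x)
}

#' Identify ecologically critical areas
#'
#' Cells with `ECI > T` (strict inequality). NA cells are excluded.
#'
#' @param eci_raster numeric ECI raster.
#' @param threshold scalar T or an `eca_threshold` object.
#' @return logical raster of class `eca_mask` with attributes `threshold`,
#'   `n_eca` (grid count) and `share` (fraction of valid cells).
#' @export
identify_eca <- function(eci_raster, threshold) {
  t0 <- if (inherits(threshold, "eca_threshold")) threshold$threshold else threshold
  stopifnot(is.finite(t0))
  mask <- !is.na(eci_raster) & eci_raster > t0
  structure(mask, threshold = t0, n_eca = sum(mask),
            share = sum(mask) / sum(!is.na(eci_raster)), class = "eca_mask")
}

#' @export
print.eca_mask <- function(x, ...) {
  cat(sprintf("<eca_mask> %d ECA cells (%.1f%% of valid) at T = %.4f\n",
              attr(x, "n_eca"), 100 * attr(x, "share"), attr(x, "threshold")))
  invisible(x)
}

#' Full criticality surface for one period
#'
#' Convenience wrapper chaining [mesli()], [eci()], [extract_threshold()] and
#' [identify_eca()] for one period's service stack and LESSI surface.
#'
#' @param services named list of service rasters for the period.
#' @param lessi_raster per-cell LESSI raster.
#' @param n_bins,smooth_window forwarded to [extract_threshold()].
#' @param period optional period label.
#' @return object of class `eca_criticality`: list with `period`, `mesli`,
#'   `lessi`, `eci`, `threshold` (`eca_threshold`), `mask` (`eca_mask`).
#' @export
criticality_surface <- function(services, lessi_raster, n_bins = 100,
                                smooth_window = 5, period = NA_character_) {
  m <- mesli(services)
  e <- eci(m, lessi_raster)
  th <- extract_threshold(e, n_bins = n_bins, smooth_window = smooth_window)
  mask <- identify_eca(e, th)
  structure(list(period = period, mesli = m, lessi = lessi_raster, eci = e,
                 threshold = th, mask = mask),
            class = "eca_criticality")
}

#' @export
print.eca_criticality <- function(x, ...) {
  cat(sprintf("<eca_criticality>%s T = %.4f, %d ECA cells (%.1f%%)\n",
              if (is.na(x$period)) "" else paste0(" period ", x$period, ":"),
              x$threshold$threshold, attr(x$mask, "n_eca"),
              100 * attr(x$mask, "share")))
  invisible(x)
}
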