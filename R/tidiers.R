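# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted evolution table
#'
#' @param x an `eca_evolution` object.
#' @param ... unused.
#' @return the patch tibble (patch, mode, type, lei, a0, ae, ap, n_cells,
#'   area).
#' @method tidy eca_evolution
#' @export
tidy.eca_evolution <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of an evolution result
#'
#' @param x an `eca_evolution` object.
#' @param ... unused.
#' @return tibble: n_patches, n_expansion, n_degradation, changed_cells,
#'   expansion_prop_pct.
#' @method glance eca_evolution
#' @export
glance.eca_evolution <- function(x, ...) {
  p <- as_tibble(x)
  exp_cells <- sum(p$n_cells[p$mode == "expansion"])
  deg_cells <- sum(p$n_cells[p$mode == "degradation"])
  tot <- exp_cells + deg_cells
  tibble(
    n_patches = nrow(p),
    n_expansion = sum(p$mode == "expansion"),
    n_degradation = sum(p$mode == "degradation"),
    changed_cells = tot,
    expansion_prop_pct = if (tot > 0) 100 * exp_cells / tot else NA_real_
  )
}

#' Tidy a fitted driver forest
#'
#' @param x an `eca_forest` object.
#' @param grades if `TRUE`, attach geometric-interval grades.
#' @param ... unused.
#' @return tibble: variable, p_pct (and grade).
#' @method tidy eca_forest
#' @export
tidy.eca_forest <- function(x, grades = TRUE, ...) {
  imp <- gini_importance(x)
  if (!grades) return(imp)
  gr <- geometric_interval_grades(stats::setNames(imp$p_pct, imp$variable))
  dplyr::mutate(imp, grade = gr$grade)
}

#' One-row summary of a fitted driver forest
#'
#' @param x an `eca_forest` object.
#' @param ... unused.
#' @return tibble: response, n, n_trees, accuracy_pct.
#' @method glance eca_forest
#' @export
glance.eca_forest <- function(x, ...) {
  tibble(response = x$response, n = x$n, n_trees = x$n_trees,
         accuracy_pct = x$accuracy)
}

raster_df <- function(m) {
  tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a raster matrix
#'
#' @param m matrix.
#' @param name legend title.
#' @return a ggplot.
#' @export
plot_raster <- function(m, name = "value") {
  df <- raster_df(m + 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = name) +
    ggplot2::theme_minimal()
}

#' @method autoplot eca_threshold
#' @export
autoplot.eca_threshold <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$mid, .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "ECI", y = "frequency",
                  title = sprintf("extraction threshold T = %.3f", object$threshold)) +
    ggplot2::theme_minimal()
}

#' @method autoplot eca_criticality
#' @export
autoplot.eca_criticality <- function(object, what = c("eci", "mesli", "lessi", "mask"),
                                     ...) {
  what <- match.arg(what)
  m <- if (what == "mask") unclass(object$mask) + 0 else object[[what]]
  plot_raster(m, name = toupper(what)) +
    ggplot2::ggtitle(if (is.na(object$period)) toupper(what)
                     else sprintf("%s (%s)", toupper(what), object$period))
}

#' @method autoplot eca_evolution
#' @export
autoplot.eca_evolution <- function(object, ...) {
  labs <- attr(object, "labels")
  tab <- as_tibble(object)
  type_of <- function(mode) {
    lab <- labs[[mode]]
    idx <- which(lab > 0L)
    sub <- tab[tab$mode == mode, ]
    tibble(cell = idx, type = sub$type[match(lab[idx], sub$patch)])
  }
  df <- dplyr::bind_rows(type_of("expansion"), type_of("degradation"))
  nr <- nrow(labs$expansion)
  df$row <- ((df$cell - 1L) %% nr) + 1L
  df$col <- ((df$cell - 1L) %/% nr) + 1L
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$type)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "evolution type") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
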