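# Driver-table assembly, random-forest attribution, percent Gini importance
# and geometric-interval grading.

make_drivers <- function(nr, nc, val = 1) {
  nm <- c("dem", "slope", "temperature", "precipitation", "gdp", "population",
          "nightlight")
  stats::setNames(lapply(nm, function(x) matrix(val, nr, nc)), nm)
}

test_that("predictors aggregate as documented", {
  nr <- 1; nc <- 4
  lc <- matrix(c(eca_classes[["impervious"]], rep(eca_classes[["forest"]], 3)), nr, nc)
  zones <- matrix(c(1L, 2L, 2L, 2L), nr, nc)
  drv <- make_drivers(nr, nc)
  a <- matrix(FALSE, nr, nc)
  b <- a; b[1, 4] <- TRUE
  ev <- classify_evolution(a, b)
  # no cropland cell exists, so the x12 distance transform warns
  expect_warning(
    tbl <- assemble_driver_table(drv, lc, zones, list(`p1-p2` = ev)),
    "empty source"
  )
  u2 <- tbl[tbl$unit == 2, ]
  expect_equal(u2$x5, 1)                     # fully forested unit
  expect_equal(u2$x6, 0); expect_equal(u2$x7, 0)
  expect_equal(tbl$x11[tbl$unit == 1], 0)    # impervious cell itself
  expect_equal(u2$x11, mean(c(1, 2, 3)))     # hand mean of the distance transform
  expect_equal(u2$x4, 3)                     # total (sum) precipitation
  expect_equal(u2$mode, "expansion")
  expect_true(is.na(tbl$mode[tbl$unit == 1]))  # no changed cells -> excluded
})

test_that("dominant labels break ties toward degradation", {
  nr <- 2; nc <- 4
  lc <- matrix(eca_classes[["forest"]], nr, nc)
  lc[1, 1] <- eca_classes[["impervious"]]; lc[2, 1] <- eca_classes[["cropland"]]
  zones <- matrix(1L, nr, nc)
  a <- matrix(FALSE, nr, nc); a[1, 3] <- TRUE            # will degrade
  b <- matrix(FALSE, nr, nc); b[2, 4] <- TRUE            # expands elsewhere
  ev <- classify_evolution(a, b)
  tbl <- assemble_driver_table(make_drivers(nr, nc), lc, zones, list(`p1-p2` = ev))
  expect_equal(tbl$mode, "degradation")                  # 1 vs 1 tie
})

test_that("the forest nails a leaked response and is seed-stable", {
  withr::with_seed(51, {
    n <- 400
    tbl <- tibble::tibble(!!!stats::setNames(
      lapply(1:12, function(i) rnorm(n)), paste0("x", 1:12)
    ))
    tbl$mode <- ifelse(tbl$x3 > 0, "expansion", "degradation")  # x3 leaks the label
    f <- fit_forest(tbl, "mode", n_trees = 200, seed = 1)
    expect_gte(f$accuracy, 95)
    expect_equal(gini_importance(f)$variable[1], "x3")
    f2 <- fit_forest(tbl, "mode", n_trees = 200, seed = 1)
    expect_identical(f$accuracy, f2$accuracy)
  })
})

test_that("degenerate training tables fail loudly", {
  tbl <- tibble::tibble(!!!stats::setNames(
    lapply(1:12, function(i) rnorm(30)), paste0("x", 1:12)
  ))
  tbl$mode <- "degradation"
  expect_error(fit_forest(tbl, "mode"), "single class")
  tbl$mode <- rep(c("expansion", "degradation"), 15)
  expect_error(fit_forest(tbl[1:10, ], "mode"), "20")
})

test_that("percent contributions sum to 100 and ignore unused predictors", {
  withr::with_seed(52, {
    n <- 300
    tbl <- tibble::tibble(!!!stats::setNames(
      lapply(1:12, function(i) rnorm(n)), paste0("x", 1:12)
    ))
    tbl$x12 <- 0                                    # constant: never splittable
    tbl$mode <- ifelse(tbl$x1 + rnorm(n, 0, 0.5) > 0, "a", "b")
    f <- fit_forest(tbl, "mode", n_trees = 200, seed = 3)
    imp <- gini_importance(f)
    expect_equal(sum(imp$p_pct), 100, tolerance = 1e-9)
    expect_equal(imp$p_pct[imp$variable == "x12"], 0)
  })
})

test_that("grade presets map importances to the printed classes", {
  g <- geometric_interval_grades(c(a = 0.2, b = 10.0, c = 39), breaks = grade_breaks_preset)
  expect_equal(as.character(g$grade), c("I", "V", "VI"))
  g2 <- geometric_interval_grades(c(0.5037, 0.5038, 18.4052, 18.4053),
                                  breaks = grade_breaks_preset)
  expect_equal(as.character(g2$grade), c("I", "II", "V", "VI"))
  expect_error(geometric_interval_grades(1:3, breaks = c(3, 2, 1)), "ascending")
})

test_that("computed geometric-interval breaks are increasing and span the data", {
  withr::with_seed(53, {
    x <- rexp(50, 1) * 10
    g <- geometric_interval_grades(x, n_classes = 6)
    b <- attr(g, "breaks")
    expect_length(b, 7)
    expect_true(all(diff(b) > 0))
    expect_equal(b[1], min(x)); expect_equal(b[7], max(x))
    # grade monotone in importance
    ord <- order(g$p_pct)
    expect_true(!is.unsorted(as.integer(g$grade[ord])))
  })
  expect_warning(geometric_interval_grades(rep(2, 5)), "equal")
})

test_that("broom-style accessors expose the fitted attribution", {
  withr::with_seed(54, {
    n <- 200
    tbl <- tibble::tibble(!!!stats::setNames(
      lapply(1:12, function(i) rnorm(n)), paste0("x", 1:12)
    ))
    tbl$mode <- ifelse(tbl$x2 > 0, "a", "b")
    f <- fit_forest(tbl, "mode", n_trees = 100, seed = 4)
    td <- tidy(f)
    expect_named(td, c("variable", "p_pct", "grade"))
    expect_equal(nrow(td), 12)
    gl <- glance(f)
    expect_equal(gl$response, "mode")
    expect_equal(gl$n, n)
  })
})
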