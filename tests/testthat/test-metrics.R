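# Patch delineation and the five structure metrics against hand values and a
# brute-force flood-fill oracle; LESSI bounds and monotonicity.

test_that("patch delineation matches analytic cases", {
  uni <- matrix(1L, 10, 10)
  d <- delineate_patches(uni)
  expect_equal(nrow(d$patches), 1)
  expect_equal(d$patches$area, 100)
  expect_equal(d$patches$perimeter, 40)

  chk <- matrix(rep_len(c(1L, 2L), 64), 8, 8)   # checkerboard columns alternate
  chk <- outer(1:8, 1:8, function(r, c) ((r + c) %% 2) + 1L)
  d4 <- delineate_patches(chk, connectivity = 4)
  expect_equal(nrow(d4$patches), 64)            # every cell its own patch
  expect_true(all(d4$patches$area == 1))

  expect_error(delineate_patches(matrix(NA_integer_, 3, 3)), "empty")
})

test_that("patch sets equal an independent flood-fill oracle", {
  withr::with_seed(11, {
    for (i in 1:5) {
      lc <- random_landcover(16, 16)
      got <- delineate_patches(lc, connectivity = 8)
      want <- oracle_patches(lc, connectivity = 8)
      expect_equal(nrow(got$patches), nrow(want))
      # identical partitions: compare sorted per-patch cell sets
      got_sets <- lapply(seq_len(max(got$labels)), function(k) sort(which(got$labels == k)))
      want_sets <- want$cells
      key <- function(s) paste(s, collapse = ",")
      expect_setequal(vapply(got_sets, key, ""), vapply(want_sets, key, ""))
    }
  })
})

test_that("unit metrics match hand computation for a lone square patch", {
  lc <- matrix(2L, 10, 10)
  lc[5:6, 5:6] <- 1L                      # one 2x2 patch (a=4, p=8) in a 100 km2 unit
  zones <- matrix(1L, 10, 10)
  m <- compute_metrics(lc, zones)
  cl <- m[m$class == "1", ]
  expect_equal(cl$awmsi, 0.25 * 8 / sqrt(4))          # = 1.0
  expect_equal(cl$division, 1 - (4 / 100)^2)          # = 0.9984
  expect_equal(cl$pd, 1 / 100)
  expect_equal(cl$ed, 8 / 100)
  # a square filling its unit has shape index exactly 1
  m1 <- compute_metrics(matrix(1L, 10, 10), zones)
  expect_equal(m1$awmsi[m1$class == "landscape"], 1)
  expect_equal(m1$division[m1$class == "landscape"], 0)
})

test_that("all five metrics equal a brute-force oracle on random rasters", {
  withr::with_seed(22, {
    for (i in 1:6) {
      lc <- random_landcover(20, 20, n_classes = 3)
      zones <- matrix(rep(1:2, each = 200), 20, 20)
      m <- compute_metrics(lc, zones)
      for (u in 1:2) {
        lc_u <- lc
        lc_u[zones != u] <- NA
        want <- oracle_unit_metrics(lc_u)
        got <- m[m$unit == u, ]
        for (cls in want$class) {
          g <- got[got$class == cls, ]
          w <- want[want$class == cls, ]
          for (col in c("pd", "ed", "awmsi", "frac_dim", "division")) {
            expect_equal(g[[col]], w[[col]], tolerance = 1e-12)
          }
        }
      }
    }
  })
})

test_that("perimeter-derived quantities scale with cell size", {
  lc <- matrix(2L, 10, 10); lc[5:6, 5:6] <- 1L
  d1 <- delineate_patches(lc, cell_size = 1)$patches
  d2 <- delineate_patches(lc, cell_size = 2)$patches
  expect_equal(d2$area, 4 * d1$area)
  expect_equal(d2$perimeter, 2 * d1$perimeter)
})

test_that("fragmentation composite follows its weights", {
  expect_equal(fragmentation_v(0, 0, 0), 0)
  expect_equal(fragmentation_v(1, 1, 1), 1)
  expect_equal(fragmentation_v(0.5, 0.2, 0.9), 0.25 + 0.06 + 0.18)
  expect_error(fragmentation_v(0.5, 0.5, 0.5, weights = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("LESSI lies in [0,1] and rewards intact units", {
  scen <- generate_timeseries(small_config(seed = 12))
  m <- compute_metrics(scen$landcover, scen$zones)
  lt <- lessi(m)
  expect_true(all(lt$lessi >= 0 & lt$lessi <= 1))
  # a uniform single-class unit is the most secure after rescaling
  lc <- matrix(1L, 20, 20)
  lc[, 11:20] <- rep(c(1L, 2L, 3L), length.out = 200)  # fragmented right half
  zones <- matrix(rep(1:2, each = 200), 20, 20)
  lt2 <- lessi(compute_metrics(lc, zones))
  expect_equal(lt2$lessi[lt2$unit == 1], 1)
  expect_lt(lt2$lessi[lt2$unit == 2], lt2$lessi[lt2$unit == 1])
})

test_that("raising fragmentation never raises LESSI (theoretical rescale)", {
  base <- tibble::tibble(
    unit = 1:4, class = "landscape", n_patches = 1L, n_cells = 100L,
    area = 100, pd = c(0.01, 0.05, 0.10, 0.20), ed = c(0.1, 0.3, 0.5, 0.9),
    awmsi = c(1, 1.4, 1.9, 2.5), frac_dim = c(1, 1.1, 1.2, 1.3),
    division = c(0, 0.4, 0.7, 0.95), missing = FALSE
  )
  l0 <- lessi(base, rescale = "theoretical")
  worse <- base
  worse$awmsi[3] <- 2.2; worse$division[3] <- 0.9
  l1 <- lessi(worse, rescale = "theoretical")
  expect_lte(l1$lessi[3], l0$lessi[3])
  expect_true(all(l0$lessi >= 0 & l0$lessi <= 1))
})

test_that("moving-window LESSI stays bounded and sized like the input", {
  lc <- random_landcover(15, 15, 3)
  lw <- lessi_window(lc, window = 7)
  expect_equal(dim(lw), c(15L, 15L))
  expect_true(all(lw >= 0 & lw <= 1, na.rm = TRUE))
})

test_that("units without valid cells are flagged missing", {
  lc <- matrix(c(1L, NA), 4, 4)
  lc[, 3:4] <- NA
  zones <- matrix(rep(1:2, each = 8), 4, 4)
  m <- compute_metrics(lc, zones)
  expect_true(m$missing[m$unit == 2][1])
  expect_false(any(m$missing[m$unit == 1]))
})
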