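# Mask differencing, buffer-overlap patch building, LEI geometry against a
# cell-enumeration oracle, and the six-type classification.

mask_of <- function(nr, nc, cells) {
  m <- matrix(FALSE, nr, nc)
  m[cells] <- TRUE
  m
}

test_that("mask differencing follows the truth table", {
  withr::with_seed(41, {
    a <- matrix(runif(64) > 0.5, 8, 8)
    b <- matrix(runif(64) > 0.5, 8, 8)
    d <- diff_masks(a, b)
    expect_equal(d$expansion, !a & b)
    expect_equal(d$degradation, a & !b)
    expect_equal(d$retained, a & b)
    expect_false(any(d$expansion & d$degradation))
    same <- diff_masks(a, a)
    expect_equal(sum(same$expansion) + sum(same$degradation), 0)
  })
  empty <- matrix(FALSE, 4, 4)
  k <- mask_of(4, 4, c(2, 7, 11))
  d2 <- diff_masks(empty, k)
  expect_equal(sum(d2$expansion), 3)
  expect_equal(sum(d2$degradation), 0)
  expect_error(diff_masks(empty, matrix(FALSE, 5, 5)), "mismatch")
})

test_that("buffer overlap groups cells into the expected patches", {
  m1 <- mask_of(7, 7, c(cell <- (3 - 1) * 7 + 3, (4 - 1) * 7 + 3))  # orthogonal neighbours
  expect_equal(max(build_patches(m1)), 1)
  m2 <- matrix(FALSE, 7, 7); m2[3, 2] <- TRUE; m2[3, 4] <- TRUE     # 2 km apart
  expect_equal(max(build_patches(m2)), 1)                           # buffers share the middle cell
  m3 <- matrix(FALSE, 9, 9); m3[5, 2] <- TRUE; m3[5, 7] <- TRUE     # 5 km apart
  expect_equal(max(build_patches(m3)), 2)
  expect_equal(max(build_patches(matrix(FALSE, 5, 5))), 0)
})

test_that("single-cell LEI matches the cross-buffer enumeration", {
  nr <- 7; nc <- 7
  patch <- mask_of(nr, nc, (4 - 1) * nr + 4)       # centre cell
  none <- matrix(FALSE, nr, nc)
  r0 <- lei(patch, none)
  expect_equal(r0$lei, 0)                           # isolation
  expect_equal(r0$ae, 5); expect_equal(r0$ap, 1)
  ring <- mask_of(nr, nc, c((4 - 1) * nr + 3, (4 - 1) * nr + 5,
                            (3 - 1) * nr + 4, (5 - 1) * nr + 4))
  expect_equal(lei(patch, ring)$lei, 100)           # fully embedded
  half <- mask_of(nr, nc, c((4 - 1) * nr + 3, (3 - 1) * nr + 4))
  expect_equal(lei(patch, half)$lei, 50)
  expect_error(lei(none, ring), "empty")
  expect_error(lei(patch, patch), "disjoint")
})

test_that("LEI geometry equals the brute-force oracle on random masks", {
  withr::with_seed(42, {
    for (i in 1:8) {
      nr <- sample(8:24, 1); nc <- sample(8:24, 1)
      change <- matrix(runif(nr * nc) < 0.08, nr, nc)
      ref <- matrix(runif(nr * nc) < 0.2, nr, nc) & !change
      if (!any(change)) next
      labs <- build_patches(change)
      for (k in seq_len(max(labs))) {
        pm <- labs == k
        got <- lei(pm, ref)
        want <- oracle_lei(which(pm), ref)
        expect_identical(got[c("a0", "ae", "ap")], want[c("a0", "ae", "ap")])
        expect_equal(got$lei, want$lei)
      }
    }
  })
})

test_that("LEI is invariant under translation of the whole scene", {
  nr <- 12
  patch <- mask_of(nr, nr, c(29, 30, 41))
  ref <- mask_of(nr, nr, c(17, 18, 28, 40, 52))
  ref <- ref & !patch
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nr)
    idx <- which(m, arr.ind = TRUE)
    out[cbind(idx[, 1] + dr, idx[, 2] + dc)] <- TRUE
    out
  }
  a <- lei(patch, ref)
  b <- lei(shift(patch, 2, 3), shift(ref, 2, 3))
  expect_equal(a, b)
})

test_that("specific types follow the printed LEI intervals", {
  expect_equal(classify_type("expansion", 0), "isolation")
  expect_equal(classify_type("expansion", 50), "spread")
  expect_equal(classify_type("expansion", 50 + 1e-9), "infilling")
  expect_equal(classify_type("expansion", 100), "infilling")
  expect_equal(classify_type("degradation", 0), "departed")
  expect_equal(classify_type("degradation", 37.2), "atrophy")
  expect_equal(classify_type("degradation", 88), "disintegration")
  expect_error(classify_type("expansion", 101), "LEI")
  expect_error(classify_type("expansion", -1), "LEI")
  expect_error(classify_type("growth", 10), "mode")
})

test_that("classified patches partition the change set, mode-pure", {
  withr::with_seed(43, {
    a <- matrix(runif(400) < 0.3, 20, 20)
    b <- matrix(runif(400) < 0.3, 20, 20)
    ev <- classify_evolution(a, b)
    labs <- attr(ev, "labels")
    d <- diff_masks(a, b)
    expect_equal(labs$expansion > 0, d$expansion)
    expect_equal(labs$degradation > 0, d$degradation)
    tab <- tidy(ev)
    expect_equal(sum(tab$n_cells), sum(d$expansion) + sum(d$degradation))
    expect_true(all(tab$lei >= 0 & tab$lei <= 100))
    expect_true(all(tab$ae >= tab$ap))
    expect_true(all(tab$a0 <= tab$ae - tab$ap))
  })
})

test_that("evolution summaries reproduce reported proportion arithmetic", {
  patches <- tibble::tibble(
    patch = 1:2, mode = c("expansion", "degradation"),
    type = c("spread", "atrophy"),
    lei = c(30, 30), a0 = 0, ae = 0, ap = 0,
    n_cells = c(1537L, 17305L), area = c(1537, 17305)
  )
  s <- summarize_evolution(patches)
  expect_equal(round(s$modes$prop_count[s$modes$mode == "expansion"], 2), 8.16)
  expect_equal(round(s$modes$prop_count[s$modes$mode == "degradation"], 2), 91.84)
  patches$n_cells <- c(11248L, 3379L)
  s2 <- summarize_evolution(patches)
  expect_equal(round(s2$modes$prop_count[s2$modes$mode == "expansion"], 2), 76.90)
  expect_equal(round(s2$modes$prop_count[s2$modes$mode == "degradation"], 2), 23.10)
  s3 <- summarize_evolution(patches[1, ])
  expect_equal(s3$modes$prop_count, 100)
  expect_equal(s3$types$prop_count, 100)
  expect_equal(s3$types$prop_area, 100)
})

test_that("percent change matches reported overall decline", {
  expect_equal(percent_change(49068, 19105), 61.06)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 25), 75)
  expect_equal(percent_change(100, 150), -50)
  expect_error(percent_change(0, 10), "count_a")
})
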