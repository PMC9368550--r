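# Independent brute-force oracles: plain queue-based flood fill and explicit
# per-cell loops, sharing no code with the package's igraph/EBImage paths.

# flood-fill labeling of TRUE cells
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  nxt <- 0L
  for (start in which(mask & lab == 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- ((cur - 1) %% nr) + 1; c <- ((cur - 1) %/% nr) + 1
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        idx <- (cc - 1) * nr + rr
        if (mask[idx] && lab[idx] == 0L) {
          lab[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
    }
  }
  lab
}

# per-patch area and perimeter by explicit edge counting; perimeter counts
# every cell edge whose neighbour is NA, a different class, or off-raster
oracle_patches <- function(lc, connectivity = 8, cell_size = 1) {
  nr <- nrow(lc); nc <- ncol(lc)
  out <- list()
  for (k in sort(unique(lc[!is.na(lc)]))) {
    lab <- flood_fill_labels(!is.na(lc) & lc == k, connectivity)
    for (p in seq_len(max(lab))) {
      cells <- which(lab == p)
      per <- 0L; edge_int <- 0L
      for (cur in cells) {
        r <- ((cur - 1) %% nr) + 1; c <- ((cur - 1) %/% nr) + 1
        for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          rr <- r + o[1]; cc <- c + o[2]
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) { per <- per + 1L; next }
          v <- lc[rr, cc]
          if (is.na(v)) { per <- per + 1L
          } else if (v != k) { per <- per + 1L; edge_int <- edge_int + 1L }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        class = k, n_cells = length(cells),
        area = length(cells) * cell_size^2, perimeter = per * cell_size,
        interior_edge = edge_int * cell_size,
        cells = I(list(sort(cells)))
      )
    }
  }
  do.call(rbind, out)
}

# brute-force unit metrics from the oracle patch table
oracle_unit_metrics <- function(lc_u, cell_size = 1, connectivity = 8) {
  pt <- oracle_patches(lc_u, connectivity, cell_size)
  A <- sum(!is.na(lc_u)) * cell_size^2
  fterm <- function(a, p) if (abs(log(a)) < 1e-12) 1 else 2 * log(0.25 * p) / log(a)
  landscape <- data.frame(
    class = "landscape",
    pd = nrow(pt) / A,
    ed = sum(pt$interior_edge) / A,
    awmsi = sum(0.25 * pt$perimeter / sqrt(pt$area) * pt$area / A),
    frac_dim = sum(mapply(fterm, pt$area, pt$perimeter) * pt$area / A),
    division = 1 - sum((pt$area / A)^2)
  )
  per_class <- do.call(rbind, lapply(split(pt, pt$class), function(s) {
    ta <- sum(s$area)
    data.frame(
      class = as.character(s$class[1]),
      pd = nrow(s) / A, ed = sum(s$interior_edge) / A,
      awmsi = sum(0.25 * s$perimeter / sqrt(s$area) * s$area / ta),
      frac_dim = sum(mapply(fterm, s$area, s$perimeter) * s$area / ta),
      division = 1 - sum((s$area / A)^2)
    )
  }))
  rbind(landscape, per_class)
}

# cell-enumeration oracle for LEI geometry: buffer by pairwise centre
# distances
oracle_lei <- function(patch_cells, ref_mask, radius = 1, cell_size = 1) {
  nr <- nrow(ref_mask); nc <- ncol(ref_mask)
  pr <- ((patch_cells - 1) %% nr) + 1; pc <- ((patch_cells - 1) %/% nr) + 1
  zone <- logical(nr * nc)
  for (i in seq_len(nr * nc)) {
    r <- ((i - 1) %% nr) + 1; c <- ((i - 1) %/% nr) + 1
    d2 <- (pr - r)^2 + (pc - c)^2
    if (min(d2) * cell_size^2 <= radius^2 + 1e-9) zone[i] <- TRUE
  }
  ap <- length(patch_cells) * cell_size^2
  ae <- sum(zone) * cell_size^2
  a0 <- sum(ref_mask[zone]) * cell_size^2
  list(lei = if (ae > ap) 100 * a0 / (ae - ap) else 0, a0 = a0, ae = ae, ap = ap)
}

# random categorical raster with spatial blobs (for oracle comparisons)
random_landcover <- function(nr, nc, n_classes = 4) {
  base <- matrix(sample.int(n_classes, nr * nc, replace = TRUE), nr, nc)
  # a little smoothing so patches are non-trivial
  for (i in 1:2) {
    r0 <- sample(nr - 3, 1); c0 <- sample(nc - 3, 1)
    base[r0:(r0 + 3), c0:(c0 + 3)] <- sample.int(n_classes, 1)
  }
  base
}

small_config <- function(seed = 1, ...) {
  scenario_config(seed = seed, shape = c(64L, 64L), n_zones = 16L, ...)
}
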