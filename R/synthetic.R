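#' Land-cover class codes
#'
#' Integer codes of the seven land-cover classes used throughout the package.
#' @export
eca_classes <- c(
  cropland = 1L, forest = 2L, grassland = 3L, water = 4L,
  wetland = 5L, impervious = 6L, other = 7L
)

#' Build a change rule for the synthetic scenario
#'
#' @param pair character(2): consecutive period labels the rule applies to.
#' @param mode `"expansion"` or `"degradation"`.
#' @param type geometric placement of the planted change: `"edge"` (one-cell
#'   rings on the ECA boundary), `"isolated"` (far from any ECA) or
#'   `"interior"` (holes/cores).
#' @param magnitude fraction of the current ECA cell count to change,
#'   in (0, 1).
#' @return a named list describing the rule.
#' @export
change_rule <- function(pair, mode = c("expansion", "degradation"),
                        type = c("edge", "isolated", "interior"),
                        magnitude = 0.05) {
  mode <- match.arg(mode); type <- match.arg(type)
  stopifnot(length(pair) == 2, is.numeric(magnitude))
  if (magnitude <= 0 || magnitude >= 1) abort("magnitude must lie in (0, 1)")
  list(pair = as.character(pair), mode = mode, type = type, magnitude = magnitude)
}

default_change_rules <- function(periods) {
  if (length(periods) < 4) return(list())
  p <- periods
  # a degradation--expansion--degradation trajectory exercising all six
  # geometric placements over the three period pairs
  list(
    change_rule(c(p[1], p[2]), "degradation", "edge", 0.025),
    change_rule(c(p[1], p[2]), "degradation", "interior", 0.01),
    change_rule(c(p[1], p[2]), "expansion", "edge", 0.012),
    change_rule(c(p[1], p[2]), "expansion", "isolated", 0.01),
    change_rule(c(p[2], p[3]), "expansion", "edge", 0.03),
    change_rule(c(p[2], p[3]), "expansion", "interior", 0.008),
    change_rule(c(p[2], p[3]), "degradation", "edge", 0.012),
    change_rule(c(p[2], p[3]), "degradation", "isolated", 0.012),
    change_rule(c(p[3], p[4]), "degradation", "edge", 0.03),
    change_rule(c(p[3], p[4]), "expansion", "edge", 0.012),
    change_rule(c(p[3], p[4]), "expansion", "isolated", 0.01)
  )
}

#' Configure a synthetic landscape scenario
#'
#' Holds every knob of the seeded generator. The same config and seed always
#' reproduce bit-identical outputs.
#'
#' @param seed integer master seed; every generator operation derives its own
#'   RNG substream from it, so adding operations never perturbs earlier draws.
#' @param shape integer(2), raster rows and columns (each >= 16).
#' @param cell_size cell side length in km.
#' @param n_zones number of contiguous rectangular analysis units (counties).
#' @param periods ordered character vector of period labels.
#' @param change_rules list of [change_rule()] entries; the default emulates a
#'   degradation--expansion--degradation trajectory over four periods.
#' @param driver_effect list(driver=, direction=, strength=): the driver raster
#'   constructed to covary with where change is planted, its sign, and its
#'   strength in units of the driver's standard deviation.
#' @param eca_share areal share of the baseline critical region.
#' @param trans_share areal share of the transitional (semi-natural) belt:
#'   cells with intermediate service levels, below every critical cell. The
#'   mode of this belt forms the last interior peak of the ECI histogram, so
#'   the extracted threshold separates critical cores from everything else.
#' @param trans_level common service ceiling of transitional cells.
#' @param noise_sd standard deviation of the smooth service noise field.
#' @param corr_len correlation length of the noise field, cells.
#' @param boost_base minimum margin by which a critical cell's services
#'   exceed the hotspot ceiling 1.0 (8 times `noise_sd` by default, well
#'   above the 3-sd separation needed downstream).
#' @param boost_spread scale of the truncated-exponential excess above the
#'   floor, giving criticality its right-skewed intensity.
#' @return a list of class `eca_config`.
#' @export
scenario_config <- function(seed = 1L,
                            shape = c(96L, 96L),
                            cell_size = 1,
                            n_zones = 25L,
                            periods = c("p1", "p2", "p3", "p4"),
                            change_rules = NULL,
                            driver_effect = list(driver = "precipitation",
                                                 direction = 1, strength = 3),
                            eca_share = 0.08,
                            trans_share = 0.08,
                            trans_level = 1.0,
                            noise_sd = 0.05,
                            corr_len = 3,
                            boost_base = 0.4,
                            boost_spread = 0.3) {
  stopifnot(length(shape) == 2, is.numeric(seed))
  if (any(shape < 16)) abort("shape dims must each be >= 16")
  if (n_zones < 1) abort("n_zones must be >= 1")
  periods <- as.character(periods)
  if (anyDuplicated(periods)) abort("period labels must be unique")
  if (is.null(change_rules)) change_rules <- default_change_rules(periods)
  for (r in change_rules) {
    i <- match(r$pair[1], periods); j <- match(r$pair[2], periods)
    if (is.na(i) || is.na(j) || j != i + 1L) {
      abort(sprintf("change rule pair (%s, %s) is not a consecutive period pair",
                    r$pair[1], r$pair[2]))
    }
  }
  structure(list(
    seed = as.integer(seed), shape = as.integer(shape), cell_size = cell_size,
    n_zones = as.integer(n_zones), periods = periods,
    change_rules = change_rules, driver_effect = driver_effect,
    eca_share = eca_share, trans_share = trans_share,
    trans_level = trans_level, noise_sd = noise_sd, corr_len = corr_len,
    boost_base = boost_base, boost_spread = boost_spread
  ), class = "eca_config")
}

# smooth criticality field in [0,1]; own substream so every generator
# operation can rebuild it identically
crit_field <- function(config) {
  withr::with_seed(substream_seed(config$seed, "field"), {
    norm01(gauss_field(config$shape[1], config$shape[2], corr_len = 8, sd = 1))
  })
}

crit_core <- function(config) {
  f <- crit_field(config)
  f > stats::quantile(f, 1 - config$eca_share)
}

# corner block (quadrant-sized) with least overlap with the critical core;
# hosts the deliberately fragmented "urban" mosaic
urban_block <- function(config, core) {
  nr <- config$shape[1]; nc <- config$shape[2]
  hr <- max(4L, nr %/% 4L); hc <- max(4L, nc %/% 4L)
  corners <- list(
    list(r = 1:hr, c = 1:hc), list(r = 1:hr, c = (nc - hc + 1L):nc),
    list(r = (nr - hr + 1L):nr, c = 1:hc),
    list(r = (nr - hr + 1L):nr, c = (nc - hc + 1L):nc)
  )
  ov <- vapply(corners, function(b) sum(core[b$r, b$c]), numeric(1))
  corners[[which.min(ov)]]
}

#' Generate a categorical land-cover raster
#'
#' Cluster-grown (seeded multiplicatively-weighted Voronoi) mosaic of the
#' seven classes. The landscape is coupled to a smooth criticality field:
#' an intact forest-dominated interior, a patchier agricultural exterior and
#' one heavily fragmented urban corner, so that landscape-structure metrics
#' are non-degenerate and ecologically plausible.
#'
#' @param config an [scenario_config()] object.
#' @return integer matrix with values in [eca_classes]; attribute `classes`
#'   carries the code table.
#' @export
generate_landcover <- function(config) {
  stopifnot(inherits(config, "eca_config"))
  nr <- config$shape[1]; nc <- config$shape[2]
  if (nr * nc < length(eca_classes)) abort("raster too small to host all 7 classes")
  core <- crit_core(config)
  blk <- urban_block(config, core)
  withr::with_seed(substream_seed(config$seed, "landcover"), {
    in_block <- matrix(FALSE, nr, nc); in_block[blk$r, blk$c] <- TRUE
    region <- ifelse(core & !in_block, 1L, ifelse(in_block, 3L, 2L))
    area_scale <- max(1, (nr * nc) / (96 * 96))
    # the urban corner is seeded densely (one seed per ~4 cells) so it anchors
    # the upper end of the fragmentation scale; everywhere else patches are
    # large and few
    seed_plan <- list(
      `1` = rep(c("forest", "grassland", "wetland"),
                pmax(1, round(c(4, 1, 1) * area_scale))),
      `2` = rep(c("cropland", "grassland", "water", "other", "impervious"),
                pmax(1, round(c(4, 1, 1, 2, 1) * area_scale)))
    )
    lc <- matrix(NA_integer_, nr, nc)
    # the urban corner is a per-cell mosaic: it pins the top of every
    # fragmentation axis (patch density, edge density, shape complexity) so
    # the cross-unit rescaling of the structure metrics is anchored there
    urb <- which(region == 3L)
    lc[urb] <- eca_classes[sample(c("impervious", "cropland", "other"),
                                  length(urb), replace = TRUE)]
    for (reg in 1:2) {
      cells <- which(region == reg)
      if (!length(cells)) next
      classes <- seed_plan[[as.character(reg)]]
      k <- min(length(classes), length(cells))
      classes <- classes[seq_len(k)]
      pos <- sample(cells, k)
      w <- stats::runif(k, 0.75, 1.3)
      pr <- ((pos - 1L) %% nr) + 1L; pc <- ((pos - 1L) %/% nr) + 1L
      cr <- ((cells - 1L) %% nr) + 1L; cc <- ((cells - 1L) %/% nr) + 1L
      d <- outer(cr, pr, `-`)^2 + outer(cc, pc, `-`)^2
      d <- sqrt(d) / rep(w, each = length(cells))
      lc[cells] <- eca_classes[classes[max.col(-d, ties.method = "first")]]
    }
    attr(lc, "classes") <- eca_classes
    lc
  })
}

# class-conditioned mean service levels; forest > grassland > cropland >
# impervious holds for every service
service_class_means <- function() {
  m <- rbind(
    carbon          = c(0.45, 0.90, 0.65, 0.30, 0.70, 0.10, 0.25),
    water_yield     = c(0.40, 0.85, 0.60, 0.55, 0.75, 0.10, 0.30),
    soil_retention  = c(0.35, 0.90, 0.70, 0.40, 0.60, 0.05, 0.30),
    habitat_quality = c(0.30, 0.95, 0.70, 0.60, 0.85, 0.05, 0.35)
  )
  colnames(m) <- names(eca_classes)
  m
}

#' Generate co-registered ecosystem-service rasters
#'
#' Four continuous layers (carbon, water yield, soil retention, habitat
#' quality): a class-conditioned mean plus a smooth Gaussian noise field.
#'
#' @param landcover raster from [generate_landcover()].
#' @param config an [scenario_config()] object.
#' @return named list of four numeric matrices.
#' @export
generate_services <- function(landcover, config) {
  stopifnot(inherits(config, "eca_config"),
            all(dim(landcover) == config$shape))
  means <- service_class_means()
  withr::with_seed(substream_seed(config$seed, "services"), {
    out <- lapply(rownames(means), function(s) {
      base <- matrix(means[s, landcover], nrow(landcover), ncol(landcover))
      if (config$noise_sd > 0) {
        base <- base + gauss_field(nrow(landcover), ncol(landcover),
                                   corr_len = config$corr_len,
                                   sd = config$noise_sd)
      }
      base
    })
    names(out) <- rownames(means)
    out
  })
}

#' Generate environmental and socioeconomic driver rasters
#'
#' DEM from a smoothed random surface; slope derived from the DEM;
#' temperature decreasing with elevation (6.5 degrees C per km lapse);
#' precipitation as a west-east gradient plus noise; GDP, population and
#' nightlight decaying with distance from impervious cells. Distances from
#' impervious/cropland are not generated here; they are computed downstream
#' by distance transform.
#'
#' @inheritParams generate_services
#' @return named list of numeric matrices: `dem`, `slope`, `temperature`,
#'   `precipitation`, `gdp`, `population`, `nightlight`.
#' @export
generate_drivers <- function(landcover, config) {
  stopifnot(inherits(config, "eca_config"),
            all(dim(landcover) == config$shape))
  nr <- nrow(landcover); nc <- ncol(landcover)
  withr::with_seed(substream_seed(config$seed, "drivers"), {
    dem <- 500 + 3000 * norm01(gauss_field(nr, nc, corr_len = 6, sd = 1))
    slope <- slope_from_dem(dem, config$cell_size)
    temperature <- 28 - 6.5 * dem / 1000 + gauss_field(nr, nc, 3, 0.5)
    precipitation <- pmax(0, 600 + 900 * matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE) +
                            gauss_field(nr, nc, 3, 60))
    imp <- landcover == eca_classes[["impervious"]]
    d_imp <- if (any(imp)) distance_to(imp, config$cell_size) else
      matrix(0, nr, nc)
    gdp <- pmax(0, 8 * exp(-d_imp / 2) + gauss_field(nr, nc, 2, 0.3))
    population <- pmax(0, 600 * exp(-d_imp / 1.5) + gauss_field(nr, nc, 2, 25))
    nightlight <- pmax(0, 63 * exp(-d_imp / 2) + gauss_field(nr, nc, 2, 2))
    list(dem = dem, slope = slope, temperature = temperature,
         precipitation = precipitation, gdp = gdp, population = population,
         nightlight = nightlight)
  })
}

#' Generate the analysis-unit (county) raster
#'
#' Rectangular tiling of the grid into `n_zones` contiguous blocks.
#'
#' @param config an [scenario_config()] object.
#' @return integer matrix of unit ids 1..n_zones.
#' @export
generate_zones <- function(config) {
  stopifnot(inherits(config, "eca_config"))
  n <- config$n_zones
  divs <- which(n %% seq_len(n) == 0)
  r <- divs[which.min(abs(divs - sqrt(n)))]
  cb <- n %/% r
  ri <- as.integer(cut(seq_len(config$shape[1]), r, labels = FALSE))
  ci <- as.integer(cut(seq_len(config$shape[2]), cb, labels = FALSE))
  matrix((ri - 1L), config$shape[1], config$shape[2]) * cb +
    matrix(ci, config$shape[1], config$shape[2], byrow = TRUE)
}

# ---- planted-change candidate sets -----------------------------------------

count_open_neighbours <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- M
  open <- matrix(0L, nr, nc)
  for (off in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    open <- open + !pad[2:(nr + 1L) + off[1], 2:(nc + 1L) + off[2], drop = FALSE]
  }
  open
}

# connected hole components (not touching the raster border, small)
hole_components <- function(M, max_size = 60) {
  holes <- label_components(!M, connectivity = 4)
  border <- unique(c(holes[1, ], holes[nrow(holes), ],
                     holes[, 1], holes[, ncol(holes)]))
  keep <- setdiff(setdiff(unique(as.vector(holes)), 0L), border)
  sizes <- table(holes[holes %in% keep])
  keep <- as.integer(names(sizes)[sizes <= max_size])
  holes[!(holes %in% keep)] <- 0L
  holes
}

cand_cells <- function(M, mode, type, cs) {
  eps <- 1e-9
  switch(paste(mode, type, sep = "_"),
    expansion_edge = which(!M & distance_to(M, cs) <= cs + eps),
    expansion_isolated = which(!M & distance_to(M, cs) > 3),
    # degradation starts at promontories: boundary cells with at least two
    # open 4-neighbours, whose loss reads as edge retreat (LEI <= 50) rather
    # than the loss of an enclosed core; tiny fragments are left to the
    # "isolated" rules
    degradation_edge = {
      labs <- label_components(M, 8)
      big <- tabulate(labs[labs > 0L])
      which(M & count_open_neighbours(M) >= 2L &
              matrix(big[pmax(labs, 1L)] >= 5, nrow(M), ncol(M)))
    },
    degradation_interior = which(M & distance_to(!M, cs) > 1.5 * cs),
    abort("unknown candidate type")
  )
}

# greedy selection keeping a minimum spacing (cells), used for interior
# degradation so removed cores keep intact surroundings
spaced_sample <- function(cells, n, nr, prob, min_d2 = 5) {
  ord <- sample(cells, length(cells), prob = prob)
  picked <- integer(0)
  for (cl in ord) {
    r <- ((cl - 1L) %% nr) + 1L; c <- ((cl - 1L) %/% nr) + 1L
    ok <- TRUE
    if (length(picked)) {
      pr <- ((picked - 1L) %% nr) + 1L; pc <- ((picked - 1L) %/% nr) + 1L
      ok <- all((pr - r)^2 + (pc - c)^2 >= min_d2)
    }
    if (ok) picked <- c(picked, cl)
    if (length(picked) == n) break
  }
  picked
}

#' Generate the full multi-period scenario with planted ground truth
#'
#' Builds the land cover, zones, drivers and per-period service stacks, plants
#' expansion/degradation change between consecutive periods by raising or
#' lowering service values on geometrically controlled cell sets, and boosts
#' the configured driver in the zones where change is preferentially planted
#' so the driver-attribution stage has a known signal to recover.
#'
#' @param config an [scenario_config()] object.
#' @return an object of class `eca_scenario`: list with elements `config`,
#'   `landcover`, `zones`, `drivers`, `services` (one stack per period) and
#'   `truth` (`true_eca` masks per period, `planted` tibble of planted sets
#'   with a `cells` list-column, `planted_driver`, per-zone `tendency`).
#' @export
generate_timeseries <- function(config) {
  stopifnot(inherits(config, "eca_config"))
  nr <- config$shape[1]; nc <- config$shape[2]; cs <- config$cell_size
  lc <- generate_landcover(config)
  zones <- generate_zones(config)
  drivers <- generate_drivers(lc, config)
  services0 <- generate_services(lc, config)
  np <- length(config$periods)

  withr::with_seed(substream_seed(config$seed, "timeseries"), {
    mask <- crit_core(config)
    # the urbanised corner is never critical, whatever the field says there
    blk0 <- urban_block(config, mask)
    mask[blk0$r, blk0$c] <- FALSE
    # carve interior holes (material for "interior" expansion rules)
    deep <- which(mask & distance_to(!mask, cs) > 3 * cs)
    if (length(deep)) {
      for (ctr in sample(deep, min(3L, length(deep)))) {
        r <- ((ctr - 1L) %% nr) + 1L; c <- ((ctr - 1L) %/% nr) + 1L
        rr <- pmax(1L, r - 1L):pmin(nr, r + 1L)
        cc <- pmax(1L, c - 1L):pmin(nc, c + 1L)
        mask[rr, cc] <- FALSE
      }
    }
    blk <- urban_block(config, crit_core(config))
    in_blk <- matrix(FALSE, nr, nc); in_blk[blk$r, blk$c] <- TRUE
    # transitional semi-natural belt: intermediate service levels on its own
    # smooth field, kept clear of the critical region (2-km margin) and the
    # urban corner, and static across periods
    tf <- gauss_field(nr, nc, corr_len = 6, sd = 1)
    trans_ok <- !mask & distance_to(mask, cs) > 2 * cs & !in_blk
    want <- round(config$trans_share * nr * nc)
    trans <- matrix(FALSE, nr, nc)
    elig <- which(trans_ok)
    if (length(elig) > want) {
      trans[elig[order(tf[elig], decreasing = TRUE)[seq_len(want)]]] <- TRUE
    } else trans[elig] <- TRUE
    # add small isolated critical blobs (material for "isolated" degradation
    # rules), away from the core, the urban corner and the belt
    far <- which(!mask & !in_blk & !trans & distance_to(mask, cs) > 5 * cs)
    placed <- integer(0)
    for (ctr in sample(far, length(far))) {
      if (length(placed) >= 2L) break
      r <- ((ctr - 1L) %% nr) + 1L; c <- ((ctr - 1L) %/% nr) + 1L
      if (r < 3 || c < 3 || r > nr - 2 || c > nc - 2) next
      if (any(trans[(r - 1L):(r + 1L), (c - 1L):(c + 1L)])) next
      if (length(placed)) {
        pr <- ((placed - 1L) %% nr) + 1L; pc <- ((placed - 1L) %/% nr) + 1L
        if (any((pr - r)^2 + (pc - c)^2 < 144)) next
      }
      mask[(r - 1L):(r + 1L), (c - 1L):(c + 1L)] <- TRUE
      placed <- c(placed, ctr)
    }

    # right-skewed criticality intensity: a hard floor at boost_base plus a
    # capped exponential excess, so critical cells are at least boost_base
    # above the hotspot ceiling but some are far richer; the cap keeps the
    # min-max normalisation of the service layers from being dominated by a
    # single extreme cell
    cap <- 3 * config$boost_spread
    u <- stats::runif(nr * nc) * (1 - exp(-cap / config$boost_spread))
    intensity <- config$boost_base +
      matrix(-config$boost_spread * log(1 - u), nr, nc)
    # per-service uplift on critical cells: raise the cell to a common
    # hotspot ceiling (1.0) regardless of its land-cover baseline, plus the
    # intensity excess; degradation subtracts the same amount, restoring the
    # class-conditioned baseline
    means <- service_class_means()
    uplift <- lapply(rownames(means), function(s) {
      (1.0 - matrix(means[s, lc], nr, nc)) + intensity
    })
    names(uplift) <- rownames(means)
    # transitional cells sit at a common intermediate ceiling with a gentle
    # shared jitter; always below every critical cell
    jit <- gauss_field(nr, nc, corr_len = 3, sd = 0.04)
    trans_uplift <- lapply(rownames(means), function(s) {
      (config$trans_level - matrix(means[s, lc], nr, nc)) + jit
    })
    names(trans_uplift) <- rownames(means)

    # per-zone evolution tendency (+1 expansion-prone, -1 degradation-prone),
    # stratified over the zones that can actually host boundary change so
    # both tendencies are always represented where change lands
    bz <- unique(zones[mask & count_open_neighbours(mask) >= 1L])
    tend <- rep(-1L, config$n_zones)
    if (length(bz) > 1L) tend[sample(bz, ceiling(length(bz) / 2))] <- 1L
    oz <- setdiff(seq_len(config$n_zones), bz)
    if (length(oz) > 1L) tend[sample(oz, floor(length(oz) / 2))] <- 1L

    masks <- vector("list", np); names(masks) <- config$periods
    services <- vector("list", np); names(services) <- config$periods
    masks[[1]] <- mask
    services[[1]] <- lapply(names(services0), function(s) {
      services0[[s]] + uplift[[s]] * mask + trans_uplift[[s]] * trans
    })
    names(services[[1]]) <- names(services0)
    planted <- list()

    for (i in seq_len(np - 1L)) {
      M <- masks[[i]]
      cur <- M
      svc <- services[[i]]
      pair_lab <- c(config$periods[i], config$periods[i + 1L])
      rules <- Filter(function(r) identical(r$pair, pair_lab), config$change_rules)
      taken <- matrix(FALSE, nr, nc)
      for (ru in rules) {
        n_req <- max(1L, round(ru$magnitude * sum(M)))
        sign <- if (ru$mode == "expansion") 1L else -1L
        if (ru$mode == "degradation" && ru$type == "isolated") {
          labs <- label_components(M, 8)
          comp_ids <- setdiff(unique(as.vector(labs)), 0L)
          iso <- integer(0)
          for (k in comp_ids) {
            rest <- M & labs != k
            if (!any(rest)) next
            if (min(distance_to(rest, cs)[labs == k]) > 3) iso <- c(iso, k)
          }
          if (!length(iso)) abort("no isolated ECA component available for degradation rule")
          # prefer components sitting in degradation-prone zones
          wk <- vapply(iso, function(k) {
            if (mean(tend[zones[labs == k]] == sign) > 0.5) 1e6 else 1
          }, numeric(1))
          ord <- if (length(iso) == 1L) iso else sample(iso, length(iso), prob = wk)
          pick <- integer(0)
          for (k in ord) {
            pick <- c(pick, which(labs == k))
            if (length(pick) >= n_req) break
          }
          sel <- pick
        } else if (ru$mode == "expansion" && ru$type == "interior") {
          # fill whole holes so the new patch is enclosed by original ECA
          holes <- hole_components(M)
          ids <- setdiff(unique(as.vector(holes)), 0L)
          if (!length(ids)) abort("no interior hole available for expansion rule")
          pick <- integer(0)
          for (k in sample(ids, length(ids))) {
            pick <- c(pick, which(holes == k))
            if (length(pick) >= n_req) break
          }
          sel <- pick
        } else {
          cands <- setdiff(cand_cells(M, ru$mode, ru$type, cs), which(taken))
          if (ru$mode == "expansion") cands <- setdiff(cands, which(trans))
          if (length(cands) < n_req) {
            abort(sprintf("change rule %s/%s: requested %d cells but only %d available",
                          ru$mode, ru$type, n_req, length(cands)))
          }
          # near-exclusive preference for matching-tendency zones: a single
          # off-tendency cell would flip that unit's dominant-mode label
          w <- ifelse(tend[zones[cands]] == sign, 1e6, 1)
          if (ru$type %in% c("edge", "interior")) {
            # spaced picks keep planted cells from chaining into merged
            # patches whose aggregate LEI would sit on the 50 knife-edge;
            # edge picks are spaced so their buffers never merge at all
            sel <- spaced_sample(cands, n_req, nr, w,
                                 min_d2 = if (ru$type == "edge") 10 else 5)
            if (length(sel) < n_req) {
              abort(sprintf("%s %s rule: requested %d cells but only %d spaced candidates",
                            ru$mode, ru$type, n_req, length(sel)))
            }
          } else {
            sel <- sample(cands, n_req, prob = w)
          }
        }
        taken[sel] <- TRUE
        cur[sel] <- ru$mode == "expansion"
        for (s in names(svc)) {
          svc[[s]][sel] <- svc[[s]][sel] + sign * uplift[[s]][sel]
        }
        planted[[length(planted) + 1L]] <- list(
          set = length(planted) + 1L, pair = paste(pair_lab, collapse = "-"),
          mode = ru$mode, type = ru$type, cells = sel
        )
      }
      masks[[i + 1L]] <- cur
      services[[i + 1L]] <- svc
    }

    eff <- config$driver_effect
    if (!is.null(eff$driver) && eff$driver %in% names(drivers)) {
      dmat <- drivers[[eff$driver]]
      tmat <- matrix(tend[zones], nr, nc)
      drivers[[eff$driver]] <- dmat +
        eff$direction * eff$strength * stats::sd(as.vector(dmat)) * tmat
    }

    planted_tbl <- tibble(
      set = vapply(planted, `[[`, integer(1), "set"),
      pair = vapply(planted, `[[`, character(1), "pair"),
      mode = vapply(planted, `[[`, character(1), "mode"),
      type = vapply(planted, `[[`, character(1), "type"),
      n_cells = vapply(planted, function(p) length(p$cells), integer(1)),
      cells = lapply(planted, `[[`, "cells")
    )

    structure(list(
      config = config, landcover = lc, zones = zones, drivers = drivers,
      services = services,
      truth = list(true_eca = masks, planted = planted_tbl,
                   planted_driver = eff$driver, tendency = tend)
    ), class = "eca_scenario")
  })
}

#' @export
print.eca_scenario <- function(x, ...) {
  cat(sprintf("<eca_scenario> %dx%d cells, %d zones, periods: %s\n",
              x$config$shape[1], x$config$shape[2], x$config$n_zones,
              paste(x$config$periods, collapse = ", ")))
  cat(sprintf("  planted change sets: %d; planted driver: %s\n",
              nrow(x$truth$planted), x$truth$planted_driver %||% "<none>"))
  invisible(x)
}
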