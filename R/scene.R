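# Synthetic landscape scenes: a seeded generator producing paired categorical
# rasters (opening/closing date), a watershed partition, a protection layer, a
# river network and deterministic per-SELU account line items, so that every
# downstream account can be tested against constructed ground truth.

#' Configuration for a synthetic scene
#'
#' @param grid_shape Integer vector `c(rows, cols)` in pixels.
#' @param pixel_area Pixel area in hectares (default 0.0225 ha = 15 m pixels).
#' @param palette Land-cover nomenclature, see [default_palette()].
#' @param class_params Per-class parameters, see [default_class_params()].
#' @param n_watersheds Number of sub-watersheds partitioning the grid.
#' @param protection List with `fraction` (target share of area inside the
#'   hard-core protection zone) and `weight` (high-nature-value multiplier
#'   inside the zone, >= 1).
#' @param climate List with `Pavg` (mm/yr long-run precipitation), `ETravg`
#'   (mm/yr long-run evapotranspiration) and `P_series` (mm per accounting
#'   period, length 2: opening then closing date).
#' @param etr_orientation Orientation of the evapotranspiration ratio, see
#'   [estimate_etr()].
#' @param n_patches Number of contiguous land-cover patches grown on the grid;
#'   default scales with grid size.
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(grid_shape = c(60L, 60L),
                         pixel_area = 0.0225,
                         palette = default_palette(),
                         class_params = default_class_params(),
                         n_watersheds = 7L,
                         protection = list(fraction = 0.25, weight = 1.14),
                         climate = list(Pavg = 1554, ETravg = 1300,
                                        P_series = c(1554, 1480)),
                         etr_orientation = "inverted",
                         n_patches = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(!is.finite(grid_shape)) ||
      any(grid_shape < 2L)) {
    stop("'grid_shape' must be two integers >= 2", call. = FALSE)
  }
  if (!is.numeric(pixel_area) || pixel_area <= 0) {
    stop("'pixel_area' must be > 0", call. = FALSE)
  }
  if (is.null(palette) || nrow(palette) == 0L) {
    stop("'palette' must contain at least one class", call. = FALSE)
  }
  class_params <- class_params[class_params$class_id %in% palette$class_id, ]
  missing <- setdiff(palette$class_id, class_params$class_id)
  if (length(missing) > 0L) {
    stop("no class parameters for class id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(class_params$greenness < 0 | class_params$greenness > 100)) {
    stop("greenness weights must lie in [0, 100]", call. = FALSE)
  }
  dens <- c(class_params$agb_tc_ha, class_params$soc_tc_ha,
            class_params$npp_tc_ha)
  if (any(dens < 0)) stop("carbon densities must be >= 0", call. = FALSE)
  n_watersheds <- as.integer(n_watersheds)
  if (n_watersheds < 1L) stop("'n_watersheds' must be >= 1", call. = FALSE)
  if (length(climate$P_series) == 1L) {
    climate$P_series <- rep(climate$P_series, 2L)
  }
  if (is.null(n_patches)) {
    n_patches <- max(nrow(palette), round(prod(grid_shape) / 80))
  }
  structure(
    list(grid_shape = grid_shape, pixel_area = pixel_area,
         palette = palette, class_params = class_params,
         n_watersheds = n_watersheds, protection = protection,
         climate = climate, etr_orientation = etr_orientation,
         n_patches = as.integer(n_patches), seed = as.integer(seed)),
    class = "scene_config"
  )
}

# 4-neighbour indices of linear (column-major) pixel indices
neighbours4 <- function(idx, nr, nc) {
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  out <- c(ifelse(r > 1L, idx - 1L, NA_integer_),
           ifelse(r < nr, idx + 1L, NA_integer_),
           ifelse(c > 1L, idx - nr, NA_integer_),
           ifelse(c < nc, idx + nr, NA_integer_))
  out[!is.na(out)]
}

# Voronoi partition of the grid: each pixel labelled by its nearest seed
# point (squared Euclidean distance on pixel centres, ties to the lowest id).
voronoi_partition <- function(nr, nc, seeds_rc) {
  px_r <- rep(seq_len(nr), times = nc)
  px_c <- rep(seq_len(nc), each = nr)
  best <- rep(1L, nr * nc)
  bestd <- (px_r - seeds_rc[1, 1])^2 + (px_c - seeds_rc[1, 2])^2
  if (nrow(seeds_rc) > 1L) {
    for (k in 2:nrow(seeds_rc)) {
      d <- (px_r - seeds_rc[k, 1])^2 + (px_c - seeds_rc[k, 2])^2
      upd <- d < bestd
      best[upd] <- k
      bestd[upd] <- d[upd]
    }
  }
  matrix(best, nr, nc)
}

# Seeded region growing: multi-source randomized BFS from one seed pixel per
# patch, producing contiguous patches that tile the grid.
grow_patches <- function(nr, nc, n_patches) {
  npix <- nr * nc
  n_patches <- min(n_patches, npix)
  seeds <- sample.int(npix, n_patches)
  label <- integer(npix)
  label[seeds] <- seq_len(n_patches)
  frontier <- as.list(seeds)
  active <- rep(TRUE, n_patches)
  while (any(active)) {
    act <- which(active)
    for (p in act[sample.int(length(act))]) {
      cand <- frontier[[p]]
      nb <- unique(unlist(lapply(cand, neighbours4, nr = nr, nc = nc)))
      nb <- nb[label[nb] == 0L]
      if (length(nb) == 0L) {
        active[p] <- FALSE
        frontier[[p]] <- integer()
      } else {
        # claim a random subset each round for irregular boundaries; skipped
        # neighbours stay reachable because the frontier keeps its cells
        take <- nb[stats::runif(length(nb)) < 0.8]
        if (length(take) == 0L) take <- nb[1L]
        label[take] <- p
        keep <- cand[vapply(cand, function(i) {
          any(label[neighbours4(i, nr, nc)] == 0L)
        }, logical(1))]
        frontier[[p]] <- c(keep, take)
      }
    }
  }
  stopifnot(all(label > 0L))
  matrix(label, nr, nc)
}

# Minimum spanning tree over watershed centroids (Prim), oriented towards the
# outlet (northernmost centroid). Returns a data frame of river segments with
# per-segment length (km) and discharge (m3/s) growing downstream.
build_rivers <- function(watersheds, cellsize_m = 15) {
  ids <- sort(unique(as.vector(watersheds)))
  n <- length(ids)
  cent <- t(vapply(ids, function(i) {
    w <- which(watersheds == i, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  root <- which.min(cent[, 1])
  parent <- rep(NA_integer_, n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(cent))
    in_tree <- rep(FALSE, n)
    in_tree[root] <- TRUE
    for (step in seq_len(n - 1L)) {
      dd <- d
      dd[, !in_tree] <- Inf
      dd[in_tree, ] <- Inf
      pick <- arrayInd(which.min(dd), dim(dd))
      parent[pick[1]] <- pick[2]
      in_tree[pick[1]] <- TRUE
    }
  }
  subtree <- function(i) 1L + sum(vapply(which(parent == i), subtree, 1L))
  sizes <- vapply(seq_len(n), subtree, 1L)
  inner <- which(!is.na(parent))
  # the outlet watershed drains to the sea (to_ws = 0)
  seg <- data.frame(
    segment_id = seq_len(length(inner) + 1L),
    from_ws = c(ids[inner], ids[root]),
    to_ws = c(ids[parent[inner]], 0L),
    length_km = c(
      if (n > 1L) d[cbind(inner, parent[inner])] * cellsize_m / 1000,
      max(1, cent[root, 1] * cellsize_m / 1000)
    ),
    # discharge grows with the drained subtree; the 2 m3/s floor keeps
    # log10(discharge) positive even after dry-period rescaling
    discharge = 2 * c(sizes[inner], n)
  )
  seg
}

#' Generate a synthetic scene
#'
#' Produces a deterministic (for a fixed seed) synthetic study area: an
#' opening land-cover raster grown as contiguous patches, an identical closing
#' raster (edit it with [apply_change_scenario()]), a watershed partition of
#' the grid, a protection (high-nature-value) layer, a river network, and
#' per-SELU water and carbon line items derived from the rasters and climate.
#'
#' @param config A [scene_config()].
#' @return Object of class `enca_scene` with elements `opening`, `closing`
#'   (integer class rasters), `watersheds` (label raster), `hnvi` (multiplier
#'   raster), `rivers` (segment data frame), `truth` (transition counts and
#'   flow totals) and `line_items` (per-date water and carbon tables).
#' @export
#' @examples
#' sc <- generate_scene(scene_config(grid_shape = c(20, 20), seed = 42))
#' table(sc$opening)
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) {
    stop("'config' must be a scene_config object", call. = FALSE)
  }
  set.seed(config$seed)
  nr <- config$grid_shape[1]
  nc <- config$grid_shape[2]
  npix <- nr * nc

  # watershed partition: Voronoi cells of random seed points
  ws_seeds <- cbind(sample.int(nr, config$n_watersheds, replace = TRUE),
                    sample.int(nc, config$n_watersheds, replace = TRUE))
  while (anyDuplicated(ws_seeds)) {
    ws_seeds <- cbind(sample.int(nr, config$n_watersheds, replace = TRUE),
                      sample.int(nc, config$n_watersheds, replace = TRUE))
  }
  watersheds <- voronoi_partition(nr, nc, ws_seeds)

  # land cover: contiguous patches, every palette class present when possible
  patches <- grow_patches(nr, nc, config$n_patches)
  k <- nrow(config$palette)
  n_pat <- max(patches)
  ids_pool <- config$palette$class_id
  resample <- function(x, ...) x[sample.int(length(x), ...)]
  pclass <- integer(n_pat)
  first <- resample(ids_pool, k)
  take <- min(k, n_pat)
  pclass[seq_len(take)] <- first[seq_len(take)]
  if (n_pat > k) {
    pclass[(k + 1):n_pat] <- resample(ids_pool, n_pat - k, replace = TRUE)
  }
  opening <- matrix(pclass[patches], nr, nc)

  # protection hard core: watersheds with most woody habitat, up to the
  # target area fraction
  tree_ids <- config$class_params$class_id[config$class_params$tree]
  ws_ids <- sort(unique(as.vector(watersheds)))
  woody <- vapply(ws_ids, function(i) {
    sum(opening[watersheds == i] %in% tree_ids)
  }, numeric(1))
  size <- vapply(ws_ids, function(i) sum(watersheds == i), numeric(1))
  ord <- order(woody / size, decreasing = TRUE)
  cum <- cumsum(size[ord]) / npix
  n_prot <- which(cum >= config$protection$fraction)[1]
  if (is.na(n_prot)) n_prot <- length(ws_ids)
  protected_ws <- ws_ids[ord[seq_len(n_prot)]]
  hnvi <- matrix(1, nr, nc)
  hnvi[watersheds %in% protected_ws] <- config$protection$weight

  rivers <- build_rivers(watersheds)

  scene <- structure(
    list(config = config, opening = opening, closing = opening,
         watersheds = watersheds, hnvi = hnvi, rivers = rivers,
         protected_ws = protected_ws),
    class = "enca_scene"
  )
  scene$truth <- scene_truth(scene)
  scene$line_items <- list(
    water = list(opening = scene_water_items(scene, "opening"),
                 closing = scene_water_items(scene, "closing")),
    carbon = list(opening = scene_carbon_items(scene, "opening"),
                  closing = scene_carbon_items(scene, "closing"))
  )
  scene
}

scene_truth <- function(scene) {
  tm <- cross_tabulate(scene$opening, scene$closing,
                       pixel_area = scene$config$pixel_area,
                       palette = scene$config$palette)
  rules <- default_flow_rules(scene$config$palette)
  fa <- classify_flows(tm, rules)
  list(transitions = tm$counts,
       flow_totals = rowSums(fa$formation))
}

#' @export
print.enca_scene <- function(x, ...) {
  cat("Synthetic scene:", paste(x$config$grid_shape, collapse = " x "),
      "pixels,", nrow(x$config$palette), "classes,",
      x$config$n_watersheds, "watersheds\n")
  changed <- sum(x$opening != x$closing, na.rm = TRUE)
  cat("Changed pixels opening -> closing:", changed,
      sprintf("(%.1f ha)\n", changed * x$config$pixel_area))
  invisible(x)
}

#' @export
plot.enca_scene <- function(x, which = c("opening", "closing", "watersheds"),
                            ...) {
  which <- match.arg(which)
  m <- x[[which]]
  image(t(m[nrow(m):1, , drop = FALSE]), axes = FALSE, main = which, ...)
  invisible(x)
}

#' Apply a change scenario to a synthetic scene
#'
#' Converts the requested number of (still unchanged) pixels of each origin
#' class to the destination class in the closing raster, then refreshes the
#' scene's ground-truth transition counts, flow totals and closing-date line
#' items. Pixel choice is seeded from the scene configuration, so the same
#' scene and scenario always give the same closing raster.
#'
#' @param scene An `enca_scene`.
#' @param scenario Data frame with columns `from`, `to` (class ids) and
#'   `n_pixels`.
#' @return The modified scene.
#' @export
apply_change_scenario <- function(scene, scenario) {
  stopifnot(inherits(scene, "enca_scene"))
  if (nrow(scenario) == 0L) return(scene)
  need <- c("from", "to", "n_pixels")
  if (!all(need %in% names(scenario))) {
    stop("'scenario' needs columns from, to, n_pixels", call. = FALSE)
  }
  ids <- scene$config$palette$class_id
  bad <- setdiff(c(scenario$from, scenario$to), ids)
  if (length(bad) > 0L) {
    stop("scenario uses class id(s) outside the palette: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  # oversubscription check against *unchanged* pixels available per class
  avail <- vapply(unique(scenario$from), function(cl) {
    sum(scene$closing == cl & scene$opening == scene$closing)
  }, numeric(1))
  names(avail) <- unique(scenario$from)
  asked <- tapply(scenario$n_pixels, scenario$from, sum)
  short <- asked - avail[names(asked)]
  if (any(short > 0)) {
    s <- short[short > 0]
    stop("scenario oversubscribes class(es): ",
         paste(sprintf("class %s short by %d pixels", names(s), as.integer(s)),
               collapse = "; "), call. = FALSE)
  }
  set.seed(scene$config$seed + 7919L)
  closing <- scene$closing
  for (i in seq_len(nrow(scenario))) {
    pool <- which(closing == scenario$from[i] & scene$opening == closing)
    pick <- if (length(pool) == 1L) pool else
      sample(pool, scenario$n_pixels[i])
    closing[pick] <- scenario$to[i]
  }
  scene$closing <- closing
  scene$truth <- scene_truth(scene)
  scene$line_items$water$closing <- scene_water_items(scene, "closing")
  scene$line_items$carbon$closing <- scene_carbon_items(scene, "closing")
  scene
}

# ---- deterministic line-item synthesis -------------------------------------

# Sum of named vector entries for keys that exist (toy palettes may lack some
# classes).
area_of <- function(a, keys) sum(a[intersect(as.character(keys), names(a))])

# Areas (ha) per land-cover class within each watershed.
zonal_class_areas <- function(raster, zones, pixel_area, class_ids) {
  zid <- sort(unique(as.vector(zones[!is.na(zones)])))
  tab <- table(factor(as.vector(raster), levels = class_ids),
               factor(as.vector(zones), levels = zid))
  m <- matrix(as.numeric(tab), nrow = length(class_ids),
              dimnames = list(class_ids, zid))
  m * pixel_area
}

# Stylized per-hectare abstraction rates (1000 m3 / ha / yr) by class.
abstraction_rates <- function(class_ids) {
  r <- stats::setNames(rep(0.2, length(class_ids)), class_ids)
  r[intersect(c("11"), names(r))] <- 20
  r[intersect(c("21", "31"), names(r))] <- 8
  r[intersect(c("41"), names(r))] <- 6
  r[intersect(c("131"), names(r))] <- 1
  r[intersect(c("101", "102"), names(r))] <- 0
  r
}

scene_water_items <- function(scene, date = c("opening", "closing")) {
  date <- match.arg(date)
  cfg <- scene$config
  di <- if (date == "opening") 1L else 2L
  P <- cfg$climate$P_series[di]
  ratio <- if (identical(cfg$etr_orientation, "as_printed")) {
    cfg$climate$Pavg / cfg$climate$ETravg
  } else {
    cfg$climate$ETravg / cfg$climate$Pavg
  }
  ETr <- ratio * P
  raster <- scene[[date]]
  areas <- zonal_class_areas(raster, scene$watersheds, cfg$pixel_area,
                             cfg$palette$class_id)
  ws_ids <- as.integer(colnames(areas))
  rates <- abstraction_rates(rownames(areas))
  A <- colSums(areas)

  # mass-consistent routing: each watershed's runoff (effective rainfall)
  # accumulates down the river tree; W3_3 is its total outflow and W2_3 the
  # inflow received from upstream neighbours
  runoff <- stats::setNames(A * max(P - ETr, 0) / 100, ws_ids)
  outflow <- stats::setNames(rep(NA_real_, length(ws_ids)), ws_ids)
  calc_out <- function(ws) {
    key <- as.character(ws)
    if (!is.na(outflow[key])) return(outflow[key])
    kids <- scene$rivers$from_ws[scene$rivers$to_ws == ws]
    val <- runoff[key] + sum(vapply(kids, calc_out, numeric(1)))
    outflow[key] <<- val
    val
  }
  for (ws in ws_ids) calc_out(ws)

  items <- lapply(seq_along(ws_ids), function(j) {
    ws <- ws_ids[j]
    key <- as.character(ws)
    a <- areas[, j]
    riv_out <- scene$rivers[scene$rivers$from_ws == ws, , drop = FALSE]
    W2_1 <- unname(A[key]) * P / 100
    W3_1 <- unname(A[key]) * ETr / 100
    W3_3 <- unname(outflow[key])
    W2_3 <- W3_3 - unname(runoff[key])
    W3_4 <- sum(a * rates)
    vals <- c(
      W1_1 = area_of(a, 131) * 20,
      W1_2 = sum(riv_out$length_km) * 20,
      W1_4 = unname(A[key]) * 5,
      W1_5 = unname(A[key]) * 1,
      W2_1 = W2_1,
      W2_2 = -0.1 * W2_1,          # net percolation loss to deep groundwater
      W2_3 = W2_3,
      W2_4 = 0.05 * W3_4,
      W2_5 = 0.002 * W3_4,
      W2_6 = 0.2 * W3_4,
      W3_1 = W3_1,
      W3_3 = W3_3,
      W3_4 = W3_4,
      W3_8 = 0.01 * W3_4,
      W14 = 0.95
    )
    data.frame(selu_id = ws_label(ws), code = names(vals), value = unname(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, items)
}

scene_carbon_items <- function(scene, date = c("opening", "closing")) {
  date <- match.arg(date)
  cfg <- scene$config
  raster <- scene[[date]]
  areas <- zonal_class_areas(raster, scene$watersheds, cfg$pixel_area,
                             cfg$palette$class_id)
  ws_ids <- as.integer(colnames(areas))
  par <- cfg$class_params[match(as.integer(rownames(areas)),
                                cfg$class_params$class_id), ]
  tree <- par$tree
  items <- lapply(seq_along(ws_ids), function(j) {
    ws <- ws_ids[j]
    a <- areas[, j]
    agb <- sum(a * par$agb_tc_ha)
    C1_1 <- agb
    C1_2 <- sum(a * par$agb_tc_ha * par$litter_frac)
    C1_31 <- sum(a * par$agb_tc_ha * par$root_shoot)
    C1_32 <- sum(a * par$soc_tc_ha)
    C1_4 <- 0.015 * area_of(a, c(51, 21, 41))
    C2_3 <- sum(a * par$npp_tc_ha)
    C3_11 <- 0.8 * area_of(a, 21)
    C3_13 <- 3.0 * area_of(a, 31)
    C3_199 <- 0.5 * area_of(a, 41)
    C3_3 <- 0.8 * area_of(a, c(51, 71))
    C3_4 <- 1.2 * sum(a[tree])
    C4_33 <- 0.1 * C3_4
    C4_34 <- 0.02 * C2_3
    C5 <- C3_11 + C3_13 + C3_199 + C3_3 + C3_4 + C4_33 + C4_34
    pf <- mean(scene$watersheds == ws & scene$hnvi > 1) /
      mean(scene$watersheds == ws)
    vals <- c(C1_1 = C1_1, C1_2 = C1_2, C1_31 = C1_31, C1_32 = C1_32,
              C1_4 = C1_4, C2_3 = C2_3,
              C3_11 = C3_11, C3_13 = C3_13, C3_199 = C3_199, C3_3 = C3_3,
              C3_4 = C3_4, C4_33 = C4_33, C4_34 = C4_34,
              C10_1 = max(0, C2_3 - C5),
              C10_2 = 0.7 * (1 - pf) + 0.1 * pf,
              CEH = 1)
    data.frame(selu_id = ws_label(ws), code = names(vals), value = unname(vals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, items)
}

ws_label <- function(ws) sprintf("WS%02d", as.integer(ws))

# ---- scene serialization ---------------------------------------------------

#' Write a scene to a directory of plain-text files
#'
#' Rasters go to Esri ASCII grids, the river network to GeoJSON, line items to
#' CSV and the configuration to YAML. [read_scene()] round-trips the result.
#'
#' @param scene An `enca_scene`.
#' @param dir Output directory (created if absent).
#' @return Data frame manifest with columns `file` and `kind`, invisibly
#'   returned by `read_scene` consumers; `write_scene` returns it visibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "enca_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cellsize <- sqrt(scene$config$pixel_area * 1e4)
  rasters <- c("opening", "closing", "watersheds", "hnvi")
  for (r in rasters) {
    write_ascii_grid(scene[[r]], file.path(dir, paste0(r, ".asc")),
                     cellsize = cellsize)
  }
  riv <- scene$rivers
  features <- lapply(seq_len(nrow(riv)), function(i) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(0, 0), c(riv$length_km[i], 0))),
         properties = as.list(riv[i, ]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    file.path(dir, "rivers.geojson"), auto_unbox = TRUE, digits = NA
  )
  for (acct in c("water", "carbon")) {
    for (d in c("opening", "closing")) {
      utils::write.csv(scene$line_items[[acct]][[d]],
                       file.path(dir, sprintf("%s_%s.csv", acct, d)),
                       row.names = FALSE)
    }
  }
  cfg <- scene$config
  yaml::write_yaml(
    list(grid_shape = cfg$grid_shape, pixel_area = cfg$pixel_area,
         n_watersheds = cfg$n_watersheds, protection = cfg$protection,
         climate = cfg$climate, etr_orientation = cfg$etr_orientation,
         n_patches = cfg$n_patches, seed = cfg$seed),
    file.path(dir, "config.yml")
  )
  utils::write.csv(cfg$palette, file.path(dir, "palette.csv"),
                   row.names = FALSE)
  utils::write.csv(cfg$class_params, file.path(dir, "class_params.csv"),
                   row.names = FALSE)
  manifest <- data.frame(
    file = c(paste0(rasters, ".asc"), "rivers.geojson",
             "water_opening.csv", "water_closing.csv",
             "carbon_opening.csv", "carbon_closing.csv",
             "config.yml", "palette.csv", "class_params.csv"),
    kind = c(rep("raster", 4), "vector", rep("line_items", 4),
             "config", "config", "config"),
    stringsAsFactors = FALSE
  )
  manifest
}

#' Read a scene back from a directory written by [write_scene()]
#'
#' @param dir Directory containing the scene files.
#' @return An `enca_scene`; ground-truth transition counts are recomputed from
#'   the rasters on read.
#' @export
read_scene <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yml"))
  palette <- utils::read.csv(file.path(dir, "palette.csv"),
                             stringsAsFactors = FALSE)
  class_params <- utils::read.csv(file.path(dir, "class_params.csv"),
                                  stringsAsFactors = FALSE)
  cfg <- scene_config(
    grid_shape = unlist(cfg_raw$grid_shape),
    pixel_area = cfg_raw$pixel_area,
    palette = palette, class_params = class_params,
    n_watersheds = cfg_raw$n_watersheds,
    protection = cfg_raw$protection,
    climate = list(Pavg = cfg_raw$climate$Pavg,
                   ETravg = cfg_raw$climate$ETravg,
                   P_series = unlist(cfg_raw$climate$P_series)),
    etr_orientation = cfg_raw$etr_orientation,
    n_patches = cfg_raw$n_patches,
    seed = cfg_raw$seed
  )
  rasters <- lapply(c("opening", "closing", "watersheds", "hnvi"),
                    function(r) read_ascii_grid(file.path(dir,
                                                          paste0(r, ".asc"))))
  names(rasters) <- c("opening", "closing", "watersheds", "hnvi")
  gj <- jsonlite::fromJSON(file.path(dir, "rivers.geojson"),
                           simplifyDataFrame = TRUE)
  rivers <- if (length(gj$features) == 0) {
    data.frame(segment_id = integer(), from_ws = integer(),
               to_ws = integer(), length_km = numeric(),
               discharge = numeric())
  } else {
    gj$features$properties
  }
  line_items <- list(
    water = list(
      opening = utils::read.csv(file.path(dir, "water_opening.csv"),
                                stringsAsFactors = FALSE),
      closing = utils::read.csv(file.path(dir, "water_closing.csv"),
                                stringsAsFactors = FALSE)),
    carbon = list(
      opening = utils::read.csv(file.path(dir, "carbon_opening.csv"),
                                stringsAsFactors = FALSE),
      closing = utils::read.csv(file.path(dir, "carbon_closing.csv"),
                                stringsAsFactors = FALSE))
  )
  scene <- structure(
    list(config = cfg,
         opening = rasters$opening, closing = rasters$closing,
         watersheds = rasters$watersheds, hnvi = rasters$hnvi,
         rivers = rivers,
         protected_ws = sort(unique(
           rasters$watersheds[rasters$hnvi > 1 & !is.na(rasters$hnvi)]))),
    class = "enca_scene"
  )
  scene$truth <- scene_truth(scene)
  scene$line_items <- line_items
  scene
}
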