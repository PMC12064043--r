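# Ecosystem infrastructure functional services: landscape indices (green
# background landscape index, high-nature-value multiplier, fragmentation
# from effective mesh size plus patch count and tree-cover ratio), river
# indices (length x log10 discharge accessibility, river HNV, dam-based
# fragmentation), their composites LEP/REP, the area-integrated potentials
# NLEP/NREP, and the account with use intensity (EISU) and internal unit
# value (EIIUV).

#' Green background landscape index per SELU
#'
#' Area-weighted (i.e. per-pixel) mean of the per-class greenness weights
#' (0-100 scale) over each watershed.
#'
#' @param raster Integer land-cover matrix.
#' @param watersheds Integer label matrix, same shape.
#' @param weights Named numeric vector of greenness weights keyed by class
#'   id, each in `[0, 100]`; must cover every class present.
#' @return Named numeric vector, one GBLI value per watershed id.
#' @export
gbli <- function(raster, watersheds, weights) {
  present <- unique(raster[!is.na(raster)])
  missing <- setdiff(as.character(present), names(weights))
  if (length(missing) > 0L) {
    stop("no greenness weight for class id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(weights < 0 | weights > 100)) {
    stop("greenness weights must lie in [0, 100]", call. = FALSE)
  }
  g <- matrix(weights[as.character(raster)], nrow(raster), ncol(raster))
  ids <- sort(unique(as.vector(watersheds[!is.na(watersheds)])))
  vapply(ids, function(ws) {
    mean(g[watersheds == ws & !is.na(raster)])
  }, numeric(1), USE.NAMES = FALSE) -> out
  stats::setNames(out, ids)
}

#' Label contiguous habitat patches
#'
#' Connected components of the TRUE cells of a logical mask under rook
#' (4-neighbour) adjacency, via an igraph component search.
#'
#' @param mask Logical matrix; `NA` treated as FALSE.
#' @return Integer matrix of patch labels (`NA` outside the mask).
#' @export
label_patches <- function(mask) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(NA_integer_, nr, nc)
  if (length(idx) == 0L) return(out)
  # edges between vertically and horizontally adjacent TRUE cells
  r <- ((idx - 1L) %% nr) + 1L
  down <- idx[r < nr & mask[pmin(idx + 1L, nr * nc)]]
  right <- idx[idx + nr <= nr * nc]
  right <- right[mask[right + nr]]
  edges <- rbind(cbind(down, down + 1L), cbind(right, right + nr))
  vids <- match(c(edges[, 1], edges[, 2]), idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, rbind(vids[seq_len(nrow(edges))],
                                    vids[nrow(edges) + seq_len(nrow(edges))]))
  }
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

#' Effective mesh size
#'
#' Jaeger's effective mesh size: `meff = sum(A_i^2) / A_total`, the expected
#' area of the patch containing a uniformly random point of the landscape.
#' Splitting any patch can only decrease it; a single patch covering the
#' whole landscape gives `meff = A_total` and `n` equal patches tiling it
#' give `A_total / n`.
#'
#' @param patch_areas Numeric vector of patch areas (>= 0).
#' @param total_area Total landscape area, > 0.
#' @return Effective mesh size in the units of `patch_areas`.
#' @export
#' @examples
#' effective_mesh_size(c(4, 1), 10) # (16 + 1) / 10 = 1.7
effective_mesh_size <- function(patch_areas, total_area) {
  if (!is.numeric(total_area) || total_area <= 0) {
    stop("'total_area' must be > 0", call. = FALSE)
  }
  if (any(patch_areas < 0)) stop("patch areas must be >= 0", call. = FALSE)
  if (sum(patch_areas) > total_area * (1 + 1e-9)) {
    stop("patch areas exceed the total area", call. = FALSE)
  }
  sum(patch_areas^2) / total_area
}

#' Landscape fragmentation index
#'
#' Mean of three components, each normalized to `[0, 1]` with 1 = intact:
#' the effective mesh size divided by the landscape area, the reciprocal of
#' the habitat patch count (1 for a single patch, 0 when no habitat), and
#' the tree-cover to basin-area ratio (clamped to `[0, 1]`).
#'
#' @param meff_norm,patch_count_norm,tree_ratio Components in `[0, 1]`.
#' @return Index in `[0, 1]`; higher = less fragmented.
#' @export
fragmentation_index <- function(meff_norm, patch_count_norm, tree_ratio) {
  comp <- c(meff_norm, patch_count_norm, tree_ratio)
  if (any(comp < 0 | comp > 1)) {
    stop("fragmentation components must lie in [0, 1]", call. = FALSE)
  }
  (meff_norm + patch_count_norm + tree_ratio) / 3
}

#' Fragmentation index of one SELU from a land-cover raster
#'
#' Computes the three components of [fragmentation_index()] from the woody
#' (tree-flagged) habitat mask inside one watershed.
#'
#' @param raster Integer land-cover matrix.
#' @param watersheds Label matrix.
#' @param ws Watershed id.
#' @param tree_classes Class ids counting as tree-covered habitat.
#' @param pixel_area Pixel area in ha.
#' @return List with `meff_norm`, `patch_count_norm`, `tree_ratio`, `FI`.
#' @export
selu_fragmentation <- function(raster, watersheds, ws, tree_classes,
                               pixel_area = 0.0225) {
  inside <- watersheds == ws & !is.na(raster)
  A <- sum(inside) * pixel_area
  if (A <= 0) stop("watershed ", ws, " has no valid pixels", call. = FALSE)
  mask <- inside & matrix(raster %in% tree_classes, nrow(raster))
  lab <- label_patches(mask)
  areas <- as.numeric(table(lab)) * pixel_area
  n <- length(areas)
  meff_norm <- effective_mesh_size(areas, A) / A
  patch_count_norm <- if (n == 0L) 0 else 1 / n
  tree_ratio <- min(1, sum(areas) / A)
  list(meff_norm = meff_norm, patch_count_norm = patch_count_norm,
       tree_ratio = tree_ratio,
       FI = fragmentation_index(meff_norm, patch_count_norm, tree_ratio))
}

#' Landscape ecosystem potential and its net (area-integrated) value
#'
#' `LEP = GBLI x HNVI x FI` is the per-SELU composite reported in account
#' tables. `NLEP` integrates the per-pixel product over the SELU:
#' `sum(gbli_px * hnvi_px) * FI / 100 * pixel_area`, i.e. per-pixel values
#' are multiplied first and summed, then scaled by the (SELU-level)
#' fragmentation index; the /100 rescales the 0-100 greenness to a
#' dimensionless index-hectare.
#'
#' @param GBLI Mean greenness (0-100).
#' @param HNVI High-nature-value multiplier (>= 1).
#' @param FI Fragmentation index in `[0, 1]`.
#' @param area_ha SELU area (ha) used for the net value.
#' @return List with `LEP` and `NLEP`.
#' @export
lep_nlep <- function(GBLI, HNVI, FI, area_ha) {
  LEP <- GBLI * HNVI * FI
  NLEP <- LEP / 100 * area_ha
  list(LEP = LEP, NLEP = NLEP)
}

#' River accessibility weighted index
#'
#' Sum over the river segments of a SELU of segment length times the common
#' logarithm of discharge: `RAWI = sum(length * log10(discharge))`. A
#' discharge of 1 contributes nothing; non-positive discharges are data
#' errors.
#'
#' @param segments Data frame with columns `length_km` and `discharge`
#'   (m3/s); zero rows give 0.
#' @param log_base Logarithm base (default 10).
#' @return RAWI value.
#' @export
#' @examples
#' rawi(data.frame(length_km = 10, discharge = 100)) # 10 * 2 = 20
rawi <- function(segments, log_base = 10) {
  if (nrow(segments) == 0L) return(0)
  bad <- which(segments$discharge <= 0)
  if (length(bad) > 0L) {
    stop("non-positive discharge in segment(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sum(segments$length_km * log(segments$discharge, base = log_base))
}

#' River fragmentation factor from dam count
#'
#' `1 / (1 + n_dams)`: 1 for a free-flowing watershed, decreasing with each
#' dam.
#'
#' @param n_dams Non-negative dam count, vectorized.
#' @return Factor in `(0, 1]`.
#' @export
river_fragmentation <- function(n_dams) {
  if (any(n_dams < 0)) stop("'n_dams' must be >= 0", call. = FALSE)
  1 / (1 + n_dams)
}

#' Infrastructure use intensity (EISU)
#'
#' Capped ratio of the adjusted closing to adjusted opening total ecosystem
#' infrastructure potential: `EISU = min(1, TEIP2_adj / TEIP1_adj)`.
#' Invariant under a common rescaling of both potentials. A zero opening
#' potential leaves the index undefined (`NA`).
#'
#' @param teip1_adj,teip2_adj Adjusted potentials, vectorized.
#' @return Index in `[0, 1]`, `NA` where undefined.
#' @export
infra_use_intensity <- function(teip1_adj, teip2_adj) {
  ifelse(teip1_adj == 0, NA_real_, pmin(1, teip2_adj / teip1_adj))
}

#' Assemble the ecosystem infrastructure account
#'
#' Combines per-SELU landscape and river indices for the two accounting
#' dates into the account matrix: composites `LEP = GBLI x HNVI x FI` and
#' `REP = RAWI x HNVI_riv x frag_riv`, potentials `TEIP = NLEP + NREP` per
#' date, adjusted potentials (one calibration scalar per date, a declared
#' config input), `EISU` and `EIIUV = (EISU + EHI) / 2`.
#'
#' @param landscape Data frame with one row per SELU and date, columns
#'   `selu_id`, `date` (`"opening"`/`"closing"`), `GBLI`, `HNVI`, `FI`,
#'   `NLEP`.
#' @param rivers Same shape with columns `selu_id`, `date`, `RAWI`,
#'   `HNVI_riv`, `frag_riv`, `NREP`.
#' @param EHI Named (by selu_id) or unnamed vector of composite ecosystem
#'   health indices in `[0, 1]`; computed once for the inter-date account.
#' @param adjustment Length-2 numeric: calibration scalars applied to all
#'   SELUs' TEIP at the opening and closing dates.
#' @param combiner Combiner for EIIUV, `"mean"` or `"product"`.
#' @return Matrix of class `c("infra_account", "enca_account")`.
#' @export
assemble_infra_account <- function(landscape, rivers, EHI,
                                   adjustment = c(1, 1),
                                   combiner = "mean") {
  stopifnot(all(c("selu_id", "date", "GBLI", "HNVI", "FI", "NLEP") %in%
                  names(landscape)),
            all(c("selu_id", "date", "RAWI", "HNVI_riv", "frag_riv",
                  "NREP") %in% names(rivers)),
            length(adjustment) == 2L)
  selus <- unique(landscape$selu_id)
  pick <- function(df, d) {
    sub <- df[df$date == d, ]
    if (!setequal(sub$selu_id, selus)) {
      stop("both dates must cover the same SELUs", call. = FALSE)
    }
    sub[match(selus, sub$selu_id), ]
  }
  L1 <- pick(landscape, "opening"); L2 <- pick(landscape, "closing")
  R1 <- pick(rivers, "opening"); R2 <- pick(rivers, "closing")
  if (is.null(names(EHI))) EHI <- stats::setNames(rep(EHI, length.out =
                                                        length(selus)), selus)
  EHI <- EHI[selus]
  if (any(is.na(EHI)) || any(EHI < 0 | EHI > 1)) {
    stop("'EHI' must cover every SELU with values in [0, 1]", call. = FALSE)
  }

  lep1 <- L1$GBLI * L1$HNVI * L1$FI
  lep2 <- L2$GBLI * L2$HNVI * L2$FI
  rep1 <- R1$RAWI * R1$HNVI_riv * R1$frag_riv
  rep2 <- R2$RAWI * R2$HNVI_riv * R2$frag_riv
  teip1 <- L1$NLEP + R1$NREP
  teip2 <- L2$NLEP + R2$NREP
  teip1_adj <- teip1 * adjustment[1]
  teip2_adj <- teip2 * adjustment[2]
  eisu <- infra_use_intensity(teip1_adj, teip2_adj)
  if (any(is.na(eisu))) {
    warning("EISU undefined for SELU(s) with zero opening potential: ",
            paste(selus[is.na(eisu)], collapse = ", "))
  }
  eiiuv <- combine_indices(ifelse(is.na(eisu), 0, eisu), EHI, combiner)
  eiiuv[is.na(eisu)] <- NA_real_

  nm <- function(v) stats::setNames(v, selus)
  rows <- list(
    GBLI1 = nm(L1$GBLI), HNVI1 = nm(L1$HNVI), FI1 = nm(L1$FI),
    LEP1 = nm(lep1), NLEP1 = nm(L1$NLEP),
    RAWI1 = nm(R1$RAWI), HNVI_riv1 = nm(R1$HNVI_riv),
    frag_riv1 = nm(R1$frag_riv), REP1 = nm(rep1), NREP1 = nm(R1$NREP),
    TEIP1 = nm(teip1),
    GBLI2 = nm(L2$GBLI), HNVI2 = nm(L2$HNVI), FI2 = nm(L2$FI),
    LEP2 = nm(lep2), NLEP2 = nm(L2$NLEP),
    RAWI2 = nm(R2$RAWI), HNVI_riv2 = nm(R2$HNVI_riv),
    frag_riv2 = nm(R2$frag_riv), REP2 = nm(rep2), NREP2 = nm(R2$NREP),
    TEIP2 = nm(teip2),
    TEIP1_adj = nm(teip1_adj), TEIP2_adj = nm(teip2_adj),
    EISU = nm(eisu), EHI = nm(EHI), EIIUV = nm(eiiuv)
  )
  finish_account(rows,
                 index_rows = c("GBLI1", "HNVI1", "FI1", "GBLI2", "HNVI2",
                                "FI2", "HNVI_riv1", "HNVI_riv2", "frag_riv1",
                                "frag_riv2", "EISU", "EHI", "EIIUV"),
                 class_name = "infra_account", combiner = combiner,
                 reconciliation = list())
}
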