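# Socio-ecological landscape units: one unit per sub-watershed, typed by the
# dominant land-cover group inside it at a given accounting date. Geometry
# (the watershed partition) never changes between dates; only the type label
# can.

#' Dominant land-cover group per watershed
#'
#' For every watershed, sums the area of each SELU group (via the class ->
#' group table) and returns the group with the largest area. Exact ties are
#' broken deterministically by the fixed priority order of [selu_types()]
#' (natural classes first).
#'
#' @param raster Integer land-cover matrix (`NA` = nodata).
#' @param watersheds Integer label matrix, same shape; `NA` pixels ignored.
#' @param grouping Class-to-group table, default [default_grouping()].
#' @param pixel_area Pixel area in ha.
#' @return Data frame with `watershed_id`, `dlt` (dominant group; `NA` for an
#'   all-nodata watershed, which is flagged in column `empty`) and `area_ha`.
#' @export
dominant_landcover <- function(raster, watersheds,
                               grouping = default_grouping(),
                               pixel_area = 0.0225) {
  if (!all(dim(raster) == dim(watersheds))) {
    stop("land-cover and watershed rasters are not aligned", call. = FALSE)
  }
  ids <- sort(unique(as.vector(watersheds[!is.na(watersheds)])))
  present <- unique(raster[!is.na(raster)])
  check_grouping(grouping, present)
  prio <- selu_types()
  res <- lapply(ids, function(ws) {
    vals <- raster[watersheds == ws]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) {
      return(data.frame(watershed_id = ws, dlt = NA_character_,
                        area_ha = 0, empty = TRUE,
                        stringsAsFactors = FALSE))
    }
    grp <- grouping$group[match(vals, grouping$class_id)]
    tot <- tapply(rep(pixel_area, length(grp)), factor(grp, levels = prio),
                  sum, default = 0)
    best <- prio[which.max(tot)] # which.max takes the first = highest priority
    data.frame(watershed_id = ws, dlt = best,
               area_ha = sum(tot), empty = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Build the SELU map for one accounting date
#'
#' One unit per watershed, labelled with the dominant land-cover group (which
#' is also the SELU type). Empty (all-nodata) watersheds are flagged and
#' excluded from accounts.
#'
#' @inheritParams dominant_landcover
#' @param date Label attached to every unit (e.g. `"2013"` or `"opening"`).
#' @return Data frame of class `selu_map` with columns `selu_id`,
#'   `watershed_id`, `dlt`, `selu_type`, `area_ha`, `date`, `empty`.
#' @export
build_selus <- function(raster, watersheds, grouping = default_grouping(),
                        date = "opening", pixel_area = 0.0225) {
  d <- dominant_landcover(raster, watersheds, grouping, pixel_area)
  out <- data.frame(
    selu_id = ws_label(d$watershed_id),
    watershed_id = d$watershed_id,
    dlt = d$dlt,
    selu_type = d$dlt,
    area_ha = d$area_ha,
    date = date,
    empty = d$empty,
    stringsAsFactors = FALSE
  )
  class(out) <- c("selu_map", class(out))
  out
}

#' @export
print.selu_map <- function(x, ...) {
  cat("SELU map (", x$date[1], "): ", nrow(x), " units, ",
      round(sum(x$area_ha)), " ha\n", sep = "")
  print.data.frame(x[, c("selu_id", "selu_type", "area_ha")], row.names = FALSE)
  invisible(x)
}
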