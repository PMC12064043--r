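# Worked-example data: the published ecosystem accounts of the
# Mahavavy-Kinkony Complex protected area (north-western Madagascar),
# accounting period 2013-2018, transcribed as long line-item tables. These
# are the raw per-SELU line items only; every derived row (balances, use
# indices, internal unit values, capabilities) is recomputed by the package's
# assemblers.

mkc_path <- function(file) {
  p <- system.file("extdata", "mahavavy_kinkony", file,
                   package = "encaland")
  if (p == "") stop("example data file not found: ", file, call. = FALSE)
  p
}

mkc_read <- function(file) {
  utils::read.csv(mkc_path(file), stringsAsFactors = FALSE)
}

#' Mahavavy-Kinkony Complex example accounts
#'
#' Line-item tables of the published 2013-2018 ecosystem accounts of the
#' Mahavavy-Kinkony Complex protected area, used as worked examples and
#' reference inputs: water (1000 m3) and carbon (tonnes C) line items per
#' SELU and year, the inter-date infrastructure index table, the published
#' per-SELU capability components, and the land-cover flow table (ha) of the
#' 16-class nomenclature.
#'
#' `mkc_landcover_account()` returns a ready [flow_account()] built from the
#' published opening stocks and per-flow-class formation/consumption cells.
#' `mkc_infrastructure()` returns the wide per-SELU index table; the
#' published adjusted/raw potential ratios are constant within a year
#' (x1.1287 in 2013, x1.0854 in 2018) and are exposed as the `adjustment`
#' attribute.
#'
#' @param year 2013 or 2018.
#' @return Data frames; see each function.
#' @name mkc_data
NULL

#' @rdname mkc_data
#' @export
mkc_water_items <- function(year = 2013) {
  mkc_read(sprintf("water_%d.csv", year))
}

#' @rdname mkc_data
#' @export
mkc_carbon_items <- function(year = 2013) {
  mkc_read(sprintf("carbon_%d.csv", year))
}

#' @rdname mkc_data
#' @export
mkc_infrastructure <- function() {
  x <- mkc_read("infrastructure.csv")
  wide <- stats::reshape(x, idvar = "selu_id", timevar = "code",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  attr(wide, "adjustment") <- c(opening = 1.1287, closing = 1.0854)
  wide
}

#' @rdname mkc_data
#' @export
mkc_capability <- function(year = 2013) {
  x <- mkc_read(sprintf("capability_%d.csv", year))
  wide <- stats::reshape(x, idvar = "selu_id", timevar = "code",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' @rdname mkc_data
#' @export
mkc_landcover_account <- function() {
  x <- mkc_read("landcover_flows.csv")
  classes <- unique(x$class_name)
  get_row <- function(item) {
    v <- x$value[x$item == item]
    stats::setNames(v, classes)
  }
  lf <- flow_codes()
  formation <- do.call(rbind, lapply(paste0("F_", lf), get_row))
  consumption <- do.call(rbind, lapply(paste0("C_", lf), get_row))
  rownames(formation) <- rownames(consumption) <- lf
  flow_account(get_row("opening"), formation, consumption)
}
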