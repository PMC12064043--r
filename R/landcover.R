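# Diachronic land-cover accounting: cross-tabulation of two co-registered
# categorical rasters, classification of every transition into one of seven
# causal land-cover flow classes (lf1..lf7, lf0 = no change), and assembly of
# the stock/flow account (opening stock, formation and consumption by flow
# class, net change, closing stock) in hectares.

#' Cross-tabulate two co-registered land-cover rasters
#'
#' Counts pixels by (opening class, closing class) pair. A pixel that is
#' nodata (`NA`) at either date is excluded at both, so opening and closing
#' universes are identical.
#'
#' @param opening,closing Integer matrices of class ids, same shape.
#' @param pixel_area Pixel area in hectares.
#' @param palette Nomenclature data frame with `class_id`; default
#'   [default_palette()]. Classes present in the rasters but absent from the
#'   palette raise an error.
#' @return Object of class `transition_matrix`: list with `classes`, square
#'   integer `counts` (rows = opening, cols = closing) and `pixel_area`.
#' @export
#' @examples
#' op <- matrix(c(61, 61, 51, 51), 2, 2)
#' cl <- matrix(c(61, 41, 51, 51), 2, 2)
#' cross_tabulate(op, cl, pixel_area = 1)$counts
cross_tabulate <- function(opening, closing, pixel_area,
                           palette = default_palette()) {
  if (!is.matrix(opening) || !is.matrix(closing)) {
    stop("rasters must be matrices", call. = FALSE)
  }
  if (!all(dim(opening) == dim(closing))) {
    stop("rasters are not aligned: shapes ",
         paste(dim(opening), collapse = "x"), " vs ",
         paste(dim(closing), collapse = "x"), call. = FALSE)
  }
  if (pixel_area <= 0) stop("'pixel_area' must be > 0", call. = FALSE)
  mask <- !is.na(opening) & !is.na(closing)
  ids <- palette$class_id
  seen <- unique(c(opening[mask], closing[mask]))
  outside <- setdiff(seen, ids)
  if (length(outside) > 0L) {
    stop("class id(s) outside the nomenclature: ",
         paste(sort(outside), collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(opening[mask], levels = ids),
                  factor(closing[mask], levels = ids))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(ids, ids))
  structure(list(classes = ids, counts = counts, pixel_area = pixel_area),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Land-cover transition matrix:", length(x$classes), "classes,",
      sum(x$counts), "pixels,", sum(x$counts) * x$pixel_area, "ha\n")
  cat("Changed area:",
      (sum(x$counts) - sum(diag(x$counts))) * x$pixel_area, "ha\n")
  invisible(x)
}

flow_codes <- function() paste0("lf", 1:7)

flow_code_labels <- function() {
  c(lf1 = "Artificial development",
    lf2 = "Agricultural extension",
    lf3 = "Internal conversions",
    lf4 = "Management and alteration of forest land",
    lf5 = "Restoration and development of habitats",
    lf6 = "Changes of land-cover due to natural and multiple causes",
    lf7 = "Other land cover changes")
}

#' Default land-cover flow classification rules
#'
#' Builds a total (class, class) -> flow-code mapping for the given palette,
#' following a destination-driven reading with origin overrides: diagonal
#' pairs are lf0 (no change); any change to village is artificialisation
#' (lf1); crop-to-crop and within-family forest-density changes are internal
#' conversions (lf3); any other change to a crop class is agricultural
#' extension (lf2); woody cover (forest, mangrove, shrubland) degrading to
#' savannah or shrubland is forest alteration (lf4); any change into forest,
#' mangrove or shrubland is restoration (lf5); changes into barren land, tan
#' or water are attributed to natural and multiple causes (lf6); everything
#' else is lf7. Pass any modified matrix to [classify_flows()] to override.
#'
#' @param palette Nomenclature data frame, default [default_palette()].
#' @return Character matrix (rows = opening class, cols = closing class) of
#'   codes in `lf0`..`lf7`.
#' @export
default_flow_rules <- function(palette = default_palette()) {
  ids <- palette$class_id
  k <- length(ids)
  chr <- as.character(ids)
  village <- intersect(chr, "11")
  crops <- intersect(chr, c("21", "31", "41"))
  dry_forest <- intersect(chr, c("61", "62"))
  mangrove <- intersect(chr, c("63", "64", "65"))
  shrub <- intersect(chr, "71")
  savannah <- intersect(chr, "51")
  woody <- c(dry_forest, mangrove, shrub)
  natural_dest <- intersect(chr, c("101", "102", "131"))

  rules <- matrix("lf7", k, k, dimnames = list(chr, chr))
  # order of assignment = reverse priority; later assignments win
  rules[, natural_dest] <- "lf6"
  rules[, woody] <- "lf5"
  rules[c(dry_forest, mangrove), c(savannah, shrub)] <- "lf4"
  if (length(shrub) && length(savannah)) rules[shrub, savannah] <- "lf4"
  rules[, crops] <- "lf2"
  rules[crops, crops] <- "lf3"
  rules[dry_forest, dry_forest] <- "lf3"
  rules[mangrove, mangrove] <- "lf3"
  rules[, village] <- "lf1"
  diag(rules) <- "lf0"
  rules
}

#' Classify land-cover transitions into flow classes
#'
#' Assigns the area of every off-diagonal transition cell to exactly one flow
#' class, recording it once as formation of the destination class and once as
#' consumption of the origin class. Diagonal (lf0) area enters neither.
#'
#' @param tm A [cross_tabulate()] result.
#' @param rules Character matrix as from [default_flow_rules()]; must cover
#'   every class pair of `tm`.
#' @return Object of class `flow_account`: opening/closing stocks (ha) per
#'   class, formation and consumption matrices (flow class x land-cover
#'   class, ha), their totals and the net change.
#' @export
classify_flows <- function(tm, rules = default_flow_rules()) {
  stopifnot(inherits(tm, "transition_matrix"))
  chr <- as.character(tm$classes)
  if (!all(chr %in% rownames(rules)) || !all(chr %in% colnames(rules))) {
    stop("flow rules do not cover every class of the transition matrix",
         call. = FALSE)
  }
  rules <- rules[chr, chr, drop = FALSE]
  k <- length(chr)
  lf <- flow_codes()
  formation <- matrix(0, length(lf), k, dimnames = list(lf, chr))
  consumption <- matrix(0, length(lf), k, dimnames = list(lf, chr))
  area <- tm$counts * tm$pixel_area
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j || area[i, j] == 0) next
      code <- rules[i, j]
      if (identical(code, "lf0")) next
      formation[code, j] <- formation[code, j] + area[i, j]
      consumption[code, i] <- consumption[code, i] + area[i, j]
    }
  }
  opening <- rowSums(area)
  closing <- colSums(area)
  flow_account(opening, formation, consumption, closing = closing)
}

#' Construct a land-cover flow account
#'
#' Low-level constructor used both by [classify_flows()] and to ingest an
#' already-tabulated account (e.g. a published table) from its opening stocks
#' and formation/consumption cells. Derived rows (totals, net change, closing
#' stock) are always recomputed from the cells at full precision.
#'
#' @param opening_stock Named numeric vector, ha per class.
#' @param formation,consumption Numeric matrices, flow class (`lf1`..`lf7`)
#'   by land-cover class, in ha.
#' @param closing Optional closing stocks; when omitted they are derived from
#'   the stock-closure identity `closing = opening + formation - consumption`.
#' @return Object of class `flow_account`.
#' @export
flow_account <- function(opening_stock, formation, consumption,
                         closing = NULL) {
  classes <- names(opening_stock)
  if (is.null(classes)) classes <- colnames(formation)
  stopifnot(!is.null(classes),
            all(colnames(formation) == classes),
            all(colnames(consumption) == classes))
  total_formation <- colSums(formation)
  total_consumption <- colSums(consumption)
  net <- total_formation - total_consumption
  derived_closing <- opening_stock + net
  structure(
    list(classes = classes,
         opening_stock = opening_stock,
         formation = formation,
         consumption = consumption,
         total_formation = total_formation,
         total_consumption = total_consumption,
         net_change = net,
         closing_stock = if (is.null(closing)) derived_closing else closing),
    class = "flow_account"
  )
}

#' @export
print.flow_account <- function(x, ...) {
  cat("Land-cover flow account:", length(x$classes), "classes\n")
  cat("Total area:", round(sum(x$opening_stock)), "ha; changed area:",
      round(sum(x$total_formation)), "ha\n")
  invisible(x)
}

#' Assemble the land-cover account table
#'
#' Emits the standard account layout: one column per land-cover class plus a
#' Total column; rows are opening stock, formation by flow class, total
#' formation, consumption by flow class, total consumption, net change and
#' closing stock. All values in hectares at full precision (round only for
#' presentation).
#'
#' @param fa A [flow_account()].
#' @return A data frame of class `landcover_account`.
#' @export
assemble_account <- function(fa) {
  stopifnot(inherits(fa, "flow_account"))
  lf <- flow_codes()
  rows <- rbind(
    `Opening stock` = fa$opening_stock,
    `F_` = fa$formation,
    `Total formation` = fa$total_formation,
    `C_` = fa$consumption,
    `Total consumption` = fa$total_consumption,
    `Net change` = fa$net_change,
    `Closing stock` = fa$closing_stock
  )
  rownames(rows) <- c("Opening stock", paste0("F_", lf), "Total formation",
                      paste0("C_", lf), "Total consumption", "Net change",
                      "Closing stock")
  out <- as.data.frame(rows, check.names = FALSE)
  out$Total <- rowSums(rows)
  class(out) <- c("landcover_account", class(out))
  out
}

#' @export
print.landcover_account <- function(x, digits = 0, ...) {
  y <- as.data.frame(lapply(x, round, digits = digits))
  rownames(y) <- rownames(x)
  print.data.frame(y, ...)
  invisible(x)
}
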