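# Ecosystem carbon account: per-SELU biocarbon stocks (C1_x, tonnes C),
# inflows (C2_x, dominated by net primary production), withdrawals (C3_x) and
# indirect losses (C4_x), the net accessible surplus C10, the sustainable
# intensity of carbon use SCU, the health index CEH (an input) and the
# carbon internal unit value CIUV.

#' Carbon stocks from a land-cover raster
#'
#' Linear per-class scaling of aboveground biomass, litter, root and soil
#' organic carbon pools over each watershed/SELU: `C1_1` is area times
#' aboveground density, `C1_2` applies the litter fraction, `C1_31` the
#' root:shoot ratio and `C1_32` the soil organic carbon density.
#'
#' @param raster Integer land-cover matrix.
#' @param watersheds Integer label matrix, same shape.
#' @param params Per-class parameter table with columns `class_id`,
#'   `agb_tc_ha`, `litter_frac`, `root_shoot`, `soc_tc_ha`
#'   (see [default_class_params()]); must cover every class present.
#' @param pixel_area Pixel area in ha.
#' @return Long data frame (`selu_id`, `code`, `value`) of C1_x stocks in
#'   tonnes C.
#' @export
stocks_from_landcover <- function(raster, watersheds,
                                  params = default_class_params(),
                                  pixel_area = 0.0225) {
  present <- unique(raster[!is.na(raster)])
  missing <- setdiff(present, params$class_id)
  if (length(missing) > 0L) {
    stop("no carbon parameters for class id(s): ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  areas <- zonal_class_areas(raster, watersheds, pixel_area,
                             params$class_id)
  par <- params[match(as.integer(rownames(areas)), params$class_id), ]
  out <- lapply(seq_len(ncol(areas)), function(j) {
    a <- areas[, j]
    vals <- c(
      C1_1 = sum(a * par$agb_tc_ha),
      C1_2 = sum(a * par$agb_tc_ha * par$litter_frac),
      C1_31 = sum(a * par$agb_tc_ha * par$root_shoot),
      C1_32 = sum(a * par$soc_tc_ha)
    )
    data.frame(selu_id = ws_label(colnames(areas)[j]), code = names(vals),
               value = unname(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Net ecosystem accessible carbon surplus (C10)
#'
#' The accessible inflow after applying the nature-protection limitation
#' index: `C10 = C10_1 * C10_2`.
#'
#' @param C10_1 Net accessible biomass carbon inflow (tC), >= 0, vectorized.
#' @param C10_2 Index of limitation of use due to nature protection, in
#'   `[0, 1]`.
#' @return Accessible surplus in tC.
#' @export
accessible_surplus <- function(C10_1, C10_2) {
  if (any(C10_1 < 0)) stop("'C10_1' must be >= 0", call. = FALSE)
  if (any(C10_2 < 0 | C10_2 > 1)) {
    stop("'C10_2' must lie in [0, 1]", call. = FALSE)
  }
  C10_1 * C10_2
}

#' Sustainable intensity of carbon use (SCU)
#'
#' Capped ratio of accessible surplus to total use and induced loss:
#' `SCU = min(1, C10 / C5)`; zero use scores 1.
#'
#' @param C10 Accessible surplus (tC), vectorized.
#' @param C5 Total use and induced loss (tC), >= 0.
#' @return Index in `[0, 1]`.
#' @export
sustainable_use_index <- function(C10, C5) {
  if (any(C5 < 0)) stop("'C5' must be >= 0", call. = FALSE)
  ifelse(C5 == 0, 1, pmin(1, pmax(0, C10 / C5)))
}

#' Ecosystem carbon internal unit value (CIUV)
#'
#' Combines the sustainable-use index with the carbon health index, by
#' arithmetic mean by default (same combiner convention as the water
#' account).
#'
#' @param SCU,CEH Indices in `[0, 1]`, vectorized.
#' @param combiner `"mean"` (default) or `"product"`.
#' @return Index in `[0, 1]`.
#' @export
carbon_internal_value <- function(SCU, CEH, combiner = "mean") {
  combine_indices(SCU, CEH, combiner)
}

carbon_required_codes <- function() c("C10_1", "C10_2")

#' Assemble the ecosystem carbon account
#'
#' Builds the account matrix from long-format line items. Derived rows:
#' `C1` = sum of C1_x stocks, `C2` = sum of supplied C2_x inflows, `C3` =
#' sum of supplied C3_x withdrawals, `C4` = sum of C4_x losses,
#' `C5 = C3 + C4`, `C10 = C10_1 * C10_2`, `SCU = min(1, C10/C5)` and
#' `CIUV`. Supplied aggregate rows (C1, C2, C3, C4) are authoritative, with
#' the component-sum gap kept in the `reconciliation` attribute — published
#' accounts routinely carry unprinted component lines. Total-column masses
#' are sums, indices unweighted cross-SELU means. `CEH` defaults to 1 when
#' not supplied.
#'
#' @param items Data frame (`selu_id`, `code`, `value`); masses in tonnes C.
#'   Required per SELU: C10_1 and C10_2.
#' @param combiner Combiner for CIUV, `"mean"` or `"product"`.
#' @return Matrix of class `c("carbon_account", "enca_account")`.
#' @export
assemble_carbon_account <- function(items, combiner = "mean") {
  M <- items_to_matrix(items, carbon_required_codes(), "carbon account")
  masses <- grep("^C[1-4]_", rownames(M), value = TRUE)
  if (any(M[masses, , drop = FALSE] < 0)) {
    stop("carbon masses (C1_x..C4_x) must be >= 0", call. = FALSE)
  }
  rec <- list()
  agg <- function(code, pattern) {
    comp <- grep(pattern, rownames(M), value = TRUE)
    a <- aggregate_row(M, code, comp, rec)
    rec <<- a$reconciliation
    a$value
  }
  C1 <- agg("C1", "^C1_")
  C2 <- agg("C2", "^C2_")
  C3 <- agg("C3", "^C3_")
  C4 <- agg("C4", "^C4_")
  C5 <- C3 + C4
  C10 <- accessible_surplus(M["C10_1", ], M["C10_2", ])
  SCU <- sustainable_use_index(C10, C5)
  CEH <- if ("CEH" %in% rownames(M)) M["CEH", ] else
    stats::setNames(rep(1, ncol(M)), colnames(M))
  CIUV <- carbon_internal_value(SCU, CEH, combiner)

  supplied <- grep("^C[1-4]_", rownames(M), value = TRUE)
  supplied <- supplied[order(substr(supplied, 2, 2), supplied)]
  rows <- c(
    lapply(stats::setNames(supplied, supplied), function(cd) M[cd, ]),
    list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
         C10_1 = M["C10_1", ], C10_2 = M["C10_2", ], C10 = C10,
         SCU = SCU, CEH = CEH, CIUV = CIUV)
  )
  finish_account(rows, index_rows = c("C10_2", "SCU", "CEH", "CIUV"),
                 class_name = "carbon_account", combiner = combiner,
                 reconciliation = rec)
}
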