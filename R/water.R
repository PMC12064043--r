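# Ecosystem water account: per-SELU stocks (W1_x), inflows (W2_x), outflows
# (W3_x) in thousand cubic metres, derived balances, the sustainable-use
# index W13, the composite health index W14 (an input) and the water
# ecological internal unit value W15.

#' Estimate real evapotranspiration from precipitation
#'
#' Scales per-period precipitation by the ratio of long-run average
#' precipitation to long-run average evapotranspiration. The ratio
#' orientation is configurable: the `"as_printed"` form `(Pavg/ETravg) * P`
#' produces ETr > P whenever long-run precipitation exceeds long-run
#' evapotranspiration, which is physically inconsistent for a quantity meant
#' to be bounded by rainfall; the default `"inverted"` orientation
#' `(ETravg/Pavg) * P` is used instead, with a message when the default is
#' applied implicitly.
#'
#' @param P Per-period precipitation (mm), vectorized.
#' @param Pavg Long-run average precipitation (mm/yr), > 0.
#' @param ETravg Long-run average evapotranspiration (mm/yr), > 0.
#' @param orientation `"inverted"` (default) or `"as_printed"`.
#' @return Estimated real evapotranspiration, same length as `P`.
#' @export
#' @examples
#' estimate_etr(100, Pavg = 1554, ETravg = 777, orientation = "inverted")
#' estimate_etr(100, Pavg = 1554, ETravg = 777, orientation = "as_printed")
estimate_etr <- function(P, Pavg, ETravg, orientation) {
  if (!is.numeric(Pavg) || !is.numeric(ETravg) || Pavg <= 0 || ETravg <= 0) {
    stop("'Pavg' and 'ETravg' must be positive", call. = FALSE)
  }
  if (missing(orientation)) {
    message("estimate_etr: using the inverted ratio ETravg/Pavg ",
            "(set 'orientation' explicitly to silence)")
    orientation <- "inverted"
  }
  orientation <- match.arg(orientation, c("inverted", "as_printed"))
  ratio <- if (orientation == "as_printed") Pavg / ETravg else ETravg / Pavg
  ratio * P
}

#' Water sustainable-use index (W13)
#'
#' Ratio of accessible resource (W6, net primary and secondary water) to
#' total use (W9), capped at 1. A negative accessible resource clamps to 0;
#' zero use scores 1 (no pressure).
#'
#' @param W6 Net primary & secondary water resource (1000 m3), vectorized.
#' @param W9 Total use of ecosystem water (1000 m3), >= 0.
#' @return Index in `[0, 1]`.
#' @export
water_use_index <- function(W6, W9) {
  if (any(W9 < 0)) stop("'W9' must be >= 0", call. = FALSE)
  ifelse(W9 == 0, 1, pmin(1, pmax(0, W6 / W9)))
}

#' Water ecological internal unit value (W15)
#'
#' Combines the sustainable-use index W13 with the composite health index
#' W14. The default combiner is the arithmetic mean, which reproduces
#' published internal unit values; a multiplicative combiner is available.
#'
#' @param W13,W14 Indices in `[0, 1]`, vectorized.
#' @param combiner `"mean"` (default) or `"product"`.
#' @return Index in `[0, 1]`.
#' @export
water_internal_value <- function(W13, W14, combiner = "mean") {
  combine_indices(W13, W14, combiner)
}

water_required_codes <- function() c("W2_1", "W3_1", "W3_4", "W14")

#' Assemble the ecosystem water account
#'
#' Builds the full account matrix (one column per SELU plus a Total column)
#' from long-format line items. Derived rows: `W2a = W2_1+W2_2+W2_3`,
#' `W2b = W2_4+W2_5+W2_6`, `W2 = W2a+W2b`, `W3` = sum of all supplied
#' `W3_x` items, `W4 = W2-W3`, `W4a = W2_1-W3_1`,
#' `W6 = W2a+W2b-W3_2-W3_3`, `W9 = W3_1+W3_4`, `W13`, `W15`. Total-column
#' volumes are sums across SELUs, indices are unweighted means. A supplied
#' aggregate row (e.g. a published `W3`) is authoritative and the gap versus
#' the component sum is kept in the `reconciliation` attribute.
#'
#' @param items Data frame with columns `selu_id`, `code`, `value` (1000 m3;
#'   indices unitless). Required codes per SELU: W2_1, W3_1, W3_4, W14.
#'   Unsupplied optional codes (e.g. W3_2 transfers) default to 0.
#' @param combiner Combiner for W15, `"mean"` or `"product"`.
#' @return Matrix of class `c("water_account", "enca_account")`.
#' @export
assemble_water_account <- function(items, combiner = "mean") {
  M <- items_to_matrix(items, water_required_codes(), "water account")
  stock_use <- grep("^W[13]_", rownames(M), value = TRUE)
  if (any(M[stock_use, , drop = FALSE] < 0)) {
    stop("water stocks and uses (W1_x, W3_x) must be >= 0", call. = FALSE)
  }
  if (any(M["W14", ] < 0 | M["W14", ] > 1)) {
    stop("W14 must lie in [0, 1]", call. = FALSE)
  }
  rec <- list()
  g <- function(code) if (code %in% rownames(M)) M[code, ] else
    stats::setNames(rep(0, ncol(M)), colnames(M))
  W2a <- g("W2_1") + g("W2_2") + g("W2_3")
  W2b <- g("W2_4") + g("W2_5") + g("W2_6")
  a2 <- aggregate_row(M, "W2", paste0("W2_", 1:6), rec)
  W2 <- a2$value; rec <- a2$reconciliation
  w3_codes <- setdiff(grep("^W3_", rownames(M), value = TRUE), character())
  a3 <- aggregate_row(M, "W3", w3_codes, rec)
  W3 <- a3$value; rec <- a3$reconciliation
  W4 <- W2 - W3
  W4a <- g("W2_1") - g("W3_1")
  W6 <- W2a + W2b - g("W3_2") - g("W3_3")
  W9 <- g("W3_1") + g("W3_4")
  W13 <- water_use_index(W6, W9)
  W15 <- water_internal_value(W13, M["W14", ], combiner)

  supplied <- setdiff(rownames(M), c("W2", "W3", "W14"))
  supplied <- supplied[order(match(substr(supplied, 1, 2), c("W1", "W2", "W3")),
                             supplied)]
  rows <- c(
    lapply(stats::setNames(supplied, supplied), function(cd) M[cd, ]),
    list(W2 = W2, W2a = W2a, W2b = W2b, W3 = W3, W4 = W4, W4a = W4a,
         W6 = W6, W9 = W9, W13 = W13, W14 = M["W14", ], W15 = W15)
  )
  finish_account(rows, index_rows = c("W13", "W14", "W15"),
                 class_name = "water_account", combiner = combiner,
                 reconciliation = rec)
}
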