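# Ecosystem capability: the three accounts' internal unit values (CIUV, W15,
# EIIUV) averaged into the per-SELU ecosystem capability unit value ECU_P,
# multiplied by the accessible resources (C10 tonnes C, W6 thousand m3,
# adjusted TEIP index-ha) to give the carbon, water and infrastructure
# capabilities; their sum is the Total Ecosystem Capability (TEC) in ECU, and
# the inter-date difference is the ecological debt (negative) or credit
# (positive).

#' Per-SELU ecosystem capability unit value
#'
#' Arithmetic mean of the three internal unit values:
#' `ECU_P = (CIUV + WIUV + EIIUV) / 3`.
#'
#' @param CIUV,W15,EIIUV Indices in `[0, 1]`, vectorized.
#' @return Index in `[0, 1]`.
#' @export
ecu_average <- function(CIUV, W15, EIIUV) {
  v <- c(CIUV, W15, EIIUV)
  if (any(v < 0 | v > 1, na.rm = TRUE)) {
    stop("internal unit values must lie in [0, 1]", call. = FALSE)
  }
  (CIUV + W15 + EIIUV) / 3
}

#' Capabilities from resources and the unit value
#'
#' Multiplies each accessible resource by the (unrounded) per-SELU unit
#' value: `C_EC = C10 * ECU_P`, `W_EC = W6 * ECU_P`,
#' `EI_EC = TEIP_adj * ECU_P`, `TEC = C_EC + W_EC + EI_EC`. Linear in every
#' resource at fixed ECU_P.
#'
#' @param C10 Accessible carbon surplus (tC), >= 0, vectorized.
#' @param W6 Accessible water resource (1000 m3), >= 0 (negative balances
#'   clamp to 0 contribution).
#' @param TEIP_adj Adjusted infrastructure potential (index-ha), >= 0.
#' @param ECU_P Unit value in `[0, 1]`.
#' @return Data frame with columns `C_EC`, `W_EC`, `EI_EC`, `TEC`.
#' @export
ecosystem_capabilities <- function(C10, W6, TEIP_adj, ECU_P) {
  if (any(c(C10, TEIP_adj) < 0)) {
    stop("resources must be >= 0", call. = FALSE)
  }
  W6 <- pmax(0, W6)
  C_EC <- C10 * ECU_P
  W_EC <- W6 * ECU_P
  EI_EC <- TEIP_adj * ECU_P
  data.frame(C_EC = C_EC, W_EC = W_EC, EI_EC = EI_EC,
             TEC = C_EC + W_EC + EI_EC)
}

#' Ecological balance between two accounting dates
#'
#' `dTEC = TEC_close - TEC_open`; the percentage is rounded to the nearest
#' integer as published. A negative difference is an ecological debt, a
#' positive one a credit. A zero (or negative) opening TEC leaves the
#' percentage undefined.
#'
#' @param TEC_open,TEC_close Total ecosystem capability (ECU), vectorized.
#' @return Data frame with `delta`, `percent` (integer, `NA` if undefined)
#'   and `label` (`"debt"`, `"credit"` or `"balanced"`).
#' @export
#' @examples
#' ecological_balance(5418668, 5143504)
ecological_balance <- function(TEC_open, TEC_close) {
  delta <- TEC_close - TEC_open
  percent <- ifelse(TEC_open > 0, round(100 * delta / TEC_open), NA_real_)
  label <- ifelse(delta < 0, "debt", ifelse(delta > 0, "credit", "balanced"))
  data.frame(delta = delta, percent = percent, label = label,
             stringsAsFactors = FALSE)
}

#' Assemble the capability ledger
#'
#' Combines per-SELU accessible resources and internal unit values for the
#' opening and closing dates into the capability account: per-SELU ECU_P,
#' capabilities and TEC for each date, totals, and the inter-date ecological
#' balance. All multiplications chain full-precision indices; rounding is
#' presentation only. The infrastructure internal unit value is computed
#' once from the inter-date infrastructure account and used for both dates,
#' so both dates must share the same SELU frame.
#'
#' @param open,close Data frames with one row per SELU and columns
#'   `selu_id`, `C10`, `CIUV`, `W6`, `W15`, `TEIP_adj`, `EIIUV`.
#' @return Object of class `capability_ledger`: list with per-date ledgers,
#'   per-SELU balance, and the total balance.
#' @export
capability_ledger <- function(open, close) {
  cols <- c("selu_id", "C10", "CIUV", "W6", "W15", "TEIP_adj", "EIIUV")
  stopifnot(all(cols %in% names(open)), all(cols %in% names(close)))
  if (!setequal(open$selu_id, close$selu_id)) {
    stop("opening and closing dates must share the same SELU frame",
         call. = FALSE)
  }
  close <- close[match(open$selu_id, close$selu_id), ]
  per_date <- function(df) {
    ecu <- ecu_average(df$CIUV, df$W15, df$EIIUV)
    cap <- ecosystem_capabilities(df$C10, df$W6, df$TEIP_adj, ecu)
    cbind(df[, cols], ECU_P = ecu, cap)
  }
  o <- per_date(open)
  c2 <- per_date(close)
  bal <- ecological_balance(o$TEC, c2$TEC)
  bal <- cbind(selu_id = o$selu_id, bal, stringsAsFactors = FALSE)
  total <- ecological_balance(sum(o$TEC), sum(c2$TEC))
  structure(list(opening = o, closing = c2, balance = bal,
                 total = cbind(TEC_open = sum(o$TEC),
                               TEC_close = sum(c2$TEC), total)),
            class = "capability_ledger")
}

#' @export
print.capability_ledger <- function(x, ...) {
  t <- x$total
  cat("Ecosystem capability ledger:", nrow(x$opening), "SELUs\n")
  cat(sprintf("  TEC opening: %s ECU\n  TEC closing: %s ECU\n",
              format(round(t$TEC_open), big.mark = ","),
              format(round(t$TEC_close), big.mark = ",")))
  cat(sprintf("  Ecological %s: %s ECU (%d%%)\n", t$label,
              format(round(t$delta), big.mark = ","), t$percent))
  invisible(x)
}

#' Extract capability inputs from the three account objects
#'
#' Pulls the per-SELU accessible resources and internal unit values out of
#' assembled water, carbon and infrastructure accounts for one date.
#'
#' @param carbon A `carbon_account`.
#' @param water A `water_account`.
#' @param infra An `infra_account` (inter-date).
#' @param date `"opening"` or `"closing"` (selects TEIP1_adj or TEIP2_adj).
#' @return Data frame suitable for [capability_ledger()].
#' @export
capability_inputs <- function(carbon, water, infra,
                              date = c("opening", "closing")) {
  date <- match.arg(date)
  selus <- setdiff(colnames(carbon), "Total")
  stopifnot(identical(selus, setdiff(colnames(water), "Total")),
            identical(selus, setdiff(colnames(infra), "Total")))
  teip_row <- if (date == "opening") "TEIP1_adj" else "TEIP2_adj"
  data.frame(
    selu_id = selus,
    C10 = carbon["C10", selus],
    CIUV = carbon["CIUV", selus],
    W6 = water["W6", selus],
    W15 = water["W15", selus],
    TEIP_adj = infra[teip_row, selus],
    EIIUV = infra["EIIUV", selus],
    stringsAsFactors = FALSE
  )
}
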