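# Shared machinery for coded-line-item accounts (water W-codes, carbon
# C-codes): long (selu_id, code, value) input, a codes x SELU matrix, derived
# aggregate rows, and a Total column that sums volumes/masses but averages
# indices across SELUs.

# Long line items -> codes x SELU numeric matrix, with schema validation.
items_to_matrix <- function(items, required, account_name) {
  need <- c("selu_id", "code", "value")
  if (!all(need %in% names(items))) {
    stop(account_name, ": line items need columns selu_id, code, value",
         call. = FALSE)
  }
  selus <- unique(items$selu_id)
  codes <- unique(items$code)
  for (s in selus) {
    have <- items$code[items$selu_id == s]
    miss <- setdiff(required, have)
    if (length(miss) > 0L) {
      stop(account_name, ": SELU '", s, "' is missing required code(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  M <- matrix(0, length(codes), length(selus),
              dimnames = list(codes, selus))
  M[cbind(match(items$code, codes), match(items$selu_id, selus))] <-
    items$value
  M
}

# Aggregate row: the supplied aggregate (if any) is authoritative and the gap
# against the component sum is recorded; otherwise the component sum is used.
aggregate_row <- function(M, code, components, reconciliation) {
  comp <- components[components %in% rownames(M)]
  total <- if (length(comp) > 0L) {
    colSums(M[comp, , drop = FALSE])
  } else {
    stats::setNames(rep(0, ncol(M)), colnames(M))
  }
  if (code %in% rownames(M)) {
    supplied <- M[code, ]
    gap <- supplied - total
    if (any(abs(gap) > 1e-9)) {
      reconciliation[[code]] <- gap
    }
    total <- supplied
  }
  list(value = total, reconciliation = reconciliation)
}

combine_indices <- function(a, b, combiner = c("mean", "product")) {
  combiner <- match.arg(combiner)
  if (any(a < 0 | a > 1, na.rm = TRUE) || any(b < 0 | b > 1, na.rm = TRUE)) {
    stop("index values must lie in [0, 1]", call. = FALSE)
  }
  if (combiner == "mean") (a + b) / 2 else a * b
}

# Assemble the final account matrix: per-SELU columns plus a Total column
# (sum for quantity rows, unweighted cross-SELU mean for index rows).
finish_account <- function(rows, index_rows, class_name, combiner,
                           reconciliation) {
  M <- do.call(rbind, rows)
  total <- rowSums(M)
  idx <- rownames(M) %in% index_rows
  total[idx] <- rowMeans(M[idx, , drop = FALSE])
  out <- cbind(M, Total = total)
  structure(out, class = c(class_name, "enca_account"),
            index_rows = index_rows, combiner = combiner,
            reconciliation = reconciliation)
}

#' Print an ecosystem account
#'
#' Quantity rows are printed to the nearest unit, index rows to two decimals;
#' internal storage keeps full precision.
#'
#' @param x An account produced by [assemble_water_account()],
#'   [assemble_carbon_account()] or [assemble_infra_account()].
#' @param ... Unused.
#' @export
print.enca_account <- function(x, ...) {
  idx <- rownames(x) %in% attr(x, "index_rows")
  y <- unclass(x)
  y[!idx, ] <- round(y[!idx, , drop = FALSE])
  y[idx, ] <- round(y[idx, , drop = FALSE], 2)
  print(y)
  rec <- attr(x, "reconciliation")
  if (length(rec) > 0L) {
    cat("\nReconciliation gaps (supplied aggregate minus component sum):\n")
    for (code in names(rec)) {
      cat(" ", code, ":", paste(round(rec[[code]]), collapse = " "), "\n")
    }
  }
  invisible(x)
}

#' Cross-SELU total of a row of per-SELU values
#'
#' Quantity rows (volumes, masses, potentials) total as sums; index rows as
#' unweighted means across SELUs.
#'
#' @param values Numeric vector, one value per SELU (at least one).
#' @param kind `"volume"` (sum) or `"index"` (mean).
#' @return Scalar total.
#' @export
#' @examples
#' totals_row(c(0.50, 0.53, 1, 1, 0.78, 0.50, 0.98), kind = "index")
totals_row <- function(values, kind = c("volume", "index")) {
  kind <- match.arg(kind)
  if (length(values) < 1L) stop("at least one SELU required", call. = FALSE)
  if (kind == "volume") sum(values) else mean(values)
}
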