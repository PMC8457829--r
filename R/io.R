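#' Tabulate trade-off results
#'
#' Flattens a list of \code{"tradeoff_result"} objects into a data frame,
#' one row per (boundary, decay length) pair, suitable for CSV export.
#'
#' @param results a \code{"tradeoff_result"} or list of them.
#' @return data frame with one row per result.
#' @export
tradeoff_table <- function(results) {
  if (inherits(results, "tradeoff_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(xb = r$xb, lam = r$lam, cost = r$cost,
               precision_sq = r$precision_sq, product = r$product,
               product_normalized = r$product_normalized,
               lambda_min = r$lambda_min, product_min = r$product_min,
               measurement_model = r$measurement_model)
  }))
}

#' Write trade-off results to CSV and JSON
#'
#' @param results a \code{"tradeoff_result"} or list of them.
#' @param csv_path,json_path output paths (either may be \code{NULL} to
#'   skip).
#' @return invisibly, the paths written.
#' @export
write_tradeoff_results <- function(results, csv_path = NULL, json_path = NULL) {
  tab <- tradeoff_table(results)
  written <- character()
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, json_path)
  }
  invisible(written)
}
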