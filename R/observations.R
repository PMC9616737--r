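#' Observed sebaceous-gland cell counts
#'
#' Long-form container for the calibration data: one row per observed
#' quantity per postnatal day. Each day may carry any subset of the basal
#' count (`P`), suprabasal count (`D`) and the `total`; weights are
#' per-observation and non-negative.
#'
#' @param day Postnatal day of each observation.
#' @param quantity Character vector, each element one of `"P"`, `"D"`,
#'   `"total"`.
#' @param value Observed cell count, >= 0.
#' @param weight Non-negative weight, recycled to the number of rows.
#'   Default 1.
#' @return A data frame of class `"count_observations"` with columns
#'   `day`, `quantity`, `value`, `weight`.
#' @examples
#' count_observations(day = c(2, 9, 9), quantity = c("total", "P", "D"),
#'                    value = c(11, 40, 210))
#' @export
count_observations <- function(day, quantity, value, weight = 1) {
  quantity <- as.character(quantity)
  if (length(day) == 0L) stop("at least one observation is required")
  if (!all(quantity %in% c("P", "D", "total")))
    stop("'quantity' entries must be one of \"P\", \"D\", \"total\"")
  if (length(day) != length(quantity) || length(day) != length(value))
    stop("'day', 'quantity' and 'value' must have equal length")
  if (any(!is.finite(value)) || any(value < 0))
    stop("observed values must be finite and >= 0")
  weight <- rep_len(as.numeric(weight), length(day))
  if (any(!is.finite(weight)) || any(weight < 0))
    stop("weights must be finite and >= 0")
  if (anyDuplicated(paste(day, quantity)))
    stop("duplicate (day, quantity) observations")
  structure(data.frame(day = as.numeric(day), quantity = quantity,
                       value = as.numeric(value), weight = weight),
            class = c("count_observations", "data.frame"))
}

#' Read count observations from TSV
#'
#' Expects a header with columns `day`, `quantity` (`P`, `D` or `total`),
#' `value` and optionally `weight` (default 1).
#'
#' @param path Path to a tab-separated file.
#' @return A [count_observations()] object.
#' @export
read_count_observations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("day", "quantity", "value")
  if (!all(need %in% names(tab)))
    stop("observation TSV must have columns: day, quantity, value")
  count_observations(tab$day, tab$quantity, tab$value,
                     if ("weight" %in% names(tab)) tab$weight else 1)
}

#' Write count observations to TSV
#'
#' @param obs A [count_observations()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_observations <- function(obs, path) {
  stopifnot(inherits(obs, "count_observations"))
  utils::write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
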