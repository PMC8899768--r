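# Long-format serialization of simulation time series.

#' Convert a simulation series to tidy long format
#'
#' Reshapes a wide state series (from [integrate_transit()],
#' [integrate_cfu()] or the `series` element of [integrate_meal()]) into
#' `(time_min, variable, value)` rows, optionally writing CSV.
#'
#' @param x A data frame whose first column is `time`.
#' @param path Optional CSV output path.
#' @return The long-format data frame, invisibly if `path` is given.
#' @export
tidy_series <- function(x, path = NULL) {
  stopifnot(is.data.frame(x), "time" %in% names(x))
  vars <- setdiff(names(x), "time")
  long <- data.frame(
    time_min = rep(x$time, times = length(vars)),
    variable = rep(vars, each = nrow(x)),
    value = unlist(x[vars], use.names = FALSE)
  )
  if (!is.null(path)) {
    utils::write.csv(long, path, row.names = FALSE)
    return(invisible(long))
  }
  long
}
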