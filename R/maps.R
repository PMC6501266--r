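#' Channels x time map
#'
#' Common container for any channels-by-time matrix produced by the
#' analyses: ERP difference maps, sensitivity maps, effect-size maps
#' and t-statistic maps.
#'
#' @param values Numeric matrix, channels in rows, time samples in
#'   columns.
#' @param channel_names Channel labels (row names).
#' @param times_ms Time stamps in ms (column labels).
#' @param kind One of `"sensitivity"`, `"erp_difference"`,
#'   `"effect_size"`, `"t_statistic"`.
#' @return A list of class `scalp_time_map`.
#' @export
scalp_time_map <- function(values, channel_names, times_ms,
                           kind = c("sensitivity", "erp_difference",
                                    "effect_size", "t_statistic")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != length(channel_names))
    stop("values rows must match channel_names")
  if (ncol(values) != length(times_ms))
    stop("values columns must match times_ms")
  dimnames(values) <- list(channel_names, times_ms)
  structure(list(values = values, channel_names = channel_names,
                 times_ms = times_ms, kind = kind),
            class = "scalp_time_map")
}

#' @export
print.scalp_time_map <- function(x, ...) {
  cat(sprintf("<scalp_time_map> kind = %s, %d channels x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write a scalp-time map to CSV
#'
#' Rows are channels, columns are time samples (headers in ms), plus a
#' leading `channel` column.
#'
#' @param map A [scalp_time_map()].
#' @param path Output file path.
#' @export
write_map_csv <- function(map, path) {
  df <- data.frame(channel = map$channel_names, map$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
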