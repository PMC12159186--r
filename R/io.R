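#' Write / read a trial table as CSV
#'
#' @param trials Trial table data frame.
#' @param path Output CSV path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise a simulation configuration to JSON
#'
#' The JSON round-trips through [read_sim_config()]; a `schema_version`
#' field tags the layout.
#'
#' @param config A [sim_config()].
#' @param path Output JSON path.
#' @export
write_sim_config <- function(config, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON export", call. = FALSE)
  obj <- c(list(schema_version = 1L), unclass(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for JSON import", call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$schema_version <- NULL
  do.call(sim_config, obj)
}

#' Export a source map as a plain table
#'
#' @param map A `source_map` from [dics_map()].
#' @param path Output CSV path.
#' @param percent Mask percentage passed to [top_percent_mask()].
#' @export
write_source_map <- function(map, path, percent = 1) {
  mask <- top_percent_mask(map, percent)
  pos <- map$positions
  if (is.null(pos)) pos <- matrix(NA_real_, length(map$coherence), 3)
  df <- data.frame(grid_index = seq_along(map$coherence),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   coherence = map$coherence, mask = mask)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
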