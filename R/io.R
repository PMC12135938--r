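#' Read and write spot tables
#'
#' Spot tables are plain CSV with the schema
#' `spot_id,x_um,y_um,z_um,intensity,hemisegment_id,genotype,true_region`
#' (extra columns such as `side` or detector scores are preserved).
#'
#' @param spots a spot table `data.frame`
#' @param path CSV path
#' @return `path` invisibly (writer); a `data.frame` (reader)
#' @export
write_spot_table <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "z_um")
  if (!all(need %in% names(df))) {
    stop("spot table must contain x_um, y_um, z_um columns", call. = FALSE)
  }
  df
}

spot_xyz <- function(spots) {
  as.matrix(spots[, c("x_um", "y_um", "z_um"), drop = FALSE])
}

#' Write region definitions to JSON
#'
#' @param regions a list of `region_definition` objects
#' @param path JSON path
#' @return `path` invisibly
#' @export
write_region_definitions <- function(regions, path) {
  payload <- lapply(regions, function(r) {
    list(
      label = r$label,
      mean_offset = as.list(r$mean_offset),
      sd = as.list(r$sd),
      halfwidth = as.list(r$halfwidth),
      box = list(lower = r$box["lower", ], upper = r$box["upper", ]),
      n_reference = r$n_reference
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
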