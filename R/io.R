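#' Read a long-format species biomass table
#'
#' Reads delimited text with one row per plot x year x species (optionally
#' per harvest), validates it, and pools harvests by summing within
#' (plot, year, species). Malformed rows (unparseable year or biomass, empty
#' ids) are dropped with a message; negative biomass is a hard error.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter (default comma).
#' @param plot_col,year_col,species_col,biomass_col Column names in the file.
#' @return A data.frame with columns `plot_id`, `year`, `species_id`,
#'   `biomass`, unique in (plot_id, year, species_id).
#' @export
read_biomass <- function(path, delim = ",",
                         plot_col = "plot_id", year_col = "year",
                         species_col = "species_id", biomass_col = "biomass") {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(plot_col, year_col, species_col, biomass_col)) {
    if (!col %in% names(raw))
      stop("required column '", col, "' not found in ", path)
  }
  x <- data.frame(
    plot_id = as.character(raw[[plot_col]]),
    year = suppressWarnings(as.integer(raw[[year_col]])),
    species_id = as.character(raw[[species_col]]),
    biomass = suppressWarnings(as.numeric(raw[[biomass_col]])),
    stringsAsFactors = FALSE)
  if (nrow(x) == 0L) {
    warning("no data rows in ", path)
    return(x)
  }
  bad <- is.na(x$year) | is.na(x$biomass) |
    is.na(x$plot_id) | x$plot_id == "" |
    is.na(x$species_id) | x$species_id == ""
  if (any(bad)) {
    message(sum(bad), " malformed row(s) dropped while reading ", path)
    x <- x[!bad, , drop = FALSE]
  }
  if (nrow(x) == 0L) {
    warning("no valid data rows in ", path)
    rownames(x) <- NULL
    return(x)
  }
  if (any(x$biomass < 0)) {
    stop("negative biomass in ", path, " at data row(s): ",
         paste(utils::head(which(x$biomass < 0), 5L), collapse = ", "))
  }
  agg <- stats::aggregate(biomass ~ plot_id + year + species_id,
                          data = x, FUN = sum)
  message(nrow(raw), " rows read; ", nrow(agg),
          " plot-year-species records after harvest pooling")
  agg <- agg[order(agg$plot_id, agg$year, agg$species_id),
             c("plot_id", "year", "species_id", "biomass")]
  rownames(agg) <- NULL
  agg
}

#' Write a tabular result to delimited text
#'
#' Writes with stable column order and full floating precision (17 significant
#' digits), so numeric values round-trip exactly through [read_table()].
#' List columns (e.g. a design's `composition`) are collapsed with ";".
#'
#' @param x A data.frame (or coercible) to write. Must not be NULL.
#' @param path Output path; the directory must exist.
#' @param delim Field delimiter.
#' @return Invisibly, the path.
#' @export
write_table <- function(x, path, delim = ",") {
  if (is.null(x)) stop("records must not be NULL")
  x <- as.data.frame(x)
  y <- x
  for (j in seq_along(y)) {
    if (is.numeric(y[[j]]) && !is.integer(y[[j]])) {
      y[[j]] <- sprintf("%.17g", y[[j]])
      y[[j]][is.na(x[[j]]) & !is.nan(x[[j]])] <- NA_character_
    } else if (is.list(y[[j]])) {
      y[[j]] <- vapply(y[[j]], paste, "", collapse = ";")
    }
  }
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  utils::write.table(y, path, sep = delim, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to the file.
#' @param delim Field delimiter.
#' @return A data.frame.
#' @export
read_table <- function(path, delim = ",") {
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE)
}
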