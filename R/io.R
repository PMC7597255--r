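#' Write a time-series matrix as CSV
#'
#' Comma-separated, one column per channel, a single header row of channel
#' names, '.' decimal separator, no row index. Values are printed with 17
#' significant digits so that reading the file back reproduces the numeric
#' matrix bit for bit.
#'
#' @param data numeric matrix (time in rows, channels in columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(data, path) {
  data <- as_block(data)
  if (is.null(colnames(data))) colnames(data) <- paste0("Y", seq_len(ncol(data)))
  chr <- apply(data, 2, function(col) sprintf("%.17g", col))
  chr <- matrix(chr, nrow = nrow(data), dimnames = dimnames(data))
  write.table(chr, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a time-series matrix from CSV
#'
#' Counterpart of [write_timeseries_csv()]; also accepts any delimited
#' numeric table with one header row (use `sep = "\t"` for TSV).
#'
#' @param path input file path.
#' @param sep field separator (default comma).
#' @return A numeric matrix with channel names from the header.
#' @export
read_timeseries_csv <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.csv(path, sep = sep, check.names = FALSE)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop(sprintf("non-numeric column(s) in %s", path))
  as.matrix(df)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to re-run a result bit-identically: the
#' resolved configuration, seeds, package and R versions, a timestamp and
#' the input/output paths.
#'
#' @param path output JSON path.
#' @param config configuration list (e.g. a [nue_config()]).
#' @param seeds integer vector of seeds actually used.
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seeds = integer(),
                               inputs = character(),
                               outputs = character()) {
  manifest <- list(
    package = "nuecte",
    version = as.character(utils::packageVersion("nuecte")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "neighbor")],
    seeds = seeds,
    inputs = inputs,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write per-target embedding selections as JSON
#'
#' @param selections a list of [run_nue()] results (or a single one).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(selections, path) {
  if (inherits(selections, "nue_selection")) selections <- list(selections)
  payload <- lapply(selections, function(s) {
    if (is.null(s)) return(NULL)
    list(target = s$target,
         selected = s$selected,
         termination_reason = s$termination_reason,
         n_iterations = s$n_iterations,
         trace = s$trace)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
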