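#' Read and write pipeline artifacts
#'
#' Plain-text persistence for the pipeline's data products: cohort tables as
#' CSV, matrices (time series, connectomes, feature tables) as TSV, and a
#' JSON run manifest recording file names, shapes, the generating seed and
#' spec. These formats round-trip exactly enough for reproducibility checks
#' (`write_matrix_tsv` stores full double precision).
#'
#' @param cohort,x,path,file,manifest arguments of the individual helpers.
#' @name bbpredict-io
NULL

#' @rdname bbpredict-io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname bbpredict-io
#' @export
read_cohort_csv <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname bbpredict-io
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "parc_ts")) x <- x$data
  utils::write.table(format(as.matrix(x), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname bbpredict-io
#' @export
read_matrix_tsv <- function(path)
  unname(as.matrix(utils::read.table(path, sep = "\t", header = FALSE)))

#' @rdname bbpredict-io
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname bbpredict-io
#' @export
read_manifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
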