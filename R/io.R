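# TSV interchange: header row, '#'-prefixed metadata lines, UTF-8, NA for
# missing values. Every file written by the pipeline records the config
# fingerprint and seed in its metadata lines.

# fingerprint covers the analytic settings only, not where results land
config_fingerprint <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$input_dir <- NULL
  fnv1a32(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                           force = TRUE))
}

output_header <- function(config = NULL, seed = NULL) {
  c(sprintf("# hormetrics %s", as.character(utils::packageVersion("hormetrics"))),
    sprintf("# config_hash=%s seed=%s",
            if (is.null(config)) fnv1a32("") else config_fingerprint(config),
            seed %||% (if (is.list(config)) config$rng_seed %||% "NA" else "NA")))
}

write_tsv_hdr <- function(df, path, header = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# Rectangular matrix with row labels in the first column
write_matrix_tsv <- function(mat, path, header = character(0),
                             rowname_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_col
  write_tsv_hdr(df, path, header)
}

#' Read a pipeline TSV (skipping `#` metadata lines)
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a rectangular matrix TSV written by the pipeline
#'
#' @param path File path; first column holds row labels.
#' @return A numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}
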