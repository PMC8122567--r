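SCHEMA_VERSION <- 1L

schema_header <- function(kind) {
  sprintf("# spliceshift_schema\t%s\t%d", kind, SCHEMA_VERSION)
}

write_table_with_schema <- function(df, path, kind, sep = "\t") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(schema_header(kind), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_table_with_schema <- function(path, sep = "\t") {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# spliceshift_schema"))
    warning("no schema header in ", path)
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read and write pipeline artifacts
#'
#' Tabular artifacts (event catalogs, junction counts, truth tables, PSI
#' tables, screen results, gel lanes, survival cohorts) are plain TSV/CSV
#' with a schema-version comment line; sequences are FASTA with one record
#' per region, identified as \code{event_id|region}.
#'
#' @param x the object to write (a data.frame, or a sequence table with
#'   \code{event_id}, \code{region}, \code{seq} for FASTA).
#' @param path file path.
#' @name spliceshift-io
NULL

#' @rdname spliceshift-io
#' @export
write_events_tsv <- function(x, path) write_table_with_schema(x, path, "events")

#' @rdname spliceshift-io
#' @export
read_events_tsv <- function(path) read_table_with_schema(path)

#' @rdname spliceshift-io
#' @export
write_counts_tsv <- function(x, path) write_table_with_schema(x, path, "counts")

#' @rdname spliceshift-io
#' @export
read_counts_tsv <- function(path) read_table_with_schema(path)

#' @rdname spliceshift-io
#' @export
write_truth_tsv <- function(x, path) write_table_with_schema(x, path, "truth")

#' @rdname spliceshift-io
#' @export
read_truth_tsv <- function(path) read_table_with_schema(path)

#' @rdname spliceshift-io
#' @export
write_psi_tsv <- function(x, path) write_table_with_schema(x, path, "psi")

#' @rdname spliceshift-io
#' @export
write_screen_tsv <- function(x, path)
  write_table_with_schema(as.data.frame(x), path, "screen")

#' @rdname spliceshift-io
#' @export
read_screen_tsv <- function(path) read_table_with_schema(path)

#' @rdname spliceshift-io
#' @export
write_lanes_tsv <- function(x, path) write_table_with_schema(x, path, "lanes")

#' @rdname spliceshift-io
#' @export
read_lanes_tsv <- function(path) read_table_with_schema(path)

#' @rdname spliceshift-io
#' @export
write_cohort_csv <- function(x, path)
  write_table_with_schema(x, path, "cohort", sep = ",")

#' @rdname spliceshift-io
#' @export
read_cohort_csv <- function(path) read_table_with_schema(path, sep = ",")

#' @rdname spliceshift-io
#' @export
write_sequences_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- paste(x$event_id, x$region, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname spliceshift-io
#' @export
read_sequences_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  data.frame(event_id = vapply(parts, `[`, "", 1),
             region = vapply(parts, `[`, "", 2),
             seq = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}
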