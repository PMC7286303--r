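#' Read and write connectomes and tables
#'
#' Connectomes are serialized as square CSV with a header row and first
#' column of region names; streamline tables as TSV; cohort, behavior
#' and metric tables as CSV. File naming in [run_pipeline()] encodes
#' subject, timepoint and kind.
#'
#' @name longconn_io
NULL

#' @rdname longconn_io
#' @param x a `connectome`.
#' @param path file path.
#' @export
write_connectome_csv <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  df <- data.frame(region = x$nodes, x$weights, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname longconn_io
#' @param kind weight kind of the stored connectome.
#' @param subject_id,timepoint_index optional provenance tags.
#' @export
read_connectome_csv <- function(path, kind, subject_id = NA_character_,
                                timepoint_index = NA_integer_) {
  df <- read.csv(path, check.names = FALSE)
  nodes <- df[[1]]
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- nodes
  if (!identical(colnames(w), as.character(nodes)))
    stop("connectome CSV header does not match its region column")
  connectome(w, nodes, kind, subject_id, timepoint_index)
}

#' @rdname longconn_io
#' @param streamlines a streamline table.
#' @export
write_streamline_tsv <- function(streamlines, path) {
  write.table(streamlines, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname longconn_io
#' @export
read_streamline_tsv <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("streamline_table", "data.frame")
  out
}
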