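# Gene-call tables and their on-disk representations.
#
# A call set is a plain data.frame (class rnp_calls) with one row per
# predicted gene.  Coordinates are 1-based inclusive on the forward strand
# with a strand column, as in standard genome annotation; `sequence` and
# `structure` are in transcript orientation.

.call_columns <- c("seq_id", "strand", "start", "end", "subfamily",
                   "dm_variant", "local_score", "global_score", "evalue",
                   "length", "sequence", "structure", "flags")

new_calls <- function(df = NULL) {
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(seq_id = character(0), strand = character(0),
                     start = integer(0), end = integer(0),
                     subfamily = character(0), dm_variant = character(0),
                     local_score = numeric(0), global_score = numeric(0),
                     evalue = numeric(0), length = integer(0),
                     sequence = character(0), structure = character(0),
                     flags = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(.call_columns %in% names(df)))
  df <- df[, .call_columns]
  class(df) <- c("rnp_calls", "data.frame")
  df
}

#' Write gene calls as TSV, FASTA or structure-annotated FASTA
#'
#' @param calls an `rnp_calls` data.frame (from [scan_all()] etc.).
#' @param path output file, or `NULL` to only return the text.
#' @param style `"tsv"` (one row per call; fixed column order `seq_id`,
#'   `strand`, `start_1based`, `end_1based`, `subfamily`, `dm_variant`,
#'   `local_score_bits`, `global_score_bits`, `evalue`, `length`),
#'   `"fasta"`, or `"fasta+structure"` (header, sequence line, and a
#'   dot-bracket line of equal length).
#' @return the file content as a single string, invisibly.
#' @export
write_calls <- function(calls, path = NULL,
                        style = c("tsv", "fasta", "fasta+structure")) {
  style <- match.arg(style)
  if (style == "fasta+structure" &&
      nrow(calls) && any(nchar(calls$structure) != nchar(calls$sequence)))
    stop("internal consistency error: structure/sequence length mismatch")
  if (style == "tsv") {
    header <- paste("seq_id", "strand", "start_1based", "end_1based",
                    "subfamily", "dm_variant", "local_score_bits",
                    "global_score_bits", "evalue", "length", sep = "\t")
    body <- if (nrow(calls)) {
      vapply(seq_len(nrow(calls)), function(i) {
        paste(calls$seq_id[i], calls$strand[i], calls$start[i],
              calls$end[i], calls$subfamily[i], calls$dm_variant[i],
              sprintf("%.4f", calls$local_score[i]),
              sprintf("%.4f", calls$global_score[i]),
              sprintf("%.6e", calls$evalue[i]),
              calls$length[i], sep = "\t")
      }, character(1))
    } else character(0)
    txt <- paste0(paste(c(header, body), collapse = "\n"), "\n")
  } else {
    hdr <- sprintf(">%s/%d-%d(%s) %s %s E=%.6e",
                   calls$seq_id, calls$start, calls$end, calls$strand,
                   calls$subfamily, calls$dm_variant, calls$evalue)
    blocks <- if (style == "fasta") paste0(hdr, "\n", calls$sequence)
              else paste0(hdr, "\n", calls$sequence, "\n", calls$structure)
    txt <- if (nrow(calls)) paste0(paste(blocks, collapse = "\n"), "\n")
           else ""
  }
  if (!is.null(path)) cat(txt, file = path)
  invisible(txt)
}

#' @export
print.rnp_calls <- function(x, ...) {
  cat(sprintf("%d gene call(s)\n", nrow(x)))
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[, c("seq_id", "strand", "start",
                                             "end", "subfamily",
                                             "dm_variant", "evalue")], 15L)
    print(show, row.names = FALSE)
    if (nrow(x) > 15L) cat("...\n")
  }
  invisible(x)
}
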