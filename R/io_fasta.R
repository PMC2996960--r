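#' Read a FASTA file into a table of sequence records
#'
#' Residues are normalized to the canonical internal alphabet (uppercase DNA,
#' U folded to T); DNA and RNA input are therefore interchangeable.
#'
#' @param path FASTA file (plain or gzip).
#' @return a `data.frame` of class `rnp_seqs` with columns `id`,
#'   `description`, `residues`, `length`, one row per record, input order
#'   preserved.
#' @details Duplicate ids raise a warning and are suffixed to be unique.
#'   An empty file or a non-IUPAC residue symbol is an error (the error
#'   names the offending position).
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    warning("duplicate sequence ids; suffixing to make them unique")
    ids <- make.unique(ids, sep = "_")
  }
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  residues <- normalize_residues(as.character(set), what = "record")
  new_rnp_seqs(ids, residues, desc)
}

#' Construct a sequence-record table
#'
#' @param id,residues,description per-record fields; `residues` are
#'   normalized.
#' @return an `rnp_seqs` data.frame.
#' @export
new_rnp_seqs <- function(id, residues, description = "") {
  residues <- normalize_residues(residues, what = "record")
  out <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description),
                                          length(id)),
                    residues = residues,
                    length = nchar(residues),
                    stringsAsFactors = FALSE)
  class(out) <- c("rnp_seqs", "data.frame")
  out
}

#' Write sequence records as FASTA
#'
#' @param seqs an `rnp_seqs` table (or anything with `id`, `residues` and
#'   optionally `description` columns).
#' @param path output file; `NULL` returns the text invisibly without
#'   writing.
#' @param width line-wrap width.
#' @return the FASTA text, invisibly.
#' @export
write_fasta <- function(seqs, path = NULL, width = 60L) {
  blocks <- vapply(seq_len(nrow(seqs)), function(i) {
    hdr <- if (!is.null(seqs$description) && nzchar(seqs$description[i]))
      paste(seqs$id[i], seqs$description[i]) else seqs$id[i]
    body <- gsub(sprintf("(.{%d})", width), "\\1\n", seqs$residues[i])
    body <- sub("\n$", "", body)
    paste0(">", hdr, "\n", body)
  }, character(1))
  txt <- paste0(paste(blocks, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' @export
print.rnp_seqs <- function(x, ...) {
  cat(sprintf("%d sequence record(s), %d nt total\n",
              nrow(x), sum(x$length)))
  show <- utils::head(x, 10L)
  for (i in seq_len(nrow(show))) {
    r <- show$residues[i]
    if (nchar(r) > 50L) r <- paste0(substr(r, 1L, 50L), "...")
    cat(sprintf("  %s (%d nt) %s\n", show$id[i], show$length[i], r))
  }
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
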