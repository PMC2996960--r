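# Stockholm structural alignments.
#
# A minimal single-alignment Stockholm reader/writer: sequence rows plus one
# '#=GC SS_cons' consensus-structure annotation.  WUSS structure symbols are
# mapped onto the internal bracket alphabet: '<'/'>' for nested helices
# (all of '<>()[]{}' collapse onto this tier), 'A'/'a', 'B'/'b', ... for
# pseudoknot tiers, and '.' for unpaired columns.

.canonical_structure <- function(s) {
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  x[x %in% c("(", "[", "{")] <- "<"
  x[x %in% c(")", "]", "}")] <- ">"
  x[x %in% c(",", ":", "_", "-", "~", ".")] <- "."
  bad <- !(x %in% c("<", ">", ".") | grepl("[A-Za-z]", x))
  if (any(bad))
    stop("unsupported structure symbol '", x[which(bad)[1L]], "'")
  paste(x, collapse = "")
}

# pair lists per tier from a canonical structure string.
# Nested brackets of the four WUSS types are matched with independent stacks
# (WUSS uses them as nesting-depth markers of one tier), then merged.
.structure_pairs <- function(struct, canonical = FALSE) {
  if (!canonical) struct <- .canonical_structure(struct)
  x <- strsplit(struct, "", fixed = TRUE)[[1L]]
  pairs <- list()
  stack <- integer(0)
  for (i in seq_along(x)) {
    if (x[i] == "<") stack <- c(stack, i)
    else if (x[i] == ">") {
      if (!length(stack)) stop("unbalanced brackets in helix tier 1")
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced brackets in helix tier 1")
  tier1 <- if (length(pairs)) do.call(rbind, pairs)
           else matrix(integer(0), 0L, 2L)
  tier1 <- tier1[order(tier1[, 1L]), , drop = FALSE]

  pk <- list()
  for (L in intersect(LETTERS, toupper(x[grepl("[A-Za-z]", x)]))) {
    op <- which(x == L); cl <- which(x == tolower(L))
    if (length(op) != length(cl))
      stop("unbalanced brackets in pseudoknot tier ", L)
    if (length(op))
      pk[[L]] <- cbind(op, rev(cl))  # innermost-first nesting within tier
  }
  list(tier1 = tier1, pk = pk, struct = struct)
}

#' Read a Stockholm alignment with a consensus structure
#'
#' @param path Stockholm file containing one alignment and exactly one
#'   `#=GC SS_cons` annotation (split across interleaved blocks is fine).
#' @return an object of class `rnp_aln`: list with `ids`, `seqs` (gapped
#'   rows, normalized alphabet, gaps as `-`), `structure` (canonical bracket
#'   string) and `columns`.
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list(); ss <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || ln == "//" ||
        grepl("^# STOCKHOLM", ln)) next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (grepl("^#", ln)) {
      next  # other markup ignored
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) != 2L) stop("malformed Stockholm row: ", ln)
      seqs[[f[1L]]] <- paste0(if (is.null(seqs[[f[1L]]])) ""
                              else seqs[[f[1L]]], f[2L])
    }
  }
  if (!length(ss))
    stop("Stockholm file has no #=GC SS_cons structure line: ", path)
  if (!length(seqs)) stop("Stockholm file has no sequence rows: ", path)
  structure_line <- paste(ss, collapse = "")
  rows <- unlist(seqs)
  new_rnp_aln(names(rows), unname(rows), structure_line)
}

#' Construct a structural alignment
#'
#' @param ids,seqs row names and gapped row strings (equal lengths; gaps
#'   `-` or `.`).
#' @param structure consensus structure (WUSS or canonical brackets), same
#'   length as the rows; bracket balance is validated per tier.
#' @return an `rnp_aln` object.
#' @export
new_rnp_aln <- function(ids, seqs, structure) {
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  nc <- unique(nchar(seqs))
  struct <- .canonical_structure(structure)
  if (length(nc) != 1L || nc != nchar(struct))
    stop("alignment rows and consensus structure must have identical length")
  bad <- regexpr("[^ACGTRYSWKMBDHVN-]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("row %s: non-IUPAC symbol at column %d", ids[i], bad[i]))
  }
  .structure_pairs(struct, canonical = TRUE)  # validates balance
  out <- list(ids = as.character(ids), seqs = unname(seqs),
              structure = struct, columns = nc)
  class(out) <- "rnp_aln"
  out
}

#' Write a structural alignment in Stockholm format
#' @param aln an `rnp_aln` object.
#' @param path output file, or `NULL` to only return the text.
#' @return the text, invisibly.
#' @export
write_stockholm <- function(aln, path = NULL) {
  w <- max(nchar(aln$ids), nchar("#=GC SS_cons"))
  rows <- sprintf("%-*s %s", w, aln$ids, aln$seqs)
  txt <- paste(c("# STOCKHOLM 1.0", "", rows,
                 sprintf("%-*s %s", w, "#=GC SS_cons", aln$structure),
                 "//"), collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(paste0(txt, "\n"))
}

#' @export
print.rnp_aln <- function(x, ...) {
  cat(sprintf("structural alignment: %d rows x %d columns\n",
              length(x$ids), x$columns))
  pr <- .structure_pairs(x$structure, canonical = TRUE)
  tiers <- paste(names(pr$pk), collapse = " ")
  cat(sprintf("  %d nested base pairs; pseudoknot tiers: %s\n",
              nrow(pr$tier1), if (nzchar(tiers)) tiers else "none"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
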