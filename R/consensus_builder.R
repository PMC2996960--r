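# Descriptor construction from annotated structural alignments.
#
# Column-wise consensus follows the degenerate-IUPAC/gap rule: a column is
# summarized by the unique IUPAC code whose expansion equals exactly the set
# of bases observed in it, or by the gap character as soon as the column
# contains at least one gap.  Region selection is an input (a region table),
# not an inference: which regions are conserved enough to anchor a filter is
# a curation decision, so the builder only mechanizes the emission of a
# descriptor from a chosen region set.  A per-column entropy helper is
# provided to guide that choice, but it is not authoritative.

# reverse lookup mask -> IUPAC symbol (prefer T over U)
.mask_to_iupac <- local({
  m <- .iupac_mask[setdiff(names(.iupac_mask), "U")]
  out <- character(15L)
  out[m] <- names(m)
  out
})

#' Summarize one alignment column as an IUPAC symbol or gap
#'
#' @param column character vector of residues/gaps observed in the column
#'   (one entry per row; `-` or `.` are gaps).
#' @return the gap character `"-"` if any gap is present, else the unique
#'   IUPAC code whose expansion equals the set of observed bases
#'   (ambiguous residues contribute their whole expansion).
#' @export
column_consensus <- function(column) {
  if (!length(column)) stop("empty alignment column")
  column <- chartr("U", "T", toupper(column))
  if (any(column %in% c("-", "."))) return("-")
  m <- .iupac_mask[column]
  if (anyNA(m)) stop("invalid residue in column: ",
                     column[which(is.na(m))[1L]])
  .mask_to_iupac[Reduce(bitwOr, m)]
}

#' Column-wise consensus of a structural alignment
#'
#' @param aln an `rnp_aln` alignment.
#' @return an object of class `rnp_consensus`: list with
#'   `consensus` (text over IUPAC codes and `-`), `alignment` (the source),
#'   and `counts` (per-column base tallies).
#' @export
alignment_consensus <- function(aln) {
  rows <- strsplit(aln$seqs, "", fixed = TRUE)
  cols <- lapply(seq_len(aln$columns), function(j)
    vapply(rows, `[[`, character(1), j))
  cons <- vapply(cols, column_consensus, character(1))
  counts <- lapply(cols, function(cc) table(factor(cc, levels = c(
    "A", "C", "G", "T", "-"))))
  out <- list(consensus = paste(cons, collapse = ""), alignment = aln,
              counts = counts)
  class(out) <- "rnp_consensus"
  out
}

#' Per-column Shannon entropy of an alignment
#'
#' Advisory helper for choosing descriptor regions; low entropy marks
#' well-conserved columns.
#'
#' @param aln an `rnp_aln` alignment.
#' @return numeric vector (bits) over columns; `NA` for all-gap columns.
#'   Gap rows are excluded from the frequencies.
#' @export
column_entropy <- function(aln) {
  rows <- strsplit(aln$seqs, "", fixed = TRUE)
  vapply(seq_len(aln$columns), function(j) {
    cc <- vapply(rows, `[[`, character(1), j)
    cc <- cc[cc != "-"]
    if (!length(cc)) return(NA_real_)
    p <- table(cc) / length(cc)
    -sum(p * log2(p))
  }, numeric(1))
}

#' Read a descriptor region table
#'
#' @param path TSV with header columns `element_label`,
#'   `kind` (`ss`/`helix5`/`helix3`), `col_start`, `col_end` (1-based
#'   inclusive alignment columns) and `budget`.
#' @return a data.frame.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element_label", "kind", "col_start", "col_end", "budget")
  if (!all(need %in% names(tab)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  tab
}

# observed ungapped stretch lengths across rows for a column range
.stretch_lengths <- function(aln, cols) {
  if (!length(cols)) return(c(0L, 0L))
  vapply(strsplit(aln$seqs, "", fixed = TRUE), function(r)
    sum(r[cols] != "-"), integer(1))
}

.run_token <- function(lens, slack) {
  list(type = "run", min = max(0L, min(lens) - slack),
       max = max(lens) + slack)
}

#' Build a descriptor model from a consensus annotation and a region table
#'
#' SS patterns take the consensus symbols of the selected columns; maximal
#' gap-column stretches inside an SS region, and the stretches between
#' regions, become run tokens bounded by the ungapped stretch lengths
#' observed across the alignment rows (widened by `slack`).  Helix regions
#' come as `helix5`/`helix3` column-range pairs of equal width and must be
#' gap-free.
#'
#' @param annotation an `rnp_consensus` from [alignment_consensus()].
#' @param regions region table (see [read_region_table()]), ordered and
#'   non-overlapping.
#' @param name,subfamily,variant passed to the emitted model.
#' @param slack widening applied to run-token bounds (default 0); the knob
#'   for trading false-positive rate against sensitivity.
#' @return an `rnp_dm` descriptor.
#' @export
build_descriptor <- function(annotation, regions, name, subfamily,
                             variant = "general", slack = 0L) {
  aln <- annotation$alignment
  cons <- strsplit(annotation$consensus, "", fixed = TRUE)[[1L]]
  regions <- regions[order(regions$col_start), , drop = FALSE]
  if (any(regions$col_start > regions$col_end) ||
      any(regions$col_start < 1L) || any(regions$col_end > aln$columns))
    stop("region outside alignment columns")
  if (nrow(regions) > 1L &&
      any(regions$col_start[-1L] <= regions$col_end[-nrow(regions)]))
    stop("overlapping regions")

  elements <- list()
  topology <- character(0)
  synth <- 0L
  add_gap_run <- function(cols) {
    if (!length(cols)) return()
    synth <<- synth + 1L
    lab <- sprintf("s%d_gap", synth)
    elements[[lab]] <<- list(kind = "ss", label = lab, budget = 0L,
                             tokens = list(.run_token(
                               .stretch_lengths(aln, cols), slack)))
    topology <<- c(topology, lab)
  }

  prev_end <- NULL
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!is.null(prev_end) && r$col_start > prev_end + 1L)
      add_gap_run(seq.int(prev_end + 1L, r$col_start - 1L))
    prev_end <- r$col_end
    cols <- seq.int(r$col_start, r$col_end)
    if (r$kind == "ss") {
      toks <- list()
      j <- 1L
      while (j <= length(cols)) {
        if (cons[cols[j]] == "-") {
          k <- j
          while (k < length(cols) && cons[cols[k + 1L]] == "-") k <- k + 1L
          toks[[length(toks) + 1L]] <-
            .run_token(.stretch_lengths(aln, cols[j:k]), slack)
          j <- k + 1L
        } else {
          toks[[length(toks) + 1L]] <- list(type = "sym",
                                            sym = cons[cols[j]])
          j <- j + 1L
        }
      }
      elements[[r$element_label]] <- list(kind = "ss",
                                          label = r$element_label,
                                          budget = as.integer(r$budget),
                                          tokens = toks)
      topology <- c(topology, r$element_label)
    } else if (r$kind %in% c("helix5", "helix3")) {
      strand <- paste(cons[cols], collapse = "")
      if (grepl("-", strand, fixed = TRUE))
        stop("helix region ", r$element_label,
             " contains gap consensus columns")
      lab <- r$element_label
      if (r$kind == "helix5") {
        elements[[lab]] <- list(kind = "helix", label = lab,
                                budget = as.integer(r$budget),
                                strand5 = strand, strand3 = NULL,
                                pairs = default_pair_set())
        topology <- c(topology, lab)
      } else {
        if (is.null(elements[[lab]]) || !is.null(elements[[lab]]$strand3))
          stop("helix3 region without preceding helix5: ", lab)
        if (nchar(strand) != nchar(elements[[lab]]$strand5))
          stop("helix ", lab, ": 5' and 3' region widths differ")
        elements[[lab]]$strand3 <- strand
        topology <- c(topology, paste0(lab, "'"))
      }
    } else stop("unknown region kind: ", r$kind)
  }
  open_helices <- vapply(elements, function(e)
    e$kind == "helix" && is.null(e$strand3), logical(1))
  if (any(open_helices))
    stop("helix5 region without helix3: ",
         paste(names(elements)[open_helices], collapse = ", "))
  new_descriptor(name, subfamily, variant, topology, elements)
}

#' @export
print.rnp_consensus <- function(x, ...) {
  cat("consensus annotation over", nchar(x$consensus), "columns\n")
  cat(" ", x$consensus, "\n")
  invisible(x)
}
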