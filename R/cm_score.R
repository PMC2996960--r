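# Scoring sequences against a covariance model.

.subject_codes <- function(residues) {
  m <- .residue_masks(residues)
  code <- match(m, c(1L, 2L, 4L, 8L)) - 1L
  code[is.na(code)] <- 4L  # ambiguity codes emit averaged log-odds
  code
}

.cm_alignment <- function(cm, res, out, global) {
  L <- nchar(res)
  colpos <- out$colpos  # 0-based subject positions, -1 = deleted column
  span <- c(out$start, out$end)
  schars <- rep(".", span[2L] - span[1L])
  cons <- strsplit(cm$structure, "", fixed = TRUE)[[1L]]
  matched <- which(colpos >= 0L)
  if (length(matched))
    schars[colpos[matched] - span[1L] + 1L] <- cons[matched]
  core <- if (length(matched)) range(colpos[matched]) else c(NA, NA)
  flags <- character(0)
  if (!length(matched)) flags <- c(flags, "all_deleted")
  st <- list(score = out$score,
             start = span[1L] + 1L, end = span[2L],
             core_start = core[1L] + 1L, core_end = core[2L] + 1L,
             structure = paste(schars, collapse = ""),
             colpos = ifelse(colpos >= 0L, colpos + 1L, NA_integer_),
             mode = if (global) "global" else "local",
             flags = flags)
  class(st) <- "rnp_cm_alignment"
  st
}

.cm_score <- function(cm, residues, global, short_fraction = 0.5) {
  stopifnot(inherits(cm, "rnp_cm"))
  if (cm$M < 1L) stop("empty covariance model")
  residues <- normalize_residues(residues)
  if (!nchar(residues)) stop("cannot score an empty sequence")
  out <- cpp_cm_score(cm$nodes, cm$top, as.list(cm$gaps),
                      .subject_codes(residues), cm$M, global)
  al <- .cm_alignment(cm, residues, out, global)
  if (global && nchar(residues) < short_fraction * cm$M)
    al$flags <- c(al$flags, "short_input")
  al
}

#' Score a sequence against a covariance model in global mode
#'
#' Maximum-score parse aligning the whole model to the whole input:
#' subject residues not assigned to consensus columns are charged insert
#' penalties, unused consensus columns delete penalties.  The matched span
#' is the full input; `core_start`/`core_end` give the sub-span covered by
#' consensus columns.
#'
#' @param cm an `rnp_cm` model.
#' @param residues subject sequence (non-empty).
#' @param short_fraction inputs shorter than this fraction of the model
#'   length are scored (an all-delete parse always exists) but flagged
#'   `short_input`.
#' @return an `rnp_cm_alignment`: list with `score` (bits), `start`/`end`
#'   (matched span, 1-based inclusive), `core_start`/`core_end`,
#'   `structure` (dot-bracket over the matched span; deleted columns
#'   omitted, inserted residues unpaired), `colpos` (subject position per
#'   consensus column, `NA` when deleted) and `flags`.
#' @export
cm_score_global <- function(cm, residues, short_fraction = 0.5)
  .cm_score(cm, residues, global = TRUE, short_fraction = short_fraction)

#' Score a sequence against a covariance model in local mode
#'
#' The whole model is aligned, but any prefix/suffix of the subject is free
#' (score 0 per flanking residue); the matched span excludes the free
#' flanks.  Model truncation is not supported: the DM filter has already
#' localized the candidate, so locality on the subject side suffices.
#'
#' @inheritParams cm_score_global
#' @return an `rnp_cm_alignment`; see [cm_score_global()].
#' @export
cm_score_local <- function(cm, residues)
  .cm_score(cm, residues, global = FALSE)

#' @export
print.rnp_cm_alignment <- function(x, ...) {
  cat(sprintf("%s CM alignment: score %.2f bits, span %d-%d\n",
              x$mode, x$score, x$start, x$end))
  if (nchar(x$structure) <= 70L) cat(" ", x$structure, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}
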