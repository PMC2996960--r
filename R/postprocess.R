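# Post-scan analyses: unique genes, subfamily tallies, GC content,
# nearest-homolog assignment and gene-size/genome-size correlation.

#' Collapse gene calls to unique genes
#'
#' Identity is exact sequence equality after strand normalization (a
#' sequence and its reverse complement are the same gene).  The
#' representative is the first call in input order; the operation is
#' idempotent and conserves total multiplicity.
#'
#' @param calls an `rnp_calls` data.frame (a `multiplicity` column from a
#'   previous [dedup_calls()] round is honoured).
#' @param identity grouping threshold in `[0, 1]`.  The default 1 groups
#'   exact sequences only; below 1, near-duplicates are clustered greedily
#'   (a call joins the first representative whose global alignment
#'   identity reaches the threshold).
#' @return an object of class `rnp_unique_genes`: the representative calls
#'   with a `multiplicity` column.
#' @export
dedup_calls <- function(calls, identity = 1) {
  mult <- if (!is.null(calls$multiplicity)) calls$multiplicity
          else rep(1L, nrow(calls))
  canon <- vapply(calls$sequence, function(s) {
    rc <- reverse_complement(s)
    if (s <= rc) s else rc
  }, character(1), USE.NAMES = FALSE)
  if (identity < 1 && nrow(calls) > 1L) {
    reps <- integer(0)            # indices of cluster representatives
    rep_idx <- integer(nrow(calls))
    for (i in seq_len(nrow(calls))) {
      hit <- 0L
      for (r in reps) {
        if (canon[i] == canon[r]) { hit <- r; break }
        pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
          Biostrings::DNAString(canon[i]), Biostrings::DNAString(canon[r]),
          type = "global"))
        if (pid >= 100 * identity) { hit <- r; break }
      }
      if (hit == 0L) { reps <- c(reps, i); hit <- i }
      rep_idx[i] <- hit
    }
    first <- seq_len(nrow(calls)) %in% reps
    rep_idx <- match(rep_idx, which(first))
    out <- calls[first, , drop = FALSE]
    out$multiplicity <- as.integer(tapply(mult, rep_idx, sum))
    class(out) <- c("rnp_unique_genes", "data.frame")
    return(out)
  }
  first <- !duplicated(canon)
  rep_idx <- match(canon, canon[first])
  out <- calls[first, , drop = FALSE]
  out$multiplicity <- as.integer(tapply(mult, rep_idx, sum))
  class(out) <- c("rnp_unique_genes", "data.frame")
  out
}

#' GC content of a sequence
#'
#' @param residues character vector of sequences.
#' @return `(G + C) / (length - N_count)` per sequence, in `[0, 1]`;
#'   all-N sequences are an error.
#' @export
gc_content <- function(residues) {
  residues <- toupper(residues)
  n <- nchar(residues)
  gc <- nchar(gsub("[^GCgcSs]", "", residues))
  nn <- nchar(gsub("[^Nn]", "", residues))
  if (any(n == 0L) || any(n == nn))
    stop("GC content undefined for empty or all-N sequence")
  gc / (n - nn)
}

# Karlin-Altschul lambda for a match/mismatch scoring scheme with uniform
# base composition: solve sum p_i p_j exp(lambda * s_ij) = 1
.ka_lambda <- function(match, mismatch) {
  f <- function(l) 4 / 16 * exp(l * match) + 12 / 16 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 2), tol = 1e-9)$root
}

#' Assign the nearest reference homolog to a gene call
#'
#' Local alignment (match +5, mismatch -4, gap open -10, extend -1) of the
#' query against every reference; per-reference E-values use a
#' Karlin-Altschul-style statistic with the query length and the total
#' reference length as the search space (`K` is a fixed heuristic 0.1 for
#' this scheme; gapped scores make the tail estimate conservative).
#' The assignment level is `"species"` when exactly one reference passes
#' the cutoff, `"genus"` when several pass but share a genus, and `"none"`
#' otherwise (multiple genera set the `multi_genus` flag).
#'
#' @param query one-row `rnp_calls` data.frame, or a residue string.
#' @param references data.frame with columns `id`, `species`, `genus`,
#'   `residues`.
#' @param evalue_cutoff strict upper bound for a passing reference
#'   (default 1e-50).
#' @param match,mismatch,gap_open,gap_extend alignment parameters.
#' @return an object of class `rnp_homolog`.
#' @export
assign_homolog <- function(query, references, evalue_cutoff = 1e-50,
                           match = 5, mismatch = -4, gap_open = 10,
                           gap_extend = 1) {
  if (!nrow(references)) stop("references must be non-empty")
  qres <- if (is.character(query)) query else query$sequence
  qid <- if (is.character(query)) "query" else
    sprintf("%s:%d-%d", query$seq_id, query$start, query$end)
  qres <- normalize_residues(qres)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  lambda <- .ka_lambda(match, mismatch)
  K <- 0.1
  n_total <- sum(nchar(references$residues))
  scores <- vapply(references$residues, function(r) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qres), Biostrings::DNAString(r),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  ev <- K * nchar(qres) * n_total * exp(-lambda * scores)
  passing <- ev < evalue_cutoff
  genera <- unique(references$genus[passing])
  level <- if (sum(passing) == 1L) "species"
           else if (sum(passing) > 1L && length(genera) == 1L) "genus"
           else "none"
  out <- list(query_id = qid,
              hits = data.frame(id = references$id,
                                species = references$species,
                                genus = references$genus,
                                score = scores, evalue = ev,
                                passing = passing,
                                stringsAsFactors = FALSE),
              level = level,
              best_score = max(scores), best_evalue = min(ev),
              multi_genus = sum(passing) > 1L && length(genera) > 1L)
  class(out) <- "rnp_homolog"
  out
}

#' @export
print.rnp_homolog <- function(x, ...) {
  cat(sprintf("homolog assignment for %s: level=%s (%d passing)\n",
              x$query_id, x$level, sum(x$hits$passing)))
  invisible(x)
}

#' Subfamily tally of a unique gene set
#'
#' @param unique an `rnp_unique_genes` set (or any call table with a
#'   `subfamily` column).
#' @return data.frame with one row per subfamily (all seven, zeros
#'   included) and the representative count.
#' @export
subfamily_summary <- function(unique) {
  tab <- table(factor(unique$subfamily, levels = .subfamilies))
  data.frame(subfamily = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Gene-size versus genome-size rank correlation per subfamily
#'
#' @param pairs data.frame with columns `subfamily`, `gene_length`,
#'   `genome_length`, one row per organism.
#' @param min_n groups with fewer pairs are skipped with a warning
#'   (default 3).
#' @return data.frame with `subfamily`, `rho` (Spearman, average ranks for
#'   ties) and `n`.
#' @export
size_correlation <- function(pairs, min_n = 3L) {
  out <- list()
  for (sf in unique(pairs$subfamily)) {
    g <- pairs[pairs$subfamily == sf, ]
    if (nrow(g) < min_n) {
      warning("subfamily ", sf, ": fewer than ", min_n,
              " pairs, skipped")
      next
    }
    rho <- stats::cor(g$gene_length, g$genome_length, method = "spearman")
    out[[length(out) + 1L]] <- data.frame(subfamily = sf, rho = rho,
                                          n = nrow(g),
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(subfamily = character(0),
                                      rho = numeric(0), n = integer(0)))
  do.call(rbind, out)
}
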