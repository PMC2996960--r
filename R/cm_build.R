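# Simplified covariance models (profile SCFGs).
#
# A covariance model captures position-specific sequence and base-pair
# conservation of an RNA family.  This implementation is deliberately lean:
# a guide tree of MATL (unpaired consensus column), MATP (paired columns),
# BIF and END nodes with log-odds emission tables, and four fixed, shared
# gap penalties (insert open/extend, delete open/extend) instead of per-node
# learned transitions.  A MATP either emits both pair residues or deletes
# both of its columns; pseudoknot tiers of the consensus structure cannot be
# represented in a context-free grammar and are dropped (descriptors carry
# them instead).

.NODE_MATL <- 0L; .NODE_MATP <- 1L; .NODE_BIF <- 2L; .NODE_END <- 3L

# log-odds with N-averaged margins: 4 -> 5 vector, 16 (col-major b5 fast) -> 25
.extend_single <- function(p) {
  lo <- log2(p / 0.25)
  c(lo, log2(mean(p) / 0.25))
}
.extend_pair <- function(p16) {
  m <- matrix(p16, 4L, 4L)  # rows b5, cols b3
  e <- matrix(0, 5L, 5L)
  e[1:4, 1:4] <- m
  e[5L, 1:4] <- colMeans(m)
  e[1:4, 5L] <- rowMeans(m)
  e[5L, 5L] <- mean(m)
  log2(e / (1 / 16))
}

#' Build a covariance model from a structural alignment
#'
#' @param aln an `rnp_aln` alignment with a consensus structure.
#' @param gap_threshold columns with a gap fraction below this are match
#'   columns (default 0.5).
#' @param pseudocount Laplace weight added to emission counts (default 1).
#' @param gaps named numeric of gap penalties in bits (all `<= 0`):
#'   `insert_open`, `insert_extend`, `delete_open`, `delete_extend`.
#' @return an object of class `rnp_cm` (uncalibrated; see
#'   [cm_calibrate()]).
#' @details Emission scores are
#'   `log2((count + pseudocount) / (total + k * pseudocount) / background)`
#'   with background 1/4 for single columns (k = 4) and 1/16 for pairs
#'   (k = 16).  A structure pair whose partner falls on a gap-majority
#'   (non-match) column is demoted to an unpaired match column with a
#'   warning.
#' @export
build_cm <- function(aln, gap_threshold = 0.5, pseudocount = 1,
                     gaps = c(insert_open = -3, insert_extend = -1,
                              delete_open = -3, delete_extend = -1)) {
  stopifnot(inherits(aln, "rnp_aln"), pseudocount > 0)
  rows <- strsplit(aln$seqs, "", fixed = TRUE)
  nrows <- length(rows)
  colchars <- lapply(seq_len(aln$columns), function(j)
    vapply(rows, `[[`, character(1), j))
  gapfrac <- vapply(colchars, function(cc) mean(cc == "-"), numeric(1))
  match_cols <- which(gapfrac < gap_threshold)
  if (!length(match_cols)) stop("alignment yields no match columns")
  M <- length(match_cols)
  col2m <- integer(aln$columns)
  col2m[match_cols] <- seq_len(M)

  pr <- .structure_pairs(aln$structure, canonical = TRUE)
  partner <- integer(M)  # model-coordinate partner, 0 = unpaired
  if (nrow(pr$tier1)) {
    for (k in seq_len(nrow(pr$tier1))) {
      a <- pr$tier1[k, 1L]; b <- pr$tier1[k, 2L]
      ma <- col2m[a]; mb <- col2m[b]
      if (ma > 0L && mb > 0L) {
        partner[ma] <- mb; partner[mb] <- ma
      } else if (ma > 0L || mb > 0L) {
        warning("structure pairs a match column with a gap-majority ",
                "column; pair demoted to unpaired (columns ", a, "/", b,
                ")")
      }
    }
  }

  pc <- pseudocount
  count_single <- function(cc) {
    tab <- table(factor(cc, levels = c("A", "C", "G", "T")))
    (as.numeric(tab) + pc) / (sum(tab) + 4 * pc)
  }
  count_pair <- function(c5, c6) {
    ok <- c5 %in% c("A", "C", "G", "T") & c6 %in% c("A", "C", "G", "T")
    tab <- table(factor(c5[ok], levels = c("A", "C", "G", "T")),
                 factor(c6[ok], levels = c("A", "C", "G", "T")))
    (as.numeric(tab) + pc) / (sum(tab) + 16 * pc)
  }

  # guide tree over model columns 1..M, nodes appended in postorder
  type <- integer(0); child <- integer(0); left <- integer(0)
  right <- integer(0); col5 <- integer(0); col3 <- integer(0)
  emit <- list()
  add_node <- function(t, ch = -1L, l = -1L, r = -1L, c5 = 0L, c3 = 0L,
                       e = NULL) {
    type[[length(type) + 1L]] <<- t
    child[[length(child) + 1L]] <<- ch
    left[[length(left) + 1L]] <<- l
    right[[length(right) + 1L]] <<- r
    col5[[length(col5) + 1L]] <<- c5
    col3[[length(col3) + 1L]] <<- c3
    emit[[length(emit) + 1L]] <<- e %||% numeric(0)
    length(type) - 1L  # 0-based index
  }
  node_for <- function(lo, hi) {
    if (lo > hi) return(add_node(.NODE_END))
    p <- partner[lo]
    if (p == 0L || p < lo) {  # unpaired (p<lo cannot happen with nesting)
      cc <- colchars[[match_cols[lo]]]
      e <- .extend_single(count_single(cc[cc != "-"]))
      ch <- node_for(lo + 1L, hi)
      return(add_node(.NODE_MATL, ch = ch, c5 = lo, e = e))
    }
    if (p == hi) {
      e <- .extend_pair(count_pair(colchars[[match_cols[lo]]],
                                   colchars[[match_cols[hi]]]))
      ch <- node_for(lo + 1L, hi - 1L)
      return(add_node(.NODE_MATP, ch = ch, c5 = lo, c3 = hi,
                      e = as.numeric(e)))
    }
    l <- node_for(lo, p)
    r <- node_for(p + 1L, hi)
    add_node(.NODE_BIF, l = l, r = r)
  }
  top <- node_for(1L, M)

  struct <- rep(".", M)
  struct[partner > seq_len(M)] <- "<"
  struct[partner > 0L & partner < seq_len(M)] <- ">"

  consensus <- vapply(match_cols, function(j) {
    cc <- colchars[[j]]; cc <- cc[cc %in% c("A", "C", "G", "T")]
    if (!length(cc)) "A" else names(which.max(table(cc)))
  }, character(1))

  out <- list(name = "cm", subfamily = "bacA", M = M,
              match_cols = match_cols, partner = partner,
              structure = paste(struct, collapse = ""),
              consensus = paste(consensus, collapse = ""),
              nodes = list(type = unlist(type), child = unlist(child),
                           left = unlist(left), right = unlist(right),
                           col5 = unlist(col5), col3 = unlist(col3),
                           emit = emit),
              top = top,
              gaps = gaps, n_rows = nrows, evd = NULL)
  class(out) <- "rnp_cm"
  out
}

#' @export
print.rnp_cm <- function(x, ...) {
  cat(sprintf("covariance model '%s' (%s): %d match columns, %d pairs\n",
              x$name, x$subfamily, x$M, sum(x$partner > 0) / 2L))
  if (is.null(x$evd)) cat("  uncalibrated\n")
  else cat(sprintf("  Gumbel: lambda=%.4f mu=%.2f (n_decoys=%d)\n",
                   x$evd$lambda, x$evd$mu, x$evd$n_decoys))
  invisible(x)
}
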