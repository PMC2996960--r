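# Nucleotide alphabet utilities.
#
# The package keeps one canonical internal alphabet: uppercase DNA (U is
# folded into T on input).  Base-pairing logic treats T as U, so RNA helices
# can be expressed and checked on DNA-encoded sequences.

# bitmask per IUPAC symbol: A=1, C=2, G=4, T=8
.iupac_mask <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.mask_base <- c("A", "C", "G", "T")  # index = log2(bit) + 1

#' Expand an IUPAC nucleotide code
#'
#' @param sym a single IUPAC symbol (case-insensitive; `U` is an alias of `T`).
#' @return character vector of the concrete bases (`A`, `C`, `G`, `T`) the
#'   code stands for.
#' @examples
#' iupac_expand("R")  # A, G
#' @export
iupac_expand <- function(sym) {
  m <- .iupac_mask[toupper(sym)]
  if (is.na(m)) stop("invalid IUPAC code: ", sym)
  .mask_base[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Test a base against an IUPAC pattern symbol
#'
#' `N` expands to all four bases.  Both arguments may be any valid IUPAC
#' code; the match succeeds when their expansions intersect, so an ambiguous
#' subject base (e.g. an assembly `N`) satisfies every pattern symbol.
#'
#' @param pattern_symbol IUPAC code from a pattern.
#' @param base subject nucleotide (IUPAC code).
#' @return `TRUE` iff the expansions intersect.
#' @export
iupac_match <- function(pattern_symbol, base) {
  pm <- .iupac_mask[toupper(pattern_symbol)]
  bm <- .iupac_mask[toupper(base)]
  if (anyNA(pm)) stop("invalid IUPAC code: ",
                      pattern_symbol[which(is.na(pm))[1L]])
  if (anyNA(bm)) stop("invalid IUPAC code: ", base[which(is.na(bm))[1L]])
  unname(bitwAnd(pm, bm) > 0L)
}

#' Default RNA pair set (Watson-Crick plus G-U wobble)
#' @return character vector of allowed pairs, 5' base first.
#' @export
default_pair_set <- function() c("AU", "UA", "GC", "CG", "GU", "UG")

.norm_pair <- function(p) chartr("T", "U", toupper(p))

#' Check whether two bases may pair
#'
#' Pairing treats T as U.  Ambiguous bases (anything outside `A`,`C`,`G`,`T`)
#' never count as paired: the caller should treat them as mispairs.
#'
#' @param b5 5' base, @param b3 3' base.
#' @param pair_set allowed pairs as two-letter strings (RNA letters; T
#'   accepted), 5' base first.  Default includes the G-U wobble.
#' @return `TRUE` iff `paste0(b5, b3)` is in the set.
#' @export
pairs_ok <- function(b5, b3, pair_set = default_pair_set()) {
  b5 <- chartr("T", "U", toupper(b5)); b3 <- chartr("T", "U", toupper(b3))
  ok <- b5 %in% c("A", "C", "G", "U") & b3 %in% c("A", "C", "G", "U")
  ok & paste0(b5, b3) %in% .norm_pair(pair_set)
}

# 4x4 logical matrix over A,C,G,T for the C++ matcher
.pair_matrix <- function(pair_set) {
  m <- matrix(FALSE, 4L, 4L, dimnames = list(.mask_base, .mask_base))
  for (p in .norm_pair(pair_set)) {
    b5 <- chartr("U", "T", substr(p, 1L, 1L))
    b3 <- chartr("U", "T", substr(p, 2L, 2L))
    m[b5, b3] <- TRUE
  }
  m
}

#' Normalize residues to the canonical internal alphabet
#'
#' Uppercases, folds U to T and validates every symbol against the IUPAC
#' alphabet.  Idempotent.
#'
#' @param residues character vector of sequences.
#' @param what label used in error messages.
#' @return normalized character vector.
#' @export
normalize_residues <- function(residues, what = "sequence") {
  out <- chartr("u", "T", chartr("U", "T", toupper(residues)))
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("%s %d: non-IUPAC symbol '%s' at position %d",
                 what, i, substr(out[i], bad[i], bad[i]), bad[i]))
  }
  out
}

#' Reverse complement
#'
#' IUPAC ambiguity codes are mapped to their complements (R to Y, etc.);
#' the operation is involutive.
#'
#' @param residues character vector over the IUPAC alphabet (DNA or RNA;
#'   output is always DNA).
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(residues) {
  x <- chartr("U", "T", chartr("u", "t", toupper(residues)))
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# residues -> integer masks (internal; subject must be normalized)
.residue_masks <- function(residues) {
  s <- strsplit(residues, "", fixed = TRUE)[[1L]]
  m <- .iupac_mask[s]
  if (anyNA(m)) stop("non-IUPAC symbol in sequence")
  unname(m)
}

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
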