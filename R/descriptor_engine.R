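# Descriptor models: parsing, validation and scanning.
#
# A descriptor model (DM) is an ordered pattern of single-strand (SS)
# elements and helices used as a fast structural filter for candidate rnpB
# genes.  SS elements mix IUPAC symbols with bounded arbitrary runs and
# carry a mismatch budget; helices are fixed-length complementary strand
# pairs with a mispair budget.  Crossed helix topologies (the CR-I/CR-V P4
# pseudoknot) are expressible because the two strands of a helix are
# independent topology slots.
#
# Descriptor files use the "BDM v1" dialect:
#   # comment
#   name: toyA
#   subfamily: bacA
#   variant: selective
#   topology: s1 h1 s2 h1' s3
#   s1 1:GARGN(2,4)Y        <mismatch_budget>:<pattern with runs N(min,max)>
#   h1 0:GGGC:GCCC pairs=GC,CG,AU,UA,GU,UG

.subfamilies <- c("arcA", "arcM", "bacA", "bacB", "nucA", "fugA", "fugB")

.parse_ss_pattern <- function(pattern, label) {
  toks <- list()
  rest <- pattern
  while (nzchar(rest)) {
    m <- regexpr("^N\\((\\d+),(\\d+)\\)", rest)
    if (m == 1L) {
      run <- regmatches(rest, m)
      nums <- as.integer(strsplit(gsub("[N()]", "", run), ",")[[1L]])
      if (nums[1L] > nums[2L])
        stop(label, ": run token with min > max: ", run)
      toks[[length(toks) + 1L]] <- list(type = "run", min = nums[1L],
                                        max = nums[2L])
      rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
    } else {
      sym <- substr(rest, 1L, 1L)
      if (is.na(.iupac_mask[sym]))
        stop(label, ": invalid pattern symbol '", sym, "'")
      toks[[length(toks) + 1L]] <- list(type = "sym", sym = sym)
      rest <- substr(rest, 2L, nchar(rest))
    }
  }
  toks
}

#' Parse a descriptor model file (BDM v1)
#'
#' @param path file path, or the descriptor text itself (anything containing
#'   a newline is treated as literal text).
#' @return an object of class `rnp_dm`.
#' @export
read_descriptor <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path)) {
    readLines(path, warn = FALSE)
  } else {
    strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  header <- list()
  elements <- list()
  topology <- NULL
  for (ln in lines) {
    if (grepl("^(name|subfamily|variant|topology):", ln)) {
      key <- sub(":.*$", "", ln)
      val <- trimws(sub("^[a-z]+:", "", ln))
      if (key == "topology") topology <- strsplit(val, "\\s+")[[1L]]
      else header[[key]] <- val
      next
    }
    f <- regmatches(ln, regexec("^([sh]\\d+)\\s+(\\d+):(.*)$", ln))[[1L]]
    if (length(f) != 4L) stop("malformed descriptor line: ", ln)
    label <- f[2L]; budget <- as.integer(f[3L]); body <- f[4L]
    if (startsWith(label, "s")) {
      elements[[label]] <- list(kind = "ss", label = label, budget = budget,
                                tokens = .parse_ss_pattern(trimws(body),
                                                           label))
    } else {
      pairs <- default_pair_set()
      pm <- regexpr("\\s+pairs=\\S+", body)
      if (pm > 0L) {
        pairs <- strsplit(sub("^\\s+pairs=", "", regmatches(body, pm)),
                          ",")[[1L]]
        body <- sub("\\s+pairs=\\S+", "", body)
      }
      strands <- strsplit(trimws(body), ":", fixed = TRUE)[[1L]]
      if (length(strands) != 2L)
        stop(label, ": helix line must be budget:strand5:strand3")
      s5 <- toupper(strands[1L]); s3 <- toupper(strands[2L])
      if (nchar(s5) != nchar(s3))
        stop(label, ": helix strand length mismatch (",
             nchar(s5), " vs ", nchar(s3), ")")
      for (s in c(s5, s3))
        if (grepl("[^ACGTURYSWKMBDHVN]", s))
          stop(label, ": invalid helix strand symbol")
      elements[[label]] <- list(kind = "helix", label = label,
                                budget = budget,
                                strand5 = chartr("U", "T", s5),
                                strand3 = chartr("U", "T", s3),
                                pairs = pairs)
    }
  }
  new_descriptor(name = header$name %||% "unnamed",
                 subfamily = header$subfamily %||% "bacA",
                 variant = header$variant %||% "general",
                 topology = topology, elements = elements)
}

#' Construct and validate a descriptor model
#'
#' @param name model name.
#' @param subfamily one of `arcA`, `arcM`, `bacA`, `bacB`, `nucA`, `fugA`,
#'   `fugB`.
#' @param variant `"selective"` (tight budgets) or `"general"` (relaxed
#'   fallback).
#' @param topology character vector of element labels; each helix label
#'   `h<k>` must appear exactly twice, as `h<k>` (opening strand) and
#'   `h<k>'` (closing strand), with the closing strand after the opening
#'   one.
#' @param elements named list of element definitions as produced by
#'   [read_descriptor()].
#' @return an `rnp_dm` object.
#' @export
new_descriptor <- function(name, subfamily, variant, topology, elements) {
  if (is.null(topology) || !length(topology))
    stop("descriptor has no topology line")
  subfamily <- match.arg(subfamily, .subfamilies)
  variant <- match.arg(variant, c("selective", "general"))
  base <- sub("'$", "", topology)
  for (lab in unique(base)) {
    el <- elements[[lab]]
    if (is.null(el)) stop("topology references undefined element: ", lab)
    n <- sum(base == lab)
    if (el$kind == "ss" && n != 1L)
      stop("SS element ", lab, " must appear exactly once in topology")
    if (el$kind == "helix") {
      if (n != 2L || sum(topology == lab) != 1L ||
          sum(topology == paste0(lab, "'")) != 1L)
        stop("helix ", lab, " must appear exactly twice, as ", lab,
             " and ", lab, "'")
      if (which(topology == paste0(lab, "'")) < which(topology == lab))
        stop("helix ", lab, ": closing strand before opening strand")
    }
  }
  extra <- setdiff(names(elements), base)
  if (length(extra)) stop("element not referenced by topology: ",
                          paste(extra, collapse = ", "))
  out <- list(name = name, subfamily = subfamily, variant = variant,
              topology = topology, elements = elements)
  class(out) <- "rnp_dm"
  out
}

#' Write a descriptor model in BDM v1 format
#' @param dm an `rnp_dm` object.
#' @param path output file, or `NULL`.
#' @return the text, invisibly.
#' @export
write_descriptor <- function(dm, path = NULL) {
  fmt_tok <- function(t)
    if (t$type == "run") sprintf("N(%d,%d)", t$min, t$max) else t$sym
  lines <- c(sprintf("name: %s", dm$name),
             sprintf("subfamily: %s", dm$subfamily),
             sprintf("variant: %s", dm$variant),
             sprintf("topology: %s", paste(dm$topology, collapse = " ")))
  for (lab in unique(sub("'$", "", dm$topology))) {
    el <- dm$elements[[lab]]
    lines <- c(lines, if (el$kind == "ss") {
      sprintf("%s %d:%s", lab, el$budget,
              paste(vapply(el$tokens, fmt_tok, character(1)),
                    collapse = ""))
    } else {
      sprintf("%s %d:%s:%s pairs=%s", lab, el$budget, el$strand5,
              el$strand3, paste(el$pairs, collapse = ","))
    })
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

# encode for the C++ matcher: one entry per topology slot
.dm_encode <- function(dm) {
  lapply(seq_along(dm$topology), function(i) {
    lab <- dm$topology[i]
    base <- sub("'$", "", lab)
    el <- dm$elements[[base]]
    if (el$kind == "ss") {
      tt <- vapply(el$tokens, function(t) if (t$type == "run") 1L else 0L,
                   integer(1))
      list(type = 0L, budget = el$budget, tok_type = tt,
           sym = vapply(el$tokens, function(t)
             if (t$type == "run") 0L else unname(.iupac_mask[t$sym]),
             integer(1)),
           rmin = vapply(el$tokens, function(t)
             if (t$type == "run") t$min else 0L, integer(1)),
           rmax = vapply(el$tokens, function(t)
             if (t$type == "run") t$max else 0L, integer(1)))
    } else if (!endsWith(lab, "'")) {
      list(type = 1L, budget = 0L,
           mask = unname(.iupac_mask[strsplit(el$strand5, "")[[1L]]]))
    } else {
      list(type = 2L, budget = el$budget,
           mask = unname(.iupac_mask[strsplit(el$strand3, "")[[1L]]]),
           open_idx = which(dm$topology == base) - 1L,
           pairmat = as.integer(.pair_matrix(el$pairs)))
    }
  })
}

# minimal number of residues a full match consumes
dm_min_span <- function(dm) {
  sum(vapply(dm$topology, function(lab) {
    el <- dm$elements[[sub("'$", "", lab)]]
    if (el$kind == "helix") nchar(el$strand5)
    else sum(vapply(el$tokens, function(t)
      if (t$type == "run") t$min else 1L, integer(1)))
  }, integer(1)))
}

.hit_row <- function(h, dm, seq_id, strand, L) {
  spans <- h$spans  # 0-based half-open, match-strand coordinates
  if (strand == "-") {
    fs <- L - h$end; fe <- L - h$start
    spans <- cbind(L - spans[, 2L], L - spans[, 1L])
  } else {
    fs <- h$start; fe <- h$end
  }
  spans[, 1L] <- spans[, 1L] + 1L  # to 1-based inclusive
  rownames(spans) <- dm$topology
  colnames(spans) <- c("start", "end")
  data.frame(seq_id = seq_id, strand = strand,
             start = fs + 1L, end = fe,
             mismatches = h$mismatches, mispairs = h$mispairs,
             element_spans = I(list(spans)),
             stringsAsFactors = FALSE)
}

#' Scan a sequence with a descriptor model
#'
#' Reports at most one hit per (anchor position, strand): the first match in
#' the deterministic enumeration order (topology order, run tokens shortest
#' first).  Overlapping anchors are all reported; deduplication happens
#' downstream in the cascade.
#'
#' @param seqs an `rnp_seqs` table or a single residue string.
#' @param dm an `rnp_dm` descriptor.
#' @param strands `"+"`, `"-"` or `"both"`.  Minus-strand hits are found on
#'   the reverse complement and reported in forward coordinates.
#' @return data.frame with columns `seq_id`, `strand`, `start`, `end`
#'   (1-based inclusive, forward strand), `mismatches`, `mispairs` and a
#'   list column `element_spans` (per-element forward spans, 1-based
#'   inclusive).
#' @export
dm_scan <- function(seqs, dm, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (is.character(seqs)) seqs <- new_rnp_seqs("seq", seqs)
  enc <- .dm_encode(dm)
  ms <- dm_min_span(dm)
  rows <- list()
  for (i in seq_len(nrow(seqs))) {
    res <- seqs$residues[i]
    L <- nchar(res)
    if (strands %in% c("both", "+")) {
      for (h in cpp_dm_scan(.residue_masks(res), enc, ms))
        rows[[length(rows) + 1L]] <- .hit_row(h, dm, seqs$id[i], "+", L)
    }
    if (strands %in% c("both", "-")) {
      rc <- reverse_complement(res)
      for (h in cpp_dm_scan(.residue_masks(rc), enc, ms))
        rows[[length(rows) + 1L]] <- .hit_row(h, dm, seqs$id[i], "-", L)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               mismatches = integer(0), mispairs = integer(0),
               element_spans = I(list()), stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Match a descriptor at a fixed anchor position
#'
#' @param residues a residue string (forward strand).
#' @param pos 1-based anchor position (`1` to `nchar(residues) + 1`).
#' @param dm an `rnp_dm` descriptor.
#' @return a one-row hit data.frame as in [dm_scan()], or `NULL` if no
#'   match is anchored at `pos`.
#' @export
dm_match_at <- function(residues, pos, dm) {
  residues <- normalize_residues(residues)
  h <- cpp_dm_match_at(.residue_masks(residues), .dm_encode(dm),
                       pos - 1L)
  if (is.null(h)) return(NULL)
  .hit_row(h, dm, "seq", "+", nchar(residues))
}

#' @export
print.rnp_dm <- function(x, ...) {
  cat(sprintf("descriptor model '%s' (%s, %s)\n", x$name, x$subfamily,
              x$variant))
  cat("  topology:", paste(x$topology, collapse = " "), "\n")
  cat(sprintf("  minimal span: %d nt\n", dm_min_span(x)))
  invisible(x)
}
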