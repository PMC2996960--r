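# Synthetic fixtures: random backgrounds, descriptor-consistent planted
# genes, decoys and a packaged toy model library.
#
# The toy models are small (around 80 match columns, so CYK refinement runs
# in well under a second per window) but structured like real rnpB models:
# an anchoring conserved block, several helices (one crossed pair in the
# arcA toy, mirroring the CR-I/CR-V P4 pseudoknot), degenerate positions
# and bounded variable-length runs.  They are synthetic stand-ins for the
# hand-curated production descriptor/CM library, which is expert curation
# and out of scope here.

#' Random background sequence
#'
#' @param length sequence length in nt.
#' @param gc GC fraction; `P(G) = P(C) = gc / 2`.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @param id record id.
#' @return a one-row `rnp_seqs` table.
#' @export
random_background <- function(length, gc = 0.5, seed = NULL,
                              id = "background") {
  stopifnot(gc >= 0, gc <= 1, length >= 0)
  res <- with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  new_rnp_seqs(id, res)
}

#' Sample a sequence accepted by a descriptor model
#'
#' Draws one residue string the model matches with zero budget usage:
#' IUPAC tokens sample uniformly from their expansion, run tokens a uniform
#' length then i.i.d. residues, helix closing strands complementary
#' residues consistent with their own tokens.
#'
#' @param dm an `rnp_dm` descriptor.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return residue string with attribute `layout` (per-element spans,
#'   1-based inclusive).
#' @export
sample_from_descriptor <- function(dm, seed = NULL) {
  with_seed(seed, {
    for (attempt in 1:50) {
      chars <- character(0)
      open_chars <- list()
      layout <- matrix(0L, length(dm$topology), 2L,
                       dimnames = list(dm$topology, c("start", "end")))
      ok <- TRUE
      for (si in seq_along(dm$topology)) {
        lab <- dm$topology[si]
        el <- dm$elements[[sub("'$", "", lab)]]
        start <- length(chars) + 1L
        if (el$kind == "ss") {
          for (t in el$tokens) {
            if (t$type == "sym") {
              chars <- c(chars, sample(iupac_expand(t$sym), 1L))
            } else {
              len <- if (t$max > t$min)
                t$min + sample.int(t$max - t$min + 1L, 1L) - 1L else t$min
              if (len > 0L)
                chars <- c(chars, sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE))
            }
          }
        } else if (!endsWith(lab, "'")) {
          syms <- strsplit(el$strand5, "")[[1L]]
          drawn <- vapply(syms, function(s) sample(iupac_expand(s), 1L),
                          character(1))
          open_chars[[sub("'$", "", lab)]] <- drawn
          chars <- c(chars, drawn)
        } else {
          o <- open_chars[[sub("'$", "", lab)]]
          len <- length(o)
          syms3 <- strsplit(el$strand3, "")[[1L]]
          drawn <- character(len)
          for (m in seq_len(len)) {
            partner <- o[len + 1L - m]
            cand <- iupac_expand(syms3[m])
            cand <- cand[pairs_ok(partner, cand, el$pairs)]
            if (!length(cand)) { ok <- FALSE; break }
            drawn[m] <- sample(cand, 1L)
          }
          if (!ok) break
          chars <- c(chars, drawn)
        }
        layout[si, ] <- c(start, length(chars))
      }
      if (ok) {
        out <- paste(chars, collapse = "")
        attr(out, "layout") <- layout
        return(out)
      }
    }
    stop("helix tokens incompatible with any complement after 50 attempts")
  })
}

#' Plant a gene into a background sequence
#'
#' The insert replaces (does not displace) the span starting at `position`,
#' keeping all coordinates stable; minus-strand planting inserts the
#' reverse complement.
#'
#' @param background a one-row `rnp_seqs` table, or an `rnp_planted`
#'   genome from a previous call (plants accumulate).
#' @param insert residue string (transcript orientation).
#' @param position 0-based start of the replaced span.
#' @param strand `"+"` or `"-"`.
#' @param subfamily,model provenance recorded in the truth table.
#' @return an `rnp_planted` object: list with `record` (the modified
#'   `rnp_seqs` row) and `truth` (data.frame of 0-based half-open spans
#'   with `strand`, `subfamily`, `model`).
#' @export
plant_gene <- function(background, insert, position, strand = "+",
                       subfamily = "bacA", model = NA_character_) {
  if (inherits(background, "rnp_planted")) {
    record <- background$record
    truth <- background$truth
  } else {
    record <- background
    truth <- data.frame(start = integer(0), end = integer(0),
                        strand = character(0), subfamily = character(0),
                        model = character(0), stringsAsFactors = FALSE)
  }
  insert <- normalize_residues(insert)
  len <- nchar(insert)
  L <- record$length
  if (position < 0 || position + len > L)
    stop("plant out of range: [", position, ", ", position + len,
         ") in ", L, " nt")
  placed <- if (strand == "-") reverse_complement(insert) else insert
  res <- record$residues
  substr(res, position + 1L, position + len) <- placed
  record$residues <- res
  truth <- rbind(truth, data.frame(
    start = as.integer(position), end = as.integer(position + len),
    strand = strand, subfamily = subfamily, model = model,
    stringsAsFactors = FALSE))
  out <- list(record = record, truth = truth)
  class(out) <- "rnp_planted"
  out
}

# ---- toy library ------------------------------------------------------

.toy_selective_dm <- list(
  bacA = paste(
    "name: bacA-toy",
    "subfamily: bacA",
    "variant: selective",
    "topology: s1 h1 s2 h1' s3 h2 s4 h2' s5",
    "s1 0:GAAGCTGRCCAGTAGCTAAC",
    "h1 0:GGCAGCTG:NNNNNNNN",
    "s2 0:TTCN(4,4)GARTCAG",
    "s3 0:ACYGGATCAGTCA",
    "h2 0:CCGTAGGACG:NNNNNNNNNN",
    "s4 0:GCAARN(4,4)TCG",
    "s5 0:CGATTAGGCTGACCTA",
    sep = "\n"),
  arcA = paste(
    "name: arcA-toy",
    "subfamily: arcA",
    "variant: selective",
    "topology: s1 h1 s2 h2 s3 h1' s4 h2' s5",  # h1/h2 crossed: pseudoknot
    "s1 0:CGGTARCCTGACTTGCAAGC",
    "h1 0:GCGTCAGC:NNNNNNNN",
    "s2 0:AAYGN(3,3)GGATC",
    "h2 0:TACGGCT:NNNNNNN",
    "s3 0:TGCATCCGATCC",
    "s4 0:CARTN(4,4)GG",
    "s5 0:GGATCCTAAGGCTTGACC",
    sep = "\n"))

# relax a selective descriptor into its general fallback variant
.generalize_dm <- function(dm, ss_budget = 1L, helix_budget = 1L,
                           run_widen = 2L) {
  g <- dm
  g$variant <- "general"
  g$name <- sub("toy", "toy-general", g$name)
  for (lab in names(g$elements)) {
    el <- g$elements[[lab]]
    if (el$kind == "helix") {
      el$budget <- el$budget + helix_budget
    } else {
      nfixed <- sum(vapply(el$tokens, function(t) t$type == "sym",
                           logical(1)))
      if (nfixed >= 3L) el$budget <- el$budget + ss_budget
      el$tokens <- lapply(el$tokens, function(t) {
        if (t$type == "run") {
          t$min <- max(0L, t$min - run_widen)
          t$max <- t$max + run_widen
        }
        t
      })
    }
    g$elements[[lab]] <- el
  }
  g
}

# consensus structure string from a fixed-width descriptor layout:
# nested helices on the '<>' tier, crossed helices on pseudoknot letters
.layout_structure <- function(dm, layout) {
  n <- layout[nrow(layout), 2L]
  s <- rep(".", n)
  helices <- unique(sub("'$", "", grep("^h", dm$topology, value = TRUE)))
  iv <- t(vapply(helices, function(h) {
    c(which(dm$topology == h), which(dm$topology == paste0(h, "'")))
  }, integer(2)))
  tier1 <- character(0)
  pk <- 0L
  for (k in seq_along(helices)) {
    crossed <- FALSE
    for (prev in tier1) {
      p <- iv[match(prev, helices), ]
      crossed <- crossed ||
        (p[1L] < iv[k, 1L] && iv[k, 1L] < p[2L] && p[2L] < iv[k, 2L]) ||
        (iv[k, 1L] < p[1L] && p[1L] < iv[k, 2L] && iv[k, 2L] < p[2L])
    }
    o <- layout[iv[k, 1L], ]; c3 <- layout[iv[k, 2L], ]
    if (!crossed) {
      tier1 <- c(tier1, helices[k])
      s[o[1L]:o[2L]] <- "<"
      s[c3[1L]:c3[2L]] <- ">"
    } else {
      pk <- pk + 1L
      s[o[1L]:o[2L]] <- LETTERS[pk]
      s[c3[1L]:c3[2L]] <- letters[pk]
    }
  }
  paste(s, collapse = "")
}

# break one base pair of the last helix: one extra mispair, token-legal
.make_aberrant <- function(dm, member) {
  layout <- attr(member, "layout")
  helices <- unique(sub("'$", "", grep("^h", dm$topology, value = TRUE)))
  h <- helices[length(helices)]
  open_span <- layout[which(dm$topology == h), ]
  close_span <- layout[which(dm$topology == paste0(h, "'")), ]
  len <- open_span[2L] - open_span[1L] + 1L
  m <- (len + 1L) %/% 2L                      # middle closing position
  partner_pos <- open_span[1L] + (len - m)
  s <- member
  substr(s, close_span[1L] + m - 1L, close_span[1L] + m - 1L) <-
    substr(member, partner_pos, partner_pos)  # b3 := b5, never pairs
  attributes(s) <- attributes(member)
  s
}

#' Build the packaged toy model library
#'
#' Two subfamilies (a `bacA`-style nested model and an `arcA`-style model
#' with a crossed helix pair) each get a tight-budget selective descriptor,
#' a relaxed general descriptor, a structural alignment of sampled members,
#' and a calibrated covariance model.  One held-out aberrant member per
#' subfamily carries a single extra helix mispair, so it fails the
#' selective descriptor but matches the general one — the fixture for the
#' selective-to-general fallback.
#'
#' @param seed integer seed; the library is fully deterministic in it.
#' @param n_members alignment rows sampled per subfamily (>= 8 keeps
#'   emissions informative).
#' @param n_decoys decoys per CM calibration.
#' @return an `rnp_library`; each subfamily entry also carries `members`
#'   and `aberrant` fixtures.
#' @export
make_toy_library <- function(seed = 42L, n_members = 8L, n_decoys = 150L) {
  subfamilies <- list()
  for (k in seq_along(.toy_selective_dm)) {
    sf <- names(.toy_selective_dm)[k]
    sel <- read_descriptor(.toy_selective_dm[[sf]])
    gen <- .generalize_dm(sel)
    members <- with_seed(seed + 1000L * k, {
      lapply(seq_len(n_members), function(i)
        sample_from_descriptor(sel, seed = NULL))
    })
    aberrant <- .make_aberrant(sel, members[[1L]])
    layout <- attr(members[[1L]], "layout")
    aln <- new_rnp_aln(sprintf("%s_m%d", sf, seq_len(n_members)),
                       unlist(members), .layout_structure(sel, layout))
    cm <- build_cm(aln)
    cm$name <- paste0(sf, "-toy")
    cm$subfamily <- sf
    cm <- cm_calibrate(cm, n_decoys = n_decoys, seed = seed + 77L * k)
    subfamilies[[sf]] <- list(selective = sel, general = gen, cm = cm,
                              alignment = aln, members = members,
                              aberrant = aberrant)
  }
  out <- list(subfamilies = subfamilies, seed = seed)
  class(out) <- "rnp_library"
  out
}

#' Simulate planted genomes with truth annotations
#'
#' Each genome is an i.i.d. random background with one descriptor-consistent
#' gene planted (subfamilies cycled, strands alternated so half the plants
#' are on the minus strand), at least 1 kb away from the sequence ends.
#'
#' @param n_genomes number of genomes.
#' @param genome_length length of each genome in nt.
#' @param gc background GC fraction.
#' @param seed integer seed.
#' @param library an `rnp_library` (default: the toy library built from
#'   `seed`).
#' @param out optional output directory: writes `genomes.fasta` and a
#'   BED-like `truth.tsv` (`seq_id`, 0-based `start`, `end`, `strand`,
#'   `subfamily`).
#' @return list with `genomes` (an `rnp_seqs` table), `truth` (data.frame
#'   with `seq_id` prepended) and `library`, invisibly when `out` is given.
#' @export
simulate_genomes <- function(n_genomes, genome_length = 50000L, gc = 0.5,
                             seed = 1L, library = NULL, out = NULL) {
  if (is.null(library)) library <- make_toy_library(seed)
  sfs <- names(library$subfamilies)
  sim <- with_seed(seed + 31L, {
    genomes <- list(); truth <- list()
    for (g in seq_len(n_genomes)) {
      id <- sprintf("genome%04d", g)
      bg <- random_background(genome_length, gc = gc, seed = NULL,
                              id = id)
      sf <- sfs[(g - 1L) %% length(sfs) + 1L]
      ins <- sample_from_descriptor(library$subfamilies[[sf]]$selective,
                                    seed = NULL)
      strand <- if (g %% 2L == 0L) "-" else "+"
      margin <- 1000L
      pos <- margin +
        sample.int(genome_length - nchar(ins) - 2L * margin, 1L)
      pl <- plant_gene(bg, ins, pos, strand, subfamily = sf,
                       model = library$subfamilies[[sf]]$selective$name)
      genomes[[g]] <- pl$record
      tr <- pl$truth
      tr$seq_id <- id
      truth[[g]] <- tr[, c("seq_id", "start", "end", "strand",
                           "subfamily", "model")]
    }
    list(genomes = do.call(rbind, genomes), truth = do.call(rbind, truth))
  })
  class(sim$genomes) <- c("rnp_seqs", "data.frame")
  sim$library <- library
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$genomes, file.path(out, "genomes.fasta"))
    utils::write.table(sim$truth, file.path(out, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(sim))
  }
  sim
}
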