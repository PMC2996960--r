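# Independent oracles used to validate the C++ matcher and CYK scorer.
#
# The descriptor oracle enumerates every run-length combination as a flat
# grid (in the matcher's declared order: leftmost run most significant,
# shortest first) and checks each fixed layout with vectorized position
# arithmetic over all anchors -- no backtracking, no shared code with the
# DFS matcher.
#
# The CM oracle enumerates parse derivations top-down over explicit
# subject regions with insert-length loops (memoized), mirroring the
# grammar definition rather than the production deck DP.

.oracle_masks <- function(residues)
  unname(rnpscan:::.iupac_mask[strsplit(residues, "", fixed = TRUE)[[1L]]])

# forward-strand oracle; returns hits with 0-based half-open spans
oracle_dm_forward <- function(residues, dm) {
  m <- .oracle_masks(residues)
  L <- length(m)
  concrete <- m %in% c(1L, 2L, 4L, 8L)

  slots <- lapply(dm$topology, function(lab) {
    el <- dm$elements[[sub("'$", "", lab)]]
    if (el$kind == "ss") {
      list(kind = "ss", budget = el$budget, tokens = el$tokens)
    } else if (!endsWith(lab, "'")) {
      list(kind = "open", label = sub("'$", "", lab),
           mask = unname(rnpscan:::.iupac_mask[strsplit(el$strand5,
                                                        "")[[1L]]]))
    } else {
      list(kind = "close", label = sub("'$", "", lab),
           budget = el$budget,
           mask = unname(rnpscan:::.iupac_mask[strsplit(el$strand3,
                                                        "")[[1L]]]),
           pairmat = rnpscan:::.pair_matrix(el$pairs))
    }
  })

  # run-token registry
  runs <- list()
  for (si in seq_along(slots)) {
    if (slots[[si]]$kind != "ss") next
    for (ti in seq_along(slots[[si]]$tokens)) {
      t <- slots[[si]]$tokens[[ti]]
      if (t$type == "run")
        runs[[length(runs) + 1L]] <- list(si = si, ti = ti, min = t$min,
                                          max = t$max)
    }
  }
  combos <- if (length(runs)) {
    g <- do.call(expand.grid, rev(lapply(runs, function(r) r$min:r$max)))
    as.matrix(g[, rev(seq_along(runs)), drop = FALSE])
  } else matrix(0L, 1L, 0L)

  base_idx <- function(mask) match(mask, c(1L, 2L, 4L, 8L))

  assigned <- rep(NA_integer_, L + 1L)     # anchor (0-based) -> combo row
  info <- vector("list", L + 1L)

  for (ci in seq_len(nrow(combos))) {
    lens <- combos[ci, ]
    # lay out token offsets for this combo
    off <- 0L
    ri <- 0L
    layout <- list()   # per slot: list(start, tokens(off,width,sym) or mask)
    ok_layout <- TRUE
    for (si in seq_along(slots)) {
      sl <- slots[[si]]
      st <- off
      if (sl$kind == "ss") {
        toks <- list()
        for (ti in seq_along(sl$tokens)) {
          t <- sl$tokens[[ti]]
          if (t$type == "run") {
            ri <- ri + 1L
            w <- lens[ri]
            toks[[ti]] <- list(off = off, width = w, sym = NA)
            off <- off + w
          } else {
            toks[[ti]] <- list(off = off, width = 1L,
                               sym = unname(rnpscan:::.iupac_mask[t$sym]))
            off <- off + 1L
          }
        }
        layout[[si]] <- list(kind = "ss", start = st, tokens = toks,
                             budget = sl$budget)
      } else {
        w <- length(sl$mask)
        layout[[si]] <- c(sl, list(start = st, width = w))
        off <- off + w
      }
    }
    W <- off
    if (W > L) next
    anchors <- 0:(L - W)
    nA <- length(anchors)
    ok <- rep(TRUE, nA)
    mm_tot <- rep(0L, nA)
    mp_tot <- rep(0L, nA)
    open_at <- list()
    for (si in seq_along(layout)) {
      ly <- layout[[si]]
      if (ly$kind == "ss") {
        mm <- rep(0L, nA)
        for (t in ly$tokens) {
          if (is.na(t$sym)) next
          sym_ok <- bitwAnd(m[anchors + t$off + 1L], t$sym) > 0L
          mm <- mm + !sym_ok
        }
        ok <- ok & mm <= ly$budget
        mm_tot <- mm_tot + mm
      } else if (ly$kind == "open") {
        for (k in seq_len(ly$width)) {
          sym_ok <- bitwAnd(m[anchors + ly$start + k], ly$mask[k]) > 0L
          ok <- ok & sym_ok
        }
        open_at[[ly$label]] <- ly$start
      } else {
        w <- ly$width
        o5 <- open_at[[ly$label]]
        mp <- rep(0L, nA)
        for (k in seq_len(w)) {     # closing position k (1-based)
          b3 <- m[anchors + ly$start + k]
          b5 <- m[anchors + o5 + (w - k) + 1L]
          sym_ok <- bitwAnd(b3, ly$mask[k]) > 0L
          i5 <- base_idx(b5); i3 <- base_idx(b3)
          pair_ok <- !is.na(i5) & !is.na(i3)
          pair_ok[pair_ok] <- ly$pairmat[cbind(i5[pair_ok], i3[pair_ok])]
          mp <- mp + !(sym_ok & pair_ok)
        }
        ok <- ok & mp <= ly$budget
        mp_tot <- mp_tot + mp
      }
    }
    hit_anchors <- anchors[ok]
    for (a in hit_anchors) {
      if (!is.na(assigned[a + 1L])) next
      assigned[a + 1L] <- ci
      ia <- which(anchors == a)
      spans <- t(vapply(layout, function(ly) {
        w <- if (ly$kind != "ss") ly$width
             else if (!length(ly$tokens)) 0L
             else {
               lt <- ly$tokens[[length(ly$tokens)]]
               lt$off + lt$width - ly$start
             }
        c(a + ly$start, a + ly$start + w)
      }, integer(2)))
      info[[a + 1L]] <- list(start = a, end = a + W, spans = spans,
                             mm = mm_tot[ia], mp = mp_tot[ia])
    }
  }
  info[!vapply(info, is.null, logical(1))]
}

# full oracle scan matching dm_scan()'s output contract
oracle_dm_scan <- function(residues, dm, strands = "both") {
  residues <- rnpscan::normalize_residues(residues)
  L <- nchar(residues)
  rows <- list()
  emit <- function(hits, strand) {
    for (h in hits) {
      if (strand == "-") {
        fs <- L - h$end; fe <- L - h$start
        spans <- cbind(L - h$spans[, 2L], L - h$spans[, 1L])
      } else {
        fs <- h$start; fe <- h$end
        spans <- h$spans
      }
      spans[, 1L] <- spans[, 1L] + 1L
      rownames(spans) <- dm$topology
      colnames(spans) <- c("start", "end")
      rows[[length(rows) + 1L]] <<- data.frame(
        seq_id = "seq", strand = strand, start = fs + 1L, end = fe,
        mismatches = h$mm, mispairs = h$mp,
        element_spans = I(list(spans)), stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "+"))
    emit(oracle_dm_forward(residues, dm), "+")
  if (strands %in% c("both", "-"))
    emit(oracle_dm_forward(rnpscan::reverse_complement(residues), dm),
         "-")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               mismatches = integer(0), mispairs = integer(0),
               element_spans = I(list()), stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

# ---- CM parse-enumeration oracle -------------------------------------

oracle_cm_score <- function(cm, residues, global = TRUE) {
  x <- rnpscan:::.subject_codes(rnpscan::normalize_residues(residues)) + 1L
  nd <- cm$nodes
  io <- cm$gaps[["insert_open"]]; ie <- cm$gaps[["insert_extend"]]
  dopen <- cm$gaps[["delete_open"]]; de <- cm$gaps[["delete_extend"]]
  ins <- function(k) if (k == 0L) 0 else io + (k - 1L) * ie
  memo <- new.env(hash = TRUE, parent = emptyenv())
  enum <- function(v, i, j, p) {
    key <- paste(v, i, j, p)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    t <- nd$type[v]
    best <- -Inf
    n <- j - i
    if (t == 3L) {                                  # END
      best <- if (n == 0L) 0 else ins(n)
    } else if (t == 0L) {                           # MATL
      ch <- nd$child[v] + 1L
      e <- nd$emit[[v]]
      if (n >= 1L) for (m in 0:(n - 1L))
        best <- max(best, ins(m) + e[x[i + m + 1L]] +
                      enum(ch, i + m + 1L, j, "N"))
      best <- max(best, (if (p == "D") de else dopen) +
                    enum(ch, i, j, "D"))
      if (n >= 1L) for (m in 1:n)
        best <- max(best, ins(m) + dopen + enum(ch, i + m, j, "D"))
    } else if (t == 1L) {                           # MATP
      ch <- nd$child[v] + 1L
      e <- matrix(nd$emit[[v]], 5L, 5L)
      if (n >= 2L) for (m in 0:(n - 2L)) {
        pe <- e[x[i + m + 1L], x[j]]
        for (q in (i + m + 1L):(j - 1L))
          best <- max(best, ins(m) + pe + enum(ch, i + m + 1L, q, "N") +
                        ins(j - 1L - q))
      }
      best <- max(best, (if (p == "D") 2 * de else dopen + de) +
                    enum(ch, i, j, "D"))
      if (n >= 1L) for (m in 1:n)
        best <- max(best, ins(m) + dopen + de + enum(ch, i + m, j, "D"))
    } else {                                        # BIF
      l <- nd$left[v] + 1L; r <- nd$right[v] + 1L
      for (k in i:j)
        best <- max(best, enum(l, i, k, p) + enum(r, k, j, "N"))
    }
    memo[[key]] <- best
    best
  }
  top <- cm$top + 1L
  L <- length(x)
  best <- -Inf
  for (a in 0:L) for (b in a:L) {
    v <- enum(top, a, b, "N")
    tot <- if (global) ins(a) + v + ins(L - b) else v
    best <- max(best, tot)
  }
  best
}

# ---- random case generators ------------------------------------------

random_subject <- function(len, n_rate = 0.02) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  nn <- runif(len) < n_rate
  ch[nn] <- "N"
  paste(ch, collapse = "")
}

random_ss_pattern <- function(n_fixed, with_run) {
  syms <- sample(c("A", "C", "G", "T", "R", "Y", "N"), n_fixed,
                 replace = TRUE, prob = c(rep(0.2, 4), 0.07, 0.07, 0.06))
  pat <- paste(syms, collapse = "")
  if (with_run) {
    lo <- sample(0:3, 1L)
    hi <- lo + sample(0:3, 1L)
    at <- sample(0:n_fixed, 1L)
    pat <- paste0(substr(pat, 1L, at), sprintf("N(%d,%d)", lo, hi),
                  substr(pat, at + 1L, n_fixed))
  }
  pat
}

# a small random descriptor (<= 4 elements, <= 2 run tokens, budgets <= 2)
random_dm <- function() {
  helix_line <- function(lab) {
    len <- sample(2:5, 1L)
    s5 <- paste(sample(c("A", "C", "G", "T", "R", "N"), len,
                       replace = TRUE,
                       prob = c(rep(0.18, 4), 0.08, 0.2)), collapse = "")
    s3 <- paste(sample(c("N", "A", "C", "G", "T"), len, replace = TRUE,
                       prob = c(0.6, rep(0.1, 4))), collapse = "")
    sprintf("%s %d:%s:%s", lab, sample(0:2, 1L), s5, s3)
  }
  ss_line <- function(lab, with_run)
    sprintf("%s %d:%s", lab, sample(0:2, 1L),
            random_ss_pattern(sample(1:5, 1L), with_run))
  template <- sample(3L, 1L)
  if (template == 1L) {
    topo <- "s1"
    lines <- ss_line("s1", TRUE)
  } else if (template == 2L) {
    topo <- "s1 h1 s2 h1'"
    lines <- c(ss_line("s1", sample(c(TRUE, FALSE), 1L)),
               helix_line("h1"), ss_line("s2", TRUE))
  } else {
    topo <- "h1 s1 h1' s2"
    lines <- c(helix_line("h1"), ss_line("s1", TRUE),
               ss_line("s2", FALSE))
  }
  rnpscan::read_descriptor(paste(c("name: rnd", "subfamily: bacA",
                                   "variant: general",
                                   paste("topology:", topo), lines),
                                 collapse = "\n"))
}

# random tiny CM (M <= 8) plus a compatible short subject
random_cm_case <- function(max_m = 8L, max_subject = 10L) {
  repeat {
    M0 <- sample(4:max_m, 1L)
    templates <- list(
      strrep(".", M0),
      paste0("<", strrep(".", M0 - 2L), ">"),
      if (M0 >= 6L) paste0("<<", strrep(".", M0 - 4L), ">>"),
      if (M0 >= 6L) paste0("<.>", strrep(".", M0 - 6L), "<.>"),
      if (M0 >= 5L) paste0(strrep(".", M0 - 4L), "<..>"))
    templates <- Filter(Negate(is.null), templates)
    struct <- templates[[sample(length(templates), 1L)]]
    rows <- vapply(1:3, function(i) {
      ch <- sample(c("A", "C", "G", "T", "-"), M0, replace = TRUE,
                   prob = c(rep(0.225, 4), 0.1))
      paste(ch, collapse = "")
    }, character(1))
    aln <- try(rnpscan::new_rnp_aln(paste0("r", 1:3), rows, struct),
               silent = TRUE)
    if (inherits(aln, "try-error")) next
    cmx <- try(suppressWarnings(rnpscan::build_cm(aln)), silent = TRUE)
    if (inherits(cmx, "try-error")) next
    subject <- random_subject(sample.int(max_subject, 1L), n_rate = 0.05)
    return(list(cm = cmx, subject = subject))
  }
}
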