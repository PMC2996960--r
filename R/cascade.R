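# The scan cascade: local to global, selective to general.
#
# Subfamily-specific descriptor models locate candidates fast; the
# subfamily's covariance model validates each candidate in local mode; the
# selective descriptor's candidates are tried first and the general
# descriptor only runs when the selective stage produced no validated hit.
# Validated hits are extended by 150 nt (5') and 300 nt (3'), rescored with
# the model-global covariance alignment over the extended window to refine
# the gene boundaries, and re-thresholded.  Both phases require
# E <= 1e-10 by default.

#' Scan configuration
#'
#' @param evalue_threshold maximum E-value at both the validation and the
#'   refinement phase (default 1e-10).
#' @param extension_5prime,extension_3prime window extension in nt applied
#'   upstream/downstream of a validated hit, in transcript orientation
#'   (defaults 150 and 300).
#' @param strands `"both"`, `"+"` or `"-"`.
#' @param seed integer seed recorded on results (scanning itself is
#'   deterministic).
#' @param report_partials also emit sub-threshold refined candidates,
#'   flagged `low_confidence` (off by default).
#' @param use_selective,use_general per-stage toggles.
#' @return an `rnp_scan_config` list.
#' @export
scan_config <- function(evalue_threshold = 1e-10,
                        extension_5prime = 150L, extension_3prime = 300L,
                        strands = c("both", "+", "-"), seed = NULL,
                        report_partials = FALSE,
                        use_selective = TRUE, use_general = TRUE) {
  strands <- match.arg(strands)
  stopifnot(evalue_threshold > 0, extension_5prime >= 0,
            extension_3prime >= 0)
  out <- list(evalue_threshold = evalue_threshold,
              extension_5prime = as.integer(extension_5prime),
              extension_3prime = as.integer(extension_3prime),
              strands = strands, seed = seed,
              report_partials = report_partials,
              use_selective = use_selective, use_general = use_general)
  class(out) <- "rnp_scan_config"
  out
}

.strand_factor <- function(config)
  if (config$strands == "both") 2L else 1L

#' Extend a candidate span into a refinement window
#'
#' Extensions are applied in transcript orientation: on the minus strand
#' the 5' extension grows the forward-coordinate end.  The window is
#' clipped to the sequence bounds and clipping is flagged.
#'
#' @param start,end candidate span, 0-based half-open forward coordinates.
#' @param record_length sequence length.
#' @param strand `"+"` or `"-"`.
#' @param ext5,ext3 extensions in nt.
#' @return list with `start`, `end` (0-based half-open) and `flags`
#'   (`clipped_5prime` / `clipped_3prime`).
#' @export
extend_window <- function(start, end, record_length, strand = "+",
                          ext5 = 150L, ext3 = 300L) {
  stopifnot(start >= 0, end >= start, end <= record_length)
  if (strand == "+") {
    ws <- start - ext5; we <- end + ext3
    cf5 <- ws < 0; cf3 <- we > record_length
  } else {
    ws <- start - ext3; we <- end + ext5
    cf5 <- we > record_length; cf3 <- ws < 0
  }
  flags <- c(if (cf5) "clipped_5prime", if (cf3) "clipped_3prime")
  list(start = max(0L, ws), end = min(record_length, we),
       flags = flags %||% character(0))
}

#' Validate a descriptor hit with the covariance model in local mode
#'
#' @param hit one-row hit data.frame from [dm_scan()].
#' @param record one-row `rnp_seqs` table.
#' @param cm calibrated `rnp_cm`.
#' @param config `rnp_scan_config`.
#' @return list with `alignment` (an `rnp_cm_alignment`) and `evalue`,
#'   or `NULL` when the hit does not reach the E-value threshold.
#' @export
validate_candidate <- function(hit, record, cm, config = scan_config()) {
  if (is.null(cm$evd)) stop("model is not calibrated; run cm_calibrate()")
  wres <- substr(record$residues, hit$start, hit$end)
  if (hit$strand == "-") wres <- reverse_complement(wres)
  al <- cm_score_local(cm, wres)
  ev <- cm_evalue(cm, al$score, record$length, .strand_factor(config))
  if (ev <= config$evalue_threshold) list(alignment = al, evalue = ev)
  else NULL
}

# refine one validated hit on its extended window; returns a call row or NULL
.refine_hit <- function(hit, val, record, cm, subfamily, variant, config) {
  L <- record$length
  w <- extend_window(hit$start - 1L, hit$end, L, hit$strand,
                     config$extension_5prime, config$extension_3prime)
  wres <- substr(record$residues, w$start + 1L, w$end)
  if (hit$strand == "-") wres <- reverse_complement(wres)
  ref <- cm_score_local(cm, wres)
  ev <- cm_evalue(cm, ref$score, L, .strand_factor(config))
  below <- ev <= config$evalue_threshold
  if (!below && !config$report_partials) return(NULL)
  if (is.na(ref$core_start)) return(NULL)
  a <- ref$start; b <- ref$end        # 1-based inclusive, window-local
  if (hit$strand == "+") {
    fs <- w$start + a; fe <- w$start + b
  } else {
    fs <- w$end - b + 1L; fe <- w$end - a + 1L
  }
  seqres <- substr(wres, a, b)
  flags <- unique(c(w$flags, ref$flags, if (!below) "low_confidence"))
  new_calls(data.frame(
    seq_id = record$id, strand = hit$strand, start = fs, end = fe,
    subfamily = subfamily, dm_variant = variant,
    local_score = val$alignment$score, global_score = ref$score,
    evalue = ev, length = fe - fs + 1L,
    sequence = seqres, structure = ref$structure,
    flags = paste(flags, collapse = ","), stringsAsFactors = FALSE))
}

#' Scan one record with one subfamily's models
#'
#' Runs the selective descriptor (when present and enabled), validates each
#' hit with the CM; if the selective stage yields no validated hit, the
#' general descriptor is applied.  Every validated hit is extended,
#' rescored over the window and re-thresholded.
#'
#' @param record one-row `rnp_seqs` table.
#' @param models list with `selective` (optional `rnp_dm`), `general`
#'   (`rnp_dm`) and `cm` (calibrated `rnp_cm`).
#' @param subfamily subfamily label recorded on the calls.
#' @param config `rnp_scan_config`.
#' @return an `rnp_calls` data.frame with attribute `stage_log`
#'   (data.frame of per-stage hit/validation counts).
#' @export
scan_subfamily <- function(record, models, subfamily = models$cm$subfamily,
                           config = scan_config()) {
  cm <- models$cm
  log <- list()
  run_stage <- function(dm, variant) {
    hits <- dm_scan(record, dm, config$strands)
    validated <- list()
    for (k in seq_len(nrow(hits))) {
      v <- validate_candidate(hits[k, ], record, cm, config)
      if (!is.null(v))
        validated[[length(validated) + 1L]] <- list(hit = hits[k, ],
                                                    val = v)
    }
    log[[length(log) + 1L]] <<- data.frame(
      seq_id = record$id, subfamily = subfamily, stage = variant,
      n_hits = nrow(hits), n_validated = length(validated),
      stringsAsFactors = FALSE)
    validated
  }
  validated <- list(); variant <- NA_character_
  if (!is.null(models$selective) && config$use_selective) {
    validated <- run_stage(models$selective, "selective")
    variant <- "selective"
  }
  if (!length(validated) && config$use_general) {
    validated <- run_stage(models$general, "general")
    variant <- "general"
  }
  calls <- list()
  for (vh in validated) {
    cr <- .refine_hit(vh$hit, vh$val, record, cm, subfamily, variant,
                      config)
    if (!is.null(cr)) calls[[length(calls) + 1L]] <- cr
  }
  out <- if (length(calls)) new_calls(do.call(rbind, calls))
         else new_calls(NULL)
  out <- unique(out)
  out <- new_calls(out[order(out$start, out$strand, out$evalue), ,
                       drop = FALSE])
  attr(out, "stage_log") <- if (length(log)) do.call(rbind, log) else NULL
  out
}

#' Resolve overlapping gene calls
#'
#' Among calls whose spans overlap on the same strand of the same
#' sequence, the lowest E-value wins; ties break by higher global score,
#' then lexicographically first subfamily (deterministic).
#'
#' @param calls an `rnp_calls` data.frame.
#' @return the reduced call set, input order of survivors preserved by
#'   position.
#' @export
resolve_overlaps <- function(calls) {
  if (nrow(calls) < 2L) return(calls)
  keep <- logical(nrow(calls))
  for (grp in split(seq_len(nrow(calls)),
                    paste(calls$seq_id, calls$strand))) {
    o <- grp[order(calls$start[grp])]
    cluster <- list(); cend <- -Inf
    clusters <- list()
    for (i in o) {
      if (calls$start[i] > cend) {
        if (length(cluster)) clusters[[length(clusters) + 1L]] <- cluster
        cluster <- list()
        cend <- -Inf
      }
      cluster[[length(cluster) + 1L]] <- i
      cend <- max(cend, calls$end[i])
    }
    if (length(cluster)) clusters[[length(clusters) + 1L]] <- cluster
    for (cl in clusters) {
      idx <- unlist(cl)
      best <- idx[order(calls$evalue[idx], -calls$global_score[idx],
                        calls$subfamily[idx])][1L]
      keep[best] <- TRUE
    }
  }
  new_calls(calls[keep, , drop = FALSE])
}

#' Scan sequences with a full model library
#'
#' Applies every subfamily's cascade to every record, resolves
#' cross-subfamily overlaps by E-value, and sorts by position.
#'
#' @param seqs an `rnp_seqs` table (or a residue string).
#' @param library an `rnp_library` with calibrated CMs.
#' @param config `rnp_scan_config`.
#' @return an `rnp_calls` data.frame with a `stage_log` attribute.
#' @export
scan_all <- function(seqs, library, config = scan_config()) {
  if (is.character(seqs)) seqs <- new_rnp_seqs("seq", seqs)
  all_calls <- list(); logs <- list()
  for (i in seq_len(nrow(seqs))) {
    rec_calls <- list()
    for (sf in names(library$subfamilies)) {
      entry <- library$subfamilies[[sf]]
      cs <- scan_subfamily(seqs[i, ], entry, sf, config)
      if (!is.null(attr(cs, "stage_log")))
        logs[[length(logs) + 1L]] <- attr(cs, "stage_log")
      if (nrow(cs)) rec_calls[[length(rec_calls) + 1L]] <- cs
    }
    if (length(rec_calls)) {
      merged <- new_calls(do.call(rbind, rec_calls))
      all_calls[[length(all_calls) + 1L]] <- resolve_overlaps(merged)
    }
  }
  out <- if (length(all_calls)) new_calls(do.call(rbind, all_calls))
         else new_calls(NULL)
  out <- new_calls(out[order(out$seq_id, out$start), , drop = FALSE])
  attr(out, "stage_log") <- if (length(logs)) do.call(rbind, logs) else NULL
  out
}

#' Scan with the covariance model only (no descriptor filter)
#'
#' Slides windows of length `2 * M` with 50% overlap, scores each in local
#' mode, merges overlapping passing windows, refines each merged window and
#' thresholds.  Around 100x slower than the cascade but immune to
#' descriptor blind spots (unusual local variations the patterns cannot
#' absorb).
#'
#' @param seqs an `rnp_seqs` table or residue string.
#' @param cm calibrated `rnp_cm`.
#' @param config `rnp_scan_config`.
#' @param subfamily label for the emitted calls.
#' @return an `rnp_calls` data.frame (dm_variant `"cm-only"`).
#' @export
scan_cm_only <- function(seqs, cm, config = scan_config(),
                         subfamily = cm$subfamily) {
  if (is.null(cm$evd)) stop("model is not calibrated; run cm_calibrate()")
  if (is.character(seqs)) seqs <- new_rnp_seqs("seq", seqs)
  wlen <- 2L * cm$M
  step <- cm$M
  strands <- switch(config$strands, both = c("+", "-"),
                    config$strands)
  calls <- list()
  for (i in seq_len(nrow(seqs))) {
    L <- seqs$length[i]
    for (strand in strands) {
      sres <- if (strand == "+") seqs$residues[i]
              else reverse_complement(seqs$residues[i])
      starts <- unique(c(seq.int(0L, max(0L, L - wlen), by = step),
                         max(0L, L - wlen)))
      pass <- list()
      best_local <- -Inf
      for (s0 in starts) {
        e0 <- min(L, s0 + wlen)
        al <- cm_score_local(cm, substr(sres, s0 + 1L, e0))
        ev <- cm_evalue(cm, al$score, L, .strand_factor(config))
        if (ev <= config$evalue_threshold) {
          pass[[length(pass) + 1L]] <- c(s0, e0, al$score)
        }
      }
      if (!length(pass)) next
      pm <- do.call(rbind, pass)
      pm <- pm[order(pm[, 1L]), , drop = FALSE]
      # merge overlapping passing windows (strand-local coordinates)
      merged <- list(); cur <- pm[1L, ]
      for (k in seq_len(nrow(pm))[-1L]) {
        if (pm[k, 1L] <= cur[2L]) {
          cur[2L] <- max(cur[2L], pm[k, 2L])
          cur[3L] <- max(cur[3L], pm[k, 3L])
        } else {
          merged[[length(merged) + 1L]] <- cur
          cur <- pm[k, ]
        }
      }
      merged[[length(merged) + 1L]] <- cur
      for (m in merged) {
        ref <- cm_score_local(cm, substr(sres, m[1L] + 1L, m[2L]))
        ev <- cm_evalue(cm, ref$score, L, .strand_factor(config))
        if (ev > config$evalue_threshold || is.na(ref$core_start)) next
        a0 <- m[1L] + ref$start - 1L   # strand-local 0-based
        b0 <- m[1L] + ref$end
        if (strand == "+") { fs <- a0 + 1L; fe <- b0 }
        else { fs <- L - b0 + 1L; fe <- L - a0 }
        calls[[length(calls) + 1L]] <- new_calls(data.frame(
          seq_id = seqs$id[i], strand = strand, start = fs, end = fe,
          subfamily = subfamily, dm_variant = "cm-only",
          local_score = m[3L], global_score = ref$score, evalue = ev,
          length = fe - fs + 1L,
          sequence = substr(sres, a0 + 1L, b0),
          structure = ref$structure,
          flags = paste(ref$flags, collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  out <- if (length(calls)) new_calls(do.call(rbind, calls))
         else new_calls(NULL)
  out <- resolve_overlaps(out)
  new_calls(out[order(out$seq_id, out$start), , drop = FALSE])
}
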