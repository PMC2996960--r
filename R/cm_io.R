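# Plain-text serialization of covariance models and model libraries.
#
# A model archive is one directory per subfamily holding the descriptor
# files (selective/general), the training Stockholm alignment, and the CM
# parameter file written here.

#' Write a covariance model as plain text
#' @param cm an `rnp_cm` model.
#' @param path output file, or `NULL`.
#' @return the text, invisibly.
#' @export
write_cm <- function(cm, path = NULL) {
  lines <- c("RNPSCAN-CM v1",
             paste("name:", cm$name),
             paste("subfamily:", cm$subfamily),
             paste("M:", cm$M),
             paste("structure:", cm$structure),
             paste("consensus:", cm$consensus),
             paste("gaps:", paste(sprintf("%.8g", cm$gaps), collapse = " ")),
             paste("n_rows:", cm$n_rows))
  nt <- cm$nodes$type
  for (v in seq_along(nt)) {
    if (nt[v] == .NODE_MATL) {
      lines <- c(lines, sprintf("L %d %s", cm$nodes$col5[v],
                 paste(sprintf("%.8g", cm$nodes$emit[[v]][1:4]),
                       collapse = " ")))
    } else if (nt[v] == .NODE_MATP) {
      e <- matrix(cm$nodes$emit[[v]], 5L, 5L)
      lines <- c(lines, sprintf("P %d %d %s", cm$nodes$col5[v],
                 cm$nodes$col3[v],
                 paste(sprintf("%.8g", as.numeric(e[1:4, 1:4])),
                       collapse = " ")))
    }
  }
  if (!is.null(cm$evd))
    lines <- c(lines, sprintf("evd: %.8g %.8g %d %d %d %s",
                              cm$evd$lambda, cm$evd$mu, cm$evd$n_decoys,
                              cm$evd$decoy_length, cm$evd$seed,
                              cm$evd$method))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

#' Read a covariance model written by [write_cm()]
#' @param path model parameter file.
#' @return an `rnp_cm`.
#' @export
read_cm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1L] != "RNPSCAN-CM v1")
    stop("not an RNPSCAN-CM v1 file: ", path)
  field <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(ln)) stop("CM file missing field: ", key)
    sub(paste0("^", key, ": "), "", ln[1L])
  }
  M <- as.integer(field("M"))
  struct <- field("structure")
  gaps <- as.numeric(strsplit(field("gaps"), " ")[[1L]])
  names(gaps) <- c("insert_open", "insert_extend", "delete_open",
                   "delete_extend")

  # rebuild a toy alignment-independent model: reconstruct the guide tree
  # from the structure, then overwrite emissions from the stored log-odds
  Lrows <- strsplit(grep("^L ", lines, value = TRUE), " ")
  Prows <- strsplit(grep("^P ", lines, value = TRUE), " ")
  lo_single <- list(); lo_pair <- list()
  for (r in Lrows)
    lo_single[[as.integer(r[2L])]] <- as.numeric(r[3:6])
  pair_key <- integer(0)
  for (r in Prows) {
    c5 <- as.integer(r[2L])
    lo_pair[[c5]] <- as.numeric(r[4:19])
    pair_key[c5] <- as.integer(r[3L])
  }

  fake_rows <- strrep("A", M)
  aln <- new_rnp_aln("template", fake_rows, struct)
  cm <- build_cm(aln, gap_threshold = 2, pseudocount = 1, gaps = gaps)
  cm$name <- field("name")
  cm$subfamily <- field("subfamily")
  cm$n_rows <- as.integer(field("n_rows"))
  for (v in seq_along(cm$nodes$type)) {
    t <- cm$nodes$type[v]
    if (t == .NODE_MATL) {
      lo <- lo_single[[cm$nodes$col5[v]]]
      if (is.null(lo)) stop("CM file missing emissions for column ",
                            cm$nodes$col5[v])
      p <- 2^lo * 0.25
      cm$nodes$emit[[v]] <- .extend_single(p)
    } else if (t == .NODE_MATP) {
      lo <- lo_pair[[cm$nodes$col5[v]]]
      if (is.null(lo)) stop("CM file missing emissions for pair at column ",
                            cm$nodes$col5[v])
      p <- 2^lo / 16
      cm$nodes$emit[[v]] <- as.numeric(.extend_pair(p))
    }
  }
  cons <- field("consensus")
  cm$consensus <- cons
  ev <- grep("^evd: ", lines, value = TRUE)
  if (length(ev)) {
    f <- strsplit(sub("^evd: ", "", ev[1L]), " ")[[1L]]
    cm$evd <- list(lambda = as.numeric(f[1L]), mu = as.numeric(f[2L]),
                   n_decoys = as.integer(f[3L]),
                   decoy_length = as.integer(f[4L]),
                   seed = as.integer(f[5L]), method = f[6L])
  }
  cm
}

#' Write a model library to a directory
#'
#' One sub-directory per subfamily with `selective.dm` (optional),
#' `general.dm`, `alignment.sto` and `model.cm`.
#'
#' @param library an `rnp_library` (see [make_toy_library()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_library <- function(library, dir) {
  for (sf in names(library$subfamilies)) {
    sub <- file.path(dir, sf)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    entry <- library$subfamilies[[sf]]
    if (!is.null(entry$selective))
      write_descriptor(entry$selective, file.path(sub, "selective.dm"))
    write_descriptor(entry$general, file.path(sub, "general.dm"))
    if (!is.null(entry$alignment))
      write_stockholm(entry$alignment, file.path(sub, "alignment.sto"))
    write_cm(entry$cm, file.path(sub, "model.cm"))
  }
  invisible(dir)
}

#' Read a model library directory
#' @param dir directory written by [write_model_library()].
#' @return an `rnp_library`.
#' @export
read_model_library <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  if (!length(subs)) stop("no subfamily directories under ", dir)
  subfamilies <- list()
  for (sub in subs) {
    sf <- basename(sub)
    sel <- file.path(sub, "selective.dm")
    entry <- list(
      selective = if (file.exists(sel)) read_descriptor(sel) else NULL,
      general = read_descriptor(file.path(sub, "general.dm")),
      alignment = if (file.exists(file.path(sub, "alignment.sto")))
        read_stockholm(file.path(sub, "alignment.sto")) else NULL,
      cm = read_cm(file.path(sub, "model.cm")))
    subfamilies[[sf]] <- entry
  }
  out <- list(subfamilies = subfamilies)
  class(out) <- "rnp_library"
  out
}

#' @export
print.rnp_library <- function(x, ...) {
  cat("model library:", length(x$subfamilies), "subfamilies\n")
  for (sf in names(x$subfamilies)) {
    e <- x$subfamilies[[sf]]
    cat(sprintf("  %s: %sgeneral DM, CM (M=%d%s)\n", sf,
                if (!is.null(e$selective)) "selective DM, " else "",
                e$cm$M,
                if (is.null(e$cm$evd)) ", uncalibrated" else ", calibrated"))
  }
  invisible(x)
}
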