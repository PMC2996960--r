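# E-value calibration: dinucleotide-shuffled decoys and a Gumbel null.
#
# Local-mode scores of a CM on random sequence follow an extreme-value
# (Gumbel) distribution.  The calibration scores a set of decoys that
# preserve the dinucleotide composition of real background (an Euler-path
# shuffle), fits (lambda, mu) by maximum likelihood, and E-values are then
# window counts times the Gumbel tail probability.

#' Dinucleotide-preserving shuffle (Euler-path method)
#'
#' Draws a sequence with exactly the original dinucleotide counts: the
#' sequence is viewed as an Euler path in the dinucleotide multigraph, a
#' random last-exit arborescence toward the terminal vertex is chosen, the
#' remaining edges are permuted, and the path is rewalked.
#'
#' @param residues sequence of length >= 2.
#' @param seed integer seed for determinism; `NULL` uses (and advances) the
#'   current RNG stream.
#' @return a shuffled sequence with identical dinucleotide (and hence
#'   mononucleotide) counts.
#' @export
dinucleotide_shuffle <- function(residues, seed = NULL) {
  s <- strsplit(residues, "", fixed = TRUE)[[1L]]
  n <- length(s)
  if (n < 2L) stop("sequence must have length >= 2")
  verts <- unique(s)
  if (length(verts) == 1L) return(residues)
  with_seed(seed, {
    vi <- match(s, verts)
    nv <- length(verts)
    adj <- vector("list", nv)          # outgoing edge targets, per vertex
    for (v in seq_len(nv)) adj[[v]] <- vi[which(vi[-n] == v) + 1L]
    last <- vi[n]
    src <- setdiff(which(lengths(adj) > 0L), last)
    # random last-exit edges forming an arborescence toward `last`
    repeat {
      pick <- vapply(src, function(v) {
        a <- adj[[v]]; a[sample.int(length(a), 1L)]
      }, integer(1))
      nxt <- integer(nv); nxt[src] <- pick
      ok <- TRUE
      for (v in src) {
        seen <- integer(0); w <- v
        while (w != last) {
          if (w %in% seen || (w != last && nxt[w] == 0L)) { ok <- FALSE; break }
          seen <- c(seen, w); w <- nxt[w]
        }
        if (!ok) break
      }
      if (ok) break
    }
    lists <- vector("list", nv)
    for (v in seq_len(nv)) {
      a <- adj[[v]]
      if (v != last && length(a)) {
        drop <- which(a == nxt[v])[1L]  # reserve one instance as last exit
        a <- a[-drop]
        a <- if (length(a)) a[sample.int(length(a))] else integer(0)
        lists[[v]] <- c(a, nxt[v])
      } else {
        lists[[v]] <- if (length(a)) a[sample.int(length(a))] else integer(0)
      }
    }
    ptr <- rep(1L, nv)
    out <- integer(n)
    out[1L] <- vi[1L]
    cur <- vi[1L]
    for (k in 2L:n) {
      nx <- lists[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[k] <- nx
      cur <- nx
    }
    paste(verts[out], collapse = "")
  })
}

# Gumbel fit: maximum likelihood with a method-of-moments fallback
fit_gumbel <- function(x) {
  if (stats::sd(x) < 1e-9) stop("degenerate score distribution")
  lam0 <- pi / (stats::sd(x) * sqrt(6))
  mu0 <- mean(x) - 0.5772156649 / lam0
  nll <- function(par) {
    lam <- exp(par[1L])
    z <- lam * (x - par[2L])
    -(length(x) * log(lam) - sum(z) - sum(exp(-z)))
  }
  fit <- tryCatch(stats::optim(c(log(lam0), mu0), nll, method = "BFGS"),
                  error = function(e) NULL)
  if (!is.null(fit) && fit$convergence == 0L && is.finite(fit$value))
    list(lambda = exp(fit$par[1L]), mu = fit$par[2L], method = "ml")
  else
    list(lambda = lam0, mu = mu0, method = "moments")
}

#' Calibrate a covariance model's E-value statistics on shuffled decoys
#'
#' Scores `n_decoys` dinucleotide-shuffled windows of length `2 * M` in
#' local mode and fits Gumbel location/scale by maximum likelihood
#' (method of moments on non-convergence).
#'
#' @param cm an `rnp_cm` model.
#' @param n_decoys number of decoys (>= 50).
#' @param decoy_source `NULL` (uniform random background), a residue string
#'   (tiled into windows before shuffling), or a `function(i)` returning the
#'   i-th window.
#' @param seed integer seed; all decoys derive deterministically from it.
#' @return the model with an `evd` field (`lambda`, `mu`, `n_decoys`,
#'   `decoy_length`, `seed`, `method`).
#' @export
cm_calibrate <- function(cm, n_decoys = 200L, decoy_source = NULL,
                         seed = 1L) {
  stopifnot(inherits(cm, "rnp_cm"))
  if (n_decoys < 50L) stop("calibration requires n_decoys >= 50")
  wlen <- 2L * cm$M
  windows <- with_seed(seed, {
    vapply(seq_len(n_decoys), function(i) {
      w <- if (is.null(decoy_source)) {
        paste(sample(c("A", "C", "G", "T"), wlen, replace = TRUE),
              collapse = "")
      } else if (is.function(decoy_source)) {
        decoy_source(i)
      } else {
        src <- decoy_source
        o <- ((i - 1L) * wlen) %% max(1L, nchar(src) - wlen) + 1L
        substr(src, o, o + wlen - 1L)
      }
      dinucleotide_shuffle(w, seed = NULL)
    }, character(1))
  })
  scores <- vapply(windows, function(w) cm_score_local(cm, w)$score,
                   numeric(1))
  fit <- fit_gumbel(scores)
  cm$evd <- list(lambda = fit$lambda, mu = fit$mu,
                 n_decoys = as.integer(n_decoys),
                 decoy_length = wlen, seed = seed, method = fit$method)
  cm
}

#' E-value of a covariance-model score
#'
#' `E = W * (1 - exp(-exp(-lambda * (s - mu))))` with window count
#' `W = strands * search_space / M`; strictly decreasing in the score.
#'
#' @param cm a calibrated `rnp_cm`.
#' @param score score(s) in bits.
#' @param search_space nucleotides scanned (per strand).
#' @param strands 1 or 2.
#' @return E-value(s).
#' @export
cm_evalue <- function(cm, score, search_space, strands = 2L) {
  if (is.null(cm$evd)) stop("model is not calibrated; run cm_calibrate()")
  W <- strands * search_space / cm$M
  z <- cm$evd$lambda * (score - cm$evd$mu)
  # tail-stable: for large z, 1 - exp(-exp(-z)) ~ exp(-z)
  p <- ifelse(z > 30, exp(-z), 1 - exp(-exp(-z)))
  W * p
}
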