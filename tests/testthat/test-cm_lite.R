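test_that("emission log-odds follow the pseudocount formula", {
  # 4 rows, all A in an unpaired match column, pseudocount 1:
  # log2((5/8)/(1/4)) = log2(2.5)
  aln <- new_rnp_aln(paste0("r", 1:4), rep("A", 4L), ".")
  cm <- build_cm(aln)
  v <- cm$nodes$emit[[which(cm$nodes$type == 0L)[1L]]]
  expect_equal(v[1L], log2(2.5), tolerance = 1e-12)
  # all-G:C pair, pseudocount 1: log2((5/20)/(1/16)) = 2 bits
  aln2 <- new_rnp_aln(paste0("r", 1:4), rep("GAC", 4L), "<.>")
  cm2 <- build_cm(aln2)
  pv <- matrix(cm2$nodes$emit[[which(cm2$nodes$type == 1L)]], 5L, 5L)
  expect_equal(pv[3L, 2L], 2, tolerance = 1e-12)  # (G, C) entry
})

test_that("gap-majority columns are excluded from the match set", {
  aln <- new_rnp_aln(paste0("r", 1:4),
                     c("A-CG", "A-CG", "A-CG", "ATCG"), "....")
  cm <- build_cm(aln, gap_threshold = 0.5)
  expect_equal(cm$M, 3L)
  expect_equal(cm$match_cols, c(1L, 3L, 4L))
})

test_that("pairs onto non-match columns are demoted with a warning", {
  aln <- new_rnp_aln(paste0("r", 1:4),
                     c("G-CA", "G-CA", "G-CA", "GTCA"), "<>..")
  expect_warning(cm <- build_cm(aln), "demoted")
  expect_equal(sum(cm$nodes$type == 1L), 0L)
  expect_equal(cm$M, 3L)
})

test_that("an alignment with no match columns is rejected", {
  aln <- new_rnp_aln(c("a", "b"), c("A-", "-A"), "..")
  expect_error(build_cm(aln, gap_threshold = 0.4), "no match columns")
})

test_that("global score on the training sequence equals the emission sum", {
  cm <- build_cm(tiny_aln())
  g <- cm_score_global(cm, "GGGCAAAGCCC")
  pair_bits <- log2((2 + 1) / (2 + 16) * 16)
  single_bits <- log2((2 + 1) / (2 + 4) * 4)
  expect_equal(g$score, 4 * pair_bits + 3 * single_bits,
               tolerance = 1e-9)
  expect_equal(g$structure, "<<<<...>>>>")
  expect_equal(c(g$start, g$end), c(1L, 11L))
  expect_equal(c(g$core_start, g$core_end), c(1L, 11L))
})

test_that("a deletion costs delete_open plus the forgone emission", {
  aln <- new_rnp_aln(c("a", "b"), c("GACGT", "GACGT"), ".....")
  cm <- build_cm(aln)
  full <- cm_score_global(cm, "GACGT")$score
  single_bits <- log2((2 + 1) / (2 + 4) * 4)
  del <- cm_score_global(cm, "GACG")$score
  expect_equal(del, full - single_bits + cm$gaps[["delete_open"]],
               tolerance = 1e-9)
  expect_equal(del, oracle_cm_score(cm, "GACG", global = TRUE),
               tolerance = 1e-9)
})

test_that("local mode equals global on the exact consensus and finds an embedded copy", {
  cm <- build_cm(tiny_aln())
  g <- cm_score_global(cm, "GGGCAAAGCCC")
  l <- cm_score_local(cm, "GGGCAAAGCCC")
  expect_equal(l$score, g$score, tolerance = 1e-9)
  emb <- cm_score_local(cm, paste0("TTATT", "GGGCAAAGCCC", "ATTTA"))
  expect_equal(emb$score, g$score, tolerance = 1e-9)
  expect_equal(c(emb$start, emb$end), c(6L, 16L))
  expect_equal(emb$structure, "<<<<...>>>>")
})

test_that("scoring rejects empty input and flags short input", {
  cm <- build_cm(tiny_aln())
  expect_error(cm_score_global(cm, ""), "empty")
  short <- cm_score_global(cm, "GGG")
  expect_true("short_input" %in% short$flags)
  expect_true(is.finite(short$score))
})

test_that("global scores match exhaustive parse enumeration on random tiny cases", {
  set.seed(501)
  for (rep in 1:40) {
    case <- random_cm_case(max_m = 6L, max_subject = 8L)
    got <- cm_score_global(case$cm, case$subject)$score
    want <- oracle_cm_score(case$cm, case$subject, global = TRUE)
    expect_equal(got, want, tolerance = 1e-6,
                 info = paste("subject", case$subject))
  }
})

test_that("local scores match the oracle with free flanks", {
  set.seed(502)
  for (rep in 1:15) {
    case <- random_cm_case(max_m = 6L, max_subject = 8L)
    got <- cm_score_local(case$cm, case$subject)$score
    want <- oracle_cm_score(case$cm, case$subject, global = FALSE)
    expect_equal(got, want, tolerance = 1e-6,
                 info = paste("subject", case$subject))
  }
})

test_that("dinucleotide shuffle preserves composition and is seeded", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1L), "AAAA")
  dicounts <- function(x) {
    sp <- strsplit(x, "")[[1L]]
    table(factor(paste0(sp[-length(sp)], sp[-1L]),
                 levels = as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"),
                                          paste0))))
  }
  set.seed(88)
  for (rep in 1:60) {
    s <- random_subject(sample(5:80, 1L), n_rate = 0)
    sh <- dinucleotide_shuffle(s, seed = rep)
    expect_equal(dicounts(sh), dicounts(s))
    expect_identical(dinucleotide_shuffle(s, seed = rep), sh)
  }
  expect_error(dinucleotide_shuffle("A"), "length")
})

test_that("calibration enforces preconditions and is deterministic", {
  cm <- toy_lib()$subfamilies$bacA$cm
  expect_error(cm_calibrate(cm, n_decoys = 10L), "50")
  a <- cm_calibrate(cm, n_decoys = 60L, seed = 5L)
  b <- cm_calibrate(cm, n_decoys = 60L, seed = 5L)
  expect_identical(a$evd, b$evd)
  expect_gt(a$evd$lambda, 0)
})

test_that("Gumbel parameters are recovered from simulated scores", {
  set.seed(11)
  lambda <- 0.69; mu <- 5
  x <- mu - log(-log(runif(500))) / lambda
  fit <- rnpscan:::fit_gumbel(x)
  expect_lt(abs(fit$lambda - lambda) / lambda, 0.15)
  expect_lt(abs(fit$mu - mu), 0.5)
  expect_error(rnpscan:::fit_gumbel(rep(3, 100)), "degenerate")
})

test_that("E-values follow the Gumbel tail and scale with the window count", {
  cm <- build_cm(tiny_aln())
  cm$evd <- list(lambda = 0.69, mu = 10, n_decoys = 100L,
                 decoy_length = 22L, seed = 1L, method = "ml")
  # at s = mu with W = 1: E = 1 - exp(-1)
  expect_equal(cm_evalue(cm, 10, cm$M, strands = 1L), 1 - exp(-1),
               tolerance = 1e-9)
  e1 <- cm_evalue(cm, 20, 1000 * cm$M, strands = 1L)
  expect_equal(e1, 1000 * (1 - exp(-exp(-0.69 * 10))), tolerance = 1e-6)
  # monotone decreasing in score, linear in search space
  ss <- cm_evalue(cm, seq(5, 40, by = 5), 1e4, strands = 2L)
  expect_true(all(diff(ss) < 0))
  expect_equal(cm_evalue(cm, 25, 2e4, 2L) / cm_evalue(cm, 25, 1e4, 2L), 2,
               tolerance = 1e-9)
  expect_equal(cm_evalue(cm, 1e4, 1e4, 2L), 0)
  cm$evd <- NULL
  expect_error(cm_evalue(cm, 10, 1e4), "calibrat")
})

test_that("training rows outscore dinucleotide shuffles of themselves", {
  lib <- toy_lib()
  for (sf in names(lib$subfamilies)) {
    e <- lib$subfamilies[[sf]]
    for (row in e$alignment$seqs[1:3]) {
      seqrow <- gsub("-", "", row)
      own <- cm_score_global(e$cm, seqrow)$score
      shuf <- vapply(1:25, function(i)
        cm_score_global(e$cm,
                        dinucleotide_shuffle(seqrow, seed = i))$score,
        numeric(1))
      expect_gt(own, max(shuf))
    }
  }
})

test_that("CM text serialization round-trips scores and calibration", {
  lib <- toy_lib()
  cm <- lib$subfamilies$arcA$cm
  f <- withr::local_tempfile(fileext = ".cm")
  write_cm(cm, f)
  back <- read_cm(f)
  expect_equal(back$M, cm$M)
  expect_equal(back$structure, cm$structure)
  expect_equal(back$evd$lambda, cm$evd$lambda, tolerance = 1e-7)
  member <- lib$subfamilies$arcA$members[[1L]]
  expect_equal(cm_score_global(back, member)$score,
               cm_score_global(cm, member)$score, tolerance = 1e-5)
})
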