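test_that("deduplication groups exact sequences and conserves multiplicity", {
  s1 <- "GGGCAAAGCCC"; s2 <- "TTTTTGGGGGA"
  calls <- rbind(make_call_row(seq_id = "a", sequence = s1, end = 11L),
                 make_call_row(seq_id = "b", sequence = s1, end = 11L),
                 make_call_row(seq_id = "c", sequence = s2, end = 11L))
  u <- dedup_calls(calls)
  expect_equal(nrow(u), 2L)
  expect_equal(u$multiplicity, c(2L, 1L))
  expect_equal(sum(u$multiplicity), nrow(calls))
  expect_equal(u$seq_id[1L], "a")  # representative = first in input order
  # idempotence
  u2 <- dedup_calls(u)
  expect_equal(u2$multiplicity, u$multiplicity)
  expect_equal(u2$sequence, u$sequence)
})

test_that("near-duplicate clustering groups highly similar sequences", {
  base <- strrep("ACGGTTACGGATCCTTAGGCA", 5L)          # 105 nt
  near <- paste0(substr(base, 1L, 50L), "T", substr(base, 52L, 105L))
  far <- paste(rep("TTTTAAAACCCCGGGG", 7L), collapse = "")
  calls <- rbind(make_call_row(seq_id = "a", sequence = base, end = 105L),
                 make_call_row(seq_id = "b", sequence = near, end = 105L),
                 make_call_row(seq_id = "c", sequence = far, end = 112L))
  exact <- dedup_calls(calls)
  expect_equal(nrow(exact), 3L)
  clustered <- dedup_calls(calls, identity = 0.97)
  expect_equal(nrow(clustered), 2L)
  expect_equal(clustered$multiplicity, c(2L, 1L))
})

test_that("deduplication is strand-normalized", {
  s <- "GGGCAAAGCCT"
  calls <- rbind(make_call_row(seq_id = "a", sequence = s, end = 11L),
                 make_call_row(seq_id = "b", strand = "-",
                               sequence = reverse_complement(s),
                               end = 11L))
  expect_equal(nrow(dedup_calls(calls)), 1L)
})

test_that("GC content excludes Ns and is reverse-complement invariant", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GANT"), 1 / 3, tolerance = 1e-12)
  expect_error(gc_content("NNN"), "all-N")
  set.seed(6)
  for (rep in 1:10) {
    s <- random_subject(50L, n_rate = 0.1)
    expect_equal(gc_content(s), gc_content(reverse_complement(s)))
  }
})

test_that("homolog assignment distinguishes species, genus and none", {
  set.seed(91)
  qry <- random_subject(300L, n_rate = 0)
  other1 <- random_subject(300L, n_rate = 0)
  other2 <- random_subject(300L, n_rate = 0)
  refs <- data.frame(
    id = c("ref1", "ref2", "ref3"),
    species = c("Alpha one", "Beta two", "Gamma three"),
    genus = c("Alpha", "Beta", "Gamma"),
    residues = c(qry, other1, other2), stringsAsFactors = FALSE)
  a <- assign_homolog(qry, refs, evalue_cutoff = 1e-50)
  expect_equal(a$level, "species")
  expect_equal(a$hits$id[a$hits$passing], "ref1")
  # two passing references of the same genus: genus-level assignment
  refs2 <- refs
  refs2$residues[2L] <- qry
  refs2$genus[2L] <- "Alpha"
  expect_equal(assign_homolog(qry, refs2, 1e-50)$level, "genus")
  # two passing references of different genera: none + multi_genus
  refs3 <- refs
  refs3$residues[2L] <- qry
  a3 <- assign_homolog(qry, refs3, 1e-50)
  expect_equal(a3$level, "none")
  expect_true(a3$multi_genus)
  # nothing passes a tiny cutoff
  a4 <- assign_homolog(random_subject(300L, n_rate = 0), refs, 1e-300)
  expect_equal(a4$level, "none")
  expect_false(a4$multi_genus)
})

test_that("raising the homolog E cutoff never shrinks the passing set", {
  set.seed(92)
  qry <- random_subject(250L, n_rate = 0)
  refs <- data.frame(
    id = paste0("r", 1:4),
    species = paste("sp", 1:4), genus = paste("g", 1:4),
    residues = c(qry,
                 paste0(substr(qry, 1L, 150L),
                        random_subject(100L, n_rate = 0)),
                 random_subject(250L, n_rate = 0),
                 random_subject(250L, n_rate = 0)),
    stringsAsFactors = FALSE)
  cuts <- c(1e-80, 1e-50, 1e-20, 1e-5, 1)
  sizes <- vapply(cuts, function(ct)
    sum(assign_homolog(qry, refs, ct)$hits$passing), integer(1))
  expect_true(all(diff(sizes) >= 0L))
})

test_that("subfamily summary covers all seven subfamilies", {
  calls <- rbind(make_call_row(subfamily = "bacA"),
                 make_call_row(subfamily = "bacA"),
                 make_call_row(subfamily = "bacA"),
                 make_call_row(subfamily = "arcA"))
  s <- subfamily_summary(calls)
  expect_equal(nrow(s), 7L)
  expect_equal(sum(s$n), 4L)
  expect_equal(s$n[s$subfamily == "bacA"], 3L)
  expect_equal(s$n[s$subfamily == "arcA"], 1L)
  expect_equal(s$n[s$subfamily == "fugB"], 0L)
  empty <- subfamily_summary(make_call_row()[0L, ])
  expect_equal(sum(empty$n), 0L)
})

test_that("size correlation recovers monotone and simulated relationships", {
  inc <- data.frame(subfamily = "bacA", gene_length = 1:10,
                    genome_length = (1:10) * 1e5)
  expect_equal(size_correlation(inc)$rho, 1)
  dec <- inc; dec$genome_length <- rev(dec$genome_length)
  expect_equal(size_correlation(dec)$rho, -1)
  expect_warning(size_correlation(inc[1:2, ]), "skipped")
  # bivariate normal with rank correlation ~0.5
  set.seed(13)
  n <- 200L
  z <- matrix(rnorm(2L * n), ncol = 2L)
  rho_target <- 2 * sin(pi / 6 * 1)  # pearson rho giving spearman ~0.48
  x <- z[, 1L]
  y <- 0.52 * z[, 1L] + sqrt(1 - 0.52^2) * z[, 2L]
  sim <- data.frame(subfamily = "arcA",
                    gene_length = 300 + 50 * x,
                    genome_length = 3e6 + 1e6 * y)
  got <- size_correlation(sim)
  expect_lt(abs(got$rho - 0.5), 0.15)
  expect_equal(got$n, n)
})
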