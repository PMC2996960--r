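test_that("window extension applies 5'/3' margins in transcript orientation", {
  w <- extend_window(200L, 500L, 10000L, "+")
  expect_equal(c(w$start, w$end), c(50L, 800L))
  expect_length(w$flags, 0L)
  w2 <- extend_window(100L, 400L, 10000L, "+")
  expect_equal(c(w2$start, w2$end), c(0L, 700L))
  expect_true("clipped_5prime" %in% w2$flags)
  # minus strand: the 5' extension grows the forward-coordinate end
  w3 <- extend_window(200L, 500L, 10000L, "-")
  expect_equal(c(w3$start, w3$end), c(0L, 650L))
  expect_true("clipped_3prime" %in% w3$flags)
})

test_that("validation accepts a planted member and rejects its shuffle", {
  lib <- toy_lib()
  e <- lib$subfamilies$bacA
  member <- as.character(e$members[[3L]])
  bg <- random_background(20000L, seed = 21L)
  pl <- plant_gene(bg, member, 5000L)
  hits <- dm_scan(pl$record, e$selective, "+")
  expect_gte(nrow(hits), 1L)
  cfg <- scan_config()
  v <- validate_candidate(hits[1L, ], pl$record, e$cm, cfg)
  expect_false(is.null(v))
  expect_lte(v$evalue, cfg$evalue_threshold)
  # uncalibrated model is an error
  raw <- e$cm; raw$evd <- NULL
  expect_error(validate_candidate(hits[1L, ], pl$record, raw, cfg),
               "calibrat")
  # decoy window at the same coordinates fails validation
  dec <- pl
  dec$record$residues <- dinucleotide_shuffle(pl$record$residues,
                                              seed = 4L)
  fake <- hits[1L, ]
  expect_null(validate_candidate(fake, dec$record, e$cm, cfg))
})

test_that("a candidate exactly at the threshold is accepted", {
  lib <- toy_lib()
  e <- lib$subfamilies$bacA
  member <- as.character(e$members[[3L]])
  bg <- random_background(20000L, seed = 22L)
  pl <- plant_gene(bg, member, 5000L)
  hits <- dm_scan(pl$record, e$selective, "+")
  v <- validate_candidate(hits[1L, ], pl$record, e$cm, scan_config())
  # re-run with the threshold set exactly to the observed E ("<=")
  cfg_eq <- scan_config(evalue_threshold = v$evalue)
  expect_false(is.null(validate_candidate(hits[1L, ], pl$record, e$cm,
                                          cfg_eq)))
})

test_that("selective-to-general fallback triggers only on aberrant members", {
  lib <- toy_lib()
  e <- lib$subfamilies$bacA
  cfg <- scan_config()
  # a normal member: called via the selective DM; general never executed
  pl <- plant_gene(random_background(20000L, seed = 31L),
                   as.character(e$members[[2L]]), 8000L)
  calls <- scan_subfamily(pl$record, e, "bacA", cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$dm_variant, "selective")
  log <- attr(calls, "stage_log")
  expect_false("general" %in% log$stage)
  # the aberrant member (one extra mispair): fails selective, called via
  # the general DM
  pl2 <- plant_gene(random_background(20000L, seed = 32L),
                    as.character(e$aberrant), 8000L)
  calls2 <- scan_subfamily(pl2$record, e, "bacA", cfg)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$dm_variant, "general")
  log2 <- attr(calls2, "stage_log")
  expect_equal(log2$n_validated[log2$stage == "selective"], 0L)
})

test_that("refined spans stay inside the extended window and pass the threshold", {
  lib <- toy_lib()
  sim <- simulate_genomes(4L, genome_length = 20000L, seed = 61L,
                          library = lib)
  cfg <- scan_config()
  calls <- scan_all(sim$genomes, lib, cfg)
  expect_equal(nrow(calls), 4L)
  expect_true(all(calls$evalue <= cfg$evalue_threshold))
  for (k in seq_len(nrow(calls))) {
    tr <- sim$truth[sim$truth$seq_id == calls$seq_id[k], ]
    ext <- extend_window(tr$start, tr$end, 20000L, tr$strand)
    expect_gte(calls$start[k], ext$start + 1L)
    expect_lte(calls$end[k], ext$end)
    expect_equal(nchar(calls$sequence[k]), calls$length[k])
    expect_equal(nchar(calls$structure[k]), calls$length[k])
  }
})

test_that("overlap resolution keeps the lowest E-value deterministically", {
  a <- make_call_row(seq_id = "c", start = 100L, end = 200L,
                     subfamily = "bacA", evalue = 1e-30)
  b <- make_call_row(seq_id = "c", start = 150L, end = 250L,
                     subfamily = "arcA", evalue = 1e-12)
  r <- resolve_overlaps(rbind(a, b))
  expect_equal(nrow(r), 1L)
  expect_equal(r$subfamily, "bacA")
  # non-overlapping calls are both kept
  c2 <- make_call_row(seq_id = "c", start = 300L, end = 400L,
                      subfamily = "arcA", evalue = 1e-12)
  expect_equal(nrow(resolve_overlaps(rbind(a, c2))), 2L)
  # opposite strands never compete
  d <- make_call_row(seq_id = "c", strand = "-", start = 150L,
                     end = 250L, evalue = 1e-5)
  expect_equal(nrow(resolve_overlaps(rbind(a, d))), 2L)
  # exact tie in E and score: lexicographically first subfamily, stably
  t1 <- make_call_row(seq_id = "c", start = 1L, end = 50L,
                      subfamily = "bacB", evalue = 1e-15)
  t2 <- make_call_row(seq_id = "c", start = 10L, end = 60L,
                      subfamily = "arcM", evalue = 1e-15)
  for (perm in list(rbind(t1, t2), rbind(t2, t1))) {
    r2 <- resolve_overlaps(perm)
    expect_equal(r2$subfamily, "arcM")
  }
})

test_that("cm-only mode rescues a plant an over-strict descriptor misses", {
  lib <- toy_lib()
  e <- lib$subfamilies$bacA
  member <- as.character(e$members[[5L]])
  pl <- plant_gene(random_background(15000L, seed = 71L), member, 6000L)
  # over-tighten both DM variants: impossible anchor pattern
  strict <- e
  for (v in c("selective", "general")) {
    strict[[v]]$elements$s1$tokens[[1L]] <- list(type = "sym", sym = "C")
    strict[[v]]$elements$s1$tokens[[2L]] <- list(type = "sym", sym = "C")
  }
  strict_lib <- lib
  strict_lib$subfamilies$bacA <- strict
  strict_lib$subfamilies$arcA <- NULL
  cfg <- scan_config()
  expect_equal(nrow(scan_all(pl$record, strict_lib, cfg)), 0L)
  rescue <- scan_cm_only(pl$record, e$cm, cfg)
  expect_equal(nrow(rescue), 1L)
  expect_equal(rescue$dm_variant, "cm-only")
  # the cascade (with the real DM) and cm-only refine to the same span
  casc <- scan_all(pl$record, lib, cfg)
  expect_equal(casc$start, rescue$start)
  expect_equal(casc$end, rescue$end)
})

test_that("empty input and all-decoy input give clean empty results", {
  lib <- toy_lib()
  cfg <- scan_config()
  empty <- scan_all(new_rnp_seqs(character(0), character(0)), lib, cfg)
  expect_equal(nrow(empty), 0L)
  decoy <- new_rnp_seqs("d1", dinucleotide_shuffle(
    random_background(30000L, seed = 81L)$residues, seed = 82L))
  expect_equal(nrow(scan_all(decoy, lib, cfg)), 0L)
  expect_equal(nrow(scan_cm_only(decoy, lib$subfamilies$arcA$cm, cfg)),
               0L)
})
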