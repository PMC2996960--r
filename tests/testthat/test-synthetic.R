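test_that("random backgrounds honour length, GC and seed", {
  b <- random_background(0L, seed = 1L)
  expect_equal(b$length, 0L)
  gc1 <- random_background(500L, gc = 1, seed = 2L)
  expect_true(grepl("^[GC]+$", gc1$residues))
  big <- random_background(1e5, gc = 0.5, seed = 3L)
  expect_lt(abs(gc_content(big$residues) - 0.5), 0.01)
  expect_identical(random_background(100L, seed = 4L)$residues,
                   random_background(100L, seed = 4L)$residues)
})

test_that("descriptor samples match their model with zero budget usage", {
  lib <- toy_lib()
  for (sf in names(lib$subfamilies)) {
    sel <- lib$subfamilies[[sf]]$selective
    for (i in 1:40) {
      s <- sample_from_descriptor(sel, seed = 1000L + i)
      h <- dm_match_at(as.character(s), 1L, sel)
      expect_false(is.null(h))
      expect_equal(h$mismatches, 0L)
      expect_equal(h$mispairs, 0L)
      expect_equal(h$end, nchar(s))
    }
  }
})

test_that("degenerate tokens only emit bases from their expansion", {
  dm <- read_descriptor(paste("name: r", "subfamily: bacA",
                              "variant: selective", "topology: s1",
                              "s1 0:RRRRRRRR", sep = "\n"))
  for (i in 1:20) {
    s <- sample_from_descriptor(dm, seed = i)
    expect_true(grepl("^[AG]+$", s))
  }
})

test_that("incompatible helix tokens are rejected with an error", {
  # strand5 G pairs C or T, but strand3 only allows A: unsatisfiable
  dm <- read_descriptor(paste("name: bad", "subfamily: bacA",
                              "variant: selective",
                              "topology: h1 s1 h1'",
                              "h1 0:G:A", "s1 0:AA", sep = "\n"))
  expect_error(sample_from_descriptor(dm, seed = 1L), "incompatible")
})

test_that("planting replaces the span and records truth", {
  bg <- random_background(500L, seed = 5L)
  p <- plant_gene(bg, "GGGCAAAGCCC", 100L)
  expect_equal(p$record$length, 500L)
  expect_equal(p$truth$start, 100L)
  expect_equal(p$truth$end, 111L)
  expect_equal(substr(p$record$residues, 101L, 111L), "GGGCAAAGCCC")
  # minus strand: the forward span holds the reverse complement
  pm <- plant_gene(bg, "GGGCAAAGCCC", 100L, strand = "-")
  expect_equal(substr(pm$record$residues, 101L, 111L),
               reverse_complement("GGGCAAAGCCC"))
  # plants accumulate; out-of-range is an error
  p2 <- plant_gene(p, "TTTT", 300L, subfamily = "arcA")
  expect_equal(nrow(p2$truth), 2L)
  expect_error(plant_gene(bg, "AAAA", 498L), "out of range")
})

test_that("the toy library satisfies its construction contract", {
  lib <- toy_lib()
  expect_gte(length(lib$subfamilies), 2L)
  for (sf in names(lib$subfamilies)) {
    e <- lib$subfamilies[[sf]]
    expect_s3_class(e$selective, "rnp_dm")
    expect_s3_class(e$general, "rnp_dm")
    expect_equal(e$selective$variant, "selective")
    expect_equal(e$general$variant, "general")
    expect_gte(length(e$alignment$ids), 8L)
    expect_false(is.null(e$cm$evd))
    expect_gt(e$cm$evd$lambda, 0)
    expect_gte(e$cm$evd$n_decoys, 50L)
    # every alignment row matched by its general DM
    for (row in e$alignment$seqs)
      expect_false(is.null(dm_match_at(gsub("-", "", row), 1L,
                                       e$general)))
    # the held-out aberrant member: selective misses, general matches
    expect_equal(nrow(dm_scan(as.character(e$aberrant), e$selective)), 0L)
    gen_hit <- dm_match_at(as.character(e$aberrant), 1L, e$general)
    expect_false(is.null(gen_hit))
    expect_equal(gen_hit$mispairs, 1L)
  }
})

test_that("the toy library is deterministic in its seed", {
  a <- make_toy_library(seed = 7L, n_members = 8L, n_decoys = 50L)
  b <- make_toy_library(seed = 7L, n_members = 8L, n_decoys = 50L)
  expect_identical(a$subfamilies$bacA$members, b$subfamilies$bacA$members)
  expect_identical(a$subfamilies$bacA$cm$evd, b$subfamilies$bacA$cm$evd)
})

test_that("simulated genomes carry recoverable descriptor-consistent truth", {
  lib <- toy_lib()
  sim <- simulate_genomes(4L, genome_length = 8000L, seed = 17L,
                          library = lib)
  expect_equal(nrow(sim$genomes), 4L)
  expect_equal(nrow(sim$truth), 4L)
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
  for (k in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[k, ]
    sel <- lib$subfamilies[[tr$subfamily]]$selective
    hits <- dm_scan(sim$genomes[sim$genomes$id == tr$seq_id, ], sel,
                    tr$strand)
    expect_true(any(hits$start == tr$start + 1L & hits$end == tr$end))
  }
})

test_that("model library archives round-trip through a directory", {
  lib <- toy_lib()
  dir <- withr::local_tempdir()
  write_model_library(lib, dir)
  back <- read_model_library(dir)
  expect_setequal(names(back$subfamilies), names(lib$subfamilies))
  for (sf in names(lib$subfamilies)) {
    expect_equal(back$subfamilies[[sf]]$general$topology,
                 lib$subfamilies[[sf]]$general$topology)
    expect_equal(back$subfamilies[[sf]]$cm$evd$lambda,
                 lib$subfamilies[[sf]]$cm$evd$lambda, tolerance = 1e-7)
    member <- lib$subfamilies[[sf]]$members[[1L]]
    expect_equal(
      cm_score_local(back$subfamilies[[sf]]$cm, member)$score,
      cm_score_local(lib$subfamilies[[sf]]$cm, member)$score,
      tolerance = 1e-5)
  }
})

test_that("simulate_genomes writes FASTA and truth files on request", {
  lib <- toy_lib()
  dir <- withr::local_tempdir()
  simulate_genomes(2L, genome_length = 6000L, seed = 23L, library = lib,
                   out = dir)
  expect_true(file.exists(file.path(dir, "genomes.fasta")))
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tr), 2L)
  fa <- read_fasta(file.path(dir, "genomes.fasta"))
  expect_equal(nrow(fa), 2L)
  expect_equal(fa$length, c(6000L, 6000L))
})
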