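# Shared fixtures, built once per test session.

toy_lib <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- rnpscan::make_toy_library(seed = 42L)
    lib
  }
})

# the 11-nt worked example: one helix closing a 3-nt loop
example1_dm <- function(mispair_budget = 0L) {
  rnpscan::read_descriptor(paste(
    "name: ex1", "subfamily: bacA", "variant: selective",
    "topology: s1 h1 s2 h1' s3",
    "s1 0:",
    sprintf("h1 %d:GGGC:GCCC", mispair_budget),
    "s2 0:AAA",
    "s3 0:",
    sep = "\n"))
}

# tiny two-row alignment used across CM unit tests
tiny_aln <- function() {
  rnpscan::new_rnp_aln(c("a", "b"), c("GGGCAAAGCCC", "GGGCAAAGCCC"),
                       "<<<<...>>>>")
}

make_call_row <- function(seq_id = "s", strand = "+", start = 1L,
                          end = 10L, subfamily = "bacA",
                          dm_variant = "selective", local_score = 50,
                          global_score = 60, evalue = 1e-20,
                          sequence = strrep("A", end - start + 1L),
                          structure = strrep(".", end - start + 1L),
                          flags = "") {
  rnpscan:::new_calls(data.frame(
    seq_id = seq_id, strand = strand, start = start, end = end,
    subfamily = subfamily, dm_variant = dm_variant,
    local_score = local_score, global_score = global_score,
    evalue = evalue, length = end - start + 1L, sequence = sequence,
    structure = structure, flags = flags, stringsAsFactors = FALSE))
}
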