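# Shared fixtures: a maximally separated toy library, a matching sample
# sheet, and read construction following a layout.

toy_library <- function() {
  barcode_library(c("b1", "b2", "b3", "ref"),
                  c(strrep("A", 20), strrep("C", 20),
                    strrep("G", 20), strrep("T", 20)))
}

toy_layout <- function(...) read_layout(...)

toy_sheet <- function(layout = toy_layout()) {
  data.frame(
    sample_id = c("s1", "s2"),
    fwd_index = c("ACGTACGTA", "GGTACCAATCGG"),   # 9 and 12 bp
    rev_index = c("TTGGCCAAT", "CCAATTGGCCAA"),
    expected_barcodes = I(list(c("b1", "ref"), c("b2", "ref"))),
    pool_id = c("p1", "p2"),
    treatment_id = c("t1", "t1"),
    timepoint = c("generation-0", "generation-0"),
    replicate = c(1L, 1L),
    stringsAsFactors = FALSE)
}

# Build a read exactly as the layout lays it out.
make_read <- function(fwd, barcode_seq, rev, layout = toy_layout()) {
  rev_obs <- if (layout$reverse_index_orientation == "reverse-complement")
    reverse_complement(rev) else rev
  paste0(fwd, layout$forward_spacer, barcode_seq, layout$reverse_spacer,
         rev_obs)
}

write_fastq_lines <- function(seqs, path) {
  if (length(seqs)) {
    ids <- sprintf("@r%d", seq_along(seqs))
    writeLines(paste0(ids, "\n", seqs, "\n+\n", strrep("I", nchar(seqs))),
               path)
  } else writeLines(character(0), path)
  path
}

random_dna <- function(n, len) {
  vapply(rep(len, length.out = n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), character(1))
}
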