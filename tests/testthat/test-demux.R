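test_that("library validation measures pairwise separation", {
  lib <- barcode_library(c("b1", "b2"), c(strrep("A", 20), strrep("C", 20)))
  v <- validate_library(lib)
  expect_equal(v$min_distance, 20)
  expect_true(v$pass)

  dup_seq <- barcode_library(c("b1", "b2"),
                             c(strrep("A", 20), strrep("A", 20)))
  v2 <- validate_library(dup_seq)
  expect_false(v2$pass)
  expect_equal(v2$violations$distance, 0)

  expect_error(barcode_library(c("b1", "b1"), c(strrep("A", 20),
                                                strrep("C", 20))),
               "duplicate")
  expect_error(barcode_library(c("b1", "b2"),
                               c(strrep("A", 20), strrep("C", 19))),
               "length")
})

test_that("library validation equals an exhaustive pairwise scan", {
  set.seed(11)
  for (rep in 1:5) {
    seqs <- random_dna(10, 20)
    lib <- barcode_library(sprintf("b%02d", 1:10), seqs)
    v <- validate_library(lib, min_distance = 6)
    expect_equal(v$min_distance, oracle_hamming_scan(seqs))
    expect_equal(v$pass, oracle_hamming_scan(seqs) >= 6)
  }
})

test_that("read matching is exact on all three elements", {
  lib <- toy_library()
  layout <- toy_layout()
  sheet <- toy_sheet()
  read <- make_read(sheet$fwd_index[1], lib$sequence[1],
                    sheet$rev_index[1], layout)
  hit <- match_read(read, layout, sheet$fwd_index, sheet$rev_index, lib)
  expect_equal(hit$fwd_index, sheet$fwd_index[1])
  expect_equal(hit$rev_index, sheet$rev_index[1])
  expect_equal(hit$barcode_id, "b1")

  # one substitution inside the barcode flips the read to discarded
  bad_bc <- sub("^A", "C", lib$sequence[1])
  read2 <- make_read(sheet$fwd_index[1], bad_bc, sheet$rev_index[1],
                     layout)
  expect_equal(match_read(read2, layout, sheet$fwd_index,
                          sheet$rev_index, lib)$reason, "no-barcode")

  # garbage prefix fails on the forward index first
  expect_equal(match_read(paste0("N", read), layout, sheet$fwd_index,
                          sheet$rev_index, lib)$reason,
               "no-forward-index")
})

test_that("matching agrees with a position-by-position oracle", {
  set.seed(23)
  lib <- toy_library()
  layout <- toy_layout()
  sheet <- toy_sheet()
  n <- 1000
  fwd <- sample(sheet$fwd_index, n, replace = TRUE)
  rev <- sample(sheet$rev_index, n, replace = TRUE)
  bc <- lib$sequence[sample.int(nrow(lib), n, replace = TRUE)]
  corrupt <- runif(n) < 0.10
  bc[corrupt] <- vapply(bc[corrupt], function(s) {
    pos <- sample.int(20, 1)
    substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, pos, pos)), 1)
    s
  }, character(1))
  reads <- make_read(fwd, bc, rev, layout)
  for (i in sample.int(n, 200)) {
    got <- match_read(reads[i], layout, sheet$fwd_index, sheet$rev_index,
                      lib)
    want <- oracle_match(reads[i], layout, sheet$fwd_index,
                         sheet$rev_index, lib)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})

test_that("demultiplexing recovers simulator truth and conserves reads", {
  set.seed(7)
  lib <- toy_library()
  layout <- toy_layout()
  sheet <- toy_sheet()
  truth <- matrix(c(9000L, 0L, 0L, 4000L,
                    0L, 7000L, 0L, 5000L),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(sheet$sample_id, lib$barcode_id))
  fq <- tempfile(fileext = ".fastq")
  emit_fastq(truth, sheet, lib, layout, fq)
  res <- demultiplex(fq, sheet, layout, lib)
  expect_identical(res$counts, truth)
  expect_equal(res$summary$raw_reads, sum(truth))
  expect_equal(res$summary$retained_reads +
                 sum(res$summary$discard_tally),
               res$summary$raw_reads)

  # determinism: same file, bit-identical matrix
  res2 <- demultiplex(fq, sheet, layout, lib)
  expect_identical(res2$counts, res$counts)
  unlink(fq)
})

test_that("empty FASTQ gives a zero matrix", {
  lib <- toy_library()
  sheet <- toy_sheet()
  fq <- write_fastq_lines(character(0), tempfile(fileext = ".fastq"))
  res <- demultiplex(fq, sheet, toy_layout(), lib)
  expect_equal(sum(res$counts), 0)
  expect_equal(res$summary$raw_reads, 0)
  unlink(fq)
})

test_that("corrupted reads are tallied by their first failing element", {
  lib <- toy_library()
  layout <- toy_layout()
  sheet <- toy_sheet()
  good <- make_read(sheet$fwd_index[1], lib$sequence[1],
                    sheet$rev_index[1], layout)
  no_fwd <- paste0(strrep("N", 9), substr(good, 10, nchar(good)))
  bad_bc <- make_read(sheet$fwd_index[1], strrep("N", 20),
                      sheet$rev_index[1], layout)
  bad_rev <- make_read(sheet$fwd_index[1], lib$sequence[1],
                       strrep("N", 9), layout)
  # valid elements but an index pair not present in the sheet
  unlisted <- make_read(sheet$fwd_index[1], lib$sequence[1],
                        sheet$rev_index[2], layout)
  fq <- write_fastq_lines(c(good, no_fwd, bad_bc, bad_rev, unlisted),
                          tempfile(fileext = ".fastq"))
  res <- demultiplex(fq, sheet, layout, lib)
  tally <- res$summary$discard_tally
  expect_equal(unname(tally["no-forward-index"]), 1L)
  expect_equal(unname(tally["no-barcode"]), 1L)
  expect_equal(unname(tally["no-reverse-index"]), 1L)
  expect_equal(unname(tally["index-pair-unlisted"]), 1L)
  expect_equal(res$summary$retained_reads, 1L)
  expect_equal(sum(res$counts), 1L)
  unlink(fq)
})

test_that("ambiguous index prefixes are rejected at sheet validation", {
  lib <- toy_library()
  sheet <- toy_sheet()
  sheet$fwd_index[2] <- paste0(sheet$fwd_index[1], "GGG")
  expect_error(validate_sample_sheet(sheet, lib), "prefix")
})

test_that("retention summary reproduces the printed retention fraction", {
  s <- retention_summary(142243245, 104365740)
  expect_equal(s$retained_percent, 73.4)
  expect_equal(s$retained_fraction, 104365740 / 142243245)
})
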