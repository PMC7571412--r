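test_that("neutral deterministic evolution is a fixed point", {
  sim <- simulate_serial_transfer(
    dilution = 1000, days = 25,
    init = data.frame(barcode = c("x", "y"), s = 0, freq = c(0.3, 0.7)),
    U = 0, deterministic_mode = TRUE)
  expect_true(all(abs(sim$proportions["x", ] - 0.3) < 1e-12))
  s <- summarize_trajectory(sim$generations, sim$proportions["x", ])
  expect_equal(s$m_max, 0)
  expect_equal(s$total_change, 0)
})

test_that("deterministic selection follows the logistic closed form", {
  s_adv <- 0.05; f0 <- 0.01
  sim <- simulate_serial_transfer(
    dilution = 1000, days = 25,
    init = data.frame(barcode = c("mut", "wt"), s = c(s_adv, 0),
                      freq = c(f0, 1 - f0)),
    U = 0, deterministic_mode = TRUE)
  g <- sim$generations
  r_t <- (f0 / (1 - f0)) * exp(s_adv * g)   # ratio grows exponentially
  expect_equal(unname(sim$proportions["mut", ]), r_t / (1 + r_t),
               tolerance = 1e-9)
})

test_that("one neutral cycle shows binomial bottleneck variance", {
  set.seed(107)
  nb <- 2000; p0 <- 0.4
  p1 <- replicate(3000, {
    sim <- simulate_serial_transfer(
      dilution = 1000, days = 1,
      init = data.frame(barcode = c("x", "y"), s = 0,
                        freq = c(p0, 1 - p0)),
      U = 0, saturation_density = nb * 1000 / 0.6, volume = 0.6,
      sampling_days = c(0, 1))
    sim$proportions["x", 2]
  })
  expect_equal(var(p1), p0 * (1 - p0) / nb, tolerance = 0.1)
})

test_that("contamination injection hits the target rate", {
  lib <- sprintf("b%03d", 1:154)
  expected <- c("b001", "b002")
  row <- stats::setNames(integer(154), lib)
  row[expected] <- c(500000L, 500000L)

  expect_identical(inject_contamination(row, 0, lib, expected), row)

  det <- inject_contamination(row, 4e-4, lib, expected,
                              deterministic_mode = TRUE)
  b <- contamination_rate(det, expected, lib)$B_j
  expect_equal(b, 4e-4, tolerance = 2e-3)

  set.seed(109)
  rates <- replicate(500, {
    r <- stats::setNames(integer(154), lib)
    r[expected] <- as.integer(rmultinom(1, 6000, c(0.5, 0.5)))
    contamination_rate(inject_contamination(r, 4e-4, lib, expected),
                       expected, lib)$B_j
  })
  expect_lt(abs(mean(rates) - 4e-4) / 4e-4, 0.10)
})

test_that("pooled assays propagate fitness into count ratios", {
  m <- c(focal = 0.05, ref = 0)
  p0 <- c(focal = 0.5, ref = 0.5)
  det <- simulate_pooled_assay(m, p0, depth = 100000, generations = 20,
                               deterministic_mode = TRUE)
  ratio0 <- det$counts_0h["focal"] / det$counts_0h["ref"]
  ratio48 <- det$counts_48h["focal"] / det$counts_48h["ref"]
  expect_equal(unname(ratio48 / ratio0), exp(1), tolerance = 1e-3)

  # neutral: proportions unchanged
  neut <- simulate_pooled_assay(c(a = 0, b = 0), c(a = 0.3, b = 0.7),
                                depth = 100000,
                                deterministic_mode = TRUE)
  expect_equal(unname(neut$counts_48h / sum(neut$counts_48h)),
               c(0.3, 0.7), tolerance = 1e-4)
})

test_that("the log-ratio estimator recovers true fitness at assay depth", {
  set.seed(113)
  true_m <- 0.03
  est <- replicate(300, {
    sim <- simulate_pooled_assay(c(f = true_m, r = 0),
                                 c(f = 0.5, r = 0.5), depth = 3000)
    as.numeric(malthusian_fitness(sim$counts_0h["f"], sim$counts_0h["r"],
                                  sim$counts_48h["f"],
                                  sim$counts_48h["r"]))
  })
  expect_lt(abs(mean(est) - true_m), 2 * sd(est) / sqrt(300))
})

test_that("FASTQ emission round-trips exactly and respects error rates", {
  set.seed(127)
  lib <- toy_library()
  sheet <- toy_sheet()
  layout <- toy_layout()
  counts <- matrix(c(120L, 0L, 0L, 60L,
                     0L, 90L, 0L, 30L), 2, byrow = TRUE,
                   dimnames = list(sheet$sample_id, lib$barcode_id))
  fq <- tempfile(fileext = ".fastq")
  truth <- emit_fastq(counts, sheet, lib, layout, fq)
  expect_equal(nrow(truth), sum(counts))
  res <- demultiplex(fq, sheet, layout, lib)
  expect_identical(res$counts, counts)

  # substitution errors knock out ~1 - (1-eps)^L of reads
  eps <- 0.01
  emit_fastq(counts, sheet, lib, layout, fq, error_rate = eps)
  res_err <- demultiplex(fq, sheet, layout, lib)
  L <- nchar(make_read(sheet$fwd_index[1], lib$sequence[1],
                       sheet$rev_index[1], layout))
  expected_frac <- (1 - eps)^L   # lengths vary by ~3 bp across samples
  expect_equal(res_err$summary$retained_fraction, expected_frac,
               tolerance = 0.08)

  # empty matrix gives an empty file
  empty <- matrix(integer(0), 0, 4,
                  dimnames = list(NULL, lib$barcode_id))
  expect_error(emit_fastq(empty, sheet, lib, layout, fq), NA)
  expect_equal(length(readLines(fq)), 0)
  unlink(fq)
})

test_that("generated studies match the design scale and are reproducible", {
  cfg <- sim_config(seed = 202)
  st <- generate_study(cfg)
  expect_equal(nrow(st$populations), 76 * 7)   # 532 dynamics samples
  expect_equal(length(unique(st$populations$population_id)), 76)
  # 152 strains x 2 timepoints x 4 replicates = 1,216 measurements
  n_meas <- sum(vapply(seq_len(nrow(st$manifest)), function(i) {
    pool <- st$sheet$expected_barcodes[[
      match(st$manifest$sample_0h[i], st$sheet$sample_id)]]
    length(pool) - 1L
  }, numeric(1)))
  expect_equal(n_meas, 1216)
  # pools stay within 8-22 barcodes
  pool_sizes <- vapply(unique(st$manifest$sample_0h), function(s)
    length(st$sheet$expected_barcodes[[match(s, st$sheet$sample_id)]]),
    numeric(1))
  expect_true(all(pool_sizes >= 8 & pool_sizes <= 22))

  st2 <- generate_study(sim_config(seed = 202))
  expect_identical(st$counts, st2$counts)
  expect_identical(st$truth$fitness, st2$truth$fitness)

  # a mutation-free configuration has no true fitness change
  tr0 <- default_treatments()
  tr0$U <- 0
  st0 <- generate_study(sim_config(seed = 203, treatments = tr0))
  expect_true(all(st0$truth$fitness$delta_w_truth == 0))
})

test_that("library and index generation respect their constraints", {
  st <- generate_study(sim_config(seed = 204))
  v <- validate_library(st$library)
  expect_true(v$pass)
  expect_gte(v$min_distance, 6)
  expect_error(validate_sample_sheet(st$sheet, st$library), NA)
})
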