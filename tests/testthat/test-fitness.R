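test_that("Malthusian fitness follows the log-ratio-change formula", {
  expect_equal(as.numeric(malthusian_fitness(1000, 1000, 1000, 1000)), 0)
  expect_equal(as.numeric(malthusian_fitness(1000, 1000, 2000, 1000)),
               log(2) / 20)
  # antisymmetry under focal/reference swap
  m_fwd <- as.numeric(malthusian_fitness(300, 700, 900, 400))
  m_rev <- as.numeric(malthusian_fitness(700, 300, 400, 900))
  expect_equal(m_fwd, -m_rev)
  # scale invariance at each timepoint
  m_scaled <- as.numeric(malthusian_fitness(300 * 5, 700 * 5, 900, 400))
  expect_equal(m_fwd, m_scaled)
})

test_that("zero counts follow the pseudocount policy", {
  m <- malthusian_fitness(0, 1000, 500, 1000)
  expect_true(attr(m, "flagged"))
  expect_equal(as.numeric(m), (log(500.5 / 1000.5) - log(0.5 / 1000.5)) / 20)
  strict <- malthusian_fitness(0, 1000, 500, 1000, zero_policy = "strict")
  expect_true(is.na(as.numeric(strict)))
  expect_true(attr(strict, "flagged"))
  clean <- malthusian_fitness(10, 1000, 500, 1000)
  expect_false(attr(clean, "flagged"))
})

test_that("Wrightian/Malthusian conversions are exact inverses", {
  expect_equal(to_wrightian(0), 1)
  expect_equal(to_wrightian(log(2) / 20), 2^(1 / 20))
  set.seed(3)
  x <- rnorm(50, 0, 0.1)
  expect_equal(to_malthusian(to_wrightian(x)), x)
  expect_error(to_malthusian(-1), "positive")
})

test_that("fitness change is the Wrightian difference", {
  expect_equal(fitness_change(1.00, 1.05), 0.05)
  expect_equal(fitness_change(1.02, 1.02), 0)
})

test_that("harmonic weight is dominated by the smallest component", {
  expect_equal(harmonic_weight(c(1000, 4000)), 1600)
  expect_equal(harmonic_weight(c(500, 500, 500)), 500)
  expect_equal(harmonic_weight(c(1000, 0, 4000)), 0)
  expect_error(harmonic_weight(numeric(0)), "empty")
  # harmonic <= arithmetic always
  set.seed(9)
  for (i in 1:20) {
    x <- rpois(4, 200) + 1
    expect_lte(harmonic_weight(x), mean(x))
  }
})

test_that("replicate aggregation reduces to textbook forms", {
  expect_equal(aggregate_replicates(c(1, 3))$mean, 2)
  expect_equal(aggregate_replicates(c(1, 3), c(3, 1))$mean, 1.5)
  # equal weights reduce exactly to the unweighted mean and SE
  set.seed(17)
  x <- rnorm(8)
  a <- aggregate_replicates(x, rep(2, 8))
  expect_equal(a$mean, mean(x))
  expect_equal(a$se, sd(x) / sqrt(8))
  expect_true(is.na(aggregate_replicates(5)$se))
})

test_that("pooled rMSE recovers the replicate noise scale", {
  set.seed(29)
  sigma <- 0.04
  strains <- rep(sprintf("s%02d", 1:91), each = 10)
  mu <- rep(rnorm(91, 1, 0.05), each = 10)
  vals <- mu + rnorm(length(strains), 0, sigma)
  est <- pooled_rmse(vals, strains)
  # sqrt of a chi-square mean with 91*9 df: well within 10%
  expect_lt(abs(est - sigma) / sigma, 0.1)
})

test_that("per-strain significance behaves on null and structured data", {
  # identical strains, no noise: nothing significant, p side-appropriate
  d0 <- data.frame(strain = rep(c("a", "b"), each = 3), value = 0)
  s0 <- strain_significance(d0, tail = "two.sided")
  expect_true(all(s0$p_value == 1))
  expect_true(all(s0$q_value == 1))

  # equal weights equal per-strain OLS means
  set.seed(37)
  d <- data.frame(strain = rep(sprintf("s%d", 1:5), each = 4),
                  value = rnorm(20), weight = 1)
  s <- strain_significance(d)
  expect_equal(s$estimate,
               as.numeric(tapply(d$value, d$strain, mean)[s$strain]))
  expect_true(all(s$q_value >= s$p_value))

  expect_error(strain_significance(
    data.frame(strain = c("a", "a", "b"), value = 1:3)), "replicates")
})

test_that("BH-controlled strain tests keep FDR near nominal", {
  set.seed(43)
  n_strain <- 152; n_true <- 35; reps <- 4; sigma <- 0.043
  fdp <- replicate(60, {
    delta <- c(rep(0.05, n_true), rep(0, n_strain - n_true))
    d <- data.frame(strain = rep(sprintf("s%03d", 1:n_strain),
                                 each = reps),
                    value = rep(delta, each = reps) +
                      rnorm(n_strain * reps, 0, sigma))
    s <- strain_significance(d, tail = "greater")
    hits <- s$strain[s$q_value <= 0.01]
    if (!length(hits)) 0 else
      mean(!(hits %in% sprintf("s%03d", 1:n_true)))
  })
  # empirical FDR should sit at or below ~1% (plus Monte-Carlo slack)
  expect_lt(mean(fdp), 0.03)
})

test_that("assay fitness estimates and change records flow end to end", {
  lib <- toy_library()
  sheet <- data.frame(
    sample_id = c("a0", "a48", "b0", "b48"),
    fwd_index = rep("ACGTACGTA", 4),
    rev_index = c("TTGGCCAAT", "CCAATTGGCC", "GGTTAACCG", "AACCGGTTA"),
    expected_barcodes = I(rep(list(c("b1", "b2", "ref")), 4)),
    pool_id = "p1", treatment_id = "t1",
    timepoint = rep(c("generation-0", "generation-250"), each = 2),
    replicate = 1L, stringsAsFactors = FALSE)
  counts <- matrix(0L, 4, 4,
                   dimnames = list(sheet$sample_id, lib$barcode_id))
  counts["a0", c("b1", "b2", "ref")] <- c(1000L, 1000L, 1000L)
  counts["a48", c("b1", "b2", "ref")] <- c(2000L, 1000L, 1000L)
  counts["b0", c("b1", "b2", "ref")] <- c(1000L, 1000L, 1000L)
  counts["b48", c("b1", "b2", "ref")] <- c(4000L, 1000L, 1000L)
  manifest <- data.frame(
    pool_id = "p1", replicate = 1L,
    timepoint = c("generation-0", "generation-250"),
    sample_0h = c("a0", "b0"), sample_48h = c("a48", "b48"),
    reference_barcode = "ref", stringsAsFactors = FALSE)
  est <- assay_fitness(counts, manifest, sheet)
  expect_equal(nrow(est), 4)  # two focal strains x two timepoints
  m_b1_g0 <- est$m[est$strain == "b1" & est$timepoint == "generation-0"]
  expect_equal(m_b1_g0, log(2) / 20)
  # weight is the harmonic mean of the four entering counts
  expect_equal(est$weight[est$strain == "b1" &
                            est$timepoint == "generation-0"],
               harmonic_weight(c(1000, 3000, 2000, 4000)))

  fc <- fitness_change_records(est)
  b1 <- fc$records[fc$records$strain == "b1", ]
  expect_equal(b1$delta_w, exp(log(4) / 20) - exp(log(2) / 20))
  expect_equal(fc$records$delta_w[fc$records$strain == "b2"], 0)
})
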