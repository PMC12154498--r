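test_that("model parameter validation rejects invalid settings", {
  expect_error(population_model(n_pops = 0), ">= 1")
  expect_error(population_model(missing_rate = 1), "missing_rate")
  expect_error(population_model(admix_alpha = 0), "admix_alpha")
})

test_that("dosage follows Hardy-Weinberg expectation at K=1", {
  # allele frequency pinned (essentially) at 0.5: E[dosage] = 1
  m <- population_model(n_pops = 1, n_loci = 1, n_samples = 10000,
                        freq_prior = c(1, 1), freq_range = c(0.4999, 0.5001),
                        seed = 5)
  panel <- simulate_panel(m)
  dos <- gt_dosage(panel$genotypes)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(dos) - 1), 3 * se)
})

test_that("dosage mean matches 2P per locus under K=1 (law of large numbers)", {
  m <- population_model(n_pops = 1, n_loci = 5, n_samples = 10000,
                        freq_prior = c(2, 2), seed = 8)
  panel <- simulate_panel(m)
  dos <- gt_dosage(panel$genotypes)
  for (j in 1:5) {
    p <- panel$true_P[1, j]
    se <- sqrt(2 * p * (1 - p) / 10000)
    expect_lt(abs(mean(dos[, j]) - 2 * p), 3 * se)
  }
})

test_that("missingness is absent at rate 0 and calibrated otherwise", {
  p0 <- simulate_panel(population_model(n_loci = 20, n_samples = 50,
                                        missing_rate = 0, seed = 2))
  expect_false(anyNA(p0$genotypes$calls))
  rate <- 0.1
  p1 <- simulate_panel(population_model(n_loci = 50, n_samples = 200,
                                        missing_rate = rate, seed = 2))
  n <- length(p1$genotypes$calls)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(is.na(p1$genotypes$calls)) - rate), 3 * se)
})

test_that("simulation is reproducible under a fixed seed", {
  m <- population_model(n_pops = 8, n_loci = 32, n_samples = 280,
                        admix_alpha = 0.05, freq_prior = c(0.2, 0.2),
                        seed = 77)
  a <- simulate_panel(m); b <- simulate_panel(m)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$true_Q, b$true_Q)
})

test_that("ancestry rows sum to one and frequencies stay in (0,1)", {
  p <- simulate_panel(population_model(n_pops = 4, n_loci = 10,
                                       n_samples = 30, seed = 3))
  expect_equal(rowSums(p$true_Q), rep(1, 30), tolerance = 1e-9)
  expect_true(all(p$true_P > 0 & p$true_P < 1))
})

test_that("planted duplicates share pre-missingness calls and are recovered", {
  m <- population_model(n_pops = 3, n_loci = 24, n_samples = 30,
                        missing_rate = 0, seed = 10)
  panel <- plant_duplicates(simulate_panel(m), list(c(1L, 2L, 3L, 4L)))
  expect_equal(panel$calls_complete[2, ], panel$calls_complete[1, ])
  grp <- duplicate_groups(panel$genotypes)
  expect_true(any(vapply(grp, function(g)
    setequal(g, paste0("S", sprintf("%03d", 1:4))), logical(1))))
})

test_that("two planted pairs give exactly two duplicate groups", {
  m <- population_model(n_pops = 3, n_loci = 24, n_samples = 30,
                        missing_rate = 0, seed = 12)
  panel <- plant_duplicates(simulate_panel(m), list(c(5L, 6L), c(7L, 8L)))
  expect_length(duplicate_groups(panel$genotypes), 2L)
})

test_that("empty and overlapping duplicate groups behave as specified", {
  m <- population_model(n_loci = 8, n_samples = 10, seed = 1)
  panel <- simulate_panel(m)
  expect_identical(plant_duplicates(panel, list())$genotypes$calls,
                   panel$genotypes$calls)
  expect_error(plant_duplicates(panel, list(c(1L, 2L), c(2L, 3L))),
               "disjoint")
})

test_that("simulated VCF plants annotation violations exactly", {
  vs <- simulate_vcf(60, 10, n_violate = c(QD = 7L, MQ = 4L), seed = 31)
  hf <- hard_filter(vs)
  planted <- attr(vs, "planted")$violations
  expect_length(planted$QD, 7L)
  expect_length(planted$MQ, 4L)
  expect_setequal(vs$sites$id[!hf$pass], unlist(planted))
  expect_setequal(unique(hf$reason[!hf$pass]), c("QD", "MQ"))
})

test_that("clustered sites violate flank isolation, clean sets do not", {
  clean <- simulate_vcf(40, 5, clustered_fraction = 0,
                        chrom_lengths = c(chr1 = 1e7), seed = 4)
  expect_true(all(flank_isolation(clean, 100L)))
  clustered <- simulate_vcf(40, 5, clustered_fraction = 0.25,
                            chrom_lengths = c(chr1 = 1e7), seed = 4)
  keep <- flank_isolation(clustered, 100L)
  expect_true(all(attr(clustered, "planted")$clustered
                  %in% clustered$sites$id[!keep]))
})

test_that("flank templates have the requested length, composition and seed", {
  t1 <- simulate_flank_template(100, gc_target = 0.4, seed = 6)
  expect_equal(nchar(t1$seq), 201L)
  expect_equal(t1$snp_pos, 101L)
  expect_equal(substr(t1$seq, 101, 101), t1$ref)
  t2 <- simulate_flank_template(100, gc_target = 0.4, seed = 6)
  expect_identical(t1$seq, t2$seq)
  at_only <- simulate_flank_template(50, gc_target = 0,
                                     alleles = c("A", "T"), seed = 7)
  expect_false(grepl("[GC]", at_only$seq))
  expect_error(simulate_flank_template(10), ">= 20")
})
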