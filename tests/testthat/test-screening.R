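test_that("hard filter uses strict inequalities and ignores absent annotations", {
  s <- toy_sites(3)
  vs <- toy_vs(s, QD = c(1.9, 2.0, NA))
  vs$sites$MQ[3] <- NA; vs$sites$MQRankSum[3] <- NA
  vs$sites$ReadPosRankSum[3] <- NA
  hf <- hard_filter(vs)
  expect_equal(hf$pass, c(FALSE, TRUE, TRUE))
  expect_equal(hf$reason[1], "QD")
})

test_that("hard filter refuses non-SNP records", {
  s <- toy_sites(1); s$alt <- "GT"
  expect_error(hard_filter(toy_vs(s)), "SNP")
})

test_that("site filter enforces mac, missingness boundary and allele count", {
  # 50 diploid samples, exactly 2 alt alleles in total -> mac = 2 < 3
  d <- rep(0L, 50); d[1] <- 1L; d[2] <- 1L
  vs <- toy_vs(toy_sites(1), list(d))
  sf <- site_filter(vs)
  expect_false(sf$pass)
  expect_match(sf$reason, "mac")

  # exactly half missing passes (vcftools --max-missing is inclusive)
  d2 <- c(rep(1L, 10), rep(NA, 10))
  sf2 <- site_filter(toy_vs(toy_sites(1), list(d2)))
  expect_true(sf2$pass)

  # triallelic fails on allele count
  s3 <- toy_sites(1); s3$alt <- "G,T"
  sf3 <- site_filter(toy_vs(s3, list(c(0L, 1L, 1L, 0L, 1L, 1L, 0L, 1L))))
  expect_false(sf3$pass)
  expect_match(sf3$reason, "alleles")

  # all calls missing fails with its own reason
  sf4 <- site_filter(toy_vs(toy_sites(1), list(c(NA, NA, NA))))
  expect_false(sf4$pass)
  expect_match(sf4$reason, "all-missing")
})

test_that("flank isolation is symmetric with a strict > boundary", {
  near <- toy_vs(toy_sites(2, pos = c(1000L, 1050L)))
  expect_equal(flank_isolation(near, 100L), c(FALSE, FALSE))
  apart <- toy_vs(toy_sites(2, pos = c(1000L, 1101L)))
  expect_equal(flank_isolation(apart, 100L), c(TRUE, TRUE))
  lone <- toy_vs(toy_sites(1))
  expect_true(flank_isolation(lone, 100L))
})

test_that("flank isolation requires sorted input and ignores order otherwise", {
  unsorted <- toy_vs(toy_sites(2, pos = c(2000L, 1000L)))
  expect_error(flank_isolation(unsorted, 100L), "sorted")
  vs <- simulate_vcf(30, 4, clustered_fraction = 0.3, seed = 15)
  base <- flank_isolation(vs, 100L)
  perm <- sample(length(vs))
  resort <- order(vs$sites$chrom[perm], vs$sites$pos[perm])
  again <- flank_isolation(vs[perm][resort], 100L)
  expect_equal(vs[perm][resort]$sites$id[again], vs$sites$id[base])
})

test_that("frequency window keeps [0.30, 0.70] inclusive on alt frequency", {
  mk_d <- function(freq) {       # 10 samples, alt dosage summing to freq*20
    n_alt <- round(freq * 20)
    d <- integer(10); i <- 1
    while (n_alt > 0) { add <- min(2L, n_alt); d[i] <- add
                        n_alt <- n_alt - add; i <- i + 1 }
    d
  }
  vs <- toy_vs(toy_sites(3), lapply(c(0.30, 0.25, 0.65), mk_d))
  expect_equal(frequency_window(vs), c(TRUE, FALSE, TRUE))
})

test_that("even selection apportions per chromosome and picks extremes", {
  s <- toy_sites(24, chrom = rep(sprintf("chr%02d", 1:12), each = 2),
                 pos = rep(c(1000L, 5000L), 12))
  vs <- toy_vs(s, replicate(24, c(0L, 1L, 2L), simplify = FALSE))
  keep <- distribute_evenly(vs, 12L)
  expect_equal(sum(keep), 12L)
  expect_true(all(table(vs$sites$chrom[keep]) == 1L))

  s2 <- toy_sites(3, pos = c(1L, 50L, 100L))
  vs2 <- toy_vs(s2)
  keep2 <- distribute_evenly(vs2, 2L)
  expect_equal(vs2$sites$pos[keep2], c(1L, 100L))  # farthest pair, brute force
  expect_true(all(distribute_evenly(vs2, 3L)))     # identity selection
  expect_error(distribute_evenly(vs2, 4L), "exceeds")
})

test_that("per-chromosome quotas differ from proportionality by at most 1", {
  set.seed(19)
  counts <- table(sample(sprintf("chr%02d", 1:12), 300, replace = TRUE))
  s <- toy_sites(300, chrom = rep(names(counts), counts),
                 pos = unlist(lapply(counts, function(k) sort(sample(1e6, k)))))
  vs <- toy_vs(s)
  keep <- distribute_evenly(vs, 120L)
  got <- table(factor(vs$sites$chrom[keep], levels = names(counts)))
  exact <- 120 * as.integer(counts) / 300
  expect_true(all(abs(as.integer(got) - exact) <= 1))
})

test_that("variant classifier names exactly 12 ordered categories", {
  expect_equal(classify_variant_type("A", "G"), "A/G")
  expect_error(classify_variant_type("A", "A"), "differ")
  census <- variant_type_census(c("A", "A", "C"), c("G", "G", "T"))
  expect_equal(nrow(census), 12L)
  expect_equal(census$proportion[census$type == "A/G"], 2 / 3)
  expect_equal(census$proportion[census$type == "C/T"], 1 / 3)
  expect_equal(sum(census$count), 3L)
})

test_that("screening funnel is monotone and recovers planted violations", {
  vs <- simulate_vcf(300, 20, n_violate = c(QD = 12L, MQ = 8L),
                     clustered_fraction = 0.1, maf_range = c(0.1, 0.9),
                     seed = 23)
  rep_ <- screen_snps(vs, filter_thresholds(), n_target = 40L)
  expect_true(all(diff(rep_$counts) <= 0))
  expect_equal(rep_$counts[["input"]], 300L)
  expect_equal(rep_$counts[["hard_filter"]], 300L - 20L)
  expect_equal(rep_$counts[["selected"]], 40L)
  # survivors respect the frequency window
  g <- kaspanel:::site_geno_stats(rep_$kept)
  expect_true(all(g$alt_freq >= 0.3 & g$alt_freq <= 0.7))
  # report serializes
  f <- tempfile(fileext = ".json")
  write_screen_report(rep_, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})
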