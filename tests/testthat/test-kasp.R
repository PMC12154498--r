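test_that("GC fraction is a direct base count", {
  expect_equal(primer_gc("AAAAAAAA"), 0)
  expect_equal(primer_gc("GGCCGGCC"), 1)
  expect_equal(primer_gc("ATGCATGCATGCATGCATGC"), 0.5)
  expect_error(primer_gc("ATGNNATGCA"), "non-ACGT")
})

test_that("Tm is non-decreasing when appending GC to random 20-mers", {
  set.seed(41)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
               collapse = "")
    expect_gte(primer_tm(paste0(s, "GC")), primer_tm(s))
  }
})

test_that("designed assays satisfy every constraint by construction", {
  set.seed(17)
  n_ok <- 0
  for (i in 1:10) {
    tpl <- simulate_flank_template(100, gc_target = 0.45, seed = 100 + i)
    a <- design_assay(tpl, marker_id = paste0("mk", i))
    if (inherits(a, "kasp_failure")) next
    n_ok <- n_ok + 1
    expect_lte(a$product_size, 120L)
    expect_true(all(a$gc < 0.60))
    expect_true(all(a$tm >= 55 & a$tm <= 62))
    # allele-specific pair differs only at the 3' base, tails are universal
    fam <- sub(paste0("^", KASP_FAM_TAIL), "", a$fam_primer)
    hex <- sub(paste0("^", KASP_HEX_TAIL), "", a$hex_primer)
    expect_equal(nchar(fam), nchar(hex))
    n <- nchar(fam)
    expect_identical(substr(fam, 1, n - 1), substr(hex, 1, n - 1))
    expect_false(substr(fam, n, n) == substr(hex, n, n))
    expect_true(startsWith(a$fam_primer, KASP_FAM_TAIL))
    expect_true(startsWith(a$hex_primer, KASP_HEX_TAIL))
  }
  expect_gte(n_ok, 5)  # templates at moderate GC should usually design
})

test_that("assay design is deterministic for a fixed template", {
  tpl <- simulate_flank_template(100, gc_target = 0.45, seed = 55)
  a <- design_assay(tpl); b <- design_assay(tpl)
  expect_identical(a, b)
})

test_that("an unreachable product size yields a product_size failure report", {
  tpl <- simulate_flank_template(100, gc_target = 0.45, seed = 56)
  fail <- design_assay(tpl, max_product = 30L)
  expect_s3_class(fail, "kasp_failure")
  expect_equal(fail$reason, "product_size")
})

test_that("templates too short for primer design are rejected", {
  tpl <- list(seq = paste(rep("A", 61), collapse = ""), snp_pos = 31L,
              ref = "A", alt = "G")
  expect_error(design_assay(tpl), "40 bp")
})

test_that("marker QC drops monomorphic and high-missing markers", {
  gm <- toy_gm(list(rep("AA", 10),                       # monomorphic
                    c(rep(NA, 4), "AA", rep("AG", 5)),   # 40% missing
                    c(rep("AA", 5), rep("AG", 5)),       # clean
                    c(rep(NA, 4), rep("CC", 6))),        # both
               markers = data.frame(id = paste0("m", 1:4), chrom = "chr1",
                                    pos = 1:4 * 100L,
                                    ref = c("A", "A", "A", "C"),
                                    alt = c("G", "G", "G", "T")))
  qc <- marker_qc(gm, missing_threshold = 0.20)
  expect_equal(qc$markers$verdict,
               c("drop_monomorphic", "drop_missing", "retain", "drop_both"))
  expect_equal(qc$retained, "m3")
  # verdicts partition the marker set
  expect_equal(sort(unique(c(qc$retained,
                             qc$markers$id[qc$markers$verdict != "retain"]))),
               sort(gm$markers$id))
})

test_that("samples beyond the missing-rate threshold are excluded first", {
  calls <- rbind(matrix("AG", 6, 8), matrix(NA_character_, 2, 8))
  calls[1, 1] <- "AA"  # keep marker 1 polymorphic among clean samples
  rownames(calls) <- paste0("s", 1:8)
  gm <- genotype_matrix(calls, toy_markers(8))
  qc <- marker_qc(gm, sample_threshold = 0.5)
  expect_setequal(qc$dropped_samples, c("s7", "s8"))
  # with the all-missing samples gone, markers have no missing calls
  expect_true(all(qc$markers$missing_rate == 0))
})

test_that("a planted QC funnel yields the expected retained count", {
  # 96 markers: 8 high-missing, 46 monomorphic, 42 clean -> 42 retained
  set.seed(77)
  n <- 40
  cols <- c(replicate(8, {
    x <- sample(c("AA", "AG", "GG"), n, TRUE); x[sample(n, 15)] <- NA; x
  }, simplify = FALSE),
  replicate(46, rep("AA", n), simplify = FALSE),
  replicate(42, sample(c("AA", "AG", "GG"), n, TRUE), simplify = FALSE))
  gm <- toy_gm(cols, markers = toy_markers(96))
  qc <- marker_qc(gm, missing_threshold = 0.20)
  expect_equal(sum(qc$markers$verdict == "retain"), 42L)
  expect_equal(sum(qc$markers$verdict == "drop_missing"), 8L)
  expect_equal(sum(qc$markers$verdict == "drop_monomorphic"), 46L)
})
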