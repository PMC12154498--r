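# shared fixture builders (all in code; nothing on disk)

toy_markers <- function(n, chrom = "chr1", ref = "A", alt = "G") {
  data.frame(id = paste0("m", seq_len(n)), chrom = chrom,
             pos = 100L * seq_len(n), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# small hand-specified genotype matrix; calls given column-major per marker
toy_gm <- function(calls_by_marker, samples = NULL, markers = NULL) {
  L <- length(calls_by_marker)
  n <- length(calls_by_marker[[1]])
  calls <- do.call(cbind, calls_by_marker)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  rownames(calls) <- samples
  if (is.null(markers)) markers <- toy_markers(L)
  genotype_matrix(calls, markers)
}

# variant_set with one site per row of `sites`, genotypes built from
# alt-dosage vectors (NA = missing call)
toy_vs <- function(sites, dosages = NULL, qual = 1000,
                   QD = 20, MQ = 55, MQRankSum = 0, ReadPosRankSum = 0) {
  n <- nrow(sites)
  rep_or <- function(x) if (length(x) == 1L) rep(x, n) else x
  sites$qual <- rep_or(qual); sites$QD <- rep_or(QD)
  sites$MQ <- rep_or(MQ); sites$MQRankSum <- rep_or(MQRankSum)
  sites$ReadPosRankSum <- rep_or(ReadPosRankSum)
  if (is.null(dosages)) dosages <- lapply(seq_len(n), function(i) c(0L, 1L, 2L))
  ns <- length(dosages[[1]])
  gt <- t(vapply(dosages, function(d)
    ifelse(is.na(d), NA_character_, c("0/0", "0/1", "1/1")[d + 1L]),
    character(ns)))
  colnames(gt) <- paste0("s", seq_len(ns))
  variant_set(sites, gt, samples = colnames(gt))
}

toy_sites <- function(n, chrom = "chr1", pos = NULL, ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = if (is.null(pos)) 1000L * seq_len(n) else pos,
             id = paste0("v", seq_len(n)), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
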