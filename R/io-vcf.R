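#' Variant-call set
#'
#' A compact container for the sites of one VCF: a sites table (chrom, pos,
#' id, ref, alt, qual and the GATK annotations the hard filters consume) plus
#' per-sample genotype ("0/0", "0/1", ...; \code{NA} = ./.) and depth
#' matrices. Annotations absent from a record are \code{NA}, never zero:
#' an absent annotation must not fail a filter clause.
#'
#' @param sites data.frame with columns chrom, pos, id, ref, alt, qual and
#'   optionally QD, MQ, MQRankSum, ReadPosRankSum, DP
#' @param gt character matrix (sites x samples) of allele-index genotypes
#' @param dp integer matrix of per-sample read depths (may be NULL)
#' @param samples character vector of sample names
#' @return an object of class \code{variant_set}
#' @export
variant_set <- function(sites, gt, dp = NULL, samples = colnames(gt)) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  for (k in c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "DP"))
    if (is.null(sites[[k]])) sites[[k]] <- NA_real_
  if (is.null(sites$id)) sites$id <- paste0(sites$chrom, "_", sites$pos)
  if (is.null(sites$qual)) sites$qual <- NA_real_
  stopifnot(nrow(sites) == nrow(gt))
  if (any(sites$pos < 1L)) stop_param("positions are 1-based, must be >= 1")
  gt[gt %in% c("./.", ".|.", ".")] <- NA_character_
  gt[] <- gsub("|", "/", gt, fixed = TRUE)  # phasing ignored
  structure(list(sites = sites, gt = gt, dp = dp, samples = samples),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$sites)

#' Subset a variant set by site index
#' @param x a \code{variant_set}
#' @param i site index
#' @param ... unused
#' @return a \code{variant_set}
#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$sites[i, , drop = FALSE], x$gt[i, , drop = FALSE],
              if (!is.null(x$dp)) x$dp[i, , drop = FALSE], x$samples)
}

is_snp <- function(vs) {
  nchar(vs$sites$ref) == 1L &
    vapply(strsplit(vs$sites$alt, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1L), logical(1))
}

n_alleles <- function(vs) {
  1L + lengths(strsplit(vs$sites$alt, ",", fixed = TRUE))
}

#' Read a VCF file into a variant set
#'
#' Thin wrapper over \code{vcfR}: records are kept in file order, the GATK
#' site annotations (QD, MQ, MQRankSum, ReadPosRankSum, DP) are pulled from
#' INFO (absent keys stay \code{NA}), genotypes are parsed with phasing
#' ignored and \code{./.} as missing.
#'
#' @param path a VCF v4.x file (plain or gzipped)
#' @return a \code{\link{variant_set}}
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                  paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                  fix[, "ID"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                      stringsAsFactors = FALSE)
  for (k in c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "DP"))
    sites[[k]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = k)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt))
    stop_param("VCF has no genotype (GT) data")
  dp <- NULL
  if (any(grepl("DP", v@gt[1, "FORMAT"], fixed = TRUE)))
    dp <- suppressWarnings(
      matrix(as.integer(vcfR::extract.gt(v, element = "DP")),
             nrow = nrow(gt), dimnames = dimnames(gt)))
  variant_set(sites, gt, dp, colnames(gt))
}

#' Write a variant set as a plain-text VCF v4.2 file
#'
#' @param vs a \code{\link{variant_set}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_vcf <- function(vs, path) {
  info_keys <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "DP")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   info_keys, info_keys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vs$samples), collapse = "\t"))
  s <- vs$sites
  info <- vapply(seq_len(nrow(s)), function(i) {
    vals <- unlist(s[i, info_keys])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(paste0(info_keys[keep], "=",
                 format(vals[keep], trim = TRUE, digits = 6)), collapse = ";")
  }, character(1))
  gt <- vs$gt
  gt[is.na(gt)] <- "./."
  has_dp <- !is.null(vs$dp)
  fmt <- if (has_dp) "GT:DP" else "GT"
  samp_cols <- if (has_dp) {
    dp <- vs$dp
    dp_chr <- ifelse(is.na(dp), ".", as.character(dp))
    matrix(paste(gt, dp_chr, sep = ":"), nrow = nrow(gt))
  } else gt
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i], s$id[i], s$ref[i], s$alt[i],
            ifelse(is.na(s$qual[i]), ".",
                   format(s$qual[i], trim = TRUE, digits = 8)),
            "PASS", info[i], fmt, samp_cols[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# extract per-site allele-index matrices (a1, a2) from GT strings
gt_allele_idx <- function(vs) {
  a1 <- suppressWarnings(matrix(as.integer(substr(vs$gt, 1, 1)),
                                nrow = nrow(vs$gt)))
  a2 <- suppressWarnings(matrix(as.integer(substr(vs$gt, 3, 3)),
                                nrow = nrow(vs$gt)))
  list(a1 = a1, a2 = a2)
}

#' Convert biallelic SNP records to a genotype matrix
#'
#' @param vs a \code{\link{variant_set}} of biallelic SNPs
#' @return a \code{\link{genotype_matrix}} (samples x sites)
#' @export
variant_set_to_genotypes <- function(vs) {
  if (!all(is_snp(vs)) || !all(n_alleles(vs) == 2L))
    stop_param("all records must be biallelic SNPs")
  idx <- gt_allele_idx(vs)
  alleles <- cbind(vs$sites$ref, vs$sites$alt)
  n_site <- nrow(vs$sites)
  calls <- matrix(NA_character_, length(vs$samples), n_site,
                  dimnames = list(vs$samples, vs$sites$id))
  for (i in seq_len(n_site)) {
    a1 <- idx$a1[i, ]; a2 <- idx$a2[i, ]
    ok <- !is.na(a1) & !is.na(a2)
    calls[ok, i] <- canonical_call(alleles[i, a1[ok] + 1L],
                                   alleles[i, a2[ok] + 1L])
  }
  genotype_matrix(calls, data.frame(id = vs$sites$id, chrom = vs$sites$chrom,
                                    pos = vs$sites$pos, ref = vs$sites$ref,
                                    alt = vs$sites$alt,
                                    stringsAsFactors = FALSE))
}
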