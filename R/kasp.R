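#' Universal KASP tail sequences
#'
#' The two universal 5' tails prepended to the allele-specific primers: the
#' FAM-labelled tail to the primer carrying the first allele, the HEX tail
#' to the second. Tails are identical across assays and are excluded from
#' GC and Tm calculations.
#' @export
KASP_FAM_TAIL <- "GAAGGTGACCAAGTTCATGCT"

#' @rdname KASP_FAM_TAIL
#' @export
KASP_HEX_TAIL <- "GAAGGTCGGAGTCAACGGATT"

#' Reaction conditions for the nearest-neighbor melting-temperature model
#'
#' Declared constants: monovalent cation concentration and total primer
#' concentration used in the Tm calculation. Centralized so the
#' thermodynamic assumptions are auditable and changeable in one place.
#' @export
kasp_tm_conditions <- function() {
  list(Na_mM = 50, primer_nM = 200)
}

#' GC fraction of a primer sequence
#' @param seq primer sequence over A/C/G/T (vectorized)
#' @return GC fraction in [0, 1]
#' @export
primer_gc <- function(seq) {
  check_acgt(seq)
  vapply(strsplit(toupper(seq), "", fixed = TRUE), function(b)
    mean(b %in% c("G", "C")), numeric(1))
}

check_acgt <- function(seq) {
  if (any(grepl("[^ACGTacgt]", seq)))
    stop_param("sequence contains non-ACGT (ambiguous?) bases")
  if (any(nchar(seq) < 8L))
    stop_param("primer sequences must be at least 8 bases")
  invisible(TRUE)
}

# SantaLucia (1998) unified nearest-neighbor parameters:
# dH in kcal/mol, dS in cal/(mol K), keyed by the top-strand dinucleotide
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

#' Nearest-neighbor primer melting temperature
#'
#' Two-state nearest-neighbor model with the unified duplex parameter set,
#' terminal A/T and G/C initiation corrections, an entropic salt correction
#' proportional to ln[Na+], and the standard non-self-complementary factor
#' CT/4 at the declared primer concentration
#' (see \code{\link{kasp_tm_conditions}}).
#'
#' @param seq primer sequence over A/C/G/T, length >= 8 (vectorized)
#' @param conditions list with \code{Na_mM} and \code{primer_nM}
#' @return melting temperature in degrees Celsius
#' @export
primer_tm <- function(seq, conditions = kasp_tm_conditions()) {
  check_acgt(seq)
  vapply(toupper(seq), function(s) {
    n <- nchar(s)
    nn <- substring(s, 1:(n - 1), 2:n)
    dH <- sum(NN_DH[nn])
    dS <- sum(NN_DS[nn])
    for (end in c(substr(s, 1, 1), substr(s, n, n))) {
      if (end %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
      else { dH <- dH + 2.3; dS <- dS + 4.1 }
    }
    dS <- dS + 0.368 * (n - 1) * log(conditions$Na_mM / 1000)
    ct <- conditions$primer_nM * 1e-9
    dH * 1000 / (dS + 1.987 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Design a KASP assay for one SNP template
#'
#' Designs the primer triple of a KASP assay: two allele-specific primers
#' whose 3'-terminal base is the respective allele (FAM tail on the first,
#' HEX on the second) and one common primer on the opposite strand
#' downstream. Allele-specific candidates of length 18--30 ending exactly at
#' the SNP are combined with common-primer windows such that the product does
#' not exceed \code{max_product} bp; the first triple -- by smallest product,
#' then longest primers -- whose gene-specific portions all satisfy
#' GC < \code{gc_max} and Tm within \code{tm_range} is returned. The forward
#' strand is tried first; if no forward triple passes, the design is repeated
#' on the reverse complement. On failure, the report counts which constraint
#' excluded the candidates.
#'
#' @param template list with \code{seq}, \code{snp_pos}, \code{ref},
#'   \code{alt} (as from \code{\link{simulate_flank_template}})
#' @param max_product maximum amplicon size in bp
#' @param gc_max maximum GC fraction (exclusive) per primer
#' @param tm_range inclusive Tm window in degrees Celsius
#' @param primer_len range of candidate primer lengths
#' @param marker_id optional marker name carried into the result
#' @return on success, a list of class \code{kasp_assay} with the tailed
#'   allele-specific primers, the common primer, product size and per-primer
#'   GC/Tm; on failure, a list of class \code{kasp_failure} with constraint
#'   exclusion counts and the binding constraint
#' @export
design_assay <- function(template, max_product = 120L, gc_max = 0.60,
                         tm_range = c(55, 62), primer_len = c(18L, 30L),
                         marker_id = "marker") {
  seq <- toupper(template$seq)
  c0 <- template$snp_pos
  if (c0 - 1L < 40L || nchar(seq) - c0 < 40L)
    stop_param("template must extend >= 40 bp on each side of the SNP")

  res <- design_on_strand(seq, c0, template$ref, template$alt, max_product,
                          gc_max, tm_range, primer_len)
  strand <- "forward"
  if (is.null(res$assay)) {
    rc_seq <- revcomp(seq)
    rc_pos <- nchar(seq) - c0 + 1L
    comp <- function(b) chartr("ACGT", "TGCA", b)
    res2 <- design_on_strand(rc_seq, rc_pos, comp(template$ref),
                             comp(template$alt), max_product, gc_max,
                             tm_range, primer_len)
    if (!is.null(res2$assay)) { res <- res2; strand <- "reverse" }
    else {
      excl <- res$excluded + res2$excluded
      binding <- if (sum(excl) == 0) "product_size"
                 else names(excl)[which.max(excl)]
      return(structure(list(marker = marker_id, excluded = excl,
                            reason = binding), class = "kasp_failure"))
    }
  }
  a <- res$assay
  structure(list(marker = marker_id, strand = strand,
                 fam_primer = paste0(KASP_FAM_TAIL, a$as1),
                 hex_primer = paste0(KASP_HEX_TAIL, a$as2),
                 fam_allele = a$allele1, hex_allele = a$allele2,
                 common_primer = a$common, product_size = a$product,
                 gc = c(fam = primer_gc(a$as1), hex = primer_gc(a$as2),
                        common = primer_gc(a$common)),
                 tm = c(fam = primer_tm(a$as1), hex = primer_tm(a$as2),
                        common = primer_tm(a$common))),
            class = "kasp_assay")
}

design_on_strand <- function(seq, c0, ref, alt, max_product, gc_max,
                             tm_range, primer_len) {
  n <- nchar(seq)
  lens <- seq(primer_len[1], primer_len[2])
  excluded <- c(gc = 0L, tm = 0L)
  # enumerate (as_len, common start p1, common len), ordered by product asc,
  # then total primer length desc
  cand <- expand.grid(as_len = lens, p1 = (c0 + 1L):min(n, c0 + max_product),
                      com_len = lens)
  cand$p2 <- cand$p1 + cand$com_len - 1L
  cand$s <- c0 - cand$as_len + 1L
  cand$product <- cand$p2 - cand$s + 1L
  cand <- cand[cand$p2 <= n & cand$product <= max_product & cand$s >= 1L, ]
  if (nrow(cand) == 0L)
    return(list(assay = NULL, excluded = excluded))
  cand <- cand[order(cand$product, -(cand$as_len + cand$com_len)), ]
  for (i in seq_len(nrow(cand))) {
    as_len <- cand$as_len[i]; p1 <- cand$p1[i]; p2 <- cand$p2[i]
    stem <- substr(seq, cand$s[i], c0 - 1L)
    as1 <- paste0(stem, ref)
    as2 <- paste0(stem, alt)
    common <- revcomp(substr(seq, p1, p2))
    gcs <- primer_gc(c(as1, as2, common))
    if (any(gcs >= gc_max)) { excluded["gc"] <- excluded["gc"] + 1L; next }
    tms <- primer_tm(c(as1, as2, common))
    if (any(tms < tm_range[1] | tms > tm_range[2])) {
      excluded["tm"] <- excluded["tm"] + 1L; next
    }
    return(list(assay = list(as1 = as1, as2 = as2, allele1 = ref,
                             allele2 = alt, common = common,
                             product = cand$product[i]),
                excluded = excluded))
  }
  list(assay = NULL, excluded = excluded)
}

#' @export
print.kasp_assay <- function(x, ...) {
  cat(sprintf("KASP assay %s (%s strand), product %d bp\n", x$marker,
              x$strand, x$product_size))
  cat(sprintf("  FAM (%s): %s\n", x$fam_allele, x$fam_primer))
  cat(sprintf("  HEX (%s): %s\n", x$hex_allele, x$hex_primer))
  cat(sprintf("  common  : %s\n", x$common_primer))
  cat(sprintf("  Tm %.1f/%.1f/%.1f C, GC %.2f/%.2f/%.2f\n",
              x$tm[1], x$tm[2], x$tm[3], x$gc[1], x$gc[2], x$gc[3]))
  invisible(x)
}

#' Marker- and sample-level genotyping QC
#'
#' Classifies each marker as retained or dropped for a high missing rate
#' (over all samples), monomorphism (a single genotype class among
#' non-missing calls), or both; samples whose own missing rate exceeds
#' \code{sample_threshold} are flagged for exclusion first, mirroring the QC
#' funnel applied to KASP plate results.
#'
#' @param x a \code{\link{genotype_matrix}}
#' @param missing_threshold per-marker missing-rate cutoff (drop when
#'   strictly above)
#' @param sample_threshold per-sample missing-rate cutoff
#' @return list of class \code{marker_qc}: \code{markers} data.frame
#'   (id, missing_rate, n_classes, verdict), \code{dropped_samples},
#'   \code{retained} marker IDs
#' @export
marker_qc <- function(x, missing_threshold = 0.20, sample_threshold = 0.50) {
  if (nrow(x$calls) == 0L || ncol(x$calls) == 0L)
    stop_param("empty genotype matrix")
  sample_miss <- rowMeans(is.na(x$calls))
  dropped_samples <- rownames(x$calls)[sample_miss > sample_threshold]
  keep <- !(rownames(x$calls) %in% dropped_samples)
  calls <- x$calls[keep, , drop = FALSE]

  miss <- colMeans(is.na(calls))
  n_classes <- apply(calls, 2L, function(cj) length(unique(cj[!is.na(cj)])))
  high_miss <- miss > missing_threshold
  mono <- n_classes <= 1L
  verdict <- ifelse(high_miss & mono, "drop_both",
                    ifelse(high_miss, "drop_missing",
                           ifelse(mono, "drop_monomorphic", "retain")))
  df <- data.frame(id = x$markers$id, missing_rate = miss,
                   n_classes = n_classes, verdict = verdict,
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(markers = df, dropped_samples = dropped_samples,
                 retained = df$id[df$verdict == "retain"]),
            class = "marker_qc")
}

#' @export
print.marker_qc <- function(x, ...) {
  cat(sprintf("marker QC: %d retained / %d markers; %d sample(s) dropped\n",
              length(x$retained), nrow(x$markers), length(x$dropped_samples)))
  print(table(x$markers$verdict))
  invisible(x)
}
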