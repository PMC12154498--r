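#' Filter thresholds for candidate-SNP screening
#'
#' Collects every tunable of the screening funnel with the defaults of the
#' GATK/vcftools recipe the pipeline mirrors: GATK hard filters
#' (QD < 2.0, MQ < 40.0, MQRankSum < -12.5, ReadPosRankSum < -8.0 fail),
#' vcftools-style site filters (mac >= 3, maf >= 0.05, exactly 2 alleles,
#' mean depth >= 4, QUAL >= 30, non-missing fraction >= 0.5), flank
#' isolation at 100 bp (200 bp available by configuration) and a
#' mid-frequency window of [0.30, 0.70] on the alternate-allele frequency.
#'
#' @param qd_min,mq_min,mqranksum_min,readpos_min GATK hard-filter bounds
#' @param mac_min minimum minor-allele count
#' @param maf_min minimum minor-allele frequency over non-missing calls
#' @param alleles_exact required allele count (biallelic = 2)
#' @param mean_dp_min minimum mean per-sample depth
#' @param qual_min minimum site QUAL
#' @param max_missing minimum fraction of non-missing genotypes
#'   (vcftools \code{--max-missing} semantics, boundary inclusive)
#' @param flank_bp isolation radius: a kept site has no other variant within
#'   this many bp
#' @param freq_window inclusive alternate-allele frequency window
#' @return a list of class \code{filter_thresholds}
#' @export
filter_thresholds <- function(qd_min = 2.0, mq_min = 40.0,
                              mqranksum_min = -12.5, readpos_min = -8.0,
                              mac_min = 3L, maf_min = 0.05,
                              alleles_exact = 2L, mean_dp_min = 4,
                              qual_min = 30, max_missing = 0.5,
                              flank_bp = 100L, freq_window = c(0.30, 0.70)) {
  if (max_missing < 0 || max_missing > 1)
    stop_param("max_missing must lie in [0, 1]")
  if (flank_bp < 0) stop_param("flank_bp must be >= 0")
  if (freq_window[1] < 0 || freq_window[2] > 1 ||
      freq_window[1] >= freq_window[2])
    stop_param("freq_window must be an interval within [0, 1]")
  structure(list(qd_min = qd_min, mq_min = mq_min,
                 mqranksum_min = mqranksum_min, readpos_min = readpos_min,
                 mac_min = mac_min, maf_min = maf_min,
                 alleles_exact = alleles_exact, mean_dp_min = mean_dp_min,
                 qual_min = qual_min, max_missing = max_missing,
                 flank_bp = as.integer(flank_bp), freq_window = freq_window),
            class = "filter_thresholds")
}

#' GATK-style hard filtering on site annotations
#'
#' A site fails iff any \emph{present} annotation violates its threshold
#' (strict inequality, e.g. QD exactly 2.0 passes). An absent annotation
#' never fails its clause.
#'
#' @param vs a \code{\link{variant_set}} of SNP records
#' @param t a \code{\link{filter_thresholds}}
#' @return data.frame with columns \code{pass} (logical) and \code{reason}
#'   (failing annotation names, "" when passing)
#' @export
hard_filter <- function(vs, t = filter_thresholds()) {
  if (!all(is_snp(vs)))
    stop_param("hard_filter expects SNP records only")
  s <- vs$sites
  clauses <- cbind(QD = !is.na(s$QD) & s$QD < t$qd_min,
                   MQ = !is.na(s$MQ) & s$MQ < t$mq_min,
                   MQRankSum = !is.na(s$MQRankSum) &
                     s$MQRankSum < t$mqranksum_min,
                   ReadPosRankSum = !is.na(s$ReadPosRankSum) &
                     s$ReadPosRankSum < t$readpos_min)
  reason <- apply(clauses, 1L, function(r)
    paste(colnames(clauses)[r], collapse = ","))
  data.frame(pass = !apply(clauses, 1L, any), reason = reason,
             stringsAsFactors = FALSE)
}

# per-site genotype-derived quantities for biallelic SNPs
site_geno_stats <- function(vs) {
  idx <- gt_allele_idx(vs)
  nonmiss <- !is.na(idx$a1) & !is.na(idx$a2)
  n_nm <- rowSums(nonmiss)
  alt_count <- rowSums((idx$a1 == 1L) + (idx$a2 == 1L), na.rm = TRUE)
  total <- 2L * n_nm
  alt_freq <- ifelse(total > 0, alt_count / total, NA_real_)
  mac <- pmin(alt_count, total - alt_count)
  mean_dp <- if (!is.null(vs$dp)) rowMeans(vs$dp, na.rm = TRUE)
             else vs$sites$DP / length(vs$samples)
  data.frame(n_nonmissing = n_nm,
             nonmiss_frac = n_nm / length(vs$samples),
             alt_freq = alt_freq, mac = mac,
             maf = pmin(alt_freq, 1 - alt_freq), mean_dp = mean_dp)
}

#' vcftools-style site filtering on genotypes and quality
#'
#' A site passes iff it is biallelic, minor-allele count and frequency meet
#' their minima (over non-missing calls), mean per-sample depth and QUAL meet
#' their minima, and the non-missing genotype fraction is at least
#' \code{max_missing} (boundary inclusive, matching vcftools
#' \code{--max-missing}).
#'
#' @inheritParams hard_filter
#' @return data.frame with \code{pass} and \code{reason} columns
#' @export
site_filter <- function(vs, t = filter_thresholds()) {
  if (!all(is_snp(vs)))
    stop_param("site_filter expects SNP records only")
  g <- site_geno_stats(vs)
  s <- vs$sites
  all_missing <- g$n_nonmissing == 0L
  clauses <- cbind(
    `all-missing` = all_missing,
    alleles = n_alleles(vs) != t$alleles_exact,
    mac = !all_missing & g$mac < t$mac_min,
    maf = !all_missing & g$maf < t$maf_min,
    meanDP = !is.na(g$mean_dp) & g$mean_dp < t$mean_dp_min,
    qual = !is.na(s$qual) & s$qual < t$qual_min,
    missing = g$nonmiss_frac < t$max_missing)
  reason <- apply(clauses, 1L, function(r)
    paste(colnames(clauses)[r], collapse = ","))
  data.frame(pass = !apply(clauses, 1L, any), reason = reason,
             stringsAsFactors = FALSE)
}

#' Flank isolation: drop sites with any neighbouring variant
#'
#' Keeps a site iff no other variant (of any type) lies on the same
#' chromosome within \code{flank_bp} of it; the relation is symmetric, so
#' clustered sites remove each other. Keeping requires a distance strictly
#' greater than \code{flank_bp}: a clean primer-binding window must be
#' devoid of any other variant.
#'
#' @param vs a \code{\link{variant_set}} sorted by (chrom, pos)
#' @param flank_bp isolation radius in bp
#' @param against optional \code{\link{variant_set}} of neighbours to test
#'   against (defaults to \code{vs} itself); used to test candidate SNPs
#'   against the full variant set including non-SNPs
#' @return logical vector: TRUE for isolated (kept) sites
#' @export
flank_isolation <- function(vs, flank_bp = 100L, against = vs) {
  s <- vs$sites
  if (is.unsorted(order(s$chrom, s$pos)) ||
      any(diff(order(order(s$chrom, s$pos))) < 0))
    stop_param("records must be sorted by (chrom, pos)")
  a <- against$sites
  keep <- logical(nrow(s))
  for (ch in unique(s$chrom)) {
    si <- which(s$chrom == ch)
    ai <- which(a$chrom == ch)
    pos_s <- s$pos[si]
    pos_a <- a$pos[ai]
    for (u in seq_along(si)) {
      d <- abs(pos_a - pos_s[u])
      # a site is not its own neighbour: ignore zero distance at same id once
      same <- which(d == 0L & a$id[ai] == s$id[si[u]])
      if (length(same)) d <- d[-same[1L]]
      keep[si[u]] <- !any(d <= flank_bp)
    }
  }
  keep
}

#' Mid-frequency window filter
#'
#' Keeps biallelic SNPs whose alternate-allele frequency over non-missing
#' calls lies in the window, boundaries inclusive. The published window of
#' "minor allele frequencies 30--70\%" can only describe the alternate (or
#' major) allele frequency, since a minor frequency cannot exceed 0.5; the
#' filter therefore acts on alternate-allele frequency.
#'
#' @param vs a \code{\link{variant_set}} of biallelic SNPs
#' @param window inclusive frequency interval
#' @return logical keep vector
#' @export
frequency_window <- function(vs, window = c(0.30, 0.70)) {
  g <- site_geno_stats(vs)
  !is.na(g$alt_freq) & g$alt_freq >= window[1] & g$alt_freq <= window[2]
}

#' Even genome-wide selection of a target number of candidates
#'
#' Per-chromosome quotas by largest-remainder apportionment of
#' \code{n_target} proportional to candidate counts (minimum one where
#' candidates exist); within a chromosome, greedy farthest-point selection
#' on position, maximizing the minimum pairwise distance, ties broken
#' toward the lower position. Deterministic.
#'
#' @param vs a \code{\link{variant_set}} of candidates
#' @param n_target number of sites to select
#' @return logical keep vector over the rows of \code{vs}
#' @export
distribute_evenly <- function(vs, n_target) {
  s <- vs$sites
  n <- nrow(s)
  if (n_target > n) stop_param("n_target (%d) exceeds candidates (%d)",
                               n_target, n)
  counts <- table(s$chrom)
  chroms <- names(counts)
  quota <- largest_remainder_quota(as.integer(counts), n_target)
  keep <- logical(n)
  for (ci in seq_along(chroms)) {
    idx <- which(s$chrom == chroms[ci])
    idx <- idx[order(s$pos[idx])]
    sel <- farthest_point_select(s$pos[idx], quota[ci])
    keep[idx[sel]] <- TRUE
  }
  keep
}

# largest-remainder apportionment with a minimum of 1 per non-empty stratum
largest_remainder_quota <- function(counts, n_target) {
  k <- length(counts)
  exact <- n_target * counts / sum(counts)
  q <- floor(exact)
  q[counts > 0 & q == 0L] <- 1L
  q <- pmin(q, counts)
  rem <- n_target - sum(q)
  while (rem > 0L) {
    frac <- exact - q
    frac[q >= counts] <- -Inf
    j <- which.max(frac)
    q[j] <- q[j] + 1L
    rem <- rem - 1L
  }
  while (rem < 0L) {
    frac <- exact - q
    frac[q <= 1L & counts > 0L] <- Inf  # keep the minimum-1 guarantee if we can
    j <- which.min(frac)
    if (!is.finite(frac[j])) j <- which.max(q)
    q[j] <- q[j] - 1L
    rem <- rem + 1L
  }
  q
}

# greedy farthest-point selection on sorted positions; returns indices
farthest_point_select <- function(pos, k) {
  n <- length(pos)
  if (k <= 0L) return(integer(0))
  if (k >= n) return(seq_len(n))
  if (k == 1L) {
    # single pick: the candidate closest to the span midpoint, lower on ties
    mid <- (min(pos) + max(pos)) / 2
    return(which.min(abs(pos - mid) * 2 + (pos > mid) * 1e-9))
  }
  chosen <- c(which.min(pos), which.max(pos))
  while (length(chosen) < k) {
    rest <- setdiff(seq_len(n), chosen)
    mind <- vapply(rest, function(i) min(abs(pos[i] - pos[chosen])),
                   numeric(1))
    best <- rest[mind == max(mind)]
    chosen <- c(chosen, best[which.min(pos[best])])
  }
  sort(chosen)
}

#' Classify a biallelic substitution into one of the 12 ordered categories
#'
#' @param ref,alt single distinct bases (vectorized)
#' @return character vector of labels like \code{"A/G"}; exactly 12 labels
#'   are possible (4 bases x 3 alternates)
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop_param("ref and alt must be single bases")
  if (any(ref == alt)) stop_param("ref and alt must differ")
  if (!all(c(ref, alt) %in% DNA_BASES)) stop_param("bases must be A/C/G/T")
  paste0(ref, "/", alt)
}

#' Census of variant types over a set of sites
#'
#' @param ref,alt base vectors
#' @return data.frame with columns type, count, proportion covering all 12
#'   possible ordered categories (zero counts included)
#' @export
variant_type_census <- function(ref, alt) {
  labels <- classify_variant_type(ref, alt)
  pairs <- ordered_base_pairs()
  all_types <- paste0(pairs$ref, "/", pairs$alt)
  counts <- table(factor(labels, levels = all_types))
  data.frame(type = all_types, count = as.integer(counts),
             proportion = as.numeric(counts) / length(labels),
             stringsAsFactors = FALSE)
}

#' Run the full candidate-SNP screening funnel
#'
#' Applies, in order: restriction to SNPs, hard filtering, site filtering,
#' flank isolation (against the \emph{full} input variant set, so non-SNP
#' variants also disqualify neighbours), the mid-frequency window, and even
#' genome-wide selection down to \code{n_target} (skipped when
#' \code{n_target} is NULL or exceeds the surviving pool).
#'
#' @param vs input \code{\link{variant_set}} (any variant types)
#' @param t a \code{\link{filter_thresholds}}
#' @param n_target final number of candidates, or NULL to keep all survivors
#' @return list of class \code{screen_report}: \code{kept} (the surviving
#'   \code{variant_set}), \code{counts} (named funnel counts, non-increasing),
#'   \code{reasons} (per-stage removal reasons), \code{census}
#'   (variant-type census of the final set)
#' @export
screen_snps <- function(vs, t = filter_thresholds(), n_target = NULL) {
  counts <- c(input = length(vs))
  reasons <- list()

  snp <- is_snp(vs)
  cur <- vs[which(snp)]
  counts["snp"] <- length(cur)

  hf <- hard_filter(cur, t)
  reasons$hard_filter <- table(hf$reason[!hf$pass])
  cur <- cur[which(hf$pass)]
  counts["hard_filter"] <- length(cur)

  # site filter requires biallelic accounting; non-biallelic fail inside it
  sf <- site_filter(cur, t)
  reasons$site_filter <- table(sf$reason[!sf$pass])
  cur <- cur[which(sf$pass)]
  counts["site_filter"] <- length(cur)

  ord <- order(cur$sites$chrom, cur$sites$pos)
  cur <- cur[ord]
  iso <- flank_isolation(cur, t$flank_bp, against = vs_sorted(vs))
  cur <- cur[which(iso)]
  counts["flank_isolation"] <- length(cur)

  fw <- frequency_window(cur, t$freq_window)
  cur <- cur[which(fw)]
  counts["frequency_window"] <- length(cur)

  if (!is.null(n_target) && n_target < length(cur)) {
    sel <- distribute_evenly(cur, n_target)
    cur <- cur[which(sel)]
  }
  counts["selected"] <- length(cur)

  if (any(diff(counts) > 0))
    stop("internal error: funnel counts increased")  # invariant guard

  structure(list(kept = cur, counts = counts, reasons = reasons,
                 census = if (length(cur))
                   variant_type_census(cur$sites$ref, cur$sites$alt)),
            class = "screen_report")
}

vs_sorted <- function(vs) vs[order(vs$sites$chrom, vs$sites$pos)]

#' @export
print.screen_report <- function(x, ...) {
  cat("SNP screening funnel:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write a screening report as JSON
#' @param report a \code{\link{screen_snps}} result
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_screen_report <- function(report, path) {
  jsonlite::write_json(list(counts = as.list(report$counts),
                            reasons = lapply(report$reasons, as.list),
                            census = report$census),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
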